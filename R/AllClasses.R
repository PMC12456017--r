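#' @import methods
#' @importClassesFrom Biostrings DNAStringSet
#' @importFrom Biostrings DNAStringSet DNAString readDNAStringSet
#'   readAAStringSet oligonucleotideFrequency reverseComplement translate
#'   letterFrequency writeXStringSet width
#' @importFrom stats runif setNames
#' @importFrom utils read.delim write.table
#' @useDynLib chromidFinder, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

VALID_ROLES  <- c("CHROMOSOME", "CHROMID", "OTHER", "UNASSIGNED")
MARKER_CATEGORIES <- c("REP", "PAR", "CORE", "DNAA")

#' A set of replicons from one assembly (or a pooled collection)
#'
#' `RepliconSet` holds the nucleotide sequences of one bacterial assembly —
#' or of a pool of independent sequences, as used for MAG screening — as a
#' [Biostrings::DNAStringSet] whose names are the replicon identifiers.
#' Sequences are normalized on construction: lowercase is uppercased and any
#' IUPAC ambiguity code other than N becomes N, keeping the k-mer alphabet
#' at four letters.
#'
#' @slot sequences A [Biostrings::DNAStringSet]; names are unique replicon ids.
#' @slot assemblyId Single string naming the assembly (or pool).
#' @slot source Character vector, one entry per replicon, recording the
#'   genome/sample of origin (may be `NA`).
#'
#' @seealso [RepliconSet()], [readFasta()], [gcContent()]
#' @export
setClass("RepliconSet",
  representation(
    sequences  = "DNAStringSet",
    assemblyId = "character",
    source     = "character"
  )
)

setValidity("RepliconSet", function(object) {
  ids <- names(object@sequences)
  if (is.null(ids) || any(is.na(ids)) || any(!nzchar(ids)))
    return("all replicons must be named")
  if (anyDuplicated(ids))
    return(sprintf("duplicate replicon id(s): %s",
                   paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (length(object@assemblyId) != 1L || is.na(object@assemblyId))
    return("assemblyId must be a single string")
  if (length(object@source) != length(object@sequences))
    return("source must have one entry per replicon")
  TRUE
})

#' Strand-symmetrized k-mer relative-abundance signature
#'
#' The genomic signature of a sequence: for every word w = x1..xk the ratio
#' of the observed (strand-symmetrized) word frequency to the product of its
#' mononucleotide frequencies. Words whose mononucleotide product is zero
#' get value 0 and are excluded from `nInformative`.
#'
#' @slot k Word size (2 for dinucleotide, 4 for tetranucleotide signatures).
#' @slot values Named numeric vector of length 4^k in lexicographic word
#'   order; all finite and non-negative.
#' @slot nInformative Number of words with a non-zero mononucleotide product.
#'
#' @seealso [relativeAbundance()], [signatureDistance()]
#' @export
setClass("CompositionSignature",
  representation(
    k            = "integer",
    values       = "numeric",
    nInformative = "integer"
  )
)

setValidity("CompositionSignature", function(object) {
  if (length(object@k) != 1L || !object@k %in% c(1L, 2L, 4L))
    return("k must be 1, 2 or 4")
  if (length(object@values) != 4L^object@k)
    return(sprintf("values must have 4^k = %d entries", 4L^object@k))
  if (any(!is.finite(object@values)) || any(object@values < 0))
    return("signature values must be finite and non-negative")
  if (object@nInformative < 0L || object@nInformative > length(object@values))
    return("nInformative out of range")
  TRUE
})

#' Decision thresholds for chromid classification
#'
#' Bundles every tunable cutoff of the two decision procedures. GC deltas
#' are absolute percentage points; the signature-distance cutoffs are read
#' on the configured `scale` (the distance is the mean absolute difference
#' between relative-abundance vectors multiplied by `scale`). The
#' tetranucleotide comparison is strict (`distance < tetraDistMax`); the
#' optional dinucleotide pre-screen is inclusive (`distance <= dinucDistMax`).
#'
#' @slot gcDeltaMax Maximum |GC difference| to the chromosome/center, in
#'   percentage points (default 1.0).
#' @slot tetraDistMax Tetranucleotide distance cutoff on the configured
#'   scale (default 1.6).
#' @slot dinucDistMax Dinucleotide pre-screen cutoff; `NA` disables the
#'   pre-screen (the default). 0.4 is the conventional value when enabled.
#' @slot markerRule `"strict"` requires Rep AND Par AND core markers;
#'   `"relaxed"` requires (Rep OR Par) AND core.
#' @slot scale Multiplier applied to the mean absolute signature difference
#'   (default 10); thresholds are interpreted on this scale and the two are
#'   always reported together in output metadata.
#'
#' @seealso [chromidThresholds()]
#' @export
setClass("ChromidThresholds",
  representation(
    gcDeltaMax   = "numeric",
    tetraDistMax = "numeric",
    dinucDistMax = "numeric",
    markerRule   = "character",
    scale        = "numeric"
  )
)

setValidity("ChromidThresholds", function(object) {
  if (length(object@gcDeltaMax) != 1L || !is.finite(object@gcDeltaMax) ||
      object@gcDeltaMax <= 0)
    return("gcDeltaMax must be a single positive number")
  if (length(object@tetraDistMax) != 1L || is.na(object@tetraDistMax) ||
      object@tetraDistMax < 0)
    return("tetraDistMax must be a single non-negative number (Inf allowed)")
  if (length(object@dinucDistMax) != 1L ||
      (!is.na(object@dinucDistMax) && object@dinucDistMax < 0))
    return("dinucDistMax must be NA (disabled) or non-negative")
  if (!identical(object@markerRule, "strict") &&
      !identical(object@markerRule, "relaxed"))
    return("markerRule must be 'strict' or 'relaxed'")
  if (length(object@scale) != 1L || !is.finite(object@scale) ||
      object@scale <= 0)
    return("scale must be a single positive number")
  TRUE
})

#' Marker database with a category manifest
#'
#' A set of marker models, each assigned to exactly one of the four
#' categories REP (plasmid replication), PAR (plasmid partitioning), CORE
#' (chromosomal core genes) or DNAA (chromosomal replication initiator and
#' homologs). Categories come from the manifest, never from marker names.
#' Two backends share this container: `"motif"` models are literal
#' amino-acid motifs matched exactly (hits report E-value 0); `"hmm"` models
#' are paths to HMMER3 profile files searched with `hmmsearch`.
#'
#' @slot backend `"motif"` or `"hmm"`.
#' @slot manifest data.frame with columns `marker_id`, `category`.
#' @slot models Named character vector (names = marker ids): motif strings
#'   or HMM file paths.
#'
#' @seealso [markerDatabase()], [readMarkerManifest()], [scanMarkers()]
#' @export
setClass("MarkerDatabase",
  representation(
    backend  = "character",
    manifest = "data.frame",
    models   = "character"
  )
)

setValidity("MarkerDatabase", function(object) {
  if (!identical(object@backend, "motif") && !identical(object@backend, "hmm"))
    return("backend must be 'motif' or 'hmm'")
  man <- object@manifest
  if (!all(c("marker_id", "category") %in% names(man)))
    return("manifest must have columns marker_id and category")
  if (nrow(man) == 0L)
    return("marker database is empty")
  if (anyDuplicated(man$marker_id))
    return("each marker must have exactly one category (duplicate marker_id)")
  if (!all(man$category %in% MARKER_CATEGORIES))
    return(sprintf("categories must be one of %s",
                   paste(MARKER_CATEGORIES, collapse = "/")))
  if (!setequal(names(object@models), man$marker_id))
    return("models and manifest must cover the same marker ids")
  TRUE
})

#' Result of a chromid classification run
#'
#' Per-replicon role calls with the evidence that forced each call, plus the
#' DnaA-centered clusters (MAG mode) and the thresholds used. `calls` has
#' one row per input replicon with columns `replicon_id`, `source`,
#' `length`, `gc_pct`, `role`, `center_id`, `delta_gc`, `tetra_dist`,
#' `n_rep`, `n_par`, `n_core`, `n_dnaa`, `evidence`.
#'
#' @slot mode `"complete_genome"` or `"mag"`.
#' @slot calls data.frame as described above.
#' @slot clusters List of clusters; each is a list with elements `center`
#'   (replicon id) and `members` (data.frame with `replicon_id`,
#'   `delta_gc`, `tetra_dist`, `passed`).
#' @slot thresholds The [ChromidThresholds-class] used.
#'
#' @seealso [runChromidFinder()], [classifyCompleteGenome()], [writeResults()]
#' @export
setClass("ChromidClassification",
  representation(
    mode       = "character",
    calls      = "data.frame",
    clusters   = "list",
    thresholds = "ChromidThresholds"
  )
)

setValidity("ChromidClassification", function(object) {
  if (!object@mode %in% c("complete_genome", "mag"))
    return("mode must be 'complete_genome' or 'mag'")
  if (nrow(object@calls) > 0 && !all(object@calls$role %in% VALID_ROLES))
    return(sprintf("roles must be one of %s", paste(VALID_ROLES, collapse = "/")))
  TRUE
})

#' Confusion matrix for the chromid-positive class
#'
#' @slot tp,fp,fn,tn Non-negative integer counts; the positive class is
#'   CHROMID, every other role (including UNASSIGNED) is a negative
#'   prediction.
#'
#' @seealso [confusionMatrix()], [chromidConfusion()], [accuracy()]
#' @export
setClass("ConfusionMatrix",
  representation(tp = "integer", fp = "integer", fn = "integer", tn = "integer")
)

setValidity("ConfusionMatrix", function(object) {
  counts <- c(object@tp, object@fp, object@fn, object@tn)
  if (length(counts) != 4L || any(is.na(counts)) || any(counts < 0L))
    return("tp, fp, fn, tn must be single non-negative integers")
  TRUE
})
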