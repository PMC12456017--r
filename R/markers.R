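# markers: gene prediction and marker detection in four categories
# (REP, PAR, CORE, DNAA) with pluggable scanner backends.

#' Construct a marker database
#'
#' @param models Named character vector (names = marker ids). For the
#'   `"motif"` backend each value is a literal amino-acid motif; for the
#'   `"hmm"` backend each value is the path to a HMMER3 profile file whose
#'   NAME matches the marker id.
#' @param categories Character vector (same order as `models`) of
#'   categories: REP, PAR, CORE or DNAA. Category identity always comes
#'   from this manifest, never from the marker name.
#' @param backend `"motif"` or `"hmm"`.
#' @return A [MarkerDatabase-class].
#' @examples
#' db <- markerDatabase(c(repA = "WQKRPLDSRE", rpoB = "DEHWKQLRTV"),
#'                      c("REP", "CORE"))
#' @export
markerDatabase <- function(models, categories, backend = c("motif", "hmm")) {
  backend <- match.arg(backend)
  new("MarkerDatabase",
      backend  = backend,
      manifest = data.frame(marker_id = names(models),
                            category = as.character(categories),
                            stringsAsFactors = FALSE),
      models   = models)
}

#' Read a marker manifest and model files
#'
#' The manifest is a TSV with columns `marker_id` and `category` (and, for
#' the motif backend, `motif`). For the HMM backend, model files named
#' `<marker_id>.hmm` are looked up under `modelDir`.
#'
#' @param manifestPath Path to the manifest TSV.
#' @param modelDir Directory holding `<marker_id>.hmm` files (hmm backend).
#' @param backend `"motif"` or `"hmm"`.
#' @return A [MarkerDatabase-class].
#' @export
readMarkerManifest <- function(manifestPath, modelDir = NULL,
                               backend = c("motif", "hmm")) {
  backend <- match.arg(backend)
  man <- utils::read.delim(manifestPath, stringsAsFactors = FALSE)
  if (backend == "motif") {
    if (!"motif" %in% names(man))
      stop("motif backend manifest needs a 'motif' column: ", manifestPath)
    models <- setNames(man$motif, man$marker_id)
  } else {
    paths <- file.path(modelDir, paste0(man$marker_id, ".hmm"))
    missing <- !file.exists(paths)
    if (any(missing))
      stop("model file(s) unreadable: ",
           paste(paths[missing], collapse = ", "))
    models <- setNames(paths, man$marker_id)
  }
  markerDatabase(models, man$category, backend = backend)
}

setMethod("show", "MarkerDatabase", function(object) {
  tab <- table(object@manifest$category)
  cat(sprintf("MarkerDatabase (%s backend): %s\n", object@backend,
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
})

emptyGeneFrame <- function() {
  data.frame(replicon_id = character(0), gene_id = character(0),
             protein = character(0), start = integer(0), end = integer(0),
             strand = character(0), length_aa = integer(0),
             stringsAsFactors = FALSE)
}

# Naive ORF finder on one strand orientation of one sequence.
# Returns, per reading frame, the longest ORF (first ATG after each stop)
# of >= minAa residues. Coordinates are 1-based inclusive on `s`.
.orfsOneStrand <- function(s, minAa) {
  n <- nchar(s)
  out <- vector("list", 3L)
  for (off in 0:2) {
    usable <- n - off
    if (usable < 3L) next
    frame <- substr(s, off + 1L, off + (usable %/% 3L) * 3L)
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(frame),
                                             if.fuzzy.codon = "X"))
    # leftmost M per stop-free segment, greedily extended to the stop:
    # the longest ORF terminating at that stop codon
    m <- gregexpr("M[^*]*\\*", aa, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    len <- attr(m, "match.length")
    keep <- len >= (minAa + 1L)   # include the stop in the match
    if (!any(keep)) next
    starts <- as.integer(m[keep])
    lens <- as.integer(len[keep])
    prot <- substring(aa, starts, starts + lens - 2L)  # strip the stop
    ntStart <- off + (starts - 1L) * 3L + 1L
    ntEnd <- ntStart + lens * 3L - 1L                  # includes stop codon
    out[[off + 1L]] <- data.frame(protein = prot, start = ntStart,
                                  end = ntEnd, length_aa = lens - 1L,
                                  stringsAsFactors = FALSE)
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

.predictGenesNaive <- function(id, seq, minAa) {
  n <- nchar(seq)
  fwd <- .orfsOneStrand(seq, minAa)
  rcs <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  rev <- .orfsOneStrand(rcs, minAa)
  if (!is.null(fwd) && nrow(fwd)) fwd$strand <- "+"
  if (!is.null(rev) && nrow(rev)) {
    # map back to forward-strand coordinates
    s0 <- rev$start
    rev$start <- n - rev$end + 1L
    rev$end <- n - s0 + 1L
    rev$strand <- "-"
  }
  genes <- rbind(fwd, rev)
  if (is.null(genes) || nrow(genes) == 0L) return(emptyGeneFrame())
  genes$replicon_id <- id
  genes$gene_id <- sprintf("%s_orf%04d", id, seq_len(nrow(genes)))
  genes[, c("replicon_id", "gene_id", "protein", "start", "end",
            "strand", "length_aa")]
}

.predictGenesProdigal <- function(id, seq, prodigalMode) {
  if (Sys.which("prodigal") == "")
    stop("prodigal not found on PATH; select backend = \"naive\" for the ",
         "built-in ORF finder")
  fa <- tempfile(fileext = ".fna")
  faa <- tempfile(fileext = ".faa")
  on.exit(unlink(c(fa, faa)), add = TRUE)
  writeLines(c(paste0(">", id), seq), fa)
  if (is.null(prodigalMode))
    prodigalMode <- if (nchar(seq) < 100000) "meta" else "single"
  status <- system2("prodigal",
                    c("-i", fa, "-a", faa, "-p", prodigalMode, "-q",
                      "-o", if (.Platform$OS.type == "unix") "/dev/null"
                            else tempfile()),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L || !file.exists(faa))
    stop("prodigal failed on replicon ", id,
         "; select backend = \"naive\" for the built-in ORF finder")
  prot <- tryCatch(Biostrings::readAAStringSet(faa),
                   error = function(e) NULL)
  if (is.null(prot) || length(prot) == 0L) return(emptyGeneFrame())
  # header: "<id>_<n> # start # end # strand # ..."
  hdr <- strsplit(names(prot), " # ", fixed = TRUE)
  genes <- data.frame(
    replicon_id = id,
    gene_id = vapply(hdr, `[`, "", 1L),
    protein = sub("\\*$", "", as.character(prot)),
    start = as.integer(vapply(hdr, `[`, "", 2L)),
    end = as.integer(vapply(hdr, `[`, "", 3L)),
    strand = ifelse(vapply(hdr, `[`, "", 4L) == "1", "+", "-"),
    stringsAsFactors = FALSE)
  genes$length_aa <- nchar(genes$protein)
  genes
}

#' Predict protein-coding genes on replicons
#'
#' Two backends share one contract: a table of translated proteins with
#' 1-based inclusive nucleotide coordinates and strand. `"prodigal"` shells
#' out to the Prodigal prokaryotic gene finder; `"naive"` is a built-in
#' dependency-free ORF finder reporting, per reading frame on both strands,
#' the longest open reading frame (first start codon after each stop) of at
#' least `minAa` residues under the standard code.
#'
#' @param x A [RepliconSet-class].
#' @param backend `"naive"` or `"prodigal"`.
#' @param minAa Minimum protein length for the naive backend (default 30).
#' @param prodigalMode `"meta"` or `"single"`; default picks `"meta"` for
#'   sequences under 100 kb.
#' @return data.frame with columns `replicon_id`, `gene_id`, `protein`,
#'   `start`, `end`, `strand`, `length_aa`.
#' @export
predictGenes <- function(x, backend = c("naive", "prodigal"), minAa = 30L,
                         prodigalMode = NULL) {
  backend <- match.arg(backend)
  seqs <- repliconSequences(x)
  out <- lapply(names(seqs), function(id) {
    if (backend == "naive") .predictGenesNaive(id, seqs[[id]], minAa)
    else .predictGenesProdigal(id, seqs[[id]], prodigalMode)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- emptyGeneFrame()
  rownames(out) <- NULL
  out
}

emptyHitFrame <- function() {
  data.frame(replicon_id = character(0), gene_id = character(0),
             marker_id = character(0), category = character(0),
             score = numeric(0), e_value = numeric(0),
             stringsAsFactors = FALSE)
}

.scanMotif <- function(genes, db) {
  hits <- lapply(seq_len(nrow(db@manifest)), function(i) {
    marker <- db@manifest$marker_id[i]
    hit <- grepl(db@models[[marker]], genes$protein, fixed = TRUE)
    if (!any(hit)) return(NULL)
    data.frame(replicon_id = genes$replicon_id[hit],
               gene_id = genes$gene_id[hit],
               marker_id = marker,
               category = db@manifest$category[i],
               score = nchar(db@models[[marker]]),
               e_value = 0,
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits[!vapply(hits, is.null, logical(1))])
  if (is.null(hits)) emptyHitFrame() else hits
}

.scanHmm <- function(genes, db, eThreshold) {
  if (Sys.which("hmmsearch") == "")
    stop("hmmsearch not found on PATH; the hmm backend needs HMMER")
  missing <- !file.exists(db@models)
  if (any(missing))
    stop("model file(s) unreadable: ",
         paste(db@models[missing], collapse = ", "))
  faa <- tempfile(fileext = ".faa")
  hmmfile <- tempfile(fileext = ".hmm")
  tbl <- tempfile(fileext = ".tbl")
  on.exit(unlink(c(faa, hmmfile, tbl)), add = TRUE)
  writeLines(paste0(">", genes$gene_id, "\n", genes$protein), faa)
  # concatenate all profiles into one database file
  file.create(hmmfile)
  for (p in db@models) file.append(hmmfile, p)
  status <- system2("hmmsearch",
                    c("--tblout", tbl, "--noali", "-E",
                      format(eThreshold, scientific = TRUE), hmmfile, faa),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop("hmmsearch failed")
  lines <- readLines(tbl)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0L) return(emptyHitFrame())
  fields <- strsplit(trimws(lines), "\\s+")
  geneIdx <- match(vapply(fields, `[`, "", 1L), genes$gene_id)
  marker <- vapply(fields, `[`, "", 3L)
  catIdx <- match(marker, db@manifest$marker_id)
  hits <- data.frame(
    replicon_id = genes$replicon_id[geneIdx],
    gene_id = genes$gene_id[geneIdx],
    marker_id = marker,
    category = db@manifest$category[catIdx],
    score = as.numeric(vapply(fields, `[`, "", 6L)),
    e_value = as.numeric(vapply(fields, `[`, "", 5L)),
    stringsAsFactors = FALSE)
  hits[!is.na(hits$category) & hits$e_value <= eThreshold, , drop = FALSE]
}

#' Scan predicted proteins against a marker database
#'
#' Reports one hit per (protein, marker) pair passing the E-value
#' threshold. The `"motif"` backend declares a hit when the marker's
#' literal amino-acid motif is a substring of the protein (E-value reported
#' as 0); the `"hmm"` backend runs HMMER's `hmmsearch` over the
#' concatenated profile files. Scanning is deterministic for a fixed
#' backend, database and threshold.
#'
#' @param genes Gene table from [predictGenes()].
#' @param db A [MarkerDatabase-class].
#' @param eThreshold Full-sequence E-value cutoff (default 1e-5,
#'   conventional hmmsearch practice; ignored by the motif backend whose
#'   hits are exact).
#' @return data.frame with columns `replicon_id`, `gene_id`, `marker_id`,
#'   `category`, `score`, `e_value`.
#' @export
scanMarkers <- function(genes, db, eThreshold = 1e-5) {
  stopifnot(is(db, "MarkerDatabase"))
  if (nrow(genes) == 0L) return(emptyHitFrame())
  hits <- if (db@backend == "motif") .scanMotif(genes, db)
          else .scanHmm(genes, db, eThreshold)
  rownames(hits) <- NULL
  hits
}

#' Per-replicon marker profiles
#'
#' Collapses marker hits to per-replicon, per-category counts of distinct
#' markers: several hits to the same marker on one replicon count once,
#' since the screening rules are presence/absence rules. DnaA models count
#' only toward `n_dnaa`, never toward `n_core`.
#'
#' @param hits Hit table from [scanMarkers()].
#' @param repliconIds Ids to profile; replicons without hits get all-zero
#'   rows. If `NULL`, only replicons present in `hits` are profiled.
#' @return data.frame with columns `replicon_id`, `n_rep`, `n_par`,
#'   `n_core`, `n_dnaa`, `has_dnaa`.
#' @export
profileReplicons <- function(hits, repliconIds = NULL) {
  if (is.null(repliconIds)) repliconIds <- unique(hits$replicon_id)
  foreign <- setdiff(unique(hits$replicon_id), repliconIds)
  if (length(foreign))
    stop("hits reference replicon id(s) not being profiled: ",
         paste(foreign, collapse = ", "))
  countCat <- function(cat) {
    sub <- hits[hits$category == cat, c("replicon_id", "marker_id")]
    sub <- unique(sub)
    tab <- table(factor(sub$replicon_id, levels = repliconIds))
    as.integer(tab)
  }
  out <- data.frame(
    replicon_id = repliconIds,
    n_rep  = countCat("REP"),
    n_par  = countCat("PAR"),
    n_core = countCat("CORE"),
    n_dnaa = countCat("DNAA"),
    stringsAsFactors = FALSE)
  out$has_dnaa <- out$n_dnaa > 0L
  out
}
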