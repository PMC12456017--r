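# synthetic: seeded generator of multipartite genomes with ground truth.
# The chromosome and its chromids are drawn from the same fitted Markov
# model (compositional kinship is a signature property, not merely a GC
# property); plasmids are drawn at a diverged GC or with markers withheld.

# Fixed toy marker motifs (10-aa literals, one category each). Planted
# genes embed these; the motif scanner backend recognizes them exactly.
TOY_MOTIFS <- c(
  repA = "WQKRPLDSRE", repB = "FHNDLVEQWR",   # plasmid replication
  parA = "KDWHTRLQEV", parB = "YHQLDNRWTE",   # plasmid partitioning
  rpoB = "DEHWKQLRTV", gyrB = "NWQHEDLRKT",   # chromosomal core genes
  recA = "QLHWDKTRNE",
  dnaA = "HWDQKENRLT"                         # replication initiator
)
TOY_CATEGORIES <- c(repA = "REP", repB = "REP", parA = "PAR", parB = "PAR",
                    rpoB = "CORE", gyrB = "CORE", recA = "CORE",
                    dnaA = "DNAA")

# one stop-free codon per amino acid (standard code)
CODON_OF <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
              Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
              L = "CTG", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
              S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")

#' Toy marker database for the motif scanner backend
#'
#' Eight fixed 10-residue amino-acid motifs — two Rep, two Par, three core
#' and one DnaA — matching the genes planted by [generateAssembly()]. This
#' is a synthetic test fixture, not a biological marker set.
#'
#' @return A [MarkerDatabase-class] with the `"motif"` backend.
#' @export
toyMarkerDatabase <- function() {
  markerDatabase(TOY_MOTIFS, TOY_CATEGORIES[names(TOY_MOTIFS)],
                 backend = "motif")
}

#' Write the toy marker manifest to a TSV
#'
#' @param path Output path for a manifest readable by
#'   [readMarkerManifest()] (columns `marker_id`, `category`, `motif`).
#' @return Invisibly, `path`.
#' @export
writeToyMarkerManifest <- function(path) {
  man <- data.frame(marker_id = names(TOY_MOTIFS),
                    category = TOY_CATEGORIES[names(TOY_MOTIFS)],
                    motif = TOY_MOTIFS, stringsAsFactors = FALSE)
  utils::write.table(man, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parameters for the synthetic multipartite-genome generator
#'
#' Defaults emulate a modestly sized multipartite bacterial genome: a
#' 500 kb chromosome at 60% GC carrying a DnaA gene; one 150 kb chromid
#' drawn from the same compositional model with its GC nudged by +0.3
#' percentage points and carrying Rep, Par and core genes; one 40 kb
#' plasmid whose GC diverges by +5 percentage points and which carries Rep
#' and Par but no core gene.
#'
#' @param chromosomeLength,chromidLength,plasmidLength Lengths in bp.
#' @param chromidCount,plasmidCount Number of chromids / plasmids (>= 0).
#' @param chromosomeGc Target chromosome GC as a fraction in (0, 1).
#' @param chromidGcOffset,plasmidGcOffset GC offsets in percentage points.
#' @param markovOrder 0 or 1 (default 1): order of the background model.
#' @param plasmidMode Planted failure mode that makes plasmids
#'   distinguishable: `"gc_divergent"` (default; Rep and Par planted but no
#'   core gene, GC diverged), `"no_markers"` (no genes planted, GC matched),
#'   or `"marker_bearing"` (a stress mode: Rep, Par and a core gene planted
#'   so composition is the only separator — used to probe false-positive
#'   behavior as `plasmidGcOffset` varies).
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return A validated list of class `"GeneratorParams"`.
#' @export
generatorParams <- function(chromosomeLength = 500000L, chromidCount = 1L,
                            chromidLength = 150000L, plasmidCount = 1L,
                            plasmidLength = 40000L, chromosomeGc = 0.60,
                            chromidGcOffset = 0.3, plasmidGcOffset = 5.0,
                            markovOrder = 1L,
                            plasmidMode = c("gc_divergent", "no_markers",
                                            "marker_bearing"),
                            seed = 1L) {
  plasmidMode <- match.arg(plasmidMode)
  p <- list(chromosomeLength = as.integer(chromosomeLength),
            chromidCount = as.integer(chromidCount),
            chromidLength = as.integer(chromidLength),
            plasmidCount = as.integer(plasmidCount),
            plasmidLength = as.integer(plasmidLength),
            chromosomeGc = as.numeric(chromosomeGc),
            chromidGcOffset = as.numeric(chromidGcOffset),
            plasmidGcOffset = as.numeric(plasmidGcOffset),
            markovOrder = as.integer(markovOrder),
            plasmidMode = plasmidMode,
            seed = as.integer(seed))
  with(p, {
    if (chromosomeLength <= 0L || chromidLength <= 0L || plasmidLength <= 0L)
      stop("all lengths must be positive")
    if (chromidCount < 0L || plasmidCount < 0L)
      stop("counts must be >= 0")
    if (chromidGcOffset < 0 || plasmidGcOffset < 0)
      stop("GC offsets must be >= 0")
    if (chromosomeGc <= 0 || chromosomeGc >= 1)
      stop("chromosomeGc must lie in (0, 1)")
    for (gc in c(chromosomeGc + chromidGcOffset / 100,
                 chromosomeGc + plasmidGcOffset / 100))
      if (gc <= 0 || gc >= 1)
        stop("GC offset pushes target GC outside (0, 1): ", gc)
    if (!markovOrder %in% c(0L, 1L)) stop("markovOrder must be 0 or 1")
  })
  structure(p, class = "GeneratorParams")
}

# Fixed transition-preference structure shared by every replicon of an
# assembly: mild CG and TA suppression, the classic prokaryotic pattern.
# Rows = previous base (A,C,G,T), columns = next base.
TRANSITION_PREFERENCE <- matrix(c(
  1.15, 0.95, 1.05, 0.85,
  1.05, 1.00, 0.45, 1.10,
  0.95, 1.10, 1.00, 0.95,
  0.70, 1.05, 1.15, 1.00), nrow = 4, byrow = TRUE,
  dimnames = list(c("A", "C", "G", "T"), c("A", "C", "G", "T")))

# Build the order-`order` model at target GC: stationary-ish base weights
# pi scaled by the shared preference matrix.
.markovModel <- function(gc, order) {
  pi0 <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  if (order == 0L) {
    trans <- matrix(rep(pi0, 4), nrow = 4, byrow = TRUE)
  } else {
    trans <- TRANSITION_PREFERENCE * rep(pi0, each = 4)
    trans <- trans / rowSums(trans)
  }
  list(init = pi0, trans = trans)
}

.sampleSequence <- function(n, model) {
  u <- stats::runif(n)
  codes <- sample_markov_chain(cumsum(model$init),
                               t(apply(model$trans, 1, cumsum)), u)
  paste(c("A", "C", "G", "T")[codes], collapse = "")
}

# Encode "M <pad1> <motif> <pad2>" + stop as DNA. Pads are drawn from the
# current RNG stream; the cassette is a valid ORF for both gene callers.
.geneCassette <- function(motif, padAa = c(10L, 20L)) {
  aaPool <- setdiff(names(CODON_OF), "M")  # keep the start M leftmost-ish
  pad1 <- paste(sample(aaPool, padAa[1L], replace = TRUE), collapse = "")
  pad2 <- paste(sample(aaPool, padAa[2L], replace = TRUE), collapse = "")
  protein <- paste0("M", pad1, motif, pad2)
  dna <- paste(CODON_OF[strsplit(protein, "")[[1]]], collapse = "")
  list(protein = protein, dna = paste0(dna, "TAA"))
}

# Plant cassettes at jittered positions in equal bins; alternate strands.
.plantGenes <- function(seq, markers) {
  if (length(markers) == 0L)
    return(list(sequence = seq, genes = NULL))
  n <- nchar(seq)
  k <- length(markers)
  genes <- vector("list", k)
  for (j in seq_len(k)) {
    cass <- .geneCassette(TOY_MOTIFS[[markers[j]]])
    w <- nchar(cass$dna)
    binStart <- floor((j - 1) * n / k) + 1L
    binLen <- floor(j * n / k) - binStart + 1L
    if (binLen <= w) stop("replicon too short to plant ", k, " genes")
    pos <- binStart + sample.int(binLen - w, 1L) - 1L
    strand <- if (j %% 2L == 1L) "+" else "-"
    insert <- if (strand == "+") cass$dna else
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(cass$dna)))
    substr(seq, pos, pos + w - 1L) <- insert
    genes[[j]] <- data.frame(marker_id = markers[j],
                             category = TOY_CATEGORIES[[markers[j]]],
                             protein = cass$protein,
                             start = pos, end = pos + w - 1L,
                             strand = strand, stringsAsFactors = FALSE)
  }
  list(sequence = seq, genes = do.call(rbind, genes))
}

#' Generate one synthetic multipartite assembly with ground truth
#'
#' Draws a chromosome from an order-0 or order-1 Markov model at the target
#' GC and plants a DnaA-motif gene on it; draws each chromid from the same
#' model with the GC target nudged by `chromidGcOffset` and plants Rep, Par
#' and core genes; draws each plasmid either at a GC diverged by
#' `plasmidGcOffset` with Rep/Par genes but no core gene (default), or at
#' the chromosome's GC with no markers at all (`plasmidMode =
#' "no_markers"`). Deterministic for a fixed seed.
#'
#' @param params A [generatorParams()] list.
#' @param id Assembly identifier used as the replicon-id prefix.
#' @return A list with elements `assembly` (a [RepliconSet-class]),
#'   `truth` (data.frame: `replicon_id`, `role` in
#'   CHROMOSOME/CHROMID/PLASMID, `planted_markers`), `genes` (data.frame of
#'   planted gene records incl. proteins and coordinates) and `params`.
#' @export
generateAssembly <- function(params = generatorParams(), id = "synth") {
  stopifnot(inherits(params, "GeneratorParams"))
  set.seed(params$seed)
  baseModel <- .markovModel(params$chromosomeGc, params$markovOrder)

  seqs <- character(0)
  truth <- list()
  genes <- list()
  addReplicon <- function(rid, role, length, model, markers) {
    s <- .sampleSequence(length, model)
    planted <- .plantGenes(s, markers)
    seqs[[rid]] <<- planted$sequence
    truth[[rid]] <<- data.frame(
      replicon_id = rid, role = role,
      planted_markers = paste(markers, collapse = ","),
      stringsAsFactors = FALSE)
    if (!is.null(planted$genes)) {
      g <- planted$genes
      g$replicon_id <- rid
      genes[[rid]] <<- g
    }
  }

  addReplicon(paste0(id, "_chromosome"), "CHROMOSOME",
              params$chromosomeLength, baseModel, c("dnaA", "rpoB"))
  if (params$chromidCount > 0L) {
    chromidModel <- .markovModel(params$chromosomeGc +
                                 params$chromidGcOffset / 100,
                                 params$markovOrder)
    for (i in seq_len(params$chromidCount))
      addReplicon(sprintf("%s_chromid%d", id, i), "CHROMID",
                  params$chromidLength, chromidModel,
                  c("repA", "parA", "rpoB", "gyrB"))
  }
  if (params$plasmidCount > 0L) {
    if (params$plasmidMode == "no_markers") {
      plasmidModel <- baseModel
      plasmidMarkers <- character(0)
    } else {
      plasmidModel <- .markovModel(params$chromosomeGc +
                                   params$plasmidGcOffset / 100,
                                   params$markovOrder)
      plasmidMarkers <- if (params$plasmidMode == "gc_divergent")
        c("repB", "parB") else c("repB", "parB", "recA")
    }
    for (i in seq_len(params$plasmidCount))
      addReplicon(sprintf("%s_plasmid%d", id, i), "PLASMID",
                  params$plasmidLength, plasmidModel, plasmidMarkers)
  }

  list(assembly = RepliconSet(unlist(seqs), assemblyId = id, source = id),
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
       genes = do.call(rbind, c(genes, list(make.row.names = FALSE))),
       params = params)
}

#' Generate a pooled benchmark of synthetic assemblies
#'
#' Generates `n` assemblies with per-assembly seeds derived as
#' `seed + index`, strips the genome groupings (the pooled-screening
#' treatment: every sequence becomes an independent input) and returns the
#' pooled replicons, the union truth table and the toy motif database the
#' scanner backend expects.
#'
#' @param n Number of assemblies (>= 1).
#' @param params Template [generatorParams()]; its `seed` is replaced per
#'   assembly.
#' @param seed Base seed for the benchmark.
#' @return A list with `pool` (a pooled [RepliconSet-class]), `truth`
#'   (data.frame with an extra `assembly` column), `genes`, and `db`
#'   (the [toyMarkerDatabase()]).
#' @export
generateBenchmark <- function(n, params = generatorParams(), seed = 11L) {
  stopifnot(n >= 1L)
  sims <- lapply(seq_len(n), function(i) {
    p <- params
    p$seed <- as.integer(seed + i)
    generateAssembly(p, id = sprintf("g%03d", i))
  })
  pool <- poolReplicons(lapply(sims, `[[`, "assembly"), assemblyId = "pool")
  truth <- do.call(rbind, lapply(seq_len(n), function(i) {
    tr <- sims[[i]]$truth
    tr$assembly <- sprintf("g%03d", i)
    tr
  }))
  genes <- do.call(rbind, lapply(sims, `[[`, "genes"))
  rownames(truth) <- rownames(genes) <- NULL
  list(pool = pool, truth = truth, genes = genes, db = toyMarkerDatabase())
}

#' Write a benchmark to disk
#'
#' Emits the pooled FASTA, the truth TSV and the toy motif manifest, the
#' on-disk form consumed by the command-line interface.
#'
#' @param bench Result of [generateBenchmark()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
writeBenchmark <- function(bench, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeFasta(bench$pool, file.path(dir, "pool.fasta"))
  utils::write.table(bench$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeToyMarkerManifest(file.path(dir, "markers.tsv"))
  invisible(dir)
}
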