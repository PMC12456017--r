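# helper: a DNA cassette encoding "M <aa...> *" with one codon per residue
codonEncode <- function(protein) {
  codons <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
              Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
              L = "CTG", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
              S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")
  paste0(paste(codons[strsplit(protein, "")[[1]]], collapse = ""), "TAA")
}

test_that("naive ORF finder reports a planted gene starting with M", {
  set.seed(1)
  protein <- paste0("M", strrep("KDE", 12))  # 37 aa
  seq <- paste0(randomDNA(500), codonEncode(protein), randomDNA(500))
  genes <- predictGenes(RepliconSet(c(r = seq), "toy"), backend = "naive")
  expect_gt(nrow(genes), 0L)
  expect_true(all(startsWith(genes$protein, "M")))
  expect_true(any(grepl(protein, genes$protein, fixed = TRUE)))
})

test_that("naive ORF finder returns nothing for an all-N replicon", {
  genes <- predictGenes(RepliconSet(c(n = strrep("N", 500)), "toy"),
                        backend = "naive")
  expect_equal(nrow(genes), 0L)
})

test_that("naive backend recovers all planted genes on both strands", {
  sim <- generateAssembly(smallParams(seed = 13))
  genes <- predictGenes(sim$assembly, backend = "naive")
  expect_setequal(unique(sim$genes$strand), c("+", "-"))
  for (i in seq_len(nrow(sim$genes))) {
    planted <- sim$genes[i, ]
    hit <- grepl(planted$protein, genes$protein, fixed = TRUE) &
      genes$replicon_id == planted$replicon_id
    expect_true(any(hit), label = sprintf(
      "planted %s gene on %s recovered", planted$marker_id,
      planted$replicon_id))
    # coordinates of the recovered ORF contain the planted cassette
    g <- genes[which(hit)[1], ]
    expect_lte(g$start, planted$start)
    expect_gte(g$end, planted$end)
    expect_identical(g$strand, planted$strand)
  }
})

test_that("naive ORF coordinates map back onto the input sequence", {
  set.seed(2)
  seq <- paste0(randomDNA(200), codonEncode(paste0("M", strrep("HV", 16))),
                randomDNA(200))
  rs <- RepliconSet(c(r = seq), "toy")
  genes <- predictGenes(rs, backend = "naive")
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    nt <- substr(repliconSequences(rs)[["r"]], g$start, g$end)
    if (g$strand == "-") nt <- oracleRevComp(nt)
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt)))
    expect_identical(aa, paste0(g$protein, "*"))
  }
})

test_that("motif scanner finds planted motifs with their manifest category", {
  db <- markerDatabase(c(repX = "WKRPLASREP"), "REP")
  genes <- data.frame(replicon_id = "r", gene_id = "r_1",
                      protein = "MAAWKRPLASREPDD", start = 1L, end = 48L,
                      strand = "+", length_aa = 15L,
                      stringsAsFactors = FALSE)
  hits <- scanMarkers(genes, db)
  expect_equal(nrow(hits), 1L)
  expect_identical(hits$category, "REP")
  expect_identical(hits$e_value, 0)

  noHit <- genes
  noHit$protein <- "MAADDKKEE"
  expect_equal(nrow(scanMarkers(noHit, db)), 0L)
})

test_that("repeated hits to one marker collapse to one distinct marker", {
  db <- markerDatabase(c(coreX = "DEHWKQLRTV"), "CORE")
  genes <- data.frame(replicon_id = "r", gene_id = sprintf("r_%d", 1:5),
                      protein = rep("MDEHWKQLRTVA", 5), start = 1L,
                      end = 39L, strand = "+", length_aa = 12L,
                      stringsAsFactors = FALSE)
  hits <- scanMarkers(genes, db)
  expect_equal(nrow(hits), 5L)
  prof <- profileReplicons(hits)
  expect_identical(prof$n_core, 1L)
})

test_that("marker profiles count distinct markers per category", {
  noGenes <- data.frame(replicon_id = character(0), gene_id = character(0),
                        protein = character(0), stringsAsFactors = FALSE)
  empty <- profileReplicons(scanMarkers(noGenes, toyMarkerDatabase()), "r")
  expect_identical(empty$n_rep + empty$n_par + empty$n_core + empty$n_dnaa, 0L)
  expect_false(empty$has_dnaa)

  hits <- data.frame(
    replicon_id = "r",
    gene_id = sprintf("r_%d", 1:5),
    marker_id = c("repA", "parA", "rpoB", "dnaA", "dnaA2"),
    category = c("REP", "PAR", "CORE", "DNAA", "DNAA"),
    score = 10, e_value = 0, stringsAsFactors = FALSE)
  prof <- profileReplicons(hits)
  expect_identical(prof[, c("n_rep", "n_par", "n_core", "n_dnaa")],
                   data.frame(n_rep = 1L, n_par = 1L, n_core = 1L,
                              n_dnaa = 2L))
  expect_true(prof$has_dnaa)

  expect_error(profileReplicons(hits, repliconIds = "other"), "r")
})

test_that("scanning is deterministic for fixed backend and database", {
  sim <- generateAssembly(smallParams(seed = 4))
  genes <- predictGenes(sim$assembly, backend = "naive")
  h1 <- scanMarkers(genes, toyMarkerDatabase())
  h2 <- scanMarkers(genes, toyMarkerDatabase())
  expect_identical(h1, h2)
})

test_that("marker manifest TSV round-trips through readMarkerManifest", {
  path <- tempfile(fileext = ".tsv")
  writeToyMarkerManifest(path)
  db <- readMarkerManifest(path, backend = "motif")
  hitsA <- scanMarkers(data.frame(replicon_id = "r", gene_id = "g",
                                  protein = "MAHWDQKENRLTK",
                                  stringsAsFactors = FALSE), db)
  expect_identical(hitsA$marker_id, "dnaA")
  expect_identical(hitsA$category, "DNAA")
})

test_that("HMM and motif backends agree on planted-fixture hits", {
  sim <- generateAssembly(smallParams(seed = 21))
  set.seed(22)
  aaAlphabet <- strsplit("ACDEFGHIKLNPQRSTVWY", "")[[1]]
  decoys <- vapply(1:6, function(i)
    paste0("M", paste(sample(aaAlphabet, 40, TRUE), collapse = "")), "")
  genes <- data.frame(
    replicon_id = c(sim$genes$replicon_id, rep("decoy", 6)),
    gene_id = sprintf("p%02d", seq_len(nrow(sim$genes) + 6)),
    protein = c(sim$genes$protein, decoys),
    stringsAsFactors = FALSE)

  motifDb <- toyMarkerDatabase()
  # build one single-sequence profile per planted marker protein
  hmmDir <- tempfile()
  dir.create(hmmDir)
  trainIdx <- !duplicated(sim$genes$marker_id)
  paths <- character(0)
  for (i in which(trainIdx)) {
    marker <- sim$genes$marker_id[i]
    fa <- file.path(hmmDir, paste0(marker, ".fa"))
    writeLines(c(paste0(">", marker), sim$genes$protein[i]), fa)
    hmm <- file.path(hmmDir, paste0(marker, ".hmm"))
    status <- system2("hmmbuild", c("-n", marker, "--amino", hmm, fa),
                      stdout = FALSE, stderr = FALSE)
    expect_identical(status, 0L)
    paths[marker] <- hmm
  }
  cats <- motifDb@manifest$category[match(names(paths),
                                          motifDb@manifest$marker_id)]
  hmmDb <- markerDatabase(paths, cats, backend = "hmm")

  motifHits <- scanMarkers(genes, motifDb)
  hmmHits <- scanMarkers(genes, hmmDb)
  key <- function(h) sort(paste(h$gene_id, h$marker_id))
  expect_identical(key(hmmHits), key(motifHits))
  expect_true(all(hmmHits$e_value <= 1e-5))
})

test_that("prodigal backend honors the gene-table contract", {
  sim <- generateAssembly(smallParams(seed = 6))
  rs <- sim$assembly[repliconIds(sim$assembly)[1]]
  genes <- predictGenes(rs, backend = "prodigal")
  expect_true(all(c("replicon_id", "gene_id", "protein", "start", "end",
                    "strand", "length_aa") %in% names(genes)))
  if (nrow(genes)) {
    len <- repliconLengths(rs)[[1]]
    expect_true(all(genes$start >= 1L & genes$end <= len))
    expect_true(all(genes$strand %in% c("+", "-")))
    expect_true(all((genes$end - genes$start + 1L) %% 3L == 0L))
  }
})
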