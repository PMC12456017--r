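# Independent brute-force oracles for the signature computations. These
# deliberately avoid Biostrings: words are enumerated with substring(),
# counted with table(), and reverse complements built with chartr(), so
# agreement with the package is a genuine dual-route check.

oracleAllWords <- function(k) {
  w <- c("A", "C", "G", "T")
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      w <- as.vector(t(outer(w, c("A", "C", "G", "T"), paste0)))
    }
  }
  sort(w)
}

oracleRevComp <- function(s) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

oracleCountWords <- function(s, k) {
  n <- nchar(s)
  lv <- oracleAllWords(k)
  if (n < k) return(table(factor(character(0), levels = lv)))
  subs <- substring(s, 1:(n - k + 1), k:n)
  subs <- subs[!grepl("N", subs, fixed = TRUE)]
  table(factor(subs, levels = lv))
}

oracleKmerFreq <- function(s, k, symmetrize = TRUE) {
  counts <- oracleCountWords(s, k)
  if (symmetrize) counts <- counts + oracleCountWords(oracleRevComp(s), k)
  f <- as.numeric(counts) / sum(counts)
  names(f) <- oracleAllWords(k)
  f
}

oracleRelAbund <- function(s, k) {
  fk <- oracleKmerFreq(s, k)
  f1 <- oracleKmerFreq(s, 1)
  vapply(names(fk), function(w) {
    p <- prod(f1[strsplit(w, "", fixed = TRUE)[[1]]])
    if (p > 0) fk[[w]] / p else 0
  }, numeric(1))
}

oracleDistance <- function(s1, s2, k, scale = 10) {
  scale * sum(abs(oracleRelAbund(s1, k) - oracleRelAbund(s2, k))) / 4^k
}

# ---- sequence construction helpers ------------------------------------

randomDNA <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# sequence of `len` bp (multiple of 1000) with exactly gcPct percent G+C
exactGcSeq <- function(len, gcPct) {
  stopifnot(len %% 1000 == 0)
  nGC <- round(gcPct * 10)
  unit <- paste0(strrep("G", ceiling(nGC / 2)), strrep("C", floor(nGC / 2)),
                 strrep("A", ceiling((1000 - nGC) / 2)),
                 strrep("T", floor((1000 - nGC) / 2)))
  strrep(unit, len %/% 1000)
}

# marker profile row in the profileReplicons() output format
profileRow <- function(id, n_rep = 0L, n_par = 0L, n_core = 0L, n_dnaa = 0L) {
  data.frame(replicon_id = id, n_rep = as.integer(n_rep),
             n_par = as.integer(n_par), n_core = as.integer(n_core),
             n_dnaa = as.integer(n_dnaa), has_dnaa = n_dnaa > 0L,
             stringsAsFactors = FALSE)
}

# small generator parameters used by most pipeline tests; study-scale
# defaults are exercised in the acceptance suite
smallParams <- function(seed = 1L, ...) {
  generatorParams(chromosomeLength = 60000L, chromidLength = 25000L,
                  plasmidLength = 12000L, seed = seed, ...)
}
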