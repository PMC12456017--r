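# signatures: strand-symmetrized k-mer relative abundance and the
# dinucleotide / tetranucleotide signature distances.

#' k-mer frequencies of a DNA sequence
#'
#' Sliding-window word frequencies over all windows consisting solely of
#' A/C/G/T; windows overlapping an N (or any normalized ambiguity base) are
#' dropped rather than imputed, since gap-rich MAG sequences would
#' otherwise bias the ratios. With `symmetrize = TRUE` counts are
#' accumulated from the sequence and its reverse complement before
#' normalization, so a sequence and its reverse complement have identical
#' frequencies.
#'
#' @param sequence A single DNA string (character or
#'   [Biostrings::DNAString]); normalized as in [RepliconSet()].
#' @param k Word size: 1, 2 or 4.
#' @param symmetrize Accumulate counts from both strands (default TRUE).
#' @return Named numeric vector of 4^k frequencies (lexicographic word
#'   order) summing to 1.
#' @examples
#' kmerFrequencies("AAAA", k = 1, symmetrize = FALSE)  # f(A) = 1
#' kmerFrequencies("AAAA", k = 1)                      # f(A) = f(T) = 0.5
#' @export
kmerFrequencies <- function(sequence, k, symmetrize = TRUE) {
  stopifnot(length(k) == 1L, k %in% c(1, 2, 4))
  k <- as.integer(k)
  s <- Biostrings::DNAString(normalizeSequence(sequence))
  counts <- Biostrings::oligonucleotideFrequency(s, width = k)
  if (symmetrize)
    counts <- counts +
      Biostrings::oligonucleotideFrequency(Biostrings::reverseComplement(s),
                                           width = k)
  total <- sum(counts)
  if (total == 0)
    stop("no window of ", k, " consecutive non-N bases in sequence")
  counts / total
}

#' k-mer relative-abundance signature
#'
#' Computes the zero-order (mononucleotide-normalized) relative abundance
#' signature on strand-symmetrized frequencies: for each word w = x1..xk,
#' value(w) = f*(w) / (f*(x1) ... f*(xk)), where f* denotes frequencies
#' accumulated over both strands. For a sequence with no compositional
#' structure beyond base composition every value is near 1; departures from
#' 1 are the genomic signature. Words whose mononucleotide product is zero
#' get value 0 and do not count as informative.
#'
#' @param sequence A single DNA string.
#' @param k 2 (dinucleotide) or 4 (tetranucleotide).
#' @return A [CompositionSignature-class].
#' @seealso [signatureDistance()]
#' @export
relativeAbundance <- function(sequence, k = 4) {
  stopifnot(length(k) == 1L, k %in% c(2, 4))
  k <- as.integer(k)
  fk <- kmerFrequencies(sequence, k = k, symmetrize = TRUE)
  f1 <- kmerFrequencies(sequence, k = 1L, symmetrize = TRUE)
  words <- names(fk)
  # product of mononucleotide frequencies per word
  prod1 <- rep(1, length(words))
  for (pos in seq_len(k)) {
    prod1 <- prod1 * f1[substring(words, pos, pos)]
  }
  informative <- prod1 > 0
  values <- numeric(length(words))
  values[informative] <- fk[informative] / prod1[informative]
  names(values) <- words
  new("CompositionSignature", k = k, values = values,
      nInformative = sum(informative))
}

setMethod("show", "CompositionSignature", function(object) {
  cat(sprintf("CompositionSignature k=%d (%d/%d informative words)\n",
              object@k, object@nInformative, length(object@values)))
  cat(sprintf("  value range: [%.4f, %.4f]\n",
              min(object@values), max(object@values)))
})

#' Relative-abundance distance between two signatures
#'
#' The mean absolute difference between two relative-abundance vectors over
#' all 4^k words, multiplied by `scale`:
#' \deqn{d = \frac{scale}{4^k} \sum_w |\rho_f(w) - \rho_g(w)|}
#' The distance is symmetric, zero iff the signatures are identical, and —
#' because signatures are strand-symmetrized — exactly zero between a
#' sequence and its reverse complement. The working thresholds (1.6 for
#' tetranucleotide clustering, 0.4 for the dinucleotide pre-screen) are
#' interpreted on the configured scale; the default scale is 10.
#'
#' @param sigF,sigG [CompositionSignature-class] objects with equal `k`.
#' @param scale Multiplier on the mean absolute difference (default 10).
#' @return Single non-negative number.
#' @export
signatureDistance <- function(sigF, sigG, scale = 10) {
  stopifnot(is(sigF, "CompositionSignature"), is(sigG, "CompositionSignature"))
  if (sigF@k != sigG@k)
    stop("signatures have different word sizes (k = ",
         sigF@k, " vs ", sigG@k, ")")
  scale * sum(abs(sigF@values - sigG@values)) / length(sigF@values)
}

#' Pairwise signature distances between sequences
#'
#' Convenience wrapper: computes [relativeAbundance()] signatures for a set
#' of sequences and returns the full symmetric distance matrix.
#'
#' @param x A [RepliconSet-class] or named character vector of sequences.
#' @param k 2 or 4 (default 4).
#' @param scale Passed to [signatureDistance()].
#' @return Symmetric numeric matrix with replicon ids as dimnames.
#' @export
signatureDistanceMatrix <- function(x, k = 4, scale = 10) {
  seqs <- if (is(x, "RepliconSet")) repliconSequences(x) else x
  sigs <- lapply(seqs, relativeAbundance, k = k)
  n <- length(sigs)
  m <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        m[i, j] <- m[j, i] <- signatureDistance(sigs[[i]], sigs[[j]],
                                                scale = scale)
      }
    }
  }
  m
}
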