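# seq_io: FASTA input, sequence normalization, per-replicon statistics,
# and result (TSV/JSON) output.

RESULT_COLUMNS <- c("replicon_id", "source", "length", "gc_pct", "role",
                    "center_id", "delta_gc", "tetra_dist",
                    "n_rep", "n_par", "n_core", "n_dnaa", "evidence")

# Uppercase and collapse every non-ACGTN letter to N.
normalizeSequence <- function(x) {
  x <- toupper(as.character(x))
  gsub("[^ACGTN]", "N", x, perl = TRUE)
}

#' Construct a RepliconSet
#'
#' @param sequences Named character vector or [Biostrings::DNAStringSet]
#'   of replicon sequences. Names become replicon ids and must be unique.
#' @param assemblyId Single string naming the assembly.
#' @param source Optional character vector (recycled if length 1) recording
#'   each replicon's genome/sample of origin.
#'
#' @return A [RepliconSet-class].
#' @examples
#' rs <- RepliconSet(c(chr = "ACGTACGT", pls = "acgtRYacgt"), "toy")
#' repliconLengths(rs)
#' @export
RepliconSet <- function(sequences, assemblyId = "assembly", source = NA_character_) {
  seqs <- normalizeSequence(sequences)
  names(seqs) <- names(sequences)
  if (length(source) == 1L) source <- rep(source, length(seqs))
  new("RepliconSet",
      sequences  = Biostrings::DNAStringSet(seqs),
      assemblyId = as.character(assemblyId),
      source     = as.character(source))
}

#' Read replicons from FASTA
#'
#' Reads a (optionally gzipped) multi-FASTA nucleotide file. In
#' `"per_genome"` mode the file is one assembly: one [RepliconSet-class]
#' holding one replicon per record. In `"pooled"` mode every record is
#' treated as an independent single-replicon assembly — the treatment used
#' when screening pooled sequences whose genome of origin is unknown or
#' deliberately discarded.
#'
#' @param path Path to a FASTA or gzipped FASTA file.
#' @param mode `"per_genome"` or `"pooled"`.
#' @param minLength Drop records shorter than this many bp (default 0, i.e.
#'   keep everything; chromids as small as tens of kb are real).
#'
#' @return A list of [RepliconSet-class] objects (length 1 in
#'   `"per_genome"` mode).
#' @export
readFasta <- function(path, mode = c("per_genome", "pooled"), minLength = 0L) {
  mode <- match.arg(mode)
  if (!file.exists(path))
    stop("cannot read FASTA file: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L)
    stop("empty FASTA input: ", path)
  # FASTA descriptions: keep the first whitespace-delimited token as the id
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate record id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(seqs) <- ids
  keep <- Biostrings::width(seqs) >= minLength
  seqs <- seqs[keep]
  if (length(seqs) == 0L)
    stop("no records of length >= ", minLength, " in ", path)
  base <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(path))
  chr <- as.character(seqs)
  names(chr) <- names(seqs)
  if (mode == "per_genome") {
    list(RepliconSet(chr, assemblyId = base, source = base))
  } else {
    lapply(names(chr), function(id)
      RepliconSet(chr[id], assemblyId = id, source = base))
  }
}

#' Write replicons to FASTA
#'
#' @param x A [RepliconSet-class].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
writeFasta <- function(x, path) {
  Biostrings::writeXStringSet(x@sequences, path)
  invisible(path)
}

#' Pool several RepliconSets into one
#'
#' Concatenates the replicons of several assemblies into a single pooled
#' set (replicon ids must remain unique). Each replicon's `source` records
#' the assembly it came from.
#'
#' @param sets A list of [RepliconSet-class] objects.
#' @param assemblyId Name for the pooled set.
#' @return A [RepliconSet-class].
#' @export
poolReplicons <- function(sets, assemblyId = "pool") {
  chr <- unlist(lapply(sets, function(s) {
    out <- as.character(s@sequences)
    names(out) <- names(s@sequences)
    out
  }))
  src <- unlist(lapply(sets, function(s) {
    ifelse(is.na(s@source), s@assemblyId, s@source)
  }))
  RepliconSet(chr, assemblyId = assemblyId, source = src)
}

#' @rdname repliconAccessors
#' @param x A [RepliconSet-class].
#' @return `repliconIds`: character vector of ids; `repliconLengths`: named
#'   integer vector of lengths in bp; `assemblyId`: single string;
#'   `repliconSource`: named character vector of origins.
#' @name repliconAccessors
#' @aliases repliconIds repliconLengths assemblyId repliconSource
NULL

#' @rdname repliconAccessors
#' @export
setMethod("repliconIds", "RepliconSet", function(x) names(x@sequences))

#' @rdname repliconAccessors
#' @export
setMethod("repliconLengths", "RepliconSet", function(x)
  setNames(Biostrings::width(x@sequences), names(x@sequences)))

#' @rdname repliconAccessors
#' @export
setMethod("assemblyId", "RepliconSet", function(x) x@assemblyId)

#' @rdname repliconAccessors
#' @export
setMethod("repliconSource", "RepliconSet", function(x)
  setNames(x@source, names(x@sequences)))

#' Extract replicon sequences as character strings
#'
#' @param x A [RepliconSet-class].
#' @param ids Optional ids to extract (default all).
#' @return Named character vector of sequences.
#' @export
repliconSequences <- function(x, ids = NULL) {
  out <- as.character(x@sequences)
  names(out) <- names(x@sequences)
  if (!is.null(ids)) out <- out[ids]
  out
}

#' @export
setMethod("[", "RepliconSet", function(x, i, j, ..., drop = TRUE) {
  new("RepliconSet",
      sequences  = x@sequences[i],
      assemblyId = x@assemblyId,
      source     = setNames(x@source, names(x@sequences))[i])
})

setMethod("show", "RepliconSet", function(object) {
  cat(sprintf("RepliconSet '%s' with %d replicon(s)\n",
              object@assemblyId, length(object@sequences)))
  w <- Biostrings::width(object@sequences)
  info <- data.frame(replicon_id = names(object@sequences), length = w)
  print(utils::head(info, 10))
  if (nrow(info) > 10) cat("  ...\n")
})

# GC over non-N bases; returns NA where no A/C/G/T base exists.
.gcOrNA <- function(seqs) {
  counts <- Biostrings::letterFrequency(seqs, c("A", "C", "G", "T"))
  denom <- rowSums(counts)
  gc <- (counts[, "C"] + counts[, "G"]) / denom
  gc[denom == 0] <- NA_real_
  setNames(as.numeric(gc), names(seqs))
}

#' GC content of replicons
#'
#' Fraction of G+C among non-N bases: (#G + #C) / (#A + #C + #G + #T).
#' N bases contribute to neither numerator nor denominator, so gappy MAG
#' sequences are not biased toward any value.
#'
#' @param x A [RepliconSet-class], [Biostrings::DNAStringSet], or character
#'   vector of DNA sequences.
#' @param ... Unused.
#' @return Numeric vector of fractions in \[0, 1\], named by replicon id
#'   where ids exist.
#' @examples
#' gcContent(RepliconSet(c(a = "ATGC", b = "AATGN"), "toy"))  # 0.5, 0.25
#' @export
#' @name gcContent
setMethod("gcContent", "RepliconSet", function(x, ...) {
  gc <- .gcOrNA(x@sequences)
  if (anyNA(gc))
    stop("GC content undefined (all-N or empty sequence) for: ",
         paste(names(gc)[is.na(gc)], collapse = ", "))
  gc
})

#' @rdname gcContent
#' @export
setMethod("gcContent", "DNAStringSet", function(x, ...) {
  gc <- .gcOrNA(x)
  if (anyNA(gc))
    stop("GC content undefined (all-N or empty sequence)")
  gc
})

#' @rdname gcContent
#' @export
setMethod("gcContent", "character", function(x, ...) {
  gcContent(Biostrings::DNAStringSet(normalizeSequence(x)))
})

emptyCallsFrame <- function() {
  data.frame(
    replicon_id = character(0), source = character(0),
    length = integer(0), gc_pct = numeric(0), role = character(0),
    center_id = character(0), delta_gc = numeric(0), tetra_dist = numeric(0),
    n_rep = integer(0), n_par = integer(0), n_core = integer(0),
    n_dnaa = integer(0), evidence = character(0),
    stringsAsFactors = FALSE
  )
}

.callsOf <- function(result) {
  if (is(result, "ChromidClassification")) result@calls else result
}

#' Write classification results
#'
#' One row (TSV) or object (JSON) per replicon: id, source, length, GC%,
#' role, cluster center id, GC delta and tetranucleotide distance to the
#' center, and the four marker-category counts. The file round-trips
#' losslessly through [readResults()].
#'
#' @param result A [ChromidClassification-class] or a calls data.frame.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return Invisibly, `path`.
#' @export
writeResults <- function(result, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  calls <- .callsOf(result)
  if (nrow(calls) == 0L) calls <- emptyCallsFrame()
  calls <- calls[, RESULT_COLUMNS]
  if (format == "tsv") {
    ok <- tryCatch({
      utils::write.table(calls, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, na = "NA")
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop("cannot write results to ", path)
  } else {
    jsonlite::write_json(calls, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read classification results written by writeResults
#'
#' @param path Input path.
#' @param format `"tsv"` or `"json"`.
#' @return A calls data.frame with the standard result columns.
#' @export
readResults <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    out <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                             colClasses = c(
                               replicon_id = "character", source = "character",
                               length = "integer", gc_pct = "numeric",
                               role = "character", center_id = "character",
                               delta_gc = "numeric", tetra_dist = "numeric",
                               n_rep = "integer", n_par = "integer",
                               n_core = "integer", n_dnaa = "integer",
                               evidence = "character"))
  } else {
    out <- jsonlite::fromJSON(path)
    if (length(out) == 0L || is.null(dim(out))) out <- emptyCallsFrame()
    for (col in RESULT_COLUMNS) if (!col %in% names(out)) out[[col]] <- NA
    out <- out[, RESULT_COLUMNS]
    out$length <- as.integer(out$length)
    for (col in c("n_rep", "n_par", "n_core", "n_dnaa"))
      out[[col]] <- as.integer(out[[col]])
    for (col in c("gc_pct", "delta_gc", "tetra_dist"))
      out[[col]] <- as.numeric(out[[col]])
    for (col in c("replicon_id", "source", "role", "center_id", "evidence"))
      out[[col]] <- as.character(out[[col]])
  }
  out
}
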