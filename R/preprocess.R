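# Read preprocessing: quality filter, 3' adapter trim, length floor,
# collapse to unique tags.

#' Remove reads below a mean base-quality threshold
#'
#' The original instrument-side chastity filter is not recoverable; a
#' configurable mean-Phred threshold (default Q20) stands in for it.
#'
#' @param reads data frame (id, sequence, quality), Phred+33.
#' @param min_mean_q minimum mean Phred score to keep a read.
#' @return the surviving reads, with attribute `n_removed`.
#' @export
quality_filter <- function(reads, min_mean_q = 20) {
  keep <- phred_means(reads$quality) >= min_mean_q
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Trim the 3' adapter from read sequences
#'
#' Finds, per read, the leftmost position where a prefix of the adapter
#' aligns to the read suffix with overlap >= `min_overlap` and mismatch
#' rate <= `max_mismatch_rate`, and truncates there. Reads with no
#' adapter hit are kept whole and flagged (a 36-cycle read can be all
#' insert); reads that become empty after trimming are rejected.
#'
#' @param reads data frame (id, sequence, quality) or character vector of
#'   sequences.
#' @param adapter3 adapter sequence (non-empty).
#' @param min_overlap minimum adapter-read overlap (nt).
#' @param max_mismatch_rate maximum fraction of mismatching bases in the
#'   overlap.
#' @return for a data frame input: surviving reads with trimmed
#'   `sequence`/`quality` and a logical `adapter_found` column, plus
#'   attribute `n_rejected` (reads empty after trimming); for a character
#'   input: the trimmed sequences ("" where the whole read was adapter).
#' @export
trim_adapter <- function(reads, adapter3, min_overlap = 6,
                         max_mismatch_rate = 0.1) {
  if (!nzchar(adapter3)) stop("adapter3 must be non-empty")
  adapter3 <- normalize_dna(adapter3)
  seqs <- if (is.data.frame(reads)) reads$sequence else reads
  cut <- .adapter_cut_positions(seqs, adapter3, as.integer(min_overlap),
                                max_mismatch_rate)
  trimmed <- ifelse(cut >= 0, substr(seqs, 1, cut), seqs)
  if (!is.data.frame(reads)) return(trimmed)
  out <- reads
  out$sequence <- trimmed
  out$quality <- substr(out$quality, 1, nchar(trimmed))
  out$adapter_found <- cut >= 0
  keep <- nzchar(out$sequence)
  res <- out[keep, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_rejected") <- sum(!keep)
  res
}

#' Discard tags shorter than a minimum length
#'
#' Small RNA inserts shorter than 15 nt cannot be assigned reliably and
#' are discarded.
#'
#' @param x data frame with a `sequence` column, or character vector.
#' @param min_len minimum surviving length (nt).
#' @return the surviving rows/sequences, with attribute `n_removed`.
#' @export
length_filter <- function(x, min_len = 15) {
  seqs <- if (is.data.frame(x)) x$sequence else x
  keep <- nchar(seqs) >= min_len
  out <- if (is.data.frame(x)) {
    r <- x[keep, , drop = FALSE]; rownames(r) <- NULL; r
  } else x[keep]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Collapse reads into unique tags with counts
#'
#' @param reads data frame with a `sequence` column, or character vector.
#' @param library_id label attached to every tag.
#' @return data frame (sequence, count, library_id) sorted by decreasing
#'   count then sequence; sum of counts equals the number of input reads.
#' @export
collapse_tags <- function(reads, library_id) {
  seqs <- if (is.data.frame(reads)) reads$sequence else reads
  if (length(seqs) == 0)
    return(data.frame(sequence = character(0), count = integer(0),
                      library_id = character(0), stringsAsFactors = FALSE))
  tab <- table(seqs)
  out <- data.frame(sequence = names(tab), count = as.integer(tab),
                    library_id = library_id, stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$sequence), ]
  rownames(out) <- NULL
  out
}

#' Full preprocessing of one library
#'
#' Quality filter, adapter trim, length filter and tag collapsing, with a
#' conservation log: reads_in = removed_quality + rejected_trim +
#' removed_length + sum of tag counts.
#'
#' @param reads data frame (id, sequence, quality) or FASTQ path.
#' @param library_id label for the library.
#' @param min_mean_q,adapter3,min_overlap,max_mismatch_rate,min_len
#'   stage parameters, see the individual filters.
#' @return list with `tags` (ReadTag table) and `log` (named counts).
#' @export
preprocess_library <- function(reads, library_id,
                               min_mean_q = 20,
                               adapter3 = "TCGTATGCCGTCTTCTGCTTG",
                               min_overlap = 6, max_mismatch_rate = 0.1,
                               min_len = 15) {
  if (is.character(reads) && length(reads) == 1) reads <- read_fastq(reads)
  n_in <- nrow(reads)
  q <- quality_filter(reads, min_mean_q)
  t <- trim_adapter(q, adapter3, min_overlap, max_mismatch_rate)
  l <- length_filter(t, min_len)
  tags <- collapse_tags(l, library_id)
  log <- c(reads_in = n_in,
           removed_quality = attr(q, "n_removed"),
           rejected_trim = attr(t, "n_rejected"),
           removed_length = attr(l, "n_removed"),
           no_adapter = if (nrow(l)) sum(!l$adapter_found) else 0L,
           tags_out = nrow(tags),
           reads_out = sum(tags$count))
  stopifnot(log[["reads_in"]] == log[["removed_quality"]] +
              log[["rejected_trim"]] + log[["removed_length"]] +
              log[["reads_out"]])
  list(tags = tags, log = log)
}
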