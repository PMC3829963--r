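# Per-miRNA abundance: low-count tag filter, isomiR aggregation under the
# dominant-isomiR and sum-of-isomiRs estimators, RPM normalization, and
# the mapped-read length histogram.

#' Discard low-count tags
#'
#' Tags seen fewer than `min_count` times in a library (singletons by
#' default) are discarded before expression is calculated; they are
#' dominated by sequencing error.
#'
#' @param tags ReadTag table (sequence, count, library_id).
#' @param min_count minimum per-library count to keep a tag.
#' @return the surviving tags, attribute `n_removed`.
#' @export
filter_low_count <- function(tags, min_count = 2) {
  keep <- tags$count >= min_count
  out <- tags[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Aggregate isomiR hits into per-miRNA expression records
#'
#' For each mature miRNA: `sum_count` is the summed (assigned) count over
#' all accepted isomiR tags and `dominant_count` the count of the single
#' most abundant isomiR — ties broken toward the most canonical tag
#' (smallest |offset5| + |offset3|), then lexicographically by sequence,
#' so the choice is deterministic.
#'
#' @param hits resolved hit table from [match_tags()].
#' @param library_id optional label stamped on the records (default taken
#'   from the hits).
#' @return ExpressionRecord data frame: mature_id, library_id,
#'   dominant_count, sum_count, n_isomirs.
#' @export
aggregate_isomirs <- function(hits, library_id = NULL) {
  if (nrow(hits) == 0)
    return(data.frame(mature_id = character(0), library_id = character(0),
                      dominant_count = numeric(0), sum_count = numeric(0),
                      n_isomirs = integer(0), stringsAsFactors = FALSE))
  library_id <- library_id %||% hits$library_id[1]
  h <- hits
  h$absoff <- abs(h$offset5) + abs(h$offset3)
  h <- h[order(h$mature_id, -h$assigned_count, h$absoff, h$tag_sequence), ,
         drop = FALSE]
  first <- !duplicated(h$mature_id)
  out <- data.frame(
    mature_id = h$mature_id[first],
    library_id = library_id,
    dominant_count = h$assigned_count[first],
    sum_count = as.numeric(tapply(h$assigned_count, h$mature_id, sum)[
      h$mature_id[first]]),
    n_isomirs = as.integer(tapply(h$assigned_count, h$mature_id, length)[
      h$mature_id[first]]),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  stopifnot(all(out$dominant_count <= out$sum_count + 1e-9))
  out
}

#' Normalize expression records to reads per million mapped
#'
#' Both estimators are divided by the same denominator — the total mapped
#' read count of the library — so that comparing them reflects only the
#' numerator choice.
#'
#' @param records ExpressionRecord table from [aggregate_isomirs()].
#' @param mapped_total total mapped read count of the library (each read
#'   counted once, after low-count filtering).
#' @return `records` with `dominant_rpm` and `sum_rpm` columns.
#' @export
rpm_normalize <- function(records, mapped_total) {
  if (length(mapped_total) != 1 || is.na(mapped_total) || mapped_total <= 0)
    stop("zero mapped reads for library ",
         paste(unique(records$library_id), collapse = ","), call. = FALSE)
  records$dominant_rpm <- records$dominant_count * 1e6 / mapped_total
  records$sum_rpm <- records$sum_count * 1e6 / mapped_total
  records
}

#' Length histogram of mapped reads
#'
#' @param hits resolved hit table from [match_tags()].
#' @return data frame (length, reads) over mapped tags (each tag's reads
#'   counted once, whatever it multi-maps to), with attribute `mode`, the
#'   modal read length.
#' @export
length_histogram <- function(hits) {
  u <- hits[!duplicated(hits$tag_sequence), , drop = FALSE]
  if (nrow(u) == 0) {
    out <- data.frame(length = integer(0), reads = numeric(0))
    attr(out, "mode") <- NA_integer_
    return(out)
  }
  tab <- tapply(u$count, nchar(u$tag_sequence), sum)
  out <- data.frame(length = as.integer(names(tab)),
                    reads = as.numeric(tab))
  out <- out[order(out$length), ]
  rownames(out) <- NULL
  attr(out, "mode") <- out$length[which.max(out$reads)]
  out
}

#' Quantify one library against a precursor set
#'
#' Applies the low-count filter, matches the surviving tags, aggregates
#' isomiRs under both estimators and RPM-normalizes with the library's
#' mapped-read total (reads of mapped tags, each counted once).
#'
#' @param tags ReadTag table from preprocessing.
#' @param ps a `precursor_set`.
#' @param min_count low-count floor (reads with tag count below it are
#'   discarded before expression is calculated).
#' @param max_mismatch,window,policy matching parameters, see
#'   [match_tags()].
#' @return list: `records` (normalized ExpressionRecord table), `hits`,
#'   `histogram`, `mapped_total`, `log` (tag/read accounting).
#' @export
quantify_library <- function(tags, ps, min_count = 2, max_mismatch = 1,
                             window = 4,
                             policy = c("all", "fractional",
                                        "unique-only")) {
  policy <- match.arg(policy)
  kept <- filter_low_count(tags, min_count)
  hits <- match_tags(kept, ps, max_mismatch, window, policy)
  mapped_total <- sum(hits$count[!duplicated(hits$tag_sequence)])
  records <- aggregate_isomirs(hits)
  records <- rpm_normalize(records, mapped_total)
  list(records = records, hits = hits,
       histogram = length_histogram(hits),
       mapped_total = mapped_total,
       log = c(tags_in = nrow(tags),
               tags_low_count = attr(kept, "n_removed"),
               tags_mapped = length(unique(hits$tag_sequence)),
               reads_mapped = mapped_total))
}
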