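# Tag-to-precursor matching: exhaustive ungapped placement with at most
# one mismatch, isomiR acceptance within +/- 4 nt of an annotated mature
# terminus, and multi-mapping resolution.

#' Exhaustively scan a tag against a precursor
#'
#' Returns every ungapped placement of the tag on the precursor with at
#' most `max_mismatch` Hamming mismatches (no indels), equivalent to a
#' brute-force sliding window.
#'
#' @param tag tag sequence (DNA).
#' @param precursor precursor sequence (DNA) or a single-row slice of a
#'   `precursor_set` precursor table.
#' @param max_mismatch mismatch budget per placement.
#' @return data frame with `start` (0-based) and `mismatches`; empty when
#'   the tag is longer than the precursor.
#' @export
scan_precursor <- function(tag, precursor, max_mismatch = 1) {
  pseq <- if (is.data.frame(precursor)) precursor$sequence else precursor
  stopifnot(length(tag) == 1, length(pseq) == 1)
  hits <- .hamming_scan_all(normalize_dna(tag), normalize_dna(pseq),
                            as.integer(max_mismatch))
  data.frame(start = hits$start, mismatches = hits$mismatches)
}

#' Classify a placement as an isomiR of an annotated mature
#'
#' A placement is accepted for a mature miRNA when both termini fall
#' within the acceptance window: `offset5` (tag 5' end minus mature 5'
#' end) and `offset3` (tag 3' end minus mature 3' end) each in
#' `[-window, +window]` nt. Placements overlapping no mature within the
#' window are rejected.
#'
#' @param start 0-based placement start on the precursor.
#' @param tag_len tag length (nt).
#' @param mismatches mismatch count of the placement.
#' @param matures mature annotation table of that precursor (columns
#'   mature_id, arm, p_start, p_end).
#' @param window terminal offset window (nt).
#' @return data frame of accepted hits (mature_id, arm, offset5, offset3,
#'   mismatches), zero rows if rejected.
#' @export
classify_isomir <- function(start, tag_len, mismatches, matures,
                            window = 4) {
  off5 <- start - matures$p_start
  off3 <- (start + tag_len) - matures$p_end
  ok <- abs(off5) <= window & abs(off3) <= window
  data.frame(mature_id = matures$mature_id[ok], arm = matures$arm[ok],
             offset5 = off5[ok], offset3 = off3[ok],
             mismatches = rep_len(mismatches, sum(ok)),
             stringsAsFactors = FALSE)
}

#' Resolve tags hitting several mature miRNAs
#'
#' Within one precursor only the best placement survives upstream; here
#' tags that hit distinct matures (typically identical paralogs) are
#' resolved. Policy `"all"` attributes the full tag count to every mature
#' hit (paralogs share counts); `"fractional"` splits the count equally;
#' `"unique-only"` discards multi-mapping tags.
#'
#' @param hits classified hit table (one row per tag x mature) with
#'   columns tag_sequence and count.
#' @param policy multi-mapping policy.
#' @return `hits` with `n_matches` and `assigned_count` columns
#'   (unique-only: multi-mapping rows dropped).
#' @export
resolve_multimap <- function(hits, policy = c("all", "fractional",
                                              "unique-only")) {
  policy <- match.arg(policy)
  nm <- stats::ave(seq_len(nrow(hits)), hits$tag_sequence,
                   FUN = length)
  hits$n_matches <- as.integer(nm)
  hits$assigned_count <- switch(policy,
    "all" = as.numeric(hits$count),
    "fractional" = hits$count / hits$n_matches,
    "unique-only" = as.numeric(hits$count))
  if (policy == "unique-only") hits <- hits[hits$n_matches == 1, ,
                                            drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Match a tag table against a precursor set
#'
#' For every tag: scan all precursors exhaustively, classify placements
#' against the annotated matures, keep per precursor the single best
#' accepted placement (fewest mismatches, then smallest
#' |offset5| + |offset3|, then 5'-most), and resolve multi-mapping across
#' precursors.
#'
#' @param tags ReadTag table from [collapse_tags()] (sequence, count,
#'   library_id).
#' @param ps a `precursor_set`.
#' @param max_mismatch mismatch budget (default 1).
#' @param window terminal offset window (default 4 nt).
#' @param policy multi-mapping policy, see [resolve_multimap()].
#' @return hit table: tag_sequence, count, library_id, precursor_id,
#'   mature_id, arm, offset5, offset3, mismatches, n_matches,
#'   assigned_count.
#' @export
match_tags <- function(tags, ps, max_mismatch = 1, window = 4,
                       policy = c("all", "fractional", "unique-only")) {
  policy <- match.arg(policy)
  empty <- data.frame(tag_sequence = character(0), count = numeric(0),
                      library_id = character(0),
                      precursor_id = character(0),
                      mature_id = character(0), arm = character(0),
                      offset5 = integer(0), offset3 = integer(0),
                      mismatches = integer(0), n_matches = integer(0),
                      assigned_count = numeric(0), stringsAsFactors = FALSE)
  if (nrow(tags) == 0) return(empty)

  pl <- .hamming_scan_all(tags$sequence, ps$precursors$sequence,
                          as.integer(max_mismatch))
  if (nrow(pl) == 0) return(empty)
  pl$precursor_id <- ps$precursors$id[pl$prec_idx]
  pl$tag_len <- nchar(tags$sequence)[pl$tag_idx]

  # expand placements against the mature annotations of their precursor
  h <- merge(pl, ps$matures, by = "precursor_id")
  h$offset5 <- h$start - h$p_start
  h$offset3 <- (h$start + h$tag_len) - h$p_end
  h <- h[abs(h$offset5) <= window & abs(h$offset3) <= window, ,
         drop = FALSE]
  if (nrow(h) == 0) return(empty)

  # best placement per tag x precursor
  h$absoff <- abs(h$offset5) + abs(h$offset3)
  h <- h[order(h$tag_idx, h$precursor_id, h$mismatches, h$absoff,
               h$start), , drop = FALSE]
  h <- h[!duplicated(h[, c("tag_idx", "precursor_id")]), , drop = FALSE]

  hits <- data.frame(tag_sequence = tags$sequence[h$tag_idx],
                     count = as.numeric(tags$count[h$tag_idx]),
                     library_id = tags$library_id[h$tag_idx],
                     precursor_id = h$precursor_id,
                     mature_id = h$mature_id, arm = h$arm,
                     offset5 = h$offset5, offset3 = h$offset3,
                     mismatches = h$mismatches, stringsAsFactors = FALSE)
  resolve_multimap(hits, policy)
}
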