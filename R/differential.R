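# Two-condition comparison: per-miRNA log2 fold change under both
# estimators, classification at a strict cutoff, and the
# estimator-comparison report.

#' Log2 fold change between two RPM values
#'
#' `log2((rpm_case + pseudocount) / (rpm_control + pseudocount))`.
#' Vectorized; antisymmetric in its two RPM arguments.
#'
#' @param rpm_case,rpm_control non-negative RPM values.
#' @param pseudocount added to both numerator and denominator; needed
#'   when a miRNA is undetected in one condition.
#' @return numeric log2 ratio(s).
#' @export
log2fc <- function(rpm_case, rpm_control, pseudocount = 0) {
  if (any(pseudocount == 0 & rpm_case == 0 & rpm_control == 0))
    stop("log2fc undefined: both inputs zero with pseudocount 0",
         call. = FALSE)
  log2((rpm_case + pseudocount) / (rpm_control + pseudocount))
}

#' Classify a log2 fold change
#'
#' Strict inequalities: `fc > threshold` is "up", `fc < -threshold` is
#' "down", anything else (including exactly the threshold) "unchanged".
#' The default threshold of 2 on the log2 scale (a 4-fold change) follows
#' the stricter of the two cutoffs in common use; set `threshold = 1` for
#' a plain 2-fold cutoff.
#'
#' @param fc log2 fold change(s).
#' @param threshold positive cutoff on the log2 scale.
#' @return character vector: "up", "down" or "unchanged".
#' @export
classify_fc <- function(fc, threshold = 2) {
  ifelse(fc > threshold, "up", ifelse(fc < -threshold, "down", "unchanged"))
}

#' Differential expression table between two libraries
#'
#' Joins the two conditions' expression records, computes log2 fold
#' changes under both estimators with a shared pseudocount, and
#' classifies each miRNA on the configured estimator. miRNAs undetected
#' in both conditions never enter the table; miRNAs undetected in one
#' are zero-filled on that side and rescued by the pseudocount.
#'
#' @param records_case,records_control RPM-normalized ExpressionRecord
#'   tables for the case (numerator) and control (denominator) libraries.
#' @param pseudocount RPM pseudocount (default 0.5).
#' @param threshold classification cutoff on the log2 scale (default 2).
#' @param estimator which estimator drives the up/down call.
#' @return DifferentialRecord data frame: mature_id, rpm columns per
#'   condition, log2fc_dominant, log2fc_sum, estimator_divergence,
#'   status.
#' @export
differential_table <- function(records_case, records_control,
                               pseudocount = 0.5, threshold = 2,
                               estimator = c("sum", "dominant")) {
  estimator <- match.arg(estimator)
  keep <- c("mature_id", "dominant_rpm", "sum_rpm")
  j <- merge(records_case[, keep], records_control[, keep],
             by = "mature_id", all = TRUE,
             suffixes = c("_case", "_control"))
  for (col in setdiff(names(j), "mature_id")) j[[col]][is.na(j[[col]])] <- 0

  out <- data.frame(
    mature_id = j$mature_id,
    dominant_rpm_case = j$dominant_rpm_case,
    dominant_rpm_control = j$dominant_rpm_control,
    sum_rpm_case = j$sum_rpm_case,
    sum_rpm_control = j$sum_rpm_control,
    log2fc_dominant = log2fc(j$dominant_rpm_case, j$dominant_rpm_control,
                             pseudocount),
    log2fc_sum = log2fc(j$sum_rpm_case, j$sum_rpm_control, pseudocount),
    stringsAsFactors = FALSE)
  out$estimator_divergence <- abs(out$log2fc_dominant - out$log2fc_sum)
  drive <- if (estimator == "sum") out$log2fc_sum else out$log2fc_dominant
  out$status <- classify_fc(drive, threshold)
  out[order(-abs(out$log2fc_sum)), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Estimator-comparison report and ranked top lists
#'
#' Emits, per miRNA, both estimators' log2 fold change and their
#' divergence (sorted by |log2fc_sum|), plus the top-N up- and
#' down-regulated miRNAs ranked on the driving estimator.
#'
#' @param diff a [differential_table()].
#' @param top_n list length for the ranked up/down tables.
#' @param estimator ranking estimator.
#' @return list: `comparison`, `top_up`, `top_down`.
#' @export
compare_estimators <- function(diff, top_n = 10,
                               estimator = c("sum", "dominant")) {
  estimator <- match.arg(estimator)
  fc <- if (estimator == "sum") diff$log2fc_sum else diff$log2fc_dominant
  comparison <- diff[order(-abs(diff$log2fc_sum)),
                     c("mature_id", "log2fc_dominant", "log2fc_sum",
                       "estimator_divergence", "status")]
  rownames(comparison) <- NULL
  up <- diff[order(-fc), ][fc[order(-fc)] > 0, , drop = FALSE]
  down <- diff[order(fc), ][fc[order(fc)] < 0, , drop = FALSE]
  list(comparison = comparison,
       top_up = head(up, top_n),
       top_down = head(down, top_n))
}

#' Sensitivity of the up/down calls to the fold-change cutoff
#'
#' The cutoff for "differentially expressed" is sometimes stated on the
#' log2 scale (|log2 FC| > 2, i.e. 4-fold) and sometimes as a plain
#' 2-fold difference (|log2 FC| > 1); this reports the calls under each
#' candidate threshold side by side.
#'
#' @param diff a [differential_table()].
#' @param thresholds log2-scale cutoffs to compare.
#' @param estimator which estimator drives the calls.
#' @return data frame: threshold, n_up, n_down, n_unchanged.
#' @export
threshold_sensitivity <- function(diff, thresholds = c(2, 1),
                                  estimator = c("sum", "dominant")) {
  estimator <- match.arg(estimator)
  fc <- if (estimator == "sum") diff$log2fc_sum else diff$log2fc_dominant
  do.call(rbind, lapply(thresholds, function(th) {
    s <- classify_fc(fc, th)
    data.frame(threshold = th, n_up = sum(s == "up"),
               n_down = sum(s == "down"),
               n_unchanged = sum(s == "unchanged"))
  }))
}
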