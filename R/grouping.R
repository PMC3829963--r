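# miRNA gene clusters (genomic proximity) and gene families (shared seed
# or an explicit map), with a sign-concordance statistic for within-group
# dysregulation.

#' Build miRNA gene clusters by genomic proximity
#'
#' Single-linkage chaining of precursor loci on the same chromosome and
#' strand whose inter-locus gap is at most `max_gap` (default 10 kb, the
#' prevailing miRNA-cluster window). Singletons are not clusters.
#'
#' @param ps a `precursor_set` with genomic coordinates.
#' @param max_gap maximum gap (bp) between chained loci.
#' @return data frame (group_id, precursor_id) covering clustered
#'   precursors only.
#' @export
build_clusters <- function(ps, max_gap = 10000) {
  p <- ps$precursors
  gr <- GenomicRanges::GRanges(p$chrom,
                               IRanges::IRanges(p$start + 1L, p$end),
                               strand = p$strand)
  red <- GenomicRanges::reduce(gr, min.gapwidth = max_gap + 1L,
                               with.revmap = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  keep <- lengths(revmap) >= 2
  if (!any(keep))
    return(data.frame(group_id = character(0), precursor_id = character(0),
                      stringsAsFactors = FALSE))
  members <- revmap[keep]
  data.frame(group_id = rep(sprintf("cluster_%d", seq_along(members)),
                            lengths(members)),
             precursor_id = p$id[unlist(members)],
             stringsAsFactors = FALSE)
}

#' Build miRNA gene families
#'
#' When an explicit family map (two columns: family_id, mature_id) is
#' supplied it is used as-is; otherwise matures sharing an identical seed
#' (positions 2-8 of the mature sequence) are grouped, and only groups of
#' two or more are reported.
#'
#' @param ps a `precursor_set`.
#' @param family_map optional data frame (family_id, mature_id);
#'   overrides the seed rule.
#' @return data frame (group_id, mature_id).
#' @export
build_families <- function(ps, family_map = NULL) {
  if (!is.null(family_map)) {
    stopifnot(all(c("family_id", "mature_id") %in% names(family_map)))
    return(data.frame(group_id = family_map$family_id,
                      mature_id = family_map$mature_id,
                      stringsAsFactors = FALSE))
  }
  mseq <- mature_sequences(ps)
  seed <- substr(mseq, 2, 8)
  tab <- split(names(mseq), seed)
  tab <- tab[lengths(tab) >= 2]
  if (length(tab) == 0)
    return(data.frame(group_id = character(0), mature_id = character(0),
                      stringsAsFactors = FALSE))
  data.frame(group_id = rep(sprintf("family_%d", seq_along(tab)),
                            lengths(tab)),
             mature_id = unlist(tab, use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Sign concordance of a group's fold changes
#'
#' Fraction of detected members whose log2 fold-change sign matches the
#' majority sign; an exact up/down tie scores 0.5. Members with fold
#' change exactly zero vote for neither sign but stay in the denominator.
#'
#' @param fcs numeric log2 fold changes of the detected group members
#'   (length >= 2).
#' @return concordance in `[0, 1]`.
#' @export
concordance <- function(fcs) {
  stopifnot(length(fcs) >= 2)
  n_pos <- sum(fcs > 0)
  n_neg <- sum(fcs < 0)
  if (n_pos == n_neg) return(0.5)
  max(n_pos, n_neg) / length(fcs)
}

#' Per-group dysregulation report
#'
#' Joins cluster/family membership with the differential table and
#' scores, per group with at least two detected members, the sign
#' concordance and the expression span (log2 ratio of the largest to the
#' smallest member `sum_rpm`, averaged over the two conditions) — groups
#' can span orders of magnitude in abundance yet still move in the same
#' direction.
#'
#' @param clusters [build_clusters()] output (mapped to matures via the
#'   precursor annotations).
#' @param families [build_families()] output.
#' @param ps a `precursor_set`.
#' @param diff a [differential_table()].
#' @return data frame: group_id, kind, n_members, n_detected,
#'   concordance, expression_span, member_ids, member_log2fc.
#' @export
group_report <- function(clusters, families, ps, diff) {
  cl_m <- merge(clusters, ps$matures[, c("mature_id", "precursor_id")],
                by = "precursor_id")[, c("group_id", "mature_id")]
  groups <- rbind(cbind(cl_m, kind = "cluster"),
                  cbind(families, kind = "family"))
  if (nrow(groups) == 0)
    return(data.frame(group_id = character(0), kind = character(0),
                      n_members = integer(0), n_detected = integer(0),
                      concordance = numeric(0),
                      expression_span = numeric(0),
                      member_ids = character(0),
                      member_log2fc = character(0),
                      stringsAsFactors = FALSE))
  out <- lapply(split(groups, list(groups$kind, groups$group_id),
                      drop = TRUE), function(g) {
    d <- diff[diff$mature_id %in% g$mature_id, , drop = FALSE]
    mean_rpm <- (d$sum_rpm_case + d$sum_rpm_control) / 2
    detected <- nrow(d)
    conc <- if (detected >= 2) concordance(d$log2fc_sum) else NA_real_
    span <- if (detected >= 2 && min(mean_rpm) > 0)
      log2(max(mean_rpm) / min(mean_rpm)) else NA_real_
    data.frame(group_id = g$group_id[1], kind = g$kind[1],
               n_members = nrow(g), n_detected = detected,
               concordance = conc, expression_span = span,
               member_ids = paste(g$mature_id, collapse = ";"),
               member_log2fc = paste(
                 sprintf("%s=%.3f", d$mature_id, d$log2fc_sum),
                 collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$kind, out$group_id), , drop = FALSE]
}
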