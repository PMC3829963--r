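# End-to-end orchestration: simulate an experiment to disk, run the full
# two-condition analysis, and write every result table as TSV.

#' Pipeline configuration
#'
#' Collects the input paths and every tunable of the analysis stages.
#' Paths are validated when the pipeline runs, before any computation.
#'
#' @param precursor_fasta precursor hairpin FASTA.
#' @param mature_gff3,mature_fasta mature annotations (exactly one).
#' @param fastq named character vector of FASTQ paths, names are library
#'   ids; exactly two libraries, case first.
#' @param case,control library ids of the numerator and denominator
#'   conditions (default: first and second FASTQ).
#' @param family_map optional two-column family table path (family_id,
#'   mature_id).
#' @param target_table optional validated miRNA-target table path.
#' @param gmt optional GMT pathway file path.
#' @param background optional background gene vector for enrichment
#'   (default: all genes in the target table).
#' @param min_mean_q,adapter3,min_overlap,max_mismatch_rate,min_len
#'   preprocessing tunables.
#' @param min_count,max_mismatch,window,policy quantification tunables.
#' @param pseudocount,fc_threshold,estimator,top_n differential tunables.
#' @param cluster_max_gap clustering gap (bp).
#' @param out_dir where result tables are written (created if needed).
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(precursor_fasta, mature_gff3 = NULL,
                            mature_fasta = NULL, fastq,
                            case = names(fastq)[1],
                            control = names(fastq)[2],
                            family_map = NULL, target_table = NULL,
                            gmt = NULL, background = NULL,
                            min_mean_q = 20,
                            adapter3 = "TCGTATGCCGTCTTCTGCTTG",
                            min_overlap = 6, max_mismatch_rate = 0.1,
                            min_len = 15, min_count = 2,
                            max_mismatch = 1, window = 4, policy = "all",
                            pseudocount = 0.5, fc_threshold = 2,
                            estimator = "sum", top_n = 10,
                            cluster_max_gap = 10000,
                            out_dir = tempfile("isomirquant_")) {
  stopifnot(length(fastq) == 2, !is.null(names(fastq)),
            all(nzchar(names(fastq))))
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(config) {
  paths <- c(config$precursor_fasta, config$mature_gff3,
             config$mature_fasta, config$fastq, config$family_map,
             config$target_table, config$gmt)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  stopifnot(config$fc_threshold > 0, config$pseudocount >= 0,
            config$min_len >= 1, config$window >= 0)
  invisible(config)
}

#' Simulate a two-condition experiment to disk
#'
#' Writes, under `out_dir`: precursor FASTA + mature GFF3, one FASTQ per
#' condition, the expression-profile truth table, per-read origin tables,
#' and a manifest recording the seed and every generator parameter.
#' Byte-identical across reruns with the same config.
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory.
#' @param conditions length-2 labels, case first.
#' @param coherent_groups passed to [make_profile()].
#' @return (invisibly) list of paths, plus the in-memory `precursor_set`
#'   and truth tables.
#' @export
simulate_experiment <- function(cfg, out_dir,
                                conditions = c("obob", "WT"),
                                coherent_groups = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ps <- make_precursors(cfg)
  truth <- make_profile(ps, cfg, conditions, coherent_groups)
  paths <- list(fasta = file.path(out_dir, "precursors.fa"),
                gff3 = file.path(out_dir, "matures.gff3"),
                truth = file.path(out_dir, "truth_profile.tsv"),
                manifest = file.path(out_dir, "manifest.tsv"))
  write_precursor_set(ps, paths$fasta, paths$gff3)
  write_tsv(truth, paths$truth)
  libs <- list()
  for (cond in conditions) {
    lib <- simulate_library(ps, truth, cond, cfg)
    fq <- file.path(out_dir, paste0(cond, ".fastq"))
    rt <- file.path(out_dir, paste0(cond, "_read_truth.tsv"))
    write_fastq(lib$reads, fq)
    write_tsv(lib$read_truth, rt)
    paths[[paste0("fastq_", cond)]] <- fq
    paths[[paste0("read_truth_", cond)]] <- rt
    libs[[cond]] <- lib
  }
  flat <- vapply(cfg, function(x) paste(x, collapse = ","), character(1))
  write_tsv(data.frame(key = names(flat), value = unname(flat)),
            paths$manifest)
  invisible(list(paths = paths, precursors = ps, truth = truth,
                 libraries = libs))
}

#' Run the full two-condition analysis
#'
#' Preprocess each library, quantify against the precursor set under
#' both estimators, compute the differential table and ranked lists, the
#' cluster/family concordance report, and (when a target table and GMT
#' are configured) the hypergeometric enrichment of the differential
#' miRNAs' validated targets. All tables are written as TSV under
#' `config$out_dir`; stage read counts are logged and conserved.
#'
#' @param config a [pipeline_config()].
#' @return list with every result object: `precursors`, `preprocess`
#'   (per-library logs), `tags`, `quant` (per-library), `expression`
#'   (combined table), `histograms`, `diff`, `report` (estimator
#'   comparison + top lists), `sensitivity`, `groups`, `enrichment`
#'   (NULL when not configured), `paths`.
#' @export
run_pipeline <- function(config) {
  validate_pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  ps <- read_precursor_set(config$precursor_fasta,
                           mature_gff3 = config$mature_gff3,
                           mature_fasta = config$mature_fasta)

  pre <- list(); quant <- list(); tags <- list(); hist <- list()
  for (lib in names(config$fastq)) {
    p <- preprocess_library(config$fastq[[lib]], lib,
                            min_mean_q = config$min_mean_q,
                            adapter3 = config$adapter3,
                            min_overlap = config$min_overlap,
                            max_mismatch_rate = config$max_mismatch_rate,
                            min_len = config$min_len)
    q <- quantify_library(p$tags, ps, min_count = config$min_count,
                          max_mismatch = config$max_mismatch,
                          window = config$window, policy = config$policy)
    pre[[lib]] <- p$log
    tags[[lib]] <- p$tags
    quant[[lib]] <- q
    hist[[lib]] <- q$histogram
  }

  expression <- do.call(rbind, lapply(quant, `[[`, "records"))
  rownames(expression) <- NULL
  diff <- differential_table(quant[[config$case]]$records,
                             quant[[config$control]]$records,
                             pseudocount = config$pseudocount,
                             threshold = config$fc_threshold,
                             estimator = config$estimator)
  report <- compare_estimators(diff, top_n = config$top_n,
                               estimator = config$estimator)
  sensitivity <- threshold_sensitivity(diff,
                                       estimator = config$estimator)

  clusters <- build_clusters(ps, config$cluster_max_gap)
  fam_map <- if (!is.null(config$family_map))
    read_tsv(config$family_map) else NULL
  families <- build_families(ps, fam_map)
  groups <- group_report(clusters, families, ps, diff)

  enr <- NULL
  if (!is.null(config$target_table) && !is.null(config$gmt)) {
    targets <- read_target_table(config$target_table)
    de_ids <- diff$mature_id[diff$status != "unchanged"]
    query <- map_targets(de_ids, targets)
    bg <- config$background %||% unique(targets$gene)
    enr <- list(query = query,
                table = hypergeom_enrich(query$gene, read_gmt(config$gmt),
                                         bg))
  }

  paths <- write_pipeline_outputs(config$out_dir, pre, tags, expression,
                                  hist, diff, report, sensitivity,
                                  groups, enr)
  list(precursors = ps, preprocess = pre, tags = tags, quant = quant,
       expression = expression, histograms = hist, diff = diff,
       report = report, sensitivity = sensitivity, groups = groups,
       enrichment = enr, paths = paths)
}

write_pipeline_outputs <- function(out_dir, pre, tags, expression, hist,
                                   diff, report, sensitivity, groups,
                                   enr) {
  paths <- character(0)
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    write_tsv(df, p)
    paths[[name]] <<- p
  }
  prelog <- do.call(rbind, lapply(names(pre), function(l)
    data.frame(library_id = l, stage = names(pre[[l]]),
               reads = as.numeric(pre[[l]]), stringsAsFactors = FALSE)))
  emit(prelog, "preprocess_log.tsv")
  emit(do.call(rbind, tags), "tags.tsv")
  emit(expression, "expression.tsv")
  histdf <- do.call(rbind, lapply(names(hist), function(l)
    cbind(library_id = l, hist[[l]])))
  emit(histdf, "length_histogram.tsv")
  emit(diff, "differential.tsv")
  emit(report$comparison, "estimator_comparison.tsv")
  emit(report$top_up, "top_up.tsv")
  emit(report$top_down, "top_down.tsv")
  emit(sensitivity, "threshold_sensitivity.tsv")
  emit(groups, "group_report.tsv")
  if (!is.null(enr)) {
    emit(enr$query, "target_genes.tsv")
    emit(enr$table, "enrichment.tsv")
  }
  paths
}
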