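#' Configuration for the synthetic small RNA-seq world
#'
#' Defines the generative model the rest of the package is exercised
#' against: a set of hairpin precursors (some in genomic clusters, some in
#' seed families), a skewed two-condition expression profile with known
#' log2 effects, and 36-cycle single-end libraries in which each read is a
#' mature miRNA isomiR (imprecise Drosha/Dicer cleavage is modelled as
#' independent 5' and 3' end offsets), plus 3' adapter read-through,
#' per-base substitution error, and a small fraction of low-quality reads.
#'
#' @param n_precursors number of hairpin precursors.
#' @param n_clusters number of genomic clusters (each of `cluster_size`
#'   precursors placed on one chromosome with inter-locus gaps at most
#'   `cluster_span`).
#' @param cluster_size precursors per cluster (>= 2).
#' @param cluster_span maximum gap (bp) between adjacent cluster members.
#' @param n_families number of seed families; members share mature
#'   positions 2-8.
#' @param family_size matures per family.
#' @param mature_len_range inclusive range (nt) of mature lengths.
#' @param both_arms_prob probability that a precursor carries annotated
#'   matures on both arms (else one arm at random).
#' @param read_len sequencing read length (cycles); default 36.
#' @param adapter3 3' adapter sequence appended after the insert.
#' @param error_rate per-base substitution error probability in `[0, 1)`.
#' @param cleavage_offset_probs named numeric vector mapping integer end
#'   offsets (nt, within -6..+6) to probabilities summing to 1; 5' and 3'
#'   offsets are drawn independently from it.
#' @param lib_depth reads per library.
#' @param frac_de fraction of mature miRNAs differentially expressed.
#' @param effect_log2 true |log2 fold change| for DE miRNAs (> 0).
#' @param low_quality_frac fraction of reads emitted with uniformly low
#'   base qualities (Q2) to exercise the quality filter.
#' @param abundance_sdlog sdlog of the log-normal draw for baseline
#'   abundance (miRNA libraries are strongly skewed; 2 gives a realistic
#'   several-order-of-magnitude dynamic range).
#' @param seed integer seed; all generator stages derive their streams
#'   from it, so a fixed config is byte-reproducible.
#'
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_precursors = 50,
                       n_clusters = 4,
                       cluster_size = 2,
                       cluster_span = 10000,
                       n_families = 4,
                       family_size = 3,
                       mature_len_range = c(20L, 24L),
                       both_arms_prob = 0.6,
                       read_len = 36L,
                       adapter3 = "TCGTATGCCGTCTTCTGCTTG",
                       error_rate = 0.005,
                       cleavage_offset_probs = c(`0` = 0.6, `1` = 0.15,
                                                 `-1` = 0.15, `2` = 0.05,
                                                 `-2` = 0.05),
                       lib_depth = 1e5,
                       frac_de = 0.2,
                       effect_log2 = 3,
                       low_quality_frac = 0.01,
                       abundance_sdlog = 2,
                       seed = 1L) {
  cfg <- list(n_precursors = as.integer(n_precursors),
              n_clusters = as.integer(n_clusters),
              cluster_size = as.integer(cluster_size),
              cluster_span = as.integer(cluster_span),
              n_families = as.integer(n_families),
              family_size = as.integer(family_size),
              mature_len_range = as.integer(mature_len_range),
              both_arms_prob = both_arms_prob,
              read_len = as.integer(read_len),
              adapter3 = normalize_dna(adapter3),
              error_rate = error_rate,
              cleavage_offset_probs = cleavage_offset_probs,
              lib_depth = as.integer(lib_depth),
              frac_de = frac_de,
              effect_log2 = effect_log2,
              low_quality_frac = low_quality_frac,
              abundance_sdlog = abundance_sdlog,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_precursors >= 1, cfg$read_len >= 15,
            length(cfg$mature_len_range) == 2,
            cfg$mature_len_range[1] <= cfg$mature_len_range[2])
  if (cfg$error_rate < 0 || cfg$error_rate >= 1)
    stop("error_rate must lie in [0, 1)", call. = FALSE)
  if (cfg$effect_log2 <= 0)
    stop("effect_log2 must be > 0", call. = FALSE)
  if (cfg$frac_de < 0 || cfg$frac_de > 1)
    stop("frac_de must lie in [0, 1]", call. = FALSE)
  p <- cfg$cleavage_offset_probs
  offs <- suppressWarnings(as.integer(names(p)))
  if (anyNA(offs) || any(abs(offs) > 6))
    stop("cleavage_offset_probs names must be integer offsets in -6..+6",
         call. = FALSE)
  if (abs(sum(p) - 1) > 1e-9)
    stop("cleavage_offset_probs must sum to 1", call. = FALSE)
  if (cfg$n_precursors < cfg$n_clusters)
    stop("invalid config: n_precursors < n_clusters", call. = FALSE)
  if (cfg$n_clusters > 0 &&
      cfg$n_precursors < cfg$n_clusters * cfg$cluster_size)
    stop("invalid config: not enough precursors for the requested clusters",
         call. = FALSE)
  invisible(cfg)
}

#' Generate a synthetic precursor set
#'
#' Builds hairpins of the form 5' flank + 5p mature + loop + 3p mature +
#' 3' flank, annotates one or both arms, places cluster members on shared
#' chromosomes with bounded gaps, and forces family members to share an
#' identical seed (mature positions 2-8). Deterministic for a fixed seed.
#'
#' @param cfg a [sim_config()].
#' @return a `precursor_set`: list with data frames `precursors`
#'   (id, chrom, start, end, strand, sequence, cluster_id; genomic
#'   coordinates 0-based half-open) and `matures` (mature_id,
#'   precursor_id, arm, p_start, p_end, family_id; precursor coordinates
#'   0-based half-open).
#' @export
make_precursors <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  n <- cfg$n_precursors
  lenr <- cfg$mature_len_range

  flank5 <- sample(8:12, n, replace = TRUE)
  len5   <- sample_vec(lenr[1]:lenr[2], n, replace = TRUE)
  loop   <- sample(10:16, n, replace = TRUE)
  len3   <- sample_vec(lenr[1]:lenr[2], n, replace = TRUE)
  flank3 <- sample(8:12, n, replace = TRUE)
  total  <- flank5 + len5 + loop + len3 + flank3
  seqs   <- random_dna(total)

  prec_id <- sprintf("syn-mir-%d", seq_len(n))
  p5_start <- flank5                 # 0-based half-open on the hairpin
  p5_end   <- flank5 + len5
  p3_start <- flank5 + len5 + loop
  p3_end   <- p3_start + len3

  # which arms carry an annotated mature
  both <- runif(n) < cfg$both_arms_prob
  lone_arm <- ifelse(runif(n) < 0.5, "5p", "3p")

  matures <- do.call(rbind, lapply(seq_len(n), function(i) {
    arms <- if (both[i]) c("5p", "3p") else lone_arm[i]
    data.frame(mature_id = sprintf("%s-%s", prec_id[i], arms),
               precursor_id = prec_id[i],
               arm = arms,
               p_start = ifelse(arms == "5p", p5_start[i], p3_start[i]),
               p_end = ifelse(arms == "5p", p5_end[i], p3_end[i]),
               family_id = NA_character_,
               stringsAsFactors = FALSE)
  }))

  # seed families: overwrite mature positions 2-8 with a shared 7-mer
  if (cfg$n_families > 0) {
    pool <- seq_len(n)
    for (f in seq_len(cfg$n_families)) {
      if (length(pool) < cfg$family_size) break
      members <- sample(pool, cfg$family_size)
      pool <- setdiff(pool, members)
      seed7 <- random_dna(7)
      for (i in members) {
        j <- which(matures$precursor_id == prec_id[i])[1]
        s <- matures$p_start[j]
        substr(seqs[i], s + 2, s + 8) <- seed7
        matures$family_id[matures$mature_id == matures$mature_id[j]] <-
          sprintf("fam%d", f)
      }
    }
  }

  # genomic placement: cluster members chained on one chromosome,
  # the rest isolated on their own chromosomes
  chrom <- sprintf("chrU%d", seq_len(n))
  gstart <- rep(100000L, n)
  cluster_id <- rep(NA_character_, n)
  if (cfg$n_clusters > 0) {
    members <- matrix(seq_len(cfg$n_clusters * cfg$cluster_size),
                      nrow = cfg$n_clusters, byrow = TRUE)
    for (k in seq_len(cfg$n_clusters)) {
      idx <- members[k, ]
      chrom[idx] <- sprintf("chrC%d", k)
      cluster_id[idx] <- sprintf("cluster%d", k)
      pos <- 50000L
      for (i in idx) {
        gstart[i] <- pos
        gap <- sample_vec(200:cfg$cluster_span, 1)
        pos <- pos + total[i] + gap
      }
    }
  }

  precursors <- data.frame(id = prec_id, chrom = chrom, start = gstart,
                           end = gstart + total, strand = "+",
                           sequence = seqs, cluster_id = cluster_id,
                           stringsAsFactors = FALSE)
  new_precursor_set(precursors, matures)
}

new_precursor_set <- function(precursors, matures) {
  stopifnot(all(matures$precursor_id %in% precursors$id),
            all(matures$p_end - matures$p_start >= 16),
            all(matures$p_end - matures$p_start <= 28))
  structure(list(precursors = precursors, matures = matures),
            class = "precursor_set")
}

#' @export
print.precursor_set <- function(x, ...) {
  cat(sprintf("precursor_set: %d hairpins, %d mature miRNAs (%d clustered, %d in families)\n",
              nrow(x$precursors), nrow(x$matures),
              sum(!is.na(x$precursors$cluster_id)),
              sum(!is.na(x$matures$family_id))))
  invisible(x)
}

#' Mature miRNA sequences of a precursor set
#'
#' @param ps a `precursor_set`.
#' @return named character vector of mature sequences (DNA).
#' @export
mature_sequences <- function(ps) {
  seqs <- setNames(ps$precursors$sequence, ps$precursors$id)
  out <- substr(seqs[ps$matures$precursor_id],
                ps$matures$p_start + 1, ps$matures$p_end)
  setNames(unname(out), ps$matures$mature_id)
}

#' Generate a two-condition expression profile with known effects
#'
#' Baseline abundances are log-normal (heavily skewed, as in real miRNA
#' libraries). A fraction `frac_de` of matures receives a true effect of
#' `+effect_log2` (half, rounded down to the "down" side) or
#' `-effect_log2` applied to the case condition; per-condition abundances
#' are renormalized to sum to 1.
#'
#' @param ps a `precursor_set`.
#' @param cfg a [sim_config()].
#' @param conditions length-2 character vector, case first.
#' @param coherent_groups if TRUE, members of one cluster or family share
#'   DE status and direction (the co-regulation pattern the grouping
#'   module looks for); DE counts are then approximate.
#' @return data frame (one row per mature x condition): mature_id,
#'   condition, true_abundance, true_log2fc, is_de, cluster_id, family_id.
#' @export
make_profile <- function(ps, cfg, conditions = c("obob", "WT"),
                         coherent_groups = FALSE) {
  if (nrow(ps$matures) == 0) stop("precursor set has no matures")
  if (cfg$frac_de > 1) stop("invalid config: frac_de > 1", call. = FALSE)
  stopifnot(length(conditions) == 2)
  set.seed(cfg$seed + 1L)

  m <- nrow(ps$matures)
  base <- exp(rnorm(m, 0, cfg$abundance_sdlog))
  lfc <- numeric(m)
  n_de <- round(cfg$frac_de * m)
  if (n_de > 0) {
    de_idx <- sample(m, n_de)
    n_down <- floor(n_de / 2)
    lfc[de_idx] <- rep(c(-cfg$effect_log2, cfg$effect_log2),
                       c(n_down, n_de - n_down))
  }

  cluster_of <- ps$precursors$cluster_id[match(ps$matures$precursor_id,
                                               ps$precursors$id)]
  if (coherent_groups) {
    for (grp in list(cluster_of, ps$matures$family_id)) {
      for (g in unique(grp[!is.na(grp)])) {
        idx <- which(grp == g)
        de <- idx[lfc[idx] != 0]
        if (length(de) > 0) lfc[idx] <- lfc[de[1]]
      }
    }
  }

  a_control <- base / sum(base)
  a_case <- base * 2^lfc
  a_case <- a_case / sum(a_case)

  truth <- rbind(
    data.frame(mature_id = ps$matures$mature_id, condition = conditions[1],
               true_abundance = a_case, stringsAsFactors = FALSE),
    data.frame(mature_id = ps$matures$mature_id, condition = conditions[2],
               true_abundance = a_control, stringsAsFactors = FALSE))
  truth$true_log2fc <- rep(lfc, 2)
  truth$is_de <- truth$true_log2fc != 0
  truth$cluster_id <- rep(cluster_of, 2)
  truth$family_id <- rep(ps$matures$family_id, 2)
  rownames(truth) <- NULL
  truth
}

# Stable per-condition RNG stream derived from the master seed.
condition_seed <- function(seed, condition) {
  (as.integer(seed) + sum(utf8ToInt(condition)) * 131L) %% 2147483647L
}

#' Simulate one sequencing library
#'
#' Each read: sample a mature by its condition abundance; draw independent
#' 5' and 3' cleavage offsets and excise the corresponding hairpin
#' substring (out-of-bounds excisions are resampled and counted); apply
#' per-base substitution errors; append the 3' adapter and truncate to
#' `read_len`; assign uniform Q40 qualities except for a `low_quality_frac`
#' of reads emitted at Q2.
#'
#' @param ps a `precursor_set`.
#' @param truth profile from [make_profile()].
#' @param condition which condition's abundances to use.
#' @param cfg a [sim_config()].
#' @return list with `reads` (data frame: id, sequence, quality),
#'   `read_truth` (per-read origin: read_id, mature_id, offset5, offset3,
#'   n_errors, low_quality), and `n_resampled`.
#' @export
simulate_library <- function(ps, truth, condition, cfg) {
  tr <- truth[truth$condition == condition, ]
  if (nrow(tr) == 0) stop("condition not present in truth: ", condition)
  stopifnot(all(ps$matures$mature_id %in% tr$mature_id))
  set.seed(condition_seed(cfg$seed, condition))

  depth <- cfg$lib_depth
  mt <- ps$matures[match(tr$mature_id, ps$matures$mature_id), ]
  pseq <- setNames(ps$precursors$sequence, ps$precursors$id)[mt$precursor_id]
  plen <- nchar(pseq)

  midx <- sample.int(nrow(tr), depth, replace = TRUE,
                     prob = tr$true_abundance)
  offs <- as.integer(names(cfg$cleavage_offset_probs))
  opr <- cfg$cleavage_offset_probs
  off5 <- sample_vec(offs, depth, replace = TRUE, prob = opr)
  off3 <- sample_vec(offs, depth, replace = TRUE, prob = opr)

  # resample offsets whose excision leaves the hairpin (or is empty)
  n_resampled <- 0L
  repeat {
    s0 <- mt$p_start[midx] + off5
    e0 <- mt$p_end[midx] + off3
    bad <- which(s0 < 0 | e0 > plen[midx] | e0 - s0 < 1)
    if (length(bad) == 0) break
    n_resampled <- n_resampled + length(bad)
    off5[bad] <- sample_vec(offs, length(bad), replace = TRUE, prob = opr)
    off3[bad] <- sample_vec(offs, length(bad), replace = TRUE, prob = opr)
  }

  insert <- substr(pseq[midx], s0 + 1, e0)

  # per-base substitution error on the insert
  n_err <- integer(depth)
  if (cfg$error_rate > 0) {
    ilen <- nchar(insert)
    n_err <- rbinom(depth, ilen, cfg$error_rate)
    for (i in which(n_err > 0)) {
      pos <- sample.int(ilen[i], n_err[i])
      for (p in pos) {
        orig <- substr(insert[i], p, p)
        substr(insert[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                                  orig), 1)
      }
    }
  }

  # 3' adapter read-through, truncate to the read length
  full <- paste0(insert, cfg$adapter3,
                 strrep("A", max(0, cfg$read_len - min(nchar(insert)) -
                                   nchar(cfg$adapter3))))
  read_seq <- substr(full, 1, cfg$read_len)

  lowq <- runif(depth) < cfg$low_quality_frac
  qual <- strrep(ifelse(lowq, "#", "I"), nchar(read_seq))

  ids <- sprintf("r%d|%s", seq_len(depth), condition)
  list(reads = data.frame(id = ids, sequence = read_seq, quality = qual,
                          stringsAsFactors = FALSE),
       read_truth = data.frame(read_id = ids, mature_id = tr$mature_id[midx],
                               offset5 = off5, offset3 = off3,
                               n_errors = n_err, low_quality = lowq,
                               stringsAsFactors = FALSE),
       n_resampled = n_resampled)
}

#' Synthetic validated-target table and pathway sets
#'
#' Builds a random miRNA-to-target-gene map and GMT-style pathway sets
#' over a synthetic gene universe, for exercising the enrichment module
#' without external databases. Pathways are biased to draw from the
#' targets of a subset of miRNAs so that real over-representation exists.
#'
#' @param mature_ids mature miRNA identifiers.
#' @param n_genes size of the synthetic gene universe.
#' @param targets_per_mirna targets drawn per miRNA.
#' @param n_pathways number of gene sets.
#' @param pathway_size range of set sizes.
#' @param seed integer seed.
#' @return list with `targets` (data frame: mature_id, gene) and
#'   `pathways` (named list of gene vectors).
#' @export
simulate_target_sets <- function(mature_ids, n_genes = 400,
                                 targets_per_mirna = 8, n_pathways = 10,
                                 pathway_size = c(15, 40), seed = 1L) {
  set.seed(seed)
  genes <- sprintf("Gene%04d", seq_len(n_genes))
  targets <- do.call(rbind, lapply(mature_ids, function(m) {
    data.frame(mature_id = m,
               gene = sample(genes, targets_per_mirna),
               stringsAsFactors = FALSE)
  }))
  pathways <- lapply(seq_len(n_pathways), function(k) {
    sz <- sample(pathway_size[1]:pathway_size[2], 1)
    # half the sets are enriched for targets of a random miRNA subset
    if (k %% 2 == 0) {
      src <- targets$gene[targets$mature_id %in%
                            sample(mature_ids, min(5, length(mature_ids)))]
      core <- unique(src)
      core <- core[seq_len(min(length(core), sz %/% 2))]
      unique(c(core, sample(genes, sz - length(core))))
    } else {
      sample(genes, sz)
    }
  })
  names(pathways) <- sprintf("pathway_%02d", seq_len(n_pathways))
  list(targets = targets, pathways = pathways)
}
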