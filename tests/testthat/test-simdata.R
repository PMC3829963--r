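test_that("generator is deterministic under a fixed seed", {
  cfg <- small_cfg()
  ps1 <- make_precursors(cfg)
  ps2 <- make_precursors(cfg)
  expect_identical(ps1, ps2)
  truth <- make_profile(ps1, cfg)
  lib1 <- simulate_library(ps1, truth, "WT", cfg)
  lib2 <- simulate_library(ps1, truth, "WT", cfg)
  expect_identical(lib1, lib2)
  # and byte-identical on disk
  d1 <- tempfile(); d2 <- tempfile()
  simulate_experiment(cfg, d1)
  simulate_experiment(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("precursor construction honors clusters, families and arms", {
  cfg <- sim_config(n_precursors = 15, n_clusters = 2, cluster_size = 3,
                    cluster_span = 10000, n_families = 1, family_size = 3,
                    seed = 3)
  ps <- make_precursors(cfg)
  # adjacent cluster members at most cluster_span apart
  for (cl in unique(na.omit(ps$precursors$cluster_id))) {
    m <- ps$precursors[which(ps$precursors$cluster_id == cl), ]
    m <- m[order(m$start), ]
    expect_true(all(m$chrom == m$chrom[1]))
    gaps <- m$start[-1] - m$end[-nrow(m)]
    expect_true(all(gaps <= 10000))
  }
  # family members share mature positions 2-8
  fam <- ps$matures[!is.na(ps$matures$family_id), ]
  expect_equal(nrow(fam), 3)
  seeds <- substr(mature_sequences(ps)[fam$mature_id], 2, 8)
  expect_length(unique(seeds), 1)
  # arms consistent with position relative to the hairpin midpoint
  plen <- nchar(ps$precursors$sequence)[match(ps$matures$precursor_id,
                                              ps$precursors$id)]
  auto <- ifelse((ps$matures$p_start + ps$matures$p_end) / 2 < plen / 2,
                 "5p", "3p")
  expect_identical(ps$matures$arm, auto)
  # mature intervals lie inside the hairpin, 1-2 per precursor
  expect_true(all(ps$matures$p_start >= 0 & ps$matures$p_end <= plen))
  expect_true(all(table(ps$matures$precursor_id) <= 2))
})

test_that("invalid generator configurations are rejected", {
  expect_error(sim_config(n_precursors = 2, n_clusters = 3),
               "n_precursors < n_clusters")
  expect_error(sim_config(error_rate = 1), "error_rate")
  expect_error(sim_config(effect_log2 = 0), "effect_log2")
  expect_error(sim_config(frac_de = 1.2), "frac_de")
  expect_error(sim_config(cleavage_offset_probs = c(`0` = 0.5)),
               "sum to 1")
  expect_error(sim_config(cleavage_offset_probs = c(`7` = 1)), "-6")
})

test_that("expression profile carries the configured effects", {
  cfg <- sim_config(n_precursors = 40, n_clusters = 0, n_families = 0,
                    both_arms_prob = 0.25, frac_de = 0.2, effect_log2 = 3,
                    seed = 11)
  ps <- make_precursors(cfg)
  truth <- make_profile(ps, cfg)
  m <- nrow(ps$matures)
  one <- truth[truth$condition == "WT", ]
  n_de <- round(0.2 * m)
  expect_equal(sum(one$is_de), n_de)
  expect_equal(sum(one$true_log2fc > 0), n_de - floor(n_de / 2))
  expect_equal(sum(one$true_log2fc < 0), floor(n_de / 2))
  expect_true(all(one$true_log2fc[!one$is_de] == 0))
  expect_true(all(abs(one$true_log2fc[one$is_de]) == 3))
  # abundances normalized per condition
  for (cond in c("obob", "WT"))
    expect_equal(sum(truth$true_abundance[truth$condition == cond]), 1,
                 tolerance = 1e-9)
  # frac_de = 0 leaves everything flat
  cfg0 <- sim_config(n_precursors = 10, n_clusters = 0, n_families = 0,
                     frac_de = 0, seed = 5)
  t0 <- make_profile(make_precursors(cfg0), cfg0)
  expect_true(all(t0$true_log2fc == 0))
})

test_that("simulated libraries have the stated structure", {
  cfg <- small_cfg(lib_depth = 1000)
  ps <- make_precursors(cfg)
  truth <- make_profile(ps, cfg)
  lib <- simulate_library(ps, truth, "WT", cfg)
  expect_equal(nrow(lib$reads), 1000)
  expect_true(all(nchar(lib$reads$sequence) == cfg$read_len))
  # noiseless limit: every read trimmed of its adapter is a canonical
  # mature sequence
  trimmed <- trim_adapter(lib$reads$sequence, cfg$adapter3)
  mseqs <- mature_sequences(ps)
  expect_true(all(trimmed %in% mseqs))
  expect_identical(unname(trimmed),
                   unname(mseqs[lib$read_truth$mature_id]))
})

test_that("offset frequencies follow the cleavage model (binomial, 3 SD)", {
  probs <- c(`0` = 0.6, `1` = 0.2, `-1` = 0.2)
  cfg <- sim_config(n_precursors = 10, n_clusters = 0, n_families = 0,
                    lib_depth = 1e5, error_rate = 0,
                    low_quality_frac = 0, frac_de = 0,
                    cleavage_offset_probs = probs, seed = 8)
  ps <- make_precursors(cfg)
  truth <- make_profile(ps, cfg)
  lib <- simulate_library(ps, truth, "WT", cfg)
  n <- nrow(lib$read_truth)
  for (off in names(probs)) {
    p <- probs[[off]]
    sd3 <- 3 * sqrt(n * p * (1 - p))
    for (col in c("offset5", "offset3")) {
      obs <- sum(lib$read_truth[[col]] == as.integer(off))
      expect_lt(abs(obs - n * p), sd3,
                label = sprintf("%s=%s count", col, off))
    }
  }
  expect_true(lib$n_resampled >= 0)
})

test_that("empirical read fractions converge to the true abundances", {
  cfg <- sim_config(n_precursors = 10, n_clusters = 0, n_families = 0,
                    lib_depth = 1e5, error_rate = 0, low_quality_frac = 0,
                    frac_de = 0, cleavage_offset_probs = c(`0` = 1),
                    seed = 21)
  ps <- make_precursors(cfg)
  truth <- make_profile(ps, cfg)
  lib <- simulate_library(ps, truth, "WT", cfg)
  tw <- truth[truth$condition == "WT", ]
  obs <- table(factor(lib$read_truth$mature_id, levels = tw$mature_id))
  n <- nrow(lib$read_truth)
  sd3 <- 3 * sqrt(n * tw$true_abundance * (1 - tw$true_abundance))
  expect_true(all(abs(as.numeric(obs) - n * tw$true_abundance) <=
                    pmax(sd3, 3)))
})
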