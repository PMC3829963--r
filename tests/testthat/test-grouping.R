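mk_ps <- function(chrom, start, end, strand = rep("+", length(chrom))) {
  n <- length(chrom)
  precursors <- data.frame(id = sprintf("p%d", seq_len(n)), chrom = chrom,
                           start = start, end = end, strand = strand,
                           sequence = vapply(end - start, function(L)
                             strrep("A", max(L, 60)), ""),
                           cluster_id = NA_character_,
                           stringsAsFactors = FALSE)
  matures <- data.frame(mature_id = sprintf("p%d-5p", seq_len(n)),
                        precursor_id = precursors$id, arm = "5p",
                        p_start = 6L, p_end = 28L,
                        family_id = NA_character_,
                        stringsAsFactors = FALSE)
  isomiRQuant:::new_precursor_set(precursors, matures)
}

test_that("cluster building chains loci by gap on one chromosome", {
  # 5 kb apart: one cluster; 50 kb apart: none
  near <- mk_ps(c("chr1", "chr1"), c(0L, 5100L), c(100L, 5200L))
  cl <- build_clusters(near, max_gap = 10000)
  expect_equal(sort(cl$precursor_id), c("p1", "p2"))
  expect_length(unique(cl$group_id), 1)
  far <- mk_ps(c("chr1", "chr1"), c(0L, 50100L), c(100L, 50200L))
  expect_equal(nrow(build_clusters(far, max_gap = 10000)), 0)
  # single linkage: A-B 8 kb, B-C 8 kb chains all three
  chain <- mk_ps(rep("chr1", 3), c(0L, 8100L, 16200L),
                 c(100L, 8200L, 16300L))
  cl3 <- build_clusters(chain, max_gap = 10000)
  expect_equal(sort(cl3$precursor_id), c("p1", "p2", "p3"))
  expect_length(unique(cl3$group_id), 1)
  # opposite strands never cluster
  anti <- mk_ps(c("chr1", "chr1"), c(0L, 5100L), c(100L, 5200L),
                strand = c("+", "-"))
  expect_equal(nrow(build_clusters(anti, max_gap = 10000)), 0)
})

test_that("cluster construction is permutation-invariant", {
  cfg <- small_cfg()
  ps <- make_precursors(cfg)
  cl <- build_clusters(ps)
  set.seed(2)
  perm <- sample(nrow(ps$precursors))
  ps2 <- ps
  ps2$precursors <- ps$precursors[perm, ]
  cl2 <- build_clusters(ps2)
  norm <- function(x) {
    sets <- split(x$precursor_id, x$group_id)
    unname(lapply(sets, sort)[order(vapply(lapply(sets, sort), `[`, "", 1))])
  }
  expect_identical(norm(cl), norm(cl2))
  # and the generator's declared clusters are recovered
  truth_sets <- split(ps$precursors$id,
                      ps$precursors$cluster_id)
  expect_identical(norm(cl), unname(lapply(truth_sets, sort)[
    order(vapply(lapply(truth_sets, sort), `[`, "", 1))]))
})

test_that("families come from the seed rule unless a map is given", {
  cfg <- small_cfg()
  ps <- make_precursors(cfg)
  fam <- build_families(ps)
  declared <- ps$matures$mature_id[!is.na(ps$matures$family_id)]
  expect_equal(nrow(fam), 3)   # the one synthetic family of 3
  expect_setequal(fam$mature_id, declared)
  # identical positions 2-8 within each reported family
  seeds <- substr(mature_sequences(ps)[fam$mature_id], 2, 8)
  expect_length(unique(seeds), 1)
  # an explicit map takes precedence over the seed rule
  map <- data.frame(family_id = "custom",
                    mature_id = ps$matures$mature_id[1:2])
  fam2 <- build_families(ps, family_map = map)
  expect_identical(fam2$group_id, c("custom", "custom"))
})

test_that("concordance scores majority sign agreement", {
  expect_equal(concordance(c(2.5, 3.1, 0.4)), 1)
  expect_equal(concordance(c(2, -1)), 0.5)
  expect_equal(concordance(c(2, 1, -3)), 2 / 3)
  expect_error(concordance(1.5))
  # bounds and the all-same-sign iff condition
  set.seed(6)
  for (i in 1:100) {
    fcs <- rnorm(sample(2:8, 1))
    cc <- concordance(fcs)
    expect_gte(cc, 0); expect_lte(cc, 1)
    if (all(fcs > 0) || all(fcs < 0)) expect_equal(cc, 1)
    if (cc == 1) expect_true(all(fcs > 0) || all(fcs < 0))
  }
})

test_that("coherently dysregulated groups approach full concordance", {
  cfg <- sim_config(n_precursors = 16, n_clusters = 3, cluster_size = 2,
                    n_families = 2, family_size = 3, lib_depth = 5e4,
                    error_rate = 0, low_quality_frac = 0, frac_de = 0.5,
                    effect_log2 = 3, cleavage_offset_probs = c(`0` = 1),
                    seed = 31)
  ps <- make_precursors(cfg)
  truth <- make_profile(ps, cfg, coherent_groups = TRUE)
  recs <- list()
  for (cond in c("obob", "WT")) {
    lib <- simulate_library(ps, truth, cond, cfg)
    pre <- preprocess_library(lib$reads, cond, adapter3 = cfg$adapter3)
    recs[[cond]] <- quantify_library(pre$tags, ps)$records
  }
  d <- differential_table(recs$obob, recs$WT)
  rep <- group_report(build_clusters(ps), build_families(ps), ps, d)
  # groups whose members all carry the same strong true effect
  tw <- truth[truth$condition == "WT", ]
  strong <- tapply(tw$true_log2fc, tw$cluster_id,
                   function(x) all(x != 0) && length(unique(x)) == 1)
  strong_ids <- names(strong)[strong]
  got <- rep[rep$kind == "cluster", ]
  # declared cluster k corresponds to the report's cluster on the same
  # members; check concordance of every fully-DE coherent cluster
  for (cid in strong_ids) {
    members <- tw$mature_id[!is.na(tw$cluster_id) & tw$cluster_id == cid]
    row <- got[vapply(strsplit(got$member_ids, ";"), function(m)
      setequal(m, members), logical(1)), ]
    if (nrow(row) == 1 && row$n_detected >= 2)
      expect_equal(row$concordance, 1)
  }
})
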