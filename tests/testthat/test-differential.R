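test_that("log2 fold change follows the stated formula", {
  expect_equal(log2fc(400, 100, 0), 2)
  expect_equal(log2fc(123.4, 123.4, 0.7), 0)
  expect_equal(log2fc(400, 0, 0.5), 9.64565843, tolerance = 1e-7)
  expect_error(log2fc(0, 0, 0), "undefined")
})

test_that("log2 fold change is antisymmetric and monotone", {
  set.seed(4)
  a <- runif(200, 0, 1e4)
  b <- runif(200, 0, 1e4)
  pc <- rep(c(0.5, 1), 100)
  expect_equal(log2fc(a, b, pc), -log2fc(b, a, pc))
  x <- sort(runif(50, 0, 100))
  fc <- log2fc(x, 10, 0.5)
  expect_true(all(diff(fc) > 0))
})

test_that("classification uses strict inequalities at the cutoff", {
  expect_equal(classify_fc(2.1), "up")
  expect_equal(classify_fc(-2.1), "down")
  expect_equal(classify_fc(2.0), "unchanged")
  expect_equal(classify_fc(-2.0), "unchanged")
  expect_equal(classify_fc(1.5, threshold = 1), "up")
})

test_that("differential table joins conditions and compares estimators", {
  case <- data.frame(mature_id = c("a", "b", "c"),
                     library_id = "case", dominant_count = c(40, 10, 6),
                     sum_count = c(50, 10, 12), n_isomirs = c(3, 1, 2),
                     stringsAsFactors = FALSE)
  ctrl <- data.frame(mature_id = c("a", "b"),
                     library_id = "ctrl", dominant_count = c(4, 10),
                     sum_count = c(5, 10), n_isomirs = c(2, 1),
                     stringsAsFactors = FALSE)
  case <- rpm_normalize(case, 100)
  ctrl <- rpm_normalize(ctrl, 100)
  d <- differential_table(case, ctrl, pseudocount = 0.5, threshold = 2)
  expect_setequal(d$mature_id, c("a", "b", "c"))
  # single-isomiR miRNA: zero divergence between the estimators
  expect_equal(d$estimator_divergence[d$mature_id == "b"], 0)
  # miRNA undetected in the control is rescued by the pseudocount
  expect_true(is.finite(d$log2fc_sum[d$mature_id == "c"]))
  expect_equal(d$status[d$mature_id == "a"], "up")  # 50x vs 5x RPM
  # swapping case/control negates every fold change
  rev <- differential_table(ctrl, case, pseudocount = 0.5)
  rev <- rev[match(d$mature_id, rev$mature_id), ]
  expect_equal(rev$log2fc_sum, -d$log2fc_sum)
  expect_equal(rev$log2fc_dominant, -d$log2fc_dominant)
})

test_that("estimator report ranks and sorts as documented", {
  d <- data.frame(mature_id = letters[1:5],
                  dominant_rpm_case = 1, dominant_rpm_control = 1,
                  sum_rpm_case = 1, sum_rpm_control = 1,
                  log2fc_dominant = c(3, -4, 0.5, -1, 2.5),
                  log2fc_sum = c(3.2, -4.1, 0.4, -1.2, 2.6),
                  stringsAsFactors = FALSE)
  d$estimator_divergence <- abs(d$log2fc_dominant - d$log2fc_sum)
  d$status <- classify_fc(d$log2fc_sum)
  rep <- compare_estimators(d, top_n = 2)
  expect_equal(rep$top_up$mature_id, c("a", "e"))
  expect_equal(rep$top_down$mature_id, c("b", "d"))
  expect_equal(rep$comparison$mature_id[1], "b")  # largest |log2fc_sum|
})

test_that("threshold sensitivity reports both cutoff readings", {
  d <- data.frame(log2fc_sum = c(2.5, 1.5, -1.5, -2.5, 0.2),
                  log2fc_dominant = c(2.5, 1.5, -1.5, -2.5, 0.2))
  s <- threshold_sensitivity(d, thresholds = c(2, 1))
  expect_equal(s$n_up, c(1, 2))
  expect_equal(s$n_down, c(1, 2))
  expect_equal(s$n_unchanged, c(3, 1))
})

test_that("true effects are recovered on simulated data", {
  cfg <- sim_config(n_precursors = 30, n_clusters = 0, n_families = 0,
                    lib_depth = 5e4, error_rate = 0, low_quality_frac = 0,
                    frac_de = 0.2, effect_log2 = 3,
                    cleavage_offset_probs = c(`0` = 1), seed = 17)
  ps <- make_precursors(cfg)
  truth <- make_profile(ps, cfg)
  recs <- list()
  for (cond in c("obob", "WT")) {
    lib <- simulate_library(ps, truth, cond, cfg)
    pre <- preprocess_library(lib$reads, cond, adapter3 = cfg$adapter3)
    recs[[cond]] <- quantify_library(pre$tags, ps)$records
  }
  d <- differential_table(recs$obob, recs$WT)
  tw <- truth[truth$condition == "WT", ]
  de <- tw[tw$is_de, ]
  # detection floor: at least 10 expected reads in each condition
  floor_ids <- truth$mature_id[ave(truth$true_abundance,
                                   truth$mature_id, FUN = min) *
                                 cfg$lib_depth >= 10]
  de <- de[de$mature_id %in% floor_ids, ]
  est <- d$log2fc_sum[match(de$mature_id, d$mature_id)]
  expect_true(all(sign(est) == sign(de$true_log2fc)))
  expect_lt(median(abs(est - de$true_log2fc)), 0.5)
})
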