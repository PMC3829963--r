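test_that("precursor scan finds exact and 1-mismatch placements only", {
  ps <- make_toy_precursor()
  pseq <- ps$precursors$sequence
  m5 <- substr(pseq, 7, 28)           # the 5p mature, 0-based [6, 28)
  hits <- scan_precursor(m5, pseq)
  expect_true(any(hits$start == 6 & hits$mismatches == 0))
  # two substitutions kill the only placement
  tag2 <- m5
  substr(tag2, 3, 3) <- if (substr(tag2, 3, 3) == "A") "C" else "A"
  substr(tag2, 10, 10) <- if (substr(tag2, 10, 10) == "A") "C" else "A"
  expect_false(6 %in% scan_precursor(tag2, pseq)$start)
  # tag longer than the precursor: empty
  expect_equal(nrow(scan_precursor(strrep("A", nchar(pseq) + 1), pseq)), 0)
})

test_that("compiled scan equals the brute-force Hamming oracle", {
  set.seed(99)
  for (i in 1:250) {
    plen <- sample(30:200, 1)
    tlen <- sample(15:30, 1)
    prec <- random_seq(plen)
    # half the tags are derived from the precursor so placements exist
    tag <- if (i %% 2 == 0) random_seq(tlen) else {
      s <- sample(plen - tlen + 1, 1)
      t <- substr(prec, s, s + tlen - 1)
      if (i %% 4 == 1) substr(t, sample(tlen, 1), sample(tlen, 1)) <- "A"
      t
    }
    got <- scan_precursor(tag, prec)
    want <- brute_force_scan(tag, prec)
    expect_identical(got, want)
  }
})

test_that("compiled scan agrees with Biostrings matchPattern", {
  set.seed(7)
  prec <- random_seq(120)
  for (i in 1:20) {
    tlen <- sample(16:24, 1)
    s <- sample(120 - tlen + 1, 1)
    tag <- substr(prec, s, s + tlen - 1)
    if (i %% 2 == 0) substr(tag, sample(tlen, 1), 1 + (i %% tlen)) <- "T"
    got <- scan_precursor(tag, prec)
    bs <- Biostrings::matchPattern(tag, Biostrings::DNAString(prec),
                                   max.mismatch = 1, with.indels = FALSE)
    expect_setequal(got$start, BiocGenerics::start(bs) - 1L)
  }
})

test_that("isomiR classification applies the +/-4 nt terminal windows", {
  ps <- make_toy_precursor(flank5 = "GGGGGG")
  m <- ps$matures[ps$matures$arm == "5p", ]
  mlen <- m$p_end - m$p_start
  # canonical mature
  hit <- classify_isomir(m$p_start, mlen, 0, ps$matures)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$offset5, 0)
  expect_equal(hit$offset3, 0)
  expect_equal(hit$arm, "5p")
  # 5' base removed: offset5 = +1, offset3 = 0
  hit <- classify_isomir(m$p_start + 1, mlen - 1, 0, ps$matures)
  expect_equal(hit$offset5, 1)
  expect_equal(hit$offset3, 0)
  # 4 nt upstream is still accepted, 5 nt upstream is rejected
  expect_equal(nrow(classify_isomir(m$p_start - 4, mlen + 4, 0,
                                    ps$matures)), 1)
  expect_equal(nrow(classify_isomir(m$p_start - 5, mlen + 5, 0,
                                    ps$matures)), 0)
})

test_that("multi-mapping policies attribute counts as declared", {
  hits <- data.frame(tag_sequence = c("T1", "T1", "T2"),
                     count = c(10, 10, 4),
                     mature_id = c("mirA", "mirB", "mirC"),
                     stringsAsFactors = FALSE)
  all_ <- resolve_multimap(hits, "all")
  expect_equal(all_$assigned_count, c(10, 10, 4))
  frac <- resolve_multimap(hits, "fractional")
  expect_equal(frac$assigned_count, c(5, 5, 4))
  uniq <- resolve_multimap(hits, "unique-only")
  expect_equal(uniq$mature_id, "mirC")
})

test_that("matching a tag table yields sound, canonical-recovering hits", {
  cfg <- small_cfg(lib_depth = 4000)
  ps <- make_precursors(cfg)
  truth <- make_profile(ps, cfg)
  lib <- simulate_library(ps, truth, "WT", cfg)
  pre <- preprocess_library(lib$reads, "WT", adapter3 = cfg$adapter3)
  hits <- match_tags(pre$tags, ps)
  # window/mismatch soundness
  expect_true(all(abs(hits$offset5) <= 4))
  expect_true(all(abs(hits$offset3) <= 4))
  expect_true(all(hits$mismatches <= 1))
  # canonical recovery on noiseless data with offsets {0: 1}
  expect_true(all(hits$offset5 == 0))
  expect_true(all(hits$offset3 == 0))
  expect_true(all(hits$mismatches == 0))
  # every canonical mature tag was mapped
  expect_setequal(unique(hits$tag_sequence),
                  intersect(pre$tags$sequence, mature_sequences(ps)))
})

test_that("within a precursor only the best placement survives", {
  # hairpin whose 5p mature reappears (shifted) nowhere else; craft a tag
  # equal to the mature so that window overlap yields several candidate
  # placements only through mismatches; the 0-mismatch one must win
  ps <- make_toy_precursor()
  mseq <- mature_sequences(ps)[["toy-mir-1-5p"]]
  tags <- data.frame(sequence = mseq, count = 5, library_id = "L",
                     stringsAsFactors = FALSE)
  hits <- match_tags(tags, ps)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$mismatches, 0)
  expect_equal(hits$offset5 + hits$offset3, 0)
})
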