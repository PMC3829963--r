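# Shared fixtures: a tiny hand-built precursor set and a small generator
# configuration reused across tests.

# Hairpin with 6-nt flanks around a 22-nt 5p mature and a 22-nt 3p
# mature separated by a 12-nt loop; coordinates 0-based half-open.
make_toy_precursor <- function(m5 = "TGGAGTGTGACAATGGTGTTTG",
                               m3 = "ACCACAAACACCATTGTCACAC",
                               flank5 = "GGGGGG", flank3 = "TTTTTT",
                               loop = "ATATATATATAT", id = "toy-mir-1") {
  seqs <- paste0(flank5, m5, loop, m3, flank3)
  p5 <- nchar(flank5)
  p3 <- nchar(flank5) + nchar(m5) + nchar(loop)
  precursors <- data.frame(id = id, chrom = "chr1", start = 1000L,
                           end = 1000L + nchar(seqs), strand = "+",
                           sequence = seqs, cluster_id = NA_character_,
                           stringsAsFactors = FALSE)
  matures <- data.frame(mature_id = paste0(id, c("-5p", "-3p")),
                        precursor_id = id, arm = c("5p", "3p"),
                        p_start = c(p5, p3),
                        p_end = c(p5 + nchar(m5), p3 + nchar(m3)),
                        family_id = NA_character_,
                        stringsAsFactors = FALSE)
  isomiRQuant:::new_precursor_set(precursors, matures)
}

# Pure-R brute-force Hamming scan: the independent oracle for the
# compiled sliding-window matcher.
brute_force_scan <- function(tag, precursor, max_mismatch = 1) {
  tchars <- strsplit(tag, "")[[1]]
  pchars <- strsplit(precursor, "")[[1]]
  L <- length(tchars)
  starts <- integer(0); mms <- integer(0)
  if (L <= length(pchars)) {
    for (s in 0:(length(pchars) - L)) {
      mm <- sum(tchars != pchars[(s + 1):(s + L)])
      if (mm <= max_mismatch) {
        starts <- c(starts, s); mms <- c(mms, mm)
      }
    }
  }
  data.frame(start = starts, mismatches = mms)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# Upper-tail hypergeometric probability as an explicit combinatorial sum
# (independent of the phyper-based implementation path).
enum_tail <- function(N, K, n, k) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

small_cfg <- function(...) {
  args <- modifyList(
    list(n_precursors = 12, n_clusters = 2, cluster_size = 2,
         n_families = 1, family_size = 3, lib_depth = 5000,
         error_rate = 0, low_quality_frac = 0, frac_de = 0.25,
         cleavage_offset_probs = c(`0` = 1), seed = 42),
    list(...))
  do.call(sim_config, args)
}
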