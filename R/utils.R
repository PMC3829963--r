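# Internal helpers shared across modules.

# Normalize an RNA/DNA character vector to DNA over ACGT (U -> T, upper case).
normalize_dna <- function(x) {
  x <- toupper(x)
  gsub("U", "T", x, fixed = TRUE)
}

assert_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop(sprintf("%s contains non-ACGT characters (first offender: %s)",
                 what, x[which(bad)[1]]), call. = FALSE)
  }
  invisible(x)
}

# Mean Phred score (+33 encoding) per quality string, vectorized.
phred_means <- function(qual) {
  vapply(qual, function(q) mean(utf8ToInt(q)) - 33, numeric(1),
         USE.NAMES = FALSE)
}

# Deterministic random DNA of given lengths.
random_dna <- function(lens) {
  vapply(lens, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample() treats a length-1 numeric first argument as 1:x; this always
# samples from the elements of x.
sample_vec <- function(x, n, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), n, replace = replace, prob = prob)]
}
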