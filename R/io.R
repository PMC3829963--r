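# On-disk interchange: precursor FASTA (+ mature GFF3 or mature FASTA),
# four-line Sanger FASTQ, and the tab-separated truth/result tables.

#' Write a precursor set to FASTA + mature GFF3
#'
#' Genomic location and cluster labels travel in the FASTA description
#' (`chrom=... start=... end=... strand=... cluster=...`; coordinates
#' 0-based half-open). Mature coordinates are written as GFF3 on the
#' hairpin sequence, 1-based inclusive per the GFF3 convention.
#'
#' @param ps a `precursor_set`.
#' @param fasta,gff3 output paths.
#' @return invisibly, the two paths.
#' @export
write_precursor_set <- function(ps, fasta, gff3) {
  p <- ps$precursors
  hdr <- sprintf("%s chrom=%s start=%d end=%d strand=%s cluster=%s",
                 p$id, p$chrom, p$start, p$end, p$strand,
                 ifelse(is.na(p$cluster_id), ".", p$cluster_id))
  dna <- Biostrings::DNAStringSet(setNames(p$sequence, hdr))
  Biostrings::writeXStringSet(dna, fasta)

  m <- ps$matures
  attrs <- sprintf("ID=%s;arm=%s%s", m$mature_id, m$arm,
                   ifelse(is.na(m$family_id), "",
                          paste0(";family=", m$family_id)))
  lines <- c("##gff-version 3",
             sprintf("%s\tisomiRQuant\tmiRNA\t%d\t%d\t.\t+\t.\t%s",
                     m$precursor_id, m$p_start + 1L, m$p_end, attrs))
  writeLines(lines, gff3)
  invisible(c(fasta = fasta, gff3 = gff3))
}

parse_fasta_header_field <- function(desc, key, default = NA_character_) {
  m <- regmatches(desc, regexpr(sprintf("%s=[^ ]+", key), desc))
  out <- rep(default, length(desc))
  hit <- grepl(sprintf("%s=", key), desc)
  out[hit] <- sub(sprintf("^%s=", key), "", m)
  out
}

#' Read a precursor set from FASTA plus mature annotations
#'
#' Mature annotations come either from a GFF3 of coordinates on the
#' hairpin (1-based inclusive, converted internally to 0-based half-open)
#' or from a mature FASTA whose sequences are located in the hairpins by
#' exact substring (a mature occurring more than once within one hairpin
#' is ambiguous and raises an error; a mature found in several hairpins
#' annotates each, as paralogs do). Arms are taken from a `-5p`/`-3p` id
#' suffix or a GFF3 `arm` attribute when present, else auto-assigned by
#' the mature midpoint relative to the hairpin midpoint. U is normalized
#' to T on ingestion.
#'
#' @param fasta precursor FASTA path.
#' @param mature_gff3 optional GFF3 path of mature coordinates.
#' @param mature_fasta optional mature FASTA path.
#' @return a `precursor_set`.
#' @export
read_precursor_set <- function(fasta, mature_gff3 = NULL,
                               mature_fasta = NULL) {
  if (is.null(mature_gff3) == is.null(mature_fasta))
    stop("provide exactly one of mature_gff3 or mature_fasta")
  # read as raw strings: reference hairpins are often RNA (U, not T)
  dna <- Biostrings::readBStringSet(fasta)
  desc <- names(dna)
  id <- sub(" .*", "", desc)
  seqs <- normalize_dna(as.character(dna))
  assert_dna(seqs, "precursor sequence")
  chrom <- parse_fasta_header_field(desc, "chrom")
  start <- suppressWarnings(as.integer(parse_fasta_header_field(desc, "start")))
  end <- suppressWarnings(as.integer(parse_fasta_header_field(desc, "end")))
  strand <- parse_fasta_header_field(desc, "strand", "+")
  cluster <- parse_fasta_header_field(desc, "cluster")
  cluster[cluster == "."] <- NA_character_
  precursors <- data.frame(id = id, chrom = ifelse(is.na(chrom), id, chrom),
                           start = ifelse(is.na(start), 0L, start),
                           end = ifelse(is.na(end), nchar(seqs), end),
                           strand = ifelse(is.na(strand), "+", strand),
                           sequence = unname(seqs), cluster_id = cluster,
                           stringsAsFactors = FALSE)

  matures <- if (!is.null(mature_gff3)) {
    read_mature_gff3(mature_gff3, precursors)
  } else {
    locate_matures(mature_fasta, precursors)
  }
  new_precursor_set(precursors, matures)
}

read_mature_gff3 <- function(path, precursors) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) != 9)
  if (length(bad))
    stop("malformed GFF3 line ", bad[1], " in ", path)
  f <- do.call(rbind, f)
  attr_field <- function(a, key) {
    v <- regmatches(a, regexpr(sprintf("(^|;)%s=[^;]+", key), a))
    out <- rep(NA_character_, length(a))
    hit <- grepl(sprintf("(^|;)%s=", key), a)
    out[hit] <- sub(sprintf("^;?%s=", key), "", v)
    out
  }
  ids <- attr_field(f[, 9], "ID")
  if (anyNA(ids)) stop("GFF3 mature records must carry an ID attribute")
  m <- data.frame(mature_id = ids, precursor_id = f[, 1],
                  arm = attr_field(f[, 9], "arm"),
                  p_start = as.integer(f[, 4]) - 1L,   # to 0-based half-open
                  p_end = as.integer(f[, 5]),
                  family_id = attr_field(f[, 9], "family"),
                  stringsAsFactors = FALSE)
  missing <- setdiff(m$precursor_id, precursors$id)
  if (length(missing))
    stop("GFF3 references unknown precursor(s): ",
         paste(missing, collapse = ", "))
  m$arm <- ifelse(is.na(m$arm),
                  auto_arm(m, precursors), m$arm)
  m
}

locate_matures <- function(mature_fasta, precursors) {
  dna <- Biostrings::readBStringSet(mature_fasta)
  mid <- sub(" .*", "", names(dna))
  mseq <- normalize_dna(as.character(dna))
  assert_dna(mseq, "mature sequence")
  rows <- list()
  for (i in seq_along(mseq)) {
    found <- FALSE
    for (j in seq_len(nrow(precursors))) {
      hits <- gregexpr(mseq[i], precursors$sequence[j], fixed = TRUE)[[1]]
      if (hits[1] == -1) next
      if (length(hits) > 1)
        stop("mature ", mid[i], " occurs ", length(hits),
             " times in precursor ", precursors$id[j], ": ambiguous")
      found <- TRUE
      rows[[length(rows) + 1]] <- data.frame(
        mature_id = mid[i], precursor_id = precursors$id[j],
        arm = NA_character_,
        p_start = hits[1] - 1L, p_end = hits[1] - 1L + nchar(mseq[i]),
        family_id = NA_character_, stringsAsFactors = FALSE)
    }
    if (!found) warning("mature ", mid[i], " not found in any precursor")
  }
  m <- do.call(rbind, rows)
  suffix <- regmatches(m$mature_id, regexpr("-(5p|3p)$", m$mature_id))
  has <- grepl("-(5p|3p)$", m$mature_id)
  m$arm[has] <- sub("^-", "", suffix)
  m$arm[!has] <- auto_arm(m[!has, , drop = FALSE], precursors)
  m
}

# Arm assignment by mature midpoint relative to the hairpin midpoint.
auto_arm <- function(m, precursors) {
  if (nrow(m) == 0) return(character(0))
  plen <- nchar(precursors$sequence)[match(m$precursor_id, precursors$id)]
  ifelse((m$p_start + m$p_end) / 2 < plen / 2, "5p", "3p")
}

#' Write reads as four-line Sanger FASTQ
#'
#' @param reads data frame with columns id, sequence, quality.
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$sequence, "\n+\n",
                    reads$quality), con, sep = "\n")
  invisible(path)
}

#' Read four-line Sanger FASTQ (Phred+33)
#'
#' @param path FASTQ path.
#' @return data frame with columns id, sequence, quality.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0)
    stop("malformed FASTQ: ", path, " has ", length(lines),
         " lines (not a multiple of 4)")
  n <- length(lines) / 4
  i1 <- seq(1, length(lines), by = 4)
  hdr_ok <- startsWith(lines[i1], "@")
  sep_ok <- startsWith(lines[i1 + 2], "+")
  len_ok <- nchar(lines[i1 + 1]) == nchar(lines[i1 + 3])
  bad <- which(!(hdr_ok & sep_ok & len_ok))
  if (length(bad))
    stop("malformed FASTQ record ", bad[1], " in ", path)
  data.frame(id = sub("^@", "", lines[i1]),
             sequence = normalize_dna(lines[i1 + 1]),
             quality = lines[i1 + 3], stringsAsFactors = FALSE)
}
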