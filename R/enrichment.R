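# Target mapping and hypergeometric pathway over-representation with
# Benjamini-Hochberg adjustment, over user-supplied validated-target
# tables and GMT gene sets.

#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT: set name, description, then member genes.
#'
#' @param path GMT file path.
#' @return named list of unique gene vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(f) < 3)
  if (length(short))
    stop("malformed GMT line ", short[1], ": fewer than 3 fields")
  setNames(lapply(f, function(x) unique(x[-(1:2)])),
           vapply(f, `[`, "", 1))
}

#' Write gene sets as GMT
#'
#' @param pathways named list of gene vectors.
#' @param path output path.
#' @export
write_gmt <- function(pathways, path) {
  writeLines(vapply(names(pathways), function(n) {
    paste(c(n, n, pathways[[n]]), collapse = "\t")
  }, character(1)), path)
  invisible(path)
}

#' Read a validated miRNA-target table
#'
#' Two tab-separated columns (mature miRNA id, target gene symbol), with
#' or without a header; deduplicated on load.
#'
#' @param path file path.
#' @return data frame (mature_id, gene).
#' @export
read_target_table <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("target table must have two columns")
  df <- df[, 1:2]
  names(df) <- c("mature_id", "gene")
  if (identical(tolower(df[1, 1]), "mature_id")) df <- df[-1, , drop = FALSE]
  unique(df[order(df$mature_id, df$gene), , drop = FALSE])
}

#' Map differential miRNAs to their validated target genes
#'
#' Union of the target genes of the query miRNAs, with per-gene
#' provenance (which miRNAs contributed it). Query miRNAs absent from
#' the table contribute nothing and are reported in the `missing`
#' attribute.
#'
#' @param mirna_ids query mature miRNA ids.
#' @param target_table data frame (mature_id, gene), e.g. from
#'   [read_target_table()].
#' @return data frame (gene, mirnas) — one row per distinct gene, the
#'   contributing miRNAs ";"-collapsed — with attribute `missing`.
#' @export
map_targets <- function(mirna_ids, target_table) {
  target_table <- unique(target_table[, c("mature_id", "gene")])
  hit <- target_table[target_table$mature_id %in% mirna_ids, , drop = FALSE]
  missing <- setdiff(mirna_ids, target_table$mature_id)
  if (nrow(hit) == 0) {
    out <- data.frame(gene = character(0), mirnas = character(0),
                      stringsAsFactors = FALSE)
  } else {
    prov <- tapply(hit$mature_id, hit$gene,
                   function(x) paste(sort(unique(x)), collapse = ";"))
    out <- data.frame(gene = names(prov), mirnas = unname(prov),
                      stringsAsFactors = FALSE)
    out <- out[order(out$gene), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "missing") <- missing
  out
}

#' Hypergeometric pathway over-representation
#'
#' For each pathway with K genes in an N-gene background, the upper-tail
#' probability that a query of n genes contains at least the observed k
#' pathway genes: `P(X >= k)`, X ~ hypergeometric(N, K, n). P-values are
#' Benjamini-Hochberg adjusted across the tested pathways and results
#' sorted ascending by p. Pathways with no gene in the background are
#' skipped (recorded in the `skipped` attribute).
#'
#' @param query_genes query gene set (must lie within the background).
#' @param pathways named list of gene vectors (e.g. [read_gmt()]).
#' @param background background gene universe.
#' @return data frame: pathway_id, k, K, n, N, p_value, p_adjusted,
#'   hit_genes (";"-collapsed); attribute `skipped`.
#' @export
hypergeom_enrich <- function(query_genes, pathways, background) {
  background <- unique(background)
  query_genes <- unique(query_genes)
  outside <- setdiff(query_genes, background)
  if (length(outside))
    stop("query genes outside the background: ",
         paste(head(outside, 5), collapse = ", "))
  N <- length(background)
  n <- length(query_genes)
  K <- vapply(pathways, function(g) length(intersect(g, background)), 0L)
  skipped <- names(pathways)[K == 0]
  pathways <- pathways[K > 0]
  K <- K[K > 0]
  hit <- lapply(pathways, function(g) intersect(query_genes, g))
  k <- lengths(hit)
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(pathway_id = names(pathways), k = as.integer(k),
                    K = as.integer(K), n = n, N = N, p_value = p,
                    p_adjusted = p.adjust(p, "BH"),
                    hit_genes = vapply(hit, paste, "", collapse = ";"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
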