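#' Read a gene expression matrix from TSV
#'
#' First column gene ids, header row of array ids, `NA` for missing entries.
#'
#' @param path Path to the file.
#' @return A tibble: `gene` column plus one numeric column per array.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  names(raw)[1] <- "gene"
  raw$gene <- as.character(raw$gene)
  if (anyDuplicated(raw$gene)) abort("Duplicate gene ids in expression file.")
  as_tibble(raw)
}

#' Filter an expression matrix by missingness
#'
#' Two-stage filter with a deterministic order: first drop arrays whose
#' missing fraction exceeds `max_array_missing_frac` (default 10 percent),
#' then drop genes missing in more than `max_gene_missing_arrays` of the
#' remaining arrays (default 7, an absolute count that is dataset-specific and
#' therefore exposed). The filter is idempotent on its own output.
#'
#' @param m An expression tibble (`gene` column + array columns).
#' @param max_array_missing_frac Strict upper bound on an array's missing
#'   fraction.
#' @param max_gene_missing_arrays Strict upper bound on a gene's count of
#'   missing arrays.
#' @return The filtered tibble, with attributes `removed_arrays` and
#'   `removed_genes` listing what was dropped.
#' @export
filter_expression <- function(m, max_array_missing_frac = 0.10,
                              max_gene_missing_arrays = 7) {
  if (!"gene" %in% names(m)) names(m)[1] <- "gene"
  arrays <- setdiff(names(m), "gene")
  if (length(arrays) == 0) abort("No array columns found.")
  x <- as.matrix(m[, arrays])
  arr_frac <- colMeans(is.na(x))
  drop_arr <- arrays[arr_frac > max_array_missing_frac]
  keep_arr <- setdiff(arrays, drop_arr)
  if (length(keep_arr) == 0) abort("All arrays filtered out.")
  x2 <- x[, keep_arr, drop = FALSE]
  gene_miss <- rowSums(is.na(x2))
  drop_gene <- m$gene[gene_miss > max_gene_missing_arrays]
  out <- m[!(m$gene %in% drop_gene), c("gene", keep_arr)]
  if (nrow(out) == 0) abort("All genes filtered out.")
  attr(out, "removed_arrays") <- drop_arr
  attr(out, "removed_genes") <- drop_gene
  out
}

#' Build a gene co-expression network by correlation thresholding
#'
#' Computes the Pearson correlation of every gene pair over pairwise-complete
#' arrays (pairs sharing fewer than `min_shared` non-missing arrays get no
#' edge) and connects pairs whose absolute correlation strictly exceeds the
#' threshold. The absolute value means strong negative co-expression also
#' forms an edge.
#'
#' @param m A (typically filtered) expression tibble.
#' @param threshold Strict absolute-correlation threshold (default 0.65).
#' @param min_shared Minimum shared non-missing arrays per pair.
#' @return A canonical edge tibble with an extra column `r`, the correlation.
#' @export
coexpression_network <- function(m, threshold = 0.65, min_shared = 3) {
  if (!"gene" %in% names(m)) names(m)[1] <- "gene"
  arrays <- setdiff(names(m), "gene")
  if (nrow(m) < 2) abort("Need at least 2 genes.")
  x <- t(as.matrix(m[, arrays]))   # arrays x genes
  colnames(x) <- m$gene
  suppressWarnings(cc <- cor(x, use = "pairwise.complete.obs"))
  shared <- crossprod(!is.na(x))   # pairwise non-missing counts
  cc[shared < min_shared] <- NA
  cc[!is.finite(cc)] <- NA
  ut <- which(upper.tri(cc) & !is.na(cc) & abs(cc) > threshold,
              arr.ind = TRUE)
  if (nrow(ut) == 0) {
    out <- tibble(from = character(0), to = character(0), r = numeric(0))
    return(out)
  }
  g1 <- colnames(cc)[ut[, 1]]
  g2 <- colnames(cc)[ut[, 2]]
  out <- tibble(from = pmin(g1, g2), to = pmax(g1, g2),
                r = cc[ut]) %>%
    arrange(.data$from, .data$to)
  out
}
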