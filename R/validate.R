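#' Validate counts and cluster labels, filtering low-evidence genes
#'
#' Applies the standard inclusion rule for ambient-RNA estimation: a gene
#' is kept only if it has at least `min_counts` total UMIs and is
#' detected (nonzero) in at least `min_cells` cells. Cells left with zero
#' counts after gene filtering are dropped with a warning, and labels are
#' re-checked so that at least two non-empty populations remain --- with a
#' single population the contamination distribution (a combination of the
#' *other* populations' profiles) is undefined.
#'
#' @param counts A genes x cells matrix of non-negative integer UMI
#'   counts; dense matrices are coerced to sparse `dgCMatrix`.
#' @param labels Per-cell cluster labels: an integer/factor/character
#'   vector of length `ncol(counts)`.
#' @param min_counts Minimum total counts per gene (default 3).
#' @param min_cells Minimum number of cells in which a gene must be
#'   detected (default 3).
#' @return A list with elements `counts` (filtered `dgCMatrix`), `labels`
#'   (integer vector in `1..K` with a `levels` attribute giving the
#'   original label of each index), `gene_mask` (logical over the input
#'   genes, `TRUE` = kept), and `cell_mask` (logical over input cells).
#' @examples
#' X <- Matrix::rsparsematrix(20, 12, 0.5,
#'   rand.x = function(n) rpois(n, 2) + 1)
#' v <- validate_inputs(X, rep(1:2, each = 6))
#' dim(v$counts)
#' @export
validate_inputs <- function(counts, labels, min_counts = 3, min_cells = 3) {
  X <- as_count_matrix(counts)
  if (nrow(X) < 1L || ncol(X) < 1L) {
    stop("counts must have at least one gene and one cell", call. = FALSE)
  }
  if (any(X@x < 0) || any(X@x != round(X@x))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (length(labels) != ncol(X)) {
    stop(sprintf(
      "dimension mismatch: %d cells in counts but %d labels",
      ncol(X), length(labels)
    ), call. = FALSE)
  }
  labels <- normalize_labels(labels)

  keep_gene <- Matrix::rowSums(X) >= min_counts &
    Matrix::rowSums(X > 0) >= min_cells
  if (!any(keep_gene)) {
    stop(sprintf(
      "all %d genes removed by the filter (>= %d counts across >= %d cells)",
      nrow(X), min_counts, min_cells
    ), call. = FALSE)
  }
  Xf <- X[keep_gene, , drop = FALSE]

  keep_cell <- Matrix::colSums(Xf) > 0
  if (!all(keep_cell)) {
    warning(sprintf(
      "dropping %d cell(s) with zero counts after gene filtering",
      sum(!keep_cell)
    ), call. = FALSE)
    Xf <- Xf[, keep_cell, drop = FALSE]
    labels <- normalize_labels(attr(labels, "levels")[labels[keep_cell]])
  }

  check_populations(labels)
  list(
    counts = Xf,
    labels = labels,
    gene_mask = stats::setNames(keep_gene, rownames(X)),
    cell_mask = stats::setNames(keep_cell, colnames(X))
  )
}

# Map arbitrary labels to integers 1..K; original labels kept in the
# "levels" attribute.
normalize_labels <- function(labels) {
  if (anyNA(labels)) stop("labels contain missing values", call. = FALSE)
  f <- factor(labels)
  z <- as.integer(f)
  attr(z, "levels") <- levels(f)
  z
}

check_populations <- function(z) {
  lev <- attr(z, "levels")
  K <- if (is.null(lev)) max(z) else length(lev)
  if (K < 2L) {
    stop(paste(
      "a single cell population was supplied;",
      "contamination profiles require at least two populations"
    ), call. = FALSE)
  }
  if (length(unique(z)) != K) {
    stop("every population index in 1..K must have at least one cell",
      call. = FALSE)
  }
  invisible(K)
}
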