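#' Fallback clustering for unlabelled data
#'
#' Supplies per-cell population labels when none are available: counts
#' are library-size normalised, log-transformed, projected onto the
#' leading principal components and partitioned by k-means. This is a
#' deliberately simple stand-in --- any fast clustering can feed the
#' decontamination model --- and the number of clusters must be chosen by
#' the user.
#'
#' @param counts Genes x cells count matrix.
#' @param k Number of clusters (>= 2, <= number of cells).
#' @param n_components Number of principal components (default 10,
#'   capped by the data dimensions).
#' @param scale_factor Library-size scaling factor (default 1e4).
#' @param log_transform Apply `log1p` after scaling (default `TRUE`).
#' @param seed Integer seed for the k-means initialisation (default 1).
#' @return Integer labels in `1..k` with a `levels` attribute; no
#'   cluster is empty (re-initialised up to 10 times, then an error
#'   advises supplying explicit labels).
#' @examples
#' sim <- simulate_ambient_counts(M = 60, G = 40, K = 2,
#'   umis_per_cell = 200, seed = 3)
#' table(estimate_clusters(sim$counts, k = 2), sim$labels)
#' @export
estimate_clusters <- function(counts, k, n_components = 10,
                              scale_factor = 1e4, log_transform = TRUE,
                              seed = 1L) {
  X <- as_count_matrix(counts)
  M <- ncol(X)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (k > M) {
    stop(sprintf("k = %d exceeds the number of cells (%d)", k, M),
      call. = FALSE)
  }
  N <- Matrix::colSums(X)
  if (any(N == 0)) stop("cells with zero counts cannot be clustered",
    call. = FALSE)

  Y <- t(as.matrix(X) / rep(N, each = nrow(X)) * scale_factor)
  if (log_transform) Y <- log1p(Y)
  d <- min(n_components, M - 1L, ncol(Y))
  pcs <- prcomp(Y, center = TRUE, scale. = FALSE, rank. = d)$x

  for (attempt in seq_len(10L)) {
    set.seed(seed + attempt - 1L)
    km <- tryCatch(
      kmeans(pcs, centers = k, nstart = 5L, iter.max = 100L),
      error = function(e) NULL
    )
    if (!is.null(km) && length(unique(km$cluster)) == k) {
      return(normalize_labels(km$cluster))
    }
  }
  stop(paste(
    "clustering failed to produce", k, "non-empty clusters;",
    "supply explicit labels instead"
  ), call. = FALSE)
}
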