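#' Estimate and remove ambient RNA contamination
#'
#' Fits the two-component multinomial mixture by coordinate-ascent
#' variational inference. One sweep updates, in order: the per-count
#' native responsibilities, the per-cell Beta posteriors, the native
#' expression profiles, the contamination profiles, and (optionally) the
#' Beta prior hyperparameters by a safeguarded Newton step. The lower
#' bound is recorded every sweep; iteration stops when the largest
#' absolute change in any cell's contamination fraction falls below
#' `tol`, or after `max_iter` sweeps. The fit itself involves no random
#' draws and is deterministic given its inputs.
#'
#' @param counts Genes x cells matrix of non-negative integer UMI counts
#'   (sparse `dgCMatrix` or dense; 10X orientation).
#' @param labels Per-cell population labels (length `ncol(counts)`), or
#'   `NULL` to derive them with [estimate_clusters()] (requires `k`).
#' @param k Number of populations for the fallback clustering when
#'   `labels` is `NULL`.
#' @param max_iter Maximum number of coordinate-ascent sweeps
#'   (default 500).
#' @param tol Convergence tolerance on the maximum absolute per-cell
#'   change in contamination between sweeps (default 1e-3).
#' @param estimate_prior Update the Beta prior `(a1, a2)` by
#'   empirical-Bayes Newton steps (default `TRUE`); when `FALSE` the
#'   prior stays at `(a1, a2)` and the recorded lower bound is
#'   non-decreasing.
#' @param a1,a2 Initial (or fixed) Beta prior hyperparameters
#'   (default 10, 10: a mild, symmetric prior).
#' @param epsilon Smoothing floor for profile probabilities
#'   (default 1e-20).
#' @param min_counts,min_cells Gene filter: keep genes with at least
#'   `min_counts` total counts across at least `min_cells` cells
#'   (defaults 3 and 3).
#' @param integer_output Return integer decontaminated counts, rounded
#'   per cell by largest remainder (default `FALSE`; real-valued).
#' @param pi_init Initial native responsibility (default 0.9).
#' @param seed Seed for the fallback clustering only; the fit is
#'   deterministic.
#' @param verbose Print per-sweep progress to standard error.
#' @return An object of class `scambient`: a list with
#'   `contamination` (per-cell fraction), `native_counts` and
#'   `contamination_counts` (sparse matrices summing to the filtered
#'   counts), `counts` (the filtered input), `labels`, `profiles`,
#'   `state`, `gene_mask`, `cell_mask`, and `trace` (lower-bound path,
#'   iterations, convergence flag, final Newton gradient/Hessian, config
#'   echo).
#' @examples
#' sim <- simulate_ambient_counts(M = 60, G = 40, K = 2,
#'   umis_per_cell = 200, seed = 7)
#' fit <- decontaminate(sim$counts, sim$labels, max_iter = 50)
#' summary(fit$contamination)
#' @export
decontaminate <- function(counts, labels = NULL, k = NULL,
                          max_iter = 500L, tol = 1e-3,
                          estimate_prior = TRUE, a1 = 10, a2 = 10,
                          epsilon = 1e-20, min_counts = 3L, min_cells = 3L,
                          integer_output = FALSE, pi_init = 0.9,
                          seed = NULL, verbose = FALSE) {
  X0 <- as_count_matrix(counts)
  if (is.null(labels)) {
    if (is.null(k)) {
      stop("either labels or k (for fallback clustering) must be given",
        call. = FALSE)
    }
    labels <- estimate_clusters(X0, k = k, seed = if (is.null(seed)) 1L else seed)
  }
  v <- validate_inputs(X0, labels, min_counts = min_counts,
                       min_cells = min_cells)
  X <- v$counts
  z <- v$labels

  init <- initialize_state(X, z, pi_init = pi_init, a1 = a1, a2 = a2,
                           epsilon = epsilon)
  profiles <- init$profiles
  state <- init$state

  elbo <- numeric(0)
  contam_prev <- contamination_fraction(state)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    state <- update_responsibilities(X, z, profiles, state)
    state <- update_theta_posterior(X, state)
    profiles$phi <- update_native_profiles(X, z, state, epsilon)$phi
    contam_upd <- update_contamination_profiles(X, z, state, epsilon)
    profiles$eta <- contam_upd$eta
    profiles$weights <- contam_upd$weights

    elbo[it] <- compute_elbo(X, z, profiles, state)
    if (!is.finite(elbo[it])) {
      stop(sprintf("lower bound became non-finite at iteration %d", it),
        call. = FALSE)
    }
    if (estimate_prior) {
      state <- update_prior_newton(state)
    }

    contam <- contamination_fraction(state)
    delta <- max(abs(contam - contam_prev))
    contam_prev <- contam
    if (verbose) {
      message(sprintf("sweep %3d  elbo %.4f  max|d contamination| %.2e",
                      it, elbo[it], delta))
    }
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }

  parts <- decompose_counts(X, state, integer_output = integer_output)
  res <- list(
    contamination = stats::setNames(contamination_fraction(state),
                                    colnames(X)),
    native_counts = parts$native,
    contamination_counts = parts$contamination,
    counts = X,
    labels = z,
    profiles = profiles,
    state = state,
    gene_mask = v$gene_mask,
    cell_mask = v$cell_mask,
    trace = list(
      elbo = elbo,
      iterations = it,
      converged = converged,
      newton = state$newton,
      config = list(
        max_iter = max_iter, tol = tol, estimate_prior = estimate_prior,
        a1 = a1, a2 = a2, epsilon = epsilon, min_counts = min_counts,
        min_cells = min_cells, integer_output = integer_output,
        pi_init = pi_init, seed = seed
      )
    )
  )
  class(res) <- "scambient"
  res
}

#' @export
print.scambient <- function(x, ...) {
  cat(sprintf(
    "scAmbient fit: %d genes x %d cells, %d populations\n",
    nrow(x$counts), ncol(x$counts), length(attr(x$labels, "levels"))
  ))
  q <- stats::quantile(x$contamination, c(0, 0.5, 1))
  cat(sprintf(
    "contamination: median %.3f (range %.3f-%.3f)\n", q[2], q[1], q[3]
  ))
  cat(sprintf(
    "%d sweep(s), %sconverged; final lower bound %.4f\n",
    x$trace$iterations, if (x$trace$converged) "" else "NOT ",
    x$trace$elbo[length(x$trace$elbo)]
  ))
  if (!is.null(x$trace$config$estimate_prior) &&
      x$trace$config$estimate_prior) {
    cat(sprintf("estimated Beta prior: (%.3f, %.3f)\n",
                x$state$prior[1], x$state$prior[2]))
  }
  invisible(x)
}
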