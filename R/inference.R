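#' @name updates
#' @rdname updates
#' @title Coordinate-ascent updates for the ambient-RNA mixture model
#'
#' @description
#' Low-level building blocks of [decontaminate()], exported so the
#' variational updates can be inspected, unit-tested and reused. The
#' model treats transcript `t` of cell `j` as native
#' (probability `theta_j`) or contamination (`1 - theta_j`); native
#' transcripts are multinomial draws from the profile `phi[k, ]` of the
#' cell's population `k = z_j`, contaminating transcripts draws from
#' `eta[k, ]`, a weighted combination of the other populations'
#' profiles. The variational posterior factorises into a Beta
#' distribution `(gamma_j1, gamma_j2)` per cell and a Bernoulli
#' responsibility per transcript. Because every per-transcript update
#' depends on `t` only through its gene, responsibilities are stored
#' once per (cell, gene) pair with a nonzero count, weighted by the
#' count.
#'
#' @param counts Validated genes x cells `dgCMatrix`.
#' @param labels Integer vector of population indices in `1..K`.
#' @param profiles List with `phi`, `eta` (each `K x G`, rows sum to 1)
#'   and `weights` (`K x K`, row `k` giving each other population's share
#'   of expected native transcripts, zero diagonal).
#' @param state List with `pi1` (responsibility that each stored nonzero
#'   count is native, aligned with the nonzero slots of `counts`),
#'   `gamma` (`M x 2`, per-cell Beta posterior parameters) and `prior`
#'   (`c(a1, a2)`, the Beta prior hyperparameters).
#' @param epsilon Smoothing floor added to profile numerators before row
#'   normalisation, guaranteeing strictly positive probabilities and a
#'   finite objective.
NULL

#' Initialise profiles and variational state
#'
#' `phi` starts from the smoothed, normalised raw count sums of each
#' population; `eta` from the contamination update evaluated with all
#' responsibilities set to `pi_init`; `gamma_j` to
#' `(a1 + pi_init * N_j, a2 + (1 - pi_init) * N_j)`.
#'
#' @rdname updates
#' @param pi_init Initial native responsibility applied uniformly
#'   (default 0.9, i.e. an assumed 10% contamination).
#' @param a1,a2 Beta prior hyperparameters (default 10 and 10).
#' @return `initialize_state()`: list with `profiles` and `state`.
#' @export
initialize_state <- function(counts, labels, pi_init = 0.9,
                             a1 = 10, a2 = 10, epsilon = 1e-20) {
  K <- check_populations(labels)
  N <- Matrix::colSums(counts)
  state <- list(
    pi1 = rep.int(pi_init, length(counts@x)),
    gamma = cbind(a1 + pi_init * N, a2 + (1 - pi_init) * N),
    prior = c(a1, a2)
  )
  profiles <- update_native_profiles(
    counts, labels,
    list(pi1 = rep.int(1, length(counts@x))), epsilon
  )
  contam <- update_contamination_profiles(counts, labels, state, epsilon)
  profiles$eta <- contam$eta
  profiles$weights <- contam$weights
  list(profiles = profiles, state = state)
}

#' Update per-(cell, gene) native responsibilities
#'
#' The optimum for the responsibility of a count of gene `g` in cell `j`
#' is proportional to `phi[z_j, g] * exp(digamma(gamma_j1) -
#' digamma(gamma_j1 + gamma_j2))` for the native component, and to the
#' same expression with `eta` and `gamma_j2` for contamination,
#' normalised to sum to one.
#'
#' @rdname updates
#' @return `update_responsibilities()`: the state with `pi1` replaced.
#' @export
update_responsibilities <- function(counts, labels, profiles, state) {
  if (any(state$gamma <= 0)) {
    stop("gamma parameters must be positive", call. = FALSE)
  }
  if (max(abs(rowSums(profiles$phi) - 1)) > 1e-6 ||
      max(abs(rowSums(profiles$eta) - 1)) > 1e-6) {
    stop("profile rows must be normalised", call. = FALSE)
  }
  tr <- nz_triplets(counts)
  z <- labels[tr$j]
  d1 <- digamma(state$gamma[, 1])[tr$j]
  d2 <- digamma(state$gamma[, 2])[tr$j]
  l1 <- log(profiles$phi[cbind(z, tr$g)]) + d1
  l2 <- log(profiles$eta[cbind(z, tr$g)]) + d2
  state$pi1 <- 1 / (1 + exp(l2 - l1))
  state
}

#' Update per-cell Beta posterior parameters
#'
#' `gamma_ji = a_i + sum_g x_jg * pi_jgi`, so that
#' `gamma_j1 + gamma_j2 = a1 + a2 + N_j`.
#'
#' @rdname updates
#' @return `update_theta_posterior()`: the state with `gamma` replaced.
#' @export
update_theta_posterior <- function(counts, state) {
  native <- nz_colsums(counts, counts@x * state$pi1)
  N <- Matrix::colSums(counts)
  state$gamma <- cbind(state$prior[1] + native,
                       state$prior[2] + (N - native))
  state
}

# Expected native counts aggregated per gene and population: G x K.
native_mass_by_cluster <- function(counts, labels, state) {
  K <- max(labels)
  Z <- Matrix::sparseMatrix(
    i = seq_along(labels), j = labels, x = 1,
    dims = c(length(labels), K)
  )
  as.matrix(nz_replace(counts, counts@x * state$pi1) %*% Z)
}

#' Update native expression profiles
#'
#' `phi[k, g]` is proportional to the expected native count of gene `g`
#' over the cells of population `k`, smoothed by `epsilon` and
#' renormalised. A population whose expected native mass is entirely
#' zero yields a uniform profile with a warning.
#'
#' @rdname updates
#' @return `update_native_profiles()`: list with element `phi`.
#' @export
update_native_profiles <- function(counts, labels, state, epsilon = 1e-20) {
  mass <- t(native_mass_by_cluster(counts, labels, state))  # K x G
  tot <- rowSums(mass)
  if (any(tot == 0)) {
    warning(sprintf(
      "population(s) %s have zero expected native mass; using uniform profiles",
      paste(which(tot == 0), collapse = ", ")
    ), call. = FALSE)
  }
  phi <- mass + epsilon
  phi <- phi / rowSums(phi)
  dimnames(phi) <- list(NULL, rownames(counts))
  list(phi = phi)
}

#' Update contamination profiles and mixture weights
#'
#' The contamination profile of population `k` pools the expected native
#' counts of every *other* population: `eta[k, g]` is proportional to
#' the total expected native count of gene `g` over all cells outside
#' `k`. Equivalently, `eta[k, ] = sum_{k' != k} w_{k'} * phi[k', ]` with
#' `w_{k'}` the share of population `k'` in the expected native
#' transcripts outside `k`; the weights are returned alongside.
#'
#' @rdname updates
#' @return `update_contamination_profiles()`: list with `eta` and
#'   `weights`.
#' @export
update_contamination_profiles <- function(counts, labels, state,
                                          epsilon = 1e-20) {
  mass <- native_mass_by_cluster(counts, labels, state)  # G x K
  K <- ncol(mass)
  tot_g <- rowSums(mass)
  s <- colSums(mass)                                     # native mass per pop
  eta <- matrix(0, K, length(tot_g), dimnames = list(NULL, rownames(counts)))
  weights <- matrix(0, K, K)
  for (k in seq_len(K)) {
    out <- tot_g - mass[, k]
    eta[k, ] <- (out + epsilon) / sum(out + epsilon)
    denom <- sum(s) - s[k]
    if (denom > 0) weights[k, -k] <- s[-k] / denom
  }
  list(eta = eta, weights = weights)
}

# Per-cell expectations E[log theta_ji] = digamma(gamma_ji) -
# digamma(gamma_j1 + gamma_j2), returned as an M x 2 matrix.
elog_theta <- function(gamma) {
  digamma(gamma) - digamma(rowSums(gamma))
}

#' Evidence lower bound
#'
#' Sum of the five expectation terms of the variational objective
#' (Beta prior, Bernoulli assignments, multinomial emission, minus the
#' Beta and Bernoulli entropies of the variational posterior), with
#' `0 * log 0` treated as 0. Transcript sums are computed as
#' count-weighted per-gene sums.
#'
#' @rdname updates
#' @return `compute_elbo()`: a single numeric value.
#' @export
compute_elbo <- function(counts, labels, profiles, state) {
  a <- state$prior
  g <- state$gamma
  el <- elog_theta(g)
  m <- nrow(g)

  t_prior <- m * (lgamma(a[1] + a[2]) - lgamma(a[1]) - lgamma(a[2])) +
    (a[1] - 1) * sum(el[, 1]) + (a[2] - 1) * sum(el[, 2])

  tr <- nz_triplets(counts)
  p1 <- state$pi1
  p2 <- 1 - p1
  t_assign <- sum(tr$x * (p1 * el[tr$j, 1] + p2 * el[tr$j, 2]))

  z <- labels[tr$j]
  t_emit <- sum(tr$x * (p1 * log(profiles$phi[cbind(z, tr$g)]) +
                        p2 * log(profiles$eta[cbind(z, tr$g)])))

  t_q_theta <- sum(lgamma(rowSums(g)) - lgamma(g[, 1]) - lgamma(g[, 2]) +
    (g[, 1] - 1) * el[, 1] + (g[, 2] - 1) * el[, 2])

  xlogx <- function(p) ifelse(p > 0, p * log(p), 0)
  t_q_y <- sum(tr$x * (xlogx(p1) + xlogx(p2)))

  t_prior + t_assign + t_emit - t_q_theta - t_q_y
}

# Profile objective of the Beta hyperparameters given the per-cell
# variational posteriors (the terms of the lower bound containing a).
prior_objective <- function(a, gamma) {
  el <- elog_theta(gamma)
  nrow(gamma) * (lgamma(a[1] + a[2]) - lgamma(a[1]) - lgamma(a[2])) +
    (a[1] - 1) * sum(el[, 1]) + (a[2] - 1) * sum(el[, 2])
}

prior_gradient <- function(a, gamma) {
  el <- elog_theta(gamma)
  nrow(gamma) * (digamma(a[1] + a[2]) - digamma(a)) + colSums(el)
}

prior_hessian <- function(a, m) {
  h_off <- m * trigamma(a[1] + a[2])
  matrix(c(h_off - m * trigamma(a[1]), h_off,
           h_off, h_off - m * trigamma(a[2])), 2, 2)
}

#' Empirical-Bayes Newton update of the Beta prior
#'
#' Takes damped Newton steps on the marginal objective of `(a1, a2)`
#' given the current per-cell Beta posteriors. Steps are halved (up to
#' 20 times) until both components are positive and the objective does
#' not decrease; a singular Hessian skips the update with a warning.
#'
#' @rdname updates
#' @param max_newton_iter Number of Newton steps per call (default 1).
#' @param damping Initial step scaling in (0, 1] (default 1).
#' @return `update_prior_newton()`: the state with `prior` replaced and
#'   a `newton` element recording the last gradient, Hessian and
#'   objective.
#' @export
update_prior_newton <- function(state, max_newton_iter = 1L, damping = 1) {
  gamma <- state$gamma
  m <- nrow(gamma)
  a <- state$prior
  grad <- prior_gradient(a, gamma)
  hess <- prior_hessian(a, m)
  for (iter in seq_len(max_newton_iter)) {
    grad <- prior_gradient(a, gamma)
    hess <- prior_hessian(a, m)
    step <- tryCatch(solve(hess, grad), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      warning("singular Hessian in prior update; keeping current prior",
        call. = FALSE)
      break
    }
    obj_old <- prior_objective(a, gamma)
    scale <- damping
    accepted <- FALSE
    for (h in seq_len(20L)) {
      a_new <- a - scale * step
      if (all(a_new > 0) && prior_objective(a_new, gamma) >= obj_old) {
        a <- a_new
        accepted <- TRUE
        break
      }
      scale <- scale / 2
    }
    if (!accepted) break
  }
  state$prior <- a
  state$newton <- list(gradient = grad, hessian = hess,
                       objective = prior_objective(a, gamma))
  state
}

#' Per-cell contamination fraction
#'
#' The posterior mean contamination of cell `j` under the variational
#' Beta posterior: `gamma_j2 / (gamma_j1 + gamma_j2)`.
#'
#' @param state A variational state (or fitted `scambient` object).
#' @return Numeric vector of per-cell contamination fractions in `[0, 1]`.
#' @export
contamination_fraction <- function(state) {
  if (inherits(state, "scambient")) state <- state$state
  unname(state$gamma[, 2] / rowSums(state$gamma))
}

#' Decompose observed counts into native and contamination matrices
#'
#' Each observed count is split by its fitted responsibility:
#' `native = x * pi1`, `contamination = x * (1 - pi1)`; the two outputs
#' sum to the observed matrix entrywise. The optional integer mode
#' rounds native counts per cell by largest remainder so that native
#' column sums are preserved to the nearest integer and conservation
#' still holds exactly.
#'
#' @param counts Validated genes x cells `dgCMatrix`.
#' @param state Fitted variational state (or `scambient` object).
#' @param integer_output Round to integer counts (default `FALSE`).
#' @return List with sparse matrices `native` and `contamination`.
#' @export
decompose_counts <- function(counts, state, integer_output = FALSE) {
  if (inherits(state, "scambient")) state <- state$state
  native_x <- counts@x * state$pi1
  if (integer_output) {
    native_x <- round_preserving_colsums(counts, native_x)
  }
  list(
    native = nz_replace(counts, native_x),
    contamination = nz_replace(counts, counts@x - native_x)
  )
}

# Largest-remainder rounding of the native values within each cell:
# floors every entry, then promotes the largest fractional remainders
# (capped by the observed count) until the column total matches the
# rounded real-valued total.
round_preserving_colsums <- function(counts, native_x) {
  p <- counts@p
  x <- counts@x
  out <- floor(native_x)
  frac <- native_x - out
  target <- round(nz_colsums(counts, native_x))
  for (j in seq_len(ncol(counts))) {
    idx <- if (p[j + 1L] > p[j]) (p[j] + 1L):p[j + 1L] else integer()
    deficit <- target[j] - sum(out[idx])
    if (deficit > 0) {
      room <- x[idx] - out[idx]
      ord <- idx[order(frac[idx], decreasing = TRUE)]
      ord <- ord[x[ord] - out[ord] > 0][seq_len(min(deficit, sum(room > 0)))]
      out[ord] <- out[ord] + 1
    }
  }
  out
}
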