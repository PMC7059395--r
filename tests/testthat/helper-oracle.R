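# Independent transcript-level oracle: every UMI is its own transcript
# and all updates and the lower bound are computed by literal loops.
# Deliberately naive and independent of the package's aggregated,
# count-weighted implementation.

# one vector of gene indices per cell, ascending gene order
make_transcripts <- function(X) {
  m <- as.matrix(X)
  lapply(seq_len(ncol(m)), function(j) {
    rep(seq_len(nrow(m)), m[, j])
  })
}

# expand a per-nonzero vector (column-major, ascending gene within a
# cell, as stored by dgCMatrix) to per-transcript lists
expand_nz_to_transcripts <- function(X, v) {
  m <- as.matrix(X)
  out <- vector("list", ncol(m))
  idx <- 0L
  for (j in seq_len(ncol(m))) {
    nzg <- which(m[, j] > 0)
    out[[j]] <- rep(v[idx + seq_along(nzg)], m[nzg, j])
    idx <- idx + length(nzg)
  }
  out
}

# collapse per-transcript values back to one value per nonzero (they
# must be constant within a (cell, gene) pair)
collapse_transcripts_to_nz <- function(X, trans, vals) {
  m <- as.matrix(X)
  out <- numeric(0)
  for (j in seq_len(ncol(m))) {
    nzg <- which(m[, j] > 0)
    first <- match(nzg, trans[[j]])
    out <- c(out, vals[[j]][first])
  }
  out
}

oracle_pi <- function(trans, z, phi, eta, gamma) {
  lapply(seq_along(trans), function(j) {
    vapply(trans[[j]], function(g) {
      p1 <- phi[z[j], g] *
        exp(digamma(gamma[j, 1]) - digamma(gamma[j, 1] + gamma[j, 2]))
      p2 <- eta[z[j], g] *
        exp(digamma(gamma[j, 2]) - digamma(gamma[j, 1] + gamma[j, 2]))
      p1 / (p1 + p2)
    }, numeric(1))
  })
}

oracle_gamma <- function(trans, pis, a) {
  t(vapply(seq_along(trans), function(j) {
    c(a[1] + sum(pis[[j]]), a[2] + sum(1 - pis[[j]]))
  }, numeric(2)))
}

oracle_phi <- function(trans, z, pis, K, G, eps = 1e-20) {
  phi <- matrix(0, K, G)
  for (j in seq_along(trans)) {
    for (t in seq_along(trans[[j]])) {
      g <- trans[[j]][t]
      phi[z[j], g] <- phi[z[j], g] + pis[[j]][t]
    }
  }
  phi <- phi + eps
  phi / rowSums(phi)
}

oracle_eta <- function(trans, z, pis, K, G, eps = 1e-20) {
  eta <- matrix(0, K, G)
  for (k in seq_len(K)) {
    num <- numeric(G)
    for (j in seq_along(trans)) {
      if (z[j] == k) next
      for (t in seq_along(trans[[j]])) {
        num[trans[[j]][t]] <- num[trans[[j]][t]] + pis[[j]][t]
      }
    }
    eta[k, ] <- (num + eps) / sum(num + eps)
  }
  eta
}

# two-step construction: weights as each outside population's share of
# expected native transcripts, combined with that population's
# expected-native profile
oracle_eta_two_step <- function(trans, z, pis, K, G) {
  S <- numeric(K)
  prof <- matrix(0, K, G)
  for (j in seq_along(trans)) {
    for (t in seq_along(trans[[j]])) {
      g <- trans[[j]][t]
      prof[z[j], g] <- prof[z[j], g] + pis[[j]][t]
      S[z[j]] <- S[z[j]] + pis[[j]][t]
    }
  }
  prof <- prof / S
  eta <- matrix(0, K, G)
  w_all <- matrix(0, K, K)
  for (k in seq_len(K)) {
    w <- S
    w[k] <- 0
    w <- w / sum(w)
    w_all[k, ] <- w
    eta[k, ] <- colSums(w * prof)
  }
  list(eta = eta, weights = w_all)
}

oracle_elbo <- function(trans, z, pis, gamma, a, phi, eta) {
  M <- length(trans)
  el <- cbind(
    digamma(gamma[, 1]) - digamma(rowSums(gamma)),
    digamma(gamma[, 2]) - digamma(rowSums(gamma))
  )
  xlogx <- function(p) if (p > 0) p * log(p) else 0
  t7 <- t8 <- t9 <- t10 <- t11 <- 0
  for (j in seq_len(M)) {
    t7 <- t7 + lgamma(a[1] + a[2]) - lgamma(a[1]) - lgamma(a[2]) +
      (a[1] - 1) * el[j, 1] + (a[2] - 1) * el[j, 2]
    t10 <- t10 + lgamma(sum(gamma[j, ])) - lgamma(gamma[j, 1]) -
      lgamma(gamma[j, 2]) + (gamma[j, 1] - 1) * el[j, 1] +
      (gamma[j, 2] - 1) * el[j, 2]
    for (t in seq_along(trans[[j]])) {
      g <- trans[[j]][t]
      p1 <- pis[[j]][t]
      t8 <- t8 + p1 * el[j, 1] + (1 - p1) * el[j, 2]
      t9 <- t9 + p1 * log(phi[z[j], g]) + (1 - p1) * log(eta[z[j], g])
      t11 <- t11 + xlogx(p1) + xlogx(1 - p1)
    }
  }
  list(total = t7 + t8 + t9 - t10 - t11,
       t_prior = t7, t_assign = t8, t_emit = t9,
       t_q_theta = t10, t_q_y = t11)
}

# marginal objective of the Beta prior hyperparameters given the
# per-cell variational posteriors, for finite-difference checks
oracle_prior_objective <- function(a, gamma) {
  el <- cbind(
    digamma(gamma[, 1]) - digamma(rowSums(gamma)),
    digamma(gamma[, 2]) - digamma(rowSums(gamma))
  )
  sum(lgamma(a[1] + a[2]) - lgamma(a[1]) - lgamma(a[2]) +
        (a[1] - 1) * el[, 1] + (a[2] - 1) * el[, 2])
}

# a random tiny model instance for collapse-equivalence checks
random_tiny_instance <- function(seed) {
  set.seed(seed)
  M <- sample(2:3, 1)
  G <- sample(3:5, 1)
  K <- 2L
  X <- matrix(0L, G, M)
  for (j in seq_len(M)) {
    n <- sample(1:10, 1)
    draw <- sample.int(G, n, replace = TRUE)
    X[, j] <- tabulate(draw, G)
  }
  dimnames(X) <- list(sprintf("g%d", seq_len(G)), sprintf("c%d", seq_len(M)))
  Xs <- methods::as(Matrix::Matrix(X, sparse = TRUE), "CsparseMatrix")
  z <- c(1L, 2L, sample.int(K, M - 2L, replace = TRUE))
  rdir <- function(n) {
    v <- rgamma(n, 1) + 1e-3
    v / sum(v)
  }
  list(
    X = Xs, z = z, K = K, G = G, M = M,
    phi = t(replicate(K, rdir(G))),
    eta = t(replicate(K, rdir(G))),
    gamma = cbind(runif(M, 0.5, 5), runif(M, 0.5, 5)),
    a = runif(2, 0.5, 5),
    pi1 = runif(length(Xs@x), 0.05, 0.95)
  )
}

# a mid-sized random model instance for invariant sweeps
random_instance <- function(seed, M = 15, G = 25, K = 3) {
  set.seed(seed)
  sim <- simulate_ambient_counts(
    M = M, G = G, K = K, umis_per_cell = c(30, 80),
    profile_concentration = 0.5, seed = seed
  )
  sim
}
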