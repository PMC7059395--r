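# fixture: a small validated instance with handpicked state
tiny_fixture <- function() {
  X <- matrix(c(
    4, 0, 1,
    2, 3, 0,
    0, 2, 5,
    1, 1, 1
  ), nrow = 4, byrow = TRUE,
  dimnames = list(paste0("g", 1:4), paste0("c", 1:3)))
  Xs <- methods::as(Matrix::Matrix(X, sparse = TRUE), "CsparseMatrix")
  list(X = Xs, z = c(1L, 2L, 2L))
}

test_that("initialization honours its closed forms and invariants", {
  f <- tiny_fixture()
  N <- Matrix::colSums(f$X)
  init <- initialize_state(f$X, f$z, pi_init = 1, a1 = 3, a2 = 7)
  # pi_init = 1: all mass native, so gamma = (a1 + N, a2)
  expect_equal(unname(init$state$gamma[, 1]), unname(3 + N))
  expect_equal(unname(init$state$gamma[, 2]), rep(7, 3))
  expect_equal(contamination_fraction(init$state), 7 / (3 + 7 + N),
               ignore_attr = TRUE)

  init2 <- initialize_state(f$X, f$z, pi_init = 0.9)
  expect_equal(rowSums(init2$profiles$phi), rep(1, 2))
  expect_equal(rowSums(init2$profiles$eta), rep(1, 2))
  expect_equal(rowSums(init2$profiles$weights), rep(1, 2))
  expect_true(all(init2$profiles$phi > 0))
  expect_equal(unname(init2$state$gamma[, 1]), unname(10 + 0.9 * N))
})

test_that("disjoint expression blocks give one-hot-block initial profiles", {
  X <- rbind(
    matrix(5L, 3, 2), matrix(0L, 3, 2)
  )
  X <- cbind(X, rbind(matrix(0L, 3, 2), matrix(4L, 3, 2)))
  dimnames(X) <- list(paste0("g", 1:6), paste0("c", 1:4))
  init <- initialize_state(methods::as(Matrix::Matrix(X, sparse = TRUE),
                                       "CsparseMatrix"),
                           c(1L, 1L, 2L, 2L))
  expect_equal(unname(init$profiles$phi[1, ]),
               c(rep(1 / 3, 3), rep(0, 3)), tolerance = 1e-12)
  expect_equal(unname(init$profiles$phi[2, ]),
               c(rep(0, 3), rep(1 / 3, 3)), tolerance = 1e-12)
})

test_that("responsibility update matches hand-computed values", {
  # symmetric case: identical profiles and gamma components give 1/2
  f <- tiny_fixture()
  G <- nrow(f$X)
  profiles <- list(
    phi = matrix(1 / G, 2, G),
    eta = matrix(1 / G, 2, G)
  )
  state <- list(pi1 = rep(0.5, length(f$X@x)),
                gamma = cbind(rep(2, 3), rep(2, 3)),
                prior = c(1, 1))
  st <- update_responsibilities(f$X, f$z, profiles, state)
  expect_equal(st$pi1, rep(0.5, length(f$X@x)))

  # phi = 0.3, eta = 0.1, gamma = (2, 1): digamma(2) - digamma(3) = -1/2
  # and digamma(1) - digamma(3) = -3/2 exactly; one count on gene 1
  X2 <- methods::as(Matrix::Matrix(matrix(c(1, 0, 1, 0), 2, 2,
    dimnames = list(c("g1", "g2"), c("c1", "c2"))), sparse = TRUE),
    "CsparseMatrix")
  profiles2 <- list(
    phi = matrix(c(0.3, 0.7, 0.3, 0.7), 2, 2, byrow = TRUE),
    eta = matrix(c(0.1, 0.9, 0.1, 0.9), 2, 2, byrow = TRUE)
  )
  state2 <- list(pi1 = rep(0.5, 2),
                 gamma = cbind(c(2, 2), c(1, 1)),
                 prior = c(1, 1))
  st2 <- update_responsibilities(X2, c(1L, 2L), profiles2, state2)
  expected <- 0.3 * exp(-1 / 2) / (0.3 * exp(-1 / 2) + 0.1 * exp(-3 / 2))
  expect_equal(st2$pi1, rep(expected, 2), tolerance = 1e-12)
  expect_equal(expected, 0.8908, tolerance = 1e-4)

  # contamination probability at the smoothing floor: native dominates
  profiles3 <- list(
    phi = matrix(c(0.5, 0.5, 0.5, 0.5), 2, 2, byrow = TRUE),
    eta = matrix(c(1e-20, 1 - 1e-20, 1e-20, 1 - 1e-20), 2, 2, byrow = TRUE)
  )
  st3 <- update_responsibilities(X2, c(1L, 2L), profiles3, state2)
  expect_true(all(st3$pi1 > 1 - 1e-6))
})

test_that("responsibility update rejects inconsistent state", {
  f <- tiny_fixture()
  profiles <- list(phi = matrix(1 / 4, 2, 4), eta = matrix(1 / 4, 2, 4))
  bad_gamma <- list(pi1 = rep(0.5, length(f$X@x)),
                    gamma = cbind(c(-1, 1, 1), c(1, 1, 1)),
                    prior = c(1, 1))
  expect_error(update_responsibilities(f$X, f$z, profiles, bad_gamma),
               "positive")
  bad_profiles <- list(phi = matrix(1, 2, 4), eta = matrix(1 / 4, 2, 4))
  ok_state <- list(pi1 = rep(0.5, length(f$X@x)),
                   gamma = cbind(c(1, 1, 1), c(1, 1, 1)),
                   prior = c(1, 1))
  expect_error(update_responsibilities(f$X, f$z, bad_profiles, ok_state),
               "normalised")
})

test_that("Beta posterior update follows its closed form", {
  # all counts native, N_j = 100, a = (1, 1)
  X <- methods::as(Matrix::Matrix(matrix(c(60, 40, 50, 50), 2, 2,
    dimnames = list(c("g1", "g2"), c("c1", "c2"))), sparse = TRUE),
    "CsparseMatrix")
  st <- list(pi1 = rep(1, 4), gamma = NULL, prior = c(1, 1))
  st <- update_theta_posterior(X, st)
  expect_equal(unname(st$gamma), cbind(c(101, 101), c(1, 1)))

  # all pi = 0.5, N_j = 10, a = (2, 3)
  X2 <- methods::as(Matrix::Matrix(matrix(c(6, 4), 2, 1,
    dimnames = list(c("g1", "g2"), "c1")), sparse = TRUE), "CsparseMatrix")
  st2 <- list(pi1 = rep(0.5, 2), gamma = NULL, prior = c(2, 3))
  st2 <- update_theta_posterior(X2, st2)
  expect_equal(unname(st2$gamma), cbind(7, 8))

  # invariant: gamma_1 + gamma_2 = a1 + a2 + N_j
  set.seed(4)
  inst <- random_tiny_instance(99)
  st3 <- list(pi1 = inst$pi1, gamma = NULL, prior = inst$a)
  st3 <- update_theta_posterior(inst$X, st3)
  expect_equal(unname(rowSums(st3$gamma)),
               unname(sum(inst$a) + Matrix::colSums(inst$X)),
               tolerance = 1e-12)
})

test_that("native profile update reduces to empirical profiles and flags degeneracy", {
  f <- tiny_fixture()
  nnz <- length(f$X@x)
  phi <- update_native_profiles(f$X, f$z, list(pi1 = rep(1, nnz)))$phi
  raw <- as.matrix(f$X)
  expect_equal(unname(phi[1, ]), unname(raw[, 1] / sum(raw[, 1])),
               tolerance = 1e-12)
  expect_equal(unname(phi[2, ]),
               unname(rowSums(raw[, 2:3]) / sum(raw[, 2:3])),
               tolerance = 1e-12)

  expect_warning(
    phi0 <- update_native_profiles(f$X, f$z, list(pi1 = rep(0, nnz)))$phi,
    "zero expected native mass"
  )
  expect_equal(unname(phi0), matrix(1 / 4, 2, 4), tolerance = 1e-12)
})

test_that("native profile update matches a loop-based oracle", {
  inst <- random_tiny_instance(7)
  trans <- make_transcripts(inst$X)
  pis <- expand_nz_to_transcripts(inst$X, inst$pi1)
  got <- update_native_profiles(inst$X, inst$z,
                                list(pi1 = inst$pi1))$phi
  want <- oracle_phi(trans, inst$z, pis, inst$K, inst$G)
  expect_equal(unname(got), want, tolerance = 1e-12)
})

test_that("two-population contamination profiles swap expected-native profiles", {
  f <- tiny_fixture()
  set.seed(12)
  state <- list(pi1 = runif(length(f$X@x), 0.2, 0.9))
  upd <- update_contamination_profiles(f$X, f$z, state)
  nat <- as.matrix(f$X) * 0
  tr <- Matrix::summary(f$X)
  nat[cbind(tr$i, tr$j)] <- tr$x * state$pi1
  prof2 <- rowSums(nat[, f$z == 2, drop = FALSE])
  expect_equal(unname(upd$eta[1, ]), unname(prof2 / sum(prof2)),
               tolerance = 1e-10)
  prof1 <- nat[, f$z == 1]
  expect_equal(unname(upd$eta[2, ]), unname(prof1 / sum(prof1)),
               tolerance = 1e-10)
  expect_equal(rowSums(upd$eta), rep(1, 2), tolerance = 1e-10)
  expect_equal(rowSums(upd$weights), rep(1, 2), tolerance = 1e-10)
})

test_that("direct contamination update equals the weights-then-combine construction", {
  for (seed in c(3, 14, 15)) {
    set.seed(seed)
    M <- 9
    G <- 6
    X <- matrix(rpois(G * M, 2) + 1, G, M,
                dimnames = list(paste0("g", 1:G), paste0("c", 1:M)))
    Xs <- methods::as(Matrix::Matrix(X, sparse = TRUE), "CsparseMatrix")
    z <- rep(1:3, each = 3)
    st <- list(pi1 = runif(length(Xs@x), 0.1, 0.95))
    got <- update_contamination_profiles(Xs, z, st, epsilon = 0)
    trans <- make_transcripts(Xs)
    pis <- expand_nz_to_transcripts(Xs, st$pi1)
    want <- oracle_eta_two_step(trans, z, pis, 3, G)
    expect_equal(unname(got$eta), want$eta, tolerance = 1e-12)
    expect_equal(unname(got$weights), want$weights, tolerance = 1e-12)
  }
})

test_that("contamination profiles rise with expression outside the population", {
  f <- tiny_fixture()
  st <- list(pi1 = rep(0.8, length(f$X@x)))
  base <- update_contamination_profiles(f$X, f$z, st)
  # add counts of gene 1 to a cell outside population 1 (cell 2, pop 2)
  X2 <- as.matrix(f$X)
  X2["g1", "c2"] <- X2["g1", "c2"] + 10
  Xs2 <- methods::as(Matrix::Matrix(X2, sparse = TRUE), "CsparseMatrix")
  st2 <- list(pi1 = rep(0.8, length(Xs2@x)))
  more <- update_contamination_profiles(Xs2, f$z, st2)
  expect_gt(more$eta[1, "g1"], base$eta[1, "g1"])
})
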