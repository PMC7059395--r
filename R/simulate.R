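#' Simulate population expression profiles
#'
#' Draws `K` gene-probability vectors from a symmetric Dirichlet
#' distribution (gamma draws normalised per row). Small concentrations
#' give the spiky, heavy-tailed profiles typical of real expression
#' data; concentration `-> Inf` approaches uniform.
#'
#' @param K Number of populations (>= 2).
#' @param G Number of genes.
#' @param concentration Symmetric Dirichlet concentration (default 0.1).
#' @param seed Optional integer seed.
#' @return `K x G` matrix, rows summing to 1.
#' @export
simulate_profiles <- function(K, G, concentration = 0.1, seed = NULL) {
  if (K < 2L) stop("K must be at least 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  phi <- matrix(rgamma(K * G, shape = concentration, rate = 1), K, G)
  # guard against all-zero rows at tiny concentrations
  zero <- rowSums(phi) == 0
  phi[zero, ] <- 1 / G
  phi / rowSums(phi)
}

#' Simulate contaminated single-cell counts with known ground truth
#'
#' Emulates the generative process of droplet contamination: each cell
#' draws a population `z_j`, a native proportion `theta_j` from
#' `Beta(beta_a1, beta_a2)` (or a fixed value), and a depth `N_j`; it
#' then receives `round(theta_j * N_j)` native transcripts from its own
#' population's multinomial profile and the remainder from a weighted
#' combination of the other populations' profiles. With
#' `contamination_weights = "native_mass"` the weights are proportional
#' to each other population's expected total native UMIs (its expected
#' contribution to the ambient pool); `"uniform"` weights all other
#' populations equally.
#'
#' @param true_phi `K x G` matrix of population profiles, or `NULL` to
#'   draw them via [simulate_profiles()].
#' @param M Number of cells (default 600).
#' @param G Number of genes (default 500); ignored when `true_phi` is
#'   given.
#' @param K Number of populations (default 3); ignored when `true_phi`
#'   is given.
#' @param umis_per_cell Fixed UMI depth per cell, or a length-2 range
#'   sampled uniformly (default 1000).
#' @param beta_a1,beta_a2 Beta prior of the native proportion
#'   (default 8 and 2: mean contamination 20%).
#' @param theta Optional fixed native proportion for every cell,
#'   overriding the Beta draw.
#' @param cluster_proportions Length-`K` probability vector of
#'   population sizes (default uniform).
#' @param profile_concentration Dirichlet concentration for drawn
#'   profiles (default 0.1).
#' @param contamination_weights `"native_mass"` (default) or
#'   `"uniform"`.
#' @param seed Optional integer seed; same seed gives bit-identical
#'   output.
#' @return List with `counts` (genes x cells `dgCMatrix`), `labels`
#'   (integer populations), `true_phi`, `true_theta` (drawn native
#'   proportions), `true_native_counts`, `true_contamination_counts`
#'   (integer matrices summing to `counts` exactly) and
#'   `true_contamination` (realised per-cell contamination fraction,
#'   contamination column sum over depth).
#' @examples
#' sim <- simulate_ambient_counts(M = 50, G = 30, K = 2,
#'   umis_per_cell = 100, seed = 1)
#' mean(sim$true_contamination)
#' @export
simulate_ambient_counts <- function(true_phi = NULL, M = 600, G = 500,
                                    K = 3, umis_per_cell = 1000,
                                    beta_a1 = 8, beta_a2 = 2,
                                    theta = NULL,
                                    cluster_proportions = NULL,
                                    profile_concentration = 0.1,
                                    contamination_weights = c(
                                      "native_mass", "uniform"),
                                    seed = NULL) {
  contamination_weights <- match.arg(contamination_weights)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(true_phi)) {
    true_phi <- simulate_profiles(K, G, profile_concentration)
  } else {
    true_phi <- as.matrix(true_phi)
    K <- nrow(true_phi)
    G <- ncol(true_phi)
  }
  if (K < 2L) stop("K must be at least 2", call. = FALSE)
  if (is.null(cluster_proportions)) {
    cluster_proportions <- rep(1 / K, K)
  }
  if (length(cluster_proportions) != K ||
      abs(sum(cluster_proportions) - 1) > 1e-8 ||
      any(cluster_proportions <= 0)) {
    stop("cluster_proportions must be K positive values summing to 1",
      call. = FALSE)
  }
  if (M < K) stop("M must be at least K", call. = FALSE)
  if (any(umis_per_cell < 1) || length(umis_per_cell) > 2) {
    stop("umis_per_cell must be a positive count or a length-2 range",
      call. = FALSE)
  }

  z <- sample.int(K, M, replace = TRUE, prob = cluster_proportions)
  # guarantee non-empty populations so the labels are valid model input
  z[seq_len(K)] <- sample.int(K, K)

  N <- if (length(umis_per_cell) == 2L) {
    sample(seq.int(umis_per_cell[1], umis_per_cell[2]), M, replace = TRUE)
  } else {
    rep.int(as.integer(umis_per_cell), M)
  }
  th <- if (is.null(theta)) rbeta(M, beta_a1, beta_a2) else rep_len(theta, M)

  # expected native UMI mass contributed by each population to the pool
  pool_mass <- cluster_proportions * mean(N) *
    (if (is.null(theta)) beta_a1 / (beta_a1 + beta_a2) else mean(th))

  native <- matrix(0L, G, M)
  contam <- matrix(0L, G, M)
  for (j in seq_len(M)) {
    n_nat <- round(th[j] * N[j])
    n_con <- N[j] - n_nat
    if (n_nat > 0) {
      native[, j] <- rmultinom(1, n_nat, true_phi[z[j], ])
    }
    if (n_con > 0) {
      w <- if (contamination_weights == "native_mass") {
        pool_mass
      } else {
        rep(1, K)
      }
      w[z[j]] <- 0
      w <- w / sum(w)
      contam[, j] <- rmultinom(1, n_con, colSums(w * true_phi))
    }
  }

  counts <- native + contam
  dimnames(counts) <- list(sprintf("gene_%d", seq_len(G)),
                           sprintf("cell_%d", seq_len(M)))
  dimnames(native) <- dimnames(counts)
  dimnames(contam) <- dimnames(counts)
  list(
    counts = as_count_matrix(counts),
    labels = normalize_labels(z),
    true_phi = true_phi,
    true_theta = th,
    true_native_counts = native,
    true_contamination_counts = contam,
    true_contamination = colSums(contam) / N
  )
}
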