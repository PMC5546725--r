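# Shared fixtures and independent oracles. Expensive objects are built once
# per session and cached.

.fixtures <- new.env(parent = emptyenv())

# random symmetric z matrix with NA diagonal
rsym <- function(n, mean = 0, sd = 0.3) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- stats::rnorm(n * (n - 1) / 2, mean, sd)
  m <- m + t(m)
  diag(m) <- NA_real_
  m
}

# assemble a query z-data object directly from z matrices
make_zdata <- function(zmats, theta0, sigma0_sq, present = NULL) {
  n <- nrow(zmats[[1]])
  D <- length(zmats)
  z <- array(NA_real_, c(n, n, D))
  for (d in seq_len(D)) {
    m <- zmats[[d]]
    diag(m) <- NA_real_
    z[, , d] <- m
  }
  if (is.null(present)) present <- matrix(TRUE, n, D)
  structure(list(query = sprintf("g%02d", seq_len(n)), z = z,
                 present = present, theta0 = theta0, sigma0_sq = sigma0_sq,
                 dataset_ids = sprintf("ds%02d", seq_len(D))),
            class = "clic_zdata")
}

# independent 2-D quadrature of the Normal-Inverse-Gamma marginal: integrates
# the raw integrand prod_c N(z_c | theta, s2) N(theta | mu, s2/kappa)
# InvGamma(s2 | alpha, beta) over (theta, s2) with pracma::integral2
quad_nig <- function(zs, ctl) {
  a <- ctl$alpha_sigma; b <- ctl$beta_sigma
  mu <- ctl$mu_theta; kap <- ctl$kappa_theta
  C <- length(zs)
  s2lo <- b / stats::qgamma(1 - 1e-13, a)
  s2hi <- b / stats::qgamma(1e-13, a)
  pm <- (kap * mu + sum(zs)) / (kap + C)
  sd_th <- sqrt(s2hi / (kap + C))
  logf <- function(th, s2) {
    ll <- 0
    for (z in zs) ll <- ll + stats::dnorm(z, th, sqrt(s2), log = TRUE)
    ll + stats::dnorm(th, mu, sqrt(s2 / kap), log = TRUE) +
      a * log(b) - lgamma(a) - (a + 1) * log(s2) - b / s2
  }
  shift <- logf(pm, b / (a + 1))
  q <- pracma::integral2(function(t, s) exp(logf(t, s) - shift),
                         pm - 12 * sd_th, pm + 12 * sd_th, s2lo, s2hi,
                         reltol = 1e-11)
  log(q$Q) + shift
}

# brute-force marginalization over all dataset-selection configurations
# S in {0,1}^(D x K); uses dnorm sums for the background branch
brute_collapsed <- function(I, zd, ctl, K) {
  n <- length(I)
  D <- length(zd$dataset_ids)
  terms <- numeric(2^(K * D))
  for (bits in seq_along(terms) - 1L) {
    S <- matrix(as.integer(intToBits(bits))[seq_len(K * D)], D, K)
    lp <- sum(S) * log(ctl$pi_s) + (K * D - sum(S)) * log(1 - ctl$pi_s)
    for (d in seq_len(D)) {
      for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
        fg <- I[i] == I[j] && I[i] > 0 && S[d, I[i]] == 1
        if (!fg)
          lp <- lp + stats::dnorm(zd$z[i, j, d], zd$theta0[d],
                                  sqrt(zd$sigma0_sq[d]), log = TRUE)
      }
      for (k in seq_len(K)) if (S[d, k] == 1) {
        idx <- which(I == k)
        zs <- if (length(idx) >= 2)
          zd$z[idx, idx, d][upper.tri(diag(length(idx)))] else numeric()
        lp <- lp + log_nig_marginal(zs, ctl)
      }
    }
    terms[bits + 1L] <- lp
  }
  m <- max(terms)
  m + log(sum(exp(terms - m)))
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

# small compendium with one planted module, a pool, and a hub; shared by the
# unit tests (10 datasets x 30 samples, 68 genes)
tiny_sim_config <- function(seed = 42) {
  sim_config(n_datasets = 10, samples_per_dataset = 30,
             n_background_genes = 150,
             modules = list(module_spec(sprintf("tmA%d", 1:5), 1:3, 0.81,
                                        pool = c("tpA1", "tpA2"))),
             hub_genes = "thub1", seed = seed)
}

get_tiny_comp <- function() {
  if (is.null(.fixtures$tiny)) {
    sim <- simulate_compendium(tiny_sim_config())
    .fixtures$tiny <- list(sim = sim,
                           comp = build_compendium(sim$datasets),
                           query = c(sprintf("tmA%d", 1:5),
                                     sprintf("bg%03d", 1:3)))
  }
  .fixtures$tiny
}

tiny_control <- function(seed = 11)
  clic_control(k_bar = 3, sweeps = 300, seed = seed)

get_tiny_fit <- function() {
  if (is.null(.fixtures$tiny_fit)) {
    tc <- get_tiny_comp()
    .fixtures$tiny_fit <- clic(tc$query, tc$comp, tiny_control())
  }
  .fixtures$tiny_fit
}
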