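#' Hyperparameters of the partition model
#'
#' Conjugate priors: within-CEM z-correlations in a selected dataset are
#' N(theta, sigma^2) with theta ~ N(`mu_theta`, sigma^2 / `kappa_theta`) and
#' sigma^2 ~ Inv-Gamma(`alpha_sigma`, `beta_sigma`); dataset selection
#' indicators are Bernoulli(`pi_s`); the partition prior is
#' P(I) proportional to exp(-`v_k` K), K being the number of labels occupied
#' by at least two genes.
#'
#' @param mu_theta Prior mean of the within-CEM z-correlation (default 1.5,
#'   i.e. Pearson ~ 0.9).
#' @param kappa_theta Prior precision scale for theta (default 100).
#' @param alpha_sigma,beta_sigma Inverse-gamma shape and rate for sigma^2
#'   (defaults 1000, 1000: sigma^2 concentrated near 1, matching the
#'   variance-stabilized z scale).
#' @param pi_s Prior probability that a dataset supports a CEM (default 0.1).
#' @param v_k Penalty on the number of modules; `NULL` (default) means n/D,
#'   filled in at fit time.
#' @param k_bar Maximum number of CEM labels; one fixed-K chain is run for
#'   each K in 1..`k_bar` (default 5).
#' @param sweeps Gibbs sweeps per chain (default 1000).
#' @param seed Integer RNG seed (default 1). Chain K uses stream offset
#'   `seed + K`.
#' @return A list of class `"clic_control"`.
#' @export
clic_control <- function(mu_theta = 1.5, kappa_theta = 100,
                         alpha_sigma = 1000, beta_sigma = 1000,
                         pi_s = 0.1, v_k = NULL, k_bar = 5L,
                         sweeps = 1000L, seed = 1L) {
  stopifnot(kappa_theta > 0, alpha_sigma > 0, beta_sigma > 0,
            pi_s > 0, pi_s < 1, is.null(v_k) || v_k >= 0,
            k_bar >= 1, sweeps >= 1)
  structure(list(mu_theta = mu_theta, kappa_theta = kappa_theta,
                 alpha_sigma = alpha_sigma, beta_sigma = beta_sigma,
                 pi_s = pi_s, v_k = v_k, k_bar = as.integer(k_bar),
                 sweeps = as.integer(sweeps), seed = as.integer(seed)),
            class = "clic_control")
}

#' Marginal likelihood of a set of z values under the co-expression model
#'
#' Log of the Normal-Inverse-Gamma marginal
#' \deqn{\int\int \prod_c N(z_c \mid \theta, \sigma^2)\,
#'   d\pi(\theta)\,d\pi(\sigma^2)}
#' under theta ~ N(mu, sigma^2/kappa), sigma^2 ~ Inv-Gamma(alpha, beta).
#' Computed entirely in log space via `lgamma`. The empty set returns 0.
#'
#' @param zs Numeric vector of z-correlations (may be empty).
#' @param control A [clic_control()] supplying the hyperparameters.
#' @return Log marginal likelihood (scalar).
#' @export
log_nig_marginal <- function(zs, control = clic_control()) {
  .nig_m1(length(zs), sum(zs), sum(zs^2), control)
}

# sufficient-statistic form, vectorized over (C, Sz, Szz)
.nig_m1 <- function(C, Sz, Szz, control) {
  mu <- control$mu_theta; kap <- control$kappa_theta
  a <- control$alpha_sigma; b <- control$beta_sigma
  beta_n <- b + 0.5 * (Szz + kap * mu^2 - (kap * mu + Sz)^2 / (kap + C))
  if (any(beta_n <= 0)) stop("internal error: non-positive posterior scale")
  -C / 2 * log(2 * pi) + 0.5 * (log(kap) - log(kap + C)) +
    a * log(b) - lgamma(a) + lgamma(a + C / 2) - (a + C / 2) * log(beta_n)
}

#' Log-likelihood of z values under a background distribution
#'
#' Sum of normal log-densities N(z | theta0, sigma0_sq); the empty set
#' returns 0.
#'
#' @param zs Numeric vector of z-correlations.
#' @param theta0,sigma0_sq Background mean and variance.
#' @return Scalar log-likelihood.
#' @export
log_background_lik <- function(zs, theta0, sigma0_sq) {
  stopifnot(sigma0_sq > 0)
  .bg_m0(length(zs), sum(zs), sum(zs^2), theta0, sigma0_sq)
}

.bg_m0 <- function(C, Sz, Szz, theta0, sigma0_sq) {
  -C / 2 * log(2 * pi * sigma0_sq) -
    (Szz - 2 * theta0 * Sz + C * theta0^2) / (2 * sigma0_sq)
}

.logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  m + log(exp(a - m) + exp(b - m))
}

#' Extract query z-correlation data from a compendium
#'
#' Builds, for each QC-passing dataset, the symmetric z-correlation
#' sub-matrix among the query genes (entries `NA` where a gene is absent
#' from the dataset) together with the dataset background moments.
#'
#' @param compendium A `"clic_compendium"`.
#' @param query Character vector of query gene identifiers.
#' @return A list of class `"clic_zdata"` with elements `query` (genes
#'   present in at least one dataset, query order), `z` (n x n x D array),
#'   `present` (n x D logical), `theta0`, `sigma0_sq`, `dataset_ids`.
#' @export
query_zdata <- function(compendium, query) {
  stopifnot(inherits(compendium, "clic_compendium"))
  query <- unique(as.character(query))
  entries <- compendium$datasets
  if (!length(entries)) stop("compendium has no QC-passing datasets")
  present_any <- vapply(entries, function(e) query %in% rownames(e$expr),
                        logical(length(query)))
  present_any <- matrix(present_any, nrow = length(query))
  keep <- rowSums(present_any) > 0L
  if (any(!keep))
    warning("query gene(s) absent from every dataset: ",
            paste(query[!keep], collapse = ", "))
  query <- query[keep]
  n <- length(query)
  if (n < 2L)
    stop("a co-expression query requires at least 2 genes measured in the compendium")
  D <- length(entries)
  z <- array(NA_real_, dim = c(n, n, D), dimnames = list(query, query, names(entries)))
  present <- matrix(FALSE, n, D, dimnames = list(query, names(entries)))
  theta0 <- numeric(D); sigma0_sq <- numeric(D)
  for (d in seq_len(D)) {
    e <- entries[[d]]
    idx <- intersect(query, rownames(e$expr))
    theta0[d] <- e$background$theta0
    sigma0_sq[d] <- e$background$sigma0_sq
    if (length(idx) >= 2L) {
      zz <- fisher_z(stats::cor(t(e$expr[idx, , drop = FALSE])))
      diag(zz) <- NA_real_
      z[idx, idx, d] <- zz
      present[idx, d] <- TRUE
    } else if (length(idx) == 1L) {
      present[idx, d] <- TRUE
    }
  }
  structure(list(query = query, z = z, present = present,
                 theta0 = theta0, sigma0_sq = sigma0_sq,
                 dataset_ids = names(entries)),
            class = "clic_zdata")
}

# within-CEM sufficient statistics for label k in dataset d
.cem_stats <- function(zdata, I, k) {
  idx <- which(I == k)
  D <- length(zdata$dataset_ids)
  C <- Sz <- Szz <- numeric(D)
  if (length(idx) >= 2L) {
    for (d in seq_len(D)) {
      zs <- zdata$z[idx, idx, d][upper.tri(diag(length(idx)))]
      zs <- zs[is.finite(zs)]
      C[d] <- length(zs); Sz[d] <- sum(zs); Szz[d] <- sum(zs^2)
    }
  }
  list(C = C, Sz = Sz, Szz = Szz)
}

#' Collapsed log-likelihood of a membership configuration
#'
#' log P(Z | I) with the dataset-selection indicators S marginalized out:
#' the background log-likelihood of all pairs plus, for every dataset d and
#' CEM k, log-sum-exp of the selected branch (pi_s times the NIG marginal of
#' the within-CEM pairs) and the unselected branch ((1 - pi_s) times their
#' background likelihood), minus the background term counted in the total.
#'
#' @param I Integer membership vector over `zdata$query` with values in
#'   0..K (0 = null group).
#' @param zdata A [query_zdata()] object.
#' @param control A [clic_control()].
#' @return Scalar log-likelihood.
#' @export
log_collapsed_lik <- function(I, zdata, control = clic_control()) {
  stopifnot(length(I) == length(zdata$query), all(I >= 0))
  D <- length(zdata$dataset_ids)
  total_bg <- 0
  for (d in seq_len(D)) {
    zs <- zdata$z[, , d][upper.tri(diag(length(I)))]
    zs <- zs[is.finite(zs)]
    total_bg <- total_bg + log_background_lik(zs, zdata$theta0[d], zdata$sigma0_sq[d])
  }
  extra <- 0
  for (k in seq_len(max(0L, max(I)))) {
    st <- .cem_stats(zdata, I, k)
    m1 <- .nig_m1(st$C, st$Sz, st$Szz, control)
    m0 <- .bg_m0(st$C, st$Sz, st$Szz, zdata$theta0, zdata$sigma0_sq)
    extra <- extra + sum(.logsumexp2(log(control$pi_s) + m1,
                                     log1p(-control$pi_s) + m0) - m0)
  }
  total_bg + extra
}

#' Log prior of a membership configuration
#'
#' P(I) proportional to exp(-v_k K) where K is the number of module labels
#' occupied by at least two genes (singletons and the null group carry no
#' penalty). Returned up to the constant of proportionality, which cancels
#' in all posterior comparisons.
#'
#' @param I Integer membership vector (0 = null group).
#' @param v_k Penalty intensity.
#' @return Scalar log prior (up to a constant).
#' @export
log_prior_partition <- function(I, v_k) {
  occ <- if (any(I > 0)) sum(tabulate(I[I > 0]) >= 2L) else 0L
  -v_k * occ
}
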