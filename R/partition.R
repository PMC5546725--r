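#' Partition a query gene set into co-expressed modules
#'
#' Fits the Bayesian partition model: module memberships are sampled by a
#' collapsed Gibbs sampler (per-CEM Normal parameters and dataset-selection
#' indicators integrated out analytically), one fixed-K chain per K in
#' 1..`k_bar`, each initialized with every gene in the null group. The
#' maximum a posteriori configuration over all chains and sweeps is
#' returned, with CEMs relabelled in decreasing size order and singleton
#' labels demoted to the null group. Conditional on the MAP partition, the
#' per-dataset per-CEM means and variances are estimated by maximum
#' likelihood, each dataset receives a posterior selection weight, and each
#' CEM a strength score phi (weighted average log Bayes factor; phi > 0.1
#' indicates co-expression, phi > 1 strong co-expression).
#'
#' @param query Character vector of at least 2 query gene identifiers.
#' @param compendium A preprocessed `"clic_compendium"` from
#'   [build_compendium()].
#' @param control Hyperparameters and sampler settings, see [clic_control()].
#' @param no_partition If `TRUE`, skip the sampler and treat the whole query
#'   as a single CEM (ablation of the partition step).
#' @return An object of class `"clic"` with elements `membership` (named
#'   integer vector, 0 = null), `k_hat`, `cems` (list of gene-id vectors),
#'   `theta_hat`, `sigma_sq_hat`, `weights` (D x K matrices; rows named by
#'   dataset), `phi`, `log_posterior`, `diagnostics`, `zdata`, `control`,
#'   and the `compendium` (for [predict.clic()]).
#' @examples
#' cfg <- sim_config(n_datasets = 8, samples_per_dataset = 20,
#'                   n_background_genes = 40,
#'                   modules = list(module_spec(paste0("m", 1:4), 1:3, 0.81)),
#'                   seed = 1)
#' comp <- build_compendium(simulate_compendium(cfg)$datasets)
#' fit <- clic(c(paste0("m", 1:4), "bg001", "bg002"), comp,
#'             clic_control(sweeps = 100, seed = 1))
#' fit
#' @export
clic <- function(query, compendium, control = clic_control(),
                 no_partition = FALSE) {
  stopifnot(inherits(compendium, "clic_compendium"))
  if (length(query) < 2L)
    stop("a co-expression query requires at least 2 genes; ",
         "the method cannot be run on a single gene")
  zdata <- query_zdata(compendium, query)
  n <- length(zdata$query)
  D <- length(zdata$dataset_ids)
  if (is.null(control$v_k)) control$v_k <- n / D

  diagnostics <- NULL
  if (no_partition) {
    I_best <- rep(1L, n)
  } else {
    I_best <- rep(0L, n)
    lp_best <- -Inf
    per_k <- numeric(control$k_bar)
    for (K in seq_len(control$k_bar)) {
      set.seed(control$seed + K)
      ch <- run_gibbs_chain(zdata, K = K, sweeps = control$sweeps,
                            control = control)
      per_k[K] <- ch$logpost_best
      if (ch$logpost_best > lp_best) {  # ties keep the smaller K (parsimony)
        lp_best <- ch$logpost_best
        I_best <- ch$I_best
      }
    }
    diagnostics <- list(logpost_by_k = per_k)
  }

  I_hat <- relabel_partition(I_best)
  K_hat <- max(I_hat, 0L)
  names(I_hat) <- zdata$query
  cems <- lapply(seq_len(K_hat), function(k) zdata$query[I_hat == k])

  params <- mle_cem_params(I_hat, zdata)
  w <- dataset_weights(I_hat, zdata, control)
  phi <- cem_strength(I_hat, zdata, control, weights = w)
  lp <- log_prior_partition(I_hat, control$v_k) +
    log_collapsed_lik(I_hat, zdata, control)

  structure(
    list(membership = I_hat, k_hat = K_hat, cems = cems,
         theta_hat = params$theta_hat, sigma_sq_hat = params$sigma_sq_hat,
         weights = w, phi = phi, log_posterior = lp,
         diagnostics = diagnostics, zdata = zdata, control = control,
         no_partition = no_partition, compendium = compendium),
    class = "clic")
}

#' Run one fixed-K collapsed Gibbs chain
#'
#' Low-level access to the sampler: `sweeps` full sweeps over the genes in
#' fixed ascending index order, each gene's label drawn from its conditional
#' over \{0, 1, ..., K\} (the null label included). Randomness comes from R's
#' generator, so `set.seed()` beforehand makes the trajectory reproducible.
#'
#' @param zdata A [query_zdata()] object.
#' @param K Number of module labels in this chain.
#' @param sweeps Number of sweeps.
#' @param control A [clic_control()]; `v_k = NULL` is replaced by n/D.
#' @param init Initial membership vector (default all-null).
#' @param track_states If `TRUE`, return the membership vector after every
#'   sweep (rows of `$states`).
#' @return List with `I_best`, `logpost_best`, `lp_sweep`, and (optionally)
#'   `states`.
#' @export
run_gibbs_chain <- function(zdata, K, sweeps, control = clic_control(),
                            init = NULL, track_states = FALSE) {
  stopifnot(inherits(zdata, "clic_zdata"), K >= 1, sweeps >= 1)
  n <- length(zdata$query)
  if (is.null(control$v_k)) control$v_k <- n / length(zdata$dataset_ids)
  if (is.null(init)) init <- rep(0L, n)
  stopifnot(length(init) == n, all(init >= 0L), all(init <= K))
  present <- zdata$present
  storage.mode(present) <- "integer"
  res <- .gibbs_chain_cpp(zdata$z, present, zdata$theta0, zdata$sigma0_sq,
                          as.integer(K), as.integer(sweeps),
                          control$mu_theta, control$kappa_theta,
                          control$alpha_sigma, control$beta_sigma,
                          control$pi_s, control$v_k,
                          isTRUE(track_states), as.integer(init))
  if (!track_states) res$states <- NULL
  res
}

#' One Gibbs sweep over the membership vector
#'
#' Convenience wrapper around [run_gibbs_chain()] performing a single sweep
#' from a given state and returning the updated membership vector.
#'
#' @inheritParams run_gibbs_chain
#' @param state Integer membership vector in \{0, ..., K\}.
#' @return The updated membership vector.
#' @export
gibbs_sweep <- function(state, zdata, K = max(state, 1L),
                        control = clic_control()) {
  res <- run_gibbs_chain(zdata, K = K, sweeps = 1L, control = control,
                         init = as.integer(state), track_states = TRUE)
  as.integer(res$states[1L, ])
}

# canonical form: labels in decreasing CEM size (first-seen order breaks
# ties), singleton labels demoted to null
relabel_partition <- function(I) {
  I <- as.integer(I)
  if (!any(I > 0)) return(I)
  sizes <- tabulate(I[I > 0])
  I[I > 0 & sizes[pmax(I, 1L)] < 2L] <- 0L
  labs <- which(sizes >= 2L)
  if (!length(labs)) return(I)
  labs <- labs[order(-sizes[labs], labs)]
  out <- I
  for (new in seq_along(labs)) out[I == labs[new]] <- new
  out
}

#' Maximum-likelihood CEM parameters conditional on a partition
#'
#' Per dataset d and CEM k, the sample mean and population variance of the
#' within-CEM z-correlations. Variances are floored at `var_floor` so that a
#' CEM with a single pair (or zero empirical variance) in a dataset keeps
#' the expansion densities finite. CEMs with no pair in a dataset get `NA`.
#'
#' @param I Membership vector (0 = null).
#' @param zdata A [query_zdata()] object.
#' @param var_floor Lower bound on the variance estimates (default 1e-6).
#' @return List of D x K matrices `theta_hat` and `sigma_sq_hat`.
#' @export
mle_cem_params <- function(I, zdata, var_floor = 1e-6) {
  K <- max(I, 0L)
  D <- length(zdata$dataset_ids)
  theta <- sig <- matrix(NA_real_, D, K,
                         dimnames = list(zdata$dataset_ids, NULL))
  for (k in seq_len(K)) {
    st <- .cem_stats(zdata, I, k)
    has <- st$C > 0
    theta[has, k] <- st$Sz[has] / st$C[has]
    sig[has, k] <- pmax(st$Szz[has] / st$C[has] - theta[has, k]^2, var_floor)
  }
  list(theta_hat = theta, sigma_sq_hat = sig)
}

#' Posterior dataset-selection weights
#'
#' For each dataset d and CEM k, the posterior probability that d supports
#' k: `pi_s * m1 / (pi_s * m1 + (1 - pi_s) * m0)` on the natural scale,
#' where m1 is the NIG marginal of the within-CEM z-correlations and m0
#' their background likelihood. A CEM with no pair in a dataset has equal
#' marginals and weight `pi_s`.
#'
#' @inheritParams mle_cem_params
#' @param control A [clic_control()].
#' @return D x K matrix of weights in (0, 1), rows named by dataset.
#' @export
dataset_weights <- function(I, zdata, control = clic_control()) {
  K <- max(I, 0L)
  D <- length(zdata$dataset_ids)
  w <- matrix(NA_real_, D, K, dimnames = list(zdata$dataset_ids, NULL))
  for (k in seq_len(K)) {
    st <- .cem_stats(zdata, I, k)
    m1 <- .nig_m1(st$C, st$Sz, st$Szz, control)
    m0 <- .bg_m0(st$C, st$Sz, st$Szz, zdata$theta0, zdata$sigma0_sq)
    w[, k] <- stats::plogis(log(control$pi_s) - log1p(-control$pi_s) + m1 - m0)
  }
  w
}

#' CEM strength
#'
#' phi_k = (1/D) sum_d p_hat\[d, k\] (log m1 - log m0): the average over all
#' datasets of the log Bayes factor comparing the within-CEM foreground
#' marginal to the dataset background, weighted by the posterior selection
#' probability. phi > 0.1 is read as "co-expressed", phi > 1 as "strongly
#' co-expressed".
#'
#' @inheritParams dataset_weights
#' @param weights Optional precomputed matrix from [dataset_weights()].
#' @return Numeric vector of length K.
#' @export
cem_strength <- function(I, zdata, control = clic_control(), weights = NULL) {
  K <- max(I, 0L)
  if (is.null(weights)) weights <- dataset_weights(I, zdata, control)
  D <- length(zdata$dataset_ids)
  phi <- numeric(K)
  for (k in seq_len(K)) {
    st <- .cem_stats(zdata, I, k)
    m1 <- .nig_m1(st$C, st$Sz, st$Szz, control)
    m0 <- .bg_m0(st$C, st$Sz, st$Szz, zdata$theta0, zdata$sigma0_sq)
    phi[k] <- sum(weights[, k] * (m1 - m0)) / D
  }
  phi
}
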