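ctl <- clic_control()

test_that("gibbs chains are reproducible given the seed", {
  set.seed(17)
  zd <- make_zdata(lapply(1:3, function(d) rsym(6, 0.3, 0.4)),
                   rep(0, 3), rep(0.09, 3))
  set.seed(7)
  ch1 <- run_gibbs_chain(zd, K = 2, sweeps = 40, control = ctl,
                         track_states = TRUE)
  set.seed(7)
  ch2 <- run_gibbs_chain(zd, K = 2, sweeps = 40, control = ctl,
                         track_states = TRUE)
  expect_identical(ch1$states, ch2$states)
  expect_identical(ch1$logpost_best, ch2$logpost_best)
})

test_that("the incremental sampler log-posterior matches full recomputation", {
  set.seed(18)
  zd <- make_zdata(lapply(1:4, function(d) rsym(7, 0.3, 0.5)),
                   runif(4, -0.1, 0.1), runif(4, 0.04, 0.16))
  ctl2 <- clic_control(v_k = 1.5)
  set.seed(3)
  ch <- run_gibbs_chain(zd, K = 3, sweeps = 30, control = ctl2,
                        track_states = TRUE)
  for (s in c(1, 15, 30)) {
    I <- ch$states[s, ]
    expect_equal(ch$lp_sweep[s],
                 log_collapsed_lik(I, zd, ctl2) + log_prior_partition(I, 1.5),
                 tolerance = 1e-9)
  }
  expect_equal(ch$logpost_best,
               log_collapsed_lik(ch$I_best, zd, ctl2) +
                 log_prior_partition(ch$I_best, 1.5),
               tolerance = 1e-9)
})

test_that("a gene matching a module's signature joins it; background data
           stays null", {
  set.seed(19)
  # genes 1-4 strongly co-expressed near the prior mean in every dataset
  D <- 5
  zm <- lapply(1:D, function(d) {
    z <- rsym(6, 0, 0.2)
    z[1:4, 1:4][upper.tri(diag(4))] <- rnorm(6, 1.5, 0.1)
    z[lower.tri(z)] <- t(z)[lower.tri(z)]
    diag(z) <- NA
    z
  })
  zd <- make_zdata(zm, rep(0, D), rep(0.04, D))
  ctl2 <- clic_control(v_k = 6 / D)
  # from a state where the module lacks gene 4, one sweep pulls it in
  joins <- 0L
  for (rep in 1:20) {
    set.seed(100 + rep)
    st <- gibbs_sweep(c(1L, 1L, 1L, 0L, 0L, 0L), zd, K = 2, control = ctl2)
    joins <- joins + (st[4] == 1L)
  }
  expect_gte(joins, 19L)

  # with pure background data the null label dominates
  zd0 <- make_zdata(lapply(1:D, function(d) rsym(6, 0, 0.2)),
                    rep(0, D), rep(0.04, D))
  set.seed(5)
  ch <- run_gibbs_chain(zd0, K = 2, sweeps = 200, control = ctl2)
  expect_identical(clicr:::relabel_partition(ch$I_best), rep(0L, 6))
})

test_that("relabelling orders CEMs by size and demotes singletons", {
  expect_identical(clicr:::relabel_partition(c(3L, 3L, 1L, 1L, 1L, 0L, 2L)),
                   c(2L, 2L, 1L, 1L, 1L, 0L, 0L))
  expect_identical(clicr:::relabel_partition(c(2L, 2L, 0L)), c(1L, 1L, 0L))
  expect_identical(clicr:::relabel_partition(rep(0L, 4)), rep(0L, 4))
})

test_that("CEM parameter MLEs are the within-module moments, floored", {
  z <- matrix(NA_real_, 4, 4)
  z[1, 2] <- z[2, 1] <- 1.4
  z[1, 3] <- z[3, 1] <- 1.6
  z[2, 3] <- z[3, 2] <- 1.5
  z[1, 4] <- z[4, 1] <- z[2, 4] <- z[4, 2] <- z[3, 4] <- z[4, 3] <- 0
  zd <- make_zdata(list(z), 0, 0.04)
  p <- mle_cem_params(c(1L, 1L, 1L, 0L), zd)
  expect_equal(unname(p$theta_hat[1, 1]), 1.5)
  expect_equal(unname(p$sigma_sq_hat[1, 1]), mean((c(1.4, 1.6, 1.5) - 1.5)^2))

  # two genes, one pair: variance floored
  p2 <- mle_cem_params(c(1L, 1L, 0L, 0L), zd)
  expect_equal(unname(p2$theta_hat[1, 1]), 1.4)
  expect_equal(unname(p2$sigma_sq_hat[1, 1]), 1e-6)

  # permutation invariance of the mean
  p3 <- mle_cem_params(c(1L, 1L, 1L, 0L)[c(3, 1, 2, 4)], zd)
  expect_equal(unname(p3$theta_hat[1, 1]), 1.5)
})

test_that("dataset weights follow the posterior selection formula", {
  z <- rsym(5, 0.4, 0.3)
  zd <- make_zdata(list(z), 0.1, 0.04)
  I <- c(1L, 1L, 1L, 0L, 0L)
  zs <- c(z[1, 2], z[1, 3], z[2, 3])
  m1 <- log_nig_marginal(zs, ctl)
  m0 <- log_background_lik(zs, 0.1, 0.04)
  expected <- 1 / (1 + exp(log(1 - ctl$pi_s) - log(ctl$pi_s) + m0 - m1))
  expect_equal(unname(dataset_weights(I, zd, ctl)[1, 1]), expected,
               tolerance = 1e-12)

  # a CEM absent from a dataset keeps the prior weight pi_s
  present <- matrix(TRUE, 5, 2); present[1:3, 2] <- FALSE
  zd2 <- make_zdata(list(z, rsym(5, 0, 0.2)), c(0.1, 0), c(0.04, 0.04),
                    present = present)
  zd2$z[1:3, , 2] <- NA; zd2$z[, 1:3, 2] <- NA
  w <- dataset_weights(I, zd2, ctl)
  expect_equal(unname(w[2, 1]), ctl$pi_s)

  # saturation for overwhelming evidence
  zstrong <- matrix(NA_real_, 4, 4)
  zstrong[upper.tri(zstrong)] <- 1.5
  zstrong[lower.tri(zstrong)] <- 1.5
  zd3 <- make_zdata(list(zstrong), 0, 0.01)
  w3 <- dataset_weights(c(1L, 1L, 1L, 1L), zd3, ctl)
  expect_gt(unname(w3[1, 1]), 1 - 1e-15)
})

test_that("CEM strength is the weight-averaged log Bayes factor", {
  set.seed(20)
  D <- 10
  zms <- lapply(1:D, function(d) rsym(4, 0.1, 0.2))
  zms[[1]][1:3, 1:3][upper.tri(diag(3))] <- c(1.45, 1.5, 1.55)
  zms[[1]][lower.tri(zms[[1]])] <- t(zms[[1]])[lower.tri(zms[[1]])]
  zd <- make_zdata(zms, rep(0.1, D), rep(0.04, D))
  I <- c(1L, 1L, 1L, 0L)
  w <- dataset_weights(I, zd, ctl)
  # independent recomputation of phi from its definition
  phi_manual <- 0
  for (d in 1:D) {
    zs <- c(zd$z[1, 2, d], zd$z[1, 3, d], zd$z[2, 3, d])
    lbf <- log_nig_marginal(zs, ctl) - log_background_lik(zs, 0.1, 0.04)
    phi_manual <- phi_manual + w[d, 1] * lbf / D
  }
  expect_equal(cem_strength(I, zd, ctl)[1], unname(phi_manual),
               tolerance = 1e-9)
  # one strongly supportive dataset among ten dominates phi
  expect_gt(cem_strength(I, zd, ctl)[1], 1)
})

test_that("the fitted partition on a planted compendium recovers the module
           and is reproducible", {
  tc <- get_tiny_comp()
  fit <- get_tiny_fit()
  truth <- ifelse(tc$query %in% tc$sim$truth$modules[[1]], 1L, 0L)
  expect_identical(unname(fit$membership), truth)
  expect_identical(fit$k_hat, 1L)
  expect_gt(fit$phi[1], 1)
  # supportive datasets get weight ~1, others low
  expect_gt(min(fit$weights[1:3, 1]), 0.9)
  expect_lt(max(fit$weights[4:10, 1]), 0.5)

  fit2 <- clic(tc$query, tc$comp, tiny_control())
  expect_identical(fit2$membership, fit$membership)
  expect_identical(fit2$log_posterior, fit$log_posterior)

  # the recorded MAP log posterior matches an R-side recomputation
  ctl2 <- fit$control
  expect_equal(fit$log_posterior,
               log_collapsed_lik(unname(fit$membership), fit$zdata, ctl2) +
                 log_prior_partition(fit$membership, ctl2$v_k),
               tolerance = 1e-9)
})

test_that("single-gene queries are rejected", {
  tc <- get_tiny_comp()
  expect_error(clic("tmA1", tc$comp), "single gene")
})
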