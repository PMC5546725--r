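test_that("per-dataset LLR has its closed form and is additive in members", {
  # one member, z at the foreground mean, equal variances
  th <- 1.2; t0 <- 0.1; s2 <- 0.04
  expect_equal(llr_gene_dataset(th, th, s2, t0, s2), (th - t0)^2 / (2 * s2),
               tolerance = 1e-12)
  # doubling the members with identical z doubles the LLR
  z <- c(0.8, 1.1, 0.9)
  one <- llr_gene_dataset(z, 1.0, 0.02, 0.05, 0.03)
  two <- llr_gene_dataset(c(z, z), 1.0, 0.02, 0.05, 0.03)
  expect_equal(two, 2 * one, tolerance = 1e-12)
  # data drawn from the gene's own background scores near zero on average
  set.seed(21)
  llrs <- replicate(200, llr_gene_dataset(rnorm(5, 0.1, 0.2), 0.1, 0.04,
                                          0.1, 0.04))
  expect_lt(abs(mean(llrs)), 0.2)
})

test_that("integrated LLR is the weighted sum over datasets", {
  expect_equal(integrated_llr(c(10, -2), c(0.9, 0.1)), 8.8)
  expect_identical(integrated_llr(c(5, 7), c(0, 0)), 0)
  # a zero-LLR dataset is weight-invariant
  expect_equal(integrated_llr(c(3, 0), c(0.5, 0.2)),
               integrated_llr(c(3, 0), c(0.5, 0.9)))
})

test_that("expansion ranks planted pool genes on top and respects the
           score decomposition", {
  tc <- get_tiny_comp()
  fit <- get_tiny_fit()
  pr <- predict(fit)
  expect_identical(sort(unique(pr$cem)), 1L)
  # nLLR decomposition
  expect_equal(pr$nllr * length(fit$cems[[1]]), pr$llr, tolerance = 1e-9)
  # pool genes scored above every background candidate, significantly
  pool <- tc$sim$truth$pools[[1]]
  pool_rank <- match(pool, pr$gene_id)
  bg_best <- min(grep("^bg", pr$gene_id))
  expect_true(all(pool_rank < bg_best))
  expect_true(all(pr$llr[pool_rank] > 10))
  expect_true(all(pr$significant[pool_rank]))
  # sorted by decreasing LLR
  expect_true(all(diff(pr$llr) <= 1e-9))
})

test_that("a member-equivalent gene is a top CEM+ candidate", {
  # the foreground density rewards candidates whose z-correlations match the
  # estimated CEM mean; a noisy copy of a member, carrying the module signal
  # at member strength, must score significant and above every background
  # gene (an *exact* copy would instead carry one clamped z ~ 7 that the
  # peaked foreground density heavily penalizes)
  tc <- get_tiny_comp()
  set.seed(22)
  datasets <- lapply(tc$sim$datasets, function(ds) {
    row <- ds$values["tmA1", ]
    vals <- rbind(ds$values,
                  copy1 = row + rnorm(length(row), 0, 0.72 * sd(row)))
    clic_dataset(ds$dataset_id, vals)
  })
  comp <- build_compendium(datasets)
  fit <- clic(tc$query, comp, tiny_control())
  pr <- predict(fit, cems = 1)
  r <- match("copy1", pr$gene_id)
  expect_true(pr$in_cem_plus[r])
  expect_true(pr$significant[r])
  expect_lt(r, min(grep("^bg", pr$gene_id)))
})

test_that("datasets with zero weight do not affect integrated scores", {
  fit <- get_tiny_fit()
  d_drop <- "ds007"  # non-supportive for the planted module
  fit0 <- fit
  fit0$weights[d_drop, 1] <- 0
  pr_zero <- predict(fit0)
  fit1 <- fit0
  fit1$compendium$datasets[[d_drop]] <- NULL
  pr_drop <- predict(fit1)
  common <- intersect(pr_zero$gene_id, pr_drop$gene_id)
  expect_equal(pr_zero$llr[match(common, pr_zero$gene_id)],
               pr_drop$llr[match(common, pr_drop$gene_id)],
               tolerance = 1e-9)
})

test_that("an infinite inclusion threshold empties the CEM+ set", {
  fit <- get_tiny_fit()
  pr <- predict(fit, llr_threshold = Inf)
  expect_false(any(pr$in_cem_plus))
})

test_that("hub genes improve in rank when gene-specific backgrounds are
           ablated", {
  if (is.null(.fixtures$hubfit)) {
    cfg <- sim_config(
      n_datasets = 10, samples_per_dataset = 50, n_background_genes = 300,
      modules = list(module_spec(sprintf("wm%02d", 1:8), 1:5,
                                 target_pearson = 0.49,
                                 pool = c(sprintf("mp%02d", 1:8),
                                          sprintf("nm%02d", 1:4)),
                                 pool_pearson = c(rep(0.44, 8),
                                                  rep(0.3, 4)))),
      hub_genes = "hub01", seed = 21)
    comp <- build_compendium(simulate_compendium(cfg)$datasets)
    .fixtures$hubfit <- clic(c(sprintf("wm%02d", 1:8), "bg001", "bg002"),
                             comp, clic_control(sweeps = 500, seed = 9))
  }
  fit <- .fixtures$hubfit
  pr_def <- predict(fit, cems = 1)
  pr_abl <- predict(fit, cems = 1, background = "dataset")
  rank_def <- match("hub01", pr_def$gene_id)
  rank_abl <- match("hub01", pr_abl$gene_id)
  expect_lt(rank_abl, rank_def)
  # and the ablated score itself is inflated
  expect_gt(pr_abl$llr[rank_abl], pr_def$llr[rank_def])
})

test_that("uncharacterized genes are assigned by size-normalized LLR", {
  mk <- function(gene, cem, llr, size) {
    data.frame(gene_id = gene, cem = cem, llr = llr, nllr = llr / size,
               n_datasets = 10L, in_cem_plus = llr > 0,
               significant = llr > 10, stringsAsFactors = FALSE)
  }
  res <- assign_uncharacterized(
    "gX", list(setA = mk("gX", 1L, 30, 10), setB = mk("gX", 1L, 20, 4)))
  expect_identical(res$gene_set, "setB")   # nLLR 5 beats 3
  expect_equal(res$nllr, 5)

  one <- assign_uncharacterized("gX", list(only = mk("gX", 2L, 4, 8)))
  expect_identical(one$gene_set, "only")
  expect_identical(one$cem, 2L)

  neg <- assign_uncharacterized("gX", list(s = mk("gX", 1L, -3, 5)))
  expect_false(neg$significant)

  none <- assign_uncharacterized("gZ", list(s = mk("gX", 1L, 5, 5)))
  expect_true(is.na(none$gene_set))
})
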