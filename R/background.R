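#' Fisher z-transformation
#'
#' Variance-stabilizing map of a Pearson correlation,
#' z = (1/2) log((1 + r) / (1 - r)) = atanh(r). Inputs are clamped to
#' |r| <= 1 - 1e-6 so perfectly correlated gene pairs yield a large finite z
#' rather than an infinity that would break downstream likelihoods.
#'
#' @param r Numeric vector of correlations in \[-1, 1\].
#' @return z-transformed correlations.
#' @export
fisher_z <- function(r) {
  if (!all(is.finite(r))) stop("non-finite correlation passed to fisher_z()")
  atanh(pmin(pmax(r, -(1 - 1e-6)), 1 - 1e-6))
}

#' @rdname fisher_z
#' @param z Numeric vector of z-correlations.
#' @export
inverse_fisher_z <- function(z) tanh(z)

#' Pairwise z-correlation matrix of a dataset
#'
#' Pearson correlations between all gene rows, Fisher z-transformed. Genes
#' with zero variance across samples have undefined correlations and are
#' excluded; their identifiers are recorded in the `"excluded"` attribute.
#'
#' @param dataset A [clic_dataset()] (normalized) or a plain numeric matrix
#'   with gene row names.
#' @return Symmetric numeric matrix of z-correlations with `NA` diagonal.
#' @export
compute_z_matrix <- function(dataset) {
  vals <- if (inherits(dataset, "clic_dataset")) dataset$values else dataset
  stopifnot(is.matrix(vals))
  v <- apply(vals, 1L, stats::var)
  excluded <- rownames(vals)[v == 0]
  vals <- vals[v > 0, , drop = FALSE]
  if (nrow(vals) < 2L)
    stop("fewer than 2 genes with non-zero variance; cannot compute correlations")
  z <- fisher_z(stats::cor(t(vals)))
  diag(z) <- NA_real_
  attr(z, "excluded") <- excluded
  z
}

#' Dataset-specific background of z-correlations
#'
#' Mean and variance of all N(N-1)/2 pairwise z-correlations of a dataset;
#' the variance uses the population divisor N(N-1)/2.
#'
#' @param z_matrix Symmetric z-correlation matrix from [compute_z_matrix()].
#' @return List with `theta0` and `sigma0_sq`.
#' @export
estimate_dataset_background <- function(z_matrix) {
  if (!is.matrix(z_matrix) || nrow(z_matrix) < 2L)
    stop("need a z-correlation matrix over at least 2 genes")
  zs <- z_matrix[upper.tri(z_matrix)]
  theta0 <- mean(zs)
  list(theta0 = theta0, sigma0_sq = mean((zs - theta0)^2))
}

#' Gene-specific backgrounds of z-correlations
#'
#' For each gene i, the mean and (population) variance of the z-correlations
#' between i and the other N-1 genes. Corrects expansion scores for "hubby"
#' genes that correlate with everything. The mean over genes of `theta0`
#' equals the dataset background mean.
#'
#' @inheritParams estimate_dataset_background
#' @return List with named numeric vectors `theta0` and `sigma0_sq` (one
#'   entry per gene).
#' @export
estimate_gene_backgrounds <- function(z_matrix) {
  if (!is.matrix(z_matrix) || nrow(z_matrix) < 2L)
    stop("need a z-correlation matrix over at least 2 genes")
  n1 <- nrow(z_matrix) - 1L
  s1 <- rowSums(z_matrix, na.rm = TRUE)
  s2 <- rowSums(z_matrix^2, na.rm = TRUE)
  theta0 <- s1 / n1
  sigma0_sq <- s2 / n1 - theta0^2
  sigma0_sq[sigma0_sq < 0] <- 0  # guard against rounding at tiny N
  list(theta0 = theta0, sigma0_sq = sigma0_sq)
}

#' Total-variation-distance QC of the z background
#'
#' Compares a Gaussian kernel-density fit p(z) of the background z sample
#' with the normal fit q(z) = N(theta0, sigma0_sq) via the total variation
#' distance delta = integral |p(z) - q(z)| dz. High-quality datasets have a
#' unimodal, near-normal background (small delta); bad normalization or batch
#' structure produces multimodal backgrounds (large delta). A dataset fails
#' if delta > `tv_threshold` or sigma0_sq > `var_threshold`.
#'
#' The kernel fit uses a Gaussian kernel with Silverman bandwidth, evaluated
#' on a 1024-point grid spanning theta0 +/- 6 sqrt(sigma0_sq); the integral
#' is a trapezoid rule on that grid.
#'
#' @param z_sample Numeric vector of background z values (all pairs or a
#'   subsample; at least 100 values).
#' @param theta0,sigma0_sq Background moments from
#'   [estimate_dataset_background()].
#' @param tv_threshold,var_threshold Removal thresholds (defaults 0.1 and 1).
#' @return List with `tv_distance`, `qc_pass`, and `status` (one of `"pass"`,
#'   `"background_nonnormal"`, `"background_overdispersed"`).
#' @export
tv_distance_qc <- function(z_sample, theta0, sigma0_sq,
                           tv_threshold = 0.1, var_threshold = 1) {
  z_sample <- z_sample[is.finite(z_sample)]
  if (length(z_sample) < 100L)
    stop("need at least 100 z values for a reliable kernel density fit")
  stopifnot(sigma0_sq > 0)
  s0 <- sqrt(sigma0_sq)
  grid_lo <- theta0 - 6 * s0
  grid_hi <- theta0 + 6 * s0
  kde <- stats::density(z_sample, bw = "nrd0", kernel = "gaussian",
                        from = grid_lo, to = grid_hi, n = 1024L)
  q <- stats::dnorm(kde$x, mean = theta0, sd = s0)
  dy <- abs(kde$y - q)
  delta <- sum(diff(kde$x) * (dy[-1L] + dy[-length(dy)]) / 2)
  status <- if (delta > tv_threshold) "background_nonnormal"
            else if (sigma0_sq > var_threshold) "background_overdispersed"
            else "pass"
  list(tv_distance = delta, qc_pass = status == "pass", status = status)
}

#' Full background summary of one dataset
#'
#' Computes the z-correlation matrix, the dataset and gene-specific
#' backgrounds, and the TV-distance QC verdict for one normalized dataset.
#'
#' @inheritParams build_compendium
#' @param dataset A normalized [clic_dataset()].
#' @return An object of class `"clic_background"`.
#' @keywords internal
dataset_background <- function(dataset, tv_threshold = 0.1, var_threshold = 1,
                               max_tv_pairs = 1e6, seed = 1L) {
  z <- compute_z_matrix(dataset)
  bg <- estimate_dataset_background(z)
  gene_bg <- estimate_gene_backgrounds(z)
  zs <- z[upper.tri(z)]
  if (length(zs) > max_tv_pairs) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(seed)
    zs <- zs[sample.int(length(zs), max_tv_pairs)]
  }
  qc <- tv_distance_qc(zs, bg$theta0, bg$sigma0_sq,
                       tv_threshold = tv_threshold, var_threshold = var_threshold)
  structure(
    list(dataset_id = dataset$dataset_id,
         theta0 = bg$theta0, sigma0_sq = bg$sigma0_sq,
         gene_theta0 = gene_bg$theta0, gene_sigma0_sq = gene_bg$sigma0_sq,
         tv_distance = qc$tv_distance, qc_pass = qc$qc_pass, status = qc$status,
         retained_genes = rownames(z),
         excluded_genes = attr(z, "excluded")),
    class = "clic_background")
}

# save/restore .Random.seed so cached preprocessing does not perturb user RNG
.Random.seed_get <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_set <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", seed, envir = globalenv())
}
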