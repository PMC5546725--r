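#' Specify a planted co-expression module
#'
#' @param genes Character vector of module gene identifiers.
#' @param supportive Integer indices of the datasets in which the module is
#'   active (co-expressed); elsewhere its genes behave as background.
#' @param target_pearson Within-module pairwise Pearson correlation in
#'   supportive datasets (default 0.81).
#' @param pool Character vector of extra genes carrying the same latent
#'   signal but not intended for the query: ground truth for expansion tests.
#' @param pool_pearson Pairwise Pearson correlation of pool genes with each
#'   other in supportive datasets (scalar or one value per pool gene;
#'   default `target_pearson`). Values below `target_pearson` give pool
#'   genes a weaker version of the module signal.
#' @return A list of class `"clic_module_spec"`.
#' @export
module_spec <- function(genes, supportive, target_pearson = 0.81,
                        pool = character(), pool_pearson = target_pearson) {
  stopifnot(length(genes) >= 2L, target_pearson > 0, target_pearson < 1,
            all(pool_pearson > 0), all(pool_pearson < 1),
            !anyDuplicated(c(genes, pool)))
  structure(list(module_gene_ids = as.character(genes),
                 supportive_dataset_ids = as.integer(supportive),
                 target_pearson = target_pearson,
                 expansion_pool_ids = as.character(pool),
                 pool_pearson = rep(pool_pearson, length.out = length(pool))),
            class = "clic_module_spec")
}

#' Configure a synthetic compendium
#'
#' Latent-factor generative model emulating a curated expression compendium.
#' Each dataset draws per-sample latent factors; genes combine them with
#' fixed loadings plus independent noise (unit total variance), so pairwise
#' correlations are products of loadings:
#' \itemize{
#'   \item a dataset-wide factor with squared loading
#'     `background_correlation` on every gene. Column-mean normalization in
#'     preprocessing removes (to first order) any factor loaded equally by
#'     all genes, so this term mimics the raw-data dataset effect that
#'     preprocessing is expected to strip.
#'   \item a \emph{block} factor shared by the last
#'     `block_fraction * n_background_genes` background genes (squared
#'     loading `block_loading`), by module and pool genes (squared loading
#'     `member_block_loading`), and by hub genes (squared loading
#'     `hub_loading`). Because only part of the transcriptome carries it,
#'     this factor survives column normalization: hub genes stay correlated
#'     with a large slice of the genome in every dataset — the stress case
#'     the gene-specific background corrects for.
#'   \item one factor per planted module, present only in its supportive
#'     datasets, giving within-module pairwise Pearson correlation
#'     `target_pearson` on the generated (pre-normalization) scale.
#'   \item optionally, datasets with two sample blocks of gene-specific
#'     opposite mean shifts, whose bimodal z background should fail
#'     total-variation QC.
#' }
#'
#' Values are mapped to expression scale as `expr_offset + expr_scale * x`,
#' floored at 1, so datasets are linear scale, strictly positive, and pass
#' the magnitude filters. With `modules = NULL` a default two-module study
#' design is built: an 8-gene module supported by datasets 1..10 and a
#' 6-gene module supported by 11..20 (at `n_datasets = 40`), each with a
#' 10-gene expansion pool, plus one hub gene.
#'
#' @param n_datasets Number of datasets (default 40).
#' @param samples_per_dataset Samples per dataset (default 50).
#' @param n_background_genes Number of pure background genes (default 500).
#' @param modules List of [module_spec()]s, or `NULL` for the default design.
#' @param background_correlation Squared loading of the dataset-wide factor
#'   (default 0.1).
#' @param block_fraction Fraction of background genes in the correlated
#'   block (default 0.3; 0 disables the block factor).
#' @param block_loading,member_block_loading Squared block-factor loadings
#'   of block background genes (default 0.25) and of module/pool genes
#'   (default 0.2).
#' @param hub_genes Identifiers of hub genes (`NULL` gives the default
#'   design's single hub).
#' @param hub_loading Squared loading of hub genes on the block factor
#'   (default 0.81).
#' @param bimodal_datasets Integer indices of datasets given a two-block
#'   sample-mean structure (default none).
#' @param expr_offset,expr_scale Affine map from latent scale to expression
#'   scale (defaults 1000 and 250).
#' @param seed Integer seed; fully determines the compendium.
#' @return A list of class `"clic_sim_config"`.
#' @export
sim_config <- function(n_datasets = 40L, samples_per_dataset = 50L,
                       n_background_genes = 500L, modules = NULL,
                       background_correlation = 0.1,
                       block_fraction = 0.3, block_loading = 0.25,
                       member_block_loading = 0.2,
                       hub_genes = NULL, hub_loading = 0.81,
                       bimodal_datasets = integer(),
                       expr_offset = 1000, expr_scale = 250, seed = 1L) {
  stopifnot(n_datasets >= 1L, samples_per_dataset >= 6L,
            background_correlation >= 0, background_correlation < 1,
            block_fraction >= 0, block_fraction <= 1,
            block_loading >= 0, member_block_loading >= 0,
            background_correlation + block_loading < 1,
            hub_loading > 0, background_correlation + hub_loading < 1)
  if (block_fraction == 0) member_block_loading <- 0
  if (is.null(modules)) {
    modules <- list(
      module_spec(sprintf("modA%02d", 1:8), 1:10, 0.81,
                  pool = sprintf("poolA%02d", 1:10)),
      module_spec(sprintf("modB%02d", 1:6), 11:20, 0.81,
                  pool = sprintf("poolB%02d", 1:10)))
    if (is.null(hub_genes)) hub_genes <- "hub01"
  }
  if (is.null(hub_genes)) hub_genes <- character()
  mod_genes <- unlist(lapply(modules, function(m)
    c(m$module_gene_ids, m$expansion_pool_ids)))
  if (anyDuplicated(mod_genes))
    stop("gene sets across modules must be disjoint")
  base <- background_correlation + member_block_loading
  for (m in modules) {
    stopifnot(all(m$supportive_dataset_ids >= 1L),
              all(m$supportive_dataset_ids <= n_datasets))
    if (m$target_pearson <= base + 1e-9 || any(m$pool_pearson < base - 1e-9))
      stop("target_pearson must exceed, and pool_pearson be at least, ",
           "background_correlation + member_block_loading")
  }
  bg <- sprintf("bg%03d", seq_len(n_background_genes))
  if (anyDuplicated(c(bg, mod_genes, hub_genes)))
    stop("module/pool/hub gene identifiers collide with background genes")
  structure(
    list(n_datasets = as.integer(n_datasets),
         samples_per_dataset = as.integer(samples_per_dataset),
         n_background_genes = as.integer(n_background_genes),
         background_genes = bg, modules = modules,
         background_correlation = background_correlation,
         block_fraction = block_fraction, block_loading = block_loading,
         member_block_loading = member_block_loading,
         hub_genes = as.character(hub_genes), hub_loading = hub_loading,
         bimodal_datasets = as.integer(bimodal_datasets),
         expr_offset = expr_offset, expr_scale = expr_scale,
         seed = as.integer(seed)),
    class = "clic_sim_config")
}

#' Generate one synthetic dataset
#'
#' Each sample draws a dataset-wide factor, a block factor, and one factor
#' per active module; a gene's value is its loading combination plus
#' independent noise, with unit total variance, so pairwise correlations
#' equal the products of loadings (see [sim_config()]). The dataset seed is
#' derived from the config seed and the dataset index, so generation is
#' deterministic and order-independent.
#'
#' @param config A [sim_config()].
#' @param d Dataset index in 1..`config$n_datasets`.
#' @return A [clic_dataset()] (linear scale, positive, max above 1000 for
#'   the default affine map).
#' @export
simulate_dataset <- function(config, d) {
  stopifnot(inherits(config, "clic_sim_config"),
            d >= 1L, d <= config$n_datasets)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(config$seed + 1009L * as.integer(d))

  ns <- config$samples_per_dataset
  genes <- c(config$background_genes,
             unlist(lapply(config$modules, function(m)
               c(m$module_gene_ids, m$expansion_pool_ids))),
             config$hub_genes)
  ng <- length(genes)
  b <- config$background_correlation

  if (d %in% config$bimodal_datasets) {
    # two sample blocks with gene-specific opposite mean shifts: the pairwise
    # correlations split into two modes and the z background is bimodal
    u <- rep(c(1, -1), length.out = ns)
    g <- sample(c(1, -1), ng, replace = TRUE)
    amp <- 0.7
    x <- amp * outer(g, u) +
      sqrt(1 - amp^2) * matrix(stats::rnorm(ng * ns), ng, ns)
  } else {
    F0 <- stats::rnorm(ns)
    x <- sqrt(b) * matrix(F0, ng, ns, byrow = TRUE)
    load_sq <- rep(b, ng)                # accumulated squared loadings
    names(load_sq) <- rownames(x) <- genes
    n_block <- floor(config$block_fraction * config$n_background_genes)
    if (n_block > 0) {
      Fblk <- stats::rnorm(ns)
      blk_ids <- config$background_genes[
        seq(config$n_background_genes - n_block + 1L,
            config$n_background_genes)]
      mem_ids <- unlist(lapply(config$modules, function(m)
        c(m$module_gene_ids, m$expansion_pool_ids)))
      lo <- c(rep(config$block_loading, length(blk_ids)),
              rep(config$member_block_loading, length(mem_ids)),
              rep(config$hub_loading, length(config$hub_genes)))
      ids <- c(blk_ids, mem_ids, config$hub_genes)
      x[ids, ] <- x[ids, ] + sqrt(lo) * matrix(Fblk, length(ids), ns,
                                               byrow = TRUE)
      load_sq[ids] <- load_sq[ids] + lo
    } else if (length(config$hub_genes)) {
      x[config$hub_genes, ] <- sqrt(config$hub_loading) *
        matrix(F0, length(config$hub_genes), ns, byrow = TRUE)
      load_sq[config$hub_genes] <- config$hub_loading
    }
    for (m in config$modules) {
      if (d %in% m$supportive_dataset_ids) {
        ids <- c(m$module_gene_ids, m$expansion_pool_ids)
        rho <- c(rep(m$target_pearson, length(m$module_gene_ids)),
                 m$pool_pearson)
        q <- pmax(rho - b - config$member_block_loading, 0)
        Fm <- stats::rnorm(ns)
        x[ids, ] <- x[ids, ] + sqrt(q) * matrix(Fm, length(ids), ns,
                                                byrow = TRUE)
        load_sq[ids] <- load_sq[ids] + q
      }
    }
    x <- x + sqrt(pmax(1 - load_sq, 0)) * matrix(stats::rnorm(ng * ns), ng, ns)
  }
  expr <- pmax(config$expr_offset + config$expr_scale * x, 1)
  dimnames(expr) <- list(genes, sprintf("s%03d", seq_len(ns)))
  clic_dataset(sprintf("ds%03d", as.integer(d)), expr)
}

#' Generate a synthetic compendium with truth labels
#'
#' @param config A [sim_config()].
#' @return List with `datasets` (list of [clic_dataset()]s) and `truth`
#'   (module memberships, supportive dataset ids, expansion pools, hub and
#'   background genes).
#' @export
simulate_compendium <- function(config) {
  stopifnot(inherits(config, "clic_sim_config"))
  datasets <- lapply(seq_len(config$n_datasets),
                     function(d) simulate_dataset(config, d))
  ids <- vapply(datasets, function(x) x$dataset_id, character(1))
  truth <- list(
    modules = lapply(config$modules, function(m) m$module_gene_ids),
    supportive = lapply(config$modules,
                        function(m) ids[m$supportive_dataset_ids]),
    pools = lapply(config$modules, function(m) m$expansion_pool_ids),
    hub_genes = config$hub_genes,
    background_genes = config$background_genes,
    bimodal_datasets = ids[config$bimodal_datasets])
  list(datasets = datasets, truth = truth)
}
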