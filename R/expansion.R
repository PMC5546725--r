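#' Per-dataset log-likelihood ratio of a candidate gene against a CEM
#'
#' Sum over CEM members of the difference between the foreground normal
#' log-density (CEM mean/variance estimated in the Partition step) and the
#' candidate's gene-specific background log-density. The gene-specific
#' background is what stops "hubby" genes — correlated with everything —
#' from trivially topping every expansion list.
#'
#' @param z Numeric vector of z-correlations between the candidate and the
#'   CEM members present in the dataset.
#' @param theta_hat,sigma_sq_hat Foreground CEM parameters in this dataset.
#' @param theta0_i,sigma0_sq_i The candidate's gene-specific background mean
#'   and variance in this dataset.
#' @return Scalar LLR.
#' @export
llr_gene_dataset <- function(z, theta_hat, sigma_sq_hat, theta0_i, sigma0_sq_i) {
  sum(stats::dnorm(z, theta_hat, sqrt(sigma_sq_hat), log = TRUE) -
      stats::dnorm(z, theta0_i, sqrt(sigma0_sq_i), log = TRUE))
}

#' Weight-integrated LLR
#'
#' @param llrs Numeric vector of per-dataset LLR scores.
#' @param weights Matching posterior dataset-selection weights.
#' @return `sum(weights * llrs)`.
#' @export
integrated_llr <- function(llrs, weights) {
  stopifnot(length(llrs) == length(weights))
  sum(weights * llrs)
}

#' Expand CEMs: score candidate genes by integrated LLR
#'
#' Scores every gene of the candidate universe (present in at least one
#' QC-passing dataset and absent from the query) against each CEM: the
#' per-dataset LLR of the candidate's z-correlations to the CEM members,
#' summed over datasets with the posterior selection weights. Candidates
#' with integrated LLR above `llr_threshold` (default 0) form the CEM+ list;
#' scores above `significant_threshold` (default 10) are flagged
#' significant. nLLR divides the integrated LLR by the CEM size so that
#' assignments can be compared across CEMs of different sizes.
#'
#' @param object A fitted `"clic"` model.
#' @param cems Integer vector of CEM indices to expand (default all).
#' @param candidates Candidate gene identifiers (default: every non-query
#'   gene in the compendium).
#' @param llr_threshold CEM+ inclusion threshold (default 0).
#' @param significant_threshold Significance flag threshold (default 10).
#' @param background `"gene"` (default) uses gene-specific backgrounds for
#'   the null model; `"dataset"` uses the dataset background for every
#'   candidate (the no-background ablation).
#' @param ... Unused.
#' @return A data frame with columns `gene_id`, `cem`, `llr`, `nllr`,
#'   `n_datasets` (datasets contributing to the score), `in_cem_plus`,
#'   `significant`, sorted within CEM by decreasing `llr` (ties broken
#'   lexicographically by `gene_id`).
#' @export
predict.clic <- function(object, cems = seq_len(object$k_hat),
                         candidates = NULL,
                         llr_threshold = 0, significant_threshold = 10,
                         background = c("gene", "dataset"), ...) {
  background <- match.arg(background)
  entries <- object$compendium$datasets
  if (object$k_hat == 0L || !length(cems)) {
    warning("fitted model has no CEMs to expand")
    return(empty_expansion())
  }
  stopifnot(all(cems >= 1L), all(cems <= object$k_hat))
  if (is.null(candidates)) {
    candidates <- sort(unique(unlist(lapply(entries, function(e)
      e$background$retained_genes))))
    candidates <- setdiff(candidates, names(object$membership))
  } else {
    candidates <- unique(as.character(candidates))
  }
  if (!length(candidates)) {
    warning("empty candidate universe")
    return(empty_expansion())
  }
  nc <- length(candidates)
  llr <- matrix(0, nc, length(cems), dimnames = list(candidates, NULL))
  ndat <- matrix(0L, nc, length(cems), dimnames = list(candidates, NULL))
  for (e in entries) {
    d <- e$dataset_id   # weight/parameter rows are indexed by dataset id
    cand_d <- candidates[candidates %in% rownames(e$expr)]
    if (!length(cand_d) || !d %in% rownames(object$weights)) next
    for (jj in seq_along(cems)) {
      k <- cems[jj]
      mem <- object$cems[[k]]
      mem <- mem[mem %in% rownames(e$expr)]
      th <- object$theta_hat[d, k]
      if (!length(mem) || !is.finite(th)) next
      sg <- object$sigma_sq_hat[d, k]
      z <- fisher_z(stats::cor(t(e$expr[cand_d, , drop = FALSE]),
                               t(e$expr[mem, , drop = FALSE])))
      h1 <- -0.5 * log(2 * pi * sg) - (z - th)^2 / (2 * sg)
      if (background == "gene") {
        t0 <- e$background$gene_theta0[cand_d]
        s0 <- pmax(e$background$gene_sigma0_sq[cand_d], 1e-12)
      } else {
        t0 <- rep(e$background$theta0, length(cand_d))
        s0 <- rep(e$background$sigma0_sq, length(cand_d))
      }
      h0 <- -0.5 * log(2 * pi * s0) - (z - t0)^2 / (2 * s0)
      d_llr <- rowSums(h1) - rowSums(h0)
      w <- object$weights[d, k]
      llr[cand_d, jj] <- llr[cand_d, jj] + w * d_llr
      ndat[cand_d, jj] <- ndat[cand_d, jj] + 1L
    }
  }
  out <- do.call(rbind, lapply(seq_along(cems), function(jj) {
    k <- cems[jj]
    df <- data.frame(gene_id = candidates, cem = k, llr = llr[, jj],
                     nllr = llr[, jj] / length(object$cems[[k]]),
                     n_datasets = ndat[, jj], stringsAsFactors = FALSE)
    df <- df[df$n_datasets > 0L, , drop = FALSE]
    df[order(-df$llr, df$gene_id), , drop = FALSE]
  }))
  rownames(out) <- NULL
  out$in_cem_plus <- out$llr > llr_threshold
  out$significant <- out$llr > significant_threshold
  out
}

empty_expansion <- function() {
  data.frame(gene_id = character(), cem = integer(), llr = numeric(),
             nllr = numeric(), n_datasets = integer(),
             in_cem_plus = logical(), significant = logical(),
             stringsAsFactors = FALSE)
}

#' @rdname predict.clic
#' @param k A single CEM index.
#' @export
expand_cem <- function(object, k, ...) {
  stopifnot(inherits(object, "clic"))
  predict(object, cems = k, ...)
}

#' Assign an uncharacterized gene to its best-matching gene set
#'
#' Given expansion tables computed against several query gene sets, returns
#' the (gene set, CEM) pair that scores the gene highest by nLLR — the
#' integrated LLR divided by CEM size, which makes assignments comparable
#' across CEMs of different sizes.
#'
#' @param gene A gene identifier.
#' @param expansions Named list of expansion data frames from
#'   [predict.clic()], one per query gene set.
#' @return List with `gene_set`, `cem`, `nllr`, `llr`, and `significant`
#'   (`llr > 0`); all `NA`/`FALSE` when no CEM scored the gene.
#' @export
assign_uncharacterized <- function(gene, expansions) {
  stopifnot(is.list(expansions), length(expansions) >= 1L,
            !is.null(names(expansions)))
  best <- NULL
  for (nm in names(expansions)) {
    rows <- expansions[[nm]][expansions[[nm]]$gene_id == gene, , drop = FALSE]
    if (!nrow(rows)) next
    top <- rows[which.max(rows$nllr), , drop = FALSE]
    if (is.null(best) || top$nllr > best$nllr)
      best <- list(gene_set = nm, cem = top$cem, nllr = top$nllr,
                   llr = top$llr, significant = top$llr > 0)
  }
  if (is.null(best))
    best <- list(gene_set = NA_character_, cem = NA_integer_,
                 nllr = NA_real_, llr = NA_real_, significant = FALSE)
  best
}
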