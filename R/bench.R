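#' Leave-one-out cross-validation of partition + expansion
#'
#' For each query gene i: fit the partition on the reduced query (the gene
#' held out), expand every CEM over the candidate universe (which contains
#' i), and record i's best integrated LLR over CEMs and its rank among all
#' candidates (candidates ranked by their own best-over-CEM LLR, ties broken
#' lexicographically). The per-gene chain seed is `control$seed + index`, so
#' the whole benchmark is reproducible and the compendium background cache
#' is reused across runs.
#'
#' @param query Character vector of at least 3 gene identifiers.
#' @param compendium A `"clic_compendium"`.
#' @param control A [clic_control()].
#' @param no_partition Propagated to [clic()] (single-CEM ablation).
#' @param background Propagated to [predict.clic()].
#' @return A list of class `"clic_loocv"` with `records` (one row per held
#'   out gene: `held_out_gene`, `best_llr`, `rank`, `cem_strength_of_source`)
#'   and `scores` (pooled candidate scores: `run`, `gene_id`, `llr`,
#'   `is_test`) for precision-recall curves. Runs whose reduced query yields
#'   no CEM get `best_llr = -Inf` and `rank = Inf`.
#' @export
clic_loocv <- function(query, compendium, control = clic_control(),
                       no_partition = FALSE, background = "gene") {
  query <- unique(as.character(query))
  if (length(query) < 3L)
    stop("leave-one-out cross-validation requires at least 3 query genes")
  records <- vector("list", length(query))
  scores <- vector("list", length(query))
  for (i in seq_along(query)) {
    gene <- query[i]
    ctl <- control
    ctl$seed <- control$seed + i
    fit <- clic(setdiff(query, gene), compendium, ctl,
                no_partition = no_partition)
    if (fit$k_hat == 0L) {
      records[[i]] <- data.frame(held_out_gene = gene, best_llr = -Inf,
                                 rank = Inf, cem_strength_of_source = NA_real_,
                                 stringsAsFactors = FALSE)
      next
    }
    pr <- predict(fit, background = background)
    # keep the query universe comparable across runs: other query genes are
    # not candidates, the held-out gene is
    pr <- pr[!(pr$gene_id %in% setdiff(query, gene)), , drop = FALSE]
    best <- stats::aggregate(llr ~ gene_id, data = pr, FUN = max)
    best <- best[order(-best$llr, best$gene_id), , drop = FALSE]
    best$rank <- seq_len(nrow(best))
    row <- match(gene, best$gene_id)
    if (is.na(row)) {
      records[[i]] <- data.frame(held_out_gene = gene, best_llr = -Inf,
                                 rank = Inf, cem_strength_of_source = NA_real_,
                                 stringsAsFactors = FALSE)
    } else {
      rows_i <- pr[pr$gene_id == gene, , drop = FALSE]
      src_cem <- rows_i$cem[which.max(rows_i$llr)]
      records[[i]] <- data.frame(
        held_out_gene = gene, best_llr = best$llr[row], rank = best$rank[row],
        cem_strength_of_source = fit$phi[src_cem],
        stringsAsFactors = FALSE)
    }
    scores[[i]] <- data.frame(run = gene, gene_id = best$gene_id,
                              llr = best$llr, is_test = best$gene_id == gene,
                              stringsAsFactors = FALSE)
  }
  structure(list(records = do.call(rbind, records),
                 scores = do.call(rbind, scores)),
            class = "clic_loocv")
}

#' @export
print.clic_loocv <- function(x, ...) {
  cat("<clic_loocv> ", nrow(x$records), " held-out genes; median best LLR = ",
      signif(stats::median(x$records$best_llr), 4), "\n", sep = "")
  invisible(x)
}

#' Precision-recall curve over LLR thresholds
#'
#' Precision: fraction of pooled candidate predictions above the threshold
#' that are held-out (test) genes. Recall: fraction of test genes scored
#' above the threshold. Both as proportions in \[0, 1\].
#'
#' @param loocv A `"clic_loocv"` result (or its `$scores` data frame).
#' @param thresholds Numeric vector of LLR thresholds.
#' @return Data frame with `threshold`, `precision`, `recall`,
#'   `n_predictions`.
#' @export
precision_recall <- function(loocv, thresholds = c(-20, -10, -5, 0, 5, 10,
                                                   20, 50, 100)) {
  scores <- if (inherits(loocv, "clic_loocv")) loocv$scores else loocv
  stopifnot(nrow(scores) >= 1L)
  n_test <- sum(scores$is_test)
  out <- lapply(thresholds, function(t) {
    pred <- scores$llr > t
    tp <- sum(pred & scores$is_test)
    data.frame(threshold = t,
               precision = if (any(pred)) tp / sum(pred) else NA_real_,
               recall = tp / n_test, n_predictions = sum(pred))
  })
  do.call(rbind, out)
}

#' Recall within the top N predictions
#'
#' Fraction of held-out genes recovered at rank at most N, optionally
#' stratified by the strength phi of the CEM that scored them.
#'
#' @param loocv A `"clic_loocv"` result (or its `$records` data frame).
#' @param ranks Integer vector of rank cutoffs (default 10..400 by 10).
#' @param phi_cutoffs Optional numeric vector; each cutoff c adds a stratum
#'   restricted to records with `cem_strength_of_source > c`.
#' @return Data frame with `group`, `rank`, `recall`, `n`.
#' @export
recall_at_rank <- function(loocv, ranks = seq(10L, 400L, by = 10L),
                           phi_cutoffs = NULL) {
  records <- if (inherits(loocv, "clic_loocv")) loocv$records else loocv
  strata <- list(all = records)
  for (c in phi_cutoffs) {
    keep <- !is.na(records$cem_strength_of_source) &
      records$cem_strength_of_source > c
    strata[[paste0("phi>", c)]] <- records[keep, , drop = FALSE]
  }
  out <- lapply(names(strata), function(g) {
    rec <- strata[[g]]
    data.frame(group = g, rank = ranks,
               recall = vapply(ranks, function(N)
                 if (nrow(rec)) mean(rec$rank <= N) else NA_real_, numeric(1)),
               n = nrow(rec), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Average-correlation baseline on a single dataset
#'
#' Ranks candidate genes by their mean Pearson correlation with the input
#' genes in one dataset — the classical single-dataset guilt-by-association
#' baseline.
#'
#' @param gene_set Character vector of input gene identifiers.
#' @param dataset A [clic_dataset()] or numeric matrix with gene row names.
#' @param candidates Candidate identifiers (default: all other genes in the
#'   dataset).
#' @return Data frame `gene_id`, `avcorr`, `rank`, sorted by decreasing
#'   average correlation (ties broken lexicographically).
#' @export
avcorr_baseline <- function(gene_set, dataset, candidates = NULL) {
  vals <- if (inherits(dataset, "clic_dataset")) dataset$values else dataset
  gene_set <- intersect(as.character(gene_set), rownames(vals))
  if (!length(gene_set)) stop("no input genes present in the dataset")
  if (is.null(candidates)) candidates <- setdiff(rownames(vals), gene_set)
  candidates <- intersect(as.character(candidates), rownames(vals))
  r <- stats::cor(t(vals[candidates, , drop = FALSE]),
                  t(vals[gene_set, , drop = FALSE]))
  av <- rowMeans(r)
  out <- data.frame(gene_id = candidates, avcorr = av,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$avcorr, out$gene_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Leave-one-out records for the average-correlation baseline
#'
#' @inheritParams avcorr_baseline
#' @param query Character vector of at least 3 gene identifiers.
#' @return Data frame with `held_out_gene` and `rank` (rank of the held-out
#'   gene among all candidates by average correlation with the reduced set).
#' @export
loocv_avcorr <- function(query, dataset) {
  query <- unique(as.character(query))
  if (length(query) < 3L)
    stop("leave-one-out cross-validation requires at least 3 query genes")
  out <- lapply(query, function(gene) {
    rk <- avcorr_baseline(setdiff(query, gene), dataset)
    data.frame(held_out_gene = gene,
               rank = if (gene %in% rk$gene_id)
                 rk$rank[rk$gene_id == gene] else Inf,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
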