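# Paired-sample validation of the individualized calls, and the fold-change
# contrast between called and never-called genes.

#' K-fold paired-sample cross-validation of IDE calls
#'
#' Tumor-normal pairs are partitioned into `k` folds by a seeded shuffle.
#' For each fold, stable pairs are mined from the training pairs' normals
#' and calls are made on each held-out tumor; a call (gene g, sample s,
#' direction v) is concordant iff `sign(tumor[g, s] - matched_normal[g, s])`
#' equals v.  A delta of exactly zero counts as discordant (conservative).
#' Accuracies are concordant/evaluated, pooled over folds: per gene
#' (lncRNA-level) and per sample (sample-level).
#'
#' @param cohort a [paired_cohort()].
#' @param k number of folds (>= 2, <= number of pairs).
#' @param threshold_f stability threshold for the per-fold pair mining.
#' @param params a [call_params()].
#' @param seed integer seed for the fold shuffle.
#' @return list with `folds` (per-fold data.frames of evaluated calls),
#'   `lncRNA_accuracy` (per-gene pooled), `sample_accuracy` (per-sample
#'   pooled), `mean_lncRNA_accuracy`, `mean_sample_accuracy`,
#'   `n_calls_evaluated`.
#' @export
kfold_paired_validation <- function(cohort, k = 5, threshold_f = 0.99,
                                    params = call_params(), seed = 1) {
  stopifnot(inherits(cohort, "paired_cohort"))
  tumors <- names(cohort$pairing)
  n <- length(tumors)
  if (k < 2) stop("k must be >= 2")
  if (k > n) stop("k (", k, ") exceeds the number of pairs (", n, ")")
  perm <- with_seed(seed, sample(n))
  fold_of <- rep_len(seq_len(k), n)[order(perm)]
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    test_t <- tumors[fold_of == f]
    train_t <- tumors[fold_of != f]
    train_normals <- expression_matrix(
      unclass(cohort$normal)[, cohort$pairing[train_t], drop = FALSE])
    sp <- find_stable_pairs(train_normals, threshold_f)
    rows <- list()
    for (s in test_t) {
      res <- call_sample(sp, cohort$tumor[, s], params)
      res <- res[res$call != 0L, , drop = FALSE]
      if (!nrow(res)) next
      delta <- cohort$tumor[res$gene_id, s] -
        cohort$normal[res$gene_id, cohort$pairing[s]]
      rows[[s]] <- data.frame(fold = f, sample_id = s,
                              gene_id = res$gene_id, call = res$call,
                              delta = as.numeric(delta),
                              concordant = sign(delta) == res$call,
                              stringsAsFactors = FALSE)
    }
    per_fold[[f]] <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  all_calls <- do.call(rbind, per_fold)
  if (is.null(all_calls) || !nrow(all_calls))
    return(list(folds = per_fold, lncRNA_accuracy = numeric(0),
                sample_accuracy = numeric(0),
                mean_lncRNA_accuracy = NA_real_,
                mean_sample_accuracy = NA_real_, n_calls_evaluated = 0L))
  acc_g <- tapply(all_calls$concordant, all_calls$gene_id, mean)
  acc_s <- tapply(all_calls$concordant, all_calls$sample_id, mean)
  list(folds = per_fold,
       lncRNA_accuracy = acc_g, sample_accuracy = acc_s,
       mean_lncRNA_accuracy = mean(acc_g),
       mean_sample_accuracy = mean(acc_s),
       n_calls_evaluated = nrow(all_calls))
}

#' Fold-change contrast between called and never-called genes
#'
#' Per gene, log2 fold change = median over tumor-normal pairs of
#' `log2((tumor + 1) / (normal + 1))` (pseudocount 1).  Genes called
#' non-zero in >= 1 profile sample whose majority call sign matches the
#' sign of that median are the "consistent IDE" group; genes never called
#' are the comparison group.  Within the up stratum (IDE-up vs never-called
#' with positive FC) and down stratum (IDE-down vs never-called with
#' negative FC) separately, group medians and a two-sided Wilcoxon
#' rank-sum p are reported.
#'
#' @param cohort a [paired_cohort()].
#' @param profile an [ide_profile()] covering the cohort's tumor samples.
#' @return list with `per_gene` (gene_id, log2fc, group, direction) and
#'   `strata`: for each of `up`, `down`, the IDE / non-IDE medians,
#'   group sizes and Wilcoxon p (`NA` when a group is empty).
#' @export
fc_compare <- function(cohort, profile) {
  stopifnot(inherits(cohort, "paired_cohort"),
            inherits(profile, "ide_profile"))
  tumors <- names(cohort$pairing)
  if (!all(tumors %in% colnames(profile$calls)))
    stop("profile does not cover the cohort's tumor samples")
  genes <- rownames(cohort$tumor)
  tm <- unclass(cohort$tumor)[, tumors, drop = FALSE]
  nm <- unclass(cohort$normal)[, cohort$pairing[tumors], drop = FALSE]
  l2fc <- apply(log2((tm + 1) / (nm + 1)), 1, median)
  calls <- profile$calls[genes, , drop = FALSE]
  n_up <- rowSums(calls == 1L)
  n_dn <- rowSums(calls == -1L)
  called <- (n_up + n_dn) > 0
  maj <- sign(n_up - n_dn)  # majority call sign; 0 on exact split
  consistent <- called & maj != 0 & sign(l2fc) == maj
  group <- ifelse(!called, "non_IDE",
                  ifelse(consistent, "IDE_consistent", "IDE_inconsistent"))
  per_gene <- data.frame(gene_id = genes, log2fc = l2fc, group = group,
                         direction = maj, row.names = NULL,
                         stringsAsFactors = FALSE)
  stratum <- function(dir) {
    ide <- l2fc[consistent & maj == dir]
    non <- l2fc[!called & sign(l2fc) == dir]
    p <- if (length(ide) && length(non))
      wilcoxon_rank_sum(ide, non)$p else NA_real_
    list(n_ide = length(ide), n_non = length(non),
         median_ide = if (length(ide)) median(ide) else NA_real_,
         median_non = if (length(non)) median(non) else NA_real_,
         p = p)
  }
  list(per_gene = per_gene,
       strata = list(up = stratum(1), down = stratum(-1)))
}
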