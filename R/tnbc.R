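# Prognostic selection and two-class stratification of a subtype (the
# TNBC-style analysis): pick lncRNAs whose DE status separates survival,
# cluster samples on their ternary call vectors, then contrast the two
# classes on continuous covariates, call frequencies and mutation burden.

#' Select prognostic genes by DE-vs-unaltered log-rank
#'
#' Per gene, samples are split into called (call != 0) vs unaltered and
#' compared with [logrank_test()]; genes with fewer than `min_events`
#' events in either stratum are skipped (logged in the output), and genes
#' with raw `p < alpha` are kept.
#'
#' @param profile an [ide_profile()] (typically restricted to a subtype's
#'   specific lncRNAs and samples).
#' @param survival data.frame with `sample_id`, `time`, `event`.
#' @param alpha raw log-rank p cutoff; default 0.05.
#' @param min_events minimum events per stratum; default 3.
#' @return list with `genes` (kept gene IDs) and `table` (per tested gene:
#'   p, chi_square, n_de, n_unaltered, status kept/dropped/skipped).
#' @export
prognostic_filter <- function(profile, survival, alpha = 0.05,
                              min_events = 3) {
  stopifnot(inherits(profile, "ide_profile"),
            all(c("sample_id", "time", "event") %in% names(survival)))
  survival <- survival[complete.cases(survival[c("sample_id", "time",
                                                 "event")]), ]
  samples <- intersect(colnames(profile$calls), survival$sample_id)
  sv <- survival[match(samples, survival$sample_id), ]
  rows <- list()
  for (g in rownames(profile$calls)) {
    de <- profile$calls[g, samples] != 0L
    ev_de <- sum(sv$event[de]); ev_un <- sum(sv$event[!de])
    if (ev_de < min_events || ev_un < min_events) {
      rows[[g]] <- data.frame(gene_id = g, chi_square = NA_real_,
                              p = NA_real_, n_de = sum(de),
                              n_unaltered = sum(!de), status = "skipped",
                              stringsAsFactors = FALSE)
      next
    }
    lr <- logrank_test(sv$time, sv$event, ifelse(de, "DE", "unaltered"))
    rows[[g]] <- data.frame(gene_id = g, chi_square = lr$chi_square,
                            p = lr$p, n_de = sum(de),
                            n_unaltered = sum(!de),
                            status = if (lr$p < alpha) "kept" else "dropped",
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, c(rows, make.row.names = FALSE))
  list(genes = tab$gene_id[tab$status == "kept"], table = tab)
}

#' Hamming distance between ternary call vectors
#'
#' Fraction of genes on which two samples' calls differ.
#'
#' @param calls ternary genes x samples matrix.
#' @return a `dist` object over samples.
#' @export
ternary_hamming <- function(calls) {
  n <- ncol(calls)
  d <- matrix(0, n, n, dimnames = list(colnames(calls), colnames(calls)))
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (j > i)
        d[j, i] <- d[i, j] <- mean(calls[, i] != calls[, j])
  as.dist(d)
}

#' Two-class hierarchical clustering of ternary profiles
#'
#' Average-linkage agglomeration on the Hamming distance between samples'
#' call vectors, cut at k = 2.  The larger class is labelled 1 (the class
#' containing the lexicographically first sample wins ties).  A degenerate
#' cut (all samples identical, or one class empty) is flagged.
#'
#' @param profile an [ide_profile()] restricted to the genes to cluster on
#'   (e.g. the prognostic list).
#' @return list with `assignments` (data.frame `sample_id`, `class_label`),
#'   `order` (dendrogram leaf order), `hclust` (the tree), `degenerate`
#'   (logical).
#' @export
cluster_two_classes <- function(profile) {
  stopifnot(inherits(profile, "ide_profile"))
  calls <- profile$calls
  if (ncol(calls) < 2) stop("need >= 2 samples to cluster")
  if (nrow(calls) < 1) stop("need >= 1 gene to cluster on")
  calls <- calls[, order(colnames(calls)), drop = FALSE]  # deterministic
  d <- ternary_hamming(calls)
  hc <- hclust(d, method = "average")
  cl <- cutree(hc, k = 2)
  degenerate <- max(d) == 0 || length(unique(cl)) < 2
  sizes <- table(cl)
  big <- if (sizes[1] == sizes[2]) cl[1] else as.integer(names(which.max(sizes)))
  label <- ifelse(cl == big, 1L, 2L)
  list(assignments = data.frame(sample_id = names(cl), class_label = label,
                                row.names = NULL, stringsAsFactors = FALSE),
       order = colnames(calls)[hc$order], hclust = hc,
       degenerate = degenerate)
}

#' Compare classes on continuous covariates
#'
#' Two-sided Wilcoxon rank-sum per covariate, optional BH across
#' covariates.  A covariate constant across all samples is reported with
#' p = 1 and flagged.
#'
#' @param covariates data.frame of numeric covariates, plus a `sample_id`
#'   column.
#' @param assignments data.frame `sample_id`, `class_label` from
#'   [cluster_two_classes()].
#' @param adjust apply BH across covariates; default TRUE.
#' @return data.frame per covariate: medians per class, `p`, `q`,
#'   `constant` flag.
#' @export
compare_classes_continuous <- function(covariates, assignments,
                                       adjust = TRUE) {
  stopifnot("sample_id" %in% names(covariates))
  m <- merge(covariates, assignments, by = "sample_id")
  vars <- setdiff(names(covariates), "sample_id")
  rows <- lapply(vars, function(v) {
    x <- m[[v]][m$class_label == 1L]
    y <- m[[v]][m$class_label == 2L]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2)
      stop("covariate '", v, "' has < 2 values in a class")
    constant <- length(unique(c(x, y))) == 1
    p <- if (constant) 1 else wilcoxon_rank_sum(x, y)$p
    data.frame(covariate = v, median_class1 = median(x),
               median_class2 = median(y), p = p, constant = constant,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- if (adjust) bh_adjust(out$p) else NA_real_
  rownames(out) <- NULL
  out
}

#' Compare classes on per-gene upregulation frequency
#'
#' Per gene, a two-sided Fisher exact test on upregulated (call = +1)
#' vs-not across the two classes.
#'
#' @param profile an [ide_profile()] (or a binary genes x samples matrix,
#'   tested as flag-vs-not).
#' @param assignments data.frame `sample_id`, `class_label`.
#' @param gene_ids genes to test; default all rows.
#' @return data.frame per gene: up/not-up counts per class, `odds_ratio`,
#'   `p`.
#' @export
compare_classes_frequency <- function(profile, assignments,
                                      gene_ids = NULL) {
  flags <- if (inherits(profile, "ide_profile"))
    profile$calls == 1L else as.matrix(profile) != 0L
  if (is.null(gene_ids)) gene_ids <- rownames(flags)
  samples <- intersect(colnames(flags), assignments$sample_id)
  cl <- assignments$class_label[match(samples, assignments$sample_id)]
  rows <- lapply(gene_ids, function(g) {
    x <- flags[g, samples]
    a <- sum(x & cl == 1L); b <- sum(!x & cl == 1L)
    c_ <- sum(x & cl == 2L); d <- sum(!x & cl == 2L)
    ft <- fisher_exact_2x2(c(a, b, c_, d))
    data.frame(gene_id = g, up_class1 = a, not_class1 = b, up_class2 = c_,
               not_class2 = d, odds_ratio = ft$odds_ratio, p = ft$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-sample mutation burden
#'
#' Column sums of the mutation and non-silent mutation flag matrices.
#'
#' @param mutation,nonsilent [alteration_matrix()] objects sharing samples.
#' @return data.frame `sample_id`, `n_mutations`, `n_nonsilent`.
#' @export
tmb_counts <- function(mutation, nonsilent) {
  stopifnot(inherits(mutation, "alteration_matrix"),
            inherits(nonsilent, "alteration_matrix"))
  samples <- intersect(colnames(mutation$flags), colnames(nonsilent$flags))
  if (!length(samples)) stop("matrices share no samples")
  data.frame(sample_id = samples,
             n_mutations = colSums(mutation$flags[, samples, drop = FALSE]),
             n_nonsilent = colSums(nonsilent$flags[, samples, drop = FALSE]),
             row.names = NULL, stringsAsFactors = FALSE)
}
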