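# The individualization core: one tumor sample's expression vector is
# reduced, gene by gene, to a 2x2 table of stable-partner orderings
# (reference vs this sample) and tested with Fisher's exact test; BH across
# genes within the sample gives the per-sample discovery set.  An optional
# refinement pass (RankComp-v2 style) re-tests each gene after dropping
# partners themselves called dysregulated, which de-contaminates the
# reference proportions.

#' Calling parameters
#'
#' @param alpha within-sample FDR level for calls, in (0, 1); default 0.05.
#' @param min_pairs minimum number of stable partners a gene needs to be
#'   testable; default 5.  Below it the gene is called 0 with missing p.
#' @param max_iter total passes (>= 1); default 2, i.e. one refinement pass.
#'   Set 1 to disable refinement.
#' @return list of validated parameters, class `call_params`.
#' @export
call_params <- function(alpha = 0.05, min_pairs = 5, max_iter = 2) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  if (min_pairs < 1) stop("min_pairs must be >= 1")
  if (max_iter < 1) stop("max_iter must be >= 1")
  structure(list(alpha = alpha, min_pairs = as.integer(min_pairs),
                 max_iter = as.integer(max_iter)), class = "call_params")
}

# Vectorised two-sided Fisher p for tables [[a,b],[c,d]]; same
# minimum-likelihood rule as fisher_exact_2x2 (oracle-checked against it).
fisher_p_vec <- function(a, b, c_, d) {
  vapply(seq_along(a), function(i) {
    r1 <- a[i] + b[i]
    c1 <- a[i] + c_[i]
    n <- r1 + c_[i] + d[i]
    lo <- max(0L, c1 - (n - r1))
    hi <- min(r1, c1)
    xs <- lo:hi
    probs <- dhyper(xs, c1, n - c1, r1)
    min(1, sum(probs[probs <= probs[xs == a[i]] * (1 + .REL_EPS)]))
  }, numeric(1))
}

#' Call up/down/unaltered status for one sample
#'
#' @param stable_pairs a [stable_pair_set()] (the reference criterion).
#' @param sample_values named numeric vector of the sample's expression,
#'   covering every gene in the pair set.
#' @param params a [call_params()].
#' @return data.frame with columns `gene_id`, `call` (-1/0/+1), `p`, `q`
#'   (NA where the gene had fewer than `min_pairs` stable partners).
#' @export
call_sample <- function(stable_pairs, sample_values, params = call_params()) {
  stopifnot(inherits(stable_pairs, "stable_pair_set"),
            inherits(params, "call_params"))
  pairs <- stable_pairs$pairs
  if (!nrow(pairs)) stop("empty stable pair set")
  genes <- sort(unique(c(pairs$high_gene, pairs$low_gene)))
  missing <- setdiff(genes, names(sample_values))
  if (length(missing))
    stop("sample lacks values for: ", paste(head(missing, 5), collapse = ", "))
  idx <- index_pairs(pairs, genes)
  v <- as.numeric(sample_values[genes])
  ng <- length(genes)

  call <- integer(ng)
  p <- rep(NA_real_, ng)
  q <- rep(NA_real_, ng)
  for (iter in seq_len(params$max_iter)) {
    active <- call == 0L
    a <- integer(ng); b <- integer(ng); c_ <- integer(ng)
    for (gi in seq_len(ng)) {
      hp <- idx$high_partners[[gi]]; hp <- hp[active[hp]]
      lp <- idx$low_partners[[gi]];  lp <- lp[active[lp]]
      a[gi] <- length(hp)
      b[gi] <- length(lp)
      c_[gi] <- sum(v[gi] > v[hp]) + sum(v[gi] >= v[lp])
    }
    d <- a + b - c_
    testable <- (a + b) >= params$min_pairs
    p_new <- rep(NA_real_, ng)
    p_new[testable] <- fisher_p_vec(a[testable], b[testable], c_[testable],
                                    d[testable])
    q_new <- bh_adjust(p_new)
    call_new <- integer(ng)
    sig <- !is.na(q_new) & q_new <= params$alpha
    up <- sig & (c_ / (a + b) > a / (a + b))
    down <- sig & (c_ / (a + b) < a / (a + b))
    call_new[up] <- 1L
    call_new[down] <- -1L
    p <- p_new; q <- q_new
    converged <- identical(call_new, call)
    call <- call_new
    if (converged) break
  }
  data.frame(gene_id = genes, call = call, p = p, q = q,
             stringsAsFactors = FALSE)
}

#' Assemble the cohort IDE profile
#'
#' Runs [call_sample()] on every tumor column and stacks the results.
#' Genes present in the tumor matrix but absent from the pair set are
#' carried as call 0 with missing p (they had no stable partners).
#'
#' @param expr_tumors an [expression_matrix()] of tumor samples sharing the
#'   pair set's gene universe.
#' @param stable_pairs a [stable_pair_set()].
#' @param params a [call_params()].
#' @return An [ide_profile()] over all genes of `expr_tumors`.
#' @export
build_profile <- function(expr_tumors, stable_pairs,
                          params = call_params()) {
  genes <- rownames(expr_tumors)
  samples <- colnames(expr_tumors)
  calls <- matrix(0L, length(genes), length(samples),
                  dimnames = list(genes, samples))
  pv <- matrix(NA_real_, length(genes), length(samples),
               dimnames = list(genes, samples))
  qv <- pv
  if (length(samples) == 0)
    return(ide_profile(calls, pv, qv, alpha = params$alpha))
  for (s in samples) {
    res <- call_sample(stable_pairs, expr_tumors[, s], params)
    ix <- match(res$gene_id, genes)
    if (anyNA(ix))
      stop("pair set contains genes absent from the tumor matrix")
    calls[ix, s] <- res$call
    pv[ix, s] <- res$p
    qv[ix, s] <- res$q
  }
  ide_profile(calls, pv, qv, alpha = params$alpha)
}

#' Per-gene differential expression frequency
#'
#' @param profile an [ide_profile()].
#' @return list with `per_gene` (data.frame `gene_id`, `frac_up`,
#'   `frac_down`) and cohort means `mean_up`, `mean_down`, `mean_de`
#'   (mean of up + down).
#' @export
de_frequency <- function(profile) {
  stopifnot(inherits(profile, "ide_profile"))
  n <- ncol(profile$calls)
  if (n == 0) stop("empty profile")
  fu <- rowMeans(profile$calls == 1L)
  fd <- rowMeans(profile$calls == -1L)
  list(per_gene = data.frame(gene_id = rownames(profile$calls),
                             frac_up = fu, frac_down = fd,
                             row.names = NULL, stringsAsFactors = FALSE),
       mean_up = mean(fu), mean_down = mean(fd), mean_de = mean(fu + fd))
}
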