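# Mining the reference criterion: gene pairs whose relative expression
# ordering is stable across the normal cohort.  Ties always count against
# stability (a tied sample supports neither direction), which keeps the two
# directions mutually exclusive for any threshold f > 0.5.

#' Support of one ordered gene pair in the normal cohort
#'
#' Fraction of normal samples in which gene `i` is strictly above gene `j`.
#'
#' @param expr_normals an [expression_matrix()] of the normal cohort.
#' @param i,j gene IDs.
#' @return fraction in \[0, 1\].
#' @export
pair_support <- function(expr_normals, i, j) {
  if (!(i %in% rownames(expr_normals)) || !(j %in% rownames(expr_normals)))
    stop("unknown gene: ", paste(setdiff(c(i, j), rownames(expr_normals)),
                                 collapse = ", "))
  mean(expr_normals[i, ] > expr_normals[j, ])
}

#' Find all stably ordered gene pairs
#'
#' For every unordered gene pair, counts in how many normal samples each
#' direction holds strictly and keeps the direction (at most one, since
#' `threshold_f > 0.5`) whose support reaches `threshold_f`.  The scan is
#' O(G^2 * N); use `gene_subset` to bound it on large universes.
#'
#' @param expr_normals an [expression_matrix()] with >= 2 samples.
#' @param threshold_f stability threshold in (0.5, 1]; default 0.99.
#' @param gene_subset optional character vector restricting the gene
#'   universe before the all-pairs pass.
#' @return A [stable_pair_set()]; pairs ordered by (high_gene, low_gene).
#' @export
find_stable_pairs <- function(expr_normals, threshold_f = 0.99,
                              gene_subset = NULL) {
  if (!(threshold_f > 0.5 && threshold_f <= 1))
    stop("threshold_f must be in (0.5, 1]")
  x <- unclass(expr_normals)
  if (!is.null(gene_subset)) {
    missing <- setdiff(gene_subset, rownames(x))
    if (length(missing))
      stop("gene_subset not in matrix: ", paste(missing, collapse = ", "))
    x <- x[gene_subset, , drop = FALSE]
  }
  n <- ncol(x)
  if (n < 2) stop("need >= 2 normal samples")
  g <- nrow(x)
  genes <- rownames(x)
  if (g < 2)
    return(stable_pair_set(data.frame(high_gene = character(0),
                                      low_gene = character(0),
                                      support = numeric(0)),
                           threshold_f, n))
  # wins[i, j] = number of samples with x[i, s] > x[j, s]
  wins <- matrix(0L, g, g)
  for (s in seq_len(n)) {
    v <- x[, s]
    wins <- wins + (outer(v, v, ">") * 1L)
  }
  need <- threshold_f * n
  hit <- which(wins >= need - 1e-9, arr.ind = TRUE)
  if (nrow(hit)) {
    df <- data.frame(high_gene = genes[hit[, 1]], low_gene = genes[hit[, 2]],
                     support = wins[hit] / n, stringsAsFactors = FALSE)
    df <- df[order(df$high_gene, df$low_gene), , drop = FALSE]
  } else {
    df <- data.frame(high_gene = character(0), low_gene = character(0),
                     support = numeric(0))
  }
  stable_pair_set(df, threshold_f, n)
}

# Internal: index stable pairs by gene for fast per-sample evaluation.
# Returns, per gene, the integer positions (into `genes`) of partners it is
# above (high_partners) and below (low_partners) in the reference.
index_pairs <- function(pairs_df, genes) {
  hi <- match(pairs_df$high_gene, genes)
  lo <- match(pairs_df$low_gene, genes)
  if (anyNA(hi) || anyNA(lo))
    stop("stable pair references a gene missing from the expression matrix")
  list(high_partners = split(lo, factor(hi, levels = seq_along(genes))),
       low_partners = split(hi, factor(lo, levels = seq_along(genes))))
}

#' Per-gene rank-reversal counts for one sample
#'
#' For each gene g with stable partners, builds the contingency counts of
#' the rank-reversal test: `a` = number of stable pairs in which g is the
#' high gene, `b` = number in which it is the low gene (reference
#' proportions), and `c`, `d` = how many of those same partners g sits
#' above / below in this sample.  A tie in the sample always counts as a
#' reversal of the reference direction (conservative): for a high-partner
#' it counts toward `d`, for a low-partner toward `c`.
#'
#' @param stable_pairs a [stable_pair_set()].
#' @param sample_values named numeric vector covering every gene in the
#'   pair set.
#' @return data.frame with columns `gene_id`, `a`, `b`, `c`, `d`
#'   (one row per gene appearing in the pair set).
#' @export
evaluate_sample <- function(stable_pairs, sample_values) {
  stopifnot(inherits(stable_pairs, "stable_pair_set"))
  pairs <- stable_pairs$pairs
  genes <- sort(unique(c(pairs$high_gene, pairs$low_gene)))
  missing <- setdiff(genes, names(sample_values))
  if (length(missing))
    stop("sample lacks values for: ", paste(head(missing, 5), collapse = ", "))
  idx <- index_pairs(pairs, genes)
  v <- sample_values[genes]
  counts_for <- function(gi) {
    hp <- idx$high_partners[[gi]]  # partners g should be above
    lp <- idx$low_partners[[gi]]   # partners g should be below
    a <- length(hp); b <- length(lp)
    c_ <- sum(v[gi] > v[hp]) + sum(v[gi] >= v[lp])
    data.frame(gene_id = genes[gi], a = a, b = b, c = c_, d = a + b - c_,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(seq_along(genes), counts_for))
  rownames(out) <- NULL
  out
}
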