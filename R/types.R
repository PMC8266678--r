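#' Construct an expression matrix
#'
#' The raw substrate of all ordering statistics: a dense genes x samples
#' matrix of non-negative, finite expression values (FPKM-like continuous
#' units; the method only consumes within-sample orderings, so the unit is
#' irrelevant as long as it is monotone in abundance).
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param gene_ids character vector of unique gene identifiers; defaults to
#'   `rownames(values)`.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to `colnames(values)`.
#' @return An object of class `expression_matrix`: the numeric matrix with
#'   `dimnames` set to the IDs.
#' @examples
#' em <- expression_matrix(matrix(1:4, 2, dimnames = list(c("g1", "g2"),
#'                                                        c("s1", "s2"))))
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(gene_ids) && nrow(values) == 0) gene_ids <- character(0)
  if (is.null(sample_ids) && ncol(values) == 0) sample_ids <- character(0)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("gene_ids and sample_ids are required (or set dimnames)")
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values))
    stop("gene_ids length (", length(gene_ids), ") != nrow(values) (",
         nrow(values), ")")
  if (length(sample_ids) != ncol(values))
    stop("sample_ids length (", length(sample_ids), ") != ncol(values) (",
         ncol(values), ")")
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup))
    stop("duplicate gene IDs: ", paste(dup, collapse = ", "))
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup))
    stop("duplicate sample IDs: ", paste(dup, collapse = ", "))
  if (!is.numeric(values) || anyNA(values) || any(!is.finite(values)))
    stop("expression values must be numeric and finite")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop("negative expression value at gene '", gene_ids[bad[1]],
         "', sample '", sample_ids[bad[2]], "'")
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(values, class = c("expression_matrix", "matrix", "array"))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x), "genes x", ncol(x), "samples\n")
  invisible(x)
}

#' Construct a paired tumor-normal cohort
#'
#' @param normal,tumor `expression_matrix` objects over an identical gene
#'   universe (same IDs, same order).
#' @param pairing named character vector mapping tumor sample ID to its
#'   matched normal sample ID; must be injective into `normal`'s samples.
#' @return An object of class `paired_cohort` (list with `normal`, `tumor`,
#'   `pairing`).
#' @export
paired_cohort <- function(normal, tumor, pairing) {
  stopifnot(inherits(normal, "expression_matrix"),
            inherits(tumor, "expression_matrix"))
  if (!identical(rownames(normal), rownames(tumor)))
    stop("normal and tumor must share an identical gene_ids vector")
  if (is.null(names(pairing)))
    stop("pairing must be a named vector: names = tumor IDs")
  if (!all(names(pairing) %in% colnames(tumor)))
    stop("pairing names must be tumor sample IDs")
  if (!all(pairing %in% colnames(normal)))
    stop("pairing values must be normal sample IDs")
  if (anyDuplicated(pairing) || anyDuplicated(names(pairing)))
    stop("pairing must be a bijection onto a subset of normal samples")
  structure(list(normal = normal, tumor = tumor,
                 pairing = pairing[names(pairing)]),
            class = "paired_cohort")
}

#' @export
print.paired_cohort <- function(x, ...) {
  cat("paired_cohort:", length(x$pairing), "tumor-normal pairs,",
      nrow(x$normal), "genes\n")
  invisible(x)
}

#' Construct a stable pair set
#'
#' The reference criterion: ordered gene pairs (high_gene, low_gene) whose
#' ordering high > low holds in at least `threshold_f` of the normal cohort.
#'
#' @param pairs data.frame with columns `high_gene`, `low_gene`, `support`.
#' @param threshold_f stability threshold used, in (0.5, 1].
#' @param n_normals number of reference normal samples the supports were
#'   computed from.
#' @return An object of class `stable_pair_set`.
#' @export
stable_pair_set <- function(pairs, threshold_f, n_normals) {
  stopifnot(is.data.frame(pairs),
            all(c("high_gene", "low_gene", "support") %in% names(pairs)))
  if (!(threshold_f > 0.5 && threshold_f <= 1))
    stop("threshold_f must be in (0.5, 1]")
  pairs$high_gene <- as.character(pairs$high_gene)
  pairs$low_gene <- as.character(pairs$low_gene)
  if (any(pairs$high_gene == pairs$low_gene))
    stop("self-pairs are not allowed")
  if (nrow(pairs) && any(pairs$support < threshold_f))
    stop("all supports must be >= threshold_f")
  key <- ifelse(pairs$high_gene < pairs$low_gene,
                paste(pairs$high_gene, pairs$low_gene),
                paste(pairs$low_gene, pairs$high_gene))
  if (anyDuplicated(key))
    stop("an unordered gene pair appears more than once")
  rownames(pairs) <- NULL
  structure(list(pairs = pairs[c("high_gene", "low_gene", "support")],
                 threshold_f = threshold_f, n_normals = as.integer(n_normals)),
            class = "stable_pair_set")
}

#' @export
print.stable_pair_set <- function(x, ...) {
  cat("stable_pair_set:", nrow(x$pairs), "pairs (f >=", x$threshold_f,
      "over", x$n_normals, "normals)\n")
  invisible(x)
}

#' Construct an individualized differential expression (IDE) profile
#'
#' The pipeline's central object: a ternary genes x samples matrix of calls
#' (-1 down, 0 unaltered, +1 up) with sibling matrices of per-call p-values
#' and within-sample BH-adjusted q-values.  p is `NA` where a gene had fewer
#' stable partners than `min_pairs` at call time.
#'
#' @param calls integer matrix in \{-1, 0, 1\}, dimnames = genes x samples.
#' @param p_values,q_values numeric matrices of the same shape, entries in
#'   \[0, 1\] or `NA`.
#' @param alpha the FDR level the calls were made at.
#' @return An object of class `ide_profile`.
#' @export
ide_profile <- function(calls, p_values, q_values, alpha = 0.05) {
  calls <- as.matrix(calls)
  if (!all(calls %in% c(-1L, 0L, 1L)))
    stop("calls must be in {-1, 0, +1}")
  storage.mode(calls) <- "integer"
  chk <- function(m, nm) {
    m <- as.matrix(m)
    if (!identical(dim(m), dim(calls)))
      stop(nm, " must have the same shape as calls")
    if (any(m < 0 | m > 1, na.rm = TRUE))
      stop(nm, " must lie in [0, 1]")
    dimnames(m) <- dimnames(calls)
    m
  }
  structure(list(calls = calls, p_values = chk(p_values, "p_values"),
                 q_values = chk(q_values, "q_values"), alpha = alpha),
            class = "ide_profile")
}

#' @export
print.ide_profile <- function(x, ...) {
  cat("ide_profile:", nrow(x$calls), "genes x", ncol(x$calls), "samples;",
      sum(x$calls == 1L), "up calls,", sum(x$calls == -1L),
      "down calls (alpha =", x$alpha, ")\n")
  invisible(x)
}

ALTERATION_TYPES <- c("mutation", "nonsilent_mutation", "amplification",
                      "deletion", "hypermethylation", "hypomethylation")

#' Construct a binary alteration matrix
#'
#' @param flags binary genes x samples matrix (0/1), dimnames set.
#' @param alteration_type one of `"mutation"`, `"nonsilent_mutation"`,
#'   `"amplification"`, `"deletion"`, `"hypermethylation"`,
#'   `"hypomethylation"`.
#' @return An object of class `alteration_matrix`.
#' @export
alteration_matrix <- function(flags, alteration_type) {
  alteration_type <- match.arg(alteration_type, ALTERATION_TYPES)
  flags <- as.matrix(flags)
  if (!all(flags %in% c(0L, 1L)))
    stop("alteration flags must be 0/1")
  if (is.null(rownames(flags)) || is.null(colnames(flags)))
    stop("flags must carry gene and sample IDs as dimnames")
  storage.mode(flags) <- "integer"
  structure(list(flags = flags, alteration_type = alteration_type),
            class = "alteration_matrix")
}

#' @export
print.alteration_matrix <- function(x, ...) {
  cat("alteration_matrix [", x$alteration_type, "]: ", nrow(x$flags),
      " genes x ", ncol(x$flags), " samples, ", sum(x$flags),
      " flags set\n", sep = "")
  invisible(x)
}

#' Construct a per-sample annotation table
#'
#' @param sample_id character vector of unique sample IDs.
#' @param subtype optional character vector of subtype labels (`NA` allowed).
#' @param surv_time,surv_event optional survival time (non-negative, days)
#'   and event indicator (0/1); each must be present or `NA` together.
#' @param covariates optional data.frame of numeric per-sample covariates
#'   (e.g. an HRD score).
#' @param drug_response optional data.frame with columns `sample_id`, `drug`
#'   and either `response` (\code{"responder"}/\code{"non-responder"}) or
#'   `act_area` (numeric dose-response activity area).
#' @return An object of class `sample_annotation` (list of the validated
#'   pieces; `$table` holds the per-sample frame).
#' @export
sample_annotation <- function(sample_id, subtype = NULL, surv_time = NULL,
                              surv_event = NULL, covariates = NULL,
                              drug_response = NULL) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("duplicate sample IDs in annotation")
  n <- length(sample_id)
  rec <- function(x, default) if (is.null(x)) rep(default, n) else x
  subtype <- rec(subtype, NA_character_)
  surv_time <- rec(surv_time, NA_real_)
  surv_event <- rec(surv_event, NA_real_)
  if (length(subtype) != n || length(surv_time) != n ||
      length(surv_event) != n)
    stop("annotation columns must match sample_id length")
  if (any(xor(is.na(surv_time), is.na(surv_event))))
    stop("surv_event must be present exactly where surv_time is")
  if (any(surv_time < 0, na.rm = TRUE)) stop("surv_time must be >= 0")
  if (!all(surv_event %in% c(0, 1, NA))) stop("surv_event must be 0/1")
  tab <- data.frame(sample_id = sample_id, subtype = as.character(subtype),
                    surv_time = as.numeric(surv_time),
                    surv_event = as.integer(surv_event),
                    stringsAsFactors = FALSE)
  if (!is.null(covariates)) {
    stopifnot(is.data.frame(covariates), nrow(covariates) == n)
    if (any(vapply(covariates, function(v) any(!is.finite(v) & !is.na(v)),
                   logical(1))))
      stop("covariates must be finite or NA")
    tab <- cbind(tab, covariates)
  }
  if (!is.null(drug_response)) {
    stopifnot(is.data.frame(drug_response),
              all(c("sample_id", "drug") %in% names(drug_response)))
    if (!("response" %in% names(drug_response)) &&
        !("act_area" %in% names(drug_response)))
      stop("drug_response needs a 'response' or 'act_area' column")
    if ("act_area" %in% names(drug_response) &&
        any(!is.finite(drug_response$act_area) & !is.na(drug_response$act_area)))
      stop("act_area values must be finite")
  }
  structure(list(table = tab, covariate_names = names(covariates),
                 drug_response = drug_response),
            class = "sample_annotation")
}

#' @export
print.sample_annotation <- function(x, ...) {
  cat("sample_annotation:", nrow(x$table), "samples;",
      sum(!is.na(x$table$subtype)), "subtyped,",
      sum(!is.na(x$table$surv_time)), "with survival\n")
  invisible(x)
}

#' Construct a 2x2 contingency table
#'
#' Layout is `[[a, b], [c, d]]` (row-major).  Used both for the per-gene
#' rank-reversal counts (row 1 = stable partners below/above the gene in
#' normals, row 2 = the same partners below/above it in one tumor sample)
#' and for every downstream Fisher test.
#'
#' @param a,b,c,d non-negative integer counts.
#' @return A 2x2 integer matrix of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  x <- c(a, b, c, d)
  if (anyNA(x) || any(x < 0) || any(x != round(x)))
    stop("counts must be non-negative integers")
  if (sum(x) == 0) stop("all-zero table")
  m <- matrix(as.integer(x), 2, 2, byrow = TRUE)
  class(m) <- c("contingency_2x2", "matrix", "array")
  m
}

as_contingency_2x2 <- function(x) {
  if (inherits(x, "contingency_2x2")) return(x)
  if (is.matrix(x) && all(dim(x) == c(2, 2)))
    return(contingency_2x2(x[1, 1], x[1, 2], x[2, 1], x[2, 2]))
  if (is.numeric(x) && length(x) == 4)
    return(contingency_2x2(x[1], x[2], x[3], x[4]))
  stop("cannot interpret input as a 2x2 table")
}
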