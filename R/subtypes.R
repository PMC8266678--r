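# Subtype-level analyses on the ternary profile: over-representation of DE
# within a subtype, exclusivity, UpSet-style intersection counts,
# lncRNA-gene alteration co-occurrence, and generic hypergeometric
# over-representation of gene sets.

#' Subtype over-represented genes
#'
#' Per subtype S and gene g, tests DE-vs-not (call != 0) against in-S-vs-
#' rest with a one-sided (greater) Fisher exact test, adjusts BH within the
#' subtype, and keeps genes with q <= `alpha` whose within-subtype DE
#' frequency exceeds `min_freq`.
#'
#' @param profile an [ide_profile()].
#' @param subtypes named character vector: sample ID -> subtype label;
#'   profiled samples without a label are excluded.
#' @param alpha within-subtype FDR level; default 0.05.
#' @param min_freq within-subtype DE frequency gate; default 0.05
#'   (strictly greater than).
#' @return list with `sets` (per-subtype character vectors of gene IDs) and
#'   `table` (per subtype x gene: counts, p, q, freq, kept).
#' @export
over_represented <- function(profile, subtypes, alpha = 0.05,
                             min_freq = 0.05) {
  stopifnot(inherits(profile, "ide_profile"))
  samples <- intersect(colnames(profile$calls),
                       names(subtypes)[!is.na(subtypes)])
  lab <- subtypes[samples]
  de <- profile$calls[, samples, drop = FALSE] != 0L
  rows <- list()
  sets <- list()
  for (s in sort(unique(lab))) {
    in_s <- lab == s
    if (sum(in_s) < 2) {
      warning("subtype '", s, "' has < 2 samples; skipped")
      next
    }
    a <- rowSums(de[, in_s, drop = FALSE])          # DE within S
    b <- sum(in_s) - a
    c_ <- rowSums(de[, !in_s, drop = FALSE])        # DE in the rest
    d <- sum(!in_s) - c_
    n <- sum(in_s) + sum(!in_s)
    # one-sided (greater) Fisher == hypergeometric upper tail
    p <- phyper(a - 1, a + c_, n - (a + c_), a + b, lower.tail = FALSE)
    q <- bh_adjust(p)
    freq <- a / sum(in_s)
    kept <- q <= alpha & freq > min_freq
    rows[[s]] <- data.frame(subtype = s, gene_id = rownames(de),
                            de_in = a, not_de_in = b, de_out = c_,
                            not_de_out = d, freq = freq, p = p, q = q,
                            kept = kept, row.names = NULL,
                            stringsAsFactors = FALSE)
    sets[[s]] <- rownames(de)[kept]
  }
  list(sets = sets, table = do.call(rbind, c(rows, make.row.names = FALSE)))
}

#' Subtype-specific genes
#'
#' A gene is specific to subtype S iff it is over-represented in S and in
#' no other subtype.
#'
#' @param sets named list of per-subtype over-represented gene ID vectors.
#' @return named list of per-subtype exclusive gene ID vectors.
#' @export
subtype_specific <- function(sets) {
  if (!length(sets)) return(list())
  counts <- table(unlist(sets, use.names = FALSE))
  lapply(sets, function(g) g[counts[g] == 1])
}

#' Exclusive intersection counts (UpSet-style)
#'
#' @param sets named list of character vectors.
#' @return data.frame with `combination` (set names joined by `&`) and
#'   `count`; zero-count combinations omitted.
#' @export
intersection_counts <- function(sets) {
  if (!length(sets)) stop("need at least one set")
  universe <- unique(unlist(sets, use.names = FALSE))
  if (!length(universe))
    return(data.frame(combination = character(0), count = integer(0)))
  membership <- vapply(sets, function(g) universe %in% g,
                       logical(length(universe)))
  if (is.null(dim(membership)))
    membership <- matrix(membership, nrow = length(universe))
  key <- apply(membership, 1, function(m)
    paste(names(sets)[m], collapse = "&"))
  tab <- table(key)
  out <- data.frame(combination = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(-out$count, out$combination), , drop = FALSE]
}

#' lncRNA-gene alteration co-occurrence network
#'
#' Within one subtype's samples, tests each (lncRNA, gene) combination for
#' co-occurrence between the lncRNA's DE status (|call| != 0; direction is
#' collapsed) and the gene's binary alteration flag, with a two-sided
#' Fisher exact test.  Edges are kept when `p < p_cut` and the odds ratio
#' exceeds 1 (co-occurrence, not mutual exclusivity).  lncRNAs or genes
#' altered in none of the subtype's samples are skipped.
#'
#' @param profile an [ide_profile()].
#' @param alteration an [alteration_matrix()] for the protein-coding genes.
#' @param subtype_samples character vector of sample IDs forming the
#'   subtype; must intersect both matrices' samples.
#' @param lncRNA_ids,gene_ids the candidate node sets (e.g. subtype-specific
#'   lncRNAs and a coding-gene panel).
#' @param p_cut raw p-value cutoff; default 0.05.
#' @return data.frame of kept edges: `lncRNA_id`, `gene_id`,
#'   `alteration_type`, `a`..`d` (both-altered / lncRNA-only / gene-only /
#'   neither), `odds_ratio`, `p`.
#' @export
cooccurrence_network <- function(profile, alteration, subtype_samples,
                                 lncRNA_ids, gene_ids, p_cut = 0.05) {
  stopifnot(inherits(profile, "ide_profile"),
            inherits(alteration, "alteration_matrix"))
  samples <- Reduce(intersect, list(subtype_samples,
                                    colnames(profile$calls),
                                    colnames(alteration$flags)))
  if (!length(samples)) stop("no usable samples in the subtype")
  lncRNA_ids <- intersect(lncRNA_ids, rownames(profile$calls))
  gene_ids <- intersect(gene_ids, rownames(alteration$flags))
  de <- profile$calls[lncRNA_ids, samples, drop = FALSE] != 0L
  fl <- alteration$flags[gene_ids, samples, drop = FALSE] == 1L
  edges <- list()
  for (l in lncRNA_ids) {
    x <- de[l, ]
    if (!any(x)) next
    for (g in gene_ids) {
      y <- fl[g, ]
      if (!any(y)) next
      a <- sum(x & y); b <- sum(x & !y); c_ <- sum(!x & y)
      d <- length(samples) - a - b - c_
      ft <- fisher_exact_2x2(c(a, b, c_, d))
      if (ft$p < p_cut && !is.nan(ft$odds_ratio) && ft$odds_ratio > 1)
        edges[[length(edges) + 1L]] <-
          data.frame(lncRNA_id = l, gene_id = g,
                     alteration_type = alteration$alteration_type,
                     a = a, b = b, c = c_, d = d,
                     odds_ratio = ft$odds_ratio, p = ft$p,
                     stringsAsFactors = FALSE)
    }
  }
  if (!length(edges))
    return(data.frame(lncRNA_id = character(0), gene_id = character(0),
                      alteration_type = character(0), a = integer(0),
                      b = integer(0), c = integer(0), d = integer(0),
                      odds_ratio = numeric(0), p = numeric(0)))
  out <- do.call(rbind, edges)
  rownames(out) <- NULL
  out
}

#' Hypergeometric over-representation analysis
#'
#' @param selected character vector of selected genes (subset of
#'   `universe`).
#' @param pathways named list of gene sets; each is intersected with the
#'   universe before testing.
#' @param universe character vector of testable genes.
#' @return data.frame per pathway: `pathway`, `size` (in-universe),
#'   `overlap`, `p` (upper tail), `q` (BH across pathways).
#' @export
ora_hypergeometric <- function(selected, pathways, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  selected <- unique(intersect(selected, universe))
  res <- lapply(names(pathways), function(nm) {
    pw <- intersect(pathways[[nm]], universe)
    ov <- length(intersect(selected, pw))
    p <- hypergeom_upper_tail(length(universe), length(pw),
                              length(selected), ov)
    data.frame(pathway = nm, size = length(pw), overlap = ov, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}

#' Read pathway gene sets from a GMT file
#'
#' @param path GMT path (name, description, then member genes, tab-sep).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) f[-(1:2)])
  names(out) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, "", 1)
  out
}
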