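# Agreement between IDE calls and CNV / promoter-methylation alterations.
# An up call is supported by amplification or hypomethylation, a down call
# by deletion or hypermethylation; a called (gene, sample) with no
# directional alteration flag of any type is excluded from the denominator.

SUPPORTING_TYPES <- list(up = c("amplification", "hypomethylation"),
                         down = c("deletion", "hypermethylation"))
DIRECTIONAL_TYPES <- unlist(SUPPORTING_TYPES, use.names = FALSE)

#' Per-gene consistency of IDE calls with CNV / methylation
#'
#' Genes are ranked by total DE frequency (ties broken lexicographically by
#' gene ID) and the `top_k` most frequent are scored: for each DE call of
#' the gene, the call is consistent iff that sample carries a supporting
#' alteration flag (any one suffices, even if a contradicting flag
#' co-occurs).  Called samples carrying no directional flag at all for the
#' gene are dropped from the denominator.
#'
#' @param profile an [ide_profile()].
#' @param alterations list of [alteration_matrix()] objects of the
#'   directional types (amplification, deletion, hypermethylation,
#'   hypomethylation); mutation matrices are ignored with a warning.
#' @param top_k number of top-frequency genes to score; default 100.
#' @return data.frame with one row per scored gene: `gene_id`,
#'   `n_evaluable`, `n_consistent`, `ratio`, `category` (one of `full`,
#'   `partial`, `none`, `no_data`).
#' @export
consistency_ratio <- function(profile, alterations, top_k = 100) {
  stopifnot(inherits(profile, "ide_profile"))
  if (top_k <= 0) stop("top_k must be positive")
  if (inherits(alterations, "alteration_matrix"))
    alterations <- list(alterations)
  types <- vapply(alterations, function(a) a$alteration_type, character(1))
  if (any(!types %in% DIRECTIONAL_TYPES)) {
    warning("ignoring non-directional alteration matrices: ",
            paste(unique(types[!types %in% DIRECTIONAL_TYPES]),
                  collapse = ", "))
    alterations <- alterations[types %in% DIRECTIONAL_TYPES]
    types <- types[types %in% DIRECTIONAL_TYPES]
  }
  freq <- de_frequency(profile)$per_gene
  total <- freq$frac_up + freq$frac_down
  ord <- order(-total, freq$gene_id)
  keep <- freq$gene_id[ord][seq_len(min(top_k, nrow(freq)))]
  samples <- colnames(profile$calls)

  flag_at <- function(alt, gene, sample) {
    if (!(gene %in% rownames(alt$flags)) ||
        !(sample %in% colnames(alt$flags))) return(FALSE)
    alt$flags[gene, sample] == 1L
  }
  score_gene <- function(g) {
    calls <- profile$calls[g, ]
    called <- samples[calls != 0L]
    n_eval <- 0L; n_cons <- 0L
    for (s in called) {
      hit <- types[vapply(alterations, flag_at, logical(1), g, s)]
      if (!length(hit)) next  # no directional flag at all: excluded
      n_eval <- n_eval + 1L
      supp <- SUPPORTING_TYPES[[if (calls[s] == 1L) "up" else "down"]]
      if (any(hit %in% supp)) n_cons <- n_cons + 1L
    }
    ratio <- if (n_eval > 0) n_cons / n_eval else NA_real_
    category <- if (n_eval == 0) "no_data"
    else if (ratio == 1) "full"
    else if (ratio == 0) "none"
    else "partial"
    data.frame(gene_id = g, n_evaluable = n_eval, n_consistent = n_cons,
               ratio = ratio, category = category, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(keep, score_gene))
  rownames(out) <- NULL
  out
}

#' Tally consistency categories
#'
#' @param records output of [consistency_ratio()].
#' @return named integer vector over `full`, `partial`, `none`, `no_data`.
#' @export
consistency_census <- function(records) {
  if (!nrow(records)) stop("no consistency records")
  cats <- c("full", "partial", "none", "no_data")
  out <- table(factor(records$category, levels = cats))
  setNames(as.integer(out), cats)
}
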