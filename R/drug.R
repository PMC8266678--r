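# Drug-response association: Fisher exact on clinical responder status in
# treated patients, and Welch's t on cell-line ActArea (activity area;
# larger = more drug-sensitive).

#' Associate IDE status with clinical drug response
#'
#' Restricted to samples treated with `drug`, per lncRNA a two-sided Fisher
#' exact test of DE (call != 0, direction collapsed) against
#' responder/non-responder.  Associations with `p < alpha` are kept; an
#' odds ratio above 1 for DE x responder marks a sensitivity association,
#' below 1 resistance.
#'
#' @param profile an [ide_profile()].
#' @param annotation a [sample_annotation()] with a `drug_response` table
#'   (`sample_id`, `drug`, `response` in responder/non-responder).
#' @param drug drug name to test.
#' @param alpha raw p cutoff; default 0.05.
#' @return data.frame of kept associations: `lncRNA_id`, `drug`, counts
#'   `a`..`d` (DE-responder, DE-non, notDE-responder, notDE-non),
#'   `odds_ratio`, `p`, `direction`.
#' @export
clinical_response_association <- function(profile, annotation, drug,
                                          alpha = 0.05) {
  stopifnot(inherits(profile, "ide_profile"),
            inherits(annotation, "sample_annotation"))
  dr <- annotation$drug_response
  if (is.null(dr) || !("response" %in% names(dr)))
    stop("annotation carries no clinical drug response table")
  dr <- dr[dr$drug == drug & !is.na(dr$response), , drop = FALSE]
  if (!nrow(dr)) stop("drug '", drug, "' absent from annotations")
  dr <- dr[dr$sample_id %in% colnames(profile$calls), , drop = FALSE]
  resp <- dr$response == "responder"
  if (sum(resp) < 2 || sum(!resp) < 2)
    stop("need >= 2 responders and >= 2 non-responders among treated samples")
  calls <- profile$calls[, dr$sample_id, drop = FALSE]
  rows <- list()
  for (g in rownames(calls)) {
    de <- calls[g, ] != 0L
    a <- sum(de & resp); b <- sum(de & !resp)
    c_ <- sum(!de & resp); d <- sum(!de & !resp)
    ft <- fisher_exact_2x2(c(a, b, c_, d))
    if (ft$p < alpha)
      rows[[g]] <- data.frame(
        lncRNA_id = g, drug = drug, a = a, b = b, c = c_, d = d,
        odds_ratio = ft$odds_ratio, p = ft$p,
        direction = if (!is.nan(ft$odds_ratio) && ft$odds_ratio > 1)
          "sensitivity" else "resistance",
        stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(lncRNA_id = character(0), drug = character(0),
                      a = integer(0), b = integer(0), c = integer(0),
                      d = integer(0), odds_ratio = numeric(0),
                      p = numeric(0), direction = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Associate IDE status with cell-line ActArea
#'
#' Partitions cell lines by call per `group_rule` (default: downregulated
#' vs unaltered) and compares ActArea with Welch's t test.  A lower mean
#' ActArea in the DE group flags a resistance association.  lncRNAs whose
#' groups fall below 2 lines are skipped (recorded in the output).
#'
#' @param profile an [ide_profile()] over cell lines.
#' @param act_area data.frame `sample_id`, `drug`, `act_area`.
#' @param drug drug name.
#' @param group_rule `"down_vs_unaltered"` (default), `"up_vs_unaltered"`
#'   or `"de_vs_unaltered"` (|call| != 0).
#' @return data.frame per testable lncRNA: group sizes and means, `t`,
#'   `df`, `p`, `resistance` flag, `status` (tested/skipped).
#' @export
cellline_actarea_association <- function(profile, act_area, drug,
                                         group_rule = c("down_vs_unaltered",
                                                        "up_vs_unaltered",
                                                        "de_vs_unaltered")) {
  group_rule <- match.arg(group_rule)
  stopifnot(inherits(profile, "ide_profile"),
            all(c("sample_id", "drug", "act_area") %in% names(act_area)))
  aa <- act_area[act_area$drug == drug & !is.na(act_area$act_area), ]
  if (!nrow(aa)) stop("drug '", drug, "' absent from ActArea table")
  aa <- aa[aa$sample_id %in% colnames(profile$calls), , drop = FALSE]
  calls <- profile$calls[, aa$sample_id, drop = FALSE]
  in_de <- switch(group_rule,
                  down_vs_unaltered = function(v) v == -1L,
                  up_vs_unaltered = function(v) v == 1L,
                  de_vs_unaltered = function(v) v != 0L)
  rows <- lapply(rownames(calls), function(g) {
    v <- calls[g, ]
    de_grp <- aa$act_area[in_de(v)]
    un_grp <- aa$act_area[v == 0L]
    base <- data.frame(lncRNA_id = g, drug = drug, n_de = length(de_grp),
                       n_unaltered = length(un_grp),
                       stringsAsFactors = FALSE)
    if (length(de_grp) < 2 || length(un_grp) < 2)
      return(cbind(base, mean_de = NA_real_, mean_unaltered = NA_real_,
                   t = NA_real_, df = NA_real_, p = NA_real_,
                   resistance = NA, status = "skipped"))
    wt <- welch_t(de_grp, un_grp)
    cbind(base, mean_de = mean(de_grp), mean_unaltered = mean(un_grp),
          t = wt$t, df = wt$df, p = wt$p,
          resistance = wt$p < 0.05 && mean(de_grp) < mean(un_grp),
          status = "tested")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
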