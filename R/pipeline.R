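# End-to-end orchestration: one config, a fixed stage order, TSV outputs
# under one directory, and a manifest recording what ran, with what
# parameters and seeds, and the checksum of every output.  Stages whose
# optional inputs are absent are skipped (recorded), not failed.

#' Pipeline configuration
#'
#' All inputs are TSV paths (see the readers in this package); `NULL`
#' marks an input as absent, which skips the stages needing it.
#'
#' @param normals path to the reference normal expression TSV (required).
#' @param tumors path to the tumor expression TSV (required).
#' @param paired_normals,pairing optional matched-normal expression TSV
#'   and 2-column pairing TSV (`tumor_id`, `normal_id`) enabling the
#'   cross-validation stage.
#' @param alterations named list of alteration TSV paths; names are
#'   alteration types (`amplification`, `deletion`, `hypermethylation`,
#'   `hypomethylation`, `mutation`, `nonsilent_mutation`).
#' @param annotation optional sample annotation TSV.
#' @param drug_response optional drug response TSV (`sample_id`, `drug`,
#'   `response` and/or `act_area`).
#' @param gmt optional GMT pathway file for over-representation of the
#'   clustered subtype's specific genes.
#' @param out_dir output directory.
#' @param threshold_f,alpha,min_pairs,max_iter stable-pair and calling
#'   parameters.
#' @param subtype_alpha,min_freq over-representation parameters.
#' @param p_cut co-occurrence raw-p cutoff.
#' @param top_k consistency census size.
#' @param k_folds cross-validation folds.
#' @param target_subtype subtype whose specific genes drive the
#'   prognostic clustering stage; default `"Basal"`.
#' @param seed global seed.
#' @return validated config list, class `pipeline_config`.
#' @export
pipeline_config <- function(normals, tumors, out_dir,
                            paired_normals = NULL, pairing = NULL,
                            alterations = list(), annotation = NULL,
                            drug_response = NULL, gmt = NULL,
                            threshold_f = 0.99, alpha = 0.05,
                            min_pairs = 5, max_iter = 2,
                            subtype_alpha = 0.05, min_freq = 0.05,
                            p_cut = 0.05, top_k = 100, k_folds = 5,
                            target_subtype = "Basal", seed = 1) {
  cfg <- as.list(environment())
  paths <- c(normals, tumors, paired_normals, pairing,
             unlist(alterations), annotation, drug_response, gmt)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  structure(cfg, class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Stage order: stable-pairs, individualize, evaluate (needs paired data),
#' consistency (needs alterations), subtypes (needs annotation),
#' cooccurrence (needs both), tnbc-cluster (needs annotation with
#' survival), drugs (needs drug response).  Re-running with unchanged
#' inputs reproduces identical outputs and manifest hashes.
#'
#' @param config a [pipeline_config()].
#' @return data.frame manifest (stage, status, output, md5, seed),
#'   invisibly also written to `out_dir/manifest.tsv`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cf <- config
  dir.create(cf$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  note <- function(stage, status, outputs = character(0)) {
    md5 <- if (length(outputs))
      unname(tools::md5sum(file.path(cf$out_dir, outputs)))
    else NA_character_
    manifest[[length(manifest) + 1L]] <<-
      data.frame(stage = stage, status = status,
                 output = if (length(outputs)) outputs else NA_character_,
                 md5 = md5, seed = cf$seed, stringsAsFactors = FALSE)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  normals <- read_expression_tsv(cf$normals)
  tumors <- read_expression_tsv(cf$tumors)

  sp <- run_stage("stable-pairs", {
    s <- find_stable_pairs(normals, cf$threshold_f)
    write_stable_pairs_tsv(s, file.path(cf$out_dir, "stable_pairs.tsv"))
    note("stable-pairs", "complete", "stable_pairs.tsv")
    s
  })

  params <- call_params(cf$alpha, cf$min_pairs, cf$max_iter)
  profile <- run_stage("individualize", {
    p <- build_profile(tumors, sp, params)
    write_profile_dir(p, file.path(cf$out_dir, "profile"))
    freq <- de_frequency(p)
    write.table(freq$per_gene, file.path(cf$out_dir, "de_frequency.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    note("individualize", "complete",
         c("profile/calls.tsv", "profile/pvals.tsv", "profile/qvals.tsv",
           "de_frequency.tsv"))
    p
  })

  if (!is.null(cf$paired_normals) && !is.null(cf$pairing)) {
    run_stage("evaluate", {
      pn <- read_expression_tsv(cf$paired_normals)
      pm <- read.delim(cf$pairing, stringsAsFactors = FALSE)
      cohort <- paired_cohort(pn, tumors, setNames(pm[[2]], pm[[1]]))
      cv <- kfold_paired_validation(cohort, cf$k_folds, cf$threshold_f,
                                    params,
                                    seed = stage_seed(cf$seed, "evaluate"))
      out <- data.frame(metric = c("mean_lncRNA_accuracy",
                                   "mean_sample_accuracy",
                                   "n_calls_evaluated"),
                        value = c(cv$mean_lncRNA_accuracy,
                                  cv$mean_sample_accuracy,
                                  cv$n_calls_evaluated))
      write.table(out, file.path(cf$out_dir, "cv_accuracy.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      fc <- fc_compare(cohort, profile)
      write.table(fc$per_gene, file.path(cf$out_dir, "fc_groups.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      note("evaluate", "complete", c("cv_accuracy.tsv", "fc_groups.tsv"))
    })
  } else note("evaluate", "skipped (no paired data)")

  alts <- lapply(names(cf$alterations), function(ty)
    read_alteration_tsv(cf$alterations[[ty]], ty))
  names(alts) <- names(cf$alterations)
  directional <- alts[names(alts) %in% DIRECTIONAL_TYPES]

  if (length(directional)) {
    run_stage("consistency", {
      rec <- consistency_ratio(profile, unname(directional), cf$top_k)
      write.table(rec, file.path(cf$out_dir, "consistency.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      note("consistency", "complete", "consistency.tsv")
    })
  } else note("consistency", "skipped (no directional alterations)")

  ann <- if (!is.null(cf$annotation))
    read_annotation_tsv(cf$annotation, cf$drug_response) else NULL
  specific <- NULL
  if (!is.null(ann) && any(!is.na(ann$table$subtype))) {
    specific <- run_stage("subtypes", {
      labels <- setNames(ann$table$subtype, ann$table$sample_id)
      ov <- over_represented(profile, labels, cf$subtype_alpha,
                             cf$min_freq)
      sp_sets <- subtype_specific(ov$sets)
      write.table(ov$table, file.path(cf$out_dir, "over_represented.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      spec_df <- data.frame(
        subtype = rep(names(sp_sets), lengths(sp_sets)),
        gene_id = unlist(sp_sets, use.names = FALSE))
      write.table(spec_df, file.path(cf$out_dir, "subtype_specific.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      ic <- intersection_counts(ov$sets)
      write.table(ic, file.path(cf$out_dir, "intersections.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      note("subtypes", "complete",
           c("over_represented.tsv", "subtype_specific.tsv",
             "intersections.tsv"))
      sp_sets
    })
  } else note("subtypes", "skipped (no subtype labels)")

  if (!is.null(specific) && length(alts)) {
    run_stage("cooccurrence", {
      labels <- setNames(ann$table$subtype, ann$table$sample_id)
      edges <- list()
      for (s in names(specific)) {
        if (!length(specific[[s]])) next
        samples <- names(labels)[!is.na(labels) & labels == s]
        for (ty in names(alts)) {
          e <- cooccurrence_network(profile, alts[[ty]], samples,
                                    specific[[s]],
                                    rownames(alts[[ty]]$flags), cf$p_cut)
          if (nrow(e)) edges[[paste(s, ty)]] <- cbind(subtype = s, e)
        }
      }
      out <- if (length(edges)) do.call(rbind, c(edges,
                                                 make.row.names = FALSE))
      else data.frame(subtype = character(0))
      write.table(out, file.path(cf$out_dir, "cooccurrence_edges.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      note("cooccurrence", "complete", "cooccurrence_edges.tsv")
    })
  } else note("cooccurrence", "skipped (needs subtypes and alterations)")

  if (!is.null(ann) && any(!is.na(ann$table$surv_time)) &&
      !is.null(specific) && cf$target_subtype %in% names(specific) &&
      length(specific[[cf$target_subtype]]) >= 1) {
    run_stage("tnbc-cluster", {
      labels <- setNames(ann$table$subtype, ann$table$sample_id)
      samples <- intersect(colnames(profile$calls),
                           names(labels)[!is.na(labels) &
                                           labels == cf$target_subtype])
      sub <- ide_profile(
        profile$calls[specific[[cf$target_subtype]], samples,
                      drop = FALSE],
        profile$p_values[specific[[cf$target_subtype]], samples,
                         drop = FALSE],
        profile$q_values[specific[[cf$target_subtype]], samples,
                         drop = FALSE], alpha = cf$alpha)
      surv <- data.frame(sample_id = ann$table$sample_id,
                         time = ann$table$surv_time,
                         event = ann$table$surv_event)
      prog <- prognostic_filter(sub, surv)
      outs <- "prognostic.tsv"
      write.table(prog$table, file.path(cf$out_dir, "prognostic.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      if (length(prog$genes) >= 1 && length(samples) >= 2) {
        cl <- cluster_two_classes(
          ide_profile(sub$calls[prog$genes, , drop = FALSE],
                      sub$p_values[prog$genes, , drop = FALSE],
                      sub$q_values[prog$genes, , drop = FALSE]))
        write.table(cl$assignments,
                    file.path(cf$out_dir, "class_assignments.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        outs <- c(outs, "class_assignments.tsv")
        sv <- surv[match(cl$assignments$sample_id, surv$sample_id), ]
        ok <- tapply(sv$event, cl$assignments$class_label, sum,
                     default = 0)
        if (length(ok) == 2 && all(ok >= 1)) {
          lr <- logrank_test(sv$time, sv$event,
                             cl$assignments$class_label)
          write.table(data.frame(chi_square = lr$chi_square, p = lr$p),
                      file.path(cf$out_dir, "class_logrank.tsv"),
                      sep = "\t", quote = FALSE, row.names = FALSE)
          outs <- c(outs, "class_logrank.tsv")
        }
        covs <- setdiff(names(ann$table),
                        c("sample_id", "subtype", "surv_time",
                          "surv_event"))
        if (length(covs)) {
          cc <- compare_classes_continuous(
            ann$table[c("sample_id", covs)], cl$assignments)
          write.table(cc, file.path(cf$out_dir, "class_covariates.tsv"),
                      sep = "\t", quote = FALSE, row.names = FALSE)
          outs <- c(outs, "class_covariates.tsv")
        }
      }
      note("tnbc-cluster", "complete", outs)
    })
  } else note("tnbc-cluster", "skipped (needs survival and specific genes)")

  dr <- if (!is.null(ann)) ann$drug_response else NULL
  if (!is.null(dr) && "response" %in% names(dr) &&
      any(!is.na(dr$response))) {
    run_stage("drugs", {
      rows <- list()
      for (d in unique(dr$drug[!is.na(dr$response)])) {
        res <- tryCatch(
          clinical_response_association(profile, ann, d, cf$alpha),
          error = function(e) NULL)
        if (!is.null(res) && nrow(res)) rows[[d]] <- res
      }
      out <- if (length(rows)) do.call(rbind, c(rows,
                                                make.row.names = FALSE))
      else data.frame(lncRNA_id = character(0))
      write.table(out, file.path(cf$out_dir, "drug_associations.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      note("drugs", "complete", "drug_associations.tsv")
    })
  } else note("drugs", "skipped (no clinical drug response)")

  man <- do.call(rbind, c(manifest, make.row.names = FALSE))
  write.table(man, file.path(cf$out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  man
}
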