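# Ground-truth synthetic data with the statistical structure every pipeline
# stage assumes: a normal cohort with stable orderings (log-normal baseline
# per gene, small within-gene noise), tumors copying a matched normal draw
# with planted per-sample shifts, subtype- and class-coupled planting,
# survival, coupled alteration flags and drug response.  One global seed;
# each stage draws from a sub-stream keyed by its name, so re-running a
# stage (or reordering stages) never perturbs the others.

#' Simulation configuration
#'
#' Defaults state the emulated world: a cohort in which lncRNAs are
#' differentially expressed in 9.8% of tumors on average, with the
#' down:up sample-fraction split at 12.2:6.8, large planted effects
#' (|log2FC| = 4), and alteration flags supporting the planted direction
#' 90% of the time.
#'
#' @param n_genes,n_normals,n_tumors universe sizes; defaults 300 genes,
#'   50 reference normals, 200 tumors (all paired with their own matched
#'   normal draw).
#' @param baseline_spread s.d. (log2 scale) of per-gene baseline means;
#'   default 2 — wide enough that most orderings are stable.
#' @param noise_sd within-gene s.d. (log2 scale) per sample; default 0.1
#'   (a clean-normals world: orderings stable by construction).
#' @param frac_dysregulated fraction of non-planted genes eligible for
#'   global dysregulation; default 1.
#' @param de_fraction per-gene probability a tumor carries the gene's
#'   planted shift; default 0.098.
#' @param down_up_ratio odds a dysregulated gene's direction is down;
#'   default 12.2/6.8, so cohort mean down- and up-fractions land on the
#'   12.2%/6.8% split.
#' @param effect_log2fc planted |log2 fold change|; default 4.
#' @param n_subtypes,subtype_labels,n_subtype_genes subtype structure:
#'   default 4 equiprobable subtypes with 3 planted subtype-specific genes
#'   each.
#' @param subtype_de_fraction,background_subtype_fraction within- and
#'   out-of-subtype DE fraction for planted subtype genes; defaults 0.4
#'   and 0.02.
#' @param n_prognostic_genes genes coupled to the latent survival class;
#'   default 5.
#' @param prognostic_de_fraction DE fraction of prognostic genes in
#'   (class 2, class 1); default c(0.6, 0.05).
#' @param class2_prob latent class-2 probability; default 0.25.
#' @param class_hazard_ratio hazard ratio of class 2 vs class 1; default 3.
#' @param base_hazard class-1 exponential hazard per day; default
#'   log(2)/1825 (5-year median survival).
#' @param censor_range uniform administrative censoring window (days);
#'   default c(1000, 3000).
#' @param consistency_prob probability a planted DE event gets a
#'   supporting alteration flag; default 0.9.
#' @param background_alteration_rate per-(gene, sample) rate of spurious
#'   flags in each directional matrix; default 0.01.
#' @param mutation_rate per-(gene, sample) mutation rate by latent class
#'   `c(class1, class2)`; default c(0.03, 0.015) (class 1 is the
#'   high-burden, immune-like class).
#' @param nonsilent_prob probability a mutation is non-silent; default 0.7.
#' @param n_drug_genes genes coupled to drug response; default 2.
#' @param drug_name drug label; default "drugX".
#' @param drug_odds_ratio odds ratio of response given DE of a coupled
#'   gene; default 10.
#' @param drug_base_rate responder rate without DE; default 0.3.
#' @param treated_fraction fraction of tumors treated; default 0.3.
#' @param actarea_mean,actarea_sd ActArea distribution; default N(3, 0.7).
#' @param actarea_shift_sd ActArea shift (in s.d. units) for lines with DE
#'   of a coupled gene; default -1.5 (resistance).
#' @param hrd_mean HRD-score mean by class `c(class1, class2)`; default
#'   c(30, 20), s.d. 10.
#' @param seed global integer seed.
#' @return validated config list, class `sim_config`.
#' @export
sim_config <- function(n_genes = 300, n_normals = 50, n_tumors = 200,
                       baseline_spread = 2, noise_sd = 0.1,
                       frac_dysregulated = 1, de_fraction = 0.098,
                       down_up_ratio = 12.2 / 6.8, effect_log2fc = 4,
                       n_subtypes = 4,
                       subtype_labels = c("LumA", "LumB", "HER2", "Basal"),
                       n_subtype_genes = 3, subtype_de_fraction = 0.4,
                       background_subtype_fraction = 0.02,
                       n_prognostic_genes = 5,
                       prognostic_de_fraction = c(0.6, 0.05),
                       class2_prob = 0.25, class_hazard_ratio = 3,
                       base_hazard = log(2) / 1825,
                       censor_range = c(1000, 3000),
                       consistency_prob = 0.9,
                       background_alteration_rate = 0.01,
                       mutation_rate = c(0.03, 0.015),
                       nonsilent_prob = 0.7, n_drug_genes = 2,
                       drug_name = "drugX", drug_odds_ratio = 10,
                       drug_base_rate = 0.3, treated_fraction = 0.3,
                       actarea_mean = 3, actarea_sd = 0.7,
                       actarea_shift_sd = -1.5, hrd_mean = c(30, 20),
                       seed = 1) {
  cfg <- as.list(environment())
  fracs <- c(frac_dysregulated, de_fraction, subtype_de_fraction,
             background_subtype_fraction, prognostic_de_fraction,
             class2_prob, consistency_prob, background_alteration_rate,
             mutation_rate, nonsilent_prob, drug_base_rate,
             treated_fraction)
  if (any(fracs < 0 | fracs > 1)) stop("all fractions must lie in [0, 1]")
  if (effect_log2fc <= 0) stop("effect_log2fc must be > 0")
  if (length(subtype_labels) != n_subtypes)
    stop("need one label per subtype")
  n_planted <- n_subtypes * n_subtype_genes + n_prognostic_genes
  if (n_planted >= n_genes)
    stop("planted genes (", n_planted, ") must be fewer than n_genes (",
         n_genes, ")")
  if (n_drug_genes > n_genes - n_planted)
    stop("n_drug_genes exceeds the globally dysregulated pool")
  structure(cfg, class = "sim_config")
}

#' Generate a full synthetic dataset with ground truth
#'
#' @param config a [sim_config()].
#' @return list with `normals` (reference cohort [expression_matrix()]),
#'   `cohort` (a [paired_cohort()]: every tumor with its matched normal
#'   draw), `tumors`, `annotation` (a [sample_annotation()] with subtype,
#'   survival, HRD covariate and drug tables), `alterations` (named list
#'   of [alteration_matrix()]), `truth` (list: `status` ternary matrix,
#'   `gene_direction`, `gene_role`, `subtype_of_gene`, `latent_class`,
#'   `prognostic_genes`, `drug_genes`, `seed`).
#' @export
generate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  genes <- sprintf("G%04d", seq_len(cf$n_genes))
  normal_ids <- sprintf("N%03d", seq_len(cf$n_normals))
  tumor_ids <- sprintf("T%03d", seq_len(cf$n_tumors))
  matched_ids <- sprintf("MN%03d", seq_len(cf$n_tumors))

  base_mu <- with_seed(stage_seed(cf$seed, "baseline"),
                       rnorm(cf$n_genes, 0, cf$baseline_spread))

  # --- gene roles ----------------------------------------------------
  roles <- with_seed(stage_seed(cf$seed, "roles"), {
    perm <- sample(cf$n_genes)
    ns <- cf$n_subtypes * cf$n_subtype_genes
    subtype_genes <- perm[seq_len(ns)]
    prog_genes <- perm[ns + seq_len(cf$n_prognostic_genes)]
    pool <- perm[-(seq_len(ns + cf$n_prognostic_genes))]
    global_genes <- pool[runif(length(pool)) < cf$frac_dysregulated]
    drug_genes <- global_genes[seq_len(min(cf$n_drug_genes,
                                           length(global_genes)))]
    p_down <- cf$down_up_ratio / (1 + cf$down_up_ratio)
    direction <- integer(cf$n_genes)
    active <- c(subtype_genes, prog_genes, global_genes)
    direction[active] <- ifelse(runif(length(active)) < p_down, -1L, 1L)
    subtype_of <- rep(NA_character_, cf$n_genes)
    subtype_of[subtype_genes] <- rep(cf$subtype_labels,
                                     each = cf$n_subtype_genes)
    list(subtype_genes = subtype_genes, prog_genes = prog_genes,
         global_genes = global_genes, drug_genes = drug_genes,
         direction = direction, subtype_of = subtype_of)
  })

  # --- sample structure ----------------------------------------------
  ann_draw <- with_seed(stage_seed(cf$seed, "samples"), {
    subtype <- sample(cf$subtype_labels, cf$n_tumors, replace = TRUE)
    latent <- ifelse(runif(cf$n_tumors) < cf$class2_prob, 2L, 1L)
    list(subtype = subtype, latent = latent)
  })

  # --- planted ternary truth -----------------------------------------
  status <- with_seed(stage_seed(cf$seed, "planting"), {
    st <- matrix(0L, cf$n_genes, cf$n_tumors,
                 dimnames = list(genes, tumor_ids))
    prob <- matrix(0, cf$n_genes, cf$n_tumors)
    prob[roles$global_genes, ] <- cf$de_fraction
    for (gi in roles$subtype_genes) {
      in_s <- ann_draw$subtype == roles$subtype_of[gi]
      prob[gi, ] <- ifelse(in_s, cf$subtype_de_fraction,
                           cf$background_subtype_fraction)
    }
    for (gi in roles$prog_genes)
      prob[gi, ] <- ifelse(ann_draw$latent == 2L,
                           cf$prognostic_de_fraction[1],
                           cf$prognostic_de_fraction[2])
    hit <- matrix(runif(length(prob)), nrow(prob)) < prob
    st[hit] <- rep(roles$direction, cf$n_tumors)[hit]
    st
  })

  # --- expression ----------------------------------------------------
  expr <- with_seed(stage_seed(cf$seed, "expression"), {
    draw <- function(n) 2^(base_mu + matrix(rnorm(cf$n_genes * n, 0,
                                                  cf$noise_sd),
                                            cf$n_genes, n))
    normals <- draw(cf$n_normals)
    matched <- draw(cf$n_tumors)
    # each tumor is its own draw from the normal process (independent of
    # its matched normal) with the planted shifts multiplied in
    tumors <- draw(cf$n_tumors) * 2^(status * cf$effect_log2fc)
    dimnames(normals) <- list(genes, normal_ids)
    dimnames(matched) <- list(genes, matched_ids)
    dimnames(tumors) <- list(genes, tumor_ids)
    list(normals = normals, matched = matched, tumors = tumors)
  })

  # --- survival + covariates -----------------------------------------
  surv <- with_seed(stage_seed(cf$seed, "survival"), {
    hz <- cf$base_hazard *
      ifelse(ann_draw$latent == 2L, cf$class_hazard_ratio, 1)
    t_ev <- rexp(cf$n_tumors, hz)
    t_cn <- runif(cf$n_tumors, cf$censor_range[1], cf$censor_range[2])
    hrd <- rnorm(cf$n_tumors, cf$hrd_mean[ann_draw$latent], 10)
    list(time = pmin(t_ev, t_cn), event = as.integer(t_ev <= t_cn),
         hrd = hrd)
  })

  # --- alterations ----------------------------------------------------
  alterations <- with_seed(stage_seed(cf$seed, "alterations"), {
    blank <- function() matrix(0L, cf$n_genes, cf$n_tumors,
                               dimnames = list(genes, tumor_ids))
    mats <- list(amplification = blank(), deletion = blank(),
                 hypermethylation = blank(), hypomethylation = blank())
    for (ty in names(mats))
      mats[[ty]][matrix(runif(cf$n_genes * cf$n_tumors), cf$n_genes) <
                   cf$background_alteration_rate] <- 1L
    idx <- which(status != 0L, arr.ind = TRUE)
    if (nrow(idx)) {
      supported <- runif(nrow(idx)) < cf$consistency_prob
      pick <- runif(nrow(idx)) < 0.5
      for (r in which(supported)) {
        up <- status[idx[r, 1], idx[r, 2]] == 1L
        ty <- if (up) c("amplification", "hypomethylation")[1 + pick[r]]
        else c("deletion", "hypermethylation")[1 + pick[r]]
        mats[[ty]][idx[r, 1], idx[r, 2]] <- 1L
      }
    }
    rate <- cf$mutation_rate[ann_draw$latent]
    mut <- (matrix(runif(cf$n_genes * cf$n_tumors), cf$n_genes) <
              matrix(rate, cf$n_genes, cf$n_tumors, byrow = TRUE)) * 1L
    nsl <- mut * (matrix(runif(cf$n_genes * cf$n_tumors), cf$n_genes) <
                    cf$nonsilent_prob)
    dimnames(mut) <- dimnames(nsl) <- list(genes, tumor_ids)
    mats$mutation <- mut
    mats$nonsilent_mutation <- nsl
    mats
  })
  alterations <- Map(alteration_matrix, alterations, names(alterations))

  # --- drug response ---------------------------------------------------
  drug <- with_seed(stage_seed(cf$seed, "drugs"), {
    treated <- sort(sample(cf$n_tumors, round(cf$treated_fraction *
                                                cf$n_tumors)))
    de_any <- if (length(roles$drug_genes))
      colSums(status[roles$drug_genes, treated, drop = FALSE] != 0L) > 0
    else rep(FALSE, length(treated))
    p_resp <- stats::plogis(stats::qlogis(cf$drug_base_rate) +
                              log(cf$drug_odds_ratio) * de_any)
    resp <- ifelse(runif(length(treated)) < p_resp, "responder",
                   "non-responder")
    de_aa <- if (length(roles$drug_genes))
      status[roles$drug_genes[1], ] != 0L else rep(FALSE, cf$n_tumors)
    aa <- rnorm(cf$n_tumors, cf$actarea_mean, cf$actarea_sd) +
      cf$actarea_shift_sd * cf$actarea_sd * de_aa
    rbind(data.frame(sample_id = tumor_ids[treated], drug = cf$drug_name,
                     response = resp, act_area = NA_real_,
                     stringsAsFactors = FALSE),
          data.frame(sample_id = tumor_ids, drug = cf$drug_name,
                     response = NA_character_, act_area = aa,
                     stringsAsFactors = FALSE))
  })

  annotation <- sample_annotation(
    tumor_ids, subtype = ann_draw$subtype, surv_time = surv$time,
    surv_event = surv$event,
    covariates = data.frame(hrd_score = surv$hrd),
    drug_response = drug)

  normals <- expression_matrix(expr$normals)
  matched <- expression_matrix(expr$matched)
  tumors <- expression_matrix(expr$tumors)
  cohort <- paired_cohort(matched, tumors,
                          setNames(matched_ids, tumor_ids))
  list(normals = normals, cohort = cohort, tumors = tumors,
       annotation = annotation, alterations = alterations,
       truth = list(status = status, gene_direction = roles$direction,
                    gene_role = list(subtype = genes[roles$subtype_genes],
                                     prognostic = genes[roles$prog_genes],
                                     global = genes[roles$global_genes]),
                    subtype_of_gene = setNames(roles$subtype_of, genes),
                    latent_class = setNames(ann_draw$latent, tumor_ids),
                    prognostic_genes = genes[roles$prog_genes],
                    drug_genes = genes[roles$drug_genes],
                    seed = cf$seed))
}

#' Score a called profile against the planted truth
#'
#' @param profile an [ide_profile()].
#' @param truth the `truth` element of [generate_dataset()] output (or any
#'   ternary matrix of the same shape as the profile's calls in
#'   `truth$status`).
#' @return list with `precision` (correct non-zero calls / all non-zero
#'   calls, sign included; `NA` when no calls), `recall` (over planted
#'   statuses), `sign_accuracy` (agreement over the intersection; `NA`
#'   when empty).
#' @export
truth_metrics <- function(profile, truth) {
  status <- if (is.list(truth)) truth$status else truth
  calls <- profile$calls[rownames(status), colnames(status)]
  if (!identical(dim(calls), dim(status)))
    stop("profile and truth shapes differ")
  called <- calls != 0L
  planted <- status != 0L
  correct <- calls == status
  precision <- if (any(called)) sum(called & correct) / sum(called)
  else NA_real_
  recall <- if (any(planted)) sum(planted & correct) / sum(planted)
  else NA_real_
  both <- called & planted
  sign_accuracy <- if (any(both)) mean(calls[both] == status[both])
  else NA_real_
  list(precision = precision, recall = recall,
       sign_accuracy = sign_accuracy)
}

#' Simulate a two-archetype ternary profile
#'
#' Two archetype call vectors are drawn over the genes (entries -1/0/+1,
#' forced to differ on at least half the genes); each sample copies its
#' class archetype and every entry is then flipped to a random different
#' value with probability `flip_prob`.  Used to exercise two-class
#' clustering recovery.
#'
#' @param n_genes number of genes; default 30.
#' @param n_class1,n_class2 samples per latent class; defaults 30 and 10.
#' @param flip_prob per-entry call-noise probability; default 0.1.
#' @param seed integer seed.
#' @return list with `profile` (an [ide_profile()]) and `latent_class`
#'   (named integer vector).
#' @export
simulate_archetype_profile <- function(n_genes = 30, n_class1 = 30,
                                       n_class2 = 10, flip_prob = 0.1,
                                       seed = 1) {
  with_seed(seed, {
    vals <- c(-1L, 0L, 1L)
    arch1 <- sample(vals, n_genes, replace = TRUE)
    arch2 <- arch1
    flip <- sample(n_genes, max(1, ceiling(n_genes / 2)))
    arch2[flip] <- vapply(arch1[flip], function(v)
      sample(setdiff(vals, v), 1), integer(1))
    n <- n_class1 + n_class2
    cls <- rep(c(1L, 2L), c(n_class1, n_class2))
    calls <- vapply(seq_len(n), function(s) {
      v <- if (cls[s] == 1L) arch1 else arch2
      noisy <- runif(n_genes) < flip_prob
      v[noisy] <- vapply(v[noisy], function(x)
        sample(setdiff(vals, x), 1), integer(1))
      v
    }, integer(n_genes))
    dimnames(calls) <- list(sprintf("G%03d", seq_len(n_genes)),
                            sprintf("S%03d", seq_len(n)))
    na <- matrix(NA_real_, n_genes, n,
                 dimnames = dimnames(calls))
    list(profile = ide_profile(calls, na, na),
         latent_class = setNames(cls, colnames(calls)))
  })
}

#' Rand index between two partitions
#'
#' Fraction of sample pairs on whose co-membership the two partitions
#' agree.
#'
#' @param a,b equal-length label vectors.
#' @return value in \[0, 1\].
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  ij <- combn(length(a), 2)
  same_a <- a[ij[1, ]] == a[ij[2, ]]
  same_b <- b[ij[1, ]] == b[ij[2, ]]
  mean(same_a == same_b)
}
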