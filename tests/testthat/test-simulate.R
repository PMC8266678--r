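test_that("sim_config validates its stated world", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(de_fraction = 1.2), "fractions")
  expect_error(sim_config(effect_log2fc = 0), "effect")
  expect_error(sim_config(n_genes = 15), "planted")
  expect_error(sim_config(subtype_labels = "A"), "label per subtype")
})

test_that("generation is deterministic from the seed", {
  a <- generate_dataset(sim_config(n_genes = 50, n_tumors = 20,
                                   n_normals = 10, n_subtype_genes = 1,
                                   n_prognostic_genes = 1, seed = 9))
  b <- generate_dataset(sim_config(n_genes = 50, n_tumors = 20,
                                   n_normals = 10, n_subtype_genes = 1,
                                   n_prognostic_genes = 1, seed = 9))
  expect_identical(a, b)
  c <- generate_dataset(sim_config(n_genes = 50, n_tumors = 20,
                                   n_normals = 10, n_subtype_genes = 1,
                                   n_prognostic_genes = 1, seed = 10))
  expect_false(identical(unclass(a$tumors), unclass(c$tumors)))
})

test_that("generated structure honours its own invariants", {
  ds <- generate_dataset(sim_config(n_genes = 150, n_tumors = 150,
                                    seed = 13))
  st <- ds$truth$status
  # planted direction is per-gene coherent
  for (g in rownames(st)) {
    vals <- unique(st[g, st[g, ] != 0L])
    expect_lte(length(vals), 1)
  }
  # tumor-vs-matched-normal log ratios center on 0 / +4 / -4 by status
  ratio <- log2(unclass(ds$cohort$tumor) / unclass(ds$cohort$normal))
  expect_lt(abs(mean(ratio[st == 0L])), 0.05)
  expect_lt(abs(mean(ratio[st == 1L]) - 4), 3 * 0.15 / sqrt(sum(st == 1L)) + 0.1)
  expect_lt(abs(mean(ratio[st == -1L]) + 4), 0.1)
  # non-silent mutations are a subset of mutations
  expect_true(all(ds$alterations$nonsilent_mutation$flags <=
                    ds$alterations$mutation$flags))
  # survival annotation is complete and non-negative
  expect_true(all(ds$annotation$table$surv_time >= 0))
  expect_true(all(ds$annotation$table$surv_event %in% 0:1))
  # down:up planted ratio matches the configured odds within 3 sigma
  n_down <- sum(ds$truth$gene_direction == -1L)
  n_act <- sum(ds$truth$gene_direction != 0L)
  p <- (12.2 / 6.8) / (1 + 12.2 / 6.8)
  expect_lt(abs(n_down / n_act - p), 3 * sqrt(p * (1 - p) / n_act))
})

test_that("null world plants nothing and matches normals", {
  ds <- generate_dataset(sim_config(n_genes = 60, n_tumors = 20,
                                    n_normals = 10, frac_dysregulated = 0,
                                    n_subtype_genes = 0,
                                    n_prognostic_genes = 0,
                                    n_drug_genes = 0, seed = 14))
  expect_true(all(ds$truth$status == 0L))
  # exchangeable with normals: pooled log-values have matching moments
  lt <- log2(unclass(ds$cohort$tumor)); ln <- log2(unclass(ds$normals))
  expect_lt(abs(mean(lt) - mean(ln)), 0.2)
  expect_lt(abs(sd(lt) - sd(ln)), 0.2)
})

test_that("perfect alteration coupling yields full consistency for planted calls", {
  ds <- generate_dataset(sim_config(n_genes = 100, n_tumors = 60,
                                    n_normals = 10, consistency_prob = 1,
                                    background_alteration_rate = 0,
                                    seed = 15))
  na <- matrix(NA_real_, 100, 60, dimnames = dimnames(ds$truth$status))
  prof <- ide_profile(ds$truth$status, na, na)
  rec <- consistency_ratio(
    prof, unname(ds$alterations[c("amplification", "deletion",
                                  "hypermethylation", "hypomethylation")]),
    100)
  called <- rec[rec$n_evaluable > 0, ]
  expect_true(all(called$category == "full"))
})

test_that("truth_metrics scores calls against planted statuses", {
  st <- matrix(c(1L, -1L, 0L, 0L), 2,
               dimnames = list(c("g1", "g2"), c("s1", "s2")))
  na <- matrix(NA_real_, 2, 2, dimnames = dimnames(st))
  perfect <- truth_metrics(ide_profile(st, na, na), st)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  none <- truth_metrics(ide_profile(st * 0L, na, na), st)
  expect_equal(none$recall, 0)
  expect_true(is.na(none$precision))
  # one sign flipped of 10 planted
  st10 <- matrix(rep(c(1L, 0L), c(10, 10)), 4, 5,
                 dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
  calls <- st10; calls[which(st10 == 1L)[1]] <- -1L
  na10 <- matrix(NA_real_, 4, 5, dimnames = dimnames(st10))
  m <- truth_metrics(ide_profile(calls, na10, na10), st10)
  expect_equal(m$sign_accuracy, 0.9)
})

test_that("drug response coupling follows the configured odds ratio", {
  ds <- generate_dataset(sim_config(n_genes = 100, n_tumors = 400,
                                    n_normals = 10, treated_fraction = 1,
                                    drug_odds_ratio = 10, seed = 16))
  dr <- ds$annotation$drug_response
  dr <- dr[!is.na(dr$response), ]
  de <- colSums(ds$truth$status[ds$truth$drug_genes, dr$sample_id,
                                drop = FALSE] != 0L) > 0
  p1 <- mean(dr$response[de] == "responder")
  p0 <- mean(dr$response[!de] == "responder")
  or_hat <- (p1 / (1 - p1)) / (p0 / (1 - p0))
  expect_gt(or_hat, 2)  # strongly coupled, noisy small-n estimate
})
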