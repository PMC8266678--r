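tp <- function(calls) {
  na <- matrix(NA_real_, nrow(calls), ncol(calls),
               dimnames = dimnames(calls))
  ide_profile(calls, na, na)
}

test_that("prognostic_filter keeps separating genes and gates thin strata", {
  samples <- sprintf("s%02d", 1:20)
  calls <- matrix(0L, 3, 20, dimnames = list(c("gSep", "gThin", "gNull"),
                                             samples))
  calls["gSep", 1:8] <- 1L   # DE samples die early
  calls["gThin", 1] <- -1L   # DE in one sample only
  surv <- data.frame(sample_id = samples,
                     time = c(seq(30, 240, 30), seq(2000, 3100, 100)),
                     event = c(rep(1L, 8), rep(1L, 4), rep(0L, 8)))
  pf <- prognostic_filter(tp(calls), surv, alpha = 0.05, min_events = 3)
  expect_true("gSep" %in% pf$genes)
  expect_identical(pf$table$status[pf$table$gene_id == "gThin"], "skipped")
  expect_identical(pf$table$status[pf$table$gene_id == "gNull"], "skipped")
  # oracle on the kept gene
  lr <- logrank_test(surv$time, surv$event,
                     ifelse(calls["gSep", ] != 0, "DE", "un"))
  expect_equal(pf$table$p[pf$table$gene_id == "gSep"], lr$p)
})

test_that("prognostic_filter type-I rate under permuted survival is near alpha", {
  set.seed(61)
  n <- 60
  samples <- sprintf("s%02d", 1:n)
  surv <- data.frame(sample_id = samples, time = rexp(n, 1 / 500),
                     event = rbinom(n, 1, 0.8))
  hits <- 0; total <- 0
  for (perm in 1:200) {
    calls <- matrix(0L, 1, n, dimnames = list("g", samples))
    calls[1, sample(n, 20)] <- 1L
    pf <- prognostic_filter(tp(calls), surv, alpha = 0.05)
    if (pf$table$status != "skipped") {
      total <- total + 1
      hits <- hits + (pf$table$status == "kept")
    }
  }
  expect_gt(total, 150)
  # binomial 3-sigma band around 0.05
  expect_lt(hits / total, 0.05 + 3 * sqrt(0.05 * 0.95 / total))
})

test_that("cluster_two_classes: distances, recovery, determinism, degeneracy", {
  calls <- matrix(c(1L, 0L, -1L,
                    1L, 1L, -1L), 3,
                  dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  expect_equal(as.numeric(ternary_hamming(calls)), 1 / 3)

  # two identical pairs with distinct profiles cluster as the pairs
  calls4 <- cbind(a1 = c(1L, 1L, 0L), a2 = c(1L, 1L, 0L),
                  b1 = c(-1L, 0L, 1L), b2 = c(-1L, 0L, 1L))
  rownames(calls4) <- paste0("g", 1:3)
  cl <- cluster_two_classes(tp(calls4))
  ass <- setNames(cl$assignments$class_label, cl$assignments$sample_id)
  expect_equal(ass[["a1"]], ass[["a2"]])
  expect_equal(ass[["b1"]], ass[["b2"]])
  expect_false(ass[["a1"]] == ass[["b1"]])

  # invariant to gene order and sample order up to label permutation
  perm <- tp(calls4[c(3, 1, 2), c(2, 4, 1, 3)])
  cl2 <- cluster_two_classes(perm)
  ass2 <- setNames(cl2$assignments$class_label, cl2$assignments$sample_id)
  expect_equal(rand_index(ass[names(ass)], ass2[names(ass)]), 1)

  degen <- tp(matrix(1L, 2, 3, dimnames = list(c("g1", "g2"),
                                               c("s1", "s2", "s3"))))
  expect_true(cluster_two_classes(degen)$degenerate)
})

test_that("larger class is labelled 1 and archetype recovery works", {
  sim <- simulate_archetype_profile(n_class1 = 30, n_class2 = 10,
                                    flip_prob = 0.1, seed = 62)
  cl <- cluster_two_classes(sim$profile)
  sizes <- table(cl$assignments$class_label)
  expect_gte(sizes[["1"]], sizes[["2"]])
  expect_gte(rand_index(cl$assignments$class_label,
                        sim$latent_class[cl$assignments$sample_id]), 0.9)
})

test_that("compare_classes_continuous runs Wilcoxon per covariate", {
  ass <- data.frame(sample_id = sprintf("s%d", 1:6),
                    class_label = rep(1:2, each = 3))
  cov <- data.frame(sample_id = sprintf("s%d", 1:6),
                    hrd = c(1, 2, 3, 4, 5, 6), flat = rep(7, 6))
  res <- compare_classes_continuous(cov, ass)
  expect_equal(res$p[res$covariate == "hrd"], 0.1)
  expect_equal(res$p[res$covariate == "flat"], 1)
  expect_true(res$constant[res$covariate == "flat"])
  cov$bad <- c(1, 2, 3, NA, NA, NA)
  expect_error(compare_classes_continuous(cov, ass), "bad")
})

test_that("compare_classes_frequency reproduces the printed Fisher tests", {
  # class 1: 42 up / 24 not; class 2: 7 up / 15 not
  n1 <- 66; n2 <- 22
  samples <- c(sprintf("c1_%02d", 1:n1), sprintf("c2_%02d", 1:n2))
  calls <- matrix(0L, 2, n1 + n2, dimnames = list(c("PDCD1", "CD274"),
                                                  samples))
  calls["PDCD1", c(1:42, n1 + 1:7)] <- 1L
  calls["CD274", c(1:14, n1 + 1:2)] <- 1L
  ass <- data.frame(sample_id = samples,
                    class_label = rep(1:2, c(n1, n2)))
  res <- compare_classes_frequency(tp(calls), ass)
  expect_equal(signif(res$p[res$gene_id == "PDCD1"], 2), 0.013)
  expect_equal(signif(res$p[res$gene_id == "CD274"], 2), 0.34)
  even <- matrix(0L, 1, 20, dimnames = list("g", sprintf("s%02d", 1:20)))
  even[1, c(1:5, 11:15)] <- 1L
  ass2 <- data.frame(sample_id = sprintf("s%02d", 1:20),
                     class_label = rep(1:2, each = 10))
  expect_equal(compare_classes_frequency(tp(even), ass2)$p, 1)
})

test_that("tmb_counts sums flags per sample", {
  genes <- paste0("g", 1:4); samples <- paste0("s", 1:3)
  mut <- matrix(0L, 4, 3, dimnames = list(genes, samples))
  mut[1:3, 2] <- 1L
  nsl <- mut; nsl[3, 2] <- 0L
  tm <- tmb_counts(alteration_matrix(mut, "mutation"),
                   alteration_matrix(nsl, "nonsilent_mutation"))
  expect_equal(tm$n_mutations, c(0, 3, 0))
  expect_equal(tm$n_nonsilent, c(0, 2, 0))
  expect_true(all(tm$n_nonsilent <= tm$n_mutations))
})
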