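ternary_profile <- function(calls) {
  na <- matrix(NA_real_, nrow(calls), ncol(calls),
               dimnames = dimnames(calls))
  ide_profile(calls, na, na)
}

# profile with one gene DE in de_in of subtype-A samples and de_out of the
# rest (deterministic counts, not draws)
two_arm_profile <- function(n_in, n_out, de_in, de_out,
                            gene = "gX", extra_genes = character(0)) {
  samples <- c(sprintf("a%02d", seq_len(n_in)),
               sprintf("r%02d", seq_len(n_out)))
  genes <- c(gene, extra_genes)
  calls <- matrix(0L, length(genes), length(samples),
                  dimnames = list(genes, samples))
  calls[gene, c(seq_len(de_in), n_in + seq_len(de_out))] <- 1L
  list(profile = ternary_profile(calls),
       subtypes = setNames(rep(c("A", "rest"), c(n_in, n_out)), samples))
}

test_that("over_represented applies the one-sided test and frequency gate", {
  # DE in 8/10 of subtype A vs 2/30 of the rest
  w <- two_arm_profile(10, 30, 8, 2)
  res <- over_represented(w$profile, w$subtypes, alpha = 0.05,
                          min_freq = 0.05)
  row <- res$table[res$table$subtype == "A" & res$table$gene_id == "gX", ]
  expect_equal(row$p, brute_fisher_greater(8, 2, 2, 28), tolerance = 1e-12)
  expect_lt(row$p, 1e-4)
  expect_true("gX" %in% res$sets$A)

  # uniform 10% DE is not over-represented anywhere
  u <- two_arm_profile(20, 20, 2, 2)
  res <- over_represented(u$profile, u$subtypes)
  expect_false("gX" %in% res$sets$A)

  # frequency gate: 1/20 within-subtype DE is excluded regardless of p
  g <- two_arm_profile(20, 200, 1, 0)
  res <- over_represented(g$profile, g$subtypes, min_freq = 0.05)
  expect_false("gX" %in% res$sets$A)

  # subtypes with < 2 samples are skipped with a warning
  tiny <- two_arm_profile(1, 10, 1, 0)
  expect_warning(over_represented(tiny$profile, tiny$subtypes),
                 "< 2 samples")
})

test_that("subtype_specific enforces exclusivity", {
  sets <- list(A = c("x", "y"), B = c("y", "z"))
  sp <- subtype_specific(sets)
  expect_equal(sp$A, "x")
  expect_equal(sp$B, "z")
  expect_identical(subtype_specific(list()), list())
  # disjoint from each other, subsets of their inputs
  expect_length(intersect(sp$A, sp$B), 0)
  expect_true(all(sp$A %in% sets$A) && all(sp$B %in% sets$B))
})

test_that("intersection_counts is an exact exclusive tally", {
  ic <- intersection_counts(list(A = c("x", "y"), B = c("y", "z")))
  expect_equal(ic$count[match(c("A", "B", "A&B"), ic$combination)],
               c(1L, 1L, 1L))
  expect_equal(sum(ic$count), 3)  # |union|
  disjoint <- intersection_counts(list(A = "x", B = "y"))
  expect_false(any(grepl("&", disjoint$combination)))
  same <- intersection_counts(list(A = c("x", "y"), B = c("x", "y")))
  expect_equal(same$combination, "A&B")
  expect_equal(same$count, 2L)
  expect_error(intersection_counts(list()), "at least one")
})

test_that("cooccurrence_network keeps positively associated edges only", {
  samples <- sprintf("s%02d", 1:10)
  calls <- matrix(0L, 1, 10, dimnames = list("lnc1", samples))
  calls[1, 1:5] <- 1L
  fl <- matrix(0L, 2, 10, dimnames = list(c("gene1", "gene2"), samples))
  fl["gene1", 1:5] <- 1L    # perfectly co-occurring
  fl["gene2", 6:10] <- 1L   # perfectly exclusive
  alt <- alteration_matrix(fl, "mutation")
  edges <- cooccurrence_network(ternary_profile(calls), alt, samples,
                                "lnc1", c("gene1", "gene2"), 0.05)
  expect_equal(nrow(edges), 1)
  expect_identical(edges$gene_id, "gene1")
  expect_equal(edges$p, 2 / 252, tolerance = 1e-12)
  expect_identical(edges$odds_ratio, Inf)

  # independent proportions ([[2,3],[2,3]]): p = 1, no edge
  fl2 <- matrix(0L, 1, 10, dimnames = list("gene3", samples))
  fl2[1, c(1, 2, 6, 7)] <- 1L
  calls2 <- matrix(0L, 1, 10, dimnames = list("lnc1", samples))
  calls2[1, 1:5] <- 1L
  e2 <- cooccurrence_network(ternary_profile(calls2),
                             alteration_matrix(fl2, "mutation"), samples,
                             "lnc1", "gene3", 0.05)
  expect_equal(nrow(e2), 0)
})

test_that("cooccurrence edges are symmetric in the two binary vectors", {
  set.seed(51)
  samples <- sprintf("s%02d", 1:20)
  x <- rbinom(20, 1, 0.4); y <- as.integer(x | rbinom(20, 1, 0.2))
  calls <- matrix(as.integer(x), 1, 20, dimnames = list("v1", samples))
  fl <- matrix(y, 1, 20, dimnames = list("v2", samples))
  e1 <- cooccurrence_network(ternary_profile(calls),
                             alteration_matrix(fl, "amplification"),
                             samples, "v1", "v2", 1.1)
  callsT <- matrix(y, 1, 20, dimnames = list("v2", samples))
  flT <- matrix(as.integer(x), 1, 20, dimnames = list("v1", samples))
  e2 <- cooccurrence_network(ternary_profile(callsT),
                             alteration_matrix(flT, "amplification"),
                             samples, "v2", "v1", 1.1)
  expect_equal(e1$p, e2$p, tolerance = 1e-12)
  expect_equal(e1$odds_ratio, e2$odds_ratio, tolerance = 1e-12)
})

test_that("ora_hypergeometric evaluates exact tails and GMT parsing", {
  universe <- sprintf("u%02d", 1:20)
  res <- ora_hypergeometric(universe[1:5],
                            list(hit = universe[1:5],
                                 none = universe[6:10],
                                 all = universe), universe)
  expect_equal(res$p[res$pathway == "hit"], 1 / 15504)
  expect_equal(res$p[res$pathway == "none"], 1)
  expect_equal(res$p[res$pathway == "all"], 1)
  expect_error(ora_hypergeometric("x", list(a = "x"), character(0)),
               "empty universe")
  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("pwA\tdesc\tu01\tu02", "pwB\tdesc\tu03"), gmt)
  sets <- read_gmt(gmt)
  expect_equal(sets, list(pwA = c("u01", "u02"), pwB = "u03"))
})
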