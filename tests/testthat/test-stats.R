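test_that("fisher_exact_2x2 reproduces printed and derived p-values", {
  expect_equal(signif(fisher_exact_2x2(c(42, 24, 7, 15))$p, 2), 0.013)
  expect_equal(signif(fisher_exact_2x2(c(14, 52, 2, 20))$p, 2), 0.34)
  expect_equal(fisher_exact_2x2(c(5, 0, 0, 5))$p, 2 / 252)
  expect_equal(fisher_exact_2x2(c(2, 3, 2, 3))$p, 1)
  expect_error(fisher_exact_2x2(c(0, 0, 0, 0)), "all-zero")
})

test_that("fisher_exact_2x2 odds ratio follows the ad/bc convention", {
  expect_equal(fisher_exact_2x2(c(6, 2, 1, 3))$odds_ratio, 9)
  expect_identical(fisher_exact_2x2(c(3, 0, 0, 3))$odds_ratio, Inf)
  expect_identical(fisher_exact_2x2(c(0, 3, 3, 0))$odds_ratio, 0)
  expect_true(is.nan(fisher_exact_2x2(c(0, 3, 0, 3))$odds_ratio))
})

test_that("fisher_exact_2x2 matches enumeration and stats::fisher.test", {
  set.seed(42)
  for (i in 1:60) {
    tb <- rpois(4, sample(1:8, 1))
    if (sum(tb) == 0) next
    mine <- fisher_exact_2x2(tb)
    expect_equal(mine$p, brute_fisher_two(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-12)
    ref <- stats::fisher.test(matrix(tb, 2, byrow = TRUE))
    expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
    expect_equal(fisher_exact_2x2(tb, "greater")$p,
                 brute_fisher_greater(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-12)
  }
})

test_that("fisher_exact_2x2 symmetries hold", {
  set.seed(7)
  for (i in 1:25) {
    tb <- rpois(4, 4)
    if (sum(tb) == 0) next
    swapped <- tb[c(3, 4, 1, 2)]
    expect_equal(fisher_exact_2x2(tb, "greater")$p,
                 fisher_exact_2x2(swapped, "less")$p, tolerance = 1e-12)
    transposed <- tb[c(1, 3, 2, 4)]
    expect_equal(fisher_exact_2x2(tb)$p, fisher_exact_2x2(transposed)$p,
                 tolerance = 1e-12)
  }
})

test_that("bh_adjust matches the step-up formula and p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_identical(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(1)
  p <- runif(50)
  expect_equal(bh_adjust(p), stats::p.adjust(p, "BH"))
  # NA passthrough: NA stays NA and does not count as a test
  pna <- c(0.01, NA, 0.04)
  expect_equal(bh_adjust(pna), c(stats::p.adjust(c(0.01, 0.04), "BH")[1],
                                 NA, stats::p.adjust(c(0.01, 0.04), "BH")[2]))
  # never below min raw p, never above 1
  q <- bh_adjust(p)
  expect_true(all(q >= min(p) & q <= 1))
})

test_that("wilcoxon_rank_sum: exact branch, ties branch, degenerate cases", {
  r <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p, 0.1)
  expect_identical(r$method, "exact")
  expect_equal(wilcoxon_rank_sum(1, 2)$p, 1)
  tied <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))
  expect_equal(tied$p, 1)
  expect_identical(tied$method, "normal")
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
  set.seed(3)
  for (i in 1:15) {
    x <- rnorm(sample(2:6, 1)); y <- rnorm(sample(2:6, 1))
    expect_equal(wilcoxon_rank_sum(x, y)$p, brute_wilcox_two(x, y),
                 tolerance = 1e-12)
    expect_equal(wilcoxon_rank_sum(x, y)$p,
                 stats::wilcox.test(x, y)$p.value, tolerance = 1e-9)
  }
  # large/tied samples agree with wilcox.test's corrected approximation
  set.seed(4)
  x <- round(rnorm(30), 1); y <- round(rnorm(25, 0.5), 1)
  expect_equal(wilcoxon_rank_sum(x, y)$p,
               stats::wilcox.test(x, y, exact = FALSE)$p.value,
               tolerance = 1e-9)
})

test_that("welch_t matches closed form and t.test", {
  r <- welch_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t, -3.674, tolerance = 1e-3)
  expect_equal(r$df, 4)
  same <- welch_t(c(0, 0, 1), c(0, 0, 1))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(welch_t(c(1, 1), c(2, 2)), "variances")
  set.seed(5)
  x <- rnorm(8); y <- rnorm(12, 1)
  ref <- stats::t.test(x, y)
  mine <- welch_t(x, y)
  expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
})

test_that("hypergeom_upper_tail is exact", {
  expect_equal(hypergeom_upper_tail(20, 5, 5, 5), 1 / 15504)
  expect_equal(hypergeom_upper_tail(20, 5, 5, 0), 1)
  expect_equal(hypergeom_upper_tail(20, 12, 10, 10),
               choose(12, 10) / choose(20, 10))
  expect_error(hypergeom_upper_tail(10, 12, 5, 2), "inconsistent")
  set.seed(6)
  for (i in 1:20) {
    N <- sample(5:30, 1); K <- sample(0:N, 1); n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hypergeom_upper_tail(N, K, n, k),
                 brute_hyper_upper(N, K, n, k), tolerance = 1e-12)
  }
})

test_that("logrank_test agrees with closed form and survdiff", {
  toy <- logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(toy$chi_square, 2.882, tolerance = 1e-3)
  same <- logrank_test(c(1, 2, 3, 1, 2, 3), c(1, 1, 1, 1, 1, 1),
                       rep(c("A", "B"), 3))
  expect_equal(same$chi_square, 0)
  expect_equal(same$p, 1)
  expect_error(logrank_test(c(1, 2), c(0, 1), c("A", "B")), "event")
  skip_if_not_installed("survival")
  set.seed(8)
  for (i in 1:10) {
    n <- 30
    time <- rexp(n, 0.1); event <- rbinom(n, 1, 0.7)
    grp <- sample(c("A", "B"), n, replace = TRUE)
    if (any(tapply(event, grp, sum) < 1) || length(unique(grp)) < 2) next
    ref <- survival::survdiff(survival::Surv(time, event) ~ grp)
    expect_equal(logrank_test(time, event, grp)$chi_square, ref$chisq,
                 tolerance = 1e-9)
  }
})
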