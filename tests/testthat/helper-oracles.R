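# Independent brute-force oracles, deliberately built from first
# principles (choose(), full enumeration) rather than the package's or
# base R's test machinery.

# All 2x2 tables with the same margins as (a,b,c,d), with their exact
# point probabilities from binomial coefficients.
enumerate_margin_tables <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  n <- r1 + r2
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, xs) * choose(r2, c1 - xs) / choose(n, c1)
  list(xs = xs, probs = probs)
}

# Minimum-likelihood two-sided Fisher p by enumeration.
brute_fisher_two <- function(a, b, c, d) {
  e <- enumerate_margin_tables(a, b, c, d)
  p_obs <- e$probs[e$xs == a]
  min(1, sum(e$probs[e$probs <= p_obs * (1 + 1e-7)]))
}

# One-sided (greater on the [1,1] cell) Fisher p by enumeration.
brute_fisher_greater <- function(a, b, c, d) {
  e <- enumerate_margin_tables(a, b, c, d)
  sum(e$probs[e$xs >= a])
}

# Hypergeometric upper tail by term-wise summation.
brute_hyper_upper <- function(N, K, n, k) {
  xs <- k:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs) / choose(N, n))
}

# Exact two-sided Wilcoxon rank-sum p by enumerating every assignment of
# ranks to the first group (untied data only).
brute_wilcox_two <- function(x, y) {
  nx <- length(x)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  groups <- combn(length(x) + length(y), nx)
  us <- apply(groups, 2, function(ix) sum(r[ix])) - nx * (nx + 1) / 2
  mu <- nx * length(y) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Tiny deterministic expression fixture used across files: 4 normals in
# which g1 > g2 always, g3 > g2 always, g1 > g3 in 3 of 4 samples.
toy_normals <- function() {
  expression_matrix(matrix(
    c(10, 9, 8, 10,
      5, 5, 4, 6,
      7, 8, 9, 7),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("g1", "g2", "g3"), paste0("n", 1:4))))
}

# Star-shaped pair fixture: gene "g" above h1..h_k and below l1..l_m, with
# sample values that preserve or reverse chosen partner orderings.
star_pairs <- function(n_high = 5, n_low = 5) {
  hi <- if (n_high) paste0("h", seq_len(n_high)) else character(0)
  lo <- if (n_low) paste0("l", seq_len(n_low)) else character(0)
  stable_pair_set(data.frame(
    high_gene = c(rep("g", n_high), lo),
    low_gene = c(hi, rep("g", n_low)),
    support = rep(1, n_high + n_low)), threshold_f = 0.99, n_normals = 10)
}

# Sample vector for the star fixture: g at `g_value`, h-partners at 1..k
# (low), l-partners at 100 + 1..m (high) unless overridden.
star_sample <- function(n_high = 5, n_low = 5, g_value = 50,
                        h_values = NULL, l_values = NULL) {
  h <- if (is.null(h_values)) seq_len(n_high) else h_values
  l <- if (is.null(l_values)) 100 + seq_len(n_low) else l_values
  v <- c(g_value, h, l)
  names(v) <- c("g",
                if (n_high) paste0("h", seq_len(n_high)),
                if (n_low) paste0("l", seq_len(n_low)))
  v
}
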