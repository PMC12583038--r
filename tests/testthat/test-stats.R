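# Independent oracles ------------------------------------------------------

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
enum_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  combs <- utils::combn(length(pooled), n)
  u_obs <- sum(rank(pooled)[seq_len(n)]) - n * (n + 1) / 2
  us <- apply(combs, 2, function(idx) {
    sum(rank(pooled)[idx]) - n * (n + 1) / 2
  })
  mu <- n * (length(y)) / 2
  mean(abs(us - mu) >= abs(u_obs - mu))
}

# Literal step-up definition of Benjamini-Hochberg.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  ps <- p[o]
  q_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(ps[i:m] * m / (i:m)))
  }, numeric(1))
  q[o] <- q_sorted
  q
}

test_that("median split follows the closest-neighbor rule", {
  expect_equal(as.character(classify_by_median(c(10, 20, 30, 40))),
               c("small", "small", "large", "large"))
  # odd count: median cell 14 joins its closest neighbor 10 (small)
  expect_equal(as.character(classify_by_median(c(10, 14, 30))),
               c("small", "small", "large"))
  # odd count, neighbor at equal distance: tie broken to small
  expect_equal(as.character(classify_by_median(c(10, 20, 30))),
               c("small", "small", "large"))
  # the median cell joins large when its nearest neighbor is above
  expect_equal(as.character(classify_by_median(c(10, 26, 30))),
               c("small", "large", "large"))
  expect_error(classify_by_median(c(5, 5, 5)), "degenerate")

  # properties: near-balanced split; rank-based part of the rule (every
  # non-median cell) is invariant under monotone rescaling. The median
  # cell's own assignment depends on metric distances to its neighbors, so
  # full invariance holds for even counts and for linear rescaling.
  set.seed(31)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    len <- sample(seq(10, 400, by = 0.5), n)  # distinct lengths
    cls <- classify_by_median(len)
    expect_lte(abs(sum(cls == "small") - sum(cls == "large")), 1)
    expect_identical(as.character(cls),
                     as.character(classify_by_median(len * 3.7 + 2)))
    if (n %% 2 == 0) {
      expect_identical(as.character(cls),
                       as.character(classify_by_median(len^3 / 1e4)))
    } else {
      i_med <- which(len == stats::median(len))
      expect_identical(as.character(cls)[-i_med],
                       as.character(classify_by_median(len^3 / 1e4))[-i_med])
    }
  }
})

test_that("Mann-Whitney matches exact enumeration and is symmetric", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)
  expect_equal(mw$method, "exact")

  # enumeration oracle over random small samples without ties
  set.seed(7)
  for (i in 1:15) {
    x <- sample(seq(0, 100, 0.25), sample(3:6, 1))
    y <- sample(seq(0.1, 100.1, 0.25), sample(3:6, 1))
    expect_equal(mann_whitney(x, y)$p, enum_mw_p(x, y))
  }

  # symmetry and identical-sample behavior
  x <- rnorm(15); y <- rnorm(18)
  expect_equal(mann_whitney(x, y)$p, mann_whitney(y, x)$p)
  z <- c(1, 3, 3, 7, 9, 12)
  expect_equal(mann_whitney(z, z)$p, 1)
  expect_error(mann_whitney(numeric(0), 1:3))
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")

  set.seed(12)
  for (i in 1:50) {
    p <- stats::runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), brute_bh(p))
  }
})

test_that("Kruskal-Wallis/Dunn agree with rank-based expectations", {
  # two groups: KW p equals the tie-corrected MW normal approximation
  set.seed(5)
  x <- round(rnorm(12), 1); y <- round(rnorm(14) + 0.4, 1)
  kw <- kruskal_dunn(c(x, y), rep(c("a", "b"), c(12, 14)))
  expect_equal(kw$p_omnibus, mann_whitney(x, y)$p, tolerance = 1e-6)

  # identical groups: H = 0, p = 1
  g <- rep(c("a", "b", "c"), each = 3)
  kw0 <- kruskal_dunn(rep(c(1, 2, 3), 3), g)
  expect_equal(kw0$H, 0)
  expect_equal(kw0$p_omnibus, 1)

  # a strongly shifted group owns the smallest adjusted p-values
  set.seed(6)
  vals <- c(rnorm(10), rnorm(10), rnorm(10) + 50)
  kw2 <- kruskal_dunn(vals, rep(c("a", "b", "c"), each = 10))
  involved <- kw2$pairwise$group1 == "c" | kw2$pairwise$group2 == "c"
  expect_true(max(kw2$pairwise$p_adj[involved]) <
                min(kw2$pairwise$p_adj[!involved]))

  expect_error(kruskal_dunn(1:5, rep("a", 5)), "2 groups")
})

test_that("t-test and two-way ANOVA behave on constructed designs", {
  x <- c(1, 2, 3, 4)
  expect_equal(welch_t(x, x)$p, 1)

  # additive cell means with balanced within-cell deviations: the
  # interaction sum of squares is exactly zero, so its p-value is 1
  a <- rep(c("wt", "mut"), each = 8)
  b <- rep(rep(c("ctrl", "trt"), each = 4), 2)
  mu <- ifelse(a == "mut", 2, 0) + ifelse(b == "trt", 5, 0)
  dev <- rep(c(-1, 1, -2, 2), 4)
  res <- two_way_anova(mu + dev, a, b)
  expect_equal(res$p[res$term == "A:B"], 1)
  expect_lt(res$p[res$term == "B"], 0.01)

  # power check: genotype shift of 1 SD, n = 40 per cell, 2x2 design
  set.seed(99)
  hits <- replicate(200, {
    a2 <- rep(c("wt", "mut"), each = 80)
    b2 <- rep(rep(c("ctrl", "trt"), each = 40), 2)
    v <- rnorm(160) + (a2 == "mut") * 1
    two_way_anova(v, a2, b2)$p[1] < 0.01
  })
  expect_gte(mean(hits), 0.9)
})

test_that("stratified comparison adjusts one family per metric", {
  set.seed(21)
  df <- data.frame(
    cell_id = 1:40,
    condition_label = rep(c("WT", "mutant"), each = 20),
    length_um = stats::runif(40, 20, 60),
    value = c(stats::rnorm(20, 5), stats::rnorm(20, 0)))
  rep1 <- stratified_compare(df, "value")
  expect_equal(nrow(rep1), 2)             # small + large stratum
  expect_equal(rep1$p_adj, bh_adjust(rep1$p_raw))
  expect_true(all(rep1$p_adj >= rep1$p_raw))
  expect_true(all(rep1$p_adj <= 1))
  expect_true(all(rep1$p_adj[rep1$stratum == "small"] <= 0.05))

  # identical groups: everything NS
  df2 <- df; df2$value <- rep(c(1, 2, 3, 4, 5), 8)
  rep2 <- stratified_compare(df2, "value")
  expect_true(all(rep2$stars == "NS"))

  # star bands are a pure function of the adjusted p
  expect_equal(significance_stars(c(0.005, 0.01, 0.03, 0.07, 0.1, 0.4)),
               c("**", "**", "*", "(*)", "NS", "NS"))
})
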