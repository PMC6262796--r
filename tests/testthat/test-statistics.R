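# statistics module: mean±sem, ANOVA/Tukey, Kruskal-Wallis/Dunn, stars

test_that("mean_sem hand-computable cases", {
  ms <- mean_sem(c(1, 2, 3))
  expect_equal(ms$mean, 2)
  expect_equal(ms$sem, 1 / sqrt(3))
  expect_equal(mean_sem(rep(4.2, 5))$sem, 0)
  expect_true(is.na(mean_sem(7)$sem))
  expect_error(mean_sem(numeric(0)), "at least one")

  # Monte-Carlo oracle: sem estimates sigma/sqrt(n)
  set.seed(101)
  x <- rnorm(1000, 5, 2)
  expect_equal(mean_sem(x)$sem, 2 / sqrt(1000), tolerance = 0.15)
})

test_that("ANOVA matches the closed-form oracle", {
  g <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5))
  cmp <- group_compare(g, mode = "parametric")
  # SSB = 6 on 2 df, SSW = 6 on 6 df -> F = 3; p = P(F_{2,6} >= 3)
  expect_equal(cmp$omnibus$statistic, 3)
  expect_equal(cmp$omnibus$p, 1 - pf(3, 2, 6))
  expect_equal(cmp$omnibus$p, 0.125)
  expect_equal(cmp$summary$sem, rep(1 / sqrt(3), 3))

  same <- list(x = c(5, 6, 7, 8), y = c(5, 6, 7, 8))
  cmp0 <- group_compare(same, mode = "parametric")
  expect_equal(cmp0$omnibus$statistic, 0)
  expect_equal(cmp0$omnibus$p, 1)
})

test_that("Kruskal-Wallis matches the rank-sum formula without ties", {
  g <- list(a = c(1, 2), b = c(3, 4), c = c(5, 6))
  cmp <- group_compare(g, mode = "nonparametric")
  # H = 12/(N(N+1)) * sum(R_i^2/n_i) - 3(N+1), ranks 1..6
  H <- 12 / (6 * 7) * ((1 + 2)^2 / 2 + (3 + 4)^2 / 2 + (5 + 6)^2 / 2) -
    3 * 7
  expect_equal(cmp$omnibus$statistic, H)
  expect_equal(cmp$omnibus$test, "kruskal")
})

test_that("Dunn pairwise z tests match an independent hand computation", {
  g <- list(a = c(12, 15, 11, 19), b = c(25, 31, 28), c = c(40, 38, 45, 41))
  cmp <- group_compare(g, mode = "nonparametric", dunn_adjust = "bonferroni")

  # independent oracle: explicit ranks, no ties in this data
  values <- unlist(g); grp <- rep(names(g), lengths(g))
  r <- rank(values); N <- length(values)
  p_raw <- c()
  for (pr in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
    ri <- mean(r[grp == pr[1]]); rj <- mean(r[grp == pr[2]])
    ni <- sum(grp == pr[1]); nj <- sum(grp == pr[2])
    z <- (ri - rj) / sqrt(N * (N + 1) / 12 * (1 / ni + 1 / nj))
    p_raw <- c(p_raw, 2 * pnorm(-abs(z)))
  }
  p_adj <- pmin(p_raw * 3, 1)
  expect_equal(cmp$pairwise["a", "b"], p_adj[1])
  expect_equal(cmp$pairwise["a", "c"], p_adj[2])
  expect_equal(cmp$pairwise["b", "c"], p_adj[3])
})

test_that("ANOVA p agrees with a Monte-Carlo permutation oracle", {
  set.seed(55)
  g <- list(a = c(3.1, 4.5, 2.8, 5.0), b = c(4.9, 6.2, 5.4, 7.1),
            c = c(4.0, 5.1, 4.4, 6.0))
  cmp <- group_compare(g, mode = "parametric")
  vals <- unlist(g); lab <- rep(names(g), lengths(g))
  fstat <- function(v) {
    m <- tapply(v, lab, mean); n <- tapply(v, lab, length)
    ssb <- sum(n * (m - mean(v))^2)
    ssw <- sum((v - m[lab])^2)
    (ssb / 2) / (ssw / (length(v) - 3))
  }
  f0 <- fstat(vals)
  perm <- replicate(4000, fstat(sample(vals)))
  expect_lt(abs(cmp$omnibus$p - mean(perm >= f0 - 1e-12)), 0.02)
})

test_that("stars follow the printed convention", {
  expect_equal(p_stars(c(0.2, 0.049, 0.009, 0.0009, 0.00009)),
               c("ns", "*", "**", "***", "****"))
  expect_equal(p_stars(c(0.05, 0.01, 0.001, 1e-4)),
               c("ns", "*", "**", "***"))
})

test_that("auto mode switches on Shapiro-Wilk failure and logs it", {
  set.seed(8)
  normal <- list(a = rnorm(20), b = rnorm(20), c = rnorm(20))
  cmp_n <- group_compare(normal, mode = "auto")
  expect_equal(cmp_n$mode, "parametric")
  skewed <- list(a = exp(rnorm(20, 0, 1.5)), b = exp(rnorm(20, 0.5, 1.5)))
  cmp_s <- group_compare(skewed, mode = "auto")
  expect_equal(cmp_s$mode, "nonparametric")
  expect_match(cmp_s$note, "Shapiro")
})

test_that("group order permutation leaves results invariant", {
  set.seed(13)
  g <- list(a = rnorm(8, 1), b = rnorm(8, 2), c = rnorm(8, 1.5))
  c1 <- group_compare(g, mode = "parametric")
  c2 <- group_compare(g[c("c", "a", "b")], mode = "parametric")
  expect_equal(c1$omnibus$statistic, c2$omnibus$statistic)
  expect_equal(c1$omnibus$p, c2$omnibus$p)
  expect_equal(c1$pairwise["a", "c"], c2$pairwise["c", "a"])
  expect_equal(c1$pairwise["a", "b"], c2$pairwise["b", "a"])
})

test_that("input validation: group sizes, names, NA handling", {
  expect_error(group_compare(list(a = 1:3)), "at least 2 groups")
  expect_error(group_compare(list(1:3, 2:4)), "named")
  expect_error(group_compare(list(a = c(1, 2), b = 5), mode = "parametric"),
               "fewer than 2")
  g <- list(a = c(1, 2, 3, NA), b = c(2, 3, 4, 5))
  cmp <- group_compare(g, mode = "parametric")
  expect_equal(cmp$summary$dropped_na, c(1L, 0L))
  expect_equal(cmp$summary$n, c(3L, 4L))
})
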