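# Independent brute-force oracle: two-sided exact Mann-Whitney p by direct
# recursion over rank-sum distributions is replaced here by a literal
# re-enumeration with a different U computation (pairwise comparison counts
# rather than rank sums).
oracle_mw <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  vals <- c(a, b)
  u_pairs <- function(x, y)
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  ua <- u_pairs(a, b)
  u_obs <- min(ua, n1 * n2 - ua)
  combos <- utils::combn(n1 + n2, n1)
  cnt <- 0L
  for (j in seq_len(ncol(combos))) {
    x <- vals[combos[, j]]
    y <- vals[-combos[, j]]
    if (u_pairs(x, y) <= u_obs + 1e-9) cnt <- cnt + 1L
  }
  min(1, 2 * cnt / ncol(combos))
}

test_that("exact Mann-Whitney reproduces the attainable small-sample p values", {
  sep <- mannwhitney_exact(1:5, 6:10)
  expect_equal(sep$u, 0)
  expect_equal(sep$p, 2 / 252)
  expect_equal(round(sep$p, 3), 0.008)

  u2 <- mannwhitney_exact(c(1, 2, 3, 4, 7), c(5, 6, 8, 9, 10))
  expect_equal(u2$u, 2)
  expect_equal(u2$p, 8 / 252)
  expect_equal(round(u2$p, 3), 0.032)

  u3 <- mannwhitney_exact(c(1, 2, 3, 5, 7), c(4, 6, 8, 9, 10))
  expect_equal(u3$u, 3)
  expect_equal(u3$p, 14 / 252)
  expect_equal(round(u3$p, 3), 0.056)

  same <- mannwhitney_exact(c(3, 1, 4), c(3, 1, 4))
  expect_equal(same$p, 1)
})

test_that("exact Mann-Whitney agrees with enumeration and reference oracles", {
  set.seed(42)
  for (rep in 1:8) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    a <- sample(1:50, n1)          # tie-free
    b <- sample(setdiff(1:50, a), n2)
    ours <- mannwhitney_exact(a, b)
    expect_equal(ours$p, oracle_mw(a, b), tolerance = 1e-12)
    ref <- stats::wilcox.test(a, b, exact = TRUE, correct = FALSE)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
    expect_equal(min(ref$statistic, n1 * n2 - ref$statistic), ours$u)
  }
  # tied data: still agrees with the enumeration oracle
  a <- c(1, 2, 2, 5); b <- c(2, 3, 3, 6, 7)
  expect_equal(mannwhitney_exact(a, b)$p, oracle_mw(a, b), tolerance = 1e-12)
  expect_error(mannwhitney_exact(numeric(0), 1:3), "empty")
  expect_error(mannwhitney_exact(1:15, 1:10), "combined n")
})

test_that("percent change matches the printed-table arithmetic", {
  expect_equal(round(percent_change(100, 115)), 15)
  expect_equal(round(percent_change(25, 21)), -16)
  expect_equal(percent_change(7, 7), 0)
  f <- 0.137
  expect_equal(percent_change(3.2, 3.2 * (1 + f)), 100 * f)
  expect_error(percent_change(0, 5), "zero baseline")
})

test_that("correlation matches a direct-formula oracle", {
  x <- 1:6
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  set.seed(11)
  n <- 10
  x <- rnorm(n)
  y <- 0.8 * x + sqrt(1 - 0.8^2) * rnorm(n)
  ours <- pearson_correlation(x, y)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(ours$r, r_direct, tolerance = 1e-12)
  tstat <- r_direct * sqrt((n - 2) / (1 - r_direct^2))
  expect_equal(ours$p, 2 * stats::pt(-abs(tstat), n - 2), tolerance = 1e-12)
  expect_error(pearson_correlation(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson_correlation(1:2, 1:2), "length >= 3")
})

test_that("the comparison report has one row per metric with exact statistics", {
  set.seed(3)
  metrics <- data.frame(
    group = rep(c("lowfat", "highfat"), each = 5),
    ecc_endo = c(rnorm(5, -17, 1), rnorm(5, -15, 1)),
    mass_mg = c(rnorm(5, 100, 8), rnorm(5, 115, 8)),
    torsion = c(rnorm(5, 8.8, 1.9), rnorm(5, 6.6, 0.5)))
  rep_ <- build_report(metrics, reference = "lowfat")
  expect_setequal(rep_$metric, c("ecc_endo", "mass_mg", "torsion"))
  for (i in seq_len(nrow(rep_))) {
    cn <- rep_$metric[i]
    a <- metrics[[cn]][metrics$group == "lowfat"]
    b <- metrics[[cn]][metrics$group == "highfat"]
    expect_equal(rep_$p_two_sided[i], mannwhitney_exact(a, b)$p)
    expect_equal(rep_$percent_change[i], percent_change(mean(a), mean(b)))
  }
  # one subject per group: minimal attainable two-sided p is 1
  one <- data.frame(group = c("a", "b"), m = c(1, 2))
  expect_equal(build_report(one)$p_two_sided, 1)
  expect_error(build_report(data.frame(group = character(0),
                                       m = numeric(0))), "empty")
  three <- data.frame(group = c("a", "b", "c"), m = 1:3)
  expect_error(build_report(three), "two groups")
})
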