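test_that("Pearson chi-square agrees with the reference implementation", {
  set.seed(2)
  for (i in 1:5) {
    obs <- matrix(rpois(6, 20) + 1, 2, 3)
    ours <- chi_square_independence(contingency_table(obs))
    ref <- suppressWarnings(chisq.test(obs, correct = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(ours$df, unname(ref$parameter))
    # expected counts conserve the observed margins
    expect_equal(unname(rowSums(ours$expected)), rowSums(obs),
                 tolerance = 1e-9)
    expect_equal(unname(colSums(ours$expected)), colSums(obs),
                 tolerance = 1e-9)
  }
})

test_that("chi-square edge cases and invariances", {
  eq <- chi_square_independence(contingency_table(matrix(10, 2, 2)))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  obs <- rbind(c(12, 5, 9), c(3, 14, 6))
  r1 <- chi_square_independence(contingency_table(obs))
  r2 <- chi_square_independence(contingency_table(obs[2:1, c(3, 1, 2)]))
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-12)
  expect_error(chi_square_independence(
    contingency_table(rbind(c(0, 0, 0), c(5, 5, 5)))), "marginal")
})

test_that("binary tables are built from positives and totals", {
  t1 <- build_binary_table(c(7, 1, 0), c(60, 28, 24), "c9_positive")
  expect_equal(unname(t1$observed[2, ]), c(53, 27, 24))
  expect_equal(rownames(t1$observed), c("c9_positive", "not_c9_positive"))
  t2 <- build_binary_table(c(0, 0), c(10, 12))
  expect_equal(unname(t2$observed[2, ]), c(10, 12))
  t3 <- build_binary_table(c(10, 12), c(10, 12))
  expect_error(chi_square_independence(t3), "marginal")
  expect_error(build_binary_table(c(11, 1), c(10, 12)), "exceed")
})

test_that("ANCOVA F matches a brute-force normal-equations oracle", {
  df <- data.frame(
    y = c(3.1, 4.2, 2.8, 5.0, 6.1, 5.7, 4.9, 7.2, 6.8, 8.0, 7.5, 9.1),
    cl = rep(c("a", "b", "c"), each = 4),
    sex = rep(c(0, 1), 6))
  ours <- ancova_oneway(df$y, df$cl, covariates = data.frame(sex = df$sex))
  # brute force: solve both models by normal equations
  Xf <- cbind(1, df$sex, df$cl == "b", df$cl == "c")
  Xr <- cbind(1, df$sex)
  rss <- function(X, y) {
    beta <- solve(t(X) %*% X, t(X) %*% y)
    sum((y - X %*% beta)^2)
  }
  rf <- rss(Xf, df$y); rr <- rss(Xr, df$y)
  F_oracle <- ((rr - rf) / 2) / (rf / (12 - 4))
  expect_equal(ours$F, F_oracle, tolerance = 1e-8)
  expect_equal(ours$df, c(2, 8))
})

test_that("ANCOVA handles nulls, noise covariates and missing data", {
  set.seed(5)
  n <- 300
  cl <- rep(1:3, each = n / 3)
  y0 <- rnorm(n, 60, 8)                      # no cluster effect
  a_null <- ancova_oneway(y0, cl)
  expect_gt(a_null$p_value, 0.01)
  # a pure-noise covariate barely moves a clear cluster F
  y <- y0 + c(0, 4, 8)[cl]
  a0 <- ancova_oneway(y, cl)
  a1 <- ancova_oneway(y, cl, covariates = data.frame(z = rnorm(n)))
  expect_lt(abs(a1$F - a0$F) / a0$F, 0.1)
  # listwise deletion is applied and counted
  y2 <- y; y2[1:5] <- NA
  a2 <- ancova_oneway(y2, cl)
  expect_equal(a2$n_dropped, 5)
  expect_equal(sum(a2$group_sizes), n - 5)
  expect_error(ancova_oneway(y, rep(1, n)), "at least 2 clusters")
})

test_that("Tukey HSD reduces to the pooled t-test at k = 2", {
  set.seed(6)
  g <- rep(c("a", "b"), times = c(14, 18))
  y <- rnorm(32, ifelse(g == "a", 0, 1.2))
  a <- ancova_oneway(y, g)
  tk <- tukey_hsd(a)
  tt <- t.test(y ~ g, var.equal = TRUE)
  expect_equal(tk$p_adj, tt$p.value, tolerance = 1e-6)
  expect_equal(tk$q, abs(unname(tt$statistic)) * sqrt(2), tolerance = 1e-6)
})

test_that("Tukey p-values: identical means give 1, monotone in separation", {
  p_at <- function(delta)
    tukey_hsd(means = c(0, delta, 2 * delta), group_sizes = rep(20, 3),
              residual_var = 4, residual_df = 57)$p_adj[3]
  expect_gte(tukey_hsd(means = c(5, 5, 5), group_sizes = rep(10, 3),
                       residual_var = 2, residual_df = 27)$p_adj[1], 0.999)
  ps <- vapply(c(0.2, 0.5, 1, 2, 4), p_at, numeric(1))
  expect_false(is.unsorted(rev(ps)))
  expect_error(tukey_hsd(means = 5, group_sizes = 10, residual_var = 1,
                         residual_df = 9), "at least 2")
})

test_that("Shapiro-Wilk gate keeps normal data at the nominal rate", {
  set.seed(7)
  # a rejected normal sample contains negatives, so the gate errors rather
  # than transform it: count any non-"keep" outcome as a rejection
  decisions <- replicate(1000, tryCatch(normality_gate(rnorm(200))$decision,
                                        error = function(e) "log"))
  rate <- mean(decisions == "log")
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("Shapiro-Wilk gate log-transforms log-normal data", {
  set.seed(8)
  ok <- replicate(200, {
    g <- normality_gate(exp(rnorm(200)))
    g$decision == "log" && shapiro.test(g$values)$p.value >= 0.05
  })
  expect_gte(mean(ok), 0.95)
  expect_error(normality_gate(rep(1, 10)), "constant")
  set.seed(9)
  skewed_with_zero <- c(0, exp(rnorm(199)))
  expect_error(normality_gate(skewed_with_zero), "positive")
})

test_that("the bundled cohort tables carry their published statistics", {
  tabs <- als_contingency_tables()
  expect_length(tabs, 13)
  for (t in tabs) {
    expect_s3_class(t, "contingency_table")
    expect_length(attr(t, "published"), 2)
  }
  expect_equal(unname(tabs$kcl_c9$observed[2, ]), c(53, 27, 24))
})
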