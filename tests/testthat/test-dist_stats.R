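# Distribution summary, exact 1-D two-means, and the nonparametric tests.

test_that("summary statistics follow their closed-form oracles", {
  set.seed(21)
  x <- rnorm(200000)
  s <- summarize_distribution(x)
  # Pearson kurtosis of a normal is 3; SE of the sample kurtosis ~ sqrt(24/n)
  expect_lt(abs(s$kurtosis - 3), 10 * sqrt(24 / length(x)))
  expect_true(s$min <= s$median && s$median <= s$max)
  expect_equal(s$p50, s$median)

  zo <- c(rep(0, 90), rep(1, 10))
  expect_equal(summarize_distribution(zo)$proportion_positive, 0.10)

  expect_error(summarize_distribution(rep(2, 10)), "constant")
  expect_error(summarize_distribution(c(1, 2, 3)), ">= 4 values")
})

# independent oracle: naive per-cut WCSS, no shared arithmetic with kmeans_two
brute_force_two_means <- function(v) {
  s <- sort(v)
  n <- length(s)
  wcss <- vapply(seq_len(n - 1L), function(k) {
    sum((s[1:k] - mean(s[1:k]))^2) + sum((s[(k + 1):n] - mean(s[(k + 1):n]))^2)
  }, 1)
  k <- which.min(wcss)
  list(wcss = wcss[k], prevalence = (n - k) / n)
}

test_that("exact two-means matches a naive brute-force search", {
  set.seed(31)
  for (i in 1:25) {
    v <- switch(1 + i %% 3,
                rlnorm(sample(5:120, 1)),
                rnorm(sample(5:120, 1)),
                c(rnorm(40), rnorm(20, 6)))
    cl <- kmeans_two(v)
    bf <- brute_force_two_means(v)
    expect_equal(cl$wcss, bf$wcss, tolerance = 1e-10)
    expect_equal(cl$prevalence, bf$prevalence)
  }
})

test_that("two-means separates an obvious split and orders its clusters", {
  cl <- kmeans_two(c(0, 0, 0, 10, 10))
  expect_equal(cl$prevalence, 0.4)
  expect_gt(cl$threshold, 0); expect_lt(cl$threshold, 10)
  expect_gt(cl$means["exposed"], cl$means["unexposed"])
  expect_equal(as.character(cl$labels), c(rep("unexposed", 3), rep("exposed", 2)))
  expect_error(kmeans_two(rep(1, 5)), "distinct")
})

test_that("two-means prevalence is invariant to positive affine scaling", {
  set.seed(41)
  for (i in 1:10) {
    v <- rlnorm(80)
    base <- kmeans_two(v)$prevalence
    a <- runif(1, 0.1, 50); b <- runif(1, -5, 5)
    expect_equal(kmeans_two(a * v + b)$prevalence, base)
  }
})

test_that("two-means recovers the bimodal mixture weight", {
  x <- generate_bimodal_sample(10000, weight_high = 0.3, seed = 6L)
  cl <- kmeans_two(x)
  se <- sqrt(0.3 * 0.7 / 10000)
  expect_lt(abs(cl$prevalence - 0.3), 3 * se)
  # the recovered labels agree with the generator's ground truth
  expect_gt(mean((cl$labels == "exposed") == attr(x, "component_high")), 0.999)
})

test_that("Mann-Whitney U behaves at its anchors", {
  x <- c(1.1, 2.3, 3.7, 5.2, 8.1)
  expect_gt(mann_whitney_u(x, x)$p_value, 0.9)
  # complete separation: U = 0 for x-vs-y (all 6 rank arrangements beaten)
  expect_equal(mann_whitney_u(c(1, 2), c(3, 4))$statistic, 0)
  expect_error(mann_whitney_u(numeric(0), x), "nonempty")

  x2 <- generate_bimodal_sample(2000, weight_high = 0.3, seed = 7L)
  cl <- kmeans_two(x2)
  mw <- mann_whitney_u(x2[cl$labels == "exposed"],
                       x2[cl$labels == "unexposed"])
  expect_lt(mw$p_value, 0.05)
})

test_that("Shapiro-Wilk flags a lognormal sample and thins large inputs", {
  set.seed(51)
  expect_lt(shapiro_wilk(rlnorm(500))$p_value, 0.05)
  expect_error(shapiro_wilk(rep(1, 10)), "constant")
  expect_message(big <- shapiro_wilk(rlnorm(8000)), "thinning")
  expect_lt(big$p_value, 0.05)
})

test_that("Levene's test holds its nominal size under the null", {
  set.seed(61)
  rej <- mean(replicate(500, levene(rnorm(25), rnorm(25))$p_value < 0.05))
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / 500))
  expect_error(levene(rep(1, 5), rep(1, 5)), "constant")
})

test_that("Kruskal-Wallis matches the hand rank-sum oracle and has power", {
  g0 <- list(c(1, 5, 9), c(1, 5, 9))
  expect_equal(kruskal_wallis(g0)$statistic, 0)
  expect_equal(kruskal_wallis(g0)$p_value, 1)

  # ranks 1..9, rank sums 6/15/24: H = 12/90 * (36+225+576)/3 - 30 = 7.2
  g <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  kw <- kruskal_wallis(g)
  expect_equal(kw$statistic, 7.2)
  expect_equal(kw$p_value, pchisq(7.2, df = 2, lower.tail = FALSE))

  expect_error(kruskal_wallis(list(1:3)), ">= 2 groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "nonempty")

  # shift alternative of 2 sd at n = 30/group is essentially always detected
  set.seed(71)
  power <- mean(replicate(200, {
    kruskal_wallis(list(rnorm(30), rnorm(30, 2), rnorm(30, 4)))$p_value < 0.05
  }))
  expect_gte(power, 0.9)
})

test_that("assumption checks warn but never abort", {
  # perfectly normal quantiles: both Shapiro p-values are ~1 by construction
  x <- qnorm(ppoints(100)); y <- 1.2 * x + 0.3
  expect_warning(res <- check_mw_assumptions(x, y), "normality")
  set.seed(81)
  expect_named(res, c("shapiro_x", "shapiro_y", "levene"))
  ln <- rlnorm(100); lm2 <- rlnorm(100, sdlog = 2)
  expect_silent(res2 <- check_mw_assumptions(ln, lm2))
  expect_true(all(vapply(res2, function(t) t$p_value, 1) >= 0))
})
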