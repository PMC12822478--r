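test_that("rank-sum test matches symmetry and enumeration cases", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  res <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_true(res$exact_flag)
  expect_equal(res$p_value, 0.1)  # 2/20 assignments as extreme
  expect_warning(res0 <- wilcoxon_rank_sum(c(1, 1, 1), c(1, 1, 1)), "tied")
  expect_equal(res0$p_value, 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "at least one")
})

test_that("rank-sum exact branch agrees with exhaustive enumeration", {
  set.seed(42)
  for (i in 1:20) {
    n1 <- sample(2:7, 1); n2 <- sample(2:7, 1)
    v <- sample(1:60, n1 + n2)  # tie-free
    x <- v[seq_len(n1)]; y <- v[-seq_len(n1)]
    expect_equal(wilcoxon_rank_sum(x, y)$p_value, enum_rank_sum_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("signed-rank test matches enumeration and sign symmetry", {
  res <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5))
  expect_true(res$exact_flag)
  expect_equal(res$p_value, 0.0625)  # 2/2^5
  expect_warning(res0 <- wilcoxon_signed_rank(c(0, 0, 0)), "zero")
  expect_equal(res0$p_value, 1)
  expect_equal(wilcoxon_signed_rank(-c(1, 2, 3, 4, 5))$p_value, res$p_value)
  set.seed(7)
  for (i in 1:15) {
    d <- sample(1:50, sample(3:10, 1)) * sample(c(-1, 1), 1)
    d <- d + stats::runif(length(d), -0.2, 0.2)  # untied magnitudes
    expect_equal(wilcoxon_signed_rank(d)$p_value, enum_signed_rank_p(d),
                 tolerance = 1e-12)
  }
})

test_that("exact and normal-approximation Wilcoxon branches agree on n = 8", {
  set.seed(11)
  for (i in 1:25) {
    v <- sample(1:100, 16)
    x <- v[1:8]; y <- v[9:16]
    p_exact <- wilcoxon_rank_sum(x, y, exact = TRUE)$p_value
    p_approx <- wilcoxon_rank_sum(x, y, exact = FALSE)$p_value
    expect_lt(abs(p_exact - p_approx), 0.02)
  }
})

test_that("rank-sum type-I error is calibrated under a Gaussian null", {
  set.seed(123)
  rej <- mean(replicate(2000, {
    wilcoxon_rank_sum(rnorm(20), rnorm(20))$p_value < 0.05
  }))
  expect_gte(rej, 0.038)
  expect_lte(rej, 0.062)
})

test_that("BH adjustment matches hand cases and the brute-force definition", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.5)), c(0.01, 0.5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(5)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), brute_bh(p), tolerance = 1e-12)
  }
})

test_that("Spearman correlation handles monotone, tied and degenerate input", {
  x <- 1:10
  expect_equal(spearman_corr(x, x^3)$rho, 1)
  expect_equal(spearman_corr(x, -x^3)$rho, -1)
  res <- spearman_corr(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(res$rho, 0.6)  # 1 - 6*4/(4*15)
  const <- spearman_corr(rep(1, 5), 1:5)
  expect_true(const$degenerate)
  expect_true(is.na(const$rho))
  # p from t-approximation with n-2 df
  n <- res$n
  tval <- 0.6 * sqrt((n - 2) / (1 - 0.36))
  expect_equal(res$p, 2 * pt(-abs(tval), n - 2))
})

test_that("Fisher 2x2 matches hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2))$p, 1 / 3,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(c(0, 3, 0, 4), 2))$p, 1)
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2))$p, 2 / choose(10, 5),
               tolerance = 1e-12)
  expect_error(fisher_exact_2x2(matrix(c(-1, 0, 0, 2), 2)), "non-negative")
})

test_that("hypergeometric enrichment matches closed forms", {
  expect_equal(hypergeom_enrich(5, 5, 5, 20), 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(hypergeom_enrich(0, 5, 5, 20), 1)
  expect_equal(hypergeom_enrich(5, 5, 5, 5), 1)
  expect_error(hypergeom_enrich(6, 5, 5, 20), "inconsistent")
})

test_that("KM curve matches the hand product-limit and is order-invariant", {
  cv <- km_curve(c(1, 2, 3), c(1, 0, 1))
  expect_equal(cv$surv[cv$time == 1], 2 / 3)
  expect_equal(cv$surv[cv$time == 3], 0)
  all_cens <- km_curve(c(5, 6, 7), c(0, 0, 0))
  expect_true(all(all_cens$surv == 1))
  single <- km_curve(4, 1)
  expect_equal(single$surv, 0)
  expect_error(km_curve(numeric(0), numeric(0)), "empty")
  set.seed(3)
  times <- rexp(30); events <- rbinom(30, 1, 0.7)
  perm <- sample(30)
  a <- km_curve(times, events)
  b <- km_curve(times[perm], events[perm])
  expect_equal(a, b)
  # against the independent hand oracle
  hk <- hand_km(times, events)
  expect_equal(a$surv[match(hk$time, a$time)], hk$surv, tolerance = 1e-12)
})

test_that("log-rank test matches the hand-computed worked example", {
  same <- logrank_test(c(1, 2, 3), c(1, 1, 0), c(1, 2, 3), c(1, 1, 0))
  expect_equal(same$statistic, 0, tolerance = 1e-9)
  expect_equal(same$p_value, 1)
  res <- logrank_test(c(1, 2), c(1, 1), c(3, 4), c(1, 1))
  expect_equal(res$statistic, 49 / 17, tolerance = 1e-9)  # (2 - 5/6)^2 / (17/36)
  expect_equal(res$p_value, pchisq(49 / 17, 1, lower.tail = FALSE))
  expect_warning(deg <- logrank_test(c(1, 2), c(0, 0), c(3, 4), c(0, 0)), "no events")
  expect_equal(deg$p_value, 1)
})

test_that("median-split survival follows the low-tie convention", {
  scores <- c(a = 1, b = 2, c = 3, d = 4)
  res <- median_split_survival(scores, c(10, 20, 30, 40), c(1, 1, 1, 1))
  expect_equal(unname(res$strata), factor(c("low", "low", "high", "high"),
                                          levels = c("low", "high")))
  expect_error(median_split_survival(rep(1, 6), 1:6, rep(1, 6)), "degenerate")
})
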