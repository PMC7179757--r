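test_that("normality screen accepts normal and rejects heavy-tailed data", {
  # under H0 the p-value should rarely fall below 0.05
  p_norm <- vapply(1:60, function(s) {
    x <- withr::with_seed(s, stats::rnorm(500, 10, 2))
    normality_check(x)$p
  }, 0)
  expect_gte(mean(p_norm > 0.05), 0.90)
  # lognormal data must be flagged essentially always at n = 500
  p_lnorm <- vapply(1:60, function(s) {
    x <- withr::with_seed(s, stats::rlnorm(500))
    normality_check(x)$p
  }, 0)
  expect_gte(mean(p_lnorm < 0.05), 0.90)
})

test_that("degenerate samples are flagged, small samples rejected", {
  out <- normality_check(rep(3, 10))
  expect_true(out$degenerate)
  expect_true(is.na(out$p))
  expect_error(normality_check(c(1, 2, 3)), "at least 5")
})

test_that("Friedman statistic matches closed forms", {
  # perfectly consistent ordering, n = 10, k = 4: rank sums 10,20,30,40
  m <- matrix(rep(1:4, each = 10), 10)
  om <- friedman_omnibus(m)
  expect_equal(om$chi2, 30)
  expect_equal(om$df, 3L)
  # identical columns: every rank is the mid-rank, chi2 = 0
  expect_equal(friedman_omnibus(matrix(5, 6, 4))$chi2, 0)
  expect_error(friedman_omnibus(matrix(c(1, NA, 2, 3, 4, 5, 6, 7), 2)),
               "missing")
})

test_that("Friedman agrees with the reference implementation on tie-free data", {
  withr::with_seed(31, {
    for (i in 1:5) {
      m <- matrix(stats::rnorm(10 * 4), 10, 4)
      ref <- stats::friedman.test(m)
      om <- friedman_omnibus(m)
      expect_equal(om$chi2, unname(ref$statistic))
      expect_equal(om$p, ref$p.value)
    }
  })
})

test_that("small-instance Friedman matches exhaustive permutation oracle", {
  # n = 4, k = 3: enumerate all (3!)^4 = 1296 within-row rank orders to
  # get the exact permutation distribution of the statistic
  m <- matrix(c(1.2, 0.4, 2.7,
                0.8, 1.9, 2.2,
                2.5, 0.3, 1.1,
                0.9, 1.4, 3.0), 4, 3, byrow = TRUE)
  obs <- friedman_omnibus(m)$chi2
  perms <- matrix(c(1, 2, 3, 1, 3, 2, 2, 1, 3, 2, 3, 1, 3, 1, 2, 3, 2, 1),
                  ncol = 3, byrow = TRUE)
  stat_from_ranks <- function(r) {
    rj <- colSums(r)
    12 / (4 * 3 * 4) * sum(rj^2) - 3 * 4 * 4
  }
  stats_all <- apply(expand.grid(1:6, 1:6, 1:6, 1:6), 1, function(idx) {
    stat_from_ranks(perms[unlist(idx), , drop = FALSE])
  })
  # the observed statistic is itself a point of the permutation lattice
  expect_true(any(abs(stats_all - obs) < 1e-12))
  p_exact <- mean(stats_all >= obs - 1e-12)
  # the chi-square approximation is crude at n = 4; agreement within 0.1
  # is the documented error bound for this instance
  expect_lt(abs(friedman_omnibus(m)$p - p_exact), 0.1)
})

test_that("Friedman is invariant to strictly monotone row transforms", {
  withr::with_seed(17, {
    m <- matrix(stats::runif(8 * 4), 8, 4)
    ref <- friedman_omnibus(m)$chi2
    m2 <- exp(m)           # monotone on all rows
    m3 <- m^3 + 5
    expect_equal(friedman_omnibus(m2)$chi2, ref)
    expect_equal(friedman_omnibus(m3)$chi2, ref)
  })
})

test_that("Wilcoxon post-hoc reproduces the forced all-positive case", {
  out <- wilcoxon_posthoc(rep(0, 10), 1:10)
  expect_equal(round(out$Z, 2), -2.80)
  expect_equal(round(out$p, 3), 0.005)
  expect_true(out$significant)
  # symmetric rank split: tied top ranks 9.5 + 9.5, positives carry
  # ranks {1,2,3,4,8,9.5} = 27.5 and negatives {5,6,7,9.5} = 27.5
  d <- c(1, 2, 3, 4, -5, -6, -7, 8, 9, -9)
  out2 <- wilcoxon_posthoc(rep(0, 10), d)
  expect_equal(out2$Z, 0)
})

test_that("Wilcoxon normal approximation stays near the exact distribution", {
  # exact null: enumerate all 2^6 sign assignments of the (tie-free)
  # ranks 1..6
  a <- c(10, 12, 9, 15, 11, 14)
  b <- c(11, 14, 12, 11, 16, 20)   # d = 1, 2, 3, -4, 5, 6
  d <- b - a
  r <- rank(abs(d))
  signs <- expand.grid(rep(list(c(0, 1)), 6))
  w_plus_all <- as.matrix(signs) %*% r
  t_obs <- min(sum(r[d > 0]), sum(r[d < 0]))
  t_all <- pmin(w_plus_all, sum(r) - w_plus_all)
  p_exact <- mean(t_all <= t_obs)
  out <- wilcoxon_posthoc(a, b)
  expect_lt(abs(out$p - p_exact), 0.06)
})

test_that("Wilcoxon handles zeros, sign swaps and degenerate input", {
  # zero differences are dropped before ranking
  out <- wilcoxon_posthoc(c(5, 5, 1, 2, 3, 4, 6), c(5, 5, 2, 4, 6, 8, 12))
  expect_equal(out$n, 5)
  # |Z| is unchanged when the pair order is swapped
  withr::with_seed(23, {
    a <- stats::rnorm(12)
    b <- stats::rnorm(12, 0.5)
    expect_equal(abs(wilcoxon_posthoc(a, b)$Z), abs(wilcoxon_posthoc(b, a)$Z))
  })
  expect_error(wilcoxon_posthoc(1:5, 1:5), "zero")
  expect_error(wilcoxon_posthoc(c(1, 2, 3, 4), c(2, 3, 4, 5)), "at least 5")
})

test_that("Bonferroni level for the planned family is alpha / 4", {
  out <- wilcoxon_posthoc(rep(0, 10), 1:10, family_size = 4, alpha = 0.05)
  expect_identical(out$level, 0.05 / 4)
  expect_identical(out$level, 0.0125)
})

test_that("characterize composes the component tests faithfully", {
  withr::with_seed(41, {
    m <- matrix(stats::rnorm(40, 10), 10, 4,
                dimnames = list(NULL, c("baseline", "easy", "medium", "hard")))
  })
  rep_out <- characterize(list(hr = m))
  expect_equal(rep_out$omnibus$chi2, friedman_omnibus(m)$chi2)
  direct <- wilcoxon_posthoc(m[, "baseline"], m[, "easy"], family_size = 4)
  expect_equal(rep_out$posthoc$Z[rep_out$posthoc$pair == "baseline vs easy"],
               direct$Z)
  expect_equal(nrow(rep_out$posthoc), 4)
  expect_setequal(rep_out$posthoc$pair,
                  c("baseline vs easy", "baseline vs medium",
                    "baseline vs hard", "easy vs hard"))
})

test_that("post-hoc family keeps family-wise type-I error below alpha", {
  # null simulation: 4 contrasts at the 0.0125 level, 400 replicates
  n_rep <- 400
  any_sig <- withr::with_seed(53, vapply(seq_len(n_rep), function(i) {
    m <- matrix(stats::rnorm(40), 10, 4,
                dimnames = list(NULL, c("baseline", "easy", "medium", "hard")))
    rep_i <- characterize(list(f = m))
    any(rep_i$posthoc$significant)
  }, NA))
  fwer <- mean(any_sig)
  # Monte-Carlo 95% bound: 0.05 + 2 sqrt(0.05 * 0.95 / 400) ~ 0.072
  expect_lte(fwer, 0.072)
})
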