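test_that("segment GLM matches the normal equations and standardization", {
  set.seed(10)
  n <- 46
  x <- rnorm(n); age <- rnorm(n, 21, 1.5)
  y <- 0.4 * x + 0.1 * age + rnorm(n)
  res <- glm_segment(y, x, age)
  # brute-force normal equations
  X <- cbind(1, x, age)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(res$beta_std, beta[2] * sd(x) / sd(y), tolerance = 1e-10)
  s2 <- sum((y - X %*% beta)^2) / (n - 3)
  expect_equal(res$t_stat, beta[2] / sqrt(s2 * solve(t(X) %*% X)[2, 2]),
               tolerance = 1e-10)

  # invariance to affine rescaling of y and regressor
  res2 <- glm_segment(3 * y + 7, 0.1 * x - 2, age)
  expect_equal(res2$beta_std, res$beta_std, tolerance = 1e-10)
  expect_equal(res2$t_stat, res$t_stat, tolerance = 1e-10)

  # perfect fit: beta_std = 1, t capped and flagged
  resp <- glm_segment(x, x, NULL)
  expect_equal(resp$beta_std, 1, tolerance = 1e-9)
  expect_true(isTRUE(attr(resp$t_stat, "exact_fit")))

  # null calibration: |t| < t_{.975}(43) in about 95% of simulations
  set.seed(11)
  hits <- replicate(400, {
    abs(glm_segment(rnorm(n), x, age)$t_stat) < qt(0.975, n - 3)
  })
  expect_gt(mean(hits), 0.90)
  expect_lt(mean(hits), 0.99)

  expect_error(glm_segment(y, x, x), "rank-deficient")
})

test_that("TFCE matches closed forms and reduces to cluster extent", {
  expect_equal(tfce_1d(rep(0, 10)), rep(0, 10))

  # isolated peak of height h: e = 1 across thresholds -> integral h^3/3
  h <- 2.5
  v <- c(0, 0, h, 0, 0)
  out <- tfce_1d(v, E = 0.5, H = 2, dh = h / 5000)
  expect_equal(out[3], h^3 / 3, tolerance = 0.01 * h^3 / 3)
  expect_equal(out[c(1, 2, 4, 5)], rep(0, 4))

  # scaling the map scales every nonzero enhancement up
  set.seed(3)
  stat <- pmax(rnorm(30), 0)
  t1 <- tfce_1d(stat); t2 <- tfce_1d(2 * stat)
  nz <- stat > 0
  expect_true(all(t2[nz] > t1[nz]))

  # H = 0, E = 1, single threshold recovers cluster extent
  stat2 <- c(0, 3, 3, 3, 0, 0, 3, 0)
  ext <- tfce_1d(stat2, E = 1, H = 0, dh = 3)
  expect_equal(ext, c(0, 9, 9, 9, 0, 0, 3, 0))  # extent * dh per cluster
})

test_that("permutation FWE is seed-stable and detects the planted effect", {
  spec <- cohort_spec(seed = 21)
  sim <- simulate_profiles(spec)
  r1 <- permutation_fwe(sim$profiles, sim$t_er_ms, sim$age, n_perm = 100,
                        seed = 5)
  r2 <- permutation_fwe(sim$profiles, sim$t_er_ms, sim$age, n_perm = 100,
                        seed = 5)
  expect_identical(r1$p_fwe, r2$p_fwe)
  expect_true(all(r1$p_fwe >= 1 / 101, na.rm = TRUE))
  expect_true(all(r1$p_fwe <= 1, na.rm = TRUE))

  r3 <- permutation_fwe(sim$profiles, sim$t_er_ms, sim$age, n_perm = 1000,
                        seed = 5)
  sig <- which(r3$p_fwe[, "NDI"] < 0.05)
  expect_gt(length(intersect(sig, spec$effect_segments)),
            0.6 * length(spec$effect_segments))
  # planted effect is negative
  expect_true(all(r3$beta_std[sig, "NDI"] < 0))
  # specificity: other metrics stay clean
  expect_equal(sum(r3$p_fwe[, c("ODI", "FA", "MD")] < 0.05, na.rm = TRUE), 0)

  # constant cell flagged, not significant
  vals <- sim$profiles$values
  vals[, 3, 2] <- 0.5
  r4 <- permutation_fwe(vals, sim$t_er_ms, sim$age, n_perm = 100, seed = 2)
  expect_true(is.na(r4$p_fwe[3, 2]))
})

test_that("missing segments fall back to pairwise deletion", {
  spec <- cohort_spec(seed = 31)
  sim <- simulate_profiles(spec)
  vals <- sim$profiles$values
  vals[1:3, 5, 1] <- NA
  r <- permutation_fwe(vals, sim$t_er_ms, sim$age, n_perm = 100, seed = 9)
  expect_false(is.na(r$p_fwe[5, 1]))
  sig <- which(r$p_fwe[, 1] < 0.05)
  expect_gt(length(intersect(sig, spec$effect_segments)), 5)
})

test_that("correlation report matches closed forms and the Bayes oracle", {
  # closed-form grid before rounding
  for (r0 in c(-0.5, 0.062, 0.114, 0.3)) for (n in c(20, 46, 100)) {
    d <- vectors_with_correlation(r0, n, seed = n)
    rep <- pearson_report(d$x, d$y)
    expect_equal(rep$r, r0, tolerance = 1e-10)
    ct <- cor.test(d$x, d$y)
    expect_equal(rep$p, unname(ct$p.value), tolerance = 1e-6)
    z <- atanh(r0); hw <- 1.959964 / sqrt(n - 3)
    expect_equal(rep$ci95, tanh(c(z - hw, z + hw)), tolerance = 1e-6)
    # numerical-integration BF vs closed-form hypergeometric oracle
    expect_equal(rep$bf10, bf10_closed_form(r0, n), tolerance = 1e-4)
  }
  expect_error(pearson_report(rep(1, 10), rnorm(10)), "zero-variance")
})

test_that("repeated-measures ANOVA matches car and handles 2-level sphericity", {
  skip_if_not_installed("car")
  set.seed(17)
  n <- 14; a <- 2; b <- 6
  dat <- array(rnorm(n * a * b), c(n, a, b))
  dat <- dat + rep(seq(0, 1.2, length.out = b), each = n * a)
  res <- rm_anova_gg(dat)

  Y <- matrix(aperm(dat, c(1, 3, 2)), n)
  idata <- expand.grid(B = factor(1:b), A = factor(1:a))
  av <- car::Anova(lm(Y ~ 1), idata = idata, idesign = ~ A * B, type = 3)
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  ut <- s$univariate.tests
  expect_equal(res$A$F, unname(ut["A", "F value"]), tolerance = 1e-8)
  expect_equal(res$B$F, unname(ut["B", "F value"]), tolerance = 1e-8)
  expect_equal(res$AB$F, unname(ut["A:B", "F value"]), tolerance = 1e-8)
  pa <- s$pval.adjustments
  expect_equal(res$B$eps_gg, unname(pa["B", "GG eps"]), tolerance = 1e-8)
  expect_equal(res$AB$eps_gg, unname(pa["A:B", "GG eps"]), tolerance = 1e-8)
  expect_equal(res$B$p_gg, unname(pa["B", "Pr(>F[GG])"]), tolerance = 1e-8)

  # two-level factor is automatically spherical
  expect_equal(res$A$eps_gg, 1)
  # epsilon bounded below by 1/(k-1)
  expect_gt(res$B$eps_gg, 1 / (b - 1))
  expect_lte(res$B$eps_gg, 1)

  # identical values everywhere -> degenerate, flagged
  resd <- rm_anova_gg(array(1, c(5, 2, 3)))
  expect_true(is.na(resd$B$F))
  expect_error(rm_anova_gg(array(c(NA, rnorm(39)), c(5, 2, 4))), "missing")
})
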