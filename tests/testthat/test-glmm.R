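make_sim_data <- function(G, m, beta0, beta1, sigma, seed) {
  set.seed(seed)
  u <- stats::rnorm(G, 0, sigma)
  x <- rep(c(0, 1), G)
  g <- rep(seq_len(G), each = 2)
  p <- stats::plogis(beta0 + beta1 * x + u[g])
  glmm_data(g, x, stats::rbinom(2 * G, m, p), rep(m, 2 * G))
}

test_that("Laplace likelihood collapses exactly to the binomial GLM at
           sigma = 0 and increases toward the empty-success boundary", {
  d <- make_sim_data(6, 30, 0.3, -0.4, 0.5, seed = 1)
  for (b in list(c(0, 0), c(0.3, -0.4), c(-1, 1))) {
    exact <- sum(stats::dbinom(d$k, d$m,
                               stats::plogis(b[1] + b[2] * d$x), log = TRUE))
    expect_equal(laplace_loglik(b[1], b[2], 0, d), exact, tolerance = 1e-12)
  }
  zero <- glmm_data(rep(1:4, each = 2), rep(c(0, 1), 4), rep(0L, 8),
                    rep(10L, 8))
  ll <- vapply(-(1:8), function(b0) laplace_loglik(b0, 0, 0.3, zero),
               numeric(1))
  expect_true(all(diff(ll) > 0))
})

test_that("Laplace agrees with 51-node adaptive Gauss-Hermite quadrature", {
  # 3-group toy at sigma = 0.5, tight tolerance
  d <- make_sim_data(3, 40, 0.2, 0.3, 0.5, seed = 2)
  expect_equal(laplace_loglik(0.2, 0.3, 0.5, d),
               agq_loglik(0.2, 0.3, 0.5, d), tolerance = 1e-3)

  # randomized small-instance suite: the intrinsic Laplace error is O(1/m),
  # so the bound scales with the information per group; an implementation
  # bug would produce O(1) discrepancies
  set.seed(3)
  for (i in 1:12) {
    G <- sample(3:6, 1); m <- sample(20:100, 1)
    b0 <- stats::runif(1, -1, 1); b1 <- stats::runif(1, -1, 1)
    sg <- stats::runif(1, 0.2, 1.5)
    d <- make_sim_data(G, m, b0, b1, sg, seed = 100 + i)
    gap <- abs(laplace_loglik(b0, b1, sg, d) - agq_loglik(b0, b1, sg, d))
    expect_lt(gap, 0.05)
    if (m >= 80) expect_lt(gap, 1e-2)
  }
  # the gap shrinks as the per-group information grows
  gaps <- vapply(c(20, 80, 320, 1280), function(m) {
    d <- make_sim_data(4, m, 0.3, -0.4, 1.2, seed = 50)
    abs(laplace_loglik(0.3, -0.4, 1.2, d) - agq_loglik(0.3, -0.4, 1.2, d))
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
})

test_that("fit with sigma fixed at 0 equals the IRLS logistic GLM", {
  d <- make_sim_data(8, 50, 0.4, -0.6, 0.4, seed = 4)
  fit <- fit_glmm(d, fix_sigma = 0)
  glm_fit <- stats::glm(cbind(k, m - k) ~ x, family = stats::binomial(),
                        data = as.data.frame(unclass(d)))
  expect_equal(fit$beta0, unname(stats::coef(glm_fit)[1]), tolerance = 1e-8)
  expect_equal(fit$beta1, unname(stats::coef(glm_fit)[2]), tolerance = 1e-8)
  expect_equal(fit$loglik, as.numeric(stats::logLik(glm_fit)),
               tolerance = 1e-8)
})

test_that("estimates, SEs and likelihood reproduce an independent Laplace
           fitter on interior-optimum data", {
  skip_if_not_installed("lme4")
  d <- make_sim_data(12, 60, 0.2, -0.5, 0.7, seed = 5)
  fit <- fit_glmm(d)
  dd <- as.data.frame(unclass(d))
  gm <- lme4::glmer(cbind(k, m - k) ~ x + (1 | group), data = dd,
                    family = stats::binomial())
  expect_equal(fit$beta0, unname(lme4::fixef(gm)[1]), tolerance = 1e-3)
  expect_equal(fit$beta1, unname(lme4::fixef(gm)[2]), tolerance = 1e-3)
  expect_equal(fit$sigma_u,
               sqrt(unname(unlist(lme4::VarCorr(gm)))), tolerance = 1e-3)
  expect_equal(fit$loglik, as.numeric(stats::logLik(gm)), tolerance = 1e-4)
  expect_equal(fit$se_beta1, stats::coef(summary(gm))[2, 2],
               tolerance = 1e-2)
  expect_equal(unname(fit$conditional_modes),
               lme4::ranef(gm)$group[, 1], tolerance = 1e-2)

  dd$obs <- factor(seq_len(nrow(dd)))
  fo <- fit_glmm(d, olre = TRUE)
  gm2 <- lme4::glmer(cbind(k, m - k) ~ x + (1 | group) + (1 | obs),
                     data = dd, family = stats::binomial())
  vc <- as.data.frame(lme4::VarCorr(gm2))
  expect_equal(fo$beta1, unname(lme4::fixef(gm2)[2]), tolerance = 1e-3)
  expect_equal(fo$sigma_obs, sqrt(vc$vcov[vc$grp == "obs"]),
               tolerance = 1e-2)
  expect_equal(fo$loglik, as.numeric(stats::logLik(gm2)), tolerance = 1e-3)
})

test_that("symmetric null data give a numerically zero dye coefficient", {
  d <- glmm_data(rep(1:6, 2), rep(c(0, 1), each = 6),
                 rep(c(12L, 18L, 25L, 30L, 14L, 22L), 2), rep(50L, 12))
  fit <- fit_glmm(d)
  expect_lt(abs(fit$beta1), 1e-6)
})

test_that("the likelihood surface is invariant under group relabelling and
           equivariant under treatment recoding", {
  d <- make_sim_data(8, 40, 0.3, -0.5, 0.6, seed = 6)
  relab <- glmm_data(paste0("z", rev(as.integer(d$group))), d$x, d$k, d$m)
  expect_equal(laplace_loglik(0.3, -0.5, 0.6, relab),
               laplace_loglik(0.3, -0.5, 0.6, d), tolerance = 1e-10)
  swap <- glmm_data(d$group, 1 - d$x, d$k, d$m)
  # (b0, b1) -> (b0 + b1, -b1) is an exact reparameterization
  expect_equal(laplace_loglik(0.3 - 0.5, 0.5, 0.6, swap),
               laplace_loglik(0.3, -0.5, 0.6, d), tolerance = 1e-10)

  f1 <- fit_glmm(d); f2 <- fit_glmm(swap)
  expect_equal(f2$beta1, -f1$beta1, tolerance = 1e-5)
  expect_equal(f2$loglik, f1$loglik, tolerance = 1e-7)
  expect_equal(abs(wald_test(f2)$statistic), abs(wald_test(f1)$statistic),
               tolerance = 1e-4)
})

test_that("Wald inference maps statistics to p-values correctly", {
  fit <- make_fit(beta1 = 0.5, se_beta1 = 0.25, n_obs = 20L)
  wt <- wald_test(fit)
  expect_equal(wt$statistic, 2)
  expect_equal(wt$df, 17L)
  expect_equal(wt$p_value, 2 * stats::pt(-2, 17), tolerance = 1e-12)

  expect_equal(wald_test(make_fit(beta1 = 0))$statistic, 0)
  expect_equal(wald_test(make_fit(beta1 = 0))$p_value, 1)

  big <- wald_test(make_fit(beta1 = 0.5, se_beta1 = 0.25), df = 1e6)
  expect_lt(abs(big$p_value - big$p_value_z), 1e-6)

  # quasi-style SE inflation scales the statistic down accordingly
  infl <- wald_test(make_fit(beta1 = 0.5, se_beta1 = 0.25), se_inflate = 2)
  expect_equal(infl$statistic, 1)
  expect_equal(infl$stderr, 0.5)

  expect_error(wald_test(make_fit(se_beta1 = 0)), "degenerate")
})

test_that("dispersion diagnostics: exact residuals, binomial calibration,
           saturated limit, OLRE reduction", {
  # hand-built fit whose conditional probabilities equal k/m: zero residuals
  d <- glmm_data(1:6, rep(c(0, 1), 3), c(3L, 5L, 7L, 2L, 8L, 6L),
                 rep(10L, 6))
  fit <- make_fit(beta0 = 0, beta1 = 0,
                  modes = stats::qlogis(d$k / d$m), data = d)
  rep0 <- dispersion(fit, df = 3)
  expect_equal(rep0$residual_deviance, 0, tolerance = 1e-10)
  expect_equal(rep0$pearson_chi2, 0, tolerance = 1e-10)

  # pure binomial data are not overdispersed (averaged over seeds)
  disp <- vapply(1:30, function(s) {
    f <- suppressWarnings(fit_glmm(generate_paired_binomial(10, 100, 0.5, 0,
                                                            seed = s)))
    dispersion(f)$dispersion_pearson
  }, numeric(1))
  expect_gt(mean(disp), 0.7)
  expect_lt(mean(disp), 1.3)

  # on overdispersed data the OLRE variant strictly reduces Pearson
  # dispersion, seed by seed
  for (s in 1:8) {
    dd <- with_overdispersion(seed = s)
    base <- suppressWarnings(fit_glmm(dd))
    olre <- suppressWarnings(fit_glmm(dd, olre = TRUE))
    expect_lt(dispersion(olre)$dispersion_pearson,
              dispersion(base)$dispersion_pearson)
  }
})

test_that("degenerate designs are reported, not silently fit", {
  sep <- glmm_data(rep(1:4, 2), rep(c(0, 1), each = 4),
                   c(5L, 6L, 4L, 7L, 0L, 0L, 0L, 0L), rep(10L, 8))
  expect_warning(fit_glmm(sep), "separation")
  expect_error(fit_glmm(glmm_data(rep(1, 2), c(0, 1), c(1L, 2L),
                                  c(10L, 10L))), "2 groups")
  one_arm <- glmm_data(rep(1:3, 2), rep(0, 6), rep(3L, 6), rep(10L, 6))
  expect_error(fit_glmm(one_arm), "both treatment levels")
  expect_error(glmm_data(1:2, c(0, 1), c(5L, 11L), c(10L, 10L)),
               "k <= m")
})
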