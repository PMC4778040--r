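test_that("percent-motile paired t matches the closed form and its limits", {
  # identical percentages everywhere: no difference is a certainty, not NaN
  set.seed(1)
  kin <- random_kinematics(5)
  same <- make_motility(kin, kin, motile = c(50, 60, 55, 40, 45) * 2L,
                        total = rep(200L, 5))
  res <- percent_motile_test(same)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$df, 4L)

  # 3 males, hand-checkable percent pairs (undyed, dyed):
  # (50,40), (60,45), (55,50)
  kin3 <- random_kinematics(3)
  samples <- make_motility(kin3, kin3,
                           motile = c(50L, 60L, 55L), total = rep(100L, 3))
  samples$motile_count[samples$treatment == "dyed"] <- c(40L, 45L, 50L)
  res <- percent_motile_test(samples)
  oracle <- paired_t_oracle(c(50, 60, 55) - c(40, 45, 50))
  expect_equal(res$statistic, oracle$statistic, tolerance = 1e-12)
  expect_equal(res$p_value, oracle$p_value, tolerance = 1e-12)
  expect_equal(res$df, 2L)

  expect_error(percent_motile_test(make_motility(kin3[1, , drop = FALSE],
                                                 kin3[1, , drop = FALSE])),
               "at least 2")
})

test_that("difference direction and the square-root transform are applied to
           raw values before differencing", {
  set.seed(2)
  und <- random_kinematics(4); dye <- und
  und$bcf <- rep(36, 4); dye$bcf <- rep(25, 4)
  s <- make_motility(und, dye)
  d <- compute_differences(s, transform = "bcf")
  expect_equal(unname(d$diffs[, "bcf"]), rep(1, 4))   # sqrt(36) - sqrt(25)
  expect_true(d$transformed[["bcf"]])
  expect_false(any(d$transformed[setdiff(names(d$transformed), "bcf")]))

  d0 <- compute_differences(make_motility(und, und))
  expect_true(all(d0$diffs == 0))

  neg <- und; neg$bcf <- c(-4, 2, 3, 4)
  expect_error(compute_differences(make_motility(und, neg),
                                   transform = "bcf"), "domain error")
  expect_error(compute_differences(s, transform = "velocity"),
               "unknown trait")
})

test_that("Shapiro-Wilk screen is calibrated under normality and powered
           against heavy tails", {
  set.seed(3)
  template <- compute_differences(generate_motility(seed = 1))
  n <- 18
  p_null <- replicate(60, {
    template$diffs[] <- stats::rnorm(n * 7)
    normality_screen(template)$p_value
  })
  rate <- mean(p_null <= 0.05)
  expect_gt(rate, 0.01); expect_lt(rate, 0.11)

  p_exp <- replicate(40, {
    template$diffs[] <- stats::rexp(n * 7)
    mean(normality_screen(template)$p_value <= 0.05)
  })
  expect_gt(mean(p_exp), 0.25)   # far above the nominal 5%

  template$diffs[, 1] <- 1       # constant column: W undefined
  expect_error(normality_screen(template), "degenerate input.*vap")
})

test_that("screen-transform-rescreen flags exactly the heavy-tailed trait and
           the transform restores normality", {
  # undyed/dyed BCF are squared normals: raw differences are skewed, square
  # roots are normal, so the workflow must flag bcf, transform it, and pass
  set.seed(8)
  n <- 18
  und <- random_kinematics(n); dye <- random_kinematics(n)
  und$bcf <- stats::rnorm(n, 6.0, 2)^2
  dye$bcf <- stats::rnorm(n, 5.0, 0.3)^2
  s <- make_motility(und, dye)
  d <- auto_transform_differences(s, alpha = 0.05)
  before <- attr(d, "screen_before")
  after <- attr(d, "screen_after")
  expect_identical(before$trait[before$flagged], "bcf")
  expect_true(d$transformed[["bcf"]])
  expect_false(after$flagged[after$trait == "bcf"])
})

test_that("correlation-matrix PCA matches analytic toys and an SVD oracle", {
  # two perfectly correlated variables: eigenvalues (2, 0), unit loadings
  toy <- structure(list(male_ids = sprintf("m%d", 1:6),
                        traits = c("a", "b"),
                        diffs = cbind(a = c(1, 2, 3, 4, 5, 6),
                                      b = 2 * c(1, 2, 3, 4, 5, 6)),
                        transformed = c(a = FALSE, b = FALSE)),
                   class = "paired_diffs")
  p <- pca_differences(toy)
  expect_equal(p$eigenvalues, c(2, 0), tolerance = 1e-12)
  expect_equal(unname(p$loadings[, 1]), c(1, 1), tolerance = 1e-12)
  expect_equal(p$retained, 1L)
  expect_equal(p$cum_var_pct[1], 100)

  # 5 x 3 toy against the independent SVD route (prcomp)
  set.seed(4)
  X <- matrix(stats::rnorm(15), 5, 3, dimnames = list(NULL, c("a", "b", "c")))
  toy3 <- structure(list(male_ids = sprintf("m%d", 1:5),
                         traits = colnames(X), diffs = X,
                         transformed = stats::setNames(rep(FALSE, 3),
                                                       colnames(X))),
                    class = "paired_diffs")
  p3 <- pca_differences(toy3)
  pr <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  expect_equal(p3$eigenvalues, pr$sdev^2, tolerance = 1e-10)
  expect_equal(abs(unclass(p3$loadings)),
               abs(pr$rotation %*% diag(pr$sdev)),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(abs(unclass(p3$scores)), abs(pr$x),
               tolerance = 1e-10, ignore_attr = TRUE)

  bad <- toy3; bad$diffs[, "b"] <- 7
  expect_error(pca_differences(bad), "zero-variance.*b")
})

test_that("PCA invariants: trace identity, reconstruction, row-order
           invariance, zero-mean scores", {
  for (s in 1:5) {
    mot <- generate_motility(seed = 300 + s)
    d <- compute_differences(mot)
    p <- pca_differences(d)
    expect_equal(sum(p$eigenvalues), 7, tolerance = 1e-10)
    expect_true(all(abs(p$loadings) <= 1 + 1e-8))
    expect_true(all(diff(p$eigenvalues) <= 1e-12))
    expect_lt(max(abs(colMeans(p$scores))), 1e-12)
    # reconstruction of the standardized matrix from all components
    V <- p$loadings %*% diag(1 / sqrt(p$eigenvalues))
    Z <- scale(d$diffs)
    expect_equal(p$scores %*% t(V), Z, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  mot <- generate_motility(seed = 77)
  perm <- mot[sample(nrow(mot)), ]
  class(perm) <- class(mot)
  p1 <- pca_differences(compute_differences(mot))
  p2 <- pca_differences(compute_differences(perm))
  expect_equal(p1$eigenvalues, p2$eigenvalues, tolerance = 1e-10)
  expect_equal(p1$scores[order(rownames(p1$scores)), ],
               p2$scores[order(rownames(p2$scores)), ], tolerance = 1e-8)
})

test_that("one-sample t on PC scores is structurally null yet correct for
           externally supplied scores", {
  for (s in 1:10) {
    p <- pca_differences(compute_differences(generate_motility(seed = 400 + s)))
    res <- pc_score_tests(p)
    expect_true(all(vapply(res, function(r) abs(r$statistic) < 1e-8,
                           logical(1))))
    expect_true(all(vapply(res, function(r) r$p_value > 1 - 1e-8,
                           logical(1))))
    expect_match(attr(res, "note"), "structural_zero_mean")
  }
  # scores with a forced nonzero mean match the closed-form one-sample t
  set.seed(5)
  fake <- pca_differences(compute_differences(generate_motility(seed = 6)))
  fake$scores[, 1] <- stats::rnorm(18, 0.5, 1)
  fake$retained <- 1L
  res <- pc_score_tests(fake)
  expect_length(res, 1L)
  oracle <- paired_t_oracle(fake$scores[, 1])
  expect_equal(res[[1]]$statistic, oracle$statistic, tolerance = 1e-12)
  expect_equal(res[[1]]$p_value, oracle$p_value, tolerance = 1e-12)
})

test_that("the assembled motility pipeline retains Kaiser components and
           reports every stage", {
  res <- motility_analysis(generate_motility(seed = 42))
  expect_s3_class(res, "motility_result")
  expect_true(all(res$pca$eigenvalues[res$pca$retained] > 1))
  expect_equal(res$percent_motile$df, 17L)
  expect_equal(nrow(res$screen_before), 7L)
  expect_true(length(res$pc_tests) >= 1)
})
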