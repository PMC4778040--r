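#' Assemble data for the binomial logit mixed model
#'
#' Builds the container consumed by [fit_glmm()] and [laplace_loglik()]: one
#' row per binomial observation, with a grouping factor (the competing pair in
#' the fertilisation design), a binary treatment indicator (1 = dyed), a
#' success count and a denominator.
#'
#' @param group grouping identifiers (coerced to factor); every group must
#'   contain at least one observation.
#' @param x treatment indicator, each element 0 or 1.
#' @param k integer success counts, `0 <= k <= m`.
#' @param m positive integer binomial denominators.
#' @return A `data.frame` of class `"glmm_data"` with columns
#'   `group`, `x`, `k`, `m`.
#' @examples
#' glmm_data(group = rep(1:3, each = 2), x = rep(0:1, 3),
#'           k = c(5, 3, 6, 4, 7, 6), m = rep(10, 6))
#' @export
glmm_data <- function(group, x, k, m) {
  n <- length(k)
  stopifnot(length(group) == n, length(x) == n, length(m) == n, n >= 1)
  if (!all(x %in% c(0, 1))) stop("treatment indicator `x` must be 0 or 1")
  k <- as.integer(round(k)); m <- as.integer(round(m))
  if (any(m <= 0)) stop("binomial denominators `m` must be positive")
  if (any(k < 0) || any(k > m)) stop("success counts must satisfy 0 <= k <= m")
  d <- data.frame(group = factor(group), x = as.numeric(x), k = k, m = m)
  class(d) <- c("glmm_data", "data.frame")
  d
}

## log(1 + exp(eta)) without overflow
log1pexp <- function(eta) pmax(eta, 0) + log1p(exp(-abs(eta)))

## binomial log-likelihood contributions at linear predictor eta,
## including the choose(m, k) constant so values are comparable with logLik()
## from other fitters
binom_ll <- function(k, m, eta) {
  lchoose(m, k) + k * eta - m * log1pexp(eta)
}

#' Laplace-approximated marginal log-likelihood of the random-intercept model
#'
#' For each group the 1-D integral over the Gaussian random intercept
#' \eqn{u_i \sim N(0, \sigma_u^2)} is approximated by Laplace's method around
#' the conditional mode, found by a safeguarded (step-halving) Newton
#' iteration on the concave penalized log-likelihood. At `sigma_u = 0` the
#' value equals the plain binomial GLM log-likelihood exactly.
#'
#' @param beta0,beta1 intercept and treatment coefficient on the logit scale.
#' @param sigma_u random-intercept standard deviation (logit scale), `>= 0`.
#' @param data a [glmm_data()] object.
#' @param modes logical; also return the per-group conditional modes.
#' @return The scalar log-likelihood, or (if `modes = TRUE`) a list with
#'   elements `loglik` and `modes`.
#' @export
laplace_loglik <- function(beta0, beta1, sigma_u, data, modes = FALSE) {
  stopifnot(inherits(data, "glmm_data"), sigma_u >= 0, is.finite(sigma_u))
  eta0 <- beta0 + beta1 * data$x
  if (sigma_u == 0) {
    ll <- sum(binom_ll(data$k, data$m, eta0))
    if (modes) return(list(loglik = ll,
                           modes = structure(rep(0, nlevels(data$group)),
                                             names = levels(data$group))))
    return(ll)
  }
  gidx <- as.integer(data$group)
  G <- nlevels(data$group)
  s2 <- sigma_u^2
  k <- data$k; m <- data$m

  pen_obj <- function(u) {  # per-group penalized conditional log-likelihood
    eta <- eta0 + u[gidx]
    as.numeric(rowsum(binom_ll(k, m, eta), gidx)) - u^2 / (2 * s2)
  }

  u <- rep(0, G)
  f <- pen_obj(u)
  for (it in seq_len(100L)) {
    eta <- eta0 + u[gidx]
    p <- stats::plogis(eta)
    g1 <- as.numeric(rowsum(k - m * p, gidx)) - u / s2
    if (max(abs(g1)) < 1e-10) break
    h <- -as.numeric(rowsum(m * p * (1 - p), gidx)) - 1 / s2  # < 0
    step <- g1 / h
    u_new <- u - step
    f_new <- pen_obj(u_new)
    ## step-halve any group whose penalized objective decreased
    for (hv in seq_len(40L)) {
      bad <- f_new < f - 1e-12
      if (!any(bad)) break
      step[bad] <- step[bad] / 2
      u_new[bad] <- u[bad] - step[bad]
      f_new[bad] <- pen_obj(u_new)[bad]
    }
    if (max(abs(u_new - u)) < 1e-12) { u <- u_new; f <- f_new; break }
    u <- u_new; f <- f_new
    if (it == 100L)
      stop("inner Newton iteration failed to converge for group(s): ",
           paste(levels(data$group)[abs(g1) >= 1e-6], collapse = ", "))
  }
  eta <- eta0 + u[gidx]
  p <- stats::plogis(eta)
  neg_h2 <- as.numeric(rowsum(m * p * (1 - p), gidx)) + 1 / s2
  ## Laplace: h(u_hat) + log phi(u_hat) terms folded in; the log(2*pi) from
  ## the integral cancels the one in the normal density
  ll <- sum(f - log(sigma_u) - 0.5 * log(neg_h2))
  if (modes) list(loglik = ll, modes = structure(u, names = levels(data$group)))
  else ll
}

## Joint Laplace over (u_i, e_i1..e_in) per group for the OLRE variant.
## The negated Hessian is an arrowhead matrix; the Newton step and its log
## determinant are solved by the Schur complement, vectorized across groups.
laplace_loglik_olre <- function(beta0, beta1, sigma_u, sigma_obs, data,
                                modes = FALSE) {
  stopifnot(inherits(data, "glmm_data"), sigma_u >= 0, sigma_obs >= 0)
  if (sigma_obs == 0) return(laplace_loglik(beta0, beta1, sigma_u, data, modes))
  if (sigma_u == 0) {
    ## each observation is its own independent 1-D integral
    d1 <- glmm_data(seq_len(nrow(data)), data$x, data$k, data$m)
    res <- laplace_loglik(beta0, beta1, sigma_obs, d1, modes = TRUE)
    if (modes) return(list(loglik = res$loglik,
                           modes = structure(rep(0, nlevels(data$group)),
                                             names = levels(data$group)),
                           obs_modes = unname(res$modes)))
    return(res$loglik)
  }
  eta0 <- beta0 + beta1 * data$x
  gidx <- as.integer(data$group)
  G <- nlevels(data$group)
  N <- nrow(data)
  su2 <- sigma_u^2; so2 <- sigma_obs^2
  k <- data$k; m <- data$m

  pen_obj <- function(u, e) {
    eta <- eta0 + u[gidx] + e
    as.numeric(rowsum(binom_ll(k, m, eta) - e^2 / (2 * so2), gidx)) -
      u^2 / (2 * su2)
  }

  u <- rep(0, G); e <- rep(0, N)
  f <- pen_obj(u, e)
  for (it in seq_len(200L)) {
    eta <- eta0 + u[gidx] + e
    p <- stats::plogis(eta)
    r <- k - m * p
    gu <- as.numeric(rowsum(r, gidx)) - u / su2
    ge <- r - e / so2
    if (max(abs(gu)) < 1e-10 && max(abs(ge)) < 1e-10) break
    w <- m * p * (1 - p)
    dj <- w + 1 / so2
    a <- as.numeric(rowsum(w, gidx)) + 1 / su2
    schur <- a - as.numeric(rowsum(w^2 / dj, gidx))
    su_step <- (gu - as.numeric(rowsum(w / dj * ge, gidx))) / schur
    se_step <- (ge - w * su_step[gidx]) / dj
    scale <- rep(1, G)
    for (hv in seq_len(40L)) {
      u_new <- u + scale * su_step
      e_new <- e + scale[gidx] * se_step
      f_new <- pen_obj(u_new, e_new)
      bad <- f_new < f - 1e-12
      if (!any(bad)) break
      scale[bad] <- scale[bad] / 2
    }
    u <- u + scale * su_step
    e <- e + scale[gidx] * se_step
    f <- pen_obj(u, e)
  }
  eta <- eta0 + u[gidx] + e
  p <- stats::plogis(eta)
  w <- m * p * (1 - p)
  dj <- w + 1 / so2
  schur <- (as.numeric(rowsum(w, gidx)) + 1 / su2) -
    as.numeric(rowsum(w^2 / dj, gidx))
  logdet <- as.numeric(rowsum(log(so2 * dj), gidx)) + log(su2 * schur)
  ll <- sum(f - 0.5 * logdet)
  if (modes) list(loglik = ll, modes = structure(u, names = levels(data$group)),
                  obs_modes = e)
  else ll
}

## Newton polish of the fixed effects at sigma = 0 (exact binomial loglik,
## analytic gradient/Hessian); brings boundary fits to machine precision
polish_glm <- function(b0, b1, data, iter = 30L) {
  X <- cbind(1, data$x)
  beta <- c(b0, b1)
  for (i in seq_len(iter)) {
    p <- stats::plogis(drop(X %*% beta))
    g <- crossprod(X, data$k - data$m * p)
    H <- crossprod(X * (data$m * p * (1 - p)), X)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    beta <- beta + drop(step)
    if (max(abs(beta)) > 20) return(c(b0, b1))  # separation: keep bounded fit
    if (max(abs(step)) < 1e-12) break
  }
  beta
}

## crude empirical-logit starting values (no external fitter involved)
glmm_start <- function(data) {
  p1 <- (sum(data$k[data$x == 1]) + 0.5) / (sum(data$m[data$x == 1]) + 1)
  p0 <- (sum(data$k[data$x == 0]) + 0.5) / (sum(data$m[data$x == 0]) + 1)
  c(beta0 = stats::qlogis(p0), beta1 = stats::qlogis(p1) - stats::qlogis(p0))
}

#' Fit the binomial logit mixed model by Laplace approximation
#'
#' Maximizes the Laplace-approximated marginal likelihood over the intercept,
#' treatment coefficient and log-parameterized random-effect standard
#' deviation(s), using box-constrained quasi-Newton iteration (`optim`
#' L-BFGS-B) from empirical-logit starting values. A fit whose pair-level SD
#' lands on the lower box bound is refit exactly at `sigma_u = 0` and flagged
#' as a boundary fit. The standard error of the treatment coefficient comes
#' from the inverse observed information of the fixed effects, with the
#' variance components held at their estimates.
#'
#' @param data a [glmm_data()] object with at least 2 groups and both
#'   treatment levels present.
#' @param olre logical; add an observation-level random effect (one
#'   independent Gaussian intercept per observation) to absorb
#'   overdispersion.
#' @param fix_sigma optional non-negative value at which to fix the pair-level
#'   SD instead of estimating it (used mainly for diagnostics; `0` gives the
#'   plain binomial GLM).
#' @return An object of class `"glmm_fit"`: a list with elements `beta0`,
#'   `beta1`, `sigma_u`, `sigma_obs` (`NA` unless `olre`), `loglik`,
#'   `se_beta0`, `se_beta1`, `conditional_modes`, `obs_modes`, `n_obs`,
#'   `n_groups`, `n_fixed`, `n_var`, `boundary`, `separation`, `olre`, and the
#'   fitting `data`.
#' @seealso [wald_test()], [dispersion()]
#' @export
fit_glmm <- function(data, olre = FALSE, fix_sigma = NULL) {
  stopifnot(inherits(data, "glmm_data"))
  if (nlevels(data$group) < 2) stop("need at least 2 groups")
  if (length(unique(data$x)) < 2) stop("both treatment levels must be present")
  separation <- any(vapply(c(0, 1), function(xx) {
    kk <- data$k[data$x == xx]; mm <- data$m[data$x == xx]
    all(kk == 0) || all(kk == mm)
  }, logical(1)))
  if (separation)
    warning("complete separation in a treatment arm; estimates held finite ",
            "by box constraints")

  start <- glmm_start(data)
  lo_ls <- log(1e-4)
  ll_fun <- if (olre) {
    function(b0, b1, su, so) laplace_loglik_olre(b0, b1, su, so, data)
  } else {
    function(b0, b1, su, so) laplace_loglik(b0, b1, su, data)
  }

  fixed_sigma <- !is.null(fix_sigma)
  if (fixed_sigma) stopifnot(length(fix_sigma) == 1, fix_sigma >= 0)

  nll <- function(par) {
    b0 <- par[1]; b1 <- par[2]
    su <- if (fixed_sigma) fix_sigma else exp(par[3])
    so <- if (olre) exp(par[length(par)]) else 0
    -ll_fun(b0, b1, su, so)
  }
  par0 <- c(start, if (!fixed_sigma) log_sigma_u = log(0.3),
            if (olre) log_sigma_obs = log(0.3))
  lower <- c(-20, -20, if (!fixed_sigma) lo_ls, if (olre) lo_ls)
  upper <- c(20, 20, if (!fixed_sigma) log(20), if (olre) log(20))
  opt <- stats::optim(par0, nll, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(factr = 1e4, pgtol = 1e-8,
                                     maxit = 500L))
  if (opt$convergence != 0 && opt$convergence != 52)
    stop("GLMM optimization did not converge: ", opt$convergence, " ",
         opt$message)
  if (-opt$value < -nll(par0) - 1e-8)
    stop("optimizer returned a worse likelihood than its starting value")
  par <- opt$par
  b0 <- par[1]; b1 <- par[2]
  su <- if (fixed_sigma) fix_sigma else exp(par[3])
  so <- if (olre) exp(par[length(par)]) else NA_real_
  boundary <- FALSE

  ## explicit sigma_u = 0 refit when the optimizer sits on the lower box bound
  if (!fixed_sigma && par[3] <= lo_ls + 1e-6) {
    nll0 <- function(b) -ll_fun(b[1], b[2], 0, if (olre) so else 0)
    opt0 <- stats::optim(c(b0, b1), nll0, method = "L-BFGS-B",
                         lower = c(-20, -20), upper = c(20, 20),
                         control = list(factr = 1e4, pgtol = 1e-8))
    if (-opt0$value >= -opt$value - 1e-8) {
      b0 <- opt0$par[1]; b1 <- opt0$par[2]; su <- 0
      opt$value <- opt0$value
      boundary <- TRUE
    }
  }
  if (olre && !is.na(so) && log(so) <= lo_ls + 1e-6) boundary <- TRUE

  ## at sigma = 0 the model is a plain binomial GLM: polish to full precision
  if (!olre && su == 0) {
    bb <- polish_glm(b0, b1, data)
    b0 <- bb[1]; b1 <- bb[2]
    opt$value <- -ll_fun(b0, b1, 0, 0)
  }

  loglik <- -opt$value
  cond <- if (olre) {
    laplace_loglik_olre(b0, b1, su, ifelse(is.na(so), 0, so), data,
                        modes = TRUE)
  } else {
    laplace_loglik(b0, b1, su, data, modes = TRUE)
  }

  ## observed information of the fixed effects at the optimum
  fe_nll <- function(b) -ll_fun(b[1], b[2], su, if (olre) so else 0)
  H <- stats::optimHess(c(b0, b1), fe_nll)
  V <- tryCatch(solve(H), error = function(e) matrix(NA_real_, 2, 2))
  se <- sqrt(pmax(diag(V), 0))
  if (!all(is.finite(se)) || se[2] == 0)
    warning("degenerate observed information; standard errors unreliable")

  structure(list(
    beta0 = unname(b0), beta1 = unname(b1), sigma_u = unname(su),
    sigma_obs = unname(so), loglik = loglik,
    se_beta0 = unname(se[1]), se_beta1 = unname(se[2]),
    conditional_modes = cond$modes,
    obs_modes = if (olre) cond$obs_modes else NULL,
    n_obs = nrow(data), n_groups = nlevels(data$group),
    n_fixed = 2L, n_var = if (olre) 2L else 1L,
    boundary = boundary, separation = separation, olre = olre,
    data = data), class = "glmm_fit")
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat("Binomial logit mixed model (Laplace approximation)\n")
  cat(sprintf("  observations: %d   groups: %d%s\n", x$n_obs, x$n_groups,
              if (x$olre) "   + observation-level random effect" else ""))
  cat(sprintf("  beta0 (intercept)   % .4f  (SE %.4f)\n", x$beta0, x$se_beta0))
  cat(sprintf("  beta1 (dye effect)  % .4f  (SE %.4f)\n", x$beta1, x$se_beta1))
  cat(sprintf("  sigma_u (pair SD)    %.4f%s\n", x$sigma_u,
              if (x$boundary) "  [boundary]" else ""))
  if (x$olre) cat(sprintf("  sigma_obs (OLRE SD)  %.4f\n", x$sigma_obs))
  cat(sprintf("  log-likelihood      % .3f\n", x$loglik))
  invisible(x)
}

#' Wald test of the treatment (dye) coefficient
#'
#' Computes `t = beta1 / se(beta1)` and refers it to a t distribution whose
#' residual degrees of freedom default to observations minus fixed effects
#' minus one pair-level variance component (20 - 2 - 1 = 17 in a 10-pair
#' reciprocal design). The large-sample Wald Z p-value is reported alongside.
#'
#' @param fit a converged [fit_glmm()] object.
#' @param df residual degrees of freedom; default `n_obs - n_fixed - 1`.
#' @param se_inflate multiplicative SE inflation factor, e.g.
#'   `sqrt(dispersion(fit)$dispersion_pearson)` for a quasi-likelihood-style
#'   sensitivity check. Default 1 (model-based SEs).
#' @return A `"test_result"` list: `statistic`, `df`, `p_value`, `estimate`,
#'   `stderr`, plus `z_value` and `p_value_z`.
#' @export
wald_test <- function(fit, df = NULL, se_inflate = 1) {
  stopifnot(inherits(fit, "glmm_fit"), se_inflate > 0)
  if (!is.finite(fit$se_beta1) || fit$se_beta1 <= 0)
    stop("degenerate fit: standard error of the dye coefficient is zero")
  if (is.null(df)) df <- fit$n_obs - fit$n_fixed - 1L
  stopifnot(df >= 1)
  t <- fit$beta1 / (fit$se_beta1 * se_inflate)
  res <- list(statistic = t, df = df,
              p_value = 2 * stats::pt(-abs(t), df),
              estimate = fit$beta1, stderr = fit$se_beta1 * se_inflate,
              z_value = t, p_value_z = 2 * stats::pnorm(-abs(t)))
  class(res) <- "test_result"
  res
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("t = %.4g, df = %.4g, two-sided p = %.4g (estimate %.4g, SE %.4g)\n",
              x$statistic, x$df, x$p_value, x$estimate, x$stderr))
  invisible(x)
}

## D/df arithmetic shared by dispersion() and its report printer
dispersion_ratio <- function(stat, df) {
  stopifnot(stat >= 0, df >= 1)
  stat / df
}

#' Overdispersion diagnostics for a fitted binomial mixed model
#'
#' Deviance and Pearson residuals are evaluated at the conditional fitted
#' probabilities (fixed effects plus conditional random-effect modes; plus
#' observation-level modes for the OLRE variant). Both the deviance-based and
#' Pearson-based dispersion ratios are reported; a well-specified binomial
#' model has dispersion near 1.
#'
#' @param fit a converged [fit_glmm()] object.
#' @param df residual degrees of freedom; default counts the pair-level
#'   variance component only: `n_obs - n_fixed - 1`.
#' @return A `"dispersion_report"` list: `residual_deviance`, `pearson_chi2`,
#'   `residual_df`, `dispersion_deviance`, `dispersion_pearson`.
#' @export
dispersion <- function(fit, df = NULL) {
  stopifnot(inherits(fit, "glmm_fit"))
  data <- fit$data
  eta <- fit$beta0 + fit$beta1 * data$x +
    fit$conditional_modes[as.integer(data$group)]
  if (fit$olre && !is.null(fit$obs_modes)) eta <- eta + fit$obs_modes
  p <- stats::plogis(eta)
  k <- data$k; m <- data$m
  ## deviance residuals: saturated term with 0*log(0) = 0
  dev_term <- function(a, b) ifelse(a == 0, 0, a * log(a / b))
  d2 <- 2 * (dev_term(k, m * p) + dev_term(m - k, m * (1 - p)))
  D <- sum(pmax(d2, 0))
  pearson <- sum((k - m * p)^2 / (m * p * (1 - p)))
  if (is.null(df)) df <- fit$n_obs - fit$n_fixed - 1L
  stopifnot(df >= 1)
  structure(list(residual_deviance = D, pearson_chi2 = pearson,
                 residual_df = as.integer(df),
                 dispersion_deviance = dispersion_ratio(D, df),
                 dispersion_pearson = dispersion_ratio(pearson, df)),
            class = "dispersion_report")
}

#' @export
print.dispersion_report <- function(x, ...) {
  cat(sprintf("residual deviance %.2f on %d df (dispersion %.2f); Pearson X2 %.2f (dispersion %.2f)\n",
              x$residual_deviance, x$residual_df, x$dispersion_deviance,
              x$pearson_chi2, x$dispersion_pearson))
  invisible(x)
}
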