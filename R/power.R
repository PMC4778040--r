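## Simulation-based power analysis: paired binomial experiments at a grid of
## dye effect sizes, each refit with the Laplace GLMM and tested with the
## Wald t at n_obs - 3 degrees of freedom.

#' Configuration for the power simulation
#'
#' Defaults reproduce the study's simulation design: 10 pairs, 100 eggs per
#' binomial observation, undyed share 0.5, pure binomial noise, two-sided
#' alpha 0.05 with 17 residual degrees of freedom, and 1000 replicates per
#' effect size over the grid 0.01–0.10.
#'
#' @param delta_grid probability-scale decreases in dyed success, each in
#'   `(0, baseline_share)`.
#' @param n_sims replicates per effect size.
#' @param n_pairs pairs per replicate.
#' @param eggs_scored eggs per binomial observation.
#' @param baseline_share undyed success probability.
#' @param alpha two-sided significance level.
#' @return A list of class `"power_config"`.
#' @export
power_config <- function(delta_grid = seq(0.01, 0.10, by = 0.01),
                         n_sims = 1000L, n_pairs = 10L, eggs_scored = 100L,
                         baseline_share = 0.5, alpha = 0.05) {
  stopifnot(n_sims >= 1, n_pairs >= 2, eggs_scored >= 1,
            baseline_share > 0, baseline_share < 1,
            all(delta_grid > 0), all(delta_grid < baseline_share),
            alpha > 0, alpha < 1)
  structure(list(delta_grid = sort(unique(delta_grid)),
                 n_sims = as.integer(n_sims), n_pairs = as.integer(n_pairs),
                 eggs_scored = as.integer(eggs_scored),
                 baseline_share = baseline_share, alpha = alpha),
            class = "power_config")
}

#' Simulate one paired experiment and test the dye effect
#'
#' Draws one paired-binomial dataset at the given effect size, fits the
#' random-intercept GLMM, and applies the two-sided Wald t at
#' `2 * n_pairs - 3` degrees of freedom. Replicates whose fit fails are
#' reported as non-converged, never as significant.
#'
#' @param delta probability-scale decrease in dyed success (0 allowed, for
#'   type-I calibration).
#' @param cfg a [power_config()].
#' @param seed integer seed for this replicate.
#' @return A list: `significant`, `converged`, `p_value`.
#' @export
simulate_one <- function(delta, cfg = power_config(), seed = 1L) {
  stopifnot(inherits(cfg, "power_config"))
  data <- generate_paired_binomial(cfg$n_pairs, cfg$eggs_scored,
                                   cfg$baseline_share, delta, seed)
  fit <- tryCatch(suppressWarnings(fit_glmm(data)), error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$se_beta1) || fit$se_beta1 <= 0)
    return(list(significant = FALSE, converged = FALSE, p_value = NA_real_))
  wt <- wald_test(fit)
  list(significant = wt$p_value < cfg$alpha, converged = TRUE,
       p_value = wt$p_value)
}

#' Estimate the power curve over the effect-size grid
#'
#' For each effect size, runs `n_sims` replicates with sub-seeds derived
#' deterministically from the master seed via [mix_seed()] (so the curve is
#' reproducible and independent of evaluation order). Power is the fraction of
#' converged replicates declared significant; its Monte-Carlo standard error
#' is `sqrt(p * (1 - p) / n_converged)`. Rows where more than 1% of
#' replicates failed to converge are flagged.
#'
#' @param cfg a [power_config()].
#' @param seed master integer seed.
#' @return A `data.frame` of class `"power_curve"` with columns `delta,
#'   power, mc_se, n_converged, n_sims, flagged`.
#' @export
power_curve <- function(cfg = power_config(), seed = 1L) {
  stopifnot(inherits(cfg, "power_config"))
  rows <- lapply(seq_along(cfg$delta_grid), function(di) {
    delta <- cfg$delta_grid[di]
    res <- vapply(seq_len(cfg$n_sims), function(ri) {
      r <- simulate_one(delta, cfg, seed = mix_seed(seed, di, ri))
      c(r$significant, r$converged)
    }, numeric(2))
    n_conv <- sum(res[2, ])
    p <- if (n_conv > 0) sum(res[1, ]) / n_conv else NA_real_
    data.frame(delta = delta, power = p,
               mc_se = if (n_conv > 0) sqrt(p * (1 - p) / n_conv)
                       else NA_real_,
               n_converged = as.integer(n_conv), n_sims = cfg$n_sims,
               flagged = n_conv < 0.99 * cfg$n_sims)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("power_curve", "data.frame")
  out
}

#' Bracket the minimum detectable effect at a target power
#'
#' Isotonic-smooths the estimated power curve (power is monotone in the true
#' effect; raw estimates wiggle within Monte-Carlo error) and returns the grid
#' interval over which the smoothed curve crosses the target.
#'
#' @param curve a [power_curve()] result.
#' @param target_power target power in (0, 1), default 0.8.
#' @return A list: `delta_lo`, `delta_hi`, `smoothed` (the isotonic power
#'   values).
#' @export
minimum_detectable_effect <- function(curve, target_power = 0.8) {
  stopifnot(inherits(curve, "power_curve"), target_power > 0,
            target_power < 1, nrow(curve) >= 2)
  iso <- stats::isoreg(curve$delta, curve$power)$yf
  if (all(iso >= target_power))
    stop("no crossing: power already at or above the target over the whole ",
         "grid (direction: below the smallest effect size)")
  if (all(iso < target_power))
    stop("no crossing: power below the target over the whole grid ",
         "(direction: beyond the largest effect size)")
  hi <- min(which(iso >= target_power))
  lo <- max(which(iso < target_power & seq_along(iso) < hi))
  list(delta_lo = curve$delta[lo], delta_hi = curve$delta[hi], smoothed = iso)
}

#' Closed-form normal-approximation power (reference check)
#'
#' Large-sample approximation to the power of the paired design at
#' probability-scale effect `delta`: the mean share difference has standard
#' error `sqrt(2 p (1 - p) / (m n))`, and the criterion is a two-sided t at
#' the residual degrees of freedom. Used as an analytic cross-check of the
#' simulation, not as the primary method.
#'
#' @param delta effect size on the probability scale.
#' @param cfg a [power_config()].
#' @return Approximate power.
#' @export
power_normal_approx <- function(delta, cfg = power_config()) {
  p <- cfg$baseline_share - delta / 2
  se <- sqrt(2 * p * (1 - p) / (cfg$eggs_scored * cfg$n_pairs))
  df <- 2L * cfg$n_pairs - 3L
  tcrit <- stats::qt(1 - cfg$alpha / 2, df)
  stats::pnorm(delta / se - tcrit) + stats::pnorm(-delta / se - tcrit)
}
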