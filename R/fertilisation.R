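## Reciprocal-cross assembly and the dye-effect GLMM comparison.
##
## Design: in cross A the focal male's sperm is dyed (his success X), in B the
## rival's is dyed (success Y), in C both are undyed and the overall
## fertilisation rate Z is measured. Under no dye effect, X = Z - Y, so the
## focal male's dyed share (from A) is compared with his undyed share implied
## by Z - Y, as paired binomial observations with a pair random intercept.

#' Assemble reciprocal-cross trials into paired competition observations
#'
#' Computes per pair: `X = labelled_A / fertilised_A` (focal dyed success),
#' the rival's dyed success `Y`, `Z = fertilised_C / eggs_scored_C`, and the
#' two binomial observations for the model — the dyed arm
#' `k = labelled_A over m = fertilised_A`, and the undyed arm as the focal
#' share implied by `Z - Y` converted to counts over `m = fertilised_C`
#' (round-half-even).
#'
#' Under the default `"fertilised"` share convention, `Y` is the rival's share
#' of fertilised eggs in B and the implied focal undyed share is `1 - Y`;
#' under `"scored"`, `Y = labelled_B / eggs_scored_B` is a proportion of all
#' scored eggs and the share is `(Z - Y) / Z`. A pair whose implied undyed
#' share is negative (`Z < Y`) is truncated to 0 and flagged, not dropped.
#' Pairs with `Z = 0` or no fertilised eggs in cross A are excluded with a
#' message.
#'
#' @param trials a `"fertilisation_trials"` object (complete A/B/C triplets).
#' @param share_convention see [analysis_config()].
#' @return A `data.frame` of class `"competition_pairs"` with columns
#'   `pair_id, X, Y, Z, share_dyed, share_undyed, k_dyed, m_dyed, k_undyed,
#'   m_undyed, flagged`.
#' @export
assemble_pairs <- function(trials,
                           share_convention = c("fertilised", "scored")) {
  stopifnot(inherits(trials, "fertilisation_trials"))
  share_convention <- match.arg(share_convention)
  get <- function(cross) {
    d <- trials[trials$cross == cross, ]
    d[order(d$pair_id), ]
  }
  A <- get("A_focal_dyed"); B <- get("B_rival_dyed"); C <- get("C_undyed")
  stopifnot(identical(A$pair_id, B$pair_id), identical(A$pair_id, C$pair_id))
  if (any(A$fertilised_count == 0 & A$labelled_count > 0))
    stop("data inconsistency: labelled eggs with zero fertilised eggs in ",
         "cross A for pair ",
         paste(A$pair_id[A$fertilised_count == 0 & A$labelled_count > 0],
               collapse = ", "))
  Z <- C$fertilised_count / C$eggs_scored
  keep <- Z > 0 & A$fertilised_count > 0 & B$fertilised_count > 0
  if (any(!keep))
    message("excluding pair(s) with no fertilised eggs in a cross: ",
            paste(A$pair_id[!keep], collapse = ", "))
  A <- A[keep, ]; B <- B[keep, ]; C <- C[keep, ]; Z <- Z[keep]
  X <- A$labelled_count / A$fertilised_count
  if (share_convention == "fertilised") {
    Y <- B$labelled_count / B$fertilised_count
    share_undyed <- 1 - Y
  } else {
    Y <- B$labelled_count / B$eggs_scored
    share_undyed <- (Z - Y) / Z
  }
  flagged <- share_undyed < 0
  share_undyed <- pmin(pmax(share_undyed, 0), 1)
  out <- data.frame(pair_id = A$pair_id, X = X, Y = Y, Z = Z,
                    share_dyed = X, share_undyed = share_undyed,
                    k_dyed = A$labelled_count, m_dyed = A$fertilised_count,
                    k_undyed = as.integer(round(share_undyed *
                                                  C$fertilised_count)),
                    m_undyed = C$fertilised_count,
                    flagged = flagged, stringsAsFactors = FALSE)
  class(out) <- c("competition_pairs", "data.frame")
  out
}

#' Dye-effect analysis of competitive fertilisation success
#'
#' Builds the paired binomial dataset (two observations per pair: dyed `x =
#' 1`, undyed `x = 0`), fits the random-pair-intercept binomial logit GLMM and
#' its observation-level random effect (OLRE) variant, tests the dye
#' coefficient with a Wald t at `n_obs - 3` degrees of freedom, and reports
#' deviance and Pearson dispersion for both fits plus the descriptive summary
#' of the per-pair share differences (mean, s.e.m., range).
#'
#' @param pairs a [assemble_pairs()] result with at least 2 pairs.
#' @param cfg an [analysis_config()].
#' @return A list of class `"dye_effect_result"`: `fit`, `test`,
#'   `dispersion`, `olre_fit`, `olre_test`, `olre_dispersion`, `pairs`,
#'   `summary`.
#' @export
dye_effect_analysis <- function(pairs, cfg = analysis_config()) {
  stopifnot(inherits(pairs, "competition_pairs"))
  if (nrow(pairs) < 2) stop("insufficient data: need at least 2 pairs")
  data <- glmm_data(group = rep(pairs$pair_id, 2),
                    x = rep(c(1, 0), each = nrow(pairs)),
                    k = c(pairs$k_dyed, pairs$k_undyed),
                    m = c(pairs$m_dyed, pairs$m_undyed))
  fit <- fit_glmm(data)
  olre_fit <- fit_glmm(data, olre = TRUE)
  d <- pairs$share_dyed - pairs$share_undyed
  structure(list(
    fit = fit, test = wald_test(fit), dispersion = dispersion(fit),
    olre_fit = olre_fit, olre_test = wald_test(olre_fit),
    olre_dispersion = dispersion(olre_fit),
    pairs = pairs,
    summary = list(mean_difference = mean(d),
                   sem = stats::sd(d) / sqrt(length(d)),
                   range = range(d),
                   mean_Z = mean(pairs$Z),
                   sem_Z = stats::sd(pairs$Z) / sqrt(length(pairs$Z)),
                   range_Z = range(pairs$Z),
                   n_pairs = nrow(pairs),
                   n_flagged = sum(pairs$flagged))),
    class = "dye_effect_result")
}

#' @export
print.dye_effect_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Competitive fertilisation, %d pairs (%d flagged Z < Y)\n",
              s$n_pairs, s$n_flagged))
  cat(sprintf("  overall fertilisation rate Z: mean %.3f +/- %.3f s.e.m., range %.3f-%.3f\n",
              s$mean_Z, s$sem_Z, s$range_Z[1], s$range_Z[2]))
  cat(sprintf("  dyed - undyed share: mean %.3f +/- %.3f s.e.m., range %.3f-%.3f\n",
              s$mean_difference, s$sem, s$range[1], s$range[2]))
  cat("Base model Wald t: "); print(x$test)
  cat("  "); print(x$dispersion)
  cat("OLRE model Wald t: "); print(x$olre_test)
  cat("  "); print(x$olre_dispersion)
  invisible(x)
}

#' @export
write_report.dye_effect_result <- function(x, path) {
  stem <- sub("\\.(csv|json)$", "", path)
  p1 <- paste0(stem, "_pairs.csv")
  p2 <- paste0(stem, "_model.json")
  write_csv_full(as.data.frame(x$pairs), p1)
  obj <- list(
    base = list(beta0 = x$fit$beta0, beta1 = x$fit$beta1,
                sigma_u = x$fit$sigma_u, loglik = x$fit$loglik,
                se_beta1 = x$fit$se_beta1, wald = unclass(x$test),
                dispersion = unclass(x$dispersion)),
    olre = list(beta0 = x$olre_fit$beta0, beta1 = x$olre_fit$beta1,
                sigma_u = x$olre_fit$sigma_u,
                sigma_obs = x$olre_fit$sigma_obs,
                loglik = x$olre_fit$loglik, se_beta1 = x$olre_fit$se_beta1,
                wald = unclass(x$olre_test),
                dispersion = unclass(x$olre_dispersion)),
    summary = x$summary)
  jsonlite::write_json(obj, p2, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(p1, p2))
}
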