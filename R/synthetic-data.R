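## Seeded generators emulating the two experiment types: 18 dyed/undyed CASA
## motility sample pairs, and 10 reciprocal-cross fertilisation triplets.
## All randomness is local: the caller's RNG state is saved and restored.

with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Deterministic sub-seed derivation
#'
#' Mixes a master seed with up to two stream indices into a new seed below
#' 2^31, so that replicate streams are reproducible and independent of loop
#' order. Uses a multiplicative congruential hash evaluated exactly in double
#' precision.
#'
#' @param master integer master seed.
#' @param i,j nonnegative stream indices (e.g. grid position and replicate).
#' @return A single integer seed in `[1, 2147483628]`.
#' @export
mix_seed <- function(master, i = 0L, j = 0L) {
  s <- as.numeric(master) %% 100003
  as.integer(((s * 69069 + as.numeric(i) * 30011 + as.numeric(j) * 7919) %%
                2147483628) + 1)
}

## default base-kinematic setup: means/SDs in CASA units, one shared
## correlation giving the strong inter-trait correlation structure
BASE_TRAITS <- c("vap", "vsl", "vcl", "alh", "bcf")
default_trait_means <- c(vap = 62, vsl = 48, vcl = 95, alh = 3.6, bcf = 35)
default_trait_sds <- c(vap = 10, vsl = 9, vcl = 14, alh = 0.7, bcf = 5)

#' Default between-male covariance of the base kinematic traits
#'
#' An equicorrelated covariance over (VAP, VSL, VCL, ALH, BCF) built from
#' per-trait SDs and a single correlation, reflecting the strong positive
#' correlation typically seen among CASA kinematics.
#'
#' @param sds named vector of per-trait SDs.
#' @param rho common inter-trait correlation.
#' @return A 5x5 covariance matrix.
#' @export
default_trait_cov <- function(sds = default_trait_sds, rho = 0.6) {
  R <- matrix(rho, length(sds), length(sds),
              dimnames = list(names(sds), names(sds)))
  diag(R) <- 1
  diag(sds) %*% R %*% diag(sds)
}

#' Configuration for the synthetic motility generator
#'
#' Describes the paired dyed/undyed CASA experiment: per-male base kinematics
#' drawn from a multivariate normal, two treatment measurements sharing the
#' male's base values plus correlated within-male measurement noise, and an
#' optional additive dye effect. The five base traits (VAP, VSL, VCL, ALH,
#' BCF) are sampled; the ratio traits STR = VSL/VCL and LIN = VAP/VCL are
#' derived, which enforces the kinematic ordering and `[0, 1]` ratio
#' invariants by construction (VCL is additionally taken as the maximum of the
#' three velocities).
#'
#' @param n_males number of males (default 18, the study design).
#' @param trait_means named 5-vector of base-trait means (`vap`, `vsl`, `vcl`
#'   in um/s, `alh` in um, `bcf` in Hz).
#' @param trait_cov 5x5 symmetric positive-semidefinite covariance of the
#'   between-male base traits.
#' @param dye_effect named 5-vector of additive shifts applied to the dyed
#'   measurement (default all 0 — the no-effect null).
#' @param noise_frac within-male measurement noise SD as a fraction of the
#'   between-male SD, applied with the same correlation structure.
#' @param pct_motile_mean mean proportion of motile cells.
#' @param cells_per_sample_mean mean number of motile cells recorded per
#'   sample (default 149, the study's reported mean).
#' @return A list of class `"motility_gen_config"`.
#' @export
motility_gen_config <- function(n_males = 18L,
                                trait_means = default_trait_means,
                                trait_cov = default_trait_cov(),
                                dye_effect = stats::setNames(
                                  numeric(5), BASE_TRAITS),
                                noise_frac = 0.35,
                                pct_motile_mean = 0.8,
                                cells_per_sample_mean = 149) {
  stopifnot(n_males >= 2, length(trait_means) == 5, length(dye_effect) == 5,
            all(dim(trait_cov) == c(5, 5)), noise_frac > 0,
            pct_motile_mean > 0, pct_motile_mean < 1,
            cells_per_sample_mean > 0)
  if (max(abs(trait_cov - t(trait_cov))) > 1e-8)
    stop("config error: trait_cov must be symmetric")
  if (min(eigen(trait_cov, symmetric = TRUE, only.values = TRUE)$values) <
        -1e-8 * max(abs(trait_cov)))
    stop("config error: trait_cov must be positive semi-definite")
  structure(list(n_males = as.integer(n_males),
                 trait_means = trait_means, trait_cov = trait_cov,
                 dye_effect = dye_effect, noise_frac = noise_frac,
                 pct_motile_mean = pct_motile_mean,
                 cells_per_sample_mean = cells_per_sample_mean),
            class = "motility_gen_config")
}

rmvn <- function(n, mu, Sigma) {
  ev <- eigen(Sigma, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), length(mu))
  sweep(matrix(stats::rnorm(n * length(mu)), n) %*% t(L), 2, mu, `+`)
}

#' Generate a synthetic paired motility dataset
#'
#' @param cfg a [motility_gen_config()].
#' @param seed integer seed; identical seeds give identical datasets.
#' @return A `"motility_samples"` data.frame with `2 * n_males` rows.
#' @export
generate_motility <- function(cfg = motility_gen_config(), seed = 1L) {
  stopifnot(inherits(cfg, "motility_gen_config"))
  with_local_seed(seed, {
    n <- cfg$n_males
    base <- rmvn(n, cfg$trait_means, cfg$trait_cov)
    noise_cov <- cfg$noise_frac^2 * cfg$trait_cov
    undyed <- base + rmvn(n, rep(0, 5), noise_cov)
    dyed <- base + rmvn(n, rep(0, 5), noise_cov) +
      matrix(cfg$dye_effect, n, 5, byrow = TRUE)
    build <- function(tr) {
      colnames(tr) <- BASE_TRAITS
      tr[, c("vap", "vsl")] <- pmax(tr[, c("vap", "vsl")], 1)
      tr[, "alh"] <- pmax(tr[, "alh"], 0.05)
      tr[, "bcf"] <- pmax(tr[, "bcf"], 0.5)
      tr[, "vcl"] <- pmax(tr[, "vcl"], tr[, "vap"], tr[, "vsl"])
      data.frame(vap = tr[, "vap"], vsl = tr[, "vsl"], vcl = tr[, "vcl"],
                 str = tr[, "vsl"] / tr[, "vcl"],
                 lin = tr[, "vap"] / tr[, "vcl"],
                 alh = tr[, "alh"], bcf = tr[, "bcf"])
    }
    pct <- stats::plogis(stats::qlogis(cfg$pct_motile_mean) +
                           stats::rnorm(n, 0, 0.4))
    total <- pmax(stats::rpois(n, cfg$cells_per_sample_mean /
                                 cfg$pct_motile_mean), 10L)
    ids <- sprintf("M%02d", seq_len(n))
    rows <- lapply(c("undyed", "dyed"), function(trt) {
      kin <- build(if (trt == "undyed") undyed else dyed)
      tot <- pmax(total + stats::rpois(n, 5) - 5L, 10L)
      mot <- stats::rbinom(n, tot, pct)
      cbind(data.frame(male_id = ids, treatment = trt, motile_count = mot,
                       total_count = tot, stringsAsFactors = FALSE), kin)
    })
    out <- do.call(rbind, rows)[, MOTILITY_COLS]
    out <- out[order(out$male_id, out$treatment), ]
    rownames(out) <- NULL
    validate_motility(out, "<generated>")
  })
}

#' Configuration for the synthetic fertilisation generator
#'
#' Describes the reciprocal-cross competitive fertilisation experiment. Per
#' pair, an overall fertilisation probability `z` is drawn from a scaled Beta
#' distribution with mean `fert_rate_mean` supported on `fert_rate_range`; the
#' focal male's share of fertilised eggs when undyed is
#' `plogis(qlogis(baseline_share) + u + e)` with pair intercept
#' `u ~ N(0, pair_sd^2)` and per-observation noise `e ~ N(0, obs_sd^2)`.
#' Dying a male's sperm lowers his share by `dye_delta` on the probability
#' scale (clamped to `[0.001, 0.999]`); set `dye_scale = "logit"` to apply the
#' decrease on the logit scale instead. Egg counts are then binomial: cross C
#' scores `eggs_scored` eggs at rate `z`; crosses A and B additionally label a
#' binomial share of the fertilised eggs for the dyed male.
#'
#' Defaults are the pure-binomial regime used for power simulation
#' (`eggs_scored = 100`, no pair or observation noise). The overdispersed
#' regime mimicking the observed dataset is available as
#' `fertilisation_gen_config(preset = "realistic")`: 50 eggs per trial,
#' `obs_sd = 0.42`, `pair_sd = 0.25`.
#'
#' @param n_pairs number of focal/rival/female triplets (default 10).
#' @param eggs_scored eggs scored per trial.
#' @param baseline_share focal male's expected share of fertilised eggs when
#'   undyed, in (0, 1).
#' @param dye_delta decrease in share when dyed; `0 <= dye_delta <
#'   baseline_share`.
#' @param pair_sd SD of pair-level logit intercepts.
#' @param obs_sd SD of observation-level logit noise (0 = pure binomial).
#' @param fert_rate_mean mean overall fertilisation probability (default
#'   0.733, the study's reported mean).
#' @param fert_rate_range support of the fertilisation probability (default
#'   0.46–0.94, the study's reported range).
#' @param dye_scale scale on which the dye decrease acts.
#' @param preset `"power"` (the defaults) or `"realistic"`.
#' @return A list of class `"fertilisation_gen_config"`.
#' @export
fertilisation_gen_config <- function(n_pairs = 10L, eggs_scored = 100L,
                                     baseline_share = 0.5, dye_delta = 0,
                                     pair_sd = 0, obs_sd = 0,
                                     fert_rate_mean = 0.733,
                                     fert_rate_range = c(0.46, 0.94),
                                     dye_scale = c("probability", "logit"),
                                     preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("power", "realistic"))
    if (preset == "realistic" && missing(eggs_scored)) eggs_scored <- 50L
    if (preset == "realistic" && missing(obs_sd)) obs_sd <- 0.42
    if (preset == "realistic" && missing(pair_sd)) pair_sd <- 0.25
  }
  stopifnot(n_pairs >= 1, eggs_scored >= 1, baseline_share > 0,
            baseline_share < 1, pair_sd >= 0, obs_sd >= 0,
            fert_rate_mean > 0, fert_rate_mean < 1,
            length(fert_rate_range) == 2, all(fert_rate_range > 0),
            all(fert_rate_range < 1),
            fert_rate_range[1] < fert_rate_range[2],
            fert_rate_mean >= fert_rate_range[1],
            fert_rate_mean <= fert_rate_range[2])
  if (dye_delta < 0 || dye_delta >= baseline_share)
    stop("config error: need 0 <= dye_delta < baseline_share")
  structure(list(n_pairs = as.integer(n_pairs),
                 eggs_scored = as.integer(eggs_scored),
                 baseline_share = baseline_share, dye_delta = dye_delta,
                 pair_sd = pair_sd, obs_sd = obs_sd,
                 fert_rate_mean = fert_rate_mean,
                 fert_rate_range = fert_rate_range,
                 dye_scale = match.arg(dye_scale)),
            class = "fertilisation_gen_config")
}

clamp_share <- function(p) pmin(pmax(p, 0.001), 0.999)

apply_dye <- function(share, delta, scale) {
  if (scale == "logit") clamp_share(stats::plogis(stats::qlogis(share) - delta))
  else clamp_share(share - delta)
}

## scaled Beta on fert_rate_range with the configured mean; concentration 4
## keeps draws spread over most of the range
draw_fert_rate <- function(n, cfg) {
  lo <- cfg$fert_rate_range[1]; hi <- cfg$fert_rate_range[2]
  mu <- (cfg$fert_rate_mean - lo) / (hi - lo)
  conc <- 4
  lo + (hi - lo) * stats::rbeta(n, mu * conc, (1 - mu) * conc)
}

#' Generate a synthetic reciprocal-cross fertilisation dataset
#'
#' @param cfg a [fertilisation_gen_config()].
#' @param seed integer seed; identical seeds give identical datasets.
#' @return A `"fertilisation_trials"` data.frame with `3 * n_pairs` rows
#'   (crosses A, B, C per pair).
#' @export
generate_fertilisation <- function(cfg = fertilisation_gen_config(),
                                   seed = 1L) {
  stopifnot(inherits(cfg, "fertilisation_gen_config"))
  with_local_seed(seed, {
    n <- cfg$n_pairs
    z <- draw_fert_rate(n, cfg)
    u <- stats::rnorm(n, 0, cfg$pair_sd)
    base_logit <- stats::qlogis(cfg$baseline_share)
    share_undyed <- function() {
      clamp_share(stats::plogis(base_logit + u + stats::rnorm(n, 0, cfg$obs_sd)))
    }
    p_A <- share_undyed()                 # focal undyed share in trial A
    p_B <- share_undyed()                 # focal undyed share in trial B
    share_focal_dyed <- apply_dye(p_A, cfg$dye_delta, cfg$dye_scale)
    share_rival_dyed <- apply_dye(1 - p_B, cfg$dye_delta, cfg$dye_scale)
    m <- cfg$eggs_scored
    fert_A <- stats::rbinom(n, m, z)
    fert_B <- stats::rbinom(n, m, z)
    fert_C <- stats::rbinom(n, m, z)
    lab_A <- stats::rbinom(n, fert_A, share_focal_dyed)
    lab_B <- stats::rbinom(n, fert_B, share_rival_dyed)
    ids <- sprintf("P%02d", seq_len(n))
    out <- data.frame(
      pair_id = rep(ids, each = 3),
      cross = rep(CROSS_LEVELS, n),
      eggs_scored = rep(m, 3 * n),
      fertilised_count = as.vector(rbind(fert_A, fert_B, fert_C)),
      labelled_count = as.vector(rbind(lab_A, lab_B, NA)),
      stringsAsFactors = FALSE)
    validate_fertilisation(out, "<generated>")
  })
}

#' Generate one paired-binomial power-simulation dataset
#'
#' The power simulation's observation model: per pair, one undyed binomial
#' draw at success probability `baseline_share` and one dyed draw at
#' `baseline_share - delta`, each over `eggs_scored` eggs, returned directly
#' as model-ready [glmm_data()].
#'
#' @param n_pairs number of pairs.
#' @param eggs_scored binomial denominator per observation.
#' @param baseline_share undyed success probability.
#' @param delta probability-scale decrease when dyed.
#' @param seed integer seed.
#' @return A [glmm_data()] object with `2 * n_pairs` rows.
#' @export
generate_paired_binomial <- function(n_pairs = 10L, eggs_scored = 100L,
                                     baseline_share = 0.5, delta = 0,
                                     seed = 1L) {
  stopifnot(delta >= 0, delta < baseline_share, baseline_share < 1)
  with_local_seed(seed, {
    k_undyed <- stats::rbinom(n_pairs, eggs_scored, baseline_share)
    k_dyed <- stats::rbinom(n_pairs, eggs_scored, baseline_share - delta)
    glmm_data(group = rep(seq_len(n_pairs), 2),
              x = rep(c(0, 1), each = n_pairs),
              k = c(k_undyed, k_dyed),
              m = rep(as.integer(eggs_scored), 2 * n_pairs))
  })
}
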