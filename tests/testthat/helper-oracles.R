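# Independent numerical oracles used across the suite. Nothing here calls the
# package's own integration or fitting code paths.

# Gauss-Hermite nodes/weights (weight exp(-z^2)) via Golub-Welsch:
# eigendecomposition of the symmetric tridiagonal Jacobi matrix.
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  ev <- eigen(J, symmetric = TRUE)
  ord <- order(ev$values)
  list(nodes = ev$values[ord],
       weights = (sqrt(pi) * ev$vectors[1, ]^2)[ord])
}

# Adaptive Gauss-Hermite marginal log-likelihood of the random-intercept
# binomial logit model: per group, center/scale the rule at the posterior mode
# found by generic 1-D optimization (stats::optimize), then log-sum-exp.
agq_loglik <- function(beta0, beta1, sigma, data, n_nodes = 51) {
  gh <- gauss_hermite(n_nodes)
  total <- 0
  for (g in levels(data$group)) {
    d <- data[data$group == g, , drop = FALSE]
    h <- function(u) {
      sum(stats::dbinom(d$k, d$m, stats::plogis(beta0 + beta1 * d$x + u),
                        log = TRUE)) +
        stats::dnorm(u, 0, sigma, log = TRUE)
    }
    uhat <- stats::optimize(h, c(-8 * sigma - 8, 8 * sigma + 8),
                            maximum = TRUE, tol = 1e-10)$maximum
    eps <- 1e-4
    h2 <- (h(uhat + eps) - 2 * h(uhat) + h(uhat - eps)) / eps^2
    shat <- 1 / sqrt(max(-h2, 1e-10))
    z <- uhat + sqrt(2) * shat * gh$nodes
    hv <- vapply(z, h, numeric(1)) + gh$nodes^2
    mx <- max(hv)
    total <- total + log(sqrt(2) * shat) + mx +
      log(sum(gh$weights * exp(hv - mx)))
  }
  total
}

# Closed-form paired / one-sample t oracle.
paired_t_oracle <- function(d) {
  n <- length(d)
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  list(statistic = t, df = n - 1, p_value = 2 * stats::pt(-abs(t), n - 1))
}

# Build a motility_samples object directly (bypassing the CSV reader) from a
# per-treatment list of kinematic matrices; counts default to benign values.
make_motility <- function(undyed, dyed, motile = NULL, total = NULL) {
  n <- nrow(undyed)
  ids <- sprintf("M%02d", seq_len(n))
  if (is.null(total)) total <- rep(180L, n)
  if (is.null(motile)) motile <- rep(140L, n)
  one <- function(kin, trt, mot, tot) {
    cbind(data.frame(male_id = ids, treatment = trt, motile_count = mot,
                     total_count = tot, stringsAsFactors = FALSE),
          as.data.frame(kin))
  }
  out <- rbind(one(undyed, "undyed", motile, total),
               one(dyed, "dyed", motile, total))
  class(out) <- c("motility_samples", "data.frame")
  out
}

# Random kinematic matrix satisfying the ordering invariants.
random_kinematics <- function(n) {
  vap <- stats::rnorm(n, 60, 8)
  vsl <- stats::rnorm(n, 45, 7)
  vcl <- pmax(stats::rnorm(n, 90, 10), vap, vsl)
  data.frame(vap = vap, vsl = vsl, vcl = vcl, str = vsl / vcl,
             lin = vap / vcl, alh = stats::rnorm(n, 3.5, 0.5),
             bcf = stats::rnorm(n, 35, 4))
}

# Hand-build a fertilisation_trials object (bypassing the reader).
make_trials <- function(pair_id, fert_A, lab_A, fert_B, lab_B, fert_C,
                        eggs = 100L) {
  n <- length(pair_id)
  out <- data.frame(
    pair_id = rep(pair_id, each = 3),
    cross = rep(c("A_focal_dyed", "B_rival_dyed", "C_undyed"), n),
    eggs_scored = rep(eggs, 3 * n),
    fertilised_count = as.vector(rbind(fert_A, fert_B, fert_C)),
    labelled_count = as.vector(rbind(lab_A, lab_B, NA)),
    stringsAsFactors = FALSE)
  class(out) <- c("fertilisation_trials", "data.frame")
  out
}

# Overdispersed paired binomial data: independent logit noise added to every
# observation on top of the pair layout.
with_overdispersion <- function(n_pairs = 10, m = 80, sd = 0.6, seed = 1) {
  set.seed(seed)
  g <- rep(seq_len(n_pairs), 2)
  x <- rep(c(0, 1), each = n_pairs)
  p <- stats::plogis(0.2 + stats::rnorm(2 * n_pairs, 0, sd))
  glmm_data(g, x, stats::rbinom(2 * n_pairs, m, p), rep(m, 2 * n_pairs))
}

# Minimal hand-built glmm_fit (for testing downstream arithmetic in
# isolation from the optimizer).
make_fit <- function(beta0 = 0, beta1 = 0, se_beta1 = 1, n_obs = 20L,
                     modes = NULL, data = NULL) {
  if (is.null(data)) {
    data <- glmm_data(rep(seq_len(n_obs / 2), 2),
                      rep(c(0, 1), each = n_obs / 2),
                      rep(5L, n_obs), rep(10L, n_obs))
  }
  if (is.null(modes))
    modes <- structure(rep(0, nlevels(data$group)),
                       names = levels(data$group))
  structure(list(beta0 = beta0, beta1 = beta1, sigma_u = 0,
                 sigma_obs = NA_real_, loglik = NA_real_, se_beta0 = 1,
                 se_beta1 = se_beta1, conditional_modes = modes,
                 obs_modes = NULL, n_obs = nrow(data),
                 n_groups = nlevels(data$group), n_fixed = 2L, n_var = 1L,
                 boundary = FALSE, separation = FALSE, olre = FALSE,
                 data = data), class = "glmm_fit")
}
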