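## CSV dialect shared by readers/writers: UTF-8, comma, header row.
## Enum spellings are case-insensitive on read, canonical on write.

TREATMENT_LEVELS <- c("dyed", "undyed")
CROSS_LEVELS <- c("A_focal_dyed", "B_rival_dyed", "C_undyed")
MOTILITY_COLS <- c("male_id", "treatment", "motile_count", "total_count",
                   "vap", "vsl", "vcl", "str", "lin", "alh", "bcf")
KINEMATIC_TRAITS <- c("vap", "vsl", "vcl", "str", "lin", "alh", "bcf")
FERT_COLS <- c("pair_id", "cross", "eggs_scored", "fertilised_count",
               "labelled_count")

check_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("format error in '", path, "': missing column(s) ",
         paste(missing, collapse = ", "))
}

as_numeric_col <- function(x, col, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & trimws(x) != "")
  if (length(bad))
    stop("parse error in '", path, "', column '", col, "': non-numeric value ",
         "at data row(s) ", paste(bad, collapse = ", "))
  out
}

match_enum <- function(x, levels, what, path) {
  idx <- match(tolower(trimws(x)), tolower(levels))
  ## single-letter shorthand accepted for crosses (A/B/C)
  if (anyNA(idx) && identical(levels, CROSS_LEVELS)) {
    short <- match(toupper(trimws(x)), substr(levels, 1, 1))
    idx[is.na(idx)] <- short[is.na(idx)]
  }
  if (anyNA(idx))
    stop("format error in '", path, "': invalid ", what, " value(s): ",
         paste(unique(x[is.na(idx)]), collapse = ", "))
  levels[idx]
}

#' Read a CASA motility summary table
#'
#' Reads per-male, per-treatment motility summaries: motile and total cell
#' counts plus the seven kinematic traits (VAP, VSL, VCL, STR, LIN, ALH, BCF).
#' Every male must appear exactly once per treatment; count and kinematic
#' invariants are checked (`motile_count <= total_count` is an error;
#' violations of the velocity ordering `vsl <= vcl`, `vap <= vcl` produce a
#' warning naming the rows).
#'
#' @param path CSV file with header columns `male_id, treatment,
#'   motile_count, total_count, vap, vsl, vcl, str, lin, alh, bcf`.
#' @return A `data.frame` of class `"motility_samples"`, one row per sample.
#' @export
read_motility_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  check_columns(df, MOTILITY_COLS, path)
  out <- data.frame(male_id = trimws(df$male_id),
                    treatment = match_enum(df$treatment, TREATMENT_LEVELS,
                                           "treatment", path),
                    stringsAsFactors = FALSE)
  for (col in setdiff(MOTILITY_COLS, c("male_id", "treatment")))
    out[[col]] <- as_numeric_col(df[[col]], col, path)
  validate_motility(out, path)
}

validate_motility <- function(out, path = "<data>") {
  bad <- which(out$motile_count > out$total_count | out$motile_count < 0 |
                 out$total_count <= 0)
  if (length(bad))
    stop("invariant violation in '", path, "': motile_count/total_count ",
         "ordering at row(s) ", paste(bad, collapse = ", "))
  neg <- which(apply(out[KINEMATIC_TRAITS] < 0, 1, any))
  if (length(neg))
    stop("invariant violation in '", path, "': negative kinematic value(s) ",
         "at row(s) ", paste(neg, collapse = ", "))
  ord <- which(out$vsl > out$vcl + 1e-9 | out$vap > out$vcl + 1e-9)
  if (length(ord))
    warning("kinematic ordering violated (vsl or vap exceeds vcl) at row(s) ",
            paste(ord, collapse = ", "))
  tab <- table(out$male_id, out$treatment)
  offenders <- rownames(tab)[rowSums(tab == 1) != 2 | rowSums(tab) != 2]
  if (length(offenders))
    stop("pairing error in '", path, "': male(s) without exactly one dyed ",
         "and one undyed sample: ", paste(offenders, collapse = ", "))
  class(out) <- c("motility_samples", "data.frame")
  out
}

#' Read a competitive fertilisation trial table
#'
#' Reads per-pair egg counts from the three reciprocal crosses: A (focal male
#' dyed), B (rival dyed), C (both undyed). `labelled_count` must be blank for
#' cross C (no dyed sperm present) and satisfy
#' `labelled_count <= fertilised_count <= eggs_scored` elsewhere. Each pair
#' must have exactly the crosses A, B and C.
#'
#' @param path CSV file with header `pair_id, cross, eggs_scored,
#'   fertilised_count, labelled_count`. Cross values may be spelled
#'   `A_focal_dyed`/`B_rival_dyed`/`C_undyed` or shortened to `A`/`B`/`C`
#'   (case-insensitive).
#' @return A `data.frame` of class `"fertilisation_trials"`, one row per
#'   trial, `labelled_count` `NA` for cross C.
#' @export
read_fertilisation_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  check_columns(df, FERT_COLS, path)
  out <- data.frame(pair_id = trimws(df$pair_id),
                    cross = match_enum(df$cross, CROSS_LEVELS, "cross", path),
                    eggs_scored = as_numeric_col(df$eggs_scored, "eggs_scored",
                                                 path),
                    fertilised_count = as_numeric_col(df$fertilised_count,
                                                      "fertilised_count", path),
                    labelled_count = as_numeric_col(df$labelled_count,
                                                    "labelled_count", path),
                    stringsAsFactors = FALSE)
  validate_fertilisation(out, path)
}

validate_fertilisation <- function(out, path = "<data>") {
  is_c <- out$cross == "C_undyed"
  if (any(!is.na(out$labelled_count[is_c])))
    stop("format error in '", path, "': labelled_count present for cross C ",
         "(pair ", paste(out$pair_id[is_c & !is.na(out$labelled_count)],
                         collapse = ", "), ")")
  if (any(is.na(out$labelled_count[!is_c])))
    stop("format error in '", path, "': labelled_count missing for a dyed ",
         "cross (pair ",
         paste(out$pair_id[!is_c & is.na(out$labelled_count)], collapse = ", "),
         ")")
  lab <- ifelse(is_c, 0, out$labelled_count)
  bad <- which(out$eggs_scored <= 0 | out$fertilised_count < 0 |
                 out$fertilised_count > out$eggs_scored |
                 lab < 0 | lab > out$fertilised_count)
  if (length(bad))
    stop("invariant violation in '", path, "': need labelled_count <= ",
         "fertilised_count <= eggs_scored at row(s) ",
         paste(bad, collapse = ", "))
  dup <- duplicated(out[c("pair_id", "cross")])
  if (any(dup))
    stop("duplication error in '", path, "': repeated (pair_id, cross): ",
         paste(unique(out$pair_id[dup]), collapse = ", "))
  tab <- table(out$pair_id, factor(out$cross, levels = CROSS_LEVELS))
  incomplete <- rownames(tab)[rowSums(tab == 1) != 3]
  if (length(incomplete))
    stop("completeness error in '", path, "': pair(s) without exactly one A, ",
         "B and C cross: ", paste(incomplete, collapse = ", "))
  class(out) <- c("fertilisation_trials", "data.frame")
  out
}

## full-precision CSV writer (doubles survive a read/write round trip)
write_csv_full <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
    if (is.logical(out[[j]])) out[[j]] <- as.character(out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
}

#' Write a motility or fertilisation table in the canonical dialect
#'
#' @param x a `motility_samples` or `fertilisation_trials` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  stopifnot(inherits(x, c("motility_samples", "fertilisation_trials")))
  write_csv_full(as.data.frame(x), path)
  invisible(path)
}

#' Write machine-readable reports of stage results
#'
#' Serializes a stage result to disk: tabular objects (power curves, per-pair
#' tables, data frames) as CSV at full numeric precision, model fits and test
#' results as JSON. `dye_effect_result` objects write both a per-pair CSV and
#' a model JSON next to each other.
#'
#' @param x a stage result.
#' @param path destination file (CSV or JSON depending on the object; for
#'   `dye_effect_result`, the stem used for `<stem>_pairs.csv` and
#'   `<stem>_model.json`).
#' @return the path(s) written, invisibly.
#' @export
write_report <- function(x, path) UseMethod("write_report")

#' @export
write_report.data.frame <- function(x, path) {
  write_csv_full(as.data.frame(x), path)
  invisible(path)
}

#' @export
write_report.glmm_fit <- function(x, path) {
  keep <- c("beta0", "beta1", "sigma_u", "sigma_obs", "loglik", "se_beta0",
            "se_beta1", "n_obs", "n_groups", "boundary", "separation", "olre")
  obj <- x[keep]
  obj$conditional_modes <- as.list(x$conditional_modes)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @export
write_report.test_result <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
write_report.dispersion_report <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Analysis configuration
#'
#' Bundles the tunable settings shared by the pipeline stages. Defaults follow
#' the study design: two-sided alpha 0.05 and principal components retained at
#' eigenvalue > 1 (Kaiser criterion on a correlation-matrix PCA).
#'
#' @param alpha significance level in (0, 1).
#' @param eigenvalue_threshold PC retention cutoff, > 0.
#' @param rng_seed integer seed recorded for provenance.
#' @param dispersion_flavour which dispersion ratio to emphasise in reports;
#'   both are always computed.
#' @param share_convention how the rival's success Y is expressed when
#'   deriving the focal male's undyed share: `"fertilised"` (Y is the rival's
#'   share of fertilised eggs in cross B; undyed share `1 - Y`) or `"scored"`
#'   (Y is a proportion of all scored eggs; undyed share `(Z - Y)/Z`).
#' @param power a [power_config()] for the simulation stage.
#' @return A list of class `"analysis_config"`.
#' @export
analysis_config <- function(alpha = 0.05, eigenvalue_threshold = 1.0,
                            rng_seed = 1L,
                            dispersion_flavour = c("both", "deviance",
                                                   "pearson"),
                            share_convention = c("fertilised", "scored"),
                            power = power_config()) {
  stopifnot(alpha > 0, alpha < 1, eigenvalue_threshold > 0)
  structure(list(alpha = alpha,
                 eigenvalue_threshold = eigenvalue_threshold,
                 rng_seed = as.integer(rng_seed),
                 dispersion_flavour = match.arg(dispersion_flavour),
                 share_convention = match.arg(share_convention),
                 power = power), class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' Unknown keys are rejected; keys under `power:` are passed to
#' [power_config()].
#'
#' @param path YAML file.
#' @return An [analysis_config()] object.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- setdiff(names(formals(analysis_config)), "power")
  extra <- setdiff(names(raw), c(known, "power"))
  if (length(extra))
    stop("unknown configuration key(s): ", paste(extra, collapse = ", "))
  pw <- do.call(power_config, as.list(raw$power))
  raw$power <- NULL
  do.call(analysis_config, c(raw, list(power = pw)))
}
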