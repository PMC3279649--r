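#' Construct and validate a two-follow-up trial dataset
#'
#' A `trial_dataset` holds per-participant records from a two-arm randomised
#' trial with outcomes measured at two follow-up times, a record of which
#' contact attempt (if any) elicited the second outcome, and website-use
#' (compliance) counts.  The object is a `data.frame` with attributes `K`
#' (maximum number of contact attempts) and `covariates` (ordered names of
#' the complete baseline covariates).
#'
#' Required columns:
#' \describe{
#'   \item{id}{unique participant identifier (character).}
#'   \item{z}{randomised arm, 0 = control, 1 = intervention.}
#'   \item{y1, y2}{log-scale outcomes at the two follow-up times; `NA` when
#'     unobserved.  The recommended transform is [log_transform()].}
#'   \item{r1, r2}{response indicators, 0/1, consistent with `y1`/`y2`.}
#'   \item{wave2}{attempt index (1..`attempts_made`) at which `y2` was
#'     obtained, `NA` for never-responders.}
#'   \item{attempts_made}{number of contact attempts actually issued
#'     (defaults to `K` for never-responders; early refusal truncates it).}
#'   \item{logins_1mo, pages_1mo, logins_3mo, pages_3mo}{non-negative
#'     website-use counts from server logs (always complete).}
#' }
#' plus the baseline covariate columns named in `covariates`.
#'
#' @param df data.frame with the columns above.
#' @param K maximum number of contact attempts (default 3).
#' @param covariates character vector of baseline covariate column names.
#' @return A validated `trial_dataset`.
#' @export
trial_dataset <- function(df, K = 3L,
                          covariates = intersect(dyd_covariate_names(),
                                                 names(df))) {
  stopifnot(is.data.frame(df), K >= 1)
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  required <- c("id", "z", "y1", "y2", "r1", "r2", "wave2", "attempts_made",
                "logins_1mo", "pages_1mo", "logins_3mo", "pages_3mo")
  missing_cols <- setdiff(c(required, covariates), names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  df$id <- as.character(df$id)
  out <- df[, c(required, covariates)]
  attr(out, "K") <- as.integer(K)
  attr(out, "covariates") <- covariates
  class(out) <- c("trial_dataset", "data.frame")
  validate_trial_dataset(out)
  out
}

#' Baseline covariate names used by the bundled trial emulation
#' @return Character vector of column names.
#' @export
dyd_covariate_names <- function() {
  c("age", "male", "degree", "audit_c", "eq5d", "confidence", "base_y")
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat(sprintf("trial_dataset: %d participants (%d intervention, %d control), K = %d attempts\n",
              nrow(x), sum(x$z == 1), sum(x$z == 0), attr(x, "K")))
  cat(sprintf("  3-month response: %.0f%% intervention, %.0f%% control\n",
              100 * mean(x$r2[x$z == 1]), 100 * mean(x$r2[x$z == 0])))
  cat("  covariates:", paste(attr(x, "covariates"), collapse = ", "), "\n")
  invisible(x)
}

validate_trial_dataset <- function(data) {
  K <- attr(data, "K")
  if (anyDuplicated(data$id))
    stop("participant ids are not unique")
  if (!all(data$z %in% c(0, 1)))
    stop("z must be 0 (control) or 1 (intervention)")
  bad <- function(cond, what) {
    idx <- which(cond)
    if (length(idx))
      stop("record ", data$id[idx[1]], ": ", what, call. = FALSE)
  }
  bad(xor(data$r1 == 1, !is.na(data$y1)), "r1 inconsistent with presence of y1")
  bad(xor(data$r2 == 1, !is.na(data$y2)), "r2 inconsistent with presence of y2")
  bad(data$r2 == 1 & (is.na(data$wave2) | data$wave2 < 1 |
                        data$wave2 > data$attempts_made),
      "responder must have wave2 in 1..attempts_made")
  bad(data$r2 == 0 & !is.na(data$wave2), "never-responder must have wave2 = NA")
  bad(data$attempts_made < 1 | data$attempts_made > K,
      "attempts_made must lie in 1..K")
  for (v in c("logins_1mo", "pages_1mo", "logins_3mo", "pages_3mo"))
    bad(is.na(data[[v]]) | data[[v]] < 0, paste(v, "must be a non-negative count"))
  for (v in attr(data, "covariates"))
    bad(is.na(data[[v]]), paste("baseline covariate", v, "must be complete"))
  invisible(data)
}

#' Log-transform weekly consumption units
#'
#' Outcomes are analysed as `log(units + 1)` so that zero consumption maps
#' to zero and the effect scale is a ratio of geometric means (of units + 1).
#'
#' @param units non-negative consumption, units/week.
#' @return `log(units + 1)`.
#' @export
log_transform <- function(units) {
  if (any(units < 0, na.rm = TRUE)) stop("units must be non-negative")
  log(units + 1)
}

#' Read a trial dataset from CSV
#'
#' Missing outcomes are stored as empty fields, never numeric sentinels.
#' `schema` maps the canonical column names to those in the file; it may be
#' a named list/vector, or a path to a YAML/JSON file with entries
#' `columns:` (the map) and optionally `K:`.
#'
#' @param path CSV file path.
#' @param schema optional column-name map or YAML/JSON config path.
#' @param K maximum attempts (overridden by the schema file if it sets one).
#' @param covariates baseline covariate names (post-renaming).
#' @return A validated [trial_dataset()].
#' @export
read_trial_csv <- function(path, schema = NULL, K = 3L,
                           covariates = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.character(schema) && length(schema) == 1 && file.exists(schema)) {
    cfg <- read_config(schema)
    if (!is.null(cfg$K)) K <- as.integer(cfg$K)
    schema <- cfg$columns
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(id = "character"))
  if (!is.null(schema)) {
    schema <- unlist(schema)
    pos <- match(schema, names(df))
    if (anyNA(pos))
      stop("schema names column(s) absent from file: ",
           paste(schema[is.na(pos)], collapse = ", "))
    names(df)[pos] <- names(schema)
  }
  if (is.null(covariates)) covariates <- intersect(dyd_covariate_names(), names(df))
  trial_dataset(df, K = K, covariates = covariates)
}

#' Write a trial dataset to CSV
#'
#' Round-trips with [read_trial_csv()]: absent outcomes are written as empty
#' fields.
#'
#' @param data a `trial_dataset`.
#' @param path output file path.
#' @export
write_trial_csv <- function(data, path) {
  stopifnot(inherits(data, "trial_dataset"))
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, na = "")
  invisible(path)
}

read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' Tabulate second outcomes by the attempt that elicited them
#'
#' Produces, per arm, counts, percentages of the arm total, and mean/SD of
#' the second outcome among participants who responded at each contact
#' attempt, plus the never-responders and an overall responder total.
#' SDs use the n - 1 denominator.
#'
#' @param data a `trial_dataset`.
#' @return A `wave_summary`: data.frame with columns `arm`, `wave`, `n`,
#'   `percent`, `mean`, `sd`.
#' @export
wave_summary <- function(data) {
  stopifnot(inherits(data, "trial_dataset"))
  K <- attr(data, "K")
  rows <- list()
  for (arm in c(1, 0)) {
    sub <- data[data$z == arm, ]
    n_arm <- nrow(sub)
    for (k in seq_len(K)) {
      y <- sub$y2[!is.na(sub$wave2) & sub$wave2 == k]
      rows[[length(rows) + 1L]] <- data.frame(
        arm = arm, wave = as.character(k), n = length(y),
        percent = 100 * length(y) / n_arm,
        mean = if (length(y)) mean(y) else NA_real_,
        sd = if (length(y) > 1) stats::sd(y) else NA_real_)
    }
    nev <- sum(sub$r2 == 0)
    rows[[length(rows) + 1L]] <- data.frame(
      arm = arm, wave = "never", n = nev, percent = 100 * nev / n_arm,
      mean = NA_real_, sd = NA_real_)
    yall <- sub$y2[sub$r2 == 1]
    rows[[length(rows) + 1L]] <- data.frame(
      arm = arm, wave = "total", n = n_arm, percent = 100,
      mean = if (length(yall)) mean(yall) else NA_real_,
      sd = if (length(yall) > 1) stats::sd(yall) else NA_real_)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("wave_summary", "data.frame")
  out
}

#' Combine per-wave summaries into a responder total
#'
#' The count-weighted mean of per-wave means equals the overall responder
#' mean; the pooled SD combines within- and between-wave variation with
#' n - 1 denominators throughout.  Useful when only a published wave table
#' is available rather than record-level data.
#'
#' @param n per-wave responder counts.
#' @param mean per-wave outcome means.
#' @param sd per-wave outcome SDs (optional).
#' @return List with `n`, `mean` and (when SDs supplied) `sd`.
#' @export
wave_totals <- function(n, mean, sd = NULL) {
  stopifnot(length(n) == length(mean), all(n >= 0))
  N <- sum(n)
  m <- sum(n * mean) / N
  out <- list(n = N, mean = m)
  if (!is.null(sd)) {
    ss <- sum((n - 1) * sd^2) + sum(n * (mean - m)^2)
    out$sd <- sqrt(ss / (N - 1))
  }
  out
}

#' Present a log-scale effect as a ratio of geometric means
#'
#' The trial's effect scale: `exp(beta)` is the ratio of geometric mean
#' (units + 1) consumption, intervention / control, with a normal-theory
#' confidence interval.
#'
#' @param beta log-scale effect.
#' @param se standard error of `beta` (>= 0).
#' @param level confidence level in (0, 1).
#' @param method label recording which analysis produced the estimate.
#' @param adjusted logical flag: covariate-adjusted analysis?
#' @param alpha_hat,gamma_hat optional intercept / covariate coefficients.
#' @return An `effect_estimate` list with `beta`, `se`, `ci_low`, `ci_high`
#'   (log scale), `ratio`, `ratio_ci` (exp scale), `method`, `adjusted`.
#' @export
effect_to_ratio <- function(beta, se, level = 0.95, method = "unspecified",
                            adjusted = FALSE, alpha_hat = NULL,
                            gamma_hat = NULL) {
  if (!is.na(se) && se < 0) stop("se must be non-negative")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  zq <- stats::qnorm(1 - (1 - level) / 2)
  est <- list(beta = beta, se = se,
              ci_low = beta - zq * se, ci_high = beta + zq * se,
              ratio = exp(beta),
              ratio_ci = exp(c(beta - zq * se, beta + zq * se)),
              level = level, method = method, adjusted = adjusted,
              alpha_hat = alpha_hat, gamma_hat = gamma_hat)
  class(est) <- "effect_estimate"
  est
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("%s (%s): ratio %.3f (%.3f to %.3f)  [beta %.4f, se %.4f]\n",
              x$method, if (isTRUE(x$adjusted)) "adjusted" else "unadjusted",
              x$ratio, x$ratio_ci[1], x$ratio_ci[2], x$beta, x$se))
  invisible(x)
}

# design matrix (1, z [, x]) shared by the regression-type fits
design_matrix <- function(data, adjust) {
  X <- cbind(`(Intercept)` = 1, z = data$z)
  if (adjust) {
    covs <- attr(data, "covariates")
    X <- cbind(X, as.matrix(as.data.frame(data)[, covs, drop = FALSE]))
  }
  X
}
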