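#' Compliance definitions for the structural mean model
#'
#' Binary rule: a complier logged in at least `logins_min` times or hit
#' more than `pages_min` pages in the first month.  Continuous rule:
#' pages in the first month, capped at `cap` and expressed per `unit`
#' pages.  Control-arm compliance is 0 by construction (the control
#' website's use is ignored, i.e. its causal effect is taken as zero).
#'
#' @param mode `"binary"` or `"continuous"`.
#' @param logins_min,pages_min binary-rule thresholds (defaults 2 and 10).
#' @param cap,unit continuous-rule cap and denominator (defaults 300 and
#'   100 pages).
#' @return A `compliance_definition`.
#' @export
compliance_definition <- function(mode = c("binary", "continuous"),
                                  logins_min = 2, pages_min = 10,
                                  cap = 300, unit = 100) {
  mode <- match.arg(mode)
  structure(list(mode = mode, logins_min = logins_min,
                 pages_min = pages_min, cap = cap, unit = unit),
            class = "compliance_definition")
}

#' Compute per-participant compliance
#'
#' @param data a [trial_dataset()].
#' @param defn a [compliance_definition()].
#' @return Numeric vector `d` over records (attribute `complier_fraction`
#'   gives the intervention-arm complier proportion under the binary rule).
#' @export
define_compliance <- function(data, defn = compliance_definition()) {
  stopifnot(inherits(data, "trial_dataset"),
            inherits(defn, "compliance_definition"))
  d <- if (defn$mode == "binary") {
    as.numeric(data$z == 1 &
                 (data$logins_1mo >= defn$logins_min |
                    data$pages_1mo > defn$pages_min))
  } else {
    ifelse(data$z == 1, pmin(data$pages_1mo, defn$cap) / defn$unit, 0)
  }
  attr(d, "complier_fraction") <- complier_fraction(data)
  attr(d, "defn") <- defn
  d
}

# just-identified (weighted) IV: instrument matrix Z, regressor matrix X,
# same dimension; robust sandwich covariance
iv_solve <- function(Z, X, y, w = NULL) {
  if (is.null(w)) w <- rep(1, length(y))
  A <- crossprod(Z * w, X)
  beta <- solve(A, crossprod(Z * w, y))
  e <- drop(y - X %*% beta)
  B <- crossprod(Z * (w * e))
  Ai <- solve(A)
  n <- length(y); p <- ncol(X)
  V <- Ai %*% B %*% t(Ai) * n / (n - p)
  dimnames(V) <- list(colnames(X), colnames(X))
  list(coefficients = drop(beta), vcov = V, residuals = e)
}

smm_result <- function(psi, se, method, defn, adjust, level, extra = list()) {
  unit_label <- if (defn$mode == "binary") "CACE (compliers vs non-compliers)"
  else sprintf("per %g pages downloaded (capped at %g)", defn$unit, defn$cap)
  fit <- c(list(psi = psi, se = se, method = method,
                compliance = defn$mode, unit_label = unit_label,
                effect = effect_to_ratio(psi, se, level,
                                         method = sprintf("SMM %s, %s", defn$mode, method),
                                         adjusted = adjust)),
           extra)
  class(fit) <- "smm_fit"
  fit
}

#' @export
print.smm_fit <- function(x, ...) {
  cat(sprintf("Structural mean model (%s; %s)\n", x$unit_label, x$method))
  print(x$effect)
  if (!is.null(x$first_stage_t))
    cat(sprintf("  first-stage instrument t = %.1f\n", x$first_stage_t))
  invisible(x)
}

#' Instrumental-variable SMM fit on complete cases
#'
#' Solves the structural-mean estimating equations via just-identified IV
#' (two-stage least squares) with randomised arm as the instrument for
#' compliance, optional exogenous baseline covariates, and robust sandwich
#' standard errors.  Valid under MCAR given the covariates.
#'
#' @param data a [trial_dataset()].
#' @param d compliance vector from [define_compliance()].
#' @param adjust include baseline covariates as exogenous regressors?
#' @param level confidence level.
#' @param weights optional per-record weights (internal use by the IPW
#'   method).
#' @return An `smm_fit` with `psi`, `se`, `vcov`, `first_stage_t`, and an
#'   `effect` presentation (`exp(psi)` = ratio of geometric means per unit
#'   compliance).
#' @export
fit_iv_complete <- function(data, d, adjust = FALSE, level = 0.95,
                            weights = NULL) {
  stopifnot(length(d) == nrow(data))
  defn <- attr(d, "defn") %||% compliance_definition("continuous")
  cc <- data$r2 == 1
  covX <- if (adjust) design_matrix(data, TRUE)[, -(1:2), drop = FALSE] else NULL
  X <- cbind(`(Intercept)` = 1, d = d, covX)[cc, , drop = FALSE]
  Z <- cbind(`(Intercept)` = 1, z = data$z, covX)[cc, , drop = FALSE]
  # first stage: instrument strength
  f1 <- stats::lm.fit(Z, X[, "d"])
  v1 <- sandwich_ols(Z, f1$residuals)
  t1 <- f1$coefficients[["z"]] / sqrt(v1["z", "z"])
  if (abs(f1$coefficients[["z"]]) < 1e-10)
    stop("instrument does not predict compliance (first-stage coefficient 0)")
  w <- if (is.null(weights)) NULL else weights[cc]
  sol <- iv_solve(Z, X, data$y2[cc], w)
  smm_result(sol$coefficients[["d"]], sqrt(sol$vcov["d", "d"]),
             if (is.null(weights)) "complete-case IV" else "IPW IV",
             defn, adjust, level,
             list(vcov = sol$vcov, first_stage_t = t1,
                  coefficients = sol$coefficients))
}

#' IV SMM with stabilised inverse-probability-of-response weights
#'
#' Logistic response models `p(r | x, z = 1, d)` and `p(r | x, z = 1)` are
#' fitted in the intervention arm; the stabilised weight for an
#' intervention-arm complete case is their ratio of fitted values, and
#' control-arm weights are 1 (compliance does not vary there).  Weighted IV
#' follows with robust standard errors.  Fitted probabilities are floored
#' at `p_floor` (with a warning) to keep weights bounded.
#'
#' @inheritParams fit_iv_complete
#' @param p_floor positivity floor for fitted response probabilities.
#' @return An `smm_fit`; the weights used are attached as `weights`.
#' @export
fit_iv_ipw <- function(data, d, adjust = FALSE, level = 0.95,
                       p_floor = 0.01) {
  stopifnot(length(d) == nrow(data))
  w <- rep(1, nrow(data))
  arm1 <- data$z == 1
  if (any(data$r2[arm1] == 0)) {
    covs <- attr(data, "covariates")
    X1 <- cbind(1, as.matrix(as.data.frame(data)[arm1, covs, drop = FALSE]))
    r1v <- data$r2[arm1]
    p_den <- stats::glm.fit(cbind(X1, d = d[arm1]), r1v,
                            family = stats::binomial())$fitted.values
    p_num <- stats::glm.fit(X1, r1v, family = stats::binomial())$fitted.values
    if (any(pmin(p_den, p_num) < p_floor))
      warning("fitted response probabilities below ", p_floor,
              " were floored; positivity is questionable")
    w[arm1] <- pmax(p_num, p_floor) / pmax(p_den, p_floor)
  }
  fit <- fit_iv_complete(data, d, adjust, level, weights = w)
  fit$method <- "IPW IV"
  fit$weights <- w
  fit
}

#' Adjusted-treatment-received SMM fit
#'
#' Stage 1 regresses compliance on arm (and covariates) over *all*
#' randomised participants -- compliance comes from server logs and is
#' complete; stage 2 regresses the observed outcome on compliance, the
#' stage-1 residual and the covariates among complete cases.  Equivalent
#' to IV on complete data; valid under MAR.  The reported second-stage
#' standard error ignores uncertainty in the estimated residuals and may
#' be an underestimate (`se_caveat` is set); a nonparametric bootstrap is
#' available.
#'
#' @inheritParams fit_iv_complete
#' @param bootstrap draw bootstrap standard errors instead?
#' @param B bootstrap replicates (default 500).
#' @param seed bootstrap seed.
#' @return An `smm_fit` with `se_caveat = TRUE` unless bootstrapped.
#' @export
fit_iv_atr <- function(data, d, adjust = FALSE, level = 0.95,
                       bootstrap = FALSE, B = 500L, seed = 1L) {
  stopifnot(length(d) == nrow(data))
  defn <- attr(d, "defn") %||% compliance_definition("continuous")
  atr_psi <- function(data, d) {
    covX <- if (adjust) design_matrix(data, TRUE)[, -(1:2), drop = FALSE] else NULL
    Z1 <- cbind(1, z = data$z, covX)
    e1 <- stats::lm.fit(Z1, d)$residuals
    cc <- data$r2 == 1
    X2 <- cbind(1, d = d, ehat = e1, covX)[cc, , drop = FALSE]
    f2 <- stats::lm.fit(X2, data$y2[cc])
    list(psi = f2$coefficients[["d"]],
         vc = sandwich_ols(X2, f2$residuals)["d", "d"])
  }
  main <- atr_psi(data, d)
  if (bootstrap) {
    set.seed(seed)
    n <- nrow(data)
    reps <- vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      db <- data[idx, ]
      atr_psi(db, d[idx])$psi
    }, numeric(1))
    se <- stats::sd(reps)
  } else se <- sqrt(main$vc)
  fit <- smm_result(main$psi, se, if (bootstrap) "ATR (bootstrap SE)" else "ATR",
                    defn, adjust, level)
  fit$se_caveat <- !bootstrap
  fit
}

#' IV SMM with multiply imputed outcomes
#'
#' Imputes the outcomes with the website-use auxiliaries in the imputation
#' model (the richer of the two standard specifications), runs the
#' complete-data IV fit on each completed dataset, and pools the causal
#' parameter by Rubin's rules.
#'
#' @inheritParams fit_iv_complete
#' @param spec an [imputation_spec()]; `aux = TRUE` by default here.
#' @return An `smm_fit` with pooling components `W`, `B`, `T`, `df`.
#' @export
fit_iv_mi <- function(data, d, adjust = FALSE,
                      spec = imputation_spec(aux = TRUE), level = 0.95) {
  stopifnot(length(d) == nrow(data))
  defn <- attr(d, "defn") %||% compliance_definition("continuous")
  imp <- impute_chained(data, spec)
  res <- lapply(imp$datasets, function(di) {
    di$r2 <- 1L  # completed data: every record enters the IV fit
    f <- fit_iv_complete(di, d, adjust, level)
    list(est = f$psi, var = f$se^2)
  })
  pooled <- pool_rubin(vapply(res, `[[`, numeric(1), "est"),
                       vapply(res, `[[`, numeric(1), "var"),
                       dfcom = nrow(data) - 2, level = level)
  fit <- smm_result(pooled$estimate, pooled$se, "MI IV", defn, adjust, level,
                    list(W = pooled$W, B = pooled$B, T = pooled$T,
                         df = pooled$df, M = spec$M))
  fit$effect$ci_low <- pooled$ci[1]
  fit$effect$ci_high <- pooled$ci[2]
  fit$effect$ratio_ci <- exp(pooled$ci)
  fit
}
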