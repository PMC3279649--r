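#' Specification of the repeated-attempts selection model
#'
#' The selection model identifies the association between the second
#' outcome and response from the repeated contact attempts: the log odds
#' ratio for response per unit outcome (`delta`) is assumed common across
#' attempts, while per-attempt intercepts are free.  `variant` chooses a
#' common `delta` across arms or arm-specific `delta0`, `delta1`.
#'
#' @param variant `"common_delta"` or `"by_arm_delta"`.
#' @param adjust include baseline covariates in both the outcome and the
#'   response models?
#' @param nodes number of Gauss-Hermite quadrature nodes used to integrate
#'   over the unobserved outcomes of never-responders (default 40).
#' @param reltol optimiser relative tolerance.
#' @param max_iter optimiser iteration cap.
#' @return An `alho_spec`.
#' @export
alho_spec <- function(variant = c("common_delta", "by_arm_delta"),
                      adjust = FALSE, nodes = 40L, reltol = 1e-10,
                      max_iter = 1000L) {
  variant <- match.arg(variant)
  stopifnot(nodes >= 10)
  structure(list(variant = variant, adjust = adjust,
                 nodes = as.integer(nodes), reltol = reltol,
                 max_iter = as.integer(max_iter)),
            class = "alho_spec")
}

# numerically stable log(1 / (1 + exp(-x))), vectorised; much faster than
# plogis(x, log.p = TRUE) inside the optimiser loop
log_sigmoid <- function(x) pmin(x, 0) - log1p(exp(-abs(x)))

.gh_env <- new.env(parent = emptyenv())
gauss_hermite_cached <- function(n) {
  key <- as.character(n)
  if (is.null(.gh_env[[key]])) .gh_env[[key]] <- pracma::gaussHermite(n)
  .gh_env[[key]]
}

# parameter layout helpers -------------------------------------------------
alho_layout <- function(data, spec) {
  U <- design_matrix(data, spec$adjust)          # outcome design (1, z[, x])
  Ur <- U[, -1, drop = FALSE]                    # response covariates (z[, x])
  K <- attr(data, "K")
  n_delta <- if (spec$variant == "by_arm_delta") 2L else 1L
  list(U = U, Ur = Ur, K = K, n_delta = n_delta,
       p_out = ncol(U), p_resp = ncol(Ur),
       names = c(paste0("out:", colnames(U)), "log_sigma",
                 paste0("lambda", seq_len(K)),
                 paste0("resp:", colnames(Ur)),
                 if (n_delta == 2) c("delta0", "delta1") else "delta"))
}

alho_unpack <- function(par, lay) {
  i <- 0L
  xi <- par[i + seq_len(lay$p_out)]; i <- i + lay$p_out
  sigma <- exp(par[i + 1L]); i <- i + 1L
  lambda <- par[i + seq_len(lay$K)]; i <- i + lay$K
  eta <- par[i + seq_len(lay$p_resp)]; i <- i + lay$p_resp
  delta <- par[i + seq_len(lay$n_delta)]
  list(xi = xi, sigma = sigma, lambda = lambda, eta = eta, delta = delta)
}

#' Observed-data log-likelihood of the repeated-attempts model
#'
#' A responder at attempt `k` contributes the normal outcome density times
#' the probability of failing attempts `1..k-1` and succeeding at `k`,
#' where the per-attempt response probability is
#' `logit p_j(y) = lambda_j + eta' u + delta_z * y`.  A never-responder
#' contributes the integral of the normal outcome density times the
#' probability of failing all attempts actually made, evaluated by
#' Gauss-Hermite quadrature under `y = mu_i + sqrt(2) * sigma * t`.
#'
#' @param par parameter vector in the order outcome coefficients,
#'   log residual SD, attempt intercepts, response covariate coefficients,
#'   delta (or `delta0`, `delta1`).
#' @param data a [trial_dataset()].
#' @param spec an [alho_spec()].
#' @return Scalar log-likelihood.
#' @export
alho_loglik <- function(par, data, spec = alho_spec()) {
  alho_loglik_impl(par, alho_layout(data, spec), data, spec)
}

alho_loglik_impl <- function(par, lay, data, spec) {
  th <- alho_unpack(par, lay)
  gh <- gauss_hermite_cached(spec$nodes)
  mu <- drop(lay$U %*% th$xi)
  lin_r <- drop(lay$Ur %*% th$eta)
  delta_z <- if (lay$n_delta == 2L) th$delta[data$z + 1L] else rep(th$delta, nrow(data))

  ll <- 0
  resp <- data$r2 == 1
  if (any(resp)) {
    y <- data$y2[resp]
    eta_y <- lin_r[resp] + delta_z[resp] * y
    wv <- data$wave2[resp]
    contrib <- stats::dnorm(y, mu[resp], th$sigma, log = TRUE)
    for (k in seq_len(lay$K)) {
      lp <- th$lambda[k] + eta_y
      at_k <- wv == k
      contrib[at_k] <- contrib[at_k] + log_sigmoid(lp[at_k])
      past_k <- wv > k
      contrib[past_k] <- contrib[past_k] + log_sigmoid(-lp[past_k])
    }
    ll <- ll + sum(contrib)
  }
  if (any(!resp)) {
    nr <- which(!resp)
    yq <- outer(mu[nr], sqrt(2) * th$sigma * gh$x, `+`)   # n_nr x nodes
    lsurv <- matrix(0, length(nr), spec$nodes)
    att <- data$attempts_made[nr]
    for (k in seq_len(lay$K)) {
      active <- att >= k
      lp <- th$lambda[k] + lin_r[nr][active] + delta_z[nr][active] * yq[active, , drop = FALSE]
      lsurv[active, ] <- lsurv[active, ] + log_sigmoid(-lp)
    }
    # row-wise log-sum-exp keeps the integral finite even when every
    # survival probability underflows
    mx <- lsurv[cbind(seq_len(nrow(lsurv)), max.col(lsurv))]
    log_ints <- mx + log(exp(lsurv - mx) %*% gh$w) - 0.5 * log(pi)
    if (any(is.nan(log_ints)))
      stop("non-finite never-responder contribution, first at record ",
           data$id[nr[which(is.nan(log_ints))[1]]])
    ll <- ll + sum(log_ints)
  }
  as.numeric(ll)
}

# delta = 0 decoupled starting fit: normal regression among responders plus
# a sequential (attempt-level) logistic response model
alho_start <- function(data, spec) {
  lay <- alho_layout(data, spec)
  resp <- data$r2 == 1
  f_out <- stats::lm.fit(lay$U[resp, , drop = FALSE], data$y2[resp])
  sigma <- sqrt(sum(f_out$residuals^2) / sum(resp))
  # expand to one row per attempt made
  n_att <- ifelse(resp, data$wave2, data$attempts_made)
  idx <- rep(seq_len(nrow(data)), n_att)
  att <- unlist(lapply(n_att, seq_len))
  succ <- as.integer(resp[idx] & att == n_att[idx])
  Xr <- cbind(stats::model.matrix(~ factor(att, levels = seq_len(lay$K)) - 1),
              lay$Ur[idx, , drop = FALSE])
  f_resp <- stats::glm.fit(Xr, succ, family = stats::binomial())
  list(par = c(f_out$coefficients, log(sigma),
               f_resp$coefficients, rep(0, lay$n_delta)),
       loglik_decoupled = sum(stats::dnorm(data$y2[resp],
                                           drop(lay$U[resp, , drop = FALSE] %*% f_out$coefficients),
                                           sigma, log = TRUE)) +
         sum(succ * stats::plogis(drop(Xr %*% f_resp$coefficients), log.p = TRUE) +
               (1 - succ) * stats::plogis(-drop(Xr %*% f_resp$coefficients), log.p = TRUE)))
}

#' Fit the repeated-attempts selection model by full maximum likelihood
#'
#' Maximises [alho_loglik()] jointly over the normal outcome model and the
#' sequential response model, starting from the decoupled `delta = 0` fit
#' (responders-only regression plus attempt-level logistic regression).
#' Standard errors come from the inverse numerical Hessian at the optimum.
#'
#' @param data a [trial_dataset()]; must contain both responders and
#'   never-responders.
#' @param spec an [alho_spec()].
#' @param level confidence level.
#' @param hessian compute the numerical Hessian for standard errors?
#'   Skipping it (e.g. inside simulation loops that only need point
#'   estimates) roughly halves the fitting time; SEs are then `NA`.
#' @return An `alho_fit` with `coefficients` (named), `vcov`, `logLik`,
#'   `delta` (named vector with SEs in `se_delta`), `spec`, and `effect`
#'   (the outcome-model arm coefficient as an [effect_to_ratio()]).
#' @export
fit_alho <- function(data, spec = alho_spec(), level = 0.95, hessian = TRUE) {
  stopifnot(inherits(data, "trial_dataset"))
  if (!any(data$r2 == 0) || !any(data$r2 == 1))
    stop("need both responders and never-responders to identify the model")
  lay <- alho_layout(data, spec)
  st <- alho_start(data, spec)
  neg <- function(p) -alho_loglik_impl(p, lay, data, spec)
  opt <- stats::optim(st$par, neg, method = "BFGS",
                      control = list(maxit = spec$max_iter,
                                     reltol = spec$reltol),
                      hessian = hessian)
  if (opt$convergence != 0)
    stop("likelihood maximisation did not converge (code ", opt$convergence, ")")
  vc <- if (hessian) tryCatch(solve(opt$hessian), error = function(e) NULL)
  hess_pd <- !is.null(vc) && all(diag(vc) > 0)
  if (hessian && !hess_pd)
    warning("Hessian not positive definite at the optimum; standard errors ",
            "unavailable or unreliable -- profile the likelihood to check")
  par <- opt$par
  names(par) <- lay$names
  if (!is.null(vc)) dimnames(vc) <- list(lay$names, lay$names)
  th <- alho_unpack(par, lay)
  iz <- which(lay$names == "out:z")
  idel <- grep("^delta", lay$names)
  se <- if (hess_pd) sqrt(diag(vc)) else rep(NA_real_, length(par))
  fit <- list(coefficients = par, vcov = vc, logLik = -opt$value,
              sigma = th$sigma, lambda = th$lambda,
              delta = par[idel], se_delta = se[idel],
              hessian_pd = hess_pd, spec = spec, K = lay$K,
              start_loglik = st$loglik_decoupled,
              effect = effect_to_ratio(unname(par[iz]), unname(se[iz]), level,
                                       method = if (lay$n_delta == 2) "attempts model (arm-specific delta)"
                                       else "attempts model (common delta)",
                                       adjusted = spec$adjust))
  class(fit) <- "alho_fit"
  fit
}

#' @export
print.alho_fit <- function(x, ...) {
  cat("Repeated-attempts selection model (full likelihood)\n")
  dl <- paste(sprintf("%s = %.3f (se %.3f)", names(x$delta), x$delta,
                      x$se_delta), collapse = ", ")
  cat(" informative-missingness:", dl, "\n")
  print(x$effect)
  invisible(x)
}

#' Wald tests for departure from MAR in an arm-specific attempts-model fit
#'
#' @param fit an `alho_fit` with `variant = "by_arm_delta"`.
#' @return An `alho_tests` list: `z_delta1`/`p_delta1` (intervention-arm
#'   delta = 0), `z_equal`/`p_equal` (equality of the two deltas), and
#'   `chisq_2df`/`p_2df` (joint test that both are zero).
#' @export
alho_tests <- function(fit) {
  stopifnot(inherits(fit, "alho_fit"))
  if (fit$spec$variant != "by_arm_delta")
    stop("arm-specific tests need a fit with variant = 'by_arm_delta'")
  if (!fit$hessian_pd) stop("no valid covariance available for Wald tests")
  idel <- grep("^delta", names(fit$coefficients))
  d <- fit$coefficients[idel]
  V <- fit$vcov[idel, idel]
  z1 <- d[["delta1"]] / sqrt(V["delta1", "delta1"])
  dd <- d[["delta0"]] - d[["delta1"]]
  v_dd <- V["delta0", "delta0"] + V["delta1", "delta1"] -
    2 * V["delta0", "delta1"]
  z_eq <- if (v_dd > 0) dd / sqrt(v_dd) else 0
  chi2 <- drop(t(d) %*% solve(V) %*% d)
  out <- list(z_delta1 = z1, p_delta1 = 2 * stats::pnorm(-abs(z1)),
              z_equal = z_eq, p_equal = 2 * stats::pnorm(-abs(z_eq)),
              chisq_2df = chi2, p_2df = stats::pchisq(chi2, 2, lower.tail = FALSE))
  class(out) <- "alho_tests"
  out
}

#' @export
print.alho_tests <- function(x, ...) {
  cat(sprintf("delta1 = 0:        z = %.2f, p = %.3f\n", x$z_delta1, x$p_delta1))
  cat(sprintf("delta0 = delta1:   z = %.2f, p = %.3f\n", x$z_equal, x$p_equal))
  cat(sprintf("both zero (2 df):  chisq = %.2f, p = %.3f\n", x$chisq_2df, x$p_2df))
  invisible(x)
}

#' Inverse-probability weights from a fitted attempts model (experimental)
#'
#' Exports, for each responder, the inverse of the fitted probability of
#' having responded by their observed attempt.  Weighted complete-case
#' analysis is an alternative to the full-likelihood fit, but the weights
#' are estimated with considerable uncertainty which a naive weighted
#' analysis ignores; treat the resulting standard errors with caution.
#'
#' @param fit an `alho_fit`.
#' @param data the `trial_dataset` the model was fitted to.
#' @return Numeric vector (length `nrow(data)`): weights for responders,
#'   `NA` for never-responders.
#' @export
alho_ipw_weights <- function(fit, data) {
  lay <- alho_layout(data, fit$spec)
  th <- alho_unpack(fit$coefficients, lay)
  delta_z <- if (lay$n_delta == 2L) th$delta[data$z + 1L] else rep(th$delta, nrow(data))
  lin_r <- drop(lay$Ur %*% th$eta)
  w <- rep(NA_real_, nrow(data))
  resp <- which(data$r2 == 1)
  p_resp <- rep(0, length(resp))
  surv <- rep(1, length(resp))
  for (k in seq_len(lay$K)) {
    pk <- stats::plogis(th$lambda[k] + lin_r[resp] + delta_z[resp] * data$y2[resp])
    active <- data$wave2[resp] >= k
    p_resp[active] <- p_resp[active] + surv[active] * pk[active]
    surv[active] <- surv[active] * (1 - pk[active])
  }
  w[resp] <- 1 / p_resp
  w
}
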