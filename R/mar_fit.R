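#' Complete-case analysis of the second outcome
#'
#' Ordinary least squares of `y2` on arm (and baseline covariates when
#' `adjust = TRUE`) among participants with `y2` observed, with
#' heteroscedasticity-robust (HC1) standard errors.  Valid under
#' covariate-dependent MCAR.
#'
#' @param data a [trial_dataset()].
#' @param adjust include the baseline covariates?
#' @param level confidence level.
#' @return An [effect_to_ratio()] `effect_estimate` for the arm coefficient.
#' @export
fit_complete_case <- function(data, adjust = FALSE, level = 0.95) {
  stopifnot(inherits(data, "trial_dataset"))
  cc <- data[data$r2 == 1, ]
  if (!all(c(0, 1) %in% cc$z))
    stop("no complete cases in one arm; complete-case fit impossible")
  X <- design_matrix(cc, adjust)
  fit <- stats::lm.fit(X, cc$y2)
  vc <- sandwich_ols(X, fit$residuals)
  effect_to_ratio(fit$coefficients[["z"]], sqrt(vc["z", "z"]), level,
                  method = "complete-case", adjusted = adjust,
                  alpha_hat = fit$coefficients[["(Intercept)"]],
                  gamma_hat = fit$coefficients[setdiff(names(fit$coefficients),
                                                       c("(Intercept)", "z"))])
}

# HC1-type sandwich for an OLS fit given design and residuals
sandwich_ols <- function(X, e) {
  n <- nrow(X); p <- ncol(X)
  XtXi <- solve(crossprod(X))
  meat <- crossprod(X * e)
  vc <- XtXi %*% meat %*% XtXi * n / (n - p)
  dimnames(vc) <- list(colnames(X), colnames(X))
  vc
}

# Long-format stacking of the jointly modelled variables.  Outcomes keep
# their missingness; auxiliary website-use counts enter as log(1 + count),
# rescaled to the observed SD of y2 so the equal-variance working model is
# reasonable.  Individuals with neither outcome observed are dropped.
stack_responses <- function(data, adjust, aux) {
  vars <- list(y1 = data$y1, y2 = data$y2)
  if (length(aux)) {
    s2 <- stats::sd(data$y2, na.rm = TRUE)
    for (a in aux) {
      v <- log1p(data[[a]])
      vars[[paste0("log_", a)]] <- v * s2 / stats::sd(v)
    }
  }
  keep <- !(is.na(data$y1) & is.na(data$y2))
  U <- design_matrix(data, adjust)[keep, , drop = FALSE]
  Y <- sapply(vars, function(v) v[keep])
  list(U = U, Y = as.matrix(Y), J = length(vars), vars = names(vars),
       z = data$z[keep])
}

# solve restricted to identified coefficients (a variable with no observed
# rows leaves its block of the information matrix empty)
active_idx <- function(A) which(diag(A) > 1e-12)
solve_active <- function(A, b) {
  act <- active_idx(A)
  out <- rep(0, length(b))
  out[act] <- solve(A[act, act, drop = FALSE], b[act])
  out
}
invert_active <- function(A) {
  act <- active_idx(A)
  V <- matrix(NA_real_, nrow(A), ncol(A))
  V[act, act] <- solve(A[act, act, drop = FALSE])
  V
}

# observed-variable pattern id per individual
pattern_ids <- function(Y) {
  obs <- !is.na(Y)
  apply(obs, 1, function(r) paste(which(r), collapse = ","))
}

#' Linear generalised estimating equations for the two outcomes
#'
#' Fits time-specific mean models (coefficients free to differ between the
#' two follow-up times, i.e. full time-by-covariate interactions) by
#' estimating equations with an unstructured working correlation -- for two
#' time points identical to exchangeable -- and a common residual variance.
#' Standard errors are robust (sandwich, with an `n/(n - p)` small-sample
#' factor).  Each participant contributes their observed rows only;
#' participants with neither outcome are dropped.  Optional complete
#' auxiliary website-use variables (named count columns) are log(1+count)
#' transformed, rescaled to the outcome SD, and stacked as extra response
#' rows so that missingness may depend on them.
#'
#' @param data a [trial_dataset()].
#' @param adjust include baseline covariates in every mean model?
#' @param aux character vector of compliance count columns to stack (e.g.
#'   `c("pages_1mo", "logins_1mo")`), or `NULL`.
#' @param level confidence level.
#' @param tol relative parameter-change convergence tolerance.
#' @param max_iter iteration cap; exceeding it is an error carrying the
#'   last iterate.
#' @return A `gee_fit` with elements `coefficients` (named list per
#'   variable), `sigma2`, `corr` (working correlation), `vcov` (sandwich),
#'   and `effect` (the [effect_to_ratio()] presentation of the arm effect
#'   on `y2`).
#' @export
fit_gee <- function(data, adjust = FALSE, aux = NULL, level = 0.95,
                    tol = 1e-8, max_iter = 200L) {
  st <- stack_responses(data, adjust, aux)
  U <- st$U; Y <- st$Y; J <- st$J
  p_u <- ncol(U); p <- p_u * J
  pat <- pattern_ids(Y)
  groups <- split(seq_len(nrow(Y)), pat)
  R <- diag(J); sigma2 <- stats::var(as.vector(Y), na.rm = TRUE)
  beta <- rep(0, p)
  obs <- !is.na(Y)
  for (iter in seq_len(max_iter)) {
    A <- matrix(0, p, p); b <- rep(0, p)
    for (g in groups) {
      S <- which(obs[g[1], ])
      W <- solve(sigma2 * R[S, S, drop = FALSE])
      Ug <- U[g, , drop = FALSE]
      UtU <- crossprod(Ug)
      for (ja in seq_along(S)) for (jb in seq_along(S)) {
        ia <- (S[ja] - 1) * p_u + seq_len(p_u)
        ib <- (S[jb] - 1) * p_u + seq_len(p_u)
        A[ia, ib] <- A[ia, ib] + W[ja, jb] * UtU
        b[ia] <- b[ia] + W[ja, jb] * crossprod(Ug, Y[g, S[jb]])
      }
    }
    beta_new <- solve_active(A, b)
    done <- max(abs(beta_new - beta)) < tol * (1 + max(abs(beta_new)))
    beta <- beta_new
    # moment updates for the working variance and correlation
    E <- Y - U %*% matrix(beta, p_u, J)
    sigma2 <- sum(E^2, na.rm = TRUE) / (sum(obs) - p)
    for (ja in 1:J) for (jb in 1:J) if (ja != jb) {
      both <- obs[, ja] & obs[, jb]
      R[ja, jb] <- sum(E[both, ja] * E[both, jb]) / (sigma2 * sum(both))
    }
    if (done) break
    if (iter == max_iter)
      stop("GEE did not converge in ", max_iter,
           " iterations; last beta: ", paste(round(beta, 4), collapse = ", "))
  }
  # sandwich covariance
  E <- Y - U %*% matrix(beta, p_u, J)
  A <- matrix(0, p, p); B <- matrix(0, p, p)
  n_ind <- nrow(Y)
  for (g in groups) {
    S <- which(obs[g[1], ])
    W <- solve(sigma2 * R[S, S, drop = FALSE])
    Ug <- U[g, , drop = FALSE]
    UtU <- crossprod(Ug)
    Fg <- E[g, S, drop = FALSE] %*% W
    for (ja in seq_along(S)) for (jb in seq_along(S)) {
      ia <- (S[ja] - 1) * p_u + seq_len(p_u)
      ib <- (S[jb] - 1) * p_u + seq_len(p_u)
      A[ia, ib] <- A[ia, ib] + W[ja, jb] * UtU
      B[ia, ib] <- B[ia, ib] + crossprod(Ug * Fg[, ja], Ug * Fg[, jb])
    }
  }
  act <- active_idx(A)
  Ai <- invert_active(A)
  V <- matrix(NA_real_, p, p)
  V[act, act] <- Ai[act, act] %*% B[act, act] %*% Ai[act, act] *
    n_ind / (n_ind - length(act))
  cn <- as.vector(outer(colnames(U), st$vars, function(a, b) paste(b, a, sep = ":")))
  dimnames(V) <- list(cn, cn)
  names(beta) <- cn
  i2 <- which(cn == "y2:z")
  fit <- list(coefficients = beta, sigma2 = sigma2, corr = R, vcov = V,
              n = n_ind, vars = st$vars,
              effect = effect_to_ratio(unname(beta[i2]), sqrt(V[i2, i2]), level,
                                       method = "GEE", adjusted = adjust))
  class(fit) <- "gee_fit"
  fit
}

# log-Cholesky pack/unpack for a J x J covariance
chol_pack <- function(S) {
  L <- t(chol(S))
  diag(L) <- log(diag(L))
  L[lower.tri(L, diag = TRUE)]
}
chol_unpack <- function(par, J) {
  L <- matrix(0, J, J)
  L[lower.tri(L, diag = TRUE)] <- par
  diag(L) <- exp(diag(L))
  tcrossprod(L)
}

#' Bivariate normal mixed model for the repeated outcomes
#'
#' Adds a multivariate-normal assumption to the GEE mean model: each
#' participant's observed sub-vector of jointly modelled variables follows a
#' normal distribution with time-specific mean models and an unstructured
#' covariance matrix, optionally different in each randomised arm.
#' Estimated by (restricted) maximum likelihood with the mean coefficients
#' profiled out by generalised least squares and the covariance optimised
#' over its log-Cholesky factors.  Model-based standard errors.
#'
#' @inheritParams fit_gee
#' @param by_arm_sigma allow the covariance matrix to differ by arm?
#' @param reml restricted maximum likelihood (default) or ML?
#' @return A `mixed_fit` with `coefficients`, `Sigma` (per-arm list),
#'   `vcov`, `logLik`, `reml`, `effect`.
#' @export
fit_mixed <- function(data, adjust = FALSE, aux = NULL, by_arm_sigma = TRUE,
                      reml = TRUE, level = 0.95) {
  st <- stack_responses(data, adjust, aux)
  U <- st$U; Y <- st$Y; J <- st$J; z <- st$z
  p_u <- ncol(U); p <- p_u * J
  obs <- !is.na(Y)
  key <- paste(if (by_arm_sigma) z else 0L, pattern_ids(Y))
  groups <- split(seq_len(nrow(Y)), key)
  n_arms <- if (by_arm_sigma) 2L else 1L
  # start at the complete-case sample covariance (shrunk towards its
  # diagonal so a start on the PD boundary cannot occur)
  ccY <- Y[stats::complete.cases(Y), , drop = FALSE]
  S0 <- if (nrow(ccY) > J + 1) stats::cov(ccY)
  else diag(apply(Y, 2, stats::var, na.rm = TRUE), J)
  diag(S0)[!is.finite(diag(S0)) | diag(S0) <= 0] <- 1
  S0[!is.finite(S0)] <- 0
  S0 <- 0.95 * S0 + 0.05 * diag(diag(S0), J)
  par0 <- rep(chol_pack(S0), n_arms)
  npar_s <- J * (J + 1) / 2

  gls_pieces <- function(Sigmas) {
    A <- matrix(0, p, p); b <- rep(0, p)
    for (nm in names(groups)) {
      g <- groups[[nm]]
      arm <- if (by_arm_sigma) as.integer(substr(nm, 1, 1)) else 0L
      S <- which(obs[g[1], ])
      W <- solve(Sigmas[[arm + 1L]][S, S, drop = FALSE])
      Ug <- U[g, , drop = FALSE]
      UtU <- crossprod(Ug)
      for (ja in seq_along(S)) for (jb in seq_along(S)) {
        ia <- (S[ja] - 1) * p_u + seq_len(p_u)
        ib <- (S[jb] - 1) * p_u + seq_len(p_u)
        A[ia, ib] <- A[ia, ib] + W[ja, jb] * UtU
        b[ia] <- b[ia] + W[ja, jb] * crossprod(Ug, Y[g, S[jb]])
      }
    }
    list(A = A, b = b)
  }
  neg2ll <- function(par) tryCatch({
    Sigmas <- lapply(seq_len(n_arms), function(a)
      chol_unpack(par[(a - 1) * npar_s + seq_len(npar_s)], J))
    if (n_arms == 1L) Sigmas <- list(Sigmas[[1]], Sigmas[[1]])
    gp <- gls_pieces(Sigmas)
    beta <- tryCatch(solve_active(gp$A, gp$b), error = function(e) NULL)
    if (is.null(beta)) return(1e10)
    E <- Y - U %*% matrix(beta, p_u, J)
    val <- 0
    for (nm in names(groups)) {
      g <- groups[[nm]]
      arm <- if (by_arm_sigma) as.integer(substr(nm, 1, 1)) else 0L
      S <- which(obs[g[1], ])
      Ss <- Sigmas[[arm + 1L]][S, S, drop = FALSE]
      W <- solve(Ss)
      Eg <- E[g, S, drop = FALSE]
      val <- val + length(g) * determinant(Ss)$modulus[1] +
        sum((Eg %*% W) * Eg)
    }
    if (reml) {
      act <- active_idx(gp$A)
      val <- val + determinant(gp$A[act, act, drop = FALSE])$modulus[1]
    }
    if (!is.finite(val)) 1e10 else val
  }, error = function(e) 1e10)
  opt <- stats::optim(par0, neg2ll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  Sigmas <- lapply(seq_len(n_arms), function(a)
    chol_unpack(opt$par[(a - 1) * npar_s + seq_len(npar_s)], J))
  if (n_arms == 1L) Sigmas <- list(Sigmas[[1]], Sigmas[[1]])
  gp <- gls_pieces(Sigmas)
  beta <- solve_active(gp$A, gp$b)
  V <- invert_active(gp$A)
  cn <- as.vector(outer(colnames(U), st$vars, function(a, b) paste(b, a, sep = ":")))
  names(beta) <- cn; dimnames(V) <- list(cn, cn)
  i2 <- which(cn == "y2:z")
  fit <- list(coefficients = beta, Sigma = Sigmas[seq_len(n_arms)],
              vcov = V, logLik = -0.5 * opt$value, reml = reml,
              converged = opt$convergence == 0, vars = st$vars,
              effect = effect_to_ratio(unname(beta[i2]), sqrt(V[i2, i2]), level,
                                       method = if (reml) "mixed (REML)" else "mixed (ML)",
                                       adjusted = adjust))
  class(fit) <- "mixed_fit"
  fit
}

#' @export
print.gee_fit <- function(x, ...) {
  cat("Linear GEE, unstructured working correlation\n")
  print(x$effect); invisible(x)
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat(sprintf("Multivariate normal mixed model (%s)\n",
              if (x$reml) "REML" else "ML"))
  print(x$effect); invisible(x)
}
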