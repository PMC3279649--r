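#' Specification of the chained-equations imputation model
#'
#' Both outcomes are imputed, separately in each arm, by chained equations:
#' each incomplete outcome is regressed on the other outcome and the
#' baseline covariates (and, when `aux = TRUE`, on the log(1 + count)
#' transforms of the four website-use variables), parameters are drawn from
#' their Bayesian posterior, and predictive mean matching replaces each
#' missing cell with the observed value of a randomly chosen close donor.
#'
#' @param M number of imputations (default 50).
#' @param pmm_k number of nearest donors to sample among (default 5).
#' @param cycles chained-equation cycles per imputation (default 10; with
#'   only two incomplete variables this is generous).
#' @param by_arm impute separately per randomised arm (default TRUE).
#' @param aux include website-use auxiliaries in the imputation models?
#'   (`FALSE` gives the outcomes+baselines model, `TRUE` adds the
#'   compliance transforms.)
#' @param seed integer seed controlling all imputation randomness.
#' @return An `imputation_spec`.
#' @export
imputation_spec <- function(M = 50L, pmm_k = 5L, cycles = 10L,
                            by_arm = TRUE, aux = FALSE, seed = 1L) {
  stopifnot(M >= 2, pmm_k >= 1, cycles >= 1)
  structure(list(M = as.integer(M), pmm_k = as.integer(pmm_k),
                 cycles = as.integer(cycles), by_arm = by_arm,
                 aux = aux, seed = as.integer(seed)),
            class = "imputation_spec")
}

aux_columns <- function(data) {
  counts <- c("pages_1mo", "logins_1mo", "pages_3mo", "logins_3mo")
  out <- lapply(counts, function(v) log1p(data[[v]]))
  names(out) <- paste0("log_", counts)
  as.data.frame(out)
}

# Bayesian linear regression draw: sigma2 from the scaled inverse chi-square
# posterior, coefficients from their conditional normal
bayes_lm_draw <- function(X, y) {
  qr_ <- qr(X)
  bhat <- qr.coef(qr_, y)
  res <- y - X %*% bhat
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / stats::rchisq(1, df)
  R <- qr.R(qr_)
  bdraw <- bhat + backsolve(R, stats::rnorm(ncol(X))) * sqrt(sigma2)
  list(bhat = bhat, bdraw = bdraw)
}

# type-1 predictive mean matching: donor predictions from the posterior
# mode, target predictions from the posterior draw; each target receives
# the observed value of one of the k nearest donors, chosen uniformly.
# The k nearest donors of a point among sorted values form a contiguous
# block, found here by a vectorised two-pointer expansion.
pmm_match <- function(pred_obs, y_obs, pred_mis, k) {
  ord <- order(pred_obs)
  po <- pred_obs[ord]; yo <- y_obs[ord]
  n_don <- length(po)
  k <- min(k, n_don)
  l <- findInterval(pred_mis, po)   # left candidate pointer
  r <- l + 1L                       # right candidate pointer
  for (step in seq_len(k)) {
    dl <- ifelse(l >= 1L, pred_mis - po[pmax(l, 1L)], Inf)
    dr <- ifelse(r <= n_don, po[pmin(r, n_don)] - pred_mis, Inf)
    left <- dl <= dr
    l <- l - left
    r <- r + !left
  }
  # block of k nearest donors is (l+1)..(r-1); draw one uniformly
  pick <- l + sample.int(k, length(pred_mis), replace = TRUE)
  yo[pick]
}

#' Multiple imputation by chained equations with predictive mean matching
#'
#' @param data a [trial_dataset()].
#' @param spec an [imputation_spec()].
#' @return An `imputation_set`: list with `datasets` (M completed
#'   `trial_dataset`s in which only originally missing `y1`/`y2` cells
#'   differ from the input) and `spec`.
#' @export
impute_chained <- function(data, spec = imputation_spec()) {
  stopifnot(inherits(data, "trial_dataset"), inherits(spec, "imputation_spec"))
  covs <- attr(data, "covariates")
  base_X <- as.matrix(as.data.frame(data)[, covs, drop = FALSE])
  if (spec$aux) base_X <- cbind(base_X, as.matrix(aux_columns(data)))
  arms <- if (spec$by_arm) c(0, 1) else NA
  for (a in c(0, 1)) {
    sub <- data$z == a
    for (v in c("y1", "y2")) {
      n_obs <- sum(!is.na(data[[v]][sub]))
      if (n_obs < ncol(base_X) + 4)
        stop("arm ", a, ": too few observed ", v,
             " values (", n_obs, ") to fit the imputation model")
    }
  }
  completed <- vector("list", spec$M)
  for (m in seq_len(spec$M)) {
    ym <- data.frame(y1 = data$y1, y2 = data$y2)
    for (a in arms) {
      idx <- if (is.na(a)) seq_len(nrow(data)) else which(data$z == a)
      set.seed(stage_seed(spec$seed, 100L * m + ifelse(is.na(a), 7L, a)))
      Xa <- base_X[idx, , drop = FALSE]
      cur <- ym[idx, ]
      mis <- lapply(cur, is.na)
      # initialise missing cells by resampling observed values
      for (v in c("y1", "y2"))
        if (any(mis[[v]]))
          cur[[v]][mis[[v]]] <- sample(cur[[v]][!mis[[v]]],
                                       sum(mis[[v]]), replace = TRUE)
      for (cyc in seq_len(spec$cycles)) {
        for (v in c("y1", "y2")) {
          if (!any(mis[[v]])) next
          other <- setdiff(c("y1", "y2"), v)
          Xfull <- cbind(1, cur[[other]], Xa)
          obs <- !mis[[v]]
          dr <- bayes_lm_draw(Xfull[obs, , drop = FALSE], cur[[v]][obs])
          pred_obs <- drop(Xfull[obs, , drop = FALSE] %*% dr$bhat)
          pred_mis <- drop(Xfull[!obs, , drop = FALSE] %*% dr$bdraw)
          cur[[v]][!obs] <- pmm_match(pred_obs, cur[[v]][obs], pred_mis,
                                      spec$pmm_k)
        }
      }
      ym[idx, ] <- cur
    }
    di <- data
    di$y1 <- ym$y1; di$y2 <- ym$y2
    completed[[m]] <- di
  }
  structure(list(datasets = completed, spec = spec), class = "imputation_set")
}

#' @export
print.imputation_set <- function(x, ...) {
  cat(sprintf("imputation_set: M = %d completed datasets (pmm_k = %d, %s)\n",
              x$spec$M, x$spec$pmm_k,
              if (x$spec$aux) "with website-use auxiliaries" else "outcomes + baselines"))
  invisible(x)
}

#' Combine estimates across imputations by Rubin's rules
#'
#' Total variance is within + (1 + 1/M) between; the degrees of freedom use
#' the Barnard-Rubin small-sample formula when a complete-data df is
#' supplied, otherwise the classical large-sample formula.
#'
#' @param points per-imputation point estimates.
#' @param variances per-imputation squared standard errors.
#' @param dfcom optional complete-data residual degrees of freedom.
#' @param level confidence level.
#' @return A `pooled_estimate` with `estimate`, `W`, `B`, `T`, `se`, `df`,
#'   `ci`.
#' @export
pool_rubin <- function(points, variances, dfcom = Inf, level = 0.95) {
  M <- length(points)
  if (M < 2) stop("Rubin's rules need at least 2 imputations")
  stopifnot(length(variances) == M)
  qbar <- mean(points)
  W <- mean(variances)
  B <- stats::var(points)
  Tv <- W + (1 + 1 / M) * B
  if (B > 0) {
    r <- (1 + 1 / M) * B / W
    df_old <- (M - 1) * (1 + 1 / r)^2
    if (is.finite(dfcom)) {
      df_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * W / Tv
      df <- 1 / (1 / df_old + 1 / df_obs)
    } else df <- df_old
  } else df <- if (is.finite(dfcom)) dfcom else Inf
  tq <- stats::qt(1 - (1 - level) / 2, df)
  out <- list(estimate = qbar, W = W, B = B, T = Tv, se = sqrt(Tv),
              df = df, M = M,
              ci = c(qbar - tq * sqrt(Tv), qbar + tq * sqrt(Tv)),
              level = level)
  class(out) <- "pooled_estimate"
  out
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("pooled over M = %d: %.4f (se %.4f; W %.5f, B %.5f, df %.1f)\n",
              x$M, x$estimate, x$se, x$W, x$B, x$df))
  invisible(x)
}

#' Impute, analyse each completed dataset, and pool
#'
#' The covariates always enter the imputation model, even when the analysis
#' is unadjusted.
#'
#' @param data a [trial_dataset()].
#' @param spec an [imputation_spec()].
#' @param analysis a function taking a completed `trial_dataset` and
#'   returning `list(est = , var = )`; [analysis_itt()] and
#'   [analysis_iv()] build the standard ones.
#' @param level confidence level.
#' @return A `pooled_estimate` with an additional `effect` element
#'   presenting the pooled log-scale effect as a ratio of geometric means.
#' @export
fit_mi <- function(data, spec = imputation_spec(), analysis = analysis_itt(),
                   level = 0.95) {
  imp <- impute_chained(data, spec)
  res <- lapply(imp$datasets, analysis)
  pts <- vapply(res, `[[`, numeric(1), "est")
  vrs <- vapply(res, `[[`, numeric(1), "var")
  pooled <- pool_rubin(pts, vrs, dfcom = nrow(data) - 2, level = level)
  pooled$effect <- effect_to_ratio(pooled$estimate, pooled$se, level,
                                   method = if (spec$aux) "MI2" else "MI1",
                                   adjusted = attr(analysis, "adjusted") %||% FALSE)
  # use the t-based pooled interval rather than the normal one
  pooled$effect$ci_low <- pooled$ci[1]
  pooled$effect$ci_high <- pooled$ci[2]
  pooled$effect$ratio_ci <- exp(pooled$ci)
  pooled
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Analysis descriptor: intention-to-treat regression of y2 on arm
#' @param adjust include baseline covariates?
#' @return Function for [fit_mi()]'s `analysis` argument.
#' @export
analysis_itt <- function(adjust = FALSE) {
  f <- function(completed) {
    X <- design_matrix(completed, adjust)
    fit <- stats::lm.fit(X, completed$y2)
    vc <- sandwich_ols(X, fit$residuals)
    list(est = fit$coefficients[["z"]], var = vc["z", "z"])
  }
  attr(f, "adjusted") <- adjust
  f
}
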