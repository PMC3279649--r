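fmt_ratio <- function(eff) {
  if (is.null(eff)) return("")
  if (inherits(eff, "effect_estimate"))
    sprintf("%.3f (%.3f to %.3f)", eff$ratio, eff$ratio_ci[1], eff$ratio_ci[2])
  else sprintf("%.3f", eff)
}

try_fit <- function(expr, log) {
  t0 <- Sys.time()
  out <- tryCatch(expr, error = function(e) {
    structure(list(reason = conditionMessage(e)), class = "failed_fit")
  })
  attr(out, "elapsed") <- as.numeric(Sys.time() - t0, units = "secs")
  out
}

cell <- function(fit) {
  if (inherits(fit, "failed_fit")) paste0("failed:", fit$reason)
  else fmt_ratio(if (inherits(fit, "effect_estimate")) fit else fit$effect)
}

#' Run the full analysis sequence on a trial dataset
#'
#' Executes, unadjusted and covariate-adjusted: complete-case regression,
#' GEE, the mixed model, multiple imputation without and with website-use
#' auxiliaries, the pattern-mixture sensitivity sweep, both variants of
#' the repeated-attempts model, and the structural mean model (binary and
#' continuous compliance, each by complete-case IV, IPW, ATR and MI).
#' Individual fit failures are recorded and do not stop the run.
#'
#' @param data a [trial_dataset()].
#' @param M imputations for the MI-based fits (default 50).
#' @param seed seed for the imputation draws.
#' @param grid sensitivity grid (default [default_sensitivity_grid()]).
#' @param level confidence level.
#' @return A `trial_report` list with all fit objects, the tables from
#'   [make_table3()] / [make_table5()], the wave table, and a structured
#'   log.
#' @export
run_all <- function(data, M = 50L, seed = 1L,
                    grid = default_sensitivity_grid(), level = 0.95) {
  stopifnot(inherits(data, "trial_dataset"))
  fits <- list()
  aux4 <- c("pages_1mo", "logins_1mo", "pages_3mo", "logins_3mo")
  for (adj in c(FALSE, TRUE)) {
    key <- if (adj) "adjusted" else "unadjusted"
    fits[[key]] <- list(
      cc = try_fit(fit_complete_case(data, adj, level)),
      gee = try_fit(fit_gee(data, adj, level = level)),
      mixed = try_fit(fit_mixed(data, adj, level = level)),
      mi1 = try_fit(fit_mi(data, imputation_spec(M = M, seed = seed),
                           analysis_itt(adj), level)),
      mi2 = try_fit(fit_mi(data, imputation_spec(M = M, seed = seed + 1L,
                                                 aux = TRUE),
                           analysis_itt(adj), level)),
      sensitivity = try_fit(sensitivity_sweep(data, grid = grid,
                                              adjust = adj, level = level)),
      alho1 = try_fit(fit_alho(data, alho_spec("common_delta", adjust = adj),
                               level)),
      alho2 = try_fit(fit_alho(data, alho_spec("by_arm_delta", adjust = adj),
                               level)))
    for (mode in c("binary", "continuous")) {
      d <- define_compliance(data, compliance_definition(mode))
      fits[[key]][[paste0("smm_", mode)]] <- list(
        ipw = try_fit(fit_iv_ipw(data, d, adj, level)),
        atr = try_fit(fit_iv_atr(data, d, adj, level)),
        mi = try_fit(fit_iv_mi(data, d, adj,
                               imputation_spec(M = M, seed = seed + 2L,
                                               aux = TRUE), level)))
    }
  }
  rep <- list(fits = fits,
              waves = wave_summary(data),
              table3 = make_table3(fits),
              table5 = make_table5(fits),
              log = list(seed = seed, M = M, n = nrow(data),
                         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                         level = level))
  class(rep) <- "trial_report"
  rep
}

#' Assemble the missing-data results table
#'
#' One row per approach/assumption/method, with unadjusted and adjusted
#' ratio-of-geometric-means cells formatted as `estimate (low to high)` to
#' 3 decimal places.  Moderate sensitivity rows carry a `*` marker.
#'
#' @param fits the `fits` element of a [run_all()] result.
#' @return A `report_table` data.frame.
#' @export
make_table3 <- function(fits) {
  u <- fits$unadjusted; a <- fits$adjusted
  rows <- list(
    c("Complete cases", "CD-MCAR", "", cell(u$cc), cell(a$cc)),
    c("Repeated outcomes", "MAR", "GEE", cell(u$gee), cell(a$gee)),
    c("Repeated outcomes", "MAR", "Mixed model", cell(u$mixed), cell(a$mixed)),
    c("Repeated outcomes", "MAR", "MI1", cell(u$mi1), cell(a$mi1)),
    c("Website use", "MAR", "MI2", cell(u$mi2), cell(a$mi2)))
  sens_u <- u$sensitivity; sens_a <- a$sensitivity
  if (!is.null(sens_u) && !inherits(sens_u, "failed_fit")) {
    for (i in seq_len(nrow(sens_u))) {
      lab <- paste0(sens_u$label[i], if (sens_u$moderate[i]) " *" else "")
      au <- sprintf("%.3f (%.3f to %.3f)", sens_u$ratio[i],
                    sens_u$ci_low[i], sens_u$ci_high[i])
      aa <- if (!inherits(sens_a, "failed_fit"))
        sprintf("%.3f (%.3f to %.3f)", sens_a$ratio[i],
                sens_a$ci_low[i], sens_a$ci_high[i]) else "failed"
      rows[[length(rows) + 1L]] <- c("Sensitivity", "MNAR", lab, au, aa)
    }
  } else if (!is.null(sens_u)) {
    rows[[length(rows) + 1L]] <- c("Sensitivity", "MNAR", "",
                                   paste0("failed:", sens_u$reason), "")
  }
  rows[[length(rows) + 1L]] <- c("Number of attempts", "MNAR, common delta",
                                 "Alho 1", cell(u$alho1), cell(a$alho1))
  rows[[length(rows) + 1L]] <- c("Number of attempts", "MNAR, arm-specific delta",
                                 "Alho 2", cell(u$alho2), cell(a$alho2))
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- c("approach", "assumption", "method", "unadjusted", "adjusted")
  class(out) <- c("report_table", "data.frame")
  out
}

#' Assemble the incomplete-uptake results table
#'
#' @inheritParams make_table3
#' @return A `report_table` data.frame: binary then continuous compliance,
#'   each with IPW, ATR and MI rows.
#' @export
make_table5 <- function(fits) {
  rows <- list()
  for (mode in c("binary", "continuous")) {
    blk_u <- fits$unadjusted[[paste0("smm_", mode)]]
    blk_a <- fits$adjusted[[paste0("smm_", mode)]]
    lab <- if (mode == "binary") "Binary compliance (CACE)"
    else "Continuous compliance (per 100 pages)"
    for (m in c("ipw", "atr", "mi")) {
      rows[[length(rows) + 1L]] <- c(lab, toupper(m),
                                     cell(blk_u[[m]]), cell(blk_a[[m]]))
    }
  }
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- c("compliance", "method", "unadjusted", "adjusted")
  class(out) <- c("report_table", "data.frame")
  out
}

#' @export
print.trial_report <- function(x, ...) {
  cat("== Missing-outcome analyses ==\n")
  print(as.data.frame(x$table3), right = FALSE)
  cat("\n== Incomplete-uptake analyses ==\n")
  print(as.data.frame(x$table5), right = FALSE)
  invisible(x)
}

#' Write a report to disk
#'
#' Writes the two result tables and the wave table as CSV plus a
#' structured JSON log.  Outputs are deterministic for a fixed dataset and
#' seed.
#'
#' @param report a `trial_report` from [run_all()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "trial_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    table3 = file.path(dir, "missing_data_table.csv"),
    table5 = file.path(dir, "uptake_table.csv"),
    waves = file.path(dir, "wave_table.csv"),
    log = file.path(dir, "run_log.json"))
  utils::write.csv(as.data.frame(report$table3), paths["table3"], row.names = FALSE)
  utils::write.csv(as.data.frame(report$table5), paths["table5"], row.names = FALSE)
  utils::write.csv(as.data.frame(report$waves), paths["waves"], row.names = FALSE)
  log <- report$log
  log$timestamp <- NULL  # keep reruns byte-identical
  jsonlite::write_json(log, paths["log"], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
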