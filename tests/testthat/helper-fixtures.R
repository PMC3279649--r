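# hand-built 4-participant dataset exercising every response pattern
toy_trial <- function() {
  trial_dataset(data.frame(
    id = c("a", "b", "c", "d"),
    z = c(1, 1, 0, 0),
    age = c(30, 40, 35, 50), male = c(1, 0, 1, 0),
    degree = c(1, 1, 0, 0), audit_c = c(8, 9, 7, 10),
    eq5d = c(0.9, 0.8, 0.85, 0.7), confidence = c(3, 2, 4, 3),
    base_y = c(3.5, 4.0, 3.8, 4.2),
    y1 = c(3.2, NA, 3.5, 3.9), y2 = c(3.0, 3.6, NA, 4.1),
    r1 = c(1, 0, 1, 1), r2 = c(1, 1, 0, 1),
    wave2 = c(1, 3, NA, 2), attempts_made = c(1, 3, 3, 2),
    logins_1mo = c(2, 1, 1, 0), pages_1mo = c(25, 8, 12, 0),
    logins_3mo = c(3, 1, 1, 0), pages_3mo = c(30, 8, 14, 0),
    stringsAsFactors = FALSE))
}

# small simulated trial; full_response drops all missingness
small_sim <- function(n = 300L, seed = 1L, full_response = FALSE, ...) {
  over <- list(...)
  cfg <- do.call(default_dyd_config,
                 c(list(n_intervention = as.integer(n),
                        n_control = as.integer(n)), over))
  if (full_response)
    cfg <- default_dyd_config(n_intervention = as.integer(n),
                              n_control = as.integer(n),
                              response2 = utils::modifyList(
                                cfg$response2, list(lambda = rep(10, 3))),
                              response1 = list(intercept = 10),
                              ...)
  simulate_trial(cfg, seed = seed)
}

# independent least-squares oracle via the normal equations
ols_oracle <- function(X, y) solve(crossprod(X), crossprod(X, y))
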