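test_that("compliance definitions follow the binary and capped rules", {
  d <- toy_trial()
  db <- define_compliance(d, compliance_definition("binary"))
  # a: z=1, 2 logins -> complier; b: z=1, 1 login, 8 pages -> not
  expect_identical(as.numeric(db), c(1, 0, 0, 0))
  df <- as.data.frame(d)
  df$pages_1mo[2] <- 450
  dc <- define_compliance(trial_dataset(df),
                          compliance_definition("continuous"))
  expect_equal(as.numeric(dc), c(0.25, 3.0, 0, 0))  # capped at 300 pages
  expect_equal(max(dc), 3.0)
})

test_that("intervention-arm complier fraction matches its target", {
  d <- simulate_trial(default_dyd_config(n_intervention = 10000L,
                                         n_control = 1000L), seed = 121)
  db <- define_compliance(d, compliance_definition("binary"))
  expect_lt(abs(mean(db[d$z == 1]) - 0.78), 0.02)
})

test_that("perfect compliance reduces the IV fit to intention to treat", {
  d <- small_sim(n = 300, seed = 123)
  dz <- structure(as.numeric(d$z), defn = compliance_definition("binary"))
  f <- fit_iv_complete(d, dz)
  itt <- fit_complete_case(d)
  expect_equal(f$psi, itt$beta, tolerance = 1e-12)
  expect_equal(f$se, itt$se, tolerance = 1e-12)
})

test_that("binary compliance without covariates gives the Wald ratio", {
  d <- small_sim(n = 400, seed = 127)
  db <- define_compliance(d, compliance_definition("binary"))
  f <- fit_iv_complete(d, db)
  cc <- d$r2 == 1
  wald <- (mean(d$y2[cc & d$z == 1]) - mean(d$y2[cc & d$z == 0])) /
    (mean(db[cc & d$z == 1]) - mean(db[cc & d$z == 0]))
  expect_equal(f$psi, wald, tolerance = 1e-10)
})

test_that("ATR equals IV on complete data and its residuals are orthogonal", {
  d <- small_sim(n = 300, seed = 131, full_response = TRUE)
  dc <- define_compliance(d, compliance_definition("continuous"))
  for (adj in c(FALSE, TRUE)) {
    expect_equal(fit_iv_atr(d, dc, adjust = adj)$psi,
                 fit_iv_complete(d, dc, adjust = adj)$psi,
                 tolerance = 1e-10)
  }
  # stage-1 residuals orthogonal to the stage-1 design
  X <- cbind(1, d$z)
  e1 <- lm.fit(X, as.numeric(dc))$residuals
  expect_lt(max(abs(crossprod(X, e1))), 1e-8)
})

test_that("rescaling the compliance unit rescales psi exactly", {
  d <- small_sim(n = 300, seed = 137)
  d100 <- define_compliance(d, compliance_definition("continuous", unit = 100))
  d1 <- define_compliance(d, compliance_definition("continuous", unit = 1))
  f100 <- fit_iv_complete(d, d100)
  f1 <- fit_iv_complete(d, d1)
  expect_equal(f100$psi, f1$psi * 100, tolerance = 1e-8)
  expect_equal(f100$se, f1$se * 100, tolerance = 1e-8)
})

test_that("with full response IPW weights are unity and the fits agree", {
  d <- small_sim(n = 250, seed = 139, full_response = TRUE)
  dc <- define_compliance(d, compliance_definition("continuous"))
  f_ipw <- fit_iv_ipw(d, dc)
  expect_true(all(f_ipw$weights == 1))
  f_cc <- fit_iv_complete(d, dc)
  expect_equal(f_ipw$psi, f_cc$psi, tolerance = 1e-12)
})

test_that("when missingness ignores compliance IPW matches unweighted IV", {
  # default response model depends on covariates and arm but not on pages,
  # so the weight numerator and denominator models estimate the same thing
  d <- small_sim(n = 2000, seed = 141)
  dc <- define_compliance(d, compliance_definition("continuous"))
  f_ipw <- fit_iv_ipw(d, dc)
  f_cc <- fit_iv_complete(d, dc)
  expect_lt(max(abs(f_ipw$weights - 1)), 0.25)
  expect_lt(abs(f_ipw$psi - f_cc$psi), 0.02)
})

test_that("IPW and ATR correct compliance-dependent missingness; IV does not", {
  # latent engagement links page counts to the outcome in both arms, and
  # 3-month response depends on intervention-arm compliance: complete-case
  # IV is then biased while IPW and ATR recover the generating effect of
  # 0.1 per 100 capped pages
  miss_d <- list(engagement_sd = 0.5,
                 response2 = list(eta_base = 0, eta_d = c(0, -0.8)))
  big <- do.call(small_sim, c(list(n = 50000, seed = 555), miss_d))
  dc_big <- define_compliance(big, compliance_definition("continuous"))
  # large-n oracle for the complete-case bias: clearly below the truth
  expect_lt(fit_iv_complete(big, dc_big, adjust = TRUE)$psi, 0.05)

  n_rep <- 30
  res <- vapply(seq_len(n_rep), function(i) {
    d <- do.call(small_sim, c(list(n = 800, seed = 8200 + i), miss_d))
    dc <- define_compliance(d, compliance_definition("continuous"))
    c(ipw = fit_iv_ipw(d, dc, adjust = TRUE)$psi,
      atr = fit_iv_atr(d, dc, adjust = TRUE)$psi)
  }, numeric(2))
  mcse <- apply(res, 1, sd) / sqrt(n_rep)
  expect_lt(abs(mean(res["ipw", ]) - 0.1), 3 * mcse["ipw"])
  expect_lt(abs(mean(res["atr", ]) - 0.1), 3 * mcse["atr"])
  # the two corrections behave very similarly
  expect_lt(abs(mean(res["ipw", ] - res["atr", ])),
            3 * sd(res["ipw", ] - res["atr", ]) / sqrt(n_rep) + 0.01)
})

test_that("weak instruments are refused", {
  d <- small_sim(n = 100, seed = 149)
  dzero <- structure(rep(0, nrow(d)), defn = compliance_definition("binary"))
  expect_error(fit_iv_complete(d, dzero), "instrument")
})

test_that("MI-based IV equals the complete-data fit when nothing is missing", {
  d <- small_sim(n = 200, seed = 151, full_response = TRUE)
  dc <- define_compliance(d, compliance_definition("continuous"))
  f_mi <- fit_iv_mi(d, dc, spec = imputation_spec(M = 3, aux = TRUE, seed = 5))
  f_cc <- fit_iv_complete(d, dc)
  expect_equal(f_mi$psi, f_cc$psi, tolerance = 1e-12)
  expect_equal(f_mi$B, 0)
  # determinism under a fixed seed
  d2 <- small_sim(n = 200, seed = 153)
  dc2 <- define_compliance(d2, compliance_definition("continuous"))
  spec <- imputation_spec(M = 3, aux = TRUE, seed = 5)
  expect_identical(fit_iv_mi(d2, dc2, spec = spec)$psi,
                   fit_iv_mi(d2, dc2, spec = spec)$psi)
})

test_that("bootstrap ATR standard errors are available and flagged", {
  d <- small_sim(n = 150, seed = 157)
  dc <- define_compliance(d, compliance_definition("continuous"))
  f <- fit_iv_atr(d, dc)
  expect_true(f$se_caveat)
  fb <- fit_iv_atr(d, dc, bootstrap = TRUE, B = 30L, seed = 2)
  expect_false(fb$se_caveat)
  expect_gt(fb$se, 0)
})
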