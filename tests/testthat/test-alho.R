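test_that("likelihood decouples at delta = 0 into its two factor fits", {
  d <- small_sim(n = 150, seed = 101)
  for (variant in c("common_delta", "by_arm_delta")) {
    spec <- alho_spec(variant)
    st <- trialmnar:::alho_start(d, spec)
    expect_equal(alho_loglik(st$par, d, spec), st$loglik_decoupled,
                 tolerance = 1e-10)
  }
  # adjusted variant too
  spec_a <- alho_spec("common_delta", adjust = TRUE)
  st_a <- trialmnar:::alho_start(d, spec_a)
  expect_equal(alho_loglik(st_a$par, d, spec_a), st_a$loglik_decoupled,
               tolerance = 1e-10)
})

test_that("quadrature is converged at the default node count", {
  d <- small_sim(n = 100, seed = 103)
  spec40 <- alho_spec("by_arm_delta")
  st <- trialmnar:::alho_start(d, spec40)
  par <- st$par
  par[length(par) - 1] <- -0.4  # non-trivial deltas so integrals matter
  par[length(par)] <- -0.2
  l40 <- alho_loglik(par, d, spec40)
  l80 <- alho_loglik(par, d, alho_spec("by_arm_delta", nodes = 80L))
  expect_lt(abs(l40 - l80), 1e-8)
})

test_that("an impossible first attempt contributes nothing for never-responders", {
  # single-attempt design with attempt intercept -> -inf: response
  # probability -> 0, so a never-responder's integral -> 1 and log -> 0
  df <- as.data.frame(toy_trial())[3, ]
  df$wave2 <- NA_integer_; df$r2 <- 0; df$y2 <- NA_real_
  df$attempts_made <- 1L
  d1 <- trial_dataset(df, K = 1L)
  spec <- alho_spec("common_delta")
  # pars: xi (2), log_sigma, lambda_1, eta_z, delta
  par <- c(3.5, 0.1, log(1), -30, 0, 0.5)
  expect_equal(alho_loglik(par, d1, spec), 0, tolerance = 1e-10)
})

test_that("full-likelihood fit recovers a known informative-missingness value", {
  # correctly specified unadjusted model: response depends on arm and the
  # realised 3-month outcome only
  cfg <- default_dyd_config(n_intervention = 700L, n_control = 700L,
                            response2 = list(delta_r = c(-0.3, -0.3),
                                             eta_base = 0))
  n_rep <- 12
  dh <- vapply(seq_len(n_rep), function(i)
    as.numeric(fit_alho(simulate_trial(cfg, seed = 7100 + i),
                        alho_spec("common_delta", nodes = 20L),
                        hessian = FALSE)$delta),
    numeric(1))
  mcse <- sd(dh) / sqrt(n_rep)
  expect_lt(abs(mean(dh) + 0.3), 3 * mcse)
})

test_that("MNAR correction moves the effect against the missingness imbalance", {
  # more missingness in the intervention arm and delta < 0 (heavier
  # drinkers respond less): the MNAR effect estimate must exceed the
  # responders-only MAR estimate
  cfg <- default_dyd_config(n_intervention = 2000L, n_control = 2000L,
                            response2 = list(delta_r = c(-0.35, -0.35),
                                             eta_base = 0))
  d <- simulate_trial(cfg, seed = 113)
  expect_gt(mean(d$r2[d$z == 0]), mean(d$r2[d$z == 1]))
  f <- fit_alho(d, alho_spec("common_delta", nodes = 20L),
                hessian = FALSE)
  mar_beta <- fit_complete_case(d)$beta
  expect_gt(f$effect$beta, mar_beta)
})

test_that("arm-specific deltas cost precision relative to a common delta", {
  cfg <- default_dyd_config(n_intervention = 600L, n_control = 600L,
                            response2 = list(delta_r = c(-0.3, -0.3),
                                             eta_base = 0))
  wider <- vapply(1:5, function(i) {
    d <- simulate_trial(cfg, seed = 7200 + i)
    f1 <- fit_alho(d, alho_spec("common_delta", nodes = 20L))
    f2 <- fit_alho(d, alho_spec("by_arm_delta", nodes = 20L))
    f2$effect$se >= f1$effect$se
  }, logical(1))
  expect_gte(mean(wider), 0.8)
})

test_that("Wald tests match hand-computed quadratic forms", {
  fake <- structure(list(
    coefficients = c(`out:z` = 0.1, delta0 = -0.2, delta1 = -0.5),
    vcov = diag(c(0.01, 0.04, 0.04)),
    hessian_pd = TRUE,
    spec = alho_spec("by_arm_delta")), class = "alho_fit")
  dimnames(fake$vcov) <- list(names(fake$coefficients),
                              names(fake$coefficients))
  tst <- alho_tests(fake)
  expect_equal(tst$z_delta1, -0.5 / 0.2)
  expect_equal(tst$z_equal, (-0.2 + 0.5) / sqrt(0.08))
  expect_equal(tst$chisq_2df, 0.2^2 / 0.04 + 0.5^2 / 0.04)
  expect_equal(tst$p_2df, pchisq(tst$chisq_2df, 2, lower.tail = FALSE))

  fake$coefficients[c("delta0", "delta1")] <- c(-0.3, -0.3)
  tst2 <- alho_tests(fake)
  expect_equal(tst2$z_equal, 0)
  expect_equal(tst2$p_equal, 1)

  fake$spec <- alho_spec("common_delta")
  expect_error(alho_tests(fake), "by_arm_delta")
})

test_that("exported response weights are positive and attempt-consistent", {
  d <- small_sim(n = 200, seed = 107)
  f <- fit_alho(d, alho_spec("common_delta", nodes = 20L))
  w <- alho_ipw_weights(f, d)
  expect_true(all(is.na(w[d$r2 == 0])))
  expect_true(all(w[d$r2 == 1] >= 1))
})
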