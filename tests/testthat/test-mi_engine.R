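test_that("zero missingness makes imputation the identity and B = 0", {
  d <- small_sim(n = 150, seed = 61, full_response = TRUE)
  spec <- imputation_spec(M = 3, seed = 7)
  imp <- impute_chained(d, spec)
  for (di in imp$datasets) {
    expect_identical(di$y1, d$y1)
    expect_identical(di$y2, d$y2)
  }
  pooled <- fit_mi(d, spec, analysis_itt(FALSE))
  single <- analysis_itt(FALSE)(d)
  expect_equal(pooled$estimate, single$est)
  expect_equal(pooled$B, 0)
  expect_equal(pooled$T, pooled$W)
  expect_equal(pooled$W, single$var)
})

test_that("observed cells are untouched and PMM draws only observed donors", {
  d <- small_sim(n = 300, seed = 67)
  imp <- impute_chained(d, imputation_spec(M = 4, seed = 3))
  obs2 <- d$r2 == 1
  obs1 <- d$r1 == 1
  for (di in imp$datasets) {
    expect_identical(di$y2[obs2], d$y2[obs2])
    expect_identical(di$y1[obs1], d$y1[obs1])
    for (arm in c(0, 1)) {
      sel <- d$z == arm & !obs2
      expect_true(all(di$y2[sel] %in% d$y2[d$z == arm & obs2]))
      sel1 <- d$z == arm & !obs1
      expect_true(all(di$y1[sel1] %in% d$y1[d$z == arm & obs1]))
    }
  }
})

test_that("imputation is deterministic and per-arm independent", {
  d <- small_sim(n = 200, seed = 71)
  i1 <- impute_chained(d, imputation_spec(M = 3, seed = 11))
  i2 <- impute_chained(d, imputation_spec(M = 3, seed = 11))
  expect_identical(lapply(i1$datasets, `[[`, "y2"),
                   lapply(i2$datasets, `[[`, "y2"))
  i3 <- impute_chained(d, imputation_spec(M = 3, seed = 12))
  expect_false(identical(i1$datasets[[1]]$y2, i3$datasets[[1]]$y2))

  # permuting intervention-arm records leaves control-arm imputations alone
  df <- as.data.frame(d)
  idx1 <- which(df$z == 1)
  set.seed(99)
  df[idx1, ] <- df[sample(idx1), ]
  dperm <- trial_dataset(df)
  ip <- impute_chained(dperm, imputation_spec(M = 2, seed = 11))
  io <- impute_chained(d, imputation_spec(M = 2, seed = 11))
  ctl <- which(d$z == 0)
  expect_identical(io$datasets[[1]]$y2[ctl], ip$datasets[[1]]$y2[ctl])
  expect_identical(io$datasets[[2]]$y1[ctl], ip$datasets[[2]]$y1[ctl])
})

test_that("Rubin's rules match hand arithmetic", {
  p <- pool_rubin(points = c(0, 1), variances = c(1, 1))
  expect_equal(p$estimate, 0.5)
  expect_equal(p$W, 1)
  expect_equal(p$B, 0.5)
  expect_equal(p$T, 1 + (1 + 1 / 2) * 0.5)  # 1.75
  expect_error(pool_rubin(1, 1), "at least 2")

  pid <- pool_rubin(points = rep(0.3, 5), variances = rep(0.04, 5))
  expect_equal(pid$B, 0)
  expect_equal(pid$T, pid$W)

  # CI widens as between-imputation variance grows, W fixed
  wide <- pool_rubin(points = c(-1, 2), variances = c(1, 1))
  expect_gt(diff(wide$ci), diff(p$ci))
})

test_that("website-use auxiliaries remove pages-dependent missingness bias", {
  # response depends on intervention-arm page counts, which are linked to
  # the outcome through a latent engagement propensity: the imputation
  # model without compliance (MI1) is misspecified, the one with the
  # log(1 + count) compliance transforms (MI2) matches the mechanism.
  # Truth is the ITT effect in large pre-deletion (fully observed) data.
  miss_p <- list(engagement_sd = 0.5,
                 response2 = list(eta_base = 0, eta_pages = c(0, -0.6)))
  big <- do.call(small_sim, c(list(n = 60000, seed = 700,
                                   full_response = TRUE),
                              list(engagement_sd = 0.5)))
  truth <- mean(big$y2[big$z == 1]) - mean(big$y2[big$z == 0])
  n_rep <- 20
  res <- vapply(seq_len(n_rep), function(i) {
    d <- do.call(small_sim, c(list(n = 1000, seed = 9300 + i), miss_p))
    c(mi1 = fit_mi(d, imputation_spec(M = 5, seed = i),
                   analysis_itt(FALSE))$estimate,
      mi2 = fit_mi(d, imputation_spec(M = 5, seed = i, aux = TRUE),
                   analysis_itt(FALSE))$estimate)
  }, numeric(2))
  mcse <- apply(res, 1, sd) / sqrt(n_rep)
  expect_lt(abs(mean(res["mi2", ]) - truth), 3 * mcse["mi2"])
  expect_gt(abs(mean(res["mi1", ]) - truth), abs(mean(res["mi2", ]) - truth))
})

test_that("too-small arms are refused with an informative error", {
  d <- small_sim(n = 300, seed = 73)
  df <- as.data.frame(d)[1:40, ]   # intervention arm only, few responders
  df <- df[df$z == 1, ]
  df <- rbind(df, within(as.data.frame(d)[d$z == 0, ][1:30, ], {}))
  dd <- trial_dataset(df)
  expect_error(impute_chained(dd, imputation_spec(M = 2, aux = TRUE, seed = 1)),
               "too few observed")
})
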