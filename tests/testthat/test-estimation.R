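# The Laplace objective is validated against an independent 1-D quadrature
# oracle, degenerate closed forms, and additivity; the fit by noise-free
# identifiability and simulation-based recovery (the 20-seed recovery runs
# live in the acceptance suite).

test_that("Laplace OFV matches adaptive quadrature on 1-D random-effect cases", {
  m1 <- population_model(final_model$theta, final_model$covariate_effects,
                         omega2 = c(CL = 0.29, V1 = 0, Q = 0, V2 = 0),
                         sigma2_prop = 0.174^2)
  set.seed(51)
  for (k in 1:5) {
    d <- generate_dataset(1, true_model = m1, missing_rate = 0,
                          seed = 500 + k)
    obs <- d[d$EVID == 0 & d$BLQ == 0, ]
    if (nrow(obs) < 2) next
    doses <- dose_events(d$TIME[d$EVID == 1], d$AMT[d$EVID == 1],
                         d$DUR[d$EVID == 1])
    oracle <- quad_ofv_1d(m1, obs$TIME, obs$DV, doses,
                          list(GFR = obs$GFR[1]))
    expect_equal(ofv(m1, d), oracle, tolerance = 0.1 / oracle)
  }
})

test_that("with all variances zero the OFV is the weighted least-squares deviance", {
  sigma2 <- 0.03
  m0 <- population_model(final_model$theta, final_model$covariate_effects,
                         omega2 = c(CL = 0, V1 = 0, Q = 0, V2 = 0),
                         sigma2_prop = sigma2)
  d <- generate_dataset(5, true_model = m0, missing_rate = 0, seed = 52)
  parts <- teicopk:::split_subjects(d)
  manual <- 0
  for (i in seq_along(parts$subjects)) {
    s <- parts$subjects[[i]]
    f <- conc_at(typical_params(m0, parts$cov[[i]]),
                 dose_events(s$dose_start, s$dose_amt, s$dose_dur), s$times)
    manual <- manual + sum((s$dv - f)^2 / (sigma2 * f^2) +
                             log(2 * pi * sigma2 * f^2))
  }
  expect_equal(ofv(m0, d), manual, tolerance = 1e-10)
})

test_that("duplicating a subject doubles its OFV contribution", {
  d <- generate_dataset(3, seed = 53)
  det <- ofv(final_model, d, detail = TRUE)
  dup <- d[d$ID == 2, ]
  dup$ID <- 4L
  d2 <- rbind(d, dup)
  det2 <- ofv(final_model, d2, detail = TRUE)
  expect_equal(det2$ofv, det$ofv + det$ofv_i[2], tolerance = 1e-8)
})

test_that("noise-free data identifies the structural parameters", {
  d <- noise_free_dataset(n = 6, gfr = 71.88)
  # tiny variances stand in for zero so the WLS deviance is well defined
  init <- population_model(c(CL = 1.3, V1 = 25, Q = 2.5, V2 = 80),
                           omega2 = c(CL = 0, V1 = 0, Q = 0, V2 = 0),
                           sigma2_prop = 1e-4)
  f <- fit_model(d, init, fix = "sigma2")
  expect_equal(unname(f$model$theta), c(1.03, 20.1, 3.12, 101),
               tolerance = 1e-3)
  expect_lte(f$ofv, f$init_ofv + 1e-6)
})

test_that("refitting from the truth does not worsen the objective", {
  d <- generate_dataset(12, seed = 54)
  f <- fit_model(d, final_model)
  expect_lte(f$ofv, f$init_ofv + 0.01)
  expect_true(all(dim(f$eta) == c(length(unique(f$ids)), 4)))
})

test_that("a fixed-zero covariate effect changes nothing and is not selected", {
  d <- generate_dataset(8, seed = 55)
  base <- population_model(c(CL = 1, V1 = 20, Q = 3, V2 = 100),
                           omega2 = c(CL = 0.2, V1 = 0.2, Q = 0.2, V2 = 0.1),
                           sigma2_prop = 0.03)
  with_null <- population_model(base$theta,
    list(covariate_effect("CL", "AGE", 0, reference = 72)),
    base$omega2, base$sigma2_prop)
  expect_equal(ofv(base, d), ofv(with_null, d), tolerance = 1e-10)
})

test_that("bootstrap resamples subjects and summarizes percentiles", {
  m0 <- population_model(final_model$theta, final_model$covariate_effects,
                         omega2 = c(CL = 0.29, V1 = 0, Q = 0, V2 = 0),
                         sigma2_prop = 0.174^2)
  d <- generate_dataset(12, true_model = m0, seed = 56)
  f <- fit_model(d, m0, fix = c("V1", "Q", "V2", "beta1",
                                "omega2.V1", "omega2.Q", "omega2.V2"))
  b <- bootstrap_fit(d, f$model, n_boot = 12, seed = 57,
                     fix = c("V1", "Q", "V2", "beta1",
                             "omega2.V1", "omega2.Q", "omega2.V2"))
  expect_lte(b$n_success, 12)
  expect_gte(b$n_success, 6)
  sm <- b$summary
  expect_true(all(sm$lo <= sm$median & sm$median <= sm$hi))
  # CL interval from a correctly specified model should cover the truth
  cl <- sm[sm$parameter == "CL", ]
  expect_true(cl$lo <= 1.03 * 1.3 && cl$hi >= 1.03 * 0.7)
})
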