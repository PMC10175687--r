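test_that("micro rate constants and hybrid constants match their identities", {
  mr <- micro_rates(table_params)
  expect_equal(mr[["k10"]], 1.03 / 20.1, tolerance = 1e-12)
  expect_equal(mr[["k12"]], 3.12 / 20.1, tolerance = 1e-12)
  expect_equal(mr[["k21"]], 3.12 / 101, tolerance = 1e-12)
  # frozen values from direct arithmetic on the published estimates
  expect_equal(unname(mr[c("k10", "k12", "k21")]),
               c(0.0512438, 0.1552239, 0.0308911), tolerance = 1e-5)
  expect_gt(mr[["alpha"]], mr[["beta"]])
  expect_gt(mr[["beta"]], 0)
  expect_equal(mr[["alpha"]] * mr[["beta"]], mr[["k10"]] * mr[["k21"]],
               tolerance = 1e-12)
  expect_equal(mr[["alpha"]] + mr[["beta"]],
               mr[["k10"]] + mr[["k12"]] + mr[["k21"]], tolerance = 1e-12)
})

test_that("terminal half-life of the published model sits in the label range", {
  mr <- micro_rates(table_params)
  thalf <- log(2) / mr[["beta"]]
  expect_equal(thalf, 100.93, tolerance = 1e-3)
  expect_true(thalf >= 100 && thalf <= 170)
})

test_that("one-compartment behaviour is recovered as Q goes to zero", {
  p <- structural_params(CL = 1.03, V1 = 20.1, Q = 1e-9, V2 = 101)
  mr <- micro_rates(p)
  expect_equal(mr[["alpha"]], mr[["k10"]] + mr[["k12"]], tolerance = 1e-4)
  expect_lt(mr[["beta"]], 1e-9)
})

test_that("parameter validation rejects non-positive or non-finite values", {
  expect_error(structural_params(0, 20, 3, 100), "positive")
  expect_error(structural_params(1, -1, 3, 100), "positive")
  expect_error(structural_params(1, 20, NA, 100), "positive")
  expect_error(structural_params(1, 20, 3, Inf), "positive")
})

test_that("concentration is zero with no doses and before the first dose", {
  expect_equal(conc_at(table_params, dose_events(), c(0, 10, 100)),
               c(0, 0, 0))
  doses <- dose_events(24, 400, 1)
  expect_equal(conc_at(table_params, doses, c(0, 12, 24)), c(0, 0, 0))
  expect_gt(conc_at(table_params, doses, 24.5), 0)
})

test_that("analytic concentrations match stiff ODE integration", {
  skip_if_not_installed("deSolve")
  set.seed(401)
  for (k in 1:25) {
    p <- structural_params(CL = runif(1, 0.3, 5), V1 = runif(1, 5, 50),
                           Q = runif(1, 0.5, 10), V2 = runif(1, 20, 200))
    nd <- sample(1:6, 1)
    doses <- dose_events(start = sort(runif(nd, 0, 96)),
                         amount = runif(nd, 100, 1200),
                         duration = sample(c(0.5, 1), nd, replace = TRUE))
    tt <- sort(runif(6, 1, 150))
    expect_equal(conc_at(p, doses, tt), ode_conc(p, doses, tt),
                 tolerance = 1e-6)
  }
})

test_that("superposition: multi-dose profile is the sum of single doses", {
  doses <- build_events(std_regimen)
  tt <- c(23.9, 48, 72, 100.5, 240, 263)
  total <- conc_at(table_params, doses, tt)
  parts <- rowSums(vapply(seq_len(nrow(doses)), function(j) {
    conc_at(table_params, doses[j, ], tt)
  }, numeric(length(tt))))
  expect_equal(total, parts, tolerance = 1e-10)
  # linearity: doubling amounts doubles concentrations
  doubled <- doses
  doubled$amount <- doubled$amount * 2
  expect_equal(conc_at(table_params, doubled, tt), 2 * total,
               tolerance = 1e-12)
})

test_that("concentration is continuous across infusion end", {
  doses <- dose_events(0, 975, 1)
  eps <- 1e-9
  left <- conc_at(table_params, doses, 1 - eps)
  right <- conc_at(table_params, doses, 1 + eps)
  expect_equal(left, right, tolerance = 1e-7)
  at <- conc_at(table_params, doses, 1)
  expect_equal(at, left, tolerance = 1e-7)
})

test_that("AUC identities: dose/CL to infinity, additivity, trapezoid accuracy", {
  doses <- dose_events(0, 975, 1)
  expect_equal(pk_auc(table_params, doses, 0, Inf, method = "analytic"),
               975 / 1.03, tolerance = 1e-9)
  # any multi-dose schedule: AUC(0, Inf) = total dose / CL
  sched <- build_events(std_regimen)
  expect_equal(pk_auc(table_params, sched, 0, Inf, method = "analytic"),
               sum(sched$amount) / 1.03, tolerance = 1e-9)
  # additive over adjacent windows
  a1 <- pk_auc(table_params, sched, 0, 100, method = "analytic")
  a2 <- pk_auc(table_params, sched, 100, 264, method = "analytic")
  expect_equal(a1 + a2, pk_auc(table_params, sched, 0, 264,
                               method = "analytic"), tolerance = 1e-10)
  # trapezoid on the default 0.1 h grid within 0.2% of analytic
  tr <- pk_auc(table_params, sched, 240, 264, method = "trapezoid")
  an <- pk_auc(table_params, sched, 240, 264, method = "analytic")
  expect_lt(abs(tr - an) / an, 0.002)
  expect_equal(pk_auc(table_params, dose_events(), 0, 24), 0)
  expect_error(pk_auc(table_params, sched, 24, 24), "t1 > t0")
})

test_that("dose event validation", {
  expect_error(dose_events(-1, 100, 1), "start")
  expect_error(dose_events(0, -5, 1), "start|amount")
  expect_error(dose_events(0, 100, 0), "duration")
})
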