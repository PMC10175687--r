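test_that("covariate sampling matches the cohort's GFR strata and weight", {
  set.seed(21)
  cov <- sample_covariates(1e4)
  expect_equal(nrow(cov), 1e4)
  f90 <- mean(cov$GFR >= 90)
  expect_lt(abs(f90 - 0.237), 0.015)
  expect_lt(abs(mean(cov$GFR >= 60 & cov$GFR < 90) - 0.339), 0.015)
  expect_lt(abs(mean(cov$GFR < 15) - 0.102), 0.015)
  expect_true(all(cov$GFR >= 11 & cov$GFR <= 124))
  expect_true(all(cov$WT >= 35 & cov$WT <= 90))
  expect_lt(abs(median(cov$WT) / 65 - 1), 0.02)
  expect_true(all(cov$AGE >= 28 & cov$AGE <= 92))
  expect_lt(abs(mean(cov$SEX) - 0.627), 0.02)
  expect_equal(cov$BMI, cov$WT / cov$HT^2)
  expect_equal(nrow(sample_covariates(0)), 0L)
})

test_that("the standard sparse design schedules five samples per subject", {
  for (arm in 1:3) {
    des <- standard_design(arm = arm)
    expect_equal(des$doses$start, c(0, 12, 24, 48, 72, 96))
    expect_true(all(des$doses$amount == 400))
    expect_equal(length(des$sample_times), 5L)
    expect_true(all(c(24, 48, 72, 96) %in% des$sample_times))
  }
  expect_true(73 %in% standard_design(arm = 1)$sample_times)
  expect_true(73 %in% standard_design(arm = 2)$sample_times)
  expect_true(95 %in% standard_design(arm = 3)$sample_times)
  # arm 1 samples at the end of the 5th infusion: moves with the duration
  expect_true(72.5 %in% standard_design(arm = 1,
                                        infusion_duration = 0.5)$sample_times)
})

test_that("dataset generation is seed-reproducible and well-formed", {
  d1 <- generate_dataset(10, seed = 33)
  d2 <- generate_dataset(10, seed = 33)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  # every observation has at least one dose before it
  for (id in unique(d1$ID)) {
    sub <- d1[d1$ID == id, ]
    obs_t <- sub$TIME[sub$EVID == 0]
    expect_true(all(vapply(obs_t, function(t) {
      any(sub$TIME[sub$EVID == 1] < t)
    }, logical(1))))
  }
  prov <- attr(d1, "provenance")
  expect_equal(prov$seed, 33)
  expect_equal(prov$true_theta$CL, 1.03)
})

test_that("scheduled sample count and thinning hit the study's yield", {
  d <- generate_dataset(59, missing_rate = 0, seed = 34)
  expect_equal(sum(d$EVID == 0), 295L)  # 59 subjects x 5 samples
  set.seed(35)
  counts <- vapply(1:20, function(i) {
    sum(generate_dataset(59)$EVID == 0)
  }, numeric(1))
  expect_lt(abs(mean(counts) - 249), 6)
})

test_that("below-LOQ observations are flagged and zero variance collapses", {
  d <- generate_dataset(30, seed = 36)
  obs <- d[d$EVID == 0, ]
  expect_true(all(obs$BLQ[obs$DV < 3.125] == 1L))
  expect_true(all(obs$BLQ[obs$DV >= 3.125] == 0L))
  # zero-variance model, same covariates: all subjects share one profile
  m0 <- population_model(final_model$theta, list(),
                         omega2 = c(CL = 0, V1 = 0, Q = 0, V2 = 0),
                         sigma2_prop = 0)
  d0 <- generate_dataset(6, true_model = m0, missing_rate = 0, seed = 37)
  obs0 <- d0[d0$EVID == 0, ]
  by_arm <- split(obs0$DV, (obs0$ID - 1) %% 3)
  for (v in by_arm) {
    expect_equal(length(unique(matrix(v, nrow = 5)[1, ])), 1L)
  }
})

test_that("extra-sample arms are assigned in thirds", {
  d <- generate_dataset(9, missing_rate = 0, seed = 38)
  extra <- d[d$EVID == 0 & !(d$TIME %in% c(24, 48, 72, 96)), ]
  expect_equal(nrow(extra), 9L)
  expect_equal(sum(extra$TIME == 73), 6L)  # arms 1 (72+1h inf) and 2 coincide
  expect_equal(sum(extra$TIME == 95), 3L)
})
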