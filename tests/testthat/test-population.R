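test_that("typical clearance follows the GFR power law", {
  m <- final_model
  expect_equal(unclass(typical_params(m, list(GFR = 71.88)))[["CL"]], 1.03,
               tolerance = 1e-12)
  expect_equal(unclass(typical_params(m, list(GFR = 120)))[["CL"]],
               1.03 * (120 / 71.88)^0.437, tolerance = 1e-12)
  expect_equal(unclass(typical_params(m, list(GFR = 15)))[["CL"]],
               1.03 * (15 / 71.88)^0.437, tolerance = 1e-12)
  # frozen derived values
  expect_equal(unclass(typical_params(m, list(GFR = 120)))[["CL"]], 1.28855,
               tolerance = 1e-5)
  expect_equal(unclass(typical_params(m, list(GFR = 15)))[["CL"]], 0.51934,
               tolerance = 1e-5)
  # V1, Q, V2 unaffected
  tv <- unclass(typical_params(m, list(GFR = 15)))
  expect_equal(tv[c("V1", "Q", "V2")], c(V1 = 20.1, Q = 3.12, V2 = 101))
  # log CL affine in log GFR with slope 0.437
  g <- c(20, 47, 90, 110)
  cl <- vapply(g, function(x) unclass(typical_params(m, list(GFR = x)))[["CL"]],
               numeric(1))
  slopes <- diff(log(cl)) / diff(log(g))
  expect_equal(slopes, rep(0.437, 3), tolerance = 1e-12)
})

test_that("a missing required covariate is reported by name", {
  expect_error(typical_params(final_model, list(WT = 70)), "GFR")
})

test_that("individual sampling reproduces the log-normal IIV layer", {
  m <- final_model
  set.seed(11)
  n <- 1e5
  pm <- teicopk:::sample_param_matrix(m, list(GFR = 71.88), n)
  # median equals typical value (log-normal), 1% tolerance
  expect_equal(unname(apply(pm, 2, median)), c(1.03, 20.1, 3.12, 101),
               tolerance = 0.01)
  # sd of log CL equals sqrt(0.29) (reported 53.9 %CV), 2% tolerance
  expect_equal(sd(log(pm[, "CL"])), sqrt(0.29), tolerance = 0.02)
  expect_equal(sd(log(pm[, "V2"])), sqrt(0.10), tolerance = 0.02)
})

test_that("zero variances collapse the population layer to the typical subject", {
  m0 <- population_model(final_model$theta, final_model$covariate_effects,
                         omega2 = c(CL = 0, V1 = 0, Q = 0, V2 = 0),
                         sigma2_prop = 0)
  ind <- sample_individual(m0, list(GFR = 50))
  expect_equal(unclass(ind$params),
               unclass(typical_params(m0, list(GFR = 50))))
  expect_equal(unname(ind$eta), rep(0, 4))
  expect_equal(apply_residual(c(0, 5, 20), m0), c(0, 5, 20))
})

test_that("proportional residual error has the right scale", {
  m <- final_model
  set.seed(12)
  obs <- apply_residual(rep(20, 1e5), m)
  expect_equal(mean(obs), 20, tolerance = 0.005)
  expect_equal(sd(obs), 20 * 0.174, tolerance = 0.02)
  expect_equal(apply_residual(0, m), 0)
})

test_that("population model config round-trips through YAML", {
  path <- tempfile(fileext = ".yaml")
  write_population_model(final_model, path)
  m2 <- read_population_model(path)
  expect_equal(m2$theta, final_model$theta)
  expect_equal(m2$omega2, final_model$omega2)
  expect_equal(m2$sigma2_prop, final_model$sigma2_prop)
  expect_equal(m2$covariate_effects[[1]]$beta, 0.437)
  expect_equal(m2$covariate_effects[[1]]$reference, 71.88)
  unlink(path)
})

test_that("the shipped preset equals the in-code final model", {
  preset <- read_population_model(
    system.file("extdata", "sepsis_adult_model.yaml", package = "teicopk"))
  expect_equal(preset$theta, final_model$theta)
  expect_equal(preset$omega2, final_model$omega2)
  expect_equal(preset$sigma2_prop, final_model$sigma2_prop, tolerance = 1e-12)
})

test_that("model validation rejects bad inputs", {
  expect_error(population_model(c(CL = -1, V1 = 20, Q = 3, V2 = 100)),
               "positive")
  expect_error(population_model(final_model$theta,
                                omega2 = c(CL = -0.1, V1 = 0, Q = 0, V2 = 0)),
               "non-negative")
  expect_error(covariate_effect("CL", "GFR", 0.4, reference = -1),
               "reference")
})
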