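test_that("zero IIV makes every replicate the typical subject", {
  m0 <- population_model(final_model$theta, final_model$covariate_effects,
                         omega2 = c(CL = 0, V1 = 0, Q = 0, V2 = 0),
                         sigma2_prop = 0)
  s <- simulate_regimen(m0, gfr = 120, std_regimen, n = 20, seed = 61)
  expect_equal(length(unique(s$cmin72)), 1L)
  p <- typical_params(m0, list(GFR = 120))
  doses <- build_events(std_regimen)
  expect_equal(s$cmin72[1], conc_at(p, doses, 72))
  expect_equal(s$cmin240[1], conc_at(p, doses, 240))
  expect_equal(s$auc24[1],
               pk_auc(p, doses, 240, 264, method = "trapezoid"),
               tolerance = 1e-10)
})

test_that("the AUC assessment window follows the maintenance interval", {
  q24 <- regimen_spec(c(15, 12), c(15, 24), c(15, 24), c(15, 24))
  q48 <- regimen_spec(c(15, 12), c(15, 24), c(15, 24), c(15, 48))
  q72 <- regimen_spec(c(15, 12), c(15, 24), c(15, 24), c(15, 72))
  expect_equal(teicopk:::auc_window(q24), c(240, 264))
  expect_equal(teicopk:::auc_window(q48), c(216, 264))
  expect_equal(teicopk:::auc_window(q72), c(216, 264))
})

test_that("metric summaries use median and central 95 percent interval", {
  x <- tibble::tibble(cmin72 = (1:1000) / 10)
  sm <- summarize_metrics(x)
  expect_equal(sm$median, 50.05)
  expect_lt(abs(sm$lo - 2.6), 0.5)
  expect_lt(abs(sm$hi - 97.5), 0.5)
  cst <- tibble::tibble(cmin72 = rep(7, 5))
  smc <- summarize_metrics(cst)
  expect_equal(c(smc$median, smc$lo, smc$hi), c(7, 7, 7))
  expect_error(summarize_metrics(tibble::tibble(cmin72 = numeric())))
})

test_that("medians are stable across independent seeds", {
  m <- final_model
  s1 <- summarize_metrics(simulate_regimen(m, 60, std_regimen, n = 1000,
                                           seed = 62))
  s2 <- summarize_metrics(simulate_regimen(m, 60, std_regimen, n = 1000,
                                           seed = 63))
  expect_lt(max(abs(s1$median / s2$median - 1)), 0.05)
})

test_that("exposure rises with dose and falls with renal function", {
  m <- final_model
  lo <- regimen_spec(c(15, 12), c(15, 24), c(15, 24), c(7.5, 24))
  hi <- regimen_spec(c(15, 12), c(15, 24), c(15, 24), c(15, 24))
  s_lo <- summarize_metrics(simulate_regimen(m, 60, lo, n = 400, seed = 64))
  s_hi <- summarize_metrics(simulate_regimen(m, 60, hi, n = 400, seed = 64))
  expect_gt(s_hi$median[s_hi$metric == "cmin240"],
            s_lo$median[s_lo$metric == "cmin240"])
  expect_gt(s_hi$median[s_hi$metric == "auc24"],
            s_lo$median[s_lo$metric == "auc24"])
  s_g15 <- summarize_metrics(simulate_regimen(m, 15, hi, n = 400, seed = 65))
  s_g120 <- summarize_metrics(simulate_regimen(m, 120, hi, n = 400, seed = 65))
  expect_gt(s_g15$median[s_g15$metric == "cmin72"],
            s_g120$median[s_g120$metric == "cmin72"])
})

test_that("loading-dose comparison: more loading doses raise the Day-4 trough", {
  tab <- loading_dose_table(final_model, gfr_levels = c(120, 30),
                            unit_doses = c(12, 15), n = 400, seed = 66)
  for (g in c(120, 30)) {
    for (ud in c(12, 15)) {
      m3 <- tab$median[tab$gfr == g & tab$unit_dose == ud & tab$n_loading == 3]
      m5 <- tab$median[tab$gfr == g & tab$unit_dose == ud & tab$n_loading == 5]
      expect_gt(m5, m3)
    }
  }
  # lower GFR gives higher troughs at the same loading
  for (ud in c(12, 15)) {
    expect_gt(tab$median[tab$gfr == 30 & tab$unit_dose == ud &
                           tab$n_loading == 3],
              tab$median[tab$gfr == 120 & tab$unit_dose == ud &
                           tab$n_loading == 3])
  }
})
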