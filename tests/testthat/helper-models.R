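# Shared fixtures: the published adult-sepsis model, its disposition
# parameters, and independent oracles (stiff ODE integration via deSolve,
# 1-D quadrature of the marginal likelihood).

final_model <- teicoplanin_sepsis_model()

table_params <- structural_params(CL = 1.03, V1 = 20.1, Q = 3.12, V2 = 101)

# standard maintenance regimen used in several tests:
# 15 mg/kg q12h day 1 then 15 mg/kg daily, 65 kg, 1 h infusions
std_regimen <- regimen_spec(c(15, 12), c(15, 24), c(15, 24), c(15, 24))

# ODE oracle: integrate the two-compartment infusion system with lsoda and
# return central concentrations at `times`
ode_conc <- function(p, doses, times, rtol = 1e-10) {
  mr <- micro_rates(p)
  rate_at <- function(t) {
    sum(doses$amount / doses$duration *
          (t >= doses$start & t < doses$start + doses$duration))
  }
  # integrate segment-by-segment between forcing discontinuities so the
  # solver can never step across an infusion pulse
  bounds <- sort(unique(c(0, doses$start, doses$start + doses$duration,
                          times)))
  bounds <- bounds[bounds <= max(times)]
  y <- c(0, 0)
  got <- stats::setNames(numeric(length(times)), as.character(times))
  if (0 %in% times) got[as.character(0)] <- 0
  for (j in seq_len(length(bounds) - 1)) {
    t0 <- bounds[j]
    t1 <- bounds[j + 1]
    rate <- rate_at((t0 + t1) / 2)
    rhs <- function(t, yy, parms) {
      list(c(rate - (mr[["k10"]] + mr[["k12"]]) * yy[1] + mr[["k21"]] * yy[2],
             mr[["k12"]] * yy[1] - mr[["k21"]] * yy[2]))
    }
    sol <- deSolve::lsoda(y, c(t0, t1), rhs, NULL, rtol = rtol, atol = 1e-12)
    y <- sol[nrow(sol), 2:3]
    if (t1 %in% times) got[as.character(t1)] <- y[1]
  }
  unname(got[as.character(times)]) / p[["V1"]]
}

# quadrature oracle for the single-subject marginal likelihood with IIV on
# CL only: -2 log integral over eta of p(y | eta) p(eta)
quad_ofv_1d <- function(m, subj_times, subj_dv, doses, cov) {
  tv <- unclass(typical_params(m, cov))
  s2 <- m$sigma2_prop
  w2 <- m$omega2[["CL"]]
  joint <- function(eta) {
    vapply(eta, function(e) {
      p <- structural_params(tv["CL"] * exp(e), tv["V1"], tv["Q"], tv["V2"])
      f <- conc_at(p, doses, subj_times)
      exp(sum(stats::dnorm(subj_dv, f, sqrt(s2) * f, log = TRUE)) +
            stats::dnorm(e, 0, sqrt(w2), log = TRUE))
    }, numeric(1))
  }
  -2 * log(stats::integrate(joint, -6, 6, rel.tol = 1e-10)$value)
}

# small noise-free dataset builder: identical covariates, no residual error
noise_free_dataset <- function(n = 4, gfr = 71.88) {
  m0 <- population_model(final_model$theta, final_model$covariate_effects,
                         omega2 = c(CL = 0, V1 = 0, Q = 0, V2 = 0),
                         sigma2_prop = 0)
  rows <- lapply(seq_len(n), function(i) {
    des <- standard_design(arm = (i - 1L) %% 3L + 1L)
    pr <- conc_at(typical_params(m0, list(GFR = gfr)), des$doses,
                  des$sample_times)
    rbind(
      tibble::tibble(ID = i, TIME = des$doses$start, AMT = des$doses$amount,
                     RATE = des$doses$amount / des$doses$duration,
                     DUR = des$doses$duration, EVID = 1L, MDV = 1L,
                     DV = NA_real_, BLQ = 0L, GFR = gfr),
      tibble::tibble(ID = i, TIME = des$sample_times, AMT = 0, RATE = 0,
                     DUR = 0, EVID = 0L, MDV = 0L, DV = pr, BLQ = 0L,
                     GFR = gfr))
  })
  out <- do.call(rbind, rows)
  out[order(out$ID, out$TIME, out$EVID), ]
}
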