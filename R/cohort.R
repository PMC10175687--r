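#' Sample covariate records emulating the septic ICU cohort
#'
#' Draws covariates matching the study population: GFR stratum membership is
#' multinomial with probabilities 0.237 / 0.339 / 0.237 / 0.085 / 0.102 for
#' strata >= 90, 60-90, 30-60, 15-30 and < 15 mL/min/1.73 m2, with GFR uniform
#' within stratum bounds (90-124 at the top, 11-15 at the bottom, matching the
#' observed range 11.0-124). Weight is log-normal with median 65 kg truncated
#' to [35, 90]; age is discrete uniform on 28-92 years; sex is Bernoulli with
#' P(male) = 0.627. The remaining laboratory covariates (ALT, AST, TBIL, DBIL,
#' TP, ALB, WBC, Scr, BUN, height) are sampled independently within the
#' observed ranges purely as distractors for covariate screening; they carry
#' no true effect.
#'
#' @param n Number of subjects.
#' @return Tibble of covariate records, one row per subject.
#' @export
sample_covariates <- function(n) {
  stopifnot(n >= 0)
  if (n == 0L) {
    return(tibble::tibble(GFR = numeric(), WT = numeric(), AGE = numeric(),
                          SEX = integer()))
  }
  strata <- matrix(c(90, 124, 60, 90, 30, 60, 15, 30, 11, 15),
                   ncol = 2, byrow = TRUE)
  probs <- c(0.237, 0.339, 0.237, 0.085, 0.102)
  s <- sample.int(5L, n, replace = TRUE, prob = probs)
  gfr <- stats::runif(n, strata[s, 1], strata[s, 2])
  # log-normal, median 65, truncated to the observed 35-90 kg range by
  # redrawing (sdlog 0.18 keeps truncation mild)
  wt <- stats::rlnorm(n, log(65), 0.18)
  while (any(bad <- wt < 35 | wt > 90)) {
    wt[bad] <- stats::rlnorm(sum(bad), log(65), 0.18)
  }
  age <- sample(28:92, n, replace = TRUE)
  sex <- stats::rbinom(n, 1L, 0.627)  # 1 = male
  height <- stats::runif(n, 1.33, 1.80)
  tibble::tibble(
    GFR = gfr, WT = wt, AGE = as.numeric(age), SEX = sex,
    HT = height, BMI = wt / height^2,
    ALT = stats::rlnorm(n, log(15), 0.9),
    AST = stats::rlnorm(n, log(26), 0.9),
    TBIL = stats::rlnorm(n, log(18.7), 0.8),
    DBIL = stats::rlnorm(n, log(6.8), 0.9),
    TP = stats::runif(n, 33.5, 71.0),
    ALB = stats::runif(n, 15.5, 39.4),
    WBC = stats::runif(n, 2.39, 25.9),
    SCR = stats::rlnorm(n, log(80.3), 0.6),
    BUN = stats::rlnorm(n, log(10.5), 0.7)
  )
}

#' The standard clinical design: doses and sparse TDM sampling times
#'
#' The standard regimen is 400 mg infused q12h for 3 doses then 400 mg once
#' daily (doses at 0, 12, 24, 48, 72, 96 h within the 96 h design window).
#' Four trough samples are scheduled immediately before the 3rd-6th doses
#' (24, 48, 72, 96 h). One extra sample per subject is assigned by thirds:
#' arm 1 at the end of the 5th infusion (72 h + duration), arm 2 at 1 h after
#' the start of the 5th infusion (73 h), arm 3 at 1 h before the 6th dose
#' (95 h).
#'
#' @param arm Extra-sample arm, 1, 2 or 3 (subjects are usually assigned
#'   `(i - 1) %% 3 + 1`).
#' @param infusion_duration Infusion length, h.
#' @param horizon Design window, h.
#' @return List with `doses` ([dose_events]) and `sample_times` (numeric, h).
#' @export
standard_design <- function(arm = 1, infusion_duration = 1, horizon = 96) {
  stopifnot(arm %in% 1:3)
  starts <- c(0, 12, 24, seq(48, horizon, by = 24))
  starts <- starts[starts <= horizon]
  doses <- dose_events(starts, 400, infusion_duration)
  troughs <- c(24, 48, 72, 96)
  extra <- switch(arm,
                  `1` = 72 + infusion_duration,
                  `2` = 72 + 1,
                  `3` = 95)
  times <- sort(unique(c(troughs, extra)))
  list(doses = doses, sample_times = times[times <= horizon])
}

#' Generate a synthetic estimation dataset
#'
#' Forward-simulates a sparse-sampling cohort through the structural and
#' population layers: covariates from [sample_covariates()], individual
#' parameters via [sample_individual()], the standard clinical design from
#' [standard_design()], proportional residual error per observation, optional
#' independent thinning, and below-LOQ flagging at 3.125 mg/L. Negative
#' residual draws are truncated to zero in the written observations (the
#' generative model itself is untruncated).
#'
#' The default `missing_rate` of 46/295 thins the 295 scheduled samples of a
#' 59-subject cohort to about 249, the observed yield of the study design.
#'
#' @param n Number of subjects.
#' @param true_model The generating [population_model].
#' @param missing_rate Independent per-observation thinning probability.
#' @param infusion_duration Infusion length, h.
#' @param loq Lower limit of quantification, mg/L; values below it are
#'   flagged `BLQ = 1`.
#' @param seed Optional integer seed (applied with `set.seed`).
#' @return A `pk_dataset`: tibble with columns `ID`, `TIME`, `AMT`, `RATE`,
#'   `DUR`, `EVID`, `MDV`, `DV`, `BLQ` plus covariate columns, carrying a
#'   `provenance` attribute (seed, true parameter values, generator settings).
#' @export
generate_dataset <- function(n, true_model = teicoplanin_sepsis_model(),
                             missing_rate = 46 / 295,
                             infusion_duration = 1, loq = 3.125,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cov <- sample_covariates(n)
  rows <- vector("list", n)
  etas <- matrix(NA_real_, n, 4)
  for (i in seq_len(n)) {
    des <- standard_design(arm = (i - 1L) %% 3L + 1L,
                           infusion_duration = infusion_duration)
    ind <- sample_individual(true_model, as.list(cov[i, ]))
    etas[i, ] <- ind$eta
    pred <- conc_at(ind$params, des$doses, des$sample_times)
    obs <- apply_residual(pred, true_model)
    obs <- pmax(obs, 0)
    keep <- stats::runif(length(obs)) >= missing_rate
    dose_rows <- tibble::tibble(
      ID = i, TIME = des$doses$start, AMT = des$doses$amount,
      RATE = des$doses$amount / des$doses$duration,
      DUR = des$doses$duration, EVID = 1L, MDV = 1L, DV = NA_real_, BLQ = 0L)
    obs_rows <- tibble::tibble(
      ID = i, TIME = des$sample_times[keep], AMT = 0, RATE = 0, DUR = 0,
      EVID = 0L, MDV = 0L, DV = round(obs[keep], 4),
      BLQ = as.integer(obs[keep] < loq))
    sub <- rbind(dose_rows, obs_rows)
    sub <- sub[order(sub$TIME, sub$EVID), ]  # trough precedes a same-time dose
    rows[[i]] <- cbind(sub, cov[rep(i, nrow(sub)), ])
  }
  out <- tibble::as_tibble(do.call(rbind, rows))
  attr(out, "provenance") <- list(
    seed = seed, n = n, generator = "teicopk standard sparse TDM design",
    missing_rate = missing_rate, loq = loq,
    infusion_duration = infusion_duration,
    true_theta = as.list(true_model$theta),
    true_omega2 = as.list(true_model$omega2),
    true_sigma2_prop = true_model$sigma2_prop)
  class(out) <- c("pk_dataset", class(out))
  out
}
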