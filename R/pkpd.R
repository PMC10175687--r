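#' MIC distribution
#'
#' A discrete histogram of pathogen MIC categories (mg/L) with fractions
#' summing to one, the form in which surveillance data (e.g. EUCAST-style
#' MRSA distributions) are reported. CFR is distribution-version-dependent,
#' so CFR outputs always echo the distribution used; the shipped file
#' `system.file("extdata", "mic_mrsa_synthetic.tsv", package = "teicopk")` is
#' an editable synthetic snapshot concentrated on 0.5-1 mg/L.
#'
#' @param mic Numeric vector of MIC categories, mg/L, strictly positive.
#' @param fraction Non-negative fractions summing to 1 (within 1e-9).
#' @return A `mic_distribution` tibble.
#' @export
mic_distribution <- function(mic, fraction) {
  stopifnot(length(mic) == length(fraction))
  if (any(mic <= 0) || any(fraction < 0)) {
    stop("MIC categories must be positive and fractions non-negative",
         call. = FALSE)
  }
  if (abs(sum(fraction) - 1) > 1e-9) {
    stop("MIC fractions must sum to 1", call. = FALSE)
  }
  out <- tibble::tibble(mic = as.numeric(mic), fraction = as.numeric(fraction))
  out <- out[order(out$mic), ]
  class(out) <- c("mic_distribution", class(out))
  out
}

#' @rdname mic_distribution
#' @param path Two-column whitespace/tab-separated text file (`mic`,
#'   `fraction`), `#` comments allowed.
#' @export
read_mic_distribution <- function(path) {
  df <- utils::read.table(path, header = TRUE, comment.char = "#")
  if (!all(c("mic", "fraction") %in% names(df))) {
    stop("MIC distribution file needs 'mic' and 'fraction' columns",
         call. = FALSE)
  }
  mic_distribution(df$mic, df$fraction)
}

#' Probability of target attainment
#'
#' Fraction of simulated exposures achieving `AUC_0-24 / MIC >= target`; the
#' boundary is inclusive. The efficacy target for teicoplanin against MRSA is
#' an AUC ratio of at least 610.
#'
#' @param auc_samples Per-replicate AUC_0-24 values, mg.h/L.
#' @param mic MIC, mg/L, positive scalar.
#' @param target AUC/MIC target ratio.
#' @return Fraction in `[0, 1]`.
#' @export
pta <- function(auc_samples, mic, target = 610) {
  if (length(auc_samples) == 0L) stop("no AUC samples", call. = FALSE)
  stopifnot(mic > 0, target > 0)
  mean(auc_samples / mic >= target)
}

#' PTA across the MIC grid
#'
#' @inheritParams pta
#' @param mic_grid MIC categories; the conventional grid is
#'   `c(0.25, 0.5, 1, 2, 4)` mg/L.
#' @return Named numeric vector of PTA per MIC.
#' @export
pta_profile <- function(auc_samples, mic_grid = c(0.25, 0.5, 1, 2, 4),
                        target = 610) {
  stats::setNames(vapply(mic_grid, function(m) pta(auc_samples, m, target),
                         numeric(1)),
                  as.character(mic_grid))
}

#' Cumulative fraction of response
#'
#' The PTA averaged over a pathogen MIC distribution:
#' `CFR = sum_i PTA(MIC_i) * p(MIC_i)`. Every distribution category must have
#' a PTA value.
#'
#' @param pta_by_mic Named numeric vector of PTA values keyed by MIC (as
#'   produced by [pta_profile()]).
#' @param dist A [mic_distribution].
#' @return CFR in `[0, 1]`, with the distribution echoed as attribute
#'   `mic_distribution`.
#' @export
cfr <- function(pta_by_mic, dist) {
  stopifnot(inherits(dist, "mic_distribution"))
  key <- as.character(dist$mic)
  miss <- setdiff(key, names(pta_by_mic))
  if (length(miss)) {
    stop("no PTA value for MIC category: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- sum(pta_by_mic[key] * dist$fraction)
  attr(out, "mic_distribution") <- dist
  out
}

#' Classify a regimen against the therapeutic targets
#'
#' Applies the decision rules used for regimen selection: median trough within
#' the therapeutic band (15-30 mg/L for non-complicated MRSA infection,
#' 20-40 mg/L for complicated), median AUC_0-24/MIC >= 610, PTA >= 90%, and a
#' CFR class of optimal (>= 90%), moderate (80-90%) or inadequate (< 80%).
#' A regimen meeting the trough, AUC ratio and PTA criteria is classified
#' optimal for the given infection type.
#'
#' @param summary Tibble from [summarize_metrics()] (needs `cmin240` and
#'   `auc24` rows); the steady-state trough is judged against the band.
#' @param pta_at_mic PTA at the clinically relevant MIC (scalar fraction).
#' @param cfr_value Optional CFR (scalar fraction); `NA` to skip.
#' @param mic MIC used for the AUC ratio criterion, mg/L.
#' @param infection `"non-complicated"` or `"complicated"`.
#' @return List of booleans `cmin_ok`, `auc_mic_ok`, `pta_ok`, the `cfr_class`
#'   string, and overall `optimal`.
#' @export
classify_regimen <- function(summary, pta_at_mic, cfr_value = NA_real_,
                             mic = 1,
                             infection = c("non-complicated", "complicated")) {
  infection <- match.arg(infection)
  band <- if (infection == "non-complicated") c(15, 30) else c(20, 40)
  med <- function(metric) {
    r <- summary$median[summary$metric == metric]
    if (!length(r)) NA_real_ else r
  }
  cmin <- med("cmin240")
  aucr <- med("auc24") / mic
  cmin_ok <- !is.na(cmin) && cmin >= band[1] && cmin <= band[2]
  auc_ok <- !is.na(aucr) && aucr >= 610
  pta_ok <- pta_at_mic >= 0.9
  cfr_class <- if (is.na(cfr_value)) NA_character_
    else if (cfr_value >= 0.9) "optimal"
    else if (cfr_value >= 0.8) "moderate"
    else "inadequate"
  list(cmin_ok = cmin_ok, auc_mic_ok = auc_ok, pta_ok = pta_ok,
       cfr_class = cfr_class, infection = infection,
       optimal = cmin_ok && auc_ok && pta_ok)
}

#' Recommended regimen by renal function
#'
#' The GFR-stratified regimens selected by the dosing analysis: 15 mg/kg q12h
#' for 5 doses then 15 mg/kg q24h for GFR 90-124; 15 mg/kg q12h for 3 doses,
#' 15 mg/kg on day 3, then 15 mg/kg q48h for GFR 30-60 (and 60-90); and
#' 12 mg/kg q12h for 3 doses, 12 mg/kg on day 3, then 12 mg/kg q72h for
#' GFR below 30.
#'
#' @param gfr GFR, mL/min/1.73 m2.
#' @param weight Body weight, kg.
#' @return A [regimen_spec].
#' @export
recommend_regimen <- function(gfr, weight = 65) {
  stopifnot(is.finite(gfr), gfr > 0)
  if (gfr >= 90) {
    regimen_spec(c(15, 12), c(15, 12), c(15, 24), c(15, 24), weight = weight)
  } else if (gfr >= 30) {
    regimen_spec(c(15, 12), c(15, 24), c(15, 24), c(15, 48), weight = weight)
  } else {
    regimen_spec(c(12, 12), c(12, 24), c(12, 24), c(12, 72), weight = weight)
  }
}
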