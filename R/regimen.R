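#' Declarative loading/maintenance regimen
#'
#' Describes a candidate teicoplanin schedule the way dosing tables do: a
#' per-day rule for days 1-3 (dose in mg/kg and interval within that day) and
#' a maintenance rule from day 4 onward. Day 1 starts at 0 h, day 2 at 24 h,
#' day 3 at 48 h, maintenance at 72 h.
#'
#' @param day1,day2,day3 Length-2 numeric `c(dose_mg_kg, interval_h)`; the
#'   interval must be 12 or 24 (q12h gives two doses within the day).
#' @param maintenance Length-2 numeric `c(dose_mg_kg, interval_h)`; interval
#'   must be 24, 48 or 72.
#' @param weight Body weight, kg (the simulations use a typical 65 kg patient).
#' @param infusion_duration Infusion length, h (0.5 or 1 h in practice).
#' @param horizon Simulation horizon, h; doses at or beyond it are dropped.
#' @param round_amounts If `TRUE`, round each dose to the nearest 100 mg as
#'   done for clinical convenience (15 mg/kg x 65 kg -> 1000 mg); default keeps
#'   exact mg/kg amounts.
#' @return An object of class `regimen_spec`.
#' @export
regimen_spec <- function(day1, day2, day3, maintenance, weight = 65,
                         infusion_duration = 1, horizon = 264,
                         round_amounts = FALSE) {
  chk <- function(rule, name, allowed) {
    if (length(rule) != 2L || anyNA(rule) || rule[1] < 0 ||
        !(rule[2] %in% allowed)) {
      stop(sprintf("%s rule must be c(dose_mg_kg >= 0, interval in {%s})",
                   name, paste(allowed, collapse = ",")), call. = FALSE)
    }
  }
  chk(day1, "day1", c(12, 24))
  chk(day2, "day2", c(12, 24))
  chk(day3, "day3", c(12, 24))
  chk(maintenance, "maintenance", c(24, 48, 72))
  if (!is.finite(weight) || weight <= 0) stop("weight must be > 0",
                                              call. = FALSE)
  if (infusion_duration <= 0) stop("infusion duration must be > 0",
                                   call. = FALSE)
  structure(list(day1 = day1, day2 = day2, day3 = day3,
                 maintenance = maintenance, weight = weight,
                 infusion_duration = infusion_duration, horizon = horizon,
                 round_amounts = round_amounts),
            class = "regimen_spec")
}

#' Expand a regimen specification into dose events
#'
#' Day rules place doses at the day start (0, 24, 48 h) plus a second dose
#' 12 h later when the day's interval is q12h; the maintenance rule runs from
#' 72 h at its interval. Only doses starting strictly before the horizon are
#' emitted. Amounts are `mg/kg * weight` exactly unless `round_amounts`.
#'
#' @param spec A [regimen_spec].
#' @return A [dose_events] tibble, sorted by start time.
#' @examples
#' # 15 mg/kg q12h day 1, then 15 mg/kg daily: 975 mg at 0,12,24,48,72,...,240
#' build_events(regimen_spec(c(15, 12), c(15, 24), c(15, 24), c(15, 24)))
#' @export
build_events <- function(spec) {
  stopifnot(inherits(spec, "regimen_spec"))
  amt <- function(mg_kg) {
    a <- mg_kg * spec$weight
    if (spec$round_amounts) a <- round(a / 100) * 100
    a
  }
  starts <- numeric()
  amounts <- numeric()
  add <- function(t, a) {
    starts <<- c(starts, t)
    amounts <<- c(amounts, a)
  }
  for (day in 1:3) {
    rule <- spec[[paste0("day", day)]]
    t0 <- (day - 1) * 24
    if (rule[1] > 0) {
      add(t0, amt(rule[1]))
      if (rule[2] == 12) add(t0 + 12, amt(rule[1]))
    }
  }
  if (spec$maintenance[1] > 0) {
    t <- 72
    while (t < spec$horizon) {
      add(t, amt(spec$maintenance[1]))
      t <- t + spec$maintenance[2]
    }
  }
  keep <- starts < spec$horizon
  ord <- order(starts[keep])
  dose_events(starts[keep][ord], amounts[keep][ord],
              spec$infusion_duration)
}

#' Read a regimen file
#'
#' One regimen per row, CSV with header columns `label`, `gfr`,
#' `day1_dose`, `day1_int`, `day2_dose`, `day2_int`, `day3_dose`, `day3_int`,
#' `maint_dose`, `maint_int` (doses mg/kg, intervals h) and optional `weight`,
#' `infusion_duration`, `horizon`. The shipped candidate set
#' `system.file("extdata", "candidate_regimens.csv", package = "teicopk")`
#' holds the GFR-stratified regimens evaluated in the dosing analysis.
#'
#' @param path CSV file path.
#' @return Tibble with one row per regimen and a list-column `spec` of
#'   [regimen_spec] objects.
#' @export
read_regimens <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "gfr", "day1_dose", "day1_int", "day2_dose", "day2_int",
            "day3_dose", "day3_int", "maint_dose", "maint_int")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("regimen file is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(df$weight)) df$weight <- 65
  if (is.null(df$infusion_duration)) df$infusion_duration <- 1
  if (is.null(df$horizon)) df$horizon <- 264
  df <- tibble::as_tibble(df)
  df$spec <- lapply(seq_len(nrow(df)), function(i) {
    regimen_spec(c(df$day1_dose[i], df$day1_int[i]),
                 c(df$day2_dose[i], df$day2_int[i]),
                 c(df$day3_dose[i], df$day3_int[i]),
                 c(df$maint_dose[i], df$maint_int[i]),
                 weight = df$weight[i],
                 infusion_duration = df$infusion_duration[i],
                 horizon = df$horizon[i])
  })
  df
}
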