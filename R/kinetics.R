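#' Arrhenius kinetics parameters for oxytocin degradation
#'
#' Oxytocin in aqueous solution at pH 4.5 (its most stable pH) degrades by
#' first-order kinetics with a temperature-dependent rate constant
#' \deqn{k(T) = A e^{-E_a / (R T)}}{k(T) = A * exp(-Ea/(R*T))}
#' with `T` in kelvin. This constructor validates and stores the
#' pre-exponential factor `A` (1/day), the activation energy `Ea` (J/mol) and
#' the gas constant `R` (J/(mol K)).
#'
#' @param arrhenius_A Pre-exponential factor, 1/day. Must be > 0.
#' @param activation_energy_Ea Activation energy, J/mol. Must be > 0
#'   (0 is allowed for the degenerate temperature-independent case produced
#'   by calibrating to two anchors with equal fractions).
#' @param gas_constant_R Ideal gas constant, J/(mol K). Fixed at 8.314.
#' @return An object of class `kinetics_params`.
#' @seealso [calibrate_kinetics()] to obtain parameters from stability
#'   anchors, [rate_constant()], [remaining_strength()].
#' @export
kinetics_params <- function(arrhenius_A, activation_energy_Ea,
                            gas_constant_R = 8.314) {
  stopifnot(is.numeric(arrhenius_A), length(arrhenius_A) == 1L,
            is.numeric(activation_energy_Ea), length(activation_energy_Ea) == 1L)
  if (!is.finite(arrhenius_A) || arrhenius_A <= 0)
    stop("'arrhenius_A' must be a finite positive number", call. = FALSE)
  if (!is.finite(activation_energy_Ea) || activation_energy_Ea < 0)
    stop("'activation_energy_Ea' must be finite and >= 0", call. = FALSE)
  structure(
    list(arrhenius_A = arrhenius_A,
         activation_energy_Ea = activation_energy_Ea,
         gas_constant_R = gas_constant_R),
    class = "kinetics_params")
}

#' @export
print.kinetics_params <- function(x, ...) {
  cat("Arrhenius kinetics (first-order, pH 4.5):\n")
  cat(sprintf("  A  = %.6g /day\n", x$arrhenius_A))
  cat(sprintf("  Ea = %.6g J/mol\n", x$activation_energy_Ea))
  cat(sprintf("  R  = %.4g J/(mol K)\n", x$gas_constant_R))
  invisible(x)
}

#' First-order degradation rate constant at a given temperature
#'
#' Evaluates the Arrhenius expression `k = A * exp(-Ea / (R * T))` at a
#' storage temperature given in degrees Celsius. The rate constant is
#' strictly positive and strictly increasing in temperature (for Ea > 0).
#'
#' @param temp_c Storage temperature, degrees Celsius. Vectorised. Must be
#'   finite and above absolute zero (-273.15).
#' @param params A [kinetics_params()] object; defaults to the two-point
#'   calibration of [calibrate_kinetics()].
#' @return Rate constant(s), per day.
#' @export
#' @examples
#' k <- rate_constant(35)          # about 2.45e-3 /day
#' rate_constant(45) > k           # TRUE: faster decay when warmer
rate_constant <- function(temp_c, params = calibrate_kinetics()) {
  stopifnot(inherits(params, "kinetics_params"), is.numeric(temp_c))
  if (any(!is.finite(temp_c)) || any(temp_c <= -273.15))
    stop("temperature must be finite and above absolute zero (-273.15 degC)",
         call. = FALSE)
  T_kelvin <- temp_c + 273.15
  params$arrhenius_A *
    exp(-params$activation_energy_Ea / (params$gas_constant_R * T_kelvin))
}

#' Viable dose strength remaining after storage
#'
#' Integrates first-order decay over a storage interval: in the default
#' `"exponential"` mode the remaining strength is
#' `initial_strength * exp(-k(T) * days)`. The `"discrete-linear"` mode
#' instead applies the rate-times-interval update `s <- s * (1 - 7 * k)`
#' once per 7-day week (floored at zero), a coarser scheme that agrees with
#' the exponential to first order when `7 * k` is small.
#'
#' @param initial_strength Starting viable fraction, in `[0, 1]`.
#' @param temp_c Constant storage temperature, degrees Celsius.
#' @param days Storage duration in days; must be >= 0. In
#'   `"discrete-linear"` mode it is interpreted as `days / 7` whole weekly
#'   updates (fractional remainder applied as a partial linear step).
#' @param params A [kinetics_params()] object.
#' @param mode `"exponential"` (exact closed form, default) or
#'   `"discrete-linear"`.
#' @return Remaining viable strength as a fraction in `[0, initial_strength]`.
#' @export
#' @examples
#' remaining_strength(1, 35, 91)   # 0.80 by calibration construction
#' remaining_strength(1, 45, 91)   # 0.20
remaining_strength <- function(initial_strength, temp_c, days,
                               params = calibrate_kinetics(),
                               mode = c("exponential", "discrete-linear")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(initial_strength), is.numeric(days))
  if (any(initial_strength < 0) || any(initial_strength > 1))
    stop("'initial_strength' must lie in [0, 1]", call. = FALSE)
  if (any(!is.finite(days)) || any(days < 0))
    stop("'days' must be finite and >= 0", call. = FALSE)
  k <- rate_constant(temp_c, params)
  if (mode == "exponential") {
    return(initial_strength * exp(-k * days))
  }
  # discrete-linear: per-week multiplicative update floored at 0
  step <- pmax(0, 1 - 7 * k)
  full_weeks <- floor(days / 7)
  rem_days <- days - 7 * full_weeks
  s <- initial_strength * step^full_weeks * pmax(0, 1 - k * rem_days)
  pmin(s, initial_strength)
}

#' Calibrate Arrhenius constants from two stability anchors
#'
#' Solves for the unique `(A, Ea)` pair whose first-order decay reproduces
#' two measured stability anchors exactly. Each anchor gives the viable
#' fraction remaining after a storage interval at one temperature; the
#' per-day rate at each anchor is `k = -log(fraction) / days`, and
#' \deqn{E_a = R \log(k_h/k_l) / (1/T_l - 1/T_h)}
#' with `A` recovered from either anchor. The defaults are the quarter-year
#' (91-day) anchors for oxytocin at pH 4.5: 80\% remaining at 35 degC and
#' 20\% remaining at 45 degC.
#'
#' @param anchor_low,anchor_high Named numeric vectors
#'   `c(temp_c = , strength = , days = )` at two distinct temperatures, with
#'   strengths in (0, 1) and positive durations.
#' @param gas_constant_R Ideal gas constant, J/(mol K).
#' @return A [kinetics_params()] object reproducing both anchors to
#'   round-off.
#' @export
#' @examples
#' kp <- calibrate_kinetics()
#' kp$activation_energy_Ea          # about 1.611e5 J/mol
#' remaining_strength(1, 35, 91, kp)  # 0.80
calibrate_kinetics <- function(anchor_low = oxy_defaults()$anchor_low,
                               anchor_high = oxy_defaults()$anchor_high,
                               gas_constant_R = 8.314) {
  for (a in list(anchor_low, anchor_high)) {
    if (!all(c("temp_c", "strength", "days") %in% names(a)))
      stop("anchors need named elements temp_c, strength, days", call. = FALSE)
    if (a[["strength"]] <= 0 || a[["strength"]] >= 1)
      stop("anchor strengths must lie strictly in (0, 1)", call. = FALSE)
    if (a[["days"]] <= 0)
      stop("anchor durations must be positive", call. = FALSE)
  }
  T_l <- anchor_low[["temp_c"]] + 273.15
  T_h <- anchor_high[["temp_c"]] + 273.15
  if (isTRUE(all.equal(T_l, T_h)))
    stop("calibration requires two distinct temperatures", call. = FALSE)
  k_l <- -log(anchor_low[["strength"]]) / anchor_low[["days"]]
  k_h <- -log(anchor_high[["strength"]]) / anchor_high[["days"]]
  Ea <- gas_constant_R * log(k_h / k_l) / (1 / T_l - 1 / T_h)
  A <- k_l * exp(Ea / (gas_constant_R * T_l))
  kinetics_params(A, Ea, gas_constant_R)
}

#' Viable-strength bands mapping dose strength to effective doses
#'
#' A dose at or above `full_min` strength counts in full; between
#' `double_min` and `full_min` two physical doses are needed per patient
#' (half credit); between `triple_min` and `double_min`, three (one-third
#' credit); below `triple_min` the stock is non-viable and counts for
#' nothing. Bands are half-open: `[full_min, 1]`, `[double_min, full_min)`,
#' `[triple_min, double_min)`, `[0, triple_min)`, so they partition `[0, 1]`.
#'
#' @param full_min Lower edge of the full-strength band (default 0.85).
#' @param double_min Lower edge of the double-dosing band (default 0.54).
#' @param triple_min Lower edge of the triple-dosing band (default 0.33).
#' @return An object of class `strength_bands`.
#' @export
strength_bands <- function(full_min = 0.85, double_min = 0.54,
                           triple_min = 0.33) {
  if (!(0 < triple_min && triple_min < double_min &&
        double_min < full_min && full_min < 1))
    stop("bands must satisfy 0 < triple_min < double_min < full_min < 1",
         call. = FALSE)
  structure(list(full_min = full_min, double_min = double_min,
                 triple_min = triple_min),
            class = "strength_bands")
}

#' Physical doses needed per patient dose at a given strength
#'
#' @param strength Viable strength fraction(s) in `[0, 1]`.
#' @param bands A [strength_bands()] object.
#' @return Integer multiplier 1, 2 or 3; `NA` where stock is non-viable
#'   (strength below the triple band).
#' @export
dose_multiplier <- function(strength, bands = strength_bands()) {
  stopifnot(inherits(bands, "strength_bands"))
  out <- rep(NA_integer_, length(strength))
  out[strength >= bands$full_min] <- 1L
  out[strength >= bands$double_min & strength < bands$full_min] <- 2L
  out[strength >= bands$triple_min & strength < bands$double_min] <- 3L
  out
}

#' Effective doses in a stock of partially degraded vials
#'
#' Discounts a physical stock for potency loss using the band rule: full
#' credit at >= 85\% strength, half at 54-85\%, one third at 33-54\%, zero
#' below 33\%. Divided counts are floored because doses are physical vials.
#'
#' @param stock Physical dose count, >= 0.
#' @param strength Viable strength fraction of the stock, in `[0, 1]`.
#' @param bands A [strength_bands()] object.
#' @return Effective (patient-equivalent) dose count, an integer-valued
#'   number.
#' @export
#' @examples
#' effective_doses(100, 0.90)  # 100
#' effective_doses(100, 0.70)  # 50
#' effective_doses(99, 0.40)   # 33
#' effective_doses(1000, 0.30) # 0
effective_doses <- function(stock, strength, bands = strength_bands()) {
  stopifnot(is.numeric(stock), is.numeric(strength))
  if (any(stock < 0)) stop("'stock' must be >= 0", call. = FALSE)
  if (any(strength < 0) || any(strength > 1))
    stop("'strength' must lie in [0, 1]", call. = FALSE)
  m <- dose_multiplier(strength, bands)
  ifelse(is.na(m), 0, floor(stock / as.numeric(m)))
}

#' Weekly temperature profile
#'
#' An ordered table of weekly storage temperatures. Week indices are
#' 0-based and strictly increasing; the final temperature extends beyond the
#' last listed week so any simulation horizon is covered.
#'
#' @param week Integer vector of 0-based week indices, strictly increasing.
#' @param temp_c Finite temperatures in degrees Celsius, one per week entry.
#' @return A `data.frame` of class `temperature_profile` with columns
#'   `week` and `temp_c`.
#' @seealso [temperature_at()], [constant_temperature()],
#'   [generate_temperature_fixture()].
#' @export
temperature_profile <- function(week, temp_c) {
  stopifnot(is.numeric(week), is.numeric(temp_c),
            length(week) == length(temp_c), length(week) >= 1L)
  week <- as.integer(week)
  if (any(week < 0L)) stop("week indices must be >= 0", call. = FALSE)
  if (any(diff(week) <= 0L))
    stop("week indices must be strictly increasing", call. = FALSE)
  if (any(!is.finite(temp_c)))
    stop("temperatures must be finite", call. = FALSE)
  structure(data.frame(week = week, temp_c = temp_c),
            class = c("temperature_profile", "data.frame"))
}

#' Constant temperature profile
#'
#' @param temp_c Constant storage temperature, degrees Celsius.
#' @return A single-row [temperature_profile()] (the last value extends).
#' @export
constant_temperature <- function(temp_c = oxy_defaults()$storage_temp_c) {
  temperature_profile(0L, temp_c)
}

#' Temperature in force at a given simulation week
#'
#' Step-function lookup: each listed temperature applies from its week until
#' the next listed week; the last value extends indefinitely.
#'
#' @param profile A [temperature_profile()].
#' @param week 0-based week index (vectorised).
#' @return Temperature(s) in degrees Celsius.
#' @export
temperature_at <- function(profile, week) {
  stopifnot(inherits(profile, "temperature_profile"), all(week >= 0))
  idx <- findInterval(week, profile$week)
  if (any(idx == 0L))
    stop("profile does not cover week(s) before its first entry",
         call. = FALSE)
  profile$temp_c[idx]
}

#' Tabulate dose strength across temperatures and storage times
#'
#' Convenience table behind the `stability-table` CLI subcommand: remaining
#' strength on a (temperature, days) grid under first-order kinetics.
#'
#' @param temps_c Temperatures, degrees Celsius.
#' @param days Storage durations, days.
#' @param params A [kinetics_params()] object.
#' @return A `data.frame` with columns `temp_c`, `days`, `strength`.
#' @export
stability_table <- function(temps_c = c(25, 30, 35, 40, 45, 50),
                            days = c(7, 28, 91, 182, 364),
                            params = calibrate_kinetics()) {
  grid <- expand.grid(temp_c = temps_c, days = days,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$temp_c, grid$days), , drop = FALSE]
  rownames(grid) <- NULL
  grid$strength <- remaining_strength(1, grid$temp_c, grid$days, params)
  grid
}
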