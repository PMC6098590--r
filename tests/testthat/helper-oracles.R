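# Independent oracles used across the test suite. These deliberately avoid
# the package's own code paths: closed forms, manual bisection, and a
# day-resolution brute-force re-implementation of the inventory rules.

# Closed-form per-day rate constant implied by a stability anchor:
# fraction f remaining after `days` at one temperature.
oracle_rate_from_anchor <- function(fraction, days) -log(fraction) / days

# Closed-form Arrhenius activation energy from two anchors.
oracle_Ea <- function(t_low_c, f_low, t_high_c, f_high, days = 91,
                      R = 8.314) {
  k_l <- oracle_rate_from_anchor(f_low, days)
  k_h <- oracle_rate_from_anchor(f_high, days)
  R * log(k_h / k_l) / (1 / (t_low_c + 273.15) - 1 / (t_high_c + 273.15))
}

# Share-weighted logistic cell mixture over richest x literate x rural,
# written out longhand, and a manual bisection for its baseline.
oracle_mixture <- function(b, lit, rich, rur,
                           or_w = 2.55, or_l = 1.99, or_r = 0.82) {
  inv_logit <- function(x) 1 / (1 + exp(-x))
  total <- 0
  for (w in 0:1) for (l in 0:1) for (r in 0:1) {
    wgt <- (if (w) rich else 1 - rich) * (if (l) lit else 1 - lit) *
      (if (r) rur else 1 - rur)
    total <- total + wgt *
      inv_logit(b + w * log(or_w) + l * log(or_l) + r * log(or_r))
  }
  total
}

oracle_baseline_bisect <- function(target, lit, rich, rur,
                                   lo = -20, hi = 20, iters = 60) {
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (oracle_mixture(mid, lit, rich, rur) < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Day-resolution brute-force inventory simulator. Same rules as the weekly
# engine -- equal shipments arriving at week starts, band-based effective
# doses, FIFO service with 1/2/3 physical doses per patient and cross-cohort
# straddling -- but decay advances one day at a time and patients are served
# one by one in a plain loop. Returns the average of the 52 weekly access
# ratios (recorded post-decay, pre-consumption).
oracle_day_simulator <- function(annual_doses, shipments_per_year,
                                 weekly_demand_doses, temp_c,
                                 kin = oxyaccess::calibrate_kinetics(),
                                 full_min = 0.85, double_min = 0.54,
                                 triple_min = 0.33) {
  k <- kin$arrhenius_A *
    exp(-kin$activation_energy_Ea / (kin$gas_constant_R * (temp_c + 273.15)))
  day_factor <- exp(-k)
  ship_weeks <- floor(52 * (seq_len(shipments_per_year) - 1) /
                        shipments_per_year)
  per_ship <- round(annual_doses / shipments_per_year)
  mult_of <- function(s) {
    if (s >= full_min) 1L
    else if (s >= double_min) 2L
    else if (s >= triple_min) 3L
    else NA_integer_
  }
  doses <- numeric(0); strength <- numeric(0)
  ratios <- numeric(52)
  for (wk in 0:51) {
    if (wk %in% ship_weeks && per_ship > 0) {
      doses <- c(doses, per_ship); strength <- c(strength, 1)
    }
    for (d in 1:7) strength <- strength * day_factor
    eff <- 0
    for (i in seq_along(doses)) {
      m <- mult_of(strength[i])
      if (!is.na(m)) eff <- eff + floor(doses[i] / m)
    }
    wtn <- min(c(ship_weeks[ship_weeks > wk], 52 + ship_weeks[1])) - wk
    ratios[wk + 1] <- eff / (weekly_demand_doses * wtn)
    # serve ceil(weekly demand) patients one at a time, oldest cohort first
    patients <- ceiling(weekly_demand_doses)
    while (patients > 0) {
      idx <- which(doses > 0 & !is.na(vapply(strength, mult_of, integer(1))))
      if (!length(idx)) break
      need_frac <- 1
      served <- TRUE
      while (need_frac > 1e-12) {
        idx <- which(doses > 0 &
                       !is.na(vapply(strength, mult_of, integer(1))))
        if (!length(idx)) { served <- FALSE; break }
        i <- idx[1]
        m <- mult_of(strength[i])
        need <- ceiling(need_frac * m)
        take <- min(need, doses[i])
        doses[i] <- doses[i] - take
        need_frac <- need_frac - take / m
        if (take == need) need_frac <- 0
      }
      if (!served) break
      patients <- patients - 1
    }
    keep <- doses > 0 & strength >= triple_min
    doses <- doses[keep]; strength <- strength[keep]
  }
  mean(ratios)
}
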