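#' Annual supply plan and shipment calendar
#'
#' The national order of `annual_doses` arrives in `shipments_per_year`
#' equal shipments at equally spaced weeks, the first in week 0 (0-based).
#' Shipment weeks are `floor(52 * i / n)` for `i = 0, ..., n - 1`: two
#' shipments a year arrive at weeks 0 and 26 (semiannual restock), four at
#' weeks 0, 13, 26 and 39.
#'
#' @param annual_doses Total doses ordered per year, >= 0.
#' @param shipments_per_year Number of equal shipments, >= 1.
#' @param weeks_per_year Length of the simulated year in weeks (52).
#' @return An object of class `supply_plan` with fields `annual_doses`,
#'   `shipments_per_year`, `shipment_weeks` (0-based) and
#'   `doses_per_shipment`.
#' @export
#' @examples
#' supply_plan(26500, 2)$shipment_weeks   # 0 26
#' supply_plan(52000, 4)$doses_per_shipment  # 13000
supply_plan <- function(annual_doses, shipments_per_year = 2L,
                        weeks_per_year = 52L) {
  if (!is.numeric(annual_doses) || annual_doses < 0)
    stop("'annual_doses' must be >= 0", call. = FALSE)
  if (!is.numeric(shipments_per_year) || shipments_per_year < 1)
    stop("'shipments_per_year' must be >= 1", call. = FALSE)
  n <- as.integer(shipments_per_year)
  structure(
    list(annual_doses = annual_doses,
         shipments_per_year = n,
         shipment_weeks = as.integer(floor(weeks_per_year * (seq_len(n) - 1) / n)),
         doses_per_shipment = round(annual_doses / n),
         weeks_per_year = as.integer(weeks_per_year)),
    class = "supply_plan")
}

#' Shipment calendar of a supply plan
#'
#' @param plan A [supply_plan()].
#' @return A `data.frame` with columns `week` (0-based arrival week) and
#'   `doses`.
#' @export
build_schedule <- function(plan) {
  stopifnot(inherits(plan, "supply_plan"))
  data.frame(week = plan$shipment_weeks,
             doses = rep(plan$doses_per_shipment,
                         length(plan$shipment_weeks)))
}

#' Weeks from a given week until the next shipment arrives
#'
#' Counts the current week, so the week immediately before an arrival has
#' one week of demand left to cover. After the year's last shipment the
#' horizon wraps to the first shipment of the following year.
#'
#' @param week Current 0-based week index.
#' @param plan A [supply_plan()].
#' @return Integer number of weeks >= 1.
#' @export
weeks_to_next_shipment <- function(week, plan) {
  stopifnot(inherits(plan, "supply_plan"))
  upcoming <- c(plan$shipment_weeks[plan$shipment_weeks > week],
                plan$weeks_per_year + plan$shipment_weeks[1])
  as.integer(min(upcoming) - week)
}

#' Weekly access ratio
#'
#' Effective doses in stock in a week divided by the demand those doses must
#' cover until the next shipment arrives (weekly demand times weeks to next
#' shipment, current week included). A ratio of 1.0 means supply exactly
#' meets demand; the ratio is deliberately uncapped, so oversupply shows up
#' as values above 1.
#'
#' @param effective Effective doses in stock (post-decay).
#' @param weekly_demand Expected doses demanded per week; must be > 0.
#' @param weeks_to_next Weeks until the next shipment, >= 1.
#' @return The access ratio (>= 0, possibly > 1).
#' @export
#' @examples
#' weekly_access_ratio(1000, 100, 5)  # 2
#' weekly_access_ratio(500, 100, 5)   # 1
weekly_access_ratio <- function(effective, weekly_demand, weeks_to_next) {
  if (!is.numeric(weekly_demand) || any(weekly_demand <= 0))
    stop("'weekly_demand' must be > 0 for the access ratio to be defined",
         call. = FALSE)
  if (any(weeks_to_next < 1))
    stop("'weeks_to_next' must be >= 1", call. = FALSE)
  effective / (weekly_demand * weeks_to_next)
}

#' Empty inventory state
#'
#' @return A fresh state for [step_week()]: no cohorts, zeroed dose
#'   accounting.
#' @export
new_inventory_state <- function() {
  list(arrival = integer(), doses = numeric(), strength = numeric(),
       supplied = 0, consumed = 0, written_off = 0, shortfall = 0)
}

# Serve `patients` patient-doses FIFO from the cohorts in `state`. Each
# patient draws 1/2/3 physical doses according to the serving cohort's
# strength band, atomically from one cohort; when a cohort runs out
# mid-patient the covered fraction carries over and the remainder is drawn
# from the next cohort at that cohort's own multiplier (rounded up to whole
# vials). Returns the updated state plus doses drawn and patients unserved.
.serve_fifo <- function(state, patients, bands) {
  consumed <- 0
  carry <- 0  # fraction of the current straddling patient already covered
  i <- 1L
  while (patients > 0 && i <= length(state$arrival)) {
    m <- dose_multiplier(state$strength[i], bands)
    if (is.na(m)) { i <- i + 1L; next }  # non-viable; written off later
    d <- state$doses[i]
    if (carry > 0) {
      need <- ceiling((1 - carry) * m)
      take <- min(need, d)
      d <- d - take; consumed <- consumed + take
      if (take == need) { carry <- 0; patients <- patients - 1 }
      else carry <- carry + take / m
    }
    if (carry == 0 && patients > 0) {
      n_full <- min(patients, d %/% m)
      d <- d - n_full * m
      consumed <- consumed + n_full * m
      patients <- patients - n_full
      if (patients > 0 && d > 0) {   # partial coverage of the next patient
        carry <- d / m
        consumed <- consumed + d
        d <- 0
      }
    }
    state$doses[i] <- d
    i <- i + 1L
  }
  # a patient left straddling at stock-out remains counted as unserved
  list(state = state, consumed = consumed, unserved = patients)
}

#' Advance the inventory by one week
#'
#' One tick of the weekly stock-and-flow engine, in order: (1) a shipment
#' cohort arrives at full strength if this is a shipment week; (2) every
#' cohort decays by 7 days at this week's temperature; (3) effective doses
#' are computed per cohort with the band rule and summed; (4) the week's
#' demand, rounded up to whole patient doses, is served FIFO (oldest cohort
#' first), each patient drawing 1, 2 or 3 physical doses according to the
#' serving cohort's band; (5) cohorts whose strength has fallen below the
#' non-viable threshold are written off; (6) the weekly access ratio is
#' recorded from the post-decay, pre-consumption effective doses. Unmet
#' demand is recorded as shortfall, never an error.
#'
#' @param state Inventory state from [new_inventory_state()] or a previous
#'   call.
#' @param week Current 0-based week index.
#' @param plan A [supply_plan()].
#' @param temp_profile A [temperature_profile()].
#' @param weekly_demand_doses Expected doses demanded this week (> 0 for the
#'   ratio to be defined).
#' @param bands A [strength_bands()] object.
#' @param kinetics A [kinetics_params()] object.
#' @param decay_mode Passed to [remaining_strength()].
#' @return A list with elements `state` (advanced state) and `record` (a
#'   named list: `week`, `effective_doses`, `forward_demand`,
#'   `access_ratio`, `consumed`, `shortfall`).
#' @export
step_week <- function(state, week, plan, temp_profile, weekly_demand_doses,
                      bands = strength_bands(),
                      kinetics = calibrate_kinetics(),
                      decay_mode = "exponential") {
  if (weekly_demand_doses <= 0)
    stop("'weekly_demand_doses' must be > 0 (access ratio undefined)",
         call. = FALSE)
  year_week <- week %% plan$weeks_per_year
  # (1) shipment arrival
  if (!is.na(match(year_week, plan$shipment_weeks)) &&
      plan$doses_per_shipment > 0) {
    state$arrival <- c(state$arrival, week)
    state$doses <- c(state$doses, plan$doses_per_shipment)
    state$strength <- c(state$strength, 1)
    state$supplied <- state$supplied + plan$doses_per_shipment
  }
  # (2) one week of decay at this week's temperature
  if (length(state$strength)) {
    temp <- temperature_at(temp_profile, min(week, max(temp_profile$week)))
    state$strength <- remaining_strength(state$strength, temp, 7,
                                         kinetics, decay_mode)
  }
  # (3) effective doses, post-decay pre-consumption
  effective <- if (length(state$doses))
    sum(effective_doses(state$doses, state$strength, bands)) else 0
  # (4) serve demand FIFO
  patients <- ceiling(weekly_demand_doses)
  served <- .serve_fifo(state, patients, bands)
  state <- served$state
  state$consumed <- state$consumed + served$consumed
  state$shortfall <- state$shortfall + served$unserved
  # (5) write off non-viable cohorts, drop empty ones
  nonviable <- is.na(dose_multiplier(state$strength, bands))
  state$written_off <- state$written_off + sum(state$doses[nonviable])
  keep <- !nonviable & state$doses > 0
  state$arrival <- state$arrival[keep]
  state$doses <- state$doses[keep]
  state$strength <- state$strength[keep]
  # (6) record
  wtn <- weeks_to_next_shipment(year_week, plan)
  record <- list(
    week = week,
    effective_doses = effective,
    forward_demand = weekly_demand_doses * wtn,
    access_ratio = effective / (weekly_demand_doses * wtn),
    consumed = served$consumed,
    shortfall = served$unserved)
  list(state = state, record = record)
}

#' Simulate one 52-week supply year
#'
#' Runs [step_week()] for weeks 0-51 from an empty inventory and summarises
#' the year. The average access ratio is the arithmetic mean of the 52
#' weekly ratios. Dose accounting is exact: every physical dose supplied is
#' either consumed, written off as non-viable, or carried over at year end.
#'
#' @param pop A [population_state()].
#' @param model An [access_model()]; used to derive the facility-delivery
#'   probability unless `p_access` is given directly.
#' @param demand A [demand_params()] object.
#' @param plan A [supply_plan()].
#' @param temp_profile A [temperature_profile()] (or a single number, taken
#'   as a constant temperature in degC).
#' @param bands A [strength_bands()] object.
#' @param kinetics A [kinetics_params()] object.
#' @param p_access Optional facility-delivery probability overriding the
#'   model-derived value (useful for scenario work at a pinned access
#'   level).
#' @param decay_mode Passed to [remaining_strength()].
#' @return An object of class `simulation_result`: list with `records` (52
#'   rows: `week`, `effective_doses`, `forward_demand`, `access_ratio`,
#'   `consumed`, `shortfall`), `average_access_ratio`, `weekly_demand`,
#'   `p_access`, `doses_supplied`, `doses_consumed`, `doses_lost_to_decay`,
#'   `doses_carried_over`.
#' @export
#' @examples
#' res <- simulate_year(plan = supply_plan(26500, 2), p_access = 0.5)
#' res$average_access_ratio
simulate_year <- function(pop = population_state(),
                          model = access_model(),
                          demand = demand_params(),
                          plan,
                          temp_profile = constant_temperature(),
                          bands = strength_bands(),
                          kinetics = calibrate_kinetics(),
                          p_access = NULL,
                          decay_mode = "exponential") {
  stopifnot(inherits(plan, "supply_plan"))
  if (is.numeric(temp_profile))
    temp_profile <- constant_temperature(temp_profile)
  if (is.null(p_access))
    p_access <- facility_access_probability(pop, model)
  wd <- weekly_demand(pop, p_access, demand)
  if (wd <= 0)
    stop("weekly demand must be > 0 to simulate (zero births or access)",
         call. = FALSE)
  state <- new_inventory_state()
  nw <- plan$weeks_per_year
  eff <- fwd <- ratio <- cons <- short <- numeric(nw)
  for (w in seq_len(nw) - 1L) {
    out <- step_week(state, w, plan, temp_profile, wd, bands, kinetics,
                     decay_mode)
    state <- out$state
    r <- out$record
    eff[w + 1L] <- r$effective_doses
    fwd[w + 1L] <- r$forward_demand
    ratio[w + 1L] <- r$access_ratio
    cons[w + 1L] <- r$consumed
    short[w + 1L] <- r$shortfall
  }
  records <- data.frame(week = seq_len(nw) - 1L, effective_doses = eff,
                        forward_demand = fwd, access_ratio = ratio,
                        consumed = cons, shortfall = short)
  structure(
    list(records = records,
         average_access_ratio = mean(records$access_ratio),
         weekly_demand = wd,
         p_access = p_access,
         doses_supplied = state$supplied,
         doses_consumed = state$consumed,
         doses_lost_to_decay = state$written_off,
         doses_carried_over = sum(state$doses),
         shortfall_patient_doses = state$shortfall),
    class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("52-week oxytocin supply simulation\n")
  cat(sprintf("  weekly demand        : %.2f doses\n", x$weekly_demand))
  cat(sprintf("  average access ratio : %.4f\n", x$average_access_ratio))
  cat(sprintf("  supplied %d | consumed %d | written off %d | carried over %d\n",
              round(x$doses_supplied), round(x$doses_consumed),
              round(x$doses_lost_to_decay), round(x$doses_carried_over)))
  invisible(x)
}

#' Minimal annual supply achieving a target average access ratio
#'
#' Searches over the annual order size for the smallest supply whose
#' 52-week average access ratio reaches `target_ratio`, holding all other
#' model inputs fixed. Because doses are integers the average ratio is a
#' step function of the annual order, so the bisection runs on an integer
#' bracket until it collapses and returns the smallest supply attaining the
#' target, rounded to the nearest 100 doses (requirements are reported in
#' round hundreds).
#'
#' @param target_ratio Target average access ratio, > 0.
#' @param pop,model,demand,bands,kinetics,p_access,decay_mode As in
#'   [simulate_year()].
#' @param shipments_per_year Number of equal shipments per year.
#' @param temp_profile Constant temperature (degC) or a
#'   [temperature_profile()].
#' @param round_to Rounding granularity of the reported requirement
#'   (default 100 doses; use 1 for the raw integer).
#' @return Minimal annual doses (numeric scalar).
#' @export
#' @examples
#' \donttest{
#' minimal_supply(1.0, p_access = 0.5)   # 26500 at the defaults
#' }
minimal_supply <- function(target_ratio = 1.0,
                           pop = population_state(),
                           model = access_model(),
                           demand = demand_params(),
                           shipments_per_year = 2L,
                           temp_profile = constant_temperature(),
                           bands = strength_bands(),
                           kinetics = calibrate_kinetics(),
                           p_access = NULL,
                           decay_mode = "exponential",
                           round_to = 100) {
  if (!is.numeric(target_ratio) || target_ratio <= 0)
    stop("'target_ratio' must be > 0", call. = FALSE)
  if (is.null(p_access))
    p_access <- facility_access_probability(pop, model)
  wd <- weekly_demand(pop, p_access, demand)
  if (wd <= 0)
    stop("weekly demand is zero; no finite supply meets a positive target",
         call. = FALSE)
  avg_at <- function(annual) {
    simulate_year(pop, model, demand,
                  supply_plan(annual, shipments_per_year),
                  temp_profile, bands, kinetics, p_access, decay_mode)$average_access_ratio
  }
  # bracket: grow until the target is attainable
  hi <- ceiling(52 * wd * max(1, target_ratio) * 2)
  while (avg_at(hi) < target_ratio) {
    hi <- hi * 2
    if (hi > 1e8)
      stop("target average access ratio unreachable: supply growth cannot ",
           "compensate (e.g. stock decays to non-viable before use)",
           call. = FALSE)
  }
  lo <- 0
  while (hi - lo > 1) {
    mid <- floor((lo + hi) / 2)
    if (avg_at(mid) >= target_ratio) hi <- mid else lo <- mid
  }
  round(hi / round_to) * round_to
}
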