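#' Intervention specification for multi-year projections
#'
#' Literacy campaigns raise the literacy rate by a fixed number of
#' percentage points per year (capped at 100\%); family-planning programmes
#' lower the birth growth rate. The published large long-run effects arise
#' when the birth-rate decline compounds, i.e. each intervention year
#' subtracts the stated percentage points from the growth rate again
#' (`cumulative = TRUE`, the default); a one-time reduction is available
#' with `cumulative = FALSE`.
#'
#' @param literacy_increase_per_year Percentage points of literacy gained
#'   per year (e.g. 0.02 for 2 pp/yr), as a fraction.
#' @param birth_decline_per_year Percentage points per year subtracted from
#'   the population growth rate, as a fraction (e.g. 0.005 for 0.5 pp/yr).
#' @param start_year First year (0-based) the intervention applies.
#' @param horizon_years Number of projected years beyond the baseline year.
#' @param cumulative Whether the birth-rate decline compounds yearly.
#' @param allow_negative_growth If `FALSE`, the growth rate is floored at 0.
#' @return An object of class `intervention_spec`.
#' @export
intervention_spec <- function(literacy_increase_per_year = 0,
                              birth_decline_per_year = 0,
                              start_year = 0L,
                              horizon_years,
                              cumulative = TRUE,
                              allow_negative_growth = TRUE) {
  if (horizon_years < 1) stop("'horizon_years' must be >= 1", call. = FALSE)
  if (literacy_increase_per_year < 0 || birth_decline_per_year < 0)
    stop("intervention rates must be >= 0", call. = FALSE)
  structure(
    list(literacy_increase_per_year = literacy_increase_per_year,
         birth_decline_per_year = birth_decline_per_year,
         start_year = as.integer(start_year),
         horizon_years = as.integer(horizon_years),
         cumulative = isTRUE(cumulative),
         allow_negative_growth = isTRUE(allow_negative_growth)),
    class = "intervention_spec")
}

#' Project births and literacy over a multi-year horizon
#'
#' Year 0 is the baseline; births then compound at the (possibly
#' intervention-reduced) growth rate, `births_y = births_0 * prod(1 + g)`,
#' and literacy rises linearly until it saturates at 100\%. The returned
#' table has `horizon_years + 1` rows (years 0 through the horizon).
#'
#' @param pop A [population_state()] giving the baseline.
#' @param spec An [intervention_spec()].
#' @return A `data.frame` with columns `year`, `annual_births`,
#'   `literacy_rate`, `growth_rate` (the rate applied to reach that year).
#' @export
#' @examples
#' tr <- project_population(population_state(),
#'                          intervention_spec(horizon_years = 30))
#' tr$annual_births[31] / tr$annual_births[1]  # 1.03^30 = 2.427
project_population <- function(pop, spec) {
  stopifnot(inherits(pop, "population_state"),
            inherits(spec, "intervention_spec"))
  years <- 0:spec$horizon_years
  births <- numeric(length(years))
  lit <- numeric(length(years))
  g <- numeric(length(years))
  births[1] <- pop$annual_births
  lit[1] <- pop$literacy_rate
  g[1] <- pop$growth_rate
  for (i in seq_along(years)[-1]) {
    y <- years[i]
    active_years <- max(0, y - spec$start_year)  # intervention years elapsed
    g_y <- if (spec$cumulative)
      pop$growth_rate - spec$birth_decline_per_year * active_years
    else
      pop$growth_rate -
        (if (active_years > 0) spec$birth_decline_per_year else 0)
    if (!spec$allow_negative_growth) g_y <- max(0, g_y)
    g[i] <- g_y
    births[i] <- births[i - 1] * (1 + g_y)
    lit[i] <- min(1, pop$literacy_rate +
                    spec$literacy_increase_per_year * active_years)
  }
  data.frame(year = years, annual_births = births, literacy_rate = lit,
             growth_rate = g)
}

#' Annual supply required to hold the access ratio at 1 over a projection
#'
#' For each projected year, re-runs the full weekly inventory engine
#' ([minimal_supply()]) with that year's births and literacy-driven access
#' probability, so temperature-band interactions are respected rather than
#' scaling the baseline year.
#'
#' @param trajectory Output of [project_population()].
#' @param pop Baseline [population_state()] (supplies composition fields
#'   not tracked in the trajectory).
#' @param model,demand,bands,kinetics,decay_mode As in [simulate_year()].
#' @param shipments_per_year Number of equal shipments per year.
#' @param temp_profile Constant temperature (degC) or profile.
#' @param target_ratio Target average access ratio (default 1.0).
#' @param p_access Optional fixed access probability; if `NULL` it is
#'   recomputed each year from that year's literacy rate.
#' @return The trajectory with columns `p_access` and `required_supply`
#'   appended.
#' @export
required_supply_trajectory <- function(trajectory,
                                       pop = population_state(),
                                       model = access_model(),
                                       demand = demand_params(),
                                       shipments_per_year = 2L,
                                       temp_profile = constant_temperature(),
                                       bands = strength_bands(),
                                       kinetics = calibrate_kinetics(),
                                       target_ratio = 1.0,
                                       p_access = NULL,
                                       decay_mode = "exponential") {
  stopifnot(is.data.frame(trajectory),
            all(c("year", "annual_births", "literacy_rate") %in%
                  names(trajectory)))
  n <- nrow(trajectory)
  p <- numeric(n)
  req <- numeric(n)
  for (i in seq_len(n)) {
    pop_y <- pop
    pop_y$annual_births <- trajectory$annual_births[i]
    pop_y$literacy_rate <- trajectory$literacy_rate[i]
    p[i] <- if (is.null(p_access))
      facility_access_probability(pop_y, model) else p_access
    req[i] <- minimal_supply(target_ratio, pop_y, model, demand,
                             shipments_per_year, temp_profile, bands,
                             kinetics, p_access = p[i],
                             decay_mode = decay_mode)
  }
  trajectory$p_access <- p
  trajectory$required_supply <- req
  trajectory
}

#' Access-ratio decline under a fixed annual supply
#'
#' Holds the annual order constant while births grow along the projection
#' and records each year's average access ratio from a full 52-week
#' simulation. With positive growth the series is strictly decreasing.
#'
#' @param fixed_supply Annual doses held constant, > 0.
#' @inheritParams required_supply_trajectory
#' @return The trajectory with columns `p_access` and
#'   `average_access_ratio` appended.
#' @export
access_decline_trajectory <- function(fixed_supply,
                                      trajectory,
                                      pop = population_state(),
                                      model = access_model(),
                                      demand = demand_params(),
                                      shipments_per_year = 2L,
                                      temp_profile = constant_temperature(),
                                      bands = strength_bands(),
                                      kinetics = calibrate_kinetics(),
                                      p_access = NULL,
                                      decay_mode = "exponential") {
  if (!is.numeric(fixed_supply) || fixed_supply <= 0)
    stop("'fixed_supply' must be > 0", call. = FALSE)
  stopifnot(is.data.frame(trajectory))
  n <- nrow(trajectory)
  p <- numeric(n)
  avg <- numeric(n)
  plan <- supply_plan(fixed_supply, shipments_per_year)
  for (i in seq_len(n)) {
    pop_y <- pop
    pop_y$annual_births <- trajectory$annual_births[i]
    pop_y$literacy_rate <- trajectory$literacy_rate[i]
    p[i] <- if (is.null(p_access))
      facility_access_probability(pop_y, model) else p_access
    avg[i] <- simulate_year(pop_y, model, demand, plan, temp_profile,
                            bands, kinetics, p_access = p[i],
                            decay_mode = decay_mode)$average_access_ratio
  }
  trajectory$p_access <- p
  trajectory$average_access_ratio <- avg
  trajectory
}

#' Fraction of the annual order lost before reaching patients
#'
#' Compares the doses actually ordered nationally with the requirement the
#' model computes: `(ordered - required) / ordered`. With the published
#' 100,000-dose order and the modelled 26,500-dose requirement at 50\%
#' access, 73.5\% of the national supply is unaccounted for.
#'
#' @param ordered Doses ordered per year, > 0.
#' @param required Doses required per year, in `[0, ordered]`.
#' @return The loss fraction in `[0, 1]`.
#' @export
#' @examples
#' loss_fraction(100000, 26500)  # 0.735
loss_fraction <- function(ordered, required) {
  if (!is.numeric(ordered) || ordered <= 0)
    stop("'ordered' must be > 0", call. = FALSE)
  if (!is.numeric(required) || required < 0 || required > ordered)
    stop("'required' must lie in [0, ordered]", call. = FALSE)
  (ordered - required) / ordered
}

#' Sweep storage temperature and record quality and access
#'
#' Runs a constant-temperature 52-week simulation at each temperature and
#' tabulates the end-of-quarter (91-day) dose strength and the average
#' access ratio. Degradation is negligible until about 30 degC and the
#' access ratio is non-increasing in temperature, with the collapse
#' localised above the critical ~30 degC region.
#'
#' @param temps_c Temperatures to sweep, degrees Celsius, each in (0, 60).
#' @param annual_doses Annual order size used at every temperature.
#' @inheritParams required_supply_trajectory
#' @return A `data.frame` with columns `temp_c`, `quarter_strength`,
#'   `average_access_ratio`.
#' @export
temperature_sweep <- function(temps_c,
                              annual_doses,
                              pop = population_state(),
                              model = access_model(),
                              demand = demand_params(),
                              shipments_per_year = 2L,
                              bands = strength_bands(),
                              kinetics = calibrate_kinetics(),
                              p_access = NULL,
                              decay_mode = "exponential") {
  if (any(temps_c <= 0) || any(temps_c >= 60))
    stop("'temps_c' must lie within (0, 60) degC", call. = FALSE)
  plan <- supply_plan(annual_doses, shipments_per_year)
  avg <- vapply(temps_c, function(tc) {
    simulate_year(pop, model, demand, plan, constant_temperature(tc),
                  bands, kinetics, p_access = p_access,
                  decay_mode = decay_mode)$average_access_ratio
  }, numeric(1))
  data.frame(temp_c = temps_c,
             quarter_strength = remaining_strength(1, temps_c, 91, kinetics),
             average_access_ratio = avg)
}
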