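#' Population state of the catchment area
#'
#' Demographic and socioeconomic composition driving facility-delivery
#' demand: annual births, the adult female literacy rate, wealth-quintile
#' shares, rural residence, the share living within 5 km of a delivery
#' facility, and the annual population growth rate.
#'
#' @param annual_births Births per year, >= 0.
#' @param literacy_rate Literate fraction in `[0, 1]`.
#' @param wealth_quintile_shares Five shares summing to 1 (poorest to
#'   richest); only the richest-quintile share enters the access model.
#' @param rural_share Rural-resident fraction in `[0, 1]`.
#' @param within_5km_share Fraction living within 5 km of a facility.
#' @param growth_rate Annual population growth rate (fraction/year).
#' @return An object of class `population_state`.
#' @export
#' @examples
#' pop <- population_state()
#' pop$annual_births
population_state <- function(annual_births = oxy_defaults()$annual_births,
                             literacy_rate = oxy_defaults()$literacy_rate,
                             wealth_quintile_shares =
                               oxy_defaults()$wealth_quintile_shares,
                             rural_share = oxy_defaults()$rural_share,
                             within_5km_share =
                               oxy_defaults()$within_5km_share,
                             growth_rate = oxy_defaults()$growth_rate) {
  if (!is.numeric(annual_births) || annual_births < 0)
    stop("'annual_births' must be >= 0", call. = FALSE)
  shares <- c(literacy_rate, wealth_quintile_shares, rural_share,
              within_5km_share)
  if (any(shares < 0) || any(shares > 1))
    stop("all shares must lie in [0, 1]", call. = FALSE)
  if (length(wealth_quintile_shares) != 5L)
    stop("'wealth_quintile_shares' must have length 5", call. = FALSE)
  if (abs(sum(wealth_quintile_shares) - 1) > 1e-9)
    stop("'wealth_quintile_shares' must sum to 1", call. = FALSE)
  structure(
    list(annual_births = as.numeric(annual_births),
         literacy_rate = as.numeric(literacy_rate),
         wealth_quintile_shares = as.numeric(wealth_quintile_shares),
         rural_share = as.numeric(rural_share),
         within_5km_share = as.numeric(within_5km_share),
         growth_rate = as.numeric(growth_rate)),
    class = "population_state")
}

#' Facility-delivery access model from published odds ratios
#'
#' Turns covariate odds ratios (richest wealth quintile 2.55, literacy 1.99,
#' rural residence 0.82) into a probability that a pregnant woman delivers
#' at a health facility. Two functional forms are provided because the odds
#' ratios alone do not determine one:
#'
#' * `"anchored_linear"` (default): the literacy response is pinned to the
#'   published endpoints, 41\% facility delivery for a fully illiterate
#'   population rising linearly to 53\% for a fully literate one; deviations
#'   of the richest-quintile and rural shares from their defaults perturb
#'   the result on the log-odds scale using their odds ratios.
#' * `"logistic"`: the population is partitioned into the eight
#'   richest-quintile x literate x rural cells; each cell's probability is
#'   `plogis(baseline_log_odds + sum(log OR * indicator))` and the result is
#'   the share-weighted mean. The baseline must first be calibrated (see
#'   [calibrate_baseline()]) to a known marginal such as the observed ~50\%
#'   facility-delivery fraction.
#'
#' @param or_wealth_richest Odds ratio for the richest wealth quintile.
#' @param or_literacy Odds ratio for literacy.
#' @param or_rural Odds ratio for rural residence (< 1: rural women are less
#'   likely to deliver at a facility; this is also the model's distance
#'   proxy).
#' @param baseline_log_odds Baseline log-odds of the reference cell
#'   (non-richest, illiterate, non-rural); `NA` until calibrated.
#' @param mode `"anchored_linear"` or `"logistic"`.
#' @return An object of class `access_model`.
#' @export
access_model <- function(or_wealth_richest = oxy_defaults()$or_wealth_richest,
                         or_literacy = oxy_defaults()$or_literacy,
                         or_rural = oxy_defaults()$or_rural,
                         baseline_log_odds = NA_real_,
                         mode = c("anchored_linear", "logistic")) {
  mode <- match.arg(mode)
  ors <- c(or_wealth_richest, or_literacy, or_rural)
  if (any(!is.finite(ors)) || any(ors <= 0))
    stop("odds ratios must be finite and > 0", call. = FALSE)
  structure(
    list(or_wealth_richest = or_wealth_richest, or_literacy = or_literacy,
         or_rural = or_rural, baseline_log_odds = baseline_log_odds,
         mode = mode),
    class = "access_model")
}

# Anchored-linear literacy response: published endpoints 41% -> 53%.
.anchor_p0 <- 0.41
.anchor_slope <- 0.12

#' Probability that a pregnant woman delivers at a facility
#'
#' Share-weighted facility-delivery probability for a population under an
#' [access_model()]. See that help page for the two functional forms.
#'
#' @param pop A [population_state()].
#' @param model An [access_model()]; logistic mode requires a calibrated
#'   baseline.
#' @return A probability strictly inside (0, 1).
#' @export
#' @examples
#' facility_access_probability(population_state(literacy_rate = 0))   # 0.41
#' facility_access_probability(population_state(literacy_rate = 1))   # 0.53
facility_access_probability <- function(pop, model = access_model()) {
  stopifnot(inherits(pop, "population_state"),
            inherits(model, "access_model"))
  if (model$mode == "anchored_linear") {
    d <- oxy_defaults()
    p_lin <- .anchor_p0 + .anchor_slope * pop$literacy_rate
    shift <-
      log(model$or_wealth_richest) *
        (pop$wealth_quintile_shares[5] - d$wealth_quintile_shares[5]) +
      log(model$or_rural) * (pop$rural_share - d$rural_share)
    return(stats::plogis(stats::qlogis(p_lin) + shift))
  }
  if (!is.finite(model$baseline_log_odds))
    stop("logistic mode requires a calibrated baseline; ",
         "run calibrate_baseline() first", call. = FALSE)
  .logistic_cell_mixture(model$baseline_log_odds, pop, model)
}

# Share-weighted mean of cell probabilities over the 8 covariate cells
# (richest quintile x literate x rural), assuming independent composition.
.logistic_cell_mixture <- function(baseline, pop, model) {
  rich <- pop$wealth_quintile_shares[5]
  lit <- pop$literacy_rate
  rur <- pop$rural_share
  lo <- c(log(model$or_wealth_richest), log(model$or_literacy),
          log(model$or_rural))
  total <- 0
  for (w in 0:1) for (l in 0:1) for (r in 0:1) {
    wgt <- (if (w) rich else 1 - rich) * (if (l) lit else 1 - lit) *
      (if (r) rur else 1 - rur)
    total <- total +
      wgt * stats::plogis(baseline + w * lo[1] + l * lo[2] + r * lo[3])
  }
  total
}

#' Calibrate the logistic baseline to a known facility-delivery marginal
#'
#' Finds the baseline log-odds at which the logistic cell mixture reproduces
#' a target marginal probability (for the reference setting, the observed
#' ~50\% of women delivering at a facility). The mixture is strictly
#' increasing in the baseline, so the root is unique; it is found by
#' [stats::uniroot()] to 1e-12.
#'
#' @param pop A [population_state()] giving the composition.
#' @param model An [access_model()] in `"logistic"` mode.
#' @param target Target marginal probability, strictly inside (0, 1).
#' @return The model with `baseline_log_odds` set.
#' @export
#' @examples
#' m <- calibrate_baseline(population_state(),
#'                         access_model(mode = "logistic"), 0.5)
#' facility_access_probability(population_state(), m)  # 0.5
calibrate_baseline <- function(pop, model, target = 0.5) {
  stopifnot(inherits(pop, "population_state"),
            inherits(model, "access_model"))
  if (model$mode != "logistic")
    stop("baseline calibration applies to logistic mode only", call. = FALSE)
  if (!is.numeric(target) || target <= 0 || target >= 1)
    stop("'target' must lie strictly in (0, 1)", call. = FALSE)
  f <- function(b) .logistic_cell_mixture(b, pop, model) - target
  root <- stats::uniroot(f, interval = c(-50, 50), tol = 1e-12,
                         extendInt = "upX")
  model$baseline_log_odds <- root$root
  model
}

#' Demand parameters for oxytocin at delivery
#'
#' Standard practice in the reference setting: every facility birth receives
#' one prophylactic 10 IU dose, and 2\% of women develop postpartum
#' hemorrhage (PPH), each requiring four additional therapeutic doses. With
#' these defaults expected demand is 1.08 doses per facility birth.
#'
#' @param prophylactic_doses_per_birth Doses given prophylactically per
#'   facility birth.
#' @param pph_rate PPH incidence among delivering women, in `[0, 1]`.
#' @param extra_doses_per_pph Additional doses per PPH case.
#' @param therapeutic_dose_iu Dose size in international units (recorded for
#'   reporting; demand is counted in doses).
#' @return An object of class `demand_params`.
#' @export
demand_params <- function(prophylactic_doses_per_birth =
                            oxy_defaults()$prophylactic_doses_per_birth,
                          pph_rate = oxy_defaults()$pph_rate,
                          extra_doses_per_pph =
                            oxy_defaults()$extra_doses_per_pph,
                          therapeutic_dose_iu =
                            oxy_defaults()$therapeutic_dose_iu) {
  if (pph_rate < 0 || pph_rate > 1)
    stop("'pph_rate' must lie in [0, 1]", call. = FALSE)
  if (prophylactic_doses_per_birth < 0 || extra_doses_per_pph < 0)
    stop("dose counts must be >= 0", call. = FALSE)
  structure(
    list(prophylactic_doses_per_birth = prophylactic_doses_per_birth,
         pph_rate = pph_rate, extra_doses_per_pph = extra_doses_per_pph,
         therapeutic_dose_iu = therapeutic_dose_iu),
    class = "demand_params")
}

#' Expected doses of demand per facility birth
#'
#' @param d A [demand_params()] object.
#' @return `prophylactic + pph_rate * extra_doses_per_pph` (1.08 at the
#'   defaults).
#' @export
demand_multiplier <- function(d = demand_params()) {
  stopifnot(inherits(d, "demand_params"))
  d$prophylactic_doses_per_birth + d$pph_rate * d$extra_doses_per_pph
}

#' Expected weekly oxytocin demand at facilities
#'
#' Demand is deterministic (expected value), held constant across the year:
#' `annual_births / 52` weekly births, times the facility-delivery
#' probability, times the doses-per-birth multiplier. The result is real
#' valued; rounding to whole patient doses happens only when the inventory
#' engine serves demand.
#'
#' @param pop A [population_state()].
#' @param p_access Facility-delivery probability in `[0, 1]`.
#' @param d A [demand_params()] object.
#' @return Expected doses demanded per week.
#' @export
#' @examples
#' weekly_demand(population_state(annual_births = 49074), 1)  # 1019.23
weekly_demand <- function(pop, p_access, d = demand_params()) {
  stopifnot(inherits(pop, "population_state"))
  if (!is.numeric(p_access) || p_access < 0 || p_access > 1)
    stop("'p_access' must lie in [0, 1]", call. = FALSE)
  (pop$annual_births / 52) * p_access * demand_multiplier(d)
}

#' Effect of moving women within 5 km of a facility
#'
#' Re-evaluates the access probability after a share of the population is
#' brought within 5 km of a delivery facility, e.g. by building new EmONC
#' facilities. Distance enters the model only through the rural-residence
#' odds ratio (0.82), the published distance proxy: the moved share is
#' reclassified from rural to non-rural. Because that odds ratio is close
#' to 1, even doubling the within-5-km share from 50\% to nearly 100\%
#' raises the probability by only a few percentage points.
#'
#' @param pop A [population_state()].
#' @param new_within_5km_share New within-5-km share in `[0, 1]`.
#' @param model An [access_model()].
#' @return The facility-delivery probability under the new composition.
#' @export
distance_scenario <- function(pop, new_within_5km_share,
                              model = access_model()) {
  stopifnot(inherits(pop, "population_state"))
  if (new_within_5km_share < 0 || new_within_5km_share > 1)
    stop("'new_within_5km_share' must lie in [0, 1]", call. = FALSE)
  moved <- new_within_5km_share - pop$within_5km_share
  pop$rural_share <- min(1, max(0, pop$rural_share - moved))
  pop$within_5km_share <- new_within_5km_share
  facility_access_probability(pop, model)
}
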