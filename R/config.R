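#' Load and validate a run configuration
#'
#' Reads a YAML run configuration and validates every block against the
#' model's type invariants before any simulation starts. Unknown keys are a
#' hard error (no silent typo tolerance) and all invariant violations in a
#' file are reported together. An empty file (or `NULL` path) yields the
#' full default configuration for the reference setting: 49,074 annual
#' births, 3\% growth, 67\% literacy, two shipments a year, 25 degC storage.
#'
#' Recognised blocks and keys (all optional):
#' \describe{
#'   \item{population}{`annual_births`, `literacy_rate`,
#'     `wealth_quintile_shares` (5 values), `rural_share`,
#'     `within_5km_share`, `growth_rate`}
#'   \item{access}{`or_wealth_richest`, `or_literacy`, `or_rural`, `mode`
#'     (`anchored_linear`/`logistic`), `target` (marginal used to calibrate
#'     the logistic baseline), `p_access` (direct override)}
#'   \item{demand}{`prophylactic_doses_per_birth`, `pph_rate`,
#'     `extra_doses_per_pph`, `therapeutic_dose_iu`}
#'   \item{supply}{`annual_doses`, `shipments_per_year`}
#'   \item{kinetics}{either `arrhenius_A` + `activation_energy_Ea`, or
#'     anchor lists `anchor_low`/`anchor_high` (`temp_c`, `strength`,
#'     `days`); `decay_mode`}
#'   \item{temperature}{`constant` (degC) or `csv` (path to a
#'     `week,temp_c` file)}
#'   \item{scenario}{`literacy_increase_per_year`, `birth_decline_per_year`,
#'     `start_year`, `horizon_years`, `cumulative`}
#'   \item{seed}{integer, used only by fixture generation}
#' }
#'
#' @param path Path to a YAML file, or `NULL` for all defaults.
#' @return An object of class `run_config`: a list with elements `pop`,
#'   `model`, `p_access` (or `NULL`), `demand`, `plan`, `kinetics`,
#'   `decay_mode`, `bands`, `temp_profile`, `scenario` (or `NULL`), `seed`.
#' @export
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    x <- yaml::read_yaml(path)
    if (is.null(x)) list() else x
  }
  known_blocks <- c("population", "access", "demand", "supply", "kinetics",
                    "temperature", "scenario", "seed", "output")
  errs <- character()
  unknown <- setdiff(names(raw), known_blocks)
  if (length(unknown))
    errs <- c(errs, paste0("unknown top-level key(s): ",
                           paste(unknown, collapse = ", ")))

  d <- oxy_defaults()
  get_block <- function(name, allowed) {
    blk <- raw[[name]]
    if (is.null(blk)) return(list())
    bad <- setdiff(names(blk), allowed)
    if (length(bad))
      errs <<- c(errs, paste0("unknown key(s) in '", name, "': ",
                              paste(bad, collapse = ", ")))
    blk
  }
  try_make <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      errs <<- c(errs, paste0(what, ": ", conditionMessage(e)))
      NULL
    })
  }

  pb <- get_block("population",
                  c("annual_births", "literacy_rate",
                    "wealth_quintile_shares", "rural_share",
                    "within_5km_share", "growth_rate"))
  pop <- try_make("population", population_state(
    annual_births = pb$annual_births %||% d$annual_births,
    literacy_rate = pb$literacy_rate %||% d$literacy_rate,
    wealth_quintile_shares =
      unlist(pb$wealth_quintile_shares) %||% d$wealth_quintile_shares,
    rural_share = pb$rural_share %||% d$rural_share,
    within_5km_share = pb$within_5km_share %||% d$within_5km_share,
    growth_rate = pb$growth_rate %||% d$growth_rate))

  ab <- get_block("access", c("or_wealth_richest", "or_literacy", "or_rural",
                              "mode", "target", "p_access"))
  model <- try_make("access", access_model(
    or_wealth_richest = ab$or_wealth_richest %||% d$or_wealth_richest,
    or_literacy = ab$or_literacy %||% d$or_literacy,
    or_rural = ab$or_rural %||% d$or_rural,
    mode = ab$mode %||% "anchored_linear"))
  if (!is.null(model) && model$mode == "logistic" && !is.null(pop))
    model <- try_make("access", calibrate_baseline(
      pop, model, ab$target %||% d$access_target))
  p_access <- ab$p_access
  if (!is.null(p_access) && (p_access < 0 || p_access > 1))
    errs <- c(errs, "access: 'p_access' must lie in [0, 1]")

  db <- get_block("demand", c("prophylactic_doses_per_birth", "pph_rate",
                              "extra_doses_per_pph", "therapeutic_dose_iu"))
  dem <- try_make("demand", demand_params(
    prophylactic_doses_per_birth =
      db$prophylactic_doses_per_birth %||% d$prophylactic_doses_per_birth,
    pph_rate = db$pph_rate %||% d$pph_rate,
    extra_doses_per_pph = db$extra_doses_per_pph %||% d$extra_doses_per_pph,
    therapeutic_dose_iu = db$therapeutic_dose_iu %||% d$therapeutic_dose_iu))

  sb <- get_block("supply", c("annual_doses", "shipments_per_year"))
  plan <- try_make("supply", supply_plan(
    annual_doses = sb$annual_doses %||% 26500,
    shipments_per_year = sb$shipments_per_year %||% d$shipments_per_year))

  kb <- get_block("kinetics", c("arrhenius_A", "activation_energy_Ea",
                                "anchor_low", "anchor_high", "decay_mode"))
  kin <- try_make("kinetics", {
    if (!is.null(kb$arrhenius_A) || !is.null(kb$activation_energy_Ea)) {
      kinetics_params(kb$arrhenius_A, kb$activation_energy_Ea)
    } else {
      al <- if (is.null(kb$anchor_low)) d$anchor_low else
        unlist(kb$anchor_low)[c("temp_c", "strength", "days")]
      ah <- if (is.null(kb$anchor_high)) d$anchor_high else
        unlist(kb$anchor_high)[c("temp_c", "strength", "days")]
      calibrate_kinetics(al, ah)
    }
  })
  decay_mode <- kb$decay_mode %||% "exponential"
  if (!decay_mode %in% c("exponential", "discrete-linear"))
    errs <- c(errs, "kinetics: 'decay_mode' must be exponential or discrete-linear")

  tb <- get_block("temperature", c("constant", "csv"))
  temp_profile <- try_make("temperature", {
    if (!is.null(tb$csv)) read_temperature_csv(tb$csv)
    else constant_temperature(tb$constant %||% d$storage_temp_c)
  })

  scb <- get_block("scenario",
                   c("literacy_increase_per_year", "birth_decline_per_year",
                     "start_year", "horizon_years", "cumulative"))
  scenario <- if (length(scb)) try_make("scenario", intervention_spec(
    literacy_increase_per_year = scb$literacy_increase_per_year %||% 0,
    birth_decline_per_year = scb$birth_decline_per_year %||% 0,
    start_year = scb$start_year %||% 0L,
    horizon_years = scb$horizon_years %||% 30L,
    cumulative = scb$cumulative %||% TRUE)) else NULL

  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  structure(
    list(pop = pop, model = model, p_access = p_access, demand = dem,
         plan = plan, kinetics = kin, decay_mode = decay_mode,
         bands = strength_bands(), temp_profile = temp_profile,
         scenario = scenario, seed = raw$seed %||% NULL),
    class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a weekly temperature log
#'
#' @param path CSV file with header `week,temp_c`, 0-based week indices.
#' @return A [temperature_profile()].
#' @export
read_temperature_csv <- function(path) {
  if (!file.exists(path))
    stop("temperature CSV not found: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  if (!all(c("week", "temp_c") %in% names(df)))
    stop("temperature CSV needs columns 'week' and 'temp_c'", call. = FALSE)
  temperature_profile(df$week, df$temp_c)
}

#' Write a weekly temperature log
#'
#' @param profile A [temperature_profile()].
#' @param path Output CSV path (`week,temp_c`).
#' @return The path, invisibly.
#' @export
write_temperature_csv <- function(profile, path) {
  stopifnot(inherits(profile, "temperature_profile"))
  utils::write.csv(as.data.frame(profile)[c("week", "temp_c")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Synthesize a seasonal weekly temperature log
#'
#' Emulates an annual ambient-temperature cycle: a sinusoid of the given
#' mean and amplitude over a 52-week period plus optional Gaussian noise.
#' Deterministic for a fixed seed.
#'
#' @param mean_c Seasonal mean temperature, degC.
#' @param amplitude_c Half the seasonal peak-to-trough range, degC; >= 0.
#' @param noise_sd_c Standard deviation of weekly Gaussian noise, degC.
#' @param weeks Number of weeks, >= 1.
#' @param seed Integer seed for the noise.
#' @return A [temperature_profile()] covering weeks `0 .. weeks - 1`.
#' @export
#' @examples
#' generate_temperature_fixture(27, 3, 0, weeks = 52)
generate_temperature_fixture <- function(mean_c = 27, amplitude_c = 3,
                                         noise_sd_c = 0, weeks = 52L,
                                         seed = 1L) {
  if (amplitude_c < 0) stop("'amplitude_c' must be >= 0", call. = FALSE)
  if (weeks < 1) stop("'weeks' must be >= 1", call. = FALSE)
  if (noise_sd_c < 0) stop("'noise_sd_c' must be >= 0", call. = FALSE)
  w <- seq_len(weeks) - 1L
  temps <- mean_c + amplitude_c * sin(2 * pi * w / 52)
  if (noise_sd_c > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    temps <- temps + stats::rnorm(weeks, 0, noise_sd_c)
  }
  temperature_profile(w, temps)
}

#' Write simulation or projection results as CSV
#'
#' Writes a [simulate_year()] result as the weekly series
#' `week,effective_doses,forward_demand,access_ratio,consumed,shortfall`
#' (weeks labelled 1-52 in the file), or a projection `data.frame` as
#' `year,births,p_access,required_supply,access_ratio` (absent columns
#' omitted). Floats are formatted at 6 significant digits so repeated runs
#' of the same configuration are byte-identical.
#'
#' @param x A `simulation_result` or a projection `data.frame`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_results <- function(x, path) {
  fmt <- function(v) {
    if (is.numeric(v) && !all(v == round(v) & abs(v) < 1e15, na.rm = TRUE))
      formatC(v, digits = 6, format = "g")
    else v
  }
  if (inherits(x, "simulation_result")) {
    out <- x$records
    out$week <- out$week + 1L  # report weeks 1-52
  } else if (is.data.frame(x)) {
    out <- x
    nm <- c(year = "year", annual_births = "births", p_access = "p_access",
            required_supply = "required_supply",
            average_access_ratio = "access_ratio")
    keep <- intersect(names(nm), names(out))
    out <- out[keep]
    names(out) <- nm[keep]
  } else stop("unsupported result type", call. = FALSE)
  out[] <- lapply(out, fmt)
  con <- file(path, open = "wt")
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
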