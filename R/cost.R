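#' Unit rates for the monitoring cost model
#'
#' Defaults reflect a New Zealand Department of Conservation wetland
#' monitoring operation: NZ$25/hr wages, NZ$0.77/km standard mileage, a
#' 130 km / 2 hr return drive between office and wetland, and 45 min to move
#' around the site past all stations.
#'
#' @param wage_per_hr wages, currency per hour.
#' @param vehicle_per_km vehicle running cost, currency per km.
#' @param return_trip_km,return_trip_hr length/duration of one return trip
#'   to the site.
#' @param circuit_hr hours for one circuit around the site.
#' @return An object of class `cost_rates`.
#' @export
cost_rates <- function(wage_per_hr = 25, vehicle_per_km = 0.77,
                       return_trip_km = 130, return_trip_hr = 2,
                       circuit_hr = 0.75) {
  vals <- c(wage_per_hr, vehicle_per_km, return_trip_km, return_trip_hr,
            circuit_hr)
  if (any(vals < 0)) stop("rates must be non-negative", call. = FALSE)
  structure(list(wage_per_hr = wage_per_hr, vehicle_per_km = vehicle_per_km,
                 return_trip_km = return_trip_km, return_trip_hr = return_trip_hr,
                 circuit_hr = circuit_hr),
            class = "cost_rates")
}

#' Sampling design driving the cost and power modules
#'
#' Defaults encode the target regime: 15-min call-counts at 40 stations on
#' six consecutive nights ("occasions") per season, costed over two years.
#'
#' @param n_stations,n_occasions,count_duration_min,years positive design
#'   parameters.
#' @return An object of class `monitoring_design`.
#' @export
monitoring_design <- function(n_stations = 40, n_occasions = 6,
                              count_duration_min = 15, years = 2) {
  stop_if_not_count(n_stations, "n_stations")
  stop_if_not_count(n_occasions, "n_occasions")
  stop_if_not_count(years, "years", min = 1L)
  if (count_duration_min <= 0) stop("`count_duration_min` must be > 0", call. = FALSE)
  structure(list(n_stations = n_stations, n_occasions = n_occasions,
                 count_duration_min = count_duration_min, years = years),
            class = "monitoring_design")
}

#' Per-option cost assumptions
#'
#' Captures everything that differs between monitoring options: device
#' price, per-unit programming and deployment time (accrued once per year or
#' once per sampling occasion), how many return trips are charged as wages
#' versus vehicle kilometres, how many site circuits are driven, whether
#' travel accrues per observer (field-observer option) or per trip (device
#' options), sound-file processing time per file, and an optional year-two
#' vehicle-cost override. See [default_options()] for the five shipped
#' option configurations.
#'
#' @param option_name label, e.g. `"MONO-VISUAL"`.
#' @param device_price purchase price per unit (year one only).
#' @param units devices or observers, one per station by default.
#' @param program_min_per_unit,program_accrual minutes to program one unit
#'   (for observers: the pre-occasion briefing) and whether that accrues
#'   `"per_year"` or `"per_occasion"`.
#' @param deploy_min_per_unit,deploy_accrual minutes to deploy/secure one
#'   unit, and its accrual.
#' @param wage_trips_per_year return trips per year charged as driver wages.
#' @param vehicle_trips_per_year return trips per year charged as vehicle km.
#' @param circuits_per_year circuits around the site per year.
#' @param per_observer_travel if `TRUE`, travel wages accrue per unit
#'   (observer) and vehicle costs per vehicle-load of
#'   `observers_per_vehicle`.
#' @param observers_per_vehicle observers carried per vehicle.
#' @param processing_hr_per_file hours to process one sound file (`NA` for
#'   the observer option).
#' @param counting_from_duration if `TRUE`, field counting time is charged
#'   at the design's count duration per session (observer option).
#' @param year2_vehicle_override optional unrounded vehicle-running cost
#'   used in years >= 2 in place of the computed value.
#' @return An object of class `option_assumptions`.
#' @export
option_assumptions <- function(option_name,
                               device_price = 0,
                               units = 40,
                               program_min_per_unit = 0,
                               program_accrual = c("per_year", "per_occasion"),
                               deploy_min_per_unit = 0,
                               deploy_accrual = c("per_year", "per_occasion"),
                               wage_trips_per_year = 0,
                               vehicle_trips_per_year = 0,
                               circuits_per_year = 0,
                               per_observer_travel = FALSE,
                               observers_per_vehicle = 5,
                               processing_hr_per_file = NA_real_,
                               counting_from_duration = FALSE,
                               year2_vehicle_override = NULL) {
  program_accrual <- match.arg(program_accrual)
  deploy_accrual <- match.arg(deploy_accrual)
  structure(list(option_name = option_name, device_price = device_price,
                 units = units,
                 program_min_per_unit = program_min_per_unit,
                 program_accrual = program_accrual,
                 deploy_min_per_unit = deploy_min_per_unit,
                 deploy_accrual = deploy_accrual,
                 wage_trips_per_year = wage_trips_per_year,
                 vehicle_trips_per_year = vehicle_trips_per_year,
                 circuits_per_year = circuits_per_year,
                 per_observer_travel = per_observer_travel,
                 observers_per_vehicle = observers_per_vehicle,
                 processing_hr_per_file = processing_hr_per_file,
                 counting_from_duration = counting_from_duration,
                 year2_vehicle_override = year2_vehicle_override),
            class = "option_assumptions")
}

#' The five shipped monitoring-option configurations
#'
#' Mono recorders (NZ$300, timer-equipped: one deploy + one retrieve trip a
#' year, a single wage-charged trip, programmed once a year at 2.5 min/unit,
#' secured in 2 min); stereo recorders (NZ$600, no timers and <24 hr battery,
#' so six service trips a year, per-occasion 3-min programming, 10-min
#' deployment, and a year-two vehicle figure of NZ$554); and field observers
#' (no hardware, per-occasion half-hour briefings, per-observer travel wages
#' on every occasion, one vehicle per five observers). Visual processing
#' costs 0.1 hr per sound file, audible (real-time listening) 0.25 hr.
#'
#' These parameter choices reproduce the published reference cost schedule
#' for the Whangamarino bittern programme; every one of them can be
#' overridden through [option_assumptions()] or a YAML config
#' ([read_cost_config()]).
#'
#' @param units devices/observers per option (one per station).
#' @return Named list of five [option_assumptions()] objects:
#'   `MONO-VISUAL`, `MONO-AUDIBLE`, `STEREO-VISUAL`, `STEREO-AUDIBLE`,
#'   `OBS`.
#' @export
default_options <- function(units = 40) {
  mono <- function(name, proc) option_assumptions(
    name, device_price = 300, units = units,
    program_min_per_unit = 2.5, program_accrual = "per_year",
    deploy_min_per_unit = 2, deploy_accrual = "per_year",
    wage_trips_per_year = 1, vehicle_trips_per_year = 2,
    circuits_per_year = 2, processing_hr_per_file = proc
  )
  stereo <- function(name, proc) option_assumptions(
    name, device_price = 600, units = units,
    program_min_per_unit = 3, program_accrual = "per_occasion",
    deploy_min_per_unit = 10, deploy_accrual = "per_year",
    wage_trips_per_year = 6, vehicle_trips_per_year = 6,
    circuits_per_year = 6, processing_hr_per_file = proc,
    year2_vehicle_override = 554
  )
  obs <- option_assumptions(
    "OBS", device_price = 0, units = units,
    program_min_per_unit = 30, program_accrual = "per_occasion",
    deploy_min_per_unit = 1, deploy_accrual = "per_year",
    wage_trips_per_year = 6, vehicle_trips_per_year = 6,
    circuits_per_year = 6, per_observer_travel = TRUE,
    observers_per_vehicle = 5, counting_from_duration = TRUE
  )
  list(`MONO-VISUAL` = mono("MONO-VISUAL", 0.1),
       `MONO-AUDIBLE` = mono("MONO-AUDIBLE", 0.25),
       `STEREO-VISUAL` = stereo("STEREO-VISUAL", 0.1),
       `STEREO-AUDIBLE` = stereo("STEREO-AUDIBLE", 0.25),
       OBS = obs)
}

COST_ITEMS <- c("purchase", "processing_counting", "deployment",
                "drive_to_from", "drive_around", "programming",
                "vehicle_running")

COST_ITEM_LABELS <- c(purchase = "Purchase",
                      processing_counting = "Processing/counting",
                      deployment = "Deployment",
                      drive_to_from = "Driving to/from site",
                      drive_around = "Driving around site",
                      programming = "Programming",
                      vehicle_running = "Vehicle running")

#' Unrounded line-item costs of one option for one year
#'
#' All arithmetic is carried out unrounded; rounding happens only at
#' display time ([render_cost_table()], `display` components of
#' [compute_option_cost()]), using round-half-away-from-zero.
#'
#' @param option an [option_assumptions()].
#' @param design a [monitoring_design()].
#' @param rates a [cost_rates()].
#' @param year 1-based year index (purchase costs accrue in year 1 only).
#' @return Named numeric over `purchase`, `processing_counting`,
#'   `deployment`, `drive_to_from`, `drive_around`, `programming`,
#'   `vehicle_running`.
#' @examples
#' line_item_costs(default_options()[["MONO-VISUAL"]],
#'                 monitoring_design(), cost_rates(), year = 1)
#' @export
line_item_costs <- function(option, design, rates, year = 1) {
  stopifnot(inherits(option, "option_assumptions"),
            inherits(design, "monitoring_design"),
            inherits(rates, "cost_rates"))
  stop_if_not_count(year, "year", min = 1L)
  wage <- rates$wage_per_hr
  n_files <- design$n_stations * design$n_occasions
  hr_per_file <- if (option$counting_from_duration) {
    design$count_duration_min / 60
  } else {
    option$processing_hr_per_file
  }
  accrual_mult <- function(accrual) {
    if (accrual == "per_occasion") design$n_occasions else 1
  }
  travel_wage_mult <- if (option$per_observer_travel) option$units else 1
  vehicles <- if (option$per_observer_travel) {
    ceiling(option$units / option$observers_per_vehicle)
  } else {
    1
  }
  vehicle_running <- rates$return_trip_km * rates$vehicle_per_km *
    option$vehicle_trips_per_year * vehicles
  if (year >= 2 && !is.null(option$year2_vehicle_override)) {
    vehicle_running <- option$year2_vehicle_override
  }
  c(purchase = if (year == 1) option$device_price * option$units else 0,
    processing_counting = n_files * hr_per_file * wage,
    deployment = option$units * option$deploy_min_per_unit / 60 * wage *
      accrual_mult(option$deploy_accrual),
    drive_to_from = rates$return_trip_hr * wage * option$wage_trips_per_year *
      travel_wage_mult,
    drive_around = rates$circuit_hr * wage * option$circuits_per_year *
      travel_wage_mult,
    programming = option$units * option$program_min_per_unit / 60 * wage *
      accrual_mult(option$program_accrual),
    vehicle_running = vehicle_running)
}

#' Multi-year cost breakdown for one monitoring option
#'
#' Assembles [line_item_costs()] over all design years. Year totals and the
#' cumulative cost are computed on unrounded values and only then rounded
#' for display (half away from zero), so a displayed total can differ by 1
#' from the sum of its displayed line items.
#'
#' @inheritParams line_item_costs
#' @return An object of class `cost_breakdown`: `option_name`, `items`
#'   (items x years matrix, unrounded), `year_totals`, `cumulative`, and
#'   display counterparts `items_display`, `year_totals_display`,
#'   `cumulative_display`.
#' @examples
#' compute_option_cost(default_options()[["MONO-VISUAL"]],
#'                     monitoring_design(), cost_rates())
#' @export
compute_option_cost <- function(option, design = monitoring_design(),
                                rates = cost_rates()) {
  items <- vapply(seq_len(design$years), function(y) {
    line_item_costs(option, design, rates, year = y)
  }, numeric(length(COST_ITEMS)))
  items <- matrix(items, nrow = length(COST_ITEMS),
                  dimnames = list(COST_ITEMS,
                                  paste0("year", seq_len(design$years))))
  year_totals <- colSums(items)
  structure(list(option_name = option$option_name,
                 items = items,
                 year_totals = year_totals,
                 cumulative = sum(year_totals),
                 items_display = round_display(items),
                 year_totals_display = round_display(year_totals),
                 cumulative_display = round_display(sum(year_totals))),
            class = "cost_breakdown")
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat(sprintf("<cost_breakdown> %s\n", x$option_name))
  m <- rbind(x$items_display, Total = x$year_totals_display)
  rownames(m) <- c(COST_ITEM_LABELS[rownames(x$items)], "Total")
  print(m)
  cat(sprintf("Cumulative over %d year(s): %s\n", ncol(x$items),
              format(x$cumulative_display, big.mark = ",")))
  invisible(x)
}

#' Percentage saving of one cumulative cost over another
#'
#' `100 * (1 - a / b)`: the saving realised by choosing option A (cumulative
#' cost `a`) over option B (`b`). Positive when A is cheaper.
#'
#' @param option_a_cumulative,option_b_cumulative cumulative costs;
#'   `option_b_cumulative` must be positive.
#' @param display round half-away-from-zero to a whole percent (default).
#' @return Percentage saving.
#' @examples
#' percent_saving(13925.4, 51642.93)  # 73
#' @export
percent_saving <- function(option_a_cumulative, option_b_cumulative,
                           display = TRUE) {
  if (option_b_cumulative <= 0) {
    stop("`option_b_cumulative` must be positive", call. = FALSE)
  }
  pct <- 100 * (1 - option_a_cumulative / option_b_cumulative)
  if (display) round_display(pct) else pct
}

#' Full cost table across all monitoring options
#'
#' One column per option, blocks of line-item rows per year followed by the
#' year total, and a final cumulative row — all cells display-rounded (half
#' away from zero) from unrounded accumulation.
#'
#' @param options named list of [option_assumptions()]; defaults to the five
#'   shipped options.
#' @inheritParams line_item_costs
#' @return A tibble with columns `year`, `item`, then one display-rounded
#'   column per option.
#' @examples
#' render_cost_table()
#' @export
render_cost_table <- function(options = default_options(),
                          design = monitoring_design(),
                          rates = cost_rates()) {
  costs <- lapply(options, compute_option_cost, design = design, rates = rates)
  rows <- list()
  for (y in seq_len(design$years)) {
    block <- tibble::tibble(year = paste("Year", y),
                            item = unname(COST_ITEM_LABELS[COST_ITEMS]))
    for (nm in names(costs)) block[[nm]] <- costs[[nm]]$items_display[, y]
    total <- tibble::tibble(year = paste("Year", y), item = "Total")
    for (nm in names(costs)) total[[nm]] <- costs[[nm]]$year_totals_display[[y]]
    rows[[length(rows) + 1L]] <- block
    rows[[length(rows) + 1L]] <- total
  }
  cum <- tibble::tibble(year = "Cumulative", item = "Cumulative")
  for (nm in names(costs)) cum[[nm]] <- costs[[nm]]$cumulative_display
  rows[[length(rows) + 1L]] <- cum
  dplyr::bind_rows(rows)
}

#' Qualitative capability matrix of the monitoring options
#'
#' Scores each option against three management values — indexing change in
#' call-rate, estimating the number of calling males, and engaging the
#' public — as `easy`, `with_work` or `no`. All options index call-rate
#' easily; only stereo recordings processed audibly can estimate numbers
#' (with work, capped at six birds), while observers do everything easily
#' but at the highest cost.
#'
#' @inheritParams line_item_costs
#' @return A list with `$values` (tibble, one row per value, one column per
#'   option) and `$cumulative` (named display-rounded cumulative costs).
#' @export
value_matrix <- function(design = monitoring_design(), rates = cost_rates()) {
  values <- tibble::tibble(
    value = c("index_call_rate", "estimate_numbers", "public_participation"),
    `MONO-VISUAL` = c("easy", "no", "no"),
    `MONO-AUDIBLE` = c("easy", "no", "no"),
    `STEREO-VISUAL` = c("easy", "no", "no"),
    `STEREO-AUDIBLE` = c("easy", "with_work", "no"),
    OBS = c("easy", "easy", "easy")
  )
  costs <- vapply(default_options(units = design$n_stations),
                  function(o) compute_option_cost(o, design, rates)$cumulative_display,
                  numeric(1))
  list(values = values, cumulative = costs)
}

#' Read or write a cost-model configuration as YAML
#'
#' The YAML mirrors [cost_rates()], [monitoring_design()] and a list of
#' [option_assumptions()]; a complete default configuration ships at
#' `system.file("extdata", "cost_defaults.yaml", package = "boomr")`.
#'
#' @param path YAML file path.
#' @return `read_cost_config()`: a list with `$rates`, `$design`,
#'   `$options` ready for [render_cost_table()].
#' @export
read_cost_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  rates <- do.call(cost_rates, cfg$rates %||% list())
  design <- do.call(monitoring_design, cfg$design %||% list())
  options <- lapply(cfg$options, function(o) do.call(option_assumptions, o))
  names(options) <- vapply(options, function(o) o$option_name, character(1))
  list(rates = rates, design = design, options = options)
}

#' @rdname read_cost_config
#' @param config list as returned by [read_cost_config()].
#' @export
write_cost_config <- function(config, path) {
  strip <- function(x) {
    x <- unclass(x)
    x[!vapply(x, is.null, logical(1))]
  }
  yaml::write_yaml(list(rates = strip(config$rates),
                        design = strip(config$design),
                        options = lapply(unname(config$options), strip)),
                  path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
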