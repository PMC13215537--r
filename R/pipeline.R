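#' Run the full synthetic analysis end to end
#'
#' Convenience orchestration used by the command-line wrapper and the worked
#' examples: generates a synthetic %TOC library, substrate map and event
#' tables, fits the cost-rate and log10-normal mass models from the
#' quantity-bearing records, builds the filtered %TOC pools, and propagates
#' everything through the Monte Carlo to country-, shelf- and (for the
#' port-scoped historical table) nation-level estimates.
#'
#' @param seed Master seed for generation and simulation.
#' @param n_runs Monte Carlo runs (default 10000).
#' @param countries Country codes for the modern tables.
#' @param years Years for the modern tables.
#' @param n_per_cell Records per country-year.
#' @param synth Optional [synth_config()]; by default built from `seed`.
#' @param draw_scope Passed to [simulation_config()].
#' @return List: `dists` (coastal/sand/coarse/mixed/combined pools),
#'   `mass_model`, `cost_model`, `dredging` and `aggregate` country-level
#'   `carbon_estimates`, `shelf_dredging`, `shelf_aggregate`, and the input
#'   `events` tables.
#' @export
run_synthetic_pipeline <- function(seed = 1L, n_runs = 10000,
                                   countries = c("UK", "DK", "DE", "NL"),
                                   years = 1995:2004, n_per_cell = 4,
                                   synth = NULL,
                                   draw_scope = "per_record") {
  config <- synth %||% synth_config(seed = seed)

  lib <- gen_toc_library(config)
  coastal <- filter_coastal_samples(lib$samples, lib$coastline)
  classified <- classify_samples_by_substrate(lib$samples, lib$map)
  by_class <- build_substrate_distributions(classified)
  combined <- build_combined_distribution(by_class)
  dists <- c(list(coastal = coastal), by_class, list(combined = combined))

  dredge <- gen_event_table(config, industry = "port_dredging",
                            countries = countries, years = years,
                            n_per_cell = n_per_cell)
  agg <- gen_event_table(config, industry = "aggregate",
                         countries = countries, years = years,
                         n_per_cell = n_per_cell)

  # calibrate the imputation models from the quantity-bearing records,
  # exactly as the analysis does with historical port returns
  harm_known <- harmonise_records(
    dredge$records[dredge$records$quantity_unit %in%
                     c("kg", "tonne", "tonne_long_1016", "m3", "cubic_yard"), ])
  pairs <- dredge$truth[dredge$truth$composition == "mass", ]
  cost_model <- fit_cost_rate(data.frame(
    record_id = pairs$record_id,
    cost = pairs$true_mass_kg * config$true_cost_rate,
    mass_kg = pairs$true_mass_kg))
  known_masses <- harm_known |>
    dplyr::group_by(.data$record_id) |>
    dplyr::summarise(mass_kg = sum(.data$mass_kg), .groups = "drop")
  mass_model <- fit_log10_mass_model(known_masses$mass_kg)

  cfg <- simulation_config(n_runs = n_runs, seed = seed,
                           draw_scope = draw_scope)
  ev_dredge <- harmonise_records(dredge$records, cost_model = cost_model)
  ev_agg <- harmonise_records(agg$records, cost_model = cost_model)
  est_dredge <- run_simulation(ev_dredge, dists, mass_model, cfg)
  est_agg <- run_simulation(ev_agg, dists, mass_model, cfg)

  list(
    dists = dists, mass_model = mass_model, cost_model = cost_model,
    dredging = est_dredge, aggregate = est_agg,
    shelf_dredging = aggregate_country_to_shelf(est_dredge),
    shelf_aggregate = aggregate_country_to_shelf(est_agg),
    events = list(dredging = ev_dredge, aggregate = ev_agg),
    truth = list(dredging = dredge$truth, aggregate = agg$truth),
    config = config
  )
}
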