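#' Build and validate an extraction-event record table
#'
#' One row per dredging or aggregate-extraction event or return. Quantities
#' may be reported as mass, volume, monetary cost, or be absent entirely
#' (common in pre-1903 UK port records); the harmonisation step resolves
#' each to kilograms or flags it for imputation.
#'
#' @param df Data frame with columns `record_id`, `industry`
#'   (`"port_dredging"` or `"aggregate"`), `country` (ISO-3166 alpha-2),
#'   `scope` (`"port"`, `"licence_area"`, `"national_total"`), `year_start`,
#'   `year_end`, `quantity_value`, `quantity_unit` (see
#'   [convert_quantity_to_mass()], plus `"currency"` and `"absent"`),
#'   `sediment_type` (`"sand"`, `"coarse"`, `"mixed"`, `"unknown"`).
#'   Optional: `port` (port name for port-scope records), `x`, `y`
#'   (projected coordinates, EPSG:3035), `category` (commodity tag, e.g.
#'   `"maerl"`), `source_tag`.
#' @return A validated tibble with class `extraction_records`.
#' @export
extraction_records <- function(df) {
  df <- tibble::as_tibble(df)
  required <- c("record_id", "industry", "country", "scope", "year_start",
                "year_end", "quantity_value", "quantity_unit", "sediment_type")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    rlang::abort(paste("missing columns:", paste(missing, collapse = ", ")))
  }
  for (col in c("port", "category", "source_tag")) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
  }
  if (!all(df$industry %in% c("port_dredging", "aggregate"))) {
    rlang::abort("industry must be 'port_dredging' or 'aggregate'")
  }
  if (!all(df$scope %in% c("port", "licence_area", "national_total"))) {
    rlang::abort("scope must be port, licence_area or national_total")
  }
  if (!all(df$quantity_unit %in% quantity_units)) {
    rlang::abort(paste("unknown quantity_unit; allowed:",
                       paste(quantity_units, collapse = ", ")))
  }
  if (!all(df$sediment_type %in% c("sand", "coarse", "mixed", "unknown"))) {
    rlang::abort("sediment_type must be sand, coarse, mixed or unknown")
  }
  if (any(df$year_end < df$year_start)) {
    rlang::abort("year_end must be >= year_start")
  }
  reported <- df$quantity_unit != "absent"
  if (any(reported & (is.na(df$quantity_value) | df$quantity_value < 0))) {
    rlang::abort("quantity_value must be non-negative when a unit is given")
  }
  class(df) <- c("extraction_records", class(df))
  df
}

#' Read an extraction-event table from CSV
#'
#' @param path Path to a UTF-8 CSV with a header row and the
#'   [extraction_records()] schema.
#' @return A validated `extraction_records` tibble.
#' @export
read_extraction_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  extraction_records(df)
}

#' Drop record categories excluded from carbon accounting
#'
#' Maerl (calcareous algae) extraction lacks organic-carbon
#' characterisation, and early non-aggregate extraction records (tin
#' prospecting, clay, shingle, trial boreholes) lack usable masses; both are
#' excluded before analysis.
#'
#' @param records An `extraction_records` tibble.
#' @param categories Character vector of `category` tags to drop.
#' @return A list with `retained` (records kept) and `audit` (a tibble of
#'   `record_id`, `reason` for every dropped record). The two partitions the
#'   input exactly.
#' @export
exclude_record_categories <- function(records,
                                      categories = c("maerl", "tin_prospecting",
                                                     "clay", "shingle", "borehole")) {
  drop <- !is.na(records$category) & records$category %in% categories
  list(
    retained = records[!drop, , drop = FALSE],
    audit = tibble::tibble(
      record_id = records$record_id[drop],
      reason = records$category[drop]
    )
  )
}

#' Spread a (possibly multi-year) record's mass across its years
#'
#' Period returns (e.g. 10- or 20-year dredging totals) are divided equally
#' across the years they cover; the per-year masses sum back to the input
#' mass exactly (the last year absorbs the floating-point remainder).
#' Records with no reported quantity produce a single period-level event
#' flagged for imputation, because missing masses are imputed per dredging
#' works, not per year.
#'
#' @param record One-row `extraction_records` tibble whose quantity is
#'   already in kg (`quantity_unit == "kg"`) or absent.
#' @return Tibble of harmonised-event rows (see [harmonise_records()]).
#' @export
annualise_period_record <- function(record) {
  stopifnot(nrow(record) == 1)
  years <- seq(record$year_start, record$year_end)
  n <- length(years)
  base <- list(
    record_id = record$record_id, industry = record$industry,
    country = record$country, port = record$port,
    sediment_type = record$sediment_type
  )
  if (record$quantity_unit == "absent") {
    return(tibble::tibble(
      !!!base,
      year = record$year_start, year_end = record$year_end, n_years = n,
      mass_kg = NA_real_, needs_imputation = TRUE,
      mass_provenance = "imputed"
    ))
  }
  stopifnot(record$quantity_unit == "kg")
  per_year <- rep(record$quantity_value / n, n)
  if (n > 1) per_year[n] <- record$quantity_value - sum(per_year[-n])
  tibble::tibble(
    !!!base,
    year = years, year_end = years, n_years = 1L,
    mass_kg = per_year, needs_imputation = FALSE,
    mass_provenance = record$mass_provenance
  )
}

#' Harmonise extraction records into annual events in kilograms
#'
#' Converts every reported quantity to kg (volumes via the average sediment
#' density, monetary costs via a fitted cost-per-kg model), splits
#' multi-year totals equally across their years, and flags records with no
#' usable quantity for log10-normal imputation inside the Monte Carlo.
#' Harmonising an already-harmonised table is a no-op.
#'
#' @param records An `extraction_records` tibble (or an already-harmonised
#'   `harmonised_events` tibble, returned unchanged).
#' @param cost_model Optional [fit_cost_rate()] model; required if any
#'   record's unit is `"currency"`.
#' @param density_kg_m3 Density for volume conversions (kg/m3).
#' @return A `harmonised_events` tibble: `record_id`, `industry`, `country`,
#'   `port`, `sediment_type`, `year`, `year_end`, `n_years`, `mass_kg` (NA
#'   when imputation is needed), `needs_imputation`, `mass_provenance`
#'   (`reported_mass`, `converted_volume`, `converted_cost`, or `imputed`).
#' @export
harmonise_records <- function(records, cost_model = NULL,
                              density_kg_m3 = unit_constants$default_density_kg_m3) {
  if (inherits(records, "harmonised_events")) {
    return(records)
  }
  if (nrow(records) == 0) {
    return(empty_harmonised())
  }
  unit <- records$quantity_unit
  mass <- rep(NA_real_, nrow(records))
  prov <- rep(NA_character_, nrow(records))

  is_mass <- unit %in% c("kg", "tonne", "tonne_long_1016")
  is_vol <- unit %in% c("m3", "cubic_yard")
  is_cost <- unit == "currency"
  if (any(is_mass)) {
    mass[is_mass] <- convert_quantity_to_mass(records$quantity_value[is_mass],
                                              unit[is_mass])
    prov[is_mass] <- "reported_mass"
  }
  if (any(is_vol)) {
    mass[is_vol] <- convert_quantity_to_mass(records$quantity_value[is_vol],
                                             unit[is_vol], density_kg_m3)
    prov[is_vol] <- "converted_volume"
  }
  if (any(is_cost)) {
    if (is.null(cost_model)) {
      rlang::abort("records report costs but no cost_model was supplied")
    }
    mass[is_cost] <- estimate_mass_from_cost(records$quantity_value[is_cost],
                                             cost_model)
    prov[is_cost] <- "converted_cost"
  }
  prov[unit == "absent"] <- "imputed"

  kg <- records
  kg$quantity_value <- ifelse(unit == "absent", NA_real_, mass)
  kg$quantity_unit <- ifelse(unit == "absent", "absent", "kg")
  kg$mass_provenance <- prov

  out <- dplyr::bind_rows(
    lapply(seq_len(nrow(kg)), function(i) annualise_period_record(kg[i, ]))
  )
  class(out) <- c("harmonised_events", class(tibble::tibble()))
  out
}

empty_harmonised <- function() {
  out <- tibble::tibble(
    record_id = character(), industry = character(), country = character(),
    port = character(), sediment_type = character(),
    year = integer(), year_end = integer(), n_years = integer(),
    mass_kg = double(), needs_imputation = logical(),
    mass_provenance = character()
  )
  class(out) <- c("harmonised_events", class(out))
  out
}

#' Drop industry-years with too few contributing countries
#'
#' Years in which only a single nation reported records would give a large
#' underestimate at shelf scale, so all events in such an (industry, year)
#' cell are removed before shelf-wide analysis.
#'
#' @param events A `harmonised_events` tibble.
#' @param min_countries Minimum number of distinct contributing countries an
#'   (industry, year) must have to be retained. Default 2;
#'   `min_countries = 1` retains everything.
#' @return List with `retained` events and an `audit` tibble
#'   (`industry`, `year`, `n_countries`, `n_events_dropped`).
#' @export
exclude_sparse_years <- function(events, min_countries = 2) {
  if (nrow(events) == 0) {
    return(list(retained = events,
                audit = tibble::tibble(industry = character(), year = integer(),
                                       n_countries = integer(),
                                       n_events_dropped = integer())))
  }
  counts <- events |>
    dplyr::group_by(.data$industry, .data$year) |>
    dplyr::summarise(n_countries = dplyr::n_distinct(.data$country),
                     n_events = dplyr::n(), .groups = "drop")
  sparse <- counts |> dplyr::filter(.data$n_countries < min_countries)
  drop <- paste(events$industry, events$year) %in%
    paste(sparse$industry, sparse$year)
  list(
    retained = events[!drop, , drop = FALSE],
    audit = sparse |>
      dplyr::transmute(.data$industry, .data$year, .data$n_countries,
                       n_events_dropped = .data$n_events)
  )
}
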