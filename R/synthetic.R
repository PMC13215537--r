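#' Solve log-normal parameters from a (median, p95) pair
#'
#' %TOC values are strictly positive and right-skewed; a log-normal family
#' parameterised directly by its median and 95th percentile makes the
#' generator's targets readable. `meanlog = log(median)`,
#' `sdlog = (log(p95) - log(median)) / qnorm(0.95)`.
#'
#' @param median,p95 Target quantiles, `0 < median <= p95`.
#' @return Named vector `c(meanlog, sdlog)`.
#' @export
lognormal_from_quantiles <- function(median, p95) {
  if (median <= 0 || p95 < median) {
    rlang::abort("unsatisfiable targets: need 0 < median <= p95")
  }
  c(meanlog = unname(log(median)),
    sdlog = unname((log(p95) - log(median)) / stats::qnorm(0.95)))
}

#' Configuration for the synthetic data generators
#'
#' Defaults emulate the study conditions the analysis assumes: a coastal
#' %TOC pool with median 1.78% and 95th percentile 6.46%; per-substrate
#' pools sized 7262 (sand), 720 (coarse) and 273 (mixed) whose count-pooled
#' mixture has median ~0.48% and p95 ~5.19%; extraction masses log10-normal
#' with mean 7.2 and SD 0.69 (log10 kg); a record-composition of 6/117
#' mass-reporting, 57/117 cost-only and 54/117 quantity-free records for the
#' historical port mode; sediment density 1700 kg/m3.
#'
#' @param seed Integer seed; all generators are seed-deterministic.
#' @param n_coastal Coastal (valid) %TOC samples to generate.
#' @param coastal_targets `c(median, p95)` for the coastal pool, in %TOC.
#' @param n_classes Named counts for the sand/coarse/mixed pools.
#' @param class_targets Named list of `c(median, p95)` per substrate class.
#' @param n_decoys Decoy samples per excluded category (saltmarsh, seagrass,
#'   above-MHW, offshore beyond the cutoff): generated so every filter's
#'   effect is independently checkable.
#' @param mass_log10_mu,mass_log10_sigma True extraction-mass model on
#'   log10 kg.
#' @param missing_fracs Probabilities that a historical record reports a
#'   quantity (`mass`), only a cost (`cost`), or nothing (`neither`); must
#'   sum to 1.
#' @param period_fraction Fraction of historical records spanning a
#'   multi-year period.
#' @param true_cost_rate Cost per kg used to emit cost-only records.
#' @param density_kg_m3 Sediment density used to emit volume-unit records.
#' @param extent_km `c(width, depth)` of the sea area in km (coastline along
#'   y = 0, sea at y > 0); checkerboard substrate cells of `cell_km` km.
#' @param cell_km Substrate checkerboard cell size in km.
#' @param offshore_km Inshore edge of the substrate checkerboard: extraction
#'   licence areas sit offshore, so mapped cells start this far from the
#'   coast (default 5, the coastal-filter cutoff) and inshore samples fall
#'   outside every polygon.
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1L,
                         n_coastal = 9920,
                         coastal_targets = c(median = 1.78, p95 = 6.46),
                         n_classes = c(sand = 7262, coarse = 720, mixed = 273),
                         class_targets = list(sand = c(0.46, 5.1),
                                              coarse = c(0.62, 5.8),
                                              mixed = c(0.85, 6.5)),
                         n_decoys = 200,
                         mass_log10_mu = 7.2, mass_log10_sigma = 0.69,
                         missing_fracs = c(mass = 6 / 117, cost = 57 / 117,
                                           neither = 54 / 117),
                         period_fraction = 0,
                         true_cost_rate = 0.05,
                         density_kg_m3 = 1700,
                         extent_km = c(90, 60), cell_km = 10,
                         offshore_km = 5) {
  stopifnot(abs(sum(missing_fracs) - 1) < 1e-9, all(missing_fracs >= 0),
            period_fraction >= 0, period_fraction <= 1,
            all(n_classes >= 0), n_coastal >= 0, n_decoys >= 0)
  structure(list(seed = as.integer(seed), n_coastal = n_coastal,
                 coastal_targets = coastal_targets, n_classes = n_classes,
                 class_targets = class_targets, n_decoys = n_decoys,
                 mass_log10_mu = mass_log10_mu,
                 mass_log10_sigma = mass_log10_sigma,
                 missing_fracs = missing_fracs,
                 period_fraction = period_fraction,
                 true_cost_rate = true_cost_rate,
                 density_kg_m3 = density_kg_m3,
                 extent_km = extent_km, cell_km = cell_km,
                 offshore_km = offshore_km),
            class = "synth_config")
}

#' Generate a synthetic substrate map and coastline
#'
#' A straight coastline along y = 0 (sea at y > 0) and a checkerboard of
#' sand/coarse/mixed polygons covering the configured extent, as GeoJSON-able
#' geometry. Cell class cycles with the cell indices so all three classes
#' are interleaved.
#'
#' @param config A [synth_config()].
#' @return List with `map` (a [substrate_map()]), `coastline` (vertex
#'   matrix, metres) and `cells` (tibble of cell bounds and classes, the
#'   ground truth for point classification).
#' @export
gen_substrate_map_and_coastline <- function(config = synth_config()) {
  stopifnot(all(config$extent_km > 0))
  w <- config$extent_km[1] * 1000
  d <- config$extent_km[2] * 1000
  cell <- config$cell_km * 1000
  inshore <- config$offshore_km * 1000
  nx <- ceiling(w / cell); ny <- max(1, ceiling((d - inshore) / cell))
  classes <- c("sand", "coarse", "mixed")
  ids <- character(); cls <- character(); rings <- list()
  cells <- list()
  for (i in seq_len(nx)) {
    for (j in seq_len(ny)) {
      x0 <- (i - 1) * cell; y0 <- inshore + (j - 1) * cell
      cl <- classes[((i + j) %% 3) + 1]
      id <- sprintf("cell_%d_%d", i, j)
      ids <- c(ids, id); cls <- c(cls, cl)
      rings <- c(rings, list(rbind(c(x0, y0), c(x0 + cell, y0),
                                   c(x0 + cell, y0 + cell), c(x0, y0 + cell),
                                   c(x0, y0))))
      cells[[length(cells) + 1]] <- tibble::tibble(
        polygon_id = id, substrate_class = cl,
        x0 = x0, x1 = x0 + cell, y0 = y0, y1 = y0 + cell)
    }
  }
  list(map = substrate_map(ids, cls, rings),
       coastline = cbind(c(0, w), c(0, 0)),
       cells = dplyr::bind_rows(cells))
}

#' Generate a synthetic %TOC sample library with known truth
#'
#' Coastal samples are drawn from a log-normal hitting the configured
#' (median, p95) and placed within the coastal band; per-class shelf samples
#' are drawn from their class targets and placed strictly inside substrate
#' cells of the matching class. Decoy samples are generated in every
#' excluded category (saltmarsh, seagrass, above mean high water, beyond the
#' offshore cutoff) so each filter's effect is independently assertable.
#' Values are clipped to [0, 100].
#'
#' @param config A [synth_config()].
#' @param geometry Optional result of [gen_substrate_map_and_coastline()];
#'   generated from `config` when NULL.
#' @param coastal_band_km Width of the band coastal samples are placed in
#'   (default 5, matching the filter cutoff).
#' @return List with `samples` (a [toc_samples()] tibble), `map`,
#'   `coastline`, and `truth` (generating parameters plus each sample's true
#'   role, class and coast distance).
#' @export
gen_toc_library <- function(config = synth_config(), geometry = NULL,
                            coastal_band_km = 5) {
  if (is.null(geometry)) geometry <- gen_substrate_map_and_coastline(config)
  set.seed(substream_seed(config$seed, "toc"))
  w <- config$extent_km[1] * 1000
  d <- config$extent_km[2] * 1000
  band <- coastal_band_km * 1000

  draw_pool <- function(n, targets) {
    p <- lognormal_from_quantiles(targets[1], targets[2])
    pmin(100, pmax(0, stats::rlnorm(n, p["meanlog"], p["sdlog"])))
  }

  rows <- list(); truth_role <- list()
  add <- function(n, toc, habitat, elev, x, y, role, true_class = NA_character_) {
    if (n == 0) return(invisible())
    id <- sprintf("%s_%04d", role, seq_len(n))
    rows[[length(rows) + 1]] <<- tibble::tibble(
      sample_id = id, x = x, y = y, toc_pct = toc,
      habitat = habitat, elevation_class = elev)
    truth_role[[length(truth_role) + 1]] <<- tibble::tibble(
      sample_id = id, role = role, true_class = true_class, true_dist_m = y)
  }

  n <- config$n_coastal
  add(n, draw_pool(n, config$coastal_targets), "subtidal_other", "below_MHW",
      stats::runif(n, 0, w), stats::runif(n, 0, band), "coastal")

  nd <- config$n_decoys
  add(nd, draw_pool(nd, config$coastal_targets), "saltmarsh", "below_MHW",
      stats::runif(nd, 0, w), stats::runif(nd, 0, band), "decoy_saltmarsh")
  add(nd, draw_pool(nd, config$coastal_targets), "seagrass", "below_MHW",
      stats::runif(nd, 0, w), stats::runif(nd, 0, band), "decoy_seagrass")
  add(nd, draw_pool(nd, config$coastal_targets), "subtidal_other", "above_MHW",
      stats::runif(nd, 0, w), stats::runif(nd, 0, band), "decoy_above_mhw")
  map_ymax <- max(geometry$cells$y1)
  add(nd, draw_pool(nd, config$coastal_targets), "subtidal_other", "below_MHW",
      stats::runif(nd, 0, w), stats::runif(nd, map_ymax + 1, map_ymax + 5000),
      "decoy_offshore")

  # shelf samples placed strictly inside cells of their true class and
  # offshore of the coastal band, so the coastal and substrate pools are
  # disjoint (aggregate sites sit further offshore than dredged ports)
  margin <- 1  # metres clear of cell edges, keeping classification unambiguous
  for (cl in names(config$n_classes)) {
    ncl <- config$n_classes[[cl]]
    if (ncl == 0) next
    cells <- geometry$cells[geometry$cells$substrate_class == cl &
                              geometry$cells$y1 > band + 2 * margin, ]
    pick <- sample.int(nrow(cells), ncl, replace = TRUE)
    x <- stats::runif(ncl, cells$x0[pick] + margin, cells$x1[pick] - margin)
    y <- stats::runif(ncl, pmax(cells$y0[pick], band) + margin,
                      cells$y1[pick] - margin)
    add(ncl, draw_pool(ncl, config$class_targets[[cl]]), "subtidal_other",
        "below_MHW", x, y, paste0("shelf_", cl), true_class = cl)
  }

  samples <- toc_samples(dplyr::bind_rows(rows))
  list(samples = samples, map = geometry$map, coastline = geometry$coastline,
       truth = list(per_sample = dplyr::bind_rows(truth_role),
                    coastal_targets = config$coastal_targets,
                    class_targets = config$class_targets))
}

#' Generate a synthetic extraction-event table with known true masses
#'
#' Every record has a true mass drawn from the configured log10-normal; the
#' reported quantity then reflects the missingness pattern: quantity-bearing
#' records report the mass in a random unit (kg, long ton, m3 or cubic
#' yard), cost-only records report `true_mass * true_cost_rate` as a
#' currency amount, and `neither` records report nothing. Optional decoy
#' records in excluded categories (maerl, historical non-aggregate
#' commodities) exercise the category filter.
#'
#' @param config A [synth_config()].
#' @param industry `"port_dredging"` or `"aggregate"`.
#' @param countries Character vector of country codes.
#' @param years Integer years to populate.
#' @param n_per_cell Records per country-year.
#' @param ports Optional port names: when given, records are port-scoped
#'   (one port drawn per record), as in historical UK returns.
#' @param n_maerl,n_nonaggregate Decoy record counts (category-tagged,
#'   aggregate industry).
#' @param sediment_probs Sediment-type mix for aggregate records
#'   (sand/coarse/mixed).
#' @return List with `records` (an [extraction_records()] tibble) and
#'   `truth` (tibble of `record_id`, `true_mass_kg`, `composition`).
#' @export
gen_event_table <- function(config = synth_config(),
                            industry = "port_dredging",
                            countries = "UK",
                            years = 1995:2000,
                            n_per_cell = 3,
                            ports = NULL,
                            n_maerl = 0, n_nonaggregate = 0,
                            sediment_probs = c(sand = 0.53, coarse = 0.46,
                                               mixed = 0.01)) {
  set.seed(substream_seed(config$seed, "events", industry))
  cells <- expand.grid(country = countries, year = years,
                       rep = seq_len(n_per_cell), stringsAsFactors = FALSE)
  nrec <- nrow(cells)
  true_mass <- 10^stats::rnorm(nrec, config$mass_log10_mu,
                               config$mass_log10_sigma)
  composition <- sample(names(config$missing_fracs), nrec, replace = TRUE,
                        prob = config$missing_fracs)
  is_period <- stats::runif(nrec) < config$period_fraction
  period_len <- ifelse(is_period, sample(c(5L, 10L, 20L), nrec, replace = TRUE), 1L)

  unit <- character(nrec); value <- numeric(nrec)
  for (i in seq_len(nrec)) {
    if (composition[i] == "mass") {
      u <- sample(c("kg", "tonne_long_1016", "m3", "cubic_yard"), 1)
      unit[i] <- u
      value[i] <- switch(u,
        kg = true_mass[i],
        tonne_long_1016 = true_mass[i] / unit_constants$long_ton_kg,
        m3 = true_mass[i] / config$density_kg_m3,
        cubic_yard = true_mass[i] / (unit_constants$yd3_m3 * config$density_kg_m3))
    } else if (composition[i] == "cost") {
      unit[i] <- "currency"
      value[i] <- true_mass[i] * config$true_cost_rate
    } else {
      unit[i] <- "absent"
      value[i] <- NA_real_
    }
  }

  sediment <- if (industry == "aggregate") {
    sample(names(sediment_probs), nrec, replace = TRUE, prob = sediment_probs)
  } else rep("unknown", nrec)

  rec <- tibble::tibble(
    record_id = sprintf("%s_%05d", substr(industry, 1, 3), seq_len(nrec)),
    industry = industry,
    country = cells$country,
    scope = if (is.null(ports)) "national_total" else "port",
    port = if (is.null(ports)) NA_character_ else
      sample(ports, nrec, replace = TRUE),
    year_start = cells$year,
    year_end = cells$year + period_len - 1L,
    quantity_value = value,
    quantity_unit = unit,
    sediment_type = sediment,
    category = NA_character_,
    source_tag = "synthetic"
  )

  decoys <- list()
  if (n_maerl > 0) {
    decoys[[1]] <- tibble::tibble(
      record_id = sprintf("maerl_%03d", seq_len(n_maerl)),
      industry = "aggregate", country = sample(countries, n_maerl, TRUE),
      scope = "licence_area", port = NA_character_,
      year_start = sample(years, n_maerl, TRUE),
      year_end = NA_integer_, quantity_value = NA_real_,
      quantity_unit = "absent", sediment_type = "unknown",
      category = "maerl", source_tag = "synthetic")
    decoys[[1]]$year_end <- decoys[[1]]$year_start
  }
  if (n_nonaggregate > 0) {
    cats <- sample(c("tin_prospecting", "clay", "shingle", "borehole"),
                   n_nonaggregate, replace = TRUE)
    decoys[[2]] <- tibble::tibble(
      record_id = sprintf("nonagg_%03d", seq_len(n_nonaggregate)),
      industry = "aggregate", country = sample(countries, n_nonaggregate, TRUE),
      scope = "licence_area", port = NA_character_,
      year_start = sample(years, n_nonaggregate, TRUE),
      year_end = NA_integer_, quantity_value = NA_real_,
      quantity_unit = "absent", sediment_type = "unknown",
      category = cats, source_tag = "synthetic")
    decoys[[2]]$year_end <- decoys[[2]]$year_start
  }

  records <- extraction_records(dplyr::bind_rows(c(list(rec), decoys)))
  truth <- tibble::tibble(record_id = rec$record_id,
                          true_mass_kg = true_mass,
                          composition = composition)
  list(records = records, truth = truth)
}

#' Write a generator truth record to YAML
#' @param truth Truth list or tibble from a generator.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_truth_yaml <- function(truth, path) {
  if (inherits(truth, "data.frame")) truth <- as.list(truth)
  yaml::write_yaml(truth, path)
  invisible(path)
}
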