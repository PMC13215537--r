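#' Monte Carlo simulation settings
#'
#' @param n_runs Number of Monte Carlo runs (default 10000, the point at
#'   which the convergence study shows the output has stabilised).
#' @param seed Master seed. Each (industry, scope) group gets its own
#'   deterministic substream derived from it, so a country's results are
#'   reproducible in isolation yet sum exactly to the shelf results of a
#'   joint run.
#' @param percentiles Lower/upper reporting percentiles (default 5 and 95).
#' @param draw_scope `"per_record"` (default): one %TOC draw per event per
#'   run, giving narrower bands; `"per_year_total"`: one draw per
#'   (scope-year, distribution) cell per run, giving wider bands.
#' @param redraw_imputed Redraw imputed masses every run (default TRUE); if
#'   FALSE each flagged record gets a single imputed mass fixed across runs.
#' @param keep_runs Retain the per-scope run-total vectors (needed for exact
#'   aggregation to shelf/nation).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_runs = 10000, seed = 1L,
                              percentiles = c(5, 95),
                              draw_scope = c("per_record", "per_year_total"),
                              redraw_imputed = TRUE, keep_runs = TRUE) {
  draw_scope <- match.arg(draw_scope)
  stopifnot(n_runs >= 1, length(percentiles) == 2,
            percentiles[1] > 0, percentiles[1] < percentiles[2],
            percentiles[2] < 100)
  structure(list(n_runs = as.integer(n_runs), seed = as.integer(seed),
                 percentiles = percentiles, draw_scope = draw_scope,
                 redraw_imputed = isTRUE(redraw_imputed),
                 keep_runs = isTRUE(keep_runs)),
            class = "simulation_config")
}

#' Derive a reproducible substream seed from a master seed and labels
#'
#' A small deterministic string hash folded with the master seed, kept below
#' 2^31 so it is a valid R seed. Distinct labels give distinct streams.
#'
#' @param seed Master integer seed.
#' @param ... Character labels identifying the substream.
#' @return An integer seed.
#' @export
substream_seed <- function(seed, ...) {
  key <- paste(..., sep = "|")
  m <- 2147483647
  h <- 5381
  for (code in utf8ToInt(key)) h <- (h * 33 + code) %% m
  as.integer((h * 31 + (as.numeric(seed) %% m)) %% m)
}

resolve_dist_label <- function(industry, sediment_type, dists) {
  if (industry == "port_dredging") return("coastal")
  if (sediment_type %in% c("sand", "coarse", "mixed") &&
      !is.null(dists[[sediment_type]])) {
    return(sediment_type)
  }
  "combined"
}

summarise_runs <- function(run_totals, config) {
  q <- stats::quantile(run_totals, config$percentiles / 100, names = FALSE,
                       type = 7)
  tibble::tibble(mean_kg = mean(run_totals),
                 sd_kg = stats::sd(run_totals),
                 p_low_kg = q[1], p_high_kg = q[2])
}

empty_estimates <- function() {
  out <- tibble::tibble(
    industry = character(), scope_type = character(), scope_id = character(),
    country = character(), year = integer(),
    mean_kg = double(), sd_kg = double(), p_low_kg = double(),
    p_high_kg = double(), n_runs = integer(), seed = integer(),
    run_totals = list()
  )
  class(out) <- c("carbon_estimates", class(out))
  out
}

#' Propagate %TOC and mass uncertainty to carbon-disturbance estimates
#'
#' For each Monte Carlo run, every event draws a %TOC value from the
#' distribution matching its context (port dredging uses the coastal pool;
#' aggregate extraction uses its sediment type's pool, or the combined pool
#' when the type is unknown) and, where the record reported no quantity, an
#' imputed mass from the log10-normal model. Event carbon (mass x %TOC/100)
#' is spread equally over the years the record covers and accumulated into
#' its scope. Summaries (mean, n-1 SD, and percentile bounds via linear
#' interpolation of order statistics) are computed over the run totals of
#' each (industry, scope, year) cell.
#'
#' Estimates are produced at the finest available scope: records carrying a
#' port name are summarised per port (and can be summed to a nation with
#' [aggregate_ports_to_nation()]); all others per country (summed to the
#' shelf with [aggregate_country_to_shelf()]).
#'
#' @param events A [harmonise_records()] table.
#' @param dists Named list of [toc_distribution()]s; needs `coastal` for
#'   dredging events and `sand`/`coarse`/`mixed`/`combined` as required by
#'   the aggregate events present.
#' @param mass_model A [fit_log10_mass_model()] model; required if any event
#'   needs imputation.
#' @param config A [simulation_config()].
#' @return A `carbon_estimates` tibble: one row per (industry, scope, year)
#'   with `mean_kg`, `sd_kg`, `p_low_kg`, `p_high_kg`, `n_runs`, `seed` and
#'   (when `keep_runs`) a `run_totals` list-column.
#' @export
run_simulation <- function(events, dists, mass_model = NULL,
                           config = simulation_config()) {
  events <- harmonise_records(events)
  if (nrow(events) == 0) return(empty_estimates())

  events$dist_label <- vapply(seq_len(nrow(events)), function(i) {
    resolve_dist_label(events$industry[i], events$sediment_type[i], dists)
  }, character(1))
  missing_dist <- !events$dist_label %in% names(dists)
  if (any(missing_dist)) {
    rlang::abort(paste0("no %TOC distribution for record(s): ",
                        paste(events$record_id[missing_dist], collapse = ", "),
                        " (need '", events$dist_label[which(missing_dist)[1]], "')"))
  }
  if (any(events$needs_imputation) && is.null(mass_model)) {
    rlang::abort(paste0("events need mass imputation but no mass_model given: ",
                        paste(events$record_id[events$needs_imputation],
                              collapse = ", ")))
  }

  events$scope_type <- ifelse(!is.na(events$port), "port", "country")
  events$scope_id <- ifelse(!is.na(events$port), events$port, events$country)
  key <- paste(events$industry, events$scope_type, events$scope_id, sep = "|")
  n <- config$n_runs

  rows <- list()
  for (k in sort(unique(key))) {
    ev <- events[key == k, , drop = FALSE]
    ev <- ev[order(ev$record_id, ev$year), , drop = FALSE]
    set.seed(substream_seed(config$seed, k))
    years <- sort(unique(unlist(lapply(seq_len(nrow(ev)), function(i) {
      seq(ev$year[i], ev$year_end[i])
    }))))
    totals <- matrix(0, nrow = n, ncol = length(years),
                     dimnames = list(NULL, as.character(years)))

    if (config$draw_scope == "per_record") {
      for (i in seq_len(nrow(ev))) {
        m <- event_mass_runs(ev[i, ], mass_model, n, config$redraw_imputed)
        toc <- draw_toc(dists[[ev$dist_label[i]]], n)
        span <- as.character(seq(ev$year[i], ev$year_end[i]))
        contrib <- m * toc / 100 / length(span)
        for (yr in span) totals[, yr] <- totals[, yr] + contrib
      }
    } else {
      # accumulate per-run sediment mass into (year, distribution) cells,
      # then one %TOC draw per cell per run
      cell_mass <- list()
      for (i in seq_len(nrow(ev))) {
        m <- event_mass_runs(ev[i, ], mass_model, n, config$redraw_imputed)
        span <- as.character(seq(ev$year[i], ev$year_end[i]))
        per_year <- m / length(span)
        for (yr in span) {
          ck <- paste(yr, ev$dist_label[i], sep = "|")
          cell_mass[[ck]] <- (cell_mass[[ck]] %||% 0) + per_year
        }
      }
      for (ck in sort(names(cell_mass))) {
        parts <- strsplit(ck, "|", fixed = TRUE)[[1]]
        toc <- draw_toc(dists[[parts[2]]], n)
        totals[, parts[1]] <- totals[, parts[1]] + cell_mass[[ck]] * toc / 100
      }
    }

    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    for (j in seq_along(years)) {
      s <- summarise_runs(totals[, j], config)
      rows[[length(rows) + 1]] <- tibble::tibble(
        industry = parts[1], scope_type = parts[2], scope_id = parts[3],
        country = ev$country[1], year = years[j],
        s, n_runs = n, seed = config$seed,
        run_totals = if (config$keep_runs) list(totals[, j]) else list(NULL)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  out <- out[order(out$industry, out$scope_type, out$scope_id, out$year), ]
  attr(out, "config") <- config
  attr(out, "percentile_method") <- "linear interpolation of order statistics (type 7)"
  class(out) <- c("carbon_estimates", class(out))
  out
}

event_mass_runs <- function(ev, mass_model, n, redraw) {
  if (ev$needs_imputation) {
    if (redraw) sample_imputed_mass(mass_model, n)
    else rep(sample_imputed_mass(mass_model, 1), n)
  } else {
    rep(ev$mass_kg, n)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sum country-level run totals to shelf-wide estimates
#'
#' Shelf run total r = sum over countries of country run total r, so the
#' shelf mean equals the sum of country means exactly and the percentile
#' band reflects between-country dependence in the joint run.
#'
#' @param estimates A `carbon_estimates` tibble with `run_totals` retained
#'   and `scope_type == "country"` rows.
#' @return A `carbon_estimates` tibble with `scope_type = "shelf"`, one row
#'   per (industry, year).
#' @export
aggregate_country_to_shelf <- function(estimates) {
  aggregate_runs(estimates[estimates$scope_type == "country", , drop = FALSE],
                 c("industry", "year"), "shelf", "shelf")
}

#' Sum port-level run totals to a national estimate
#'
#' Used for historical records resolved at port level: carbon is estimated
#' per port, then summed per run to a national total before summarising.
#'
#' @param estimates A `carbon_estimates` tibble with `run_totals` retained
#'   and `scope_type == "port"` rows.
#' @return A `carbon_estimates` tibble with `scope_type = "country"`, one
#'   row per (industry, country, year).
#' @export
aggregate_ports_to_nation <- function(estimates) {
  aggregate_runs(estimates[estimates$scope_type == "port", , drop = FALSE],
                 c("industry", "country", "year"), "country", NULL)
}

aggregate_runs <- function(estimates, by, new_scope_type, new_scope_id) {
  stopifnot(inherits(estimates, "carbon_estimates"))
  if (nrow(estimates) == 0) return(empty_estimates())
  if (any(vapply(estimates$run_totals, is.null, logical(1)))) {
    rlang::abort("aggregation needs retained run totals (keep_runs = TRUE)")
  }
  if (length(unique(estimates$n_runs)) != 1) {
    rlang::abort("mismatched n_runs across estimates; rerun with one config")
  }
  config <- attr(estimates, "config") %||%
    simulation_config(n_runs = estimates$n_runs[1], seed = estimates$seed[1])
  groups <- split(seq_len(nrow(estimates)),
                  interaction(lapply(by, function(b) estimates[[b]]),
                              drop = TRUE, sep = "|"))
  rows <- lapply(groups, function(idx) {
    summed <- Reduce(`+`, estimates$run_totals[idx])
    first <- estimates[idx[1], ]
    tibble::tibble(
      industry = first$industry, scope_type = new_scope_type,
      scope_id = new_scope_id %||% first$country,
      country = if (new_scope_type == "shelf") NA_character_ else first$country,
      year = first$year,
      summarise_runs(summed, config),
      n_runs = first$n_runs, seed = first$seed,
      run_totals = list(summed)
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- out[order(out$industry, out$scope_id, out$year), ]
  attr(out, "config") <- config
  class(out) <- c("carbon_estimates", class(out))
  out
}

#' @rdname run_simulation
#' @param x,... A `carbon_estimates` tibble and unused arguments, for the
#'   broom generics. `tidy()` reports megatons (1 Mt = 1e9 kg) to match the
#'   reporting convention of shelf-scale carbon budgets.
#' @method tidy carbon_estimates
#' @export
tidy.carbon_estimates <- function(x, ...) {
  tibble::tibble(
    industry = x$industry, scope_type = x$scope_type, scope_id = x$scope_id,
    year = x$year,
    mean_mt = kg_to_mt(x$mean_kg), sd_mt = kg_to_mt(x$sd_kg),
    p5_mt = kg_to_mt(x$p_low_kg), p95_mt = kg_to_mt(x$p_high_kg),
    n_runs = x$n_runs
  )
}

#' Study Monte Carlo convergence over an increasing run grid
#'
#' Runs `n_iterations` independently seeded simulations at each run count
#' and reports the spread of the grand-mean estimate between iterations.
#' The output is declared stabilised at the first run count where the
#' inter-iteration SD falls below `tolerance` times the mean.
#'
#' @param events,dists,mass_model As in [run_simulation()].
#' @param run_grid Ascending integer vector of run counts.
#' @param n_iterations Independent repeats per run count (default 10).
#' @param seed Master seed; each (run count, iteration) gets a substream.
#' @param tolerance Relative inter-iteration SD below which the output is
#'   declared stable (default 0.01).
#' @return Tibble with one row per (runs, iteration) and columns `runs`,
#'   `iteration`, `mean_kg`; a `summary` attribute holds per-run-count mean,
#'   between-iteration SD and the `stabilised` flag.
#' @export
convergence_study <- function(events, dists, mass_model = NULL,
                              run_grid = c(100, 500, 1000, 5000, 10000),
                              n_iterations = 10, seed = 1L, tolerance = 0.01) {
  stopifnot(!is.unsorted(run_grid))
  rows <- list()
  for (r in run_grid) {
    for (it in seq_len(n_iterations)) {
      cfg <- simulation_config(n_runs = r,
                               seed = substream_seed(seed, "conv", r, it),
                               keep_runs = FALSE)
      est <- run_simulation(events, dists, mass_model, cfg)
      rows[[length(rows) + 1]] <- tibble::tibble(
        runs = r, iteration = it, mean_kg = sum(est$mean_kg)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  summary <- out |>
    dplyr::group_by(.data$runs) |>
    dplyr::summarise(sd_between = stats::sd(.data$mean_kg),
                     mean_kg = mean(.data$mean_kg),
                     .groups = "drop") |>
    dplyr::relocate("mean_kg", .before = "sd_between") |>
    dplyr::mutate(stabilised = .data$sd_between / .data$mean_kg < tolerance)
  attr(out, "summary") <- summary
  out
}

#' Sensitivity of an estimate to assumed sediment-type proportions
#'
#' For records that report only a national extraction total without
#' sediment types, the %TOC pool must be assumed. This splits a total mass
#' across (sand, coarse, mixed) fractions on a grid of assumed proportions,
#' draws %TOC per fraction from the matching pool, and reports the estimate
#' at every grid point.
#'
#' @param total_mass_kg Sediment mass to allocate (kg).
#' @param dists Named list with `sand`, `coarse`, `mixed` distributions.
#' @param proportion_grid Data frame (or matrix) with columns `sand`,
#'   `coarse`, `mixed`; each row non-negative and summing to 1 (+-1e-9).
#' @param config A [simulation_config()].
#' @return Tibble: the grid columns plus `mean_kg`, `sd_kg`, `p_low_kg`,
#'   `p_high_kg`, `n_runs`.
#' @export
sensitivity_sediment_proportions <- function(total_mass_kg, dists,
                                             proportion_grid,
                                             config = simulation_config()) {
  grid <- as.data.frame(proportion_grid)
  stopifnot(all(c("sand", "coarse", "mixed") %in% names(grid)))
  sums <- grid$sand + grid$coarse + grid$mixed
  if (any(grid$sand < 0 | grid$coarse < 0 | grid$mixed < 0) ||
      any(abs(sums - 1) > 1e-9)) {
    rlang::abort("each row of proportions must be non-negative and sum to 1")
  }
  n <- config$n_runs
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    set.seed(substream_seed(config$seed, "sens", i))
    total <- numeric(n)
    for (cl in c("sand", "coarse", "mixed")) {
      p <- grid[[cl]][i]
      if (p > 0) total <- total + carbon_mass(total_mass_kg * p,
                                              draw_toc(dists[[cl]], n))
    }
    tibble::tibble(sand = grid$sand[i], coarse = grid$coarse[i],
                   mixed = grid$mixed[i], summarise_runs(total, config),
                   n_runs = n)
  })
  dplyr::bind_rows(rows)
}
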