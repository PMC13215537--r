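#' Multi-year mean +- SD of annual estimates
#'
#' Headline figures ("X +- Y Mt organic carbon per year over YYYY-YYYY") are
#' the arithmetic mean and n-1 SD of the per-year mean estimates within the
#' range. The alternative reading (pooled SD over all run totals across
#' years) is available via `method = "pooled_runs"` and labelled in the
#' output.
#'
#' @param estimates A `carbon_estimates` tibble (one scope).
#' @param year_range Length-2 inclusive year range; default spans the data.
#' @param method `"annual_means"` (default) or `"pooled_runs"` (needs
#'   retained run totals).
#' @return One-row tibble: `year_from`, `year_to`, `n_years`, `mean_mt`,
#'   `sd_mt`, `method`.
#' @export
summarise_multi_year <- function(estimates, year_range = NULL,
                                 method = c("annual_means", "pooled_runs")) {
  method <- match.arg(method)
  if (is.null(year_range)) year_range <- range(estimates$year)
  sel <- estimates[estimates$year >= year_range[1] &
                     estimates$year <= year_range[2], , drop = FALSE]
  if (nrow(sel) == 0) rlang::abort("no estimates in the requested year range")
  if (method == "annual_means") {
    m <- mean(sel$mean_kg)
    s <- stats::sd(sel$mean_kg)
  } else {
    if (any(vapply(sel$run_totals, is.null, logical(1)))) {
      rlang::abort("pooled_runs needs retained run totals")
    }
    pooled <- unlist(sel$run_totals)
    m <- mean(pooled)
    s <- stats::sd(pooled)
  }
  tibble::tibble(year_from = year_range[1], year_to = year_range[2],
                 n_years = nrow(sel), mean_mt = kg_to_mt(m),
                 sd_mt = kg_to_mt(if (is.na(s)) 0 else s), method = method)
}

#' Write / read a results CSV
#'
#' One row per (industry, scope, year) with megaton summaries, the run count
#' and seed, so any results file is regenerable from its inputs and seed.
#'
#' @param estimates A `carbon_estimates` tibble.
#' @param path Output CSV path.
#' @return `write_estimates_csv()` returns `path` invisibly;
#'   `read_estimates_csv()` a tibble of the summaries (run totals are not
#'   serialised).
#' @export
write_estimates_csv <- function(estimates, path) {
  utils::write.csv(tidy(estimates), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_estimates_csv
#' @export
read_estimates_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Per-industry multi-year report table
#'
#' @param estimates A `carbon_estimates` tibble.
#' @return Tibble with one row per (industry, scope_type, scope_id): year
#'   span and the mean +- SD of annual mean estimates, in Mt.
#' @export
report_estimates <- function(estimates) {
  estimates |>
    dplyr::group_by(.data$industry, .data$scope_type, .data$scope_id) |>
    dplyr::group_modify(function(g, key) {
      class(g) <- c("carbon_estimates", class(g))
      summarise_multi_year(g)
    }) |>
    dplyr::ungroup()
}

#' @export
print.carbon_estimates <- function(x, ...) {
  cat("Carbon-disturbance estimates (", nrow(x), " scope-years; ",
      "Mt = 1e9 kg; p", attr(x, "config")$percentiles[1] %||% 5, "/p",
      attr(x, "config")$percentiles[2] %||% 95,
      " by linear interpolation)\n", sep = "")
  print(tidy(x), ...)
  invisible(x)
}

#' Plot annual carbon-disturbance estimates
#'
#' Mean line per scope with a ribbon between the lower and upper percentile
#' bounds, faceted by industry, in Mt.
#'
#' @param object A `carbon_estimates` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot carbon_estimates
#' @export
autoplot.carbon_estimates <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$year, y = .data$mean_mt,
                                   group = .data$scope_id)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p5_mt, ymax = .data$p95_mt),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~industry, scales = "free_y") +
    ggplot2::labs(x = "Year", y = "Organic carbon disturbed (Mt)",
                  caption = "Ribbon: 5th-95th percentile of Monte Carlo run totals") +
    ggplot2::theme_minimal()
}

#' Plot an empirical %TOC pool
#'
#' @param object A [toc_distribution()].
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot toc_distribution
#' @export
autoplot.toc_distribution <- function(object, bins = 60, ...) {
  df <- tibble::tibble(toc_pct = object$values)
  med <- stats::median(object$values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$toc_pct)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = med, linetype = 2) +
    ggplot2::labs(x = "%TOC (dry weight)", y = "Samples",
                  title = paste0("%TOC pool '", object$label, "' (n = ",
                                 object$n, ", median = ",
                                 format(med, digits = 3), "%)")) +
    ggplot2::theme_minimal()
}

#' Plot a Monte Carlo convergence study
#'
#' Per-run-count iteration means with +-1 between-iteration SD error bars.
#'
#' @param study Output of [convergence_study()].
#' @return A ggplot object.
#' @export
plot_convergence <- function(study) {
  s <- attr(study, "summary")
  ggplot2::ggplot(study, ggplot2::aes(x = factor(.data$runs),
                                      y = kg_to_mt(.data$mean_kg))) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.5) +
    ggplot2::geom_errorbar(
      data = s,
      ggplot2::aes(x = factor(.data$runs),
                   y = kg_to_mt(.data$mean_kg),
                   ymin = kg_to_mt(.data$mean_kg - .data$sd_between),
                   ymax = kg_to_mt(.data$mean_kg + .data$sd_between)),
      width = 0.2, colour = "firebrick") +
    ggplot2::labs(x = "Monte Carlo runs", y = "Mean estimate (Mt)") +
    ggplot2::theme_minimal()
}

#' Plot a sediment-proportion sensitivity sweep
#'
#' @param sens Output of [sensitivity_sediment_proportions()].
#' @return A ggplot object (estimate vs assumed sand fraction).
#' @export
plot_sensitivity <- function(sens) {
  ggplot2::ggplot(sens, ggplot2::aes(x = .data$sand,
                                     y = kg_to_mt(.data$mean_kg))) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = kg_to_mt(.data$p_low_kg),
                                      ymax = kg_to_mt(.data$p_high_kg)),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Assumed sand fraction",
                  y = "Organic carbon disturbed (Mt)") +
    ggplot2::theme_minimal()
}
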