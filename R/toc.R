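#' Build and validate a %TOC sample table
#'
#' One row per georeferenced sediment total-organic-carbon measurement,
#' expressed as dry-weight percent. Habitat and tidal-elevation labels drive
#' the coastal filter; coordinates are in a projected equal-area CRS
#' (EPSG:3035 metres).
#'
#' @param df Data frame with columns `sample_id`, `x`, `y` (metres),
#'   `toc_pct` (in `[0, 100]`), `habitat` (`"seagrass"`, `"saltmarsh"`,
#'   `"subtidal_other"`), `elevation_class` (`"above_MHW"`, `"below_MHW"`).
#'   Optional `substrate_class`.
#' @return A validated tibble with class `toc_samples`.
#' @export
toc_samples <- function(df) {
  df <- tibble::as_tibble(df)
  required <- c("sample_id", "x", "y", "toc_pct", "habitat", "elevation_class")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    rlang::abort(paste("missing columns:", paste(missing, collapse = ", ")))
  }
  if (any(df$toc_pct < 0 | df$toc_pct > 100)) {
    rlang::abort("toc_pct must lie in [0, 100]")
  }
  if (!all(df$habitat %in% c("seagrass", "saltmarsh", "subtidal_other"))) {
    rlang::abort("habitat must be seagrass, saltmarsh or subtidal_other")
  }
  if (!all(df$elevation_class %in% c("above_MHW", "below_MHW"))) {
    rlang::abort("elevation_class must be above_MHW or below_MHW")
  }
  if (!"substrate_class" %in% names(df)) df$substrate_class <- NA_character_
  class(df) <- c("toc_samples", class(df))
  df
}

#' Read a %TOC sample table from CSV
#' @param path Path to a CSV with the [toc_samples()] schema.
#' @return A validated `toc_samples` tibble.
#' @export
read_toc_samples <- function(path) {
  toc_samples(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' An empirical %TOC distribution
#'
#' A labelled pool of observed %TOC values. Monte Carlo draws resample the
#' raw values uniformly with replacement (no kernel smoothing, no parametric
#' fit), so draws never leave the observed range and the pool's percentiles
#' are reproduced without extra assumptions. A weighted pool (from the
#' proportion-weighted combined policy) carries per-value draw
#' probabilities.
#'
#' @param values Numeric vector of %TOC values in `[0, 100]`; values of
#'   exactly 0 are legal.
#' @param label One of `"coastal"`, `"sand"`, `"coarse"`, `"mixed"`,
#'   `"combined"`.
#' @param weights Optional per-value draw probabilities (normalised
#'   internally).
#' @return A `toc_distribution` object.
#' @export
toc_distribution <- function(values,
                             label = c("coastal", "sand", "coarse", "mixed",
                                       "combined"),
                             weights = NULL) {
  label <- match.arg(label)
  if (length(values) < 1) rlang::abort(paste0("empty %TOC pool for '", label, "'"))
  if (any(values < 0 | values > 100)) rlang::abort("toc values must lie in [0, 100]")
  if (!is.null(weights)) {
    stopifnot(length(weights) == length(values), all(weights >= 0))
    weights <- weights / sum(weights)
  }
  structure(list(label = label, values = as.numeric(values),
                 n = length(values), weights = weights),
            class = "toc_distribution")
}

#' @export
print.toc_distribution <- function(x, ...) {
  q <- stats::quantile(x$values, c(0.05, 0.5, 0.95), names = FALSE)
  cat(sprintf("%%TOC pool '%s': n = %d, median = %.2f%%, p5 = %.2f%%, p95 = %.2f%%\n",
              x$label, x$n, q[2], q[1], q[3]))
  invisible(x)
}

#' @rdname toc_distribution
#' @param x,... A `toc_distribution` and unused arguments.
#' @method glance toc_distribution
#' @export
glance.toc_distribution <- function(x, ...) {
  q <- stats::quantile(x$values, c(0.05, 0.5, 0.95), names = FALSE)
  tibble::tibble(label = x$label, n = x$n,
                 mean = mean(x$values), median = q[2], p5 = q[1], p95 = q[3],
                 min = min(x$values), max = max(x$values),
                 weighted = !is.null(x$weights))
}

#' Filter samples to the coastal pool used for port dredging
#'
#' Port dredging is confined to estuarine, coastal and inshore areas, so the
#' %TOC pool for dredging excludes seagrass and saltmarsh samples, samples
#' above mean high water, and samples more than `max_dist_km` from the
#' coastline (boundary samples at exactly the cutoff are retained).
#'
#' @param samples A [toc_samples()] tibble.
#' @param coastline Two-column matrix of coastline vertices (metres, same
#'   CRS as the samples).
#' @param max_dist_km Offshore cutoff in kilometres (default 5).
#' @return A `toc_distribution` labelled `"coastal"`, with an `audit`
#'   attribute counting exclusions by reason and a `sample_id` attribute of
#'   retained ids.
#' @export
filter_coastal_samples <- function(samples, coastline, max_dist_km = 5) {
  stopifnot(inherits(samples, "toc_samples"))
  habitat_ok <- samples$habitat == "subtidal_other"
  elevation_ok <- samples$elevation_class == "below_MHW"
  dist_m <- dist_to_polyline(samples$x, samples$y, coastline)
  dist_ok <- dist_m <= max_dist_km * 1000
  keep <- habitat_ok & elevation_ok & dist_ok
  if (!any(keep)) rlang::abort("no coastal samples retained by the filter")
  audit <- tibble::tibble(
    reason = c("habitat", "above_MHW", "offshore", "retained"),
    n = c(sum(!habitat_ok), sum(habitat_ok & !elevation_ok),
          sum(habitat_ok & elevation_ok & !dist_ok), sum(keep))
  )
  dist <- toc_distribution(samples$toc_pct[keep], "coastal")
  attr(dist, "audit") <- audit
  attr(dist, "sample_id") <- samples$sample_id[keep]
  dist
}

#' Assign a substrate class to each sample by polygon overlay
#'
#' Point-in-polygon assignment against a classed substrate map; points
#' falling outside every polygon get class `"other"`. Each sample receives
#' exactly one class (the first containing polygon, in map order).
#'
#' @param samples A [toc_samples()] tibble.
#' @param map A [substrate_map()].
#' @return The samples with `substrate_class` filled in.
#' @export
classify_samples_by_substrate <- function(samples, map) {
  stopifnot(inherits(samples, "toc_samples"))
  cls <- rep("other", nrow(samples))
  unassigned <- rep(TRUE, nrow(samples))
  for (i in seq_len(nrow(map))) {
    if (!any(unassigned)) break
    inside <- rep(FALSE, nrow(samples))
    inside[unassigned] <- points_in_ring(samples$x[unassigned],
                                         samples$y[unassigned],
                                         map$ring[[i]])
    cls[inside] <- map$substrate_class[i]
    unassigned <- unassigned & !inside
  }
  samples$substrate_class <- cls
  samples
}

#' Build per-substrate %TOC distributions
#'
#' @param samples Classified [toc_samples()] (see
#'   [classify_samples_by_substrate()]).
#' @param classes Substrate classes to build pools for.
#' @return Named list of `toc_distribution`s, one per class.
#' @export
build_substrate_distributions <- function(samples,
                                          classes = c("sand", "coarse", "mixed")) {
  stopifnot(inherits(samples, "toc_samples"))
  out <- lapply(classes, function(cl) {
    vals <- samples$toc_pct[!is.na(samples$substrate_class) &
                              samples$substrate_class == cl]
    if (length(vals) == 0) {
      rlang::abort(paste0("no samples in substrate class '", cl, "'"))
    }
    toc_distribution(vals, cl)
  })
  stats::setNames(out, classes)
}

#' Combine the sand/coarse/mixed pools into one distribution
#'
#' Used for aggregate-extraction records that predate per-substrate
#' reporting. The default pools all raw values, so class weights are implied
#' by sample counts; the `"weighted"` policy instead draws classes in given
#' proportions (e.g. the observed 53/46/1 extraction shares), implemented as
#' per-value draw probabilities.
#'
#' @param dists Named list with `toc_distribution`s `sand`, `coarse`,
#'   `mixed`.
#' @param policy `"pooled"` (default) or `"weighted"`.
#' @param weights Length-3 non-negative class weights (sand, coarse, mixed)
#'   summing to 1; required for the weighted policy.
#' @return A `toc_distribution` labelled `"combined"`.
#' @export
build_combined_distribution <- function(dists, policy = c("pooled", "weighted"),
                                        weights = NULL) {
  policy <- match.arg(policy)
  for (cl in c("sand", "coarse", "mixed")) {
    if (is.null(dists[[cl]]) || dists[[cl]]$n < 1) {
      rlang::abort(paste0("combined distribution needs a non-empty '", cl, "' pool"))
    }
  }
  values <- c(dists$sand$values, dists$coarse$values, dists$mixed$values)
  if (policy == "pooled") {
    return(toc_distribution(values, "combined"))
  }
  stopifnot(length(weights) == 3, all(weights >= 0),
            abs(sum(weights) - 1) < 1e-9)
  w <- c(rep(weights[1] / dists$sand$n, dists$sand$n),
         rep(weights[2] / dists$coarse$n, dists$coarse$n),
         rep(weights[3] / dists$mixed$n, dists$mixed$n))
  toc_distribution(values, "combined", weights = w)
}

#' Draw %TOC values from an empirical distribution
#'
#' Uniform (or weighted) resampling with replacement from the stored raw
#' values. Consumes the current R random stream.
#'
#' @param dist A [toc_distribution()].
#' @param n Number of draws.
#' @return Numeric vector of %TOC values.
#' @export
draw_toc <- function(dist, n = 1) {
  stopifnot(inherits(dist, "toc_distribution"))
  if (dist$n == 1) return(rep(dist$values, n))
  dist$values[sample.int(dist$n, n, replace = TRUE, prob = dist$weights)]
}

#' Write a %TOC distribution to CSV (one value per row) for audit
#' @param dist A [toc_distribution()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_toc_distribution <- function(dist, path) {
  utils::write.csv(data.frame(label = dist$label, toc_pct = dist$values),
                   path, row.names = FALSE)
  invisible(path)
}
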