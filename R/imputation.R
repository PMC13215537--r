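#' Fit an average cost-per-kg rate from paired cost/mass records
#'
#' Early UK port records sometimes list both the monetary cost of dredging
#' works and the amount of sediment removed. Those pairs calibrate an
#' average cost per kilogram, later used to estimate masses for records
#' that list only a cost.
#'
#' @param pairs Data frame with columns `cost` (> 0) and `mass_kg` (> 0);
#'   an optional `record_id` column is kept for provenance.
#' @param method `"mean_ratio"` (default): unweighted mean of the per-pair
#'   cost/mass ratios. `"pooled"`: total cost over total mass, which weights
#'   pairs by mass.
#' @return A `cost_rate_model` list: `rate_per_kg`, `n_pairs`, `pair_ids`,
#'   `method`.
#' @examples
#' fit_cost_rate(data.frame(cost = c(100, 300), mass_kg = c(1000, 1000)))
#' @export
fit_cost_rate <- function(pairs, method = c("mean_ratio", "pooled")) {
  method <- match.arg(method)
  if (is.null(pairs) || nrow(pairs) == 0) rlang::abort("no calibration pairs")
  if (any(pairs$mass_kg <= 0)) rlang::abort("calibration masses must be > 0")
  if (any(pairs$cost <= 0)) rlang::abort("calibration costs must be > 0")
  rate <- switch(method,
    mean_ratio = mean(pairs$cost / pairs$mass_kg),
    pooled = sum(pairs$cost) / sum(pairs$mass_kg)
  )
  structure(
    list(
      rate_per_kg = rate,
      n_pairs = nrow(pairs),
      pair_ids = if ("record_id" %in% names(pairs)) pairs$record_id else NULL,
      method = method
    ),
    class = "cost_rate_model"
  )
}

#' Estimate sediment mass from a monetary cost
#'
#' @param cost Non-negative cost(s) in the calibration currency.
#' @param model A [fit_cost_rate()] model.
#' @return Estimated mass(es) in kg (`cost / rate_per_kg`).
#' @export
estimate_mass_from_cost <- function(cost, model) {
  stopifnot(inherits(model, "cost_rate_model"))
  if (any(cost < 0)) rlang::abort("cost must be non-negative")
  cost / model$rate_per_kg
}

#' @export
print.cost_rate_model <- function(x, ...) {
  cat("Cost-rate model:", format(x$rate_per_kg, digits = 4),
      "per kg, fitted on", x$n_pairs, "pairs (", x$method, ")\n")
  invisible(x)
}

#' Fit a normal model on log10 extraction masses
#'
#' Extraction masses span orders of magnitude and are right-skewed; on a
#' log10 scale they are adequately normal (checked with a Shapiro-Wilk
#' test). The fitted normal is resampled inside the Monte Carlo to impute
#' masses for records where neither an amount nor a cost was listed.
#'
#' @param masses_kg Numeric vector of strictly positive masses (kg), n >= 3.
#' @return A `log10_mass_model` list: `mu` and `sigma` (mean and n-1 sample
#'   SD of log10 mass), `n`, `shapiro_w`, `shapiro_p`, `degenerate` (TRUE
#'   when sigma is 0, in which case the normality test is undefined and the
#'   model refuses to impute).
#' @examples
#' fit_log10_mass_model(10^rnorm(50, 7.2, 0.69))
#' @export
fit_log10_mass_model <- function(masses_kg) {
  if (length(masses_kg) < 3) rlang::abort("insufficient data: need n >= 3 masses")
  if (any(masses_kg <= 0)) rlang::abort("all masses must be > 0")
  lg <- log10(masses_kg)
  mu <- mean(lg)
  sigma <- stats::sd(lg)
  degenerate <- sigma == 0
  if (degenerate || length(lg) > 5000) {
    # normality diagnostics are undefined for constant samples and the
    # Shapiro-Wilk statistic is defined for 3 <= n <= 5000
    w <- NA_real_; p <- NA_real_
  } else {
    sw <- stats::shapiro.test(lg)
    w <- unname(sw$statistic); p <- sw$p.value
  }
  structure(
    list(mu = mu, sigma = sigma, n = length(lg),
         shapiro_w = w, shapiro_p = p, degenerate = degenerate),
    class = "log10_mass_model"
  )
}

#' Draw imputed extraction masses from a fitted log10-normal model
#'
#' Each draw is `10^x` with `x ~ Normal(mu, sigma)`: sampled on the log
#' scale and back-transformed, so all imputed masses are strictly positive.
#' Draws consume the current R random stream; seed with [set.seed()] (or let
#' the simulation engine manage substreams) for reproducibility.
#'
#' @param model A [fit_log10_mass_model()] model.
#' @param n_draws Number of draws (>= 1).
#' @return Numeric vector of `n_draws` masses in kg.
#' @export
sample_imputed_mass <- function(model, n_draws) {
  stopifnot(inherits(model, "log10_mass_model"), n_draws >= 1)
  if (isTRUE(model$degenerate)) {
    rlang::abort("degenerate mass model (sigma = 0): refusing to impute constants")
  }
  10^stats::rnorm(n_draws, model$mu, model$sigma)
}

#' @export
print.log10_mass_model <- function(x, ...) {
  cat(sprintf("log10-normal mass model: mu = %.3f, sigma = %.3f (log10 kg), n = %d\n",
              x$mu, x$sigma, x$n))
  if (!is.na(x$shapiro_w)) {
    cat(sprintf("  Shapiro-Wilk on log10 masses: W = %.3f, p = %.3f\n",
                x$shapiro_w, x$shapiro_p))
  } else {
    cat("  degenerate fit (sigma = 0); imputation disabled\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_log10_mass_model
#' @param x,... A `log10_mass_model` and unused arguments, for the broom
#'   generics.
#' @method tidy log10_mass_model
#' @export
tidy.log10_mass_model <- function(x, ...) {
  tibble::tibble(
    term = c("mu", "sigma"),
    estimate = c(x$mu, x$sigma),
    scale = "log10 kg"
  )
}

#' @rdname fit_log10_mass_model
#' @method glance log10_mass_model
#' @export
glance.log10_mass_model <- function(x, ...) {
  tibble::tibble(n = x$n, shapiro_w = x$shapiro_w, shapiro_p = x$shapiro_p,
                 degenerate = x$degenerate)
}

#' Serialise / restore a log10 mass model
#'
#' Writes the fitted parameters (and normality diagnostics) to a small YAML
#' document so simulation runs can be reproduced without refitting.
#'
#' @param model A `log10_mass_model`.
#' @param path File path for the YAML document.
#' @return `write_mass_model()` returns `path` invisibly;
#'   `read_mass_model()` returns the restored model.
#' @export
write_mass_model <- function(model, path) {
  stopifnot(inherits(model, "log10_mass_model"))
  yaml::write_yaml(unclass(model), path, precision = 15)
  invisible(path)
}

#' @rdname write_mass_model
#' @export
read_mass_model <- function(path) {
  obj <- yaml::read_yaml(path)
  obj$shapiro_w <- if (is.null(obj$shapiro_w)) NA_real_ else obj$shapiro_w
  obj$shapiro_p <- if (is.null(obj$shapiro_p)) NA_real_ else obj$shapiro_p
  structure(obj[c("mu", "sigma", "n", "shapiro_w", "shapiro_p", "degenerate")],
            class = "log10_mass_model")
}
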