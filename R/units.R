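#' Unit constants used when harmonising extraction records
#'
#' Historical UK dredging returns report quantities in long tons (1016 kg),
#' cubic yards, or cubic metres; modern registries report tonnes (1000 kg)
#' or cubic metres. Volumes are converted to mass with a single average
#' marine-sediment density because the source records rarely state sediment
#' type or dry bulk density.
#'
#' @format A named list with elements `long_ton_kg` (1016), `tonne_kg`
#'   (1000), `yd3_m3` (0.764554858), `default_density_kg_m3` (1700) and
#'   `mt_kg` (1e9, kilograms per megaton).
#' @export
unit_constants <- list(
  long_ton_kg           = 1016,
  tonne_kg              = 1000,
  yd3_m3                = 0.764554858,
  default_density_kg_m3 = 1700,
  mt_kg                 = 1e9
)

#' Quantity units accepted in extraction-event tables
#' @keywords internal
quantity_units <- c("kg", "tonne", "tonne_long_1016", "m3", "cubic_yard",
                    "currency", "absent")

#' Convert a reported extraction quantity to kilograms
#'
#' Mass units pass through (long ton = 1016 kg, tonne = 1000 kg); volume
#' units are multiplied by an average sediment density, with cubic yards
#' first converted to cubic metres. Monetary and absent quantities are not
#' convertible here: they are handled by the cost-rate model and the
#' log10-normal imputation model respectively.
#'
#' @param value Numeric vector of non-negative reported quantities.
#' @param unit Character vector (recycled) naming each value's unit; one of
#'   `"kg"`, `"tonne"`, `"tonne_long_1016"`, `"m3"`, `"cubic_yard"`.
#' @param density_kg_m3 Average wet bulk density of marine sediment used for
#'   volume-to-mass conversion, in kg per cubic metre. Default 1700.
#' @return Numeric vector of masses in kilograms.
#' @examples
#' convert_quantity_to_mass(1, "tonne_long_1016")   # 1016
#' convert_quantity_to_mass(100, "m3")              # 170000
#' @export
convert_quantity_to_mass <- function(value, unit,
                                     density_kg_m3 = unit_constants$default_density_kg_m3) {
  stopifnot(is.numeric(value), is.character(unit), density_kg_m3 > 0)
  if (any(value < 0, na.rm = TRUE)) {
    rlang::abort("quantity values must be non-negative")
  }
  n <- max(length(value), length(unit))
  value <- rep_len(value, n)
  unit <- rep_len(unit, n)
  bad <- !unit %in% c("kg", "tonne", "tonne_long_1016", "m3", "cubic_yard")
  if (any(bad)) {
    rlang::abort(paste0(
      "unit(s) not convertible to mass: ",
      paste(unique(unit[bad]), collapse = ", "),
      " (currency needs a cost-rate model; absent needs imputation)"
    ))
  }
  factor <- c(
    kg              = 1,
    tonne           = unit_constants$tonne_kg,
    tonne_long_1016 = unit_constants$long_ton_kg,
    m3              = density_kg_m3,
    cubic_yard      = unit_constants$yd3_m3 * density_kg_m3
  )
  unname(value * factor[unit])
}

#' Organic carbon contained in a disturbed sediment mass
#'
#' The core accounting identity: kilograms of sediment disturbed times the
#' sediment's total organic carbon content (dry-weight percent) over 100
#' gives kilograms of organic carbon disturbed.
#'
#' @param mass_kg Non-negative sediment mass in kg (vectorised).
#' @param toc_pct %TOC in `[0, 100]` (vectorised).
#' @return Kilograms of organic carbon.
#' @examples
#' carbon_mass(1000, 1.78)  # 17.8 kg C
#' @export
carbon_mass <- function(mass_kg, toc_pct) {
  if (any(mass_kg < 0, na.rm = TRUE)) rlang::abort("mass_kg must be non-negative")
  if (any(toc_pct < 0 | toc_pct > 100, na.rm = TRUE)) {
    rlang::abort("toc_pct must lie in [0, 100]")
  }
  mass_kg * toc_pct / 100
}

#' Convert kilograms to megatons
#' @param kg Numeric vector in kilograms.
#' @return Numeric vector in Mt (1 Mt = 1e9 kg).
#' @export
kg_to_mt <- function(kg) kg / unit_constants$mt_kg
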