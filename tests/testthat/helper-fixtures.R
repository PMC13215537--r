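# Shared fixture builders and independent oracles.

# Brute-force ray-casting point-in-polygon, independent of the package's
# overlay routine. Crossing counting on the half-line to +x.
ray_cast_inside <- function(px, py, ring) {
  n <- nrow(ring) - 1  # closed ring: last vertex repeats the first
  vapply(seq_along(px), function(k) {
    x <- px[k]; y <- py[k]
    inside <- FALSE
    for (i in seq_len(n)) {
      x1 <- ring[i, 1]; y1 <- ring[i, 2]
      x2 <- ring[i + 1, 1]; y2 <- ring[i + 1, 2]
      if ((y1 > y) != (y2 > y)) {
        xint <- x1 + (y - y1) / (y2 - y1) * (x2 - x1)
        if (x < xint) inside <- !inside
      }
    }
    inside
  }, logical(1))
}

# Minimal valid extraction-record tibble; override fields as needed.
make_records <- function(n = 1, ...) {
  defaults <- list(
    record_id = sprintf("r%03d", seq_len(n)),
    industry = "port_dredging",
    country = "UK",
    scope = "national_total",
    year_start = 2000L,
    year_end = 2000L,
    quantity_value = 1000,
    quantity_unit = "kg",
    sediment_type = "unknown"
  )
  overrides <- list(...)
  for (nm in names(overrides)) defaults[[nm]] <- overrides[[nm]]
  extraction_records(tibble::as_tibble(defaults))
}

# A degenerate single-value %TOC pool.
const_dist <- function(value, label = "coastal") {
  toc_distribution(value, label)
}

# A reproducible non-degenerate pool.
spread_dist <- function(label = "coastal", n = 200, seed = 42) {
  set.seed(seed)
  toc_distribution(pmin(100, stats::rlnorm(n, log(1.5), 0.8)), label)
}
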