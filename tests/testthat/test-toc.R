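coast <- cbind(c(0, 100000), c(0, 0))  # straight coastline along y = 0

test_that("coastal filter applies habitat, elevation and distance rules", {
  samples <- toc_samples(tibble::tibble(
    sample_id = paste0("s", 1:5),
    x = rep(500, 5),
    y = c(1000, 6000, 2000, 3000, 4000),
    toc_pct = c(1, 2, 3, 4, 5),
    habitat = c("saltmarsh", "subtidal_other", "subtidal_other",
                "subtidal_other", "subtidal_other"),
    elevation_class = c("below_MHW", "below_MHW", "above_MHW",
                        "below_MHW", "below_MHW")
  ))
  pool <- filter_coastal_samples(samples, coast)
  expect_equal(pool$n, 2)
  expect_setequal(pool$values, c(4, 5))
  audit <- attr(pool, "audit")
  expect_equal(audit$n[audit$reason == "retained"], 2)
  expect_equal(sum(audit$n), nrow(samples))
})

test_that("samples exactly on the distance cutoff are retained", {
  samples <- toc_samples(tibble::tibble(
    sample_id = c("on", "past"), x = 0, y = c(5000, 5000.001),
    toc_pct = c(1, 2), habitat = "subtidal_other",
    elevation_class = "below_MHW"
  ))
  pool <- filter_coastal_samples(samples, coast)
  expect_equal(pool$values, 1)
})

test_that("an infinite cutoff with clean labels keeps every sample", {
  samples <- toc_samples(tibble::tibble(
    sample_id = paste0("s", 1:10), x = runif(10, 0, 1e5),
    y = runif(10, 0, 5e4), toc_pct = 1:10,
    habitat = "subtidal_other", elevation_class = "below_MHW"
  ))
  pool <- filter_coastal_samples(samples, coast, max_dist_km = Inf)
  expect_equal(pool$n, 10)
  expect_error(
    filter_coastal_samples(samples[samples$toc_pct > 100, ], coast),
    "missing|no coastal"
  )
})

test_that("substrate classification matches a ray-casting oracle", {
  # 2-class checkerboard over a 4 x 4 grid of 1 km cells
  geom <- gen_substrate_map_and_coastline(
    synth_config(extent_km = c(4, 4), cell_km = 1, offshore_km = 0))
  set.seed(5)
  n <- 1000
  samples <- toc_samples(tibble::tibble(
    sample_id = paste0("p", seq_len(n)),
    x = runif(n, -200, 4200), y = runif(n, -200, 4200),
    toc_pct = 1, habitat = "subtidal_other", elevation_class = "below_MHW"
  ))
  got <- classify_samples_by_substrate(samples, geom$map)$substrate_class

  expected <- rep("other", n)
  unclaimed <- rep(TRUE, n)
  for (i in seq_len(nrow(geom$map))) {
    inside <- ray_cast_inside(samples$x, samples$y, geom$map$ring[[i]]) &
      unclaimed
    expected[inside] <- geom$map$substrate_class[i]
    unclaimed <- unclaimed & !inside
  }
  expect_equal(got, expected)
  # partition property: each sample got exactly one class
  expect_true(all(got %in% c("sand", "coarse", "mixed", "other")))
})

test_that("points inside a sand polygon get sand; orphan points get other", {
  map <- substrate_map("p1", "sand",
                       list(rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10),
                                  c(0, 0))))
  samples <- toc_samples(tibble::tibble(
    sample_id = c("in", "out"), x = c(5, 50), y = c(5, 50),
    toc_pct = 1, habitat = "subtidal_other", elevation_class = "below_MHW"
  ))
  got <- classify_samples_by_substrate(samples, map)
  expect_equal(got$substrate_class, c("sand", "other"))
})

test_that("per-substrate pools contain exactly the matching values", {
  samples <- toc_samples(tibble::tibble(
    sample_id = paste0("s", 1:5), x = 0, y = 0,
    toc_pct = c(0.3, 0.4, 0.5, 1.2, 1.3),
    habitat = "subtidal_other", elevation_class = "below_MHW",
    substrate_class = c("sand", "sand", "sand", "coarse", "coarse")
  ))
  pools <- build_substrate_distributions(samples, c("sand", "coarse"))
  expect_equal(pools$sand$n, 3)
  expect_equal(pools$coarse$n, 2)
  expect_equal(stats::median(pools$sand$values),
               stats::median(c(0.3, 0.4, 0.5)))
  expect_error(build_substrate_distributions(samples), "mixed")
})

test_that("pooled combined distribution has n equal to the sum of parts", {
  set.seed(2)
  dists <- list(sand = toc_distribution(rlnorm(7262, log(0.46), 0.8), "sand"),
                coarse = toc_distribution(rlnorm(720, log(0.62), 0.9), "coarse"),
                mixed = toc_distribution(rlnorm(273, log(0.85), 0.8), "mixed"))
  combined <- build_combined_distribution(dists)
  expect_equal(combined$n, 7262 + 720 + 273)
  expect_equal(combined$n, 8255)

  # pooling two identical pools leaves the summary statistics unchanged
  # (median exactly; interpolated percentiles up to order-statistic spacing)
  same <- toc_distribution(rlnorm(100, log(0.5), 0.7), "sand")
  doubled <- toc_distribution(c(same$values, same$values), "combined")
  expect_equal(stats::median(doubled$values), stats::median(same$values))
  expect_equal(stats::quantile(doubled$values, 0.95, names = FALSE),
               stats::quantile(same$values, 0.95, names = FALSE),
               tolerance = 0.02)
})

test_that("weighted combined pool hits the closed-form mixture mean", {
  set.seed(3)
  dists <- list(sand = toc_distribution(rlnorm(500, log(0.5), 0.6), "sand"),
                coarse = toc_distribution(rlnorm(300, log(1.0), 0.6), "coarse"),
                mixed = toc_distribution(rlnorm(200, log(1.5), 0.6), "mixed"))
  w <- c(0.53, 0.46, 0.01)
  combined <- build_combined_distribution(dists, policy = "weighted",
                                          weights = w)
  analytic <- w[1] * mean(dists$sand$values) +
    w[2] * mean(dists$coarse$values) + w[3] * mean(dists$mixed$values)
  set.seed(4)
  draws <- draw_toc(combined, 1e6)
  pool_sd <- stats::sd(draws)
  expect_lt(abs(mean(draws) - analytic), 4 * pool_sd / sqrt(1e6))

  expect_error(build_combined_distribution(dists["sand"]), "coarse")
})

test_that("draws resample the stored values within the observed range", {
  single <- const_dist(2.0)
  expect_equal(draw_toc(single, 10), rep(2.0, 10))

  pool <- spread_dist()
  set.seed(6); a <- draw_toc(pool, 1000)
  set.seed(6); b <- draw_toc(pool, 1000)
  expect_identical(a, b)
  expect_true(all(a >= min(pool$values) & a <= max(pool$values)))
  expect_true(all(a %in% pool$values))

  set.seed(7)
  big <- draw_toc(pool, 1e6)
  expect_lt(abs(mean(big) - mean(pool$values)),
            3 * stats::sd(pool$values) / sqrt(1e6))
})

test_that("distribution objects validate and serialise", {
  expect_error(toc_distribution(numeric(), "sand"), "empty")
  expect_error(toc_distribution(c(1, 101), "sand"), "0, 100")
  expect_silent(toc_distribution(0, "sand"))  # %TOC of exactly 0 is legal

  d <- toc_distribution(c(0.5, 1.5, 2.5), "coarse")
  path <- withr::local_tempfile(fileext = ".csv")
  write_toc_distribution(d, path)
  back <- utils::read.csv(path)
  expect_equal(back$toc_pct, d$values)
  expect_equal(unique(back$label), "coarse")
})
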