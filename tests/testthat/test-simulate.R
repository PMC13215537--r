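# Small event fixtures: known masses, no imputation unless stated.
two_country_events <- function(masses = c(1e9, 2e9), years = 2000L) {
  harmonise_records(make_records(
    2, record_id = c("uk1", "dk1"), country = c("UK", "DK"),
    quantity_value = masses, year_start = years, year_end = years
  ))
}

test_that("a degenerate pool gives an exact, zero-spread estimate", {
  ev <- harmonise_records(make_records(1, quantity_value = 1e9))
  est <- run_simulation(ev, list(coastal = const_dist(2.0)),
                        config = simulation_config(n_runs = 200, seed = 1))
  expect_equal(est$mean_kg, 2e7)        # 0.02 Mt
  expect_equal(est$sd_kg, 0)
  expect_equal(est$p_low_kg, est$mean_kg)
  expect_equal(est$p_high_kg, est$mean_kg)
  expect_equal(tidy(est)$mean_mt, 0.02)
})

test_that("the Monte Carlo mean matches the analytic expectation", {
  pool <- spread_dist()
  ev <- two_country_events()
  est <- run_simulation(ev, list(coastal = pool),
                        config = simulation_config(n_runs = 4000, seed = 2))
  shelf <- aggregate_country_to_shelf(est)
  analytic <- sum(3e9 * mean(pool$values) / 100)
  se <- stats::sd(shelf$run_totals[[1]]) / sqrt(shelf$n_runs[1])
  expect_lt(abs(shelf$mean_kg - analytic), 4 * se)
})

test_that("identical seeds give bit-identical run totals", {
  ev <- two_country_events()
  cfg <- simulation_config(n_runs = 300, seed = 99)
  a <- run_simulation(ev, list(coastal = spread_dist()), config = cfg)
  b <- run_simulation(ev, list(coastal = spread_dist()), config = cfg)
  expect_identical(a$run_totals, b$run_totals)
  expect_identical(a$mean_kg, b$mean_kg)
})

test_that("doubling every mass doubles means and percentiles exactly", {
  cfg <- simulation_config(n_runs = 500, seed = 5)
  pool <- spread_dist()
  a <- run_simulation(two_country_events(c(1e9, 2e9)),
                      list(coastal = pool), config = cfg)
  b <- run_simulation(two_country_events(c(2e9, 4e9)),
                      list(coastal = pool), config = cfg)
  expect_equal(b$mean_kg, 2 * a$mean_kg)
  expect_equal(b$p_low_kg, 2 * a$p_low_kg)
  expect_equal(b$p_high_kg, 2 * a$p_high_kg)
})

test_that("every run total stays inside the pool's range bounds", {
  pool <- spread_dist()
  ev <- two_country_events(c(5e8, 1.5e9))
  est <- run_simulation(ev, list(coastal = pool),
                        config = simulation_config(n_runs = 1000, seed = 6))
  total_mass <- 2e9
  shelf <- aggregate_country_to_shelf(est)
  runs <- shelf$run_totals[[1]]
  expect_true(all(runs >= total_mass * min(pool$values) / 100 - 1e-9))
  expect_true(all(runs <= total_mass * max(pool$values) / 100 + 1e-9))
})

test_that("shelf equals the sum of countries per run, exactly", {
  pool <- spread_dist()
  ev <- harmonise_records(make_records(
    6, record_id = sprintf("e%d", 1:6),
    country = rep(c("UK", "DK", "DE"), 2),
    quantity_value = c(1e9, 2e9, 3e9, 4e9, 5e9, 6e9),
    year_start = rep(c(2000L, 2001L), each = 3),
    year_end = rep(c(2000L, 2001L), each = 3)
  ))
  est <- run_simulation(ev, list(coastal = pool),
                        config = simulation_config(n_runs = 400, seed = 7))
  shelf <- aggregate_country_to_shelf(est)
  for (yr in c(2000, 2001)) {
    countries <- est[est$year == yr, ]
    summed <- Reduce(`+`, countries$run_totals)
    expect_identical(shelf$run_totals[[which(shelf$year == yr)]], summed)
  }
  # mean additivity follows by linearity
  expect_equal(sum(shelf$mean_kg), sum(est$mean_kg))
})

test_that("country results are reproducible in isolation", {
  pool <- spread_dist()
  cfg <- simulation_config(n_runs = 300, seed = 11)
  joint <- run_simulation(two_country_events(), list(coastal = pool),
                          config = cfg)
  uk_only <- run_simulation(
    harmonise_records(make_records(1, record_id = "uk1", country = "UK",
                                   quantity_value = 1e9)),
    list(coastal = pool), config = cfg)
  expect_identical(joint$run_totals[[which(joint$scope_id == "UK")]],
                   uk_only$run_totals[[1]])
})

test_that("ports sum to a national estimate; a single port is the identity", {
  pool <- spread_dist()
  cfg <- simulation_config(n_runs = 300, seed = 8)
  ev <- harmonise_records(make_records(
    3, record_id = c("p1", "p2", "p3"), scope = "port",
    port = c("Aberdeen", "Clyde", "Ramsgate"),
    quantity_value = c(1e9, 1e9, 1e9), year_start = 1890L, year_end = 1890L
  ))
  ports <- run_simulation(ev, list(coastal = const_dist(1.0)), config = cfg)
  expect_equal(nrow(ports), 3)
  nation <- aggregate_ports_to_nation(ports)
  expect_equal(nation$mean_kg, 3 * 1e9 * 1.0 / 100)  # 0.03 Mt
  expect_equal(nation$scope_id, "UK")

  single <- run_simulation(ev[1, ], list(coastal = pool), config = cfg)
  lone <- aggregate_ports_to_nation(single)
  expect_equal(lone$mean_kg, single$mean_kg)
  expect_equal(lone$p_high_kg, single$p_high_kg)

  # aligned-run quantile subadditivity: nation p95 <= sum of port p95
  ports2 <- run_simulation(ev, list(coastal = pool), config = cfg)
  nation2 <- aggregate_ports_to_nation(ports2)
  expect_lte(nation2$p_high_kg, sum(ports2$p_high_kg) + 1e-9)
})

test_that("aggregation refuses mismatched run counts or dropped run totals", {
  pool <- const_dist(1.0)
  a <- run_simulation(two_country_events(),
                      list(coastal = pool),
                      config = simulation_config(n_runs = 100, seed = 1))
  b <- run_simulation(two_country_events(),
                      list(coastal = pool),
                      config = simulation_config(n_runs = 200, seed = 1))
  mixed <- dplyr::bind_rows(a[1, ], b[2, ])
  class(mixed) <- class(a)
  expect_error(aggregate_country_to_shelf(mixed), "n_runs")

  c <- run_simulation(two_country_events(), list(coastal = pool),
                      config = simulation_config(n_runs = 100, seed = 1,
                                                 keep_runs = FALSE))
  expect_error(aggregate_country_to_shelf(c), "run totals")
})

test_that("events resolve to their context distribution, or fail by name", {
  ev <- harmonise_records(make_records(
    3, record_id = c("d1", "a1", "a2"),
    industry = c("port_dredging", "aggregate", "aggregate"),
    sediment_type = c("unknown", "sand", "unknown"),
    quantity_value = 1e9
  ))
  dists <- list(coastal = const_dist(2), sand = const_dist(1, "sand"),
                combined = const_dist(0.5, "combined"))
  est <- run_simulation(ev, dists,
                        config = simulation_config(n_runs = 10, seed = 1))
  agg <- est[est$industry == "aggregate", ]
  # sand event draws 1%, unknown-type event draws combined 0.5%
  expect_equal(agg$mean_kg, 1e9 * (1 + 0.5) / 100)
  dre <- est[est$industry == "port_dredging", ]
  expect_equal(dre$mean_kg, 1e9 * 2 / 100)

  expect_error(run_simulation(ev, list(coastal = const_dist(2))), "a1")
  ev_imp <- harmonise_records(make_records(1, record_id = "gap",
                                           quantity_value = NA_real_,
                                           quantity_unit = "absent"))
  expect_error(run_simulation(ev_imp, dists), "gap")
})

test_that("imputed events draw masses inside the simulation", {
  model <- structure(list(mu = 6, sigma = 0.3, n = 63, shapiro_w = NA_real_,
                          shapiro_p = NA_real_, degenerate = FALSE),
                     class = "log10_mass_model")
  ev <- harmonise_records(make_records(1, record_id = "gap",
                                       quantity_value = NA_real_,
                                       quantity_unit = "absent"))
  cfg <- simulation_config(n_runs = 3000, seed = 12)
  est <- run_simulation(ev, list(coastal = const_dist(2.0)), model, cfg)
  # with a constant 2% pool, run totals are 0.02 x the imputed masses:
  # their median should sit near 0.02 x 10^mu
  expect_equal(stats::median(est$run_totals[[1]]) / (0.02 * 1e6), 1,
               tolerance = 0.05)
  expect_gt(est$sd_kg, 0)

  # fix-once mode collapses the imputation spread
  fixed <- run_simulation(ev, list(coastal = const_dist(2.0)), model,
                          simulation_config(n_runs = 100, seed = 12,
                                            redraw_imputed = FALSE))
  expect_equal(fixed$sd_kg, 0)
})

test_that("a period imputation event spreads one drawn mass over its years", {
  model <- structure(list(mu = 6, sigma = 0, n = 3, shapiro_w = NA_real_,
                          shapiro_p = NA_real_, degenerate = FALSE),
                     class = "log10_mass_model")
  # sigma 0 would refuse to impute; use tiny sigma for a near-deterministic check
  model$sigma <- 1e-12
  ev <- harmonise_records(make_records(1, record_id = "works",
                                       year_start = 1834L, year_end = 1843L,
                                       quantity_value = NA_real_,
                                       quantity_unit = "absent"))
  est <- run_simulation(ev, list(coastal = const_dist(1.0)), model,
                        simulation_config(n_runs = 50, seed = 13))
  expect_equal(nrow(est), 10)  # one estimate per year of the period
  expect_equal(est$year, 1834:1843)
  # each year carries a tenth of the (essentially constant) period carbon
  expect_equal(est$mean_kg, rep(1e6 * 0.01 / 10, 10), tolerance = 1e-6)
})

test_that("per-year-total draws give wider bands than per-record draws", {
  pool <- spread_dist()
  ev <- harmonise_records(make_records(
    20, record_id = sprintf("e%02d", 1:20), quantity_value = 1e8
  ))
  per_rec <- run_simulation(ev, list(coastal = pool),
                            config = simulation_config(n_runs = 2000, seed = 3,
                                                       draw_scope = "per_record"))
  per_year <- run_simulation(ev, list(coastal = pool),
                             config = simulation_config(n_runs = 2000, seed = 3,
                                                        draw_scope = "per_year_total"))
  # same expectation, wider spread when one draw covers the whole year
  expect_equal(per_year$mean_kg / per_rec$mean_kg, 1, tolerance = 0.05)
  expect_gt(per_year$sd_kg, 2 * per_rec$sd_kg)
})

test_that("convergence: inter-iteration spread shrinks like 1/sqrt(runs)", {
  pool <- spread_dist()
  ev <- two_country_events()
  study <- convergence_study(ev, list(coastal = pool),
                             run_grid = c(100, 400, 1600),
                             n_iterations = 10, seed = 21)
  expect_equal(nrow(study), 30)
  s <- attr(study, "summary")
  # each 4x step in runs should halve the SD; allow generous stochastic slack
  ratio1 <- s$sd_between[1] / s$sd_between[2]
  ratio2 <- s$sd_between[2] / s$sd_between[3]
  expect_gt(ratio1, 1); expect_lt(ratio1, 8)
  expect_gt(ratio2, 1); expect_lt(ratio2, 8)

  degenerate <- convergence_study(ev, list(coastal = const_dist(2)),
                                  run_grid = c(100, 500),
                                  n_iterations = 5, seed = 22)
  expect_true(all(attr(degenerate, "summary")$sd_between == 0))
  expect_true(all(attr(degenerate, "summary")$stabilised))
})

test_that("sediment-proportion sensitivity interpolates between pure pools", {
  set.seed(30)
  dists <- list(sand = toc_distribution(rlnorm(400, log(0.4), 0.5), "sand"),
                coarse = toc_distribution(rlnorm(400, log(1.2), 0.5), "coarse"),
                mixed = toc_distribution(rlnorm(400, log(0.8), 0.5), "mixed"))
  grid <- tibble::tibble(sand = c(1, 0.75, 0.5, 0.25, 0),
                         coarse = 1 - sand, mixed = 0)
  sens <- sensitivity_sediment_proportions(1e9, dists, grid,
                                           simulation_config(n_runs = 3000,
                                                             seed = 31))
  # pure-sand endpoint equals a pure-sand simulation's analytic mean
  expect_equal(sens$mean_kg[1], 1e9 * mean(dists$sand$values) / 100,
               tolerance = 0.05)
  # monotone between endpoints since mean(sand) < mean(coarse)
  expect_true(all(diff(sens$mean_kg) > 0))

  # the observed 53/46/1 split matches its closed-form mixture mean
  mix <- sensitivity_sediment_proportions(
    1e9, dists, tibble::tibble(sand = 0.53, coarse = 0.46, mixed = 0.01),
    simulation_config(n_runs = 5000, seed = 32))
  analytic <- 1e9 * (0.53 * mean(dists$sand$values) +
                       0.46 * mean(dists$coarse$values) +
                       0.01 * mean(dists$mixed$values)) / 100
  expect_equal(mix$mean_kg / analytic, 1, tolerance = 0.03)

  expect_error(sensitivity_sediment_proportions(
    1e9, dists, tibble::tibble(sand = 0.6, coarse = 0.6, mixed = 0)),
    "sum to 1")
})
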