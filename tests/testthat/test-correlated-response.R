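make_alt_records <- function(effects, n = 6, sd = 0.004, seed = 1) {
  # two populations' worth of alternate-temperature records per effect:
  # ancestor window values around 0.05, endpoint shifted by `effects`
  set.seed(seed)
  dplyr::bind_rows(lapply(seq_along(effects), function(i) {
    tibble::tibble(
      population_id = paste0("p", i), evolution_temp = "24",
      assay_temp = rep(c("37", "37"), each = n),
      generation = rep(c(100, 6000), each = n),
      rate = c(rnorm(n, 0.05, sd), rnorm(n, 0.05 + effects[i], sd)))
  }))
}

test_that("trade-off classification is three-way, thresholded, and sign-antisymmetric", {
  # evolved identical to ancestor: no change
  r0 <- tibble::tibble(population_id = "p", evolution_temp = "24",
                       assay_temp = "37",
                       generation = rep(c(0, 6000), each = 4),
                       rate = rep(c(0.05, 0.052, 0.049, 0.051), 2))
  out0 <- classify_tradeoffs(r0, m = 24)
  expect_equal(out0$classification, "no-change")
  expect_equal(attr(out0, "threshold"), 0.05 / 24, tolerance = 1e-12)

  eff <- c(0.03, -0.03, 0)
  out <- classify_tradeoffs(make_alt_records(eff), m = 3)
  expect_equal(out$classification, c("increase", "trade-off", "no-change"))
  # negating all effects swaps increase and trade-off counts
  out_neg <- classify_tradeoffs(make_alt_records(-eff), m = 3)
  expect_equal(sum(out$classification == "increase"),
               sum(out_neg$classification == "trade-off"))
  expect_equal(sum(out$classification == "trade-off"),
               sum(out_neg$classification == "increase"))

  # missing ancestor data errors
  r_bad <- r0[r0$generation != 0, ]
  expect_error(classify_tradeoffs(r_bad, m = 24), "ancestor")
})

test_that("temperature-specific loss is detected only in the arm carrying it", {
  # cold-evolved arm carries a deficit at the alternate temperature large
  # enough to overwhelm the shared gain; hot arm carries none
  hits_arm <- logical(40); hits_other <- logical(40)
  for (i in 1:40) {
    cfg <- small_sim_config(2000 + i,
                            sigma_replicate = 0.002, sigma_assay = 0.002,
                            alt_deficit = c("24" = 0.13, "37" = 0),
                            alt_onset = 500,
                            assay_schedule = seq(0, 6500, by = 100))
    ds <- simulate_evolution_experiment(cfg)
    out <- classify_tradeoffs(ds$records, endpoint_bin = 6000, m = 24)
    cold <- out[out$evolution_temp == "24", ]
    hot <- out[out$evolution_temp == "37", ]
    hits_arm[i] <- mean(cold$classification == "trade-off") > 0.5
    hits_other[i] <- any(hot$classification == "trade-off")
  }
  expect_gte(mean(hits_arm), 0.85)
  expect_lte(mean(hits_other), 0.1)
})

test_that("ET x AT interaction is null on shared trajectories and exact-zero on duplicates", {
  # one bin duplicated across assay temperatures with identical values:
  # interaction sum of squares is exactly zero
  d <- tidyr::expand_grid(genotype = c("g1", "g2", "g3"),
                          replicate = 1:4, evolution_temp = c("24", "37"),
                          assay_temp = c("24", "37"))
  d$population_id <- paste(d$genotype, d$replicate, d$evolution_temp, sep = "-")
  set.seed(171)
  per_pop <- stats::setNames(rnorm(24, 0.1, 0.01), unique(d$population_id))
  d$generation <- 6000
  d$rate <- per_pop[d$population_id] # same value at both assay temps
  scan <- interaction_through_time(d, bins = 6000, width = 1000)
  expect_equal(scan$interaction$statistic, 0, tolerance = 1e-9)
})

test_that("cross-temperature correlation and ellipse geometry behave", {
  # perfectly proportional paired rates: r = 1, degenerate minor axis
  pops <- paste0("p", 1:8)
  x <- seq(0.05, 0.12, length.out = 8)
  d <- tibble::tibble(population_id = rep(pops, 2),
                      assay_temp = rep(c("24", "37"), each = 8),
                      generation = 1000, rate = c(x, 2 * x))
  cc <- cross_temperature_correlation(d, width = 1000)
  expect_equal(cc$r, 1, tolerance = 1e-12)
  expect_equal(cc$axis_minor, 0, tolerance = 1e-9)

  # isotropic cloud: near-equal axes
  set.seed(181)
  n <- 500
  d2 <- tibble::tibble(population_id = rep(paste0("q", 1:n), 2),
                       assay_temp = rep(c("24", "37"), each = n),
                       generation = 1000,
                       rate = c(rnorm(n, 0.1, 0.01), rnorm(n, 0.1, 0.01)))
  cc2 <- cross_temperature_correlation(d2, width = 1000)
  expect_lt(abs(cc2$axis_major / cc2$axis_minor - 1), 0.15)
  # axis scale: sqrt(eigenvalue * chisq quantile) ~ sd * sqrt(5.99)
  expect_lt(abs(cc2$axis_major - 0.01 * sqrt(qchisq(0.95, 2))) /
              (0.01 * sqrt(qchisq(0.95, 2))), 0.15)

  # a decaying shared component makes per-bin r decrease across bins
  set.seed(182)
  decays <- vapply(1:30, function(i) {
    rows <- lapply(c(1000, 3000, 6000), function(b) {
      shared <- rnorm(12, 0, 0.02) * sqrt(1 - b / 7000)
      tibble::tibble(population_id = rep(paste0("p", 1:12), 2),
                     assay_temp = rep(c("24", "37"), each = 12),
                     generation = b,
                     rate = 0.1 + c(shared + rnorm(12, 0, 0.004),
                                    shared + rnorm(12, 0, 0.004)))
    })
    cc3 <- cross_temperature_correlation(dplyr::bind_rows(rows), width = 1000)
    all(diff(cc3$r[order(cc3$bin)]) < 0)
  }, logical(1))
  expect_gte(mean(decays), 0.7)

  expect_error(
    cross_temperature_correlation(d[c(1, 2, 9, 10), ], width = 1000),
    "fewer than 3")
})

test_that("serial-transfer demography matches its closed forms", {
  # printed-density closed forms
  expect_equal(generations_per_day(2500, 275000), log2(110), tolerance = 1e-12)
  expect_lt(abs(generations_per_day(2500, 275000) - 6.8), 0.03)
  expect_equal(generations_per_day(6000, 60000), log2(10), tolerance = 1e-12)
  expect_equal(generations_per_day(5, 5), 0)
  # additivity across a split day
  expect_equal(generations_per_day(2500, 20000) + generations_per_day(20000, 275000),
               generations_per_day(2500, 275000), tolerance = 1e-12)

  expect_equal(effective_population_size(c(1000, 1000, 1000)), 1000)
  expect_equal(effective_population_size(c(1000, 2000, 4000)),
               3 / (0.001 + 0.0005 + 0.00025), tolerance = 1e-12)
  # doubling series from 25,000 cells across 7 discrete generations
  ne <- effective_population_size(25000 * 2^(0:6))
  expect_equal(ne, 7 * 25000 / (2 - 2^-6), tolerance = 1e-12)
  expect_lt(abs(ne - 88200), 100)

  # harmonic <= geometric <= arithmetic on random size vectors
  set.seed(191)
  for (i in 1:20) {
    sz <- runif(8, 1e3, 1e6)
    h <- effective_population_size(sz)
    g <- exp(mean(log(sz)))
    expect_lte(h, g + 1e-9); expect_lte(g, mean(sz) + 1e-9)
  }

  expect_equal(transfer_volume(25000, 275000), 25000 / 275000, tolerance = 1e-12)
  expect_equal(transfer_volume(60000, 60000), 1)
  expect_equal(transfer_volume(25000, 550000),
               transfer_volume(25000, 275000) / 2, tolerance = 1e-12)
  expect_error(effective_population_size(c(100, -5)), "positive")
  expect_error(generations_per_day(0, 10), "positive")
  expect_error(transfer_volume(0, 10), "positive")
})
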