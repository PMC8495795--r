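#' Configuration for a simulated serial-transfer evolution experiment
#'
#' Bundles every parameter of the synthetic experiment: the factorial design
#' (genotypes x replicates x evolution temperatures, assayed at both
#' temperatures), the trajectory model followed by the expected growth-rate
#' gain, and the stochastic layers (replicate-level divergence, plate-level
#' assay noise, within-plate well noise).
#'
#' The default configuration emulates a study design of 3 founding genotypes
#' x 4 replicate populations x 2 evolution temperatures (24 populations),
#' assayed at both temperatures roughly every 25 generations over 6,500
#' generations, with a decelerating (hyperbolic) gain curve
#' `R0 + theta1 * N / (theta2 + N)`.
#'
#' Unless `theta1` is supplied explicitly, the per-genotype amplitude is
#' built by a convergence rule: genotypes with lower ancestral rates gain
#' more, `theta1[g, et] = theta1_base[et] + convergence[et] *
#' (max(baseline) - baseline[g])`.  With `convergence = 1` all genotypes
#' share one asymptote at that temperature; with `convergence = 0` initial
#' differences persist.  Defaults make convergence faster and fuller at the
#' higher temperature.
#'
#' @param genotypes Character vector of genotype labels.
#' @param n_replicates Replicate populations per genotype per evolution
#'   temperature.
#' @param evolution_temps,assay_temps Temperature labels (characters).
#' @param genotype_baselines Named numeric, ancestral mean growth rate per
#'   genotype (doublings/hour); all positive.
#' @param trajectory_model One of `"hyperbolic"`, `"power"`, `"linear"` —
#'   the mean gain curve.  For `"power"` `theta1` is the exponent and
#'   `theta2` the coefficient; for `"hyperbolic"` `theta1` is the asymptotic
#'   gain and `theta2` the half-saturation generation; for `"linear"`
#'   `theta1` is the slope.
#' @param theta1,theta2 Optional genotype x evolution-temperature matrices
#'   (dimnames genotype, temperature) of trajectory constants.  Scalars and
#'   per-temperature named vectors are recycled.  When `theta1` is `NULL`
#'   and the model is hyperbolic or linear, it is built from `theta1_base`
#'   and `convergence`.
#' @param theta1_base,convergence Per-evolution-temperature values feeding
#'   the convergence rule above (ignored when `theta1` is given).
#' @param sigma_replicate Per-evolution-temperature SD (doublings/hour) of
#'   replicate-level divergence, the cumulative SD of the replicate random
#'   walk at the final scheduled generation.
#' @param sigma_assay SD of independent plate-level measurement noise
#'   (doublings/hour).
#' @param sigma_well Within-plate well-to-well SD; defaults to
#'   `sigma_assay / 2`.
#' @param n_wells Wells per population per plate.
#' @param assay_temp_offset Named additive shift of the ancestral rate at
#'   each assay temperature (doublings/hour); default 0.
#' @param alt_deficit Per-evolution-temperature amplitude (doublings/hour)
#'   of temperature-specific adaptation: the gain expressed at the alternate
#'   assay temperature is reduced by `alt_deficit * ramp(N)` where the ramp
#'   rises linearly from `alt_onset` to the final generation.  Default 0
#'   (fully non-specific adaptation).
#' @param alt_onset Generation at which the temperature-specific deficit
#'   starts to ramp in.
#' @param assay_schedule Strictly increasing non-negative generation values
#'   at which plates are simulated.
#' @param seed Integer root seed; every simulation drawn from this config is
#'   reproducible.
#'
#' @return A `simulation_config` object (list) with resolved per-cell
#'   `theta1`/`theta2` matrices.
#' @seealso [simulate_evolution_experiment()]
#' @export
simulation_config <- function(genotypes = c("A", "B", "AxB"),
                              n_replicates = 4,
                              evolution_temps = c("24", "37"),
                              assay_temps = c("24", "37"),
                              genotype_baselines = c(A = 0.021, B = 0.045, AxB = 0.044),
                              trajectory_model = c("hyperbolic", "power", "linear"),
                              theta1 = NULL,
                              theta2 = c("24" = 700, "37" = 400),
                              theta1_base = c("24" = 0.050, "37" = 0.070),
                              convergence = c("24" = 0.6, "37" = 1.0),
                              sigma_replicate = c("24" = 0.012, "37" = 0.006),
                              sigma_assay = 0.008,
                              sigma_well = NULL,
                              n_wells = 3,
                              assay_temp_offset = 0,
                              alt_deficit = 0,
                              alt_onset = 2500,
                              assay_schedule = seq(0, 6500, by = 25),
                              seed = 1L) {
  trajectory_model <- match.arg(trajectory_model)
  genotypes <- as.character(genotypes)
  evolution_temps <- as.character(evolution_temps)
  assay_temps <- as.character(assay_temps)

  if (n_replicates < 1) stop_invalid("`n_replicates` must be >= 1")
  if (length(assay_schedule) < 1 || any(assay_schedule < 0) ||
      any(diff(assay_schedule) <= 0)) {
    stop_invalid("`assay_schedule` must be non-negative and strictly increasing")
  }
  baselines <- per_level(genotype_baselines, genotypes, "genotype_baselines")
  if (any(baselines <= 0)) stop_invalid("genotype baselines must be positive")

  sigma_replicate <- per_level(sigma_replicate, evolution_temps, "sigma_replicate")
  alt_deficit <- per_level(alt_deficit, evolution_temps, "alt_deficit")
  assay_temp_offset <- per_level(assay_temp_offset, assay_temps, "assay_temp_offset")
  if (any(sigma_replicate < 0) || sigma_assay < 0) {
    stop_invalid("noise SDs must be >= 0")
  }
  sigma_well <- sigma_well %||% (sigma_assay / 2)
  if (sigma_well < 0) stop_invalid("`sigma_well` must be >= 0")

  as_cell_matrix <- function(x, name) {
    if (is.matrix(x)) {
      if (!all(genotypes %in% rownames(x)) || !all(evolution_temps %in% colnames(x))) {
        stop_invalid("`", name, "` matrix needs genotype rownames and temperature colnames")
      }
      return(x[genotypes, evolution_temps, drop = FALSE])
    }
    v <- per_level(x, evolution_temps, name)
    matrix(rep(v, each = length(genotypes)), nrow = length(genotypes),
           dimnames = list(genotypes, evolution_temps))
  }

  theta2_mat <- as_cell_matrix(theta2, "theta2")
  if (is.null(theta1)) {
    tb <- per_level(theta1_base, evolution_temps, "theta1_base")
    cv <- per_level(convergence, evolution_temps, "convergence")
    theta1_mat <- outer(max(baselines) - baselines, cv) +
      matrix(rep(tb, each = length(genotypes)), nrow = length(genotypes))
    dimnames(theta1_mat) <- list(genotypes, evolution_temps)
  } else {
    theta1_mat <- as_cell_matrix(theta1, "theta1")
  }

  structure(
    list(genotypes = genotypes, n_replicates = as.integer(n_replicates),
         evolution_temps = evolution_temps, assay_temps = assay_temps,
         genotype_baselines = baselines, trajectory_model = trajectory_model,
         theta1 = theta1_mat, theta2 = theta2_mat,
         sigma_replicate = sigma_replicate, sigma_assay = sigma_assay,
         sigma_well = sigma_well, n_wells = as.integer(n_wells),
         assay_temp_offset = assay_temp_offset,
         alt_deficit = alt_deficit, alt_onset = alt_onset,
         assay_schedule = as.numeric(assay_schedule),
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Serial-transfer evolution simulation config\n")
  cat(sprintf("  design: %d genotypes x %d replicates x {%s} evolution temps\n",
              length(x$genotypes), x$n_replicates,
              paste(x$evolution_temps, collapse = ", ")))
  cat(sprintf("  model: %s; assays at {%s}; %d occasions to generation %g\n",
              x$trajectory_model, paste(x$assay_temps, collapse = ", "),
              length(x$assay_schedule), max(x$assay_schedule)))
  cat(sprintf("  noise: sigma_replicate = {%s}, sigma_assay = %g, seed = %d\n",
              paste(sprintf("%s: %g", names(x$sigma_replicate), x$sigma_replicate),
                    collapse = ", "),
              x$sigma_assay, x$seed))
  invisible(x)
}

# Expected gain over the ancestral rate at generations N.
#' @noRd
trajectory_gain <- function(model, N, theta1, theta2) {
  switch(model,
    linear = theta1 * N,
    power = theta2 * N^theta1,
    hyperbolic = theta1 * N / (theta2 + N),
    stop_invalid("unknown trajectory model: ", model)
  )
}

#' Simulate one well's kinetic optical-density growth curve
#'
#' Generates a lagged-logistic curve: cell density stays at the inoculum
#' until `lag` hours, then follows logistic growth at intrinsic rate
#' `max_rate * ln 2` per hour toward `capacity`.  Optical density is the
#' instrument baseline plus density, with multiplicative log-normal noise on
#' the density component (instrument noise floors are additive at the
#' baseline, biological/optical noise scales with signal).
#'
#' @param max_rate Maximum growth rate, doublings per hour (> 0).
#' @param lag Lag phase duration, hours.
#' @param capacity Carrying capacity in absorbance units (> `baseline`).
#' @param baseline Instrument/media blank absorbance (>= 0).
#' @param inoculum Initial density above baseline, absorbance units.
#' @param noise_sd Relative SD of multiplicative noise per reading.
#' @param duration Total assay duration, hours.
#' @param interval Reading interval, hours (default 5 minutes).
#' @param seed Optional integer seed; same seed gives an identical series.
#' @param well_id,plate_id Labels carried on the series.
#'
#' @return An [od_series()] object.
#' @examples
#' s <- simulate_od_curve(0.5, lag = 2, noise_sd = 0.02, seed = 1)
#' estimate_max_growth_rate(s)
#' @export
simulate_od_curve <- function(max_rate, lag = 0, capacity = 1.0,
                              baseline = 0.05, inoculum = 0.01,
                              noise_sd = 0, duration = 48, interval = 1 / 12,
                              seed = NULL, well_id = "A1", plate_id = "sim") {
  assert_scalar_pos(max_rate, "max_rate")
  assert_scalar_pos(interval, "interval")
  assert_scalar_pos(duration, "duration")
  if (noise_sd < 0) stop_invalid("`noise_sd` must be >= 0")
  if (baseline < 0 || capacity <= baseline) {
    stop_invalid("need capacity > baseline >= 0")
  }
  K <- capacity - baseline
  if (inoculum <= 0 || inoculum >= K) {
    stop_invalid("`inoculum` must lie strictly between 0 and capacity - baseline")
  }

  times <- seq(0, duration, by = interval)
  r <- max_rate * log(2)
  dens <- ifelse(
    times <= lag, inoculum,
    K * inoculum / (inoculum + (K - inoculum) * exp(-r * (times - lag)))
  )
  if (noise_sd > 0) {
    dens <- with_seed(seed, dens * exp(rnorm(length(dens), 0, noise_sd)))
  }
  od_series(times = times, od = baseline + dens, well_id = well_id,
            plate_id = plate_id, blank = baseline)
}

#' Simulate a full serial-transfer evolution experiment
#'
#' Draws one realisation of the experiment described by a
#' [simulation_config()]: for every population (genotype x replicate x
#' evolution temperature) the expected growth rate at generation `N` follows
#' the configured trajectory model; on top of the mean curve each population
#' carries a persistent replicate-divergence trajectory, simulated as a
#' Gaussian random walk over assay occasions whose per-step SD is scaled so
#' the cumulative SD at the final scheduled generation equals
#' `sigma_replicate`.  Every plate record then receives independent
#' plate-level noise (`sigma_assay`); well-level rates (optional) scatter
#' around the plate rate with `sigma_well`, centred so the plate rate is
#' exactly their mean.  Populations are assayed at every configured assay
#' temperature; adaptation expressed at the alternate temperature can be
#' reduced by the `alt_deficit`/`alt_onset` temperature-specificity ramp.
#'
#' @param config A [simulation_config()].
#' @param wells If `TRUE`, include per-well rates as a list column
#'   (`well_rates`); off by default to keep large simulations light.
#'
#' @return An `evolution_dataset`: list with `populations` (metadata
#'   tibble), `records` (one row per population x assay temperature x
#'   occasion, the plate-level growth-rate table) and `truth` (the config
#'   plus per-population curve parameters).
#' @export
simulate_evolution_experiment <- function(config, wells = FALSE) {
  if (!inherits(config, "simulation_config")) {
    stop_invalid("`config` must be a simulation_config object")
  }
  sched <- config$assay_schedule
  n_occ <- length(sched)
  n_max <- max(sched, 1e-9)
  step_sd_unit <- sqrt(c(sched[1], diff(sched)) / n_max) # unit-sigma walk steps

  pops <- expand.grid(replicate = seq_len(config$n_replicates),
                      genotype = config$genotypes,
                      evolution_temp = config$evolution_temps,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pops$population_id <- paste(pops$genotype, pops$replicate,
                              pops$evolution_temp, sep = "-")
  pops <- tibble::as_tibble(pops[c("population_id", "genotype", "replicate",
                                   "evolution_temp")])

  with_seed(config$seed, {
    rec <- vector("list", nrow(pops) * length(config$assay_temps))
    curve_rows <- vector("list", nrow(pops))
    k <- 0L
    for (i in seq_len(nrow(pops))) {
      g <- pops$genotype[i]; et <- pops$evolution_temp[i]
      R0 <- config$genotype_baselines[[g]]
      th1 <- config$theta1[g, et]; th2 <- config$theta2[g, et]
      gain <- trajectory_gain(config$trajectory_model, sched, th1, th2)
      dev <- cumsum(rnorm(n_occ, 0, config$sigma_replicate[[et]] * step_sd_unit))
      curve_rows[[i]] <- tibble::tibble(
        population_id = pops$population_id[i], genotype = g,
        evolution_temp = et, R0 = R0, theta1 = th1, theta2 = th2)
      for (at in config$assay_temps) {
        deficit <- 0
        if (!identical(at, et) && config$alt_deficit[[et]] > 0 &&
            config$alt_onset < n_max) {
          deficit <- config$alt_deficit[[et]] *
            pmax(0, sched - config$alt_onset) / (n_max - config$alt_onset)
        }
        mu <- R0 + config$assay_temp_offset[[at]] + gain + dev - deficit
        rate <- mu + rnorm(n_occ, 0, config$sigma_assay)
        row <- tibble::tibble(
          population_id = pops$population_id[i], genotype = g,
          replicate = pops$replicate[i], evolution_temp = et,
          assay_temp = at, generation = sched,
          plate_id = sprintf("%s_AT%s_g%06.0f", pops$population_id[i], at, sched),
          rate = rate, n_wells = config$n_wells)
        if (wells) {
          row$well_rates <- lapply(rate, function(r) {
            e <- rnorm(config$n_wells, 0, config$sigma_well)
            r + (e - mean(e))
          })
        } else if (config$n_wells > 0) {
          # burn the well-level draws so `wells = TRUE/FALSE` give identical
          # plate-level records under one seed
          rnorm(n_occ * config$n_wells, 0, config$sigma_well)
        }
        k <- k + 1L
        rec[[k]] <- row
      }
    }
    records <- dplyr::bind_rows(rec)
    structure(
      list(populations = pops, records = records,
           truth = list(config = config, curves = dplyr::bind_rows(curve_rows))),
      class = "evolution_dataset")
  })
}

#' @export
print.evolution_dataset <- function(x, ...) {
  cat(sprintf("evolution_dataset: %d populations, %d plate records (%s)\n",
              nrow(x$populations), nrow(x$records),
              if (is.null(x$truth)) "loaded" else "simulated"))
  cat(sprintf("  generations %g-%g; assay temps: %s\n",
              min(x$records$generation), max(x$records$generation),
              paste(unique(x$records$assay_temp), collapse = ", ")))
  invisible(x)
}

#' Simulate a pairwise competition assay
#'
#' Two strains grow exponentially at their own rates for `hours`; measured
#' final densities carry multiplicative log-normal count noise.  The
#' noiseless case is exact.
#'
#' @param density_a0,density_b0 Initial densities (cells/mL, > 0).
#' @param rate_a,rate_b Growth rates (doublings/hour).
#' @param hours Competition duration (> 0).
#' @param count_noise_sd Relative SD of counting noise on final densities.
#' @param seed Optional seed for reproducible noise.
#'
#' @return A `competition_record` list with `a_initial`, `a_final`,
#'   `b_initial`, `b_final`.
#' @seealso [competitive_fitness()]
#' @export
simulate_competition <- function(density_a0, density_b0, rate_a, rate_b,
                                 hours, count_noise_sd = 0, seed = NULL) {
  for (nm in c("density_a0", "density_b0", "hours")) {
    assert_scalar_pos(get(nm), nm)
  }
  if (count_noise_sd < 0) stop_invalid("`count_noise_sd` must be >= 0")
  fin <- c(density_a0 * 2^(rate_a * hours), density_b0 * 2^(rate_b * hours))
  if (count_noise_sd > 0) {
    fin <- with_seed(seed, fin * exp(rnorm(2, 0, count_noise_sd)))
  }
  structure(list(a_initial = density_a0, a_final = fin[1],
                 b_initial = density_b0, b_final = fin[2]),
            class = "competition_record")
}
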