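#' Configuration for the end-to-end analysis pipeline
#'
#' Collects every setting the pipeline stages consume: input paths (or the
#' embedded simulation config when simulating), growth-rate estimator
#' settings, bin widths, the per-family comparison counts for Bonferroni
#' control (always explicit, never inferred), model-fit and endpoint
#' settings, the root seed and the output directory.
#'
#' @param seed Root seed; all stage-level randomness is derived from it.
#' @param simulate If `TRUE`, inputs come from `sim`; otherwise
#'   `plate_table` and `metadata` paths are read.
#' @param sim A [simulation_config()] (its seed is overridden by `seed`).
#' @param plate_table,metadata Paths to a long-format plate table and a
#'   population metadata table (`population_id, genotype, replicate,
#'   evolution_temp`), used when `simulate = FALSE`.
#' @param window_points,min_od_delta Growth-rate estimator settings (see
#'   [estimate_max_growth_rate()]).
#' @param bin_width_repeatability,bin_width_summary Bin widths for the
#'   variance-component scan and the coarser summaries.
#' @param alpha Significance level shared by all test families.
#' @param m_pairwise,m_tradeoff,m_anova Comparison counts for the pairwise
#'   genotype family, the trade-off family and the ANOVA family.
#' @param endpoint_bin,interaction_bins Endpoint and scan bins
#'   (generations).
#' @param output_dir Directory for delimited-text outputs (`NULL` = do not
#'   write).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            simulate = TRUE,
                            sim = simulation_config(),
                            plate_table = NULL,
                            metadata = NULL,
                            window_points = 13,
                            min_od_delta = 0.02,
                            bin_width_repeatability = 250,
                            bin_width_summary = 1000,
                            alpha = 0.05,
                            m_pairwise = 42,
                            m_tradeoff = 24,
                            m_anova = 7,
                            endpoint_bin = 6000,
                            interaction_bins = c(0, 2000, 6000),
                            output_dir = NULL) {
  structure(
    list(seed = as.integer(seed), simulate = isTRUE(simulate), sim = sim,
         plate_table = plate_table, metadata = metadata,
         window_points = window_points, min_od_delta = min_od_delta,
         bin_width_repeatability = bin_width_repeatability,
         bin_width_summary = bin_width_summary, alpha = alpha,
         m_pairwise = m_pairwise, m_tradeoff = m_tradeoff, m_anova = m_anova,
         endpoint_bin = endpoint_bin, interaction_bins = interaction_bins,
         output_dir = output_dir),
    class = "pipeline_config")
}

#' Read a pipeline configuration from structured text
#'
#' Reads a YAML file whose keys mirror the arguments of
#' [pipeline_config()]; a nested `sim:` block mirrors
#' [simulation_config()].  Unspecified keys keep their defaults.
#'
#' @param path Path to the YAML file.
#' @param overrides Named list applied on top of the file (flag > file >
#'   default precedence).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path) %||% list()
  vals <- modifyList(vals, overrides)
  sim_vals <- vals$sim %||% list()
  vals$sim <- NULL
  known_sim <- names(formals(simulation_config))
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop_invalid("unknown config key(s): ",
                                paste(bad, collapse = ", "))
  bad_sim <- setdiff(names(sim_vals), known_sim)
  if (length(bad_sim)) stop_invalid("unknown sim config key(s): ",
                                    paste(bad_sim, collapse = ", "))
  for (nm in c("genotype_baselines", "sigma_replicate", "theta2",
               "theta1_base", "convergence", "alt_deficit",
               "assay_temp_offset")) {
    if (!is.null(sim_vals[[nm]])) sim_vals[[nm]] <- unlist(sim_vals[[nm]])
  }
  cfg <- do.call(pipeline_config, vals)
  cfg$sim <- do.call(simulation_config, sim_vals)
  if (!is.null(vals$seed)) cfg$sim$seed <- cfg$seed
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order: acquire plate-level growth-rate records
#' (simulate, or read plate curves and estimate rates), bin, fit and
#' compare trajectory models on home-temperature records, estimate
#' variance components and repeatability per bin and evolution
#' temperature, run pairwise genotype tests per bin, summarise maximum
#' increases, classify trade-offs, scan the evolution-by-assay temperature
#' interaction, and compute cross-temperature correlations.  Every output
#' table is stamped with the configuration hash and seed; re-running with
#' an identical configuration reproduces identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_result` list: `records`, `binned_fine`,
#'   `binned_coarse`, `model_comparison`, `vc_by_bin`, `total_vc_by_bin`,
#'   `pairwise_tests`, `increase_summary`, `tradeoffs`, `interaction`,
#'   `cross_temperature`, `log` (character vector), `config_hash`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop_invalid("`config` must be a pipeline_config")
  }
  logl <- character()
  note <- function(...) {
    line <- sprintf("%s %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                    paste0(...))
    logl <<- c(logl, line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_invalid("pipeline stage `", name, "` failed: ", conditionMessage(e))
    })
  }
  hash <- rlang::hash(config)
  note("run start; config hash ", hash, "; seed ", config$seed)

  records <- stage("growth", {
    if (config$simulate) {
      sim <- config$sim
      sim$seed <- sub_seed(config$seed, "simulate")
      note("simulating: ", length(sim$genotypes), " genotypes x ",
           sim$n_replicates, " replicates x {",
           paste(sim$evolution_temps, collapse = ","), "} (model ",
           sim$trajectory_model, ")")
      simulate_evolution_experiment(sim)$records
    } else {
      if (is.null(config$plate_table) || is.null(config$metadata)) {
        stop_invalid("plate_table and metadata paths are required when simulate = FALSE")
      }
      note("reading plate table ", config$plate_table,
           "; estimator window_points = ", config$window_points,
           ", min_od_delta = ", config$min_od_delta)
      series <- read_plate_table(config$plate_table)
      meta <- read_records(config$metadata)
      rates <- vapply(series, estimate_max_growth_rate, numeric(1),
                      window_points = config$window_points,
                      min_od_delta = config$min_od_delta)
      recs <- dplyr::bind_rows(lapply(names(series), function(k) {
        s <- series[[k]]; md <- attr(s, "metadata")
        tibble::tibble(plate_id = s$plate_id, well = s$well_id,
                       rate = rates[[k]],
                       population_id = md$population_id %||% NA_character_,
                       generation = as.numeric(md$generation %||% NA),
                       assay_temp = as.character(md$assay_temp %||% NA))
      }))
      recs <- recs[!is.na(recs$rate), ]
      # wells -> plate-level mean (the analysis unit)
      recs <- dplyr::summarise(
        dplyr::group_by(recs, .data$population_id, .data$plate_id,
                        .data$generation, .data$assay_temp),
        rate = mean(.data$rate), n_wells = dplyr::n(), .groups = "drop")
      dplyr::inner_join(recs, meta, by = "population_id")
    }
  })

  note("binning: widths ", config$bin_width_repeatability, " (repeatability) and ",
       config$bin_width_summary, " (summaries); half-open bins, boundaries up")
  binned_fine <- stage("bin", bin_records(records, config$bin_width_repeatability))
  binned_coarse <- stage("bin", bin_records(records, config$bin_width_summary))

  home <- records[records$assay_temp == records$evolution_temp, ]
  model_cmp <- stage("models", compare_trajectory_models(home))
  note("trajectory models compared on ", nrow(home),
       " home-temperature records; best = ", attr(model_cmp, "best"))

  vc_fine <- stage("repeatability",
                   vc_by_bin(records, config$bin_width_repeatability,
                             nested = TRUE))
  total_vc <- stage("repeatability",
                    vc_by_bin(records, config$bin_width_repeatability,
                              nested = FALSE))
  note("variance components: expected-mean-squares estimator, ",
       "negative estimates truncated at 0; VC scaled by squared grand mean")

  pairwise <- stage("repeatability", {
    hb <- binned_coarse[binned_coarse$assay_temp == binned_coarse$evolution_temp, ]
    cells <- unique(hb[c("evolution_temp", "bin")])
    dplyr::bind_rows(lapply(seq_len(nrow(cells)), function(i) {
      d <- hb[hb$evolution_temp == cells$evolution_temp[i] &
                hb$bin == cells$bin[i], ]
      if (length(unique(d$genotype)) < 2 || any(table(d$genotype) < 2)) {
        return(NULL)
      }
      out <- pairwise_genotype_tests(d, "mean_rate", "genotype",
                                     config$alpha, config$m_pairwise)
      out$evolution_temp <- cells$evolution_temp[i]; out$bin <- cells$bin[i]
      out
    }))
  })
  note("pairwise genotype t tests: pooled-variance, Bonferroni m = ",
       config$m_pairwise)

  incr <- stage("repeatability", increase_summary(binned_coarse))
  tradeoffs <- stage("correlated-response",
                     classify_tradeoffs(records,
                                        endpoint_bin = config$endpoint_bin,
                                        width = config$bin_width_summary,
                                        alpha = config$alpha,
                                        m = config$m_tradeoff))
  interaction <- stage("correlated-response",
                       interaction_through_time(records,
                                                bins = config$interaction_bins,
                                                width = config$bin_width_summary,
                                                alpha = config$alpha))
  xcor <- stage("correlated-response",
                cross_temperature_correlation(records,
                                              config$bin_width_summary))
  note("correlated response: endpoint bin ", config$endpoint_bin,
       ", trade-off Bonferroni m = ", config$m_tradeoff)

  result <- structure(
    list(records = records, binned_fine = binned_fine,
         binned_coarse = binned_coarse, model_comparison = model_cmp,
         vc_by_bin = vc_fine, total_vc_by_bin = total_vc,
         pairwise_tests = pairwise, increase_summary = incr,
         tradeoffs = tradeoffs, interaction = interaction,
         cross_temperature = xcor, log = logl, config_hash = hash),
    class = "pipeline_result")

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    stamp <- sprintf("config_hash=%s seed=%d", hash, config$seed)
    w <- function(x, f) write_records(x, file.path(config$output_dir, f), stamp)
    w(records, "records.csv")
    w(binned_fine, "binned_fine.csv")
    w(binned_coarse, "binned_coarse.csv")
    w(tibble::as_tibble(model_cmp), "model_comparison.csv")
    w(vc_fine, "vc_by_bin.csv")
    w(total_vc, "total_vc_by_bin.csv")
    w(pairwise, "pairwise_tests.csv")
    w(incr, "increase_summary.csv")
    w(tradeoffs, "tradeoffs.csv")
    w(interaction$interaction, "interaction.csv")
    w(interaction$by_assay_temp, "interaction_by_assay_temp.csv")
    w(xcor, "cross_temperature.csv")
    writeLines(result$log, file.path(config$output_dir, "run_log.txt"))
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result:", nrow(x$records), "plate records;",
      "best trajectory model:", attr(x$model_comparison, "best"), "\n")
  cat("  tables: binned_fine, binned_coarse, model_comparison, vc_by_bin,\n",
      "         total_vc_by_bin, pairwise_tests, increase_summary, tradeoffs,\n",
      "         interaction, cross_temperature\n")
  invisible(x)
}
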