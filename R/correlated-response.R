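#' Classify trade-offs at the alternate assay temperature
#'
#' For each evolved population, compares its endpoint growth rates at the
#' alternate assay temperature (the temperature it did not evolve at)
#' against its own ancestral (earliest-bin) rates at that temperature with
#' a two-sample pooled t test, and classifies the correlated response:
#' `"trade-off"` when the evolved mean is significantly lower than the
#' ancestor, `"increase"` when significantly higher, `"no-change"`
#' otherwise.  Significance uses the Bonferroni threshold `alpha / m`.
#'
#' @param records Plate-level records table (needs `population_id`,
#'   `evolution_temp`, `assay_temp`, `generation`, `rate`).
#' @param endpoint_bin Bin centre (generations) of the endpoint window.
#' @param ancestor_bin Bin centre of the ancestral reference window.  The
#'   comparison contract is real-time: the ancestor values are the same
#'   lineage's earliest-window assays, not frozen-stock measurements.
#' @param width Bin width.
#' @param alpha,m Level and comparison count for the Bonferroni threshold.
#' @return Tibble with one row per population: evolved and ancestral means,
#'   `t`, `p_value`, `classification`; threshold in `attr(, "threshold")`.
#' @export
classify_tradeoffs <- function(records, endpoint_bin = 6000,
                               ancestor_bin = 0, width = 1000,
                               alpha = 0.05, m = 24) {
  thr <- bonferroni_threshold(alpha, m)
  records$bin <- assign_bin(records$generation, width)
  pops <- unique(records[c("population_id", "evolution_temp")])
  ats <- unique(records$assay_temp)
  rows <- lapply(seq_len(nrow(pops)), function(i) {
    pid <- pops$population_id[i]; et <- pops$evolution_temp[i]
    alt <- setdiff(ats, et)
    if (length(alt) != 1) {
      stop_invalid("population ", pid, ": expected exactly one alternate assay temperature")
    }
    r <- records[records$population_id == pid & records$assay_temp == alt, ]
    evolved <- r$rate[r$bin == endpoint_bin]
    ancestor <- r$rate[r$bin == ancestor_bin]
    if (length(ancestor) < 2) {
      stop_invalid("population ", pid, ": missing ancestor data at the alternate temperature")
    }
    if (length(evolved) < 2) {
      stop_invalid("population ", pid, ": fewer than 2 endpoint measurements")
    }
    tt <- pooled_t(evolved, ancestor)
    cls <- if (tt$p < thr) {
      if (mean(evolved) > mean(ancestor)) "increase" else "trade-off"
    } else "no-change"
    tibble::tibble(population_id = pid, evolution_temp = et,
                   assay_temp = alt, evolved_mean = mean(evolved),
                   ancestor_mean = mean(ancestor),
                   t = tt$t, p_value = tt$p,
                   classification = cls)
  })
  structure(dplyr::bind_rows(rows), threshold = thr)
}

#' Evolution-by-assay temperature interaction through time
#'
#' For each requested generation bin, runs the full factorial ANOVA of the
#' per-population binned mean growth rates on genotype, assay temperature
#' and evolution temperature (the "48 data points": 24 populations x 2
#' assay temperatures in the emulated design) and extracts the
#' evolution-by-assay temperature interaction row.  A significant
#' interaction means adaptation is temperature specific: populations grow
#' relatively faster at their own evolution temperature.  For each assay
#' temperature stratum the effect of evolution temperature is additionally
#' summarised by Tukey-Kramer comparisons and its R-squared share
#' (`SS_ET / SS_total` within the stratum).
#'
#' @param records Plate-level records table with genotype metadata.
#' @param bins Bin centres to analyse.
#' @param width Bin width.
#' @param alpha Level for the Tukey flags.
#' @return List of class `interaction_scan`: `interaction` (per-bin tibble
#'   with the ET x AT F test) and `by_assay_temp` (per bin x assay
#'   temperature: `r2_et` and the Tukey p value).
#' @export
interaction_through_time <- function(records, bins = c(0, 2000, 6000),
                                     width = 1000, alpha = 0.05) {
  binned <- bin_records(records, width)
  int_rows <- list(); strat_rows <- list()
  for (b in bins) {
    d <- binned[binned$bin == b, ]
    if (nrow(d) == 0) stop_invalid("no data in bin ", b)
    dd <- data.frame(value = d$mean_rate, G = d$genotype,
                     AT = d$assay_temp, ET = d$evolution_temp)
    tab <- factorial_anova(dd, "value", c("G", "AT", "ET"))
    row <- tab[tab$term == "AT:ET", ]
    df2 <- tab$df[tab$term == "Residuals"]
    int_rows[[length(int_rows) + 1L]] <- tibble::tibble(
      bin = b, df1 = row$df, df2 = df2, statistic = row$statistic,
      p_value = row$p_value)
    for (at in unique(dd$AT)) {
      s <- dd[dd$AT == at, ]
      tk <- tukey_kramer(s, "value", "ET", alpha)
      ss_tot <- sum((s$value - mean(s$value))^2)
      ss_et <- sum(tapply(s$value, s$ET, function(v)
        length(v) * (mean(v) - mean(s$value))^2))
      strat_rows[[length(strat_rows) + 1L]] <- tibble::tibble(
        bin = b, assay_temp = at, r2_et = ss_et / ss_tot,
        p_tukey = min(tk$p_value), significant = any(tk$significant))
    }
  }
  structure(list(interaction = dplyr::bind_rows(int_rows),
                 by_assay_temp = dplyr::bind_rows(strat_rows)),
            class = "interaction_scan")
}

#' @export
print.interaction_scan <- function(x, ...) {
  cat("Evolution x assay temperature interaction by bin:\n")
  print(x$interaction, ...)
  cat("\nEvolution-temperature effect within each assay temperature:\n")
  print(x$by_assay_temp, ...)
  invisible(x)
}

#' Cross-temperature correlation of population growth rates
#'
#' For each generation bin, pairs every population's binned mean growth
#' rate at the two assay temperatures and reports the Pearson correlation
#' together with the 95% confidence-ellipse geometry of the paired cloud:
#' centroid, and semi-axes equal to the square roots of the covariance
#' eigenvalues scaled by the chi-square quantile with 2 degrees of freedom.
#'
#' @param records Plate-level records table.
#' @param width Bin width.
#' @param conf Ellipse coverage probability.
#' @return Tibble with one row per bin: `r`, `n_pops`, centroid
#'   coordinates, `axis_major`, `axis_minor`, `angle` (radians of the major
#'   axis).  Bins with fewer than 3 fully paired populations error.
#' @export
cross_temperature_correlation <- function(records, width = 1000,
                                          conf = 0.95) {
  binned <- bin_records(records, width)
  ats <- sort(unique(binned$assay_temp))
  if (length(ats) != 2) stop_invalid("need exactly 2 assay temperatures")
  wide <- tidyr::pivot_wider(
    binned[c("population_id", "assay_temp", "bin", "mean_rate")],
    names_from = "assay_temp", values_from = "mean_rate")
  rows <- lapply(sort(unique(wide$bin)), function(b) {
    d <- wide[wide$bin == b, ]
    x <- d[[ats[1]]]; y <- d[[ats[2]]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3) {
      stop_invalid("bin ", b, ": fewer than 3 populations assayed at both temperatures")
    }
    x <- x[ok]; y <- y[ok]
    S <- stats::cov(cbind(x, y))
    ev <- eigen(S, symmetric = TRUE)
    scale <- qchisq(conf, df = 2)
    tibble::tibble(bin = b, n_pops = length(x), r = cor(x, y),
                   centroid_x = mean(x), centroid_y = mean(y),
                   axis_major = sqrt(max(ev$values[1], 0) * scale),
                   axis_minor = sqrt(max(ev$values[2], 0) * scale),
                   angle = atan2(ev$vectors[2, 1], ev$vectors[1, 1]))
  })
  dplyr::bind_rows(rows)
}

#' Generations per day under serial transfer
#'
#' `log2(end_density / start_density)`: the number of doublings a culture
#' achieves between the post-transfer starting density and the density at
#' the next transfer.
#'
#' @param start_density,end_density Densities (cells/mL, > 0).
#' @return Doublings per day.
#' @examples
#' generations_per_day(2500, 275000)  # ~6.8
#' @export
generations_per_day <- function(start_density, end_density) {
  if (any(c(start_density, end_density) <= 0) ||
      any(!is.finite(c(start_density, end_density)))) {
    stop_invalid("densities must be positive and finite")
  }
  log2(end_density / start_density)
}

#' Effective population size under discrete generations
#'
#' Harmonic mean of the population size at each discrete generation of the
#' within-day growth cycle — the classical variance effective size for a
#' population cycling through a bottleneck.
#'
#' @param generation_sizes Population sizes (cells) at each discrete
#'   generation; all > 0.
#' @return Effective population size (cells).
#' @examples
#' effective_population_size(25000 * 2^(0:6))
#' @export
effective_population_size <- function(generation_sizes) {
  if (length(generation_sizes) == 0) stop_invalid("empty size list")
  if (any(generation_sizes <= 0) || any(!is.finite(generation_sizes))) {
    stop_invalid("all generation sizes must be positive and finite")
  }
  length(generation_sizes) / sum(1 / generation_sizes)
}

#' Transfer volume to seed a target cell number
#'
#' @param target_cells Cells to transfer (> 0).
#' @param culture_density Donor culture density (cells/mL, > 0).
#' @return Volume in mL.
#' @examples
#' transfer_volume(25000, 275000) * 1000  # ~90 uL
#' @export
transfer_volume <- function(target_cells, culture_density) {
  assert_scalar_pos(target_cells, "target_cells")
  assert_scalar_pos(culture_density, "culture_density")
  target_cells / culture_density
}
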