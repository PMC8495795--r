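#' One well's kinetic optical-density trace
#'
#' Light container for a single growth curve: reading times (hours, strictly
#' increasing), optical densities (absorbance at the instrument wavelength,
#' finite) and identifying labels.  `blank`, when known, is the absorbance
#' baseline subtracted before log-transforming; when absent the estimator
#' falls back to the median of the first three readings.
#'
#' @param times Numeric vector of reading times in hours.
#' @param od Numeric vector of optical densities, same length as `times`.
#' @param well_id,plate_id Labels.
#' @param blank Optional known baseline absorbance.
#' @return An `od_series` object.
#' @export
od_series <- function(times, od, well_id = "", plate_id = NULL, blank = NULL) {
  times <- as.numeric(times); od <- as.numeric(od)
  if (length(times) != length(od)) stop_invalid("times and od lengths differ")
  if (length(times) == 0) stop_invalid("empty series")
  if (any(!is.finite(times)) || any(!is.finite(od))) {
    stop_invalid("times and od must be finite")
  }
  if (any(diff(times) <= 0)) stop_invalid("times must be strictly increasing")
  structure(list(times = times, od = od, well_id = well_id,
                 plate_id = plate_id, blank = blank),
            class = "od_series")
}

#' @export
print.od_series <- function(x, ...) {
  cat(sprintf("od_series %s%s: %d readings over %.2f h, OD %.3f-%.3f\n",
              if (is.null(x$plate_id)) "" else paste0(x$plate_id, "/"),
              x$well_id, length(x$times), diff(range(x$times)),
              min(x$od), max(x$od)))
  invisible(x)
}

#' Maximum growth rate from an optical-density curve
#'
#' Estimates the maximum growth rate in doublings per hour by the standard
#' max-slope method: subtract the blank, floor the corrected OD at a small
#' positive epsilon, take log2, slide a window of `window_points`
#' consecutive readings along the curve, fit an ordinary least-squares line
#' of log2(OD) on time within each window, and return the steepest slope
#' among windows whose raw OD span (max - min) exceeds `min_od_delta`.
#' The span filter excludes lag- and noise-only windows where a log-slope is
#' meaningless.  Ties are broken by the earliest window.
#'
#' A curve in which no window passes the span filter is a no-growth signal:
#' the function returns `NA_real_` (distinct from an estimated rate of 0).
#'
#' @param series An [od_series()], or any list with `times` and `od`.
#' @param window_points Readings per regression window (>= 3; default 13,
#'   one hour at a 5-minute cadence).
#' @param min_od_delta Minimum raw OD span a window must cover (absorbance).
#' @param blank Baseline absorbance to subtract; defaults to the series'
#'   `blank` field, else the median of the first three readings.
#' @param eps Floor applied to blank-corrected OD before log2.
#'
#' @return Maximum growth rate (doublings/hour), or `NA_real_` for a flat
#'   curve.
#' @examples
#' s <- od_series(times = 0:20, od = 0.01 * 2^(0:20))
#' estimate_max_growth_rate(s, window_points = 5, blank = 0)  # exactly 1
#' @export
estimate_max_growth_rate <- function(series, window_points = 13,
                                     min_od_delta = 0.02, blank = NULL,
                                     eps = 1e-4) {
  times <- series$times; od <- series$od
  n <- length(od)
  if (window_points < 3) stop_invalid("`window_points` must be >= 3")
  if (n < window_points) {
    stop_invalid("insufficient data: ", n, " readings < window of ", window_points)
  }
  blank <- blank %||% series$blank %||% median(od[seq_len(min(3, n))])
  y <- log2(pmax(od - blank, eps))

  w <- as.integer(window_points)
  # embed() rows are reversed windows; orientation is irrelevant for the
  # quantities below
  TT <- embed(times, w); YY <- embed(y, w); OO <- embed(od, w)
  st <- rowSums(TT); sy <- rowSums(YY)
  sxx <- rowSums(TT^2) - st^2 / w
  sxy <- rowSums(TT * YY) - st * sy / w
  slope <- sxy / sxx
  span <- apply(OO, 1L, max) - apply(OO, 1L, min)

  ok <- span > min_od_delta & is.finite(slope)
  if (!any(ok)) return(NA_real_)
  best <- max(slope[ok])
  slope[which(ok & slope == best)[1L]]
}

#' Aggregate per-well growth rates into a plate-level record
#'
#' The per-plate population growth rate is the arithmetic mean of the
#' replicate wells measured for that population on one plate.
#'
#' @param well_rates Numeric vector of per-well rates (doublings/hour),
#'   non-empty, all finite.
#' @param population_id,plate_id Labels.
#' @param generation Cumulative generations at assay (>= 0).
#' @param assay_temp Assay temperature label.
#'
#' @return A one-row tibble with `rate` (the mean), `n_wells` and a
#'   `well_rates` list column.
#' @export
aggregate_plate <- function(well_rates, population_id = "", plate_id = "",
                            generation = 0, assay_temp = "") {
  if (length(well_rates) < 1) stop_invalid("no well rates to aggregate")
  if (any(!is.finite(well_rates))) stop_invalid("well rates must be finite")
  if (generation < 0) stop_invalid("`generation` must be >= 0")
  tibble::tibble(
    population_id = population_id, plate_id = plate_id,
    generation = as.numeric(generation), assay_temp = as.character(assay_temp),
    rate = mean(well_rates), n_wells = length(well_rates),
    well_rates = list(as.numeric(well_rates)))
}

#' Correlation between microscope counts and optical density
#'
#' Validates optical density as a proxy for cell density: the Pearson
#' product-moment correlation between paired direct counts and OD readings.
#'
#' @param counts Cell densities (cells/mL).
#' @param od Matching optical densities.
#' @return Pearson correlation coefficient in `[-1, 1]`.
#' @export
calibrate_od <- function(counts, od) {
  if (length(counts) != length(od) || length(counts) < 3) {
    stop_invalid("need equal-length vectors of >= 3 paired readings")
  }
  if (var(counts) == 0 || var(od) == 0) {
    stop_invalid("undefined correlation: zero variance in counts or od")
  }
  cor(counts, od)
}

#' Relative competitive fitness from paired density changes
#'
#' Fitness of the focal strain relative to the reference:
#' `ln(focal_final / focal_initial) / ln(reference_final / reference_initial)`
#' — the ratio of realised Malthusian parameters over the competition.
#'
#' @param focal_initial,focal_final,reference_initial,reference_final
#'   Densities (cells/mL, all > 0).  A `competition_record` from
#'   [simulate_competition()] can be passed as the first argument (strain A
#'   focal).
#' @return Dimensionless relative fitness.
#' @export
competitive_fitness <- function(focal_initial, focal_final = NULL,
                                reference_initial = NULL, reference_final = NULL) {
  if (inherits(focal_initial, "competition_record")) {
    rec <- focal_initial
    return(competitive_fitness(rec$a_initial, rec$a_final,
                               rec$b_initial, rec$b_final))
  }
  d <- c(focal_initial, focal_final, reference_initial, reference_final)
  if (length(d) != 4 || any(!is.finite(d)) || any(d <= 0)) {
    stop_invalid("all four densities must be positive and finite")
  }
  den <- log(reference_final / reference_initial)
  if (den == 0) {
    stop_invalid("reference strain did not change density; fitness undefined")
  }
  log(focal_final / focal_initial) / den
}
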