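#' Assign generations to fixed-width bins
#'
#' Bins are centred on multiples of `width` and half-open `[low, high)`,
#' with the first bin truncated at zero: for width 250 bin 0 covers
#' `[0, 125)`, bin 250 covers `[125, 375)`, and so on; for width 1000 bin 0
#' covers `[0, 500)`, bin 1000 covers `[500, 1500)`.  A generation sitting
#' exactly on a boundary goes to the upper bin.
#'
#' @param generation Numeric vector of cumulative generations (>= 0).
#' @param width Bin width in generations (canonically 250 or 1000).
#' @return Numeric vector of bin centres.
#' @examples
#' assign_bin(c(100, 130, 125), 250)   # 0, 250, 250
#' assign_bin(5600, 1000)              # 6000
#' @export
assign_bin <- function(generation, width = 250) {
  assert_scalar_pos(width, "width")
  if (any(generation < 0)) stop_invalid("generations must be >= 0")
  width * floor((generation + width / 2) / width)
}

#' Bin plate-level growth rates
#'
#' Groups records by population, assay temperature and generation bin and
#' returns the binned mean growth rate per group with its spread.
#'
#' @param records Data frame with at least `population_id`, `assay_temp`,
#'   `generation`, `rate`; metadata columns `genotype`, `replicate`,
#'   `evolution_temp` are carried through when present.
#' @param width Bin width in generations (see [assign_bin()]).
#' @return Tibble with one row per population x assay temperature x bin:
#'   `bin` (centre), `bin_width`, `mean_rate`, `n_records`, `sd`.
#' @export
bin_records <- function(records, width = 250) {
  if (nrow(records) == 0) stop_invalid("no records to bin")
  meta <- intersect(c("genotype", "replicate", "evolution_temp"),
                    names(records))
  records$bin <- assign_bin(records$generation, width)
  out <- dplyr::summarise(
    dplyr::group_by(records, dplyr::across(dplyr::all_of(
      c("population_id", meta, "assay_temp", "bin")))),
    mean_rate = mean(.data$rate),
    n_records = dplyr::n(),
    sd = sd(.data$rate),
    .groups = "drop")
  out$bin_width <- width
  out
}

#' Maximum increase in growth rate over the experiment
#'
#' For one population (at one assay temperature), the absolute increase is
#' the maximum binned mean growth rate minus the ancestral rate, and the
#' relative increase is `100 * absolute / ancestral`.
#'
#' @param binned Binned rows (from [bin_records()], typically width 1000)
#'   for a single population and assay temperature.
#' @param ancestor_rate Ancestral growth rate (doublings/hour, > 0).
#' @return One-row tibble: `absolute_increase`, `relative_increase`
#'   (percent), `best_bin`.
#' @export
max_increase <- function(binned, ancestor_rate) {
  assert_scalar_pos(ancestor_rate, "ancestor_rate")
  if (nrow(binned) < 1) stop_invalid("no bins supplied")
  i <- which.max(binned$mean_rate)
  abs_inc <- binned$mean_rate[i] - ancestor_rate
  tibble::tibble(absolute_increase = abs_inc,
                 relative_increase = 100 * abs_inc / ancestor_rate,
                 best_bin = binned$bin[i])
}

#' Group-level summary of maximum growth-rate increases
#'
#' Applies [max_increase()] to every population x assay temperature and
#' summarises by genotype x evolution temperature x assay temperature (plus
#' an overall row per evolution x assay temperature), with t-based 95%
#' confidence intervals on the group mean computed across populations
#' (`df = n_pops - 1`).
#'
#' @param binned Width-1000 binned table from [bin_records()] including
#'   `genotype` and `evolution_temp`.
#' @param ancestors Data frame mapping `population_id` (and optionally
#'   `assay_temp`) to `ancestor_rate`.  When `NULL`, each population's
#'   earliest-bin mean at the same assay temperature is used.
#' @param conf Confidence level.
#' @return Tibble with per-group mean absolute and relative increases and
#'   their confidence bounds.
#' @export
increase_summary <- function(binned, ancestors = NULL, conf = 0.95) {
  if (is.null(ancestors)) {
    ancestors <- dplyr::summarise(
      dplyr::group_by(binned, .data$population_id, .data$assay_temp),
      ancestor_rate = .data$mean_rate[which.min(.data$bin)],
      .groups = "drop")
  }
  by <- intersect(names(ancestors), c("population_id", "assay_temp"))
  d <- dplyr::inner_join(binned, ancestors, by = by)
  per_pop <- dplyr::reframe(
    dplyr::group_by(d, .data$population_id, .data$genotype,
                    .data$evolution_temp, .data$assay_temp),
    max_increase(dplyr::pick(dplyr::everything()),
                 .data$ancestor_rate[1]))

  ci <- function(x) {
    n <- length(x)
    half <- if (n > 1) qt(1 - (1 - conf) / 2, n - 1) * sd(x) / sqrt(n) else NA_real_
    c(mean(x), mean(x) - half, mean(x) + half)
  }
  summarise_group <- function(g, label) {
    out <- dplyr::summarise(
      g,
      genotype = label %||% .data$genotype[1],
      n_pops = dplyr::n(),
      .abs = list(ci(.data$absolute_increase)),
      .rel = list(ci(.data$relative_increase)),
      .groups = "drop")
    pick3 <- function(col, i) vapply(out[[col]], `[`, numeric(1), i)
    out$absolute_increase <- pick3(".abs", 1)
    out$abs_ci_low <- pick3(".abs", 2)
    out$abs_ci_high <- pick3(".abs", 3)
    out$relative_increase <- pick3(".rel", 1)
    out$rel_ci_low <- pick3(".rel", 2)
    out$rel_ci_high <- pick3(".rel", 3)
    out$.abs <- NULL; out$.rel <- NULL
    out
  }
  by_geno <- summarise_group(
    dplyr::group_by(per_pop, .data$genotype, .data$evolution_temp,
                    .data$assay_temp), NULL)
  overall <- summarise_group(
    dplyr::group_by(per_pop, .data$evolution_temp, .data$assay_temp),
    "Overall")
  dplyr::bind_rows(by_geno, overall)
}

# anova() warns on zero-residual fits; noise-free (degenerate) inputs are a
# legitimate documented case here, so that specific warning is muffled.
#' @noRd
quiet_anova <- function(fit) {
  withCallingHandlers(
    anova(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
}

#' @noRd
tidy_anova_table <- function(tab) {
  tn <- rownames(tab)
  df <- tab$Df
  ss <- tab[["Sum Sq"]]
  tibble::tibble(term = trimws(tn), df = df, sumsq = ss, meansq = ss / df,
                 statistic = if ("F value" %in% names(tab)) tab[["F value"]] else NA_real_,
                 p_value = if ("Pr(>F)" %in% names(tab)) tab[["Pr(>F)"]] else NA_real_)
}

#' Fixed-effects factorial ANOVA
#'
#' Crossed ANOVA of a response on up to three factors and all their
#' interactions.  Balanced designs use sequential sums of squares (which
#' coincide with every SS type under balance); unbalanced designs use
#' Type-II SS.  F statistics test each term mean square against the
#' residual mean square.
#'
#' @param data Data frame containing the response and factor columns.
#' @param response Name of the response column.
#' @param factors Character vector of factor column names (all interactions
#'   are included).
#' @return Tidy ANOVA tibble (`term`, `df`, `sumsq`, `meansq`, `statistic`,
#'   `p_value`) with a `Residuals` row.
#' @export
factorial_anova <- function(data, response = "value",
                            factors = c("G", "AT", "ET")) {
  if (!all(c(response, factors) %in% names(data))) {
    stop_invalid("missing columns: ",
                 paste(setdiff(c(response, factors), names(data)), collapse = ", "))
  }
  data <- as.data.frame(data)
  for (f in factors) {
    data[[f]] <- factor(data[[f]])
    if (nlevels(data[[f]]) < 2) {
      stop_invalid("factor `", f, "` needs >= 2 levels")
    }
  }
  counts <- table(data[factors])
  if (length(factors) > 1 && any(counts == 0)) {
    empty <- which(counts == 0, arr.ind = TRUE)[1, ]
    cell <- paste(mapply(function(f, i) dimnames(counts)[[f]][i],
                         seq_along(factors), empty),
                  collapse = " x ")
    stop_invalid("empty design cell with interactions requested: ", cell)
  }
  fml <- stats::as.formula(paste(response, "~", paste(factors, collapse = "*")))
  fit <- lm(fml, data = data)
  if (fit$df.residual < 1) stop_invalid("no residual degrees of freedom")
  balanced <- length(unique(as.vector(counts))) == 1L
  if (balanced) {
    tidy_anova_table(as.data.frame(quiet_anova(fit)))
  } else {
    tab <- as.data.frame(car::Anova(fit, type = 2))
    out <- tidy_anova_table(tab)
    # car::Anova orders columns Sum Sq, Df, F, Pr; rebuild meansq robustly
    out$meansq <- out$sumsq / out$df
    out
  }
}

# Expected-mean-squares coefficient n0 for a random factor whose groups
# (sizes `sizes`) are nested in parent strata given by `parent`.
#' @noRd
ems_n0 <- function(sizes, parent) {
  N <- sum(sizes)
  q <- tapply(sizes, parent, function(n) sum(n^2) / sum(n))
  df_s <- sum(tapply(sizes, parent, length) - 1L)
  if (df_s < 1) stop_invalid("no replication within any stratum")
  (N - sum(q)) / df_s
}

#' @noRd
new_variance_components <- function(vc_genotype, vc_replicate, vc_residual,
                                    grand_mean, truncated, n0, anova) {
  scaled <- vc_replicate / grand_mean^2
  structure(
    list(vc_genotype = vc_genotype, vc_replicate = vc_replicate,
         vc_residual = vc_residual,
         scaled_vc_replicate = scaled,
         repeatability = if (scaled > 0) 1 / scaled else Inf,
         truncated = truncated, n0 = n0, grand_mean = grand_mean,
         anova = anova),
    class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("Variance components (expected mean squares):\n")
  cat(sprintf("  genotype: %s   replicate-within-genotype: %.4g%s   residual: %.4g\n",
              if (is.na(x$vc_genotype)) "-" else format(x$vc_genotype, digits = 4),
              x$vc_replicate, if (x$truncated) " (truncated at 0)" else "",
              x$vc_residual))
  cat(sprintf("  mean-scaled replicate VC: %.4g   repeatability: %s\n",
              x$scaled_vc_replicate,
              if (is.infinite(x$repeatability)) "Inf" else
                format(x$repeatability, digits = 4)))
  invisible(x)
}

#' Nested ANOVA and the replicate-within-genotype variance component
#'
#' Fits the nested model `rate ~ genotype + replicate(genotype)` (optionally
#' with a crossed evolution-temperature factor,
#' `rate ~ G + ET + G:ET + replicate(G)`), treating replicate population as
#' a random effect, and estimates its variance component by the method of
#' expected mean squares: `vc_replicate = (MS_S(G) - MS_residual) / n0`
#' where `n0` is the effective per-replicate observation count (the
#' standard unequal-group-size correction; the group size itself when
#' balanced).  Negative moment estimates are truncated to zero and flagged.
#'
#' The replicate component is scaled to the squared grand mean (a squared
#' coefficient-of-variation analogue); the repeatability statistic is the
#' reciprocal of the scaled component, reported as `Inf` when the component
#' is zero (replicates indistinguishable).
#'
#' @param data Data frame of plate-level rates within one generation bin.
#' @param response,genotype,replicate Column names.
#' @param et Optional evolution-temperature column name to include as a
#'   crossed fixed factor.
#' @return A `variance_components` object (includes the sequential ANOVA
#'   table).
#' @export
nested_anova_vc <- function(data, response = "rate", genotype = "genotype",
                            replicate = "replicate", et = NULL) {
  cols <- c(response, genotype, replicate, et)
  if (!all(cols %in% names(data))) {
    stop_invalid("missing columns: ",
                 paste(setdiff(cols, names(data)), collapse = ", "))
  }
  y <- as.numeric(data[[response]])
  G <- factor(data[[genotype]])
  if (!is.null(et)) {
    E <- factor(data[[et]])
    parent <- interaction(G, E, drop = TRUE)
    pop <- interaction(G, E, factor(data[[replicate]]), drop = TRUE)
    df <- data.frame(y = y, G = G, E = E, pop = pop)
    fml <- y ~ G + E + G:E + pop
  } else {
    parent <- G
    pop <- interaction(G, factor(data[[replicate]]), drop = TRUE)
    df <- data.frame(y = y, G = G, pop = pop)
    fml <- y ~ G + pop
  }
  sizes <- as.vector(table(pop))
  pop_parent <- tapply(as.character(parent), pop, `[`, 1L)
  if (all(tapply(sizes, pop_parent, length) < 2)) {
    stop_invalid("no replication within any genotype stratum")
  }
  if (sum(sizes) - length(sizes) < 1) {
    stop_invalid("need >= 2 observations in at least one replicate")
  }

  fit <- lm(fml, data = df)
  at <- as.data.frame(quiet_anova(fit))
  tab <- tidy_anova_table(at)
  ms_pop <- tab$meansq[tab$term == "pop"]
  ms_e <- tab$meansq[tab$term == "Residuals"]
  if (!is.finite(ms_e)) ms_e <- 0
  n0 <- ems_n0(sizes, pop_parent)
  vc_rep_raw <- (ms_pop - ms_e) / n0
  truncated <- vc_rep_raw < 0
  vc_rep <- max(0, vc_rep_raw)

  # genotype component only for balanced designs (clean EMS coefficient)
  vc_g <- NA_real_
  gt <- table(parent)
  reps_per_parent <- tapply(sizes, pop_parent, length)
  if (is.null(et) && length(unique(sizes)) == 1L &&
      length(unique(reps_per_parent)) == 1L && nlevels(G) > 1) {
    b <- unname(reps_per_parent[1]); n_per <- sizes[1]
    ms_g <- tab$meansq[tab$term == "G"]
    vc_g <- max(0, (ms_g - ms_pop) / (b * n_per))
  }

  new_variance_components(vc_g, vc_rep, ms_e, mean(y), truncated, n0, tab)
}

#' Total among-population variance component
#'
#' One-way random-effects analogue of [nested_anova_vc()] without the
#' genotype stratification: partitions variance into among-population and
#' residual components by expected mean squares, showing how replicate
#' divergence and genotype differences combine.
#'
#' @param data Data frame of plate-level rates within one bin.
#' @param response,population Column names.
#' @return A `variance_components` object; the among-population component
#'   is reported in the `vc_replicate` slot (`vc_genotype` is `NA`).
#' @export
total_population_vc <- function(data, response = "rate",
                                population = "population_id") {
  if (!all(c(response, population) %in% names(data))) {
    stop_invalid("missing columns")
  }
  y <- as.numeric(data[[response]])
  pop <- factor(data[[population]])
  if (nlevels(pop) < 2) stop_invalid("need >= 2 populations")
  sizes <- as.vector(table(pop))
  if (max(sizes) < 2) stop_invalid("need >= 2 observations in some population")
  fit <- lm(y ~ pop)
  tab <- tidy_anova_table(as.data.frame(quiet_anova(fit)))
  ms_b <- tab$meansq[tab$term == "pop"]
  ms_e <- tab$meansq[tab$term == "Residuals"]
  if (!is.finite(ms_e)) ms_e <- 0
  n0 <- ems_n0(sizes, rep("all", length(sizes)))
  raw <- (ms_b - ms_e) / n0
  new_variance_components(NA_real_, max(0, raw), ms_e, mean(y), raw < 0,
                          n0, tab)
}

#' Variance components per generation bin
#'
#' The data backbone of repeatability-through-time figures: for each
#' evolution temperature and generation bin (records assayed at the home
#' temperature by default), estimates the replicate-within-genotype
#' variance component ([nested_anova_vc()]) or the total among-population
#' component ([total_population_vc()]).
#'
#' @param records Plate-level records table.
#' @param width Bin width in generations.
#' @param nested `TRUE` for replicate-within-genotype components, `FALSE`
#'   for total among-population components.
#' @param home_only Keep only records assayed at their evolution
#'   temperature.
#' @return Tibble with one row per evolution temperature x bin:
#'   `vc_replicate`, `scaled_vc_replicate`, `repeatability`, `truncated`,
#'   `n_obs`.  Bins without replication are dropped.
#' @export
vc_by_bin <- function(records, width = 250, nested = TRUE, home_only = TRUE) {
  if (home_only) {
    records <- records[records$assay_temp == records$evolution_temp, ]
  }
  records$bin <- assign_bin(records$generation, width)
  cells <- unique(records[c("evolution_temp", "bin")])
  cells <- cells[order(cells$evolution_temp, cells$bin), ]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    d <- records[records$evolution_temp == cells$evolution_temp[i] &
                   records$bin == cells$bin[i], ]
    vc <- tryCatch(
      if (nested) nested_anova_vc(d) else total_population_vc(d),
      error = function(e) NULL)
    if (is.null(vc)) return(NULL)
    tibble::tibble(evolution_temp = cells$evolution_temp[i],
                   bin = cells$bin[i], vc_replicate = vc$vc_replicate,
                   scaled_vc_replicate = vc$scaled_vc_replicate,
                   repeatability = vc$repeatability,
                   truncated = vc$truncated, n_obs = nrow(d))
  })
  dplyr::bind_rows(rows)
}

#' Levene's test for homogeneity of variances
#'
#' One-way ANOVA on absolute deviations of each observation from its group
#' centre (the mean for classic Levene; the median for the Brown-Forsythe
#' variant).
#'
#' @param groups List of numeric vectors, each of length >= 2.
#' @param center `"mean"` (default) or `"median"`.
#' @return List with `statistic` (F), `df` (numerator, denominator) and
#'   `p_value`.
#' @export
levene_test <- function(groups, center = c("mean", "median")) {
  center <- match.arg(center)
  if (length(groups) < 2) stop_invalid("need >= 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2)) {
    stop_invalid("each group needs >= 2 values")
  }
  cfun <- if (center == "mean") mean else median
  z <- unlist(lapply(groups, function(g) abs(g - cfun(g))))
  grp <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  tab <- as.data.frame(quiet_anova(lm(z ~ grp)))
  list(statistic = tab[["F value"]][1],
       df = c(tab$Df[1], tab$Df[2]),
       p_value = tab[["Pr(>F)"]][1])
}

# Two-sample pooled-variance Student t test, defined by continuity at zero
# pooled variance: identical degenerate samples give t = 0, p = 1; separated
# degenerate samples give |t| = Inf, p = 0.
#' @noRd
pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  df <- nx + ny - 2
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / df
  d <- mean(x) - mean(y)
  if (sp2 <= 0) {
    t <- if (d == 0) 0 else sign(d) * Inf
    p <- if (d == 0) 1 else 0
  } else {
    t <- d / sqrt(sp2 * (1 / nx + 1 / ny))
    p <- 2 * pt(-abs(t), df)
  }
  list(t = t, df = df, p = p)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error level.
#' @param m Number of comparisons in the family (always supplied by the
#'   caller; the family size is a study design choice, never inferred).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 1) {
  assert_scalar_pos(alpha, "alpha"); assert_scalar_pos(m, "m")
  alpha / m
}

#' Pairwise genotype comparisons with a Bonferroni threshold
#'
#' Two-sample pooled-variance Student t tests on per-population values
#' (typically binned means) for every pair of genotypes, flagged against
#' the Bonferroni-corrected threshold `alpha / m` where `m` is the total
#' comparison count of the analysis family.
#'
#' @param data Data frame with one row per population.
#' @param value,genotype Column names.
#' @param alpha Family-wise error level.
#' @param m Comparison count for the Bonferroni correction.
#' @return Tibble with one row per genotype pair: `t`, `df`, `p_value`,
#'   `significant`; the threshold is in `attr(, "threshold")`.
#' @export
pairwise_genotype_tests <- function(data, value = "mean_rate",
                                    genotype = "genotype", alpha = 0.05,
                                    m = 1) {
  g <- factor(data[[genotype]])
  if (nlevels(g) < 2) stop_invalid("need >= 2 genotypes")
  if (any(table(g) < 2)) stop_invalid("each genotype needs >= 2 populations")
  thr <- bonferroni_threshold(alpha, m)
  prs <- combn(levels(g), 2)
  rows <- apply(prs, 2, function(p) {
    x <- data[[value]][g == p[1]]; y <- data[[value]][g == p[2]]
    tt <- pooled_t(x, y)
    tibble::tibble(genotype_1 = p[1], genotype_2 = p[2],
                   t = tt$t, df = tt$df,
                   p_value = tt$p, significant = tt$p < thr)
  })
  structure(dplyr::bind_rows(rows), threshold = thr)
}

#' Tukey-Kramer pairwise comparisons
#'
#' Studentized-range pairwise comparisons of group means with the Kramer
#' correction for unequal group sizes: for groups i, j the statistic is
#' `q = |mi - mj| / sqrt(MSE/2 * (1/ni + 1/nj))`, referred to the
#' studentized-range distribution with `k` groups and the pooled residual
#' degrees of freedom.
#'
#' @param data Data frame of observations.
#' @param value,group Column names.
#' @param alpha Family-wise error level for the significance flag.
#' @return Tibble with one row per pair: mean difference, `q`, adjusted
#'   `p_value`, `significant`.
#' @export
tukey_kramer <- function(data, value = "value", group = "group",
                         alpha = 0.05) {
  g <- factor(data[[group]]); y <- as.numeric(data[[value]])
  k <- nlevels(g)
  if (k < 2) stop_invalid("need >= 2 groups")
  ni <- as.vector(table(g))
  if (any(ni < 2)) stop_invalid("each group needs >= 2 values")
  mi <- tapply(y, g, mean)
  dfw <- sum(ni) - k
  mse <- sum(tapply(y, g, function(v) sum((v - mean(v))^2))) / dfw
  if (mse <= 0) stop_invalid("degenerate groups: zero within-group variance")
  prs <- combn(k, 2)
  rows <- apply(prs, 2, function(p) {
    i <- p[1]; j <- p[2]
    se <- sqrt(mse / 2 * (1 / ni[i] + 1 / ni[j]))
    q <- abs(mi[i] - mi[j]) / se
    pv <- ptukey(q, k, dfw, lower.tail = FALSE)
    tibble::tibble(group_1 = levels(g)[i], group_2 = levels(g)[j],
                   diff = unname(mi[i] - mi[j]), q = unname(q),
                   p_value = unname(pv), significant = pv < alpha)
  })
  dplyr::bind_rows(rows)
}
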