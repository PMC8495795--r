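#' Small-sample corrected Akaike information criterion for least squares
#'
#' Gaussian-likelihood form for a model fit by minimising the residual sum
#' of squares: `n * ln(sse / n) + 2k + 2k(k + 1) / (n - k - 1)`, with `k`
#' counting the mean parameters plus one for the residual variance.
#'
#' A perfect fit (`sse = 0`) has unbounded likelihood; it is returned as
#' `-Inf`, which orders below every finite AICc.
#'
#' @param sse Residual sum of squares (>= 0).
#' @param n_obs Number of observations; must exceed `k_params + 1`.
#' @param k_params Number of estimated parameters including the residual
#'   variance.
#' @return AICc value (`-Inf` when `sse = 0`).
#' @export
aicc <- function(sse, n_obs, k_params) {
  if (sse < 0) stop_invalid("`sse` must be >= 0")
  if (n_obs <= k_params + 1) {
    stop_invalid("AICc undefined: n_obs (", n_obs, ") must exceed k_params + 1 (",
                 k_params + 1, ")")
  }
  if (sse == 0) return(-Inf)
  n_obs * log(sse / n_obs) + 2 * k_params +
    2 * k_params * (k_params + 1) / (n_obs - k_params - 1)
}

#' Evidence ratio between two AICc values
#'
#' `exp(0.5 * (aicc_candidate - aicc_reference))`: the relative likelihood
#' of the reference model against the candidate.  Values above 1 read as
#' evidence against the candidate (the reference fits better after the
#' parsimony correction).
#'
#' @param aicc_candidate,aicc_reference AICc values.
#' @return Evidence ratio (> 0).
#' @export
evidence_ratio <- function(aicc_candidate, aicc_reference) {
  exp(0.5 * (aicc_candidate - aicc_reference))
}

# Profiled SSE for the hyperbolic model: for fixed theta2 the mean curve
# R0 + theta1 * N/(theta2 + N) is linear in (R0, theta1).
#' @noRd
.hyperbolic_profile <- function(N, y, theta2) {
  x <- N / (theta2 + N)
  f <- lm.fit(cbind(1, x), y)
  list(sse = sum(f$residuals^2), R0 = unname(f$coefficients[1]),
       theta1 = unname(f$coefficients[2]))
}

# Profiled SSE for the power model: for fixed exponent theta1 the curve
# R0 + theta2 * N^theta1 is linear in (R0, theta2).
#' @noRd
.power_profile <- function(N, y, theta1) {
  x <- N^theta1
  f <- lm.fit(cbind(1, x), y)
  list(sse = sum(f$residuals^2), R0 = unname(f$coefficients[1]),
       theta2 = unname(f$coefficients[2]))
}

# Deterministic multi-start 1-D minimisation of a profiled SSE over a
# transformed parameter, with a final high-precision polish around the
# incumbent.  Returns list(par, sse).
#' @noRd
.multi_start_minimise <- function(obj, starts, lower, upper) {
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      optim(s, obj, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(factr = 1e2)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value ||
        (fit$value == best$value && fit$par < best$par)) {
      best <- fit
    }
  }
  if (is.null(best)) {
    stop_invalid("optimizer failed to converge from every start")
  }
  pol <- optimize(obj, interval = c(max(lower, best$par - 2),
                                    min(upper, best$par + 2)), tol = 1e-12)
  if (pol$objective < best$value) {
    best <- list(par = pol$minimum, value = pol$objective)
  }
  list(par = best$par, sse = best$value)
}

#' Fit one trajectory model to plate-level growth rates
#'
#' Fits the mean growth-rate gain curve over cumulative generations `N` by
#' least squares, for one of three decelerating-return candidates:
#'
#' * linear: `R0 + theta1 * N`
#' * power law: `R0 + theta2 * N^theta1`, with exponent `0 < theta1 < 1.5`
#' * hyperbolic: `R0 + theta1 * N / (theta2 + N)`, with `theta2 > 0`
#'
#' The nonlinear models are fit by profiling: for a fixed nonlinear
#' constant the remaining parameters are linear and solved in closed form,
#' leaving a one-dimensional optimisation carried out from a deterministic
#' grid of starts (half-saturation starts `{0.1, 0.5, 1, 2, 5} x median N`;
#' exponent starts `{0.1, 0.3, 0.5, 0.7, 0.9}`), ties broken by lower SSE
#' then lower `theta2`.  `k_params` counts the mean parameters plus the
#' residual variance (3 linear, 4 power/hyperbolic).
#'
#' @param records Data frame with columns `generation` and `rate` (e.g. the
#'   `records` table of an [simulate_evolution_experiment()] dataset).
#' @param model `"linear"`, `"power"` or `"hyperbolic"`.
#'
#' @return A `trajectory_fit` list: `model`, `R0`, `theta1`, `theta2`
#'   (`NA` for linear), `sse`, `n_obs`, `k_params`, `aicc`.
#' @export
fit_trajectory <- function(records, model = c("hyperbolic", "power", "linear")) {
  model <- match.arg(model)
  if (!all(c("generation", "rate") %in% names(records))) {
    stop_invalid("`records` needs `generation` and `rate` columns")
  }
  N <- as.numeric(records$generation); y <- as.numeric(records$rate)
  keep <- is.finite(N) & is.finite(y)
  N <- N[keep]; y <- y[keep]
  n <- length(y)
  if (n < 6 || length(unique(N)) < 3) {
    stop_invalid("under-determined data: need >= 6 records spanning >= 3 distinct generations")
  }
  if (model != "linear" && all(N == 0)) {
    stop_invalid("nonlinear trajectory models need nonzero generations")
  }

  if (model == "linear") {
    f <- lm.fit(cbind(1, N), y)
    R0 <- unname(f$coefficients[1]); th1 <- unname(f$coefficients[2])
    th2 <- NA_real_; sse <- sum(f$residuals^2); k <- 3L
  } else if (model == "hyperbolic") {
    medN <- max(median(N), 1e-6)
    obj <- function(b) .hyperbolic_profile(N, y, exp(b))$sse
    opt <- .multi_start_minimise(obj, starts = log(medN * c(0.1, 0.5, 1, 2, 5)),
                                 lower = log(medN * 1e-6),
                                 upper = log(max(N) * 1e4))
    th2 <- exp(opt$par)
    prof <- .hyperbolic_profile(N, y, th2)
    R0 <- prof$R0; th1 <- prof$theta1; sse <- prof$sse; k <- 4L
  } else {
    lo <- 1e-3; hi <- 1.5 - 1e-6
    obj <- function(a) .power_profile(N, y, a)$sse
    opt <- .multi_start_minimise(obj, starts = c(0.1, 0.3, 0.5, 0.7, 0.9),
                                 lower = lo, upper = hi)
    th1 <- opt$par
    prof <- .power_profile(N, y, th1)
    R0 <- prof$R0; th2 <- prof$theta2; sse <- prof$sse; k <- 4L
  }

  structure(list(model = model, R0 = R0, theta1 = th1, theta2 = th2,
                 sse = sse, n_obs = n, k_params = k,
                 aicc = aicc(sse, n, k)),
            class = "trajectory_fit")
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat(sprintf("trajectory_fit [%s]: R0 = %.5f, theta1 = %.5g, theta2 = %s\n",
              x$model, x$R0, x$theta1,
              if (is.na(x$theta2)) "-" else format(x$theta2, digits = 5)))
  cat(sprintf("  n = %d, k = %d, SSE = %.4g, AICc = %.2f\n",
              x$n_obs, x$k_params, x$sse, x$aicc))
  invisible(x)
}

#' Predicted mean growth rate from a trajectory fit
#'
#' @param object A `trajectory_fit`.
#' @param generation Generations at which to evaluate the mean curve.
#' @param ... Unused.
#' @export
predict.trajectory_fit <- function(object, generation, ...) {
  object$R0 + trajectory_gain(object$model, generation,
                              object$theta1, object$theta2)
}

#' Compare the three trajectory models by AICc
#'
#' Fits linear, power-law and hyperbolic models to the same records and
#' ranks them: `delta_aicc` is each model's AICc above the minimum and
#' `evidence_ratio = exp(0.5 * delta_aicc)` quantifies the evidence against
#' that model relative to the best.  Exact AICc ties are broken in favour
#' of the model with fewer parameters.
#'
#' @inheritParams fit_trajectory
#' @return A `model_comparison` tibble (model, k, sse, aicc, delta_aicc,
#'   evidence_ratio) ordered best first, with the fitted `trajectory_fit`
#'   objects in `attr(, "fits")` and the winner in `attr(, "best")`.
#' @export
compare_trajectory_models <- function(records) {
  models <- c("linear", "power", "hyperbolic")
  fits <- lapply(models, function(m) fit_trajectory(records, m))
  names(fits) <- models
  tab <- tibble::tibble(
    model = models,
    k = vapply(fits, function(f) f$k_params, integer(1), USE.NAMES = FALSE),
    sse = vapply(fits, function(f) f$sse, numeric(1), USE.NAMES = FALSE),
    aicc = vapply(fits, function(f) f$aicc, numeric(1), USE.NAMES = FALSE))
  ord <- order(tab$aicc, tab$k)
  tab <- tab[ord, ]
  ref <- tab$aicc[1]
  tab$delta_aicc <- tab$aicc - ref
  tab$delta_aicc[1] <- 0 # guard -Inf - -Inf
  tab$evidence_ratio <- exp(0.5 * tab$delta_aicc)
  structure(tab, fits = fits, best = tab$model[1],
            class = c("model_comparison", class(tab)))
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Trajectory model comparison (best first):\n")
  print(tibble::as_tibble(x), ...)
  cat("best:", attr(x, "best"), "\n")
  invisible(x)
}

#' Spline-by-factor surrogate for the factorial trajectory model
#'
#' Ordinary least-squares fit of plate-level growth rate on a flexible
#' generation effect and its interactions with genotype (`G`) and evolution
#' temperature (`ET`).  The generation effect is a fixed cubic B-spline
#' basis (default 8 evenly spaced interior knots over the observed
#' generation range, min-max scaled to `[0, 1]` so coefficients are scaled
#' effects); factor terms enter as indicator contrasts, interactions as
#' spline-basis-by-indicator products.  No penalisation or basis selection
#' is done: competing term sets are compared on equal footing by AICc and
#' [evidence_ratio()].
#'
#' @param records Data frame with `generation`, `rate`, and (when used in
#'   `terms`) `genotype`, `evolution_temp` columns.
#' @param terms Character subset of
#'   `c("N", "G", "ET", "N:G", "N:ET", "G:ET", "N:G:ET")` naming the model
#'   terms; the default is the full three-way model.
#' @param n_knots Number of evenly spaced interior knots.
#'
#' @return A `factorial_fit` list: `terms`, `coefficients` tibble (scaled
#'   effects), `sse`, `n_obs`, `k_params`, `aicc`.
#' @export
fit_factorial_surrogate <- function(records,
                                    terms = c("N", "G", "ET", "N:G", "N:ET",
                                              "G:ET", "N:G:ET"),
                                    n_knots = 8) {
  allowed <- c("N", "G", "ET", "N:G", "N:ET", "G:ET", "N:G:ET")
  if (!all(terms %in% allowed)) {
    stop_invalid("unknown terms: ",
                 paste(setdiff(terms, allowed), collapse = ", "))
  }
  need_g <- any(grepl("G", terms)); need_et <- any(grepl("ET", terms))
  cols <- c("generation", "rate", if (need_g) "genotype",
            if (need_et) "evolution_temp")
  if (!all(cols %in% names(records))) {
    stop_invalid("`records` needs columns: ", paste(cols, collapse = ", "))
  }
  df <- data.frame(rate = as.numeric(records$rate))
  u <- as.numeric(records$generation)
  rng <- range(u)
  u <- if (diff(rng) > 0) (u - rng[1]) / diff(rng) else u * 0
  knots <- seq(0, 1, length.out = n_knots + 2)[-c(1, n_knots + 2)]
  df$fN <- splines::bs(u, knots = knots, degree = 3,
                       Boundary.knots = c(0, 1))
  if (need_g) {
    df$G <- factor(records$genotype)
    if (nlevels(df$G) < 2) stop_invalid("need >= 2 genotypes for G terms")
  }
  if (need_et) {
    df$ET <- factor(records$evolution_temp)
    if (nlevels(df$ET) < 2) stop_invalid("need >= 2 evolution temperatures for ET terms")
  }

  map <- c(N = "fN", G = "G", ET = "ET", `N:G` = "fN:G", `N:ET` = "fN:ET",
           `G:ET` = "G:ET", `N:G:ET` = "fN:G:ET")
  rhs <- if (length(terms)) paste(map[terms], collapse = " + ") else "1"
  fit <- lm(stats::as.formula(paste("rate ~", rhs)), data = df)
  cf <- coef(fit)
  if (anyNA(cf)) {
    stop_invalid("rank-deficient design; aliased terms: ",
                 paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  sse <- sum(fit$residuals^2)
  k <- length(cf) + 1L
  structure(
    list(terms = terms,
         coefficients = tibble::tibble(term = names(cf),
                                       estimate = unname(cf)),
         sse = sse, n_obs = length(fit$residuals), k_params = k,
         aicc = aicc(sse, length(fit$residuals), k)),
    class = "factorial_fit")
}

#' @export
print.factorial_fit <- function(x, ...) {
  cat(sprintf("factorial_fit [%s]: n = %d, k = %d, SSE = %.4g, AICc = %.2f\n",
              paste(x$terms, collapse = " + "), x$n_obs, x$k_params,
              x$sse, x$aicc))
  invisible(x)
}
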