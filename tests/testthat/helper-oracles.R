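# Independent oracles used to freeze expected values: each recomputes a
# quantity by brute force / closed form, never through the code path under
# test.

# Best hyperbolic SSE over a dense (theta1, theta2) grid with R0 profiled
# out by closed-form least squares (R0 = mean(y - theta1 * x)).
oracle_hyperbolic_grid_sse <- function(N, y, theta1_range, theta2_range,
                                       n_grid = 200) {
  th1s <- seq(theta1_range[1], theta1_range[2], length.out = n_grid)
  th2s <- seq(theta2_range[1], theta2_range[2], length.out = n_grid)
  best <- Inf
  for (t2 in th2s) {
    x <- N / (t2 + N)
    for (t1 in th1s) {
      r <- y - t1 * x
      sse <- sum((r - mean(r))^2)
      if (sse < best) best <- sse
    }
  }
  best
}

# Textbook balanced nested-ANOVA expected-mean-squares estimate of the
# replicate-within-genotype variance component, computed from raw group
# means: (MS_S(G) - MS_E) / n.
oracle_nested_vc_balanced <- function(values, genotype, replicate) {
  pop <- paste(genotype, replicate)
  n <- unname(table(pop)[1])
  stopifnot(all(table(pop) == n))
  pop_means <- tapply(values, pop, mean)
  pop_geno <- tapply(genotype, pop, `[`, 1)
  geno_means <- tapply(values, genotype, mean)
  a <- length(geno_means)
  b <- length(pop_means) / a
  ss_pop <- n * sum((pop_means - geno_means[pop_geno])^2)
  ms_pop <- ss_pop / (a * (b - 1))
  ss_e <- sum((values - pop_means[pop])^2)
  ms_e <- ss_e / (length(values) - a * b)
  (ms_pop - ms_e) / n
}

# One-way random-effects EMS oracle (possibly unbalanced).
oracle_oneway_vc <- function(values, group) {
  ni <- table(group)
  k <- length(ni); N <- sum(ni)
  gm <- mean(values)
  mi <- tapply(values, group, mean)
  ms_b <- sum(ni * (mi - gm)^2) / (k - 1)
  ms_w <- sum((values - mi[as.character(group)])^2) / (N - k)
  n0 <- (N - sum(ni^2) / N) / (k - 1)
  (ms_b - ms_w) / n0
}

# Brute-force sequential sums of squares for a balanced full-factorial
# design, built from cell/marginal means.
oracle_balanced_factorial_ss <- function(value, f1, f2, f3) {
  gm <- mean(value)
  eff <- function(fac) tapply(value, fac, mean) - gm
  n <- length(value)
  ss_main <- function(fac) {
    m <- tapply(value, fac, mean)
    sum(table(fac) * (m - gm)^2)
  }
  ss_two <- function(a, b) {
    cell <- tapply(value, list(a, b), mean)
    na <- tapply(value, list(a, b), length)
    ma <- tapply(value, a, mean); mb <- tapply(value, b, mean)
    tot <- 0
    for (i in rownames(cell)) for (j in colnames(cell)) {
      tot <- tot + na[i, j] * (cell[i, j] - ma[[i]] - mb[[j]] + gm)^2
    }
    unname(tot)
  }
  list(A = unname(ss_main(f1)), B = unname(ss_main(f2)), C = unname(ss_main(f3)),
       AB = ss_two(f1, f2), AC = ss_two(f1, f3), BC = ss_two(f2, f3))
}

# Small, fast simulation design shared by several tests: coarse assay
# cadence, flat convergence, hyperbolic truth.
small_sim_config <- function(seed, ...) {
  args <- list(
    genotype_baselines = c(A = 0.03, B = 0.045, AxB = 0.05),
    theta1_base = c("24" = 0.07, "37" = 0.07),
    convergence = c("24" = 0, "37" = 0),
    theta2 = c("24" = 500, "37" = 500),
    sigma_replicate = 0.005, sigma_assay = 0.008,
    assay_schedule = seq(0, 6500, by = 250),
    seed = seed)
  do.call(simulation_config, modifyList(args, list(...)))
}
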