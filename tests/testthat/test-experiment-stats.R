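test_that("bin assignment follows the half-open centred convention", {
  expect_equal(assign_bin(130, 250), 250)
  expect_equal(assign_bin(100, 250), 0)
  expect_equal(assign_bin(5600, 1000), 6000)
  # boundaries go to the upper bin
  expect_equal(assign_bin(c(124.999, 125, 374.999, 375), 250),
               c(0, 250, 250, 500))
  expect_equal(assign_bin(c(499.999, 500), 1000), c(0, 1000))
  expect_error(assign_bin(-1), ">= 0")
})

test_that("binned means equal brute-force group means", {
  recs <- tibble::tibble(
    population_id = "p", assay_temp = "37",
    generation = c(10, 110), rate = c(0.1, 0.2))
  b <- bin_records(recs, 250)
  expect_equal(nrow(b), 1L)
  expect_equal(b$mean_rate, 0.15)
  expect_equal(b$bin, 0)

  # record exactly at a boundary joins the upper bin
  recs2 <- tibble::tibble(population_id = "p", assay_temp = "37",
                          generation = 125, rate = 0.3)
  expect_equal(bin_records(recs2, 250)$bin, 250)

  ds <- simulate_evolution_experiment(small_sim_config(101))
  b2 <- bin_records(ds$records, 250)
  key <- paste(ds$records$population_id, ds$records$assay_temp,
               assign_bin(ds$records$generation, 250))
  brute <- tapply(ds$records$rate, key, mean)
  got <- b2$mean_rate[match(names(brute),
                            paste(b2$population_id, b2$assay_temp, b2$bin))]
  expect_equal(as.numeric(got), as.numeric(brute), tolerance = 1e-12)
})

test_that("maximum-increase summaries match their arithmetic definition", {
  binned <- tibble::tibble(bin = c(0, 3000, 6000),
                           mean_rate = c(0.05, 0.12, 0.11))
  inc <- max_increase(binned, ancestor_rate = 0.05)
  expect_equal(inc$absolute_increase, 0.07)
  expect_equal(inc$relative_increase, 140)
  expect_equal(inc$best_bin, 3000)
  flat <- max_increase(tibble::tibble(bin = 0:2 * 1000,
                                      mean_rate = rep(0.06, 3)), 0.06)
  expect_equal(flat$absolute_increase, 0)
  expect_equal(flat$relative_increase, 0)
  expect_error(max_increase(binned, 0), "positive")

  # group summary: simulated hyperbolic populations; mean absolute increase
  # near the curve gain at the best late bin
  ds <- simulate_evolution_experiment(
    small_sim_config(111, sigma_replicate = 0.002, sigma_assay = 0.003))
  b1000 <- bin_records(ds$records, 1000)
  anc <- tibble::tibble(
    population_id = ds$truth$curves$population_id,
    ancestor_rate = ds$truth$curves$R0)
  s <- increase_summary(b1000, anc)
  overall <- s[s$genotype == "Overall", ]
  gain_true <- 0.07 * 6000 / (500 + 6000) # near-asymptotic bin-6000 gain
  expect_true(all(abs(overall$absolute_increase - gain_true) < 0.01))
  expect_true(all(overall$abs_ci_low <= overall$absolute_increase &
                    overall$absolute_increase <= overall$abs_ci_high))
})

test_that("factorial ANOVA reproduces the t-test identity and a brute-force SS oracle", {
  # one factor, two groups: F equals the squared pooled t statistic
  set.seed(121)
  d <- data.frame(value = rnorm(16), G = rep(c("a", "b"), each = 8))
  tab <- factorial_anova(d, "value", "G")
  tt <- t.test(value ~ G, data = d, var.equal = TRUE)
  expect_equal(tab$statistic[1], unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(tab$p_value[1], tt$p.value, tolerance = 1e-10)

  # balanced 3x2x2 x 2 reps: sequential SS equal the cell-mean oracle
  set.seed(122)
  d3 <- expand.grid(G = c("g1", "g2", "g3"), AT = c("24", "37"),
                    ET = c("24", "37"), rep = 1:2)
  d3$value <- rnorm(nrow(d3), mean = 0.1)
  tab3 <- factorial_anova(d3, "value", c("G", "AT", "ET"))
  orc <- oracle_balanced_factorial_ss(d3$value, d3$G, d3$AT, d3$ET)
  get_ss <- function(term) tab3$sumsq[tab3$term == term]
  expect_equal(get_ss("G"), orc$A, tolerance = 1e-10)
  expect_equal(get_ss("AT"), orc$B, tolerance = 1e-10)
  expect_equal(get_ss("ET"), orc$C, tolerance = 1e-10)
  expect_equal(get_ss("G:AT"), orc$AB, tolerance = 1e-10)
  expect_equal(get_ss("G:ET"), orc$AC, tolerance = 1e-10)
  expect_equal(get_ss("AT:ET"), orc$BC, tolerance = 1e-10)
  # df sum to n - 1 and SS are non-negative
  expect_equal(sum(tab3$df), nrow(d3) - 1)
  expect_true(all(tab3$sumsq >= -1e-12))

  # balanced data: sequential and Type-II/III SS agree
  fit <- lm(value ~ G * AT * ET, data = d3)
  t2 <- car::Anova(fit, type = 2)
  seq_ss <- anova(fit)
  for (term in c("G", "AT", "ET", "G:AT", "G:ET", "AT:ET", "G:AT:ET")) {
    expect_equal(seq_ss[term, "Sum Sq"], t2[term, "Sum Sq"], tolerance = 1e-8)
  }

  # empty cell with interactions requested errors with the cell named
  d_bad <- d3[!(d3$G == "g1" & d3$AT == "24"), ]
  expect_error(factorial_anova(d_bad, "value", c("G", "AT", "ET")), "g1 x 24")
})

test_that("nested ANOVA variance components match the textbook EMS oracle", {
  # literal replicate copies: zero replicate VC, infinite repeatability
  base <- data.frame(
    genotype = rep(c("g1", "g2"), each = 8),
    replicate = rep(rep(1:2, each = 4), 2),
    rate = rep(c(0.10, 0.11, 0.09, 0.12, 0.20, 0.21, 0.19, 0.22), 2))
  base$rate <- rep(base$rate[1:8][c(1:4, 1:4)], 2) # identical replicates
  vc0 <- nested_anova_vc(base)
  expect_equal(vc0$vc_replicate, 0)
  expect_identical(vc0$repeatability, Inf)

  # balanced simulated design equals the closed-form (MS_S(G)-MS_E)/n oracle
  set.seed(131)
  for (i in 1:5) {
    d <- expand.grid(genotype = c("g1", "g2", "g3"), replicate = 1:4,
                     obs = 1:6)
    rep_eff <- rnorm(12, 0, 0.01)
    names(rep_eff) <- paste(rep(c("g1", "g2", "g3"), 4), rep(1:4, each = 3))
    d$rate <- 0.1 + rep_eff[paste(d$genotype, d$replicate)] +
      rnorm(nrow(d), 0, 0.005)
    vc <- nested_anova_vc(d)
    orc <- oracle_nested_vc_balanced(d$rate, as.character(d$genotype),
                                     d$replicate)
    expect_equal(vc$vc_replicate, max(0, orc), tolerance = 1e-10)
    expect_equal(vc$n0, 6)
    expect_equal(vc$scaled_vc_replicate, vc$vc_replicate / mean(d$rate)^2,
                 tolerance = 1e-12)
  }

  # VC invariances: location shift leaves components; scaling leaves the
  # mean-scaled component
  d <- expand.grid(genotype = c("g1", "g2"), replicate = 1:3, obs = 1:5)
  set.seed(132)
  d$rate <- 0.1 + rnorm(30, 0, 0.01) +
    rep(rnorm(6, 0, 0.02), times = 5)
  v1 <- nested_anova_vc(d)
  d_shift <- d; d_shift$rate <- d$rate + 5
  expect_equal(nested_anova_vc(d_shift)$vc_replicate, v1$vc_replicate,
               tolerance = 1e-9)
  d_scale <- d; d_scale$rate <- d$rate * 3
  expect_equal(nested_anova_vc(d_scale)$scaled_vc_replicate,
               v1$scaled_vc_replicate, tolerance = 1e-9)

  # moment estimator recovers a known replicate variance on average
  set.seed(133)
  ests <- vapply(1:60, function(i) {
    d <- expand.grid(genotype = c("g1", "g2", "g3"), replicate = 1:4,
                     obs = 1:10)
    re <- rnorm(12, 0, 0.01)
    names(re) <- paste(rep(c("g1", "g2", "g3"), 4), rep(1:4, each = 3))
    d$rate <- 0.1 + re[paste(d$genotype, d$replicate)] + rnorm(120, 0, 0.005)
    nested_anova_vc(d)$vc_replicate
  }, numeric(1))
  expect_lt(abs(mean(ests) - 1e-4) / 1e-4, 0.25)

  expect_error(
    nested_anova_vc(data.frame(genotype = c("g1", "g1"), replicate = c(1, 1),
                               rate = c(1, 2))),
    "replication")
})

test_that("total among-population VC matches the one-way EMS oracle and tracks spread", {
  d <- data.frame(population_id = rep(c("p1", "p2", "p3"), each = 6),
                  rate = rep(c(0.1, 0.1, 0.1), each = 6))
  expect_equal(total_population_vc(d)$vc_replicate, 0)

  set.seed(141)
  for (i in 1:5) {
    d <- data.frame(population_id = rep(paste0("p", 1:8), each = 7),
                    rate = rnorm(56, 0.1, 0.01) +
                      rep(rnorm(8, 0, 0.02), each = 7))
    expect_equal(total_population_vc(d)$vc_replicate,
                 max(0, oracle_oneway_vc(d$rate, d$population_id)),
                 tolerance = 1e-10)
  }

  # component increases with simulated between-population spread
  set.seed(142)
  mean_vc <- vapply(c(0.005, 0.02, 0.05), function(s) {
    mean(vapply(1:40, function(i) {
      d <- data.frame(population_id = rep(paste0("p", 1:6), each = 8),
                      rate = rnorm(48, 0.1, 0.01) + rep(rnorm(6, 0, s), each = 8))
      total_population_vc(d)$vc_replicate
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_vc) > 0))
})

test_that("Levene's test is exact under identical groups and detects variance ratios", {
  g <- list(c(1, 2, 3, 4), c(1, 2, 3, 4))
  lt <- levene_test(g)
  expect_equal(lt$statistic, 0)
  expect_equal(lt$p_value, 1)

  # power against a 3x SD ratio at n = 12 per group
  set.seed(151)
  rej <- mean(vapply(1:200, function(i) {
    levene_test(list(rnorm(12, 0, 1), rnorm(12, 0, 3)))$p_value < 0.05
  }, logical(1)))
  expect_gt(rej, 0.7)
  expect_error(levene_test(list(1, 1:3)), ">= 2 values")
})

test_that("pairwise genotype t tests use the explicit Bonferroni family", {
  # printed 3-significant-figure thresholds
  expect_equal(round(bonferroni_threshold(0.05, 42), 5), 0.00119)
  expect_equal(round(bonferroni_threshold(0.05, 7), 5), 0.00714)
  expect_equal(round(bonferroni_threshold(0.05, 24), 5), 0.00208)

  d <- data.frame(genotype = rep(c("A", "B"), each = 4),
                  mean_rate = rep(c(0.1, 0.12, 0.09, 0.11), 2))
  out <- pairwise_genotype_tests(d, m = 42)
  expect_equal(out$p_value, 1)
  expect_false(out$significant)
  expect_equal(attr(out, "threshold"), 0.05 / 42)

  d2 <- data.frame(genotype = rep(c("A", "B", "C"), each = 4),
                   mean_rate = c(rnorm(4, 0.05, 1e-4), rnorm(4, 0.10, 1e-4),
                                 rnorm(4, 0.15, 1e-4)))
  out2 <- pairwise_genotype_tests(d2, m = 3)
  expect_equal(nrow(out2), 3L)
  expect_true(all(out2$significant))
})

test_that("Tukey-Kramer reduces to the t test for two groups and is null-calm for three", {
  set.seed(161)
  d <- data.frame(value = rnorm(20, 0, 1), group = rep(c("a", "b"), each = 10))
  tk <- tukey_kramer(d)
  tt <- t.test(value ~ group, data = d, var.equal = TRUE)
  # q = t * sqrt(2); the adjusted p equals the unadjusted two-sample p
  expect_equal(tk$q, abs(unname(tt$statistic)) * sqrt(2), tolerance = 1e-10)
  expect_equal(tk$p_value, tt$p.value, tolerance = 1e-7)

  d3 <- data.frame(value = rep(c(1, 2, 3, 4), 3),
                   group = rep(c("a", "b", "c"), each = 4))
  expect_true(all(tukey_kramer(d3)$p_value > 0.999))
  expect_error(tukey_kramer(data.frame(value = 1:2, group = c("a", "b"))),
               ">= 2 values")
})
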