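test_that("estimate_growth recovers exponential and degenerate rates", {
  t <- seq(0, 6, 0.5)
  g <- estimate_growth(t, 0.05 * exp(0.6 * t))
  expect_equal(g$mu_max, 0.6, tolerance = 1e-3)
  expect_equal(g$od_final, 0.05 * exp(3.6))

  expect_equal(estimate_growth(t, rep(1.3, length(t)))$mu_max, 0)

  # logistic: max d ln(OD)/dt = r * (1 - od0/K) at t = 0 for od0 << K;
  # window-averaged slope lands just below the intrinsic rate
  r <- 0.9; K <- 2.5; od0 <- 0.05
  od <- K / (1 + (K / od0 - 1) * exp(-r * t))
  mu <- estimate_growth(t, od, window_points = 4)$mu_max
  num_max <- max(diff(log(od)) / diff(t))
  expect_true(mu >= 0.8 && mu <= 0.9)
  expect_lte(mu, num_max + 1e-9)

  expect_error(estimate_growth(t, c(-1, rep(1, length(t) - 1))), "positive")
  expect_error(estimate_growth(1:3, c(1, 2, 3), window_points = 4), "fewer")
})

test_that("compute_survival arithmetic, duplicates and censoring", {
  s <- compute_survival(c(1e8, 1e8), c(1e8, 1e8))
  expect_equal(s$survival_pct, 100)
  expect_equal(s$robustness, 0)

  s <- compute_survival(1e8, 5.3e6)
  expect_equal(s$survival_pct, 5.3)
  expect_equal(s$robustness, log10(0.053), tolerance = 1e-9)

  # duplicates averaged on the count scale before the ratio
  s <- compute_survival(c(2e8, 1e8), c(1e6, 3e6))
  expect_equal(s$survival_pct, 100 * 2e6 / 1.5e8)

  expect_error(compute_survival(c(1e8, 1e8), c(0, 0)),
               class = "robustsig_censored")
  expect_error(compute_survival(c(0, 1e8), c(1, 1)), "positive")
})

test_that("dynamic_range and its scale invariance", {
  heat_il1403 <- strain_phenotypes("IL1403")$heat_60min_pct
  expect_equal(dynamic_range(heat_il1403), log10(5.3 / 0.000044),
               tolerance = 1e-12)
  expect_equal(dynamic_range(c(7, 7, 7)), 0)
  expect_equal(dynamic_range(c(1, 10, 100)), 2)
  for (k in c(0.01, 3, 250))
    expect_equal(dynamic_range(k * heat_il1403), dynamic_range(heat_il1403),
                 tolerance = 1e-9)
  expect_error(dynamic_range(c(1, 0)), "positive")
  expect_error(dynamic_range(5), "at least 2")
})

test_that("select_timepoint maximizes dynamic range with earlier-tie break", {
  expect_equal(select_timepoint(list(`10` = c(1, 1000), `30` = c(1, 100))), 10)
  expect_equal(select_timepoint(list(`30` = c(1, 100), `10` = c(1, 1000))), 10)
  expect_equal(select_timepoint(list(`60` = c(1, 10))), 60)
  expect_equal(select_timepoint(list(`30` = c(1, 50), `10` = c(1, 50))), 10)
  expect_error(select_timepoint(list()), "no timepoints")
})

test_that("pearson wrapper: exact cases, symmetry, affine invariance", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(pearson(x, 2 * x), 1.0)
  expect_equal(pearson(x, -x), -1.0)
  set.seed(11)
  for (i in 1:20) {
    a <- rnorm(10); b <- rnorm(10)
    expect_equal(pearson(a, b), pearson(b, a))
    expect_equal(pearson(2.5 * a + 3, b), pearson(a, b), tolerance = 1e-12)
  }
  expect_error(pearson(c(1, 1, 1), c(1, 2, 3)), "variance")
})

test_that("parameter_effect_ttest matches R's Welch t.test", {
  set.seed(21)
  for (i in 1:25) {
    v <- rnorm(13); g <- factor(sample(c("a", "b"), 13, TRUE,
                                       prob = c(0.45, 0.55)))
    if (min(table(g)) < 2) next
    ours <- parameter_effect_ttest(v, g)
    ref <- t.test(v ~ g)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
    expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-9)
  }
  ident <- parameter_effect_ttest(rep(c(1, 1), 2), factor(c("a", "a", "b", "b")))
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
  expect_error(parameter_effect_ttest(1:3, factor(c("a", "a", "b"))), ">= 2")
})

test_that("t-test type-I error is calibrated at ~5% over 10,000 null draws", {
  set.seed(31)
  n1 <- 6L; n2 <- 7L
  reject <- logical(10000L)
  g <- factor(rep(c("a", "b"), c(n1, n2)))
  for (i in seq_along(reject)) {
    reject[i] <- parameter_effect_ttest(rnorm(n1 + n2), g)$p < 0.05
  }
  expect_gte(mean(reject), 0.035)
  expect_lte(mean(reject), 0.065)
})

test_that("phenotype_report reproduces published strain-level statistics", {
  rp <- phenotype_report(strain_phenotypes("SK11"))
  corr <- subset(rp$correlations, stress == "oxidative" & timepoint_min == 30)
  expect_equal(abs(corr$pearson_mu), 0.79, tolerance = 0.01)

  # initial pH is the dominant effect on final biomass in all strains
  # (frozen Welch P-values computed with stats::t.test beforehand)
  frozen_p <- c(IL1403 = 0.0001537814, KF147 = 0.0002617243, SK11 = 0.002434818)
  for (s in strain_names()) {
    tt <- phenotype_report(strain_phenotypes(s))$parameter_tests
    p <- subset(tt, parameter == "initial_pH" & response == "od_final")$p
    expect_equal(p, unname(frozen_p[s]), tolerance = 1e-5)
    expect_lt(p, 0.05)
  }
  # high oxygen raises KF147 heat robustness (t ~ 3.9)
  kf <- phenotype_report(strain_phenotypes("KF147"))$parameter_tests
  ox <- subset(kf, parameter == "oxygen" & response == "heat_10min")
  expect_lt(ox$p, 0.01)
  expect_equal(abs(ox$t), 3.9, tolerance = 0.1)
})

test_that("survival->dynamic range converges to the planted spread", {
  # noise-free world, large counts: CFU-derived range matches the target
  sim <- generate_phenotypes(noise_sd = 1e-9, dynamic_range_target = 4,
                             n0 = 1e8, seed = 5)
  heat <- sim$table[sim$table$stress == "heat" & sim$table$timepoint_min == 10, ]
  expect_equal(dynamic_range(heat$survival_pct), 4, tolerance = 0.01)
})
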