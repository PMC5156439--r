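test_that("generators are seed-deterministic", {
  a <- generate_phenotypes(seed = 9)
  b <- generate_phenotypes(seed = 9)
  expect_identical(a, b)
  ra <- a$true_robustness$heat
  ea <- generate_expression(ra, 50, seed = 9)
  expect_identical(ea, generate_expression(ra, 50, seed = 9))
  pa <- generate_probe_intensities(ea$expr, 2, seed = 9)
  expect_identical(pa, generate_probe_intensities(ea$expr, 2, seed = 9))
  oa <- generate_og_map(c("s1", "s2", "s3"), 40, 0.6, seed = 9)
  expect_identical(oa, generate_og_map(c("s1", "s2", "s3"), 40, 0.6, seed = 9))
})

test_that("phenotype generator: degenerate profile, range control, errors", {
  flat <- generate_phenotypes(
    response_profile = list(heat = c(oxygen = 0), oxidative = c(salt = 0)),
    dynamic_range_target = NULL, noise_sd = 0, seed = 2)
  heat <- flat$table[flat$table$stress == "heat" & flat$table$timepoint_min == 10, ]
  expect_equal(diff(range(heat$true_robustness)), 0)
  expect_lt(dynamic_range(heat$survival_pct), 0.01)  # Poisson jitter only

  sim <- generate_phenotypes(dynamic_range_target = 5, seed = 3)
  for (stress in c("heat", "oxidative")) {
    t1 <- min(sim$table$timepoint_min[sim$table$stress == stress])
    s <- sim$table[sim$table$stress == stress & sim$table$timepoint_min == t1, ]
    expect_true(abs(dynamic_range(s$survival_pct) - 5) <= 1)
  }

  expect_error(generate_phenotypes(dynamic_range_target = -1), "positive")
  expect_error(generate_phenotypes(timepoints = list(heat = 10, oxidative = c(30, 60))),
               "at least 2 timepoints")
})

test_that("survival percent and robustness stay consistent pre-discretization", {
  sim <- generate_phenotypes(seed = 13)
  expect_equal(sim$table$true_robustness,
               log10(sim$table$true_survival_pct / 100), tolerance = 1e-9)
  ok <- !sim$table$censored
  expect_equal(sim$table$robustness[ok],
               log10(sim$table$survival_pct[ok] / 100), tolerance = 1e-9)
})

test_that("Poisson CFU sampling is unbiased at high counts", {
  # mean duplicate-derived survival across many draws within 5% of truth
  sims <- vapply(1:1000, function(s) {
    set.seed(s)
    n0 <- rpois(2, 1e6); nt <- rpois(2, 1e6 * 10^-1.5)
    compute_survival(n0, nt)$survival_pct
  }, 0)
  expect_equal(mean(sims), 100 * 10^-1.5, tolerance = 0.05)
})

test_that("a planted binary effect is detectable at the stated power", {
  # oxygen +1.8 log10 on heat robustness, noise 0.3: Welch p < 0.05 in
  # >= 95% of 100 seeds
  design <- fermentation_design()
  hits <- vapply(1:100, function(s) {
    sim <- generate_phenotypes(
      response_profile = list(heat = c(oxygen = 1.8), oxidative = c(oxygen = 1.8)),
      dynamic_range_target = NULL, noise_sd = 0.3, seed = s)
    h <- sim$table[sim$table$stress == "heat" & sim$table$timepoint_min == 10, ]
    parameter_effect_ttest(h$true_robustness, design$oxygen)$p < 0.05
  }, NA)
  expect_gte(mean(hits), 0.95)
})

test_that("expression generator plants exact linear signal", {
  r <- seq(-5, 0, length.out = 13)
  ge <- generate_expression(r, 30, planted_slopes = c(g05 = 2), noise_sd = 1e-9,
                            seed = 4)
  fit <- fit_gene_linear(ge$expr["g05", ], r)
  expect_equal(fit$slope, 2, tolerance = 1e-6)
  expect_lt(fit$p_value, 1e-10)
  expect_error(generate_expression(r, 10, n_planted = 11), "n_genes")
  expect_error(generate_expression(r, 10, planted_slopes = c(g01 = 0)), "nonzero")
})

test_that("loop design is connected and probe maps have the right shape", {
  d <- loop_design()
  expect_true(design_connected(d))
  expect_setequal(unique(c(d$cy5, d$cy3)), 1:13)
  # each sample appears at least once per dye within its loop
  expect_true(all(1:13 %in% d$cy5) && all(1:13 %in% d$cy3))

  disconnected <- data.frame(array_id = c("A1", "A2"),
                             cy5 = c(1, 3), cy3 = c(2, 4))
  expect_false(design_connected(disconnected))

  ge <- generate_expression(seq(-3, 0, length.out = 13), 40, seed = 6)
  pr <- generate_probe_intensities(ge$expr, probes_per_gene = 3, seed = 6)
  expect_equal(nrow(pr$probe_map), 3 * 40)
  expect_true(all(table(pr$probe_map$orf_id) == 3))
  expect_error(
    generate_probe_intensities(ge$expr,
                               design = data.frame(array_id = "A1", cy5 = 1, cy3 = 99)),
    "unknown fermentation")
})

test_that("noiseless identity channel preserves log-ratios exactly", {
  ge <- generate_expression(seq(-4, 0, length.out = 13), 25, seed = 8)
  pr <- generate_probe_intensities(ge$expr, probes_per_gene = 1,
                                   dye_bias = function(A) 0, noise_sd = 0, seed = 8)
  ma <- ma_transform(pr$intensities$cy5, pr$intensities$cy3)
  d <- pr$design
  for (h in seq_len(nrow(d))) {
    i <- pr$intensities$array_id == d$array_id[h]
    truth <- ge$expr[, as.character(d$cy5[h])] - ge$expr[, as.character(d$cy3[h])]
    expect_equal(ma$M[i], unname(truth[sub("_p1$", "", pr$intensities$probe_id[i])]),
                 tolerance = 1e-9)
  }
})

test_that("og map respects sharing fraction and uniqueness", {
  og <- generate_og_map(paste0("s", 1:4), 50, fraction_shared = 1, seed = 2)
  expect_true(all(stats::complete.cases(og)))
  for (s in paste0("s", 1:4)) expect_false(anyDuplicated(og[[s]]) > 0)

  og0 <- generate_og_map(paste0("s", 1:4), 50, fraction_shared = 0, seed = 2)
  expect_true(all(rowSums(is.na(og0[paste0("s", 1:4)])) >= 1))

  og5 <- generate_og_map(paste0("s", 1:3), 200, fraction_shared = 0.5, seed = 2)
  expect_equal(sum(stats::complete.cases(og5)), 100)
})
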