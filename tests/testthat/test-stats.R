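test_that("pinball loss matches its closed form", {
  expect_equal(pinball_loss(c(0, 0, 0), 0.5), 0)
  expect_equal(pinball_loss(c(1, -1), 0.5), 1)
  expect_equal(pinball_loss(c(2, -3), 0.9), 2 * 0.9 + 3 * 0.1)
  expect_error(pinball_loss(1, 0), class = "ergkit_invalid_argument")
  expect_error(pinball_loss(1, 1), class = "ergkit_invalid_argument")
})

test_that("fit_quantile solves exact special cases", {
  # intercept-only: the sample median (odd n, exact)
  f <- fit_quantile(matrix(1, 3, 1), c(1, 2, 3))
  expect_equal(f$coefficients, 2, tolerance = 1e-9)
  set.seed(5)
  for (i in 1:20) {
    y <- rnorm(2 * sample(3:15, 1) + 1, sd = 10)
    f <- fit_quantile(matrix(1, length(y), 1), y)
    expect_equal(f$coefficients, median(y), tolerance = 1e-9)
  }
  # perfect linear fit: zero loss
  x <- seq(-3, 3, length.out = 20)
  f2 <- fit_quantile(cbind(1, x), 2 * x)
  expect_equal(f2$coefficients, c(0, 2), tolerance = 1e-7)
  expect_lt(f2$loss, 1e-7)
})

test_that("fit_quantile beats a coefficient grid on random data", {
  set.seed(6)
  for (i in 1:5) {
    n <- 40
    x <- runif(n)
    y <- 1 + 2 * x + rt(n, df = 3)
    tau <- sample(c(0.25, 0.5, 0.75), 1)
    f <- fit_quantile(cbind(1, x), y, tau)
    grid <- expand.grid(b0 = seq(-2, 4, length.out = 50),
                        b1 = seq(-2, 6, length.out = 50))
    gl <- apply(grid, 1, function(b) pinball_loss(y - b[1] - b[2] * x, tau))
    expect_lte(f$loss, min(gl) + 1e-9)
  }
})

test_that("rank-deficient designs are flagged degenerate", {
  X <- cbind(1, c(1, 1, 1, 1), c(2, 2, 2, 2))
  f <- fit_quantile(X, rnorm(4))
  expect_true(f$degenerate)
  expect_error(fit_quantile(cbind(1, 1:2), rnorm(3)),
               class = "ergkit_invalid_argument")
  expect_error(fit_quantile(matrix(1, 3, 1), c(1, NA, 3)),
               class = "ergkit_invalid_argument")
})

test_that("bonferroni threshold is alpha / m and prints as 0.0063", {
  expect_equal(bonferroni_threshold(0.05, 8), 0.00625)
  expect_equal(sprintf("%.4f", bonferroni_threshold(0.05, 8)), "0.0063")
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 5), 0.002)
  expect_error(bonferroni_threshold(1.5, 8), class = "ergkit_invalid_argument")
})

test_that("bootstrap median CIs are degenerate-safe and seed-deterministic", {
  expect_equal(bootstrap_median_ci(rep(7, 10), 500, seed = 1), c(7, 7))
  x <- rnorm(30)
  expect_identical(bootstrap_median_ci(x, 1000, seed = 3),
                   bootstrap_median_ci(x, 1000, seed = 3))
  expect_false(identical(bootstrap_median_ci(x, 1000, seed = 3),
                         bootstrap_median_ci(x, 1000, seed = 4)))
  expect_error(bootstrap_median_ci(1), class = "ergkit_invalid_argument")
  expect_error(bootstrap_median_ci(1:5, n_boot = 50),
               class = "ergkit_invalid_argument")
})

test_that("spearman correlation matches rank oracles and is monotone-invariant", {
  expect_equal(spearman_cor(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_cor(1:10, -(1:10))$rho, -1)
  expect_equal(spearman_cor(1:5, c(3, 1, 2, 5, 4))$rho, 0.6)
  set.seed(8)
  for (i in 1:10) {
    x <- rnorm(20); y <- rnorm(20)
    s <- spearman_cor(x, y)
    expect_equal(s$rho, cor(x, y, method = "spearman"))
    # strictly monotone transforms leave rho unchanged
    expect_equal(spearman_cor(exp(x), y)$rho, s$rho)
    expect_equal(spearman_cor(x, 2 * atan(y) + 5)$rho, s$rho)
  }
  expect_equal(spearman_cor(rep(1, 5), 1:5)$flags, "undefined_rho")
  expect_error(spearman_cor(1:2, 1:2), class = "ergkit_invalid_argument")
})

test_that("identical groups give a zero estimate and boundary p-value", {
  cfg <- tiny_config(noise_sd = 0, animal_sd = 0, adaptations = "DA")
  tab <- extract_all(synth_cohort(cfg)$recordings, components = c("a", "b"))
  cmp <- compare_groups_overall(tab, "b", "DA", "amplitude",
                                n_boot = 1000, seed = 1)
  expect_equal(cmp$estimate, 0, tolerance = 1e-8)
  expect_equal(cmp$p_value, 1)
})

test_that("the overall comparison is seed-deterministic and validates input", {
  cfg <- tiny_config(noise_sd = 4, seed = 31, adaptations = "DA")
  tab <- extract_all(synth_cohort(cfg)$recordings, components = c("a", "b"))
  c1 <- compare_groups_overall(tab, "b", "DA", "amplitude", 1000, seed = 2)
  c2 <- compare_groups_overall(tab, "b", "DA", "amplitude", 1000, seed = 2)
  expect_identical(c1$ci95, c2$ci95)
  expect_identical(c1$p_value, c2$p_value)
  solo <- tab[tab$animal_id %in% c("wt01", "tg01", "tg02"), ]
  expect_error(compare_groups_overall(measurement_table(solo), "b", "DA",
                                      n_boot = 1000),
               class = "ergkit_invalid_argument")
  expect_error(compare_groups_overall(tab, "b", "DA", n_boot = 200),
               class = "ergkit_invalid_argument")
})

test_that("group-effect estimation is shift-equivariant", {
  cfg <- tiny_config(noise_sd = 0, animal_sd = 0.1, seed = 33,
                     adaptations = "DA")
  tab <- extract_all(synth_cohort(cfg)$recordings, components = c("a", "b"))
  base <- compare_groups_overall(tab, "b", "DA", "amplitude", 1000, seed = 5)
  shifted <- tab
  is_m <- shifted$group == "MODEL"
  shifted$b_amp[is_m] <- shifted$b_amp[is_m] + 57.3
  cmp <- compare_groups_overall(measurement_table(shifted), "b", "DA",
                                "amplitude", 1000, seed = 5)
  # exact up to LP-optimum non-uniqueness: repeated design rows create a tie
  # face along which beta0 + beta1 is constant, so the group coefficient is
  # determined only to within the width of that face (~0.02 uV here)
  expect_equal(cmp$estimate, base$estimate + 57.3, tolerance = 0.05)
})

test_that("LA analyses exclude dim flashes and flagged implicit times", {
  cfg <- tiny_config(noise_sd = 4, seed = 35, adaptations = "LA")
  tab <- extract_all(synth_cohort(cfg)$recordings)
  cmp <- compare_groups_overall(tab, "b", "LA", "amplitude", 1000, seed = 1)
  # protocol c(0.1, 1, 3, 25): the 0.1 stratum is excluded (< 1.0)
  expect_equal(cmp$n_rows, 4 * 3)
  sub <- ergkit:::analysis_rows(tab, "phnr", "it", "LA")
  expect_true(all(sub$luminance >= 1))
})

test_that("per-luminance comparisons apply the Bonferroni two-tier rule", {
  eff <- group_effects("b", "DA", amplitude_shift = 200)
  cfg <- sim_config(n_wt = 6, n_model = 6, protocol = c(0.3, 3, 25),
                    adaptations = "DA", noise_sd = 6, seed = 41,
                    effects = eff)
  tab <- extract_all(synth_cohort(cfg)$recordings, components = c("a", "b"))
  res <- compare_groups_per_luminance(tab, "b", "DA", "amplitude",
                                      alpha = 0.05, m = 8, n_boot = 1000,
                                      seed = 3)
  expect_equal(attr(res, "bonferroni_threshold"), 0.00625)
  expect_equal(nrow(res), 3)
  # bonferroni flags are a subset of nominal flags
  expect_true(all(!res$significant_bonferroni | res$significant_nominal))
  expect_true(all(res$estimate < -100))

  # a stratum with < 2 animals per group is flagged, not fatal
  drop <- tab[!(tab$group == "WT" & tab$luminance == 3), ]
  res2 <- compare_groups_per_luminance(measurement_table(drop), "b", "DA",
                                       n_boot = 1000, seed = 3)
  expect_equal(res2$flag[res2$luminance == 3], "insufficient_stratum")
})
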