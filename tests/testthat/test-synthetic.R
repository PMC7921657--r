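test_that("naka_rushton satisfies its defining identities", {
  expect_equal(naka_rushton(1, 100, 1), 50)           # I = K -> vmax/2
  expect_equal(naka_rushton(2, 100, 1, 2), 80)        # 100 * 4 / (4 + 1)
  expect_gt(naka_rushton(100, 100, 1, 1), 99)         # asymptote within 1%
  # strictly increasing, bounded by vmax
  I <- 10^seq(-3, 3, length.out = 50)
  v <- naka_rushton(I, 250, 0.5, 0.8)
  expect_true(all(diff(v) > 0))
  expect_true(all(v < 250))
  expect_error(naka_rushton(-1, 100, 1), class = "ergkit_invalid_argument")
  expect_error(naka_rushton(1, 0, 1), class = "ergkit_invalid_argument")
})

test_that("all-zero configuration yields the zero trace", {
  comps <- default_components()
  for (ad in c("DA", "LA")) {
    for (cp in names(comps[[ad]])) comps[[ad]][[cp]]$peak_amp <- 0
  }
  cfg <- sim_config(components = comps, noise_sd = 0, animal_sd = 0)
  w <- synth_waveform(cfg, adaptation = "LA", luminance = 3)
  expect_equal(max(abs(w$recording$voltage)), 0)
})

test_that("isolated kernels reproduce configured amplitude and peak time", {
  comps <- default_components()
  for (ad in c("DA", "LA")) {
    for (cp in names(comps[[ad]])) comps[[ad]][[cp]]$peak_amp <- 0
  }
  # b-wave-only: vmax 300 at I >> K gives a 300 uV maximum at the peak time
  comps$DA$b <- component_params(300, 45, 13, nr_semisat = 0.05,
                                 nr_exponent = 0.7, latency_slope = 0)
  cfg <- sim_config(components = comps, noise_sd = 0, animal_sd = 0)
  w <- synth_waveform(cfg, adaptation = "DA", luminance = 2500)
  rec <- w$recording
  i <- which.max(rec$voltage)
  expect_equal(rec$voltage[i], 300, tolerance = 0.5 / 300)
  expect_lt(abs(rec$time[i] - 45), 1000 / cfg$sampling_rate + 1e-9)

  # a-wave-only: trough equals the negated configured amplitude
  comps$DA$b$peak_amp <- 0
  comps$DA$a <- component_params(150, 14, 4.5, nr_semisat = 1)
  cfg <- sim_config(components = comps, noise_sd = 0, animal_sd = 0)
  w <- synth_waveform(cfg, adaptation = "DA", luminance = 1000)
  rec <- w$recording
  i <- which.min(rec$voltage)
  expect_equal(rec$voltage[i], -150, tolerance = 0.5 / 150)
  expect_lt(abs(rec$time[i] - 14), 1000 / cfg$sampling_rate + 1e-9)
})

test_that("waveform generation is deterministic given a seed", {
  cfg <- sim_config(noise_sd = 8)
  w1 <- synth_waveform(cfg, seed = 7)
  w2 <- synth_waveform(cfg, seed = 7)
  expect_identical(w1$recording$voltage, w2$recording$voltage)
  w3 <- synth_waveform(cfg, seed = 8)
  expect_false(identical(w1$recording$voltage, w3$recording$voltage))
})

test_that("cohorts have the full factorial shape and reproduce from seed", {
  cfg <- sim_config(n_wt = 2, n_model = 3, seed = 5)
  co <- synth_cohort(cfg)
  expect_length(co$recordings, 5 * 8 * 2)
  expect_equal(nrow(co$truth), 80)
  co2 <- synth_cohort(cfg)
  expect_identical(
    serialize(lapply(co$recordings, `[[`, "voltage"), NULL),
    serialize(lapply(co2$recordings, `[[`, "voltage"), NULL))
})

test_that("null effects with zero variability make the groups identical", {
  cfg <- tiny_config(noise_sd = 0, animal_sd = 0)
  co <- synth_cohort(cfg)
  for (ad in cfg$adaptations) {
    for (lum in cfg$protocol) {
      wt <- co$recordings[[paste("wt01", ad, lum, sep = "|")]]
      tg <- co$recordings[[paste("tg01", ad, lum, sep = "|")]]
      expect_identical(wt$voltage, tg$voltage)
    }
  }
})

test_that("amplitude effects scale the MODEL ground truth monotonically", {
  eff <- group_effects("b", "DA", amplitude_scale = 0.6)
  cfg <- tiny_config(noise_sd = 0, animal_sd = 0, effects = eff)
  tr <- synth_cohort(cfg)$truth
  da <- tr[tr$adaptation == "DA", ]
  for (lum in cfg$protocol) {
    wt <- da[da$group == "WT" & da$luminance == lum, ]
    tg <- da[da$group == "MODEL" & da$luminance == lum, ]
    expect_true(all(tg$b_amp < wt$b_amp))
    expect_equal(tg$b_amp[1], 0.6 * wt$b_amp[1])
  }
})

test_that("ground-truth b-wave amplitude is non-decreasing in luminance", {
  cfg <- sim_config(n_wt = 1, n_model = 1, noise_sd = 0, animal_sd = 0)
  tr <- synth_cohort(cfg)$truth
  for (ad in c("DA", "LA")) {
    for (grp in c("WT", "MODEL")) {
      s <- tr[tr$adaptation == ad & tr$group == grp, ]
      s <- s[order(s$luminance), ]
      expect_true(all(diff(s$b_amp) >= 0))
      expect_true(all(diff(s$b_amp_conv) >= -0.5))
    }
  }
})

test_that("noise-free extrema match convention ground truth", {
  cfg <- tiny_config(noise_sd = 0, animal_sd = 0.2, seed = 8)
  co <- synth_cohort(cfg)
  # spot-check: measured extrema of the smoothed composite equal *_conv
  lp <- design_lowpass_filter(cfg$sampling_rate, 60)
  for (key in sample(names(co$recordings), 6)) {
    rec <- co$recordings[[key]]
    tr <- co$truth[co$truth$animal_id == rec$animal_id &
                     co$truth$adaptation == rec$stimulus$adaptation &
                     co$truth$luminance == rec$stimulus$luminance, ]
    vs <- apply_fir(rec$voltage, lp)
    win <- if (rec$stimulus$adaptation == "DA") c(0, 50) else c(0, 30)
    o <- bf_min(rec$time, vs, win[1], win[2])
    expect_equal(max(0, -o$value), tr$a_amp_conv, tolerance = 1e-6)
  }
})

test_that("the biomarker link is monotone and seed-stable", {
  cfg <- tiny_config(noise_sd = 0, animal_sd = 0.3, seed = 3)
  tr <- synth_cohort(cfg)$truth
  bm <- synth_biomarker(tr, link_strength = 0.05, noise_sd = 0)
  bw <- tr[tr$adaptation == "DA" & tr$luminance == 3, ]
  bw <- bw[match(bm$animal_id, bw$animal_id), ]
  expect_equal(spearman_cor(bm$abeta_concentration, bw$b_amp)$rho, -1)

  bm0 <- synth_biomarker(tr, link_strength = 0, noise_sd = 2, seed = 1)
  bm0b <- synth_biomarker(tr, link_strength = 0, noise_sd = 2, seed = 1)
  expect_identical(bm0$abeta_concentration, bm0b$abeta_concentration)
  # zero link: concentrations are independent of the amplitudes (same seed,
  # different amplitudes, identical concentrations)
  tr2 <- tr; tr2$b_amp <- tr2$b_amp * 0.5
  bm0c <- synth_biomarker(tr2, link_strength = 0, noise_sd = 2, seed = 1)
  expect_identical(bm0$abeta_concentration, bm0c$abeta_concentration)
  expect_error(synth_biomarker(tr[tr$adaptation == "LA", ]),
               class = "ergkit_invalid_argument")
})

test_that("biomarker correlation is negative in >= 95% of seeds at n = 11", {
  cfg <- sim_config(n_wt = 5, n_model = 6, adaptations = "DA",
                    protocol = c(1, 3), noise_sd = 0, seed = 21)
  tr <- synth_cohort(cfg)$truth
  neg <- vapply(1:200, function(s) {
    bm <- synth_biomarker(tr, seed = s)
    bw <- tr[tr$adaptation == "DA" & tr$luminance == 3, ]
    bw <- bw[match(bm$animal_id, bw$animal_id), ]
    spearman_cor(bm$abeta_concentration, bw$b_amp)$rho < 0
  }, logical(1))
  expect_gte(mean(neg), 0.95)
})

test_that("configuration contracts reject invalid worlds", {
  expect_error(sim_config(n_wt = 0), class = "ergkit_invalid_argument")
  expect_error(sim_config(noise_sd = -1), class = "ergkit_invalid_argument")
  expect_error(sim_config(sampling_rate = 500),
               class = "ergkit_invalid_argument")
  expect_error(sim_config(sampling_rate = 700, op_frequency = 400),
               class = "ergkit_invalid_argument")
  expect_error(group_effects("b", "DA", amplitude_scale = -1),
               class = "ergkit_invalid_argument")
  expect_error(group_effects("c", "DA"), class = "ergkit_invalid_argument")
})
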