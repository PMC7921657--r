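# Measurement operators are exercised on hand-built traces (no smoothing:
# window_config(smooth_cutoff = 0) leaves measure_* reading the raw samples,
# so brute-force scans are exact oracles).

raw_windows <- window_config(smooth_cutoff = 0)

test_that("baseline correction zeroes the pre-flash mean and is idempotent", {
  rec <- make_recording(rep(50, 121))
  out <- baseline_correct(rec)
  expect_equal(out$voltage, rep(0, 121))
  expect_equal(baseline_correct(out)$voltage, out$voltage)

  # ramp crossing the window: resulting baseline mean is 0 (direct average)
  rec2 <- make_recording(seq(-30, 90, by = 1))
  out2 <- baseline_correct(rec2, c(-20, 0))
  sel <- out2$time >= -20 & out2$time < 0
  expect_equal(mean(out2$voltage[sel]), 0, tolerance = 1e-9)

  expect_error(baseline_correct(rec, c(-200, -150)),
               class = "ergkit_invalid_argument")
})

test_that("a-wave measurement finds the windowed trough", {
  t <- seq(-20, 100, by = 1)
  # trough -150 uV at 14 ms
  rec <- make_recording(gauss_trace(t, list(list(at = 14, sd = 4, amp = -150),
                                            list(at = 45, sd = 12, amp = 300))))
  a <- measure_a_wave(rec, raw_windows)
  expect_equal(a$a_it, 14)
  expect_equal(a$a_amp, 150, tolerance = 0.5)
  expect_length(a$flags, 0)

  # early trough at 12 ms plus a deeper post-b negativity outside a_search
  v <- gauss_trace(t, list(list(at = 12, sd = 3, amp = -80),
                           list(at = 80, sd = 6, amp = -200)))
  a2 <- measure_a_wave(make_recording(v), raw_windows)
  expect_equal(a2$a_it, 12)
  expect_equal(a2$a_amp, 80, tolerance = 0.5)

  z <- measure_a_wave(make_recording(numeric(121)), raw_windows)
  expect_equal(z$a_amp, 0)
  expect_true("a_absent" %in% z$flags)
})

test_that("fixed-time a-wave reads 6 ms (DA) / 5 ms (LA) with interpolation", {
  t <- seq(-20, 100, by = 1)
  v <- gauss_trace(t, list(list(at = 8, sd = 5, amp = -60)))
  da <- make_recording(v, adaptation = "DA")
  la <- make_recording(v, adaptation = "LA", luminance = 3)
  rda <- measure_a_wave_fixed_time(da, raw_windows)
  rla <- measure_a_wave_fixed_time(la, raw_windows)
  expect_equal(rda$a_fixed_amp, -v[t == 6][1])
  expect_equal(rla$a_fixed_amp, -v[t == 5][1])
  expect_gt(rda$a_fixed_amp, rla$a_fixed_amp)  # asymmetric lobe

  # grid without a sample at exactly 6 ms: linear interpolation oracle
  fs <- 400                                    # 2.5 ms spacing
  t2 <- seq(-20, 100, by = 1000 / fs)
  v2 <- gauss_trace(t2, list(list(at = 9, sd = 5, amp = -60)))
  rec2 <- make_recording(v2, fs = fs)
  r2 <- measure_a_wave_fixed_time(rec2, raw_windows)
  lo <- max(which(t2 <= 6)); hi <- lo + 1
  expected <- v2[lo] + (v2[hi] - v2[lo]) * (6 - t2[lo]) / (t2[hi] - t2[lo])
  expect_equal(r2$a_fixed_amp, -expected, tolerance = 1e-12)

  expect_equal(measure_a_wave_fixed_time(
    make_recording(rep(10, 121)), raw_windows)$flags, "a_fixed_absent")
})

test_that("b-wave is measured trough-to-peak with flag propagation", {
  t <- seq(-20, 160, by = 1)
  v <- gauss_trace(t, list(list(at = 12, sd = 4, amp = -100),
                           list(at = 45, sd = 12, amp = 300)))
  rec <- make_recording(v)
  a <- measure_a_wave(rec, raw_windows)
  b <- measure_b_wave(rec, a, raw_windows)
  expect_equal(b$b_it, 45)
  expect_equal(b$b_amp, v[t == 45] - v[t == 12])
  expect_gt(b$b_amp, 390)

  # absent a-wave: measured from the 0 uV baseline
  v2 <- gauss_trace(t, list(list(at = 50, sd = 15, amp = 200)))
  rec2 <- make_recording(v2)
  a2 <- measure_a_wave(rec2, raw_windows)
  b2 <- measure_b_wave(rec2, a2, raw_windows)
  expect_true("a_absent" %in% b2$flags)
  expect_equal(b2$b_amp, max(v2), tolerance = 1e-9)

  z <- measure_b_wave(make_recording(numeric(181)),
                      measure_a_wave(make_recording(numeric(181)),
                                     raw_windows),
                      raw_windows)
  expect_equal(z$b_amp, 0)
  expect_true("b_absent" %in% z$flags)
})

test_that("oscillatory potentials are recovered at injected positions", {
  fs <- 2000
  t <- seq(-20, 250, by = 1000 / fs)
  centers <- c(17, 24, 31, 38)
  v <- gauss_trace(t, list(list(at = 50, sd = 15, amp = 300)))
  for (c0 in centers) {
    v <- v + 40 * exp(-(t - c0)^2 / (2 * 3^2)) *
      cos(2 * pi * 140 * (t - c0) / 1000)
  }
  rec <- make_recording(v, fs = fs)
  ops <- extract_ops(rec, windows = raw_windows)
  expect_true(ops$present)
  expect_length(ops$peak_times, 4)
  expect_lt(max(abs(ops$peak_times - centers)), 1000 / fs + 1e-9)
  expect_true(all(diff(ops$peak_times) > 0))
  expect_true(all(ops$amplitudes > 0))

  # all energy below 50 Hz: no OPs
  slow <- make_recording(gauss_trace(t, list(list(at = 50, sd = 15,
                                                  amp = 300))), fs = fs)
  ops2 <- extract_ops(slow, windows = raw_windows)
  expect_false(ops2$present)
  expect_true("ops_absent" %in% ops2$flags)
})

test_that("default high-luminance DA synthetic waveforms yield exactly 4 OPs", {
  cfg <- sim_config(noise_sd = 0, animal_sd = 0)
  w <- synth_waveform(cfg, adaptation = "DA", luminance = 25)
  ops <- extract_ops(w$recording)
  expect_true(ops$present)
  expect_length(ops$peak_times, 4)
  # and with the default noise level under a fixed seed
  wn <- synth_waveform(cfg <- sim_config(noise_sd = 8), adaptation = "DA",
                       luminance = 25, seed = 2)
  opsn <- extract_ops(wn$recording)
  expect_true(opsn$present)
  expect_length(opsn$peak_times, 4)
})

test_that("summarize_ops averages amplitudes and sums peak times", {
  ops <- structure(list(present = TRUE, peak_times = c(17, 24, 31, 38),
                        amplitudes = c(10, 20, 30, 40), flags = character()),
                   class = "op_set")
  s <- summarize_ops(ops)
  expect_equal(s$mop_amp, 25)
  expect_equal(s$op_time_sum, 110)
  ops$peak_times <- ops$peak_times + 2
  expect_equal(summarize_ops(ops)$op_time_sum, 118)   # +2 ms each = +8 total
  s0 <- summarize_ops(structure(list(present = FALSE), class = "op_set"))
  expect_true(is.na(s0$mop_amp))
  expect_equal(s0$flags, "ops_absent")
})

test_that("PhNR is measured after the b-wave on LA recordings only", {
  t <- seq(-20, 160, by = 1)
  v <- gauss_trace(t, list(list(at = 35, sd = 10, amp = 120),
                           list(at = 90, sd = 15, amp = -30)))
  la <- make_recording(v, adaptation = "LA", luminance = 10)
  a <- measure_a_wave(la, raw_windows)
  b <- measure_b_wave(la, a, raw_windows)
  ph <- measure_phnr(la, b, raw_windows)
  expect_equal(ph$phnr_it, 90, tolerance = 1.5)
  expect_equal(ph$phnr_amp, 30, tolerance = 0.6)

  # monotone decay to zero, never negative: absent
  v2 <- gauss_trace(t, list(list(at = 35, sd = 20, amp = 120)))
  la2 <- make_recording(pmax(v2, 0), adaptation = "LA", luminance = 10)
  b2 <- measure_b_wave(la2, measure_a_wave(la2, raw_windows), raw_windows)
  ph2 <- measure_phnr(la2, b2, raw_windows)
  expect_equal(ph2$phnr_amp, 0)
  expect_true("phnr_absent" %in% ph2$flags)

  da <- make_recording(v, adaptation = "DA")
  expect_error(measure_phnr(da, b, raw_windows),
               class = "ergkit_invalid_argument")
})

test_that("reliability flagging follows amplitude and LA luminance rules", {
  w <- window_config()
  # noisy pre-flash, tiny amplitude -> unreliable IT
  set.seed(11)
  t <- seq(-20, 160, by = 0.5)
  noise <- rnorm(length(t), 0, 5)
  rec <- make_recording(gauss_trace(t, list(list(at = 45, sd = 12,
                                                 amp = 4))) + noise,
                        fs = 2000)
  row <- component_row("x1", "WT", "DA", 0.01, a_amp = 2, a_it = 14,
                       b_amp = 4, b_it = 45)
  out <- assess_reliability(rec, row, w)
  expect_true(grepl("a_it_unreliable", out$flags))
  expect_true(grepl("b_it_unreliable", out$flags))

  # LA below 1.0 cd s m^-2: flagged regardless of amplitude
  row2 <- component_row("x1", "WT", "LA", 0.1, a_amp = 500, a_it = 10,
                        b_amp = 900, b_it = 30, phnr_amp = 400, phnr_it = 80)
  out2 <- assess_reliability(rec, row2, w)
  expect_true(grepl("la_it_low_luminance", out2$flags))

  # high-SNR DA row: clean
  rec3 <- make_recording(gauss_trace(t, list(list(at = 45, sd = 12,
                                                  amp = 400))) + noise,
                         fs = 2000)
  row3 <- component_row("x1", "WT", "DA", 3, a_amp = 150, a_it = 14,
                        b_amp = 400, b_it = 45)
  expect_equal(assess_reliability(rec3, row3, w)$flags, "")
})

test_that("extract_all produces one deterministic row per recording", {
  cfg <- tiny_config(noise_sd = 4, seed = 13)
  co <- synth_cohort(cfg)
  tab <- extract_all(co$recordings)
  expect_equal(nrow(tab), length(co$recordings))
  expect_true(all(is.na(tab$phnr_amp[tab$adaptation == "DA"])))
  expect_identical(as.data.frame(extract_all(co$recordings)),
                   as.data.frame(tab))
})

test_that("noise-free cohorts are recovered to the convention ground truth", {
  cfg <- tiny_config(noise_sd = 0, animal_sd = 0.15, seed = 17)
  co <- synth_cohort(cfg)
  tab <- extract_all(co$recordings)
  key <- function(d) paste(d$animal_id, d$adaptation, d$luminance)
  tr <- co$truth[match(key(tab), key(co$truth)), ]
  dt <- 1000 / cfg$sampling_rate + 1e-9

  expect_lt(max(abs(tab$a_amp - tr$a_amp_conv)), 0.5)
  expect_lt(max(abs(tab$b_amp - tr$b_amp_conv)), 0.5)
  expect_lt(max(abs(tab$a_it - tr$a_it_conv)), dt)
  expect_lt(max(abs(tab$b_it - tr$b_it_conv)), dt)
  la <- tab$adaptation == "LA"
  expect_lt(max(abs(tab$phnr_amp[la] - tr$phnr_amp_conv[la])), 0.5)
  expect_lt(max(abs(tab$phnr_it[la] - tr$phnr_it_conv[la])), dt)
  ok <- !is.na(tab$mop_amp) & !is.na(tr$mop_amp_conv)
  expect_gt(sum(ok), 0)
  expect_lt(max(abs(tab$mop_amp[ok] - tr$mop_amp_conv[ok])), 0.5)
  expect_lt(max(abs(tab$op_time_sum[ok] - tr$op_time_sum_conv[ok])), 4 * dt)
})

test_that("broken recordings become flagged rows, not batch failures", {
  cfg <- tiny_config(noise_sd = 0)
  co <- synth_cohort(cfg)
  bad <- co$recordings[[1]]
  bad$time <- bad$time + 100       # no pre-flash segment -> baseline fails
  recs <- c(co$recordings[2:4], list(bad = bad))
  tab <- extract_all(recs)
  expect_equal(nrow(tab), 4)
  expect_true(any(grepl("measurement_error", tab$flags)))
})

test_that("windowed measurements equal brute-force scans on random traces", {
  set.seed(23)
  fs <- 1000
  t <- seq(-20, 160, by = 1000 / fs)
  for (i in 1:100) {
    v <- gauss_trace(t, list(
      list(at = runif(1, 8, 20), sd = runif(1, 2, 6), amp = -runif(1, 0, 200)),
      list(at = runif(1, 30, 70), sd = runif(1, 8, 20), amp = runif(1, 0, 500)),
      list(at = runif(1, 80, 120), sd = runif(1, 10, 25), amp = -runif(1, 0, 60)))) +
      rnorm(length(t), 0, 5)
    rec <- baseline_correct(make_recording(v, fs = fs, adaptation = "LA",
                                           luminance = 3))
    a <- measure_a_wave(rec, raw_windows)
    o <- bf_min(rec$time, rec$voltage, 0, 30)
    expect_equal(a$a_amp, max(0, -o$value))
    if (o$value < 0) expect_equal(a$a_it, o$time)
    b <- measure_b_wave(rec, a, raw_windows)
    ob <- bf_max(rec$time, rec$voltage, a$a_it, 150)
    expect_equal(b$b_it, ob$time)
    ph <- measure_phnr(rec, b, raw_windows)
    op <- bf_min(rec$time, rec$voltage, b$b_it, 150)
    expect_equal(ph$phnr_amp, max(0, -op$value))
  }
})
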