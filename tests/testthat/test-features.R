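test_that("band powers agree with a direct DFT oracle", {
  set.seed(11)
  for (i in 1:20) {
    seg <- rnorm(70) * runif(1, 0.01, 2)
    got <- sliding_band_powers(seg, 2000)
    want <- oracle_band_pair(seg, 2000)
    expect_equal(got$p_lf[1], unname(want["p_lf"]), tolerance = 1e-9)
    expect_equal(got$p_hf[1], unname(want["p_hf"]), tolerance = 1e-9)
  }
})

test_that("tones land in their band", {
  seg_hf <- sin(2 * pi * 220 * (0:69) / 2000)
  bp <- sliding_band_powers(seg_hf, 2000)
  expect_gt(bp$p_hf[1], 10 * bp$p_lf[1])

  seg_lf <- sin(2 * pi * 100 * (0:69) / 2000)
  bp <- sliding_band_powers(seg_lf, 2000)
  expect_gt(bp$p_lf[1], 10 * bp$p_hf[1])
})

test_that("a unit impulse splits its flat spectrum near-evenly at 150 Hz", {
  seg <- c(rep(0, 30), 1, rep(0, 39))
  bp <- sliding_band_powers(seg, 2000)
  rel <- bp$p_hf[1] / (bp$p_hf[1] + bp$p_lf[1])
  # oracle: flat spectrum, 16 of 31 bins in [150, 300]
  want <- oracle_band_pair(seg, 2000)
  expect_equal(rel, unname(want["p_hf"] / sum(want)), tolerance = 1e-9)
  expect_lt(abs(rel - 0.5), 0.05)
})

test_that("windows slide at the configured step and cover short beats", {
  seg <- rnorm(200)                       # 100 ms at 2000 Hz
  bp <- sliding_band_powers(seg, 2000)
  expect_equal(bp$window_start_ms, seq(0, 65, by = 5))
  short <- sliding_band_powers(rnorm(30), 2000)   # shorter than the window
  expect_identical(nrow(short), 1L)
  expect_error(sliding_band_powers(numeric(0), 2000), "empty")
  expect_error(
    sliding_band_powers(seg, 400),
    "Nyquist")
})

test_that("band powers scale quadratically with amplitude", {
  set.seed(12)
  seg <- rnorm(70)
  b1 <- sliding_band_powers(seg, 2000)
  b3 <- sliding_band_powers(3 * seg, 2000)
  expect_equal(b3$p_lf, 9 * b1$p_lf, tolerance = 1e-12)
  expect_equal(b3$p_hf, 9 * b1$p_hf, tolerance = 1e-12)
})

test_that("channel selection retains the bipole with the strongest high band", {
  # active bipole 3 carries a high-frequency wavelet; others are silent
  sig <- matrix(0, 400, 8)
  t <- (0:399) / 2000
  sig[, 3] <- 0.5 * sin(2 * pi * 220 * t) * exp(-((t - 0.1)^2) / (2 * 0.01^2))
  rec <- pv_recording(sig, fs = 2000)
  beat <- whole_beat(rec, "PV-NF")
  sp <- extract_spectral_features(rec, beat)
  expect_identical(sp$selected_channel, 3L)
  expect_true(sp$neighbor_floored)
  expect_gt(sp$p_hf_neighbor_ratio, 1)
})

test_that("the neighbour ratio is the larger of the two adjacent ratios", {
  # channel-level P_HF proportional to squared amplitude: 2 : 10 : 5
  amps <- c(0.01, 0.01, sqrt(2), sqrt(10), sqrt(5), 0.01, 0.01, 0.01)
  rec <- sine_recording(220, amps)
  sp <- extract_spectral_features(rec, whole_beat(rec))
  expect_identical(sp$selected_channel, 4L)
  expect_equal(sp$p_hf_neighbor_ratio, 5, tolerance = 1e-9)
})

test_that("identical channels tie-break to the first bipole with ratio 1", {
  rec <- sine_recording(220, rep(1, 8))
  sp <- extract_spectral_features(rec, whole_beat(rec))
  expect_identical(sp$selected_channel, 1L)
  expect_equal(sp$p_hf_neighbor_ratio, 1, tolerance = 1e-12)
})

test_that("fewer than 3 channels cannot support a neighbour ratio", {
  rec <- sine_recording(220, c(1, 1))
  expect_error(extract_spectral_features(rec, whole_beat(rec)),
               "fewer than 3 channels")
})

test_that("feature extraction is invariant to ring rotation", {
  set.seed(13)
  g <- generate_beat("PV-NF")
  fv <- extract_feature_vector(g$recording, g$beat)
  for (r in c(2, 5)) {
    rot <- pv_recording(g$recording$samples[, c((r:8), 1:(r - 1))], fs = 2000,
                        record_id = g$recording$record_id)
    fr <- extract_feature_vector(rot, g$beat)
    expect_equal(fr[, pvnf:::feature_names], fv[, pvnf:::feature_names],
                 tolerance = 1e-12)
  }
})

test_that("slew-rate proportion matches per-sample derivative counting", {
  # 150 Hz sine, 1 mV peak-to-peak: analytic max slope ~0.471 V/s, so the
  # proportion above 0.15 V/s is strictly between 0 and 1
  rec <- sine_recording(150, c(0.5, 0.5, 0.5), dur_ms = 100)
  beat <- whole_beat(rec)
  tm <- extract_temporal_features(rec, beat, 1)
  v <- rec$samples[, 1] / 1000
  n <- length(v)
  dv <- c((v[2] - v[1]) * 2000,
          (v[3:n] - v[1:(n - 2)]) * 1000,
          (v[n] - v[n - 1]) * 2000)
  expect_equal(tm$slew_rate_prop, mean(abs(dv) > 0.15))
  expect_gt(tm$slew_rate_prop, 0)
  expect_lt(tm$slew_rate_prop, 1)
  expect_equal(tm$v_max, 1, tolerance = 1e-3)
})

test_that("slew features behave on ramps, constants, and sign flips", {
  fs <- 2000
  n <- 100
  # 0.2 V/s ramp: 0.2 V/s = 0.2e3 mV/s; sample step 0.1 mV at 2000 Hz
  ramp <- matrix(rep(0.2 * 1000 * (0:(n - 1)) / fs, 3), ncol = 3)
  rec <- pv_recording(ramp, fs = fs)
  tm <- extract_temporal_features(rec, whole_beat(rec), 1)
  expect_equal(tm$slew_rate_prop, 1)

  flat <- pv_recording(matrix(0.7, n, 3), fs = fs)
  tmf <- extract_temporal_features(flat, whole_beat(flat), 2)
  expect_equal(tmf$v_max, 0)
  expect_equal(tmf$slew_rate_prop, 0)

  set.seed(14)
  x <- matrix(rnorm(300), ncol = 3)
  r1 <- pv_recording(x, fs = fs)
  r2 <- pv_recording(-x, fs = fs)
  expect_equal(extract_temporal_features(r1, whole_beat(r1), 1)$slew_rate_prop,
               extract_temporal_features(r2, whole_beat(r2), 1)$slew_rate_prop)

  tiny <- pv_recording(matrix(1, 2, 3), fs = fs)
  expect_error(extract_temporal_features(tiny, whole_beat(tiny), 1),
               "too short")
})

test_that("band-power additivity gives p_hf_rel = p_hf / (p_lf + p_hf)", {
  set.seed(15)
  for (i in 1:10) {
    g <- generate_beat(sample(c("PV-NF", "atrial-FF", "combined"), 1))
    sp <- extract_spectral_features(g$recording, g$beat)
    expect_gte(sp$p_hf_rel, 0)
    expect_lte(sp$p_hf_rel, 1)
    expect_equal(sp$p_hf_rel, sp$p_hf / (sp$p_lf + sp$p_hf),
                 tolerance = 1e-9)
  }
})

test_that("a beat over all-zero channels yields zero features on bipole 1", {
  rec <- pv_recording(matrix(0, 400, 8), fs = 2000)
  beat <- whole_beat(rec)
  fv <- extract_feature_vector(rec, beat)
  expect_identical(fv$selected_channel, 1L)
  expect_equal(fv$v_max, 0)
  expect_equal(fv$p_hf, 0)
  expect_equal(fv$slew_rate_prop, 0)
})

test_that("annotated duration is offset minus onset", {
  rec <- pv_recording(matrix(rnorm(800), ncol = 4), fs = 2000)
  beat <- pv_beat("rec", "p", "LSPV", "during", 20, 78, "PV-NF")
  fv <- extract_feature_vector(rec, beat)
  expect_equal(fv$duration_ms, 58)
})

test_that("synthetic nearfield beats have higher relative high-band power
          than matched farfield beats", {
  set.seed(16)
  nf_rel <- ff_rel <- numeric(10)
  for (i in 1:10) {
    s <- sample.int(1e6, 1)
    set.seed(s); gn <- generate_beat("PV-NF")
    set.seed(s); gf <- generate_beat("atrial-FF")
    nf_rel[i] <- extract_feature_vector(gn$recording, gn$beat)$p_hf_rel
    ff_rel[i] <- extract_feature_vector(gf$recording, gf$beat)$p_hf_rel
  }
  expect_true(all(nf_rel > ff_rel))
})
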