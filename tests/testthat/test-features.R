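test_that("cycle segmentation windows and contracts", {
  expect_equal(ncol(segment_cycles(seq_len(200), 20)), 10)
  cyc <- segment_cycles(seq_len(205), 20)
  expect_equal(dim(cyc), c(20, 10))       # 5 trailing samples dropped
  expect_equal(cyc[, 1], 1:20)
  expect_error(segment_cycles(seq_len(19), 20), class = "segmentation_error")
})

test_that("sensor features match closed forms on canonical pulses", {
  fs <- 20; p <- 20
  # constant signal over 3 cycles
  f <- sensor_features(rep(5, 60), p, fs)
  expect_equal(unname(f),
               c(5, 5 * (p - 1) / fs, 0, 0, p / fs, 5), tolerance = 1e-12)
  # symmetric triangular pulse, peak 10 N, base width 0.5 s -> FWHM 0.25 s
  fs2 <- 40; p2 <- 40
  tri <- pmax(0, 10 * (1 - abs(seq_len(p2) - 20) / 10))  # base 0.5 s at 40 Hz
  f2 <- sensor_features(rep(tri, 3), p2, fs2)
  expect_equal(unname(f2["FWHM"]), 0.25, tolerance = 1e-10)
  expect_equal(unname(f2["PPP"]), 10)
  # PTI equals the trapezoid rule computed directly
  expect_equal(unname(f2["PTI"]),
               sum((tri[-1] + tri[-p2]) / 2) / fs2, tolerance = 1e-12)
  # gradients are forward differences times fs
  expect_equal(unname(f2["maxPG"]), max(diff(tri)) * fs2)
  expect_equal(unname(f2["minPG"]), min(diff(tri)) * fs2)
  # all-zero signal degenerates to all-zero features
  expect_equal(unname(sensor_features(rep(0, 60), p, fs)), rep(0, 6))
})

test_that("symmetry index follows the bilateral formula", {
  expect_equal(symmetry_index(10, 10), 0)
  expect_equal(symmetry_index(15, 5), 100)
  expect_equal(symmetry_index(0, 0), 0)
  expect_equal(symmetry_index(-4, 4), 200)   # signed features use |.| in denom
  expect_equal(symmetry_index(1, 0), 200)    # upper bound
})

test_that("foot features match hand-computed stationary and moving cases", {
  lay <- default_layout()
  # all channels constant 1 N: TAP = 8, COP stationary
  rec <- pressure_recording(matrix(1, 100, 16))
  f <- foot_features(rec, "L", p = 20, layout = lay)
  expect_equal(unname(f["TAP"]), 8)
  expect_equal(unname(f[c("COPX", "COPY")]), c(0, 0))
  # single active sensor: COP pinned at its coordinates, zero displacement
  m <- matrix(0, 100, 16); m[, 16] <- 5
  recR <- pressure_recording(m)
  fR <- foot_features(recR, "R", p = 20, layout = lay)
  expect_equal(unname(fR[c("COPX", "COPY")]), c(0, 0))
  # alternating single-sensor frames accumulate |dx| per transition
  m2 <- matrix(0, 40, 16)
  m2[seq(1, 39, by = 2), 7] <- 3  # L7
  m2[seq(2, 40, by = 2), 8] <- 3  # L8
  rec2 <- pressure_recording(m2)
  l7 <- lay[lay$foot == "L" & lay$index == 7, ]
  l8 <- lay[lay$foot == "L" & lay$index == 8, ]
  f2 <- foot_features(rec2, "L", p = 40, layout = lay)  # 1 complete cycle
  expect_equal(unname(f2["COPX"]), 39 * abs(l8$x - l7$x), tolerance = 1e-12)
  expect_equal(unname(f2["COPY"]), 39 * abs(l8$y - l7$y), tolerance = 1e-12)
})

test_that("F/R ratio uses summed forefoot over rearfoot peaks with 0 fallback", {
  lay <- default_layout()
  m <- matrix(0, 40, 16)
  m[, 1] <- 6   # L1 forefoot
  m[, 2] <- 4   # L2 forefoot
  m[, 7] <- 5   # L7 rearfoot
  f <- foot_features(pressure_recording(m), "L", p = 20, layout = lay)
  expect_equal(unname(f["FR"]), 10 / 5)
  m[, 7] <- 0   # rearfoot never loads
  f0 <- foot_features(pressure_recording(m), "L", p = 20, layout = lay)
  expect_equal(unname(f0["FR"]), 0)
})

test_that("full feature vector has 156 named entries in canonical order", {
  expect_length(feature_names(), 156)
  expect_equal(length(unique(feature_names())), 156)
  rec <- clean_recording(period_samples = 20, duration = 60, seed = 7)
  fv <- extract_feature_vector(rec)
  expect_length(fv, 156)
  expect_named(fv, feature_names())
  # names the downstream selection stage refers to all exist
  expect_true(all(c("L1_FWHM", "L2_PPP", "R4_FWHM", "3_FWHM_SI", "2_FWHM_SI",
                    "L7_PPP", "R1_FWHM", "L3_FWHM", "R8_PPP", "R8_FWHM")
                  %in% names(fv)))
  # count identity over the families
  expect_equal(6 * 16 + 4 * 2 + 6 * 8 + 4, 156)
})

test_that("amplitude scaling covaries pressures and leaves shape features", {
  set.seed(8)
  rec <- generate_recording(0.7, gen_config(duration = 30, noise_sd = 0),
                            stride_period = 1.0)$recording
  fv1 <- extract_feature_vector(rec)
  rec2 <- rec
  rec2$pressure <- rec$pressure * 2.5
  fv2 <- extract_feature_vector(rec2)
  scale_cov <- grepl("_(PPP|PTI|maxPG|minPG|AP|TAP)$", names(fv1))
  expect_equal(fv2[scale_cov], 2.5 * fv1[scale_cov], tolerance = 1e-9)
  invariant <- grepl("_(FWHM|FR)$|_SI$|_(COPX|COPY)$", names(fv1))
  expect_equal(fv2[invariant], fv1[invariant], tolerance = 1e-9)
  expect_equal(sum(scale_cov) + sum(invariant), 156)
})

test_that("SI features stay within [0, 200] on noisy recordings", {
  set.seed(12)
  for (b in c(0.2, 0.6)) {
    rec <- generate_recording(b, gen_config(duration = 30, noise_sd = 2))$recording
    fv <- extract_feature_vector(rec)
    si <- fv[grepl("_SI$", names(fv))]
    expect_true(all(si >= 0 & si <= 200))
    expect_true(all(fv[grepl("_PPP$", names(fv))] >= 0))
  }
})
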