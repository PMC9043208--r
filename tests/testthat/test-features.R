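# Feature extraction: VMD, PRSA, peak counting, per-lead aggregation.

test_that("VMD recovers two-tone centre frequencies and reconstructs", {
  fs <- 500
  t <- seq(1 / fs, 10, by = 1 / fs)
  sig <- sin(2 * pi * 5 * t) + 0.8 * sin(2 * pi * 40 * t)
  m <- vmd_decompose(sig, K = 2, fs = fs)
  expect_equal(m$center_freqs[1], 5, tolerance = 0.1)
  expect_equal(m$center_freqs[2], 40, tolerance = 0.1)
  rec <- colSums(m$modes)
  expect_lt(sqrt(sum((rec - sig)^2) / sum(sig^2)), 0.05)
  expect_true(!is.unsorted(m$center_freqs))
})

test_that("K = 1 VMD tracks the dominant band", {
  fs <- 500
  t <- seq(1 / fs, 2, by = 1 / fs)
  sig <- sin(2 * pi * 12 * t)
  m <- vmd_decompose(sig, K = 1, fs = fs)
  expect_equal(m$center_freqs[1], 12, tolerance = 0.15)
  expect_lt(sqrt(sum((colSums(m$modes) - sig)^2) / sum(sig^2)), 0.1)
})

test_that("VMD guards its preconditions", {
  expect_error(vmd_decompose(rnorm(6), K = 5, fs = 500), "too short")
  expect_error(vmd_decompose(rnorm(100), K = 5), "fs")
})

test_that("vmd_features returns the 6 mode-3..5 quantities", {
  qrs <- beat_qrs(gen_beat(100, fs = 500))
  f <- vmd_features(vmd_decompose(qrs, K = 5))
  expect_named(f, c("vmd_cf3", "vmd_cf4", "vmd_cf5",
                    "vmd_zc3", "vmd_zc4", "vmd_zc5"))
  expect_true(all(is.finite(f)))
  expect_true(f["vmd_cf3"] <= f["vmd_cf4"] && f["vmd_cf4"] <= f["vmd_cf5"])
  m <- vmd_decompose(qrs, K = 3)
  expect_error(vmd_features(m), "K = 5")
})

test_that("zero crossings are strict sign changes", {
  # one full 10 Hz cycle at 500 Hz -> 2 crossings (generic phase so no
  # sample falls exactly on zero)
  cyc <- sin(2 * pi * 10 * seq(1 / 500, 0.1, by = 1 / 500) + 0.3)
  expect_equal(fqrs:::zero_crossings(cyc), 2L)
  expect_equal(fqrs:::zero_crossings(abs(cyc) + 0.1), 0L)
})

test_that("PRSA of a ramp is the ramp (closed form, 1e-9)", {
  s <- 0.0371
  curve <- prsa_curve(s * (1:300), L = 12)
  expect_s3_class(curve, "prsa_curve")
  expect_length(curve$curve, 24L)
  f <- prsa_features(curve)
  expect_equal(unname(f["prsa_mean_deriv"]), s, tolerance = 1e-9)
  expect_equal(unname(f["prsa_slope"]), s, tolerance = 1e-9)
})

test_that("PRSA anchor bookkeeping", {
  fs <- 500
  # sinusoid over whole cycles: increasing/decreasing anchors balance
  x <- sin(2 * pi * 5 * seq(1 / fs, 1, by = 1 / fs))
  d <- diff(x)
  inc <- sum(d > 0); dec <- sum(d < 0)
  expect_lte(abs(inc - dec), 1)
  cv <- prsa_curve(x, L = 10)
  expect_gte(cv$n_anchors, 1)
  # constant signal: no anchors
  expect_error(prsa_curve(rep(1, 100), L = 10), "anchors|degenerate")
  # too short for the window
  expect_error(prsa_curve(rnorm(10), L = 10), "2L")
})

test_that("prsa_features of exact lines and constants", {
  lin <- structure(list(curve = 0.3 * (0:19) + 1.25, L = 10L,
                        n_anchors = 5L), class = "prsa_curve")
  f <- prsa_features(lin)
  expect_equal(unname(f), c(0.3, 0.3, 1.25), tolerance = 1e-12)
  cst <- structure(list(curve = rep(2.5, 20), L = 10L, n_anchors = 5L),
                   class = "prsa_curve")
  expect_equal(unname(prsa_features(cst)), c(0, 0, 2.5), tolerance = 1e-12)
})

test_that("peak counting matches constructed morphologies", {
  fs <- 500
  # single Gaussian R wave -> 1
  r <- exp(-(seq(-0.05, 0.05, by = 1 / fs))^2 / (2 * 0.01^2))
  expect_equal(count_qrs_peaks(r), 1L)
  # RSR': two positive humps + S trough -> 3
  t <- seq(-0.06, 0.06, by = 1 / fs)
  rsr <- exp(-(t + 0.03)^2 / (2 * 0.006^2)) +
    0.8 * exp(-(t - 0.03)^2 / (2 * 0.006^2)) -
    0.6 * exp(-t^2 / (2 * 0.008^2))
  expect_equal(count_qrs_peaks(rsr), 3L)
  # prominence threshold is respected
  wig <- r + 0.02 * sin(2 * pi * 80 * seq_along(r) / fs)
  expect_gt(count_qrs_peaks(wig, prominence = 0.001), count_qrs_peaks(wig))
})

test_that("notched beats move every feature in the fragmented direction", {
  set.seed(11)
  b0 <- gen_beat(100, fs = 500)
  b1 <- inject_fqrs(b0, n_notches = 2, amp = 0.25, width_ms = 6)
  f0 <- beat_features(beat_qrs(b0))
  f1 <- beat_features(beat_qrs(b1))
  expect_gt(f1["vmd_cf5"], f0["vmd_cf5"])
  expect_gt(f1["vmd_zc5"], f0["vmd_zc5"])
  expect_lt(abs(f1["prsa_slope"]), abs(f0["prsa_slope"]))
  expect_gt(f1["n_peaks"], f0["n_peaks"])
})

test_that("lead aggregation equals single-beat features when degenerate", {
  set.seed(2)
  q <- beat_qrs(gen_beat(100, fs = 500))
  one <- extract_lead_features(list(q))
  expect_equal(one, beat_features(q))
  many <- extract_lead_features(list(q, q, q))
  expect_equal(many, beat_features(q))
  tmpl <- extract_lead_features(list(q, q), aggregate = "template",
                                template_idx = 2L)
  expect_equal(tmpl, beat_features(q))
  expect_error(extract_lead_features(list()), "unanalyzable")
  expect_length(one, 10L)
  expect_named(one, fqrs:::FEATURE_NAMES)
})

test_that("feature extraction is deterministic", {
  q <- beat_qrs(gen_beat(90, fs = 500))
  expect_identical(beat_features(q), beat_features(q))
})

test_that("recording-level features flag flat leads as missing", {
  rec <- fixture_recording(5, fqrs = list(leads = c("II", "V3"),
                                          notch_amp = 0.25))
  ecg <- rec$ecg
  ecg$samples[, 3] <- 0
  ft <- extract_recording_features(ecg)
  expect_equal(nrow(ft), 11L)
  expect_true(all(is.na(ft[ft$lead == "III", fqrs:::FEATURE_NAMES])))
  done <- ft[ft$lead != "III", ]
  expect_true(all(stats::complete.cases(done[, fqrs:::FEATURE_NAMES])))
  # fragmented leads show more peaks than clean ones
  expect_gt(mean(done$n_peaks[done$lead %in% c("II", "V3")]),
            mean(done$n_peaks[!done$lead %in% c("II", "V3")]))
})
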