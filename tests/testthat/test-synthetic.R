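# The synthetic generator is first-class code: its ground truth must be
# trustworthy for every downstream test.

test_that("gen_beat produces the stated morphology and QRS support", {
  b <- gen_beat(90, fs = 500)
  # exactly one prominent positive peak inside the QRS window
  qrs <- b$wave[b$onset:b$offset]
  pk <- fqrs:::local_maxima(qrs)
  big <- pk[fqrs:::peak_prominences(qrs, pk) > 0.5]
  expect_length(big, 1L)

  # measured support (gap-tolerant walk from R at 3% of R amplitude)
  support_ms <- function(beat, thr = 0.03, gap_ms = 12) {
    w <- abs(beat$wave); fs <- beat$fs
    gap <- round(gap_ms / 1000 * fs)
    edge <- function(dir) {
      i <- beat$r_idx; quiet <- 0L
      while (quiet < gap) {
        j <- i + dir
        if (j < 1 || j > length(w)) break
        quiet <- if (w[j] >= thr) 0L else quiet + 1L
        i <- j
      }
      i - dir * quiet
    }
    (edge(1L) - edge(-1L)) / fs * 1000
  }
  expect_equal(support_ms(b), 90, tolerance = 0.12)
  broad <- gen_beat(150, fs = 500)
  expect_gt(support_ms(broad), 120)
  flat <- gen_beat(90, amplitudes = c(p = 0, q = 0, r = 0, s = 0, t = 0))
  expect_true(all(flat$wave == 0))
})

test_that("inject_fqrs adds visible notches and respects contracts", {
  set.seed(21)
  b0 <- gen_beat(100, fs = 500)
  b1 <- inject_fqrs(b0, n_notches = 1, amp = 0.2, width_ms = 6)
  expect_gte(count_qrs_peaks(beat_qrs(b1)),
             count_qrs_peaks(beat_qrs(b0)) + 1)
  # amp 0 leaves the beat untouched
  b2 <- inject_fqrs(b0, n_notches = 2, amp = 0)
  expect_identical(b2$wave, b0$wave)
  # more notches -> more derivative sign changes
  set.seed(22)
  d_of <- function(b) fqrs:::zero_crossings(diff(b$wave[b$onset:b$offset]))
  b_1 <- inject_fqrs(b0, 1, amp = 0.25, width_ms = 6)
  b_3 <- inject_fqrs(b0, 3, amp = 0.25, width_ms = 6)
  expect_gt(d_of(b_3), d_of(b_1))
  # guards
  expect_error(inject_fqrs(b0, 1, width_ms = 80), "too large")
  expect_error(inject_fqrs(b0, 1, centers_ms = 90), "inside the QRS")
  expect_true(all(abs(b1$notch_centers_ms) <= 0.45 * b0$qrs_ms))
})

test_that("gen_recording is reproducible and honours its config", {
  cfg <- synthetic_config(seed = 77, rhythm = "af",
                          fqrs = list(leads = c("II", "V2"),
                                      notch_amp = 0.25),
                          ectopic = list(prob = 0.1))
  r1 <- gen_recording(cfg)
  r2 <- gen_recording(cfg)
  expect_identical(r1$ecg$samples, r2$ecg$samples)
  expect_identical(r1$truth, r2$truth)

  tr <- r1$truth
  # AF: irregular RR measured from ground truth
  expect_gt(stats::sd(diff(tr$r_locations)) / mean(diff(tr$r_locations)),
            0.1)
  # only the configured leads carry the fragmentation label
  expect_equal(tr$lead_names[tr$fqrs_label == 1], c("II", "V2"))
  expect_equal(tr$ordinal_label[tr$fqrs_label == 1], c(5L, 5L))
  expect_true(all(tr$ordinal_label[tr$fqrs_label == 0] == 0L))
  # truth geometry
  expect_true(all(tr$qrs_onset < tr$r_locations &
                    tr$r_locations < tr$qrs_offset))
})

test_that("ground-truth R locations sit on the clean beat apex", {
  cfg <- synthetic_config(seed = 31, noise = list(white_sd = 0,
                                                  baseline_amp = 0,
                                                  powerline_amp = 0))
  rec <- gen_recording(cfg)
  x <- rec$ecg$samples[, "II"] # positive-polarity lead
  for (r in rec$truth$r_locations) {
    win <- (r - 10):(r + 10)
    expect_equal(win[which.max(x[win])], r)
  }
})

test_that("ectopic beats are flagged and morphologically distinct", {
  cfg <- synthetic_config(seed = 99, ectopic = list(prob = 0.15))
  rec <- gen_recording(cfg)
  tr <- rec$truth
  expect_true(any(tr$ectopic) && !all(tr$ectopic))
  x <- rec$ecg$samples[, "II"]
  # inverted morphology: opposite apex sign vs sinus beats
  sinus_apex <- stats::median(x[tr$r_locations[!tr$ectopic]])
  ect_apex <- stats::median(x[tr$r_locations[tr$ectopic]])
  expect_lt(sign(ect_apex * sinus_apex), 0)
})

test_that("ordinal labels are 0/5 outside the ambiguity band only", {
  expect_equal(fqrs:::ordinal_label_from_amp(0), 0)
  expect_equal(fqrs:::ordinal_label_from_amp(0.3), 5)
  set.seed(3)
  mid <- replicate(50, fqrs:::ordinal_label_from_amp(0.11))
  expect_true(all(mid >= 1 & mid <= 4))
})

test_that("cohort composition matches the requested mixes", {
  cohort <- gen_cohort(n_recordings = 120, fqrs_prevalence = 0.3,
                       rhythm_mix = 0.1, ambiguity_frac = 0, seed = 8)
  mf <- cohort$manifest
  expect_equal(nrow(mf), 120 * 11)
  # fragmented-lead fraction within a binomial 99.9% interval of 0.3
  p <- mean(mf$binary)
  expect_lt(abs(p - 0.3), 3.3 * sqrt(0.3 * 0.7 / nrow(mf)))
  # ambiguity 0 -> ordinal labels only 0 or 5
  expect_true(all(mf$ordinal %in% c(0L, 5L)))
  # AF fraction ~ 10% of recordings
  af <- tapply(mf$rhythm, mf$recording_id, `[`, 1)
  expect_gt(mean(af == "af"), 0.03)
  expect_lt(mean(af == "af"), 0.2)
  # per-recording configs regenerate consistent labels
  i <- 25
  rec <- gen_recording(cohort$configs[[i]])
  expect_equal(rec$truth$fqrs_label,
               mf$binary[mf$recording_id == sprintf("rec%04d", i)])
})

test_that("prevalence 1 fragments every lead", {
  cohort <- gen_cohort(n_recordings = 5, fqrs_prevalence = 1,
                       ambiguity_frac = 0, seed = 2)
  expect_true(all(cohort$manifest$binary == 1L))
})

test_that("config validation names the offending field", {
  expect_error(synthetic_config(fs = 100), "fs")
  expect_error(synthetic_config(qrs_ms = 300), "qrs_ms")
  expect_error(synthetic_config(fqrs = list(leads = "nope")), "leads")
  expect_error(synthetic_config(ectopic = list(prob = 2)), "ectopic")
  expect_error(synthetic_config(noise = list(white_sd = -1)), "noise")
})
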