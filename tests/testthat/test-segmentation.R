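# Segmentation: detection, Algorithm-1 consolidation, delineation,
# Algorithm-2 consolidation and the quality filter.

test_that("detector finds all beats of a sinus strip within 20 ms", {
  rec <- fixture_recording(42)
  pe <- fixture_preprocessed(42)
  truth <- rec$truth$r_locations
  pk <- detect_rpeaks_single(pe$samples[, "II"], pe$fs)
  expect_length(pk, length(truth))
  expect_lt(max(abs(pk - truth)), 0.02 * pe$fs)
  expect_true(all(diff(pk) >= 0.2 * pe$fs))
})

test_that("detector handles flat and inverted signals", {
  expect_identical(detect_rpeaks_single(numeric(5000), 500), integer(0))
  pe <- fixture_preprocessed(42)
  up <- detect_rpeaks_single(pe$samples[, "II"], pe$fs)
  dn <- detect_rpeaks_single(-pe$samples[, "II"], pe$fs)
  expect_length(dn, length(up))
})

test_that("consolidation recovers missed beats and prunes extras", {
  rec <- fixture_recording(42)
  pe <- fixture_preprocessed(42)
  truth <- rec$truth$r_locations
  peaks <- lapply(seq_len(n_leads(pe)), function(l)
    detect_rpeaks_single(pe$samples[, l], pe$fs))

  # deficient lead: drop one detection -> must be recovered near consensus
  peaks_def <- peaks
  peaks_def[[4]] <- peaks_def[[4]][-5]
  rp <- consolidate_rpeaks(peaks_def, pe)
  expect_equal(attr(rp, "n_R"), length(truth))
  expect_true(all(apply(unclass(rp), 2, function(col)
    length(col) == length(truth) && all(diff(col) > 0))))
  expect_lt(abs(unclass(rp)[5, 4] - truth[5]), 0.02 * pe$fs)

  # spurious extra detection (T-wave oversensing): pruned again
  peaks_ext <- peaks
  spur <- peaks_ext[[6]][3] + round(0.28 * pe$fs)
  peaks_ext[[6]] <- sort(c(peaks_ext[[6]], spur))
  rp2 <- consolidate_rpeaks(peaks_ext, pe)
  expect_equal(attr(rp2, "n_R"), length(truth))
  expect_false(spur %in% unclass(rp2)[, 6])
  expect_lt(max(abs(unclass(rp2)[, 6] - truth)), 0.02 * pe$fs)

  # identical detections everywhere -> fixed point
  same <- lapply(seq_len(n_leads(pe)), function(l) truth)
  rp3 <- consolidate_rpeaks(same, pe)
  expect_true(all(unclass(rp3) == matrix(truth, length(truth),
                                         n_leads(pe))))

  expect_error(consolidate_rpeaks(rep(list(integer(0)), n_leads(pe)), pe),
               "segmentation failure")
})

test_that("delineation brackets the true QRS support", {
  fs <- 500
  for (q in c(90, 140)) {
    st <- beat_strip(gen_beat(q, fs = fs), n_beats = 4)
    dl <- delineate_single(st$x, fs, st$rpeaks)
    dur <- (dl$offset - dl$onset) / fs * 1000
    tol <- if (q <= 120) 20 else 25
    expect_true(all(abs(dur - q) <= tol),
                label = sprintf("durations %s for true %d", toString(dur), q))
    expect_true(all(dl$onset < st$rpeaks & dl$offset > st$rpeaks))
  }
})

test_that("delineation does not truncate a terminal S notch", {
  fs <- 500
  b <- gen_beat(90, fs = fs)
  notched <- inject_fqrs(b, 1, amp = 0.25, width_ms = 9,
                         centers_ms = 28, signs = 1)
  st <- beat_strip(notched, n_beats = 4)
  dl <- delineate_single(st$x, fs, st$rpeaks)
  true_s_end <- st$rpeaks + round((28 + 9) / 1000 * fs)
  expect_true(all(dl$offset >= true_s_end - round(0.01 * fs)))
})

test_that("median reallocation repairs a systematically narrow lead", {
  pe <- fixture_preprocessed(42)
  rp <- consolidate_rpeaks(lapply(seq_len(n_leads(pe)), function(l)
    detect_rpeaks_single(pe$samples[, l], pe$fs)), pe)
  delin <- lapply(seq_len(n_leads(pe)), function(l)
    delineate_single(pe$samples[, l], pe$fs, unclass(rp)[, l]))
  # squeeze lead 3 by 30 ms on every beat
  sq <- round(0.015 * pe$fs)
  delin_bad <- delin
  delin_bad[[3]]$onset <- delin_bad[[3]]$onset + sq
  delin_bad[[3]]$offset <- delin_bad[[3]]$offset - sq
  seg_ref <- consolidate_delineation(pe, rp, delin)
  seg_bad <- consolidate_delineation(pe, rp, delin_bad)
  expect_true(all(abs(seg_bad$onset[, 3] - seg_ref$onset[, 3]) <= 1))
  expect_true(all(abs(seg_bad$offset[, 3] - seg_ref$offset[, 3]) <= 1))
})

test_that("median reallocation is idempotent when all leads agree", {
  rec <- fixture_recording(42)
  pe <- fixture_preprocessed(42)
  # identical fiducials in every lead: the whole recording already agrees
  rp <- consolidate_rpeaks(lapply(seq_len(n_leads(pe)), function(l)
    rec$truth$r_locations), pe)
  n_R <- attr(rp, "n_R")
  on <- unclass(rp) - round(0.05 * pe$fs)
  off <- unclass(rp) + round(0.05 * pe$fs)
  delin <- lapply(seq_len(n_leads(pe)), function(l)
    list(onset = on[, l], offset = off[, l]))
  seg <- consolidate_delineation(pe, rp, delin)
  expect_equal(unname(seg$onset), unname(on))
  expect_equal(unname(seg$offset), unname(off))
})

test_that("ectopic beats are invalidated in every lead, sinus beats kept", {
  rec <- fixture_recording(99, ectopic = list(prob = 0.15))
  pe <- fixture_preprocessed(99, ectopic = list(prob = 0.15))
  seg <- segment_recording(pe)
  ect <- rec$truth$ectopic
  expect_true(any(ect)) # the fixture does contain ectopics
  expect_true(all(!seg$valid[ect, ]))
  expect_true(all(seg$valid[!ect, ]))
})

test_that("perfectly periodic identical beats are all valid, lags zero", {
  fs <- 500
  st <- beat_strip(gen_beat(100, fs = fs), n_beats = 6)
  ecg <- multilead_ecg(cbind(a = st$x, b = 0.8 * st$x), fs)
  seg <- segment_recording(ecg)
  expect_true(all(seg$valid))
  # zero alignment lag: onsets equal across beats relative to R
  rel <- seg$onset - unclass(seg$rpeaks)
  expect_true(all(rel == rel[1]))
})

test_that("quality filter matches its brute-force oracle", {
  set.seed(404)
  base <- gen_beat(100, fs = 500)
  w <- beat_qrs(base)$wave
  for (i in 1:25) {
    n <- sample(5:12, 1)
    mat <- t(vapply(seq_len(n), function(j)
      w + rnorm(length(w), 0, runif(1, 0.01, 0.6)), numeric(length(w))))
    for (q in c(0.5, 0.85, 0.95)) {
      expect_equal(quality_filter(mat, q = q),
                   quality_filter_oracle(mat, q = q))
    }
  }
})

test_that("quality filter keeps identical beats and drops a noise beat", {
  w <- beat_qrs(gen_beat(100, fs = 500))$wave
  mat <- rbind(t(replicate(9, w)), rnorm(length(w)))
  keep <- quality_filter(mat, q = 0.85)
  expect_equal(keep, c(rep(TRUE, 9), FALSE))
  # all identical -> all kept
  expect_true(all(quality_filter(t(replicate(5, w)))))
  # q = 0 -> everything kept
  expect_true(all(quality_filter(mat, q = 0)))
  expect_error(quality_filter(mat[1, , drop = FALSE]), "at least 2")
})

test_that("pipeline runs unchanged on AF-like irregular rhythm", {
  rec <- fixture_recording(17, rhythm = "af")
  expect_gt(stats::sd(diff(rec$truth$r_locations)) /
              mean(diff(rec$truth$r_locations)), 0.1)
  pe <- fixture_preprocessed(17, rhythm = "af")
  seg <- segment_recording(pe)
  expect_equal(attr(seg$rpeaks, "n_R"), length(rec$truth$r_locations))
  expect_gt(mean(seg$valid), 0.9)
})

test_that("diagnostic plot writes a PNG", {
  pe <- fixture_preprocessed(42)
  seg <- segment_recording(pe)
  f <- withr::local_tempfile(fileext = ".png")
  plot_segmentation(pe, seg, "II", file = f)
  expect_true(file.exists(f) && file.size(f) > 0)
})

test_that("segmentation table export is tidy", {
  pe <- fixture_preprocessed(42)
  seg <- segment_recording(pe)
  tab <- segmentation_table(seg, "recA")
  expect_equal(nrow(tab), attr(seg$rpeaks, "n_R") * n_leads(pe))
  expect_true(all(tab$onset < tab$rpeak & tab$rpeak < tab$offset))
})
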