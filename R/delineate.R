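# QRS delineation: dyadic (a trous) quadratic-spline wavelet transform with
# modulus-maxima search, followed by the multi-lead consolidation rules
# (median reallocation, template alignment, quality filtering).

# Equivalent FIR filter of the dyadic wavelet transform at level j for the
# quadratic-spline (Mallat-Zhong) pair: G(z) with two taps and H(z) = the
# 4-tap binomial smoother, upsampled "with holes" per level.
# W_j(z) = G(z^{2^{j-1}}) * prod_{l=0}^{j-2} H(z^{2^l}).
dyadic_wt_filter <- function(level) {
  g <- c(2, -2)
  h <- c(1, 3, 3, 1) / 8
  up <- function(f, k) {
    if (k == 1) return(f)
    out <- numeric((length(f) - 1) * k + 1)
    out[seq(1, length(out), by = k)] <- f
    out
  }
  f <- up(g, 2^(level - 1))
  if (level >= 2)
    for (l in 0:(level - 2)) f <- stats::convolve(f, rev(up(h, 2^l)),
                                                  type = "open")
  f
}

# Zero-phase-ish wavelet detail at the requested dyadic level: convolution
# with the equivalent filter, compensated for its (half-integer) group delay.
dyadic_wt <- function(x, level) {
  f <- dyadic_wt_filter(level)
  w <- stats::convolve(x, rev(f), type = "open")
  delay <- (length(f) - 1) / 2
  lo <- 1 + floor(delay)
  out <- w[lo:(lo + length(x) - 1)]
  out
}

# Pick the analysis level so the physical time scale matches scale 2^2 at
# the delineator's native 250 Hz: level 2 at 250 Hz, 3 at 500 Hz, 4 at 1 kHz.
wt_level_for_fs <- function(fs) max(1L, min(5L, round(log2(fs / 62.5))))

#' Delineate QRS onsets and offsets in a single lead
#'
#' Wavelet-based delineation: the signal's dyadic quadratic-spline wavelet
#' transform (scale chosen per sampling rate, 2^2 at 500 Hz) behaves as a
#' smoothed derivative; each QRS produces a dominant modulus-maxima pair
#' around the R-peak. The onset is found by walking left from the first
#' significant pre-R modulus maximum (hopping over Q-wave maxima) until the
#' modulus falls below a fraction of the main maximum, and symmetrically for
#' the offset. Implausible results (duration outside 40--250 ms) are flagged
#' missing (`NA`) and later repaired by the cross-lead median step.
#'
#' @param signal one preprocessed lead.
#' @param fs sampling rate in Hz.
#' @param rpeaks integer R-peak indices for this lead.
#' @param thr_edge modulus fraction below which the wave is deemed ended.
#' @param thr_wave modulus fraction above which a neighbouring modulus
#'   maximum counts as part of the QRS (Q/S/notch slopes).
#' @return list with integer vectors `onset` and `offset` (NA where
#'   delineation failed), one entry per R-peak.
#' @export
delineate_single <- function(signal, fs, rpeaks, thr_edge = 0.05,
                             thr_wave = 0.10) {
  n <- length(signal)
  w <- dyadic_wt(signal, wt_level_for_fs(fs))
  aw <- abs(w)
  noise_floor <- 2 * stats::median(aw) # most samples are outside the QRS
  search <- round(0.10 * fs)   # main-pair search half-window
  reach <- round(0.05 * fs)    # how far a Q/S modulus maximum may extend
  cap <- round(0.15 * fs)      # absolute bound on onset/offset distance
  onset <- offset <- rep(NA_integer_, length(rpeaks))
  mm <- local_maxima(aw)
  for (bi in seq_along(rpeaks)) {
    r <- rpeaks[bi]
    lo <- max(1L, r - search); hi <- min(n, r + search)
    pre_win <- lo:r
    post_win <- r:hi
    n_pre <- pre_win[which.max(aw[pre_win])]
    n_post <- post_win[which.max(aw[post_win])]
    m_main <- max(aw[n_pre], aw[n_post])
    if (m_main <= 0) next

    walk <- function(anchor, dir) {
      # hop over further significant modulus maxima (Q/S waves, notches);
      # a hop target must clear both the relative and the noise threshold,
      # and at most two hops are taken (Q or S wave, then one notch)
      bound <- if (dir < 0) max(1L, r - cap) else min(n, r + cap)
      thr_hop <- max(thr_wave * m_main, 2 * noise_floor)
      for (hop in 1:2) {
        rng <- if (dir < 0) {
          if (anchor - 1 < max(bound, anchor - reach)) break
          max(bound, anchor - reach):(anchor - 1)
        } else {
          if (anchor + 1 > min(bound, anchor + reach)) break
          (anchor + 1):min(bound, anchor + reach)
        }
        cand <- mm[mm %in% rng & aw[mm] > thr_hop]
        if (length(cand) == 0) break
        anchor <- if (dir < 0) max(cand) else min(cand)
      }
      # then walk until the modulus drops below the edge threshold (never
      # below the recording's noise floor)
      i <- anchor
      thr <- max(thr_edge * m_main, noise_floor)
      while (i != bound && aw[i + dir] > thr) i <- i + dir
      i + dir * min(2L, abs(bound - i)) # small margin past the threshold
    }
    on <- walk(n_pre, -1L)
    off <- walk(n_post, +1L)
    dur_ms <- (off - on) / fs * 1000
    if (on < r && off > r && dur_ms >= 40 && dur_ms <= 250) {
      onset[bi] <- on
      offset[bi] <- off
    }
  }
  list(onset = onset, offset = offset)
}

#' Normalized QRS complex
#'
#' A segmented QRS waveform scaled to maximum absolute amplitude 1.
#'
#' @param wave numeric vector (>= 5 samples, not all zero).
#' @param fs sampling rate in Hz.
#' @export
qrs_complex <- function(wave, fs) {
  wave <- as.numeric(wave)
  if (length(wave) < 5) stop("QRS segment too short", call. = FALSE)
  m <- max(abs(wave))
  if (m == 0) stop("flat QRS segment", call. = FALSE)
  structure(list(wave = wave / m, fs = fs), class = "qrs_complex")
}

#' Beat quality filter
#'
#' For each beat, the vector `rho` holds its normalized (Pearson)
#' correlations with all `n_R` beats of the lead (including itself, which
#' contributes one guaranteed entry of 1). A beat is removed iff strictly
#' more than half of the entries of `rho` fall below the quality limit `q`.
#'
#' @param beats a list of equal-meaning beat vectors (or `qrs_complex`
#'   objects), or a matrix with one row per beat. Vectors are truncated to
#'   the shortest common length.
#' @param q quality limit in `[0, 1]`; 0.85 by default.
#' @param include_self whether the self-correlation entry is part of `rho`
#'   (the default, matching a comparison against all `n_R` beats).
#' @return Logical mask of kept beats.
#' @export
quality_filter <- function(beats, q = 0.85, include_self = TRUE) {
  if (is.matrix(beats)) {
    m <- beats
  } else {
    vecs <- lapply(beats, function(b) if (inherits(b, "qrs_complex")) b$wave
                   else as.numeric(b))
    len <- min(lengths(vecs))
    m <- do.call(rbind, lapply(vecs, function(v) v[seq_len(len)]))
  }
  n <- nrow(m)
  if (n < 2) stop("quality filter needs at least 2 beats", call. = FALSE)
  rho <- suppressWarnings(stats::cor(t(m)))
  rho[!is.finite(rho)] <- 0
  # negative correlations are floored at zero: an anti-correlated beat is no
  # more similar than an uncorrelated one, and the q = 0 boundary then
  # keeps every beat as documented
  rho <- pmax(rho, 0)
  if (!include_self) diag(rho) <- NA
  below <- rowSums(rho < q, na.rm = TRUE)
  denom <- if (include_self) n else n - 1
  keep <- below <= denom / 2
  if (!any(keep))
    warning("quality filter removed every beat; lead unanalyzable",
            call. = FALSE)
  keep
}

#' Consolidate delineation across leads and filter beats
#'
#' The multi-lead post-processing of QRS delineation: (1) per beat, onset and
#' offset are reallocated to the across-lead median of their positions
#' relative to that beat's R-peak; (2) per lead, beats are segmented and
#' normalized to maximum amplitude 1; (3) the template beat is the one with
#' the highest cumulative correlation to the lead's other beats; (4) the
#' remaining beats are aligned to the template by maximizing normalized
#' cross-correlation over lags up to 25 ms (ties toward zero lag), adjusting
#' their boundaries by the found lag; (5) the correlation [quality_filter()]
#' removes irregular or erroneously delineated beats.
#'
#' @param ecg preprocessed [multilead_ecg].
#' @param rpeaks `rpeak_matrix` from [consolidate_rpeaks()].
#' @param delineation list (one per lead) of `list(onset, offset)` from
#'   [delineate_single()].
#' @param q quality limit for the filter.
#' @param max_lag_ms alignment lag bound in ms.
#' @return A `beat_segmentation`: matrices `onset`, `offset`, `valid`
#'   (`n_R x n_leads`), `rpeaks`, per-lead `template_idx` and the aligned,
#'   normalized beat matrices in `$beats` (rows = beats).
#' @export
consolidate_delineation <- function(ecg, rpeaks, delineation, q = 0.85,
                                    max_lag_ms = 25) {
  validate_ecg(ecg)
  fs <- ecg$fs
  L <- n_leads(ecg)
  n_R <- attr(rpeaks, "n_R")
  ridx <- unclass(rpeaks)

  on_rel <- off_rel <- matrix(NA_real_, n_R, L)
  for (l in seq_len(L)) {
    on_rel[, l] <- delineation[[l]]$onset - ridx[, l]
    off_rel[, l] <- delineation[[l]]$offset - ridx[, l]
  }
  # step 1: median reallocation per beat across leads; fixed +/-60 ms
  # fallback when no lead delineated a beat
  med_on <- apply(on_rel, 1, stats::median, na.rm = TRUE)
  med_off <- apply(off_rel, 1, stats::median, na.rm = TRUE)
  fb <- round(0.06 * fs)
  med_on[!is.finite(med_on)] <- -fb
  med_off[!is.finite(med_off)] <- fb
  med_on <- round(med_on); med_off <- round(med_off)

  onset <- ridx + matrix(med_on, n_R, L)
  offset <- ridx + matrix(med_off, n_R, L)
  nsamp <- n_samples(ecg)
  onset <- pmax(onset, 1L)
  offset <- pmin(offset, nsamp)

  max_lag <- max(1L, round(max_lag_ms / 1000 * fs))
  lag_order <- order(abs(-max_lag:max_lag), -max_lag:max_lag)
  lags <- (-max_lag:max_lag)[lag_order]

  valid <- matrix(FALSE, n_R, L)
  template_idx <- rep(NA_integer_, L)
  beat_list <- vector("list", L)
  pre <- -med_on # samples before R in the common window (>= 1 expected)
  post <- med_off
  for (l in seq_len(L)) {
    pre_l <- min(pre); post_l <- min(post)
    if (n_R < 2 || pre_l < 1 || post_l < 1) next
    extract <- function(centers) {
      t(vapply(centers, function(r) {
        lo <- r - pre_l; hi <- r + post_l
        if (lo < 1 || hi > nsamp) return(rep(NA_real_, pre_l + post_l + 1))
        ecg$samples[lo:hi, l]
      }, numeric(pre_l + post_l + 1)))
    }
    segs <- extract(ridx[, l])
    ok <- stats::complete.cases(segs)
    if (sum(ok) < 2) next
    norm_rows <- function(m) {
      sc <- apply(abs(m), 1, max)
      sc[sc == 0] <- 1
      m / sc
    }
    segs_n <- norm_rows(segs)
    # step 3: template = highest cumulative correlation
    cm <- suppressWarnings(stats::cor(t(segs_n[ok, , drop = FALSE])))
    cm[!is.finite(cm)] <- 0
    cum <- rowSums(cm)
    tmpl <- which(ok)[which.max(cum)]
    template_idx[l] <- tmpl
    tv <- segs_n[tmpl, ]
    # step 4: align each beat to the template over bounded lags
    lag_best <- integer(n_R)
    for (b in seq_len(n_R)) {
      if (b == tmpl) next
      best_c <- -Inf; best_lag <- 0L
      for (lag in lags) {
        lo <- ridx[b, l] + lag - pre_l; hi <- ridx[b, l] + lag + post_l
        if (lo < 1 || hi > nsamp) next
        seg <- ecg$samples[lo:hi, l]
        cc <- suppressWarnings(stats::cor(tv, seg))
        if (is.finite(cc) && cc > best_c + 1e-12) {
          best_c <- cc; best_lag <- lag
        }
      }
      lag_best[b] <- best_lag
    }
    onset[, l] <- onset[, l] + lag_best
    offset[, l] <- offset[, l] + lag_best
    aligned <- extract(ridx[, l] + lag_best)
    ok2 <- stats::complete.cases(aligned)
    aligned_n <- norm_rows(aligned)
    # step 5: quality filter on the aligned, normalized beats
    if (sum(ok2) >= 2) {
      keep <- rep(FALSE, n_R)
      keep[ok2] <- tryCatch(
        suppressWarnings(quality_filter(aligned_n[ok2, , drop = FALSE], q = q)),
        error = function(e) rep(FALSE, sum(ok2)))
      valid[, l] <- keep
    }
    beat_list[[l]] <- aligned_n
  }
  structure(list(onset = onset, offset = offset, rpeaks = rpeaks,
                 valid = valid, template_idx = template_idx,
                 beats = beat_list, lead_names = ecg$lead_names, fs = fs),
            class = "beat_segmentation")
}

#' Segment a preprocessed recording end to end
#'
#' Runs per-lead R-peak detection, cross-lead R-peak consolidation, per-lead
#' wavelet delineation and the multi-lead delineation consolidation with
#' quality filtering.
#'
#' @param ecg preprocessed [multilead_ecg].
#' @param q quality limit.
#' @return A `beat_segmentation`.
#' @export
segment_recording <- function(ecg, q = 0.85) {
  validate_ecg(ecg)
  peaks <- lapply(seq_len(n_leads(ecg)), function(l)
    detect_rpeaks_single(ecg$samples[, l], ecg$fs))
  rp <- consolidate_rpeaks(peaks, ecg)
  delin <- lapply(seq_len(n_leads(ecg)), function(l)
    delineate_single(ecg$samples[, l], ecg$fs, unclass(rp)[, l]))
  consolidate_delineation(ecg, rp, delin, q = q)
}

#' Extract the valid QRS complexes of one lead
#'
#' @param seg a `beat_segmentation`.
#' @param lead lead index or name.
#' @return list of [qrs_complex()] objects (possibly empty).
#' @export
get_qrs_complexes <- function(seg, lead) {
  stopifnot(inherits(seg, "beat_segmentation"))
  if (is.character(lead)) lead <- match(lead, seg$lead_names)
  m <- seg$beats[[lead]]
  if (is.null(m)) return(list())
  keep <- which(seg$valid[, lead])
  lapply(keep, function(b) qrs_complex(m[b, ], seg$fs))
}

#' Diagnostic segmentation plot for one lead
#'
#' Four panels: the lead signal with R-peaks and QRS boundaries, the
#' segmented beats overlaid, the aligned normalized beats, and the beats
#' kept by the quality filter (template in bold).
#'
#' @param ecg the preprocessed [multilead_ecg] that was segmented.
#' @param seg the `beat_segmentation`.
#' @param lead lead index or name.
#' @param file optional PNG path; when given the plot is written there.
#' @return `file` (or NULL), invisibly.
#' @export
plot_segmentation <- function(ecg, seg, lead, file = NULL) {
  stopifnot(inherits(seg, "beat_segmentation"))
  if (is.character(lead)) lead <- match(lead, seg$lead_names)
  if (!is.null(file)) {
    grDevices::png(file, width = 1400, height = 900, res = 110)
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mfrow = c(1, 4), mar = c(4, 3, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  x <- ecg$samples[, lead]
  fs <- seg$fs
  tt <- (seq_along(x) - 1) / fs
  r <- unclass(seg$rpeaks)[, lead]
  graphics::plot(tt, x, type = "l", xlab = "time (s)", ylab = "",
                 main = paste("lead", seg$lead_names[lead]))
  graphics::points(tt[r], x[r], col = "red", pch = 19, cex = 0.7)
  graphics::abline(v = tt[c(seg$onset[, lead], seg$offset[, lead])],
                   col = "grey70", lty = 3)
  m <- seg$beats[[lead]]
  if (is.null(m)) return(invisible(file))
  tb <- (seq_len(ncol(m)) - 1) / fs * 1000
  draw <- function(rows, main) {
    graphics::matplot(tb, t(m[rows, , drop = FALSE]), type = "l", lty = 1,
                      col = grDevices::adjustcolor("steelblue", 0.6),
                      xlab = "ms", ylab = "", main = main)
  }
  draw(seq_len(nrow(m)), "segmented beats")
  draw(seq_len(nrow(m)), "aligned beats")
  keep <- which(seg$valid[, lead])
  if (length(keep) > 0) {
    draw(keep, "kept beats")
    if (!is.na(seg$template_idx[lead]))
      graphics::lines(tb, m[seg$template_idx[lead], ], lwd = 2)
  }
  invisible(file)
}

#' Export a beat segmentation as a flat table
#'
#' @param seg a `beat_segmentation`.
#' @param recording_id identifier copied into every row.
#' @return data.frame with columns recording, lead, beat, onset, rpeak,
#'   offset, valid.
#' @export
segmentation_table <- function(seg, recording_id = "recording") {
  stopifnot(inherits(seg, "beat_segmentation"))
  n_R <- attr(seg$rpeaks, "n_R")
  L <- length(seg$lead_names)
  data.frame(recording = recording_id,
             lead = rep(seg$lead_names, each = n_R),
             beat = rep(seq_len(n_R), L),
             onset = as.vector(seg$onset),
             rpeak = as.vector(unclass(seg$rpeaks)),
             offset = as.vector(seg$offset),
             valid = as.vector(seg$valid))
}
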