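# Per-lead features: variational mode decomposition, phase-rectified signal
# averaging, and QRS peak counting. Exactly the 10 features fed to the
# classifier (VMD centre frequencies and zero-crossings of modes 3-5, PRSA
# mean derivative / fit slope / fit intercept, number of QRS peaks).

#' Variational mode decomposition
#'
#' Decomposes a signal into `K` band-limited oscillatory modes via the ADMM
#' variational scheme (Wiener-filter mode updates, centre frequencies as
#' power-weighted mean frequencies, optional dual ascent). Centre frequencies
#' are initialised uniformly over the band, so the decomposition is
#' deterministic. Modes are returned sorted by ascending centre frequency,
#' reported in Hz.
#'
#' @param x a [qrs_complex()] or numeric vector.
#' @param K number of modes (5 for the fQRS feature set).
#' @param alpha bandwidth penalty (larger = narrower modes).
#' @param tau dual-ascent step (0 = no exact-reconstruction constraint,
#'   tolerant to noise).
#' @param tol relative convergence tolerance.
#' @param max_iter iteration cap; non-convergence returns the last iterate
#'   with a warning.
#' @param fs sampling rate in Hz (taken from the `qrs_complex` if given).
#' @return A `vmd_modes` object: `modes` (K x n matrix), `center_freqs` (Hz,
#'   non-decreasing), `K`, `converged`.
#' @export
vmd_decompose <- function(x, K = 5, alpha = 2000, tau = 0, tol = 1e-7,
                          max_iter = 500, fs = NULL) {
  if (inherits(x, "qrs_complex")) {
    if (is.null(fs)) fs <- x$fs
    x <- x$wave
  }
  if (is.null(fs)) stop("fs must be supplied for a bare numeric signal",
                        call. = FALSE)
  x <- as.numeric(x)
  if (length(x) < 2 * K)
    stop("signal too short for K = ", K, " modes", call. = FALSE)
  res <- .vmd_cpp(x, as.integer(K), alpha, tau, tol, as.integer(max_iter))
  if (!res$converged)
    warning("VMD did not converge within ", max_iter, " iterations",
            call. = FALSE)
  ord <- order(res$omega)
  structure(list(modes = res$modes[ord, , drop = FALSE],
                 center_freqs = res$omega[ord] * fs,
                 K = K, fs = fs, converged = res$converged),
            class = "vmd_modes")
}

zero_crossings <- function(v) {
  s <- sign(v)
  s <- s[s != 0]
  if (length(s) < 2) return(0L)
  sum(diff(s) != 0)
}

#' VMD features of modes 3--5
#'
#' Fragmentation shows up as high-frequency notches, so the centre
#' frequencies and zero-crossing counts of the three highest-frequency modes
#' carry the discriminative information.
#'
#' @param modes a `vmd_modes` with `K = 5`.
#' @return named numeric vector `(vmd_cf3, vmd_cf4, vmd_cf5, vmd_zc3,
#'   vmd_zc4, vmd_zc5)`; frequencies in Hz, crossings as counts.
#' @export
vmd_features <- function(modes) {
  stopifnot(inherits(modes, "vmd_modes"))
  if (modes$K != 5) stop("vmd_features expects K = 5 modes", call. = FALSE)
  c(vmd_cf3 = modes$center_freqs[3],
    vmd_cf4 = modes$center_freqs[4],
    vmd_cf5 = modes$center_freqs[5],
    vmd_zc3 = as.numeric(zero_crossings(modes$modes[3, ])),
    vmd_zc4 = as.numeric(zero_crossings(modes$modes[4, ])),
    vmd_zc5 = as.numeric(zero_crossings(modes$modes[5, ])))
}

#' Phase-rectified signal averaging of a QRS complex
#'
#' Every interior sample is classified as an increasing (`x_i > x_{i-1}`) or
#' decreasing (`x_i < x_{i-1}`) anchor (ties are not anchors). A window of
#' length `2L` is taken around each anchor, windows at decreasing anchors are
#' sign-inverted so all follow a comparable trend, windows that would overrun
#' the segment are discarded, and the PRSA curve is the pointwise mean. The
#' default window is 40 ms total, i.e. `L = round(0.02 fs)`.
#'
#' @param x a [qrs_complex()] or numeric vector.
#' @param L half-window in samples.
#' @param fs sampling rate (Hz), taken from the `qrs_complex` if given.
#' @return A `prsa_curve`: `curve` (length `2L`), `L`, `n_anchors`.
#' @export
prsa_curve <- function(x, L = NULL, fs = NULL) {
  if (inherits(x, "qrs_complex")) {
    if (is.null(fs)) fs <- x$fs
    x <- x$wave
  }
  if (is.null(L)) {
    if (is.null(fs)) stop("either L or fs must be given", call. = FALSE)
    L <- max(2L, round(0.02 * fs))
  }
  n <- length(x)
  if (n <= 2 * L)
    stop("degenerate signal: need more than 2L samples for PRSA",
         call. = FALSE)
  d <- diff(x)
  anchors <- which(d != 0) + 1L # i with x_i != x_{i-1}, interior by def
  inc <- d[anchors - 1L] > 0
  keep <- anchors - L >= 1L & anchors + L - 1L <= n
  anchors <- anchors[keep]; inc <- inc[keep]
  if (length(anchors) == 0)
    stop("degenerate signal: no valid PRSA anchors", call. = FALSE)
  acc <- numeric(2 * L)
  for (j in seq_along(anchors)) {
    w <- x[(anchors[j] - L):(anchors[j] + L - 1L)]
    acc <- acc + if (inc[j]) w else -w
  }
  structure(list(curve = acc / length(anchors), L = L,
                 n_anchors = length(anchors)),
            class = "prsa_curve")
}

#' PRSA summary features
#'
#' The mean first difference of the PRSA curve, plus the slope and index-0
#' intercept of its least-squares linear fit. Notches flatten the curve, so
#' fragmented beats yield smaller slope magnitudes.
#'
#' @param curve a `prsa_curve`.
#' @return named numeric vector `(prsa_mean_deriv, prsa_slope, prsa_ycross)`
#'   (units: normalized amplitude per sample).
#' @export
prsa_features <- function(curve) {
  stopifnot(inherits(curve, "prsa_curve"))
  y <- curve$curve
  t <- seq_along(y) - 1
  slope <- stats::cov(t, y) / stats::var(t)
  intercept <- mean(y) - slope * mean(t)
  c(prsa_mean_deriv = mean(diff(y)),
    prsa_slope = slope,
    prsa_ycross = intercept)
}

# Topographic prominence of the peak at index i of v (scipy-style): height
# above the higher of the two valley floors separating it from higher ground.
peak_prominences <- function(v, peaks) {
  vapply(peaks, function(p) {
    lo <- p; left_min <- v[p]
    while (lo > 1 && v[lo - 1] <= v[p]) {
      lo <- lo - 1
      if (v[lo] < left_min) left_min <- v[lo]
    }
    hi <- p; right_min <- v[p]
    n <- length(v)
    while (hi < n && v[hi + 1] <= v[p]) {
      hi <- hi + 1
      if (v[hi] < right_min) right_min <- v[hi]
    }
    v[p] - max(left_min, right_min)
  }, numeric(1))
}

#' Count peaks in a QRS complex
#'
#' Counts local extrema (maxima of the waveform and of its negation) whose
#' topographic prominence exceeds `prominence` on the amplitude-normalized
#' beat. The paper-level notion of "number of peaks in the QRS" has no
#' operational definition in the source material; the prominence threshold is
#' a configuration knob (default 0.05 of the R amplitude).
#'
#' @param qrs a [qrs_complex()] or numeric vector (normalized internally).
#' @param prominence minimum prominence as a fraction of the maximum
#'   absolute amplitude.
#' @return integer peak count.
#' @export
count_qrs_peaks <- function(qrs, prominence = 0.05) {
  v <- if (inherits(qrs, "qrs_complex")) qrs$wave else as.numeric(qrs)
  m <- max(abs(v))
  if (m == 0) return(0L)
  v <- v / m
  count_side <- function(u) {
    pk <- local_maxima(u)
    if (length(pk) == 0) return(0L)
    sum(peak_prominences(u, pk) >= prominence)
  }
  count_side(v) + count_side(-v)
}

FEATURE_NAMES <- c("vmd_cf3", "vmd_cf4", "vmd_cf5",
                   "vmd_zc3", "vmd_zc4", "vmd_zc5",
                   "prsa_mean_deriv", "prsa_slope", "prsa_ycross",
                   "n_peaks")

#' The 10 features of one beat
#'
#' @param qrs a [qrs_complex()].
#' @inheritParams vmd_decompose
#' @inheritParams count_qrs_peaks
#' @return named numeric vector of the 10 features.
#' @export
beat_features <- function(qrs, alpha = 2000, tol = 1e-7, prominence = 0.05) {
  stopifnot(inherits(qrs, "qrs_complex"))
  modes <- suppressWarnings(vmd_decompose(qrs, K = 5, alpha = alpha,
                                          tol = tol))
  c(vmd_features(modes),
    prsa_features(prsa_curve(qrs)),
    n_peaks = as.numeric(count_qrs_peaks(qrs, prominence)))
}

#' Per-lead feature vector
#'
#' Computes the 10 features for every valid beat of a lead and aggregates
#' them. The default aggregates by averaging across beats; `"template"` uses
#' only the template beat.
#'
#' @param beats list of valid [qrs_complex()] beats (e.g. from
#'   [get_qrs_complexes()]).
#' @param aggregate `"mean"` or `"template"`.
#' @param template_idx index into `beats` used when `aggregate =
#'   "template"`.
#' @inheritParams beat_features
#' @return named numeric vector of 10 finite values.
#' @export
extract_lead_features <- function(beats, aggregate = c("mean", "template"),
                                  template_idx = 1L, alpha = 2000,
                                  tol = 1e-7, prominence = 0.05) {
  aggregate <- match.arg(aggregate)
  if (length(beats) < 1)
    stop("lead unanalyzable: no valid beats", call. = FALSE)
  if (aggregate == "template")
    return(beat_features(beats[[template_idx]], alpha, tol, prominence))
  fm <- t(vapply(beats, beat_features, numeric(10),
                 alpha = alpha, tol = tol, prominence = prominence))
  colMeans(fm)
}

#' Per-lead features for a whole recording
#'
#' Convenience wrapper: preprocess (optional), segment, and extract the
#' 10-feature vector for each analyzable lead.
#'
#' @param ecg a [multilead_ecg] (raw; preprocessing is applied unless
#'   `preprocessed = TRUE`).
#' @param preprocessed set TRUE when `ecg` is already filtered/normalized.
#' @param q segmentation quality limit.
#' @param recording_id identifier for the output rows.
#' @inheritParams extract_lead_features
#' @return data.frame: `recording_id`, `lead`, `n_beats`, and the 10 feature
#'   columns (NA rows for unanalyzable leads).
#' @export
extract_recording_features <- function(ecg, preprocessed = FALSE, q = 0.85,
                                       recording_id = "recording",
                                       aggregate = "mean") {
  na_rows <- function(leads) {
    if (length(leads) == 0) return(NULL)
    cbind(data.frame(recording_id = recording_id, lead = leads, n_beats = 0L,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(stats::setNames(rep(NA_real_, 10),
                                                FEATURE_NAMES))))
  }
  all_leads <- suppressWarnings(select_analysis_leads(ecg))$lead_names
  if (!preprocessed) {
    ecg <- bandpass(suppressWarnings(select_analysis_leads(ecg)))
    # degenerate (flat) leads cannot be normalized or analyzed: drop them
    # here and report NA feature rows, keeping the other leads alive
    sds <- apply(ecg$samples, 2, stats::sd)
    dead <- ecg$lead_names[sds == 0 | !is.finite(sds)]
    if (length(dead) > 0) {
      if (length(ecg$lead_names) - length(dead) < 2)
        stop("fewer than 2 analyzable leads", call. = FALSE)
      ecg <- ecg[setdiff(ecg$lead_names, dead)]
    }
    ecg <- normalize_ecg(ecg)
  }
  seg <- segment_recording(ecg, q = q)
  rows <- lapply(seq_along(seg$lead_names), function(l) {
    beats <- get_qrs_complexes(seg, l)
    base <- data.frame(recording_id = recording_id,
                       lead = seg$lead_names[l],
                       n_beats = length(beats), stringsAsFactors = FALSE)
    feats <- if (length(beats) >= 1)
      tryCatch(extract_lead_features(beats, aggregate = aggregate),
               error = function(e) stats::setNames(rep(NA_real_, 10),
                                                   FEATURE_NAMES))
    else stats::setNames(rep(NA_real_, 10), FEATURE_NAMES)
    cbind(base, as.data.frame(as.list(feats)))
  })
  out <- do.call(rbind, c(rows,
                          list(na_rows(setdiff(all_leads, seg$lead_names)))))
  out[match(all_leads, out$lead), , drop = FALSE]
}
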