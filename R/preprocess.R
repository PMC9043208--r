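# Digital Butterworth design via the bilinear transform, in zero-pole-gain
# form. Equivalent to the classic textbook recipe: analog prototype poles on
# the unit circle, frequency pre-warping, lp->lp / lp->hp transform, bilinear
# map at fs = 2. Orders here are small (<= 6) so polynomial expansion from
# roots is numerically unproblematic.
butter_coeffs <- function(order, cutoff_hz, fs, type = c("low", "high")) {
  type <- match.arg(type)
  wn <- cutoff_hz / (fs / 2)
  if (wn <= 0 || wn >= 1)
    stop("cutoff must lie strictly inside (0, Nyquist)", call. = FALSE)
  warped <- 4 * tan(pi * wn / 2)
  k <- seq_len(order)
  p_proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  if (type == "low") {
    p <- warped * p_proto
    z <- complex(0)
    gain <- warped^order
  } else {
    p <- warped / p_proto
    z <- rep(0 + 0i, order)
    gain <- 1
  }
  fs2 <- 4 # twice the bilinear sampling rate convention fs = 2
  zd <- (fs2 + z) / (fs2 - z)
  pd <- (fs2 + p) / (fs2 - p)
  zd <- c(zd, rep(-1 + 0i, length(p) - length(z)))
  gain <- gain * Re(prod(fs2 - z) / prod(fs2 - p))
  b <- Re(poly_from_roots(zd)) * gain
  a <- Re(poly_from_roots(pd))
  list(b = b, a = a)
}

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - ri * c(0, p)
  p
}

# Steady-state initial filter state for a unit step (the scipy lfilter_zi
# construction): suppresses start-up transients in filtfilt.
lfilter_zi <- function(b, a) {
  n <- length(a)
  if (n == 1L) return(numeric(0))
  comp <- rbind(-a[-1] / a[1], cbind(diag(1, n - 2), 0))
  if (n == 2L) comp <- matrix(-a[2] / a[1], 1, 1)
  B <- b[-1] - a[-1] * b[1]
  as.numeric(solve(diag(1, n - 1) - t(comp), B))
}

#' Zero-phase IIR filtering
#'
#' Applies the filter forward and backward (with odd-reflection padding and
#' steady-state initial conditions) so the net phase response is zero: QRS
#' morphology and notch timing are preserved.
#'
#' @param b,a filter numerator / denominator coefficients.
#' @param x numeric vector to filter.
#' @param padlen reflection pad length in samples.
#' @return Filtered vector, same length as `x`.
#' @export
filtfilt <- function(b, a, x, padlen = 3 * (max(length(a), length(b)) - 1)) {
  n <- length(x)
  if (length(b) < length(a)) b <- c(b, rep(0, length(a) - length(b)))
  if (length(a) < length(b)) a <- c(a, rep(0, length(b) - length(a)))
  padlen <- min(padlen, n - 1L)
  ext <- if (padlen > 0) {
    c(2 * x[1] - x[(padlen + 1):2], x, 2 * x[n] - x[(n - 1):(n - padlen)])
  } else x
  zi <- lfilter_zi(b, a)
  y <- .lfilter_cpp(b, a, ext, zi * ext[1])
  y <- rev(y)
  y <- .lfilter_cpp(b, a, y, zi * y[1])
  y <- rev(y)
  if (padlen > 0) y[(padlen + 1):(padlen + n)] else y
}

#' Band-pass filter an ECG
#'
#' Two cascaded zero-phase Butterworth filters: an order-4 high-pass at
#' `low_hz` (removes baseline wander) followed by an order-6 low-pass at
#' `high_hz` (removes high-frequency noise while keeping the band where QRS
#' fragmentation lives). Defaults are 0.5--70 Hz.
#'
#' @param ecg a [multilead_ecg].
#' @param low_hz high-pass edge in Hz.
#' @param high_hz low-pass edge in Hz.
#' @param order_low,order_high filter orders for the high-pass (`order_low`,
#'   at the low band edge) and low-pass (`order_high`) stages.
#' @return The filtered [multilead_ecg], same shape.
#' @export
bandpass <- function(ecg, low_hz = 0.5, high_hz = 70,
                     order_low = 4, order_high = 6) {
  validate_ecg(ecg)
  if (ecg$fs <= 2 * high_hz)
    stop(sprintf("sampling rate %g Hz must exceed twice the upper edge %g Hz",
                 ecg$fs, high_hz), call. = FALSE)
  hp <- butter_coeffs(order_low, low_hz, ecg$fs, "high")
  lp <- butter_coeffs(order_high, high_hz, ecg$fs, "low")
  # generous pad for the slow high-pass transient (~1/low_hz seconds)
  pad <- min(nrow(ecg$samples) - 1L, round(2 * ecg$fs / low_hz))
  out <- apply(ecg$samples, 2, function(x) {
    y <- filtfilt(hp$b, hp$a, x, padlen = pad)
    filtfilt(lp$b, lp$a, y)
  })
  multilead_ecg(out, ecg$fs, ecg$lead_names, ecg$meta)
}

#' Per-lead z-normalization
#'
#' Removes each lead's mean and divides by its standard deviation (over all
#' samples of that lead). Idempotent up to numerical tolerance.
#'
#' @param ecg a [multilead_ecg].
#' @return Normalized [multilead_ecg].
#' @export
normalize_ecg <- function(ecg) {
  validate_ecg(ecg)
  sds <- apply(ecg$samples, 2, stats::sd)
  if (any(sds == 0 | !is.finite(sds)))
    stop("degenerate (constant) lead cannot be normalized: ",
         paste(ecg$lead_names[sds == 0 | !is.finite(sds)], collapse = ", "),
         call. = FALSE)
  out <- scale(ecg$samples, center = TRUE, scale = sds)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  multilead_ecg(out, ecg$fs, ecg$lead_names, ecg$meta)
}

#' Drop lead aVR
#'
#' Fragmentation analysis uses all standard leads except aVR, whose
#' information mirrors other limb leads; a 12-lead recording becomes the
#' 11 analysis leads, order preserved. Recordings without an aVR column pass
#' through with a warning (or silently for non-standard synthetic lead sets).
#'
#' @param ecg a [multilead_ecg].
#' @return The [multilead_ecg] without aVR.
#' @export
select_analysis_leads <- function(ecg) {
  validate_ecg(ecg)
  if (!"aVR" %in% ecg$lead_names) {
    if (any(ecg$lead_names %in% STANDARD_12_LEADS))
      warning("no aVR lead present; recording passed through unchanged",
              call. = FALSE)
    return(ecg)
  }
  ecg[setdiff(ecg$lead_names, "aVR")]
}

#' Standard preprocessing chain
#'
#' Lead selection, band-pass, z-normalization, in that order.
#'
#' @inheritParams bandpass
#' @export
preprocess <- function(ecg, low_hz = 0.5, high_hz = 70) {
  normalize_ecg(bandpass(suppressWarnings(select_analysis_leads(ecg)),
                         low_hz, high_hz))
}
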