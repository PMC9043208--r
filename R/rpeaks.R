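# R-peak detection and cross-lead consolidation.

moving_mean <- function(x, w) {
  cs <- cumsum(c(0, x))
  n <- length(x)
  half <- w %/% 2
  lo <- pmax(0, seq_len(n) - half - 1)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1] - cs[lo + 1]) / (hi - lo)
}

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

#' Detect R-peaks in a single lead
#'
#' Envelope-based detector in the Pan--Tompkins family: zero-phase band-pass
#' at 8--30 Hz, differentiation, squaring, 150 ms moving-window integration,
#' then an adaptive signal/noise threshold with a 200 ms refractory period
#' and a search-back pass for long RR gaps. Peak positions are refined to the
#' extremum of `|signal|`, so inverted-QRS leads are handled symmetrically.
#'
#' @param signal one preprocessed lead (numeric vector).
#' @param fs sampling rate in Hz.
#' @return Strictly increasing integer sample indices (possibly empty).
#' @export
detect_rpeaks_single <- function(signal, fs) {
  n <- length(signal)
  if (n < fs) return(integer(0))
  if (all(signal == signal[1])) return(integer(0))
  bp_lo <- butter_coeffs(2, 8, fs, "high")
  bp_hi <- butter_coeffs(2, 30, fs, "low")
  y <- filtfilt(bp_hi$b, bp_hi$a, filtfilt(bp_lo$b, bp_lo$a, signal))
  d <- c(y[2] - y[1], (y[3:n] - y[1:(n - 2)]) / 2, y[n] - y[n - 1])
  integ <- moving_mean(d^2, max(3L, round(0.15 * fs)))

  cand <- local_maxima(integ)
  if (length(cand) == 0) return(integer(0))
  # enforce candidate separation >= 200 ms, keeping the larger
  refr <- round(0.2 * fs)
  keep <- logical(length(cand))
  for (i in order(-integ[cand])) {
    ci <- cand[i]
    if (!any(keep & abs(cand - ci) < refr)) keep[i] <- TRUE
  }
  cand <- sort(cand[keep])
  amps <- integ[cand]

  # adaptive two-level threshold (signal peak / noise peak running averages)
  spki <- max(integ[seq_len(min(n, 2 * fs))]) * 0.75
  npki <- mean(integ[seq_len(min(n, 2 * fs))]) * 0.5
  accepted <- logical(length(cand))
  for (i in seq_along(cand)) {
    thr <- npki + 0.25 * (spki - npki)
    if (amps[i] > thr) {
      accepted[i] <- TRUE
      spki <- 0.125 * amps[i] + 0.875 * spki
    } else {
      npki <- 0.125 * amps[i] + 0.875 * npki
    }
  }
  # search-back: recover missed beats inside long RR gaps at half threshold
  acc_idx <- which(accepted)
  if (length(acc_idx) >= 2) {
    rr_avg <- mean(diff(cand[acc_idx]))
    for (g in seq_len(length(acc_idx) - 1)) {
      a <- acc_idx[g]; b <- acc_idx[g + 1]
      if (cand[b] - cand[a] > 1.66 * rr_avg && b - a > 1) {
        mid <- (a + 1):(b - 1)
        best <- mid[which.max(amps[mid])]
        if (amps[best] > 0.3 * (npki + 0.25 * (spki - npki)))
          accepted[best] <- TRUE
      }
    }
  }
  peaks <- cand[accepted]
  if (length(peaks) == 0) return(integer(0))

  # refine to the extremum of |signal| near each envelope peak
  half <- as.integer(round(0.075 * fs))
  refined <- vapply(peaks, function(p) {
    lo <- max(1L, as.integer(p) - half); hi <- min(n, as.integer(p) + half)
    lo + which.max(abs(signal[lo:hi])) - 1L
  }, integer(1))
  refined <- sort(unique(refined))
  # final refractory dedupe
  if (length(refined) > 1) {
    out <- refined[1]
    for (r in refined[-1]) {
      if (r - out[length(out)] >= refr) out <- c(out, r)
      else if (abs(signal[r]) > abs(signal[out[length(out)]]))
        out[length(out)] <- r
    }
    refined <- out
  }
  as.integer(refined)
}

stat_mode_larger <- function(x) {
  tab <- table(x)
  m <- as.integer(names(tab)[tab == max(tab)])
  max(m) # tie -> larger count: prefer recovering beats over discarding
}

#' Consolidate per-lead R-peak detections across leads
#'
#' Implements the multi-lead consensus step: the beat count `n_R` is the mode
#' of the per-lead detection counts (ties broken upward). Detections from all
#' leads are greedily clustered within 100 ms into consensus beats; the `n_R`
#' best-supported clusters define the consensus positions. Leads with extra
#' detections keep only the `n_R` detections matched closest to the consensus
#' positions; leads with missing beats recover them by a maximum search over
#' `|signal|` in a 40 ms window centred on the cross-lead average position.
#'
#' @param per_lead_peaks list of integer index vectors, one per lead.
#' @param ecg the [multilead_ecg] the detections came from.
#' @return An `rpeak_matrix`: integer matrix `n_R x n_leads` (columns strictly
#'   increasing), with attribute `n_R`.
#' @export
consolidate_rpeaks <- function(per_lead_peaks, ecg) {
  validate_ecg(ecg)
  L <- n_leads(ecg)
  stopifnot(length(per_lead_peaks) == L)
  counts <- lengths(per_lead_peaks)
  if (all(counts == 0))
    stop("segmentation failure: no R-peaks detected in any lead",
         call. = FALSE)
  fs <- ecg$fs
  n_R <- stat_mode_larger(counts[counts > 0])

  # pool detections and cluster greedily within 100 ms
  pooled <- data.frame(
    idx = unlist(per_lead_peaks),
    lead = rep(seq_len(L), counts))
  pooled <- pooled[order(pooled$idx), ]
  tol <- 0.1 * fs
  cl <- integer(nrow(pooled))
  cl_sum <- numeric(0); cl_n <- integer(0)
  cur <- 0L
  for (i in seq_len(nrow(pooled))) {
    if (cur == 0L || pooled$idx[i] - cl_sum[cur] / cl_n[cur] > tol) {
      cur <- cur + 1L
      cl_sum[cur] <- 0; cl_n[cur] <- 0L
    }
    cl[i] <- cur
    cl_sum[cur] <- cl_sum[cur] + pooled$idx[i]
    cl_n[cur] <- cl_n[cur] + 1L
  }
  support <- vapply(seq_len(cur), function(k)
    length(unique(pooled$lead[cl == k])), integer(1))
  centers <- cl_sum / cl_n
  if (cur < n_R) n_R <- cur
  chosen <- order(-support, centers)[seq_len(n_R)]
  chosen <- chosen[order(centers[chosen])]
  cons <- centers[chosen]

  out <- matrix(NA_integer_, n_R, L)
  match_cap <- 0.15 * fs
  for (l in seq_len(L)) {
    det <- per_lead_peaks[[l]]
    assigned <- rep(NA_integer_, n_R)
    if (length(det) > 0) {
      # greedy one-to-one matching by ascending distance
      dmat <- abs(outer(cons, det, "-"))
      ord <- order(dmat)
      used_c <- logical(n_R); used_d <- logical(length(det))
      for (o in ord) {
        if (dmat[o] > match_cap) break
        ci <- (o - 1) %% n_R + 1
        di <- (o - 1) %/% n_R + 1
        if (!used_c[ci] && !used_d[di]) {
          assigned[ci] <- det[di]
          used_c[ci] <- TRUE; used_d[di] <- TRUE
        }
      }
    }
    # recover missing beats: refined |x| maximum in a 40 ms window
    sig <- ecg$samples[, l]
    half <- max(1L, round(0.02 * fs))
    for (ci in which(is.na(assigned))) {
      c0 <- round(cons[ci])
      lo <- max(1L, c0 - half); hi <- min(nrow(ecg$samples), c0 + half)
      assigned[ci] <- lo + which.max(abs(sig[lo:hi])) - 1L
    }
    out[, l] <- sort(as.integer(assigned))
  }
  structure(out, n_R = n_R, lead_names = ecg$lead_names, fs = fs,
            class = c("rpeak_matrix", class(out)))
}
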