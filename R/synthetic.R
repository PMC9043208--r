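# Synthetic multi-lead ECG with analytic ground truth.
#
# Beats are sums of Gaussian components (P, Q, R, S, T), so the true R
# location, QRS support and injected notch positions are known exactly. This
# is deliberately a *stated world* for testing the pipeline: it emulates the
# data regimes the method targets (narrow/broad QRS, sinus vs AF-like RR
# irregularity, per-lead fragmentation, ectopic beats, realistic noise), not
# the full physiology of a 12-lead vectorcardiographic projection.

#' Synthetic recording configuration
#'
#' @param fs sampling rate in Hz (>= 250).
#' @param duration_s recording length in seconds.
#' @param heart_rate_bpm mean heart rate.
#' @param rhythm `"sinus"` (near-constant RR) or `"af"` (irregular,
#'   heavy-tailed RR with no periodicity).
#' @param rr_cv RR-interval coefficient of variation; defaults to 0.03 for
#'   sinus and 0.2 for AF.
#' @param lead_names leads to synthesize (default: the 11 analysis leads).
#' @param qrs_ms QRS duration in ms (narrow <= 120 < broad).
#' @param fqrs list: `leads` (character vector to fragment), `n_notches`
#'   (1--3), `notch_amp` (fraction of R amplitude), `notch_width_ms`.
#' @param ectopic list: `prob` (per-beat probability), `scale` (QRS widening
#'   factor of the ectopic morphology).
#' @param noise list: `white_sd`, `baseline_amp`, `baseline_hz`,
#'   `powerline_amp`, `powerline_hz` (50 Hz; European mains).
#' @param seed integer seed making the recording fully reproducible.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(fs = 500, duration_s = 10, heart_rate_bpm = 60,
                             rhythm = c("sinus", "af"), rr_cv = NULL,
                             lead_names = ANALYSIS_LEADS, qrs_ms = 90,
                             fqrs = list(), ectopic = list(), noise = list(),
                             seed = 1L) {
  rhythm <- match.arg(rhythm)
  if (is.null(rr_cv)) rr_cv <- if (rhythm == "af") 0.2 else 0.03
  fqrs <- utils::modifyList(list(leads = character(0), n_notches = 2L,
                                 notch_amp = 0.2, notch_width_ms = 6), fqrs)
  ectopic <- utils::modifyList(list(prob = 0, scale = 1.8), ectopic)
  noise <- utils::modifyList(list(white_sd = 0.03, baseline_amp = 0.1,
                                  baseline_hz = 0.3, powerline_amp = 0.02,
                                  powerline_hz = 50), noise)
  cfg <- structure(list(fs = fs, duration_s = duration_s,
                        heart_rate_bpm = heart_rate_bpm, rhythm = rhythm,
                        rr_cv = rr_cv, lead_names = lead_names,
                        qrs_ms = qrs_ms, fqrs = fqrs, ectopic = ectopic,
                        noise = noise, seed = as.integer(seed)),
                   class = "synthetic_config")
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  fail <- function(field, msg) stop("invalid config field '", field, "': ",
                                    msg, call. = FALSE)
  if (cfg$fs < 250) fail("fs", "must be >= 250 Hz")
  if (cfg$duration_s <= 0) fail("duration_s", "must be positive")
  if (cfg$rr_cv < 0) fail("rr_cv", "must be >= 0")
  if (cfg$qrs_ms < 60 || cfg$qrs_ms > 200) fail("qrs_ms", "must be in [60, 200]")
  if (cfg$fqrs$notch_amp < 0) fail("fqrs$notch_amp", "must be >= 0")
  if (!all(cfg$fqrs$leads %in% cfg$lead_names))
    fail("fqrs$leads", "not a subset of lead_names")
  if (cfg$ectopic$prob < 0 || cfg$ectopic$prob > 1)
    fail("ectopic$prob", "must be a probability")
  if (any(unlist(cfg$noise) < 0)) fail("noise", "amplitudes must be >= 0")
  invisible(cfg)
}

# Run code with a private, restored RNG stream.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate one heartbeat waveform
#'
#' Gaussian-sum P-QRS-T model centred on the R peak. Component centres and
#' widths scale with the requested QRS duration so that the measurable QRS
#' support (where the waveform exceeds a few percent of the R amplitude)
#' stays within about 10% of `qrs_ms`.
#'
#' @param qrs_ms QRS duration in ms, in `[60, 200]`.
#' @param amplitudes named vector with components `p`, `q`, `r`, `s`, `t`
#'   (relative to R = 1).
#' @param fs sampling rate in Hz.
#' @return An `ecg_beat`: list with `wave`, `r_idx` (sample of the R centre),
#'   `onset`/`offset` (true QRS boundary samples), `qrs_ms`, `fs`.
#' @export
gen_beat <- function(qrs_ms = 90,
                     amplitudes = c(p = 0.12, q = -0.12, r = 1,
                                    s = -0.25, t = 0.3),
                     fs = 500) {
  stopifnot(qrs_ms >= 60, qrs_ms <= 200)
  a <- amplitudes
  qs <- qrs_ms / 1000
  # time axis: enough room for P before and T after; the grid contains
  # t = 0 exactly so the R apex sits on a sample
  n_pre <- ceiling((qs / 2 + 0.22) * fs)
  n_post <- ceiling((qs / 2 + 0.28) * fs)
  tt <- (-n_pre:n_post) / fs
  g <- function(amp, mu, sigma) amp * exp(-(tt - mu)^2 / (2 * sigma^2))
  wave <- g(a[["p"]], -(qs / 2 + 0.10), 0.022) +
    g(a[["q"]], -0.35 * qs, 0.065 * qs) +
    g(a[["r"]], 0, 0.11 * qs) +
    g(a[["s"]], 0.35 * qs, 0.065 * qs) +
    g(a[["t"]], qs / 2 + 0.16, 0.055)
  r_idx <- which.min(abs(tt))
  half <- round(qs / 2 * fs)
  structure(list(wave = as.numeric(wave), r_idx = r_idx,
                 onset = r_idx - half, offset = r_idx + half,
                 qrs_ms = qrs_ms, fs = fs),
            class = "ecg_beat")
}

#' Inject fragmentation notches into a beat
#'
#' Adds `n_notches` narrow Gaussian deflections inside the QRS support. Each
#' notch deflects *against* the local waveform (a dip carved into an upright
#' wave, a bump on a downward wave), which is how clinically visible
#' fragmentation presents. When centres are drawn automatically (through the
#' current RNG stream), placements are rejection-sampled so that -- at
#' amplitudes above the detectability range -- every notch produces a
#' distinct turning point of relief comparable to its amplitude, emulating
#' full-agreement ("clearly fragmented") morphology; at sub-threshold
#' amplitudes the notch may degrade into a slur, emulating the ambiguous
#' class. Pass `centers_ms` (and optionally `signs`) to place notches
#' explicitly.
#'
#' @param beat an `ecg_beat` from [gen_beat()].
#' @param n_notches number of notches (1--3 typical).
#' @param amp notch amplitude as a fraction of the R amplitude.
#' @param width_ms notch full width at half maximum in ms.
#' @param centers_ms optional explicit notch centres in ms relative to R.
#' @param signs optional explicit notch signs (+1/-1), recycled.
#' @return The beat with notches added; `$notch_centers_ms` records truth.
#' @export
inject_fqrs <- function(beat, n_notches = 2, amp = 0.2, width_ms = 6,
                        centers_ms = NULL, signs = NULL) {
  stopifnot(inherits(beat, "ecg_beat"))
  if (width_ms > 0.6 * beat$qrs_ms)
    stop("notch width ", width_ms, " ms too large for a ", beat$qrs_ms,
         " ms QRS", call. = FALSE)
  tt <- (seq_along(beat$wave) - beat$r_idx) / beat$fs * 1000 # ms
  sigma <- width_ms / 2.355 # FWHM -> sd
  notch_sign <- function(wave, c_ms) {
    v <- wave[which.min(abs(tt - c_ms))]
    if (abs(v) < 0.08) sample(c(-1, 1), 1) else -sign(v)
  }
  add_notch <- function(wave, c_ms, sgn)
    wave + sgn * amp * exp(-(tt - c_ms)^2 / (2 * sigma^2))
  # number of prominent turning points near a centre; a visible notch must
  # create a new one relative to the pre-injection waveform
  min_prom <- max(0.05, 0.4 * amp)
  half_win <- 4L * ceiling(sigma * beat$fs / 1000)
  prominent_extrema <- function(wave, ci) {
    win <- max(1, ci - half_win):min(length(wave), ci + half_win)
    n_ex <- 0L
    for (v in list(wave, -wave)) {
      pk <- local_maxima(v)
      pk <- pk[pk %in% win]
      if (length(pk) > 0)
        n_ex <- n_ex + sum(peak_prominences(v, pk) >= min_prom)
    }
    n_ex
  }

  if (is.null(centers_ms)) {
    # greedy placement: over a jittered candidate grid inside the QRS, pick
    # for each notch the centre whose injection adds the most prominent
    # turning points (random order breaks ties)
    lim <- 0.35 * beat$qrs_ms
    centers <- numeric(0); sgns <- numeric(0)
    wave <- beat$wave
    for (k in seq_len(n_notches)) {
      grid <- seq(-lim, lim, by = 2) + stats::runif(1, -1, 1)
      grid <- grid[abs(grid) <= 0.45 * beat$qrs_ms]
      if (length(centers) > 0)
        grid <- grid[vapply(grid, function(g)
          min(abs(centers - g)) >= 1.4 * width_ms, logical(1))]
      if (length(grid) == 0) break
      grid <- sample(grid)
      best <- NULL; best_gain <- -Inf
      for (g in grid) {
        sgn <- notch_sign(wave, g)
        cand <- add_notch(wave, g, sgn)
        ci <- which.min(abs(tt - g))
        gain <- prominent_extrema(cand, ci) - prominent_extrema(wave, ci)
        if (gain > best_gain) {
          best_gain <- gain
          best <- list(c = g, s = sgn, w = cand)
        }
      }
      wave <- best$w
      centers <- c(centers, best$c); sgns <- c(sgns, best$s)
    }
    ord <- order(centers)
    centers_ms <- centers[ord]; signs <- sgns[ord]
    if (amp > 0) beat$wave <- wave
  } else {
    if (any(abs(centers_ms) > 0.5 * beat$qrs_ms))
      stop("notch centres must lie inside the QRS support", call. = FALSE)
    if (is.null(signs))
      signs <- vapply(centers_ms, function(cm) notch_sign(beat$wave, cm),
                      numeric(1))
    signs <- rep_len(signs, length(centers_ms))
    if (amp > 0)
      for (i in seq_along(centers_ms))
        beat$wave <- add_notch(beat$wave, centers_ms[i], signs[i])
  }
  beat$notch_centers_ms <- centers_ms
  beat$notch_signs <- signs
  beat$notch_amp <- amp
  beat
}

# Fixed per-lead polarity and base gain profile: V1 is predominantly
# negative, limb leads vary in amplitude. Crude but gives the detector and
# consolidation realistic cross-lead diversity.
lead_profile <- function(lead_names) {
  pol <- ifelse(lead_names == "V1", -1, 1)
  base <- c(I = 0.8, II = 1.0, III = 0.6, aVR = 0.7, aVL = 0.5, aVF = 0.8,
            V1 = 0.7, V2 = 1.1, V3 = 1.2, V4 = 1.1, V5 = 1.0, V6 = 0.9)
  gain <- ifelse(lead_names %in% names(base), base[lead_names], 1)
  list(polarity = pol, gain = as.numeric(gain))
}

#' Generate a synthetic multi-lead recording with ground truth
#'
#' RR intervals are drawn per rhythm (sinus: Gaussian, low CV; AF: lognormal,
#' high CV, independent draws with no periodicity), beats are placed on a
#' shared timeline across leads, per-lead amplitude/polarity mixing is
#' applied, fragmentation notches are injected only in the configured leads
#' (with a fixed per-lead notch pattern across beats, as fragmentation is a
#' stable conduction property), ectopic beats replace the normal morphology
#' with a widened inverted complex, and white/baseline/powerline noise is
#' added. Fully reproducible from `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return list with `ecg` ([multilead_ecg]) and `truth` (list: `r_locations`,
#'   `qrs_onset`, `qrs_offset` (samples), `ectopic` flags, `rhythm`,
#'   `fqrs_label` and `ordinal_label` per lead, `notch_amp` per lead).
#' @export
gen_recording <- function(config = synthetic_config()) {
  validate_synthetic_config(config)
  with_seed(config$seed, {
    fs <- config$fs
    n <- round(config$duration_s * fs)
    mean_rr <- 60 / config$heart_rate_bpm
    n_max <- ceiling(config$duration_s / mean_rr * 2) + 4
    rr <- if (config$rhythm == "af") {
      sdlog <- sqrt(log(1 + config$rr_cv^2))
      stats::rlnorm(n_max, log(mean_rr) - sdlog^2 / 2, sdlog)
    } else {
      stats::rnorm(n_max, mean_rr, config$rr_cv * mean_rr)
    }
    rr <- pmax(rr, 0.35)
    r_times <- 0.45 + cumsum(c(0, rr))
    r_times <- r_times[r_times < config$duration_s - 0.45]
    n_beats <- length(r_times)
    r_loc <- round(r_times * fs) + 1L

    clean <- gen_beat(config$qrs_ms, fs = fs)
    ect_amp <- c(p = 0, q = -0.1, r = -1, s = 0.35, t = 0.45)
    ect_ms <- min(200, config$qrs_ms * config$ectopic$scale)
    ect <- gen_beat(ect_ms, amplitudes = ect_amp, fs = fs)
    ectopic <- stats::rbinom(n_beats, 1, config$ectopic$prob) == 1

    leads <- config$lead_names
    prof <- lead_profile(leads)
    frag <- leads %in% config$fqrs$leads & config$fqrs$notch_amp > 0
    lead_beats <- lapply(seq_along(leads), function(li) {
      if (frag[li])
        inject_fqrs(clean, config$fqrs$n_notches, config$fqrs$notch_amp,
                    config$fqrs$notch_width_ms)
      else clean
    })

    sig <- matrix(0, n, length(leads))
    add_beat <- function(col, beat, center) {
      idx <- center + (seq_along(beat$wave) - beat$r_idx)
      keep <- idx >= 1 & idx <= n
      col[idx[keep]] <- col[idx[keep]] + beat$wave[keep]
      col
    }
    gain_jit <- stats::runif(length(leads), 0.85, 1.15)
    for (li in seq_along(leads)) {
      col <- numeric(n)
      for (b in seq_len(n_beats)) {
        beat <- if (ectopic[b]) ect else lead_beats[[li]]
        col <- add_beat(col, beat, r_loc[b])
      }
      g <- prof$polarity[li] * prof$gain[li] * gain_jit[li]
      tvec <- (seq_len(n) - 1) / fs
      nz <- config$noise
      col <- g * col +
        stats::rnorm(n, 0, nz$white_sd) +
        nz$baseline_amp * sin(2 * pi * nz$baseline_hz * tvec +
                                stats::runif(1, 0, 2 * pi)) +
        nz$powerline_amp * sin(2 * pi * nz$powerline_hz * tvec +
                                 stats::runif(1, 0, 2 * pi))
      sig[, li] <- col
    }

    half_n <- round(config$qrs_ms / 2000 * fs)
    half_e <- round(ect_ms / 2000 * fs)
    halfs <- ifelse(ectopic, half_e, half_n)
    notch_amp_lead <- ifelse(frag, config$fqrs$notch_amp, 0)
    ordinal <- vapply(notch_amp_lead, ordinal_label_from_amp, numeric(1))

    list(ecg = multilead_ecg(sig, fs, leads,
                             meta = list(source = "synthetic",
                                         seed = config$seed,
                                         rhythm = config$rhythm)),
         truth = list(r_locations = r_loc,
                      qrs_onset = r_loc - halfs,
                      qrs_offset = r_loc + halfs,
                      ectopic = ectopic,
                      rhythm = config$rhythm,
                      fqrs_label = as.integer(frag),
                      ordinal_label = as.integer(ordinal),
                      notch_amp = notch_amp_lead,
                      lead_names = leads,
                      config = config))
  })
}

# Emulated 5-observer ordinal label (0..5) from notch amplitude. Amplitudes
# outside the ambiguity band get full agreement (0 or 5) by construction;
# inside the band the vote count is a noisy monotone function of amplitude,
# clamped to 1..4. This emulates inter-observer disagreement, it is not a
# model of any real observer panel.
ordinal_label_from_amp <- function(amp, band = c(0.06, 0.16)) {
  if (amp <= 0) return(0)
  if (amp >= band[2]) return(5)
  if (amp < band[1]) return(0)
  pos <- (amp - band[1]) / (band[2] - band[1])
  1 + stats::rbinom(1, 3, pos)
}

#' Generate a labelled synthetic cohort
#'
#' Draws per-recording rhythm (AF fraction `rhythm_mix`), QRS width (broad
#' fraction `narrow_broad_mix`) and per-lead fragmentation (independent
#' Bernoulli with probability `fqrs_prevalence`). A fraction
#' `ambiguity_frac` of fragmented leads receive sub-threshold notch
#' amplitudes and therefore ordinal labels 1--4 (observer disagreement);
#' the remainder get clearly visible notches (ordinal 5).
#'
#' Recordings are not materialized: the returned object holds one
#' [synthetic_config()] per recording (regenerate any of them with
#' [gen_recording()]) plus a per-lead manifest with all labels.
#'
#' @param n_recordings number of recordings.
#' @param fqrs_prevalence per-lead probability of fragmentation.
#' @param narrow_broad_mix fraction of recordings with broad (> 120 ms) QRS.
#' @param rhythm_mix fraction of AF recordings.
#' @param ambiguity_frac fraction of fragmented leads with ambiguous
#'   (sub-threshold) notches.
#' @param ectopic_prob per-beat ectopic probability.
#' @param seed master seed; per-recording seeds are derived from it.
#' @param out_dir if non-NULL, WFDB records and `manifest.csv` are written
#'   there.
#' @return list with `manifest` (data.frame: one row per recording x lead)
#'   and `configs` (list of per-recording configs).
#' @export
gen_cohort <- function(n_recordings = 100, fqrs_prevalence = 0.3,
                       narrow_broad_mix = 0.5, rhythm_mix = 0.1,
                       ambiguity_frac = 0.2, ectopic_prob = 0.03,
                       seed = 1L, out_dir = NULL) {
  stopifnot(fqrs_prevalence >= 0, fqrs_prevalence <= 1,
            narrow_broad_mix >= 0, narrow_broad_mix <= 1,
            rhythm_mix >= 0, rhythm_mix <= 1,
            ambiguity_frac >= 0, ambiguity_frac <= 1)
  leads <- ANALYSIS_LEADS
  with_seed(seed, {
    rows <- list()
    configs <- vector("list", n_recordings)
    for (i in seq_len(n_recordings)) {
      rhythm <- if (stats::runif(1) < rhythm_mix) "af" else "sinus"
      broad <- stats::runif(1) < narrow_broad_mix
      qrs_ms <- if (broad) round(stats::runif(1, 125, 165)) else
        round(stats::runif(1, 80, 115))
      frag_leads <- leads[stats::runif(length(leads)) < fqrs_prevalence]
      ambiguous <- length(frag_leads) > 0 && stats::runif(1) < ambiguity_frac
      notch_amp <- if (length(frag_leads) == 0) 0 else if (ambiguous)
        stats::runif(1, 0.07, 0.155) else stats::runif(1, 0.18, 0.32)
      n_notches <- sample(1:3, 1)
      hr <- round(stats::runif(1, 55, 95))
      rec_seed <- as.integer((as.numeric(seed) * 1000 + i) %% 2147483647)
      cfg <- synthetic_config(
        rhythm = rhythm, qrs_ms = qrs_ms, heart_rate_bpm = hr,
        fqrs = list(leads = frag_leads, n_notches = n_notches,
                    notch_amp = notch_amp),
        ectopic = list(prob = ectopic_prob), seed = rec_seed)
      configs[[i]] <- cfg
      ordinal <- vapply(
        ifelse(leads %in% frag_leads, notch_amp, 0),
        ordinal_label_from_amp, numeric(1))
      rows[[i]] <- data.frame(
        recording_id = sprintf("rec%04d", i), lead = leads,
        binary = as.integer(leads %in% frag_leads & notch_amp > 0),
        ordinal = as.integer(ordinal),
        notch_amp = ifelse(leads %in% frag_leads, notch_amp, 0),
        rhythm = rhythm, qrs_ms = qrs_ms, seed = rec_seed,
        stringsAsFactors = FALSE)
    }
    manifest <- do.call(rbind, rows)
    cohort <- list(manifest = manifest, configs = configs, seed = seed)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      for (i in seq_len(n_recordings)) {
        rec <- gen_recording(configs[[i]])
        write_wfdb(rec$ecg, file.path(out_dir, sprintf("rec%04d", i)))
      }
      utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                       row.names = FALSE)
    }
    cohort
  })
}
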