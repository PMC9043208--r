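#' Multi-lead ECG container
#'
#' A light S3 container for a short multi-lead ECG strip: a numeric sample
#' matrix (one column per lead), the sampling rate in Hz, ordered lead names
#' and a free-form metadata list. All pipeline stages consume and return this
#' class.
#'
#' @param samples numeric matrix, `n_samples x n_leads`.
#' @param fs sampling rate in Hz (scalar, > 0).
#' @param lead_names character vector of unique lead labels, one per column.
#' @param meta optional named list of provenance information.
#' @return An object of class `multilead_ecg`.
#' @examples
#' x <- multilead_ecg(cbind(I = sin(1:1000 / 20), II = cos(1:1000 / 20)), fs = 250)
#' n_leads(x)
#' @export
multilead_ecg <- function(samples, fs, lead_names = colnames(samples),
                          meta = list()) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (is.null(lead_names)) {
    lead_names <- paste0("L", seq_len(ncol(samples)))
  }
  colnames(samples) <- lead_names
  obj <- structure(list(samples = samples, fs = as.numeric(fs),
                        lead_names = as.character(lead_names), meta = meta),
                   class = "multilead_ecg")
  validate_ecg(obj)
  obj
}

validate_ecg <- function(x) {
  stopifnot(inherits(x, "multilead_ecg"))
  if (length(x$fs) != 1L || !is.finite(x$fs) || x$fs <= 0)
    stop("fs must be a positive scalar (Hz)", call. = FALSE)
  if (ncol(x$samples) < 2L)
    stop("a multilead_ecg needs at least 2 leads", call. = FALSE)
  if (anyDuplicated(x$lead_names))
    stop("duplicate lead names: ",
         paste(unique(x$lead_names[duplicated(x$lead_names)]), collapse = ", "),
         call. = FALSE)
  if (length(x$lead_names) != ncol(x$samples))
    stop("lead_names must match the number of sample columns", call. = FALSE)
  invisible(x)
}

#' @rdname multilead_ecg
#' @param x a `multilead_ecg` object.
#' @export
n_leads <- function(x) ncol(x$samples)

#' @rdname multilead_ecg
#' @export
n_samples <- function(x) nrow(x$samples)

#' @rdname multilead_ecg
#' @export
duration_s <- function(x) nrow(x$samples) / x$fs

#' @export
print.multilead_ecg <- function(x, ...) {
  cat(sprintf("<multilead_ecg> %d leads x %d samples @ %g Hz (%.1f s)\n",
              n_leads(x), n_samples(x), x$fs, duration_s(x)))
  cat("  leads:", paste(x$lead_names, collapse = " "), "\n")
  invisible(x)
}

#' @export
`[.multilead_ecg` <- function(x, leads) {
  if (is.character(leads)) leads <- match(leads, x$lead_names)
  multilead_ecg(x$samples[, leads, drop = FALSE], x$fs,
                x$lead_names[leads], x$meta)
}

#' Standard lead sets
#'
#' `STANDARD_12_LEADS` is the conventional 12-lead order;
#' `ANALYSIS_LEADS` is the 11-lead analysis set (aVR, whose information
#' mirrors the other limb leads, is excluded).
#' @export
STANDARD_12_LEADS <- c("I", "II", "III", "aVR", "aVL", "aVF",
                       "V1", "V2", "V3", "V4", "V5", "V6")

#' @rdname STANDARD_12_LEADS
#' @export
ANALYSIS_LEADS <- setdiff(STANDARD_12_LEADS, "aVR")
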