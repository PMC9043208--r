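#' Read a multi-lead ECG recording
#'
#' Reads a short ECG strip either from a WFDB record (`.hea` header plus
#' format-16 `.dat` signal file) or from delimited text whose first row names
#' the leads, one column per lead. A `time` column (case-insensitive) in text
#' input is ignored. Samples are returned in their original units.
#'
#' @param path path to the record: the `.hea` file (or its basename) for WFDB,
#'   or the text file for `format = "csv"`.
#' @param format `"wfdb"` or `"csv"`. Default guesses from the extension.
#' @param fs sampling rate in Hz; required for csv input (text files carry no
#'   rate), ignored for WFDB which stores it in the header.
#' @param sep field separator for text input.
#' @return A [multilead_ecg].
#' @export
read_recording <- function(path, format = c("auto", "wfdb", "csv"), fs = NULL,
                           sep = ",") {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("hea", "dat", "")) "wfdb" else "csv"
  }
  if (format == "wfdb") return(read_wfdb(path))
  if (!file.exists(path)) stop("cannot read recording: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  hdr <- gsub('^"|"$', "", trimws(strsplit(first, sep, fixed = TRUE)[[1]]))
  if (length(hdr) < 2L || !all(grepl("[A-Za-z]", hdr)))
    stop("schema error: first row of ", path,
         " must be a lead-name header", call. = FALSE)
  keep <- tolower(hdr) != "time"
  if (anyDuplicated(hdr[keep]))
    stop("schema error: duplicate lead name in header of ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE),
    error = function(e) stop("unparseable delimited file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  names(df) <- hdr
  df <- df[, keep, drop = FALSE]
  if (!all(vapply(df, is.numeric, logical(1))))
    stop("schema error: non-numeric lead column in ", path, call. = FALSE)
  if (is.null(fs)) stop("fs (Hz) must be supplied for delimited text input",
                        call. = FALSE)
  ecg <- multilead_ecg(as.matrix(df), fs = fs,
                       meta = list(source = path, format = "csv"))
  check_duration(ecg)
  ecg
}

check_duration <- function(ecg, min_s = 5) {
  if (duration_s(ecg) < min_s)
    stop(sprintf("recording too short: %.2f s < %g s", duration_s(ecg), min_s),
         call. = FALSE)
  invisible(ecg)
}

# --- Minimal WFDB support (format 16, little-endian int16) ------------------
# Only the subset of the header grammar this package writes is parsed:
#   record_name n_sig fs n_samples
#   file_name format gain(baseline)/units ... lead_name   (per signal)

#' Read a WFDB record (format 16)
#'
#' @param path path to the `.hea` file or the record basename.
#' @return A [multilead_ecg] with samples converted to physical units.
#' @export
read_wfdb <- function(path) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop("cannot read WFDB header: ", hea, call. = FALSE)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  rec <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(rec) < 4) stop("malformed WFDB record line in ", hea, call. = FALSE)
  n_sig <- as.integer(rec[2])
  fs <- as.numeric(rec[3])
  n_samp <- as.integer(rec[4])
  sig <- lines[2:(1 + n_sig)]
  parse_sig <- function(s) {
    f <- strsplit(trimws(s), "\\s+")[[1]]
    gain_spec <- f[3]
    gain <- as.numeric(sub("^([-0-9.eE+]+).*$", "\\1", gain_spec))
    baseline <- if (grepl("\\(", gain_spec))
      as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_spec)) else 0
    list(file = f[1], fmt = f[2], gain = gain, baseline = baseline,
         name = f[length(f)])
  }
  sigs <- lapply(sig, parse_sig)
  fmts <- unique(vapply(sigs, `[[`, character(1), "fmt"))
  if (!identical(fmts, "16"))
    stop("only WFDB format 16 is supported (got ", paste(fmts, collapse = ","),
         ")", call. = FALSE)
  dat <- file.path(dirname(hea), sigs[[1]]$file)
  raw <- readBin(dat, what = "integer", size = 2, signed = TRUE,
                 endian = "little", n = n_sig * n_samp)
  if (length(raw) < n_sig * n_samp)
    stop("WFDB .dat file shorter than header promises: ", dat, call. = FALSE)
  m <- matrix(as.numeric(raw), ncol = n_sig, byrow = TRUE)
  for (j in seq_len(n_sig))
    m[, j] <- (m[, j] - sigs[[j]]$baseline) / sigs[[j]]$gain
  ecg <- multilead_ecg(m, fs = fs,
                       lead_names = vapply(sigs, `[[`, character(1), "name"),
                       meta = list(source = hea, format = "wfdb"))
  check_duration(ecg)
  ecg
}

#' Write a WFDB record (format 16)
#'
#' Quantizes each lead with a fixed gain so the round trip
#' `read_wfdb(write_wfdb(x))` reproduces `x` within one quantization step.
#'
#' @param ecg a [multilead_ecg].
#' @param record record basename (directory + name, no extension).
#' @param gain ADC units per physical unit (default 1000, ~1 uV resolution
#'   for signals in mV).
#' @return The `.hea` path, invisibly.
#' @export
write_wfdb <- function(ecg, record, gain = 1000) {
  validate_ecg(ecg)
  nsig <- n_leads(ecg)
  nsamp <- n_samples(ecg)
  base <- basename(record)
  dat_name <- paste0(base, ".dat")
  q <- round(ecg$samples * gain)
  if (any(abs(q) > 32767))
    stop("signal amplitude exceeds int16 range at gain ", gain, call. = FALSE)
  hea <- c(sprintf("%s %d %g %d", base, nsig, ecg$fs, nsamp),
           sprintf("%s 16 %g(0)/mV 16 0 0 0 0 %s", dat_name, gain,
                   ecg$lead_names))
  writeLines(hea, paste0(record, ".hea"))
  con <- file(file.path(dirname(paste0(record, ".hea")), dat_name), "wb")
  on.exit(close(con))
  writeBin(as.integer(t(q)), con, size = 2, endian = "little")
  invisible(paste0(record, ".hea"))
}

#' Write / read per-lead fQRS score tables
#'
#' The score table is the pipeline's terminal output: one row per analyzed
#' lead with the continuous score in `[0, 1]` and its 0.5-threshold
#' binarization.
#'
#' @param scores data.frame with columns `recording_id`, `lead`, `score`,
#'   `binary` (`score`/`binary` may be NA for unanalyzable leads).
#' @param path output path; `.json` writes JSON, anything else CSV.
#' @export
write_score_table <- function(scores, path) {
  stopifnot(all(c("recording_id", "lead", "score", "binary") %in% names(scores)))
  ok <- stats::complete.cases(scores$score)
  if (any(scores$score[ok] < 0 | scores$score[ok] > 1))
    stop("scores must lie in [0, 1]", call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(scores, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(scores, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path)
  }
}
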