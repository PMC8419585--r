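#' @useDynLib whistlemod, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats approx median sd quantile rnorm runif rlnorm wilcox.test
#'   chisq.test fisher.test setNames aggregate complete.cases
#' @importFrom utils read.csv write.csv head
#' @importFrom graphics matplot lines legend
NULL

SPECIES_LEVELS <- c("short_beaked", "long_beaked", "unknown")

#' Construct a whistle contour
#'
#' The atomic unit of the pipeline: the fundamental-frequency trace of one
#' whistle (time in seconds relative to whistle start, frequency in Hz)
#' together with its recording metadata. Harmonics are out of scope; the
#' contour is the fundamental only.
#'
#' @param whistle_id unique identifier string.
#' @param time_s numeric vector of strictly increasing times (seconds).
#' @param freq_hz numeric vector of positive frequencies (Hz), same length.
#' @param encounter_id identifier of the school/encounter the whistle was
#'   recorded from.
#' @param species one of `"short_beaked"`, `"long_beaked"`, `"unknown"`.
#' @param sample_rate_hz recording sampling rate (Hz); every contour frequency
#'   must lie below the Nyquist frequency `sample_rate_hz / 2`.
#' @param file_id identifier of the recording file.
#' @param file_offset_s start time of the whistle within the file (seconds).
#' @param stereotype_id optional tag marking membership in a repeated
#'   stereotyped (signature-like) whistle series; `NA` if not stereotyped.
#' @param snr_db optional signal-to-noise ratio (dB) carried as metadata.
#' @return an object of class `whistle_contour`.
#' @export
whistle_contour <- function(whistle_id, time_s, freq_hz,
                            encounter_id = "enc1",
                            species = "unknown",
                            sample_rate_hz = 96000,
                            file_id = "file1",
                            file_offset_s = 0,
                            stereotype_id = NA_character_,
                            snr_db = NA_real_) {
  w <- structure(
    list(whistle_id = as.character(whistle_id),
         encounter_id = as.character(encounter_id),
         species = as.character(species),
         sample_rate_hz = as.numeric(sample_rate_hz),
         file_id = as.character(file_id),
         file_offset_s = as.numeric(file_offset_s),
         time_s = as.numeric(time_s),
         freq_hz = as.numeric(freq_hz),
         stereotype_id = as.character(stereotype_id),
         snr_db = as.numeric(snr_db)),
    class = "whistle_contour")
  validate_contour(w)
  w
}

#' Validate a whistle contour's invariants
#'
#' Checks the structural contract every downstream stage relies on: at least
#' two points, strictly increasing times, positive frequencies below the
#' Nyquist frequency of the recording, and positive duration.
#'
#' @param w a `whistle_contour`.
#' @return `w`, invisibly; errors (naming the whistle) on violation.
#' @export
validate_contour <- function(w) {
  id <- w$whistle_id
  if (length(w$time_s) < 2L)
    stop("whistle '", id, "': contour needs at least 2 points", call. = FALSE)
  if (length(w$time_s) != length(w$freq_hz))
    stop("whistle '", id, "': time and frequency vectors differ in length",
         call. = FALSE)
  if (any(diff(w$time_s) <= 0))
    stop("whistle '", id, "': times must be strictly increasing", call. = FALSE)
  if (any(!is.finite(w$freq_hz)) || any(w$freq_hz <= 0))
    stop("whistle '", id, "': all frequencies must be positive", call. = FALSE)
  if (!is.finite(w$sample_rate_hz) || w$sample_rate_hz <= 0)
    stop("whistle '", id, "': sample rate must be positive", call. = FALSE)
  if (any(w$freq_hz >= w$sample_rate_hz / 2))
    stop("whistle '", id, "': contour frequency at or above Nyquist (",
         w$sample_rate_hz / 2, " Hz)", call. = FALSE)
  if (!w$species %in% SPECIES_LEVELS)
    stop("whistle '", id, "': unknown species label '", w$species, "'",
         call. = FALSE)
  if (w$file_offset_s < 0)
    stop("whistle '", id, "': file offset must be non-negative", call. = FALSE)
  invisible(w)
}

#' @export
print.whistle_contour <- function(x, ...) {
  cat(sprintf(
    "<whistle_contour> %s | %s | %s | %d pts | %.3f s | %.0f-%.0f Hz\n",
    x$whistle_id, x$encounter_id, x$species, length(x$time_s),
    contour_duration(x), min(x$freq_hz), max(x$freq_hz)))
  invisible(x)
}

#' Duration of a contour in seconds
#' @param w a `whistle_contour`.
#' @return numeric scalar, last time minus first time.
#' @export
contour_duration <- function(w) {
  w$time_s[length(w$time_s)] - w$time_s[1L]
}

#' Construct an encounter (school) record
#'
#' One recording event of a single-species dolphin school. Schools are
#' single-species by design, so the species label lives here and is copied to
#' the school's whistles.
#'
#' @param encounter_id identifier string.
#' @param species `"short_beaked"` or `"long_beaked"`.
#' @param school_size_estimate estimated number of animals (>= 1).
#' @param year integer calendar year of the encounter.
#' @param sample_rate_hz recording sampling rate (Hz).
#' @return one-row data frame with class `encounter_record` rules applied.
#' @export
encounter_record <- function(encounter_id, species, school_size_estimate,
                             year = 2019L, sample_rate_hz = 96000) {
  if (school_size_estimate < 1)
    stop("school_size_estimate must be >= 1", call. = FALSE)
  if (!species %in% c("short_beaked", "long_beaked"))
    stop("encounters are single-species: species must be short_beaked or ",
         "long_beaked", call. = FALSE)
  data.frame(encounter_id = as.character(encounter_id),
             species = as.character(species),
             school_size_estimate = as.integer(school_size_estimate),
             year = as.integer(year),
             sample_rate_hz = as.numeric(sample_rate_hz),
             stringsAsFactors = FALSE)
}

#' Read whistle contours and metadata from CSV tables
#'
#' The on-disk layout is long-format and diff-friendly: a point table with one
#' contour point per row (`whistle_id, time_s, freq_hz`) and a metadata table
#' keyed by `whistle_id` (`whistle_id, encounter_id, species, sample_rate_hz,
#' file_id, file_offset_s, stereotype_id, snr_db`). An optional encounter table
#' (`encounter_id, species, school_size_estimate, year, sample_rate_hz`)
#' describes the schools.
#'
#' @param contour_path path to the contour point CSV.
#' @param metadata_path path to the whistle metadata CSV.
#' @param encounter_path optional path to the encounter CSV.
#' @return a list with `whistles` (named list of [whistle_contour()] objects,
#'   in metadata-row order) and `encounters` (data frame or `NULL`).
#' @export
read_contours <- function(contour_path, metadata_path, encounter_path = NULL) {
  pts <- read.csv(contour_path, stringsAsFactors = FALSE)
  meta <- read.csv(metadata_path, stringsAsFactors = FALSE)
  need <- c("whistle_id", "time_s", "freq_hz")
  if (!all(need %in% names(pts)))
    stop("contour table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!"whistle_id" %in% names(meta))
    stop("metadata table must have a whistle_id column", call. = FALSE)
  pts$whistle_id <- as.character(pts$whistle_id)
  meta$whistle_id <- as.character(meta$whistle_id)

  missing_meta <- setdiff(unique(pts$whistle_id), meta$whistle_id)
  if (length(missing_meta))
    stop("no metadata row for whistle(s): ",
         paste(missing_meta, collapse = ", "), call. = FALSE)

  by_id <- split(pts[c("time_s", "freq_hz")], pts$whistle_id)
  get_meta <- function(row, col, default) {
    if (col %in% names(meta)) meta[[col]][row] else default
  }
  whistles <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    id <- meta$whistle_id[i]
    p <- by_id[[id]]
    if (is.null(p))
      stop("metadata row for whistle '", id, "' has no contour points",
           call. = FALSE)
    whistles[[i]] <- whistle_contour(
      whistle_id = id,
      time_s = p$time_s, freq_hz = p$freq_hz,
      encounter_id = get_meta(i, "encounter_id", "enc1"),
      species = get_meta(i, "species", "unknown"),
      sample_rate_hz = get_meta(i, "sample_rate_hz", 96000),
      file_id = get_meta(i, "file_id", "file1"),
      file_offset_s = get_meta(i, "file_offset_s", 0),
      stereotype_id = as.character(get_meta(i, "stereotype_id", NA)),
      snr_db = as.numeric(get_meta(i, "snr_db", NA)))
  }
  names(whistles) <- meta$whistle_id
  encounters <- NULL
  if (!is.null(encounter_path)) {
    encounters <- read.csv(encounter_path, stringsAsFactors = FALSE)
    encounters$encounter_id <- as.character(encounters$encounter_id)
  }
  list(whistles = whistles, encounters = encounters)
}

#' Write whistle contours and metadata to CSV tables
#'
#' Inverse of [read_contours()]: the written files round-trip losslessly
#' (points and metadata fields).
#'
#' @param whistles non-empty list of `whistle_contour` objects.
#' @param contour_path output path for the point table.
#' @param metadata_path output path for the whistle metadata table.
#' @param encounter_path optional output path for the encounter table.
#' @param encounters encounter data frame (required with `encounter_path`).
#' @return invisibly, the two/three paths written.
#' @export
write_contours <- function(whistles, contour_path, metadata_path,
                           encounter_path = NULL, encounters = NULL) {
  if (length(whistles) == 0L)
    stop("cannot write an empty whistle set", call. = FALSE)
  pts <- do.call(rbind, lapply(whistles, function(w)
    data.frame(whistle_id = w$whistle_id, time_s = w$time_s,
               freq_hz = w$freq_hz, stringsAsFactors = FALSE)))
  meta <- contour_metadata(whistles)
  write.csv(pts, contour_path, row.names = FALSE)
  write.csv(meta, metadata_path, row.names = FALSE)
  paths <- c(contour_path, metadata_path)
  if (!is.null(encounter_path)) {
    if (is.null(encounters))
      stop("encounter_path given without an encounters table", call. = FALSE)
    write.csv(encounters, encounter_path, row.names = FALSE)
    paths <- c(paths, encounter_path)
  }
  invisible(paths)
}

#' Whistle metadata as a data frame
#'
#' @param whistles list of `whistle_contour` objects.
#' @return data frame with one row per whistle.
#' @export
contour_metadata <- function(whistles) {
  do.call(rbind, lapply(whistles, function(w)
    data.frame(whistle_id = w$whistle_id,
               encounter_id = w$encounter_id,
               species = w$species,
               sample_rate_hz = w$sample_rate_hz,
               file_id = w$file_id,
               file_offset_s = w$file_offset_s,
               stereotype_id = w$stereotype_id,
               snr_db = w$snr_db,
               n_points = length(w$time_s),
               duration_s = contour_duration(w),
               max_freq_hz = max(w$freq_hz),
               stringsAsFactors = FALSE)))
}

#' Resample a contour to a uniform time grid
#'
#' Traced contours arrive at FFT-frame spacing that depends on the sampling
#' rate; dynamic time warping and feature slopes operate on a fixed grid so
#' that 44.1 kHz and 96 kHz data are comparable. Frequencies are linearly
#' interpolated; the first and last original frequencies are preserved (the
#' final grid point is the contour end even when the span is not an exact
#' multiple of `step_s`).
#'
#' @param contour a `whistle_contour`.
#' @param step_s grid step in seconds (default 0.01, i.e. a 10 ms grid).
#' @return a `whistle_contour` on the uniform grid, times relative to whistle
#'   start.
#' @export
resample_contour <- function(contour, step_s = 0.01) {
  if (step_s <= 0) stop("step_s must be positive", call. = FALSE)
  dur <- contour_duration(contour)
  if (dur < step_s)
    stop("whistle '", contour$whistle_id, "': resampling step (", step_s,
         " s) exceeds contour duration (", dur, " s)", call. = FALSE)
  t0 <- contour$time_s[1L]
  n <- floor(dur / step_s + 1e-9)
  grid <- (0:n) * step_s
  if (dur - grid[n + 1L] > 1e-9) grid <- c(grid, dur) else grid[n + 1L] <- dur
  f <- approx(contour$time_s - t0, contour$freq_hz, xout = grid,
              method = "linear", rule = 2)$y
  out <- contour
  out$time_s <- grid
  out$freq_hz <- f
  out
}

#' Resampled frequency sequences for a whistle set
#'
#' Convenience wrapper used by the categorizer: every whistle on the same
#' fixed grid, returned as a named list of frequency vectors.
#'
#' @param whistles list of `whistle_contour` objects.
#' @param step_s grid step in seconds.
#' @return named list of numeric frequency vectors.
#' @export
contour_sequences <- function(whistles, step_s = 0.01) {
  out <- lapply(whistles, function(w) resample_contour(w, step_s)$freq_hz)
  names(out) <- vapply(whistles, `[[`, "", "whistle_id")
  out
}
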