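#' Whistle selection rules
#'
#' Encodes the subsampling protocol applied to the candidate whistles of an
#' encounter before analysis: a per-school whistle quota tied to the
#' estimated group size, a signal-to-noise gate, a cap on mutually
#' overlapping whistles (concurrent whistling produces bands of
#' indistinguishable contours), and a cap on repeated stereotyped
#' (signature-like) whistles of one type per recording file.
#'
#' @param max_whistles_small_school quota for schools below
#'   `small_school_threshold` animals (default 100).
#' @param small_school_threshold school size below which the small-school
#'   quota applies (default 100).
#' @param max_whistles_ceiling absolute quota ceiling for large schools
#'   (default 200).
#' @param snr_min_db minimum signal-to-noise ratio in dB (default 6);
#'   whistles without an SNR value pass the gate.
#' @param max_per_overlap_window maximum number of selected whistles whose
#'   time spans mutually overlap within one file (default 3).
#' @param max_stereotyped_per_file maximum selected whistles sharing one
#'   `stereotype_id` within one recording file (default 2).
#' @param file_length_s nominal recording file length in seconds (default
#'   300, i.e. 5-minute files).
#' @param rng_seed seed for the random index times that drive selection.
#' @return a list of class `selection_rules`.
#' @export
selection_rules <- function(max_whistles_small_school = 100L,
                            small_school_threshold = 100L,
                            max_whistles_ceiling = 200L,
                            snr_min_db = 6,
                            max_per_overlap_window = 3L,
                            max_stereotyped_per_file = 2L,
                            file_length_s = 300,
                            rng_seed = 1L) {
  if (max_whistles_small_school < 1 || max_whistles_ceiling < 1 ||
      max_per_overlap_window < 1 || max_stereotyped_per_file < 1)
    stop("all selection maxima must be >= 1", call. = FALSE)
  if (small_school_threshold > max_whistles_ceiling)
    stop("small_school_threshold must not exceed max_whistles_ceiling",
         call. = FALSE)
  structure(list(max_whistles_small_school = as.integer(max_whistles_small_school),
                 small_school_threshold = as.integer(small_school_threshold),
                 max_whistles_ceiling = as.integer(max_whistles_ceiling),
                 snr_min_db = snr_min_db,
                 max_per_overlap_window = as.integer(max_per_overlap_window),
                 max_stereotyped_per_file = as.integer(max_stereotyped_per_file),
                 file_length_s = file_length_s,
                 rng_seed = as.integer(rng_seed)),
            class = "selection_rules")
}

#' Whistle quota for a school
#'
#' Schools smaller than the threshold contribute at most the small-school
#' quota; larger schools contribute at most their estimated size, up to the
#' ceiling. With the defaults: 100 whistles for schools of fewer than 100
#' animals, otherwise `min(school_size, 200)`.
#'
#' @param school_size estimated number of animals (>= 1).
#' @param rules a [selection_rules()] object.
#' @return integer quota.
#' @export
school_quota <- function(school_size, rules = selection_rules()) {
  if (school_size < 1) stop("school_size must be >= 1", call. = FALSE)
  if (school_size < rules$small_school_threshold)
    return(rules$max_whistles_small_school)
  as.integer(min(school_size, rules$max_whistles_ceiling))
}

#' Select analysis whistles from an encounter's candidates
#'
#' Emulates the random-index-time protocol: random times are drawn across
#' the encounter's recordings and, for each, the first not-yet-considered
#' whistle beginning at or after that time is evaluated against the rules
#' (SNR gate, overlap cap, stereotype cap); an ineligible whistle is skipped
#' and the draw advances to the following whistle. Selection stops at the
#' school quota or when every candidate has been considered. Candidates are
#' ordered internally by file and offset, so the result is invariant to the
#' input order of `candidates` for a fixed seed, and the filter is
#' idempotent (re-filtering its own output returns it unchanged).
#'
#' @param candidates list of [whistle_contour()] objects, all from
#'   `encounter`.
#' @param encounter one-row encounter data frame ([encounter_record()]).
#' @param rules a [selection_rules()] object.
#' @return list of selected `whistle_contour` objects (possibly empty).
#' @export
select_whistles <- function(candidates, encounter,
                            rules = selection_rules()) {
  if (length(candidates) == 0L) return(list())
  meta <- contour_metadata(candidates)
  bad <- meta$encounter_id != encounter$encounter_id
  if (any(bad))
    stop("candidates from a different encounter: ",
         paste(meta$whistle_id[bad], collapse = ", "), call. = FALSE)

  ord <- order(meta$file_id, meta$file_offset_s, meta$whistle_id)
  candidates <- candidates[ord]
  meta <- meta[ord, , drop = FALSE]
  n <- nrow(meta)

  # absolute start time across concatenated files, for index-time draws
  files <- unique(meta$file_id)
  file_base <- setNames((seq_along(files) - 1) * rules$file_length_s, files)
  abs_start <- file_base[meta$file_id] + meta$file_offset_s
  abs_end <- abs_start + meta$duration_s
  span <- max(abs_end)

  quota <- school_quota(encounter$school_size_estimate, rules)
  processed <- rep(FALSE, n)
  selected <- rep(FALSE, n)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(rules$rng_seed)

  eligible <- function(k) {
    if (!is.na(meta$snr_db[k]) && meta$snr_db[k] < rules$snr_min_db)
      return(FALSE)
    same_file <- selected & meta$file_id == meta$file_id[k]
    if (any(same_file)) {
      ov <- same_file &
        abs_start < abs_end[k] & abs_end > abs_start[k]
      if (sum(ov) >= rules$max_per_overlap_window) return(FALSE)
      if (!is.na(meta$stereotype_id[k])) {
        st <- same_file & !is.na(meta$stereotype_id) &
          meta$stereotype_id == meta$stereotype_id[k]
        if (sum(st) >= rules$max_stereotyped_per_file) return(FALSE)
      }
    }
    TRUE
  }

  while (sum(selected) < quota && !all(processed)) {
    t <- runif(1, 0, span)
    k <- which(!processed & abs_start >= t)
    if (length(k) == 0L) k <- which(!processed)  # wrap to earliest remaining
    k <- k[1L]
    processed[k] <- TRUE
    if (eligible(k)) selected[k] <- TRUE
  }
  candidates[selected]
}

#' Harmonize a whistle set to a common Nyquist bound
#'
#' When recordings mix sampling rates, whistles whose maximum contour
#' frequency exceeds the lowest Nyquist frequency in the dataset could only
#' have been observed in the higher-rate recordings; they are dropped so
#' both rate groups cover the same frequency band.
#'
#' @param whistles list of [whistle_contour()] objects.
#' @param target_nyquist_hz frequency bound in Hz; defaults to the minimum
#'   `sample_rate_hz / 2` over the input.
#' @return list with `kept` and `dropped` (disjoint, union = input) and the
#'   `target_nyquist_hz` used.
#' @export
nyquist_harmonize <- function(whistles, target_nyquist_hz = NULL) {
  if (length(whistles) == 0L)
    return(list(kept = list(), dropped = list(),
                target_nyquist_hz = target_nyquist_hz))
  if (is.null(target_nyquist_hz)) {
    rates <- vapply(whistles, `[[`, numeric(1), "sample_rate_hz")
    target_nyquist_hz <- min(rates) / 2
  }
  if (target_nyquist_hz <= 0)
    stop("target_nyquist_hz must be positive", call. = FALSE)
  maxf <- vapply(whistles, function(w) max(w$freq_hz), numeric(1))
  keep <- maxf <= target_nyquist_hz
  list(kept = whistles[keep], dropped = whistles[!keep],
       target_nyquist_hz = target_nyquist_hz)
}
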