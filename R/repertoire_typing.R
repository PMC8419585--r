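#' Label whistle types by the sharing taxonomy
#'
#' Assigns every whistle type to exactly one of four mutually exclusive
#' categories based on which species and how many encounters (schools) its
#' member whistles come from:
#'
#' * `shared` — whistles from both species;
#' * `species_specific` — one species, at least two whistles, at least two
#'   encounters;
#' * `single_encounter_multi` — one species, at least two whistles, one
#'   encounter;
#' * `singleton` — exactly one whistle.
#'
#' Because schools are single-species, a type seen in both species is
#' necessarily a multiple-encounter type; the multiple-encounter set is
#' `shared + species_specific`.
#'
#' @param membership data frame with columns `whistle_id`, `type_id`, and
#'   either `species` and `encounter_id` directly or joinable via `metadata`.
#' @param metadata optional whistle metadata data frame (`whistle_id`,
#'   `encounter_id`, `species`) used when `membership` lacks those columns;
#'   a member whistle missing from it is a hard error.
#' @return data frame of class `type_labels`: `type_id`, `n_whistles`,
#'   `n_encounters`, `species_set` (comma-joined), `category`. Summary
#'   counts are available via [type_summary()].
#' @export
label_types <- function(membership, metadata = NULL) {
  m <- membership
  if (!all(c("species", "encounter_id") %in% names(m))) {
    if (is.null(metadata))
      stop("membership lacks species/encounter_id and no metadata given",
           call. = FALSE)
    idx <- match(m$whistle_id, metadata$whistle_id)
    if (anyNA(idx))
      stop("no metadata for whistle(s): ",
           paste(m$whistle_id[is.na(idx)], collapse = ", "), call. = FALSE)
    m$species <- metadata$species[idx]
    m$encounter_id <- metadata$encounter_id[idx]
  }
  if (anyNA(m$encounter_id) || anyNA(m$species))
    stop("member whistle with unknown encounter or species", call. = FALSE)

  sp <- split(m, m$type_id)
  lab <- do.call(rbind, lapply(sp, function(g) {
    species_set <- sort(unique(g$species))
    n_w <- nrow(g)
    n_e <- length(unique(g$encounter_id))
    category <- if (n_w == 1L) "singleton"
      else if (length(species_set) == 2L) "shared"
      else if (n_e >= 2L) "species_specific"
      else "single_encounter_multi"
    data.frame(type_id = g$type_id[1L],
               n_whistles = n_w,
               n_encounters = n_e,
               species_set = paste(species_set, collapse = ","),
               category = category,
               stringsAsFactors = FALSE)
  }))
  lab <- lab[order(lab$type_id), , drop = FALSE]
  row.names(lab) <- NULL
  class(lab) <- c("type_labels", "data.frame")
  lab
}

#' Summary counts and proportions for labelled types
#'
#' Reports, in the structure used for repertoire comparison: total types;
#' counts per category; the exclusive (one-species) total and, within it,
#' the singleton and single-encounter-multi percentages; the
#' multiple-encounter total (shared + species-specific) and the
#' species-specific percentage within it; and the per-species split of
#' species-specific types.
#'
#' @param labels a `type_labels` data frame from [label_types()].
#' @return named list of counts and percentages (percentages on the 0-100
#'   scale, rounded to 1 decimal).
#' @export
type_summary <- function(labels) {
  counts <- table(factor(labels$category,
                         levels = c("shared", "species_specific",
                                    "single_encounter_multi", "singleton")))
  n_total <- nrow(labels)
  n_shared <- unname(counts["shared"])
  n_specific <- unname(counts["species_specific"])
  n_sem <- unname(counts["single_encounter_multi"])
  n_singleton <- unname(counts["singleton"])
  n_exclusive <- n_specific + n_sem + n_singleton
  n_multi <- n_shared + n_specific
  spec <- labels[labels$category == "species_specific", , drop = FALSE]
  per_species <- table(spec$species_set)
  list(n_types = n_total,
       n_shared = n_shared,
       n_species_specific = n_specific,
       n_single_encounter_multi = n_sem,
       n_singleton = n_singleton,
       n_exclusive = n_exclusive,
       n_multi_encounter = n_multi,
       pct_exclusive = round(100 * n_exclusive / n_total, 1),
       pct_singleton_of_exclusive = round(100 * n_singleton / n_exclusive, 1),
       pct_single_encounter_multi_of_exclusive =
         round(100 * n_sem / n_exclusive, 1),
       pct_species_specific_of_multi_encounter =
         round(100 * n_specific / n_multi, 1),
       species_specific_by_species = as.list(per_species))
}

#' Oscillation-rule parameters
#'
#' Thresholds of the deterministic oscillatory-whistle rule: the contour must
#' show (i) at least `min_cycles` cycles of similar magnitude with at least
#' `min_maxima` maxima, (ii) at least `min_peak_trough_hz` between the
#' maximum and minimum of each cycle, and (iii) the pattern must span at
#' least `min_coverage` of the contour duration.
#'
#' @param min_maxima minimum number of local maxima in the qualifying run
#'   (default 2).
#' @param min_cycles minimum number of cycles (default 2); a cycle is one
#'   full peak-to-peak (or trough-to-trough) excursion, so a run of k
#'   alternating extrema contains k - 2 cycles.
#' @param min_peak_trough_hz minimum peak-trough separation in Hz
#'   (default 1000).
#' @param min_coverage minimum fraction of the contour duration spanned by
#'   the oscillatory run (default 0.5).
#' @param similar_magnitude_ratio minimum ratio of the smallest to the
#'   largest cycle amplitude within the run (default 0.5); quantifies
#'   "similar magnitude".
#' @param smoothing_window running-mean window (points, default 3) applied
#'   before extremum detection.
#' @return list of class `oscillation_params`.
#' @export
oscillation_params <- function(min_maxima = 2L, min_cycles = 2L,
                               min_peak_trough_hz = 1000,
                               min_coverage = 0.5,
                               similar_magnitude_ratio = 0.5,
                               smoothing_window = 3L) {
  if (min_peak_trough_hz <= 0 || min_maxima < 1 || min_cycles < 1)
    stop("oscillation thresholds must be positive", call. = FALSE)
  if (min_coverage <= 0 || min_coverage > 1)
    stop("min_coverage must be in (0, 1]", call. = FALSE)
  structure(list(min_maxima = as.integer(min_maxima),
                 min_cycles = as.integer(min_cycles),
                 min_peak_trough_hz = min_peak_trough_hz,
                 min_coverage = min_coverage,
                 similar_magnitude_ratio = similar_magnitude_ratio,
                 smoothing_window = as.integer(smoothing_window)),
            class = "oscillation_params")
}

# alternating interior extrema of a (smoothed) sequence:
# data frame (index, time, value, is_max)
find_extrema <- function(f, t) {
  d <- diff(f)
  sgn <- sign(d)
  nz <- which(sgn != 0)
  if (length(nz) < 2L)
    return(data.frame(index = integer(0), time = numeric(0),
                      value = numeric(0), is_max = logical(0)))
  sg <- sgn[nz]
  flips <- which(sg[-1] != sg[-length(sg)])
  idx <- nz[flips] + 1L  # vertex at end of the old-direction segment
  data.frame(index = idx, time = t[idx], value = f[idx],
             is_max = sg[flips] > 0)
}

#' Test a contour for an oscillatory frequency pattern
#'
#' Applies the three-criterion oscillation rule: the frequency trace is
#' smoothed, alternating local extrema are extracted, and adjacent extremum
#' pairs closer than the peak-trough threshold are pruned (smallest first),
#' absorbing small wiggles into the surrounding oscillation. The longest
#' remaining run of alternating extrema whose cycle amplitudes are of
#' similar magnitude is then scored: the contour is oscillatory when the run
#' has enough maxima and cycles and spans enough of the contour duration.
#' The run's time span is extended by half the mean inter-extremum gap on
#' each side (a cycle extends beyond its last extremum), clamped to the
#' contour.
#'
#' The decision is invariant to adding a constant frequency offset and to
#' uniform time stretching.
#'
#' @param contour a [whistle_contour()], or a numeric frequency sequence
#'   (then `time_s` may be given; defaults to unit spacing).
#' @param params an [oscillation_params()] object.
#' @param time_s optional times for a numeric `contour`.
#' @return list with `oscillatory` (logical) and `diagnostics` (extrema
#'   table, qualifying-run indices, `n_maxima`, `n_cycles`, `coverage`).
#' @export
is_oscillatory <- function(contour, params = oscillation_params(),
                           time_s = NULL) {
  if (inherits(contour, "whistle_contour")) {
    f <- contour$freq_hz
    t <- contour$time_s - contour$time_s[1L]
  } else {
    f <- as.numeric(contour)
    t <- if (is.null(time_s)) seq_along(f) - 1 else time_s - time_s[1L]
  }
  fail <- function(reason, ex = NULL, run = integer(0), nmax = 0L,
                   ncyc = 0, cov = 0)
    list(oscillatory = FALSE,
         diagnostics = list(reason = reason, extrema = ex, run = run,
                            n_maxima = nmax, n_cycles = ncyc, coverage = cov))
  if (length(f) < 5L) return(fail("contour too short"))
  dur <- t[length(t)] - t[1L]
  fs <- smooth3(f, params$smoothing_window)
  ex <- find_extrema(fs, t)
  if (nrow(ex) < 2L) return(fail("fewer than 2 alternating extrema", ex))

  # prune adjacent extremum pairs with sub-threshold separation
  repeat {
    if (nrow(ex) < 2L) break
    amp <- abs(diff(ex$value))
    small <- which(amp < params$min_peak_trough_hz)
    if (!length(small)) break
    k <- small[which.min(amp[small])]
    ex <- ex[-c(k, k + 1L), , drop = FALSE]
  }
  if (nrow(ex) < 2L)
    return(fail("no extrema pair separated by the peak-trough threshold", ex))

  # longest run with similar-magnitude cycle amplitudes
  amp <- abs(diff(ex$value))
  k <- nrow(ex)
  best <- c(1L, 1L)
  for (i in seq_len(k - 1L)) {
    lo <- amp[i]; hi <- amp[i]
    for (j in i:(k - 1L)) {
      lo <- min(lo, amp[j]); hi <- max(hi, amp[j])
      if (lo / hi < params$similar_magnitude_ratio) break
      if (j - i + 2L > best[2L] - best[1L] + 1L) best <- c(i, j + 1L)
    }
  }
  run <- best[1L]:best[2L]
  n_ext <- length(run)
  n_maxima <- sum(ex$is_max[run])
  n_cycles <- max(0L, n_ext - 2L)
  gaps <- diff(ex$time[run])
  ext <- if (length(gaps)) mean(gaps) / 2 else 0
  span_lo <- max(t[1L], ex$time[run[1L]] - ext)
  span_hi <- min(t[length(t)], ex$time[run[n_ext]] + ext)
  coverage <- if (dur > 0) (span_hi - span_lo) / dur else 0

  ok <- n_maxima >= params$min_maxima &&
    n_cycles >= params$min_cycles &&
    coverage >= params$min_coverage
  list(oscillatory = ok,
       diagnostics = list(reason = if (ok) "all criteria met" else
                            "criteria not met",
                          extrema = ex, run = run, n_maxima = n_maxima,
                          n_cycles = n_cycles, coverage = coverage))
}

#' Flag oscillatory whistle types
#'
#' A type is flagged oscillatory when its reference contour passes
#' [is_oscillatory()] (mirroring inspection of category reference contours);
#' when the member contours are supplied, the number of members that
#' individually pass is reported alongside, since whistle-level counts are
#' part of the standard repertoire summary.
#'
#' @param fit an [artwarp()] object (for the reference contours).
#' @param labels a `type_labels` data frame from [label_types()].
#' @param params an [oscillation_params()] object.
#' @param whistles optional list of [whistle_contour()] objects (the fitted
#'   whistles) for member-level counts.
#' @return `labels` with added columns `oscillatory` (logical) and, when
#'   `whistles` is given, `n_oscillatory_whistles`.
#' @export
label_oscillatory_types <- function(fit, labels, params = oscillation_params(),
                                    whistles = NULL) {
  stopifnot(inherits(fit, "artwarp"))
  ref_osc <- vapply(fit$types, function(ty) {
    r <- ty$reference
    is_oscillatory(r, params,
                   time_s = (seq_along(r) - 1) * fit$step_s)$oscillatory
  }, logical(1))
  labels$oscillatory <- unname(ref_osc[labels$type_id])
  if (!is.null(whistles)) {
    ids <- vapply(whistles, `[[`, "", "whistle_id")
    w_osc <- vapply(whistles, function(w)
      is_oscillatory(w, params)$oscillatory, logical(1))
    names(w_osc) <- ids
    labels$n_oscillatory_whistles <- vapply(labels$type_id, function(tid) {
      mem <- fit$types[[tid]]$member_ids
      sum(w_osc[mem], na.rm = TRUE)
    }, numeric(1))
  }
  labels
}
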