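# Feature roster ------------------------------------------------------------

.continuous_features <- c(
  "duration_s", "freq_beg_hz", "freq_end_hz", "freq_min_hz", "freq_max_hz",
  "freq_range_hz", "freq_q1_hz", "freq_q2_hz", "freq_q3_hz", "freq_mean_hz",
  "freq_median_hz", "freq_sd_hz", "freq_center_hz", "freq_iqr_hz",
  "freq_rel_bw", "freq_maxmin_ratio", "freq_begend_ratio", "freq_cofm",
  "rel_time_min", "rel_time_max",
  "slope_beg_hz_s", "slope_end_hz_s", "slope_mean_hz_s", "slope_pos_mean_hz_s",
  "slope_neg_mean_hz_s", "slope_abs_mean_hz_s", "slope_sd_hz_s",
  "slope_abs_max_hz_s",
  "prop_up", "prop_down", "prop_flat",
  "num_inflections", "inflections_per_s", "infl_dt_min_s", "infl_dt_max_s",
  "infl_dt_mean_s", "infl_dt_sd_s", "infl_dt_median_s",
  "num_steps", "steps_per_s", "num_steps_up", "num_steps_down",
  "num_local_max", "num_local_min",
  "num_sweeps_up_down", "num_sweeps_down_up", "num_sweeps_up_flat",
  "num_sweeps_flat_up", "num_sweeps_down_flat", "num_sweeps_flat_down")

.categorical_features <- c(
  "sweep_beg", "sweep_end", "sweep_overall", "has_steps", "has_inflections",
  "maxfreq_position")

#' The contour feature roster
#'
#' The fixed, versioned list of per-whistle measurements: 50 continuous
#' variables describing frequency (begin/end/min/max, quarter-point
#' frequencies, central tendency and spread), shape (slopes, slope-class
#' proportions, inflection points and their spacing, steps, local extrema,
#' sweep transitions) and duration, plus 6 categorical variables (begin/end
#' sweep direction, overall sweep, step presence, inflection presence,
#' position of the maximum frequency). Downstream statistics and classifiers
#' depend only on this roster and its declared types.
#'
#' @return data frame with columns `name` and `type`
#'   (`"continuous"`/`"categorical"`).
#' @export
feature_roster <- function() {
  data.frame(
    name = c(.continuous_features, .categorical_features),
    type = rep(c("continuous", "categorical"),
               c(length(.continuous_features), length(.categorical_features))),
    stringsAsFactors = FALSE)
}

# centered 3-point running mean; endpoints use the available partial window
smooth3 <- function(f, window = 3L) {
  n <- length(f)
  if (n < 3L || window < 3L) return(f)
  half <- window %/% 2L
  out <- f
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    out[i] <- mean(f[lo:hi])
  }
  out
}

# sign classification of interval slopes with a flat tolerance (Hz/s)
slope_classes <- function(slopes, flat_tol = 10) {
  ifelse(slopes > flat_tol, 1L, ifelse(slopes < -flat_tol, -1L, 0L))
}

#' Count inflection points of a contour
#'
#' An inflection is a sign change of the first difference of the smoothed
#' frequency trace (centered 3-point running mean, which suppresses
#' single-frame jitter). Zero differences do not break a run: the last
#' non-zero direction carries forward, so a plateau between an up and a down
#' segment counts as one inflection.
#'
#' @param contour a [whistle_contour()] with at least 3 points, or a numeric
#'   frequency vector (then `time_s` may be supplied).
#' @param time_s optional times matching a numeric `contour`.
#' @return list with `count` and `times` (seconds, relative to contour
#'   start) of the inflections.
#' @export
count_inflections <- function(contour, time_s = NULL) {
  if (inherits(contour, "whistle_contour")) {
    f <- contour$freq_hz
    t <- contour$time_s - contour$time_s[1L]
  } else {
    f <- as.numeric(contour)
    t <- if (is.null(time_s)) seq_along(f) - 1 else time_s - time_s[1L]
  }
  if (length(f) < 3L) stop("need at least 3 points", call. = FALSE)
  d <- diff(smooth3(f))
  sgn <- sign(d)
  nz <- which(sgn != 0)
  if (length(nz) < 2L) return(list(count = 0L, times = numeric(0)))
  sg <- sgn[nz]
  flips <- which(sg[-1] != sg[-length(sg)])
  # the vertex sits at the first point of the new-direction segment
  times <- t[nz[flips + 1L]]
  list(count = length(flips), times = times)
}

#' Count frequency steps in a contour
#'
#' A step is a single-interval frequency jump whose magnitude is at least
#' `step_fraction` of the preceding frequency, while the slope on both
#' neighbouring intervals is flat or keeps the jump's direction (so an
#' isolated spike does not count). Runs on the raw, unsmoothed points.
#'
#' @param contour a [whistle_contour()] or numeric frequency vector.
#' @param step_fraction jump threshold as a proportion of the preceding
#'   frequency (default 0.10).
#' @return list with `count`, `up` and `down` step counts.
#' @export
count_steps <- function(contour, step_fraction = 0.10) {
  f <- if (inherits(contour, "whistle_contour")) contour$freq_hz
       else as.numeric(contour)
  n <- length(f)
  if (n < 2L) stop("need at least 2 points", call. = FALSE)
  up <- 0L; down <- 0L
  d <- diff(f)
  for (i in seq_len(n - 1L)) {
    if (abs(d[i]) < step_fraction * f[i]) next
    s <- sign(d[i])
    before <- if (i > 1L) sign(d[i - 1L]) else 0
    after <- if (i < n - 1L) sign(d[i + 1L]) else 0
    if ((before == 0 || before == s) && (after == 0 || after == s)) {
      if (s > 0) up <- up + 1L else down <- down + 1L
    }
  }
  list(count = up + down, up = up, down = down)
}

#' Extract the contour feature vector for one whistle
#'
#' Computes the full [feature_roster()] for a contour. Frequency summaries
#' and slopes are measured on the contour resampled to a uniform `step_s`
#' grid (so they do not depend on the recorder's frame rate); inflection
#' detection additionally smooths with a 3-point running mean; step
#' detection runs on the raw traced points. For a 2-point contour the
#' frequency/duration block is computed and all shape measures are `NA`.
#'
#' When a contour has fewer than 2 inflections the inflection-spacing
#' statistics are 0 by convention, keeping the vector finite for
#' classifiers.
#'
#' @param contour a [whistle_contour()].
#' @param step_s resampling step (seconds, default 0.01).
#' @param step_fraction step-jump threshold, see [count_steps()].
#' @param flat_tol_hz_s slope magnitude (Hz/s) below which an interval
#'   counts as flat (default 10).
#' @return one-row data frame: `whistle_id`, 50 continuous columns, 6
#'   categorical columns (character).
#' @export
extract_features <- function(contour, step_s = 0.01, step_fraction = 0.10,
                             flat_tol_hz_s = 10) {
  f_raw <- contour$freq_hz
  t_raw <- contour$time_s - contour$time_s[1L]
  dur <- contour_duration(contour)
  out <- as.list(setNames(rep(NA_real_, length(.continuous_features)),
                          .continuous_features))
  cat_out <- as.list(setNames(rep(NA_character_,
                                  length(.categorical_features)),
                              .categorical_features))

  # frequency/duration block (defined for any valid contour)
  out$duration_s <- dur
  out$freq_beg_hz <- f_raw[1L]
  out$freq_end_hz <- f_raw[length(f_raw)]
  out$freq_min_hz <- min(f_raw)
  out$freq_max_hz <- max(f_raw)
  out$freq_range_hz <- out$freq_max_hz - out$freq_min_hz
  out$freq_center_hz <- out$freq_min_hz + out$freq_range_hz / 2
  out$freq_maxmin_ratio <- out$freq_max_hz / out$freq_min_hz
  out$freq_begend_ratio <- out$freq_beg_hz / out$freq_end_hz
  out$freq_rel_bw <- out$freq_range_hz / out$freq_center_hz

  shape_ok <- length(f_raw) >= 3L && dur >= step_s
  if (shape_ok) {
    rs <- resample_contour(contour, step_s)
    t <- rs$time_s
    f <- rs$freq_hz
    qf <- approx(t, f, xout = dur * c(0.25, 0.5, 0.75), rule = 2)$y
    out$freq_q1_hz <- qf[1]; out$freq_q2_hz <- qf[2]; out$freq_q3_hz <- qf[3]
    out$freq_mean_hz <- mean(f)
    out$freq_median_hz <- median(f)
    out$freq_sd_hz <- sd(f)
    out$freq_iqr_hz <- unname(diff(quantile(f, c(0.25, 0.75))))
    out$rel_time_min <- t[which.min(f)] / dur
    out$rel_time_max <- t[which.max(f)] / dur

    dt <- diff(t); df <- diff(f)
    slopes <- df / dt
    out$slope_beg_hz_s <- slopes[1L]
    out$slope_end_hz_s <- slopes[length(slopes)]
    out$slope_mean_hz_s <- mean(slopes)
    cls <- slope_classes(slopes, flat_tol_hz_s)
    pos <- slopes[cls == 1L]; neg <- slopes[cls == -1L]
    out$slope_pos_mean_hz_s <- if (length(pos)) mean(pos) else 0
    out$slope_neg_mean_hz_s <- if (length(neg)) mean(neg) else 0
    out$slope_abs_mean_hz_s <- mean(abs(slopes))
    out$slope_sd_hz_s <- if (length(slopes) > 1L) sd(slopes) else 0
    out$slope_abs_max_hz_s <- max(abs(slopes))
    out$freq_cofm <- sum(abs(df)) / 10000

    w <- dt / sum(dt)  # time-weighted slope-class proportions
    out$prop_up <- sum(w[cls == 1L])
    out$prop_down <- sum(w[cls == -1L])
    out$prop_flat <- sum(w[cls == 0L])

    infl <- count_inflections(contour)
    out$num_inflections <- infl$count
    out$inflections_per_s <- infl$count / dur
    if (infl$count >= 2L) {
      gaps <- diff(infl$times)
      out$infl_dt_min_s <- min(gaps)
      out$infl_dt_max_s <- max(gaps)
      out$infl_dt_mean_s <- mean(gaps)
      out$infl_dt_sd_s <- if (length(gaps) > 1L) sd(gaps) else 0
      out$infl_dt_median_s <- median(gaps)
    } else {
      out[c("infl_dt_min_s", "infl_dt_max_s", "infl_dt_mean_s",
            "infl_dt_sd_s", "infl_dt_median_s")] <- 0
    }

    st <- count_steps(contour, step_fraction)
    out$num_steps <- st$count
    out$steps_per_s <- st$count / dur
    out$num_steps_up <- st$up
    out$num_steps_down <- st$down

    # local extrema of the smoothed trace
    d <- diff(smooth3(f_raw)); sgn <- sign(d); nz <- which(sgn != 0)
    sg <- sgn[nz]
    if (length(sg) >= 2L) {
      flips_dn <- sum(sg[-length(sg)] == 1 & sg[-1] == -1)
      flips_up <- sum(sg[-length(sg)] == -1 & sg[-1] == 1)
    } else flips_dn <- flips_up <- 0L
    out$num_local_max <- flips_dn
    out$num_local_min <- flips_up

    # sweep transitions between collapsed slope-class runs
    runs <- rle(as.integer(cls))$values
    if (length(runs) >= 2L) {
      a <- runs[-length(runs)]; b <- runs[-1]
      out$num_sweeps_up_down <- sum(a == 1 & b == -1)
      out$num_sweeps_down_up <- sum(a == -1 & b == 1)
      out$num_sweeps_up_flat <- sum(a == 1 & b == 0)
      out$num_sweeps_flat_up <- sum(a == 0 & b == 1)
      out$num_sweeps_down_flat <- sum(a == -1 & b == 0)
      out$num_sweeps_flat_down <- sum(a == 0 & b == -1)
    } else {
      out[c("num_sweeps_up_down", "num_sweeps_down_up", "num_sweeps_up_flat",
            "num_sweeps_flat_up", "num_sweeps_down_flat",
            "num_sweeps_flat_down")] <- 0
    }

    dir_label <- function(x) c("down", "flat", "up")[x + 2L]
    cat_out$sweep_beg <- dir_label(cls[1L])
    cat_out$sweep_end <- dir_label(cls[length(cls)])
    rel_change <- (out$freq_end_hz - out$freq_beg_hz) / out$freq_beg_hz
    cat_out$sweep_overall <- if (abs(rel_change) < 0.005) "flat"
      else if (rel_change > 0) "up" else "down"
    cat_out$has_steps <- if (st$count > 0) "yes" else "no"
    cat_out$has_inflections <- if (infl$count > 0) "yes" else "no"
    cat_out$maxfreq_position <- if (out$rel_time_max <= 0.5) "first_half"
      else "second_half"
  }

  cbind(data.frame(whistle_id = contour$whistle_id, stringsAsFactors = FALSE),
        as.data.frame(out, stringsAsFactors = FALSE),
        as.data.frame(cat_out, stringsAsFactors = FALSE))
}

#' Extract features for a whistle set
#'
#' @param whistles list of [whistle_contour()] objects.
#' @param ... passed to [extract_features()].
#' @return data frame, one row per whistle, columns in roster order.
#' @export
extract_features_table <- function(whistles, ...) {
  out <- do.call(rbind, lapply(whistles, extract_features, ...))
  row.names(out) <- NULL
  out
}
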