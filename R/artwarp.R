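#' Dynamic-time-warping parameters
#'
#' Controls the contour-alignment similarity used by the categorizer. The
#' step pattern is fixed (diagonal, horizontal and vertical unit moves) and
#' the path score is the mean per-pair similarity over the alignment path,
#' so the defaults are the full parameter surface.
#'
#' @param max_warp_factor maximum total warp: the alignment path may contain
#'   at most `max_warp_factor * min(length(a), length(b))` cells (never fewer
#'   than `max(length(a), length(b))`), so one contour can be stretched at
#'   most this many fold against the other. Default 3.
#' @return a list of class `dtw_params`.
#' @export
dtw_params <- function(max_warp_factor = 3) {
  if (max_warp_factor < 1) stop("max_warp_factor must be >= 1", call. = FALSE)
  structure(list(max_warp_factor = max_warp_factor), class = "dtw_params")
}

#' Adaptive-resonance parameters
#'
#' @param vigilance_pct similarity (in percent) a whistle must reach against a
#'   category's reference contour to join that category. Default 96, the value
#'   at which signature whistles are known to sort into distinct categories.
#' @param learning_rate fraction by which a category's reference moves toward
#'   each newly (re)assigned member, in (0, 1]. Default 0.1.
#' @param max_iterations maximum number of presentation passes. Default 50.
#' @param seed integer seed for the per-pass presentation shuffle.
#' @return a list of class `art_params`.
#' @export
art_params <- function(vigilance_pct = 96, learning_rate = 0.1,
                       max_iterations = 50, seed = 1L) {
  if (vigilance_pct <= 0 || vigilance_pct > 100)
    stop("vigilance_pct must be in (0, 100]", call. = FALSE)
  if (learning_rate <= 0 || learning_rate > 1)
    stop("learning_rate must be in (0, 1]", call. = FALSE)
  if (max_iterations < 1) stop("max_iterations must be >= 1", call. = FALSE)
  structure(list(vigilance_pct = vigilance_pct,
                 learning_rate = learning_rate,
                 max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed)),
            class = "art_params")
}

#' Dynamic-time-warping similarity between two frequency sequences
#'
#' Aligns two positive frequency sequences by dynamic programming and returns
#' the maximum, over admissible monotone warping paths, of the mean per-pair
#' similarity `100 * min(f, g) / max(f, g)` along the path. Identical
#' sequences score 100; two constant contours an octave apart score 50. The
#' measure is symmetric in its arguments.
#'
#' @param a,b numeric vectors (length >= 2, all values > 0), typically
#'   contours resampled to a common time step.
#' @param params a [dtw_params()] object.
#' @return list with `similarity_pct` (scalar in (0, 100]) and `path` (a
#'   two-column matrix of aligned indices into `a` and `b`).
#' @export
dtw_similarity <- function(a, b, params = dtw_params()) {
  if (length(a) < 2L || length(b) < 2L)
    stop("sequences must have length >= 2", call. = FALSE)
  res <- dtw_core(as.numeric(a), as.numeric(b), params$max_warp_factor)
  list(similarity_pct = res$similarity_pct, path = res$path)
}

# Warp sequence `input` onto the reference time base given an alignment path
# (column 1: reference index, column 2: input index). Where several input
# samples map to one reference index their mean is taken, so the result has
# the reference's length.
warp_to_reference <- function(path, input, ref_length) {
  sums <- numeric(ref_length)
  cnts <- numeric(ref_length)
  ri <- path[, 1L]
  ii <- path[, 2L]
  for (k in seq_along(ri)) {
    sums[ri[k]] <- sums[ri[k]] + input[ii[k]]
    cnts[ri[k]] <- cnts[ri[k]] + 1
  }
  sums / cnts
}

#' Categorize whistle contours into types (ART + dynamic time warping)
#'
#' Unsupervised categorization of whistle contours into whistle types using
#' an adaptive-resonance procedure: starting from zero categories, whistles
#' are presented in seeded shuffled order; each whistle joins the most
#' similar existing category if the dynamic-time-warping similarity to that
#' category's reference contour reaches the vigilance threshold, and founds a
#' new category otherwise. On (re)assignment the winning reference moves
#' toward the warped input by the learning rate. Passes repeat, reshuffling,
#' until an entire pass produces no assignment changes (or `max_iterations`
#' is reached). The result is a partition: every whistle belongs to exactly
#' one type.
#'
#' @param whistles non-empty list of [whistle_contour()] objects.
#' @param art an [art_params()] object (vigilance, learning rate, seed).
#' @param dtw a [dtw_params()] object.
#' @param step_s resampling step applied to all contours before comparison
#'   (seconds; default 0.01).
#' @return an object of class `artwarp` with components `assignment` (named
#'   integer vector: whistle id -> type index), `types` (list with per-type
#'   `type_id`, `reference` frequency sequence and `member_ids`),
#'   `iterations`, `converged`, and the parameter objects.
#' @seealso [label_types()], [predict.artwarp()]
#' @export
artwarp <- function(whistles, art = art_params(), dtw = dtw_params(),
                    step_s = 0.01) {
  if (length(whistles) == 0L) stop("no whistles to categorize", call. = FALSE)
  seqs <- contour_sequences(whistles, step_s)
  ids <- names(seqs)
  if (anyDuplicated(ids)) stop("duplicate whistle ids", call. = FALSE)
  n <- length(seqs)

  refs <- list()                      # reference contour per category
  assign_idx <- rep(NA_integer_, n)   # category index per whistle
  eta <- art$learning_rate
  vig <- art$vigilance_pct
  iterations <- 0L
  converged <- FALSE

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(art$seed)

  for (pass in seq_len(art$max_iterations)) {
    iterations <- pass
    changes <- 0L
    for (k in sample.int(n)) {
      x <- seqs[[k]]
      if (length(refs)) {
        sims <- vapply(refs, function(r)
          dtw_core(r, x, dtw$max_warp_factor)$similarity_pct, numeric(1))
        best <- which.max(sims)  # ties: lowest (oldest) category index wins
      } else {
        sims <- numeric(0)
        best <- 0L
      }
      if (length(refs) && sims[best] >= vig) {
        if (!identical(assign_idx[k], best)) changes <- changes + 1L
        assign_idx[k] <- best
        al <- dtw_core(refs[[best]], x, dtw$max_warp_factor)
        warped <- warp_to_reference(al$path, x, length(refs[[best]]))
        refs[[best]] <- refs[[best]] + eta * (warped - refs[[best]])
      } else {
        refs[[length(refs) + 1L]] <- x
        assign_idx[k] <- length(refs)
        changes <- changes + 1L
      }
    }
    # prune categories that lost all members, renumbering compactly
    live <- sort(unique(assign_idx))
    if (length(live) < length(refs)) {
      remap <- integer(length(refs))
      remap[live] <- seq_along(live)
      refs <- refs[live]
      assign_idx <- remap[assign_idx]
    }
    if (changes == 0L) { converged <- TRUE; break }
  }

  type_ids <- sprintf("T%03d", seq_along(refs))
  types <- lapply(seq_along(refs), function(i)
    list(type_id = type_ids[i],
         reference = refs[[i]],
         member_ids = ids[assign_idx == i]))
  names(types) <- type_ids
  assignment <- setNames(assign_idx, ids)

  structure(list(assignment = assignment,
                 types = types,
                 n_whistles = n,
                 iterations = iterations,
                 converged = converged,
                 art = art, dtw = dtw, step_s = step_s),
            class = "artwarp")
}

#' @export
print.artwarp <- function(x, ...) {
  cat("ART + dynamic-time-warping whistle categorization\n")
  cat(sprintf("  %d whistles -> %d types (vigilance %.1f%%)\n",
              x$n_whistles, length(x$types), x$art$vigilance_pct))
  cat(sprintf("  %s after %d pass(es)\n",
              if (x$converged) "converged" else "iteration cap reached",
              x$iterations))
  invisible(x)
}

#' @export
summary.artwarp <- function(object, ...) {
  sizes <- vapply(object$types, function(t) length(t$member_ids), integer(1))
  out <- list(n_whistles = object$n_whistles,
              n_types = length(object$types),
              type_sizes = sizes,
              n_singletons = sum(sizes == 1L),
              iterations = object$iterations,
              converged = object$converged,
              vigilance_pct = object$art$vigilance_pct)
  class(out) <- "summary.artwarp"
  out
}

#' @export
print.summary.artwarp <- function(x, ...) {
  cat(sprintf("artwarp: %d whistles in %d types (%d singletons)\n",
              x$n_whistles, x$n_types, x$n_singletons))
  cat(sprintf("  vigilance %.1f%%; %d pass(es); converged: %s\n",
              x$vigilance_pct, x$iterations, x$converged))
  cat("  type sizes: ")
  print(summary(as.numeric(x$type_sizes)))
  invisible(x)
}

#' Type membership as a data frame
#'
#' @param fit an `artwarp` object.
#' @return data frame with columns `whistle_id`, `type_id`.
#' @export
type_membership <- function(fit) {
  stopifnot(inherits(fit, "artwarp"))
  type_ids <- names(fit$types)
  data.frame(whistle_id = names(fit$assignment),
             type_id = type_ids[fit$assignment],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Assign new whistles to fitted whistle types
#'
#' Each new contour is compared against all reference contours; it is
#' assigned to the most similar type if that similarity reaches the fitted
#' vigilance, otherwise to `NA` (no resonating category). References are not
#' updated.
#'
#' @param object an `artwarp` object.
#' @param newdata list of [whistle_contour()] objects.
#' @param ... unused.
#' @return data frame with `whistle_id`, `type_id` (`NA` when below
#'   vigilance) and `similarity_pct` to the best-matching reference.
#' @export
predict.artwarp <- function(object, newdata, ...) {
  seqs <- contour_sequences(newdata, object$step_s)
  type_ids <- names(object$types)
  res <- lapply(seqs, function(x) {
    sims <- vapply(object$types, function(t)
      dtw_core(t$reference, x, object$dtw$max_warp_factor)$similarity_pct,
      numeric(1))
    best <- which.max(sims)
    data.frame(type_id = if (sims[best] >= object$art$vigilance_pct)
                 type_ids[best] else NA_character_,
               similarity_pct = sims[best], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- cbind(data.frame(whistle_id = names(seqs), stringsAsFactors = FALSE),
               out)
  row.names(out) <- NULL
  out
}

#' Plot reference contours of fitted whistle types
#'
#' @param x an `artwarp` object.
#' @param types type ids to draw (default: all, largest first, up to `max_n`).
#' @param max_n maximum number of references to draw.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.artwarp <- function(x, types = NULL, max_n = 12, ...) {
  if (is.null(types)) {
    sizes <- vapply(x$types, function(t) length(t$member_ids), integer(1))
    types <- names(sort(sizes, decreasing = TRUE))
    types <- types[seq_len(min(max_n, length(types)))]
  }
  refs <- lapply(x$types[types], `[[`, "reference")
  len <- max(vapply(refs, length, integer(1)))
  mat <- sapply(refs, function(r) c(r, rep(NA, len - length(r))))
  matplot((seq_len(len) - 1) * x$step_s, mat / 1000, type = "l", lty = 1,
          xlab = "time (s)", ylab = "frequency (kHz)",
          main = "whistle type reference contours", ...)
  invisible(x)
}
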