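#' Count species-specific types among multiple-encounter types
#'
#' Given the whistle-level species labels of the multiple-encounter types
#' (types recorded from two or more schools), counts the types whose member
#' whistles carry exactly one species label and returns the count and its
#' proportion of all multiple-encounter types. Invariant to whistle order
#' and to renaming the species.
#'
#' @param type_id character/factor vector, one entry per whistle.
#' @param species species label per whistle (same length).
#' @return list with `count` and `proportion`.
#' @export
species_specific_count <- function(type_id, species) {
  if (length(type_id) == 0L)
    stop("no whistles supplied", call. = FALSE)
  if (length(type_id) != length(species))
    stop("type_id and species lengths differ", call. = FALSE)
  tt <- table(type_id, species)
  single <- rowSums(tt > 0) == 1L
  list(count = sum(single), proportion = sum(single) / nrow(tt))
}

#' Permutation test for an excess of species-specific whistle types
#'
#' Subsampling two species with identical repertoires produces some
#' apparently species-specific types by chance. This test asks whether the
#' observed number exceeds that expectation: the whistle-level species
#' labels of all whistles belonging to multiple-encounter types are
#' permuted uniformly at random `B` times, the species-specific type count
#' is recomputed for each permutation, and a two-tailed p-value is formed by
#' doubling the smaller add-one-smoothed tail:
#' `p = min(1, 2 * min((#\{null >= obs\} + 1), (#\{null <= obs\} + 1)) / (B + 1))`.
#'
#' @param type_id type id per whistle (multiple-encounter types only; a type
#'   appearing here is assumed to satisfy `n_encounters >= 2`).
#' @param species species label per whistle; both species must be present.
#' @param B number of permutations (default 1000).
#' @param seed integer seed.
#' @return object of class `perm_test`: `observed_count`,
#'   `observed_proportion`, `null_counts` (length `B`),
#'   `null_mean_proportion`, `p_value`, `B`, `seed`.
#' @export
permutation_test <- function(type_id, species, B = 1000L, seed = 1L) {
  type_id <- as.character(type_id)
  species <- as.character(species)
  if (length(unique(type_id)) < 2L)
    stop("need at least 2 multiple-encounter types", call. = FALSE)
  if (length(unique(species)) < 2L)
    stop("permutation test undefined with a single species", call. = FALSE)

  tf <- factor(type_id)
  n_types <- nlevels(tf)
  idx <- as.integer(tf)
  sizes <- tabulate(idx, n_types)
  x <- as.integer(species == sort(unique(species))[1L])

  count_specific <- function(lab) {
    s <- tabulate(idx[lab == 1L], n_types)
    sum(s == 0L | s == sizes)
  }
  obs <- count_specific(x)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  null_counts <- integer(B)
  for (b in seq_len(B)) null_counts[b] <- count_specific(sample(x))

  p_hi <- (sum(null_counts >= obs) + 1) / (B + 1)
  p_lo <- (sum(null_counts <= obs) + 1) / (B + 1)
  p <- min(1, 2 * min(p_hi, p_lo))

  structure(list(observed_count = obs,
                 observed_proportion = obs / n_types,
                 null_counts = null_counts,
                 null_mean_proportion = mean(null_counts) / n_types,
                 p_value = p, B = as.integer(B), seed = as.integer(seed),
                 n_types = n_types),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat("Permutation test for excess species-specific whistle types\n")
  cat(sprintf("  observed: %d of %d multiple-encounter types (%.1f%%)\n",
              x$observed_count, x$n_types, 100 * x$observed_proportion))
  cat(sprintf("  null mean proportion: %.1f%% (B = %d)\n",
              100 * x$null_mean_proportion, x$B))
  cat(sprintf("  two-tailed p = %.4g\n", x$p_value))
  invisible(x)
}

#' One whistle per type, at random
#'
#' Draws exactly one member whistle from each type (seeded), used to avoid
#' pseudoreplication in univariate comparisons: repeated whistles of one
#' type are not independent samples of the species' repertoire.
#'
#' @param membership data frame with `whistle_id` and `type_id`.
#' @param seed integer seed.
#' @return character vector of selected whistle ids, one per type.
#' @export
one_per_type_subsample <- function(membership, seed = 1L) {
  if (nrow(membership) == 0L) stop("no types supplied", call. = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  picks <- vapply(split(membership$whistle_id, membership$type_id),
                  function(ids) ids[sample.int(length(ids), 1L)], "")
  unname(picks)
}

#' Univariate species comparisons over the feature roster
#'
#' Compares every contour feature between the two species: two-sided
#' Wilcoxon rank-sum tests (normal approximation with tie correction) for
#' the 50 continuous variables and Pearson chi-squared tests on contingency
#' tables for the 6 categorical variables, with a Bonferroni-corrected alpha
#' of `alpha / 56`. A categorical level observed in neither species is
#' dropped before testing; a degenerate (constant) continuous variable gets
#' p = 1 with a warning.
#'
#' @param features data frame from [extract_features_table()].
#' @param species species label per feature row.
#' @param alpha family-wise alpha before correction (default 0.05).
#' @return data frame of class `univariate_table`: `name`, `test`,
#'   `statistic`, `p_value`, `significant_after_bonferroni`, with the
#'   corrected alpha in attribute `alpha_corrected`.
#' @export
univariate_compare <- function(features, species, alpha = 0.05) {
  species <- as.character(species)
  if (length(unique(species)) != 2L)
    stop("exactly two species required", call. = FALSE)
  roster <- feature_roster()
  n_tests <- nrow(roster)
  alpha_corr <- alpha / n_tests

  rows <- lapply(seq_len(n_tests), function(i) {
    nm <- roster$name[i]
    v <- features[[nm]]
    if (roster$type[i] == "continuous") {
      test <- "rank_sum"
      ok <- is.finite(v)
      if (length(unique(v[ok])) < 2L) {
        warning("constant continuous variable: ", nm, call. = FALSE)
        stat <- NA_real_; p <- 1
      } else {
        wt <- suppressWarnings(
          wilcox.test(v[ok] ~ species[ok], exact = FALSE, correct = FALSE))
        stat <- unname(wt$statistic); p <- wt$p.value
      }
    } else {
      test <- "chi_square"
      tab <- table(v, species)
      tab <- tab[rowSums(tab) > 0, , drop = FALSE]
      if (nrow(tab) < 2L) {
        stat <- NA_real_; p <- 1
      } else {
        ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
        stat <- unname(ct$statistic); p <- ct$p.value
      }
    }
    data.frame(name = nm, test = test, statistic = stat, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant_after_bonferroni <- out$p_value < alpha_corr
  attr(out, "alpha") <- alpha
  attr(out, "alpha_corrected") <- alpha_corr
  attr(out, "n_tests") <- n_tests
  class(out) <- c("univariate_table", "data.frame")
  out
}
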