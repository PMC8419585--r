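#' Random-forest configuration
#'
#' @param ntree_start initial forest size (default 10000).
#' @param ntree_growth_factor multiplier applied while the out-of-bag error
#'   has not stabilized (default 10).
#' @param ntree_max maximum forest size (default 100000).
#' @param stabilization_tolerance absolute change in OOB error rate below
#'   which the forest counts as stabilized (default 0.005, i.e. half a
#'   percentage point).
#' @param mtry candidate predictors per split; default
#'   `floor(sqrt(n_features))`, recomputed from the feature roster.
#' @param seed integer seed.
#' @return list of class `rf_config`.
#' @export
rf_config <- function(ntree_start = 10000L, ntree_growth_factor = 10L,
                      ntree_max = 100000L, stabilization_tolerance = 0.005,
                      mtry = NULL, seed = 1L) {
  if (ntree_start > ntree_max)
    stop("ntree_start must not exceed ntree_max", call. = FALSE)
  if (stabilization_tolerance <= 0)
    stop("stabilization_tolerance must be positive", call. = FALSE)
  structure(list(ntree_start = as.integer(ntree_start),
                 ntree_growth_factor = as.integer(ntree_growth_factor),
                 ntree_max = as.integer(ntree_max),
                 stabilization_tolerance = stabilization_tolerance,
                 mtry = mtry, seed = as.integer(seed)),
            class = "rf_config")
}

RF_SCHEMES <- c("RF1_all", "RF2_species_specific_multi", "RF3_shared",
                "RF4_single_encounter")

#' Build a whistle subset for one classification scheme
#'
#' The four schemes probe where species information lives in the
#' repertoire: all whistles (RF1); whistles of species-specific types seen
#' in more than one encounter (RF2); whistles of shared types (RF3);
#' whistles of single-encounter types, i.e. singletons plus
#' single-encounter multi-whistle types (RF4). Every whistle belongs to RF1
#' and to exactly one of RF2/RF3/RF4.
#'
#' @param features feature table from [extract_features_table()].
#' @param membership data frame with `whistle_id`, `type_id` and `species`.
#' @param labels `type_labels` from [label_types()].
#' @param scheme one of `"RF1_all"`, `"RF2_species_specific_multi"`,
#'   `"RF3_shared"`, `"RF4_single_encounter"`.
#' @return data frame: `whistle_id`, `species` (factor) and the feature
#'   columns.
#' @export
build_subset <- function(features, membership, labels,
                         scheme = c("RF1_all", "RF2_species_specific_multi",
                                    "RF3_shared", "RF4_single_encounter")) {
  scheme <- match.arg(scheme)
  cat_map <- setNames(labels$category, labels$type_id)
  categ <- cat_map[membership$type_id]
  keep <- switch(scheme,
    RF1_all = rep(TRUE, nrow(membership)),
    RF2_species_specific_multi = categ == "species_specific",
    RF3_shared = categ == "shared",
    RF4_single_encounter = categ %in% c("singleton",
                                        "single_encounter_multi"))
  ids <- membership$whistle_id[keep]
  if (length(ids) == 0L)
    stop("scheme ", scheme, ": empty whistle subset", call. = FALSE)
  idx <- match(ids, features$whistle_id)
  if (anyNA(idx))
    stop("features missing for whistle(s): ",
         paste(ids[is.na(idx)], collapse = ", "), call. = FALSE)
  out <- features[idx, , drop = FALSE]
  out$species <- factor(membership$species[keep])
  row.names(out) <- NULL
  out[c("whistle_id", "species",
        setdiff(names(features), "whistle_id"))]
}

#' Balance the two species classes by subsampling
#'
#' Takes a seeded random subset of the larger class equal to the size of the
#' smaller class, leaving the minority class untouched, so class imbalance
#' cannot inflate classification accuracy.
#'
#' @param dataset data frame with a `species` column (two levels present).
#' @param seed integer seed.
#' @return data frame with equal class sizes.
#' @export
balance_classes <- function(dataset, seed = 1L) {
  sp <- as.character(dataset$species)
  counts <- table(sp)
  if (length(counts) != 2L || any(counts == 0L))
    stop("both species classes must be present", call. = FALSE)
  n_min <- min(counts)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  keep <- unlist(lapply(names(counts), function(cl) {
    rows <- which(sp == cl)
    if (length(rows) > n_min) sort(sample(rows, n_min)) else rows
  }))
  out <- dataset[sort(keep), , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Train and evaluate a species random forest
#'
#' Grows a random forest on the contour features (continuous variables
#' numeric, categorical as factors) and evaluates it on out-of-bag samples:
#' each tree is grown on a bootstrap of the whistles, and a whistle is
#' classified by voting over the trees whose bootstrap excluded it. The
#' forest starts at `ntree_start` trees and is regrown `ntree_growth_factor`
#' times larger until the OOB error changes by less than the stabilization
#' tolerance (or `ntree_max` is reached). Variable importance is ranked by
#' mean decrease in Gini impurity.
#'
#' @param dataset balanced data frame from [balance_classes()] (columns
#'   `whistle_id`, `species`, features).
#' @param config an [rf_config()] object.
#' @return object of class `rf_species`: `scheme` (if recorded on the
#'   dataset), `n_whistles`, `overall_accuracy_pct`, `class_accuracy_pct`,
#'   `confusion` (counts), `importance` (full ranking; top 15 printed),
#'   `ntree_used`, `oob_error`.
#' @export
train_evaluate <- function(dataset, config = rf_config()) {
  sp <- droplevels(factor(dataset$species))
  if (nlevels(sp) != 2L)
    stop("dataset must contain exactly two species", call. = FALSE)
  if (min(table(sp)) < 10L)
    stop("need at least 10 whistles per class", call. = FALSE)
  roster <- feature_roster()
  x <- dataset[, intersect(roster$name, names(dataset)), drop = FALSE]
  for (nm in names(x)) {
    if (roster$type[match(nm, roster$name)] == "categorical")
      x[[nm]] <- factor(x[[nm]])
  }
  num <- vapply(x, is.numeric, logical(1))
  bad <- names(x)[num][!vapply(x[num], function(v) all(is.finite(v)),
                               logical(1))]
  if (length(bad))
    stop("non-finite feature values in: ", paste(bad, collapse = ", "),
         call. = FALSE)
  mtry <- if (is.null(config$mtry)) floor(sqrt(ncol(x))) else config$mtry

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))

  grow <- function(ntree) {
    set.seed(config$seed)
    randomForest::randomForest(x = x, y = sp, ntree = ntree, mtry = mtry,
                               importance = FALSE)
  }
  ntree <- config$ntree_start
  fit <- grow(ntree)
  err <- fit$err.rate[ntree, "OOB"]
  while (ntree * config$ntree_growth_factor <= config$ntree_max) {
    ntree2 <- ntree * config$ntree_growth_factor
    fit2 <- grow(ntree2)
    err2 <- fit2$err.rate[ntree2, "OOB"]
    stabilized <- abs(err2 - err) < config$stabilization_tolerance
    fit <- fit2; err <- err2; ntree <- ntree2
    if (stabilized) break
  }

  conf <- fit$confusion[, seq_len(nlevels(sp)), drop = FALSE]
  correct <- diag(conf)
  class_acc <- 100 * correct / rowSums(conf)
  overall <- 100 * sum(correct) / sum(conf)
  imp <- randomForest::importance(fit, type = 2)
  imp <- data.frame(variable = rownames(imp),
                    gini_importance = unname(imp[, 1]),
                    stringsAsFactors = FALSE)
  imp <- imp[order(-imp$gini_importance), , drop = FALSE]
  row.names(imp) <- NULL

  structure(list(scheme = attr(dataset, "scheme"),
                 n_whistles = nrow(dataset),
                 overall_accuracy_pct = overall,
                 class_accuracy_pct = class_acc,
                 confusion = conf,
                 importance = imp,
                 ntree_used = ntree,
                 oob_error = err,
                 mtry = mtry),
            class = "rf_species")
}

#' @export
print.rf_species <- function(x, ...) {
  cat("Random-forest species classifier (out-of-bag evaluation)\n")
  if (!is.null(x$scheme)) cat("  subset:", x$scheme, "\n")
  cat(sprintf("  %d whistles, %d trees, mtry %d\n",
              x$n_whistles, x$ntree_used, x$mtry))
  cat(sprintf("  overall OOB accuracy: %.1f%%\n", x$overall_accuracy_pct))
  for (cl in names(x$class_accuracy_pct))
    cat(sprintf("    %s: %.1f%%\n", cl, x$class_accuracy_pct[cl]))
  cat("  top predictors:",
      paste(head(x$importance$variable, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Compare two classifiers' accuracies by Fisher's exact test
#'
#' Builds the 2x2 table of correct/incorrect OOB classifications for the
#' two models and applies a two-sided Fisher's exact test. Swapping the
#' models inverts the odds ratio and leaves p unchanged.
#'
#' @param a,b `rf_species` objects from [train_evaluate()].
#' @return list with `odds_ratio`, `p_value` and the `table` tested.
#' @export
compare_accuracies <- function(a, b) {
  counts <- function(r) {
    correct <- sum(diag(r$confusion))
    c(correct = correct, incorrect = sum(r$confusion) - correct)
  }
  ca <- counts(a); cb <- counts(b)
  if (sum(ca) == 0L || sum(cb) == 0L)
    stop("a model has no classified whistles", call. = FALSE)
  tab <- rbind(a = ca, b = cb)
  ft <- fisher.test(tab)
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value, table = tab)
}
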