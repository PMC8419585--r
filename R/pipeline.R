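#' Pipeline configuration
#'
#' Bundles the per-stage parameter objects of the full analysis
#' (generate/read -> select -> Nyquist harmonize -> categorize -> label ->
#' statistics -> random forests). Exactly one of `generator` and `paths`
#' must be supplied. One master seed deterministically derives a distinct
#' seed per stage, so adding a stage does not shift the randomness of the
#' others.
#'
#' @param generator a [repertoire_config()], or `NULL` when reading data.
#' @param paths named list with `contours`, `metadata`, `encounters` CSV
#'   paths, or `NULL` when generating.
#' @param rules a [selection_rules()].
#' @param art an [art_params()].
#' @param dtw a [dtw_params()].
#' @param osc an [oscillation_params()].
#' @param rf an [rf_config()].
#' @param perm_B permutation count for the species-specificity test.
#' @param rf_schemes classification subsets to fit (default all four).
#' @param step_s contour resampling step (seconds).
#' @param seed master seed.
#' @param out_dir optional output directory for intermediate CSVs and the
#'   JSON report.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = NULL, paths = NULL,
                            rules = selection_rules(),
                            art = art_params(), dtw = dtw_params(),
                            osc = oscillation_params(), rf = rf_config(),
                            perm_B = 1000L,
                            rf_schemes = RF_SCHEMES,
                            step_s = 0.01, seed = 1L, out_dir = NULL) {
  if (is.null(generator) == is.null(paths))
    stop("supply exactly one of generator config or input paths",
         call. = FALSE)
  structure(list(generator = generator, paths = paths, rules = rules,
                 art = art, dtw = dtw, osc = osc, rf = rf,
                 perm_B = as.integer(perm_B), rf_schemes = rf_schemes,
                 step_s = step_s, seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

# stage seeds derived from the master seed by name hashing
stage_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 7919 + h) %% 2147483647)
}

#' Run the whistle-repertoire analysis pipeline
#'
#' Executes the stages in analysis order: obtain contours (synthetic
#' generation or CSV input), apply the whistle-selection rules per
#' encounter, harmonize to the common Nyquist band, categorize with
#' [artwarp()], label the taxonomy and oscillatory types, extract features,
#' run the species-specificity permutation test and the univariate
#' comparisons (one whistle per type), and fit the configured random-forest
#' subsets with pairwise accuracy comparisons. A stage failure aborts with
#' the stage name. The report is deterministic under the master seed
#' (timings aside).
#'
#' @param config a [pipeline_config()].
#' @return a `run_report` list with per-stage counts, the fitted objects'
#'   summaries and results; written as JSON (plus intermediate CSVs) when
#'   `out_dir` is configured.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  report <- list(schema_version = "1.0", master_seed = config$seed,
                 stages = list())

  # -- input ----------------------------------------------------------------
  dat <- stage("input", {
    if (!is.null(config$generator)) {
      gen <- config$generator
      gen$seed <- stage_seed(config$seed, "generate")
      generate_repertoire(gen)
    } else {
      rd <- read_contours(config$paths$contours, config$paths$metadata,
                          config$paths$encounters)
      list(whistles = rd$whistles, encounters = rd$encounters,
           ground_truth = NULL)
    }
  })
  report$stages$input <- list(n_whistles = length(dat$whistles),
                              n_encounters = nrow(dat$encounters))

  # -- selection ------------------------------------------------------------
  selected <- stage("select", {
    rules <- config$rules
    rules$rng_seed <- stage_seed(config$seed, "select")
    meta <- contour_metadata(dat$whistles)
    out <- list()
    for (e in seq_len(nrow(dat$encounters))) {
      eid <- dat$encounters$encounter_id[e]
      cand <- dat$whistles[meta$encounter_id == eid]
      out <- c(out, select_whistles(cand, dat$encounters[e, ], rules))
    }
    out
  })
  report$stages$select <- list(n_candidates = length(dat$whistles),
                               n_selected = length(selected))

  # -- Nyquist harmonization ------------------------------------------------
  ny <- stage("nyquist", nyquist_harmonize(selected))
  report$stages$nyquist <- list(target_nyquist_hz = ny$target_nyquist_hz,
                                n_kept = length(ny$kept),
                                n_dropped = length(ny$dropped))
  whistles <- ny$kept

  # -- categorization -------------------------------------------------------
  fit <- stage("categorize", {
    art <- config$art
    art$seed <- stage_seed(config$seed, "categorize")
    artwarp(whistles, art = art, dtw = config$dtw, step_s = config$step_s)
  })
  membership <- type_membership(fit)
  meta <- contour_metadata(whistles)
  membership$species <- meta$species[match(membership$whistle_id,
                                           meta$whistle_id)]
  membership$encounter_id <- meta$encounter_id[match(membership$whistle_id,
                                                     meta$whistle_id)]
  report$stages$categorize <- list(n_types = length(fit$types),
                                   iterations = fit$iterations,
                                   converged = fit$converged)

  # -- taxonomy and oscillation --------------------------------------------
  labels <- stage("label", {
    lab <- label_types(membership)
    label_oscillatory_types(fit, lab, config$osc, whistles = whistles)
  })
  summ <- type_summary(labels)
  osc_by_species <- stage("label", {
    spec <- labels[labels$category == "species_specific", , drop = FALSE]
    tapply(spec$oscillatory, spec$species_set, sum)
  })
  report$stages$label <- c(summ,
                           list(oscillatory_species_specific =
                                  as.list(osc_by_species)))

  # -- features -------------------------------------------------------------
  features <- stage("features", extract_features_table(whistles,
                                                       step_s = config$step_s))
  report$stages$features <- list(n_rows = nrow(features),
                                 n_variables = nrow(feature_roster()))

  # -- species statistics ---------------------------------------------------
  perm <- stage("permutation", {
    multi <- labels$type_id[labels$category %in%
                              c("shared", "species_specific")]
    mm <- membership[membership$type_id %in% multi, , drop = FALSE]
    permutation_test(mm$type_id, mm$species, B = config$perm_B,
                     seed = stage_seed(config$seed, "permutation"))
  })
  report$stages$permutation <- list(
    observed_count = perm$observed_count,
    observed_proportion = perm$observed_proportion,
    null_mean_proportion = perm$null_mean_proportion,
    p_value = perm$p_value, B = perm$B)

  univ <- stage("univariate", {
    ids <- one_per_type_subsample(membership,
                                  seed = stage_seed(config$seed, "univariate"))
    sub <- membership[membership$whistle_id %in% ids, , drop = FALSE]
    fsub <- features[match(sub$whistle_id, features$whistle_id), ,
                     drop = FALSE]
    univariate_compare(fsub, sub$species)
  })
  report$stages$univariate <- list(
    n_tests = attr(univ, "n_tests"),
    alpha_corrected = attr(univ, "alpha_corrected"),
    n_significant = sum(univ$significant_after_bonferroni, na.rm = TRUE))

  # -- random forests -------------------------------------------------------
  rf_results <- list()
  for (scheme in config$rf_schemes) {
    rf_results[[scheme]] <- stage(paste0("rf_", scheme), {
      ds <- build_subset(features, membership, labels, scheme)
      ds <- balance_classes(ds, seed = stage_seed(config$seed, scheme))
      attr(ds, "scheme") <- scheme
      train_evaluate(ds, config$rf)
    })
  }
  report$stages$random_forest <- lapply(rf_results, function(r)
    list(n_whistles = r$n_whistles,
         overall_accuracy_pct = r$overall_accuracy_pct,
         class_accuracy_pct = as.list(r$class_accuracy_pct),
         ntree_used = r$ntree_used,
         top_variables = head(r$importance$variable, 15)))
  if (all(c("RF2_species_specific_multi", "RF3_shared") %in%
          names(rf_results)))
    report$stages$rf_comparisons$RF2_vs_RF3 <-
      compare_accuracies(rf_results$RF2_species_specific_multi,
                         rf_results$RF3_shared)[c("odds_ratio", "p_value")]
  if (all(c("RF2_species_specific_multi", "RF1_all") %in% names(rf_results)))
    report$stages$rf_comparisons$RF2_vs_RF1 <-
      compare_accuracies(rf_results$RF2_species_specific_multi,
                         rf_results$RF1_all)[c("odds_ratio", "p_value")]

  report$objects <- list(fit = fit, labels = labels, membership = membership,
                         features = features, perm = perm, univariate = univ,
                         rf = rf_results)
  class(report) <- "run_report"

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_contours(whistles, file.path(config$out_dir, "contours.csv"),
                   file.path(config$out_dir, "metadata.csv"))
    write.csv(membership, file.path(config$out_dir, "types.csv"),
              row.names = FALSE)
    write.csv(as.data.frame(labels),
              file.path(config$out_dir, "labels.csv"), row.names = FALSE)
    write.csv(features, file.path(config$out_dir, "features.csv"),
              row.names = FALSE)
    rep_json <- report
    rep_json$objects <- NULL
    jsonlite::write_json(rep_json, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("whistlemod pipeline report (seed ", x$master_seed, ")\n", sep = "")
  s <- x$stages
  cat(sprintf("  input: %d whistles, %d encounters\n",
              s$input$n_whistles, s$input$n_encounters))
  cat(sprintf("  selected: %d; Nyquist-dropped: %d\n",
              s$select$n_selected, s$nyquist$n_dropped))
  cat(sprintf("  types: %d (shared %d, species-specific %d, single-enc %d, singleton %d)\n",
              s$label$n_types, s$label$n_shared, s$label$n_species_specific,
              s$label$n_single_encounter_multi, s$label$n_singleton))
  cat(sprintf("  permutation: observed %.1f%%, null %.1f%%, p = %.4g\n",
              100 * s$permutation$observed_proportion,
              100 * s$permutation$null_mean_proportion,
              s$permutation$p_value))
  for (nm in names(s$random_forest))
    cat(sprintf("  %s: %.1f%% OOB accuracy (n = %d)\n", nm,
                s$random_forest[[nm]]$overall_accuracy_pct,
                s$random_forest[[nm]]$n_whistles))
  invisible(x)
}

#' Synthetic fixture matching the published repertoire composition
#'
#' Builds a deterministic whistle-to-type membership table whose marginals
#' reproduce a published two-species repertoire decomposition: 447 types
#' over 1774 whistles (902 short-beaked, 872 long-beaked), of which 169 are
#' shared, 60 species-specific (32 short-beaked, 28 long-beaked over 2-5
#' encounters each), 28 single-encounter multi-whistle and 190 singletons.
#' Type sizes follow a long-tailed distribution (many rare types, few
#' common ones), as observed in delphinid repertoires; oscillatory flags
#' mark 15 short-beaked and 1 long-beaked species-specific types and 5
#' shared types. The whistle-level species counts give per-class sizes of
#' 902/872 overall and 673/619 within shared types.
#'
#' This is a synthetic reconstruction from printed summary tables, not
#' field data; it exists so the bookkeeping stages (taxonomy labelling,
#' proportions, permutation test, class balancing) can be exercised on a
#' realistic composition.
#'
#' @return list with `membership` (data frame: `whistle_id`, `type_id`,
#'   `species`, `encounter_id`) and `types` (data frame: `type_id`,
#'   `oscillatory`).
#' @export
make_composition_fixture <- function() {
  sb_enc <- sprintf("SB_E%02d", 1:14)
  lb_enc <- sprintf("LB_E%02d", 1:10)
  rows <- list()
  osc_types <- character(0)
  ti <- 0L; wi <- 0L
  sb_rr <- 0L; lb_rr <- 0L  # round-robin encounter counters

  next_enc <- function(sp) {
    if (sp == "short_beaked") {
      sb_rr <<- sb_rr + 1L
      sb_enc[(sb_rr - 1L) %% length(sb_enc) + 1L]
    } else {
      lb_rr <<- lb_rr + 1L
      lb_enc[(lb_rr - 1L) %% length(lb_enc) + 1L]
    }
  }
  add_type <- function(members_sp, encounters, oscillatory = FALSE) {
    ti <<- ti + 1L
    tid <- sprintf("PT%03d", ti)
    for (j in seq_along(members_sp)) {
      wi <<- wi + 1L
      rows[[wi]] <<- data.frame(whistle_id = sprintf("pw%04d", wi),
                                type_id = tid,
                                species = members_sp[j],
                                encounter_id = encounters[j],
                                stringsAsFactors = FALSE)
    }
    if (oscillatory) osc_types <<- c(osc_types, tid)
    tid
  }

  # shared types: long-tailed sizes, 169 types / 1292 whistles,
  # species split 673 short-beaked / 619 long-beaked
  shared_sizes <- rep(c(2, 3, 4, 6, 8, 12, 20, 17, 18),
                      c(30, 30, 25, 20, 15, 15, 14, 18, 2))
  extra_sb <- rep(FALSE, length(shared_sizes))
  extra_sb[which(shared_sizes == 17)[1:3]] <- TRUE  # 10/7 instead of 9/8
  n_shared_osc <- 0L
  for (i in seq_along(shared_sizes)) {
    k <- shared_sizes[i]
    n_sb <- ceiling(k / 2) + if (extra_sb[i]) 1L else 0L
    sp <- rep(c("short_beaked", "long_beaked"), c(n_sb, k - n_sb))
    enc <- vapply(sp, next_enc, "")
    osc <- k == 3 && n_shared_osc < 5L  # 5 shared oscillatory types, 15 whistles
    if (osc) n_shared_osc <- n_shared_osc + 1L
    add_type(sp, enc, oscillatory = osc)
  }

  # species-specific types (>= 2 whistles over 2-5 encounters of one species)
  add_specific <- function(sp, sizes, oscillatory) {
    enc_pool <- if (sp == "short_beaked") sb_enc else lb_enc
    for (i in seq_along(sizes)) {
      k <- sizes[i]
      ne <- min(5L, k, 2L + (i %% 4L))  # 2-5 encounters per type
      start <- (i * 2L) %% (length(enc_pool) - ne + 1L)
      enc_ids <- enc_pool[start + seq_len(ne)]
      enc <- enc_ids[rep_len(seq_len(ne), k)]
      add_type(rep(sp, k), enc, oscillatory = oscillatory)
    }
  }
  add_specific("short_beaked", rep(c(4, 3), c(12, 3)), TRUE)    # 57 whistles
  add_specific("short_beaked", rep(c(3, 2), c(16, 1)), FALSE)   # 50 whistles
  add_specific("long_beaked", 4, TRUE)                          # 4 whistles
  add_specific("long_beaked", rep(c(4, 3), c(16, 11)), FALSE)   # 97 whistles

  # single-encounter multi-whistle types: 28 x 3 whistles
  for (i in 1:28) {
    sp <- if (i <= 14) "short_beaked" else "long_beaked"
    enc <- next_enc(sp)
    add_type(rep(sp, 3), rep(enc, 3))
  }

  # singletons: 80 short-beaked + 110 long-beaked
  for (i in 1:80) add_type("short_beaked", next_enc("short_beaked"))
  for (i in 1:110) add_type("long_beaked", next_enc("long_beaked"))

  membership <- do.call(rbind, rows)
  row.names(membership) <- NULL
  types <- data.frame(type_id = sprintf("PT%03d", seq_len(ti)),
                      stringsAsFactors = FALSE)
  types$oscillatory <- types$type_id %in% osc_types
  list(membership = membership, types = types)
}
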