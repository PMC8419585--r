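#' Configuration for the synthetic two-species repertoire generator
#'
#' The generator emulates the statistical structure the analysis assumes:
#' two species drawing whistles from a pool of shared whistle types plus
#' species-exclusive pools; oscillatory contour templates concentrated in
#' one species; stereotyped (signature-like) whistles repeated within an
#' encounter; encounter structure with per-school whistle counts; duration
#' and frequency jitter; and two sampling rates so that the Nyquist
#' harmonization step has work to do (a configurable number of "high band"
#' shared templates exceed the 44.1 kHz Nyquist frequency and are only
#' recordable in 96 kHz encounters).
#'
#' @param seed integer master seed; a fixed seed gives identical output.
#' @param n_encounters_per_species named/two-element integer vector,
#'   default `c(short_beaked = 14, long_beaked = 10)`.
#' @param whistles_per_encounter integer range (min, max) of whistles per
#'   encounter, default `c(50, 200)`.
#' @param n_shared_types number of shared low-band templates (default 10).
#' @param n_specific_types_per_species exclusive templates per species
#'   (default 4).
#' @param oscillatory_fraction_per_species proportion of each species'
#'   exclusive templates that are oscillatory, default
#'   `c(short_beaked = 15/32, long_beaked = 1/28)`.
#' @param stereotype_rate proportion of an encounter's whistles that are
#'   repeats of an encounter-local stereotyped template (default 0.15).
#' @param jitter list with `freq_offset_sd_hz` (per-whistle frequency
#'   offset, default 30), `freq_noise_sd_hz` (per-point noise, smoothed
#'   over 3 points, default 20) and `duration_scale_sd` (log-normal sd of
#'   the duration multiplier, default 0.04). The defaults are calibrated so
#'   that expected within-template similarity stays above 97% (comfortably
#'   over the 96% vigilance) while mean between-template similarity stays
#'   at or below 90% and no pair exceeds the 93% construction bound.
#' @param sample_rates sampling rates cycled over encounters, default
#'   `c(44100, 96000)`.
#' @param n_high_band_types shared templates above the lowest Nyquist
#'   frequency (default 1; set 0 to disable).
#' @return list of class `repertoire_config`.
#' @export
repertoire_config <- function(seed = 1L,
                              n_encounters_per_species =
                                c(short_beaked = 14L, long_beaked = 10L),
                              whistles_per_encounter = c(50L, 200L),
                              n_shared_types = 10L,
                              n_specific_types_per_species = 4L,
                              oscillatory_fraction_per_species =
                                c(short_beaked = 15 / 32,
                                  long_beaked = 1 / 28),
                              stereotype_rate = 0.15,
                              jitter = list(freq_offset_sd_hz = 30,
                                            freq_noise_sd_hz = 20,
                                            duration_scale_sd = 0.04),
                              sample_rates = c(44100, 96000),
                              n_high_band_types = 1L) {
  stopifnot(length(n_encounters_per_species) == 2L,
            length(whistles_per_encounter) == 2L,
            length(oscillatory_fraction_per_species) == 2L)
  if (any(n_encounters_per_species < 1) || n_shared_types < 1 ||
      n_specific_types_per_species < 1)
    stop("all counts must be >= 1", call. = FALSE)
  if (any(oscillatory_fraction_per_species < 0 |
          oscillatory_fraction_per_species > 1) ||
      stereotype_rate < 0 || stereotype_rate > 1)
    stop("proportions must be in [0, 1]", call. = FALSE)
  if (whistles_per_encounter[1] > whistles_per_encounter[2])
    stop("whistles_per_encounter must be an increasing range", call. = FALSE)
  names(n_encounters_per_species) <- c("short_beaked", "long_beaked")
  names(oscillatory_fraction_per_species) <- c("short_beaked", "long_beaked")
  structure(list(seed = as.integer(seed),
                 n_encounters_per_species = n_encounters_per_species,
                 whistles_per_encounter = as.integer(whistles_per_encounter),
                 n_shared_types = as.integer(n_shared_types),
                 n_specific_types_per_species =
                   as.integer(n_specific_types_per_species),
                 oscillatory_fraction_per_species =
                   oscillatory_fraction_per_species,
                 stereotype_rate = stereotype_rate,
                 jitter = jitter,
                 sample_rates = sample_rates,
                 n_high_band_types = as.integer(n_high_band_types)),
            class = "repertoire_config")
}

#' Generate one analytic whistle contour
#'
#' Contour families span the shapes seen in delphinid whistles: linear
#' sweeps, concave (U) and convex (hump) arcs, sigmoid transitions and
#' oscillatory sines. Construction is deterministic given the parameters.
#' Oscillatory sines are sampled on a grid aligned with their quarter-cycle
#' points, so the sampled maximum minus minimum equals twice the amplitude
#' exactly and an `oscillatory_sine` with `amplitude_hz >= 500`,
#' `n_cycles >= 2` and `coverage >= 0.5` passes the [is_oscillatory()]
#' criteria by construction.
#'
#' @param family one of `"linear_sweep"`, `"concave"`, `"convex"`,
#'   `"sigmoid"`, `"oscillatory_sine"`.
#' @param params named list. `linear_sweep`/`sigmoid`: `f0_hz`, `f1_hz`,
#'   `duration_s`. `concave`/`convex`: `f_edge_hz`, `f_mid_hz`,
#'   `duration_s`. `oscillatory_sine`: `carrier_hz`, `amplitude_hz`,
#'   `n_cycles`, `coverage`, `duration_s`.
#' @param seed optional seed (construction is deterministic; the seed is
#'   honoured for forward compatibility with stochastic families).
#' @param step_s nominal point spacing (default 0.01 s).
#' @param ... metadata fields passed to [whistle_contour()]
#'   (`whistle_id`, `encounter_id`, `species`, `sample_rate_hz`, ...).
#' @return a [whistle_contour()].
#' @export
generate_contour <- function(family = c("linear_sweep", "concave", "convex",
                                        "sigmoid", "oscillatory_sine"),
                             params, seed = NULL, step_s = 0.01, ...) {
  family <- match.arg(family)
  if (!is.null(seed)) set.seed(seed)
  dur <- params$duration_s
  if (is.null(dur) || dur <= 0) stop("duration_s must be positive",
                                     call. = FALSE)
  if (family == "oscillatory_sine") {
    A <- params$amplitude_hz
    nc <- params$n_cycles
    cov <- if (is.null(params$coverage)) 1 else params$coverage
    if (is.null(A) || A < 0) stop("amplitude_hz must be non-negative",
                                  call. = FALSE)
    if (is.null(nc) || nc < 1) stop("n_cycles must be >= 1", call. = FALSE)
    if (cov <= 0 || cov > 1) stop("coverage must be in (0, 1]", call. = FALSE)
    sine_dur <- cov * dur
    # grid aligned to quarter cycles so sampled extrema are exact
    n_int <- 4 * nc * max(1L, round(sine_dur / (4 * nc * step_s)))
    t1 <- seq(0, sine_dur, length.out = n_int + 1)
    f1 <- params$carrier_hz + A * sin(2 * pi * nc * t1 / sine_dur)
    if (cov < 1) {
      t2 <- if (sine_dur + step_s <= dur)
        seq(sine_dur + step_s, dur, by = step_s) else numeric(0)
      if (length(t2) == 0L || t2[length(t2)] < dur) t2 <- c(t2, dur)
      t <- c(t1, t2)
      f <- c(f1, rep(params$carrier_hz, length(t2)))
    } else {
      t <- t1; f <- f1
    }
  } else {
    n_int <- max(2L, round(dur / step_s))
    t <- seq(0, dur, length.out = n_int + 1)
    u <- t / dur
    f <- switch(family,
      linear_sweep = params$f0_hz + (params$f1_hz - params$f0_hz) * u,
      sigmoid = params$f0_hz + (params$f1_hz - params$f0_hz) /
        (1 + exp(-10 * (u - 0.5))),
      convex = params$f_edge_hz +
        (params$f_mid_hz - params$f_edge_hz) * sin(pi * u),
      concave = params$f_edge_hz +
        (params$f_mid_hz - params$f_edge_hz) * sin(pi * u))
  }
  whistle_contour(time_s = t, freq_hz = f, ...)
}

# draw the parameter list for one candidate template
draw_template <- function(oscillatory, high_band = FALSE) {
  dur <- runif(1, 0.5, 1.3)
  if (high_band) {
    carrier <- runif(1, 22500, 24500)
    return(list(family = "linear_sweep",
                params = list(f0_hz = carrier, f1_hz = carrier * 1.06,
                              duration_s = dur)))
  }
  if (oscillatory) {
    carrier <- exp(runif(1, log(6000), log(16000)))
    list(family = "oscillatory_sine",
         params = list(carrier_hz = carrier,
                       amplitude_hz = max(1000, 0.2 * carrier),
                       n_cycles = sample(3:5, 1),
                       coverage = runif(1, 0.85, 1),
                       duration_s = dur))
  } else {
    family <- sample(c("linear_sweep", "concave", "convex", "sigmoid"), 1)
    spanf <- runif(1, 1.1, 1.8)
    c0 <- exp(runif(1, log(2500), log(20200 / spanf)))
    dirn <- sample(c(TRUE, FALSE), 1)
    if (family %in% c("linear_sweep", "sigmoid")) {
      f0 <- if (dirn) c0 else c0 * spanf
      f1 <- if (dirn) c0 * spanf else c0
      list(family = family,
           params = list(f0_hz = f0, f1_hz = f1, duration_s = dur))
    } else {
      fe <- c0
      fm <- if (dirn) c0 * spanf else c0 / spanf
      list(family = family,
           params = list(f_edge_hz = fe, f_mid_hz = fm, duration_s = dur))
    }
  }
}

template_sequence <- function(tpl, step_s = 0.01) {
  w <- generate_contour(tpl$family, tpl$params, step_s = step_s,
                        whistle_id = "tpl", sample_rate_hz = 96000)
  resample_contour(w, step_s)$freq_hz
}

#' Generate a synthetic two-species whistle repertoire
#'
#' Builds the template pools first (shared pool available to both species,
#' exclusive pool per species, oscillatory templates allocated by the
#' per-species oscillatory fraction), then samples each encounter's
#' whistles from its species' accessible pools with jitter. Template
#' acceptance is by rejection: a candidate whose dynamic-time-warping
#' similarity to an accepted template exceeds 93% is redrawn, keeping every
#' template pair at least three points below the categorizer's 96% vigilance
#' (and typical pairs near 70-80%) while jittered copies of one template stay
#' above it. Stereotyped
#' whistles repeat an encounter-local template and carry a `stereotype_id`.
#' Encounters cycle through the configured sampling rates; templates above
#' the lowest Nyquist frequency are only accessible to encounters recorded
#' at the higher rate.
#'
#' @param config a [repertoire_config()].
#' @return list with `whistles` (list of [whistle_contour()]), `encounters`
#'   (data frame), `ground_truth` (data frame: `whistle_id`,
#'   `template_type_id`, `species`, `is_oscillatory_template`,
#'   `is_stereotyped`) and `templates` (the template specs).
#' @export
generate_repertoire <- function(config = repertoire_config()) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)
  species <- c("short_beaked", "long_beaked")

  n_spec <- config$n_specific_types_per_species
  n_osc <- round(config$oscillatory_fraction_per_species * n_spec)
  plan <- rbind(
    data.frame(pool = "shared", oscillatory = FALSE, high_band = FALSE,
               count = config$n_shared_types, stringsAsFactors = FALSE),
    data.frame(pool = "shared", oscillatory = FALSE, high_band = TRUE,
               count = config$n_high_band_types, stringsAsFactors = FALSE),
    data.frame(pool = species, oscillatory = FALSE, high_band = FALSE,
               count = n_spec - n_osc, stringsAsFactors = FALSE),
    data.frame(pool = species, oscillatory = TRUE, high_band = FALSE,
               count = unname(n_osc), stringsAsFactors = FALSE))

  templates <- list()
  seqs <- list()
  attempts_left <- 800L * sum(plan$count)
  for (r in seq_len(nrow(plan))) {
    for (k in seq_len(plan$count[r])) {
      repeat {
        attempts_left <- attempts_left - 1L
        if (attempts_left < 0L)
          stop("template pool too crowded for the requested structure; ",
               "reduce type counts", call. = FALSE)
        cand <- draw_template(plan$oscillatory[r], plan$high_band[r])
        cs <- template_sequence(cand)
        ok <- TRUE
        for (s in seqs) {
          if (dtw_core(s, cs, 3)$similarity_pct > 93) { ok <- FALSE; break }
        }
        if (ok) break
      }
      id <- sprintf("tpl%02d", length(templates) + 1L)
      cand$template_id <- id
      cand$pool <- plan$pool[r]
      cand$oscillatory <- plan$oscillatory[r]
      cand$high_band <- plan$high_band[r]
      templates[[id]] <- cand
      seqs[[id]] <- cs
    }
  }
  tpl_pool <- vapply(templates, `[[`, "", "pool")
  tpl_max <- vapply(seqs, max, numeric(1))

  # encounters
  ne <- config$n_encounters_per_species
  enc <- do.call(rbind, lapply(species, function(sp) {
    n <- ne[[sp]]
    do.call(rbind, lapply(seq_len(n), function(i)
      encounter_record(
        encounter_id = sprintf("%s_E%02d",
                               ifelse(sp == "short_beaked", "SB", "LB"), i),
        species = sp,
        school_size_estimate = max(5L, round(exp(runif(1, log(20), log(400))))),
        year = sample(2017:2019, 1),
        sample_rate_hz = config$sample_rates[(i - 1) %%
                                               length(config$sample_rates) + 1])))
  }))
  low_nyquist <- min(config$sample_rates) / 2

  whistles <- list()
  gt <- list()
  jit <- config$jitter
  wi <- 0L
  for (e in seq_len(nrow(enc))) {
    sp <- enc$species[e]
    fs <- enc$sample_rate_hz[e]
    accessible <- names(templates)[tpl_pool %in% c("shared", sp)]
    accessible <- accessible[tpl_max[accessible] < fs / 2 - 600]
    lo <- config$whistles_per_encounter[1]
    hi <- config$whistles_per_encounter[2]
    n_w <- lo + sample.int(hi - lo + 1L, 1L) - 1L
    stereo_tpl <- sample(accessible, min(2L, length(accessible)))
    file_i <- 1L
    offset <- runif(1, 1, 10)
    for (k in seq_len(n_w)) {
      stereotyped <- runif(1) < config$stereotype_rate
      tid <- if (stereotyped) sample(stereo_tpl, 1) else
        sample(accessible, 1)
      tpl <- templates[[tid]]
      wi <- wi + 1L
      wid <- sprintf("w%05d", wi)
      base <- generate_contour(tpl$family, tpl$params,
                               whistle_id = wid, encounter_id =
                                 enc$encounter_id[e],
                               species = sp, sample_rate_hz = fs,
                               file_id = sprintf("%s_f%02d",
                                                 enc$encounter_id[e], file_i),
                               file_offset_s = offset,
                               stereotype_id = if (stereotyped)
                                 paste0(enc$encounter_id[e], "_", tid)
                               else NA_character_,
                               snr_db = rnorm(1, 12, 4))
      mult <- exp(rnorm(1, 0, jit$duration_scale_sd))
      off <- rnorm(1, 0, jit$freq_offset_sd_hz)
      noise <- smooth3(rnorm(length(base$freq_hz), 0, jit$freq_noise_sd_hz))
      base$time_s <- base$time_s * mult
      base$freq_hz <- pmax(200, base$freq_hz + off + noise)
      validate_contour(base)
      whistles[[wid]] <- base
      gt[[wid]] <- data.frame(whistle_id = wid, template_type_id = tid,
                              species = sp,
                              is_oscillatory_template = tpl$oscillatory,
                              is_stereotyped = stereotyped,
                              stringsAsFactors = FALSE)
      offset <- offset + contour_duration(base) + runif(1, 0.5, 12)
      if (offset > 295) { file_i <- file_i + 1L; offset <- runif(1, 1, 10) }
    }
  }
  gt <- do.call(rbind, gt)
  row.names(gt) <- NULL
  row.names(enc) <- NULL
  list(whistles = whistles, encounters = enc, ground_truth = gt,
       templates = templates)
}

#' Write a generated repertoire to CSV files
#'
#' Emits the contour point table, whistle metadata table and encounter
#' table of [read_contours()] plus a ground-truth table
#' (`whistle_id, template_type_id, species, is_oscillatory_template,
#' is_stereotyped`).
#'
#' @param rep result of [generate_repertoire()].
#' @param dir output directory (created if needed).
#' @return invisibly, the four paths written.
#' @export
write_repertoire <- function(rep, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(contours = file.path(dir, "contours.csv"),
             metadata = file.path(dir, "metadata.csv"),
             encounters = file.path(dir, "encounters.csv"),
             ground_truth = file.path(dir, "ground_truth.csv"))
  write_contours(rep$whistles, paths["contours"], paths["metadata"],
                 paths["encounters"], rep$encounters)
  write.csv(rep$ground_truth, paths["ground_truth"], row.names = FALSE)
  invisible(paths)
}
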