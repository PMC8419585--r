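test_that("analytic contour families have their constructed shapes", {
  s <- make_sine("s1", 8000, 2000, 3, dur = 1)
  expect_equal(max(s$freq_hz) - min(s$freq_hz), 4000)
  ex <- find_extrema_oracle(s$freq_hz)
  expect_equal(sum(ex$is_max), 3)

  sw <- make_sweep("s2", 8000, 16000, dur = 0.8)
  expect_true(all(diff(sw$freq_hz) > 0))
  expect_equal(count_inflections(sw)$count, 0)

  expect_error(make_sine("s3", 8000, -100, 3), "amplitude")
  expect_error(make_sine("s4", 8000, 500, 0.5), "n_cycles")
})

test_that("contour generation is deterministic given the parameters", {
  p <- list(carrier_hz = 9000, amplitude_hz = 1500, n_cycles = 4,
            coverage = 0.9, duration_s = 0.8)
  a <- generate_contour("oscillatory_sine", p, whistle_id = "a")
  b <- generate_contour("oscillatory_sine", p, whistle_id = "b")
  expect_equal(a$time_s, b$time_s)
  expect_equal(a$freq_hz, b$freq_hz)
})

test_that("repertoire generation respects species template accessibility", {
  cfg <- repertoire_config(seed = 7, n_encounters_per_species = c(2, 2),
                           whistles_per_encounter = c(10, 15),
                           n_shared_types = 5,
                           n_specific_types_per_species = 3,
                           n_high_band_types = 0)
  rep <- generate_repertoire(cfg)
  pool <- vapply(rep$templates, `[[`, "", "pool")
  gt <- rep$ground_truth
  for (i in seq_len(nrow(gt)))
    expect_true(pool[gt$template_type_id[i]] %in% c("shared", gt$species[i]))
  # every whistle has exactly one template
  expect_equal(nrow(gt), length(rep$whistles))
  expect_false(anyNA(gt$template_type_id))
})

test_that("zero oscillatory fraction plants no oscillatory templates", {
  cfg <- repertoire_config(seed = 3, n_encounters_per_species = c(2, 2),
                           whistles_per_encounter = c(5, 8),
                           n_shared_types = 4,
                           n_specific_types_per_species = 2,
                           oscillatory_fraction_per_species = c(0.5, 0),
                           n_high_band_types = 0)
  rep <- generate_repertoire(cfg)
  pool <- vapply(rep$templates, `[[`, "", "pool")
  osc <- vapply(rep$templates, `[[`, logical(1), "oscillatory")
  expect_false(any(osc[pool == "long_beaked"]))
  expect_true(any(osc[pool == "short_beaked"]))
})

test_that("a fixed seed reproduces the repertoire byte for byte", {
  cfg <- small_repertoire(11, wpe = c(8, 12))
  a <- generate_repertoire(cfg)
  b <- generate_repertoire(cfg)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_identical(a$encounters, b$encounters)
  expect_equal(lapply(a$whistles, `[[`, "freq_hz"),
               lapply(b$whistles, `[[`, "freq_hz"))
})

test_that("zero jitter makes template copies identical after duration normalization", {
  cfg <- small_repertoire(5, wpe = c(10, 10), shared = 3, specific = 1,
                          jitter = list(freq_offset_sd_hz = 0,
                                        freq_noise_sd_hz = 0,
                                        duration_scale_sd = 0))
  rep <- generate_repertoire(cfg)
  gt <- rep$ground_truth
  for (tid in unique(gt$template_type_id)) {
    ids <- gt$whistle_id[gt$template_type_id == tid]
    if (length(ids) < 2) next
    ref <- rep$whistles[[ids[1]]]$freq_hz
    for (id in ids[-1])
      expect_equal(rep$whistles[[id]]$freq_hz, ref)
  }
})

test_that("default jitter keeps within-template similarity above vigilance and between-template below", {
  rep <- generate_repertoire(small_repertoire(13, wpe = c(12, 12)))
  seqs <- contour_sequences(rep$whistles)
  gt <- rep$ground_truth
  within <- c(); between <- c()
  set.seed(99)
  for (i in sample(length(seqs), 30)) {
    for (j in sample(length(seqs), 5)) {
      if (i == j) next
      s <- dtw_similarity(seqs[[i]], seqs[[j]])$similarity_pct
      if (gt$template_type_id[i] == gt$template_type_id[j])
        within <- c(within, s) else between <- c(between, s)
    }
  }
  expect_gte(mean(within), 97)
  expect_lte(mean(between), 90)
  expect_lt(max(between), 96)  # no template pair resonates at vigilance
})

test_that("stronger point noise lowers within-template similarity", {
  mean_within <- function(noise_sd) {
    sims <- c()
    for (sd in 1:3) {
      cfg <- small_repertoire(sd, wpe = c(8, 8), shared = 3, specific = 1,
                              jitter = list(freq_offset_sd_hz = 0,
                                            freq_noise_sd_hz = noise_sd,
                                            duration_scale_sd = 0))
      rep <- generate_repertoire(cfg)
      seqs <- contour_sequences(rep$whistles)
      gt <- rep$ground_truth
      for (tid in unique(gt$template_type_id)) {
        ids <- which(gt$template_type_id == tid)
        if (length(ids) < 2) next
        sims <- c(sims, dtw_similarity(seqs[[ids[1]]],
                                       seqs[[ids[2]]])$similarity_pct)
      }
    }
    mean(sims)
  }
  s_small <- mean_within(10)
  s_mid <- mean_within(80)
  s_big <- mean_within(300)
  expect_gt(s_small, s_mid)
  expect_gt(s_mid, s_big)
})

test_that("the repertoire CSV bundle round-trips through the readers", {
  rep <- generate_repertoire(small_repertoire(21, wpe = c(4, 6)))
  td <- withr::local_tempdir()
  paths <- write_repertoire(rep, td)
  rd <- read_contours(paths["contours"], paths["metadata"],
                      paths["encounters"])
  expect_equal(length(rd$whistles), length(rep$whistles))
  expect_equal(nrow(rd$encounters), nrow(rep$encounters))
  gt <- read.csv(paths["ground_truth"])
  expect_equal(nrow(gt), length(rep$whistles))
})
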