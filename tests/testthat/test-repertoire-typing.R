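mk_membership <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(whistle_id = r[1], type_id = r[2], species = r[3],
               encounter_id = r[4], stringsAsFactors = FALSE)))
}

test_that("taxonomy categories follow the sharing definitions", {
  m <- mk_membership(
    c("w1", "T1", "short_beaked", "e1"),
    c("w2", "T1", "long_beaked", "e9"),
    c("w3", "T2", "short_beaked", "e1"),
    c("w4", "T2", "short_beaked", "e2"),
    c("w5", "T2", "short_beaked", "e2"),
    c("w6", "T3", "long_beaked", "e9"),
    c("w7", "T3", "long_beaked", "e9"),
    c("w8", "T4", "long_beaked", "e9"))
  lab <- label_types(m)
  cat_of <- setNames(lab$category, lab$type_id)
  expect_equal(unname(cat_of[c("T1", "T2", "T3", "T4")]),
               c("shared", "species_specific", "single_encounter_multi",
                 "singleton"))
  s <- type_summary(lab)
  expect_equal(s$n_types, 4)
  expect_equal(s$n_multi_encounter, s$n_shared + s$n_species_specific)
  expect_equal(s$n_types,
               s$n_shared + s$n_species_specific +
                 s$n_single_encounter_multi + s$n_singleton)
})

test_that("metadata joins are enforced for every member whistle", {
  m <- data.frame(whistle_id = c("w1", "w2"), type_id = "T1",
                  stringsAsFactors = FALSE)
  meta <- data.frame(whistle_id = "w1", encounter_id = "e1",
                     species = "short_beaked", stringsAsFactors = FALSE)
  expect_error(label_types(m, meta), "w2")
})

test_that("categories are exhaustive and exclusive on the composition fixture", {
  fx <- make_composition_fixture()
  lab <- label_types(fx$membership)
  expect_equal(nrow(lab), length(unique(fx$membership$type_id)))
  expect_true(all(lab$category %in% c("shared", "species_specific",
                                      "single_encounter_multi", "singleton")))
  # definitions hold row by row
  expect_true(all((lab$category == "singleton") == (lab$n_whistles == 1)))
  two_sp <- grepl(",", lab$species_set)
  expect_true(all((lab$category == "shared") == (two_sp & lab$n_whistles > 1)))
  expect_true(all((lab$category == "species_specific") ==
                    (!two_sp & lab$n_whistles >= 2 & lab$n_encounters >= 2)))
})

test_that("the oscillation rule accepts and rejects the analytic boundary contours", {
  # all three criteria met
  expect_true(is_oscillatory(make_sine("a", 8000, 2000, 3))$oscillatory)
  # (ii) peak-trough below 1 kHz
  expect_false(is_oscillatory(make_sine("b", 8000, 300, 3))$oscillatory)
  # (iii) oscillation confined to 40% of the contour
  expect_false(is_oscillatory(make_sine("c", 8000, 2000, 3,
                                        coverage = 0.4))$oscillatory)
  # no maxima at all
  flat <- make_contour("d", seq(0, 1, 0.01), rep(9000, 101))
  expect_false(is_oscillatory(flat)$oscillatory)
  # a single peak is not an oscillation
  one_max <- generate_contour("convex", list(f_edge_hz = 8000,
                                             f_mid_hz = 12000,
                                             duration_s = 1),
                              whistle_id = "e")
  expect_false(is_oscillatory(one_max)$oscillatory)
})

test_that("dissimilar cycle magnitudes disqualify the run", {
  # two large cycles followed by two tiny-but-above-threshold wiggles
  t <- seq(0, 1, 0.005)
  f <- 10000 + ifelse(t <= 0.5,
                      3000 * sin(2 * pi * 4 * t),
                      600 * sin(2 * pi * 4 * t))
  w <- make_contour("mix", t, f)
  res <- is_oscillatory(w, oscillation_params(similar_magnitude_ratio = 0.5))
  # the qualifying run cannot span both magnitude regimes
  expect_lt(res$diagnostics$coverage, 0.75)
})

test_that("the oscillation decision is invariant to offset and time stretch", {
  base <- make_sine("a", 9000, 1600, 3, dur = 0.8)
  for (w in list(base, make_sine("b", 14000, 1600, 3, dur = 0.8))) {
    shifted <- w; shifted$freq_hz <- w$freq_hz + 3000
    stretched <- w; stretched$time_s <- w$time_s * 2.5
    expect_equal(is_oscillatory(shifted)$oscillatory,
                 is_oscillatory(w)$oscillatory)
    expect_equal(is_oscillatory(stretched)$oscillatory,
                 is_oscillatory(w)$oscillatory)
  }
})

test_that("type-level oscillation flags recover the planted templates", {
  cfg <- small_repertoire(41, n_enc = c(2, 2), wpe = c(12, 12),
                          shared = 4, specific = 2,
                          jitter = list(freq_offset_sd_hz = 0,
                                        freq_noise_sd_hz = 0,
                                        duration_scale_sd = 0))
  rep <- generate_repertoire(cfg)
  fit <- artwarp(rep$whistles, art_params(seed = 2))
  m <- type_membership(fit)
  gtm <- gt_membership(rep)
  m$species <- gtm$species[match(m$whistle_id, gtm$whistle_id)]
  m$encounter_id <- gtm$encounter_id[match(m$whistle_id, gtm$whistle_id)]
  lab <- label_types(m)
  lab <- label_oscillatory_types(fit, lab, whistles = rep$whistles)
  # map recovered types back to planted templates
  m <- type_membership(fit)
  gt <- rep$ground_truth
  osc_templates <- names(which(vapply(rep$templates, `[[`, logical(1),
                                      "oscillatory")))
  for (i in seq_len(nrow(lab))) {
    mem <- fit$types[[lab$type_id[i]]]$member_ids
    planted <- unique(gt$template_type_id[match(mem, gt$whistle_id)])
    expect_length(planted, 1)
    expect_equal(lab$oscillatory[i], planted %in% osc_templates)
  }
  # member-level counts agree at zero jitter
  expect_true(all(lab$n_oscillatory_whistles ==
                    ifelse(lab$oscillatory, lab$n_whistles, 0)))
})
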