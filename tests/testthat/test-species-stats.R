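test_that("species-specific counting handles the elementary cases", {
  r <- species_specific_count(c("T1", "T1", "T2", "T2"),
                              c("A", "A", "A", "B"))
  expect_equal(r$count, 1)
  expect_equal(r$proportion, 0.5)
  r2 <- species_specific_count(c("T1", "T1", "T2", "T2"),
                               c("A", "B", "B", "A"))
  expect_equal(r2$count, 0)
  expect_error(species_specific_count(character(0), character(0)),
               "no whistles")
})

test_that("species-specific counting is invariant to order and relabeling", {
  set.seed(8)
  type_id <- rep(sprintf("T%d", 1:20), sample(2:6, 20, TRUE))
  species <- sample(c("short_beaked", "long_beaked"), length(type_id), TRUE)
  base <- species_specific_count(type_id, species)
  perm <- sample(length(type_id))
  expect_equal(species_specific_count(type_id[perm], species[perm]), base)
  relab <- c(short_beaked = "X", long_beaked = "Y")[species]
  expect_equal(species_specific_count(type_id, relab)$count, base$count)
})

test_that("the composition fixture gives 60 of 229 multiple-encounter types", {
  fx <- make_composition_fixture()
  lab <- label_types(fx$membership)
  multi <- lab$type_id[lab$category %in% c("shared", "species_specific")]
  mm <- fx$membership[fx$membership$type_id %in% multi, ]
  r <- species_specific_count(mm$type_id, mm$species)
  expect_equal(r$count, 60)
  expect_equal(round(100 * r$proportion, 1), 26.2)
})

test_that("an observed count beyond every null draw gives the +1-smoothed doubled p", {
  # 30 pure single-species types of 6 whistles each: the observed count (30)
  # is unreachable under permutation with overwhelming probability
  type_id <- rep(sprintf("T%02d", 1:30), each = 6)
  species <- rep(rep(c("short_beaked", "long_beaked"), 15), each = 6)
  r <- permutation_test(type_id, species, B = 999, seed = 4)
  expect_true(all(r$null_counts < r$observed_count))
  expect_equal(r$p_value, 2 / 1000)
})

test_that("permutation null draws are seeded and reproducible", {
  type_id <- rep(sprintf("T%d", 1:12), each = 3)
  species <- sample(c("short_beaked", "long_beaked"), 36, TRUE)
  a <- permutation_test(type_id, species, B = 50, seed = 9)
  b <- permutation_test(type_id, species, B = 50, seed = 9)
  expect_identical(a$null_counts, b$null_counts)
  expect_length(a$null_counts, 50)
  expect_error(permutation_test(c("T1", "T1", "T2"), rep("A", 3), B = 10),
               "single species")
})

test_that("one whistle is subsampled per type, deterministically", {
  m <- data.frame(whistle_id = sprintf("w%d", 1:8),
                  type_id = rep(c("T1", "T2", "T3"), c(1, 2, 5)),
                  stringsAsFactors = FALSE)
  ids <- one_per_type_subsample(m, seed = 3)
  expect_length(ids, 3)
  expect_equal(ids[1], "w1")
  expect_true(ids[2] %in% c("w2", "w3"))
  expect_identical(one_per_type_subsample(m, seed = 3), ids)

  singles <- data.frame(whistle_id = sprintf("w%d", 1:4),
                        type_id = sprintf("T%d", 1:4))
  expect_setequal(one_per_type_subsample(singles, seed = 1),
                  singles$whistle_id)
})

test_that("the Bonferroni threshold for the 56-variable roster is 0.05/56", {
  rep <- generate_repertoire(small_repertoire(3, wpe = c(6, 8)))
  feats <- extract_features_table(rep$whistles)
  tab <- univariate_compare(feats, rep$ground_truth$species)
  expect_equal(attr(tab, "n_tests"), 56)
  expect_equal(attr(tab, "alpha_corrected"), 0.05 / 56)
  expect_equal(signif(attr(tab, "alpha_corrected"), 2), 8.9e-4)
  expect_equal(nrow(tab), 56)
})

test_that("identical feature distributions yield no Bonferroni-significant variables", {
  # both species sample the same templates: any difference is sampling noise
  cfg <- small_repertoire(17, n_enc = c(3, 3), wpe = c(30, 30),
                          shared = 6, specific = 1,
                          oscillatory_fraction_per_species = c(0, 0))
  rep <- generate_repertoire(cfg)
  gt <- rep$ground_truth
  shared_ids <- gt$whistle_id[vapply(rep$templates, `[[`, "",
                                     "pool")[gt$template_type_id] == "shared"]
  feats <- extract_features_table(rep$whistles[shared_ids])
  set.seed(31)
  null_species <- sample(rep(c("short_beaked", "long_beaked"),
                             length.out = nrow(feats)))
  tab <- suppressWarnings(univariate_compare(feats, null_species))
  expect_lte(sum(tab$significant_after_bonferroni, na.rm = TRUE), 1)
})

test_that("a planted duration shift is detected after Bonferroni correction", {
  rep <- generate_repertoire(small_repertoire(23, n_enc = c(3, 3),
                                              wpe = c(40, 40)))
  feats <- extract_features_table(rep$whistles)
  sp <- rep$ground_truth$species[match(feats$whistle_id,
                                       rep$ground_truth$whistle_id)]
  # stretch all short-beaked whistles by 3 within-group SDs of duration
  sd_dur <- sd(feats$duration_s)
  feats$duration_s[sp == "short_beaked"] <-
    feats$duration_s[sp == "short_beaked"] + 3 * sd_dur
  tab <- suppressWarnings(univariate_compare(feats, sp))
  expect_true(tab$significant_after_bonferroni[tab$name == "duration_s"])
})
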