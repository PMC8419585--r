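fixture_rf_data <- function(seed = 37) {
  rep <- generate_repertoire(small_repertoire(seed, n_enc = c(3, 3),
                                              wpe = c(25, 30)))
  memb <- gt_membership(rep)
  lab <- label_types(memb)
  feats <- extract_features_table(rep$whistles)
  list(rep = rep, memb = memb, lab = lab, feats = feats)
}

test_that("subset schemes partition the whistles by type category", {
  d <- fixture_rf_data()
  rf1 <- build_subset(d$feats, d$memb, d$lab, "RF1_all")
  expect_equal(nrow(rf1), nrow(d$memb))
  others <- lapply(c("RF2_species_specific_multi", "RF3_shared",
                     "RF4_single_encounter"), function(s)
    tryCatch(build_subset(d$feats, d$memb, d$lab, s)$whistle_id,
             error = function(e) character(0)))
  expect_setequal(unlist(others), rf1$whistle_id)
  expect_equal(anyDuplicated(unlist(others)), 0)
})

test_that("an empty scheme subset is a named error", {
  m <- data.frame(whistle_id = c("w1", "w2", "w3", "w4"),
                  type_id = "T1",
                  species = c("short_beaked", "short_beaked",
                              "long_beaked", "long_beaked"),
                  encounter_id = c("e1", "e1", "e2", "e2"),
                  stringsAsFactors = FALSE)
  lab <- label_types(m)  # one shared type only
  feats <- data.frame(whistle_id = m$whistle_id)
  expect_error(build_subset(feats, m, lab, "RF2_species_specific_multi"),
               "RF2")
})

test_that("class balancing matches the published per-species arithmetic", {
  fx <- make_composition_fixture()
  ds <- data.frame(whistle_id = fx$membership$whistle_id,
                   species = fx$membership$species,
                   stringsAsFactors = FALSE)
  expect_equal(as.vector(table(ds$species)), c(872, 902))
  bal <- balance_classes(ds, seed = 1)
  expect_equal(nrow(bal), 1744)
  expect_equal(as.vector(table(bal$species)), c(872L, 872L))

  even <- ds[c(which(ds$species == "long_beaked")[1:5],
               which(ds$species == "short_beaked")[1:5]), ]
  expect_equal(balance_classes(even, seed = 2), even, ignore_attr = TRUE)

  b1 <- balance_classes(ds, seed = 7)
  b2 <- balance_classes(ds, seed = 7)
  expect_identical(b1$whistle_id, b2$whistle_id)
  # minority class untouched
  expect_true(all(ds$whistle_id[ds$species == "long_beaked"] %in%
                    b1$whistle_id))
})

test_that("a perfectly separating feature yields near-perfect OOB accuracy", {
  d <- fixture_rf_data()
  ds <- build_subset(d$feats, d$memb, d$lab, "RF1_all")
  ds <- balance_classes(ds, seed = 1)
  ds$freq_mean_hz <- ifelse(ds$species == "short_beaked", 20000, 5000)
  res <- train_evaluate(ds, rf_config(ntree_start = 200, ntree_max = 200,
                                      seed = 1))
  expect_gte(res$overall_accuracy_pct, 99)
  expect_equal(res$importance$variable[1], "freq_mean_hz")
  expect_equal(sum(res$confusion), res$n_whistles)
})

test_that("shuffled labels give chance-level OOB accuracy", {
  d <- fixture_rf_data()
  ds <- build_subset(d$feats, d$memb, d$lab, "RF1_all")
  ds <- balance_classes(ds, seed = 1)
  accs <- vapply(1:3, function(sd) {
    shuffled <- ds
    set.seed(sd)
    shuffled$species <- sample(shuffled$species)
    train_evaluate(shuffled, rf_config(ntree_start = 300, ntree_max = 300,
                                       seed = sd))$overall_accuracy_pct
  }, numeric(1))
  expect_lt(abs(mean(accs) - 50), 5)
})

test_that("training is reproducible under a fixed seed and rejects non-finite input", {
  d <- fixture_rf_data()
  ds <- build_subset(d$feats, d$memb, d$lab, "RF1_all")
  ds <- balance_classes(ds, seed = 1)
  cfg <- rf_config(ntree_start = 200, ntree_max = 200, seed = 9)
  r1 <- train_evaluate(ds, cfg)
  r2 <- train_evaluate(ds, cfg)
  expect_equal(r1$overall_accuracy_pct, r2$overall_accuracy_pct)
  expect_equal(r1$confusion, r2$confusion)
  expect_equal(r1$mtry, 7)  # floor(sqrt(56))

  bad <- ds
  bad$slope_mean_hz_s[3] <- NA
  expect_error(train_evaluate(bad, cfg), "slope_mean_hz_s")
})

test_that("forest size escalates until the OOB error stabilizes", {
  d <- fixture_rf_data()
  ds <- build_subset(d$feats, d$memb, d$lab, "RF1_all")
  ds <- balance_classes(ds, seed = 1)
  res <- train_evaluate(ds, rf_config(ntree_start = 50, ntree_max = 400,
                                      ntree_growth_factor = 2,
                                      stabilization_tolerance = 1e-9,
                                      seed = 2))
  expect_equal(res$ntree_used, 400)  # tolerance never met within the cap
  res2 <- train_evaluate(ds, rf_config(ntree_start = 50, ntree_max = 400,
                                       ntree_growth_factor = 2,
                                       stabilization_tolerance = 1,
                                       seed = 2))
  expect_equal(res2$ntree_used, 100)  # stabilized after one escalation
})

test_that("accuracy comparison equals hypergeometric enumeration and is symmetric", {
  mk <- function(correct, wrong) {
    conf <- matrix(c(correct / 2, wrong / 2, wrong / 2, correct / 2), 2,
                   dimnames = list(c("a", "b"), c("a", "b")))
    structure(list(confusion = conf, n_whistles = correct + wrong),
              class = "rf_species")
  }
  a <- mk(90, 10); b <- mk(50, 50)
  cmp <- compare_accuracies(a, b)
  expect_equal(cmp$p_value,
               fisher_p_enum(rbind(c(90, 10), c(50, 50))),
               tolerance = 1e-9)
  swapped <- compare_accuracies(b, a)
  expect_equal(swapped$p_value, cmp$p_value)
  expect_equal(swapped$odds_ratio, 1 / cmp$odds_ratio, tolerance = 1e-6)

  same <- compare_accuracies(a, mk(90, 10))
  expect_equal(same$p_value, 1)
})

test_that("species-specific subsets outclass shared subsets on planted structure", {
  accs <- sapply(c(101, 102, 103), function(sd) {
    cfg <- repertoire_config(seed = sd, n_encounters_per_species = c(4, 4),
                             whistles_per_encounter = c(30, 40),
                             n_high_band_types = 0)
    rep <- generate_repertoire(cfg)
    memb <- gt_membership(rep)
    lab <- label_types(memb)
    feats <- extract_features_table(rep$whistles)
    vapply(c("RF2_species_specific_multi", "RF3_shared"), function(sch) {
      ds <- balance_classes(build_subset(feats, memb, lab, sch), seed = sd)
      train_evaluate(ds, rf_config(ntree_start = 300, ntree_max = 300,
                                   seed = sd))$overall_accuracy_pct
    }, numeric(1))
  })
  expect_true(all(accs[1, ] > accs[2, ]))
})
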