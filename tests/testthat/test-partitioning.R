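test_that("linear prediction maps evaluate exactly", {
  expect_equal(predict_log_klipw_neutral(2, linear_map_model(1, 0)), 2)
  expect_equal(predict_log_klipw_neutral(3, linear_map_model(1.01, 0.12)), 3.15)
  expect_equal(predict_log_klipw_neutral(-4, linear_map_model(0, 1.5)), 1.5)
  expect_error(predict_log_klipw_neutral(NA_real_, linear_map_model(1, 0)),
               class = "chemtriage_missing_input")
})

test_that("liposome-water distribution is the species-weighted sum with the -1 floor", {
  expect_equal(dlipw_at_ph(2, make_species_fractions()), 2)
  half <- make_species_fractions(0.5, 0.5, 0, 0, 0)
  expect_equal(dlipw_at_ph(3, half, ion_offset = 1),
               log10(0.5 * 1000 + 0.5 * 100), tolerance = 1e-12)
  # deep hydrophilics clip at the empirical floor
  expect_equal(dlipw_at_ph(-3, make_species_fractions()), -1)
  expect_equal(dlipw_at_ph(-2.9, half), -1)
})

test_that("albumin rules: hydrophilic floor, cation=neutral, anion map", {
  neutral <- linear_map_model(0.7, 0.5)
  anion <- linear_map_model(0.3, 2.0)
  expect_equal(dbsaw_at_ph(1.0, make_species_fractions(), neutral, anion), 1.31)
  cation <- make_species_fractions(0, 0, 0, 1, 0)
  expect_equal(dbsaw_at_ph(1.5, cation, neutral, anion), 1.31)
  expect_equal(dbsaw_at_ph(3, make_species_fractions(), neutral, anion), 2.6)
  # linear reading of the floor is switchable
  expect_equal(dbsaw_at_ph(1.0, make_species_fractions(), neutral, anion,
                           floor_scale = "linear"),
               log10(1.31), tolerance = 1e-12)
  # anion species routed through the anion map
  an <- make_species_fractions(0, 1, 0, 0, 0)
  expect_equal(dbsaw_at_ph(3, an, neutral, anion), 0.3 * 3 + 2.0)
})

test_that("structural-protein distribution attenuates the anion term", {
  sp <- linear_map_model(1, 0)
  anion <- linear_map_model(0, 2)  # constant anion term 10^2
  expect_equal(dspw_at_ph(2, make_species_fractions(), sp, anion), 2)
  an <- make_species_fractions(0, 1, 0, 0, 0)
  expect_equal(dspw_at_ph(2, an, sp, anion, anion_attenuation = 1), 1.0)
  # 50/50 neutral/anion lies between the two pure-species values
  half <- make_species_fractions(0.5, 0.5, 0, 0, 0)
  v <- dspw_at_ph(2, half, sp, anion, anion_attenuation = 1)
  expect_gt(v, 1.0)
  expect_lt(v, 2.0)
})

test_that("distribution ratios are convex combinations of species constants before flooring", {
  withr::local_seed(404)
  models <- default_partition_models()
  for (i in 1:200) {
    f <- species_fractions(random_profile(), runif(1, 2, 12))
    lkow <- runif(1, 2, 6) # above hydrophilic floor to exercise both maps
    lk_n <- predict_log_klipw_neutral(lkow, models$klipw)
    d <- dlipw_at_ph(lk_n, f, ion_offset = models$ion_offset)
    expect_gte(d, min(lk_n - models$ion_offset, -1) - 1e-9)
    expect_lte(d, lk_n + 1e-9)

    db <- dbsaw_at_ph(lkow, f, models$kbsaw_neutral, models$kbsaw_anion)
    species_k <- c(models$kbsaw_neutral$slope * lkow + models$kbsaw_neutral$intercept,
                   models$kbsaw_anion$slope * lkow + models$kbsaw_anion$intercept)
    expect_gte(db, min(species_k) - 1e-9)
    expect_lte(db, max(species_k) + 1e-9)
  }
})

test_that("fully neutral chemicals reproduce the neutral-species prediction exactly", {
  models <- default_partition_models()
  f1 <- make_species_fractions()
  for (lkow in c(2.5, 3.7, 5.2)) {
    lk_n <- predict_log_klipw_neutral(lkow, models$klipw)
    expect_equal(dlipw_at_ph(lk_n, f1, models$ion_offset), lk_n)
    expect_equal(dbsaw_at_ph(lkow, f1, models$kbsaw_neutral, models$kbsaw_anion),
                 models$kbsaw_neutral$slope * lkow + models$kbsaw_neutral$intercept,
                 tolerance = 1e-12)
    expect_equal(dspw_at_ph(lkow, f1, models$kspw, models$kbsaw_anion),
                 models$kspw$slope * lkow + models$kspw$intercept,
                 tolerance = 1e-12)
  }
})

test_that("increasing log_kow never decreases any predicted log D", {
  withr::local_seed(505)
  models <- default_partition_models()
  for (i in 1:50) {
    f <- species_fractions(random_profile(), 7.4)
    kows <- sort(runif(6, -3, 7))
    dlip <- vapply(kows, function(k)
      dlipw_at_ph(predict_log_klipw_neutral(k, models$klipw), f), numeric(1))
    dbsa <- vapply(kows, function(k)
      dbsaw_at_ph(k, f, models$kbsaw_neutral, models$kbsaw_anion), numeric(1))
    dsp <- vapply(kows, function(k)
      dspw_at_ph(k, f, models$kspw, models$kbsaw_anion), numeric(1))
    expect_true(all(diff(dlip) >= -1e-9))
    expect_true(all(diff(dbsa) >= -1e-9))
    expect_true(all(diff(dsp) >= -1e-9))
  }
})

test_that("compute_partitions assembles a full table and keeps absences explicit", {
  rec <- chemical_records(
    name = c("a", "b"),
    log_kow = c(3, 2.5),
    log_kaw = c(-6, NA),
    ionization = list(ionization_profile(), ionization_profile(4.5, "acid"))
  )
  part <- compute_partitions(rec)
  expect_equal(nrow(part), 2L)
  expect_equal(part$d_aw[1], 1e-6)
  expect_true(is.na(part$d_aw[2]))
  expect_false(any(is.na(part$log_dlipw)))
  expect_equal(part$ph, c(7.4, 7.4))
})
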