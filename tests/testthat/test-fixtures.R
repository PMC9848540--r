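test_that("the same seed reproduces a bundle bit for bit", {
  b1 <- generate_fixture_bundle(7, 20, fixture_options(synonym_rate = 0.5))
  b2 <- generate_fixture_bundle(7, 20, fixture_options(synonym_rate = 0.5))
  expect_identical(b1$raw_table, b2$raw_table)
  expect_identical(b1$inflorescence_table, b2$inflorescence_table)
  expect_identical(b1$taxa_mapping, b2$taxa_mapping)
  expect_identical(b1$ground_truth, b2$ground_truth)
  b3 <- generate_fixture_bundle(8, 20, fixture_options(synonym_rate = 0.5))
  expect_false(identical(b1$raw_table, b3$raw_table))
})

test_that("manifest bookkeeping matches the emitted tables", {
  b <- generate_fixture_bundle(7, 20, fixture_options(synonym_rate = 0.5))
  expect_equal(nrow(b$raw_table), b$manifest$n_raw_records)
  # every synonym in the manifest appears as a duplicate name in the raw table
  expect_equal(b$manifest$n_synonyms, length(b$manifest$synonyms))
  expect_true(all(b$manifest$synonyms %in% b$raw_table$species))
  observed_dupes <- setdiff(unique(b$raw_table$species), b$truth$species)
  expect_setequal(observed_dupes, b$manifest$synonyms)
})

test_that("a clean bundle is recovered exactly by the pipeline", {
  opts <- fixture_options(missing_rate = 0, zero_conflict_rate = 0,
                          bad_unit_rate = 0)
  b <- generate_fixture_bundle(1, 10, opts)
  res <- build_flores(b$raw_table, b$inflorescence_table, b$taxa_mapping)
  tab <- res$tables$raw
  i <- match(tab$taxon, b$truth$species)
  expect_false(anyNA(i))
  for (s in flores_core_traits()) {
    expect_equal(tab[[s]], b$truth[[s]][i], tolerance = 1e-9)
  }
  expect_true(all(tab$completeness == "complete"))
})

test_that("imputed protein recovers genus and global means of retained truth", {
  opts <- fixture_options(missing_rate = c(protein = 0.5), synonym_rate = 0,
                          zero_conflict_rate = 0, bad_unit_rate = 0)
  b <- generate_fixture_bundle(13, 30, opts)
  res <- build_flores(b$raw_table, b$inflorescence_table, b$taxa_mapping)
  tab <- res$tables$raw
  tr <- b$truth
  observed_sp <- unique(b$raw_table$species[b$raw_table$trait == "protein"])
  obs <- tab$taxon %in% observed_sp
  genus <- tr$genus[match(tab$taxon, tr$species)]
  for (k in which(!obs)) {
    mates <- tab$protein[obs & genus == genus[k]]
    expected <- if (length(mates)) mean(mates) else mean(tab$protein[obs])
    expect_equal(tab$protein[k], expected, tolerance = 1e-9)
  }
})

test_that("the oracle reproduces hand-evaluated single cases", {
  # nectar volume + percent concentration: sugar mass and molarity follow
  bundle <- list(
    raw_table = raw_tbl(
      rec("Phacelia alba", "nectar_volume", 1, "µl/d", "single_flower"),
      rec("Phacelia alba", "sugar_conc", 40, "%")),
    inflorescence_table = infl_tbl(),
    taxa_mapping = tibble::tibble(species = character(), taxon = character()))
  gt <- oracle_standardize(bundle)
  expect_equal(gt$raw$nectar_volume, 0.001)
  expect_equal(gt$raw$sugar_conc, 0.40 * 1570 / 342.3)
  expect_equal(gt$raw$nectar_sugar_cont, 1570 * 0.001 * 0.40, tolerance = 1e-12)

  # pollen volume + genus-mate protein: density mixture then mass
  bundle2 <- list(
    raw_table = raw_tbl(
      rec("Vicia alba", "protein", 20, "%"),
      rec("Vicia alba", "pollen", 1, "mg", "single_flower"),
      rec("Vicia rubra", "pollen", 2, "µl", "single_flower")),
    inflorescence_table = infl_tbl(),
    taxa_mapping = tibble::tibble(species = character(), taxon = character()))
  gt2 <- oracle_standardize(bundle2)
  rho <- 1300 * 0.2 + (0.8 / 3) * (1440 + 900 + 1000)  # 1150.667 mg/ml
  expect_equal(gt2$raw$pollen[gt2$raw$taxon == "Vicia rubra"], 0.002 * rho,
               tolerance = 1e-12)
  expect_equal(gt2$raw$protein, c(20, 20))

  # no resource traits anywhere: everything filtered, all tables empty
  bundle3 <- list(
    raw_table = raw_tbl(
      rec("Lotus alba", "flowering_start", 120, "d"),
      rec("Lotus alba", "corolla", 4, "mm")),
    inflorescence_table = infl_tbl(),
    taxa_mapping = tibble::tibble(species = character(), taxon = character()))
  gt3 <- oracle_standardize(bundle3)
  expect_equal(nrow(gt3$raw), 0L)
  expect_equal(nrow(gt3$complete_trait), 0L)
})

test_that("contradictory generator options are rejected", {
  expect_error(fixture_options(missing_rate = 1), "every trait always missing")
  expect_error(fixture_options(synonym_rate = 1.5), "rates")
  expect_error(generate_fixture_bundle(1, 0), "n_species")
})

test_that("bundles write to disk and read back through the pipeline", {
  b <- generate_fixture_bundle(5, 6)
  dir <- withr::local_tempdir()
  write_fixture_bundle(b, dir)
  expect_true(file.exists(file.path(dir, "manifest.yml")))
  res <- build_flores(file.path(dir, "raw_database.csv"),
                      file.path(dir, "inflorescences.csv"),
                      file.path(dir, "taxa_to_aggregate.csv"))
  expect_equal(res$tables$raw$taxon, b$ground_truth$raw$taxon)
  expect_equal(res$tables$raw$nectar_volume, b$ground_truth$raw$nectar_volume,
               tolerance = 1e-9)
})
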