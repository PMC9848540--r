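test_that("parsing keeps units verbatim and quarantines invalid rows", {
  raw <- raw_tbl(
    rec("Trifolium alba", "nectar_volume", 5, "µl/d", "single_flower"),
    rec("Trifolium alba", "pollen", 2, "mg", "single_flower"),
    rec("Salvia rubra", "nectar_volume", 1, "furlongs", "single_flower"),
    rec("Salvia rubra", "corolla", 4, "mm", min = 6, max = 3),
    rec("Salvia rubra", "pollen", 1, "mg")  # no floral reference unit
  )
  parsed <- read_raw_database(raw)
  expect_equal(nrow(parsed$records), 2L)
  expect_identical(parsed$records$unit, c("µl/d", "mg"))
  expect_identical(
    sort(parsed$rejected$reason),
    sort(c("unknown unit", "value ordering violated", "missing floral reference unit"))
  )
  expect_equal(nrow(parsed$records) + nrow(parsed$rejected), nrow(raw))
})

test_that("schema errors are raised for broken inputs", {
  raw <- rec("A b", "pollen", 1, "mg", "single_flower")
  expect_error(read_raw_database(raw[, -1]), "mandatory column")
  expect_error(read_raw_database(raw[0, ]), "empty")
  expect_error(read_raw_database(tempfile(fileext = ".csv")), "not found")
})

test_that("fixture bundles parse with the manifest's record bookkeeping", {
  b <- generate_fixture_bundle(42, 30)
  parsed <- read_raw_database(b$raw_table)
  expect_equal(nrow(parsed$records) + nrow(parsed$rejected),
               b$manifest$n_raw_records)
  # the only injected invalid rows are the unregistered units
  expect_equal(nrow(parsed$rejected), length(b$manifest$bad_units))
  expect_true(all(parsed$rejected$reason == "unknown unit"))
})

test_that("source conventions resolve zeros as the sources intended", {
  raw <- raw_tbl(
    # corolla 0 with nectar present: an open flower, kept as a true zero
    rec("Taraxacum agg", "corolla", 0, "mm"),
    rec("Taraxacum agg", "nectar_volume", 0.5, "µl/d", "single_flower"),
    # pollen-only species: corolla depth unknown, record dropped
    rec("Papaver minor", "pollen", 3, "mg", "single_flower"),
    rec("Papaver minor", "corolla", 2, "mm"),
    # zero nectar contradicted by a positive record from another source
    rec("Echium lutea", "nectar_volume", 0, "ml/d", "single_flower"),
    rec("Echium lutea", "nectar_volume", 0.3, "µl/d", "single_flower",
        reference = "OtherSource")
  )
  out <- resolve_source_conventions(raw)
  removals <- attr(out, "removals")

  expect_true(any(out$species == "Taraxacum agg" & out$trait == "corolla" &
                    out$value_mean == 0))
  expect_false(any(out$species == "Papaver minor" & out$trait == "corolla"))
  kept_nectar <- out[out$species == "Echium lutea" & out$trait == "nectar_volume", ]
  expect_equal(kept_nectar$value_mean, 0.3)
  expect_setequal(removals$rule, c("corolla_na_pollen_only", "conflicting_zero_nectar"))
  expect_equal(nrow(out), nrow(raw) - nrow(removals))

  # idempotent: a second pass removes nothing
  again <- resolve_source_conventions(out)
  expect_equal(nrow(attr(again, "removals")), 0L)
  strip <- function(x) { attr(x, "removals") <- NULL; tibble::as_tibble(x) }
  expect_equal(strip(again), strip(out))
})

test_that("pollen-only detection counts any nectar trait as nectar evidence", {
  # sugar concentration alone is nectar evidence, so corolla stays
  raw <- raw_tbl(
    rec("Malva major", "pollen", 3, "mg", "single_flower"),
    rec("Malva major", "sugar_conc", 30, "%"),
    rec("Malva major", "corolla", 2, "mm")
  )
  out <- resolve_source_conventions(raw)
  expect_true(any(out$trait == "corolla"))
})

test_that("tables round-trip through CSV including missing values", {
  tab <- tibble::tibble(taxon = c("A a", "B b", "C c"),
                        x = c(1.25, NA, 3e-7), note = c("k", NA, "m"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_flores_table(tab, path)
  expect_equal(read_flores_table(path), tab)

  expect_error(write_flores_table(tab[0, ], path), "empty")
  write_flores_table(tab[0, ], path, allow_empty = TRUE)
  expect_equal(nrow(read_flores_table(path)), 0L)
})

test_that("auxiliary table readers validate their schemas", {
  expect_error(read_inflorescence_table(tibble::tibble(species = "A")),
               "lacks column")
  expect_error(read_inflorescence_table(infl_tbl("A b", 0.5)), ">= 1")
  # overrides take precedence (the pattern for species missing from the survey)
  base <- infl_tbl(c("A b", "C d"), c(10, 20))
  merged <- read_inflorescence_table(
    base, overrides = infl_tbl("A b", 50))
  expect_equal(merged$open_flowers_per_inflorescence[merged$species == "A b"], 50)

  expect_error(read_taxon_mapping(tibble::tibble(
    species = c("A b", "A b"), taxon = c("X", "Y"))), "contradictory")
  expect_warning(read_habitat_composition(tibble::tibble(
    taxon = c("A", "B"), cover_percent = c(70, 60))), "exceeds 100")
})
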