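# helpers to build raw-record tibbles tersely in tests

rec <- function(species, trait, mean = NA, unit, regarding = "not_applicable",
                min = NA, max = NA, reference = "TestSource") {
  tibble::tibble(
    species = species, species_name_reference = species, trait = trait,
    value_min = as.numeric(min), value_max = as.numeric(max),
    value_mean = as.numeric(mean), unit = unit,
    regarding_flowering_unit = regarding, reference = reference
  )
}

raw_tbl <- function(...) dplyr::bind_rows(...)

infl_tbl <- function(species = character(), f = numeric()) {
  tibble::tibble(species = species,
                 open_flowers_per_inflorescence = as.numeric(f),
                 source = "TestFlora")
}

# maximum relative deviation between matching slots of a pipeline table and
# an oracle table; requires identical taxa, NA patterns and completeness
max_rel_dev <- function(pipeline, oracle) {
  expect_identical(pipeline$taxon, oracle$taxon)
  expect_identical(pipeline$completeness, oracle$completeness)
  err <- 0
  for (s in flores_profile_traits()) {
    a <- pipeline[[s]]
    b <- oracle[[s]]
    expect_identical(is.na(a), is.na(b))
    ok <- !is.na(a)
    if (any(ok)) {
      err <- max(err, abs(a[ok] - b[ok]) / pmax(abs(b[ok]), .Machine$double.xmin))
    }
  }
  err
}
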