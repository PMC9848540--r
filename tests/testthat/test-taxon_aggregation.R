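std_rec <- function(species, trait, value) {
  tibble::tibble(species = species, trait = trait, value = value,
                 canonical_unit = "", flags = "", reference = "TestSource")
}

test_that("species aggregation takes means except the density maximum", {
  std <- dplyr::bind_rows(
    std_rec("A a", "nectar_volume", c(0.002, 0.004)),
    std_rec("A a", "flowers_m2", c(120, 250)),
    std_rec("A a", "corolla", 6),
    std_rec("B b", "pollen", 1.5)
  )
  prof <- aggregate_by_species(std)
  a <- prof[prof$species == "A a", ]
  expect_equal(a$nectar_volume, 0.003)
  expect_equal(a$flowers_m2, 250)
  expect_equal(a$corolla, 6)
  expect_equal(a$n_nectar_volume, 2L)
  expect_true(is.na(a$pollen))
  expect_equal(prof$pollen[prof$species == "B b"], 1.5)

  # identity on an already one-entry-per-species table
  single <- dplyr::bind_rows(std_rec("C c", "pollen", 2.5),
                             std_rec("C c", "flowers_m2", 10))
  prof2 <- aggregate_by_species(single)
  expect_equal(prof2$pollen, 2.5)
  expect_equal(prof2$flowers_m2, 10)
})

test_that("entry values follow the precedence mean > midpoint > single bound", {
  raw <- raw_tbl(
    rec("A a", "corolla", mean = 5, min = 2, max = 10, unit = "mm"),
    rec("B b", "corolla", min = 2, max = 10, unit = "mm"),
    rec("C c", "corolla", min = 3, unit = "mm"),
    rec("D d", "corolla", max = 8, unit = "mm")
  )
  std <- standardize_reference_units(raw, infl_tbl())
  expect_equal(std$records$value, c(5, 6, 3, 8))
})

test_that("taxon mapping unifies synonyms and deletes resource-poor profiles", {
  std <- dplyr::bind_rows(
    std_rec("Achillea alba", "nectar_volume", 0.002),
    std_rec("Achillea millefolia", "nectar_volume", 0.004),
    std_rec("Lotus major", "flowering_start", 120),  # phenology only
    std_rec("Silene x", "pollen", 2)
  )
  prof <- aggregate_by_species(std)
  mapping <- tibble::tibble(
    species = c("Achillea alba", "Achillea millefolia"),
    taxon = c("Achillea millefolium", "Achillea millefolium"))
  mapped <- map_and_filter_taxa(prof, mapping, min_resource_traits = 1)

  expect_equal(sum(mapped$taxon == "Achillea millefolium"), 2L)
  expect_false("Lotus major" %in% mapped$taxon)        # deleted, no resources
  expect_equal(attr(mapped, "deleted")$species, "Lotus major")
  expect_true("Silene x" %in% mapped$taxon)            # unmapped -> itself
})

test_that("protein imputation uses genus mates, then the global mean", {
  prof <- tibble::tibble(
    taxon = c("Vicia cracca", "Vicia sepium", "Vicia faba",
              "Papaver rhoeas", "Centaurea sp."),
    species = taxon,
    protein = c(20, 30, NA, 18, NA)
  )
  for (tr in setdiff(flores_profile_traits(), "protein")) prof[[tr]] <- NA_real_
  prof$pollen <- 1  # resource presence irrelevant here

  out <- impute_protein(prof)
  expect_equal(out$protein[out$taxon == "Vicia faba"], 25)
  expect_match(out$imputation_flags[out$taxon == "Vicia faba"], "protein_genus_mean")
  expect_equal(out$protein[out$taxon == "Vicia cracca"], 20)   # observed untouched
  expect_identical(out$imputation_flags[out$taxon == "Vicia cracca"], "")
  # no Centaurea protein anywhere: global mean of taxon-level values
  expect_equal(out$protein[out$taxon == "Centaurea sp."], mean(c(20, 30, 18)))
  expect_match(out$imputation_flags[out$taxon == "Centaurea sp."], "protein_global_mean")

  prof$protein <- NA_real_
  expect_error(impute_protein(prof), "imputation impossible")
})

test_that("designators are stripped before genus grouping", {
  prof <- tibble::tibble(
    taxon = c("Knautia arvensis", "Knautia sp.", "Knautia spp"),
    species = taxon, protein = c(40, NA, NA))
  for (tr in setdiff(flores_profile_traits(), "protein")) prof[[tr]] <- NA_real_
  out <- impute_protein(prof)
  expect_equal(out$protein, c(40, 40, 40))
})

test_that("finalization applies the default concentration and derives sugar", {
  prof <- tibble::tibble(taxon = "Phacelia x", species = "Phacelia x")
  for (tr in flores_profile_traits()) prof[[tr]] <- NA_real_
  for (tr in flores_profile_traits()) prof[[paste0("n_", tr)]] <- 0L
  prof$nectar_volume <- 0.001
  tabs <- finalize_taxa(prof)
  row <- tabs$raw
  expect_equal(row$sugar_conc, percent_to_molar(40))
  expect_equal(row$nectar_sugar_cont, 0.628, tolerance = 1e-12)
  expect_match(row$imputation_flags, "sugar_conc_default_40")
})

test_that("the partition nests and routes taxa by completeness", {
  b <- generate_fixture_bundle(21, 40)
  res <- build_flores(b$raw_table, b$inflorescence_table, b$taxa_mapping)
  t <- res$tables
  expect_true(all(t$complete_trait$taxon %in% t$no_corolla$taxon))
  expect_true(all(t$no_corolla$taxon %in% t$raw$taxon))
  nc_only <- setdiff(t$no_corolla$taxon, t$complete_trait$taxon)
  if (length(nc_only)) {
    sub <- t$raw[t$raw$taxon %in% nc_only, ]
    expect_true(all(is.na(sub$corolla)))
    expect_true(all(sub$completeness == "complete_except_corolla"))
  }
  cmp <- t$raw[t$raw$completeness == "complete", ]
  expect_false(anyNA(cmp[flores_core_traits()]))
})

test_that("database summary reports coverage, sizes and correlations", {
  raw <- raw_tbl(
    rec("S1 a", "pollen", 1, "mg", "single_flower"),
    rec("S1 a", "corolla", 5, "mm"),
    rec("S2 b", "pollen", 2, "mg", "single_flower"),
    rec("S3 c", "corolla", 3, "mm"),
    rec("S4 d", "corolla", 4, "mm"),
    rec("S5 e", "corolla", 1, "mm")
  )
  s <- summarize_database(raw)
  cov <- s$coverage
  expect_equal(cov$n_species[cov$trait == "pollen"], 2L)
  expect_equal(cov$percent[cov$trait == "pollen"], 40)  # 2 of 5 species
  expect_equal(s$traits_per_species$n_species[s$traits_per_species$n_traits == 2], 1L)

  # proportional traits over complete taxa give a perfect correlation
  tabs <- list(
    raw = tibble::tibble(),
    complete_trait = tibble::tibble(
      taxon = c("A a", "B b", "C c"),
      flowering_start = c(100, 120, 140), flowering_end = c(150, 170, 190),
      flowers_m2 = c(10, 20, 30), nectar_volume = c(0.001, 0.002, 0.003),
      sugar_conc = 1.8, nectar_sugar_cont = c(0.5, 1.0, 1.5),
      pollen = c(1, 2, 4), pollen_volume = NA_real_,
      protein = c(20, 30, 40), corolla = c(2, 4, 8)),
    no_corolla = tibble::tibble())
  tabs$raw <- tabs$complete_trait
  s2 <- summarize_database(raw, tabs)
  expect_equal(s2$correlation["nectar_volume", "nectar_sugar_cont"], 1)
  expect_true(is.na(s2$correlation["sugar_conc", "pollen"]))  # constant trait
  expect_equal(s2$table_sizes$n_taxa[s2$table_sizes$table == "complete_trait"], 3L)

  # a single-taxon table has no defined correlations at all
  one <- lapply(tabs, function(x) x[1, ])
  s3 <- summarize_database(raw, one)
  expect_null(s3$correlation)
})
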