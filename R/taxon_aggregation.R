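# Aggregation of standardized records per species, taxon mapping with the
# few-entries filter, protein imputation, the default sugar concentration,
# and the final partition into the three output tables.

#' Aggregate standardized records to one trait profile per species
#'
#' Per species and trait, multiple literature entries are combined by the
#' arithmetic mean — except floral-unit density (`flowers_m2`), where the
#' maximum is used as an approximation of the density at 100% cover of the
#' species. Entry counts are kept in `n_<trait>` columns. Records of the
#' `flowering` life-span trait carry no profile slot and are ignored.
#'
#' @param records Standardized records tibble from
#'   [standardize_reference_units()] (the `records` element).
#' @return Tibble with one row per species, one column per profile trait
#'   (see [flores_profile_traits()]) and entry-count columns.
#' @export
aggregate_by_species <- function(records) {
  records <- tibble::as_tibble(records)
  records <- records[records$trait %in% flores_profile_traits(), ]
  agg <- records |>
    dplyr::group_by(.data$species, .data$trait) |>
    dplyr::summarise(
      value = if (.data$trait[1] == "flowers_m2") max(.data$value) else mean(.data$value),
      n = dplyr::n(),
      .groups = "drop"
    )
  wide_v <- tidyr::pivot_wider(agg[, c("species", "trait", "value")],
                               names_from = "trait", values_from = "value")
  wide_n <- tidyr::pivot_wider(agg[, c("species", "trait", "n")],
                               names_from = "trait", values_from = "n",
                               names_prefix = "n_", values_fill = 0L)
  out <- dplyr::left_join(wide_v, wide_n, by = "species")
  for (tr in flores_profile_traits()) {
    if (!tr %in% names(out)) out[[tr]] <- NA_real_
    if (!paste0("n_", tr) %in% names(out)) out[[paste0("n_", tr)]] <- 0L
  }
  out <- out[c("species", flores_profile_traits(),
               paste0("n_", flores_profile_traits()))]
  dplyr::arrange(out, .data$species)
}

#' Derive missing traits of a profile from its observed traits
#'
#' The within-profile derivation pass: fills missing nectar fields via the
#' conversion identities (sugar mass from volume and concentration, volume
#' from sugar mass and concentration) using [complete_nectar_traits()], and
#' converts pollen volume to pollen mass via the protein-based mixture
#' density when a protein value is available. Observed values are never
#' overwritten; profiles with sugar mass but no concentration wait for the
#' default-concentration stage.
#'
#' @param profiles Profile tibble with the [flores_profile_traits()] columns.
#' @param constants Constants list from [flores_constants()].
#' @return Profile tibble with derivable slots filled.
#' @export
complete_profile_traits <- function(profiles, constants = flores_constants()) {
  st <- complete_nectar_traits(
    tibble::tibble(volume = profiles$nectar_volume,
                   sugar_mass = profiles$nectar_sugar_cont,
                   conc_percent = NA_real_,
                   conc_molar = profiles$sugar_conc),
    constants
  )
  profiles$nectar_volume <- st$volume
  profiles$nectar_sugar_cont <- st$sugar_mass
  profiles$sugar_conc <- st$conc_molar
  fill <- is.na(profiles$pollen) & !is.na(profiles$pollen_volume) &
    !is.na(profiles$protein)
  profiles$pollen[fill] <- profiles$pollen_volume[fill] *
    pollen_density(profiles$protein[fill] / 100, constants)
  profiles
}

#' Map species to target taxa and drop profiles with few resource entries
#'
#' Renames each species to its aggregation taxon (synonym unification or
#' grouping on genus or a higher level); species absent from the mapping
#' map to themselves. Profiles with fewer than `min_resource_traits`
#' non-missing traits among nectar volume, nectar sugar content, sugar
#' concentration and pollen (mass or volume) are deleted and logged in the
#' `"deleted"` attribute — phenology-only entries cannot contribute
#' resources.
#'
#' @param profiles Species profile tibble from [aggregate_by_species()].
#' @param mapping Taxon mapping from [read_taxon_mapping()], or `NULL` for
#'   identity mapping.
#' @param min_resource_traits Minimum count of non-missing resource traits
#'   for a profile to be retained (default 1).
#' @return Profile tibble with a `taxon` key column; deleted rows in
#'   attribute `"deleted"`.
#' @export
map_and_filter_taxa <- function(profiles, mapping = NULL, min_resource_traits = 1) {
  profiles <- tibble::as_tibble(profiles)
  if (is.null(mapping)) {
    mapping <- tibble::tibble(species = character(), taxon = character())
  } else {
    mapping <- read_taxon_mapping(mapping)
  }
  taxon <- mapping$taxon[match(profiles$species, mapping$species)]
  profiles$taxon <- ifelse(is.na(taxon), profiles$species, taxon)
  profiles <- profiles[c("taxon", setdiff(names(profiles), "taxon"))]

  has_pollen <- !is.na(profiles$pollen) | !is.na(profiles$pollen_volume)
  n_res <- (!is.na(profiles$nectar_volume)) +
    (!is.na(profiles$nectar_sugar_cont)) +
    (!is.na(profiles$sugar_conc)) + has_pollen
  keep <- n_res >= min_resource_traits
  out <- profiles[keep, ]
  attr(out, "deleted") <- profiles[!keep, c("taxon", "species")]
  out
}

#' Impute missing pollen protein content
#'
#' Protein content is fairly conserved within a genus, so a taxon with no
#' observed protein is assigned the mean protein of same-genus taxa with
#' observations; if the genus has none, the global mean of all observed
#' protein values is used. Imputations are flagged (`protein_genus_mean`,
#' `protein_global_mean`) in the `imputation_flags` column. The genus is the
#' first whitespace-separated token of the taxon name after stripping the
#' designators sp., spec., spp. and agg. The imputed value serves both as
#' the reported protein trait and as the protein fraction for the pollen
#' mixture density.
#'
#' @param profiles Taxon-keyed profile tibble from [map_and_filter_taxa()].
#' @return The same tibble with `protein` filled and `imputation_flags`
#'   updated.
#' @export
impute_protein <- function(profiles) {
  profiles <- tibble::as_tibble(profiles)
  if (!"imputation_flags" %in% names(profiles)) profiles$imputation_flags <- ""
  key <- if ("taxon" %in% names(profiles)) profiles$taxon else profiles$species

  # taxon-level observed protein: mean over rows with observations
  obs <- tapply(profiles$protein, key, function(x) {
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  })
  taxa <- names(obs)
  genus <- genus_of(taxa)
  observed <- !is.na(obs)
  if (!any(observed)) {
    stop("no protein value anywhere in the database; imputation impossible",
         call. = FALSE)
  }
  genus_mean <- tapply(obs[observed], genus[observed], mean)
  global_mean <- mean(obs[observed])

  imputed <- as.numeric(obs)
  flag <- rep("", length(taxa))
  need <- !observed
  gm <- genus_mean[match(genus, names(genus_mean))]
  use_genus <- need & !is.na(gm)
  imputed[use_genus] <- gm[use_genus]
  flag[use_genus] <- "protein_genus_mean"
  use_global <- need & is.na(gm)
  imputed[use_global] <- global_mean
  flag[use_global] <- "protein_global_mean"

  i <- match(key, taxa)
  fill <- is.na(profiles$protein) & flag[i] != ""
  profiles$protein[fill] <- imputed[i][fill]
  profiles$imputation_flags[fill] <-
    add_flag(profiles$imputation_flags[fill], flag[i][fill])
  profiles
}

#' Final aggregation, default concentration, and table partition
#'
#' The last stage of the workflow: (1) per-taxon means of the grouped
#' profiles (maximum for `flowers_m2`); (2) a second derivation pass via
#' [complete_profile_traits()], now with the more complete data; (3) taxa
#' still lacking sugar concentration receive the wildflower default
#' (40% by default, converted to mol/l) with flag `sugar_conc_default_40`,
#' followed by a final derivation pass; (4) partition into the three output
#' tables: `raw` (all taxa), `complete_trait` (all nine trait slots
#' present), `no_corolla` (complete or complete except corolla depth).
#'
#' @param profiles Taxon-keyed, protein-imputed profile tibble.
#' @param constants Constants list from [flores_constants()].
#' @return List with tibbles `raw`, `complete_trait`, `no_corolla`; the
#'   `raw` table carries `completeness` and `imputation_flags` columns.
#' @export
finalize_taxa <- function(profiles, constants = flores_constants()) {
  profiles <- tibble::as_tibble(profiles)
  if (!"taxon" %in% names(profiles)) profiles$taxon <- profiles$species
  if (!"imputation_flags" %in% names(profiles)) profiles$imputation_flags <- ""

  mean_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  max_na <- function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
  ent <- profiles |>
    dplyr::group_by(.data$taxon) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(setdiff(flores_profile_traits(), "flowers_m2")),
                    mean_na),
      flowers_m2 = max_na(.data$flowers_m2),
      dplyr::across(dplyr::all_of(paste0("n_", flores_profile_traits())),
                    ~ sum(.x)),
      imputation_flags = paste(unique(.data$imputation_flags[.data$imputation_flags != ""]),
                               collapse = ";"),
      .groups = "drop"
    )
  ent <- ent[c("taxon", flores_profile_traits(),
               paste0("n_", flores_profile_traits()), "imputation_flags")]

  ent <- complete_profile_traits(ent, constants)
  needs_default <- is.na(ent$sugar_conc)
  ent$sugar_conc[needs_default] <-
    percent_to_molar(constants$default_sugar_percent, constants)
  ent$imputation_flags[needs_default] <-
    add_flag(ent$imputation_flags[needs_default], "sugar_conc_default_40")
  ent <- complete_profile_traits(ent, constants)

  core <- as.matrix(ent[flores_core_traits()])
  n_missing <- rowSums(is.na(core))
  corolla_missing <- is.na(ent$corolla)
  ent$completeness <- ifelse(n_missing == 0, "complete",
                             ifelse(n_missing == 1 & corolla_missing,
                                    "complete_except_corolla", "incomplete"))
  ent <- dplyr::arrange(ent, .data$taxon)
  list(
    raw = ent,
    complete_trait = ent[ent$completeness == "complete", ],
    no_corolla = ent[ent$completeness %in% c("complete", "complete_except_corolla"), ]
  )
}

# genus = first token of the taxon name, ignoring sp./spec./spp./agg.
genus_of <- function(taxon) {
  x <- gsub("\\b(sp|spec|spp|agg)\\.?$", "", trimws(taxon))
  vapply(strsplit(trimws(x), "\\s+"), `[[`, "", 1)
}

#' Run the full multistep workflow
#'
#' Convenience wrapper chaining every stage: source conventions, floral-unit
#' and physical-unit standardization, species aggregation, the first
#' derivation pass, taxon mapping with the few-entries filter, protein
#' imputation, and the final aggregation with default concentration and
#' partition.
#'
#' @param records Raw records tibble (the `records` element of
#'   [read_raw_database()]), or a path to the raw CSV.
#' @param inflorescence_table Inflorescence lookup (tibble or path).
#' @param taxa_mapping Taxon mapping (tibble, path, or `NULL`).
#' @param min_resource_traits Deletion threshold, see [map_and_filter_taxa()].
#' @param constants Constants list from [flores_constants()].
#' @return List with `tables` (the [finalize_taxa()] partition) and `logs`
#'   (rejected rows, convention removals, unresolved records, deleted
#'   profiles).
#' @export
build_flores <- function(records, inflorescence_table, taxa_mapping = NULL,
                         min_resource_traits = 1,
                         constants = flores_constants()) {
  parsed <- read_raw_database(records)
  records <- parsed$records
  rejected <- parsed$rejected
  inflorescence_table <- read_inflorescence_table(inflorescence_table)
  resolved <- resolve_source_conventions(records)
  std <- standardize_reference_units(resolved, inflorescence_table,
                                     constants = constants)
  profiles <- aggregate_by_species(std$records)
  profiles <- complete_profile_traits(profiles, constants)
  mapped <- map_and_filter_taxa(profiles, taxa_mapping, min_resource_traits)
  # a database with no protein observation at all cannot support imputation;
  # protein then stays missing and the affected taxa remain incomplete
  if (nrow(mapped) > 0 && any(!is.na(mapped$protein))) {
    mapped <- impute_protein(mapped)
  }
  tables <- finalize_taxa(mapped, constants)
  list(
    tables = tables,
    logs = list(
      rejected = rejected,
      removals = attr(resolved, "removals"),
      unresolved = std$unresolved,
      deleted = attr(mapped, "deleted")
    )
  )
}
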