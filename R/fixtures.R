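# Deterministic generation of messy raw-database bundles with known latent
# truth, for testing every pipeline stage without external data.

#' Options for the fixture generator
#'
#' Rates are probabilities in \[0, 1\]. `missing_rate` is a single rate or a
#' named vector per trait; a configuration where every trait is always
#' missing is rejected. Latent trait values are drawn log-uniformly over
#' ranges spanning three orders of magnitude for floral-unit density
#' (1–1000 FU/m²), nectar volume (1e-4–1e-1 ml/FU/d) and pollen
#' (0.01–10 mg/FU), with protein uniform on 10–60%, sugar concentration
#' 20–60%, corolla depth 0–15 mm and flowering windows of 20–120 days
#' starting between day 60 and 240 — magnitudes realistic for temperate
#' wildflowers.
#'
#' @param synonym_rate Probability a species is additionally recorded under
#'   a synonymous name (a full duplicate observation set).
#' @param missing_rate Per-trait probability that a species has no record of
#'   a trait.
#' @param inflorescence_fraction Fraction of species forming inflorescences.
#' @param unit_mix Randomize unit dialects (µl vs ml, %, mol/l, ...)?
#' @param duplicate_rate Probability a trait has two literature entries
#'   (emitted symmetric about the latent truth; below it for flower density,
#'   whose aggregation rule is the maximum).
#' @param minmax_rate Probability an entry reports min/max instead of mean.
#' @param pollen_volume_rate Probability a species' pollen is reported as
#'   grain volume rather than mass.
#' @param corolla_zero_rate Probability of a true open flower (corolla 0).
#' @param zero_conflict_rate Probability of injecting a contradictory
#'   zero-nectar record for a species with positive nectar.
#' @param bad_unit_rate Probability of injecting a record with an
#'   unregistered unit (exercises the rejection report).
#' @param lifespan_rate Probability of emitting a `flowering` life-span
#'   record (accepted but unused downstream).
#' @return Named list of options.
#' @export
fixture_options <- function(synonym_rate = 0.15, missing_rate = 0.2,
                            inflorescence_fraction = 0.5, unit_mix = TRUE,
                            duplicate_rate = 0.3, minmax_rate = 0.2,
                            pollen_volume_rate = 0.3, corolla_zero_rate = 0.1,
                            zero_conflict_rate = 0.05, bad_unit_rate = 0.02,
                            lifespan_rate = 0.2) {
  opts <- list(synonym_rate = synonym_rate, missing_rate = missing_rate,
               inflorescence_fraction = inflorescence_fraction,
               unit_mix = unit_mix, duplicate_rate = duplicate_rate,
               minmax_rate = minmax_rate, pollen_volume_rate = pollen_volume_rate,
               corolla_zero_rate = corolla_zero_rate,
               zero_conflict_rate = zero_conflict_rate,
               bad_unit_rate = bad_unit_rate, lifespan_rate = lifespan_rate)
  rates <- unlist(opts[setdiff(names(opts), "unit_mix")])
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]", call. = FALSE)
  if (all(fixture_missing_rate(opts) >= 1)) {
    stop("contradictory options: every trait always missing", call. = FALSE)
  }
  opts
}

fixture_obs_traits <- function() {
  c("flowering_start", "flowering_end", "flowers_m2", "nectar_volume",
    "sugar_conc", "nectar_sugar_cont", "pollen", "protein", "corolla")
}

fixture_missing_rate <- function(options) {
  mr <- options$missing_rate
  traits <- fixture_obs_traits()
  if (length(mr) == 1L && is.null(names(mr))) {
    return(setNames(rep(mr, length(traits)), traits))
  }
  out <- setNames(rep(0, length(traits)), traits)
  out[names(mr)] <- mr
  out
}

#' Generate a seeded raw-database fixture bundle
#'
#' Draws latent true trait values per species, then emits messy literature
#' observations: randomized unit dialects, single-flower vs inflorescence
#' reference units, min/max-only entries, duplicate sources, synonym
#' duplicates, missing traits, contradictory zero-nectar records and the
#' odd unregistered unit. Multiple entries are placed symmetrically about
#' the latent truth (below it for flower density) so that with
#' `missing_rate = 0` the pipeline recovers the truth exactly. The expected
#' output tables (`ground_truth`) are computed by [oracle_standardize()],
#' an independent straight-line evaluation that shares no code with the
#' pipeline. Regenerating with the same seed and options reproduces the
#' bundle bit for bit.
#'
#' @param seed Integer seed; every stochastic draw flows from it.
#' @param n_species Number of canonical species, >= 1.
#' @param options Options list from [fixture_options()].
#' @return List with `raw_table`, `inflorescence_table`, `taxa_mapping`,
#'   `truth` (latent per-species values), `ground_truth` (oracle tables)
#'   and `manifest` (seed, options, bookkeeping, corruption log).
#' @export
generate_fixture_bundle <- function(seed, n_species,
                                    options = fixture_options()) {
  stopifnot(n_species >= 1)
  options <- do.call(fixture_options, options)
  mr <- fixture_missing_rate(options)
  mu <- "\u00b5"

  withr::with_seed(seed, {
    genera_pool <- c("Achillea", "Centaurea", "Trifolium", "Salvia", "Phacelia",
                     "Borago", "Sinapis", "Helianthus", "Vicia", "Papaver",
                     "Malva", "Origanum", "Knautia", "Lotus", "Daucus",
                     "Cirsium", "Echium", "Campanula", "Geranium", "Silene")
    epithets <- c("alba", "rubra", "lutea", "minor", "major", "vulgaris",
                  "pratensis", "arvensis", "officinalis", "sylvestris")
    n_gen <- min(length(genera_pool), max(1L, ceiling(n_species / 3)))
    genus <- sample(genera_pool[seq_len(n_gen)], n_species, replace = TRUE)
    species <- paste(genus, paste0(sample(epithets, n_species, replace = TRUE),
                                   seq_len(n_species)))

    forms_infl <- runif(n_species) < options$inflorescence_fraction
    f_i <- ifelse(forms_infl, sample(2:60, n_species, replace = TRUE), 1L)
    loguni <- function(n, lo, hi) exp(runif(n, log(lo), log(hi)))
    start <- floor(runif(n_species, 60, 241))
    len <- floor(runif(n_species, 20, 121))
    conc_perc <- runif(n_species, 20, 60)
    protein <- runif(n_species, 10, 60)
    corolla <- ifelse(runif(n_species) < options$corolla_zero_rate, 0,
                      runif(n_species, 0.5, 15))
    truth <- tibble::tibble(
      species = species, genus = genus,
      forms_inflorescence = forms_infl, f_i = as.numeric(f_i),
      flowering_start = start, flowering_end = start + len,
      flowers_m2 = loguni(n_species, 1, 1000),
      nectar_volume = loguni(n_species, 1e-4, 1e-1),
      conc_percent = conc_perc,
      sugar_conc = (conc_perc / 100) * 1570 / 342.3,
      protein = protein,
      pollen = loguni(n_species, 0.01, 10),
      corolla = corolla,
      has_synonym = runif(n_species) < options$synonym_rate
    )
    truth$nectar_sugar_cont <- 1570 * truth$nectar_volume * truth$conc_percent / 100
    rho_p <- 1300 * (protein / 100) +
      (1 - protein / 100) / 3 * (1440 + 900 + 1000)
    truth$pollen_volume <- truth$pollen / rho_p
    truth$synonym <- ifelse(truth$has_synonym, paste(truth$species, "syn"), NA)

    rows <- list()
    emit <- function(name, trait, vmin, vmax, vmean, unit, regarding, ref) {
      rows[[length(rows) + 1L]] <<- list(
        species = name, species_name_reference = name, trait = trait,
        value_min = vmin, value_max = vmax, value_mean = vmean, unit = unit,
        regarding_flowering_unit = regarding, reference = ref)
    }
    # emit one entry: value in the reporting scale, maybe min/max-only
    emit_entry <- function(name, trait, value, unit, regarding) {
      ref <- sprintf("Source%02d", sample.int(20, 1))
      if (runif(1) < options$minmax_rate) {
        emit(name, trait, 0.8 * value, 1.2 * value, NA_real_, unit, regarding, ref)
      } else if (runif(1) < 0.3) {
        emit(name, trait, 0.9 * value, 1.1 * value, value, unit, regarding, ref)
      } else {
        emit(name, trait, NA_real_, NA_real_, value, unit, regarding, ref)
      }
    }
    pick <- function(choices) if (options$unit_mix) sample(choices, 1) else choices[1]

    emit_species <- function(name, k) {
      # one full observation set for species index k under the given name
      fi <- truth$f_i[k]
      infl <- truth$forms_inflorescence[k]
      pollen_as_volume <- runif(1) < options$pollen_volume_rate
      for (trait in fixture_obs_traits()) {
        if (runif(1) < mr[[trait]]) next
        n_rec <- if (trait %in% c("flowering_start", "flowering_end")) 1L
                 else if (runif(1) < options$duplicate_rate) 2L else 1L
        v_fu <- switch(trait,
          flowering_start = truth$flowering_start[k],
          flowering_end = truth$flowering_end[k],
          flowers_m2 = truth$flowers_m2[k],
          nectar_volume = truth$nectar_volume[k],
          sugar_conc = truth$sugar_conc[k],
          nectar_sugar_cont = truth$nectar_sugar_cont[k],
          pollen = if (pollen_as_volume) truth$pollen_volume[k] else truth$pollen[k],
          protein = truth$protein[k],
          corolla = truth$corolla[k])
        values <- if (n_rec == 1L) v_fu else {
          delta <- runif(1, 0.05, 0.3)
          if (trait == "flowers_m2") c(v_fu, v_fu * (1 - delta))
          else c(v_fu * (1 - delta), v_fu * (1 + delta))
        }
        for (v in values) {
          if (trait %in% c("flowering_start", "flowering_end")) {
            emit(name, trait, NA_real_, NA_real_, v, "d", "not_applicable",
                 "FixturePhenology")
          } else if (trait == "sugar_conc") {
            unit <- pick(c("%", "mol l-1"))
            val <- if (unit == "%") 100 * v * 342.3 / 1570 else v
            emit_entry(name, trait, val, unit, "not_applicable")
          } else if (trait %in% c("protein", "corolla")) {
            unit <- if (trait == "protein") pick(c("%", "g/100g dry mass")) else "mm"
            emit_entry(name, trait, v, unit, "not_applicable")
          } else {
            # referenced traits: choose the floral reference unit per record
            regarding <- if (infl && runif(1) < 0.5) "inflorescence" else "single_flower"
            raw <- if (regarding == "inflorescence") v
                   else if (trait == "flowers_m2") v * fi else v / fi
            unit_val <- switch(trait,
              flowers_m2 = list("m-2", raw),
              nectar_volume = {
                u <- pick(c(paste0(mu, "l/d"), "ml/d"))
                list(u, if (u == "ml/d") raw else raw * 1e3)
              },
              nectar_sugar_cont = {
                u <- pick(c(paste0(mu, "g/d"), "mg/d"))
                list(u, if (u == "mg/d") raw else raw * 1e3)
              },
              pollen = if (pollen_as_volume) {
                u <- pick(c(paste0(mu, "l"), "ml"))
                list(u, if (u == "ml") raw else raw * 1e3)
              } else {
                u <- pick(c(paste0(mu, "g"), "mg", "g"))
                list(u, raw * switch(u, mg = 1, g = 1e-3, 1e3))
              })
            emit_entry(name, trait, unit_val[[2]], unit_val[[1]], regarding)
          }
        }
      }
      if (runif(1) < options$lifespan_rate) {
        emit(name, "flowering",
             NA_real_, NA_real_,
             truth$flowering_end[k] - truth$flowering_start[k],
             "d", "not_applicable", "FixturePhenology")
      }
    }

    for (k in seq_len(n_species)) {
      emit_species(truth$species[k], k)
      if (truth$has_synonym[k]) emit_species(truth$synonym[k], k)
    }
    raw <- dplyr::bind_rows(rows)

    # corruption: contradictory zero-nectar and unregistered units
    zero_conflicts <- character()
    bad_units <- character()
    if (nrow(raw)) {
      nectar_names <- unique(raw$species[raw$trait == "nectar_volume"])
      for (name in nectar_names) {
        if (runif(1) < options$zero_conflict_rate) {
          zero_conflicts <- c(zero_conflicts, name)
          raw <- dplyr::bind_rows(raw, tibble::tibble(
            species = name, species_name_reference = name,
            trait = "nectar_volume", value_min = NA_real_, value_max = NA_real_,
            value_mean = 0, unit = "ml/d",
            regarding_flowering_unit = "single_flower",
            reference = "FixtureConflict"))
        }
      }
      for (name in unique(raw$species)) {
        if (runif(1) < options$bad_unit_rate) {
          bad_units <- c(bad_units, name)
          raw <- dplyr::bind_rows(raw, tibble::tibble(
            species = name, species_name_reference = name,
            trait = "nectar_volume", value_min = NA_real_, value_max = NA_real_,
            value_mean = 1, unit = "furlongs",
            regarding_flowering_unit = "single_flower",
            reference = "FixtureBadUnit"))
        }
      }
    }

    infl_names <- c(truth$species[truth$forms_inflorescence],
                    truth$synonym[truth$forms_inflorescence & truth$has_synonym])
    infl_f <- c(truth$f_i[truth$forms_inflorescence],
                truth$f_i[truth$forms_inflorescence & truth$has_synonym])
    inflorescence_table <- tibble::tibble(
      species = infl_names,
      open_flowers_per_inflorescence = infl_f,
      source = "FixtureFlora")

    syn <- truth$has_synonym
    taxa_mapping <- tibble::tibble(
      species = c(truth$species[syn], truth$synonym[syn]),
      taxon = c(truth$species[syn], truth$species[syn]))
    # identity rows for some non-synonym species, as real mapping files have
    extra <- !syn & runif(n_species) < 0.2
    taxa_mapping <- dplyr::bind_rows(
      taxa_mapping,
      tibble::tibble(species = truth$species[extra], taxon = truth$species[extra]))

    bundle <- list(
      raw_table = raw,
      inflorescence_table = inflorescence_table,
      taxa_mapping = taxa_mapping,
      truth = truth,
      manifest = list(
        seed = seed, n_species = n_species, options = options,
        n_raw_records = nrow(raw),
        n_synonyms = sum(truth$has_synonym),
        synonyms = truth$synonym[truth$has_synonym],
        zero_conflicts = zero_conflicts,
        bad_units = bad_units)
    )
    bundle$ground_truth <- oracle_standardize(bundle)
    bundle
  })
}

#' Write a fixture bundle to disk
#'
#' Emits the three input CSVs (`raw_database.csv`,
#' `inflorescences.csv`, `taxa_to_aggregate.csv`), the latent truth and the
#' oracle ground-truth tables as CSV, and the manifest as YAML.
#'
#' @param bundle Bundle from [generate_fixture_bundle()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_flores_table(bundle$raw_table, file.path(dir, "raw_database.csv"))
  write_flores_table(bundle$inflorescence_table,
                     file.path(dir, "inflorescences.csv"), allow_empty = TRUE)
  write_flores_table(bundle$taxa_mapping,
                     file.path(dir, "taxa_to_aggregate.csv"), allow_empty = TRUE)
  write_flores_table(bundle$truth, file.path(dir, "latent_truth.csv"))
  for (nm in names(bundle$ground_truth)) {
    write_flores_table(bundle$ground_truth[[nm]],
                       file.path(dir, paste0("ground_truth_", nm, ".csv")),
                       allow_empty = TRUE)
  }
  manifest <- bundle$manifest
  manifest$options <- lapply(manifest$options, identity)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yml"))
  invisible(dir)
}
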