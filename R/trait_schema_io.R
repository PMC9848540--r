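# Reading, validating and writing the raw trait database and auxiliary
# tables, plus the source-level conventions for zeros and missing values.

#' Registry of unit dialects per trait
#'
#' One row per (trait, accepted unit string), with the multiplicative factor
#' to the canonical unit, the canonical unit label, whether the unit can be
#' expressed per floral unit at all (per-area dialects such as `l/(m2 d)` or
#' `g/m2` cannot, and are quarantined), and the trait slot the converted
#' value feeds (`pollen` reported in µl/ml is a volume and feeds the
#' `pollen_volume` slot until a pollen density is available).
#'
#' Canonical units: day-of-year (`d`), floral units per m² (`FU m-2`),
#' `ml FU-1 d-1` (nectar volume), `mol l-1` (sugar concentration),
#' `mg FU-1 d-1` (nectar sugar), `mg FU-1` (pollen mass), `ml FU-1`
#' (pollen volume), `%` (protein), `mm` (corolla depth).
#'
#' @return Tibble with columns `trait`, `unit`, `factor`, `canonical_unit`,
#'   `convertible`, `maps_to`.
#' @export
unit_registry <- function() {
  mu <- "\u00b5"
  reg <- function(trait, unit, factor, canonical_unit, convertible = TRUE,
                  maps_to = trait) {
    tibble::tibble(trait = trait, unit = unit, factor = factor,
                   canonical_unit = canonical_unit, convertible = convertible,
                   maps_to = maps_to)
  }
  dplyr::bind_rows(
    reg("flowering", "d", 1, "d"),
    reg("flowering_start", "d", 1, "d"),
    reg("flowering_end", "d", 1, "d"),
    reg("flowers_m2", c("m-2", "m^-2", "1/m2"), 1, "FU m-2"),
    reg("nectar_volume", c(paste0(mu, "l/d"), "ul/d"), 1e-3, "ml FU-1 d-1"),
    reg("nectar_volume", "ml/d", 1, "ml FU-1 d-1"),
    reg("nectar_volume", "l/(m2 d)", NA_real_, "ml FU-1 d-1", convertible = FALSE),
    reg("sugar_conc", c("mol l-1", "mol/l"), 1, "mol l-1"),
    reg("sugar_conc", "%", 1, "mol l-1"),  # converted via percent_to_molar
    reg("nectar_sugar_cont", c(paste0(mu, "g/d"), "ug/d"), 1e-3, "mg FU-1 d-1"),
    reg("nectar_sugar_cont", "mg/d", 1, "mg FU-1 d-1"),
    reg("pollen", c(paste0(mu, "g"), "ug"), 1e-3, "mg FU-1"),
    reg("pollen", "mg", 1, "mg FU-1"),
    reg("pollen", "g", 1e3, "mg FU-1"),
    reg("pollen", c(paste0(mu, "l"), "ul"), 1e-3, "ml FU-1", maps_to = "pollen_volume"),
    reg("pollen", "ml", 1, "ml FU-1", maps_to = "pollen_volume"),
    reg("pollen", "g/m2", NA_real_, "mg FU-1", convertible = FALSE),
    reg("protein", c("%", "g/100g dry mass"), 1, "%"),
    reg("corolla", "mm", 1, "mm")
  )
}

raw_columns <- function() {
  c("species", "species_name_reference", "trait", "value_min", "value_max",
    "value_mean", "unit", "regarding_flowering_unit", "reference")
}

#' Read and validate a raw trait database
#'
#' Reads a CSV with one row per species × trait × literature source
#' (columns `species`, `species_name_reference`, `trait`, `value_min`,
#' `value_max`, `value_mean`, `unit`, `regarding_flowering_unit`,
#' `reference`) and validates every row against the trait vocabulary and
#' unit registry. Invalid rows — unknown trait, unit not registered for the
#' trait, negative values, min/mean/max out of order, or a floral reference
#' unit missing where one is required — are quarantined into a rejection
#' report rather than aborting the run.
#'
#' @param path Path to the raw CSV, or a data frame already in memory.
#' @param registry Unit registry, see [unit_registry()].
#' @return List with `records` (tibble of valid rows) and `rejected`
#'   (tibble of invalid rows with a `reason` column).
#' @export
read_raw_database <- function(path, registry = unit_registry()) {
  if (is.character(path)) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    df <- readr::read_csv(path, col_types = readr::cols(
      species = readr::col_character(),
      species_name_reference = readr::col_character(),
      trait = readr::col_character(),
      value_min = readr::col_double(),
      value_max = readr::col_double(),
      value_mean = readr::col_double(),
      unit = readr::col_character(),
      regarding_flowering_unit = readr::col_character(),
      reference = readr::col_character()
    ), na = c("", "NA"), progress = FALSE)
  } else {
    df <- tibble::as_tibble(path)
  }
  missing_cols <- setdiff(raw_columns(), names(df))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0L) stop("raw database is empty", call. = FALSE)
  df <- df[raw_columns()]

  reason <- rep(NA_character_, nrow(df))
  flag <- function(cond, why) {
    reason <<- ifelse(is.na(reason) & cond, why, reason)
  }
  flag(!(df$trait %in% flores_traits()), "unknown trait")
  key <- paste(df$trait, df$unit, sep = "\r")
  flag(is.na(reason) & !(key %in% paste(registry$trait, registry$unit, sep = "\r")),
       "unknown unit")
  num <- cbind(df$value_min, df$value_mean, df$value_max)
  flag(apply(num, 1, function(r) any(!is.na(r) & r < 0)), "negative value")
  flag(!is.na(df$value_min) & !is.na(df$value_mean) & df$value_min > df$value_mean,
       "value ordering violated")
  flag(!is.na(df$value_mean) & !is.na(df$value_max) & df$value_mean > df$value_max,
       "value ordering violated")
  flag(!is.na(df$value_min) & !is.na(df$value_max) & df$value_min > df$value_max,
       "value ordering violated")
  needs_ref <- df$trait %in% referenced_traits()
  flag(needs_ref & !(df$regarding_flowering_unit %in% c("single_flower", "inflorescence")),
       "missing floral reference unit")
  flag(!needs_ref & !is.na(df$regarding_flowering_unit) &
         !(df$regarding_flowering_unit %in% c("not_applicable", NA)),
       "reference unit not applicable for trait")
  flag(is.na(df$species) | df$species == "", "missing species name")

  rejected <- df[!is.na(reason), ]
  rejected$reason <- reason[!is.na(reason)]
  list(records = df[is.na(reason), ], rejected = rejected)
}

#' Apply source-level conventions for zeros and missing values
#'
#' Three conventions of the raw database are enforced:
#' \itemize{
#'   \item A corolla depth of 0 is a true zero — the species has open
#'     flowers — and is retained.
#'   \item Species whose records contain pollen but none of the nectar
#'     traits (`nectar_volume`, `nectar_sugar_cont`, `sugar_conc`) get
#'     their corolla-depth records removed: the depth is unknown for
#'     pollen-only sources, not zero.
#'   \item A `nectar_volume = 0` record is dropped when any other record of
#'     the same species reports positive nectar volume or nectar sugar
#'     content: the zero contradicts the positive measurements.
#' }
#' Removals are logged (attribute `"removals"`, a tibble with a `rule`
#' column); the operation is a pure, idempotent filter.
#'
#' @param records Tibble of validated raw records.
#' @return Filtered tibble with attribute `"removals"`.
#' @export
resolve_source_conventions <- function(records) {
  records <- tibble::as_tibble(records)
  attr(records, "removals") <- NULL
  ev <- entry_value(records$value_min, records$value_max, records$value_mean)

  nectar_species <- unique(records$species[
    records$trait %in% c("nectar_volume", "nectar_sugar_cont", "sugar_conc")])
  pollen_species <- unique(records$species[records$trait == "pollen"])
  pollen_only <- setdiff(pollen_species, nectar_species)
  drop_corolla <- records$trait == "corolla" & records$species %in% pollen_only

  pos_nectar_species <- unique(records$species[
    records$trait %in% c("nectar_volume", "nectar_sugar_cont") & !is.na(ev) & ev > 0])
  drop_zero <- records$trait == "nectar_volume" & !is.na(ev) & ev == 0 &
    records$species %in% pos_nectar_species

  rule <- ifelse(drop_corolla, "corolla_na_pollen_only",
                 ifelse(drop_zero, "conflicting_zero_nectar", NA_character_))
  removed <- records[!is.na(rule), c("species", "trait", "unit", "reference")]
  removed$rule <- rule[!is.na(rule)]
  out <- records[is.na(rule), ]
  attr(out, "removals") <- removed
  out
}

# entry value of a record: mean, else midpoint of min and max, else the
# single reported bound
entry_value <- function(vmin, vmax, vmean) {
  mid <- (vmin + vmax) / 2
  one <- ifelse(!is.na(vmin), vmin, vmax)
  ifelse(!is.na(vmean), vmean, ifelse(!is.na(mid), mid, one))
}

#' Write and re-read pipeline tables
#'
#' All pipeline tables are written as comma-delimited, point-decimal, UTF-8
#' CSV with a header row; missing values are empty cells. The pair
#' round-trips without loss.
#'
#' @param table Tibble to write.
#' @param path Output path.
#' @param allow_empty Permit writing a header-only file.
#' @return `write_flores_table()` returns `path` invisibly;
#'   `read_flores_table()` returns a tibble.
#' @export
write_flores_table <- function(table, path, allow_empty = FALSE) {
  if (nrow(table) == 0L && !allow_empty) {
    stop("refusing to write empty table (set allow_empty = TRUE)", call. = FALSE)
  }
  readr::write_csv(table, path, na = "")
  invisible(path)
}

#' @rdname write_flores_table
#' @export
read_flores_table <- function(path) {
  readr::read_csv(path, na = c("", "NA"), show_col_types = FALSE, progress = FALSE)
}

#' Read the open-flowers-per-inflorescence lookup table
#'
#' CSV with columns `species`, `open_flowers_per_inflorescence` (>= 1) and
#' `source`. Species absent from this table are treated as not forming
#' inflorescences (single flower = floral unit); `overrides` allows
#' injecting literature values for species the survey missed.
#'
#' @param path CSV path or data frame.
#' @param overrides Optional data frame with the same columns; its rows take
#'   precedence over the table's.
#' @return Tibble with one row per species.
#' @export
read_inflorescence_table <- function(path, overrides = NULL) {
  df <- if (is.character(path)) read_flores_table(path) else tibble::as_tibble(path)
  need <- c("species", "open_flowers_per_inflorescence")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("inflorescence table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"source" %in% names(df)) df$source <- NA_character_
  if (!is.null(overrides)) {
    overrides <- tibble::as_tibble(overrides)
    if (!"source" %in% names(overrides)) overrides$source <- "override"
    df <- dplyr::bind_rows(overrides[names(df)], df[!(df$species %in% overrides$species), ])
  }
  bad <- !is.na(df$open_flowers_per_inflorescence) & df$open_flowers_per_inflorescence < 1
  if (any(bad)) {
    stop("open_flowers_per_inflorescence must be >= 1", call. = FALSE)
  }
  df <- df[!duplicated(df$species), ]
  df
}

#' Read the taxon aggregation mapping
#'
#' CSV with columns `species` and `taxon`: which target taxon (species,
#' genus, or higher level) each raw species name is aggregated into.
#' Synonymous names map to a common taxon. Species absent from the table map
#' to themselves. Contradictory duplicate rows are a configuration error.
#'
#' @param path CSV path or data frame.
#' @return Tibble with columns `species`, `taxon`.
#' @export
read_taxon_mapping <- function(path) {
  df <- if (is.character(path)) read_flores_table(path) else tibble::as_tibble(path)
  missing_cols <- setdiff(c("species", "taxon"), names(df))
  if (length(missing_cols)) {
    stop("taxon mapping lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- unique(df[c("species", "taxon")])
  dup <- df$species[duplicated(df$species)]
  if (length(dup)) {
    stop("contradictory taxon mapping for: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Read a habitat composition table
#'
#' CSV with columns `taxon` and `cover_percent` (each in \[0, 100\]).
#' A total cover above 100% draws a warning, not an error (overlapping
#' canopies occur).
#'
#' @param path CSV path or data frame.
#' @return Tibble with columns `taxon`, `cover_percent`.
#' @export
read_habitat_composition <- function(path) {
  df <- if (is.character(path)) read_flores_table(path) else tibble::as_tibble(path)
  missing_cols <- setdiff(c("taxon", "cover_percent"), names(df))
  if (length(missing_cols)) {
    stop("habitat composition lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  check_range(df$cover_percent, 0, 100, "cover_percent")
  if (sum(df$cover_percent, na.rm = TRUE) > 100) {
    warning("total cover exceeds 100%", call. = FALSE)
  }
  df
}
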