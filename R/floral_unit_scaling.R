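# Scaling densities and per-flower resources between single-flower and
# inflorescence reference units onto the common floral-unit basis.

#' Floral-unit density from single-flower density
#'
#' A floral unit is the set of flowers an insect can visit without flying —
#' a single flower up to a whole inflorescence (raceme, panicle, corymb,
#' umbel, catkin). Densities counted as single flowers per m² (`f_A`) are
#' divided by the number of open flowers per inflorescence (`f_I`) to give
#' floral units per m²: `fu_A = f_A / f_I`.
#'
#' @param f_a Single flowers per m², nonnegative.
#' @param f_i Open flowers per inflorescence, >= 1.
#' @return Floral units per m².
#' @examples
#' floral_unit_density(100, 20)
#' @export
floral_unit_density <- function(f_a, f_i) {
  if (any(is.na(f_i))) stop("no inflorescence data", call. = FALSE)
  check_range(f_a, 0, Inf, "f_a")
  check_range(f_i, 1, Inf, "f_i")
  f_a / f_i
}

#' Per-floral-unit resource from per-single-flower resource
#'
#' Resources measured per single flower (`R_f`: pollen, nectar volume, or
#' nectar sugar) are multiplied by the number of open flowers per floral
#' unit: `R_fu = R_f * f_i`.
#'
#' @param r_f Resource amount per single flower, nonnegative.
#' @param f_i Open flowers per floral unit, >= 1.
#' @return Resource amount per floral unit.
#' @examples
#' resource_per_floral_unit(0.5, 10)
#' @export
resource_per_floral_unit <- function(r_f, f_i) {
  if (any(is.na(f_i))) stop("no inflorescence data", call. = FALSE)
  check_range(r_f, 0, Inf, "r_f")
  check_range(f_i, 1, Inf, "f_i")
  r_f * f_i
}

#' Standardize raw records to canonical units per floral unit
#'
#' Collapses each raw record to a single entry value (mean, else the
#' midpoint of min and max, else the one reported bound), normalises the
#' magnitude to the trait's canonical unit, converts percent sugar
#' concentration to mol/l, and rescales density and resource records onto
#' floral units:
#' \itemize{
#'   \item records already per inflorescence pass through unchanged — the
#'     inflorescence *is* the floral unit for those taxa;
#'   \item records per single flower whose species has an entry in the
#'     inflorescence table are converted via [floral_unit_density()] /
#'     [resource_per_floral_unit()];
#'   \item records per single flower with no inflorescence entry are kept
#'     unchanged with flag `single_flower_as_floral_unit` — absent other
#'     evidence the single flower is the floral unit.
#' }
#' Records with no value or with a unit that cannot be expressed per floral
#' unit go to the unresolved report; output rows plus unresolved rows always
#' account for every input row. Because each record is scaled by the same
#' factor that rescales the density, per-area resources are conserved:
#' `f_A * R_f = fu_A * R_fu`.
#'
#' @param records Tibble of validated raw records (after
#'   [resolve_source_conventions()]).
#' @param inflorescence_table Tibble from [read_inflorescence_table()].
#' @param registry Unit registry, see [unit_registry()].
#' @param constants Constants list from [flores_constants()].
#' @return List with `records` (tibble: `species`, `trait`, `value`,
#'   `canonical_unit`, `flags`, `reference`) and `unresolved` (input rows
#'   with a `reason` column).
#' @export
standardize_reference_units <- function(records, inflorescence_table,
                                        registry = unit_registry(),
                                        constants = flores_constants()) {
  records <- tibble::as_tibble(records)
  inflorescence_table <- tibble::as_tibble(inflorescence_table)
  value <- entry_value(records$value_min, records$value_max, records$value_mean)

  idx <- match(paste(records$trait, records$unit, sep = "\r"),
               paste(registry$trait, registry$unit, sep = "\r"))
  reason <- rep(NA_character_, nrow(records))
  reason[is.na(idx)] <- "unknown unit"
  reason[is.na(reason) & !registry$convertible[idx]] <- "unit not per floral unit"
  reason[is.na(reason) & is.na(value)] <- "no value"

  ok <- is.na(reason)
  out <- tibble::tibble(
    species = records$species[ok],
    trait = registry$maps_to[idx[ok]],
    value = value[ok] * registry$factor[idx[ok]],
    canonical_unit = registry$canonical_unit[idx[ok]],
    flags = "",
    reference = records$reference[ok]
  )
  raw_trait <- records$trait[ok]
  raw_unit <- records$unit[ok]
  regarding <- records$regarding_flowering_unit[ok]

  # percent sugar concentration -> molar
  is_perc <- raw_trait == "sugar_conc" & raw_unit == "%"
  out$value[is_perc] <- percent_to_molar(out$value[is_perc], constants)
  out$flags[is_perc] <- add_flag(out$flags[is_perc], "percent_to_molar")
  out$canonical_unit[raw_trait == "pollen" & out$trait == "pollen_volume"] <- "ml FU-1"

  # floral reference unit scaling
  refed <- raw_trait %in% referenced_traits()
  f_i <- inflorescence_table$open_flowers_per_inflorescence[
    match(out$species, inflorescence_table$species)]
  per_infl <- refed & regarding == "inflorescence"
  out$flags[per_infl] <- add_flag(out$flags[per_infl], "already_floral_unit")
  per_flower <- refed & regarding == "single_flower"
  has_f <- per_flower & !is.na(f_i)
  dens <- has_f & raw_trait == "flowers_m2"
  res <- has_f & raw_trait != "flowers_m2"
  out$value[dens] <- out$value[dens] / f_i[dens]
  out$flags[dens] <- add_flag(out$flags[dens], "flowers_per_inflorescence")
  out$value[res] <- out$value[res] * f_i[res]
  out$flags[res] <- add_flag(out$flags[res], "scaled_to_inflorescence")
  no_f <- per_flower & is.na(f_i)
  out$flags[no_f] <- add_flag(out$flags[no_f], "single_flower_as_floral_unit")

  unresolved <- records[!ok, ]
  unresolved$reason <- reason[!ok]
  list(records = out, unresolved = unresolved)
}

add_flag <- function(flags, new) {
  ifelse(flags == "", new, paste(flags, new, sep = ";"))
}
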