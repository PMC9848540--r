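# Physical constants and interconversion of nectar volume, sugar mass,
# sugar concentration, and pollen volume/mass.

#' Physical constants of the workflow
#'
#' Densities and molar mass used by the conversion equations, overridable but
#' defaulting to the standard values: saccharose density 1570 mg/ml, saccharose
#' molar mass 342.3 g/mol, protein density 1300 mg/ml, starch density
#' 1440 mg/ml, fat density 900 mg/ml, water density 1000 mg/ml, and the 40%
#' wildflower default for sugar concentration in nectar.
#'
#' Nectar sugar is treated as pure saccharose; real nectar is a
#' glucose/fructose/saccharose mixture, so derived masses are approximations.
#'
#' @param ... Named overrides for individual constants.
#' @return Named list of constants.
#' @examples
#' flores_constants()$saccharose_density
#' flores_constants(default_sugar_percent = 30)
#' @export
flores_constants <- function(...) {
  defaults <- list(
    saccharose_density    = 1570,   # mg/ml (numerically also g/l)
    saccharose_molar_mass = 342.3,  # g/mol
    protein_density       = 1300,   # mg/ml
    starch_density        = 1440,   # mg/ml
    fat_density           = 900,    # mg/ml
    water_density         = 1000,   # mg/ml
    default_sugar_percent = 40      # %
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(defaults))
    if (length(bad)) stop("unknown constant(s): ", paste(bad, collapse = ", "))
    defaults[names(overrides)] <- overrides
  }
  stopifnot(all(vapply(defaults, function(x) is.numeric(x) && x > 0, TRUE)))
  defaults
}

#' Convert sugar concentration between percent and molar
#'
#' Percent concentration is interpreted as the volume fraction of pure
#' saccharose, so `c_mol = (c_perc/100) * rho_z / M_z` with the saccharose
#' density expressed in g/l and its molar mass in g/mol. 40% corresponds to
#' about 1.835 mol/l.
#'
#' @param c_perc Sugar concentration in percent, in \[0, 100\].
#' @param c_mol Sugar concentration in mol/l, nonnegative.
#' @param constants Constants list from [flores_constants()].
#' @return Numeric vector of the converted concentration.
#' @examples
#' percent_to_molar(40)
#' molar_to_percent(percent_to_molar(40))
#' @export
percent_to_molar <- function(c_perc, constants = flores_constants()) {
  check_range(c_perc, 0, 100, "c_perc")
  (c_perc / 100) * constants$saccharose_density / constants$saccharose_molar_mass
}

#' @rdname percent_to_molar
#' @export
molar_to_percent <- function(c_mol, constants = flores_constants()) {
  check_range(c_mol, 0, Inf, "c_mol")
  100 * c_mol * constants$saccharose_molar_mass / constants$saccharose_density
}

#' Sugar mass in nectar from volume and concentration
#'
#' With percent concentration: `m_z = rho_z * V_nec * c_perc / 100` (mg from
#' ml and mg/ml). With molar concentration: `m_z = V_nec * c_mol * M_z`
#' (ml times mol/l times g/mol gives mg). When both concentrations are
#' supplied the percent path is used; the two paths agree to floating-point
#' accuracy because both use the same saccharose constants.
#'
#' @param v_nec Nectar volume in ml (per floral unit and day), nonnegative.
#' @param c_perc,c_mol Sugar concentration (supply at least one).
#' @inheritParams percent_to_molar
#' @return Sugar mass in mg.
#' @examples
#' sugar_mass_from_nectar(0.001, c_perc = 40)
#' sugar_mass_from_nectar(0.001, c_mol = percent_to_molar(40))
#' @export
sugar_mass_from_nectar <- function(v_nec, c_perc = NULL, c_mol = NULL,
                                   constants = flores_constants()) {
  check_range(v_nec, 0, Inf, "v_nec")
  if (!is.null(c_perc)) {
    check_range(c_perc, 0, 100, "c_perc")
    constants$saccharose_density * v_nec * c_perc / 100
  } else if (!is.null(c_mol)) {
    check_range(c_mol, 0, Inf, "c_mol")
    v_nec * c_mol * constants$saccharose_molar_mass
  } else {
    stop("needs concentration: supply c_perc or c_mol", call. = FALSE)
  }
}

#' Nectar volume from sugar mass and concentration
#'
#' Inverse of [sugar_mass_from_nectar()]: `V_nec = 100 * m_z / (rho_z *
#' c_perc)` on the percent path, `V_nec = m_z / (c_mol * M_z)` on the molar
#' path. A zero concentration with positive sugar mass is a domain error
#' (infinite volume).
#'
#' @param m_z Sugar mass in mg, nonnegative.
#' @inheritParams sugar_mass_from_nectar
#' @return Nectar volume in ml.
#' @examples
#' nectar_volume_from_sugar(0.628, c_perc = 40)
#' @export
nectar_volume_from_sugar <- function(m_z, c_perc = NULL, c_mol = NULL,
                                     constants = flores_constants()) {
  check_range(m_z, 0, Inf, "m_z")
  if (!is.null(c_perc)) {
    check_range(c_perc, 0, 100, "c_perc")
    conc_zero <- !is.na(c_perc) & c_perc == 0 & !is.na(m_z) & m_z > 0
    if (any(conc_zero)) stop("zero concentration with positive sugar mass", call. = FALSE)
    out <- 100 * m_z / (constants$saccharose_density * c_perc)
  } else if (!is.null(c_mol)) {
    check_range(c_mol, 0, Inf, "c_mol")
    conc_zero <- !is.na(c_mol) & c_mol == 0 & !is.na(m_z) & m_z > 0
    if (any(conc_zero)) stop("zero concentration with positive sugar mass", call. = FALSE)
    out <- m_z / (c_mol * constants$saccharose_molar_mass)
  } else {
    stop("needs concentration: supply c_perc or c_mol", call. = FALSE)
  }
  # 0 mg at 0 concentration is 0 ml, not NaN
  ifelse(!is.na(m_z) & m_z == 0, 0, out)
}

#' Pollen density from protein fraction
#'
#' Fresh pollen density is modelled as a mixture: the protein fraction at
#' protein density, and the remainder split equally between starch, fat and
#' water: `rho_p = rho_prot * P + (1 - P)/3 * (rho_starch + rho_fat +
#' rho_water)`. With the default constants the density rises linearly from
#' 1113.33 mg/ml (no protein) to 1300 mg/ml (pure protein).
#'
#' @param p_prot Protein fraction of pollen, dimensionless in \[0, 1\].
#' @inheritParams percent_to_molar
#' @return Pollen density in mg/ml.
#' @examples
#' pollen_density(0.25)
#' @export
pollen_density <- function(p_prot, constants = flores_constants()) {
  check_range(p_prot, 0, 1, "p_prot")
  constants$protein_density * p_prot +
    (1 - p_prot) / 3 *
      (constants$starch_density + constants$fat_density + constants$water_density)
}

#' Pollen mass from volume
#'
#' `m_p = V_p * rho_p`, mg from ml and mg/ml. Pollen reported as grain
#' volume is converted with the species' (possibly imputed) protein content
#' via [pollen_density()].
#'
#' @param v_p Pollen volume in ml, nonnegative.
#' @param rho_p Pollen density in mg/ml, positive.
#' @return Pollen mass in mg.
#' @examples
#' pollen_mass_from_volume(0.002, pollen_density(0.25))
#' @export
pollen_mass_from_volume <- function(v_p, rho_p) {
  check_range(v_p, 0, Inf, "v_p")
  check_range(rho_p, 1e-12, Inf, "rho_p")
  v_p * rho_p
}

#' Fill derivable nectar fields of a nectar state
#'
#' Completes a nectar state (volume `volume` \[ml\], sugar mass `sugar_mass`
#' \[mg\], concentration `conc_percent` \[%\] and `conc_molar` \[mol/l\])
#' by deriving every missing field that the conversion identities determine:
#' molar from percent concentration and vice versa, sugar mass from volume
#' plus a concentration, volume from sugar mass plus a concentration.
#' Observed values are never overwritten, concentration is never inferred
#' from volume and mass, and the operation is idempotent. States with sugar
#' mass but no concentration are left for the downstream default
#' concentration stage.
#'
#' @param state A list or data frame with columns/fields `volume`,
#'   `sugar_mass`, `conc_percent`, `conc_molar` (missing fields are treated
#'   as all-`NA`).
#' @inheritParams percent_to_molar
#' @return Object of the same shape with derivable fields filled.
#' @examples
#' complete_nectar_traits(list(volume = 0.001, conc_percent = 40,
#'                             sugar_mass = NA, conc_molar = NA))
#' @export
complete_nectar_traits <- function(state, constants = flores_constants()) {
  was_list <- !is.data.frame(state)
  if (was_list) state <- tibble::as_tibble(state[lengths(state) > 0])
  for (f in c("volume", "sugar_mass", "conc_percent", "conc_molar")) {
    if (is.null(state[[f]])) state[[f]] <- NA_real_
  }
  v <- as.numeric(state$volume)
  m <- as.numeric(state$sugar_mass)
  cp <- as.numeric(state$conc_percent)
  cm <- as.numeric(state$conc_molar)

  cm <- ifelse(is.na(cm) & !is.na(cp), percent_to_molar(cp, constants), cm)
  cp <- ifelse(is.na(cp) & !is.na(cm), molar_to_percent(cm, constants), cp)
  # percent path preferred for mass, then molar
  m <- ifelse(is.na(m) & !is.na(v) & !is.na(cp),
              constants$saccharose_density * v * cp / 100, m)
  m <- ifelse(is.na(m) & !is.na(v) & !is.na(cm),
              v * cm * constants$saccharose_molar_mass, m)
  v <- ifelse(is.na(v) & !is.na(m) & m == 0, 0, v)
  v <- ifelse(is.na(v) & !is.na(m) & !is.na(cp) & cp > 0,
              100 * m / (constants$saccharose_density * cp), v)
  v <- ifelse(is.na(v) & !is.na(m) & !is.na(cm) & cm > 0,
              m / (cm * constants$saccharose_molar_mass), v)

  state$volume <- v
  state$sugar_mass <- m
  state$conc_percent <- cp
  state$conc_molar <- cm
  if (was_list) as.list(state) else state
}

#' Normalize a magnitude to the trait's canonical unit
#'
#' Applies the registered scale factor of a unit dialect: microlitres to
#' millilitres and micrograms to milligrams divide by 1000, grams to
#' milligrams multiply by 1000, `g/100g dry mass` equals percent, and
#' day-of-year, mm, percent and mol/l pass through unchanged.
#'
#' @param value Numeric value(s) in the dialect unit.
#' @param unit Unit dialect string, registered for the trait.
#' @param trait Trait code, one of [flores_traits()].
#' @param registry Unit registry, see [unit_registry()].
#' @return Value in the canonical unit of the trait.
#' @examples
#' normalize_magnitude(5, "µl/d", "nectar_volume")
#' normalize_magnitude(0.002, "g", "pollen")
#' @export
normalize_magnitude <- function(value, unit, trait, registry = unit_registry()) {
  hit <- registry[registry$trait == trait & registry$unit == unit, ]
  if (nrow(hit) != 1L) {
    stop("unknown unit '", unit, "' for trait '", trait, "'", call. = FALSE)
  }
  if (!hit$convertible) {
    stop("unit '", unit, "' cannot be expressed per floral unit", call. = FALSE)
  }
  value * hit$factor
}

# shared argument checking: NA allowed, range enforced on non-NA
check_range <- function(x, lo, hi, name) {
  if (!is.numeric(x)) stop(name, " must be numeric", call. = FALSE)
  bad <- !is.na(x) & (x < lo | x > hi)
  if (any(bad)) {
    stop(name, " out of range [", lo, ", ", hi, "]: ",
         paste(head(x[bad], 3), collapse = ", "), call. = FALSE)
  }
  invisible(x)
}
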