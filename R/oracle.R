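# Independent straight-line recomputation of the whole workflow on a
# fixture bundle. Deliberately written in plain base R, record by record,
# without calling any pipeline function, so it can serve as ground truth
# for the pipeline under test.

#' Compute expected output tables for a fixture bundle
#'
#' Evaluates every workflow rule directly on the bundle's raw tables:
#' entry values (mean, else min/max midpoint, else single bound), the
#' source conventions for corolla and zero nectar, unit and floral-unit
#' conversion, per-species mean/max aggregation, the in-profile derivation
#' of nectar traits, taxon mapping with the few-entries filter, genus/global
#' protein imputation, the default sugar concentration and the final
#' partition. Unknown and per-area units are skipped exactly as the
#' pipeline quarantines them.
#'
#' @param bundle Fixture bundle (needs `raw_table`, `inflorescence_table`,
#'   `taxa_mapping`).
#' @param min_resource_traits Deletion threshold of the few-entries filter.
#' @param constants Constants list from [flores_constants()].
#' @return List of data frames `raw`, `complete_trait`, `no_corolla`
#'   (columns: `taxon`, the profile trait slots, `completeness`); attribute
#'   `"default_conc_taxa"` on `raw` lists taxa that received the default
#'   concentration.
#' @export
oracle_standardize <- function(bundle, min_resource_traits = 1,
                               constants = flores_constants()) {
  rho_z <- constants$saccharose_density
  m_z <- constants$saccharose_molar_mass
  df <- as.data.frame(bundle$raw_table, stringsAsFactors = FALSE)
  mu <- "\u00b5"

  # --- per-record entry value -------------------------------------------
  n <- nrow(df)
  val <- numeric(n)
  for (i in seq_len(n)) {
    if (!is.na(df$value_mean[i])) {
      val[i] <- df$value_mean[i]
    } else if (!is.na(df$value_min[i]) && !is.na(df$value_max[i])) {
      val[i] <- (df$value_min[i] + df$value_max[i]) / 2
    } else if (!is.na(df$value_min[i])) {
      val[i] <- df$value_min[i]
    } else if (!is.na(df$value_max[i])) {
      val[i] <- df$value_max[i]
    } else {
      val[i] <- NA_real_
    }
  }
  df$entry <- val

  # --- schema validation mirror -----------------------------------------
  # rows with unregistered units never reach the conventions step
  unit_factor <- list(
    flowering_start = c(d = 1), flowering_end = c(d = 1),
    flowers_m2 = c("m-2" = 1, "m^-2" = 1, "1/m2" = 1),
    nectar_volume = setNames(c(1e-3, 1e-3, 1), c(paste0(mu, "l/d"), "ul/d", "ml/d")),
    sugar_conc = c("mol l-1" = 1, "mol/l" = 1, "%" = NA),  # % handled below
    nectar_sugar_cont = setNames(c(1e-3, 1e-3, 1), c(paste0(mu, "g/d"), "ug/d", "mg/d")),
    pollen = setNames(c(1e-3, 1e-3, 1, 1e3, 1e-3, 1e-3, 1),
                      c(paste0(mu, "g"), "ug", "mg", "g",
                        paste0(mu, "l"), "ul", "ml")),
    protein = c("%" = 1, "g/100g dry mass" = 1),
    corolla = c(mm = 1))
  known <- vapply(seq_len(n), function(i) {
    fac <- unit_factor[[df$trait[i]]]
    !is.null(fac) && df$unit[i] %in% names(fac)
  }, TRUE)
  df <- df[known, ]
  n <- nrow(df)

  # --- source conventions -----------------------------------------------
  nectar_tr <- c("nectar_volume", "nectar_sugar_cont", "sugar_conc")
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    sp <- df$species[i]
    if (df$trait[i] == "corolla") {
      has_pollen <- any(df$species == sp & df$trait == "pollen")
      has_nectar <- any(df$species == sp & df$trait %in% nectar_tr)
      if (has_pollen && !has_nectar) keep[i] <- FALSE
    }
    if (df$trait[i] == "nectar_volume" && !is.na(df$entry[i]) && df$entry[i] == 0) {
      others <- df$species == sp & df$trait %in% c("nectar_volume", "nectar_sugar_cont") &
        !is.na(df$entry) & df$entry > 0
      if (any(others)) keep[i] <- FALSE
    }
  }
  df <- df[keep, ]

  # --- unit + floral reference conversion -------------------------------
  volume_units <- c(paste0(mu, "l"), "ul", "ml")
  f_lookup <- setNames(bundle$inflorescence_table$open_flowers_per_inflorescence,
                       bundle$inflorescence_table$species)

  out_sp <- character(); out_tr <- character(); out_val <- numeric()
  for (i in seq_len(nrow(df))) {
    tr <- df$trait[i]; un <- df$unit[i]; v <- df$entry[i]
    if (is.na(v)) next
    fac <- unit_factor[[tr]]
    if (is.null(fac) || !(un %in% names(fac))) next  # unknown/ignored unit
    if (tr == "sugar_conc" && un == "%") {
      v <- (v / 100) * rho_z / m_z
    } else {
      v <- v * fac[[un]]
    }
    slot <- tr
    if (tr == "pollen" && un %in% volume_units) slot <- "pollen_volume"
    if (tr %in% c("flowers_m2", "nectar_volume", "nectar_sugar_cont", "pollen") &&
        identical(df$regarding_flowering_unit[i], "single_flower")) {
      f <- unname(f_lookup[df$species[i]])
      if (length(f) == 1 && !is.na(f)) {
        v <- if (tr == "flowers_m2") v / f else v * f
      }
    }
    out_sp <- c(out_sp, df$species[i]); out_tr <- c(out_tr, slot)
    out_val <- c(out_val, v)
  }

  # --- per-species aggregation ------------------------------------------
  slots <- c("flowering_start", "flowering_end", "flowers_m2", "nectar_volume",
             "sugar_conc", "nectar_sugar_cont", "pollen", "pollen_volume",
             "protein", "corolla")
  species <- sort(unique(out_sp))
  prof <- matrix(NA_real_, length(species), length(slots),
                 dimnames = list(species, slots))
  for (sp in species) {
    for (sl in slots) {
      vv <- out_val[out_sp == sp & out_tr == sl]
      if (!length(vv)) next
      prof[sp, sl] <- if (sl == "flowers_m2") max(vv) else mean(vv)
    }
  }

  complete_row <- function(p) {
    # nectar identities; concentration never inferred from volume and mass
    if (is.na(p["nectar_sugar_cont"]) && !is.na(p["nectar_volume"]) &&
        !is.na(p["sugar_conc"])) {
      cp <- 100 * p["sugar_conc"] * m_z / rho_z
      p["nectar_sugar_cont"] <- rho_z * p["nectar_volume"] * cp / 100
    }
    if (is.na(p["nectar_volume"]) && !is.na(p["nectar_sugar_cont"])) {
      if (p["nectar_sugar_cont"] == 0) {
        p["nectar_volume"] <- 0
      } else if (!is.na(p["sugar_conc"]) && p["sugar_conc"] > 0) {
        cp <- 100 * p["sugar_conc"] * m_z / rho_z
        p["nectar_volume"] <- 100 * p["nectar_sugar_cont"] / (rho_z * cp)
      }
    }
    if (is.na(p["pollen"]) && !is.na(p["pollen_volume"]) && !is.na(p["protein"])) {
      pp <- p["protein"] / 100
      rho_p <- constants$protein_density * pp + (1 - pp) / 3 *
        (constants$starch_density + constants$fat_density + constants$water_density)
      p["pollen"] <- p["pollen_volume"] * rho_p
    }
    p
  }
  for (sp in species) prof[sp, ] <- complete_row(prof[sp, ])

  # --- mapping and few-entries filter -----------------------------------
  map <- bundle$taxa_mapping
  taxon_of <- function(sp) {
    hit <- match(sp, map$species)
    if (is.na(hit)) sp else map$taxon[hit]
  }
  taxon <- vapply(species, taxon_of, "")
  n_res <- apply(prof, 1, function(p) {
    sum(!is.na(p["nectar_volume"]), !is.na(p["nectar_sugar_cont"]),
        !is.na(p["sugar_conc"]), !is.na(p["pollen"]) || !is.na(p["pollen_volume"]))
  })
  sel <- n_res >= min_resource_traits
  prof <- prof[sel, , drop = FALSE]
  taxon <- taxon[sel]

  # --- protein imputation at taxon level --------------------------------
  taxa <- sort(unique(taxon))
  tax_protein <- sapply(taxa, function(tx) {
    v <- prof[taxon == tx, "protein"]
    if (all(is.na(v))) NA_real_ else mean(v[!is.na(v)])
  })
  strip_genus <- function(x) {
    x <- sub("[[:space:]]+(sp|spec|spp|agg)\\.?$", "", trimws(x))
    strsplit(trimws(x), "[[:space:]]+")[[1]][1]
  }
  tax_genus <- vapply(taxa, strip_genus, "")
  if (length(taxa) && any(!is.na(tax_protein))) {
    global <- mean(tax_protein[!is.na(tax_protein)])
    for (tx in taxa[is.na(tax_protein)]) {
      mates <- tax_protein[tax_genus == tax_genus[taxa == tx] & !is.na(tax_protein)]
      fill <- if (length(mates)) mean(mates) else global
      rows <- which(taxon == tx & is.na(prof[, "protein"]))
      prof[rows, "protein"] <- fill
    }
  }

  # --- taxon aggregation, second derivation, default concentration ------
  ent <- matrix(NA_real_, length(taxa), length(slots),
                dimnames = list(taxa, slots))
  for (tx in taxa) {
    sub <- prof[taxon == tx, , drop = FALSE]
    for (sl in slots) {
      vv <- sub[, sl][!is.na(sub[, sl])]
      if (!length(vv)) next
      ent[tx, sl] <- if (sl == "flowers_m2") max(vv) else mean(vv)
    }
  }
  for (tx in taxa) ent[tx, ] <- complete_row(ent[tx, ])
  default_taxa <- taxa[is.na(ent[, "sugar_conc"])]
  ent[is.na(ent[, "sugar_conc"]), "sugar_conc"] <-
    (constants$default_sugar_percent / 100) * rho_z / m_z
  for (tx in taxa) ent[tx, ] <- complete_row(ent[tx, ])

  core <- setdiff(slots, "pollen_volume")
  completeness <- apply(ent, 1, function(p) {
    miss <- core[is.na(p[core])]
    if (!length(miss)) "complete"
    else if (identical(miss, "corolla")) "complete_except_corolla"
    else "incomplete"
  })
  res <- data.frame(taxon = taxa, ent, completeness = completeness,
                    row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)
  res <- res[order(res$taxon), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "default_conc_taxa") <- default_taxa
  list(raw = res,
       complete_trait = res[res$completeness == "complete", , drop = FALSE],
       no_corolla = res[res$completeness %in%
                          c("complete", "complete_except_corolla"), , drop = FALSE])
}
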