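# Descriptive statistics of the raw database and the final trait tables.

#' Summarize trait coverage and trait correlations
#'
#' Reports, from the raw records: the number and percentage of species with
#' at least one entry per trait, and the distribution of species over the
#' number of traits covered. From the final entries: taxon and genus counts
#' per output table, and the pairwise Pearson correlation matrix of the
#' numeric traits over the complete taxa, with two-sided t-test p-values.
#' Correlations that are undefined (constant trait, or fewer than three
#' complete taxa) are reported as `NA`, not as an error.
#'
#' @param records Raw records tibble (one row per species x trait x source).
#' @param tables Output of [finalize_taxa()] (or the `tables` element of
#'   [build_flores()]); may be `NULL` to summarise only the raw records.
#' @return List with `coverage` (per-trait species counts and percentages),
#'   `traits_per_species` (species counts by number of covered traits),
#'   `table_sizes` (taxa and genera per output table), `correlation`
#'   (Pearson r matrix) and `correlation_p` (p-value matrix).
#' @export
summarize_database <- function(records, tables = NULL) {
  records <- tibble::as_tibble(records)
  n_species <- length(unique(records$species))
  cov <- records |>
    dplyr::filter(.data$trait %in% flores_traits()) |>
    dplyr::distinct(.data$species, .data$trait) |>
    dplyr::count(.data$trait, name = "n_species")
  cov$percent <- 100 * cov$n_species / n_species

  per_sp <- records |>
    dplyr::filter(.data$trait %in% flores_traits()) |>
    dplyr::distinct(.data$species, .data$trait) |>
    dplyr::count(.data$species, name = "n_traits") |>
    dplyr::count(.data$n_traits, name = "n_species")

  table_sizes <- NULL
  corr <- corr_p <- NULL
  if (!is.null(tables)) {
    n_genera <- function(t) {
      if (!"taxon" %in% names(t) || nrow(t) == 0) return(0L)
      length(unique(genus_of(t$taxon)))
    }
    table_sizes <- tibble::tibble(
      table = names(tables),
      n_taxa = unname(vapply(tables, nrow, 0L)),
      n_genera = unname(vapply(tables, n_genera, 0L))
    )
    cmpl <- tables$complete_trait
    num_traits <- setdiff(flores_core_traits(), c("flowering_start", "flowering_end"))
    if (!is.null(cmpl) && nrow(cmpl) >= 3) {
      m <- as.matrix(cmpl[num_traits])
      k <- ncol(m)
      corr <- corr_p <- matrix(NA_real_, k, k, dimnames = list(num_traits, num_traits))
      for (i in seq_len(k)) for (j in seq_len(k)) {
        if (stats::sd(m[, i]) == 0 || stats::sd(m[, j]) == 0) next
        ct <- stats::cor.test(m[, i], m[, j])
        corr[i, j] <- unname(ct$estimate)
        corr_p[i, j] <- ct$p.value
      }
    }
  }
  list(coverage = cov, traits_per_species = per_sp, table_sizes = table_sizes,
       correlation = corr, correlation_p = corr_p)
}
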