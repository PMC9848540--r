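# Daily per-area nectar and pollen supply of a habitat, and provisioning
# gap detection.

#' Daily floral resource supply of a habitat
#'
#' For each resource (nectar sugar \[mg m-2 d-1\], nectar volume
#' \[ml m-2 d-1\], pollen \[mg m-2 d-1\]), the supply on a day is the sum
#' over composition taxa of `cover/100 * flowers_m2 * resource_per_FU`
#' inside the taxon's flowering window (closed interval of day-of-year),
#' and zero outside. `flowers_m2` is the floral-unit density at 100% cover,
#' so cover scales the supply linearly.
#'
#' @param flores Trait table (a [finalize_taxa()] table, typically
#'   `no_corolla` or `complete_trait`) with columns `taxon`, `flowers_m2`,
#'   `flowering_start`, `flowering_end`, `nectar_sugar_cont`,
#'   `nectar_volume`, `pollen`.
#' @param composition Habitat composition from [read_habitat_composition()]
#'   (columns `taxon`, `cover_percent`).
#' @param day Day(s) of year, 1 to 365.
#' @param allow_incomplete If `TRUE`, taxa with a missing resource trait
#'   contribute zero to that resource; the default is a hard error.
#' @return Tibble with columns `day`, `sugar`, `nectar_volume`, `pollen`.
#' @examples
#' flores <- tibble::tibble(taxon = "Trifolium pratense", flowers_m2 = 10,
#'   flowering_start = 100, flowering_end = 150,
#'   nectar_sugar_cont = 2, nectar_volume = 0.002, pollen = 0.5)
#' comp <- tibble::tibble(taxon = "Trifolium pratense", cover_percent = 50)
#' daily_supply(flores, comp, 120)
#' @export
daily_supply <- function(flores, composition, day, allow_incomplete = FALSE) {
  flores <- tibble::as_tibble(flores)
  composition <- tibble::as_tibble(composition)
  check_range(day, 1, 365, "day")
  missing_taxa <- setdiff(composition$taxon, flores$taxon)
  if (length(missing_taxa)) {
    stop("composition taxa absent from trait table: ",
         paste(missing_taxa, collapse = ", "), call. = FALSE)
  }
  i <- match(composition$taxon, flores$taxon)
  need <- c("flowers_m2", "flowering_start", "flowering_end",
            "nectar_sugar_cont", "nectar_volume", "pollen")
  sub <- flores[i, need]
  if (!allow_incomplete && anyNA(sub)) {
    offenders <- composition$taxon[rowSums(is.na(sub)) > 0]
    stop("taxa with missing traits (set allow_incomplete = TRUE to treat as zero): ",
         paste(offenders, collapse = ", "), call. = FALSE)
  }
  scale <- composition$cover_percent / 100 * sub$flowers_m2
  per_day <- function(d) {
    open <- !is.na(sub$flowering_start) & !is.na(sub$flowering_end) &
      sub$flowering_start <= d & d <= sub$flowering_end
    contrib <- function(x) sum(ifelse(open, scale * x, 0), na.rm = TRUE)
    c(sugar = contrib(sub$nectar_sugar_cont),
      nectar_volume = contrib(sub$nectar_volume),
      pollen = contrib(sub$pollen))
  }
  vals <- t(vapply(day, per_day, c(sugar = 0, nectar_volume = 0, pollen = 0)))
  tibble::tibble(day = day, sugar = unname(vals[, "sugar"]),
                 nectar_volume = unname(vals[, "nectar_volume"]),
                 pollen = unname(vals[, "pollen"]))
}

#' Seasonal resource supply profile
#'
#' Computes [daily_supply()] for every day of a range, optionally summed
#' into consecutive 7-day weeks or calendar months (non-leap year).
#'
#' @inheritParams daily_supply
#' @param from_day,to_day Day-of-year range (closed, `from_day <= to_day`).
#' @param period `"day"` (default), `"week"` (consecutive 7-day blocks from
#'   `from_day`; a trailing partial block is kept), or `"month"`.
#' @return Tibble of daily rows, or period sums with columns `period`,
#'   `start_day`, `end_day`, `n_days`, `sugar`, `nectar_volume`, `pollen`.
#' @export
seasonal_profile <- function(flores, composition, from_day = 1, to_day = 365,
                             period = c("day", "week", "month"),
                             allow_incomplete = FALSE) {
  period <- match.arg(period)
  check_range(from_day, 1, 365, "from_day")
  check_range(to_day, 1, 365, "to_day")
  if (from_day > to_day) stop("inverted day range", call. = FALSE)
  days <- seq.int(from_day, to_day)
  prof <- daily_supply(flores, composition, days, allow_incomplete)
  if (period == "day") return(prof)
  idx <- if (period == "week") {
    (days - from_day) %/% 7 + 1
  } else {
    month_of_doy(days)
  }
  prof$period <- idx
  prof |>
    dplyr::group_by(.data$period) |>
    dplyr::summarise(
      start_day = min(.data$day), end_day = max(.data$day),
      n_days = dplyr::n(),
      sugar = sum(.data$sugar),
      nectar_volume = sum(.data$nectar_volume),
      pollen = sum(.data$pollen),
      .groups = "drop"
    )
}

month_of_doy <- function(day) {
  ends <- cumsum(c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31))
  findInterval(day - 1, c(0, ends[-12]))
}

#' Locate temporal provisioning gaps
#'
#' Finds maximal runs of consecutive days on which the supply of one
#' resource falls strictly below a threshold, over a contiguous daily
#' profile. With an all-zero profile and a positive threshold the whole
#' range is one gap; with positive supply everywhere and threshold 0 there
#' are none.
#'
#' @param profile Daily profile from [seasonal_profile()] (period `"day"`).
#' @param resource One of `"sugar"`, `"nectar_volume"`, `"pollen"`.
#' @param threshold Supply level below which a day counts as a gap day.
#' @return Tibble with columns `start_day`, `end_day`, `length`, sorted by
#'   start day.
#' @export
find_gaps <- function(profile, resource = c("sugar", "nectar_volume", "pollen"),
                      threshold = 0) {
  resource <- match.arg(resource)
  profile <- tibble::as_tibble(profile)
  if (nrow(profile) == 0) {
    return(tibble::tibble(start_day = integer(), end_day = integer(),
                          length = integer()))
  }
  if (any(diff(profile$day) != 1)) {
    stop("profile must cover a contiguous day range", call. = FALSE)
  }
  below <- profile[[resource]] < threshold
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  gap <- which(r$values)
  tibble::tibble(
    start_day = profile$day[starts[gap]],
    end_day = profile$day[ends[gap]],
    length = r$lengths[gap]
  )
}
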