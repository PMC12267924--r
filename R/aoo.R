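#' Partition a species' AOO by threat status
#'
#' Routes each cleaned occurrence of one species to exactly one of three
#' partitions and computes the gridded area of occupancy of each:
#'
#' * `native_threatened` — native occurrence in a country where the species'
#'   standardized national category is threatened (see [is_threatened()]);
#' * `native_ok` — native occurrence in any other country (including
#'   unassessed ones: absence of assessment is not threat);
#' * `naturalized` — introduced occurrence in a country listed for the
#'   species in the naturalization table.
#'
#' Introduced occurrences in countries without a naturalization record, and
#' native occurrences in countries listed as naturalized for the species,
#' have no resolvable role; they are counted in an `n_unresolved` column and
#' excluded from all partitions. A grid cell reached by native occurrences
#' from both threatened and non-threatened countries contributes its area to
#' both native partitions (cell-level union per partition), so the two
#' native AOOs can sum to slightly more than the AOO of their union; the
#' straddling-cell count is reported.
#'
#' The percentage of native AOO threatened is
#' `100 * aoo_native_threatened / (aoo_native_threatened + aoo_native_ok)`,
#' `NA` for species without native occurrences.
#'
#' @param occurrences cleaned occurrence tibble (`species`, `lon`, `lat`,
#'   `country_code`, `establishment_means`), one or many species.
#' @param statuses standardized status tibble from [standardize_statuses()].
#' @param naturalizations tibble (`species`, `country_code`).
#' @param grid a [grid_spec()].
#' @param include_nt count NT listings as threatened (default `FALSE`).
#' @return tibble with one row per species: cell counts, AOOs (km2),
#'   `pct_native_threatened`, `n_unresolved`, `n_cells_straddling`.
#' @export
partition_aoo <- function(occurrences, statuses, naturalizations,
                          grid = grid_spec(), include_nt = FALSE) {
  assert_columns(occurrences, c("species", "lon", "lat", "country_code",
                                "establishment_means"), "occurrence table")
  thr <- statuses[is_threatened(statuses$category, include_nt), ]
  thr_key <- paste(thr$accepted_name, thr$country_code)
  nat_key <- paste(naturalizations$species, naturalizations$country_code)

  occ <- occurrences
  key <- paste(occ$species, occ$country_code)
  is_native <- occ$establishment_means == "native"
  in_nat <- key %in% nat_key
  part <- dplyr::case_when(
    is_native & !in_nat & key %in% thr_key ~ "native_threatened",
    is_native & !in_nat ~ "native_ok",
    !is_native & in_nat ~ "naturalized",
    TRUE ~ "unresolved"
  )

  idx <- cell_index(grid, occ$lon, occ$lat)
  occ_cells <- tibble::tibble(species = occ$species, part = part,
                              col = idx$col, row = idx$row)
  unresolved <- occ_cells |>
    dplyr::filter(.data$part == "unresolved") |>
    dplyr::count(.data$species, name = "n_unresolved")

  cells <- occ_cells |>
    dplyr::filter(.data$part != "unresolved") |>
    dplyr::distinct(.data$species, .data$part, .data$col, .data$row)
  cells$area <- cell_area_km2(grid, cells$row)

  agg <- cells |>
    dplyr::group_by(.data$species, .data$part) |>
    dplyr::summarise(n_cells = dplyr::n(), aoo = sum(.data$area),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "part",
                       values_from = c("n_cells", "aoo"),
                       values_fill = 0)
  for (col in c("n_cells_native_threatened", "n_cells_native_ok",
                "n_cells_naturalized", "aoo_native_threatened",
                "aoo_native_ok", "aoo_naturalized")) {
    if (!col %in% names(agg)) agg[[col]] <- 0
  }

  straddle <- cells |>
    dplyr::filter(.data$part %in% c("native_threatened", "native_ok")) |>
    dplyr::distinct(.data$species, .data$part, .data$col, .data$row) |>
    dplyr::count(.data$species, .data$col, .data$row) |>
    dplyr::filter(.data$n > 1) |>
    dplyr::count(.data$species, name = "n_cells_straddling")

  out <- tibble::tibble(species = unique(occ$species)) |>
    dplyr::left_join(agg, by = "species") |>
    dplyr::left_join(unresolved, by = "species") |>
    dplyr::left_join(straddle, by = "species")
  for (nm in setdiff(names(out), "species")) {
    out[[nm]][is.na(out[[nm]])] <- 0
  }
  native_total <- out$aoo_native_threatened + out$aoo_native_ok
  out$pct_native_threatened <- ifelse(
    native_total > 0, 100 * out$aoo_native_threatened / native_total, NA_real_)
  dplyr::select(
    out, "species",
    "n_cells_native_threatened", "n_cells_native_ok", "n_cells_naturalized",
    "aoo_native_threatened", "aoo_native_ok", "aoo_naturalized",
    "pct_native_threatened", "n_unresolved", "n_cells_straddling"
  )
}
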