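#' Classify species on the net-loss / paradox / net-increase continuum
#'
#' Intersects the naturalization table with the standardized native status
#' table. A species is a conservation-paradox case when it is naturalized
#' somewhere and threatened in at least one country of its native range;
#' threatened-only species are net losses, naturalized-only species net
#' increases, and species with neither signal (present only via the optional
#' `checklist`, or carrying only LC/DD/NE listings) are kept as class
#' `none` so that the four classes always partition the species set.
#'
#' A species appearing as naturalized and nationally assessed in the same
#' country violates the native/naturalized role exclusivity and raises a
#' validation error listing the offenders.
#'
#' @param naturalizations tibble (`species`, `country_code`), accepted names.
#' @param statuses standardized native status tibble from
#'   [standardize_statuses()].
#' @param include_nt count NT listings as threatened (default `FALSE`).
#' @param checklist optional species-record tibble (see [species_records()]);
#'   when given, species absent from both tables are included with class
#'   `none` and the result carries their `family`.
#' @return tibble (`species`, `is_naturalized`, `is_threatened_native`,
#'   `continuum_class`), one row per species.
#' @export
classify_species <- function(naturalizations, statuses, include_nt = FALSE,
                             checklist = NULL) {
  assert_columns(naturalizations, c("species", "country_code"),
                 "naturalization table")
  assert_columns(statuses, c("accepted_name", "country_code", "category"),
                 "status table")

  overlap <- intersect(
    paste(naturalizations$species, naturalizations$country_code),
    paste(statuses$accepted_name, statuses$country_code)
  )
  if (length(overlap) > 0) {
    abort(paste0(
      "species listed as naturalized and natively assessed in the same country: ",
      paste(head(overlap, 5), collapse = "; "),
      if (length(overlap) > 5) sprintf(" (and %d more)", length(overlap) - 5)),
      class = "natparadox_validation_error")
  }

  nat_sp <- unique(naturalizations$species)
  thr_sp <- unique(statuses$accepted_name[
    is_threatened(statuses$category, include_nt)])
  universe <- union(union(nat_sp, unique(statuses$accepted_name)),
                    if (!is.null(checklist)) checklist$accepted_name)

  out <- tibble::tibble(
    species = universe,
    is_naturalized = universe %in% nat_sp,
    is_threatened_native = universe %in% thr_sp
  )
  out$continuum_class <- dplyr::case_when(
    out$is_naturalized & out$is_threatened_native ~ "paradox",
    !out$is_naturalized & out$is_threatened_native ~ "net_loss",
    out$is_naturalized & !out$is_threatened_native ~ "net_increase",
    TRUE ~ "none"
  )
  if (!is.null(checklist)) {
    out <- dplyr::left_join(
      out, checklist[, c("accepted_name", "family")],
      by = c(species = "accepted_name"))
  }
  out
}

#' Prevalence of the conservation paradox among naturalized species
#'
#' @param classifications tibble from [classify_species()].
#' @return list with `n_naturalized`, `n_paradox`, `pct` (full precision) and
#'   `pct_reported` (rounded half-up to one decimal, the reporting style of
#'   the analyses).
#' @export
prevalence <- function(classifications) {
  n_nat <- sum(classifications$is_naturalized)
  if (n_nat == 0) {
    abort("no naturalized species: prevalence undefined",
          class = "natparadox_input_error")
  }
  n_par <- sum(classifications$continuum_class == "paradox")
  pct <- 100 * n_par / n_nat
  list(n_naturalized = n_nat, n_paradox = n_par, pct = pct,
       pct_reported = round_half_up(pct, 1))
}

#' Share of naturalized species threatened on the global Red List
#'
#' The subglobal prevalence asks "threatened in at least one country"; this
#' contrast asks how many naturalized species are threatened across their
#' whole native range according to global assessments. Unassessed species
#' (NE) stay in the denominator.
#'
#' @param classifications tibble from [classify_species()].
#' @param global_statuses tibble (`species`, `category`) of global IUCN
#'   codes; species not listed are treated as NE.
#' @param include_nt count NT as threatened.
#' @return list with `n_naturalized`, `n_globally_threatened`, `pct`,
#'   `pct_reported`, and `n_ew` (naturalized species listed Extinct in the
#'   Wild).
#' @export
global_threat_share <- function(classifications, global_statuses,
                                include_nt = FALSE) {
  assert_columns(global_statuses, c("species", "category"),
                 "global status table")
  nat <- classifications[classifications$is_naturalized, ]
  if (nrow(nat) == 0) {
    abort("no naturalized species: share undefined",
          class = "natparadox_input_error")
  }
  cat <- global_statuses$category[match(nat$species, global_statuses$species)]
  cat[is.na(cat)] <- "NE"
  thr <- is_threatened(cat, include_nt)
  pct <- 100 * sum(thr) / nrow(nat)
  list(n_naturalized = nrow(nat), n_globally_threatened = sum(thr),
       pct = pct, pct_reported = round_half_up(pct, 1),
       n_ew = sum(cat == "EW"))
}

#' Per-country share of paradox species in the naturalized flora
#'
#' For each receiving country, the fraction of its naturalized flora made of
#' species with native-range contractions (paradox class). Countries with an
#' empty naturalized flora are reported with `NA` and excluded from the
#' cross-country mean (0/0 has no share).
#'
#' @param classifications tibble from [classify_species()].
#' @param naturalizations tibble (`species`, `country_code`).
#' @return tibble (`country_code`, `n_naturalized`, `n_paradox`, `pct`) with
#'   attributes `mean_pct` (unweighted mean over countries with naturalized
#'   flora) and `n_over_50` (countries with more than half their naturalized
#'   flora in the paradox class).
#' @export
country_summary <- function(classifications, naturalizations) {
  par_sp <- classifications$species[classifications$continuum_class == "paradox"]
  tab <- naturalizations |>
    dplyr::distinct(.data$country_code, .data$species) |>
    dplyr::group_by(.data$country_code) |>
    dplyr::summarise(n_naturalized = dplyr::n(),
                     n_paradox = sum(.data$species %in% par_sp),
                     .groups = "drop") |>
    dplyr::mutate(pct = ifelse(.data$n_naturalized > 0,
                               100 * .data$n_paradox / .data$n_naturalized,
                               NA_real_))
  attr(tab, "mean_pct") <- mean(tab$pct, na.rm = TRUE)
  attr(tab, "n_over_50") <- sum(tab$pct > 50, na.rm = TRUE)
  tab
}

#' Family-level coverage of the conservation paradox
#'
#' Among families that contain at least one naturalized species, the share
#' that also contain at least one paradox species.
#'
#' @param classifications tibble from [classify_species()] run with a
#'   `checklist` (so the `family` column is present), or any tibble with
#'   `species`, `is_naturalized`, `continuum_class`, `family`.
#' @return list(`pct_families_with_paradox`, `per_family` tibble with
#'   `family`, `n_naturalized`, `n_paradox`, `has_paradox`).
#' @export
family_coverage <- function(classifications) {
  assert_columns(classifications, c("family", "is_naturalized",
                                    "continuum_class"), "classifications")
  per_family <- classifications |>
    dplyr::filter(!is.na(.data$family)) |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(
      n_naturalized = sum(.data$is_naturalized),
      n_paradox = sum(.data$continuum_class == "paradox"),
      .groups = "drop") |>
    dplyr::mutate(has_paradox = .data$n_paradox > 0)
  denom <- per_family[per_family$n_naturalized > 0, ]
  pct <- if (nrow(denom) == 0) NA_real_ else
    100 * sum(denom$has_paradox) / nrow(denom)
  list(pct_families_with_paradox = pct, per_family = per_family)
}
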