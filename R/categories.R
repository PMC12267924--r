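#' IUCN Red List category codes
#'
#' The closed set of standardized category codes used throughout the package:
#' EX (extinct), EW (extinct in the wild), CR, EN, VU, NT (near threatened),
#' LC (least concern), DD (data deficient), NE (not evaluated).
#'
#' @export
iucn_codes <- c("EX", "EW", "CR", "EN", "VU", "NT", "LC", "DD", "NE")

#' Threatened predicate on standardized categories
#'
#' A species-country listing counts as threatened when its standardized
#' category is EX, EW, CR, EN or VU; with `include_nt = TRUE`, NT as well.
#' LC, DD and NE are never threatened: absence of assessment is not threat.
#'
#' @param category character vector of codes from [iucn_codes].
#' @param include_nt also count Near Threatened (default `FALSE`).
#' @return logical vector.
#' @export
#' @examples
#' is_threatened(c("VU", "NT", "DD"))                  # TRUE FALSE FALSE
#' is_threatened("NT", include_nt = TRUE)              # TRUE
is_threatened <- function(category, include_nt = FALSE) {
  threat_set <- c("EX", "EW", "CR", "EN", "VU", if (include_nt) "NT")
  bad <- setdiff(unique(category), c(iucn_codes, NA))
  if (length(bad) > 0) {
    abort(sprintf("unknown IUCN code(s): %s (standardize first)",
                  paste(bad, collapse = ", ")),
          class = "natparadox_input_error")
  }
  !is.na(category) & category %in% threat_set
}

#' Read a national-category crosswalk
#'
#' Crosswalks are data, not code: a CSV with columns `schemeId`,
#' `nationalLabel`, `iucnCode` mapping each national Red List scheme's labels
#' onto standardized IUCN codes. A default crosswalk covering the identity
#' scheme, common long-form English labels and a German legacy scheme ships
#' with the package (`system.file("extdata", "crosswalks.csv", package =
#' "natparadox")`). Regionally Extinct ("RE") maps to EX by default.
#'
#' @param path CSV file path; default is the bundled crosswalk.
#' @return tibble (`scheme_id`, `label`, `code`).
#' @export
read_crosswalk <- function(path = system.file("extdata", "crosswalks.csv",
                                              package = "natparadox")) {
  cw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  assert_columns(cw, c("schemeId", "nationalLabel", "iucnCode"), "crosswalk")
  bad <- setdiff(unique(cw$iucnCode), iucn_codes)
  if (length(bad) > 0) {
    abort(sprintf("crosswalk targets invalid IUCN code(s): %s",
                  paste(bad, collapse = ", ")),
          class = "natparadox_input_error")
  }
  tibble::tibble(scheme_id = cw$schemeId, label = cw$nationalLabel,
                 code = cw$iucnCode)
}

#' Standardize national Red List labels to IUCN codes
#'
#' Deterministic lookup of `(scheme_id, label)` in a crosswalk. Labels absent
#' from the crosswalk map to `NE` with a warning naming the offending labels,
#' so that unassessable listings never satisfy the threatened predicate
#' silently.
#'
#' @param label character vector of national category labels.
#' @param crosswalk tibble from [read_crosswalk()].
#' @param scheme_id scheme identifier(s), length 1 or `length(label)`.
#' @return character vector of IUCN codes.
#' @export
#' @examples
#' cw <- tibble::tibble(scheme_id = "iucn", label = "CR", code = "CR")
#' standardize_category("CR", cw, "iucn")
standardize_category <- function(label, crosswalk, scheme_id = "iucn") {
  if (length(label) == 0) return(character())
  if (any(is.na(label) | !nzchar(trimws(label)))) {
    abort("empty national category label", class = "natparadox_input_error")
  }
  scheme_id <- rep_len(scheme_id, length(label))
  key <- paste(scheme_id, label, sep = "\r")
  lut <- setNames(crosswalk$code, paste(crosswalk$scheme_id, crosswalk$label, sep = "\r"))
  out <- unname(lut[key])
  unmapped <- is.na(out)
  if (any(unmapped)) {
    warn(sprintf("unmapped national label(s) set to NE: %s",
                 paste(unique(label[unmapped]), collapse = ", ")),
         class = "natparadox_unmapped_label")
    out[unmapped] <- "NE"
  }
  out
}

#' Standardize a national status table
#'
#' Applies [standardize_category()] row-wise to a raw status table
#' (`accepted_name`, `country_code`, `scheme_id`, `label`), yielding a
#' standardized status table (`accepted_name`, `country_code`, `category`).
#' Duplicate (species, country) rows keep the most severe category, with
#' severity ordered EX > EW > CR > EN > VU > NT > LC > DD > NE.
#'
#' @param statuses raw national status tibble.
#' @param crosswalk tibble from [read_crosswalk()].
#' @return standardized status tibble.
#' @export
standardize_statuses <- function(statuses, crosswalk) {
  assert_columns(statuses, c("accepted_name", "country_code", "scheme_id", "label"),
                 "status table")
  statuses$category <- standardize_category(statuses$label, crosswalk,
                                            statuses$scheme_id)
  sev <- match(statuses$category, iucn_codes) # 1 = most severe
  statuses |>
    dplyr::mutate(.sev = sev) |>
    dplyr::group_by(.data$accepted_name, .data$country_code) |>
    dplyr::slice_min(.data$.sev, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("accepted_name", "country_code", "category")
}
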