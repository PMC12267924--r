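#' Clean point occurrence records
#'
#' Standard hygiene filters applied before any AOO computation, in order:
#'
#' 1. `coordinate_missing` — missing or non-finite longitude/latitude;
#' 2. `coordinate_range` — |lat| > 90 or |lon| > 180;
#' 3. `zero_coordinates` — exact (0, 0) points (a classic database artefact);
#' 4. `outside_country` — coordinates falling outside the stated country's
#'    polygon beyond a tolerance (default 0.1 degrees, absorbing coastal
#'    jitter); records with a country code absent from the polygon set are
#'    dropped under the same rule;
#' 5. `duplicate` — exact duplicate (species, lon, lat) rows.
#'
#' Country membership is taken from the record's country-code column and
#' validated against the polygons rather than recomputed by point-in-polygon
#' alone, mirroring the structure of Darwin-Core downloads.
#'
#' @param occurrences tibble (`species`, `lon`, `lat`, `country_code`, and
#'   optionally `establishment_means`).
#' @param countries country bounding boxes, as from
#'   [read_countries_geojson()].
#' @param tolerance_deg degrees of slack for the country check (default 0.1).
#' @return list(`data` = retained rows, `drops` = tibble (`rule`, `n`) with
#'   one row per rule in application order).
#' @export
clean_occurrences <- function(occurrences, countries, tolerance_deg = 0.1) {
  assert_columns(occurrences, c("species", "lon", "lat", "country_code"),
                 "occurrence table")
  assert_columns(countries, c("country_code", "xmin", "xmax", "ymin", "ymax"),
                 "country table")
  df <- occurrences
  drops <- c(coordinate_missing = 0L, coordinate_range = 0L,
             zero_coordinates = 0L, outside_country = 0L, duplicate = 0L)

  bad <- !is.finite(df$lon) | !is.finite(df$lat)
  drops["coordinate_missing"] <- sum(bad)
  df <- df[!bad, ]

  bad <- abs(df$lat) > 90 | abs(df$lon) > 180
  drops["coordinate_range"] <- sum(bad)
  df <- df[!bad, ]

  bad <- df$lon == 0 & df$lat == 0
  drops["zero_coordinates"] <- sum(bad)
  df <- df[!bad, ]

  i <- match(df$country_code, countries$country_code)
  tol <- tolerance_deg
  inside <- !is.na(i) &
    df$lon >= countries$xmin[i] - tol & df$lon <= countries$xmax[i] + tol &
    df$lat >= countries$ymin[i] - tol & df$lat <= countries$ymax[i] + tol
  drops["outside_country"] <- sum(!inside)
  df <- df[inside, ]

  dup <- duplicated(df[, c("species", "lon", "lat")])
  drops["duplicate"] <- sum(dup)
  df <- df[!dup, ]

  list(data = df,
       drops = tibble::tibble(rule = names(drops), n = unname(drops)))
}
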