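#' Write a synthetic world to disk
#'
#' Serializes every table in the interchange formats used by the pipeline:
#' Darwin-Core-style occurrence CSV (`scientificName`, `decimalLongitude`,
#' `decimalLatitude`, `countryCode`, `establishmentMeans`), checklist CSV,
#' naturalization CSV, national/global status CSVs, countries as WGS84
#' GeoJSON polygons, the family tree as Newick, and the apomictic-genus list
#' as a one-column CSV. All CSVs are UTF-8, comma-separated, with a header
#' row and "." decimals.
#'
#' @param world a [generate_world()] result.
#' @param dir output directory (created if missing).
#' @return invisibly, a named character vector of the files written.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)

  occ <- tibble::tibble(
    scientificName = world$occurrences$species,
    decimalLongitude = world$occurrences$lon,
    decimalLatitude = world$occurrences$lat,
    countryCode = world$occurrences$country_code,
    establishmentMeans = world$occurrences$establishment_means
  )
  readr::write_csv(occ, p("occurrences.csv"), progress = FALSE)
  readr::write_csv(world$checklist, p("checklist.csv"), progress = FALSE)
  readr::write_csv(
    tibble::tibble(species = world$naturalizations$species,
                   countryCode = world$naturalizations$country_code),
    p("naturalizations.csv"), progress = FALSE)
  readr::write_csv(
    tibble::tibble(species = world$national_statuses$species,
                   countryCode = world$national_statuses$country_code,
                   schemeId = world$national_statuses$scheme_id,
                   nationalLabel = world$national_statuses$label),
    p("national_statuses.csv"), progress = FALSE)
  readr::write_csv(
    tibble::tibble(species = world$global_statuses$species,
                   iucnCode = world$global_statuses$category),
    p("global_statuses.csv"), progress = FALSE)
  readr::write_csv(tibble::tibble(genus = world$apomictic_genera),
                   p("apomictic_genera.csv"), progress = FALSE)
  write_countries_geojson(world$countries, p("countries.geojson"))
  if (!is.null(world$family_tree)) {
    ape::write.tree(world$family_tree, p("family_tree.nwk"))
  }
  files <- c(occurrences = p("occurrences.csv"), checklist = p("checklist.csv"),
             naturalizations = p("naturalizations.csv"),
             national_statuses = p("national_statuses.csv"),
             global_statuses = p("global_statuses.csv"),
             apomictic_genera = p("apomictic_genera.csv"),
             countries = p("countries.geojson"),
             family_tree = p("family_tree.nwk"))
  invisible(files[file.exists(files)])
}

#' Write country rectangles as GeoJSON
#'
#' Emits a WGS84 FeatureCollection of axis-aligned polygon features with a
#' `countryCode` property each.
#'
#' @param countries tibble (`country_code`, `xmin`, `xmax`, `ymin`, `ymax`).
#' @param path output file.
#' @export
write_countries_geojson <- function(countries, path) {
  features <- purrr::pmap(countries, function(country_code, xmin, xmax, ymin, ymax) {
    ring <- list(c(xmin, ymin), c(xmax, ymin), c(xmax, ymax),
                 c(xmin, ymax), c(xmin, ymin))
    list(
      type = "Feature",
      properties = list(countryCode = country_code),
      geometry = list(type = "Polygon", coordinates = list(ring))
    )
  })
  fc <- list(type = "FeatureCollection",
             crs = list(type = "name",
                        properties = list(name = "urn:ogc:def:crs:OGC:1.3:CRS84")),
             features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read country rectangles from GeoJSON
#'
#' Inverse of [write_countries_geojson()]: reads a FeatureCollection of
#' rectangular polygons back into the bounding-box tibble the cleaning and
#' placement code uses.
#'
#' @param path GeoJSON file.
#' @return tibble (`country_code`, `xmin`, `xmax`, `ymin`, `ymax`).
#' @export
read_countries_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  rows <- purrr::map(fc$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    xs <- vapply(ring, function(pt) as.numeric(pt[[1]]), numeric(1))
    ys <- vapply(ring, function(pt) as.numeric(pt[[2]]), numeric(1))
    tibble::tibble(country_code = f$properties$countryCode,
                   xmin = min(xs), xmax = max(xs),
                   ymin = min(ys), ymax = max(ys))
  })
  dplyr::bind_rows(rows)
}

#' Read a world from disk
#'
#' Reads the files written by [write_world()] back into a `synthetic_world`-
#' shaped list (without `config`/`truth`, which are generator-only).
#'
#' @param dir directory holding the files.
#' @return a list with the same table components as [generate_world()].
#' @export
read_world <- function(dir) {
  p <- function(f) file.path(dir, f)
  occ <- readr::read_csv(p("occurrences.csv"), col_types = "cddcc",
                         progress = FALSE)
  checklist <- readr::read_csv(p("checklist.csv"),
                               col_types = readr::cols(isHybrid = "l",
                                                       .default = "c"),
                               progress = FALSE)
  nat <- readr::read_csv(p("naturalizations.csv"), col_types = "cc",
                         progress = FALSE)
  nst <- readr::read_csv(p("national_statuses.csv"), col_types = "cccc",
                         progress = FALSE)
  gst <- readr::read_csv(p("global_statuses.csv"), col_types = "cc",
                         progress = FALSE)
  apo <- if (file.exists(p("apomictic_genera.csv"))) {
    readr::read_csv(p("apomictic_genera.csv"), col_types = "c",
                    progress = FALSE)$genus
  } else character()
  tree <- if (file.exists(p("family_tree.nwk"))) {
    ape::read.tree(p("family_tree.nwk"))
  } else NULL
  list(
    countries = read_countries_geojson(p("countries.geojson")),
    checklist = checklist,
    apomictic_genera = apo,
    naturalizations = tibble::tibble(species = nat$species,
                                     country_code = nat$countryCode),
    national_statuses = tibble::tibble(species = nst$species,
                                       country_code = nst$countryCode,
                                       scheme_id = nst$schemeId,
                                       label = nst$nationalLabel),
    global_statuses = tibble::tibble(species = gst$species,
                                     category = gst$iucnCode),
    occurrences = tibble::tibble(species = occ$scientificName,
                                 lon = occ$decimalLongitude,
                                 lat = occ$decimalLatitude,
                                 country_code = occ$countryCode,
                                 establishment_means = occ$establishmentMeans),
    family_tree = tree
  )
}
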