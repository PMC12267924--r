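#' Normalize a botanical name string for matching
#'
#' Dirty-data hygiene applied before any lookup: trim and collapse
#' whitespace, normalize hybrid markers ("x" as a standalone token becomes
#' the multiplication sign), strip author strings (tokens from the first
#' capitalized or bracketed token after the epithet onwards), lower-case the
#' epithet and capitalize only the genus.
#'
#' @param x character vector of raw names.
#' @return normalized character vector.
#' @export
#' @examples
#' normalize_name("  ABIES  alba Mill. ") # "Abies alba"
#' normalize_name("Salix x rubens")       # "Salix × rubens"
normalize_name <- function(x) {
  x <- stringr::str_squish(x)
  vapply(x, function(nm) {
    if (is.na(nm) || !nzchar(nm)) return(NA_character_)
    tokens <- strsplit(nm, " ", fixed = TRUE)[[1]]
    tokens[tokens %in% c("x", "X")] <- "×"
    is_marker <- tokens == "×"
    # genus = first token; epithet = first non-marker token after it;
    # everything after the epithet is authorship and is dropped.
    genus <- tokens[1]
    genus <- paste0(toupper(substr(genus, 1, 1)), tolower(substr(genus, 2, nchar(genus))))
    rest <- tokens[-1]
    if (length(rest) == 0) return(genus)
    epi_pos <- which(!is_marker[-1])[1]
    if (is.na(epi_pos)) return(paste(c(genus, rest), collapse = " "))
    keep <- rest[seq_len(epi_pos)]
    keep[epi_pos] <- tolower(keep[epi_pos])
    paste(c(genus, keep), collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

has_hybrid_marker <- function(x) {
  stringr::str_detect(x, stringr::fixed("×")) |
    stringr::str_detect(x, stringr::regex("(^|\\s)x\\s", ignore_case = TRUE))
}

#' Harmonize raw species names against a checklist
#'
#' Resolves raw names to accepted checklist names. Exact matches on accepted
#' names take precedence over synonym matches; anything else is unmatched.
#' Matching is on [normalize_name()]d strings, so case, spacing and author
#' citations do not matter. An optional fuzzy stage (off by default) rescues
#' near-misses at a normalized edit-similarity threshold, reporting them as
#' `match_kind = "fuzzy"`; silent fuzzy joins corrupt set intersections, so
#' the stage must be asked for explicitly.
#'
#' @param raw_names character vector of names as found in an input table.
#' @param checklist tibble with columns `rawName`, `acceptedName`, `status`
#'   (`"accepted"` or `"synonym"`), as written by [write_world()].
#' @param fuzzy enable the fuzzy stage (default `FALSE`).
#' @param fuzzy_threshold minimum normalized similarity `1 - dist/nchar`
#'   (default 0.95).
#' @return tibble (`raw_name`, `accepted_name`, `match_kind`), one row per
#'   distinct raw name in order of first appearance. `match_kind` is one of
#'   `exact`, `synonym`, `fuzzy`, `unmatched`; `accepted_name` is `NA` iff
#'   unmatched.
#' @export
harmonize_names <- function(raw_names, checklist, fuzzy = FALSE,
                            fuzzy_threshold = 0.95) {
  if (length(raw_names) == 0) {
    abort("raw_names must be non-empty", class = "natparadox_input_error")
  }
  assert_columns(checklist, c("rawName", "acceptedName", "status"), "checklist")
  if (!any(checklist$status == "accepted")) {
    abort("checklist has no accepted rows", class = "natparadox_input_error")
  }

  raw <- raw_names[!duplicated(raw_names)]
  norm <- normalize_name(raw)

  accepted <- checklist[checklist$status == "accepted", ]
  synonyms <- checklist[checklist$status == "synonym", ]
  acc_key <- normalize_name(accepted$acceptedName)
  syn_key <- normalize_name(synonyms$rawName)

  acc_lut <- setNames(accepted$acceptedName, acc_key)
  syn_lut <- setNames(synonyms$acceptedName, syn_key)

  hit_acc <- unname(acc_lut[norm])
  hit_syn <- unname(syn_lut[norm])

  accepted_name <- dplyr::coalesce(hit_acc, hit_syn)
  match_kind <- dplyr::case_when(
    !is.na(hit_acc) ~ "exact",
    !is.na(hit_syn) ~ "synonym",
    TRUE ~ "unmatched"
  )

  if (fuzzy && any(match_kind == "unmatched")) {
    idx <- which(match_kind == "unmatched")
    for (i in idx) {
      d <- utils::adist(norm[i], acc_key)[1, ]
      sim <- 1 - d / pmax(nchar(norm[i]), nchar(acc_key))
      j <- which.max(sim)
      if (length(j) == 1 && sim[j] >= fuzzy_threshold) {
        accepted_name[i] <- accepted$acceptedName[j]
        match_kind[i] <- "fuzzy"
        message(sprintf("fuzzy match: '%s' -> '%s' (similarity %.3f)",
                        raw[i], accepted$acceptedName[j], sim[j]))
      }
    }
  }

  tibble::tibble(raw_name = raw, accepted_name = accepted_name,
                 match_kind = match_kind)
}

#' Apply hybrid and apomict exclusion rules
#'
#' Drops species flagged as hybrids (checklist flag or a hybrid marker in
#' the name) and species in designated apomictic genera, returning both the
#' retained and the excluded sets so that counts always partition the input.
#'
#' @param species tibble with columns `accepted_name`, `genus`, `is_hybrid`.
#' @param apomictic_genera character vector of genus names treated as
#'   apomictic (data, not code: the membership list is an input).
#' @return list with tibbles `retained` and `excluded`; `excluded` gains a
#'   `reason` column (`"hybrid"` takes precedence over `"apomictic_genus"`).
#' @export
apply_exclusions <- function(species, apomictic_genera = character()) {
  assert_columns(species, c("accepted_name", "genus", "is_hybrid"), "species table")
  hybrid <- species$is_hybrid | has_hybrid_marker(species$accepted_name)
  apo <- species$genus %in% apomictic_genera
  drop <- hybrid | apo
  excluded <- species[drop, , drop = FALSE]
  excluded$reason <- ifelse(hybrid[drop], "hybrid", "apomictic_genus")
  list(retained = species[!drop, , drop = FALSE], excluded = excluded)
}

#' Apply a name mapping to an input table
#'
#' Replaces a raw-name column by accepted names using a mapping from
#' [harmonize_names()]. Rows whose names are unmatched are dropped and
#' counted, never silently propagated into downstream joins.
#'
#' @param df tibble with a name column.
#' @param mapping tibble from [harmonize_names()].
#' @param col name column (default `"species"`).
#' @return list(`data` with the column rewritten to accepted names,
#'   `n_unmatched` rows dropped).
#' @export
apply_name_mapping <- function(df, mapping, col = "species") {
  assert_columns(df, col, "table")
  lut <- setNames(mapping$accepted_name, mapping$raw_name)
  acc <- unname(lut[df[[col]]])
  keep <- !is.na(acc)
  out <- df[keep, , drop = FALSE]
  out[[col]] <- acc[keep]
  list(data = out, n_unmatched = sum(!keep))
}
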