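#' Build a run configuration
#'
#' A run takes either a synthetic-world block (a [world_config()]) or a
#' directory of real input files in the formats of [write_world()] —
#' exactly one of the two. Statistical options mirror the analysis stages.
#'
#' @param synthetic a [world_config()], or `NULL`.
#' @param input_dir directory with input files, or `NULL`.
#' @param include_nt count NT as threatened throughout.
#' @param cell_size_deg grid cell size (default 0.7).
#' @param ci_level confidence level for the major axis slope.
#' @param n_permutations permutations for the dispersion test.
#' @param bootstrap_ci use the bootstrap CI instead of the analytic one.
#' @param seed integer seed for every stochastic stage.
#' @return object of class `run_config`.
#' @export
run_config <- function(synthetic = NULL, input_dir = NULL, include_nt = FALSE,
                       cell_size_deg = 0.7, ci_level = 0.95,
                       n_permutations = 999, bootstrap_ci = FALSE, seed = 1L) {
  if (is.null(synthetic) == is.null(input_dir)) {
    abort("exactly one of `synthetic` and `input_dir` must be given",
          class = "natparadox_config_error")
  }
  if (!is.null(synthetic) && !inherits(synthetic, "world_config")) {
    abort("`synthetic` must be a world_config()",
          class = "natparadox_config_error")
  }
  structure(list(synthetic = synthetic, input_dir = input_dir,
                 include_nt = include_nt, cell_size_deg = cell_size_deg,
                 ci_level = ci_level, n_permutations = n_permutations,
                 bootstrap_ci = bootstrap_ci, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' The YAML mirrors [run_config()]: top-level keys `include_nt`,
#' `cell_size_deg`, `ci_level`, `n_permutations`, `bootstrap_ci`, `seed`,
#' and exactly one of `input_dir` or a `synthetic:` mapping whose keys are
#' [world_config()] arguments.
#'
#' @param path YAML file.
#' @return object of class `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  syn <- if (!is.null(y$synthetic)) do.call(world_config, y$synthetic)
  args <- y[setdiff(names(y), c("synthetic", "input_dir"))]
  do.call(run_config, c(list(synthetic = syn, input_dir = y$input_dir), args))
}

log_event <- function(log_path, stage, ...) {
  rec <- c(list(stage = stage), list(...))
  line <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  cat(line, "\n", file = log_path, sep = "", append = TRUE)
  message(sprintf("[%s] %s", stage,
                  paste(names(rec)[-1], unlist(rec[-1]), sep = "=",
                        collapse = " ")))
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
}

#' Run the full conservation-paradox pipeline
#'
#' Executes the stages in order — simulate (or load), harmonize names,
#' standardize categories, classify the continuum, gridded AOO partition,
#' range statistics, phylogenetic dispersion, summaries — and writes every
#' stage's artifact plus a manifest (input hashes, config echo, package
#' version, seed, per-stage row counts) and a JSON-lines log. A rerun with
#' the same config and seed is byte-identical.
#'
#' Artifacts written to `out_dir`: `harmonization_report.csv`,
#' `classifications.csv`, `prevalence.json`, `country_summary.csv`,
#' `family_counts.csv`, `aoo_partitions.csv`, `range_stats.json`,
#' `compensation.csv`, `pct_threatened_histogram.csv`,
#' `phylo_dispersion.json`, `manifest.json` (plus, for synthetic runs, the
#' generated input files under `world/`).
#'
#' @param config a [run_config()] or path to a YAML file.
#' @param out_dir output directory.
#' @param overwrite allow writing into a non-empty directory.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir, overwrite = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) {
    abort("config must be a run_config() or a YAML path",
          class = "natparadox_config_error")
  }
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !overwrite) {
    abort(sprintf("output directory %s is not empty (use overwrite = TRUE)",
                  out_dir), class = "natparadox_config_error")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  log_path <- p("run.log.jsonl")
  if (file.exists(log_path)) file.remove(log_path)
  grid <- grid_spec(config$cell_size_deg)
  counts <- list()

  ## stage: simulate / load --------------------------------------------
  if (!is.null(config$synthetic)) {
    world <- generate_world(config$synthetic)
    write_world(world, p("world"))
    input_dir <- p("world")
  } else {
    input_dir <- config$input_dir
  }
  world <- read_world(input_dir)
  input_files <- list.files(input_dir, full.names = TRUE)
  hashes <- tools::md5sum(sort(input_files))
  names(hashes) <- basename(names(hashes))
  log_event(log_path, "load", n_occurrences = nrow(world$occurrences),
            n_checklist = nrow(world$checklist))

  ## stage: harmonize ----------------------------------------------------
  raw_names <- unique(c(world$naturalizations$species,
                        world$national_statuses$species,
                        world$global_statuses$species,
                        world$occurrences$species))
  mapping <- harmonize_names(raw_names, world$checklist)
  readr::write_csv(
    tibble::tibble(rawName = mapping$raw_name,
                   acceptedName = mapping$accepted_name,
                   matchKind = mapping$match_kind),
    p("harmonization_report.csv"), progress = FALSE)

  species <- species_records(world$checklist)
  excl <- apply_exclusions(species, world$apomictic_genera)
  retained <- excl$retained
  keep_mapping <- mapping[!is.na(mapping$accepted_name) &
                            mapping$accepted_name %in% retained$accepted_name, ]

  nat <- apply_name_mapping(world$naturalizations, keep_mapping)
  nst <- apply_name_mapping(world$national_statuses, keep_mapping)
  gst <- apply_name_mapping(world$global_statuses, keep_mapping)
  occ_map <- apply_name_mapping(world$occurrences, keep_mapping)
  log_event(log_path, "harmonize",
            n_raw = nrow(mapping),
            n_unmatched = sum(mapping$match_kind == "unmatched"),
            n_excluded_species = nrow(excl$excluded),
            n_rows_dropped = nat$n_unmatched + nst$n_unmatched +
              gst$n_unmatched + occ_map$n_unmatched)

  ## stage: standardize --------------------------------------------------
  crosswalk <- read_crosswalk()
  statuses <- standardize_statuses(
    tibble::tibble(accepted_name = nst$data$species,
                   country_code = nst$data$country_code,
                   scheme_id = nst$data$scheme_id,
                   label = nst$data$label),
    crosswalk)
  log_event(log_path, "standardize", n_status_rows = nrow(statuses))

  ## stage: classify -----------------------------------------------------
  cls <- classify_species(nat$data, statuses, include_nt = config$include_nt,
                          checklist = retained)
  readr::write_csv(
    dplyr::rename(cls, acceptedName = "species"), p("classifications.csv"),
    progress = FALSE)
  prev <- prevalence(cls)
  cls_nt <- classify_species(nat$data, statuses, include_nt = TRUE,
                             checklist = retained)
  prev_nt <- prevalence(cls_nt)
  glob <- global_threat_share(cls, gst$data, include_nt = config$include_nt)
  class_counts <- as.list(table(cls$continuum_class))
  write_json_artifact(list(
    prevalence = prev, prevalence_with_nt = prev_nt,
    global_threat_share = glob, continuum_counts = class_counts
  ), p("prevalence.json"))
  log_event(log_path, "classify", n_species = nrow(cls),
            pct_paradox = prev$pct_reported)

  ctry <- country_summary(cls, nat$data)
  readr::write_csv(ctry, p("country_summary.csv"), progress = FALSE)
  fam <- family_coverage(cls)
  readr::write_csv(fam$per_family, p("family_counts.csv"), progress = FALSE)

  ## stage: AOO ----------------------------------------------------------
  cleaned <- clean_occurrences(occ_map$data, world$countries)
  log_event(log_path, "clean_occurrences",
            n_in = nrow(occ_map$data), n_out = nrow(cleaned$data),
            drops = sum(cleaned$drops$n))
  partitions <- partition_aoo(cleaned$data, statuses, nat$data, grid,
                              include_nt = config$include_nt)
  readr::write_csv(
    dplyr::rename(partitions, acceptedName = "species"),
    p("aoo_partitions.csv"), progress = FALSE)

  ## stage: range statistics --------------------------------------------
  paradox_sp <- cls$species[cls$continuum_class == "paradox"]
  pp <- partitions[partitions$species %in% paradox_sp, ]
  analysable <- pp[pp$aoo_naturalized > 0 & pp$aoo_native_threatened > 0, ]

  hist_sum <- pct_threatened_histogram(pp)
  readr::write_csv(hist_sum$bins, p("pct_threatened_histogram.csv"),
                   progress = FALSE)

  fit <- NULL; wil <- NULL; ba <- NULL
  if (nrow(analysable) >= 3) {
    lx <- log10(analysable$aoo_naturalized)
    ly <- log10(analysable$aoo_native_threatened)
    fit <- ma_regression(lx, ly, ci_level = config$ci_level,
                         ci_method = if (config$bootstrap_ci) "bootstrap" else "analytic")
    wil <- paired_wilcoxon(analysable$aoo_naturalized,
                           analysable$aoo_native_threatened)
    ba <- bland_altman(lx, ly)
  }
  comp <- classify_compensation(pp)
  readr::write_csv(
    dplyr::rename(comp$results, acceptedName = "species"),
    p("compensation.csv"), progress = FALSE)
  write_json_artifact(list(
    ma_regression = if (!is.null(fit)) unclass(fit),
    paired_wilcoxon = wil,
    bland_altman = if (!is.null(ba)) ba[c("mean_difference", "limits")],
    compensation = comp[c("pct_partial", "pct_net", "pct_partial_reported",
                          "pct_net_reported", "n_tie", "n_excluded_zero_aoo")],
    pct_native_threatened = hist_sum[c("mean", "median", "n", "n_excluded")]
  ), p("range_stats.json"))
  log_event(log_path, "range_stats", n_analysable = nrow(analysable))

  ## stage: phylogenetic dispersion --------------------------------------
  trait <- family_trait_table(cls)
  phylo <- NULL
  if (!is.null(world$family_tree)) {
    phylo <- lapply(
      c("n_families_with_paradox", "mean_pairwise_distance",
        "nearest_taxon_distance"),
      function(m) permutation_dispersion_test(
        world$family_tree, trait, metric = m,
        n_permutations = config$n_permutations, seed = config$seed))
    names(phylo) <- vapply(phylo, `[[`, "", "metric_name")
  }
  write_json_artifact(list(
    family_coverage_pct = family_coverage_pct(trait),
    tests = phylo
  ), p("phylo_dispersion.json"))
  log_event(log_path, "phylo", n_families = nrow(trait))

  ## manifest ------------------------------------------------------------
  manifest <- list(
    package_version = as.character(utils::packageVersion("natparadox")),
    seed = config$seed,
    config = config_echo(config),
    input_hashes = as.list(hashes),
    row_counts = list(
      occurrences_raw = nrow(world$occurrences),
      occurrences_clean = nrow(cleaned$data),
      species_classified = nrow(cls),
      paradox_species = length(paradox_sp),
      aoo_analysable = nrow(analysable)
    )
  )
  write_json_artifact(manifest, p("manifest.json"))
  log_event(log_path, "done", artifacts = length(list.files(out_dir)))
  invisible(manifest)
}

config_echo <- function(config) {
  out <- unclass(config)
  if (!is.null(out$synthetic)) out$synthetic <- unclass(out$synthetic)
  out
}
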