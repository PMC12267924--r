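#' Configuration of the synthetic world generator
#'
#' The generator emulates the joint structure of a vascular-plant checklist,
#' a naturalization database (species x country), national Red Lists
#' (species x country x category), a global Red List and point occurrence
#' records, with the statistical features the downstream analyses assume:
#'
#' * a target fraction `paradox_target` of naturalized species threatened in
#'   at least one native-range country (default 0.273);
#' * an additional `nt_only_target` fraction whose worst native listing is
#'   Near Threatened (default 0.038, so including NT raises prevalence by
#'   about 4 percentage points);
#' * per-species fractions of native area of occupancy that are threatened
#'   drawn from a right-skewed Beta distribution (default shapes give mean
#'   ~0.136 and median ~0.046);
#' * a log10-log10 allometry between threatened and naturalized AOO with
#'   slope `allometry_slope` (default 0.35) and Gaussian scatter
#'   `allometry_noise_sd` (default 0.5), anchored so the two AOO medians are
#'   about 37,000 and 61,000 km2.
#'
#' @param n_species number of accepted species (default 2000).
#' @param n_countries number of countries tiling the 60 x 40 degree region
#'   (default 24).
#' @param n_families number of plant families (default 60).
#' @param paradox_target fraction of naturalized species threatened
#'   (EX/EW/CR/EN/VU) in >= 1 native country.
#' @param nt_only_target additional fraction of naturalized species whose
#'   only native-range listing above LC is NT.
#' @param pct_threat_shape two positive Beta shape parameters for the
#'   per-species fraction of native AOO threatened.
#' @param allometry_slope log10-log10 slope linking threatened to
#'   naturalized AOO.
#' @param allometry_noise_sd log10 scatter around the allometry.
#' @param occ_per_species_mean mean occurrence count for background
#'   (non-paradox) species; counts are log-normal.
#' @param frac_naturalized fraction of species with naturalized populations.
#' @param threat_nonnat_rate fraction of non-naturalized species threatened
#'   somewhere in their native range (the net-loss pool).
#' @param global_threat_target fraction of naturalized species globally
#'   threatened (must not exceed `paradox_target`: global threat implies
#'   subglobal threat by construction).
#' @param apomict_frac fraction of genera designated apomictic.
#' @param seed integer seed; identical config + seed gives byte-identical
#'   worlds.
#' @return an object of class `world_config` (a validated list).
#' @export
world_config <- function(n_species = 2000,
                         n_countries = 24,
                         n_families = 60,
                         paradox_target = 0.273,
                         nt_only_target = 0.038,
                         pct_threat_shape = c(0.304, 1.931),
                         allometry_slope = 0.35,
                         allometry_noise_sd = 0.5,
                         occ_per_species_mean = 25,
                         frac_naturalized = 0.28,
                         threat_nonnat_rate = 0.8,
                         global_threat_target = 0.021,
                         apomict_frac = 0.02,
                         seed = 1L) {
  assert_scalar_number(n_species, "n_species", min = 1)
  assert_scalar_number(n_countries, "n_countries", min = 1)
  assert_scalar_number(n_families, "n_families", min = 1)
  assert_scalar_number(paradox_target, "paradox_target", min = 0, max = 1)
  assert_scalar_number(nt_only_target, "nt_only_target", min = 0, max = 1)
  if (!is.numeric(pct_threat_shape) || length(pct_threat_shape) != 2 ||
      any(!is.finite(pct_threat_shape)) || any(pct_threat_shape <= 0)) {
    abort("configuration field `pct_threat_shape` must be two positive shape parameters",
          class = "natparadox_config_error")
  }
  assert_scalar_number(allometry_slope, "allometry_slope", min = 1e-8)
  assert_scalar_number(allometry_noise_sd, "allometry_noise_sd", min = 0)
  assert_scalar_number(occ_per_species_mean, "occ_per_species_mean", min = 1e-8)
  assert_scalar_number(frac_naturalized, "frac_naturalized", min = 0, max = 1)
  assert_scalar_number(threat_nonnat_rate, "threat_nonnat_rate", min = 0, max = 1)
  assert_scalar_number(global_threat_target, "global_threat_target",
                       min = 0, max = 1)
  assert_scalar_number(apomict_frac, "apomict_frac", min = 0, max = 1)
  assert_scalar_number(seed, "seed", min = -2^31, max = 2^31)
  structure(list(
    n_species = as.integer(n_species), n_countries = as.integer(n_countries),
    n_families = as.integer(n_families), paradox_target = paradox_target,
    nt_only_target = nt_only_target, pct_threat_shape = pct_threat_shape,
    allometry_slope = allometry_slope, allometry_noise_sd = allometry_noise_sd,
    occ_per_species_mean = occ_per_species_mean,
    frac_naturalized = frac_naturalized,
    threat_nonnat_rate = threat_nonnat_rate,
    global_threat_target = global_threat_target,
    apomict_frac = apomict_frac, seed = as.integer(seed),
    # anchors of the AOO construction (log10 km2); the intercept places the
    # median threatened AOO at ~37,000 km2 given a median naturalized AOO of
    # ~61,000 km2 under the default slope
    nat_aoo_log_mean = 4.78, nat_aoo_log_sd = 0.65,
    allometry_intercept = log10(37066) - allometry_slope * log10(60593),
    region = c(lon_min = -30, lon_max = 30, lat_min = -20, lat_max = 20)
  ), class = "world_config")
}

# exact-count sampler: pick round(p * n) of n indices (randomized rounding of
# the fractional part). Keeps realized prevalences tight around their targets
# so small worlds still resemble the study conditions.
sample_fraction <- function(idx, p) {
  n <- length(idx)
  k <- floor(p * n) + (runif(1) < (p * n) %% 1)
  if (k <= 0) return(idx[0])
  safe_sample(idx, min(k, n))
}

country_rectangles <- function(cfg) {
  r <- cfg$region
  nc <- ceiling(sqrt(cfg$n_countries * 1.5))
  nr <- ceiling(cfg$n_countries / nc)
  codes <- paste0(rep(LETTERS, each = 26), rep(LETTERS, 26))
  grid <- expand.grid(ix = seq_len(nc), iy = seq_len(nr))[seq_len(cfg$n_countries), ]
  w <- (r["lon_max"] - r["lon_min"]) / nc
  h <- (r["lat_max"] - r["lat_min"]) / nr
  tibble::tibble(
    country_code = codes[seq_len(cfg$n_countries)],
    xmin = unname(r["lon_min"] + (grid$ix - 1) * w),
    xmax = unname(r["lon_min"] + grid$ix * w),
    ymin = unname(r["lat_min"] + (grid$iy - 1) * h),
    ymax = unname(r["lat_min"] + grid$iy * h)
  )
}

# cells of the default grid whose centre lies in each country; the jitter
# window is the intersection of cell and country so points never cross a
# border
world_cells <- function(cfg, grid) {
  countries <- country_rectangles(cfg)
  r <- cfg$region
  cs <- grid$cell_size_deg
  col_rng <- floor((c(r["lon_min"], r["lon_max"]) - grid$lon0) / cs)
  row_rng <- floor((c(r["lat_min"], r["lat_max"]) - grid$lat0) / cs)
  cells <- expand.grid(col = seq(col_rng[1], col_rng[2]),
                       row = seq(row_rng[1], row_rng[2]))
  ctr <- cell_centre(grid, cells$col, cells$row)
  cells <- tibble::as_tibble(cells)
  cells$lon <- ctr$lon
  cells$lat <- ctr$lat
  hit <- rep(NA_integer_, nrow(cells))
  for (i in seq_len(nrow(countries))) {
    inside <- is.na(hit) &
      cells$lon >= countries$xmin[i] & cells$lon < countries$xmax[i] &
      cells$lat >= countries$ymin[i] & cells$lat < countries$ymax[i]
    hit[inside] <- i
  }
  cells <- cells[!is.na(hit), ]
  cells$country_code <- countries$country_code[hit[!is.na(hit)]]
  # jitter window: cell clipped to the country rectangle
  ci <- hit[!is.na(hit)]
  cells$jx_min <- pmax(cells$lon - cs / 2, countries$xmin[ci])
  cells$jx_max <- pmin(cells$lon + cs / 2, countries$xmax[ci] - 1e-9)
  cells$jy_min <- pmax(cells$lat - cs / 2, countries$ymin[ci])
  cells$jy_max <- pmin(cells$lat + cs / 2, countries$ymax[ci] - 1e-9)
  cells
}

#' Latent AOO pair sampler
#'
#' Draws per-species (naturalized AOO, threatened AOO) pairs on the log10
#' scale along a major axis of slope `slope` through the anchor point
#' (log10 60593, log10 37066): a latent position `t` along the axis plus
#' independent Gaussian noise of sd `noise_sd` on *both* coordinates. With
#' isotropic noise the leading eigenvector of the population covariance is
#' the axis itself, so major axis regression is consistent for `slope` —
#' the model II error structure the analysis assumes (both AOOs are
#' estimates). The latent spread is chosen so the marginal sd of
#' log10(naturalized AOO) is `log_sd`. [generate_world()] realizes these
#' pairs as occurrence records on the grid; this sampler exposes the latent
#' pairs directly for calibration and recovery studies.
#'
#' @param n number of species pairs.
#' @param slope,intercept,noise_sd allometry parameters (defaults as in
#'   [world_config()]).
#' @param log_mean,log_sd centre and marginal sd of log10 naturalized AOO.
#' @return tibble (`log10_nat`, `log10_thr`).
#' @export
sample_aoo_pairs <- function(n, slope = 0.35,
                             intercept = log10(37066) - slope * log10(60593),
                             noise_sd = 0.5, log_mean = 4.78, log_sd = 0.65) {
  latent_sd <- sqrt(max(log_sd^2 - noise_sd^2, 0.04))
  t <- rnorm(n, 0, latent_sd)
  x <- log_mean + t + rnorm(n, 0, noise_sd)
  y <- intercept + slope * log_mean + slope * t + rnorm(n, 0, noise_sd)
  tibble::tibble(log10_nat = x, log10_thr = y)
}

# assign enough countries (shuffled pool) to hold n_cells cells; returns the
# country codes used, removing them from the caller's pool by reference-free
# bookkeeping (caller passes remaining pool)
take_countries <- function(pool, cap_per_country, n_cells) {
  need <- max(1L, ceiling(n_cells / cap_per_country))
  pool[seq_len(min(need, length(pool)))]
}

#' Generate a synthetic world
#'
#' Builds all input tables of the analysis from a [world_config()]:
#' rectangular countries tiling a 60 x 40 degree equator-centred region, a
#' checklist of accepted binomials with genera and families, naturalization
#' records, national and global Red List statuses (with raw labels drawn
#' from two schemes so the crosswalk stage is exercised), occurrence records
#' whose gridded AOO realizes the configured allometry, and a family-level
#' phylogeny. Identical config and seed give identical worlds.
#'
#' @param config a [world_config()].
#' @return an object of class `synthetic_world`: a list with tibbles
#'   `countries`, `checklist`, `naturalizations`, `national_statuses`,
#'   `global_statuses`, `occurrences`, the `family_tree` (an [ape::phylo]),
#'   the `config`, and `truth` (a tibble of per-species latent roles used by
#'   recovery tests).
#' @export
generate_world <- function(config) {
  if (!inherits(config, "world_config")) {
    abort("config must be created by world_config()",
          class = "natparadox_config_error")
  }
  cfg <- config
  grid <- grid_spec()
  countries <- country_rectangles(cfg)
  cells <- with_stream(cfg$seed, "cells", world_cells(cfg, grid))
  cap <- min(table(cells$country_code))

  ## taxonomy -----------------------------------------------------------
  tax <- with_stream(cfg$seed, "taxonomy", {
    families <- sprintf("F%02daceae", seq_len(cfg$n_families))
    fam_w <- 1 / seq_len(cfg$n_families)^1.6 # Zipf-like skew of family sizes
    n_genera <- max(cfg$n_families, ceiling(cfg$n_species / 8))
    genera <- sprintf("Genus%04d", seq_len(n_genera))
    genus_family <- sample(families, n_genera, replace = TRUE, prob = fam_w)
    apomicts <- sample(genera, max(0, round(cfg$apomict_frac * n_genera)))
    sp_genus <- sample(genera, cfg$n_species, replace = TRUE)
    list(
      species = tibble::tibble(
        accepted_name = sprintf("%s sp%05d", sp_genus, seq_len(cfg$n_species)),
        genus = sp_genus,
        family = genus_family[match(sp_genus, genera)],
        is_hybrid = FALSE,
        in_apomictic_genus = sp_genus %in% apomicts
      ),
      families = families, apomicts = apomicts
    )
  })
  species <- tax$species

  ## roles --------------------------------------------------------------
  roles <- with_stream(cfg$seed, "roles", {
    n <- cfg$n_species
    naturalized <- logical(n)
    naturalized[sample_fraction(seq_len(n), cfg$frac_naturalized)] <- TRUE
    idx_nat <- which(naturalized)
    paradox <- logical(n)
    paradox[sample_fraction(idx_nat, cfg$paradox_target)] <- TRUE
    rest <- setdiff(idx_nat, which(paradox))
    nt_only <- logical(n)
    if (cfg$paradox_target < 1 && length(rest) > 0) {
      p_nt <- min(1, cfg$nt_only_target / (1 - cfg$paradox_target))
      nt_only[sample_fraction(rest, p_nt)] <- TRUE
    }
    net_loss <- logical(n)
    idx_non <- which(!naturalized)
    net_loss[sample_fraction(idx_non, cfg$threat_nonnat_rate)] <- TRUE
    tibble::tibble(accepted_name = species$accepted_name,
                   naturalized = naturalized, paradox = paradox,
                   nt_only = nt_only, net_loss = net_loss)
  })

  ## ranges + AOO realization -------------------------------------------
  area_eq <- (grid$km_per_deg * grid$cell_size_deg)^2
  shp <- cfg$pct_threat_shape
  range_data <- with_stream(cfg$seed, "ranges", {
    n <- cfg$n_species
    pairs <- sample_aoo_pairs(n, cfg$allometry_slope, cfg$allometry_intercept,
                              cfg$allometry_noise_sd,
                              cfg$nat_aoo_log_mean, cfg$nat_aoo_log_sd)
    f <- pmin(pmax(rbeta(n, shp[1], shp[2]), 0.02), 0.98)
    n_nat <- pmax(1L, as.integer(round(10^pairs$log10_nat / area_eq)))
    n_thr <- pmax(1L, as.integer(round(10^pairs$log10_thr / area_eq)))
    n_ok <- pmin(pmax(0L, as.integer(round(n_thr * (1 - f) / f))), 2500L)
    list(f = f, n_nat = n_nat, n_thr = n_thr, n_ok = n_ok)
  })

  placement <- with_stream(cfg$seed, "placement", {
    cell_pool <- split(seq_len(nrow(cells)), cells$country_code)
    occ <- vector("list", cfg$n_species)
    nat_countries <- vector("list", cfg$n_species)
    native_thr <- vector("list", cfg$n_species)
    native_ok <- vector("list", cfg$n_species)

    pick_cells <- function(ctys, k) {
      pool <- unlist(cell_pool[ctys], use.names = FALSE)
      safe_sample(pool, min(k, length(pool)))
    }
    jitter_points <- function(cell_ids) {
      cc <- cells[cell_ids, ]
      tibble::tibble(
        lon = runif(nrow(cc), cc$jx_min, cc$jx_max),
        lat = runif(nrow(cc), cc$jy_min, cc$jy_max),
        country_code = cc$country_code
      )
    }

    for (i in seq_len(cfg$n_species)) {
      codes <- sample(countries$country_code)
      if (roles$paradox[i]) {
        thr_c <- take_countries(codes, cap, range_data$n_thr[i])
        codes <- setdiff(codes, thr_c)
        ok_c <- if (range_data$n_ok[i] > 0) {
          take_countries(codes, cap, range_data$n_ok[i])
        } else character()
        codes <- setdiff(codes, ok_c)
        # naturalized countries: enough capacity, with the same extra-country
        # distribution as other naturalized species
        need_nat <- max(ceiling(range_data$n_nat[i] / cap), 1L + rpois(1, 0.3))
        nat_c <- codes[seq_len(min(need_nat, length(codes)))]
        thr_cells <- pick_cells(thr_c, range_data$n_thr[i])
        ok_cells <- if (range_data$n_ok[i] > 0) pick_cells(ok_c, range_data$n_ok[i]) else integer()
        nat_cells <- pick_cells(nat_c, range_data$n_nat[i])
        pts_n <- jitter_points(c(thr_cells, ok_cells))
        pts_n$establishment_means <- "native"
        pts_i <- jitter_points(nat_cells)
        pts_i$establishment_means <- "introduced"
        occ[[i]] <- dplyr::bind_rows(pts_n, pts_i)
        native_thr[[i]] <- thr_c
        native_ok[[i]] <- ok_c
        nat_countries[[i]] <- nat_c
      } else {
        k_native <- min(1 + rpois(1, 2), length(codes) - 1)
        nat_v <- roles$naturalized[i]
        native_c <- codes[seq_len(max(1, k_native))]
        codes <- setdiff(codes, native_c)
        nat_c <- if (nat_v) codes[seq_len(min(1 + rpois(1, 0.3), length(codes)))] else character()
        if (roles$net_loss[i]) {
          f2 <- min(max(rbeta(1, shp[1], shp[2]), 0.02), 0.98)
          k_thr <- max(1, round(f2 * length(native_c)))
          native_thr[[i]] <- native_c[seq_len(k_thr)]
          native_ok[[i]] <- setdiff(native_c, native_thr[[i]])
        } else {
          native_thr[[i]] <- character()
          native_ok[[i]] <- native_c
        }
        n_occ <- pmax(1, round(rlnorm(1, log(cfg$occ_per_species_mean), 0.7)))
        n_home <- if (nat_v) ceiling(0.7 * n_occ) else n_occ
        home_cells <- pick_cells(native_c, n_home)
        pts <- jitter_points(home_cells)
        pts$establishment_means <- "native"
        if (nat_v && length(nat_c) > 0) {
          away_cells <- pick_cells(nat_c, max(1, n_occ - n_home))
          pts2 <- jitter_points(away_cells)
          pts2$establishment_means <- "introduced"
          pts <- dplyr::bind_rows(pts, pts2)
        }
        occ[[i]] <- pts
        nat_countries[[i]] <- nat_c
      }
    }
    list(occ = occ, nat_countries = nat_countries,
         native_thr = native_thr, native_ok = native_ok)
  })

  ## status tables ------------------------------------------------------
  # two national schemes: a plain IUCN-code scheme and a legacy long-label
  # scheme, so the crosswalk stage does real work
  legacy_labels <- c(EX = "Ausgestorben", CR = "Vom Aussterben bedroht",
                     EN = "Stark gefährdet", VU = "Gefährdet",
                     NT = "Vorwarnliste", LC = "Ungefährdet",
                     DD = "Daten unzureichend")
  statuses <- with_stream(cfg$seed, "statuses", {
    scheme_of <- setNames(
      sample(c("iucn", "legacy"), cfg$n_countries, replace = TRUE,
             prob = c(0.8, 0.2)),
      countries$country_code
    )
    rows <- vector("list", cfg$n_species)
    for (i in seq_len(cfg$n_species)) {
      thr_c <- placement$native_thr[[i]]
      ok_c <- placement$native_ok[[i]]
      cat_thr <- if (length(thr_c) > 0) {
        sample(c("CR", "EN", "VU", "EX"), length(thr_c), replace = TRUE,
               prob = c(0.20, 0.35, 0.42, 0.03))
      } else character()
      # incomplete assessment coverage: not every non-threatened native
      # country has a listing
      ok_keep <- ok_c[runif(length(ok_c)) < 0.6]
      cat_ok <- sample(c("LC", "DD", "NT"), length(ok_keep), replace = TRUE,
                       prob = c(0.90, 0.07, 0.03))
      if (roles$nt_only[i]) {
        # worst native listing is NT exactly
        cat_ok[cat_ok == "NT"] <- "LC"
        if (length(ok_keep) == 0) { ok_keep <- ok_c[1]; cat_ok <- "NT" }
        else cat_ok[1] <- "NT"
      } else if (!roles$paradox[i] && !roles$net_loss[i]) {
        cat_ok[cat_ok == "NT"] <- "LC"
      }
      cc <- c(thr_c, ok_keep)
      if (length(cc) == 0) next
      rows[[i]] <- tibble::tibble(
        species = species$accepted_name[i], country_code = cc,
        category = c(cat_thr, cat_ok)
      )
    }
    st <- dplyr::bind_rows(rows)
    st$scheme_id <- unname(scheme_of[st$country_code])
    st$label <- ifelse(st$scheme_id == "legacy",
                       unname(legacy_labels[st$category]), st$category)
    # the legacy scheme has no EW label; EW does not occur nationally here
    st[, c("species", "country_code", "scheme_id", "label")]
  })

  global <- with_stream(cfg$seed, "global", {
    n_nat_sp <- sum(roles$naturalized)
    idx_par <- which(roles$paradox)
    n_gt <- min(length(idx_par), round(cfg$global_threat_target * n_nat_sp))
    gt <- if (n_gt > 0) safe_sample(idx_par, n_gt) else integer()
    n_ew <- min(length(gt), max(0, round(7 / 9195 * n_nat_sp)))
    cat <- rep("LC", cfg$n_species)
    cat[sample(seq_len(cfg$n_species), round(0.3 * cfg$n_species))] <- "NE"
    if (n_gt > 0) {
      cat[gt] <- sample(c("CR", "EN", "VU"), n_gt, replace = TRUE,
                        prob = c(0.2, 0.35, 0.45))
      if (n_ew > 0) cat[gt[seq_len(n_ew)]] <- "EW"
    }
    # NT uplift: some additional paradox species are globally NT
    rest_par <- setdiff(idx_par, gt)
    n_nt <- min(length(rest_par), round(0.008 * n_nat_sp))
    if (n_nt > 0) cat[safe_sample(rest_par, n_nt)] <- "NT"
    tibble::tibble(species = species$accepted_name, category = cat)
  })

  naturalizations <- tibble::tibble(
    species = rep(species$accepted_name,
                  lengths(placement$nat_countries)),
    country_code = unlist(placement$nat_countries, use.names = FALSE)
  )

  occurrences <- dplyr::bind_rows(
    setNames(placement$occ, species$accepted_name), .id = "species"
  )
  occurrences <- occurrences[, c("species", "lon", "lat", "country_code",
                                 "establishment_means")]

  tree <- with_stream(cfg$seed, "tree", {
    if (cfg$n_families >= 2) {
      tr <- ape::rcoal(cfg$n_families, tip.label = sample(tax$families))
      tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
      tr
    } else {
      NULL
    }
  })

  checklist <- tibble::tibble(
    rawName = species$accepted_name,
    acceptedName = species$accepted_name,
    genus = species$genus,
    family = species$family,
    isHybrid = species$is_hybrid,
    status = "accepted"
  )

  structure(list(
    countries = countries,
    checklist = checklist,
    apomictic_genera = tax$apomicts,
    naturalizations = naturalizations,
    national_statuses = statuses,
    global_statuses = global,
    occurrences = occurrences,
    family_tree = tree,
    config = cfg,
    truth = dplyr::mutate(roles, pct_threat_drawn = range_data$f)
  ), class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(paste0(
    "<synthetic_world> %d species, %d countries, %d families\n",
    "  naturalizations: %d rows; national statuses: %d; occurrences: %d\n"),
    nrow(x$checklist[x$checklist$status == "accepted", ]),
    nrow(x$countries), x$config$n_families,
    nrow(x$naturalizations), nrow(x$national_statuses), nrow(x$occurrences)))
  invisible(x)
}

#' Inject taxonomic name noise into a world
#'
#' Replaces a fraction of species names in the naturalization and national
#' status tables by newly registered synonyms (the checklist gains the
#' synonym rows needed to invert the replacement), and marks a fraction of
#' species as hybrids. Half of the hybrids are marked only by the checklist
#' flag, half also carry the multiplication-sign marker in their name (the
#' name is rewritten consistently across all tables), so both detection
#' routes in [apply_exclusions()] are exercised.
#'
#' @param world a [generate_world()] result.
#' @param synonym_rate fraction of species whose table names become synonyms.
#' @param hybrid_rate fraction of species marked as hybrids.
#' @param seed integer seed.
#' @return a modified `synthetic_world`.
#' @export
inject_name_noise <- function(world, synonym_rate = 0.2, hybrid_rate = 0.05,
                              seed = 1L) {
  assert_scalar_number(synonym_rate, "synonym_rate", min = 0, max = 1)
  assert_scalar_number(hybrid_rate, "hybrid_rate", min = 0, max = 1)
  acc <- world$checklist[world$checklist$status == "accepted", ]

  with_stream(seed, "name_noise", {
    n <- nrow(acc)
    syn_idx <- sample_fraction(seq_len(n), synonym_rate)
    hyb_idx <- sample_fraction(seq_len(n), hybrid_rate)

    # synonyms: same genus, derived epithet -> unique raw names
    if (length(syn_idx) > 0) {
      syn_names <- paste0(acc$acceptedName[syn_idx], "oides")
      syn_rows <- tibble::tibble(
        rawName = syn_names, acceptedName = acc$acceptedName[syn_idx],
        genus = acc$genus[syn_idx], family = acc$family[syn_idx],
        isHybrid = FALSE, status = "synonym"
      )
      lut <- setNames(syn_names, acc$acceptedName[syn_idx])
      swap <- function(x) ifelse(x %in% names(lut), unname(lut[x]), x)
      world$naturalizations$species <- swap(world$naturalizations$species)
      world$national_statuses$species <- swap(world$national_statuses$species)
      world$checklist <- dplyr::bind_rows(world$checklist, syn_rows)
    }

    if (length(hyb_idx) > 0) {
      marked <- hyb_idx[seq_len(ceiling(length(hyb_idx) / 2))]
      flagged <- setdiff(hyb_idx, marked)
      world$checklist$isHybrid[
        world$checklist$acceptedName %in% acc$acceptedName[hyb_idx] &
          world$checklist$status == "accepted"] <- TRUE
      if (length(marked) > 0) {
        old <- acc$acceptedName[marked]
        new <- sub(" ", " ×", old, fixed = TRUE)
        relut <- setNames(new, old)
        ren <- function(x) ifelse(x %in% names(relut), unname(relut[x]), x)
        world$checklist$rawName <- ren(world$checklist$rawName)
        world$checklist$acceptedName <- ren(world$checklist$acceptedName)
        world$naturalizations$species <- ren(world$naturalizations$species)
        world$national_statuses$species <- ren(world$national_statuses$species)
        world$global_statuses$species <- ren(world$global_statuses$species)
        world$occurrences$species <- ren(world$occurrences$species)
        world$truth$accepted_name <- ren(world$truth$accepted_name)
      }
      invisible(flagged)
    }
    world
  })
}

#' Species records from a checklist
#'
#' Extracts the accepted rows of a checklist as the species-record table used
#' by [apply_exclusions()] and the family summaries.
#'
#' @param checklist checklist tibble (see [generate_world()]).
#' @return tibble (`accepted_name`, `genus`, `family`, `is_hybrid`).
#' @export
species_records <- function(checklist) {
  assert_columns(checklist, c("acceptedName", "genus", "family", "isHybrid",
                              "status"), "checklist")
  acc <- checklist[checklist$status == "accepted", ]
  tibble::tibble(accepted_name = acc$acceptedName, genus = acc$genus,
                 family = acc$family, is_hybrid = acc$isHybrid)
}
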