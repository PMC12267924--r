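test_that("identical config and seed give identical worlds", {
  cfg <- world_config(n_species = 150, seed = 42)
  w1 <- generate_world(cfg)
  w2 <- generate_world(cfg)
  expect_identical(w1$checklist, w2$checklist)
  expect_identical(w1$naturalizations, w2$naturalizations)
  expect_identical(w1$national_statuses, w2$national_statuses)
  expect_identical(w1$occurrences, w2$occurrences)
  expect_identical(ape::write.tree(w1$family_tree),
                   ape::write.tree(w2$family_tree))
})

test_that("config validation names the offending field", {
  expect_error(world_config(paradox_target = 1.2),
               "paradox_target", class = "natparadox_config_error")
  expect_error(world_config(n_species = 0), "n_species",
               class = "natparadox_config_error")
  expect_error(world_config(pct_threat_shape = c(-1, 2)),
               "pct_threat_shape", class = "natparadox_config_error")
  expect_error(generate_world(list()), class = "natparadox_config_error")
})

test_that("paradox_target = 0 produces no threatened naturalized species", {
  w <- generate_world(world_config(n_species = 200, paradox_target = 0,
                                   nt_only_target = 0, seed = 3))
  cls <- classify_species(w$naturalizations, std_statuses(w))
  expect_equal(sum(cls$continuum_class == "paradox"), 0)
})

test_that("world satisfies its geometric and referential invariants", {
  w <- test_world()
  # occurrences fall inside the polygon of their stated country
  i <- match(w$occurrences$country_code, w$countries$country_code)
  expect_false(anyNA(i))
  expect_true(all(
    w$occurrences$lon >= w$countries$xmin[i] &
      w$occurrences$lon <= w$countries$xmax[i] &
      w$occurrences$lat >= w$countries$ymin[i] &
      w$occurrences$lat <= w$countries$ymax[i]))
  # country rectangles are pairwise non-overlapping
  cc <- w$countries
  for (a in seq_len(nrow(cc) - 1)) {
    for (b in seq(a + 1, nrow(cc))) {
      overlap <- cc$xmin[a] < cc$xmax[b] & cc$xmax[a] > cc$xmin[b] &
        cc$ymin[a] < cc$ymax[b] & cc$ymax[a] > cc$ymin[b]
      expect_false(overlap)
    }
  }
  # every species in downstream tables appears in the checklist
  acc <- w$checklist$acceptedName[w$checklist$status == "accepted"]
  expect_true(all(w$naturalizations$species %in% acc))
  expect_true(all(w$national_statuses$species %in% acc))
  # native (assessed) and naturalized roles are exclusive per country
  expect_length(intersect(
    paste(w$naturalizations$species, w$naturalizations$country_code),
    paste(w$national_statuses$species, w$national_statuses$country_code)), 0)
})

test_that("realized paradox prevalence tracks its target across seeds", {
  prev <- vapply(1:20, function(s) {
    w <- generate_world(world_config(n_species = 300, seed = s))
    cls <- classify_species(w$naturalizations, std_statuses(w))
    prevalence(cls)$pct / 100
  }, numeric(1))
  n_nat <- 0.28 * 300
  se <- sqrt(0.273 * 0.727 / (20 * n_nat))
  expect_lt(abs(mean(prev) - 0.273), 2 * se + 1e-9)
})

test_that("synonym noise round-trips through harmonization", {
  w <- test_world(n = 300, seed = 9)
  noised <- inject_name_noise(w, synonym_rate = 0.3, hybrid_rate = 0, seed = 5)
  # some names really were replaced
  expect_gt(sum(!noised$naturalizations$species %in%
                  w$naturalizations$species), 0)
  m <- harmonize_names(unique(c(noised$naturalizations$species,
                                noised$national_statuses$species)),
                       noised$checklist)
  expect_true(all(m$match_kind != "unmatched"))
  mapped <- apply_name_mapping(noised$naturalizations, m)
  expect_equal(sort(unique(mapped$data$species)),
               sort(unique(w$naturalizations$species)))
  expect_equal(mapped$n_unmatched, 0)
})

test_that("synonym_rate = 0 leaves tables unchanged except hybrid flags", {
  w <- test_world(n = 300, seed = 9)
  noised <- inject_name_noise(w, synonym_rate = 0, hybrid_rate = 0, seed = 5)
  expect_identical(noised$naturalizations, w$naturalizations)
  expect_identical(noised$national_statuses, w$national_statuses)
})

test_that("hybrid marking hits the expected share and both detection routes", {
  w <- test_world(n = 500, seed = 10)
  noised <- inject_name_noise(w, synonym_rate = 0, hybrid_rate = 0.1, seed = 6)
  sp <- species_records(noised$checklist)
  n_hyb <- sum(sp$is_hybrid | grepl("×", sp$accepted_name, fixed = TRUE))
  expect_lt(abs(n_hyb - 50), 3 * sqrt(500 * 0.1 * 0.9))
  # some are flag-only, some are marker-carrying
  expect_gt(sum(sp$is_hybrid & !grepl("×", sp$accepted_name, fixed = TRUE)), 0)
  expect_gt(sum(grepl("×", sp$accepted_name, fixed = TRUE)), 0)
  out <- apply_exclusions(sp, noised$apomictic_genera)
  expect_false(any(grepl("×", out$retained$accepted_name, fixed = TRUE)))
})

test_that("latent AOO pairs sit on the configured major axis", {
  set.seed(77)
  p <- sample_aoo_pairs(50000)
  expect_lt(abs(mean(p$log10_nat) - 4.78), 0.02)
  expect_lt(abs(sd(p$log10_nat) - 0.65), 0.02)
  fit <- ma_regression(p$log10_nat, p$log10_thr)
  expect_lt(abs(fit$slope - 0.35), 0.02)
})

test_that("worlds round-trip through the on-disk interchange formats", {
  w <- test_world(n = 150, seed = 12)
  dir <- withr::local_tempdir()
  write_world(w, dir)
  back <- read_world(dir)
  expect_equal(back$naturalizations, w$naturalizations)
  expect_equal(back$checklist$acceptedName, w$checklist$acceptedName)
  expect_equal(back$countries, w$countries)
  expect_equal(nrow(back$occurrences), nrow(w$occurrences))
  expect_equal(back$occurrences$lon, w$occurrences$lon, tolerance = 1e-12)
  expect_setequal(back$family_tree$tip.label, w$family_tree$tip.label)
})
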