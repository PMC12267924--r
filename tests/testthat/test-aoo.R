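# minimal fixture: two countries on the equator, one threatened for the
# species, one not; a third country where it is naturalized
aoo_fixture <- function() {
  statuses <- tibble::tibble(
    accepted_name = "Genus alpha",
    country_code = c("TT", "OK"),
    category = c("EN", "LC"))
  naturalizations <- tibble::tibble(species = "Genus alpha",
                                    country_code = "NZ")
  list(statuses = statuses, naturalizations = naturalizations)
}

# one point per distinct 0.7-degree cell on the equator row (row of lat 0.1),
# so every cell has identical area
equator_points <- function(n, start_col = 0) {
  tibble::tibble(lon = (start_col + seq_len(n) - 1) * 0.7 + 0.35, lat = 0.1)
}

test_that("occurrences route to partitions and the percentage follows", {
  fx <- aoo_fixture()
  pts_thr <- equator_points(4)
  pts_ok <- equator_points(12, start_col = 10)
  pts_nat <- equator_points(3, start_col = 30)
  occ <- dplyr::bind_rows(
    dplyr::mutate(pts_thr, country_code = "TT", establishment_means = "native"),
    dplyr::mutate(pts_ok, country_code = "OK", establishment_means = "native"),
    dplyr::mutate(pts_nat, country_code = "NZ", establishment_means = "introduced"))
  occ$species <- "Genus alpha"
  out <- partition_aoo(occ, fx$statuses, fx$naturalizations)
  expect_equal(out$n_cells_native_threatened, 4)
  expect_equal(out$n_cells_native_ok, 12)
  expect_equal(out$n_cells_naturalized, 3)
  # equal-area cells: 4 of 16 native cells threatened -> 25.0%
  expect_equal(out$pct_native_threatened, 25)
  expect_equal(round_half_up(out$pct_native_threatened, 1), 25.0)
})

test_that("all-threatened and no-threatened native ranges give 100% and 0%", {
  fx <- aoo_fixture()
  occ <- dplyr::mutate(equator_points(5), species = "Genus alpha",
                       country_code = "TT", establishment_means = "native")
  out <- partition_aoo(occ, fx$statuses, fx$naturalizations)
  expect_equal(out$pct_native_threatened, 100)
  occ$country_code <- "OK"
  out <- partition_aoo(occ, fx$statuses, fx$naturalizations)
  expect_equal(out$pct_native_threatened, 0)
})

test_that("species without native occurrences get an absent percentage", {
  fx <- aoo_fixture()
  occ <- dplyr::mutate(equator_points(2), species = "Genus alpha",
                       country_code = "NZ", establishment_means = "introduced")
  out <- partition_aoo(occ, fx$statuses, fx$naturalizations)
  expect_true(is.na(out$pct_native_threatened))
  expect_gt(out$aoo_naturalized, 0)
})

test_that("role-less occurrences land in the unresolved bin", {
  fx <- aoo_fixture()
  occ <- tibble::tibble(
    species = "Genus alpha",
    lon = c(0.35, 1.05), lat = 0.1,
    country_code = c("ZZ", "NZ"),
    establishment_means = c("introduced", "native"))
  out <- partition_aoo(occ, fx$statuses, fx$naturalizations)
  expect_equal(out$n_unresolved, 2)
  expect_equal(out$aoo_native_threatened + out$aoo_native_ok +
                 out$aoo_naturalized, 0)
})

test_that("a cell shared by threatened and ok native points counts in both", {
  fx <- aoo_fixture()
  occ <- tibble::tibble(
    species = "Genus alpha",
    lon = c(0.3, 0.4), lat = 0.1,
    country_code = c("TT", "OK"),
    establishment_means = "native")
  out <- partition_aoo(occ, fx$statuses, fx$naturalizations)
  expect_equal(out$n_cells_native_threatened, 1)
  expect_equal(out$n_cells_native_ok, 1)
  expect_equal(out$n_cells_straddling, 1)
  expect_gte(out$aoo_native_threatened + out$aoo_native_ok,
             cell_area_km2(grid_spec(), cell_index(grid_spec(), 0.3, 0.1)$row))
})

test_that("AOO is monotone in occurrences and invariant to row order", {
  fx <- aoo_fixture()
  set.seed(8)
  base <- tibble::tibble(
    species = "Genus alpha",
    lon = runif(40, 0, 20), lat = runif(40, -5, 5),
    country_code = sample(c("TT", "OK"), 40, replace = TRUE),
    establishment_means = "native")
  out1 <- partition_aoo(base, fx$statuses, fx$naturalizations)
  more <- dplyr::bind_rows(base, dplyr::mutate(base[1:10, ], lon = lon + 15))
  out2 <- partition_aoo(more, fx$statuses, fx$naturalizations)
  for (col in c("aoo_native_threatened", "aoo_native_ok", "aoo_naturalized")) {
    expect_gte(out2[[col]], out1[[col]])
  }
  shuffled <- base[sample(nrow(base)), ]
  expect_equal(partition_aoo(shuffled, fx$statuses, fx$naturalizations), out1)
})

test_that("include_nt reroutes NT-listed countries to the threatened side", {
  statuses <- tibble::tibble(accepted_name = "Genus alpha",
                             country_code = "TT", category = "NT")
  occ <- dplyr::mutate(equator_points(4), species = "Genus alpha",
                       country_code = "TT", establishment_means = "native")
  nat <- tibble::tibble(species = character(), country_code = character())
  expect_equal(partition_aoo(occ, statuses, nat)$pct_native_threatened, 0)
  expect_equal(partition_aoo(occ, statuses, nat,
                             include_nt = TRUE)$pct_native_threatened, 100)
})
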