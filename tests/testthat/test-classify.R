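classify_fixture <- function() {
  nat <- tibble::tibble(
    species = c("A a", "A a", "C c"),
    country_code = c("X1", "X2", "X3"))
  st <- tibble::tibble(
    accepted_name = c("A a", "B b", "C c"),
    country_code = c("N1", "N1", "N2"),
    category = c("VU", "EN", "LC"))
  list(nat = nat, st = st)
}

test_that("continuum classes follow the naturalized x threatened contract", {
  fx <- classify_fixture()
  cls <- classify_species(fx$nat, fx$st)
  got <- setNames(cls$continuum_class, cls$species)
  expect_equal(unname(got["A a"]), "paradox")      # naturalized + VU native
  expect_equal(unname(got["B b"]), "net_loss")     # EN native, never naturalized
  expect_equal(unname(got["C c"]), "net_increase") # naturalized, LC native
  # class counts partition the species set
  expect_equal(sum(table(cls$continuum_class)), nrow(cls))
})

test_that("same-country naturalized+assessed rows are a validation error", {
  nat <- tibble::tibble(species = "A a", country_code = "X1")
  st <- tibble::tibble(accepted_name = "A a", country_code = "X1",
                       category = "VU")
  expect_error(classify_species(nat, st), "A a",
               class = "natparadox_validation_error")
})

test_that("prevalence reproduces reported-style percentages", {
  fx <- classify_fixture()
  cls <- classify_species(fx$nat, fx$st)
  pr <- prevalence(cls)
  expect_equal(pr$n_naturalized, 2)
  expect_equal(pr$n_paradox, 1)
  expect_equal(pr$pct, 50)
  none <- cls[cls$continuum_class == "net_loss", ]
  expect_error(prevalence(none), class = "natparadox_input_error")
})

test_that("NT inclusion can only raise prevalence", {
  w <- test_world()
  st <- std_statuses(w)
  p0 <- prevalence(classify_species(w$naturalizations, st))
  p1 <- prevalence(classify_species(w$naturalizations, st, include_nt = TRUE))
  expect_gte(p1$pct, p0$pct)
  expect_gte(p1$n_paradox, p0$n_paradox)
})

test_that("global threat share counts naturalized species on the global list", {
  cls <- tibble::tibble(
    species = sprintf("S sp%03d", 1:250),
    is_naturalized = c(rep(TRUE, 200), rep(FALSE, 50)),
    is_threatened_native = FALSE,
    continuum_class = "net_increase")
  glob <- tibble::tibble(
    species = sprintf("S sp%03d", 1:250),
    category = c(rep("CR", 2), rep("EN", 1), rep("VU", 1), rep("LC", 246)))
  out <- global_threat_share(cls, glob)
  expect_equal(out$n_naturalized, 200)
  expect_equal(out$n_globally_threatened, 4)
  expect_equal(out$pct, 2.0)
  expect_equal(out$n_ew, 0)
  # monotone in NT; all-LC gives zero
  glob$category[10] <- "NT"
  expect_gte(global_threat_share(cls, glob, include_nt = TRUE)$pct,
             global_threat_share(cls, glob)$pct)
  glob$category <- "LC"
  expect_equal(global_threat_share(cls, glob)$pct, 0)
})

test_that("global share stays below subglobal prevalence in generated worlds", {
  w <- test_world()
  st <- std_statuses(w)
  cls <- classify_species(w$naturalizations, st)
  expect_lte(global_threat_share(cls, w$global_statuses)$pct,
             prevalence(cls)$pct)
})

test_that("country summaries match an independent group-by recount", {
  w <- test_world()
  st <- std_statuses(w)
  cls <- classify_species(w$naturalizations, st)
  cs <- country_summary(cls, w$naturalizations)
  paradox_set <- cls$species[cls$continuum_class == "paradox"]
  for (ct in cs$country_code[1:8]) {
    sp <- unique(w$naturalizations$species[w$naturalizations$country_code == ct])
    expect_equal(cs$n_naturalized[cs$country_code == ct], length(sp))
    expect_equal(cs$n_paradox[cs$country_code == ct],
                 sum(sp %in% paradox_set))
  }
  expect_equal(attr(cs, "mean_pct"), mean(cs$pct, na.rm = TRUE))
})

test_that("family coverage uses naturalized families as its denominator", {
  cls <- tibble::tibble(
    species = sprintf("S sp%03d", 1:100),
    is_naturalized = TRUE,
    is_threatened_native = rep(c(TRUE, FALSE), c(37, 63)),
    continuum_class = rep(c("paradox", "net_increase"), c(37, 63)),
    family = sprintf("F%02d", c(1:37, rep(38:50, length.out = 63))))
  out <- family_coverage(cls)
  expect_equal(out$pct_families_with_paradox, 100 * 37 / 50)
  expect_equal(round_half_up(out$pct_families_with_paradox, 1), 74.0)
  # degenerate cases
  cls$continuum_class <- "net_increase"
  expect_equal(family_coverage(cls)$pct_families_with_paradox, 0)
  one <- cls[1, ]
  one$continuum_class <- "paradox"
  expect_equal(family_coverage(one)$pct_families_with_paradox, 100)
})
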