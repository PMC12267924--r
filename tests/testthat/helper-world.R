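# shared fixtures, built in code and cached for the session

.world_cache <- new.env(parent = emptyenv())

test_world <- function(n = 800, seed = 42, ...) {
  key <- paste(n, seed, ...)
  if (is.null(.world_cache[[key]])) {
    .world_cache[[key]] <- generate_world(
      world_config(n_species = n, seed = seed, ...))
  }
  .world_cache[[key]]
}

raw_statuses <- function(world) {
  tibble::tibble(accepted_name = world$national_statuses$species,
                 country_code = world$national_statuses$country_code,
                 scheme_id = world$national_statuses$scheme_id,
                 label = world$national_statuses$label)
}

std_statuses <- function(world) {
  standardize_statuses(raw_statuses(world), read_crosswalk())
}

tiny_checklist <- function() {
  tibble::tibble(
    rawName = c("Abies alba", "Picea abies", "Salix × rubens",
                "Abies pectinata", "Pinus montana"),
    acceptedName = c("Abies alba", "Picea abies", "Salix × rubens",
                     "Abies alba", "Pinus mugo"),
    genus = c("Abies", "Picea", "Salix", "Abies", "Pinus"),
    family = c("Pinaceae", "Pinaceae", "Salicaceae", "Pinaceae", "Pinaceae"),
    isHybrid = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    status = c("accepted", "accepted", "accepted", "synonym", "synonym")
  )
}

# exhaustive two-sided signed-rank p-value over all 2^n sign assignments
enum_wilcox_p <- function(d) {
  stopifnot(all(d != 0), !any(duplicated(abs(d))))
  n <- length(d)
  r <- rank(abs(d))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W <- as.vector(signs %*% r)
  w_obs <- sum(r[d > 0])
  pl <- mean(W <= w_obs)
  pu <- mean(W >= w_obs)
  min(1, 2 * min(pl, pu))
}

# brute-force perpendicular least-squares slope (grid + golden-section via
# optimize on the minimizing bracket)
perp_ss <- function(theta, x, y) {
  xc <- x - mean(x)
  yc <- y - mean(y)
  sum((-sin(theta) * xc + cos(theta) * yc)^2)
}

oracle_ma_slope <- function(x, y) {
  grid <- seq(-pi / 2 + 1e-6, pi / 2 - 1e-6, length.out = 4001)
  v <- vapply(grid, perp_ss, numeric(1), x = x, y = y)
  i <- which.min(v)
  lo <- grid[max(1, i - 2)]
  hi <- grid[min(length(grid), i + 2)]
  opt <- stats::optimize(perp_ss, c(lo, hi), x = x, y = y, tol = 1e-14)
  tan(opt$minimum)
}

# brute-force point-in-cell assignment over an explicit cell list
brute_force_cells <- function(grid, lon, lat) {
  cs <- grid$cell_size_deg
  cols <- seq(min(floor((lon - grid$lon0) / cs)), max(floor((lon - grid$lon0) / cs)))
  rows <- seq(min(floor((lat - grid$lat0) / cs)), max(floor((lat - grid$lat0) / cs)))
  out <- list()
  for (cc in cols) {
    for (rr in rows) {
      x0 <- grid$lon0 + cc * cs
      y0 <- grid$lat0 + rr * cs
      if (any(lon >= x0 & lon < x0 + cs & lat >= y0 & lat < y0 + cs)) {
        out[[length(out) + 1]] <- c(cc, rr)
      }
    }
  }
  m <- do.call(rbind, out)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}
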