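#' Family-level trait table
#'
#' Collapses species classifications to the family level: how many
#' naturalized species each family holds, and how many of them are paradox
#' cases.
#'
#' @param classifications tibble from [classify_species()] with a `family`
#'   column.
#' @return tibble (`family`, `n_naturalized`, `n_paradox`, `has_paradox`).
#' @export
family_trait_table <- function(classifications) {
  fc <- family_coverage(classifications)
  fc$per_family
}

#' Family coverage percentage
#'
#' Of the families containing at least one naturalized species, the
#' percentage that contain at least one paradox species.
#'
#' @param trait tibble from [family_trait_table()].
#' @return percentage (full precision).
#' @export
family_coverage_pct <- function(trait) {
  assert_columns(trait, c("family", "n_naturalized", "n_paradox"),
                 "family trait table")
  denom <- trait[trait$n_naturalized > 0, ]
  if (nrow(denom) == 0) {
    abort("no family contains naturalized species",
          class = "natparadox_input_error")
  }
  100 * sum(denom$n_paradox > 0) / nrow(denom)
}

#' Permutation test of phylogenetic dispersion of paradox families
#'
#' Asks whether the families containing paradox species are phylogenetically
#' clustered (or overdispersed) relative to chance. The null model holds
#' each family's naturalized richness fixed and redistributes the total
#' number of paradox species across families by multivariate hypergeometric
#' draws (equivalent to shuffling which naturalized species are paradox
#' cases), so every permutation conserves both margins.
#'
#' Metrics (computed on families with at least one paradox species):
#' * `n_families_with_paradox` — the coverage count;
#' * `mean_pairwise_distance` — mean patristic distance among those families;
#' * `nearest_taxon_distance` — mean distance to the nearest other paradox
#'   family.
#'
#' Branch lengths default to 1 when the tree has none. The p-value is
#' two-sided: `(1 + #{null >= obs}) / (1 + n_permutations)` and its lower
#' counterpart, the smaller tail doubled and capped at 1.
#'
#' @param tree an [ape::phylo] whose tips cover the trait table's families.
#' @param trait tibble from [family_trait_table()].
#' @param metric one of `"mean_pairwise_distance"` (default),
#'   `"nearest_taxon_distance"`, `"n_families_with_paradox"`.
#' @param n_permutations number of permutations (>= 99; default 999).
#' @param seed integer seed.
#' @return list(`observed`, `null_mean`, `null_sd`, `p_value`,
#'   `n_permutations`, `metric_name`).
#' @export
permutation_dispersion_test <- function(tree, trait,
                                        metric = c("mean_pairwise_distance",
                                                   "nearest_taxon_distance",
                                                   "n_families_with_paradox"),
                                        n_permutations = 999, seed = 1L) {
  metric <- match.arg(metric)
  assert_columns(trait, c("family", "n_naturalized", "n_paradox"),
                 "family trait table")
  if (n_permutations < 99) {
    abort("n_permutations must be >= 99", class = "natparadox_input_error")
  }
  trait <- trait[trait$n_naturalized > 0, ]
  missing <- setdiff(trait$family, tree$tip.label)
  if (length(missing) > 0) {
    abort(sprintf("families absent from the tree: %s",
                  paste(missing, collapse = ", ")),
          class = "natparadox_validation_error")
  }
  if (is.null(tree$edge.length)) tree$edge.length <- rep(1, nrow(tree$edge))
  dm <- cophenetic(tree)[trait$family, trait$family, drop = FALSE]

  metric_fun <- switch(metric,
    n_families_with_paradox = function(counts) sum(counts > 0),
    mean_pairwise_distance = function(counts) {
      i <- which(counts > 0)
      if (length(i) < 2) return(NA_real_)
      sub <- dm[i, i]
      mean(sub[lower.tri(sub)])
    },
    nearest_taxon_distance = function(counts) {
      i <- which(counts > 0)
      if (length(i) < 2) return(NA_real_)
      sub <- dm[i, i]
      diag(sub) <- Inf
      mean(apply(sub, 1, min))
    })

  observed <- metric_fun(trait$n_paradox)
  n_total <- sum(trait$n_paradox)

  # multivariate hypergeometric redistribution of the paradox total across
  # families, margins fixed
  slots <- rep(seq_len(nrow(trait)), trait$n_naturalized)
  null <- with_stream(seed, paste0("dispersion_", metric), {
    vapply(seq_len(n_permutations), function(i) {
      hit <- safe_sample(slots, min(n_total, length(slots)))
      metric_fun(tabulate(hit, nbins = nrow(trait)))
    }, numeric(1))
  })
  null_ok <- null[is.finite(null)]
  ge <- sum(null_ok >= observed)
  le <- sum(null_ok <= observed)
  p <- min(1, 2 * min((1 + ge) / (1 + length(null_ok)),
                      (1 + le) / (1 + length(null_ok))))
  list(observed = observed, null_mean = mean(null_ok), null_sd = sd(null_ok),
       p_value = p, n_permutations = n_permutations, metric_name = metric)
}
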