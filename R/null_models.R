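# Stratified null models. For each plot, the compared community fractions are
# redrawn from a habitat species pool (native pool when comparing aliens with
# natives; naturalized pool when comparing naturalized with invasive species),
# preserving fraction sizes, per-life-form counts and the cover multiset.
# Selection within a life-form stratum is uniform, proportional to habitat
# occurrence frequency, or proportional to the plot's Beals co-occurrence
# probability. Observed-vs-simulated statistics reduce to the deviation
# delta-D = observed D - mean(simulated D), and the empirical probability that
# a simulated E-distance is at least the observed one.

#' Beals smoothing index
#'
#' For plot i and species j, the Beals index is the mean, over the species k
#' present in i (excluding j itself), of the conditional co-occurrence rate
#' M_jk / N_k, where M_jk counts plots containing both j and k and N_k counts
#' plots containing k:
#' \deqn{b_{ij} = \frac{1}{S_i^{(j)}} \sum_{k \in i, k \ne j} M_{jk} / N_k}
#' It estimates the probability that species j occurs in plot i given the
#' plot's composition. The target species is excluded from its own prediction.
#'
#' @param pa binary plot x species presence matrix with dimnames; every
#'   species must occur at least once and every plot must contain a species.
#' @return A plot x species matrix of values in \[0, 1\].
#' @export
beals_index <- function(pa) {
  pa <- as.matrix(pa)
  if (!all(pa %in% c(0, 1))) abort("presence matrix must be binary")
  nk <- colSums(pa)
  if (any(nk == 0)) abort("species with zero occurrences: ",
                          paste(colnames(pa)[nk == 0], collapse = ", "))
  if (any(rowSums(pa) == 0)) abort("plots with no species present")
  m <- crossprod(pa)                    # species x species joint counts
  a <- sweep(m, 2, nk, `/`)             # a[j, k] = M_jk / N_k
  diag(a) <- 0                          # k != j
  num <- tcrossprod(pa, a)              # num[i, j] = sum_k pa[i,k] a[j,k]
  s <- rowSums(pa)
  denom <- matrix(s, nrow(pa), ncol(pa)) - pa   # S_i excluding j when present
  denom[denom == 0] <- 1                # plot whose only species is j itself
  b <- num / denom
  dimnames(b) <- dimnames(pa)
  pmin(pmax(b, 0), 1)
}

#' Build habitat species pools from plot data
#'
#' One pool per habitat: the species recorded in at least one plot of that
#' habitat, with status and life form from the registry and occurrence
#' frequency = number of that habitat's plots containing the species.
#'
#' @param plots long-format data.frame (`plot_id`, `habitat`, `species`, ...).
#' @param registry data.frame (`species`, `status`, `life_form`).
#' @return Named list of data.frames (`species`, `status`, `life_form`,
#'   `frequency`), one per habitat.
#' @export
build_species_pools <- function(plots, registry) {
  stopifnot(all(c("plot_id", "habitat", "species") %in% names(plots)))
  miss <- setdiff(unique(plots$species), registry$species)
  if (length(miss)) abort("species missing from registry: ",
                          paste(utils::head(miss, 5), collapse = ", "))
  lapply(split(plots, plots$habitat), function(ph) {
    freq <- table(unique(ph[, c("plot_id", "species")])$species)
    idx <- match(names(freq), registry$species)
    data.frame(species = names(freq),
               status = registry$status[idx],
               life_form = registry$life_form[idx],
               frequency = as.numeric(freq),
               stringsAsFactors = FALSE, row.names = NULL)
  })
}

# weights for candidates under one scheme; beals_row named by species
scheme_weights <- function(pool_sub, weighting, beals_row, floor = 1e-6) {
  switch(weighting,
    uniform = NULL,
    frequency = pool_sub$frequency,
    beals = {
      if (is.null(beals_row)) abort("beals weighting requires a beals_row")
      w <- beals_row[pool_sub$species]
      w[is.na(w)] <- 0
      if (all(w <= 0)) w[] <- 1       # degenerate row: fall back to uniform
      pmax(w, floor)
    },
    abort("unknown weighting scheme: ", weighting)
  )
}

#' Draw one simulated community fraction from a species pool
#'
#' Replaces each observed member with a species of the same life form drawn
#' without replacement from `pool` (sequential weighted draws), inheriting the
#' observed member's cover. Fraction size and per-life-form counts are
#' preserved exactly.
#'
#' @param members data.frame (`species`, `life_form`, `cover`) of the observed
#'   fraction.
#' @param pool habitat pool data.frame restricted to the source status (e.g.
#'   the native pool), columns `species`, `life_form`, `frequency`.
#' @param weighting `"uniform"`, `"frequency"` or `"beals"`.
#' @param beals_row named numeric vector of the plot's Beals values (only for
#'   `weighting = "beals"`).
#' @param exclude species ids that may not be drawn (used for joint disjoint
#'   redraws of two fractions).
#' @return data.frame like `members` with simulated species ids.
#' @export
draw_fraction <- function(members, pool, weighting = "uniform",
                          beals_row = NULL, exclude = character(0)) {
  out <- members
  for (g in unique(members$life_form)) {
    need <- which(members$life_form == g)
    cand <- pool[pool$life_form == g & !(pool$species %in% exclude), ,
                 drop = FALSE]
    if (nrow(cand) < length(need)) {
      abort("pool stratum exhausted for life form '", g, "' (need ",
            length(need), ", have ", nrow(cand), ")")
    }
    w <- scheme_weights(cand, weighting, beals_row)
    idx <- if (nrow(cand) == length(need)) seq_len(nrow(cand)) else
      sample.int(nrow(cand), length(need), prob = w)
    out$species[need] <- cand$species[idx]
  }
  out
}

#' Empirical overlap probability
#'
#' `(number of simulated E >= observed E + 1) / (number of simulations + 1)`.
#' Values near zero mean the observed fractions overlap less (larger
#' E-distance) than almost all simulated fraction pairs.
#'
#' @param observed_e observed E-distance.
#' @param simulated_e numeric vector of simulated E-distances.
#' @return Probability in \[1/(n+1), 1\].
#' @export
overlap_probability <- function(observed_e, simulated_e) {
  if (!length(simulated_e)) abort("no simulated E values")
  (sum(simulated_e >= observed_e) + 1) / (length(simulated_e) + 1)
}

comparison_spec <- function(comparison) {
  switch(comparison,
    native_vs_naturalized = list(ref = "native", cmp = "naturalized",
                                 source = "native"),
    native_vs_invasive = list(ref = "native", cmp = "invasive",
                              source = "native"),
    naturalized_vs_invasive = list(ref = "naturalized", cmp = "invasive",
                                   source = "naturalized"),
    abort("unknown comparison: ", comparison)
  )
}

#' Null-model simulation for one plot and one comparison
#'
#' Redraws the two compared fractions jointly and disjointly from the source
#' pool (`native` pool for comparisons against natives, `naturalized` pool for
#' the naturalized-vs-invasive comparison) `n_sim` times. In every replicate D
#' of each fraction is recomputed against the centroid of the simulated
#' reference fraction, and E between the two simulated fractions. Observed D
#' uses the observed reference-fraction centroid.
#'
#' @param members data.frame for one plot: `species`, `status`, `life_form`,
#'   `cover`.
#' @param pool the habitat's pool data.frame from [build_species_pools()].
#' @param coords standardized coordinates matrix (rownames = species) covering
#'   plot and pool species.
#' @param comparison one of `"native_vs_naturalized"`, `"native_vs_invasive"`,
#'   `"naturalized_vs_invasive"`.
#' @param n_sim number of simulations (paper default 999).
#' @param weighting pool weighting scheme, see [draw_fraction()].
#' @param beals_row plot's Beals values (for `weighting = "beals"`).
#' @param use_cover_weights logical; use sqrt(cover)-weighted D and E.
#' @param seed integer seed for this plot's stream.
#' @return A list of class `null_result`: observed/simulated summaries per
#'   fraction (`fractions` data.frame with `observed_d`, `mean_sim_d`,
#'   `delta_d`) plus `observed_e`, `p_e`, the per-replicate statistics
#'   (`sim_d`, `sim_e`) and drawn coordinate-row indices (`sim_ref_idx`,
#'   `sim_cmp_idx`, one replicate per row), `n_sim`, `weighting`,
#'   `comparison`. `NULL` if a required fraction is absent from the plot.
#' @export
simulate_plot <- function(members, pool, coords, comparison,
                          n_sim = 999, weighting = "uniform",
                          beals_row = NULL, use_cover_weights = FALSE,
                          seed = 1) {
  spec <- comparison_spec(comparison)
  ref_obs <- members[members$status == spec$ref, , drop = FALSE]
  cmp_obs <- members[members$status == spec$cmp, , drop = FALSE]
  if (!nrow(ref_obs) || !nrow(cmp_obs)) return(NULL)
  src_pool <- pool[pool$status == spec$source, , drop = FALSE]
  # feasibility: each life-form stratum must hold both fractions' joint counts
  need <- table(c(ref_obs$life_form, cmp_obs$life_form))
  have <- table(src_pool$life_form)[names(need)]
  have[is.na(have)] <- 0
  if (any(as.numeric(have) < as.numeric(need))) {
    short <- names(need)[as.numeric(have) < as.numeric(need)]
    return(structure(list(skipped = TRUE,
                          reason = paste0("pool stratum too small: ",
                                          paste(short, collapse = ", "))),
                     class = "null_result"))
  }
  cw <- function(m) if (use_cover_weights) m$cover else NULL
  xr <- coords[ref_obs$species, , drop = FALSE]
  xc <- coords[cmp_obs$species, , drop = FALSE]
  mu_obs <- native_centroid(xr, cw(ref_obs))
  obs_d_ref <- dispersion_d(xr, mu_obs, cw(ref_obs))
  obs_d_cmp <- dispersion_d(xc, mu_obs, cw(cmp_obs))
  obs_e <- e_distance(xr, xc, cw(ref_obs), cw(cmp_obs))

  # draw plan per life-form stratum: candidate coordinate rows and weights
  # are fixed across replicates; drawing the joint count per stratum and
  # splitting it (first the reference fraction's members, then the compared
  # fraction's) is the same process as sequential draws with exclusion.
  strata <- unique(c(ref_obs$life_form, cmp_obs$life_form))
  plan <- lapply(strata, function(g) {
    cand <- src_pool[src_pool$life_form == g, , drop = FALSE]
    list(rows = match(cand$species, rownames(coords)),
         w = scheme_weights(cand, weighting, beals_row),
         ref_at = which(ref_obs$life_form == g),
         cmp_at = which(cmp_obs$life_form == g))
  })
  nr <- nrow(ref_obs); nc_ <- nrow(cmp_obs)
  wr <- if (use_cover_weights) ref_obs$cover else NULL
  wc <- if (use_cover_weights) cmp_obs$cover else NULL
  ridx_mat <- matrix(0L, n_sim, nr)
  cidx_mat <- matrix(0L, n_sim, nc_)
  set.seed(seed)
  for (r in seq_len(n_sim)) {
    for (pl in plan) {
      k <- length(pl$ref_at) + length(pl$cmp_at)
      take <- if (length(pl$rows) == k) seq_len(k) else
        sample.int(length(pl$rows), k, prob = pl$w)
      ridx_mat[r, pl$ref_at] <- pl$rows[take[seq_along(pl$ref_at)]]
      if (length(pl$cmp_at)) {
        cidx_mat[r, pl$cmp_at] <-
          pl$rows[take[length(pl$ref_at) + seq_along(pl$cmp_at)]]
      }
    }
  }
  stats_ <- null_stats_cpp(coords, ridx_mat, cidx_mat,
                           fraction_weights(nr, wr),
                           fraction_weights(nc_, wc))
  sim_d_ref <- stats_$d_ref
  sim_d_cmp <- stats_$d_cmp
  sim_e <- stats_$e
  fr <- data.frame(
    fraction = c(spec$ref, spec$cmp),
    n = c(nrow(ref_obs), nrow(cmp_obs)),
    observed_d = c(obs_d_ref, obs_d_cmp),
    mean_sim_d = c(mean(sim_d_ref), mean(sim_d_cmp)),
    stringsAsFactors = FALSE)
  fr$delta_d <- fr$observed_d - fr$mean_sim_d
  structure(list(skipped = FALSE, fractions = fr, observed_e = obs_e,
                 p_e = overlap_probability(obs_e, sim_e),
                 sim_d = cbind(ref = sim_d_ref, cmp = sim_d_cmp),
                 sim_e = sim_e, sim_ref_idx = ridx_mat, sim_cmp_idx = cidx_mat,
                 n_sim = n_sim, weighting = weighting,
                 comparison = comparison, seed = seed),
            class = "null_result")
}

#' @export
print.null_result <- function(x, ...) {
  if (isTRUE(x$skipped)) {
    cat("null_result: skipped (", x$reason, ")\n", sep = "")
    return(invisible(x))
  }
  cat("null_result:", x$comparison, "| n_sim =", x$n_sim,
      "| weighting =", x$weighting, "\n")
  print(x$fractions, row.names = FALSE)
  cat(sprintf("observed E = %.4f, p_E = %.4f\n", x$observed_e, x$p_e))
  invisible(x)
}
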