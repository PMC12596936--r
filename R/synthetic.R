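# Synthetic vegetation-plot generator. Emulates the data structure the
# analysis consumes: a habitat species pool with native / naturalized /
# invasive species, life forms, eight functional traits on their raw
# measurement scales, and plots in which at least one native species co-occurs
# with at least one alien ("invaded plots"). Assembly scenarios control where
# alien species sit relative to the native trait centroid:
#   neutral   - aliens drawn from the same trait distribution as natives;
#   filtering - alien species means coincide with the native centroid
#               (environmental filtering: aliens cluster at the center);
#   eots      - naturalized species cluster at the centroid while invasive
#               species means are displaced by `alien_displacement` pooled-SD
#               units along random directions (edge of trait space).
# Under eots, invasive species keep unit scatter around their displaced
# means: in p dimensions a native point sits at expected radius ~sqrt(p)
# from the centroid, so a displaced mean with unit scatter (expected radius
# ~sqrt(d^2 + p)) exceeds the native expectation for any d > 0, whereas
# shrunken scatter around a displaced mean can land inside the native shell.

LIFE_FORMS <- c("macrophanerophyte", "nanophanerophyte", "chamaephyte",
                "herb", "epiphyte")

# raw-scale location/scale used to back-transform standardized draws; log10
# traits get raw = 10^(m + s * z), roughly matching magnitudes of a temperate
# flora (height ~0.5 m, seed mass ~1 mg, leaf area ~300 mm2, SLA ~20,
# LDMC ~250, genome size ~1000 Mbp).
TRAIT_BACKTRANSFORM <- data.frame(
  trait = c("height", "seed_mass", "leaf_area", "sla", "ldmc",
            "flowering_midpoint", "flowering_length", "genome_size"),
  m = c(-0.3, 0.0, 2.5, 1.3, 2.4, 6.5, 0.45, 3.0),
  s = c(0.45, 0.6, 0.5, 0.2, 0.15, 1.8, 0.18, 0.45),
  stringsAsFactors = FALSE
)

#' Configuration of a synthetic assembly scenario
#'
#' @param n_native,n_naturalized,n_invasive pool sizes per invasion status.
#' @param n_plots number of vegetation plots to generate.
#' @param richness_mean expected species per plot (truncated at >= 2).
#' @param lifeform_mix named proportions over life forms, summing to 1.
#' @param alien_displacement nonnegative distance (in pooled-trait SD units)
#'   of invasive species means from the native centroid under `eots`.
#' @param scenario one of `"neutral"`, `"filtering"`, `"eots"`.
#' @param trait_noise_sd SD of the scatter of alien species around their
#'   species mean under `filtering`, and of naturalized species under `eots`
#'   (natives, and invasive species under `eots`, always have unit SD).
#' @param cover_model list with `meanlog`, `sdlog` of the log-normal cover
#'   distribution, truncated to (0, 100].
#' @param status_mix named proportions of native/naturalized/invasive species
#'   within a plot (before enforcing co-occurrence).
#' @param n_habitats number of habitat labels plots are spread over.
#' @param seed integer seed.
#' @return A validated list of class `scenario_config`.
#' @export
scenario_config <- function(n_native = 150, n_naturalized = 40, n_invasive = 12,
                            n_plots = 200, richness_mean = 12,
                            lifeform_mix = c(herb = 0.85, chamaephyte = 0.05,
                                             nanophanerophyte = 0.05,
                                             macrophanerophyte = 0.05),
                            alien_displacement = 2,
                            scenario = c("neutral", "filtering", "eots"),
                            trait_noise_sd = 0.5,
                            cover_model = list(meanlog = 1.0, sdlog = 1.1),
                            status_mix = c(native = 0.75, naturalized = 0.18,
                                           invasive = 0.07),
                            n_habitats = 1, seed = 1) {
  scenario <- match.arg(scenario)
  cfg <- list(n_native = n_native, n_naturalized = n_naturalized,
              n_invasive = n_invasive, n_plots = n_plots,
              richness_mean = richness_mean, lifeform_mix = lifeform_mix,
              alien_displacement = alien_displacement, scenario = scenario,
              trait_noise_sd = trait_noise_sd, cover_model = cover_model,
              status_mix = status_mix, n_habitats = n_habitats, seed = seed)
  counts <- c(n_native, n_naturalized, n_invasive, n_plots, n_habitats)
  if (any(counts < 1) || any(counts != round(counts))) {
    abort("counts must be integers >= 1")
  }
  if (!is.finite(alien_displacement) || alien_displacement < 0) {
    abort("alien_displacement must be finite and >= 0")
  }
  if (richness_mean <= 0) abort("richness_mean must be positive")
  if (is.null(names(lifeform_mix)) ||
      !all(names(lifeform_mix) %in% LIFE_FORMS)) {
    abort("lifeform_mix names must be life forms: ",
          paste(LIFE_FORMS, collapse = ", "))
  }
  if (abs(sum(lifeform_mix) - 1) > 1e-9) abort("lifeform_mix must sum to 1")
  if (abs(sum(status_mix) - 1) > 1e-9) abort("status_mix must sum to 1")
  if (trait_noise_sd <= 0) abort("trait_noise_sd must be positive")
  structure(cfg, class = "scenario_config")
}

# back-transform a standardized-scale matrix to raw trait units
backtransform_traits <- function(z) {
  meta <- trait_metadata()
  bt <- TRAIT_BACKTRANSFORM
  raw <- z
  for (k in seq_len(nrow(bt))) {
    v <- bt$m[k] + bt$s[k] * z[, k]
    if (meta$log10[k]) {
      raw[, k] <- 10^v
    } else {
      raw[, k] <- pmin(pmax(round(v), 1), 12)  # ordinal month scale
    }
  }
  # flowering length is an integer month count in [1, 12] but stays log-flagged
  fl <- which(bt$trait == "flowering_length")
  raw[, fl] <- pmin(pmax(round(raw[, fl]), 1), 12)
  colnames(raw) <- bt$trait
  raw
}

#' Generate a habitat species pool (traits + registry)
#'
#' Native species' standardized trait vectors are multivariate normal around
#' the origin with identity covariance. Alien species follow the scenario
#' (see the module comment above). Raw trait values are back-transformed
#' (10^x for log10-flagged traits; months rounded to an integer 1-12 scale)
#' so that the preprocessing stage is exercised downstream.
#'
#' @param config a [scenario_config()].
#' @return A list with `traits` (raw trait data.frame), `registry`
#'   (data.frame: species, status, life_form) and `truth` (data.frame:
#'   species, displacement, plus the generated species mean per trait on the
#'   standardized scale).
#' @export
generate_pool <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(derive_seed(config$seed, "pool"))
  p <- nrow(trait_metadata())
  n <- c(native = config$n_native, naturalized = config$n_naturalized,
         invasive = config$n_invasive)
  status <- rep(names(n), n)
  total <- sum(n)
  species <- sprintf("sp_%s_%03d", substr(status, 1, 4), stats::ave(
    seq_len(total), status, FUN = seq_along))
  means <- matrix(0, total, p)
  noise_sd <- rep(1, total)
  alien <- status != "native"
  if (config$scenario == "filtering") {
    noise_sd[alien] <- config$trait_noise_sd
  } else if (config$scenario == "eots") {
    noise_sd[status == "naturalized"] <- config$trait_noise_sd
    inv <- which(status == "invasive")
    noise_sd[inv] <- 1
    u <- matrix(stats::rnorm(length(inv) * p), length(inv), p)
    u <- u / sqrt(rowSums(u^2))
    means[inv, ] <- config$alien_displacement * u
  }
  z <- means + matrix(stats::rnorm(total * p), total, p) * noise_sd
  raw <- backtransform_traits(z)
  traits <- data.frame(species = species, raw, stringsAsFactors = FALSE)
  lf_names <- names(config$lifeform_mix)
  life_form <- unlist(lapply(names(n), function(s) {
    k <- n[[s]]
    # deterministic rounded allocation so every status has every stratum
    cnt <- round(config$lifeform_mix * k)
    cnt[1] <- k - sum(cnt[-1])
    if (any(cnt < 0)) cnt <- table(factor(
      sample(lf_names, k, TRUE, config$lifeform_mix), levels = lf_names))
    rep(lf_names, cnt)
  }))
  registry <- data.frame(species = species, status = status,
                         life_form = life_form, stringsAsFactors = FALSE)
  truth <- data.frame(species = species,
                      displacement = sqrt(rowSums(means^2)), means,
                      stringsAsFactors = FALSE)
  names(truth)[-(1:2)] <- paste0("mean_", trait_metadata()$trait)
  list(traits = traits, registry = registry, truth = truth)
}

rcover <- function(n, cover_model) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rlnorm(n, cover_model$meanlog, cover_model$sdlog)
    out <- c(out, x[x <= 100])
  }
  out[seq_len(n)]
}

#' Generate invaded vegetation plots from a species pool
#'
#' Each plot draws a richness from a Poisson truncated at >= 2, splits it over
#' invasion statuses by `status_mix` (forcing at least one native and at least
#' one alien species, so every plot is an "invaded plot"), then draws species
#' without replacement from the status pool with selection probabilities
#' proportional to `lifeform_mix` spread evenly over each life-form stratum —
#' so the expected life-form composition follows the mix while species within
#' a stratum remain exchangeable (which the stratified null model assumes).
#' Percentage covers are log-normal truncated to (0, 100].
#'
#' @param pool result of [generate_pool()].
#' @param config a [scenario_config()].
#' @return A long-format data.frame: `plot_id`, `habitat`, `species`, `cover`.
#' @export
generate_plots <- function(pool, config) {
  stopifnot(inherits(config, "scenario_config"))
  reg <- pool$registry
  statuses <- c("native", "naturalized", "invasive")
  # per-species selection weight: life-form mix spread over the stratum
  by_status <- lapply(statuses, function(s) {
    sub <- reg[reg$status == s & reg$life_form %in% names(config$lifeform_mix), ,
               drop = FALSE]
    size <- table(sub$life_form)
    w <- config$lifeform_mix[sub$life_form] / as.numeric(size[sub$life_form])
    list(species = sub$species, w = as.numeric(w))
  })
  names(by_status) <- statuses
  rows <- vector("list", config$n_plots)
  habitats <- sprintf("H%02d", rep_len(seq_len(config$n_habitats),
                                       config$n_plots))
  for (i in seq_len(config$n_plots)) {
    plot_id <- sprintf("plot_%04d", i)
    set.seed(derive_seed(config$seed, paste0("plot:", plot_id)))
    rich <- max(2L, stats::rpois(1, config$richness_mean))
    ns <- as.vector(stats::rmultinom(1, rich, config$status_mix))
    names(ns) <- statuses
    if (ns["native"] == 0) { ns["native"] <- 1; ns <- dec_largest(ns, "native") }
    if (ns["naturalized"] + ns["invasive"] == 0) {
      ns["naturalized"] <- 1
      ns <- dec_largest(ns, "naturalized")
    }
    sel <- character(0)
    for (s in statuses) {
      if (ns[[s]] == 0) next
      cand <- by_status[[s]]
      if (length(cand$species) < ns[[s]]) {
        abort("status pool exhausted: ", s, " (need ", ns[[s]],
              ", have ", length(cand$species), ")")
      }
      pick <- cand$species[sample.int(length(cand$species), ns[[s]],
                                      prob = cand$w)]
      sel <- c(sel, pick)
    }
    rows[[i]] <- data.frame(plot_id = plot_id, habitat = habitats[i],
                            species = sel,
                            cover = rcover(length(sel), config$cover_model),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# decrement the largest other status after forcing one up, keeping richness
dec_largest <- function(ns, forced) {
  others <- setdiff(names(ns), forced)
  if (sum(ns) <= 2) return(ns)
  big <- others[which.max(ns[others])]
  if (ns[[big]] > 0) ns[[big]] <- ns[[big]] - 1
  ns
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper chaining [generate_pool()] and [generate_plots()].
#'
#' @inheritParams generate_plots
#' @return A list of class `synthetic_dataset` with `traits`, `registry`,
#'   `plots` and `truth`.
#' @export
simulate_dataset <- function(config = scenario_config()) {
  pool <- generate_pool(config)
  plots <- generate_plots(pool, config)
  structure(list(traits = pool$traits, registry = pool$registry,
                 plots = plots, truth = pool$truth, config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset:", nrow(x$traits), "species,",
      length(unique(x$plots$plot_id)), "plots, scenario =",
      x$config$scenario, "\n")
  invisible(x)
}

#' Write a synthetic dataset to the three standard input files plus truth JSON
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if absent).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(traits = file.path(dir, "traits.tsv"),
             registry = file.path(dir, "registry.csv"),
             plots = file.path(dir, "plots.csv"),
             truth = file.path(dir, "truth.json"))
  utils::write.table(dataset$traits, paths["traits"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.csv(dataset$registry, paths["registry"], row.names = FALSE)
  utils::write.csv(dataset$plots, paths["plots"], row.names = FALSE)
  jsonlite::write_json(dataset$truth, paths["truth"], digits = NA,
                       dataframe = "rows")
  invisible(paths)
}
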