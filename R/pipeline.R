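# End-to-end orchestration: read and validate inputs, standardize traits,
# compute per-plot fraction metrics, run the null models per plot and
# comparison, summarize per habitat, and fit the driver trees. All
# randomness flows from one master seed; each plot gets a child seed derived
# from (seed, plot id) so results do not depend on processing order.

#' Read and cross-validate the three standard input files
#'
#' @param plots_file long-format CSV with columns `plot_id`, `habitat`,
#'   `species`, `cover` (optional `layer`).
#' @param traits_file TSV/CSV with `species` plus the eight canonical trait
#'   columns.
#' @param registry_file CSV with `species`, `status`, `life_form`.
#' @param exclude_species character vector of species removed from plots,
#'   registry and pools before any computation (sensitivity analyses in the
#'   style of removing a dominant invader). Their trait rows are retained so
#'   the global trait scaling — and hence every unaffected plot's result — is
#'   unchanged.
#' @return A list (`plots`, `traits`, `registry`) of validated data.frames.
#' @export
load_inputs <- function(plots_file, traits_file, registry_file,
                        exclude_species = character(0)) {
  sep <- function(f) if (grepl("\\.tsv$", f)) "\t" else ","
  plots <- utils::read.table(plots_file, header = TRUE, sep = sep(plots_file),
                             stringsAsFactors = FALSE)
  traits <- utils::read.table(traits_file, header = TRUE, sep = sep(traits_file),
                              stringsAsFactors = FALSE)
  registry <- utils::read.table(registry_file, header = TRUE,
                                sep = sep(registry_file),
                                stringsAsFactors = FALSE)
  validate_inputs(plots, traits, registry, exclude_species)
}

#' Validate and cross-reference in-memory inputs
#'
#' @param plots,traits,registry data.frames as described in [load_inputs()].
#' @inheritParams load_inputs
#' @return The validated (and possibly filtered) list.
#' @export
validate_inputs <- function(plots, traits, registry,
                            exclude_species = character(0)) {
  need <- c("plot_id", "habitat", "species", "cover")
  if (!all(need %in% names(plots))) {
    abort("plots table must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(c("species", "status", "life_form") %in% names(registry))) {
    abort("registry must have columns species, status, life_form")
  }
  if (length(exclude_species)) {
    # drop from plots, registry and (hence) pools, but keep the trait rows:
    # the global scaling population stays fixed, so plots not containing an
    # excluded species give bit-identical results with and without it
    plots <- plots[!plots$species %in% exclude_species, , drop = FALSE]
    registry <- registry[!registry$species %in% exclude_species, , drop = FALSE]
  }
  if (!nrow(plots)) abort("no plot records after filtering")
  bad <- setdiff(unique(plots$species), registry$species)
  if (length(bad)) abort("plot species missing from registry: ",
                         paste(utils::head(bad, 5), collapse = ", "))
  bad <- setdiff(unique(plots$species), traits$species)
  if (length(bad)) abort("plot species missing from trait table: ",
                         paste(utils::head(bad, 5), collapse = ", "))
  if (any(!registry$status %in% c("native", "naturalized", "invasive"))) {
    abort("registry status must be native, naturalized or invasive")
  }
  if (any(plots$cover <= 0 | plots$cover > 100)) {
    abort("covers must lie in (0, 100]")
  }
  validate_trait_table(traits)
  list(plots = plots, traits = traits, registry = registry)
}

#' Read a wide plot x species cover matrix into canonical long format
#'
#' @param file CSV whose first two columns are `plot_id` and `habitat` and the
#'   remaining columns are species covers (0 = absent).
#' @return Long-format data.frame (`plot_id`, `habitat`, `species`, `cover`).
#' @export
read_wide_plots <- function(file) {
  w <- utils::read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("plot_id", "habitat") %in% names(w)[1:2])) {
    abort("wide plot matrix must start with plot_id, habitat columns")
  }
  sp <- setdiff(names(w), c("plot_id", "habitat"))
  long <- do.call(rbind, lapply(sp, function(s) {
    present <- w[[s]] > 0
    if (!any(present)) return(NULL)
    data.frame(plot_id = w$plot_id[present], habitat = w$habitat[present],
               species = s, cover = w[[s]][present], stringsAsFactors = FALSE)
  }))
  long[order(long$plot_id, long$species), , drop = FALSE]
}

# split life forms into analysis layers: herb layer vs phanerophytes
layer_of <- function(life_form) {
  ifelse(life_form %in% c("herb", "chamaephyte"), "herb_layer",
         ifelse(life_form %in% c("nanophanerophyte", "macrophanerophyte"),
                "phanerophyte_layer", NA_character_))
}

default_comparisons <- function() {
  c("native_vs_naturalized", "native_vs_invasive", "naturalized_vs_invasive")
}

#' Run the full trait-space analysis
#'
#' Standardizes traits globally over all species in the dataset, computes
#' per-plot fraction metrics, runs the stratified null model for every plot
#' and requested comparison (skipping, with a logged count, plots lacking one
#' of the two fractions), summarizes delta-D differences per habitat with
#' paired Wilcoxon tests and BH adjustment, and fits the driver trees for the
#' naturalized (herbs + dwarf shrubs only) and invasive fractions.
#'
#' @param inputs list (`plots`, `traits`, `registry`) from [load_inputs()] /
#'   [validate_inputs()], or a `synthetic_dataset`.
#' @param comparisons subset of [default_comparisons()].
#' @param n_sim null-model replicates per plot (paper default 999).
#' @param weighting `"uniform"`, `"frequency"` or `"beals"`.
#' @param use_cover_weights logical: cover-weighted D/E throughout.
#' @param distance `"euclidean_traits"` (standardized trait axes) or
#'   `"gower_pcoa"` (PCoA axes of the Gower/Podani dissimilarity).
#' @param layer_split logical: analyze scrub/forest-style layers separately
#'   (herb layer = herbs + chamaephytes; phanerophyte layer = nano- and
#'   macrophanerophytes; epiphytes dropped with a warning).
#' @param exclude_species species removed before pool construction.
#' @param fit_trees logical: fit the driver regression trees.
#' @param min_plots_for_tree minimum driver-dataset rows to attempt a tree.
#' @param seed master seed.
#' @param verbose logical: per-plot progress logging.
#' @return A list of class `traitedge_run`: `plot_metrics`, `null_table`,
#'   `summary`, `trees`, `skipped`, `manifest`.
#' @export
run_analysis <- function(inputs,
                         comparisons = default_comparisons(),
                         n_sim = 999, weighting = "beals",
                         use_cover_weights = FALSE,
                         distance = c("euclidean_traits", "gower_pcoa"),
                         layer_split = FALSE,
                         exclude_species = character(0),
                         fit_trees = TRUE, min_plots_for_tree = 40,
                         seed = 1, verbose = FALSE) {
  distance <- match.arg(distance)
  if (inherits(inputs, "synthetic_dataset")) {
    inputs <- list(plots = inputs$plots, traits = inputs$traits,
                   registry = inputs$registry)
  }
  inputs <- validate_inputs(inputs$plots, inputs$traits, inputs$registry,
                            exclude_species)
  plots <- inputs$plots
  registry <- inputs$registry
  stopifnot(all(comparisons %in% default_comparisons()))

  st <- standardize_traits(inputs$traits)
  coords <- if (distance == "euclidean_traits") {
    st$coords
  } else {
    pcoa_axes(gower_podani(inputs$traits))
  }

  if (layer_split) {
    lay <- layer_of(registry$life_form[match(plots$species, registry$species)])
    n_epi <- sum(is.na(lay))
    if (n_epi) warning(n_epi, " record(s) of epiphytes excluded from layers",
                       call. = FALSE)
    plots <- plots[!is.na(lay), , drop = FALSE]
    plots$habitat <- paste(plots$habitat, lay[!is.na(lay)], sep = ":")
  }

  pools <- build_species_pools(plots, registry)
  idx <- match(plots$species, registry$species)
  plots$status <- registry$status[idx]
  plots$life_form <- registry$life_form[idx]

  # Beals reference matrices per habitat (presence/absence)
  beals_by_hab <- NULL
  if (weighting == "beals") {
    beals_by_hab <- lapply(split(plots, plots$habitat), function(ph) {
      pa <- table(ph$plot_id, ph$species)
      pa[pa > 1] <- 1
      beals_index(unclass(as.matrix(pa)))
    })
  }

  plot_ids <- unique(plots$plot_id)
  metrics_rows <- list()
  null_rows <- list()
  skipped <- list()
  by_plot <- split(plots, plots$plot_id)
  for (pid in plot_ids) {
    members <- by_plot[[pid]]
    hab <- members$habitat[1]
    if (verbose) message("plot ", pid, " (", hab, "): ", nrow(members),
                         " species")
    if (!any(members$status == "native")) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(plot_id = pid, comparison = "all",
                   reason = "no native species", stringsAsFactors = FALSE)
      next
    }
    pm <- plot_fraction_metrics(members, coords)
    metrics_rows[[length(metrics_rows) + 1L]] <-
      cbind(plot_id = pid, habitat = hab, pm$fractions)
    beals_row <- if (!is.null(beals_by_hab)) beals_by_hab[[hab]][pid, ] else NULL
    for (cmpn in comparisons) {
      res <- simulate_plot(members, pools[[hab]], coords, cmpn,
                           n_sim = n_sim, weighting = weighting,
                           beals_row = beals_row,
                           use_cover_weights = use_cover_weights,
                           seed = derive_seed(seed, paste0(pid, ":", cmpn)))
      if (is.null(res)) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(plot_id = pid, comparison = cmpn,
                     reason = "fraction absent", stringsAsFactors = FALSE)
        next
      }
      if (isTRUE(res$skipped)) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(plot_id = pid, comparison = cmpn, reason = res$reason,
                     stringsAsFactors = FALSE)
        next
      }
      fr <- res$fractions
      null_rows[[length(null_rows) + 1L]] <- data.frame(
        plot_id = pid, habitat = hab, comparison = cmpn,
        fraction = fr$fraction, n = fr$n, observed_d = fr$observed_d,
        mean_sim_d = fr$mean_sim_d, delta_d = fr$delta_d,
        observed_e = res$observed_e, p_e = res$p_e, n_sim = n_sim,
        weighting = weighting, singleton_pair = any(fr$n == 1),
        stringsAsFactors = FALSE)
    }
  }
  plot_metrics <- do.call(rbind, metrics_rows)
  null_table <- if (length(null_rows)) do.call(rbind, null_rows) else NULL
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(plot_id = character(0), comparison = character(0),
               reason = character(0))
  summary_tab <- if (!is.null(null_table)) habitat_summary(null_table) else NULL

  trees <- list()
  if (fit_trees && !is.null(null_table)) {
    tree_specs <- list(
      naturalized = list(fraction = "naturalized",
                         comparison = "native_vs_naturalized",
                         life_forms = c("herb", "chamaephyte")),
      invasive = list(fraction = "invasive",
                      comparison = "native_vs_invasive", life_forms = NULL))
    for (nm in names(tree_specs)) {
      tsp <- tree_specs[[nm]]
      if (!tsp$comparison %in% comparisons) next
      dd <- try(build_driver_dataset(null_table, plots, registry, st,
                                     fraction = tsp$fraction,
                                     comparison = tsp$comparison,
                                     life_forms = tsp$life_forms),
                silent = TRUE)
      if (inherits(dd, "try-error") || nrow(dd) < min_plots_for_tree) next
      trees[[nm]] <- fit_regression_tree(
        dd[, -(1:2), drop = FALSE], dd$delta_d,
        seed = derive_seed(seed, paste0("tree:", nm)))
    }
  }

  manifest <- list(
    seed = seed, n_sim = n_sim, weighting = weighting,
    use_cover_weights = use_cover_weights, distance = distance,
    layer_split = layer_split, comparisons = comparisons,
    exclude_species = exclude_species,
    n_plots = length(plot_ids), n_species = nrow(inputs$traits),
    n_skipped = nrow(skipped),
    package_version = as.character(utils::packageVersion("traitedge")))
  structure(list(plot_metrics = plot_metrics, null_table = null_table,
                 summary = summary_tab, trees = trees, skipped = skipped,
                 manifest = manifest),
            class = "traitedge_run")
}

#' @export
print.traitedge_run <- function(x, ...) {
  cat("traitedge_run:", x$manifest$n_plots, "plots,",
      x$manifest$n_sim, "simulations/plot, weighting =",
      x$manifest$weighting, "\n")
  if (!is.null(x$summary) && nrow(x$summary)) {
    cat("habitat summary:\n")
    print(x$summary, row.names = FALSE, digits = 3)
  }
  if (nrow(x$skipped)) {
    cat("skipped plot x comparison combinations:", nrow(x$skipped), "\n")
  }
  invisible(x)
}

#' Write the standard output bundle of a run
#'
#' `plot_metrics.csv`, `null_results.csv`, `habitat_summary.csv`,
#' `tree_naturalized.json` / `tree_invasive.json` (when fitted) and
#' `manifest.json`. Nothing is written unless the run object is complete.
#'
#' @param run a `traitedge_run`.
#' @param dir output directory (created if absent).
#' @return Invisibly, the vector of files written.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "traitedge_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  wcsv <- function(df, name) {
    if (is.null(df)) return()
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    written <<- c(written, p)
  }
  wcsv(run$plot_metrics, "plot_metrics.csv")
  wcsv(run$null_table, "null_results.csv")
  wcsv(run$summary, "habitat_summary.csv")
  for (nm in names(run$trees)) {
    p <- file.path(dir, paste0("tree_", nm, ".json"))
    jsonlite::write_json(tree_report(run$trees[[nm]]), p, auto_unbox = TRUE,
                         digits = NA)
    written <- c(written, p)
  }
  p <- file.path(dir, "manifest.json")
  jsonlite::write_json(run$manifest, p, auto_unbox = TRUE, digits = NA)
  written <- c(written, p)
  invisible(written)
}
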