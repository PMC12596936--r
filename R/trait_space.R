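# Trait-space construction: transformation and standardization of raw trait
# tables, Gower dissimilarity with Podani's ordinal extension, and principal
# coordinates analysis. All downstream distances (D, E) are computed in the
# coordinate system produced here.

#' Canonical trait metadata
#'
#' The eight functional traits used throughout the package, with their
#' canonical units and per-trait transformation flags. All traits except the
#' middle of the flowering period are log10-transformed before z-scoring;
#' the flowering midpoint is additionally treated as an ordinal variable by
#' the Gower/Podani dissimilarity.
#'
#' @return A data.frame with columns `trait`, `unit`, `log10` (logical),
#'   `ordinal` (logical).
#' @export
#' @examples
#' trait_metadata()
trait_metadata <- function() {
  data.frame(
    trait = c("height", "seed_mass", "leaf_area", "sla", "ldmc",
              "flowering_midpoint", "flowering_length", "genome_size"),
    unit = c("m", "mg", "mm2", "mm2.mg-1", "mg.g-1",
             "month (1-12)", "months (1-12)", "Mbp"),
    log10 = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
    ordinal = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

validate_trait_table <- function(traits, metadata = trait_metadata()) {
  if (!is.data.frame(traits) || !"species" %in% names(traits)) {
    abort("trait table must be a data.frame with a 'species' column")
  }
  missing_cols <- setdiff(metadata$trait, names(traits))
  if (length(missing_cols)) {
    abort("trait table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(traits$species)) {
    abort("duplicated species in trait table")
  }
  vals <- traits[, metadata$trait, drop = FALSE]
  if (any(!vapply(vals, is.numeric, logical(1)))) {
    abort("all trait columns must be numeric")
  }
  if (anyNA(vals)) {
    bad <- metadata$trait[vapply(vals, anyNA, logical(1))]
    abort("missing trait values are not supported; impute externally first (traits: ",
          paste(bad, collapse = ", "), ")")
  }
  for (tr in metadata$trait[metadata$log10]) {
    if (any(traits[[tr]] <= 0)) {
      abort("log10-flagged trait '", tr, "' has non-positive values")
    }
  }
  fm <- traits$flowering_midpoint
  if (any(fm < 1 | fm > 12)) abort("flowering_midpoint must lie in [1, 12]")
  invisible(traits)
}

#' Standardize a raw trait table
#'
#' Applies the canonical transformation pipeline: log10 on every trait flagged
#' `log10` in the metadata (all except the flowering midpoint), then z-scoring
#' of each trait to zero mean and unit sample (n-1) standard deviation. The
#' scaling population defaults to all species in the table; pass a subset to
#' compute means/SDs over that subset while still transforming all rows, so a
#' single global scaling can be reused across plots.
#'
#' @param traits data.frame with a `species` column and the eight canonical
#'   trait columns (see [trait_metadata()]).
#' @param scaling_species optional character vector of species over which the
#'   scaling means and SDs are computed. Default: all species.
#' @param metadata trait metadata data.frame; default [trait_metadata()].
#' @return An object of class `standardized_traits`: a list with `coords`
#'   (species x trait numeric matrix, rownames = species) and `scaling`
#'   (data.frame with per-trait `mean`, `sd`, `log10` applied).
#' @export
standardize_traits <- function(traits, scaling_species = NULL,
                               metadata = trait_metadata()) {
  validate_trait_table(traits, metadata)
  if (is.null(scaling_species)) scaling_species <- traits$species
  if (!length(scaling_species)) abort("empty scaling population")
  if (!all(scaling_species %in% traits$species)) {
    abort("scaling_species not all present in trait table")
  }
  x <- as.matrix(traits[, metadata$trait, drop = FALSE])
  rownames(x) <- traits$species
  x[, metadata$log10] <- log10(x[, metadata$log10, drop = FALSE])
  sub <- x[match(scaling_species, rownames(x)), , drop = FALSE]
  mu <- colMeans(sub)
  sdv <- apply(sub, 2, stats::sd)
  if (any(sdv == 0)) {
    zero <- metadata$trait[sdv == 0]
    abort("trait(s) constant over the scaling population: ",
          paste(zero, collapse = ", "))
  }
  coords <- sweep(sweep(x, 2, mu, `-`), 2, sdv, `/`)
  structure(
    list(coords = coords,
         scaling = data.frame(trait = metadata$trait, mean = unname(mu),
                              sd = unname(sdv), log10 = metadata$log10,
                              stringsAsFactors = FALSE)),
    class = "standardized_traits"
  )
}

#' @export
print.standardized_traits <- function(x, ...) {
  cat("standardized_traits:", nrow(x$coords), "species x",
      ncol(x$coords), "traits\n")
  cat("scaling record (mean/SD on transformed scale):\n")
  print(x$scaling, row.names = FALSE)
  invisible(x)
}

# Podani (1999) rank-based dissimilarity for one ordinal variable.
# r: average ranks; Ti: number of objects tied with i (including i).
podani_ordinal_dissim <- function(x) {
  r <- rank(x, ties.method = "average")
  tab <- table(x)
  ti <- as.numeric(tab[as.character(x)])
  rmin <- min(r); rmax <- max(r)
  tmin <- ti[which.min(r)]; tmax <- ti[which.max(r)]
  denom <- rmax - rmin - (tmax - 1) / 2 - (tmin - 1) / 2
  n <- length(x)
  d <- matrix(0, n, n)
  if (denom <= 0) return(d)  # constant (or all tied): contributes 0
  dr <- abs(outer(r, r, `-`))
  num <- dr - outer((ti - 1) / 2, (ti - 1) / 2, `+`)
  d <- num / denom
  d[outer(r, r, `==`)] <- 0
  pmin(pmax(d, 0), 1)
}

#' Gower dissimilarity with Podani's extension for ordinal traits
#'
#' Computes the mean over traits of per-trait dissimilarities in \[0, 1\]:
#' range-normalized absolute differences for quantitative traits and the
#' Podani (1999) tie-corrected rank formula for ordinal traits (here the
#' flowering midpoint). Traits that are constant across species contribute 0
#' with a warning.
#'
#' @inheritParams standardize_traits
#' @return A symmetric species x species matrix with zero diagonal, values in
#'   \[0, 1\], class `dissimilarity_matrix`.
#' @export
gower_podani <- function(traits, metadata = trait_metadata()) {
  validate_trait_table(traits, metadata)
  n <- nrow(traits)
  acc <- matrix(0, n, n, dimnames = list(traits$species, traits$species))
  for (k in seq_len(nrow(metadata))) {
    tr <- metadata$trait[k]
    x <- traits[[tr]]
    if (metadata$ordinal[k]) {
      dk <- podani_ordinal_dissim(x)
    } else {
      rg <- diff(range(x))
      if (rg == 0) {
        warning("trait '", tr, "' is constant; contributes 0 to Gower distance",
                call. = FALSE)
        dk <- matrix(0, n, n)
      } else {
        dk <- abs(outer(x, x, `-`)) / rg
      }
    }
    acc <- acc + dk
  }
  d <- acc / nrow(metadata)
  diag(d) <- 0
  structure(d, class = c("dissimilarity_matrix", "matrix"))
}

#' Principal coordinates analysis of a dissimilarity matrix
#'
#' Classical PCoA: eigendecomposition of the double-centered matrix of
#' squared dissimilarities. Axes whose eigenvalue exceeds `tol` times the
#' largest eigenvalue are retained; negative-eigenvalue axes are dropped
#' without Cailliez/Lingoes correction. For Euclidean-embeddable input the
#' retained axes reproduce the original distances exactly.
#'
#' @param d symmetric dissimilarity matrix (zero diagonal).
#' @param tol relative eigenvalue tolerance for axis retention.
#' @return A numeric matrix of coordinates (rows = objects, columns = axes),
#'   with attribute `eigenvalues` (the retained eigenvalues).
#' @export
pcoa_axes <- function(d, tol = 1e-10) {
  d <- unclass(as.matrix(d))
  n <- nrow(d)
  if (n != ncol(d)) abort("dissimilarity matrix must be square")
  if (max(abs(d - t(d))) > 1e-12) abort("dissimilarity matrix must be symmetric")
  if (n == 1L) {
    out <- matrix(0, 1, 1, dimnames = list(rownames(d), NULL))
    attr(out, "eigenvalues") <- 0
    return(out)
  }
  a <- -0.5 * d^2
  b <- a - outer(rowMeans(a), colMeans(a), `+`) + mean(a)
  eg <- eigen(b, symmetric = TRUE)
  keep <- eg$values > tol * max(eg$values, 0)
  if (!any(keep)) abort("no positive eigenvalues: degenerate dissimilarity matrix")
  coords <- eg$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(eg$values[keep]), sum(keep))
  rownames(coords) <- rownames(d)
  attr(coords, "eigenvalues") <- eg$values[keep]
  coords
}

#' Write a standardized trait matrix to TSV with its scaling record
#'
#' The scaling record (per-trait mean and SD on the transformed scale, and
#' whether log10 was applied) is stored in `#`-prefixed header lines so the
#' file is self-describing and round-trippable.
#'
#' @param st a `standardized_traits` object.
#' @param path output file path.
#' @export
write_standardized_traits <- function(st, path) {
  stopifnot(inherits(st, "standardized_traits"))
  hdr <- sprintf("# scaling\t%s\tmean=%.17g\tsd=%.17g\tlog10=%s",
                 st$scaling$trait, st$scaling$mean, st$scaling$sd,
                 st$scaling$log10)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  df <- data.frame(species = rownames(st$coords), st$coords,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}
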