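# Core per-plot statistics: mean distance of a community fraction from the
# native trait-space centroid (D, the unweighted analogue of functional
# dispersion) and the two-sample energy distance (E) quantifying overlap of
# two fractions. Cover-weighted versions use sqrt(percentage cover) weights,
# normalized within each fraction, and reduce exactly to the unweighted
# statistics when all covers are equal.

fraction_weights <- function(n, covers = NULL) {
  if (is.null(covers)) return(rep(1 / n, n))
  if (length(covers) != n) abort("covers must align with coordinates")
  if (any(!is.finite(covers)) || any(covers <= 0)) {
    abort("covers must be strictly positive")
  }
  w <- sqrt(covers)
  w / sum(w)
}

#' Centroid of the native community fraction
#'
#' Arithmetic mean of the native species' trait coordinates; with covers, a
#' weighted mean using sqrt(cover) weights.
#'
#' @param coords numeric matrix (species x traits) of standardized coordinates.
#' @param covers optional positive percentage covers, one per row of `coords`.
#' @return Numeric vector: the centroid coordinates.
#' @export
native_centroid <- function(coords, covers = NULL) {
  coords <- rbind(coords)  # tolerate a single species given as a vector
  if (!nrow(coords)) abort("empty fraction: centroid undefined")
  w <- fraction_weights(nrow(coords), covers)
  as.numeric(crossprod(w, coords))
}

#' Mean distance of a fraction from a trait-space center (D)
#'
#' Unweighted: the mean Euclidean distance of the fraction's species from
#' `center`. Weighted: the sqrt(cover)-weighted mean of the same distances.
#'
#' @inheritParams native_centroid
#' @param center numeric vector, typically the plot's native centroid.
#' @return Nonnegative scalar D.
#' @export
dispersion_d <- function(coords, center, covers = NULL) {
  coords <- rbind(coords)
  if (!nrow(coords)) abort("empty fraction: D undefined")
  if (length(center) != ncol(coords)) abort("dimension mismatch in dispersion_d")
  w <- fraction_weights(nrow(coords), covers)
  di <- sqrt(rowSums(sweep(coords, 2, center, `-`)^2))
  sum(w * di)
}

#' Energy distance between two community fractions (E)
#'
#' The two-sample energy statistic
#' \deqn{E = 2 \bar d(X,Y) - \bar d(X,X) - \bar d(Y,Y)}
#' where each term averages Euclidean distances between (or within) the two
#' point sets, with zero self-distances. E is nonnegative, symmetric, and zero
#' iff the two (weighted) empirical distributions coincide; larger values mean
#' less overlap. The cover-weighted version replaces each uniform average by a
#' weighted average with sqrt(cover) weights normalized within each fraction.
#'
#' @param x,y numeric matrices (species x traits) with equal column counts.
#' @param covers_x,covers_y optional positive covers aligned with `x` / `y`.
#' @return Nonnegative scalar E.
#' @export
e_distance <- function(x, y, covers_x = NULL, covers_y = NULL) {
  x <- rbind(x); y <- rbind(y)
  if (!nrow(x) || !nrow(y)) abort("empty fraction: E undefined")
  if (ncol(x) != ncol(y)) abort("dimension mismatch in e_distance")
  wx <- fraction_weights(nrow(x), covers_x)
  wy <- fraction_weights(nrow(y), covers_y)
  e <- 2 * drop(wx %*% cross_dist(x, y) %*% wy) -
    drop(wx %*% cross_dist(x, x) %*% wx) -
    drop(wy %*% cross_dist(y, y) %*% wy)
  max(e, 0)  # clip tiny negative rounding residue
}

#' Per-plot fraction metrics
#'
#' Computes, for one plot, the size, D and cover-weighted D of each community
#' fraction present (distances always measured from the native centroid of the
#' same plot), and E plus cover-weighted E for each unordered pair of
#' fractions.
#'
#' @param members data.frame with columns `species`, `status` (one of
#'   `"native"`, `"naturalized"`, `"invasive"`) and `cover`.
#' @param coords standardized coordinate matrix with species rownames
#'   (covering at least the plot's species).
#' @return A list with `fractions` (data.frame: fraction, n, d, d_weighted)
#'   and `pairs` (data.frame: fraction_x, fraction_y, e, e_weighted), or
#'   `NULL` fractions data if no native species are present.
#' @export
plot_fraction_metrics <- function(members, coords) {
  stopifnot(all(c("species", "status", "cover") %in% names(members)))
  miss <- setdiff(members$species, rownames(coords))
  if (length(miss)) abort("species without coordinates: ",
                          paste(miss, collapse = ", "))
  statuses <- c("native", "naturalized", "invasive")
  groups <- lapply(statuses, function(s) members[members$status == s, , drop = FALSE])
  names(groups) <- statuses
  if (!nrow(groups$native)) abort("plot has no native species: centroid undefined")
  xs <- lapply(groups, function(g) coords[g$species, , drop = FALSE])
  mu <- native_centroid(xs$native)
  mu_w <- native_centroid(xs$native, groups$native$cover)
  present <- statuses[vapply(groups, nrow, integer(1)) > 0]
  fr <- do.call(rbind, lapply(present, function(s) {
    data.frame(fraction = s, n = nrow(groups[[s]]),
               d = dispersion_d(xs[[s]], mu),
               d_weighted = dispersion_d(xs[[s]], mu_w, groups[[s]]$cover),
               stringsAsFactors = FALSE)
  }))
  prs <- utils::combn(present, min(2, length(present)), simplify = FALSE)
  prs <- Filter(function(p) length(p) == 2, prs)
  pr <- if (length(prs)) do.call(rbind, lapply(prs, function(p) {
    data.frame(fraction_x = p[1], fraction_y = p[2],
               e = e_distance(xs[[p[1]]], xs[[p[2]]]),
               e_weighted = e_distance(xs[[p[1]]], xs[[p[2]]],
                                       groups[[p[1]]]$cover, groups[[p[2]]]$cover),
               stringsAsFactors = FALSE)
  })) else data.frame(fraction_x = character(0), fraction_y = character(0),
                      e = numeric(0), e_weighted = numeric(0))
  list(fractions = fr, pairs = pr)
}
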