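# Habitat-level inference on delta-D: paired Wilcoxon signed-rank tests
# between community fractions, Benjamini-Hochberg adjustment over the whole
# family of habitat x comparison tests, and effect sizes r = z / sqrt(N).

#' Paired Wilcoxon signed-rank test with normal approximation
#'
#' Zero differences are dropped before ranking (Wilcoxon's convention) and N
#' counts the retained pairs. The z statistic uses the tie-corrected variance
#' and no continuity correction, and is signed by the direction of the
#' differences (positive when x tends to exceed y). The effect size is
#' r = z / sqrt(N).
#'
#' @param x,y equal-length numeric vectors of paired observations.
#' @return A list with `z`, `p` (two-sided), `r`, `n` (retained pairs) and
#'   `direction` (sign of the median difference).
#' @export
wilcoxon_paired <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  d <- x - y
  d <- d[is.finite(d) & d != 0]
  n <- length(d)
  if (n < 2) abort("fewer than 2 non-zero differences: test undefined")
  if (n < 6) warning("fewer than 6 informative pairs; normal approximation unreliable",
                     call. = FALSE)
  r_abs <- rank(abs(d))
  w_plus <- sum(r_abs[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r_abs)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (sigma2 <= 0) abort("degenerate variance in signed-rank statistic")
  z <- (w_plus - mu) / sqrt(sigma2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)), r = z / sqrt(n), n = n,
       direction = sign(stats::median(d)))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the input order (monotone, capped at 1).
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(p[o] * m / seq(m, 1)))
  adj[order(o)]
}

#' Classify an effect size r
#'
#' Small when |r| < 0.3, medium when 0.3 <= |r| < 0.5, large when |r| >= 0.5.
#'
#' @param r numeric vector of effect sizes.
#' @return Character vector: `"small"`, `"medium"` or `"large"`.
#' @export
classify_effect <- function(r) {
  if (any(!is.finite(r))) abort("effect size must be finite")
  a <- abs(r)
  ifelse(a >= 0.5, "large", ifelse(a >= 0.3, "medium", "small"))
}

#' Habitat-level summary of delta-D differences between fractions
#'
#' For every habitat and every comparison with at least `min_n` plots in which
#' both fractions occur, runs the paired Wilcoxon test on the two fractions'
#' delta-D values, then BH-adjusts all p-values as one family.
#'
#' @param null_table tidy per-plot null-model table as produced by
#'   [run_analysis()]: columns `plot_id`, `habitat`, `comparison`, `fraction`,
#'   `delta_d` (one row per plot x comparison x fraction).
#' @param min_n minimum number of paired plots per test (default 6).
#' @return data.frame: habitat, comparison, n, z, p, p_adj, r, class,
#'   direction.
#' @export
habitat_summary <- function(null_table, min_n = 6) {
  need <- c("plot_id", "habitat", "comparison", "fraction", "delta_d")
  stopifnot(all(need %in% names(null_table)))
  out <- list()
  for (hab in unique(null_table$habitat)) {
    hb <- null_table[null_table$habitat == hab, , drop = FALSE]
    for (cmpn in unique(hb$comparison)) {
      cb <- hb[hb$comparison == cmpn, , drop = FALSE]
      spec <- comparison_spec(cmpn)
      a <- cb[cb$fraction == spec$ref, c("plot_id", "delta_d")]
      b <- cb[cb$fraction == spec$cmp, c("plot_id", "delta_d")]
      shared <- intersect(a$plot_id, b$plot_id)
      if (length(shared) < min_n) next
      da <- a$delta_d[match(shared, a$plot_id)]
      db <- b$delta_d[match(shared, b$plot_id)]
      if (all(da == db)) next
      # differences are delta_d(compared) - delta_d(reference): positive z
      # means the compared (alien) fraction lies farther from the center
      wt <- wilcoxon_paired(db, da)
      out[[length(out) + 1L]] <- data.frame(
        habitat = hab, comparison = cmpn, n = wt$n, z = wt$z, p = wt$p,
        r = wt$r, direction = wt$direction, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(habitat = character(0), comparison = character(0),
                      n = integer(0), z = numeric(0), p = numeric(0),
                      p_adj = numeric(0), r = numeric(0),
                      class = character(0), direction = numeric(0)))
  }
  res <- do.call(rbind, out)
  res$p_adj <- bh_adjust(res$p)
  res$class <- classify_effect(res$r)
  res[, c("habitat", "comparison", "n", "z", "p", "p_adj", "r", "class",
          "direction")]
}
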