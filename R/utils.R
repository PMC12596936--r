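# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a master seed and a string key
#'
#' Plot-level computations get their own RNG stream so results do not depend
#' on the order in which plots are processed. The derived seed stays below
#' 2^31 - 1 (R integers are 32-bit).
#'
#' @param master integer master seed.
#' @param key character scalar (e.g. a plot id).
#' @return A single integer seed.
#' @export
derive_seed <- function(master, key) {
  stopifnot(length(master) == 1L, is.finite(master), length(key) == 1L)
  h <- 5381
  for (b in utf8ToInt(as.character(key))) {
    h <- (h * 33 + b) %% 2147483647
  }
  as.integer((h + round(abs(master)) * 7919) %% 2147483629 + 1)
}

#' Euclidean cross-distance matrix between two coordinate sets
#' @keywords internal
#' @noRd
cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  # direct differences: the |a|^2 + |b|^2 - 2ab expansion loses precision
  # for nearby points, which matters at oracle tolerances of 1e-9
  out <- matrix(0, nrow(a), nrow(b))
  for (j in seq_len(nrow(b))) {
    out[, j] <- sqrt(rowSums(sweep(a, 2, b[j, ], `-`)^2))
  }
  out
}

# stop() with call. = FALSE everywhere for clean user-facing messages
abort <- function(...) stop(..., call. = FALSE)
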