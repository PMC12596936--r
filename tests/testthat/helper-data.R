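# Builders for small in-code fixtures used across test files.

# minimal valid raw trait table with n species; values strictly positive,
# flowering months in [1, 12]
make_trait_table <- function(n, seed = 42) {
  set.seed(seed)
  data.frame(
    species = sprintf("sp%02d", seq_len(n)),
    height = stats::rlnorm(n, -0.5, 0.5),
    seed_mass = stats::rlnorm(n, 0, 1),
    leaf_area = stats::rlnorm(n, 5, 1),
    sla = stats::rlnorm(n, 3, 0.3),
    ldmc = stats::rlnorm(n, 5.5, 0.3),
    flowering_midpoint = sample(3:9, n, replace = TRUE),
    flowering_length = sample(1:6, n, replace = TRUE),
    genome_size = stats::rlnorm(n, 7, 0.8),
    stringsAsFactors = FALSE
  )
}

# random coordinate cloud
rand_coords <- function(n, p = 3, seed = 1) {
  set.seed(seed)
  matrix(stats::rnorm(n * p), n, p,
         dimnames = list(sprintf("s%03d", seq_len(n)), NULL))
}

# independent brute-force energy distance (double loops, optional weights)
brute_e <- function(x, y, wx = NULL, wy = NULL) {
  x <- rbind(x); y <- rbind(y)
  nx <- nrow(x); ny <- nrow(y)
  wx <- if (is.null(wx)) rep(1 / nx, nx) else sqrt(wx) / sum(sqrt(wx))
  wy <- if (is.null(wy)) rep(1 / ny, ny) else sqrt(wy) / sum(sqrt(wy))
  axy <- 0
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    axy <- axy + wx[i] * wy[j] * sqrt(sum((x[i, ] - y[j, ])^2))
  }
  axx <- 0
  for (i in seq_len(nx)) for (j in seq_len(nx)) {
    if (i != j) axx <- axx + wx[i] * wx[j] * sqrt(sum((x[i, ] - x[j, ])^2))
  }
  ayy <- 0
  for (i in seq_len(ny)) for (j in seq_len(ny)) {
    if (i != j) ayy <- ayy + wy[i] * wy[j] * sqrt(sum((y[i, ] - y[j, ])^2))
  }
  2 * axy - axx - ayy
}

# independent brute-force D
brute_d <- function(x, center, covers = NULL) {
  x <- rbind(x)
  w <- if (is.null(covers)) rep(1 / nrow(x), nrow(x)) else
    sqrt(covers) / sum(sqrt(covers))
  s <- 0
  for (i in seq_len(nrow(x))) s <- s + w[i] * sqrt(sum((x[i, ] - center)^2))
  s
}

# exact null distribution of the signed-rank statistic by enumeration of all
# 2^n sign assignments (valid when |d| has no ties)
exact_signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(signs) %*% r
  p_ge <- mean(w_all >= w_obs)
  p_le <- mean(w_all <= w_obs)
  list(w = w_obs, p = min(1, 2 * min(p_ge, p_le)))
}

# a small pool data.frame for null-model tests
make_pool <- function(n_herb = 12, n_shrub = 5, status = "native",
                      prefix = "pool") {
  n <- n_herb + n_shrub
  data.frame(
    species = sprintf("%s%02d", prefix, seq_len(n)),
    status = status,
    life_form = rep(c("herb", "chamaephyte"), c(n_herb, n_shrub)),
    frequency = seq_len(n),
    stringsAsFactors = FALSE
  )
}
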