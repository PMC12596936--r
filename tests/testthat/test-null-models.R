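# independent nested-loop Beals oracle
oracle_beals <- function(pa) {
  n_plot <- nrow(pa); n_sp <- ncol(pa)
  nk <- colSums(pa)
  m <- matrix(0, n_sp, n_sp)
  for (j in seq_len(n_sp)) for (k in seq_len(n_sp)) {
    m[j, k] <- sum(pa[, j] == 1 & pa[, k] == 1)
  }
  b <- matrix(0, n_plot, n_sp)
  for (i in seq_len(n_plot)) for (j in seq_len(n_sp)) {
    ks <- which(pa[i, ] == 1 & seq_len(n_sp) != j)
    if (!length(ks)) { b[i, j] <- 0; next }
    b[i, j] <- sum(m[j, ks] / nk[ks]) / length(ks)
  }
  dimnames(b) <- dimnames(pa)
  b
}

test_that("beals_index matches the nested-loop oracle and its trivial bounds", {
  pa <- rbind(p1 = c(1, 1, 0, 1), p2 = c(1, 0, 1, 0),
              p3 = c(0, 1, 1, 1), p4 = c(1, 1, 1, 0))
  colnames(pa) <- paste0("s", 1:4)
  expect_equal(beals_index(pa), oracle_beals(pa), tolerance = 1e-12)

  set.seed(4)
  pa2 <- matrix(rbinom(15 * 8, 1, 0.5), 15, 8,
                dimnames = list(paste0("p", 1:15), paste0("s", 1:8)))
  pa2[rowSums(pa2) == 0, 1] <- 1
  pa2[1, colSums(pa2) == 0] <- 1
  b <- beals_index(pa2)
  expect_equal(b, oracle_beals(pa2), tolerance = 1e-12)
  expect_true(all(b >= 0 & b <= 1))

  # target species present in every plot: all M_jk / N_k = 1 -> index 1
  pa3 <- rbind(c(1, 1, 1), c(1, 1, 0), c(1, 0, 1))
  colnames(pa3) <- paste0("s", 1:3); rownames(pa3) <- paste0("p", 1:3)
  expect_equal(beals_index(pa3)[1, 1], 1)  # s1 occurs wherever s2, s3 do
  # species never co-occurring with the plot's species -> 0
  pa4 <- rbind(c(1, 1, 0), c(0, 0, 1))
  colnames(pa4) <- paste0("s", 1:3); rownames(pa4) <- paste0("p", 1:2)
  expect_equal(beals_index(pa4)[1, 3], 0)

  expect_error(beals_index(cbind(pa, s9 = 0)), "zero occurrences")
  expect_error(beals_index(pa * 2), "binary")
})

test_that("build_species_pools records status, life form and occurrence frequency", {
  plots <- data.frame(
    plot_id = c("a", "a", "b", "b", "c"),
    habitat = c("H1", "H1", "H1", "H1", "H2"),
    species = c("x", "y", "x", "z", "y"),
    cover = 5, stringsAsFactors = FALSE)
  reg <- data.frame(species = c("x", "y", "z"),
                    status = c("native", "native", "invasive"),
                    life_form = c("herb", "herb", "herb"),
                    stringsAsFactors = FALSE)
  pools <- build_species_pools(plots, reg)
  expect_setequal(names(pools), c("H1", "H2"))
  h1 <- pools$H1
  expect_equal(h1$frequency[h1$species == "x"], 2)
  expect_equal(h1$frequency[h1$species == "z"], 1)
  expect_equal(h1$status[h1$species == "z"], "invasive")
  expect_error(build_species_pools(
    data.frame(plot_id = "a", habitat = "H1", species = "ghost", cover = 1),
    reg), "missing from registry")
})

test_that("draw_fraction preserves size, life-form counts and cover multiset", {
  pool <- make_pool(n_herb = 12, n_shrub = 5)
  members <- data.frame(
    species = c("m1", "m2", "m3", "m4"),
    life_form = c("herb", "herb", "herb", "chamaephyte"),
    cover = c(3, 11, 0.5, 42), stringsAsFactors = FALSE)
  set.seed(1)
  for (w in c("uniform", "frequency")) {
    for (r in 1:200) {
      sim <- draw_fraction(members, pool, weighting = w)
      expect_identical(sim$life_form, members$life_form)
      expect_identical(sim$cover, members$cover)
      expect_false(anyDuplicated(sim$species) > 0)
      lf <- pool$life_form[match(sim$species, pool$species)]
      expect_identical(lf, members$life_form)   # 3 herbs + 1 chamaephyte
    }
  }
})

test_that("draw_fraction: forced draw, exclusion, and exhaustion error", {
  pool <- make_pool(n_herb = 3, n_shrub = 1)
  members <- data.frame(species = c("a", "b", "c", "d"),
                        life_form = c("herb", "herb", "herb", "chamaephyte"),
                        cover = 1:4, stringsAsFactors = FALSE)
  sim <- draw_fraction(members, pool)  # strata exactly exhausted: deterministic
  expect_setequal(sim$species, pool$species)
  expect_error(draw_fraction(members, pool, exclude = pool$species[1]),
               "stratum exhausted")
})

test_that("frequency weighting matches exact sequential-sampling inclusion probabilities", {
  # 5-species stratum, draw 2 without replacement, weights w
  w <- c(100, 1, 1, 1, 1)
  # exact inclusion probabilities by enumeration of ordered draws
  inc <- numeric(5)
  for (i in 1:5) for (j in setdiff(1:5, i)) {
    pr <- (w[i] / sum(w)) * (w[j] / (sum(w) - w[i]))
    inc[i] <- inc[i] + pr; inc[j] <- inc[j] + pr
  }
  pool <- data.frame(species = paste0("s", 1:5), status = "native",
                     life_form = "herb", frequency = w,
                     stringsAsFactors = FALSE)
  members <- data.frame(species = c("a", "b"), life_form = "herb",
                        cover = c(1, 1), stringsAsFactors = FALSE)
  set.seed(7)
  n_draw <- 10000
  counts <- setNames(numeric(5), pool$species)
  for (r in seq_len(n_draw)) {
    sim <- draw_fraction(members, pool, weighting = "frequency")
    counts[sim$species] <- counts[sim$species] + 1
  }
  phat <- counts / n_draw
  se <- sqrt(inc * (1 - inc) / n_draw)
  expect_true(all(abs(phat - inc) <= 3 * se + 1e-9))
})

test_that("overlap_probability implements the (count + 1)/(n + 1) formula", {
  expect_equal(overlap_probability(5, rep(1, 999)), 1 / 1000)
  sims <- c(rep(3, 49), rep(1, 950))
  expect_equal(overlap_probability(2, sims), 0.05)
  expect_equal(overlap_probability(0.5, rep(1, 999)), 1)
  expect_error(overlap_probability(1, numeric(0)), "no simulated")
})

test_that("simulate_plot: delta-D definition, determinism, skip logic", {
  set.seed(42)
  pool <- make_pool(n_herb = 20, n_shrub = 6)
  coords <- rand_coords(40, p = 4, seed = 2)
  rownames(coords)[1:26] <- pool$species
  members <- data.frame(
    species = c(pool$species[1:4], "al1", "al2"),
    status = c(rep("native", 4), "invasive", "invasive"),
    life_form = c(pool$life_form[1:4], "herb", "herb"),
    cover = c(5, 10, 2, 8, 30, 1), stringsAsFactors = FALSE)
  rownames(coords)[27:28] <- c("al1", "al2")
  res <- simulate_plot(members, pool, coords, "native_vs_invasive",
                       n_sim = 99, seed = 11)
  expect_s3_class(res, "null_result")
  expect_false(res$skipped)
  expect_equal(res$fractions$delta_d,
               res$fractions$observed_d - res$fractions$mean_sim_d)
  expect_equal(res$fractions$mean_sim_d[1], mean(res$sim_d[, "ref"]))
  expect_true(res$p_e >= 1 / 100 && res$p_e <= 1)

  res2 <- simulate_plot(members, pool, coords, "native_vs_invasive",
                        n_sim = 99, seed = 11)
  expect_identical(res[c("fractions", "observed_e", "p_e")],
                   res2[c("fractions", "observed_e", "p_e")])

  # fraction absent -> NULL; stratum too small -> skipped with reason
  expect_null(simulate_plot(members, pool, coords, "native_vs_naturalized",
                            n_sim = 9, seed = 1))
  members_big <- members
  members_big$life_form[5:6] <- "chamaephyte"
  small_pool <- pool[pool$life_form == "herb", ][1:10, ]
  res3 <- simulate_plot(members_big, small_pool, coords,
                        "native_vs_invasive", n_sim = 9, seed = 1)
  expect_true(res3$skipped)
  expect_match(res3$reason, "stratum")
})

test_that("compiled null kernel agrees with the pure-R metric implementations", {
  # same replicate statistics recomputed via dispersion_d / e_distance
  pool <- make_pool(n_herb = 15, n_shrub = 5)
  coords <- rand_coords(30, p = 6, seed = 9)
  rownames(coords)[1:20] <- pool$species
  members <- data.frame(
    species = c(pool$species[c(1, 2, 13)], "z1"),
    status = c(rep("native", 3), "naturalized"),
    life_form = c(pool$life_form[c(1, 2, 13)], "herb"),
    cover = c(4, 9, 25, 16), stringsAsFactors = FALSE)
  rownames(coords)[25] <- "z1"
  obs_nat <- members[members$status == "native", ]
  obs_cmp <- members[members$status == "naturalized", ]
  for (ucw in c(FALSE, TRUE)) {
    res <- simulate_plot(members, pool, coords, "native_vs_naturalized",
                         n_sim = 25, seed = 5, use_cover_weights = ucw)
    for (r in 1:25) {
      yr <- coords[res$sim_ref_idx[r, ], , drop = FALSE]
      yc <- coords[res$sim_cmp_idx[r, ], , drop = FALSE]
      cwr <- if (ucw) obs_nat$cover else NULL
      cwc <- if (ucw) obs_cmp$cover else NULL
      mu <- native_centroid(yr, cwr)
      expect_equal(unname(res$sim_d[r, "ref"]), dispersion_d(yr, mu, cwr),
                   tolerance = 1e-12)
      expect_equal(unname(res$sim_d[r, "cmp"]), dispersion_d(yc, mu, cwc),
                   tolerance = 1e-12)
      expect_equal(res$sim_e[r], e_distance(yr, yc, cwr, cwc),
                   tolerance = 1e-12)
      # joint redraw is disjoint and stratification is exact
      expect_length(intersect(res$sim_ref_idx[r, ], res$sim_cmp_idx[r, ]), 0)
      drawn <- rownames(coords)[res$sim_ref_idx[r, ]]
      expect_identical(pool$life_form[match(drawn, pool$species)],
                       obs_nat$life_form)
    }
  }
})
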