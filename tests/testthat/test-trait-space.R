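test_that("standardize applies log10 to flagged traits and z-scores with sample SD", {
  tt <- make_trait_table(3)
  tt$seed_mass <- c(10, 100, 1000)       # log10 -> 1, 2, 3 -> z = -1, 0, 1
  tt$flowering_midpoint <- c(3, 6, 9)    # exempt from log -> z = -1, 0, 1
  st <- standardize_traits(tt)
  expect_equal(unname(st$coords[, "seed_mass"]), c(-1, 0, 1))
  expect_equal(unname(st$coords[, "flowering_midpoint"]), c(-1, 0, 1))
  sc <- st$scaling
  expect_equal(sc$mean[sc$trait == "seed_mass"], 2)   # mean of log10 values
  expect_equal(sc$sd[sc$trait == "seed_mass"], 1)     # sample (n-1) SD
  expect_false(sc$log10[sc$trait == "flowering_midpoint"])
  # every column has mean 0 and SD 1 over the scaling population
  expect_true(all(abs(colMeans(st$coords)) < 1e-9))
  expect_true(all(abs(apply(st$coords, 2, sd) - 1) < 1e-9))
})

test_that("standardize honors a scaling subpopulation and rejects bad input", {
  tt <- make_trait_table(10)
  st <- standardize_traits(tt, scaling_species = tt$species[1:6])
  sub <- st$coords[tt$species[1:6], ]
  expect_true(all(abs(colMeans(sub)) < 1e-9))
  expect_true(all(abs(apply(sub, 2, sd) - 1) < 1e-9))
  # idempotence in distribution: the scaled-population block is already
  # centered/scaled, so applying the z-score step again changes nothing
  rescaled <- sweep(sweep(sub, 2, colMeans(sub), `-`), 2,
                    apply(sub, 2, sd), `/`)
  expect_equal(rescaled, sub, tolerance = 1e-9)

  bad <- tt; bad$height[2] <- -1
  expect_error(standardize_traits(bad), "non-positive")
  bad2 <- tt; bad2$sla[3] <- NA
  expect_error(standardize_traits(bad2), "missing")
  expect_error(standardize_traits(tt, scaling_species = character(0)), "empty")
})

# independent nested-loop implementation of Gower + Podani
oracle_gower <- function(tt, meta = trait_metadata()) {
  n <- nrow(tt)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    acc <- 0
    for (k in seq_len(nrow(meta))) {
      x <- tt[[meta$trait[k]]]
      if (meta$ordinal[k]) {
        r <- rank(x)
        ti <- sapply(x, function(v) sum(x == v))
        if (x[i] == x[j]) {
          dk <- 0
        } else {
          den <- max(r) - min(r) -
            (ti[which.max(r)] - 1) / 2 - (ti[which.min(r)] - 1) / 2
          dk <- (abs(r[i] - r[j]) - (ti[i] - 1) / 2 - (ti[j] - 1) / 2) / den
        }
      } else {
        rg <- max(x) - min(x)
        dk <- if (rg == 0) 0 else abs(x[i] - x[j]) / rg
      }
      acc <- acc + dk
    }
    d[i, j] <- acc / nrow(meta)
  }
  d
}

test_that("gower_podani matches element-by-element brute force, incl. ordinal ties", {
  tt <- make_trait_table(4, seed = 11)
  tt$flowering_midpoint <- c(5, 5, 7, 9)  # tied ordinal values
  g <- gower_podani(tt)
  expect_equal(unclass(g), oracle_gower(tt), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_true(isSymmetric(unclass(g)))
  expect_true(all(diag(g) == 0))
  expect_true(all(g >= 0 & g <= 1 + 1e-12))

  tt2 <- make_trait_table(7, seed = 12)
  tt2$flowering_midpoint <- c(4, 4, 4, 6, 6, 8, 9)
  expect_equal(unclass(gower_podani(tt2)), oracle_gower(tt2),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("gower_podani hits 0 for identical rows and 1 at opposite extremes", {
  tt <- make_trait_table(3)
  tt[2, -1] <- tt[1, -1]
  expect_equal(gower_podani(tt)[1, 2], 0)

  # two species at opposite extremes of every trait, no ordinal ties
  ext <- make_trait_table(2)
  ext[1, c("height", "seed_mass", "leaf_area", "sla", "ldmc",
           "flowering_length", "genome_size")] <- 1
  ext[2, c("height", "seed_mass", "leaf_area", "sla", "ldmc",
           "flowering_length", "genome_size")] <- c(10, 50, 900, 40, 400, 6, 3000)
  ext$flowering_midpoint <- c(2, 10)
  expect_equal(gower_podani(ext)[1, 2], 1)

  cst <- make_trait_table(4)
  cst$ldmc <- 200
  expect_warning(g <- gower_podani(cst), "constant")
  expect_true(all(g >= 0 & g <= 1))
})

test_that("pcoa_axes recovers Euclidean configurations and handles degenerate input", {
  pts <- rbind(c(0, 0), c(3, 0), c(0, 4))
  d <- as.matrix(dist(pts))
  ax <- pcoa_axes(d)
  expect_equal(sort(as.numeric(dist(ax))), c(3, 4, 5), tolerance = 1e-9)

  one <- matrix(0, 1, 1, dimnames = list("a", "a"))
  expect_equal(as.numeric(pcoa_axes(one)), 0)

  expect_error(pcoa_axes(matrix(c(0, 1, 1, 0), 2)[, 1, drop = FALSE]), "square")
})

test_that("D and E on PCoA axes of Euclidean distances equal direct computation", {
  st_coords <- rand_coords(12, p = 5, seed = 3)
  d <- as.matrix(dist(st_coords))
  ax <- pcoa_axes(d)
  x_idx <- 1:7; y_idx <- 8:12
  mu1 <- native_centroid(st_coords[x_idx, ])
  mu2 <- native_centroid(ax[x_idx, ])
  expect_equal(dispersion_d(ax[x_idx, ], mu2),
               dispersion_d(st_coords[x_idx, ], mu1), tolerance = 1e-6)
  expect_equal(dispersion_d(ax[y_idx, ], mu2),
               dispersion_d(st_coords[y_idx, ], mu1), tolerance = 1e-6)
  expect_equal(e_distance(ax[x_idx, ], ax[y_idx, ]),
               e_distance(st_coords[x_idx, ], st_coords[y_idx, ]),
               tolerance = 1e-6)
})

test_that("gower pipeline consistency: D/E on retained PCoA axes match an axis oracle", {
  tt <- make_trait_table(9, seed = 21)
  tt$flowering_midpoint <- c(4, 4, 6, 6, 6, 8, 9, 5, 7)
  ax <- pcoa_axes(gower_podani(tt))
  x <- ax[1:5, , drop = FALSE]; y <- ax[6:9, , drop = FALSE]
  expect_equal(e_distance(x, y), brute_e(x, y), tolerance = 1e-9)
  mu <- colMeans(x)
  expect_equal(dispersion_d(x, mu), brute_d(x, mu), tolerance = 1e-9)
})

test_that("standardized trait writer round-trips the scaling record", {
  tt <- make_trait_table(5)
  st <- standardize_traits(tt)
  f <- tempfile(fileext = ".tsv")
  write_standardized_traits(st, f)
  lines <- readLines(f)
  expect_length(grep("^# scaling", lines), 8)
  body <- read.delim(f, comment.char = "#")
  expect_equal(as.matrix(body[, -1]), st$coords, ignore_attr = TRUE,
               tolerance = 1e-12)
  unlink(f)
})
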