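test_that("perfectly separable step response yields one split, 100% variance", {
  set.seed(1)
  x <- data.frame(a = c(runif(50, -2, -1), runif(50, 1, 2)),
                  b = rnorm(100))
  y <- rep(c(0, 10), each = 50)
  tr <- fit_regression_tree(x, y, seed = 4)
  expect_equal(n_leaves(tr), 2)
  root <- tr$nodes[[1]]
  expect_equal(tr$var_names[root$var], "a")
  expect_true(root$threshold > -1 && root$threshold < 1)  # midpoint of the gap
  expect_equal(root$pct_var, 100)
  expect_equal(tr$total_pct_var, 100)
  expect_equal(sort(unique(predict(tr, x))), c(0, 10))
})

test_that("constant response yields a single-node tree", {
  x <- data.frame(a = rnorm(50))
  tr <- fit_regression_tree(x, rep(2, 50), min_split = 10, seed = 1)
  expect_equal(n_leaves(tr), 1)
  expect_equal(predict(tr, x), rep(2, 50))
})

test_that("1-SE pruning returns the root-only tree on pure noise in >= 95% of seeds", {
  n_root <- 0
  n_seeds <- 40
  for (s in seq_len(n_seeds)) {
    set.seed(s)
    x <- data.frame(a = rnorm(200), b = rnorm(200), c = rnorm(200))
    y <- rnorm(200)
    tr <- fit_regression_tree(x, y, seed = s)
    if (n_leaves(tr) == 1) n_root <- n_root + 1
  }
  expect_gte(n_root / n_seeds, 0.95)
})

test_that("linear signal in one predictor: first split on it, threshold in the IQR", {
  set.seed(9)
  x <- data.frame(sig = rnorm(300), n1 = rnorm(300), n2 = rnorm(300))
  y <- 2 * x$sig + rnorm(300, sd = 0.3)
  tr <- fit_regression_tree(x, y, seed = 2)
  root <- tr$nodes[[1]]
  expect_false(root$is_leaf)
  expect_equal(tr$var_names[root$var], "sig")
  q <- quantile(x$sig, c(0.25, 0.75))
  expect_true(root$threshold >= q[1] && root$threshold <= q[2])
})

test_that("per-split variance percentages sum to the total variance explained", {
  set.seed(14)
  x <- data.frame(a = rnorm(250), b = rnorm(250), c = rnorm(250))
  y <- 3 * (x$a > 0) + 2 * (x$b > 0.5) + rnorm(250, sd = 0.4)
  tr <- fit_regression_tree(x, y, seed = 3)
  expect_gt(n_leaves(tr), 2)
  pct <- vapply(tr$nodes,
                function(nd) if (nd$is_leaf) 0 else nd$pct_var, numeric(1))
  expect_equal(sum(pct), tr$total_pct_var, tolerance = 1e-9)
  # predictions reproduce terminal means exactly on training rows
  pred <- predict(tr, x)
  leaves <- Filter(function(nd) nd$is_leaf, tr$nodes)
  for (nd in leaves) expect_equal(unique(pred[nd$idx]), nd$mean)
  # pruned tree's CV error never exceeds min + 1 SE
  kmin <- which.min(tr$cv$cv_err)
  chosen <- which(tr$cv$beta == tr$chosen_beta)
  expect_lte(tr$cv$cv_err[chosen],
             tr$cv$cv_err[kmin] + tr$cv$cv_se[kmin] + 1e-9)
})

test_that("surrogates: exact copy agrees 1.0, independent balanced predictor is dropped", {
  set.seed(6)
  x <- data.frame(a = rnorm(200))
  x$dup <- x$a                      # duplicated predictor
  x$noise <- rnorm(200)
  y <- 4 * (x$a > 0) + rnorm(200, sd = 0.3)
  tr <- fit_regression_tree(x, y, seed = 5)
  root <- tr$nodes[[1]]
  expect_false(root$is_leaf)
  sur <- root$surrogates
  expect_true("dup" %in% sur$variable || "a" %in% sur$variable)
  expect_equal(sur$agreement[1], 1.0)
  expect_false("noise" %in% sur$variable)

  # direct check of the raw-agreement search, inclusive at the threshold
  go_left <- rep(c(TRUE, FALSE), each = 10)
  xm <- cbind(p = c(rnorm(10, -3), rnorm(10, 3)),
              q = c(seq(1, 10), seq(11, 20)))
  xm[1, "q"] <- 19.5                 # 1 of 20 misallocated -> agreement 0.95
  s <- find_surrogates(xm, go_left, primary_var = 1, agreement_threshold = 0.9)
  expect_equal(nrow(s), 1)
  expect_equal(s$agreement, 0.95)
  s2 <- find_surrogates(xm, go_left, primary_var = 1,
                        agreement_threshold = 0.95)
  expect_equal(nrow(s2), 1)          # inclusive: agreement == threshold kept
  # expected agreement of an independent predictor ~ 0.5: never listed
  set.seed(31)
  bal <- cbind(p = c(rnorm(100, -3), rnorm(100, 3)), r = rnorm(200))
  s3 <- find_surrogates(bal, rep(c(TRUE, FALSE), each = 100), 1, 0.9)
  expect_false("r" %in% rownames(s3) | any(s3$var == 2))
})

test_that("tree_report serializes nodes with surrogates and terminal stats", {
  set.seed(4)
  x <- data.frame(a = rnorm(120), b = rnorm(120))
  y <- 5 * (x$a > 0) + rnorm(120, sd = 0.5)
  tr <- fit_regression_tree(x, y, seed = 1)
  rep_ <- tree_report(tr)
  expect_equal(rep_$n, 120)
  expect_equal(rep_$n_leaves, n_leaves(tr))
  root <- rep_$nodes[[1]]
  expect_equal(root$splitter, "a")
  expect_true(is.numeric(root$pct_variance))
  json <- jsonlite::toJSON(rep_, auto_unbox = TRUE)
  expect_true(jsonlite::validate(json))
})

test_that("go-left threshold convention: x < threshold routes left, children partition", {
  set.seed(2)
  x <- data.frame(a = rnorm(100))
  y <- (x$a > 0.2) * 3 + rnorm(100, 0, 0.2)
  tr <- fit_regression_tree(x, y, seed = 7)
  root <- tr$nodes[[1]]
  l <- tr$nodes[[root$left]]; r <- tr$nodes[[root$right]]
  expect_setequal(c(l$idx, r$idx), root$idx)
  expect_true(all(x$a[l$idx] < root$threshold))
  expect_true(all(x$a[r$idx] >= root$threshold))
  expect_lt(l$mean, r$mean)
})
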