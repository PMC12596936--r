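# Regression trees (CART) for identifying which fraction-mean traits drive
# delta-D. Greedy binary splitting on SSE reduction, cost-complexity pruning,
# 10-fold cross-validation with the 1-SE rule, per-split percentage of total
# variance explained, and surrogate splits (variables sending at least 90% of
# a node's cases to the same child as the primary splitter, raw agreement
# fraction without a majority-rule baseline).

# best split of one node; returns NULL if no admissible split improves SSE
best_split <- function(x_mat, y, min_leaf) {
  n <- length(y)
  best <- NULL
  for (j in seq_len(ncol(x_mat))) {
    x <- x_mat[, j]
    o <- order(x)
    xs <- x[o]; ys <- y[o]
    cs <- cumsum(ys)
    s <- cs[n]
    k <- seq_len(n - 1)
    ok <- k >= min_leaf & (n - k) >= min_leaf & xs[k] < xs[k + 1]
    if (!any(ok)) next
    gain <- cs[k]^2 / k + (s - cs[k])^2 / (n - k) - s^2 / n
    gain[!ok] <- -Inf
    kb <- which.max(gain)    # first max: lowest threshold on ties within var
    if (is.null(best) || gain[kb] > best$gain + 1e-12) {
      best <- list(var = j, threshold = (xs[kb] + xs[kb + 1]) / 2,
                   gain = gain[kb])
    }
  }
  if (!is.null(best) && best$gain <= 1e-12) best <- NULL
  best
}

node_sse <- function(y) sum((y - mean(y))^2)

grow_tree <- function(x_mat, y, min_split, min_leaf) {
  nodes <- list()
  new_node <- function(idx, depth, parent) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- list(id = id, parent = parent, depth = depth,
                         idx = idx, n = length(idx), mean = mean(y[idx]),
                         sse = node_sse(y[idx]), is_leaf = TRUE,
                         var = NA_integer_, threshold = NA_real_,
                         improvement = NA_real_, left = NA_integer_,
                         right = NA_integer_)
    id
  }
  recurse <- function(id) {
    nd <- nodes[[id]]
    if (nd$n < min_split || nd$sse <= 1e-12) return(invisible())
    sp <- best_split(x_mat[nd$idx, , drop = FALSE], y[nd$idx], min_leaf)
    if (is.null(sp)) return(invisible())
    go_left <- x_mat[nd$idx, sp$var] < sp$threshold
    lid <- new_node(nd$idx[go_left], nd$depth + 1L, id)
    rid <- new_node(nd$idx[!go_left], nd$depth + 1L, id)
    nodes[[id]][c("is_leaf", "var", "threshold", "improvement",
                  "left", "right")] <<-
      list(FALSE, sp$var, sp$threshold, sp$gain, lid, rid)
    recurse(lid)
    recurse(rid)
  }
  root <- new_node(seq_along(y), 0L, NA_integer_)
  recurse(root)
  nodes
}

# optimal subtree for penalty alpha: bottom-up DP; returns logical vector
# "collapsed" (TRUE = behave as leaf); ties collapse (smaller tree preferred)
prune_at <- function(nodes, alpha) {
  collapsed <- rep(TRUE, length(nodes))
  cost <- numeric(length(nodes))
  eval_node <- function(id) {
    nd <- nodes[[id]]
    leaf_cost <- nd$sse + alpha
    if (nd$is_leaf) { cost[id] <<- leaf_cost; return(leaf_cost) }
    sub <- eval_node(nd$left) + eval_node(nd$right)
    if (sub < leaf_cost - 1e-12) {
      collapsed[id] <<- FALSE
      cost[id] <<- sub
    } else cost[id] <<- leaf_cost
    cost[id]
  }
  eval_node(1L)
  collapsed
}

# weakest-link alpha sequence (increasing, starting at 0)
cc_alphas <- function(nodes) {
  if (nodes[[1]]$is_leaf) return(0)
  collapsed <- vapply(nodes, function(nd) nd$is_leaf, logical(1))
  alphas <- 0
  repeat {
    if (collapsed[1L]) break
    stats_node <- function(id) {  # (R_subtree, n_leaves) under current state
      if (collapsed[id]) return(c(nodes[[id]]$sse, 1))
      l <- stats_node(nodes[[id]]$left); r <- stats_node(nodes[[id]]$right)
      l + r
    }
    g <- rep(Inf, length(nodes))
    for (id in seq_along(nodes)) {
      if (!collapsed[id]) {
        st <- stats_node(id)
        g[id] <- (nodes[[id]]$sse - st[1]) / (st[2] - 1)
      }
    }
    a <- min(g)
    alphas <- c(alphas, a)
    collapsed[g <= a + 1e-12] <- TRUE
  }
  sort(unique(alphas))
}

predict_nodes <- function(nodes, collapsed, x_mat) {
  out <- numeric(nrow(x_mat))
  for (i in seq_len(nrow(x_mat))) {
    id <- 1L
    while (!collapsed[id]) {
      nd <- nodes[[id]]
      id <- if (x_mat[i, nd$var] < nd$threshold) nd$left else nd$right
    }
    out[i] <- nodes[[id]]$mean
  }
  out
}

#' Surrogate splits for one primary split
#'
#' For each predictor other than the primary splitter, finds the threshold and
#' direction whose binary partition of the node's cases best agrees with the
#' primary left/right assignment, and keeps those whose raw agreement fraction
#' is at least `agreement_threshold` (inclusive).
#'
#' @param x_mat numeric predictor matrix for the node's cases.
#' @param go_left logical vector: the primary split's assignment.
#' @param primary_var column index of the primary splitter (excluded).
#' @param agreement_threshold minimum agreement (default 0.9).
#' @return data.frame (`var`, `threshold`, `direction`, `agreement`) sorted by
#'   decreasing agreement; `direction = "<"` means `x < threshold` goes to the
#'   same side as the primary split's left child.
#' @export
find_surrogates <- function(x_mat, go_left, primary_var,
                            agreement_threshold = 0.9) {
  n <- length(go_left)
  total_left <- sum(go_left)
  res <- list()
  for (j in setdiff(seq_len(ncol(x_mat)), primary_var)) {
    x <- x_mat[, j]
    o <- order(x)
    xs <- x[o]
    gl <- go_left[o]
    cum <- cumsum(gl)
    k <- seq_len(n - 1)
    ok <- xs[k] < xs[k + 1]
    if (!any(ok)) next
    # "<" sends left:   left-matches in 1..k plus right-matches in k+1..n
    a1 <- cum[k] + ((n - k) - (total_left - cum[k]))
    # "<" sends right:  right-matches in 1..k plus left-matches in k+1..n
    a2 <- (k - cum[k]) + (total_left - cum[k])
    a1[!ok] <- -Inf; a2[!ok] <- -Inf
    k1 <- which.max(a1); k2 <- which.max(a2)
    if (a1[k1] >= a2[k2]) {
      agree <- a1[k1] / n; thr <- (xs[k1] + xs[k1 + 1]) / 2; dir <- "<"
    } else {
      agree <- a2[k2] / n; thr <- (xs[k2] + xs[k2 + 1]) / 2; dir <- ">="
    }
    if (agree >= agreement_threshold) {
      res[[length(res) + 1L]] <- data.frame(var = j, threshold = thr,
                                            direction = dir,
                                            agreement = agree)
    }
  }
  if (!length(res)) {
    return(data.frame(var = integer(0), threshold = numeric(0),
                      direction = character(0), agreement = numeric(0)))
  }
  out <- do.call(rbind, res)
  out[order(-out$agreement, out$var), , drop = FALSE]
}

#' Fit a regression tree with cross-validated 1-SE pruning and surrogates
#'
#' Grows a CART by greedy SSE-reduction splits (thresholds at midpoints
#' between consecutive observed values; ties broken by lower variable index,
#' then lower threshold), builds the cost-complexity pruning sequence,
#' estimates cross-validation error for each candidate penalty, and returns
#' the smallest subtree whose CV error is within one standard error of the
#' minimum. Per-split percentage variance explained is the split's SSE
#' reduction over the root's total SSE.
#'
#' @param data data.frame of numeric predictors.
#' @param response numeric response vector (delta-D in the driver analysis).
#' @param min_split minimum node size to attempt a split (default 20).
#' @param min_leaf minimum cases per child (default 7).
#' @param cv_folds number of cross-validation folds (default 10).
#' @param seed integer seed controlling fold assignment.
#' @param surrogate_agreement agreement threshold for surrogates (default 0.9).
#' @return An object of class `trait_tree`.
#' @export
fit_regression_tree <- function(data, response, min_split = 20, min_leaf = 7,
                                cv_folds = 10, seed = 1,
                                surrogate_agreement = 0.9) {
  x_mat <- as.matrix(data)
  if (!is.numeric(x_mat)) abort("all predictors must be numeric")
  y <- as.numeric(response)
  if (nrow(x_mat) != length(y)) abort("response length must match data rows")
  if (anyNA(x_mat) || anyNA(y)) abort("missing values are not supported")
  n <- length(y)
  if (n < min_split) abort("fewer rows than min_split")
  tss <- node_sse(y)

  full <- grow_tree(x_mat, y, min_split, min_leaf)
  alphas <- cc_alphas(full)
  k_seq <- length(alphas)
  betas <- if (k_seq == 1) Inf else
    c(sqrt(alphas[-k_seq] * alphas[-1]), alphas[k_seq] * 2)

  # cross-validated error per candidate penalty
  set.seed(seed)
  folds <- sample(rep_len(seq_len(cv_folds), n))
  sqerr <- matrix(NA_real_, n, length(betas))
  for (f in seq_len(cv_folds)) {
    test <- folds == f
    tr_tree <- grow_tree(x_mat[!test, , drop = FALSE], y[!test],
                         min_split, min_leaf)
    for (b in seq_along(betas)) {
      coll <- prune_at(tr_tree, betas[b])
      pred <- predict_nodes(tr_tree, coll, x_mat[test, , drop = FALSE])
      sqerr[test, b] <- (y[test] - pred)^2
    }
  }
  cv_err <- colMeans(sqerr)
  cv_se <- apply(sqerr, 2, stats::sd) / sqrt(n)
  kmin <- which.min(cv_err)
  thresh <- cv_err[kmin] + cv_se[kmin]
  chosen <- max(which(cv_err <= thresh + 1e-12))  # largest penalty = smallest tree

  collapsed <- prune_at(full, betas[chosen])
  # strip child info from collapsed nodes; compute pct variance; surrogates
  keep <- rep(FALSE, length(full))
  mark <- function(id) {
    keep[id] <<- TRUE
    if (!collapsed[id]) { mark(full[[id]]$left); mark(full[[id]]$right) }
  }
  mark(1L)
  nodes <- full[keep]
  remap <- match(seq_along(full), which(keep))
  nodes <- lapply(nodes, function(nd) {
    nd$id <- remap[nd$id]
    nd$parent <- if (is.na(nd$parent)) NA_integer_ else remap[nd$parent]
    if (collapsed[which(keep)[nd$id]]) {
      nd$is_leaf <- TRUE
      nd[c("var", "threshold", "improvement")] <-
        list(NA_integer_, NA_real_, NA_real_)
      nd$left <- nd$right <- NA_integer_
    } else {
      nd$left <- remap[nd$left]; nd$right <- remap[nd$right]
      nd$pct_var <- 100 * nd$improvement / tss
      go_left <- x_mat[nd$idx, nd$var] < nd$threshold
      sur <- find_surrogates(x_mat[nd$idx, , drop = FALSE], go_left, nd$var,
                             surrogate_agreement)
      sur$variable <- colnames(x_mat)[sur$var]
      nd$surrogates <- sur
    }
    nd
  })
  leaf_sse <- sum(vapply(nodes, function(nd) if (nd$is_leaf) nd$sse else 0,
                         numeric(1)))
  structure(list(
    nodes = nodes, var_names = colnames(x_mat), n = n, tss = tss,
    total_pct_var = if (tss > 0) 100 * (1 - leaf_sse / tss) else 0,
    cv = data.frame(alpha = alphas, beta = betas, n_leaves = NA, cv_err = cv_err,
                    cv_se = cv_se),
    chosen_beta = betas[chosen],
    params = list(min_split = min_split, min_leaf = min_leaf,
                  cv_folds = cv_folds, seed = seed,
                  surrogate_agreement = surrogate_agreement)),
    class = "trait_tree")
}

#' Predict from a fitted trait tree
#'
#' @param object a `trait_tree`.
#' @param newdata data.frame with the tree's predictor columns.
#' @param ... unused.
#' @return Numeric vector of terminal-node means.
#' @export
predict.trait_tree <- function(object, newdata, ...) {
  x_mat <- as.matrix(newdata[, object$var_names, drop = FALSE])
  collapsed <- vapply(object$nodes, function(nd) nd$is_leaf, logical(1))
  predict_nodes(object$nodes, collapsed, x_mat)
}

#' Number of terminal nodes of a trait tree
#' @param tree a `trait_tree`.
#' @return Integer leaf count.
#' @export
n_leaves <- function(tree) {
  sum(vapply(tree$nodes, function(nd) nd$is_leaf, logical(1)))
}

#' @export
print.trait_tree <- function(x, digits = 3, ...) {
  cat(sprintf("trait_tree: n = %d, %d terminal node(s), %.1f%% variance explained\n",
              x$n, n_leaves(x), x$total_pct_var))
  show <- function(id, prefix) {
    nd <- x$nodes[[id]]
    if (nd$is_leaf) {
      cat(sprintf("%s* n=%d  mean dD=%.*f\n", prefix, nd$n, digits, nd$mean))
    } else {
      cat(sprintf("%s%s < %.*f  (%.1f%%)\n", prefix, x$var_names[nd$var],
                  digits, nd$threshold, nd$pct_var))
      if (nrow(nd$surrogates)) {
        cat(sprintf("%s  surrogates: %s\n", prefix,
                    paste(sprintf("%s (%.2f)", nd$surrogates$variable,
                                  nd$surrogates$agreement), collapse = ", ")))
      }
      show(nd$left, paste0(prefix, "  "))
      show(nd$right, paste0(prefix, "  "))
    }
  }
  show(1L, "")
  invisible(x)
}

#' Serializable report of a trait tree
#'
#' @param tree a `trait_tree`.
#' @return A list (JSON-ready): per node splitter, threshold, percentage
#'   variance, surrogates with agreements, terminal n and mean delta-D, plus
#'   the total variance explained.
#' @export
tree_report <- function(tree) {
  stopifnot(inherits(tree, "trait_tree"))
  nodes <- lapply(tree$nodes, function(nd) {
    base <- list(id = nd$id, n = nd$n, mean_delta_d = nd$mean,
                 terminal = nd$is_leaf)
    if (!nd$is_leaf) {
      base$splitter <- tree$var_names[nd$var]
      base$threshold <- nd$threshold
      base$pct_variance <- nd$pct_var
      base$children <- c(nd$left, nd$right)
      base$surrogates <- if (nrow(nd$surrogates)) {
        s <- nd$surrogates
        lapply(seq_len(nrow(s)), function(i) {
          list(variable = s$variable[i], threshold = s$threshold[i],
               direction = s$direction[i], agreement = s$agreement[i])
        })
      } else list()
    }
    base
  })
  list(n = tree$n, n_leaves = n_leaves(tree),
       total_pct_variance = tree$total_pct_var, nodes = nodes)
}

#' Assemble the driver dataset for the regression-tree analysis
#'
#' One row per plot x fraction: the fraction's delta-D (pooled over habitats)
#' as response and the per-trait mean of the fraction's standardized trait
#' values as predictors. Optionally restricts the fraction's members to a
#' life-form subset (the naturalized-fraction analysis uses herbs and dwarf
#' shrubs only).
#'
#' @param null_table tidy null-model table (see [habitat_summary()]).
#' @param plots long-format plot data.
#' @param registry species registry (`species`, `status`, `life_form`).
#' @param st `standardized_traits` object.
#' @param fraction which fraction's delta-D to model (`"naturalized"` or
#'   `"invasive"`).
#' @param comparison which comparison's delta-D to use as response.
#' @param life_forms optional life-form subset for the trait means.
#' @return data.frame: `plot_id`, `delta_d`, one mean-trait column per trait.
#' @export
build_driver_dataset <- function(null_table, plots, registry, st,
                                 fraction,
                                 comparison = paste0("native_vs_", fraction),
                                 life_forms = NULL) {
  sub <- null_table[null_table$fraction == fraction &
                      null_table$comparison == comparison, , drop = FALSE]
  reg_ok <- registry$species[registry$status == fraction &
                               (is.null(life_forms) |
                                  registry$life_form %in% life_forms)]
  traits <- trait_metadata()$trait
  rows <- lapply(seq_len(nrow(sub)), function(i) {
    pid <- sub$plot_id[i]
    sp <- plots$species[plots$plot_id == pid]
    sp <- intersect(sp, reg_ok)
    if (!length(sp)) return(NULL)
    mus <- colMeans(st$coords[sp, , drop = FALSE])
    cbind(data.frame(plot_id = pid, delta_d = sub$delta_d[i],
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(stats::setNames(mus, paste0("mean_", traits)))))
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) abort("no rows for driver dataset")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
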