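#' Gini impurity of a two-class node
#'
#' @param n_sp,n_rr Class counts in the node.
#' @return `1 - p^2 - (1 - p)^2` with `p = n_sp / (n_sp + n_rr)`, in
#'   \[0, 0.5\].
#' @examples
#' gini_impurity(3, 1) # 0.375
#' @export
gini_impurity <- function(n_sp, n_rr) {
  n <- n_sp + n_rr
  if (any(n < 1)) {
    abort("gini_impurity(): empty node.", class = "msclassify_domain_error")
  }
  p <- n_sp / n
  1 - p^2 - (1 - p)^2
}

# Zero-improvement splits are admitted during growth (they can enable
# deeper informative splits, e.g. checkerboard patterns); weakest-link
# pruning collapses them unless their subtree earns its keep.

# node risk in count units: n * gini(p)
node_risk <- function(n_sp, n) {
  if (n == 0) return(0)
  p <- n_sp / n
  n * (1 - p^2 - (1 - p)^2)
}

# Best split of one node.  X: numeric matrix (rows = records in the node),
# y: 0/1 integer (1 = SP).  Candidate thresholds are midpoints between
# consecutive distinct sorted values.  Returns NULL when no split has a
# positive impurity improvement.  Tie-break: larger improvement wins; at
# equal improvement the smaller threshold, then the earlier feature column.
best_split <- function(X, y, min_bucket) {
  n <- length(y)
  parent <- node_risk(sum(y), n)
  best <- NULL
  for (j in seq_len(ncol(X))) {
    ord <- order(X[, j])
    xs <- X[ord, j]
    ys <- y[ord]
    cum_sp <- cumsum(ys)
    i <- seq_len(n - 1L)
    ok <- (xs[i] < xs[i + 1L]) & (i >= min_bucket) & (n - i >= min_bucket)
    if (!any(ok)) next
    i <- i[ok]
    nl <- i
    nr <- n - i
    sl <- cum_sp[i]
    sr <- cum_sp[n] - sl
    pl <- sl / nl
    pr <- sr / nr
    risk_l <- nl * (1 - pl^2 - (1 - pl)^2)
    risk_r <- nr * (1 - pr^2 - (1 - pr)^2)
    imp <- parent - risk_l - risk_r
    k <- which.max(imp) # first max = smallest threshold (xs sorted ascending)
    if (imp[k] > -1e-12 && (is.null(best) || imp[k] > best$improvement + 1e-10)) {
      best <- list(
        var = j,
        threshold = (xs[i[k]] + xs[i[k] + 1L]) / 2,
        improvement = imp[k]
      )
    }
  }
  best
}

# Recursive greedy growth (cp = 0).  Returns a nested-list tree.
grow_node <- function(X, y, min_split, min_bucket, depth = 0L) {
  n <- length(y)
  n_sp <- sum(y)
  node <- list(n = n, n_sp = n_sp, risk = node_risk(n_sp, n), depth = depth)
  if (n < min_split || n_sp == 0L || n_sp == n || depth >= 30L) {
    node$leaf <- TRUE
    return(node)
  }
  sp <- best_split(X, y, min_bucket)
  if (is.null(sp)) {
    node$leaf <- TRUE
    return(node)
  }
  node$leaf <- FALSE
  node$var <- sp$var
  node$threshold <- sp$threshold
  node$improvement <- sp$improvement
  left_idx <- X[, sp$var] < sp$threshold
  node$left <- grow_node(X[left_idx, , drop = FALSE], y[left_idx],
                         min_split, min_bucket, depth + 1L)
  node$right <- grow_node(X[!left_idx, , drop = FALSE], y[!left_idx],
                          min_split, min_bucket, depth + 1L)
  node
}

# Flatten a nested tree to parallel vectors (preorder).  Children always have
# larger indices than their parent.
flatten_tree <- function(root) {
  env <- new.env()
  env$var <- integer(); env$threshold <- numeric(); env$left <- integer()
  env$right <- integer(); env$n <- integer(); env$n_sp <- integer()
  env$risk <- numeric(); env$improvement <- numeric(); env$depth <- integer()
  rec <- function(node) {
    id <- length(env$n) + 1L
    env$n[id] <- node$n; env$n_sp[id] <- node$n_sp
    env$risk[id] <- node$risk; env$depth[id] <- node$depth
    env$var[id] <- NA_integer_; env$threshold[id] <- NA_real_
    env$left[id] <- NA_integer_; env$right[id] <- NA_integer_
    env$improvement[id] <- NA_real_
    if (!node$leaf) {
      env$var[id] <- node$var
      env$threshold[id] <- node$threshold
      env$improvement[id] <- node$improvement
      env$left[id] <- rec(node$left)
      env$right[id] <- rec(node$right)
    }
    id
  }
  rec(root)
  tibble::tibble(
    id = seq_along(env$n), var = env$var, threshold = env$threshold,
    left = env$left, right = env$right, n = env$n, n_sp = env$n_sp,
    risk = env$risk, improvement = env$improvement, depth = env$depth
  )
}

# Weakest-link cost-complexity analysis.  For every node, the complexity
# parameter (relative to the root impurity risk) at which it collapses to a
# leaf.  True leaves collapse at 0.  Implements the classic iterative scheme:
# repeatedly find the internal node(s) with minimal
# g = (risk(node) - risk(subtree)) / (leaves(subtree) - 1)
# and collapse them (descendants collapse at the same alpha).
collapse_alphas <- function(tr) {
  m <- nrow(tr)
  alpha <- rep(0, m)
  is_leaf <- is.na(tr$left)
  root_risk <- tr$risk[1]
  if (all(is_leaf) || root_risk <= 0) {
    return(alpha)
  }
  # current subtree risk and leaf count per node
  R <- numeric(m)
  L <- integer(m)
  active_leaf <- is_leaf # leaf status under current pruning
  recompute <- function() {
    for (id in m:1) {
      if (active_leaf[id]) {
        R[id] <<- tr$risk[id]
        L[id] <<- 1L
      } else {
        R[id] <<- R[tr$left[id]] + R[tr$right[id]]
        L[id] <<- L[tr$left[id]] + L[tr$right[id]]
      }
    }
  }
  mark_subtree <- function(id, a) {
    stack <- id
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (!active_leaf[cur]) {
        alpha[cur] <<- a
        active_leaf[cur] <<- TRUE
        stack <- c(stack, tr$left[cur], tr$right[cur])
      }
    }
  }
  repeat {
    recompute()
    internal <- which(!active_leaf)
    if (!length(internal)) break
    g <- (tr$risk[internal] - R[internal]) / pmax(L[internal] - 1L, 1L)
    g_rel <- g / root_risk
    a_min <- min(g_rel)
    hit <- internal[g_rel <= a_min + 1e-12]
    # collapse top-most hits (their descendants go with them)
    for (id in hit) {
      if (!active_leaf[id]) mark_subtree(id, a_min)
    }
  }
  alpha
}

#' Fit a phenotype decision tree by recursive partitioning
#'
#' From-scratch CART for the two-class RR/SP problem: a fully grown binary
#' tree (greedy Gini splits, candidate thresholds at midpoints between
#' consecutive distinct feature values) is pruned by weakest-link
#' cost-complexity pruning.  The complexity parameter `cp` is the minimum
#' improvement in training impurity — relative to the root impurity — that a
#' split must *exceed* to survive pruning.  With `cp = "auto"` it is chosen
#' by stratified k-fold cross-validation as the value with the smallest
#' cross-validated misclassification error (ties broken toward the larger
#' `cp`, i.e. the simpler tree).
#'
#' @param data Data frame holding the feature columns and the outcome column.
#' @param outcome Name of the outcome column; values `"RR"`/`"SP"` (or a
#'   factor with those levels).
#' @param features Character vector of numeric feature columns, e.g.
#'   `c("edss", "age")`.  Records with missing features are rejected.
#' @param cp `"auto"` for cross-validated selection, or a non-negative
#'   number (the headline model uses `cp = 1e-4`).
#' @param cv_folds Number of cross-validation folds (default 10), stratified
#'   by class.
#' @param min_node_size Minimum records in a node for a split to be
#'   attempted (default 20, the rpart `minsplit` convention).
#' @param min_bucket Minimum records in a child node; defaults to
#'   `max(1, round(min_node_size / 3))` as in rpart.
#' @param seed Integer seed for the fold assignment; fits are fully
#'   deterministic given the data and seed.
#' @return An object of class `sp_tree` with `print()`, `predict()`,
#'   [generics::tidy()] and [generics::glance()] methods.
#' @examples
#' d <- data.frame(
#'   edss = c(1, 2, 2, 3, 5, 6, 6.5, 7),
#'   age = c(30, 40, 50, 45, 60, 55, 62, 70),
#'   phenotype = c("RR", "RR", "RR", "RR", "SP", "SP", "SP", "SP")
#' )
#' fit <- fit_sp_tree(d, outcome = "phenotype", cp = 0,
#'                    min_node_size = 2, min_bucket = 1)
#' predict(fit, d)
#' @export
fit_sp_tree <- function(data, outcome = "assigned_phenotype",
                        features = c("edss", "age"),
                        cp = "auto", cv_folds = 10,
                        min_node_size = 20, min_bucket = NULL,
                        seed = 1L) {
  check_columns(data, c(features, outcome), "training data")
  y_raw <- as.character(data[[outcome]])
  if (!all(y_raw %in% c("RR", "SP"))) {
    abort("Outcome column must contain only 'RR' and 'SP'.",
          class = "msclassify_domain_error")
  }
  X <- as.matrix(data[, features, drop = FALSE])
  storage.mode(X) <- "double"
  if (anyNA(X)) {
    abort("Missing feature values are not supported; remove incomplete records.",
          class = "msclassify_domain_error")
  }
  y <- as.integer(y_raw == "SP")
  if (is.null(min_bucket)) min_bucket <- max(1L, as.integer(round(min_node_size / 3)))

  root <- grow_node(X, y, min_node_size, min_bucket)
  tr <- flatten_tree(root)
  tr$collapse_alpha <- collapse_alphas(tr)

  cv_table <- NULL
  if (identical(cp, "auto")) {
    sel <- select_cp_cv(X, y, tr, cv_folds, min_node_size, min_bucket, seed)
    cp <- sel$cp
    cv_table <- sel$table
  } else {
    cp <- as.numeric(cp)
    if (is.na(cp) || cp < 0) {
      abort("cp must be 'auto' or a non-negative number.",
            class = "msclassify_domain_error")
    }
  }

  structure(
    list(
      tree = tr, cp = cp, cv_table = cv_table,
      features = features, n = length(y), n_sp = sum(y),
      min_node_size = min_node_size, min_bucket = min_bucket,
      seed = seed
    ),
    class = "sp_tree"
  )
}

# Leaf status at complexity cp: a node acts as a leaf when it is a true leaf
# or its collapse alpha is <= cp (splits must strictly exceed cp to survive).
effective_leaf <- function(tr, cp) {
  is.na(tr$left) | tr$collapse_alpha <= cp + 1e-12
}

# Route records through the (pruned) tree; returns terminal node ids.
route_to_leaves <- function(tr, X, cp) {
  leafish <- effective_leaf(tr, cp)
  n <- nrow(X)
  out <- integer(n)
  for (r in seq_len(n)) {
    id <- 1L
    while (!leafish[id]) {
      id <- if (X[r, tr$var[id]] < tr$threshold[id]) tr$left[id] else tr$right[id]
    }
    out[r] <- id
  }
  out
}

#' Predict from a fitted phenotype tree
#'
#' @param object An `sp_tree`.
#' @param newdata Data frame containing the model's feature columns.
#' @param type `"prob"` for the leaf SP fraction, `"class"` for the RR/SP
#'   label (SP when the leaf SP fraction exceeds 0.5), or `"tibble"` for
#'   both plus the terminal node id.
#' @param ... Unused.
#' @export
predict.sp_tree <- function(object, newdata,
                            type = c("tibble", "prob", "class"), ...) {
  type <- match.arg(type)
  check_columns(newdata, object$features, "newdata")
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  storage.mode(X) <- "double"
  tr <- object$tree
  leaf_id <- route_to_leaves(tr, X, object$cp)
  prob <- tr$n_sp[leaf_id] / tr$n[leaf_id]
  cls <- ifelse(prob > 0.5, "SP", "RR")
  switch(type,
    prob = prob,
    class = cls,
    tibble = tibble::tibble(node = leaf_id, sp_probability = prob, label = cls)
  )
}

# Stratified fold assignment, deterministic for a given seed.
stratified_folds <- function(y, k, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    if (length(idx) < k) {
      abort(sprintf(
        "Cannot build %d stratified folds: class with only %d record(s).",
        k, length(idx)
      ), class = "msclassify_domain_error")
    }
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

# Cross-validated cp selection over the pruning sequence of the full-data
# tree.  Candidate cps are geometric means of consecutive distinct collapse
# alphas (rpart's convention), bracketed by 0 (the full tree) and a value
# beyond the largest alpha (the root stump); thinned to at most 64 values
# for large trees.
select_cp_cv <- function(X, y, tr, k, min_split, min_bucket, seed) {
  alphas <- sort(unique(tr$collapse_alpha[tr$collapse_alpha > 0]))
  if (!length(alphas)) {
    return(list(
      cp = 0,
      table = tibble::tibble(cp = 0, n_leaves = 1L,
                             cv_error = min(mean(y), 1 - mean(y)),
                             cv_se = NA_real_)
    ))
  }
  cand <- c(0, sqrt(alphas[-length(alphas)] * alphas[-1]), max(alphas) * 1.5)
  if (length(cand) > 64) {
    keep <- unique(round(seq(1, length(cand), length.out = 64)))
    cand <- cand[keep]
  }

  fold <- stratified_folds(y, k, seed)
  n <- length(y)
  err <- matrix(0, nrow = length(cand), ncol = k) # misclassification counts

  for (f in seq_len(k)) {
    tr_idx <- fold != f
    root_f <- grow_node(X[tr_idx, , drop = FALSE], y[tr_idx],
                        min_split, min_bucket)
    tf <- flatten_tree(root_f)
    tf$collapse_alpha <- collapse_alphas(tf)
    Xte <- X[!tr_idx, , drop = FALSE]
    yte <- y[!tr_idx]
    # For each test record, the path of nodes from the root to its deepest
    # leaf; along that path collapse alphas are non-increasing, so the
    # stopping node at cp is found by counting path alphas > cp.
    for (r in seq_len(nrow(Xte))) {
      path <- integer(0)
      id <- 1L
      repeat {
        path <- c(path, id)
        if (is.na(tf$left[id])) break
        id <- if (Xte[r, tf$var[id]] < tf$threshold[id]) tf$left[id] else tf$right[id]
      }
      pa <- tf$collapse_alpha[path] # alpha at which each path node is a leaf
      # node i on the path is internal at cp iff pa[i] > cp; walking stops at
      # the first node with pa <= cp
      first_leaf <- vapply(cand, function(cc) {
        w <- which(pa <= cc + 1e-12)
        if (length(w)) w[1] else length(path)
      }, integer(1))
      pred_nodes <- path[first_leaf]
      pred_sp <- tf$n_sp[pred_nodes] / tf$n[pred_nodes] > 0.5
      err[, f] <- err[, f] + as.integer(pred_sp != (yte[r] == 1L))
    }
  }

  cv_err <- rowSums(err) / n
  cv_se <- apply(err / (n / k), 1, stats::sd) / sqrt(k)
  best_err <- min(cv_err)
  cp_sel <- max(cand[cv_err <= best_err + 1e-12]) # ties -> simpler tree
  tab <- tibble::tibble(
    cp = cand,
    n_leaves = vapply(cand, function(cc) sum(effective_leaf(tr, cc) &
      !leaf_is_internal_descendant(tr, cc)), integer(1)),
    cv_error = cv_err,
    cv_se = cv_se
  )
  list(cp = cp_sel, table = tab)
}

# Helper: nodes that are (effective) leaves but buried below an effective
# leaf ancestor must not be counted as terminal nodes.
leaf_is_internal_descendant <- function(tr, cp) {
  leafish <- effective_leaf(tr, cp)
  buried <- logical(nrow(tr))
  for (id in seq_len(nrow(tr))) {
    if (!is.na(tr$left[id]) && (leafish[id] || buried[id])) {
      buried[tr$left[id]] <- TRUE
      buried[tr$right[id]] <- TRUE
    }
  }
  buried
}

#' Number of terminal nodes of a fitted tree at its complexity parameter
#' @param object An `sp_tree`.
#' @param cp Complexity parameter; defaults to the fitted one.
#' @return Integer leaf count.
#' @export
n_leaves <- function(object, cp = object$cp) {
  tr <- object$tree
  sum(effective_leaf(tr, cp) & !leaf_is_internal_descendant(tr, cp))
}

#' Prune a fitted tree at a different complexity parameter
#'
#' Weakest-link pruning: every split whose relative impurity improvement
#' does not exceed `cp` is collapsed.  Pruned trees are nested: for
#' `cp1 <= cp2` the tree at `cp2` is a subtree of the tree at `cp1`.
#'
#' @param object An `sp_tree`.
#' @param cp New non-negative complexity parameter.
#' @return A new `sp_tree` sharing the grown tree, evaluated at `cp`.
#' @export
prune_sp_tree <- function(object, cp) {
  stopifnot(inherits(object, "sp_tree"), cp >= 0)
  object$cp <- cp
  object$cv_table <- NULL
  object
}

#' Variable importance of a fitted tree
#'
#' Per-variable sum of the impurity improvements of the splits retained at
#' the fitted `cp`, normalised to sum to one.  A stump reports all zeros.
#'
#' @param object An `sp_tree`.
#' @return A tibble with columns `variable`, `importance`.
#' @export
variable_importance <- function(object) {
  stopifnot(inherits(object, "sp_tree"))
  tr <- object$tree
  active <- !effective_leaf(tr, object$cp) &
    !leaf_is_internal_descendant(tr, object$cp)
  imp <- vapply(seq_along(object$features), function(j) {
    sum(tr$improvement[active & tr$var == j], na.rm = TRUE)
  }, numeric(1))
  total <- sum(imp)
  tibble::tibble(
    variable = object$features,
    importance = if (total > 0) imp / total else imp
  )
}

#' @export
print.sp_tree <- function(x, ...) {
  cat(sprintf(
    "<sp_tree> %d leaves (cp = %g), trained on %d records (%d SP, %d RR)\n",
    n_leaves(x), x$cp, x$n, x$n_sp, x$n - x$n_sp
  ))
  if (!is.null(x$cv_table)) {
    best <- x$cv_table[which.min(x$cv_table$cv_error), ]
    cat(sprintf("  cp selected by cross-validation (cv error %.4f)\n",
                best$cv_error))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted phenotype tree
#'
#' One row per node retained at the fitted complexity parameter, in preorder.
#'
#' @param x An `sp_tree`.
#' @param ... Unused.
#' @return A tibble with node id, depth, split variable and threshold (`NA`
#'   for leaves), record counts, leaf SP fraction and label.
#' @export
tidy.sp_tree <- function(x, ...) {
  tr <- x$tree
  leafish <- effective_leaf(tr, x$cp)
  buried <- leaf_is_internal_descendant(tr, x$cp)
  keep <- !buried
  tibble::tibble(
    node = tr$id[keep],
    depth = tr$depth[keep],
    leaf = leafish[keep],
    variable = ifelse(leafish[keep], NA_character_,
                      x$features[tr$var[keep]]),
    threshold = ifelse(leafish[keep], NA_real_, tr$threshold[keep]),
    n = tr$n[keep],
    n_sp = tr$n_sp[keep],
    sp_fraction = tr$n_sp[keep] / tr$n[keep],
    label = ifelse(tr$n_sp[keep] / tr$n[keep] > 0.5, "SP", "RR")
  )
}

#' One-row summary of a fitted phenotype tree
#' @param x An `sp_tree`.
#' @param ... Unused.
#' @export
glance.sp_tree <- function(x, ...) {
  td <- tidy(x)
  tibble::tibble(
    n = x$n,
    n_sp = x$n_sp,
    cp = x$cp,
    n_leaves = sum(td$leaf),
    depth = max(td$depth),
    cv_error = if (!is.null(x$cv_table)) min(x$cv_table$cv_error) else NA_real_
  )
}

#' Serialize / restore a fitted tree as JSON
#'
#' The JSON schema stores the node table (preorder; split variable names,
#' thresholds, counts, collapse alphas) plus the fitted `cp` and feature
#' names, so a saved tree reloads into an equivalent lookup classifier.
#'
#' @param object An `sp_tree`.
#' @param path Output path for `write_sp_tree()`; input path for
#'   `read_sp_tree()`.
#' @return `read_sp_tree()` returns an `sp_tree`.
#' @export
write_sp_tree <- function(object, path) {
  stopifnot(inherits(object, "sp_tree"))
  payload <- list(
    format = "msclassify_sp_tree",
    version = 1L,
    features = object$features,
    cp = object$cp,
    n = object$n, n_sp = object$n_sp,
    min_node_size = object$min_node_size,
    min_bucket = object$min_bucket,
    nodes = object$tree
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  invisible(path)
}

#' @rdname write_sp_tree
#' @export
read_sp_tree <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "msclassify_sp_tree")) {
    abort("Not an msclassify tree file.", class = "msclassify_io_error")
  }
  nodes <- tibble::as_tibble(payload$nodes)
  for (col in c("var", "left", "right", "n", "n_sp", "depth", "id")) {
    nodes[[col]] <- as.integer(nodes[[col]])
  }
  structure(
    list(
      tree = nodes, cp = payload$cp, cv_table = NULL,
      features = payload$features, n = payload$n, n_sp = payload$n_sp,
      min_node_size = payload$min_node_size, min_bucket = payload$min_bucket,
      seed = NA_integer_
    ),
    class = "sp_tree"
  )
}
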