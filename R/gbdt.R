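#' Gradient-boosting configuration
#'
#' Hyperparameters of the from-scratch gradient-boosted regression trees.
#' Trees are grown leaf-wise (best-first) under a simultaneous leaf-count
#' cap (`num_leaves`) and depth cap (`max_depth`), which honours both of
#' the common library presets at once. `min_child_weight` is interpreted as
#' a minimum leaf row count: under unweighted squared loss the hessian of
#' each row is 1, so the hessian sum of a leaf equals its row count.
#'
#' @param n_trees number of boosting rounds K (>= 0).
#' @param learning_rate shrinkage rho in (0, 1].
#' @param max_depth maximum tree depth (root = depth 0).
#' @param num_leaves maximum leaves per tree J (>= 2).
#' @param min_child_samples minimum rows in each child.
#' @param min_child_weight minimum hessian (row count) in each child.
#' @param subsample row fraction sampled (without replacement) per round.
#' @param colsample column fraction sampled per tree.
#' @param seed integer; round `k` reseeds the sampler with `seed + k`, so
#'   fits are bit-reproducible.
#' @return a `gbdt_config`.
#' @export
gbdt_config <- function(n_trees = 200, learning_rate = 0.1, max_depth = 5,
                        num_leaves = 15, min_child_samples = 5,
                        min_child_weight = 1, subsample = 1, colsample = 1,
                        seed = 1L) {
  if (n_trees < 0) stop("`n_trees` must be >= 0", call. = FALSE)
  if (learning_rate <= 0 || learning_rate > 1) stop("`learning_rate` must be in (0, 1]", call. = FALSE)
  if (num_leaves < 2) stop("`num_leaves` must be >= 2", call. = FALSE)
  if (max_depth < 1) stop("`max_depth` must be >= 1", call. = FALSE)
  if (subsample <= 0 || subsample > 1) stop("`subsample` must be in (0, 1]", call. = FALSE)
  if (colsample <= 0 || colsample > 1) stop("`colsample` must be in (0, 1]", call. = FALSE)
  structure(
    list(n_trees = as.integer(n_trees), learning_rate = learning_rate,
         max_depth = as.integer(max_depth), num_leaves = as.integer(num_leaves),
         min_child_samples = as.integer(min_child_samples),
         min_child_weight = min_child_weight, subsample = subsample,
         colsample = colsample, seed = as.integer(seed)),
    class = "gbdt_config"
  )
}

#' Named hyperparameter presets
#'
#' `"lgbm-paper"` and `"xgb-paper"` mirror the two library configurations
#' used in the original weight-estimation experiments (4000 and 2000 rounds
#' at learning rate 0.1); `"desk"` is the default 200-round configuration
#' sized for desk-scale synthetic experiments.
#'
#' @param name one of `"desk"`, `"lgbm-paper"`, `"xgb-paper"`.
#' @param seed integer seed stored in the config.
#' @return a [gbdt_config()].
#' @export
gbdt_preset <- function(name = c("desk", "lgbm-paper", "xgb-paper"), seed = 1L) {
  switch(match.arg(name),
    "desk" = gbdt_config(seed = seed),
    "lgbm-paper" = gbdt_config(n_trees = 4000, learning_rate = 0.1,
                               num_leaves = 15, max_depth = 5,
                               min_child_samples = 15, min_child_weight = 0.01,
                               subsample = 0.8, colsample = 1, seed = seed),
    "xgb-paper" = gbdt_config(n_trees = 2000, learning_rate = 0.1,
                              max_depth = 5, num_leaves = 32,
                              min_child_samples = 1, min_child_weight = 1,
                              subsample = 0.8, colsample = 0.7, seed = seed)
  )
}

min_child_count <- function(config) {
  max(config$min_child_samples, ceiling(config$min_child_weight))
}

new_tree <- function() {
  list(feature = integer(0), threshold = numeric(0), left = integer(0),
       right = integer(0), value = numeric(0), depth = integer(0),
       is_leaf = logical(0))
}

tree_add_node <- function(tree, rows, resid, depth) {
  i <- length(tree$value) + 1L
  tree$feature[i] <- NA_integer_
  tree$threshold[i] <- NA_real_
  tree$left[i] <- NA_integer_
  tree$right[i] <- NA_integer_
  tree$value[i] <- mean(resid[rows])
  tree$depth[i] <- depth
  tree$is_leaf[i] <- TRUE
  list(tree = tree, id = i)
}

#' Fit a single regression tree to residuals
#'
#' Greedy best-first (leaf-wise) growth: at every step the leaf whose best
#' split yields the largest squared-error reduction is split, scanning
#' midpoints of consecutive distinct sorted values in every candidate
#' column. Growth stops at `num_leaves` leaves, `max_depth`, or when no
#' split leaves `min_child_samples` (and `min_child_weight`) rows in both
#' children. Leaf values are the mean residual of their region. If the
#' root has no valid split the tree is a single leaf.
#'
#' @param X numeric feature matrix.
#' @param residuals numeric vector, one per row of `X`.
#' @param config a [gbdt_config()].
#' @param rows optional row subset to train on (default all).
#' @param cols optional column subset to consider (default all).
#' @return a `gbdt_tree`.
#' @export
fit_tree <- function(X, residuals, config = gbdt_config(), rows = NULL,
                     cols = NULL) {
  X <- as.matrix(X)
  if (is.null(rows)) rows <- seq_len(nrow(X))
  if (is.null(cols)) cols <- seq_len(ncol(X))
  ord <- apply(X, 2, order, method = "radix") - 1L
  if (!is.matrix(ord)) ord <- matrix(ord, ncol = ncol(X))
  fit_tree_impl(X, residuals, config, rows, cols, ord)
}

fit_tree_impl <- function(X, resid, config, rows, cols, ord) {
  n <- nrow(X)
  min_cnt <- min_child_count(config)
  tree <- new_tree()
  root <- tree_add_node(tree, rows, resid, 0L)
  tree <- root$tree
  node_rows <- list(rows)
  cand <- list()  # per node id: list(gain, feature, threshold) or NULL
  propose <- function(id) {
    rws <- node_rows[[id]]
    if (tree$depth[id] >= config$max_depth) return(NULL)
    if (length(rws) < max(2L * min_cnt, config$min_child_samples)) return(NULL)
    member <- logical(n)
    member[rws] <- TRUE
    sp <- gbdt_best_split(X, ord, member, resid, as.integer(cols) - 1L, min_cnt)
    # guard against floating-point phantom gains on pure nodes
    parent_score <- sum(resid[rws])^2 / length(rws)
    if (!is.finite(sp$gain) || sp$gain <= 1e-11 * max(1, parent_score)) return(NULL)
    sp
  }
  cand[[1L]] <- list(propose(1L))
  n_leaves <- 1L
  while (n_leaves < config$num_leaves) {
    gains <- vapply(seq_along(cand), function(i) {
      s <- cand[[i]][[1L]]
      if (is.null(s) || !tree$is_leaf[i]) -Inf else s$gain
    }, numeric(1))
    best <- which.max(gains)
    if (!is.finite(gains[best])) break
    sp <- cand[[best]][[1L]]
    rws <- node_rows[[best]]
    f <- sp$feature + 1L
    go_left <- X[rws, f] <= sp$threshold
    lrows <- rws[go_left]
    rrows <- rws[!go_left]
    l <- tree_add_node(tree, lrows, resid, tree$depth[best] + 1L)
    tree <- l$tree
    r <- tree_add_node(tree, rrows, resid, tree$depth[best] + 1L)
    tree <- r$tree
    tree$is_leaf[best] <- FALSE
    tree$feature[best] <- f
    tree$threshold[best] <- sp$threshold
    tree$left[best] <- l$id
    tree$right[best] <- r$id
    node_rows[[l$id]] <- lrows
    node_rows[[r$id]] <- rrows
    cand[[best]] <- list(NULL)
    cand[[l$id]] <- list(propose(l$id))
    cand[[r$id]] <- list(propose(r$id))
    n_leaves <- n_leaves + 1L
  }
  structure(tree, class = "gbdt_tree")
}

predict_tree <- function(tree, X) {
  n <- nrow(X)
  out <- numeric(n)
  stack <- list(list(id = 1L, rows = seq_len(n)))
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    id <- top$id; rws <- top$rows
    if (length(rws) == 0L) next
    if (tree$is_leaf[id]) {
      out[rws] <- tree$value[id]
    } else {
      go_left <- X[rws, tree$feature[id]] <= tree$threshold[id]
      stack <- c(stack,
                 list(list(id = tree$left[id], rows = rws[go_left]),
                      list(id = tree$right[id], rows = rws[!go_left])))
    }
  }
  out
}

#' Fit a gradient-boosted regression-tree model
#'
#' Stagewise residual boosting under squared loss: the model starts at the
#' training-mean prediction `f0 = mean(y)`; each round fits a regression
#' tree to the current residuals `y - f(x)` (the negative gradient of the
#' squared loss) on a row subsample, and the prediction is updated by
#' `learning_rate` times the tree's leaf values. Row subsampling is
#' redrawn each round (without replacement) from a sampler reseeded with
#' `config$seed + round`; the column subsample is redrawn per tree.
#'
#' @param X numeric matrix (or data frame) of features.
#' @param y numeric target (body weight, kg).
#' @param config a [gbdt_config()].
#' @return a `gbdt_model`: list with `f0`, `trees`, `learning_rate`,
#'   `config`, `feature_names`, and the per-round training MSE trace
#'   `staged_train_mse` (length `n_trees + 1`).
#' @export
fit_gbdt <- function(X, y, config = gbdt_config()) {
  X <- as.matrix(X)
  if (nrow(X) < 1L) stop("empty training data", call. = FALSE)
  if (length(y) != nrow(X)) stop("`y` length must match rows of `X`", call. = FALSE)
  if (!all(is.finite(y))) stop("target contains non-finite values", call. = FALSE)
  n <- nrow(X); p <- ncol(X)
  f0 <- mean(y)
  pred <- rep(f0, n)
  trees <- vector("list", config$n_trees)
  staged <- numeric(config$n_trees + 1L)
  staged[1L] <- mean((y - pred)^2)
  ord <- apply(X, 2, order, method = "radix") - 1L
  if (!is.matrix(ord)) ord <- matrix(ord, ncol = p)
  for (k in seq_len(config$n_trees)) {
    rows <- seq_len(n)
    cols <- seq_len(p)
    if (config$subsample < 1 || config$colsample < 1) {
      with_seed(config$seed + k, {
        if (config$subsample < 1) {
          rows <- sort(sample.int(n, max(1L, floor(config$subsample * n))))
        }
        if (config$colsample < 1) {
          cols <- sort(sample.int(p, max(1L, floor(config$colsample * p))))
        }
      })
    }
    resid <- y - pred
    tree <- fit_tree_impl(X, resid, config, rows, cols, ord)
    pred <- pred + config$learning_rate * predict_tree(tree, X)
    trees[[k]] <- tree
    staged[k + 1L] <- mean((y - pred)^2)
  }
  structure(
    list(f0 = f0, trees = trees, learning_rate = config$learning_rate,
         config = config, n_features = p, feature_names = colnames(X),
         staged_train_mse = staged),
    class = "gbdt_model"
  )
}

#' Predict body weight with a fitted GBDT model
#'
#' `f(x) = f0 + rho * sum_k tree_k(x)`. Deterministic; column count must
#' match training.
#'
#' @param object a `gbdt_model`.
#' @param newdata matrix or data frame of features.
#' @param ... unused.
#' @return numeric predictions (kg).
#' @export
predict.gbdt_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != object$n_features) {
    stop(sprintf("model was trained on %d features, got %d",
                 object$n_features, ncol(X)), call. = FALSE)
  }
  pred <- rep(object$f0, nrow(X))
  for (tree in object$trees) {
    pred <- pred + object$learning_rate * predict_tree(tree, X)
  }
  pred
}

#' @export
print.gbdt_model <- function(x, ...) {
  cat(sprintf("<gbdt_model> f0 = %.4f, %d trees, learning rate %g\n",
              x$f0, length(x$trees), x$learning_rate))
  invisible(x)
}

#' Per-round training loss of a boosted model
#'
#' Replays the boosting sequence on `(X, y)` and reports the MSE after each
#' round, a length `K + 1` curve starting at the mean-prediction loss
#' (the population variance of `y` when evaluated on the training set).
#'
#' @param model a `gbdt_model`.
#' @param X feature matrix.
#' @param y targets.
#' @return numeric vector of length `n_trees + 1`.
#' @export
staged_loss <- function(model, X, y) {
  X <- as.matrix(X)
  pred <- rep(model$f0, nrow(X))
  out <- numeric(length(model$trees) + 1L)
  out[1L] <- mean((y - pred)^2)
  for (k in seq_along(model$trees)) {
    pred <- pred + model$learning_rate * predict_tree(model$trees[[k]], X)
    out[k + 1L] <- mean((y - pred)^2)
  }
  out
}

#' Save / load a GBDT model as JSON
#'
#' The model is serialised as a documented JSON tree dump: `f0`,
#' `learning_rate`, `n_features`, `feature_names`, and one record per node
#' and tree (`feature`, `threshold`, `left`, `right`, `value`, `is_leaf`).
#'
#' @param model a `gbdt_model`.
#' @param path JSON file.
#' @return `path` invisibly (`gbdt_save`); the model (`gbdt_load`).
#' @export
gbdt_save <- function(model, path) {
  dump <- list(
    format = "broilerwt-gbdt-1",
    f0 = model$f0,
    learning_rate = model$learning_rate,
    n_features = model$n_features,
    feature_names = model$feature_names,
    trees = lapply(model$trees, function(tr) {
      data.frame(feature = tr$feature, threshold = tr$threshold,
                 left = tr$left, right = tr$right, value = tr$value,
                 depth = tr$depth, is_leaf = tr$is_leaf)
    })
  )
  jsonlite::write_json(dump, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname gbdt_save
#' @param path JSON file.
#' @export
gbdt_load <- function(path) {
  dump <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(dump$format, "broilerwt-gbdt-1")) {
    stop("not a broilerwt GBDT model file", call. = FALSE)
  }
  trees <- lapply(dump$trees, function(df) {
    structure(list(
      feature = as.integer(df$feature), threshold = as.numeric(df$threshold),
      left = as.integer(df$left), right = as.integer(df$right),
      value = as.numeric(df$value), depth = as.integer(df$depth),
      is_leaf = as.logical(df$is_leaf)
    ), class = "gbdt_tree")
  })
  structure(
    list(f0 = dump$f0, trees = trees, learning_rate = dump$learning_rate,
         config = NULL, n_features = dump$n_features,
         feature_names = dump$feature_names, staged_train_mse = NULL),
    class = "gbdt_model"
  )
}
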