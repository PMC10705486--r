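#' Regression metrics for weight estimation
#'
#' Mean absolute error, mean squared error, root mean squared error and the
#' coefficient of determination:
#' `MAE = mean(|y - yhat|)`, `MSE = mean((y - yhat)^2)`,
#' `RMSE = sqrt(MSE)`, `R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`.
#' A constant truth vector with nonzero residuals leaves R2 undefined and
#' is an error; a perfect fit reports R2 = 1 regardless.
#'
#' @param y true weights (kg).
#' @param yhat estimated weights (kg).
#' @return a `metrics_report`: list with `mae`, `mse`, `rmse`, `r2`, `n`.
#' @export
regression_metrics <- function(y, yhat) {
  if (length(y) == 0L || length(y) != length(yhat)) {
    stop("`y` and `yhat` must have equal nonzero length", call. = FALSE)
  }
  res <- y - yhat
  mse <- mean(res^2)
  sstot <- sum((y - mean(y))^2)
  r2 <- if (sum(res^2) == 0) {
    1
  } else if (sstot == 0) {
    stop("R2 is undefined: `y` is constant but residuals are nonzero", call. = FALSE)
  } else {
    1 - sum(res^2) / sstot
  }
  structure(
    list(mae = mean(abs(res)), mse = mse, rmse = sqrt(mse), r2 = r2,
         n = length(y)),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("MAE %.6f kg  MSE %.6f  RMSE %.6f kg  R2 %.6f  (n = %d)\n",
              x$mae, x$mse, x$rmse, x$r2, x$n))
  invisible(x)
}

#' Weight-class bin edges
#'
#' Five bins of width 0.3 kg spanning 0.85-2.35 kg, the grouping used to
#' diagnose accuracy across light, medium and heavy birds of the same age.
#'
#' @return numeric vector of 6 edges.
#' @export
weight_class_edges <- function() seq(0.85, 2.35, by = 0.3)

#' Per-weight-class mean absolute error
#'
#' Bins the true weights into 0.3 kg classes (half-open `[lo, hi)`, last
#' bin closed) and reports the MAE and count per occupied bin; empty bins
#' are absent from the result, not reported as zero.
#'
#' @param y true weights (kg); must lie within the bin range unless
#'   `overflow = TRUE`, which adds open-ended bins below and above.
#' @param yhat estimated weights (kg).
#' @param edges bin edges (default [weight_class_edges()]).
#' @param overflow allow weights outside the edge range.
#' @return data frame with `bin_lo`, `bin_hi`, `n`, `mae`.
#' @export
weight_class_mae <- function(y, yhat, edges = weight_class_edges(),
                             overflow = FALSE) {
  if (length(y) != length(yhat)) stop("length mismatch", call. = FALSE)
  lo <- edges[-length(edges)]
  hi <- edges[-1L]
  if (overflow) {
    lo <- c(-Inf, lo, edges[length(edges)])
    hi <- c(edges[1L], hi, Inf)
  } else if (any(y < edges[1L] | y > edges[length(edges)])) {
    stop(sprintf("weights outside [%g, %g] kg; use `overflow = TRUE` to bin them",
                 edges[1L], edges[length(edges)]), call. = FALSE)
  }
  bin <- findInterval(y, c(lo, hi[length(hi)]), rightmost.closed = TRUE)
  occupied <- sort(unique(bin))
  out <- data.frame(
    bin_lo = lo[occupied], bin_hi = hi[occupied],
    n = vapply(occupied, function(b) sum(bin == b), integer(1)),
    mae = vapply(occupied, function(b) mean(abs(y[bin == b] - yhat[bin == b])),
                 numeric(1))
  )
  out
}

#' Seeded (optionally grouped) train/test split
#'
#' Shuffles records with a fixed seed and splits them `train_fraction` /
#' `1 - train_fraction`. When `group` ids are given (several images of the
#' same physical animal), every group is kept entirely on one side to
#' prevent leakage of an animal's appearance from train to test.
#'
#' @param records data frame (or an integer count of records).
#' @param train_fraction fraction assigned to training, in (0, 1).
#' @param seed integer seed.
#' @param group optional vector of group ids (length = records) or the name
#'   of a column of `records`.
#' @return list with `train` and `test` (data frames, or index vectors when
#'   `records` was a count), plus attributes `train_idx` and `test_idx`.
#' @export
train_test_split <- function(records, train_fraction = 0.7, seed = 1L,
                             group = NULL) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must be in (0, 1)", call. = FALSE)
  }
  n <- if (is.data.frame(records)) nrow(records) else as.integer(records)
  if (n < 2L) stop("need at least 2 records to split", call. = FALSE)
  if (is.character(group) && length(group) == 1L && is.data.frame(records)) {
    group <- records[[group]]
  }
  if (is.null(group)) group <- seq_len(n)
  if (length(group) != n) stop("`group` length must match records", call. = FALSE)
  target <- floor(train_fraction * n + 1e-9)
  train_idx <- with_seed(seed, {
    gs <- unique(group)
    gs <- gs[sample.int(length(gs))]
    take <- integer(0)
    count <- 0L
    for (g in gs) {
      idx <- which(group == g)
      if (count + length(idx) > target && count > 0L) next
      take <- c(take, idx)
      count <- count + length(idx)
      if (count >= target) break
    }
    sort(take)
  })
  test_idx <- setdiff(seq_len(n), train_idx)
  if (length(test_idx) == 0L) {
    test_idx <- train_idx[length(train_idx)]
    train_idx <- train_idx[-length(train_idx)]
  }
  out <- if (is.data.frame(records)) {
    list(train = records[train_idx, , drop = FALSE],
         test = records[test_idx, , drop = FALSE])
  } else {
    list(train = train_idx, test = test_idx)
  }
  attr(out, "train_idx") <- train_idx
  attr(out, "test_idx") <- sort(test_idx)
  out
}

#' End-to-end parameter-recovery experiment on synthetic scenes
#'
#' Simulates depth scenes with known allometric weights, segments them with
#' the depth-threshold segmenter, extracts the 25 morphometric features,
#' optionally fuses each instance with its 2048-dim embedding, trains a
#' GBDT on the training side of a grouped 70/30 split, and evaluates on the
#' held-out side. Since the generating model (`weight = c * volume *
#' (1 + eps)`) is known, the test error measures how well the pipeline
#' recovers it.
#'
#' @param n_scenes number of scenes (one animal per scene by default).
#' @param seed master seed; scene seeds, the split seed and the model seed
#'   all derive from it, so a rerun reproduces the report exactly.
#' @param config a [gbdt_config()] (its seed is overridden by `seed`).
#' @param weight_sigma_rel relative sd of the weight noise.
#' @param depth_noise_sigma sensor noise, mm.
#' @param n_birds birds per scene.
#' @param use_fused fuse learned features before training.
#' @param train_fraction training fraction of the grouped split.
#' @param rows,cols scene size in px.
#' @param weight_coef allometric coefficient, kg per px^2 mm.
#' @return list with `metrics` (a `metrics_report`), `weight_class` (data
#'   frame), `n_train`, `n_test`, `mean_test_weight`, `mae_over_mean`,
#'   `config` and `seed`.
#' @export
run_recovery_experiment <- function(n_scenes = 300, seed = 1L,
                                    config = gbdt_config(),
                                    weight_sigma_rel = 0.03,
                                    depth_noise_sigma = 3,
                                    n_birds = 1,
                                    use_fused = FALSE,
                                    train_fraction = 0.7,
                                    rows = 180, cols = 240,
                                    weight_coef = 5e-6) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  tabs <- vector("list", n_scenes)
  for (i in seq_len(n_scenes)) {
    sc_seed <- seed + i
    scene <- stage("simulate", generate_depth_scene(random_scene_spec(
      seed = sc_seed, rows = rows, cols = cols, n_birds = n_birds,
      depth_noise_sigma = depth_noise_sigma,
      weight_sigma_rel = weight_sigma_rel, weight_coef = weight_coef)))
    masks <- stage("segment", threshold_segment(scene$depth))
    feats <- stage("extract", extract_scene_features(scene$depth, masks))
    # match segmented instances to ground truth by IoU to attach weights
    w <- stage("match", vapply(masks, function(mk) {
      ious <- vapply(scene$masks, function(tm) mask_iou(mk, tm), numeric(1))
      scene$truth$weight_kg[which.max(ious)]
    }, numeric(1)))
    feats$weight_kg <- w
    feats$animal_id <- sprintf("s%04d_b%02d", i, feats$instance_id)
    if (use_fused) {
      emb <- stage("fuse", t(vapply(masks, function(mk) {
        as.numeric(fuse(unlist(feats[mk$instance_id, feature_names()]),
                        default_embed(scene$depth, mk, seed = 1L)))
      }, numeric(2073))))
      colnames(emb) <- c(feature_names(), sprintf("lf_%04d", 0:2047))
      feats <- cbind(feats[, c("animal_id", "weight_kg")], as.data.frame(emb))
    }
    tabs[[i]] <- feats
  }
  records <- do.call(rbind, tabs)
  feat_cols <- setdiff(names(records), c("instance_id", "animal_id", "weight_kg"))
  split <- stage("split", train_test_split(records, train_fraction,
                                           seed = seed + n_scenes + 1L,
                                           group = "animal_id"))
  config$seed <- as.integer(seed)
  model <- stage("train", fit_gbdt(as.matrix(split$train[, feat_cols]),
                                   split$train$weight_kg, config))
  yhat <- stage("predict", predict(model, as.matrix(split$test[, feat_cols])))
  y <- split$test$weight_kg
  metrics <- stage("evaluate", regression_metrics(y, yhat))
  list(
    metrics = metrics,
    weight_class = weight_class_mae(y, yhat, overflow = TRUE),
    n_train = nrow(split$train), n_test = nrow(split$test),
    mean_test_weight = mean(y),
    mae_over_mean = metrics$mae / mean(y),
    config = config, seed = as.integer(seed)
  )
}

#' Serialise a recovery report to JSON
#' @param report output of [run_recovery_experiment()].
#' @param path JSON file.
#' @return `path`, invisibly.
#' @export
write_recovery_report <- function(report, path) {
  out <- list(
    metrics = report$metrics[c("mae", "mse", "rmse", "r2", "n")],
    weight_class = report$weight_class,
    n_train = report$n_train, n_test = report$n_test,
    mean_test_weight = report$mean_test_weight,
    mae_over_mean = report$mae_over_mean,
    config = unclass(report$config), seed = report$seed
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
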