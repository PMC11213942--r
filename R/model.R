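# User-facing forecaster: temporal_cropnet() fits the hybrid stacked
# LSTM-GRU model on per-plant growth series and predicts the next growth
# stage's height and crown area.

.records_to_series <- function(records) {
  need <- c("plant_id", "date_index", "height", "crown_area")
  if (!all(need %in% names(records)))
    stop("records need columns: ", paste(need, collapse = ", "))
  if (any(records$height <= 0) || any(records$crown_area <= 0))
    stop("plant records must have height > 0 and crown_area > 0")
  series <- split(records, records$plant_id)
  series <- lapply(series, function(d) d[order(d$date_index), , drop = FALSE])
  bad <- vapply(series, function(d) anyDuplicated(d$date_index) > 0, TRUE)
  if (any(bad))
    stop("duplicated date_index within a plant series: ",
         paste(names(series)[bad], collapse = ", "))
  series
}

# build scaled-ready arrays: inputs are the first `input_stages` stages'
# (height, crown_area), the target is the following stage's pair
.series_to_xy <- function(series, input_stages) {
  keep <- vapply(series, nrow, 0L) >= input_stages + 1
  series <- series[keep]
  if (!length(series)) stop("no series long enough for the requested input length")
  Xlist <- lapply(seq_len(input_stages), function(t)
    t(vapply(series, function(d) c(d$height[t], d$crown_area[t]), numeric(2))))
  Y <- t(vapply(series, function(d)
    c(d$height[input_stages + 1], d$crown_area[input_stages + 1]), numeric(2)))
  colnames(Y) <- c("height", "crown_area")
  list(X = Xlist, Y = Y, plant_ids = names(series),
       next_date = vapply(series, function(d) d$date_index[input_stages + 1], 0))
}

#' Split plant series into train / validation / test sets
#'
#' The split is by plant: a plant's whole series lands in exactly one set.
#' Set sizes follow the fractions with largest-remainder rounding (ties go
#' to the earlier set), and membership is deterministic under `seed`.
#'
#' @param records A long record data frame (or list of per-plant data
#'   frames) with `plant_id`, `date_index`, `height`, `crown_area`.
#' @param fractions Train/validation/test fractions summing to 1.
#' @param seed RNG seed.
#' @return A list of three record data frames (`train`, `val`, `test`) with
#'   an attribute `plant_ids` giving the membership.
#' @export
split_dataset <- function(records, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  if (is.list(records) && !is.data.frame(records))
    records <- do.call(rbind, records)
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  series <- .records_to_series(records)
  ids <- names(series)
  n <- length(ids)
  if (n < 5) stop("need at least 5 plant series to split")
  set.seed(seed)
  ids <- ids[sample.int(n)]
  sizes <- floor(n * fractions)
  rem <- n - sum(sizes)
  if (rem > 0) {
    frac <- n * fractions - floor(n * fractions)
    extra <- order(-frac, seq_along(fractions))[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1
  }
  cut <- cumsum(sizes)
  members <- list(train = ids[seq_len(cut[1])],
                  val = if (sizes[2]) ids[(cut[1] + 1):cut[2]] else character(),
                  test = if (sizes[3]) ids[(cut[2] + 1):cut[3]] else character())
  out <- lapply(members, function(m)
    do.call(rbind, c(series[m], list(make.row.names = FALSE))))
  attr(out, "plant_ids") <- members
  out
}

#' Train a hybrid model on plant records
#'
#' Fits the per-feature min-max scalers on the training split, then
#' minimizes the mean squared error of the scaled next-stage targets by
#' mini-batch gradient descent with the adaptive-moment optimizer. When a
#' validation set is given, the parameters with the best validation loss
#' are returned.
#'
#' @param model A `hybrid_model` from [init_model()].
#' @param train,val Record data frames (`val` may be `NULL`).
#' @param epochs,batch_size,learning_rate Training protocol (defaults 400,
#'   50, 1e-3).
#' @param input_stages Number of input stages; default: one less than the
#'   shortest training series.
#' @param seed Optional RNG seed for shuffling (and full reproducibility).
#' @return A list with the trained `model` and the per-epoch `history`.
#' @export
train_model <- function(model, train, val = NULL, epochs = 400,
                        batch_size = 50, learning_rate = 1e-3,
                        input_stages = NULL, seed = NULL) {
  stopifnot(inherits(model, "hybrid_model"))
  if (!is.null(seed)) set.seed(seed)
  series <- .records_to_series(train)
  if (is.null(input_stages))
    input_stages <- min(vapply(series, nrow, 0L)) - 1
  if (input_stages < 1) stop("series too short: need input_stages >= 1")
  xy <- .series_to_xy(series, input_stages)
  model$scaler_x <- .fit_scaler(do.call(rbind, xy$X))
  model$scaler_y <- .fit_scaler(xy$Y)
  model$input_stages <- as.integer(input_stages)
  Xtr <- lapply(xy$X, .scale_mat, s = model$scaler_x)
  Ytr <- .scale_mat(xy$Y, model$scaler_y)
  Xva <- Yva <- NULL
  if (!is.null(val) && nrow(val)) {
    vxy <- .series_to_xy(.records_to_series(val), input_stages)
    Xva <- lapply(vxy$X, .scale_mat, s = model$scaler_x)
    Yva <- .scale_mat(vxy$Y, model$scaler_y)
  }
  .train_network(model, Xtr, Ytr, Xva, Yva, epochs = epochs,
                 batch_size = batch_size, lr = learning_rate)
}

#' Predict the next growth stage for one plant series
#'
#' @param model A trained `hybrid_model`.
#' @param series One plant's record data frame whose length equals the
#'   model's input length.
#' @return A one-row record data frame for the next stage.
#' @export
predict_next <- function(model, series) {
  stopifnot(inherits(model, "hybrid_model"))
  if (is.null(model$input_stages)) stop("model has not been trained")
  series <- series[order(series$date_index), , drop = FALSE]
  if (nrow(series) != model$input_stages)
    stop("series length ", nrow(series), " does not match the model's input length ",
         model$input_stages)
  if (any(series$height <= 0) || any(series$crown_area <= 0))
    stop("plant records must have height > 0 and crown_area > 0")
  seq_raw <- cbind(series$height, series$crown_area)
  yhat <- hybrid_forward(.scale_mat(seq_raw, model$scaler_x), model)
  yhat <- pmax(yhat, 1e-6)  # physical parameters are strictly positive
  data.frame(plant_id = series$plant_id[1],
             date_index = series$date_index[nrow(series)] + 1L,
             height = yhat[1], crown_area = yhat[2])
}

#' Fit the hybrid stacked LSTM-GRU growth forecaster
#'
#' Splits the plant series by plant into train/validation/test sets, fits
#' the hybrid model (stacked LSTM and GRU branches with fully connected
#' heads and a final linear layer) to predict the next growth stage's
#' height and crown area from the preceding stages, and evaluates the
#' held-out test split with SMAPE and logarithmic deviations.
#'
#' @param records Long record data frame: `plant_id`, `date_index`,
#'   `height` (m), `crown_area` (m2).
#' @param input_stages Stages used as input (default: series length - 1).
#' @param hidden Units per recurrent layer.
#' @param lstm_layers,gru_layers Stack depths.
#' @param fcn_units Branch head width.
#' @param branches `"both"` (hybrid), or `"lstm"` / `"gru"` ablations.
#' @param epochs,batch_size,learning_rate Training protocol.
#' @param split Train/val/test fractions (sum 1), or `NULL` to train on all
#'   records without held-out evaluation.
#' @param seed Seed controlling the split, initialization and batching.
#' @return An object of class `temporal_cropnet`.
#' @seealso [predict.temporal_cropnet()], [cross_validate()]
#' @export
temporal_cropnet <- function(records, input_stages = NULL, hidden = 50,
                             lstm_layers = 2, gru_layers = 2, fcn_units = 50,
                             branches = c("both", "lstm", "gru"),
                             epochs = 400, batch_size = 50,
                             learning_rate = 1e-3,
                             split = c(0.6, 0.2, 0.2), seed = 1L) {
  branches <- match.arg(branches)
  cl <- match.call()
  if (!is.null(split)) {
    sets <- split_dataset(records, split, seed = seed)
  } else {
    sets <- list(train = records, val = NULL, test = NULL)
    attr(sets, "plant_ids") <- list(train = unique(records$plant_id),
                                    val = character(), test = character())
  }
  set.seed(seed)
  model <- init_model(input_dim = 2, output_dim = 2, hidden = hidden,
                      lstm_layers = lstm_layers, gru_layers = gru_layers,
                      fcn_units = fcn_units, branches = branches)
  fit <- train_model(model, sets$train, sets$val, epochs = epochs,
                     batch_size = batch_size, learning_rate = learning_rate,
                     input_stages = input_stages)
  obj <- structure(list(model = fit$model, history = fit$history,
                        split = attr(sets, "plant_ids"), sets = sets,
                        config = list(hidden = hidden, lstm_layers = lstm_layers,
                                      gru_layers = gru_layers,
                                      fcn_units = fcn_units, branches = branches,
                                      epochs = epochs, batch_size = batch_size,
                                      learning_rate = learning_rate,
                                      input_stages = fit$model$input_stages,
                                      seed = seed),
                        call = cl),
                   class = "temporal_cropnet")
  if (!is.null(sets$test) && nrow(sets$test)) {
    ev <- .evaluate_on(obj, sets$test)
    obj$test_pred <- ev$pred
    obj$test_eval <- ev$reports
  }
  obj
}

# predict the held-out target stage of every series in `records` and
# evaluate both parameters
.evaluate_on <- function(object, records) {
  k <- object$model$input_stages
  series <- .records_to_series(records)
  series <- series[vapply(series, nrow, 0L) >= k + 1]
  pred <- do.call(rbind, lapply(series, function(d)
    predict_next(object$model, d[seq_len(k), ])))
  truth <- do.call(rbind, lapply(series, function(d) d[k + 1, , drop = FALSE]))
  rownames(pred) <- rownames(truth) <- NULL
  list(pred = pred,
       truth = truth,
       reports = list(
         height = evaluation_report(pred, truth, "height"),
         crown_area = evaluation_report(pred, truth, "crown_area")))
}

#' @export
print.temporal_cropnet <- function(x, ...) {
  cfg <- x$config
  cat("temporal_cropnet fit\n")
  cat(sprintf("  branches: %s (L = %d LSTM + G = %d GRU layers, %d units)\n",
              cfg$branches, x$model$lstm_layers, x$model$gru_layers, cfg$hidden))
  cat(sprintf("  input: %d stages -> next-stage (height, crown_area)\n",
              cfg$input_stages))
  cat(sprintf("  training: %d epochs, batch %d, lr %g; final train MSE %.3g\n",
              cfg$epochs, cfg$batch_size, cfg$learning_rate,
              utils::tail(x$history$train_loss, 1)))
  if (!is.null(x$test_eval))
    cat(sprintf("  test SMAPE: height %.2f%%, crown area %.2f%%\n",
                x$test_eval$height$smape_percent,
                x$test_eval$crown_area$smape_percent))
  invisible(x)
}

#' @export
summary.temporal_cropnet <- function(object, ...) {
  print(object)
  cat(sprintf("  plants: %d train / %d val / %d test\n",
              length(object$split$train), length(object$split$val),
              length(object$split$test)))
  if (!is.null(object$test_eval)) {
    for (p in c("height", "crown_area")) {
      r <- object$test_eval[[p]]
      cat(sprintf("  %s: SMAPE %.2f%% (agreement %.2f%%), L_d sum %.3f, over/under %d/%d\n",
                  p, r$smape_percent, 100 - r$smape_percent, r$ld_sum,
                  r$over_count, r$under_count))
    }
  }
  invisible(object)
}

#' Predict next-stage records for new plant series
#'
#' @param object A fitted `temporal_cropnet`.
#' @param newdata Long record data frame; each plant must supply exactly
#'   the model's input length of stages (extra leading stages are allowed
#'   with `trim = TRUE`, which keeps the most recent ones).
#' @param trim Keep the last `input_stages` stages of longer series.
#' @param ... Unused.
#' @return A record data frame of next-stage predictions.
#' @export
predict.temporal_cropnet <- function(object, newdata, trim = FALSE, ...) {
  series <- .records_to_series(newdata)
  k <- object$model$input_stages
  out <- lapply(series, function(d) {
    if (trim && nrow(d) > k) d <- d[(nrow(d) - k + 1):nrow(d), ]
    predict_next(object$model, d)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @export
coef.temporal_cropnet <- function(object, ...) object$model$params

#' @export
residuals.temporal_cropnet <- function(object, ...) {
  ev <- .evaluate_on(object, object$sets$train)
  cbind(height = ev$pred$height - ev$truth$height,
        crown_area = ev$pred$crown_area - ev$truth$crown_area)
}

#' @export
fitted.temporal_cropnet <- function(object, ...) {
  .evaluate_on(object, object$sets$train)$pred
}

#' @export
plot.temporal_cropnet <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$train_loss, type = "l", log = "y",
                 xlab = "epoch", ylab = "MSE (scaled)",
                 main = "temporal_cropnet training history", ...)
  if (any(is.finite(h$val_loss))) {
    graphics::lines(h$epoch, h$val_loss, lty = 2)
    graphics::legend("topright", c("train", "validation"), lty = 1:2, bty = "n")
  }
  invisible(x)
}

#' Fivefold (or k-fold) cross-validation of the forecaster
#'
#' Plants are partitioned into `cv_folds` folds (deterministic under
#' `seed`); for each fold the model is trained on the remaining folds and
#' SMAPE / logarithmic deviation are computed on the held-out fold.
#'
#' @param records Long record data frame.
#' @param cv_folds Number of folds (default 5).
#' @param seed Seed for the fold partition and training.
#' @param ... Passed to [temporal_cropnet()] (epochs, hidden, ...).
#' @return An object of class `cropnet_cv`: per-fold evaluation reports and
#'   fold-mean +/- sd SMAPE per parameter.
#' @export
cross_validate <- function(records, cv_folds = 5, seed = 1L, ...) {
  series <- .records_to_series(records)
  ids <- names(series)
  if (length(ids) < cv_folds) stop("need at least cv_folds series")
  set.seed(seed)
  fold <- rep(seq_len(cv_folds), length.out = length(ids))[sample.int(length(ids))]
  names(fold) <- ids
  folds <- vector("list", cv_folds)
  for (f in seq_len(cv_folds)) {
    tr <- do.call(rbind, series[fold != f])
    te <- do.call(rbind, series[fold == f])
    fit <- temporal_cropnet(tr, split = NULL, seed = seed + f, ...)
    folds[[f]] <- .evaluate_on(fit, te)$reports
  }
  sm <- vapply(folds, function(r)
    c(height = r$height$smape_percent, crown_area = r$crown_area$smape_percent),
    numeric(2))
  structure(list(folds = folds, fold_assignment = fold,
                 smape = t(sm),
                 mean_smape = rowMeans(sm), sd_smape = apply(sm, 1, stats::sd)),
            class = "cropnet_cv")
}

#' @export
print.cropnet_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation\n", nrow(x$smape)))
  cat(sprintf("  height SMAPE: %.2f%% +/- %.2f%%\n",
              x$mean_smape["height"], x$sd_smape["height"]))
  cat(sprintf("  crown area SMAPE: %.2f%% +/- %.2f%%\n",
              x$mean_smape["crown_area"], x$sd_smape["crown_area"]))
  invisible(x)
}

# ---- model checkpointing (versioned JSON schema) ----

#' Save a trained hybrid model to a JSON checkpoint
#' @param model A `hybrid_model` (e.g. `fit$model`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "hybrid_model"))
  ser <- function(x) if (is.list(x)) lapply(x, ser) else
    if (is.matrix(x)) list(dim = dim(x), data = as.vector(x)) else
    list(dim = NULL, data = as.vector(x))
  payload <- list(schema = "phenocast-hybrid-1",
                  meta = model[setdiff(names(model), "params")],
                  params = ser(model$params))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a hybrid model checkpoint written by [save_model()]
#' @param path Checkpoint path.
#' @return A `hybrid_model`.
#' @export
load_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE,
                                 simplifyMatrix = FALSE)
  if (!identical(payload$schema, "phenocast-hybrid-1"))
    stop("unknown checkpoint schema: ", payload$schema)
  deser <- function(x) {
    if (is.list(x) && !is.null(x$data)) {
      if (!is.null(x$dim) && length(x$dim)) matrix(x$data, x$dim[1], x$dim[2])
      else as.numeric(x$data)
    } else lapply(x, deser)
  }
  meta <- payload$meta
  model <- structure(c(list(params = deser(payload$params)), meta),
                     class = "hybrid_model")
  model$scaler_x <- lapply(model$scaler_x, as.numeric)
  model$scaler_y <- lapply(model$scaler_y, as.numeric)
  model
}
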