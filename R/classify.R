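#' Leave-one-subject-out cross-validation splits
#'
#' One fold per subject: all windows of that subject form the test set and
#' every other subject's windows form the training set, so accuracy
#' measures generalization across individuals rather than within-subject
#' memorization.
#'
#' @param features feature table with a `subject_id` column.
#' @return List of folds, each `list(train = <row idx>, test = <row idx>,
#'   subject = <id>)`.
#' @export
make_loso_splits <- function(features) {
  ids <- unique(features$subject_id)
  if (length(ids) < 2) stop("leave-one-subject-out needs at least 2 subjects")
  lapply(ids, function(s) {
    test <- which(features$subject_id == s)
    list(train = setdiff(seq_len(nrow(features)), test),
         test = test, subject = s)
  })
}

#' Train a multiclass RBF-kernel SVM
#'
#' C-classification with the radial basis function kernel
#' `k(u, v) = exp(-gamma * ||u - v||^2)`; the multiclass decision uses
#' one-vs-one voting over all pairwise maximum-margin classifiers. Feature
#' scaling is handled by [fit_scaler()]/[apply_scaler()] upstream, so the
#' solver's internal rescaling is disabled.
#'
#' @param features scaled feature table (84 feature columns plus `label`).
#' @param C penalty parameter (> 0).
#' @param gamma RBF kernel width parameter (> 0).
#' @return A fitted `svm` model.
#' @export
train_svm <- function(features, C, gamma) {
  stopifnot(C > 0, gamma > 0)
  X <- as.matrix(features[, feature_names(), drop = FALSE])
  if (any(!is.finite(X))) stop("non-finite feature values")
  y <- behavior_factor(features$label)
  if (length(unique(features$label)) < 2) stop("need >= 2 classes to train")
  e1071::svm(X, y, type = "C-classification", kernel = "radial",
             cost = C, gamma = gamma, scale = FALSE)
}

#' Predict behavior labels
#'
#' @param model a [train_svm()] fit.
#' @param features scaled feature table.
#' @return Character vector of predicted class codes.
#' @export
predict_svm <- function(model, features) {
  X <- as.matrix(features[, feature_names(), drop = FALSE])
  as.character(stats::predict(model, X))
}

#' Leave-one-subject-out evaluation at one (C, gamma)
#'
#' For each fold, fits the scaler on the training subjects only, trains
#' the SVM, and predicts the held-out subject. Accuracy is pooled over all
#' held-out windows (window-level).
#'
#' @param features unscaled feature table.
#' @param C,gamma SVM parameters.
#' @param splits optional precomputed [make_loso_splits()] result.
#' @return List with `accuracy`, and `predictions` (data frame with
#'   `subject_id`, `actual`, `predicted`).
#' @export
loso_evaluate <- function(features, C, gamma, splits = NULL) {
  if (is.null(splits)) splits <- make_loso_splits(features)
  preds <- lapply(splits, function(fold) {
    train <- features[fold$train, , drop = FALSE]
    test <- features[fold$test, , drop = FALSE]
    scaler <- fit_scaler(train)
    model <- train_svm(apply_scaler(scaler, train), C, gamma)
    data.frame(subject_id = test$subject_id,
               actual = test$label,
               predicted = predict_svm(model, apply_scaler(scaler, test)),
               stringsAsFactors = FALSE)
  })
  predictions <- do.call(rbind, preds)
  list(accuracy = mean(predictions$predicted == predictions$actual),
       predictions = predictions)
}

grid_eval <- function(features, C_values, gamma_values, splits) {
  grid <- expand.grid(C = C_values, gamma = gamma_values,
                      KEEP.OUT.ATTRS = FALSE)
  grid$accuracy <- vapply(seq_len(nrow(grid)), function(i) {
    loso_evaluate(features, grid$C[i], grid$gamma[i], splits)$accuracy
  }, numeric(1))
  grid
}

#' Two-step exponential grid search under LOSO cross-validation
#'
#' Evaluates exponentially growing (C, gamma) pairs on a coarse lattice,
#' then a fine lattice centered on the coarse optimum (quarter-octave
#' steps over +/- `fine_octaves` octaves). Every pair is scored by pooled
#' leave-one-subject-out accuracy; ties are broken toward the smallest C
#' and then the smallest gamma (the simpler model).
#'
#' @param features unscaled feature table.
#' @param coarse_C,coarse_gamma coarse-grid values. Defaults are
#'   `2^seq(-5, 15, 2)` and `2^seq(-15, 3, 2)`.
#' @param fine_octaves half-width of the fine grid, octaves.
#' @param fine_step fine-grid step, octaves.
#' @param two_step set `FALSE` to skip the fine pass.
#' @return An object of class `grid_search_result`: `grid` (data frame
#'   C, gamma, accuracy over both passes, with a `stage` column), `best`
#'   (list with C, gamma), `best_accuracy`.
#' @export
grid_search <- function(features,
                        coarse_C = 2^seq(-5, 15, by = 2),
                        coarse_gamma = 2^seq(-15, 3, by = 2),
                        fine_octaves = 2, fine_step = 0.25,
                        two_step = TRUE) {
  if (!length(coarse_C) || !length(coarse_gamma)) stop("empty grid")
  splits <- make_loso_splits(features)
  coarse <- grid_eval(features, coarse_C, coarse_gamma, splits)
  coarse$stage <- "coarse"
  pick_best <- function(g) {
    g <- g[order(-g$accuracy, g$C, g$gamma), ]
    g[1, ]
  }
  best <- pick_best(coarse)
  grid <- coarse
  if (two_step && nrow(coarse) > 1) {
    offs <- 2^seq(-fine_octaves, fine_octaves, by = fine_step)
    fine_C <- unique(best$C * offs)
    fine_gamma <- unique(best$gamma * offs)
    fine <- grid_eval(features, fine_C, fine_gamma, splits)
    fine$stage <- "fine"
    grid <- rbind(coarse, fine)
    best <- pick_best(grid)
  }
  structure(list(grid = grid,
                 best = list(C = best$C, gamma = best$gamma),
                 best_accuracy = best$accuracy),
            class = "grid_search_result")
}
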