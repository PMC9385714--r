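#' Encode an activity table for classifier training
#'
#' One-hot encodes the sequences, labels each variant neutral (1) or
#' deleterious (0) by the RA threshold (inclusive), and assigns a
#' seeded 70/30 train/test split, with 10% of the training rows carved
#' out as a validation set for threshold tuning.
#'
#' @param activity Activity table (columns `sequence` and `RA_mean`, or
#'   `ra`).
#' @param cfg A [neutrality_config()].
#' @param test_fraction Fraction of rows held out as the test set.
#' @param validation_fraction Fraction of the training rows carved out
#'   for validation.
#' @return Object of class `encoded_dataset`: list with matrix `x`,
#'   labels `y`, `split` factor (`train` / `validation` / `test`), and
#'   `sequences`.
#' @export
make_dataset <- function(activity, cfg = neutrality_config(),
                         test_fraction = 0.3, validation_fraction = 0.1) {
  ra <- if ("RA_mean" %in% names(activity)) activity$RA_mean else activity$ra
  stopifnot(!is.null(ra), "sequence" %in% names(activity),
            nrow(activity) >= 1L)
  x <- one_hot(activity$sequence)
  y <- as.integer(ra >= cfg$threshold)
  n <- nrow(x)
  ord <- sample.int(n)
  n_test <- round(test_fraction * n)
  test_idx <- ord[seq_len(n_test)]
  train_idx <- ord[-seq_len(n_test)]
  n_val <- round(validation_fraction * length(train_idx))
  val_idx <- train_idx[seq_len(n_val)]
  split <- factor(rep("train", n), levels = c("train", "validation", "test"))
  split[test_idx] <- "test"
  split[val_idx] <- "validation"
  structure(list(x = x, y = y, split = split,
                 sequences = activity$sequence, threshold = cfg$threshold),
            class = "encoded_dataset")
}

#' Classifier model specification
#'
#' The five neutral/deleterious classifier families. "Default"
#' hyperparameters are pinned explicitly so results do not drift with
#' library versions: k = 5 for k-NN; L2-regularised logistic regression
#' (`lambda = 1e-4`, near the unpenalised fit); linear SVM with cost 1; gradient-boosted
#' trees with maximum depth 10, 100 rounds, learning rate 0.1; MLP with
#' dense layers 128/64/32, batch normalisation, 20% dropout, Adam at
#' learning rate 0.005, binary cross-entropy, 100 epochs, batch 1024.
#'
#' @param family One of `"logistic_regression"`,
#'   `"k_nearest_neighbors"`, `"linear_svm"`,
#'   `"gradient_boosted_trees"`, `"multilayer_perceptron"`.
#' @param ... Family-specific overrides (e.g. `k`, `cost`, `max_depth`,
#'   `nrounds`, `epochs`, `hidden`).
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(family = c("logistic_regression",
                                  "k_nearest_neighbors",
                                  "linear_svm",
                                  "gradient_boosted_trees",
                                  "multilayer_perceptron"),
                       ...) {
  family <- match.arg(family)
  defaults <- switch(family,
    logistic_regression = list(lambda = NULL),  # 1e-4 at fit time
    k_nearest_neighbors = list(k = 5L),
    linear_svm = list(cost = 1),
    gradient_boosted_trees = list(max_depth = 10L, nrounds = 100L,
                                  eta = 0.1),
    multilayer_perceptron = list(hidden = c(128L, 64L, 32L),
                                 dropout = 0.2, lr = 0.005,
                                 epochs = 100L, batch_size = 1024L))
  over <- list(...)
  defaults[names(over)] <- over
  structure(list(family = family, hyperparameters = defaults),
            class = "model_spec")
}

#' Train a neutrality classifier
#'
#' Fits the requested family on the training split (training +
#' validation rows are fitted for all families except that validation
#' rows are excluded so they can tune the decision threshold). The
#' decision threshold defaults to 0.5 until tuned with
#' [tune_threshold_roc()].
#'
#' @param spec A [model_spec()].
#' @param data An [make_dataset()] result.
#' @param seed Seed for stochastic families (GBDT feature subsampling
#'   order, MLP initialisation and dropout).
#' @return Object of class `trained_classifier`.
#' @export
train_classifier <- function(spec, data, seed = NULL) {
  stopifnot(inherits(spec, "model_spec"), inherits(data, "encoded_dataset"))
  tr <- data$split == "train"
  x <- data$x[tr, , drop = FALSE]
  y <- data$y[tr]
  if (length(unique(y)) < 2L) {
    stop("training data contain a single class")
  }
  hp <- spec$hyperparameters
  fit <- switch(spec$family,
    logistic_regression = {
      lambda <- if (is.null(hp$lambda)) 1e-4 else hp$lambda
      glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                     lambda = lambda, standardize = FALSE)
    },
    k_nearest_neighbors = list(x = x, y = y, k = hp$k),
    linear_svm = {
      if (!is.null(seed)) set.seed(seed)
      e1071::svm(x, factor(y, levels = c(0, 1)), kernel = "linear",
                 cost = hp$cost, probability = TRUE, scale = FALSE)
    },
    gradient_boosted_trees = {
      if (!is.null(seed)) set.seed(seed)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = hp$max_depth, eta = hp$eta,
                      nthread = 1L),
        data = xgboost::xgb.DMatrix(x, label = y, nthread = 1L),
        nrounds = hp$nrounds)
    },
    multilayer_perceptron =
      mlp_train(x, y, hidden = hp$hidden, dropout = hp$dropout,
                lr = hp$lr, epochs = hp$epochs,
                batch_size = hp$batch_size, seed = seed))
  structure(list(spec = spec, fit = fit, n_in = ncol(x),
                 decision_threshold = 0.5),
            class = "trained_classifier")
}

#' Neutral-class probability from a trained classifier
#'
#' @param object A [train_classifier()] result.
#' @param x One-hot matrix, or a character vector of sequences (one-hot
#'   encoded on the fly).
#' @param ... Unused.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict.trained_classifier <- function(object, x, ...) {
  if (is.character(x)) x <- one_hot(x)
  if (ncol(x) != object$n_in) {
    stop("feature width ", ncol(x),
         " does not match the classifier (", object$n_in, ")")
  }
  fit <- object$fit
  p <- switch(object$spec$family,
    logistic_regression =
      as.numeric(stats::predict(fit, newx = x, type = "response")),
    k_nearest_neighbors = {
      pr <- class::knn(fit$x, x, factor(fit$y, levels = c(0, 1)),
                       k = fit$k, prob = TRUE)
      win <- attr(pr, "prob")
      ifelse(pr == "1", win, 1 - win)
    },
    linear_svm = {
      pred <- stats::predict(fit, x, probability = TRUE)
      attr(pred, "probabilities")[, "1"]
    },
    gradient_boosted_trees = as.numeric(stats::predict(fit, x)),
    multilayer_perceptron = stats::predict(fit, x))
  as.numeric(p)
}

#' Tune the decision threshold on the ROC curve
#'
#' Scans the candidate thresholds of the validation-set ROC curve and
#' returns the one maximising the geometric mean
#' `sqrt(TPR * (1 - FPR))`; ties resolve to the lowest threshold. The
#' tuned threshold is stored in the returned classifier.
#'
#' @param model A [train_classifier()] result.
#' @param data The [make_dataset()] used for training (its validation
#'   split is scanned).
#' @return The classifier with `decision_threshold` updated;
#'   the achieved geometric mean in `attr(, "geometric_mean")`.
#' @export
tune_threshold_roc <- function(model, data) {
  stopifnot(inherits(model, "trained_classifier"),
            inherits(data, "encoded_dataset"))
  va <- data$split == "validation"
  y <- data$y[va]
  if (length(unique(y)) < 2L) {
    stop("validation split must contain both classes")
  }
  p <- stats::predict(model, data$x[va, , drop = FALSE])
  roc <- pROC::roc(response = y, predictor = p, levels = c(0, 1),
                   direction = "<", quiet = TRUE)
  gm <- sqrt(roc$sensitivities * roc$specificities)
  thr <- roc$thresholds
  finite <- is.finite(thr)
  gm <- gm[finite]
  thr <- thr[finite]
  best <- which(gm == max(gm))
  pick <- best[which.min(thr[best])]
  model$decision_threshold <- thr[pick]
  attr(model, "geometric_mean") <- gm[pick]
  model
}

#' Evaluate a classifier
#'
#' Confusion counts and the derived metrics on a chosen split:
#' precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, accuracy, F1, and the
#' null accuracy (the majority-class fraction of the evaluation set).
#' Metrics undefined for lack of positive predictions are reported as
#' `NaN` with `undefined = TRUE`.
#'
#' @param model A [train_classifier()] result.
#' @param data An [make_dataset()] result.
#' @param split Which split to score (default `"test"`).
#' @return Object of class `eval_report`.
#' @export
evaluate_classifier <- function(model, data, split = "test") {
  stopifnot(inherits(model, "trained_classifier"),
            inherits(data, "encoded_dataset"))
  sel <- data$split == split
  if (!any(sel)) stop("empty evaluation split: ", split)
  y <- data$y[sel]
  p <- stats::predict(model, data$x[sel, , drop = FALSE])
  pred <- as.integer(p >= model$decision_threshold)
  eval_report(y, pred)
}

#' @rdname evaluate_classifier
#' @param truth,predicted Integer 0/1 vectors of labels and
#'   predictions.
#' @export
eval_report <- function(truth, predicted) {
  tp <- sum(truth == 1L & predicted == 1L)
  fp <- sum(truth == 0L & predicted == 1L)
  fn <- sum(truth == 1L & predicted == 0L)
  tn <- sum(truth == 0L & predicted == 0L)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NaN
  recall <- if (tp + fn > 0) tp / (tp + fn) else NaN
  accuracy <- (tp + tn) / length(truth)
  f1 <- if (is.finite(precision) && is.finite(recall) &&
            precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NaN
  null_accuracy <- max(mean(truth == 1L), mean(truth == 0L))
  structure(list(precision = precision, recall = recall,
                 accuracy = accuracy, f1 = f1,
                 null_accuracy = null_accuracy,
                 confusion = c(TP = tp, FP = fp, FN = fn, TN = tn),
                 undefined = !is.finite(precision) || !is.finite(recall)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "precision %.3f | recall %.3f | accuracy %.3f | F1 %.3f | null accuracy %.3f\n",
    x$precision, x$recall, x$accuracy, x$f1, x$null_accuracy))
  cat("confusion:", paste(names(x$confusion), x$confusion, collapse = "  "),
      "\n")
  invisible(x)
}

#' k-fold cross-validation of a classifier family
#'
#' Seeded fold assignment over the full dataset; each fold is held out
#' once while the remainder trains a fresh model at threshold 0.5.
#'
#' @param spec A [model_spec()].
#' @param x One-hot matrix.
#' @param y Integer labels.
#' @param folds Number of folds (default 10).
#' @param seed Passed to the per-fold [train_classifier()] calls.
#' @return List with `reports` (one [eval_report()] per fold) and
#'   `summary` (mean and sd of each metric).
#' @export
cross_validate <- function(spec, x, y, folds = 10L, seed = NULL) {
  stopifnot(folds >= 2L)
  if (min(table(y)) < folds) stop("too few examples per class for ",
                                  folds, " folds")
  n <- length(y)
  assign <- sample(rep_len(seq_len(folds), n))
  reports <- vector("list", folds)
  for (f in seq_len(folds)) {
    te <- assign == f
    ds <- structure(list(x = x, y = y,
                         split = factor(ifelse(te, "test", "train"),
                                        levels = c("train", "validation",
                                                   "test"))),
                    class = "encoded_dataset")
    m <- train_classifier(spec, ds, seed = seed)
    reports[[f]] <- evaluate_classifier(m, ds)
  }
  metrics <- c("precision", "recall", "accuracy", "f1")
  vals <- sapply(reports, function(r) unlist(r[metrics]))
  list(reports = reports,
       summary = data.frame(metric = metrics,
                            mean = rowMeans(vals, na.rm = TRUE),
                            sd = apply(vals, 1L, stats::sd, na.rm = TRUE)))
}

#' Neutrality prediction interface
#'
#' Generic used by the guided evolutionary loop: any classifier that
#' can label sequences neutral/deleterious. Implemented for
#' [train_classifier()] models (probability against the tuned decision
#' threshold) and for [oracle_classifier()] lookups.
#'
#' @param object A classifier.
#' @param sequences Character vector of genotype sequences.
#' @return Logical vector: `TRUE` = predicted neutral.
#' @export
predict_neutral <- function(object, sequences) {
  UseMethod("predict_neutral")
}

#' @export
predict_neutral.trained_classifier <- function(object, sequences) {
  stats::predict(object, sequences) >= object$decision_threshold
}

#' Oracle classifier backed by ground truth
#'
#' Wraps a known landscape (or predicate function) as a classifier, so
#' the guided loop can be exercised against truth. Sequences absent
#' from the landscape are deleterious.
#'
#' @param landscape A `two_anchor_landscape`, a data frame with
#'   `sequence` and `neutral` (or `ra`), or a function mapping
#'   sequences to logicals.
#' @param cfg A [neutrality_config()] used when only `ra` is available.
#' @return Object of class `oracle_classifier`.
#' @export
oracle_classifier <- function(landscape, cfg = neutrality_config()) {
  fn <- if (is.function(landscape)) {
    landscape
  } else {
    df <- as.data.frame(landscape)
    neutral <- if ("neutral" %in% names(df)) df$neutral else
      df$ra >= cfg$threshold
    lookup <- stats::setNames(neutral, df$sequence)
    function(sequences) {
      out <- lookup[sequences]
      out[is.na(out)] <- FALSE
      unname(out)
    }
  }
  structure(list(fn = fn), class = "oracle_classifier")
}

#' @export
predict_neutral.oracle_classifier <- function(object, sequences) {
  as.logical(object$fn(sequences))
}
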