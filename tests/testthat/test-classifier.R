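# a linearly separable activity set: neutrality is a threshold on an
# additive score, so a linear decision boundary exists in one-hot space
separable_activity <- function(n = 600, L = 10, seed = 41) {
  set.seed(seed)
  wt <- random_genotype(L)
  seqs <- unique(c(wt, enumerate_single_mutants(wt),
                   sample_k_mutants(wt, 2, round(n * 0.6)),
                   sample_k_mutants(wt, 3, round(n * 0.4))))
  additive_activity(wt, seqs)
}

test_that("dataset encoding labels by inclusive threshold and splits 70/30", {
  act <- separable_activity()
  set.seed(42)
  ds <- make_dataset(act)
  expect_s3_class(ds, "encoded_dataset")
  expect_identical(ncol(ds$x), 40L)
  expect_identical(ds$y, as.integer(act$ra >= 0.2))
  expect_equal(mean(ds$split == "test"), 0.3, tolerance = 0.01)
  expect_identical(sum(table(ds$split)), nrow(act))
  # RA exactly at threshold is neutral
  ds2 <- make_dataset(data.frame(sequence = c("AAAA", "CCCC"),
                                 ra = c(0.2, 0.19999)))
  expect_identical(ds2$y, c(1L, 0L))
  # all-neutral input yields all-1 labels
  ds3 <- make_dataset(data.frame(sequence = c("AAAA", "CCCC"), ra = c(1, 2)))
  expect_identical(ds3$y, c(1L, 1L))
})

test_that("all five families train and the linear baseline aces separable data", {
  act <- separable_activity()
  set.seed(43)
  ds <- make_dataset(act)
  lr <- train_classifier(model_spec("logistic_regression"), ds)
  p_tr <- predict(lr, ds$x[ds$split == "train", , drop = FALSE])
  acc_tr <- mean((p_tr >= 0.5) == (ds$y[ds$split == "train"] == 1L))
  expect_equal(acc_tr, 1)
  lr_rep <- evaluate_classifier(lr, ds)
  expect_gte(lr_rep$accuracy, 0.9)
  for (fam in c("k_nearest_neighbors", "linear_svm",
                "gradient_boosted_trees")) {
    m <- train_classifier(model_spec(fam), ds, seed = 7)
    r <- evaluate_classifier(m, ds)
    expect_gte(r$accuracy, 0.7)
    p <- predict(m, ds$x[1:5, , drop = FALSE])
    expect_true(all(p >= 0 & p <= 1))
  }
  mlp <- train_classifier(
    model_spec("multilayer_perceptron", epochs = 30L, batch_size = 128L),
    ds, seed = 7)
  mlp_rep <- evaluate_classifier(mlp, ds)
  expect_gte(mlp_rep$accuracy, lr_rep$accuracy - 0.05)
  expect_error(train_classifier(model_spec("logistic_regression"),
                                make_dataset(data.frame(
                                  sequence = c("AAAA", "CCCC"),
                                  ra = c(1, 2)))),
               "single class")
})

test_that("deterministic families reproduce predictions under a fixed seed", {
  act <- separable_activity(300)
  set.seed(44)
  ds <- make_dataset(act)
  for (fam in c("logistic_regression", "linear_svm", "k_nearest_neighbors")) {
    set.seed(11)
    m1 <- train_classifier(model_spec(fam), ds, seed = 11)
    set.seed(11)
    m2 <- train_classifier(model_spec(fam), ds, seed = 11)
    x_te <- ds$x[ds$split == "test", , drop = FALSE]
    set.seed(12)
    p1 <- predict(m1, x_te)
    set.seed(12)
    p2 <- predict(m2, x_te)
    expect_identical(p1, p2)
  }
})

test_that("classifier metrics match their confusion-count definitions", {
  truth <- rep(c(1L, 0L), c(10L, 10L))
  pred <- c(rep(1L, 9), 0L, rep(1L, 3), rep(0L, 7))
  r <- eval_report(truth, pred)
  expect_identical(unname(r$confusion), c(9L, 3L, 1L, 7L))
  expect_equal(r$precision, 0.75)
  expect_equal(r$recall, 0.9)
  expect_equal(r$accuracy, 0.8)
  expect_equal(r$f1, 2 * 0.75 * 0.9 / 1.65)
  # perfect prediction
  r2 <- eval_report(truth, truth)
  expect_equal(r2$precision, 1)
  expect_equal(r2$recall, 1)
  # always predicting the majority class achieves exactly the null accuracy
  truth3 <- rep(c(1L, 0L), c(14L, 6L))
  r3 <- eval_report(truth3, rep(1L, 20))
  expect_equal(r3$accuracy, r3$null_accuracy)
  # no positive predictions: precision undefined and flagged
  r4 <- eval_report(truth, rep(0L, 20))
  expect_true(is.nan(r4$precision))
  expect_true(r4$undefined)
  # metrics are invariant to row order
  perm <- sample.int(20)
  r5 <- eval_report(truth[perm], pred[perm])
  expect_equal(r5$confusion, r$confusion)
})

test_that("ROC threshold tuning maximises the geometric mean", {
  act <- separable_activity()
  set.seed(45)
  ds <- make_dataset(act)
  lr <- train_classifier(model_spec("logistic_regression"), ds)
  tuned <- tune_threshold_roc(lr, ds)
  gm <- attr(tuned, "geometric_mean")
  expect_gte(gm, 0.9)  # near-perfect scorer on separable data
  # the reported maximum is reproduced when re-evaluated at the threshold
  va <- ds$split == "validation"
  p <- predict(tuned, ds$x[va, , drop = FALSE])
  pred <- as.integer(p >= tuned$decision_threshold)
  tpr <- sum(pred == 1L & ds$y[va] == 1L) / sum(ds$y[va] == 1L)
  fpr <- sum(pred == 1L & ds$y[va] == 0L) / sum(ds$y[va] == 0L)
  expect_equal(sqrt(tpr * (1 - fpr)), gm, tolerance = 1e-6)
  # a random scorer cannot beat a geometric mean of about 0.5
  set.seed(46)
  y <- rep(0:1, each = 5000)
  roc <- pROC::roc(response = y, predictor = runif(10000),
                   levels = c(0, 1), direction = "<", quiet = TRUE)
  expect_lt(max(sqrt(roc$sensitivities * roc$specificities)), 0.55)
})

test_that("cross-validation partitions the data and beats null accuracy", {
  act <- separable_activity(400)
  set.seed(47)
  x <- one_hot(act$sequence)
  y <- as.integer(act$ra >= 0.2)
  cv <- cross_validate(model_spec("logistic_regression"), x, y, folds = 5)
  expect_length(cv$reports, 5L)
  null_acc <- max(mean(y), 1 - mean(y))
  expect_gt(cv$summary$mean[cv$summary$metric == "accuracy"], null_acc)
  # folds are disjoint and exhaustive
  set.seed(48)
  assign1 <- sample(rep_len(1:5, length(y)))
  set.seed(48)
  assign2 <- sample(rep_len(1:5, length(y)))
  expect_identical(assign1, assign2)
  expect_error(cross_validate(model_spec("logistic_regression"),
                              x[1:8, ], y[1:8], folds = 10),
               "too few")
})

test_that("nonlinear families beat linear ones under strong pairwise epistasis", {
  # neutrality determined by an XOR-like pairwise rule has no useful
  # linear projection; trees must beat logistic regression directionally
  set.seed(49)
  L <- 8
  wt <- paste(rep("A", L), collapse = "")
  seqs <- unique(replicate(900, mutate_genotype(wt, prob = 0.4)))
  mutated <- one_hot(seqs)[, seq(1, 4 * L, by = 4)] == 0L  # not A => mutated
  pairs <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8), ncol = 2, byrow = TRUE)
  score <- rowSums(sapply(seq_len(nrow(pairs)), function(k)
    xor(mutated[, pairs[k, 1]], mutated[, pairs[k, 2]])))
  act <- data.frame(sequence = seqs, ra = ifelse(score >= 2, 1, 0.01))
  gap <- replicate(3, {
    ds <- make_dataset(act)
    lr <- evaluate_classifier(
      train_classifier(model_spec("logistic_regression"), ds), ds)
    gb <- evaluate_classifier(
      train_classifier(model_spec("gradient_boosted_trees", nrounds = 60L),
                       ds, seed = 1), ds)
    gb$accuracy - lr$accuracy
  })
  expect_gt(mean(gap), 0)
})

test_that("the MLP learns, clamps probabilities, and checks input width", {
  act <- separable_activity(400, seed = 50)
  x <- one_hot(act$sequence)
  y <- as.integer(act$ra >= 0.2)
  m <- mlp_train(x, y, hidden = c(32L, 16L), epochs = 40L,
                 batch_size = 64L, lr = 0.005, seed = 5)
  p <- predict(m, x)
  expect_true(all(p >= 0 & p <= 1))
  expect_gte(mean((p >= 0.5) == (y == 1L)), 0.9)
  expect_error(predict(m, x[, 1:10]), "width")
})
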