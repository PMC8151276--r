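test_that("perfectly separable synthetic families give 100% CV accuracy", {
  # two family blocks on disjoint fingerprint positions
  x <- rbind(cbind(matrix(1, 30, 5), matrix(0, 30, 5)),
             cbind(matrix(0, 30, 5), matrix(1, 30, 5)))
  colnames(x) <- paste0("f", 1:10)
  y <- rep(c("A", "B"), each = 30)
  m <- train_family_classifier(x, y, cv = cv_config(3, 1), num_trees = 50,
                               seed = 2)
  expect_true(all(vapply(m$tuning$cv_accuracy, identical, logical(1), 1)))
  expect_identical(predict_top_family(m, x), y)
})

test_that("training validates inputs", {
  x <- matrix(rnorm(40), 20, 2)
  expect_error(train_family_classifier(x, rep("A", 20), cv = cv_config(3, 1)),
               class = "gpcrtracer_schema_error")
  expect_error(train_family_classifier(x, c(rep("A", 18), "B", "B"),
                                       cv = cv_config(5, 1)),
               "fewer members")
})

test_that("probabilities normalize and argmax uses documented tie-break", {
  fx <- trained_fixture()
  p <- predict_family_probs(fx$model, fx$xte)
  expect_true(all(abs(rowSums(p) - 1) < 1e-9))
  expect_identical(colnames(p), fx$model$class_labels)

  # degenerate all-zero feature row: a valid label, never an exception
  zero <- matrix(0, 1, ncol(fx$xte),
                 dimnames = list(NULL, colnames(fx$xte)))
  expect_true(predict_top_family(fx$model, zero) %in% fx$model$class_labels)

  # argmax semantics incl. first-label tie-break, on the probability matrix
  pt <- matrix(c(0.9, 0.1, 0.5, 0.5), 2, byrow = TRUE)
  labs <- fx$model$class_labels[1:2]
  expect_identical(labs[max.col(pt, ties.method = "first")],
                   c(labs[1], labs[1]))

  expect_error(predict_family_probs(fx$model, fx$xte[, 1:3]),
               class = "gpcrtracer_schema_error")
})

test_that("evaluation matches a brute-force recount oracle and conserves counts", {
  fx <- trained_fixture()
  ev <- evaluate_classifier(fx$model, fx$xte, fx$yte)
  expect_equal(sum(ev$confusion), length(fx$yte))
  pred <- predict_top_family(fx$model, fx$xte)
  for (fam in fx$model$class_labels) {
    oracle <- naive_family_metrics(fx$yte, pred, fam)
    row <- ev$per_family[ev$per_family$family == fam, ]
    expect_equal(row$accuracy, oracle[["accuracy"]])
    expect_equal(row$sensitivity, oracle[["sensitivity"]])
    expect_equal(row$specificity, oracle[["specificity"]])
  }
  expect_equal(ev$overall_accuracy, 100 * mean(pred == fx$yte))
  expect_error(evaluate_classifier(fx$model, fx$xte, rep("NOPE", nrow(fx$xte))),
               class = "gpcrtracer_schema_error")
})

test_that("confusion_metrics equals the recount oracle on random fixtures", {
  set.seed(99)
  for (i in 1:25) {
    classes <- LETTERS[1:sample(2:5, 1)]
    true <- sample(classes, 30, replace = TRUE)
    pred <- sample(classes, 30, replace = TRUE)
    cm <- confusion_metrics(true, pred, classes)
    for (fam in classes) {
      oracle <- naive_family_metrics(true, pred, fam)
      row <- cm$per_family[cm$per_family$family == fam, ]
      expect_equal(c(row$accuracy, row$sensitivity, row$specificity),
                   unname(oracle))
    }
    expect_equal(cm$overall_accuracy, 100 * mean(true == pred))
    expect_equal(sum(cm$confusion), 30)
  }
})

test_that("randomized-label control drops to chance while real labels do not", {
  fx <- trained_fixture()
  ctrl <- randomized_label_control(fx$xtr, fx$ytr, seed = 21, num_trees = 100)
  expect_equal(ctrl$k, 4)
  # 99% binomial CI around 1/4 at the control's held-out size
  se <- sqrt(0.25 * 0.75 / ctrl$n_test)
  expect_lt(abs(ctrl$accuracy - 0.25), 2.576 * se + 1e-9)
  # control arm: the un-permuted model is far above chance on the same data
  ev <- evaluate_classifier(fx$model, fx$xte, fx$yte)
  expect_gt(ev$overall_accuracy / 100, 0.25 + 5 * se)
})

test_that("training is deterministic given the seed", {
  fx <- trained_fixture()
  m2 <- train_family_classifier(fx$xtr, fx$ytr, cv = cv_config(3, 1),
                                num_trees = 100, seed = 11)
  expect_identical(fx$model$best_mtry, m2$best_mtry)
  expect_identical(predict_family_probs(fx$model, fx$xte),
                   predict_family_probs(m2, fx$xte))
})
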