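toy_table <- function(n = 24, sep = 3) {
  withr::with_seed(31, {
    tab <- tibble::tibble(
      subject_id = sprintf("s%02d", seq_len(n)),
      group = rep(c("normal", "sarcopenia"), each = n / 2),
      f1 = rnorm(n), f2 = rnorm(n))
    tab$f1 <- tab$f1 + ifelse(tab$group == "sarcopenia", sep, 0)
    tab
  })
}

test_that("classical models separate a planted two-feature effect", {
  tab <- toy_table()
  for (kind in c("svm_linear", "svm_rbf", "rf", "mlp")) {
    pred <- train_predict(model_spec(kind), tab, tab)
    expect_gt(mean(pred == tab$group), 0.95)
  }
  # determinism of the seeded trainers
  p1 <- train_predict(model_spec("mlp", seed = 5), tab, tab)
  p2 <- train_predict(model_spec("mlp", seed = 5), tab, tab)
  expect_identical(p1, p2)
  expect_error(model_spec("rf", bogus = 1), "unknown hyperparameter")
})

test_that("tensor input is rejected by feature-based models", {
  tensors <- list(x = array(rnorm(4 * 2 * 20), c(4, 2, 20)),
                  subject_id = sprintf("s%d", 1:4),
                  group = rep(c("normal", "sarcopenia"), 2))
  expect_error(train_predict(model_spec("svm_linear"), tensors, tensors),
               "feature table")
})

test_that("deep models learn a separable stride-tensor toy problem", {
  withr::with_seed(11, {
    n <- 24
    x <- array(rnorm(n * 2 * 20), c(n, 2, 20))
    grp <- rep(c("normal", "sarcopenia"), each = n / 2)
    x[grp == "sarcopenia", 1, ] <- x[grp == "sarcopenia", 1, ] + 2
    tensors <- list(x = x, subject_id = sprintf("s%02d", 1:n), group = grp)
  })
  cnn <- model_spec("cnn", filters = 8, kernel = 4, pool = 2, dense = 16,
                    lr = 5e-3, epochs = 60)
  expect_gt(mean(train_predict(cnn, tensors, tensors) == tensors$group),
            0.9)
  bl <- model_spec("bilstm", units1 = 6, units2 = 4, dense = 12, lr = 1e-2,
                   epochs = 40)
  expect_gt(mean(train_predict(bl, tensors, tensors) == tensors$group), 0.9)
  expect_identical(train_predict(bl, tensors, tensors),
                   train_predict(bl, tensors, tensors))
})

test_that("LOSO folds hold out one subject per group exactly once", {
  tab <- toy_table(n = 8)
  ev <- loso_evaluate(tab, model_spec("svm_linear"))
  expect_equal(ev$n_folds, 4)
  expect_equal(nrow(ev$folds), 4)
  expect_setequal(ev$predictions$subject_id, tab$subject_id)
  expect_equal(nrow(ev$predictions), 8)    # each subject tested once
  expect_equal(ev$mean_accuracy, mean(ev$folds$accuracy))
  expect_equal(glance(ev)$n_folds, 4)
  expect_equal(nrow(tidy(ev)), 4)

  tab4 <- toy_table(n = 4)
  expect_equal(loso_evaluate(tab4, model_spec("svm_linear"))$n_folds, 2)
})

test_that("fold-internal statistics never see the held-out subject", {
  tab <- toy_table(n = 12)
  tab$stride <- 1L
  # corrupt one subject's features wildly; in the fold where it is held out
  # the training statistics (standardization, model) must not move, so its
  # fold partner's prediction is unchanged bit for bit
  ev1 <- loso_evaluate(tab, model_spec("svm_linear"))
  tab2 <- tab
  tab2[tab2$subject_id == "s01", c("f1", "f2")] <- 1e6
  ev2 <- loso_evaluate(tab2, model_spec("svm_linear"))
  fold_of <- ev1$predictions$fold[ev1$predictions$subject_id == "s01"]
  partner <- ev1$predictions$subject_id[
    ev1$predictions$fold == fold_of & ev1$predictions$subject_id != "s01"]
  expect_identical(
    ev1$predictions$predicted[ev1$predictions$subject_id == partner],
    ev2$predictions$predicted[ev2$predictions$subject_id == partner])
})

test_that("tensor LOSO aggregates strides by majority vote per subject", {
  withr::with_seed(13, {
    n_sub <- 6; strides <- 3
    grp_sub <- rep(c("normal", "sarcopenia"), each = n_sub / 2)
    x <- array(rnorm(n_sub * strides * 2 * 12), c(n_sub * strides, 2, 12))
    sid <- rep(sprintf("s%02d", 1:n_sub), each = strides)
    grp <- rep(grp_sub, each = strides)
    x[grp == "sarcopenia", 2, ] <- x[grp == "sarcopenia", 2, ] + 2.5
    tensors <- list(x = x, subject_id = sid, group = grp)
  })
  ev <- loso_evaluate(tensors, model_spec("cnn", filters = 6, kernel = 3,
                                          pool = 2, dense = 8, lr = 5e-3,
                                          epochs = 40))
  expect_equal(ev$n_folds, 3)
  expect_equal(nrow(ev$predictions), 6)    # subject-level decisions
  expect_gt(ev$mean_accuracy, 60)
})

test_that("label permutation drives a strong effect back to chance", {
  tab <- toy_table(n = 20, sep = 4)
  ev <- loso_evaluate(tab, model_spec("svm_linear"))
  expect_equal(ev$mean_accuracy, 100)
  acc <- purrr::map_dbl(1:6, function(s) {
    loso_evaluate(permute_group_labels(tab, seed = s),
                  model_spec("svm_linear"))$mean_accuracy
  })
  expect_lt(mean(acc), 80)
  expect_gt(mean(acc), 20)
})
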