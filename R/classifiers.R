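#' Classifier specification
#'
#' Captures the model family and its hyperparameters, defaulting to the
#' published settings: SVM (linear or RBF) with `gamma = 1.0`, `C = 5.0`;
#' random forest with 50 trees, sqrt-features, minimum leaf size 1 (the
#' recorded depth limit of 30 is vacuous at these sample sizes); MLP with
#' two tanh hidden layers of 20 units trained 70 epochs by conjugate
#' gradients; 1D CNN with 64 filters of kernel 8 and stride 1, max-pooling
#' 4/4, a dense layer (default width 1024) and softmax output; BiLSTM with
#' layers of 64 and 32 units, learning rate 0.0005 and dropout 0.2, with the
#' same dense head as the CNN.
#'
#' @param kind One of `"svm_linear"`, `"svm_rbf"`, `"rf"`, `"mlp"`,
#'   `"cnn"`, `"bilstm"`.
#' @param seed Seed controlling all stochastic training components.
#' @param ... Overrides of the defaults listed above (`gamma`, `cost`,
#'   `ntree`, `max_depth`, `min_leaf`, `hidden`, `epochs`, `filters`,
#'   `kernel`, `pool`, `dense`, `lr`, `units1`, `units2`, `dropout`).
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(kind = c("svm_linear", "svm_rbf", "rf", "mlp",
                                "cnn", "bilstm"),
                       seed = 1, ...) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    svm_linear = list(gamma = 1.0, cost = 5.0),
    svm_rbf = list(gamma = 1.0, cost = 5.0),
    rf = list(ntree = 50, max_depth = 30, min_leaf = 1),
    mlp = list(hidden = 20, epochs = 70),
    cnn = list(filters = 64, kernel = 8, pool = 4, dense = 1024,
               lr = 5e-4, epochs = 30),
    bilstm = list(units1 = 64, units2 = 32, dense = 1024, lr = 5e-4,
                  dropout = 0.2, epochs = 30))
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0L) {
    stopf("unknown hyperparameter(s) for %s: %s", kind,
          paste(unknown, collapse = ", "))
  }
  defaults[names(over)] <- over
  structure(c(list(kind = kind, seed = seed), defaults),
            class = "model_spec")
}

is_tensor_input <- function(x) is.list(x) && !is.data.frame(x) &&
  all(c("x", "group") %in% names(x))

# standardize with training statistics only (no-variance columns untouched)
standardizer <- function(train_x) {
  mu <- colMeans(train_x)
  sg <- apply(train_x, 2, sd)
  sg[sg == 0] <- 1
  function(x) sweep(sweep(x, 2, mu), 2, sg, "/")
}

#' Train a classifier and predict test labels
#'
#' Feature-based kinds (`svm_*`, `rf`, `mlp`) take feature tables (rows x
#' named features with a `group` column) and standardize them with
#' training-fold statistics; the deep kinds (`cnn`, `bilstm`) take stride
#' tensor input (a list with `x` = array `N x channels x length` and
#' `group`), or a feature table which is then treated as a length-p
#' single-channel sequence. Training is seeded and reproducible.
#'
#' @param spec A [model_spec()].
#' @param train,test Training and test inputs (same representation).
#' @return Character vector of predicted group labels for the test rows.
#' @export
train_predict <- function(spec, train, test) {
  deep <- spec$kind %in% c("cnn", "bilstm")
  if (is_tensor_input(train)) {
    if (!deep) {
      stopf("%s expects a feature table, not stride tensors", spec$kind)
    }
    xtr <- train$x; xte <- test$x
    g_train <- train$group
    g_test_n <- dim(xte)[1]
  } else {
    feats <- feature_columns(train)
    xtr_m <- as.matrix(train[, feats])
    xte_m <- as.matrix(test[, feats, drop = FALSE])
    std <- standardizer(xtr_m)
    xtr_m <- std(xtr_m); xte_m <- std(xte_m)
    g_train <- train$group
    g_test_n <- nrow(xte_m)
    if (deep) {
      xtr <- array(xtr_m, c(nrow(xtr_m), 1L, ncol(xtr_m)))
      xte <- array(xte_m, c(nrow(xte_m), 1L, ncol(xte_m)))
    }
  }
  levels <- sort(unique(g_train))
  if (length(levels) < 2L) stopf("training labels contain a single class")
  y01 <- as.numeric(g_train == levels[2])

  pred01 <- switch(spec$kind,
    svm_linear = ,
    svm_rbf = {
      kern <- if (spec$kind == "svm_rbf") "radial" else "linear"
      fit <- e1071::svm(xtr_m, factor(y01), kernel = kern,
                        gamma = spec$gamma, cost = spec$cost, scale = FALSE)
      as.numeric(as.character(predict(fit, xte_m)))
    },
    rf = {
      fit <- withr::with_seed(spec$seed, randomForest::randomForest(
        xtr_m, factor(y01), ntree = spec$ntree,
        mtry = max(1L, floor(sqrt(ncol(xtr_m)))),
        nodesize = spec$min_leaf))
      as.numeric(as.character(predict(fit, xte_m)))
    },
    mlp = {
      fit <- fit_mlp(xtr_m, y01, hidden = spec$hidden,
                     epochs = spec$epochs, seed = spec$seed)
      predict_mlp(fit, xte_m)
    },
    cnn = {
      fit <- fit_cnn(xtr, y01, filters = spec$filters,
                     kernel = spec$kernel, pool = spec$pool,
                     dense = spec$dense, lr = spec$lr,
                     epochs = spec$epochs, seed = spec$seed)
      predict_cnn(fit, xte)
    },
    bilstm = {
      fit <- fit_bilstm(tensor_to_seq(xtr), y01, units1 = spec$units1,
                        units2 = spec$units2, dense = spec$dense,
                        lr = spec$lr, dropout = spec$dropout,
                        epochs = spec$epochs, seed = spec$seed)
      predict_bilstm(fit, tensor_to_seq(xte))
    })
  levels[pred01 + 1L]
}

#' Leave-one-subject-out-per-group evaluation
#'
#' Forms one fold per matched subject pair (one normal and one sarcopenic
#' subject held out together; 10 folds at the default cohort size) and
#' reports per-fold and aggregate accuracy. Standardization, the t-test
#' screen and the Shapley-value selection are refit inside each training
#' fold by default; `pooled_selection = TRUE` performs the selection once on
#' the full table before splitting (the arrangement used with the original
#' cohort, which leaks test information and is therefore not the default).
#' Stride-level feature rows are averaged per subject before model input;
#' stride-tensor predictions are aggregated per subject by majority vote.
#'
#' @param data Feature table (with `subject_id`, `group`) or stride-tensor
#'   list (`x`, `subject_id`, `group`).
#' @param spec A [model_spec()].
#' @param screen_k If non-NULL, keep the `screen_k` lowest-p features by
#'   t-test before attribution (50 in the published pipeline).
#' @param top,floor If `top` is non-NULL, keep at most `top` features with
#'   mean absolute Shapley value at least `floor` (20 and 0.002).
#' @param pooled_selection Select features once on the full data instead of
#'   fold-internally.
#' @param gbt A [gbt_config()] for the attribution model.
#' @return A list of class `loso_eval`: `folds` tibble, `predictions`
#'   tibble, `mean_accuracy` and `sd_accuracy` (percent), `confusion`
#'   table.
#' @export
loso_evaluate <- function(data, spec, screen_k = NULL, top = NULL,
                          floor = 0.002, pooled_selection = FALSE,
                          gbt = gbt_config()) {
  tensor <- is_tensor_input(data)
  if (!tensor && "stride" %in% names(data)) {
    data <- aggregate_by_subject(data)
  }
  subj <- if (tensor) {
    tibble::tibble(subject_id = data$subject_id, group = data$group)
  } else data[, c("subject_id", "group")]
  roster <- dplyr::distinct(subj)
  groups <- sort(unique(roster$group))
  if (length(groups) != 2L) stopf("exactly two groups required")
  by_group <- purrr::map(groups, ~ sort(roster$subject_id[roster$group ==
                                                            .x]))
  n_folds <- min(lengths(by_group))
  if (n_folds < 2L) stopf("need at least 2 subjects per group")

  select_features <- function(tab) {
    if (!is.null(screen_k)) tab <- suppressWarnings(
      ttest_prescreen(tab, k = screen_k))
    if (!is.null(top)) {
      mdl <- fit_gbt(tab, gbt)
      sel <- rank_and_select(shap_values(mdl, tab), top = top,
                             floor = floor)
      tab <- tab[, c(intersect(c("subject_id", "group"), names(tab)), sel)]
    }
    feature_columns(tab)
  }
  if (!tensor && pooled_selection) {
    keep <- select_features(data)
    data <- data[, c("subject_id", "group", keep)]
    screen_k <- NULL; top <- NULL
  }

  folds <- list(); preds <- list()
  for (i in seq_len(n_folds)) {
    held <- c(by_group[[1]][i], by_group[[2]][i])
    if (tensor) {
      tr_idx <- !(data$subject_id %in% held)
      train <- list(x = data$x[tr_idx, , , drop = FALSE],
                    group = data$group[tr_idx])
      test <- list(x = data$x[!tr_idx, , , drop = FALSE],
                   group = data$group[!tr_idx])
      pred_stride <- train_predict(spec, train, test)
      te_sub <- data$subject_id[!tr_idx]
      pred <- purrr::map_chr(held, function(s) {
        votes <- table(pred_stride[te_sub == s])
        names(votes)[which.max(votes)]          # earliest label on ties
      })
      truth <- purrr::map_chr(held,
                              ~ data$group[data$subject_id == .x][1])
    } else {
      train <- data[!(data$subject_id %in% held), ]
      test <- data[data$subject_id %in% held, ]
      stopifnot(!any(test$subject_id %in% train$subject_id))
      keep <- select_features(train)
      pred <- train_predict(spec, train[, c("group", keep)],
                            test[, c("group", keep)])
      held <- test$subject_id
      truth <- test$group
    }
    folds[[i]] <- tibble::tibble(
      fold = i, n_correct = sum(pred == truth), n_total = length(truth),
      accuracy = 100 * mean(pred == truth))
    preds[[i]] <- tibble::tibble(fold = i, subject_id = held,
                                 group = truth, predicted = pred)
  }
  folds <- dplyr::bind_rows(folds)
  preds <- dplyr::bind_rows(preds)
  structure(list(
    folds = folds, predictions = preds,
    mean_accuracy = mean(folds$accuracy),
    sd_accuracy = sd(folds$accuracy),
    confusion = table(truth = preds$group, predicted = preds$predicted),
    kind = spec$kind, n_folds = n_folds),
    class = "loso_eval")
}

#' @export
print.loso_eval <- function(x, ...) {
  cat(sprintf("<loso_eval> %s, %d folds: accuracy %.1f%% (sd %.1f)\n",
              x$kind, x$n_folds, x$mean_accuracy, x$sd_accuracy))
  invisible(x)
}

#' @method tidy loso_eval
#' @export
tidy.loso_eval <- function(x, ...) x$folds

#' @method glance loso_eval
#' @export
glance.loso_eval <- function(x, ...) {
  tibble::tibble(kind = x$kind, n_folds = x$n_folds,
                 mean_accuracy = x$mean_accuracy,
                 sd_accuracy = x$sd_accuracy)
}

#' Per-fold accuracy plot for a LOSO evaluation
#'
#' @param object A [loso_evaluate()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot loso_eval
#' @export
autoplot.loso_eval <- function(object, ...) {
  ggplot2::ggplot(object$folds,
                  ggplot2::aes(x = factor(.data$fold), y = .data$accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$mean_accuracy,
                        linetype = "dashed") +
    ggplot2::labs(x = "fold (held-out subject pair)", y = "accuracy (%)",
                  title = sprintf("%s: %.1f%% mean accuracy", object$kind,
                                  object$mean_accuracy))
}

#' Permute group labels at the subject level
#'
#' Utility for chance-level (type-I error) checks: reassigns the group
#' labels among subjects uniformly at random, preserving group sizes.
#'
#' @param table Feature table with `subject_id` and `group` columns.
#' @param seed Permutation seed.
#' @return The table with permuted `group` labels.
#' @export
permute_group_labels <- function(table, seed = 1) {
  roster <- dplyr::distinct(table[, c("subject_id", "group")])
  perm <- withr::with_seed(seed, sample(roster$group))
  map <- setNames(perm, roster$subject_id)
  table$group <- unname(map[table$subject_id])
  table
}
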