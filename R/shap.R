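#' Gradient-boosted tree configuration
#'
#' Defaults are the published settings for the attribution model: binary
#' logistic objective, 20 boosting rounds, maximum depth 15, gamma 0.009,
#' subsample 0.98.
#'
#' @param nrounds Boosting rounds (default 20).
#' @param max_depth Maximum tree depth (default 15).
#' @param gamma Minimum loss reduction to split (default 0.009).
#' @param subsample Row subsample ratio per tree (default 0.98).
#' @param seed Seed for the subsampling randomness.
#' @return A list of class `gbt_config`.
#' @export
gbt_config <- function(nrounds = 20, max_depth = 15, gamma = 0.009,
                       subsample = 0.98, seed = 1) {
  structure(list(objective = "binary:logistic", nrounds = nrounds,
                 max_depth = max_depth, gamma = gamma,
                 subsample = subsample, seed = seed),
            class = "gbt_config")
}

#' Independent t-test feature prescreen
#'
#' Ranks features by the p-value of a two-sample t-test between the two
#' groups (Welch by default) and keeps the `k` smallest; ties are broken by
#' column order. Zero-variance features receive p = 1. With fewer than `k`
#' features available, all are kept with a warning.
#'
#' @param table Feature table with `group` column and feature columns.
#' @param k Number of features to retain (default 50).
#' @param var_equal Use the pooled-variance test instead of Welch.
#' @return The table restricted to the selected features (identifier columns
#'   kept); attribute `pvalues` holds a tibble of all features' p-values.
#' @export
ttest_prescreen <- function(table, k = 50, var_equal = FALSE) {
  feats <- feature_columns(table)
  groups <- unique(table$group)
  if (length(groups) != 2L) stopf("exactly two groups required, got %d",
                                  length(groups))
  x <- as.matrix(table[table$group == groups[1], feats])
  y <- as.matrix(table[table$group == groups[2], feats])
  if (nrow(x) < 2L || nrow(y) < 2L) stopf("need >= 2 rows per group")
  nx <- nrow(x); ny <- nrow(y)
  mx <- colMeans(x); my <- colMeans(y)
  vx <- apply(x, 2, var); vy <- apply(y, 2, var)
  p <- rep(1, length(feats))
  if (var_equal) {
    sp <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  ok <- se > 0
  p[ok] <- 2 * stats::pt(abs((mx - my)[ok] / se[ok]), df[if (var_equal) TRUE
                                                         else ok],
                         lower.tail = FALSE)
  if (any(!ok)) warnf("%d zero-variance feature(s) assigned p = 1", sum(!ok))
  pvals <- tibble::tibble(feature = feats, p_value = p)
  if (length(feats) < k) {
    warnf("only %d features available; keeping all (k = %d)",
          length(feats), k)
    k <- length(feats)
  }
  keep <- feats[order(p, seq_along(feats))][seq_len(k)]
  keep <- feats[feats %in% keep]                  # restore column order
  out <- table[, c(intersect(c("subject_id", "group", "stride"),
                             names(table)), keep)]
  attr(out, "pvalues") <- pvals
  out
}

#' Fit the gradient-boosted tree attribution model
#'
#' @param table Feature table with a `group` column (two classes; the second
#'   level alphabetically, e.g. "sarcopenia", is coded 1).
#' @param config A [gbt_config()].
#' @return A list of class `gbt_model` with the xgboost booster, feature
#'   names and class levels.
#' @export
fit_gbt <- function(table, config = gbt_config()) {
  feats <- feature_columns(table)
  levels <- sort(unique(table$group))
  if (length(levels) < 2L) stopf("training labels contain a single class")
  y <- as.numeric(table$group == levels[2])
  x <- as.matrix(table[, feats])
  dm <- xgboost::xgb.DMatrix(x, label = y)
  booster <- withr::with_seed(config$seed, xgboost::xgb.train(
    params = list(objective = config$objective,
                  max_depth = config$max_depth, gamma = config$gamma,
                  subsample = config$subsample, seed = config$seed,
                  nthread = 1),
    data = dm, nrounds = config$nrounds, verbose = 0))
  structure(list(booster = booster, features = feats, levels = levels,
                 config = config),
            class = "gbt_model")
}

#' Exact Shapley values by full subset enumeration
#'
#' Computes \eqn{\phi_i = \sum_{S \subseteq N \setminus \{i\}}
#' |S|!\,(n-|S|-1)!/n!\; (v(S \cup \{i\}) - v(S))} by enumerating all
#' \eqn{2^n} subsets of the player set. This is the reference oracle for any
#' approximate attribution; it refuses more than 15 players.
#'
#' @param v A set function: takes an integer vector of included player
#'   indices (possibly empty) and returns a scalar.
#' @param n Number of players (`<= 15`).
#' @return Numeric vector of `n` Shapley values.
#' @examples
#' v <- function(s) c(0, 1, 2, 4)[1 + sum(2^(s - 1))]
#' shapley_exact(v, 2)  # 1.5, 2.5
#' @export
shapley_exact <- function(v, n) {
  if (n > 15L) {
    stopf("n = %d players exceeds the 2^n enumeration limit (15); %s", n,
          "use shap_values() for tree models")
  }
  vals <- vapply(0:(2^n - 1), function(mask) {
    v(which(bitwAnd(mask, 2^(0:(n - 1))) > 0))
  }, numeric(1))
  lf <- lgamma(seq_len(n + 1))        # log factorials 0! .. n!
  wt <- function(s) exp(lf[s + 1] + lf[n - s] - lf[n + 1])
  phi <- numeric(n)
  for (i in seq_len(n)) {
    bit <- 2^(i - 1)
    masks <- 0:(2^n - 1)
    masks <- masks[bitwAnd(masks, bit) == 0]
    sizes <- vapply(masks, function(m) sum(bitwAnd(m, 2^(0:(n - 1))) > 0),
                    numeric(1))
    phi[i] <- sum(wt(sizes) * (vals[masks + bit + 1] - vals[masks + 1]))
  }
  phi
}

#' Path-conditional set function of a fitted tree ensemble
#'
#' Returns the cover-weighted conditional expectation oracle used to verify
#' tree attributions against [shapley_exact()]: for a sample `x` and a
#' feature subset `S`, splits on features in `S` follow `x` while splits on
#' unknown features average the branches by their training cover.
#'
#' @param model A [fit_gbt()] model.
#' @param x Named numeric vector (one sample).
#' @return A function `v(idx)` mapping integer indices into
#'   `model$features` to the ensemble margin contribution (sum over trees,
#'   without the intercept).
#' @export
tree_value_function <- function(model, x) {
  dump <- as.data.frame(xgboost::xgb.model.dt.tree(model = model$booster))
  trees <- split(dump, dump$Tree)
  force(x)
  function(idx) {
    known <- model$features[idx]
    total <- 0
    for (tr in trees) {
      rownames(tr) <- tr$ID
      rec <- function(id) {
        node <- tr[id, ]
        if (node$Feature == "Leaf") return(node$Gain)
        if (node$Feature %in% known) {
          branch <- if (x[[node$Feature]] < node$Split) node$Yes else node$No
          return(rec(branch))
        }
        cy <- tr[node$Yes, "Cover"]; cn <- tr[node$No, "Cover"]
        (cy * rec(node$Yes) + cn * rec(node$No)) / (cy + cn)
      }
      total <- total + rec(tr$ID[tr$Node == 0])
    }
    total
  }
}

#' Per-sample Shapley attributions for a boosted-tree model
#'
#' Uses the path-conditional TreeSHAP algorithm (xgboost's `predcontrib`) to
#' attribute each sample's margin prediction to the features. The result
#' satisfies the efficiency identity: per-sample attributions plus the base
#' value reproduce the model margin (up to the float32 precision the booster
#' computes in).
#'
#' @param model A [fit_gbt()] model.
#' @param table Feature table containing the model's feature columns.
#' @return A list of class `shap_result`: `phi` (samples x features matrix),
#'   `base` (expected margin), `importance` (tibble of mean absolute
#'   attributions with ranks), `data` (the feature values), `margin`
#'   (per-sample model margin).
#' @export
shap_values <- function(model, table) {
  missing_cols <- setdiff(model$features, names(table))
  if (length(missing_cols) > 0L) {
    stopf("table is missing model feature column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  x <- as.matrix(table[, model$features])
  dm <- xgboost::xgb.DMatrix(x)
  contrib <- predict(model$booster, dm, predcontrib = TRUE)
  phi <- contrib[, model$features, drop = FALSE]
  bias_col <- intersect(c("BIAS", "(Intercept)"), colnames(contrib))[1]
  base <- unname(contrib[, bias_col])
  margin <- qlogis(predict(model$booster, dm))
  imp <- colMeans(abs(phi))
  importance <- tibble::tibble(
    feature = model$features, importance = unname(imp))
  importance <- importance[order(-importance$importance,
                                 seq_along(model$features)), ]
  importance$rank <- seq_len(nrow(importance))
  structure(list(phi = phi, base = base, importance = importance,
                 data = tibble::as_tibble(as.data.frame(x)),
                 margin = margin, levels = model$levels),
            class = "shap_result")
}

#' @export
print.shap_result <- function(x, ...) {
  cat(sprintf("<shap_result> %d samples x %d features; top: %s\n",
              nrow(x$phi), ncol(x$phi),
              paste(head(x$importance$feature, 3), collapse = ", ")))
  invisible(x)
}

#' Select the top features by mean absolute attribution
#'
#' Orders features by mean |Shapley value| and keeps at most `top` whose
#' importance is at least `floor` (published defaults: top 20, floor 0.002).
#' Ties are broken by column order.
#'
#' @param result A [shap_values()] result.
#' @param top Maximum number of features (default 20).
#' @param floor Minimum mean absolute attribution (default 0.002).
#' @return Character vector of selected feature names; attribute `n_below`
#'   counts features excluded by the floor within the top set.
#' @export
rank_and_select <- function(result, top = 20, floor = 0.002) {
  imp <- result$importance
  cand <- imp[imp$rank <= top, ]
  sel <- cand$feature[cand$importance >= floor]
  structure(sel, n_below = sum(cand$importance < floor))
}

#' Long-format export of the attribution summary plot
#'
#' One row per (sample, feature): the attribution, the observed feature
#' value and the feature's importance rank — sufficient to redraw a SHAP
#' summary (beeswarm) plot. Rows are ordered by rank.
#'
#' @param result A [shap_values()] result.
#' @return A tibble with columns `feature`, `rank`, `sample`, `phi`,
#'   `value`.
#' @export
summary_plot_data <- function(result) {
  out <- purrr::map_dfr(seq_len(nrow(result$importance)), function(i) {
    f <- result$importance$feature[i]
    tibble::tibble(feature = f, rank = result$importance$rank[i],
                   sample = seq_len(nrow(result$phi)),
                   phi = unname(result$phi[, f]),
                   value = result$data[[f]])
  })
  out[order(out$rank, out$sample), ]
}

#' @method tidy shap_result
#' @export
tidy.shap_result <- function(x, ...) x$importance

#' @method glance shap_result
#' @export
glance.shap_result <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x$phi), n_features = ncol(x$phi),
                 base_value = mean(x$base),
                 max_efficiency_gap = max(abs(rowSums(x$phi) + x$base -
                                                x$margin)))
}

#' Summary (beeswarm-style) plot of Shapley attributions
#'
#' @param object A [shap_values()] result.
#' @param top Number of top-ranked features to show.
#' @param ... Unused.
#' @return A ggplot object: one jittered row per feature, points at their
#'   attribution values coloured by the (min-max scaled) feature value.
#' @method autoplot shap_result
#' @export
autoplot.shap_result <- function(object, top = 20, ...) {
  dat <- summary_plot_data(object)
  dat <- dat[dat$rank <= top, ]
  dat <- dplyr::mutate(dplyr::group_by(dat, .data$feature),
                       scaled = if (diff(range(.data$value)) > 0)
                         (.data$value - min(.data$value)) /
                         diff(range(.data$value)) else 0.5)
  dat$feature <- stats::reorder(dat$feature, -dat$rank)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$phi, y = .data$feature,
                                    colour = .data$scaled)) +
    ggplot2::geom_jitter(height = 0.2, width = 0, size = 0.8, alpha = 0.8) +
    ggplot2::scale_colour_viridis_c(name = "feature value\n(scaled)") +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2) +
    ggplot2::labs(x = "Shapley value (margin units)", y = NULL)
}
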