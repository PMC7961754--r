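test_that("shapley_exact reproduces hand-computed and axiomatic values", {
  v <- function(s) c(0, 1, 2, 4)[1 + sum(2^(s - 1))]
  expect_equal(shapley_exact(v, 2), c(1.5, 2.5))

  w <- c(0.4, -0.3, 1.1)
  expect_equal(shapley_exact(function(s) sum(w[s]), 3), w)
  expect_error(shapley_exact(function(s) 0, 16), "enumeration limit")

  # property over random games: efficiency, symmetry, dummy
  for (seed in 1:5) {
    n <- 5
    vals <- withr::with_seed(seed, rnorm(2^n))
    key <- function(s) 1 + sum(2^(s - 1))
    # player 4 is a dummy; players 1 and 2 are interchangeable substitutes
    v2 <- function(s) {
      both <- sum(c(1, 2) %in% s)
      s2 <- setdiff(s, c(2, 4))
      if (both >= 1) s2 <- union(s2, 1)
      base <- vals[key(sort(s2))]
      base + 0.5 * both                            # symmetric additive boost
    }
    phi <- shapley_exact(v2, n)
    expect_equal(sum(phi), v2(1:n) - v2(integer()), tolerance = 1e-10)
    expect_equal(phi[1], phi[2], tolerance = 1e-10)
    expect_equal(phi[4], 0, tolerance = 1e-10)
  }
})

test_that("t-test prescreen keeps the k most separated features", {
  co <- small_cohort()
  ft <- aggregate_by_subject(build_feature_table(co, "seven",
                                                 use = "truth"))
  kept <- ttest_prescreen(ft, k = 50)
  expect_length(feature_columns(kept), 50)
  expect_true(all(c("subject_id", "group") %in% names(kept)))

  # cap: fewer features than k
  small <- ft[, c("subject_id", "group", feature_columns(ft)[1:30])]
  expect_warning(kept30 <- ttest_prescreen(small, k = 50), "30 features")
  expect_length(feature_columns(kept30), 30)

  # a feature with a planted 3-sd separation must rank first
  set.seed(8)
  n <- 20
  tab <- tibble::as_tibble(setNames(as.data.frame(matrix(rnorm(n * 10), n)),
                                    paste0("f", 1:10)))
  tab$subject_id <- sprintf("s%02d", 1:n)
  tab$group <- rep(c("normal", "sarcopenia"), each = n / 2)
  tab$f7 <- rnorm(n, ifelse(tab$group == "sarcopenia", 3, 0), 1)
  top1 <- ttest_prescreen(tab, k = 1)
  expect_equal(feature_columns(top1), "f7")
})

test_that("the boosted-tree fit is seeded and refuses degenerate labels", {
  set.seed(5)
  tab <- tibble::tibble(f1 = rnorm(40), f2 = rnorm(40))
  tab$group <- ifelse(tab$f1 > 0, "sarcopenia", "normal")
  m1 <- fit_gbt(tab); m2 <- fit_gbt(tab)
  x <- as.matrix(tab[, 1:2])
  expect_equal(predict(m1$booster, xgboost::xgb.DMatrix(x)),
               predict(m2$booster, xgboost::xgb.DMatrix(x)))
  # boosting reduces training log-loss over rounds on separable data
  ll <- function(m) {
    p <- predict(m$booster, xgboost::xgb.DMatrix(x))
    y <- as.numeric(tab$group == "sarcopenia")
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }
  expect_lt(ll(fit_gbt(tab, gbt_config(nrounds = 20))),
            ll(fit_gbt(tab, gbt_config(nrounds = 1))))
  tab$group <- "normal"
  expect_error(fit_gbt(tab), "single class")
})

test_that("tree attributions agree with the brute-force oracle", {
  set.seed(3)
  n <- 50; p <- 6
  tab <- tibble::as_tibble(setNames(as.data.frame(matrix(rnorm(n * p), n)),
                                    paste0("f", 1:p)))
  tab$group <- ifelse(tab$f1 + 0.6 * tab$f4 + rnorm(n, 0, 0.4) > 0,
                      "sarcopenia", "normal")
  model <- fit_gbt(tab, gbt_config(nrounds = 1, max_depth = 3,
                                   subsample = 1))
  res <- shap_values(model, tab)
  for (i in c(1, 7, 23)) {
    vf <- tree_value_function(model, unlist(tab[i, model$features]))
    expect_equal(unname(res$phi[i, ]), shapley_exact(vf, p),
                 tolerance = 1e-6)
  }
  # a depth-1 tree attributes only through its split feature
  stump <- fit_gbt(tab, gbt_config(nrounds = 1, max_depth = 1,
                                   subsample = 1))
  sres <- shap_values(stump, tab)
  used <- colnames(sres$phi)[colSums(abs(sres$phi)) > 0]
  expect_length(used, 1)

  # efficiency: sum(phi) + base = margin for every sample (float32 model)
  full <- shap_values(fit_gbt(tab), tab)
  expect_lt(glance(full)$max_efficiency_gap, 1e-4)
  expect_error(shap_values(model, tab[, c("group", "f1")]), "f2")
})

test_that("selection applies the top-k cap and the importance floor", {
  fake <- structure(list(
    phi = matrix(0, 2, 3, dimnames = list(NULL, c("a", "b", "c"))),
    base = c(0, 0), margin = c(0, 0),
    importance = tibble::tibble(feature = c("a", "b", "c"),
                                importance = c(0.5, 0.4, 0.001),
                                rank = 1:3),
    data = tibble::tibble(a = 1:2, b = 1:2, c = 1:2)),
    class = "shap_result")
  expect_equal(as.character(rank_and_select(fake, top = 20)), c("a", "b"))
  expect_equal(attr(rank_and_select(fake, top = 20), "n_below"), 1)
  none <- fake
  none$importance$importance <- c(1e-4, 1e-5, 0)
  expect_length(rank_and_select(none, top = 20), 0)

  # summary export: k x m rows, rank-ordered, values pass through bit-exact
  set.seed(1)
  tab <- tibble::tibble(f1 = rnorm(30), f2 = rnorm(30))
  tab$group <- ifelse(tab$f1 > 0, "sarcopenia", "normal")
  res <- shap_values(fit_gbt(tab), tab)
  exp_rows <- nrow(tab) * 2
  spd <- summary_plot_data(res)
  expect_equal(nrow(spd), exp_rows)
  expect_true(!is.unsorted(spd$rank))
  top_feat <- res$importance$feature[1]
  expect_identical(spd$value[spd$feature == top_feat], tab[[top_feat]])
})
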