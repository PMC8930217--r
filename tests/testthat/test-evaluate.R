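test_that("confusion counts are exact", {
  y <- c(rep("tumor", 52), rep("normal", 50))
  cm <- confusion(y, y, "tumor")
  expect_equal(cm$tp, 52)
  expect_equal(cm$tn, 50)
  expect_equal(cm$fp + cm$fn, 0)

  all_pos <- confusion(y, rep("tumor", 102), "tumor")
  expect_equal(all_pos$tn, 0)
  expect_equal(all_pos$fn, 0)
  expect_equal(all_pos$fp, 50)

  # hand-built length-20 case: tp=9, fp=1, tn=8, fn=2
  y_true <- c(rep("t", 11), rep("n", 9))
  y_pred <- c(rep("t", 9), "n", "n", "t", rep("n", 8))
  cm <- confusion(y_true, y_pred, "t")
  expect_equal(unlist(cm[c("tp", "fp", "tn", "fn")]),
               c(tp = 9, fp = 1, tn = 8, fn = 2))

  expect_error(confusion(y_true, c(y_pred[-1], "x"), "t"), "unknown")
  expect_error(confusion(y_true, y_pred, "z"), "positive_label")
})

test_that("metrics match their formulas on the hand case", {
  perfect <- confusion(c("t", "t", "n"), c("t", "t", "n"), "t")
  expect_equal(unname(unclass(classification_metrics(perfect))),
               rep(100, 5))

  cm <- structure(list(tp = 9, fp = 1, tn = 8, fn = 2,
                       positive_label = "t"),
                  class = "confusion_counts")
  m <- classification_metrics(cm)
  expect_equal(round(unname(m["sensitivity"]), 2), 81.82)
  expect_equal(round(unname(m["specificity"]), 2), 88.89)
  expect_equal(round(unname(m["precision"]), 2), 90.00)
  expect_equal(round(unname(m["accuracy"]), 2), 85.00)
  expect_equal(round(unname(m["f_score"]), 2), 85.71)

  # F equals precision when precision == sensitivity
  sym <- structure(list(tp = 8, fp = 2, tn = 8, fn = 2,
                        positive_label = "t"),
                   class = "confusion_counts")
  ms <- classification_metrics(sym)
  expect_equal(unname(ms["f_score"]), unname(ms["precision"]))

  degen <- structure(list(tp = 0, fp = 0, tn = 5, fn = 0,
                          positive_label = "t"),
                     class = "confusion_counts")
  w <- capture_warnings(md <- classification_metrics(degen))
  expect_true(any(grepl("0/0", w)))  # sensitivity and precision both warn
  expect_equal(unname(md["precision"]), 0)
})

test_that("ROC endpoints, chance level, and the hand example hold", {
  sep <- roc_auc(c("a", "a", "b", "b"), c(0.9, 0.8, 0.2, 0.1), "a")
  expect_equal(sep$auc, 100)
  expect_equal(sep$curve$tpr[1], 0)
  expect_equal(utils::tail(sep$curve$tpr, 1), 1)
  expect_true(all(diff(sep$curve$tpr) >= 0))
  expect_true(all(diff(sep$curve$fpr) >= 0))

  hand <- roc_auc(c("+", "+", "-", "-"), c(0.9, 0.4, 0.6, 0.1), "+")
  expect_equal(hand$auc, 75)

  set.seed(77)
  y <- sample(c("a", "b"), 2000, replace = TRUE)
  s <- runif(2000)
  expect_lt(abs(roc_auc(y, s, "a")$auc - 50), 4)

  # invariant under strictly monotone score transforms
  expect_equal(roc_auc(y, exp(3 * s), "a")$auc, roc_auc(y, s, "a")$auc)

  expect_error(roc_auc(c("a", "a"), c(0.1, 0.2), "a"), "both classes")
})

test_that("metrics and AUC agree with the independent reference", {
  skip_if_not_installed("pROC")
  set.seed(101)
  for (i in 1:100) {
    n <- sample(20:60, 1)
    y <- sample(c("pos", "neg"), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1:2] <- c("pos", "neg")
    # ties on purpose: scores rounded to one decimal
    s <- round(runif(n) + 0.3 * (y == "pos"), 1)
    mine <- roc_auc(y, s, "pos")$auc / 100
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = y, predictor = s, levels = c("neg", "pos"),
      direction = "<", quiet = TRUE)))
    expect_lt(abs(mine - ref), 1e-9)

    pred <- ifelse(s >= 0.5, "pos", "neg")
    if (length(unique(pred)) < 2) next
    cm <- confusion(y, pred, "pos")
    m <- classification_metrics(cm)
    tab_sens <- sum(y == "pos" & pred == "pos") / sum(y == "pos")
    tab_spec <- sum(y == "neg" & pred == "neg") / sum(y == "neg")
    expect_lt(abs(m[["sensitivity"]] / 100 - tab_sens), 1e-9)
    expect_lt(abs(m[["specificity"]] / 100 - tab_spec), 1e-9)
  }
})

test_that("repeated evaluation produces rows, averages, and pooled ROC", {
  ds <- clean_dataset(n_genes = 40, n_informative = 8,
                      n_per_class = c(20, 20), effect = 3, seed = 55)
  rep <- repeated_evaluation(
    ds, preprocess = preprocess_config(do_log = FALSE),
    select = FALSE,
    train_opts = training_options(epochs = 30),
    net_hidden = c(8, 4), n_iterations = 4, base_seed = 2)
  expect_equal(nrow(rep$rows), 4)
  expect_equal(unname(rep$average),
               unname(colMeans(rep$rows[, -1])), tolerance = 1e-9)
  expect_true(all(rep$rows$accuracy >= 0 & rep$rows$accuracy <= 100))
  expect_true(rep$auc >= 0 && rep$auc <= 100)
  expect_equal(rep$positive_label, "tumor")
})

test_that("selection and training never see test labels", {
  ds <- clean_dataset(n_genes = 30, n_informative = 5,
                      n_per_class = c(16, 16), effect = 3, seed = 66)
  m <- ds$matrix
  split <- ciwo:::stratified_split(m$labels, 0.7, 11)
  run_pipeline <- function(mat) {
    tr <- subset_expr(mat, samples = split$train)
    sel <- run_ciwo(tr, ciwo_params(max_iter = 10, rng_seed = 3),
                    fitness_config())
    fit <- dnn_train(
      network_spec(sum(sel$best_mask), hidden = c(4, 2), init_seed = 5),
      t(tr$values[sel$best_mask, , drop = FALSE]),
      as.integer(tr$labels),
      training_options(epochs = 150, shuffle_seed = 6))
    list(mask = sel$best_mask, params = fit$params)
  }
  ref <- run_pipeline(m)

  # swap the labels of one correctly predicted test pair (tumor, normal)
  te <- subset_expr(m, samples = split$test)
  pred <- dnn_predict(ref$params,
                      t(te$values[ref$mask, , drop = FALSE]))$labels
  lv <- levels(m$labels)
  correct <- lv[pred] == as.character(te$labels)
  i_t <- split$test[which(correct & te$labels == "tumor")[1]]
  i_n <- split$test[which(correct & te$labels == "normal")[1]]
  perm <- m
  perm$labels[c(i_t, i_n)] <- perm$labels[c(i_n, i_t)]
  out <- run_pipeline(perm)

  # the selected mask and model parameters are untouched...
  expect_identical(out$mask, ref$mask)
  expect_identical(out$params, ref$params)

  # ...while the evaluation outcome changes
  te_perm <- subset_expr(perm, samples = split$test)
  acc1 <- mean(lv[pred] == as.character(te$labels))
  acc2 <- mean(lv[pred] == as.character(te_perm$labels))
  expect_false(isTRUE(all.equal(acc1, acc2)))
})

test_that("reports export with rounded CSV and full-precision JSON", {
  ds <- clean_dataset(n_genes = 20, n_informative = 5,
                      n_per_class = c(12, 12), effect = 3, seed = 77)
  rep <- repeated_evaluation(
    ds, preprocess = preprocess_config(do_log = FALSE), select = FALSE,
    train_opts = training_options(epochs = 20), net_hidden = c(4, 2),
    n_iterations = 2, base_seed = 3)
  csv <- tempfile(fileext = ".csv")
  js <- tempfile(fileext = ".json")
  roc <- tempfile(fileext = ".csv")
  write_report(rep, csv, js, roc)
  tab <- utils::read.csv(csv)
  expect_equal(nrow(tab), 3)  # 2 iterations + average
  expect_equal(tab$iteration[3], "Average")
  back <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(back$auc, rep$auc, tolerance = 1e-12)
  expect_equal(nrow(utils::read.csv(roc)), nrow(rep$roc))
})
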