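#' Confusion counts for a binary classifier
#'
#' @param y_true,y_pred Vectors of class labels of equal length, drawn
#'   from the same two classes.
#' @param positive_label The label treated as positive (e.g. `"tumor"`).
#' @return An object of class `confusion_counts` with fields `tp`, `fp`,
#'   `tn`, `fn` and `positive_label`.
#' @export
confusion <- function(y_true, y_pred, positive_label) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred lengths differ")
  }
  classes <- unique(y_true)
  if (!positive_label %in% classes) {
    stop("positive_label '", positive_label, "' not among observed labels")
  }
  unknown <- setdiff(unique(y_pred), classes)
  if (length(unknown)) {
    stop("unknown predicted label(s): ", paste(unknown, collapse = ", "))
  }
  pos_t <- y_true == positive_label
  pos_p <- y_pred == positive_label
  structure(
    list(tp = sum(pos_t & pos_p), fp = sum(!pos_t & pos_p),
         tn = sum(!pos_t & !pos_p), fn = sum(pos_t & !pos_p),
         positive_label = positive_label),
    class = "confusion_counts"
  )
}

#' Classification metrics from confusion counts
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, precision
#' `tp/(tp+fp)`, accuracy `(tp+tn)/total`, and F-score, the harmonic mean
#' of precision and sensitivity. All reported as percentages at full
#' precision; round only on export. A 0/0 denominator yields 0 with a
#' warning.
#'
#' @param c A [confusion()] result.
#' @return An object of class `metrics_row`: named numeric vector with
#'   entries `sensitivity`, `specificity`, `precision`, `accuracy`,
#'   `f_score`, each in \[0, 100\].
#' @export
classification_metrics <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning("0/0 in ", what, "; reporting 0")
      return(0)
    }
    num / den
  }
  sens <- safe_div(c$tp, c$tp + c$fn, "sensitivity")
  spec <- safe_div(c$tn, c$tn + c$fp, "specificity")
  prec <- safe_div(c$tp, c$tp + c$fp, "precision")
  acc <- safe_div(c$tp + c$tn, c$tp + c$fp + c$tn + c$fn, "accuracy")
  f <- if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
  structure(
    c(sensitivity = sens, specificity = spec, precision = prec,
      accuracy = acc, f_score = f) * 100,
    class = "metrics_row"
  )
}

#' ROC curve and AUC
#'
#' Sweeps a decision threshold over the unique positive-class scores
#' (ties grouped), producing monotone TPR/FPR sequences from (0,0) to
#' (1,1), and integrates the curve with the trapezoid rule.
#'
#' @param y_true Vector of true class labels.
#' @param scores Positive-class scores (e.g. predicted probabilities).
#' @param positive_label The label treated as positive.
#' @return list `curve` (data frame: `threshold`, `tpr`, `fpr`; the first
#'   row is the all-negative operating point) and `auc` (percentage in
#'   \[0, 100\]).
#' @examples
#' roc_auc(c("a", "a", "b", "b"), c(0.9, 0.4, 0.6, 0.1), "a")$auc  # 75
#' @export
roc_auc <- function(y_true, scores, positive_label) {
  y_true <- as.character(y_true)
  if (length(y_true) != length(scores)) stop("label/score lengths differ")
  pos <- y_true == positive_label
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("roc_auc needs both classes present")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- numeric(length(thr) + 1L)
  fpr <- numeric(length(thr) + 1L)
  for (i in seq_along(thr)) {
    call_pos <- scores >= thr[i]
    tpr[i + 1L] <- sum(call_pos & pos) / n_pos
    fpr[i + 1L] <- sum(call_pos & !pos) / n_neg
  }
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(
    curve = data.frame(threshold = c(Inf, thr), tpr = tpr, fpr = fpr),
    auc = auc * 100
  )
}

#' Repeated stratified hold-out evaluation of the full pipeline
#'
#' For each of `n_iterations` evaluation rounds: draw a seeded stratified
#' train/test split (default 70/30), optionally run chaotic invasive weed
#' feature selection on the training split only, train the network on the
#' training split restricted to the selected genes, predict the test
#' split, and record one metrics row. Feature selection and training
#' never see test labels. The matrix is preprocessed once up front with
#' the (label-free) cascade before splitting.
#'
#' @param dataset A `labeled_dataset` or bare [expr_matrix()].
#' @param preprocess A [preprocess_config()], or `NULL` to skip
#'   preprocessing (matrix must already be complete).
#' @param select `TRUE` to run [run_ciwo()] per iteration; `FALSE` to use
#'   all genes.
#' @param ciwo A [ciwo_params()] template; its `rng_seed` is re-derived
#'   per iteration from `base_seed`.
#' @param fitness A [fitness_config()].
#' @param net_hidden Hidden-layer widths of the classifier.
#' @param train_opts A [training_options()].
#' @param learning_rate RMSprop step size.
#' @param n_iterations Number of evaluation rounds.
#' @param train_frac Training fraction of the stratified split.
#' @param base_seed Master seed; iteration i uses `base_seed + i` streams
#'   for the split, selection and training.
#' @param positive_label Label counted as positive; default `"tumor"`
#'   when present, else the second factor level.
#' @return An object of class `evaluation_report`: list with `rows` (data
#'   frame, one metrics row per iteration), `average` (named vector of
#'   column means), `roc` and `auc` (pooled over all iterations' test
#'   predictions), `selected` (list of selected gene-id vectors), and
#'   `n_iterations`.
#' @export
repeated_evaluation <- function(dataset,
                                preprocess = preprocess_config(),
                                select = TRUE,
                                ciwo = ciwo_params(),
                                fitness = fitness_config(),
                                net_hidden = c(64L, 32L),
                                train_opts = training_options(),
                                learning_rate = 1e-3,
                                n_iterations = 10L,
                                train_frac = 0.7,
                                base_seed = 1L,
                                positive_label = NULL) {
  m <- if (inherits(dataset, "labeled_dataset")) dataset$matrix else dataset
  stopifnot(inherits(m, "expr_matrix"))
  if (n_iterations < 1L) stop("n_iterations must be >= 1")
  if (!is.null(preprocess)) m <- run_preprocess(m, preprocess)
  if (anyNA(m$values)) stop("matrix still has missing values; enable impute")
  lv <- levels(m$labels)
  if (is.null(positive_label)) {
    positive_label <- if ("tumor" %in% lv) "tumor" else lv[2]
  }

  rows <- NULL
  pooled_scores <- numeric(0)
  pooled_truth <- character(0)
  selected <- vector("list", n_iterations)

  for (i in seq_len(n_iterations)) {
    seed_i <- base_seed + i
    split <- stratified_split(m$labels, train_frac, seed_i)
    tries <- 0L
    while ((length(unique(m$labels[split$train])) < 2L ||
            length(unique(m$labels[split$test])) < 2L) && tries < 10L) {
      tries <- tries + 1L
      message("re-drawing split ", i, ": a class was missing")
      split <- stratified_split(m$labels, train_frac, seed_i + 1000L * tries)
    }
    train_m <- subset_expr(m, samples = split$train)
    test_m <- subset_expr(m, samples = split$test)

    if (select) {
      params_i <- ciwo
      params_i$rng_seed <- as.integer(seed_i * 131L %% .Machine$integer.max)
      sel <- run_ciwo(train_m, params_i, fitness)
      mask <- sel$best_mask
      if (!any(mask)) mask[] <- TRUE  # degenerate: fall back to all genes
    } else {
      mask <- rep(TRUE, nrow(m$values))
      names(mask) <- m$gene_ids
    }
    selected[[i]] <- m$gene_ids[mask]

    spec <- network_spec(n_input = sum(mask), hidden = net_hidden,
                         n_output = 2L, init_seed = seed_i)
    opts <- train_opts
    opts$shuffle_seed <- as.integer(seed_i + 500L)
    fit <- dnn_train(spec,
                     x = t(train_m$values[mask, , drop = FALSE]),
                     y = as.integer(train_m$labels),
                     opts = opts, learning_rate = learning_rate)
    pred <- dnn_predict(fit$params, t(test_m$values[mask, , drop = FALSE]))
    y_hat <- lv[pred$labels]

    cm <- confusion(as.character(test_m$labels), y_hat, positive_label)
    rows <- rbind(rows, as.data.frame(as.list(unclass(
      classification_metrics(cm)))))

    pos_col <- match(positive_label, lv)
    pooled_scores <- c(pooled_scores, pred$probabilities[, pos_col])
    pooled_truth <- c(pooled_truth, as.character(test_m$labels))
  }

  rows <- cbind(iteration = seq_len(n_iterations), rows)
  roc <- roc_auc(pooled_truth, pooled_scores, positive_label)
  structure(
    list(rows = rows,
         average = colMeans(rows[, -1, drop = FALSE]),
         roc = roc$curve, auc = roc$auc,
         selected = selected, n_iterations = n_iterations,
         positive_label = positive_label),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report: %d iterations, positive class '%s'\n",
              x$n_iterations, x$positive_label))
  print(round(x$rows, 2), row.names = FALSE)
  cat("Average:", paste(sprintf("%s %.2f", names(x$average), x$average),
                        collapse = ", "), "\n")
  cat(sprintf("Pooled AUC: %.2f%%\n", x$auc))
  invisible(x)
}

#' Export an evaluation report
#'
#' Writes the per-iteration metrics plus the average row as CSV
#' (percentages rounded to 2 decimals, matching the conventional table
#' format), and optionally the full-precision report as JSON and the ROC
#' points as CSV.
#'
#' @param report An `evaluation_report`.
#' @param csv_path Metrics table CSV path (optional).
#' @param json_path Full-precision JSON path (optional).
#' @param roc_path ROC points CSV path (optional).
#' @export
write_report <- function(report, csv_path = NULL, json_path = NULL,
                         roc_path = NULL) {
  stopifnot(inherits(report, "evaluation_report"))
  if (!is.null(csv_path)) {
    tab <- report$rows
    tab$iteration <- as.character(tab$iteration)
    avg <- c(iteration = "Average", as.list(report$average))
    tab <- rbind(tab, as.data.frame(avg))
    num <- vapply(tab, is.numeric, logical(1))
    tab[num] <- lapply(tab[num], round, 2)
    atomic_write(csv_path, function(tmp) {
      utils::write.csv(tab, tmp, row.names = FALSE)
    })
  }
  if (!is.null(json_path)) {
    atomic_write(json_path, function(tmp) {
      jsonlite::write_json(
        list(rows = report$rows, average = as.list(report$average),
             auc = report$auc, positive_label = report$positive_label),
        tmp, dataframe = "rows", auto_unbox = TRUE, digits = NA)
    })
  }
  if (!is.null(roc_path)) {
    atomic_write(roc_path, function(tmp) {
      utils::write.csv(report$roc, tmp, row.names = FALSE)
    })
  }
  invisible(report)
}
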