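#' Control parameters for chaotic invasive weed optimization
#'
#' Invasive weed optimization (IWO) evolves a population of candidate
#' solutions ("weeds"). Each iteration, weeds are ranked by fitness and
#' spawn a number of offspring ("seeds") that interpolates linearly between
#' `s_max` for the best rank and `s_min` for the worst:
#' `Seed_i = Round(s_min + (s_max - s_min) * (N_weed - rank_i)/(N_weed - 1))`.
#' Offspring are scattered around the parent with a per-dimension Gaussian
#' whose SD decays nonlinearly over iterations,
#' `sigma_iter = ((max_iter - iter)/max_iter)^n * (sigma_initial -
#' sigma_final) + sigma_final`, and competitive exclusion caps the
#' population at `p_max`. The chaotic variant seeds the initial population
#' from the logistic map `x_{k+1} = u x_k (1 - x_k)` (chaotic at `u = 4`).
#'
#' @param n_weed Initial population size (>= 2).
#' @param s_min,s_max Minimum / maximum seeds per weed.
#' @param sigma_initial,sigma_final Initial / final dispersal SD
#'   (0 < sigma_final <= sigma_initial).
#' @param modulation_n Nonlinear decay exponent `n`.
#' @param max_iter Iteration budget (>= 1).
#' @param p_max Population cap (>= n_weed).
#' @param u Logistic-map control parameter; 4 gives full chaos.
#' @param x0 Chaotic seed in (0,1), excluding 0.25, 0.5 and 0.75 (fixed or
#'   eventually-fixed points of the map at u = 4).
#' @param binarize_threshold Positions at or above this become selected
#'   features.
#' @param rng_seed Integer seed governing every random draw of the search.
#' @return An object of class `ciwo_params`.
#' @export
ciwo_params <- function(n_weed = 10L, s_min = 0L, s_max = 5L,
                        sigma_initial = 0.5, sigma_final = 0.01,
                        modulation_n = 3, max_iter = 50L, p_max = 30L,
                        u = 4, x0 = 0.7, binarize_threshold = 0.5,
                        rng_seed = 1L) {
  p <- list(n_weed = as.integer(n_weed), s_min = as.integer(s_min),
            s_max = as.integer(s_max), sigma_initial = sigma_initial,
            sigma_final = sigma_final, modulation_n = modulation_n,
            max_iter = as.integer(max_iter), p_max = as.integer(p_max),
            u = u, x0 = x0, binarize_threshold = binarize_threshold,
            rng_seed = as.integer(rng_seed))
  if (p$s_min < 0 || p$s_min > p$s_max) stop("need 0 <= s_min <= s_max")
  if (p$sigma_initial <= 0 || p$sigma_final < 0 ||
      p$sigma_final > p$sigma_initial) {
    stop("need 0 <= sigma_final <= sigma_initial, sigma_initial > 0")
  }
  if (p$n_weed < 2L) stop("n_weed must be >= 2")
  if (p$p_max < p$n_weed) stop("p_max must be >= n_weed")
  if (p$max_iter < 0L) stop("max_iter must be >= 0")
  if (p$u <= 0 || p$u > 4) stop("u must be in (0, 4]")
  if (p$binarize_threshold <= 0 || p$binarize_threshold >= 1) {
    stop("binarize_threshold must be in (0, 1)")
  }
  check_chaotic_seed(p$x0)
  class(p) <- "ciwo_params"
  p
}

check_chaotic_seed <- function(x0) {
  if (x0 <= 0 || x0 >= 1 || x0 %in% c(0.25, 0.5, 0.75)) {
    stop("chaotic seed x0 must lie in (0,1) and avoid 0.25, 0.5, 0.75, ",
         "where the logistic map at u = 4 collapses to a fixed cycle")
  }
  invisible(x0)
}

#' Fitness configuration for wrapper feature selection
#'
#' The selection fitness trades classification error against subset size:
#' `fitness = alpha * err + beta * |Y|/|T|`, where `err` is the stratified
#' `cv_folds`-fold cross-validated misclassification rate of the inner
#' classifier restricted to the selected genes Y, and `|T|` is the total
#' gene count. Lower is better. An empty subset is assigned the worst-case
#' error 1.0 so the search space stays closed.
#'
#' @param alpha,beta Nonnegative weights on error and subset size;
#'   must sum to 1. Defaults 0.99/0.01: accuracy dominates, size breaks
#'   ties.
#' @param inner_classifier `"centroid"` (nearest class centroid; fast and
#'   deterministic, the default) or `"dnn"` (a small network from
#'   [dnn_train()]; far slower, for final-stage runs).
#' @param cv_folds Number of stratified CV folds.
#' @param cv_seed Seed fixing the fold assignment.
#' @param inner_options Named list of options for the inner classifier;
#'   for `"dnn"`: `hidden`, `epochs`, `batch_size`, `learning_rate`.
#' @return An object of class `fitness_config`.
#' @export
fitness_config <- function(alpha = 0.99, beta = 0.01,
                           inner_classifier = c("centroid", "dnn"),
                           cv_folds = 5L, cv_seed = 1L,
                           inner_options = list()) {
  inner_classifier <- match.arg(inner_classifier)
  if (alpha < 0 || beta < 0) stop("alpha and beta must be >= 0")
  if (abs(alpha + beta - 1) > 1e-9) stop("alpha + beta must equal 1")
  structure(
    list(alpha = alpha, beta = beta, inner_classifier = inner_classifier,
         cv_folds = as.integer(cv_folds), cv_seed = as.integer(cv_seed),
         inner_options = inner_options),
    class = "fitness_config"
  )
}

#' Logistic chaotic map sequence
#'
#' Iterates `x_{k+1} = u * x_k * (1 - x_k)`. At `u = 4` the map is chaotic
#' and ergodic on (0,1); the starting points 0.25, 0.5 and 0.75 are
#' excluded because they fall onto fixed points (0.75 maps to itself; 0.5
#' maps to 1 and then sticks at 0).
#'
#' @param x0 Start value in (0,1), not one of 0.25, 0.5, 0.75.
#' @param u Control parameter in (0, 4].
#' @param length Sequence length (including `x0`).
#' @param check_x0 Set `FALSE` to bypass the start-value guard, e.g. to
#'   inspect the degenerate fixed points themselves.
#' @return Numeric vector of length `length`, all values in \[0, 1\].
#' @examples
#' logistic_map(0.2, 4, 3)  # 0.2, 0.64, 0.9216
#' @export
logistic_map <- function(x0, u = 4, length = 1L, check_x0 = TRUE) {
  if (u <= 0 || u > 4) stop("u must be in (0, 4]")
  if (check_x0) check_chaotic_seed(x0)
  if (length < 1L) stop("length must be >= 1")
  out <- numeric(length)
  out[1] <- x0
  x <- x0
  if (length > 1L) {
    for (k in 2:length) {
      x <- u * x * (1 - x)
      # confine round-off excursions to the unit interval
      if (x < 0) x <- 0 else if (x > 1) x <- 1
      out[k] <- x
    }
  }
  out
}

#' Initialize a chaotic weed population
#'
#' Draws `n_weed` uniform base positions in \[0,1\]^N and modulates them
#' element-wise with consecutive logistic-map values (position =
#' chaotic value x base, clipped to \[0,1\]), so the initial population
#' inherits the map's ergodic coverage of the unit cube. Masks are derived
#' by thresholding positions at `binarize_threshold`.
#'
#' @param n_weed Number of weeds.
#' @param n_features Dimension N of each position vector.
#' @param params A [ciwo_params()].
#' @return A `weed_population`: list with `position` (n_weed x N matrix),
#'   `mask` (logical matrix), `fitness` (numeric, `NA` until evaluated).
#' @export
init_chaotic_population <- function(n_weed, n_features, params) {
  stopifnot(inherits(params, "ciwo_params"), n_features >= 1)
  chaos <- logistic_map(params$x0, params$u, n_weed * n_features)
  base <- with_seed(params$rng_seed, {
    matrix(stats::runif(n_weed * n_features), n_weed, n_features)
  })
  pos <- base * matrix(chaos, n_weed, n_features, byrow = TRUE)
  pos[pos < 0] <- 0
  pos[pos > 1] <- 1
  new_population(pos, params$binarize_threshold)
}

new_population <- function(position, threshold, fitness = NULL) {
  structure(
    list(position = position,
         mask = position >= threshold,
         fitness = fitness %||% rep(NA_real_, nrow(position)),
         threshold = threshold),
    class = "weed_population"
  )
}

#' @export
print.weed_population <- function(x, ...) {
  cat(sprintf("weed_population: %d weeds x %d features, best fitness %s\n",
              nrow(x$position), ncol(x$position),
              if (all(is.na(x$fitness))) "unevaluated"
              else format(min(x$fitness, na.rm = TRUE))))
  invisible(x)
}

#' Seeds produced by a weed of a given fitness rank
#'
#' `Round(s_min + (s_max - s_min) * (n_weed - rank)/(n_weed - 1))`,
#' rounded half-up, so the best-ranked weed (rank 1) yields `s_max` seeds
#' and the worst yields `s_min`.
#'
#' @param rank Fitness rank, 1 = best, in 1..n_weed.
#' @param n_weed Population size (>= 2; a singleton population has no rank
#'   spread and the caller must special-case it to `s_max`).
#' @param s_min,s_max Seed-count endpoints.
#' @return Integer seed count.
#' @examples
#' seeds_for_rank(3, 5, 2, 6)  # 4
#' @export
seeds_for_rank <- function(rank, n_weed, s_min, s_max) {
  if (any(n_weed == 1L)) {
    stop("seeds_for_rank is undefined for n_weed = 1 (division by zero); ",
         "use s_max for a singleton population")
  }
  stopifnot(all(rank >= 1), all(rank <= n_weed))
  as.integer(round_half_up(s_min + (s_max - s_min) * (n_weed - rank) /
                             (n_weed - 1)))
}

#' Dispersal standard deviation at a given iteration
#'
#' Decays from `sigma_initial` at iteration 0 to `sigma_final` at
#' `max_iter` with nonlinear modulation exponent `n`:
#' `((max_iter - iter)/max_iter)^n * (sigma_initial - sigma_final) +
#' sigma_final`.
#'
#' @param iter Iteration counter in 0..max_iter.
#' @param params A [ciwo_params()].
#' @return The dispersal SD.
#' @export
dispersal_sd <- function(iter, params) {
  stopifnot(inherits(params, "ciwo_params"))
  stopifnot(all(iter >= 0), all(iter <= params$max_iter))
  if (params$max_iter == 0L) return(params$sigma_initial)
  ((params$max_iter - iter) / params$max_iter)^params$modulation_n *
    (params$sigma_initial - params$sigma_final) + params$sigma_final
}

# ---- fitness -------------------------------------------------------------

#' Wrapper-selection fitness of a feature mask
#'
#' Computes `alpha * err + beta * |Y|/|T|` with `err` the stratified
#' cross-validated misclassification rate of the inner classifier using
#' only the selected genes. An empty mask receives the worst-case error
#' 1.0 by convention. Deterministic given `cfg$cv_seed`. Lower is better;
#' the result lies in \[0, alpha + beta\].
#'
#' @param mask Logical vector, one entry per gene of `X`.
#' @param X A preprocessed [expr_matrix()] (no missing values).
#' @param cfg A [fitness_config()].
#' @return The fitness value.
#' @export
evaluate_fitness <- function(mask, X, cfg = fitness_config()) {
  stopifnot(inherits(X, "expr_matrix"), inherits(cfg, "fitness_config"))
  if (length(mask) != nrow(X$values)) {
    stop("mask length (", length(mask), ") != gene count (",
         nrow(X$values), ")")
  }
  folds <- stratified_folds(X$labels, cfg$cv_folds, cfg$cv_seed)
  fitness_of_mask(as.logical(mask), X, cfg, folds)
}

#' Fitness scalarization from its components
#'
#' The bi-objective scalarization `alpha * error + beta * n_selected /
#' n_total` on precomputed components; [evaluate_fitness()] composes this
#' with the cross-validated error of the inner classifier.
#'
#' @param error Misclassification rate in \[0, 1\].
#' @param n_selected Number of selected features |Y|.
#' @param n_total Total number of features |T|.
#' @param cfg A [fitness_config()] supplying `alpha` and `beta`.
#' @return The fitness value.
#' @examples
#' fitness_value(0.1, 5, 20, fitness_config(alpha = 0.99, beta = 0.01))
#' # 0.1015
#' @export
fitness_value <- function(error, n_selected, n_total,
                          cfg = fitness_config()) {
  stopifnot(error >= 0, error <= 1, n_selected >= 0, n_selected <= n_total)
  cfg$alpha * error + cfg$beta * n_selected / n_total
}

fitness_of_mask <- function(mask, X, cfg, folds) {
  n_sel <- sum(mask)
  err <- if (n_sel == 0L) 1.0 else cv_error(mask, X, cfg, folds)
  fitness_value(err, n_sel, length(mask), cfg)
}

cv_error <- function(mask, X, cfg, folds) {
  Xm <- X$values[mask, , drop = FALSE]
  y <- X$labels
  wrong <- 0L
  for (k in seq_len(max(folds))) {
    te <- folds == k
    pred <- switch(cfg$inner_classifier,
      centroid = centroid_predict(Xm, y, train = !te, test = te),
      dnn = dnn_fold_predict(Xm, y, train = !te, test = te,
                             cfg$inner_options),
      stop("unknown inner classifier: ", cfg$inner_classifier)
    )
    wrong <- wrong + sum(pred != as.integer(y[te]))
  }
  wrong / length(y)
}

# Nearest class centroid on the selected genes; ties go to the first
# factor level. Returns integer class codes for the test samples.
centroid_predict <- function(Xm, y, train, test) {
  c1 <- rowMeans(Xm[, train & y == levels(y)[1], drop = FALSE])
  c2 <- rowMeans(Xm[, train & y == levels(y)[2], drop = FALSE])
  Xte <- Xm[, test, drop = FALSE]
  d1 <- colSums((Xte - c1)^2)
  d2 <- colSums((Xte - c2)^2)
  ifelse(d1 <= d2, 1L, 2L)
}

dnn_fold_predict <- function(Xm, y, train, test, opts) {
  hidden <- opts$hidden %||% c(16L, 8L)
  spec <- network_spec(n_input = nrow(Xm), hidden = hidden,
                       init_seed = opts$init_seed %||% 11L)
  fit <- dnn_train(spec,
                   x = t(Xm[, train, drop = FALSE]),
                   y = as.integer(y[train]),
                   opts = training_options(
                     epochs = opts$epochs %||% 50L,
                     batch_size = opts$batch_size %||% 16L,
                     shuffle_seed = opts$shuffle_seed %||% 13L,
                     record_history = FALSE),
                   learning_rate = opts$learning_rate %||% 1e-3)
  dnn_predict(fit$params, t(Xm[, test, drop = FALSE]))$labels
}

# Memoizing fitness evaluator with precomputed folds; used by the search
# loop so re-visited masks cost nothing.
make_fitness_evaluator <- function(X, cfg) {
  folds <- stratified_folds(X$labels, cfg$cv_folds, cfg$cv_seed)
  cache <- new.env(parent = emptyenv(), hash = TRUE)
  calls <- 0L
  evaluate <- function(mask) {
    calls <<- calls + 1L
    key <- paste0("m", paste(which(mask), collapse = ","))
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- fitness_of_mask(mask, X, cfg, folds)
    cache[[key]] <- val
    val
  }
  list(evaluate = evaluate, n_calls = function() calls)
}

# ---- reproduction and selection ------------------------------------------

#' One IWO reproduction step
#'
#' Ranks the current weeds by ascending fitness (rank 1 = best), lets each
#' spawn [seeds_for_rank()] offspring scattered with per-dimension
#' Gaussian noise of SD [dispersal_sd()] around the parent position
#' (clipped to \[0,1\]), thresholds the offspring into masks, evaluates
#' their fitness, and returns parents and offspring together.
#'
#' Draws from the ambient RNG stream; [run_ciwo()] seeds it once per run.
#'
#' @param pop A `weed_population` with all fitnesses evaluated.
#' @param iter Current iteration (1-based).
#' @param params A [ciwo_params()].
#' @param cfg A [fitness_config()].
#' @param X The preprocessed [expr_matrix()].
#' @return The enlarged `weed_population`.
#' @export
reproduce <- function(pop, iter, params, cfg, X) {
  stopifnot(inherits(pop, "weed_population"), !anyNA(pop$fitness))
  evaluator <- make_fitness_evaluator(X, cfg)
  out <- reproduce_impl(pop, iter, params, evaluator$evaluate)
  out
}

reproduce_impl <- function(pop, iter, params, evaluate) {
  n_pop <- nrow(pop$position)
  n_feat <- ncol(pop$position)
  ranks <- rank(pop$fitness, ties.method = "first")
  n_seeds <- if (n_pop == 1L) params$s_max else {
    seeds_for_rank(ranks, n_pop, params$s_min, params$s_max)
  }
  total <- sum(n_seeds)
  if (total == 0L) return(pop)
  sd_iter <- dispersal_sd(iter, params)
  parent_idx <- rep(seq_len(n_pop), n_seeds)
  off <- pop$position[parent_idx, , drop = FALSE] +
    matrix(stats::rnorm(total * n_feat, sd = sd_iter), total, n_feat)
  off[off < 0] <- 0
  off[off > 1] <- 1
  off_mask <- off >= params$binarize_threshold
  off_fit <- vapply(seq_len(total),
                    function(i) evaluate(off_mask[i, ]), numeric(1))
  new_population(rbind(pop$position, off),
                 params$binarize_threshold,
                 fitness = c(pop$fitness, off_fit))
}

#' Competitive exclusion at the population cap
#'
#' If the population exceeds `p_max`, keeps the `p_max` lowest-fitness
#' weeds. Ties are broken by fewer selected features, then by insertion
#' order, so results are deterministic; the best weed always survives.
#'
#' @param pop A `weed_population` with all fitnesses evaluated.
#' @param p_max Population cap.
#' @return The (possibly) truncated `weed_population`.
#' @export
exclude_weakest <- function(pop, p_max) {
  stopifnot(inherits(pop, "weed_population"), !anyNA(pop$fitness))
  n <- nrow(pop$position)
  if (n <= p_max) return(pop)
  sizes <- rowSums(pop$mask)
  keep <- order(pop$fitness, sizes, seq_len(n))[seq_len(p_max)]
  keep <- sort(keep)  # preserve insertion order among survivors
  new_population(pop$position[keep, , drop = FALSE],
                 pop$threshold,
                 fitness = pop$fitness[keep])
}

#' Run chaotic invasive weed optimization for feature selection
#'
#' Initializes a chaotic population, then iterates reproduction with
#' decaying dispersal and competitive exclusion for `max_iter` iterations,
#' tracking the best weed ever seen. Fully deterministic given
#' `params$rng_seed`, `params$x0`, and `cfg$cv_seed`. Fitness values for
#' previously visited masks are cached, so the reported evaluation count
#' is the number of fitness requests, not unique model fits.
#'
#' @param X A preprocessed [expr_matrix()] (no missing values).
#' @param params A [ciwo_params()].
#' @param cfg A [fitness_config()].
#' @return A `selection_result`: list with `best_mask` (logical, named by
#'   gene id), `best_fitness`, `history` (data frame: `iter`,
#'   `best_fitness`, `mean_fitness`, `pop_size`, `sigma`), and
#'   `evaluations`.
#' @examples
#' ds <- generate_dataset(synthetic_spec(n_genes = 12, n_informative = 2,
#'                                       n_samples_per_class = c(15, 15),
#'                                       effect_size = 3, frac_missing = 0,
#'                                       n_replicate_ids = 0,
#'                                       n_flat_genes = 0, raw_scale = FALSE,
#'                                       seed = 5))
#' res <- run_ciwo(standardize(ds$matrix),
#'                 ciwo_params(max_iter = 5, rng_seed = 2),
#'                 fitness_config())
#' sum(res$best_mask)
#' @export
run_ciwo <- function(X, params = ciwo_params(), cfg = fitness_config()) {
  stopifnot(inherits(X, "expr_matrix"))
  if (anyNA(X$values)) stop("run_ciwo requires a complete matrix; impute first")
  n_features <- nrow(X$values)
  evaluator <- make_fitness_evaluator(X, cfg)

  pop <- init_chaotic_population(params$n_weed, n_features, params)
  pop$fitness <- vapply(seq_len(nrow(pop$mask)),
                        function(i) evaluator$evaluate(pop$mask[i, ]),
                        numeric(1))

  best_i <- which.min(pop$fitness)
  best <- list(mask = pop$mask[best_i, ], fitness = pop$fitness[best_i])
  history <- data.frame(iter = 0L, best_fitness = best$fitness,
                        mean_fitness = mean(pop$fitness),
                        pop_size = nrow(pop$position),
                        sigma = dispersal_sd(0, params))

  with_seed(params$rng_seed + 7919L, {
    for (iter in seq_len(params$max_iter)) {
      pop <- reproduce_impl(pop, iter, params, evaluator$evaluate)
      pop <- exclude_weakest(pop, params$p_max)
      it_best <- which.min(pop$fitness)
      if (pop$fitness[it_best] < best$fitness ||
          (pop$fitness[it_best] == best$fitness &&
           sum(pop$mask[it_best, ]) < sum(best$mask))) {
        best <- list(mask = pop$mask[it_best, ],
                     fitness = pop$fitness[it_best])
      }
      history <- rbind(history, data.frame(
        iter = iter, best_fitness = best$fitness,
        mean_fitness = mean(pop$fitness),
        pop_size = nrow(pop$position),
        sigma = dispersal_sd(iter, params)))
    }
  })

  best_mask <- best$mask
  names(best_mask) <- X$gene_ids
  structure(
    list(best_mask = best_mask, best_fitness = best$fitness,
         history = history, evaluations = evaluator$n_calls(),
         params = params, cfg = cfg),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "selection_result: %d/%d features, fitness %.6f, %d evaluations\n",
    sum(x$best_mask), length(x$best_mask), x$best_fitness, x$evaluations))
  invisible(x)
}

#' Exhaustive search over all feature subsets (test oracle)
#'
#' Evaluates every mask over at most 16 genes — the feature-selection
#' search space has 2^N arrangements — including the empty mask under its
#' worst-case-error convention, and returns the argmin with the same
#' tie-break as [exclude_weakest()] (fitness, then fewer features, then
#' enumeration order).
#'
#' @param X A preprocessed [expr_matrix()] with at most 16 genes.
#' @param cfg A [fitness_config()].
#' @return list(mask = logical vector, fitness = numeric).
#' @export
brute_force_best_subset <- function(X, cfg = fitness_config()) {
  stopifnot(inherits(X, "expr_matrix"))
  n <- nrow(X$values)
  if (n > 16L) {
    stop("brute_force_best_subset refuses more than 16 genes (2^",
         n, " masks)")
  }
  folds <- stratified_folds(X$labels, cfg$cv_folds, cfg$cv_seed)
  best <- NULL
  for (code in 0:(2^n - 1)) {
    mask <- as.logical(intToBits(code)[seq_len(n)])
    fit <- fitness_of_mask(mask, X, cfg, folds)
    if (is.null(best) || fit < best$fitness ||
        (fit == best$fitness && sum(mask) < sum(best$mask))) {
      best <- list(mask = mask, fitness = fit)
    }
  }
  names(best$mask) <- X$gene_ids
  best
}

#' Write a selected-feature list and selection history
#'
#' @param result A `selection_result` from [run_ciwo()].
#' @param genes_path Path for the one-gene-id-per-line list of selected
#'   genes (optional).
#' @param history_path Path for the per-iteration history CSV (optional).
#' @param table_path Path for a CSV joining every gene id with its
#'   selected flag (optional).
#' @export
write_selection <- function(result, genes_path = NULL, history_path = NULL,
                            table_path = NULL) {
  stopifnot(inherits(result, "selection_result"))
  if (!is.null(genes_path)) {
    atomic_write(genes_path, function(tmp) {
      writeLines(names(result$best_mask)[result$best_mask], tmp)
    })
  }
  if (!is.null(history_path)) {
    atomic_write(history_path, function(tmp) {
      utils::write.csv(result$history, tmp, row.names = FALSE)
    })
  }
  if (!is.null(table_path)) {
    atomic_write(table_path, function(tmp) {
      utils::write.csv(
        data.frame(gene_id = names(result$best_mask),
                   selected = unname(result$best_mask)),
        tmp, row.names = FALSE)
    })
  }
  invisible(result)
}
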