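test_that("logistic map follows the recurrence and stays in [0,1]", {
  s <- logistic_map(0.2, 4, 3)
  expect_equal(s, c(0.2, 0.64, 0.9216))
  # degenerate start values are rejected...
  expect_error(logistic_map(0.75, 4, 5), "0.75")
  expect_error(logistic_map(0.5, 4, 5), "0.25, 0.5, 0.75")
  expect_error(logistic_map(1.2, 4, 5))
  # ...but can be inspected with the guard off: 0.75 is a fixed point
  expect_equal(logistic_map(0.75, 4, 10, check_x0 = FALSE), rep(0.75, 10))
  # ergodic trajectory never escapes the unit interval
  long <- logistic_map(0.7, 4, 1e6)
  expect_true(all(long >= 0 & long <= 1))
})

test_that("seed counts interpolate between s_max and s_min by rank", {
  expect_equal(seeds_for_rank(1, 10, 0, 5), 5L)
  expect_equal(seeds_for_rank(10, 10, 0, 5), 0L)
  expect_equal(seeds_for_rank(3, 5, 2, 6), 4L)
  # half-up rounding: 0 + 5 * (1/2) = 2.5 -> 3
  expect_equal(seeds_for_rank(2, 3, 0, 5), 3L)
  expect_error(seeds_for_rank(1, 1, 0, 5), "n_weed = 1")
})

test_that("dispersal SD decays nonlinearly between its endpoints", {
  p <- ciwo_params(sigma_initial = 1, sigma_final = 0, modulation_n = 2,
                   max_iter = 10)
  expect_equal(dispersal_sd(0, p), 1)
  expect_equal(dispersal_sd(10, p), 0)
  expect_equal(dispersal_sd(5, p), 0.25)
  expect_error(dispersal_sd(11, p))
})

test_that("chaotic initialization is deterministic and in range", {
  p <- ciwo_params(rng_seed = 5)
  pop1 <- init_chaotic_population(10, 500, p)
  pop2 <- init_chaotic_population(10, 500, p)
  expect_identical(pop1$position, pop2$position)
  expect_equal(dim(pop1$position), c(10L, 500L))
  expect_true(all(pop1$position >= 0 & pop1$position <= 1))
  expect_identical(pop1$mask, pop1$position >= p$binarize_threshold)
  # selected fraction concentrates near the modulated-draw tail mass
  draws <- stats::runif(1e5) * logistic_map(p$x0, 4, 1e5)
  expected_frac <- mean(draws >= 0.5)
  expect_lt(abs(mean(pop1$mask) - expected_frac), 0.03)
})

test_that("fitness combines CV error and subset-size penalty", {
  cfg <- fitness_config(alpha = 0.99, beta = 0.01)
  expect_equal(fitness_value(0.1, 5, 20, cfg), 0.1015)
  # monotone in each argument
  expect_gt(fitness_value(0.2, 5, 20, cfg), fitness_value(0.1, 5, 20, cfg))
  expect_gt(fitness_value(0.1, 9, 20, cfg), fitness_value(0.1, 5, 20, cfg))

  ds <- clean_dataset(n_genes = 20, n_informative = 3, effect = 4,
                      seed = 31)
  X <- ds$matrix
  empty <- rep(FALSE, 20)
  expect_equal(evaluate_fitness(empty, X, cfg), 0.99 * 1.0)
  expect_error(evaluate_fitness(rep(TRUE, 19), X, cfg), "mask length")

  # planted-only mask beats the full mask on a strong signal
  planted <- X$gene_ids %in% ds$truth_informative
  expect_lt(evaluate_fitness(planted, X, cfg),
            evaluate_fitness(rep(TRUE, 20), X, cfg))
  # bounded and deterministic
  f <- evaluate_fitness(planted, X, cfg)
  expect_true(f >= 0 && f <= 1)
  expect_identical(f, evaluate_fitness(planted, X, cfg))
})

test_that("reproduction spawns rank-dependent offspring near parents", {
  ds <- clean_dataset(n_genes = 10, n_informative = 2, seed = 17)
  X <- ds$matrix
  cfg <- fitness_config()
  p <- ciwo_params(n_weed = 5, s_min = 2, s_max = 6, rng_seed = 1)
  pop <- init_chaotic_population(5, 10, p)
  pop$fitness <- vapply(seq_len(5),
                        function(i) evaluate_fitness(pop$mask[i, ], X, cfg),
                        numeric(1))
  set.seed(99)
  out <- reproduce(pop, 1, p, cfg, X)
  expect_equal(nrow(out$position), 5 + (2 + 3 + 4 + 5 + 6))
  expect_true(all(out$position >= 0 & out$position <= 1))
  expect_false(anyNA(out$fitness))

  # constant seed count
  pc <- ciwo_params(n_weed = 5, s_min = 3, s_max = 3)
  set.seed(99)
  outc <- reproduce(pop, 1, pc, cfg, X)
  expect_equal(nrow(outc$position), 5 + 5 * 3)

  # vanishing dispersal copies the parent masks
  pz <- ciwo_params(n_weed = 5, s_min = 1, s_max = 1,
                    sigma_initial = 1e-12, sigma_final = 1e-12)
  set.seed(99)
  outz <- reproduce(pop, 1, pz, cfg, X)
  expect_identical(outz$mask[6:10, ], pop$mask)
})

test_that("competitive exclusion keeps the fittest with stated tie-breaks", {
  pos <- matrix(c(0.9, 0.9, 0.9,   # |Y| = 3
                  0.9, 0.1, 0.1,   # |Y| = 1
                  0.9, 0.9, 0.1),  # |Y| = 2
                3, 3, byrow = TRUE)
  pop <- ciwo:::new_population(pos, 0.5,
                               fitness = c(0.3, 0.1, 0.2))
  expect_identical(exclude_weakest(pop, 5), pop)
  kept <- exclude_weakest(pop, 2)
  expect_equal(kept$fitness, c(0.1, 0.2))

  tie <- ciwo:::new_population(pos, 0.5, fitness = c(0.2, 0.2, 0.2))
  kept1 <- exclude_weakest(tie, 1)
  expect_equal(rowSums(kept1$mask), 1)  # fewest features wins the tie
})

test_that("the search is elitist, bounded, and deterministic", {
  ds <- clean_dataset(n_genes = 15, n_informative = 3, effect = 2.5,
                      seed = 23)
  X <- ds$matrix
  p <- ciwo_params(max_iter = 15, p_max = 20, rng_seed = 4)
  r1 <- run_ciwo(X, p, fitness_config())
  r2 <- run_ciwo(X, p, fitness_config())
  expect_identical(r1$best_mask, r2$best_mask)
  expect_identical(r1$history, r2$history)

  expect_equal(nrow(r1$history), 15 + 1)
  expect_true(all(diff(r1$history$best_fitness) <= 0))
  expect_true(all(r1$history$pop_size <= 20))
  expect_true(all(r1$history$pop_size >= 1))
  expect_gt(r1$evaluations, 0)

  # max_iter = 0 returns the best of the initial population
  p0 <- ciwo_params(max_iter = 0, rng_seed = 4)
  r0 <- run_ciwo(X, p0, fitness_config())
  expect_equal(nrow(r0$history), 1)
  pop <- init_chaotic_population(p0$n_weed, 15, p0)
  init_fit <- vapply(seq_len(nrow(pop$mask)), function(i) {
    evaluate_fitness(pop$mask[i, ], X, fitness_config())
  }, numeric(1))
  expect_equal(r0$best_fitness, min(init_fit))
})

test_that("exhaustive search enumerates the full mask space", {
  ds <- clean_dataset(n_genes = 8, n_informative = 2, effect = 3,
                      n_per_class = c(20, 20), seed = 41)
  X <- ds$matrix
  cfg <- fitness_config()
  opt <- brute_force_best_subset(X, cfg)
  expect_equal(opt$fitness, evaluate_fitness(opt$mask, X, cfg))
  # the optimum contains the planted pair on a strong signal
  expect_true(all(ds$truth_informative %in% names(opt$mask)[opt$mask]))

  # no non-empty mask beats it; the empty-mask convention is shared
  for (code in 0:255) {
    mask <- as.logical(intToBits(code)[1:8])
    expect_gte(evaluate_fitness(mask, X, cfg), opt$fitness)
  }

  big <- clean_dataset(n_genes = 17, n_informative = 2, seed = 1)
  expect_error(brute_force_best_subset(big$matrix, cfg), "16")
})

test_that("the search matches the exhaustive optimum on small problems", {
  ds <- clean_dataset(n_genes = 8, n_informative = 2, effect = 2.5,
                      n_per_class = c(20, 20), seed = 57)
  X <- ds$matrix
  cfg <- fitness_config()
  opt <- brute_force_best_subset(X, cfg)
  hits <- sum(vapply(1:5, function(r) {
    res <- run_ciwo(X, ciwo_params(rng_seed = r), cfg)
    res$best_fitness <= opt$fitness + 1e-12
  }, logical(1)))
  expect_gte(hits, 4)
})

test_that("selection enriches for planted genes on a strong signal", {
  ds <- clean_dataset(n_genes = 60, n_informative = 6, effect = 3,
                      n_per_class = c(25, 25), seed = 71)
  res <- run_ciwo(ds$matrix, ciwo_params(max_iter = 30, rng_seed = 2),
                  fitness_config())
  sel <- names(res$best_mask)[res$best_mask]
  frac_planted_selected <- mean(ds$truth_informative %in% sel)
  frac_null_selected <- mean(setdiff(ds$matrix$gene_ids, ds$truth_informative)
                             %in% sel)
  expect_gt(frac_planted_selected, frac_null_selected)
})

test_that("parameter constructors validate their invariants", {
  expect_error(ciwo_params(x0 = 0.25), "0.25")
  expect_error(ciwo_params(s_min = 5, s_max = 2), "s_min")
  expect_error(ciwo_params(p_max = 5, n_weed = 10), "p_max")
  expect_error(ciwo_params(binarize_threshold = 0), "binarize_threshold")
  expect_error(fitness_config(alpha = 0.5, beta = 0.2), "equal 1")
})
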