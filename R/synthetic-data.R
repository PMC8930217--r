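#' Specification for a synthetic two-class expression dataset
#'
#' Describes a genes x samples matrix with a planted set of informative
#' (differentially expressed) genes and controllable contamination:
#' replicated gene ids, missing cells, and near-constant ("flat") genes.
#' The defaults emulate a prostate-tumour microarray study of 102 tissue
#' samples (52 tumour, 50 normal) measured on 2135 genes.
#'
#' @param n_genes Total number of genes (matrix rows before replication).
#' @param n_informative Number of genes carrying a class-mean shift.
#' @param n_samples_per_class Integer pair: samples in (tumor, normal).
#' @param effect_size Standardised between-class mean shift of informative
#'   genes, in units of `noise_sd`. Non-negative.
#' @param noise_sd Within-class standard deviation on the log2 scale.
#' @param frac_missing Fraction of cells set missing, in \[0, 0.5\].
#' @param n_replicate_ids Number of gene ids duplicated (one extra copy each).
#' @param n_flat_genes Number of near-constant genes planted.
#' @param raw_scale If `TRUE`, values are exponentiated (base 2) so the
#'   matrix shows the right-skewed positive intensities a log transform is
#'   meant to symmetrise; if `FALSE`, values stay on the log2 scale.
#' @param seed Integer RNG seed; the whole dataset is a deterministic
#'   function of the spec including this seed.
#' @return An object of class `synthetic_spec`.
#' @seealso [generate_dataset()], [inject_contamination()]
#' @export
synthetic_spec <- function(n_genes = 2135L,
                           n_informative = 50L,
                           n_samples_per_class = c(52L, 50L),
                           effect_size = 2,
                           noise_sd = 1,
                           frac_missing = 0.01,
                           n_replicate_ids = 5L,
                           n_flat_genes = 10L,
                           raw_scale = TRUE,
                           seed = 1L) {
  spec <- list(
    n_genes = as.integer(n_genes),
    n_informative = as.integer(n_informative),
    n_samples_per_class = as.integer(n_samples_per_class),
    effect_size = as.numeric(effect_size),
    noise_sd = as.numeric(noise_sd),
    frac_missing = as.numeric(frac_missing),
    n_replicate_ids = as.integer(n_replicate_ids),
    n_flat_genes = as.integer(n_flat_genes),
    raw_scale = isTRUE(raw_scale),
    seed = as.integer(seed)
  )
  class(spec) <- "synthetic_spec"
  validate_synthetic_spec(spec)
  spec
}

validate_synthetic_spec <- function(spec) {
  with(spec, {
    if (n_genes < 1L) stop("invalid spec: n_genes must be >= 1")
    if (n_informative < 0L || n_informative > n_genes) {
      stop("invalid spec: n_informative must be in [0, n_genes]")
    }
    if (length(n_samples_per_class) != 2L || any(n_samples_per_class < 1L)) {
      stop("invalid spec: n_samples_per_class must be two positive counts")
    }
    if (effect_size < 0) stop("invalid spec: effect_size must be >= 0")
    if (noise_sd <= 0) stop("invalid spec: noise_sd must be > 0")
    if (frac_missing < 0 || frac_missing > 0.5) {
      stop("invalid spec: frac_missing must be in [0, 0.5]")
    }
    if (n_replicate_ids < 0L) stop("invalid spec: n_replicate_ids must be >= 0")
    if (n_flat_genes < 0L || n_flat_genes + n_informative > n_genes) {
      stop("invalid spec: n_flat_genes + n_informative must be <= n_genes")
    }
  })
  invisible(spec)
}

#' Generate a labelled synthetic expression dataset
#'
#' Draws a two-class genes x samples matrix. Each gene g has a baseline
#' log2 mean mu_g ~ Normal(6, 1); informative genes additionally receive a
#' class-dependent shift of magnitude `effect_size * noise_sd`, with the
#' sign alternating across informative genes so that no single global mean
#' filter can recover them. Within-class noise is Normal(0, noise_sd). If
#' `raw_scale`, the log2 values are exponentiated to positive right-skewed
#' intensities. Contamination (replicated ids, missing cells, flat genes)
#' is then injected as requested by the spec.
#'
#' @param spec A [synthetic_spec()].
#' @return An object of class `labeled_dataset`: list with `matrix`
#'   (an [expr_matrix()]), `truth_informative` (character gene ids), and
#'   `spec`.
#' @examples
#' ds <- generate_dataset(synthetic_spec(n_genes = 100, n_informative = 5,
#'                                       n_samples_per_class = c(10, 10),
#'                                       frac_missing = 0, n_replicate_ids = 0,
#'                                       n_flat_genes = 0, seed = 1))
#' dim(ds$matrix)
#' ds$truth_informative
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  validate_synthetic_spec(spec)
  n_pos <- spec$n_samples_per_class[1]
  n_neg <- spec$n_samples_per_class[2]
  n_samples <- n_pos + n_neg
  labels <- factor(c(rep("tumor", n_pos), rep("normal", n_neg)),
                   levels = c("normal", "tumor"))
  gene_ids <- sprintf("G%05d", seq_len(spec$n_genes))
  sample_ids <- sprintf("S%03d", seq_len(n_samples))

  ds <- with_seed(spec$seed, {
    mu <- stats::rnorm(spec$n_genes, mean = 6, sd = 1)
    informative <- sort(sample.int(spec$n_genes, spec$n_informative))
    # alternate shift direction across informative genes
    sign_g <- rep_len(c(1, -1), spec$n_informative)
    vals <- matrix(stats::rnorm(spec$n_genes * n_samples, sd = spec$noise_sd),
                   spec$n_genes, n_samples) + mu
    if (spec$n_informative > 0 && spec$effect_size > 0) {
      half_shift <- spec$effect_size * spec$noise_sd / 2
      class_dir <- ifelse(labels == "tumor", 1, -1)
      vals[informative, ] <- vals[informative, , drop = FALSE] +
        outer(sign_g * half_shift, class_dir)
    }
    if (spec$raw_scale) vals <- 2^vals
    list(vals = vals, informative = informative)
  })

  dataset <- structure(
    list(
      matrix = expr_matrix(ds$vals, gene_ids, sample_ids, labels),
      truth_informative = gene_ids[ds$informative],
      spec = spec
    ),
    class = "labeled_dataset"
  )
  if (spec$n_replicate_ids > 0 || spec$n_flat_genes > 0 ||
      spec$frac_missing > 0) {
    dataset <- inject_contamination(dataset, spec)
  }
  dataset
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("labeled_dataset with", length(x$truth_informative),
      "planted informative genes\n")
  print(x$matrix)
  invisible(x)
}

#' Inject contamination into a clean synthetic dataset
#'
#' Adds, in this order: near-constant ("flat") rows by overwriting
#' non-informative genes, one extra noisy copy of each of
#' `n_replicate_ids` randomly chosen non-informative non-flat gene ids,
#' and missing cells completely at random at rate `frac_missing`. The
#' planted informative gene set is never touched, so ground truth is
#' preserved.
#'
#' @param dataset A `labeled_dataset` generated without contamination.
#' @param spec The [synthetic_spec()] describing the contamination; defaults
#'   to the spec stored in `dataset`.
#' @return The contaminated `labeled_dataset`.
#' @export
inject_contamination <- function(dataset, spec = dataset$spec) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  validate_synthetic_spec(spec)
  m <- dataset$matrix
  vals <- m$values
  gene_ids <- m$gene_ids
  n_samples <- ncol(vals)
  truth <- dataset$truth_informative

  res <- with_seed(spec$seed + 90017L, {
    free <- which(!(gene_ids %in% truth))
    flat_idx <- integer(0)
    if (spec$n_flat_genes > 0) {
      if (length(free) < spec$n_flat_genes) {
        stop("not enough non-informative genes to plant flat rows")
      }
      flat_idx <- sort(sample(free, spec$n_flat_genes))
      level <- stats::rnorm(spec$n_flat_genes, 6, 1)
      flat_rows <- matrix(stats::rnorm(spec$n_flat_genes * n_samples,
                                       sd = 1e-5),
                          spec$n_flat_genes, n_samples) + level
      if (spec$raw_scale) flat_rows <- 2^flat_rows
      vals[flat_idx, ] <- flat_rows
    }
    dup_rows <- NULL
    dup_ids <- character(0)
    if (spec$n_replicate_ids > 0) {
      candidates <- setdiff(free, flat_idx)
      if (length(candidates) < spec$n_replicate_ids) {
        stop("not enough genes available to replicate")
      }
      rep_idx <- sort(sample(candidates, spec$n_replicate_ids))
      dup_ids <- gene_ids[rep_idx]
      jitter <- matrix(stats::rnorm(spec$n_replicate_ids * n_samples,
                                    sd = 0.05),
                       spec$n_replicate_ids, n_samples)
      dup_rows <- if (spec$raw_scale) {
        vals[rep_idx, , drop = FALSE] * 2^jitter
      } else {
        vals[rep_idx, , drop = FALSE] + jitter
      }
    }
    if (!is.null(dup_rows)) {
      vals <- rbind(vals, dup_rows)
      gene_ids <- c(gene_ids, dup_ids)
    }
    if (spec$frac_missing > 0) {
      miss <- matrix(stats::runif(length(vals)) < spec$frac_missing,
                     nrow(vals), ncol(vals))
      if (any(rowSums(!miss) == 0) || any(colSums(!miss) == 0)) {
        stop("frac_missing would erase an entire gene row or sample column")
      }
      vals[miss] <- NA_real_
    }
    list(vals = vals, gene_ids = gene_ids)
  })

  dataset$matrix <- expr_matrix(res$vals, res$gene_ids, m$sample_ids, m$labels)
  dataset
}

#' Write the planted informative gene ids, one per line
#'
#' @param dataset A `labeled_dataset`.
#' @param path Output file path.
#' @export
write_truth <- function(dataset, path) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  atomic_write(path, function(tmp) {
    writeLines(dataset$truth_informative, tmp)
  })
}
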