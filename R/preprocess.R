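#' Configuration for the preprocessing cascade
#'
#' The cascade applies, in `step_order`, any of: `log` (log transform with
#' pseudocount), `collapse` (average rows sharing a gene id), `impute`
#' (per-gene mean imputation of missing cells), `flat_filter` (drop genes
#' whose dispersion is below a threshold), and `standardize` (per-gene
#' centring and scaling to unit population SD). The default order runs the
#' flat filter before standardization so zero-variance rows never reach the
#' divide.
#'
#' @param do_log,collapse_replicates,impute,standardize,flat_filter Logical
#'   switches for the individual steps.
#' @param log_base Logarithm base, > 1. Default 2 (microarray convention).
#' @param log_shift Nonnegative pseudocount added before the log.
#' @param flat_metric Dispersion metric for the flat filter: `"variance"`
#'   or `"range"` (max - min).
#' @param flat_threshold Genes with dispersion strictly below this are
#'   dropped. Default 1e-6, which removes numerically constant rows on the
#'   log scale without touching signal.
#' @param step_order Character vector ordering the enabled steps; must be a
#'   permutation of the enabled step names.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(do_log = TRUE,
                              log_base = 2,
                              log_shift = 1,
                              collapse_replicates = TRUE,
                              impute = TRUE,
                              standardize = TRUE,
                              flat_filter = TRUE,
                              flat_metric = c("variance", "range"),
                              flat_threshold = 1e-6,
                              step_order = NULL) {
  flat_metric <- match.arg(flat_metric)
  enabled <- c(log = do_log, collapse = collapse_replicates, impute = impute,
               flat_filter = flat_filter, standardize = standardize)
  default_order <- c("log", "collapse", "impute", "flat_filter", "standardize")
  if (is.null(step_order)) {
    step_order <- default_order[enabled[default_order]]
  } else {
    step_order <- as.character(step_order)
    if (!setequal(step_order, names(enabled)[enabled]) ||
        anyDuplicated(step_order)) {
      stop("step_order must be a permutation of the enabled steps: ",
           paste(names(enabled)[enabled], collapse = ", "))
    }
  }
  if (log_base <= 1) stop("log_base must be > 1")
  if (log_shift < 0) stop("log_shift must be >= 0")
  if (flat_threshold < 0) stop("flat_threshold must be >= 0")
  structure(
    list(do_log = do_log, log_base = log_base, log_shift = log_shift,
         collapse_replicates = collapse_replicates, impute = impute,
         standardize = standardize, flat_filter = flat_filter,
         flat_metric = flat_metric, flat_threshold = flat_threshold,
         step_order = step_order),
    class = "preprocess_config"
  )
}

#' Log-transform an expression matrix
#'
#' Replaces every non-missing value v by log_base(v + shift), leaving
#' missing cells untouched. Gene-expression intensities are right-skewed;
#' the log makes them approximately symmetric so downstream parametric
#' statistics behave.
#'
#' @param m An [expr_matrix()].
#' @param base Logarithm base (> 1).
#' @param shift Nonnegative pseudocount; every value + shift must be > 0.
#' @return The transformed `expr_matrix`.
#' @export
log_transform <- function(m, base = 2, shift = 1) {
  stopifnot(inherits(m, "expr_matrix"))
  bad <- which(!is.na(m$values) & m$values + shift <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "log_transform: value %g + shift %g <= 0 at gene '%s', sample '%s'",
      m$values[bad[1, 1], bad[1, 2]], shift,
      m$gene_ids[bad[1, 1]], m$sample_ids[bad[1, 2]]))
  }
  m$values <- log(m$values + shift, base = base)
  m
}

#' Collapse replicated gene ids by averaging
#'
#' Rows sharing a gene id are replaced by a single row holding their
#' element-wise mean over non-missing entries; a cell stays missing only if
#' it is missing in every replicate. First-occurrence order is preserved
#' and unique ids pass through unchanged.
#'
#' @param m An [expr_matrix()].
#' @return An `expr_matrix` with unique gene ids.
#' @export
collapse_replicates <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (!anyDuplicated(m$gene_ids)) return(m)
  first <- !duplicated(m$gene_ids)
  keep_ids <- m$gene_ids[first]
  grp <- match(m$gene_ids, keep_ids)
  sums <- rowsum(ifelse(is.na(m$values), 0, m$values), grp)
  counts <- rowsum((!is.na(m$values)) * 1, grp)
  vals <- sums / counts           # 0/0 -> NaN where all replicates missing
  vals[counts == 0] <- NA_real_
  expr_matrix(vals, keep_ids, m$sample_ids, m$labels)
}

#' Impute missing cells with the gene's mean
#'
#' Each missing cell is replaced by the mean of its gene's non-missing
#' values; afterwards the matrix has no missing cells. Errors if any gene
#' row is entirely missing.
#'
#' @param m An [expr_matrix()].
#' @return The imputed `expr_matrix`.
#' @export
impute_missing <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  na <- is.na(m$values)
  if (!any(na)) return(m)
  n_obs <- rowSums(!na)
  if (any(n_obs == 0)) {
    stop("impute_missing: gene '", m$gene_ids[which(n_obs == 0)[1]],
         "' has no observed values")
  }
  means <- rowSums(m$values, na.rm = TRUE) / n_obs
  idx <- which(na, arr.ind = TRUE)
  m$values[na] <- means[idx[, 1]]
  m
}

#' Standardize each gene to mean 0 and unit SD
#'
#' Subtracts the per-gene mean and divides by the per-gene population SD
#' (divisor n, not n - 1), so every row ends exactly at mean 0 / SD 1.
#' Requires a complete matrix; zero-SD rows are an error, with the advice
#' to run the flat-pattern filter first.
#'
#' @param m An [expr_matrix()] without missing values.
#' @return The standardized `expr_matrix`.
#' @export
standardize <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (anyNA(m$values)) {
    stop("standardize: matrix has missing values; impute first")
  }
  n <- ncol(m$values)
  mu <- rowMeans(m$values)
  centred <- m$values - mu
  sd_pop <- sqrt(rowSums(centred^2) / n)
  if (any(sd_pop == 0)) {
    stop("standardize: gene '", m$gene_ids[which(sd_pop == 0)[1]],
         "' has zero SD; run flat_pattern_filter first")
  }
  m$values <- centred / sd_pop
  m
}

#' Remove genes with near-flat expression patterns
#'
#' Drops every gene whose dispersion — row variance or max-min range —
#' is strictly below `threshold`. Such genes carry no class information
#' and only inflate the search space.
#'
#' @param m An [expr_matrix()] without missing values.
#' @param metric `"variance"` or `"range"`.
#' @param threshold Nonnegative cutoff; genes with dispersion < threshold
#'   are removed.
#' @return The filtered `expr_matrix`, with the removed gene ids in
#'   attribute `"removed_genes"`.
#' @export
flat_pattern_filter <- function(m, metric = c("variance", "range"),
                                threshold = 1e-6) {
  stopifnot(inherits(m, "expr_matrix"))
  metric <- match.arg(metric)
  if (anyNA(m$values)) {
    stop("flat_pattern_filter: matrix has missing values; impute first")
  }
  disp <- switch(metric,
    variance = {
      mu <- rowMeans(m$values)
      rowSums((m$values - mu)^2) / ncol(m$values)
    },
    range = apply(m$values, 1, function(r) max(r) - min(r))
  )
  drop <- disp < threshold
  if (all(drop)) stop("flat_pattern_filter: all genes would be removed")
  removed <- m$gene_ids[drop]
  out <- subset_expr(m, genes = !drop)
  attr(out, "removed_genes") <- removed
  out
}

#' Run the full preprocessing cascade
#'
#' Applies the enabled steps in `cfg$step_order` (default: log, collapse
#' replicates, impute, flat filter, standardize) and records a provenance
#' entry (genes in/out) per step.
#'
#' @param m An [expr_matrix()].
#' @param cfg A [preprocess_config()].
#' @return The preprocessed `expr_matrix`; attribute `"provenance"` holds a
#'   data frame with one row per executed step (`step`, `genes_in`,
#'   `genes_out`, `genes_removed`), exportable as JSON via
#'   [write_provenance()].
#' @examples
#' ds <- generate_dataset(synthetic_spec(n_genes = 50, n_informative = 5,
#'                                       n_samples_per_class = c(8, 8),
#'                                       n_flat_genes = 2, seed = 3))
#' pp <- run_preprocess(ds$matrix, preprocess_config())
#' attr(pp, "provenance")
#' @export
run_preprocess <- function(m, cfg = preprocess_config()) {
  stopifnot(inherits(m, "expr_matrix"), inherits(cfg, "preprocess_config"))
  prov <- data.frame(step = character(0), genes_in = integer(0),
                     genes_out = integer(0), genes_removed = integer(0))
  for (step in cfg$step_order) {
    n_in <- nrow(m$values)
    m <- switch(step,
      log = log_transform(m, cfg$log_base, cfg$log_shift),
      collapse = collapse_replicates(m),
      impute = impute_missing(m),
      flat_filter = flat_pattern_filter(m, cfg$flat_metric,
                                        cfg$flat_threshold),
      standardize = standardize(m),
      stop("unknown preprocessing step: ", step)
    )
    n_out <- nrow(m$values)
    prov <- rbind(prov, data.frame(step = step, genes_in = n_in,
                                   genes_out = n_out,
                                   genes_removed = n_in - n_out))
  }
  attr(m, "provenance") <- prov
  m
}

#' Export a preprocessing provenance record as JSON
#'
#' @param m The output of [run_preprocess()].
#' @param path Output file path.
#' @export
write_provenance <- function(m, path) {
  prov <- attr(m, "provenance")
  if (is.null(prov)) stop("no provenance attribute on this matrix")
  atomic_write(path, function(tmp) {
    jsonlite::write_json(prov, tmp, dataframe = "rows", pretty = TRUE)
  })
}
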