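# Shared fixture builders: everything is generated in code at test time.

# A tiny hand-built matrix with known values.
tiny_matrix <- function(values = matrix(c(1, 2, 3,
                                          4, 5, 6), 2, 3, byrow = TRUE),
                        gene_ids = c("gA", "gB"),
                        labels = c("normal", "tumor", "tumor")) {
  expr_matrix(values, gene_ids,
              sample_ids = paste0("s", seq_len(ncol(values))), labels)
}

# A clean (contamination-free) synthetic dataset on the log scale.
clean_dataset <- function(n_genes = 50, n_informative = 5,
                          n_per_class = c(15, 15), effect = 3, seed = 1) {
  generate_dataset(synthetic_spec(
    n_genes = n_genes, n_informative = n_informative,
    n_samples_per_class = n_per_class, effect_size = effect,
    frac_missing = 0, n_replicate_ids = 0, n_flat_genes = 0,
    raw_scale = FALSE, seed = seed))
}

# Linearly separable 2-D two-class point cloud.
separable_2d <- function(n = 100, seed = 3) {
  set.seed(seed)
  half <- n / 2
  x <- rbind(cbind(rnorm(half, -2, 0.5), rnorm(half, -2, 0.5)),
             cbind(rnorm(half, 2, 0.5), rnorm(half, 2, 0.5)))
  list(x = x, y = rep(1:2, each = half))
}

# Mean per-sample loss of a network on a batch; used by the
# finite-difference gradient oracle.
batch_loss <- function(params, x, y, loss) {
  P <- dnn_forward(params, x)$a[[length(params$W) + 1L]]
  n <- nrow(P)
  if (loss == "nll") {
    mean(-log(pmax(P[cbind(seq_len(n), y)], 1e-12)))
  } else {
    Tm <- matrix(0, n, ncol(P))
    Tm[cbind(seq_len(n), y)] <- 1
    mean(rowSums((Tm - P)^2) / 2)
  }
}

# Central-difference gradients with respect to every weight and bias.
numeric_gradients <- function(params, x, y, loss, h = 1e-5) {
  num <- params
  for (part in c("W", "b")) {
    for (l in seq_along(params[[part]])) {
      tensor <- params[[part]][[l]]
      g <- tensor
      for (i in seq_along(tensor)) {
        up <- params; up[[part]][[l]][i] <- tensor[i] + h
        dn <- params; dn[[part]][[l]][i] <- tensor[i] - h
        g[i] <- (batch_loss(up, x, y, loss) -
                   batch_loss(dn, x, y, loss)) / (2 * h)
      }
      num[[part]][[l]] <- g
    }
  }
  num
}

max_grad_discrepancy <- function(ana, num) {
  worst <- 0
  for (part in c("W", "b")) {
    for (l in seq_along(ana[[part]])) {
      a <- as.numeric(ana[[part]][[l]])
      n <- as.numeric(num[[part]][[l]])
      worst <- max(worst, abs(a - n) / pmax(1, abs(a), abs(n)))
    }
  }
  worst
}
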