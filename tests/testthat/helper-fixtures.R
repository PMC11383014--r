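# Small fixtures built in code, shared across test files.

# A tiny annotated quantification matrix with a few missing cells.
tiny_qm <- function(n = 6, m = 4, missing = 3, seed = 1, cohort = "cohortA") {
  set.seed(seed)
  v <- matrix(rnorm(n * m), n, m,
              dimnames = list(sprintf("P%02d", seq_len(n)),
                              sprintf("s%02d", seq_len(m))))
  if (missing > 0) v[sample(length(v), missing)] <- NA
  quant_matrix(v, cohort = cohort)
}

# A moderate i.i.d. standard-normal matrix with no missing values, for
# partition-distribution checks.
normal_qm <- function(n = 300, m = 100, seed = 5) {
  set.seed(seed)
  quant_matrix(matrix(rnorm(n * m), n, m,
                      dimnames = list(sprintf("P%04d", seq_len(n)),
                                      sprintf("s%03d", seq_len(m)))),
               cohort = "sim")
}

# Rank-1 noiseless matrix: exactly representable by a small factor model.
rank1_qm <- function(n = 30, m = 20, seed = 3) {
  set.seed(seed)
  u <- rnorm(n)
  v <- rnorm(m)
  quant_matrix(outer(u, v) |>
                 `dimnames<-`(list(sprintf("P%02d", seq_len(n)),
                                   sprintf("s%02d", seq_len(m)))),
               cohort = "toy")
}

# Hand-built single-linear-layer model (no hidden layers): prediction is
# dot(concat(W_i, H_j), w) + b.
linear_model <- function(W, H, w, b) {
  structure(list(W = W, H = H,
                 layers = list(list(W = matrix(w, ncol = 1L), b = b)),
                 config = model_config(n_protein_factors = ncol(W),
                                       n_sample_factors = nrow(H),
                                       n_hidden_layers = 1,
                                       n_nodes_per_layer = 1)),
            class = "factor_model")
}

# Independent step-up BH oracle.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Independent rank-then-Pearson Spearman oracle (mid-ranks for ties).
spearman_oracle <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  cor(rank(x[ok]), rank(y[ok]))
}

# Expected MNAR test share for an i.i.d. Normal(mu, sd) matrix under the
# partition defaults: P(X < T) * bernoulli_p with X - T Normal.
closed_form_test_fraction <- function(values, params = partition_params()) {
  x <- as.vector(values[!is.na(values)])
  q <- quantile(x, params$center_quantile)
  s <- sd(x)
  p_below <- pnorm(0, mean = mean(x) - q,
                   sd = sqrt(s^2 + (params$sd_multiplier * s)^2))
  unname(p_below * params$bernoulli_p)
}
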