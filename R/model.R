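#' Model hyperparameters and training settings
#'
#' @param n_protein_factors Number of protein embedding dimensions `p`
#'   (default 128).
#' @param n_sample_factors Number of sample embedding dimensions `s`
#'   (default 128).
#' @param n_hidden_layers Hidden layers in the perceptron (default 2).
#' @param n_nodes_per_layer Nodes per hidden layer (default 1024).
#' @param leaky_slope Negative slope of the leaky-ReLU activations
#'   (default 0.1).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param batch_size Training batch size (default 128).
#' @param tolerance Relative-improvement tolerance of stopping criterion 1
#'   (default 0.001).
#' @param patience Successive qualifying epochs before criterion 1 fires
#'   (default 10).
#' @param wilcoxon_alpha One-sided rank-sum significance level of stopping
#'   criterion 2 (default 0.05).
#' @param max_epochs Hard cap on training epochs (default 500); the two
#'   stopping criteria normally fire first.
#' @param seed RNG seed for initialization and batch sampling.
#' @return A `model_config` list.
#' @export
model_config <- function(n_protein_factors = 128, n_sample_factors = 128,
                         n_hidden_layers = 2, n_nodes_per_layer = 1024,
                         leaky_slope = 0.1, learning_rate = 0.001,
                         batch_size = 128, tolerance = 0.001, patience = 10,
                         wilcoxon_alpha = 0.05, max_epochs = 500,
                         seed = NULL) {
  stopifnot(n_protein_factors >= 1, n_sample_factors >= 1,
            n_hidden_layers >= 1, n_nodes_per_layer >= 1,
            leaky_slope >= 0, leaky_slope < 1,
            learning_rate > 0, batch_size >= 1, tolerance > 0,
            patience >= 1, wilcoxon_alpha > 0, max_epochs >= 1)
  structure(list(n_protein_factors = as.integer(n_protein_factors),
                 n_sample_factors = as.integer(n_sample_factors),
                 n_hidden_layers = as.integer(n_hidden_layers),
                 n_nodes_per_layer = as.integer(n_nodes_per_layer),
                 leaky_slope = leaky_slope, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), tolerance = tolerance,
                 patience = as.integer(patience),
                 wilcoxon_alpha = wilcoxon_alpha,
                 max_epochs = as.integer(max_epochs), seed = seed),
            class = "model_config")
}

#' Initialize a factor model
#'
#' Protein factors `W` (proteins x p) and sample factors `H` (s x samples)
#' are drawn i.i.d. Normal with variance 1/n_factors; perceptron weights use
#' uniform fan-in scaling, biases start at zero. Deterministic given the
#' config seed.
#'
#' @param config A [model_config()].
#' @param n_proteins,n_samples Matrix dimensions the model will complete.
#' @return A `factor_model` list with elements `W`, `H`, `layers` (hidden
#'   plus linear output layer, each a list with `W` and `b`) and `config`.
#' @export
init_model <- function(config, n_proteins, n_samples) {
  stopifnot(n_proteins >= 1, n_samples >= 1)
  p <- config$n_protein_factors
  s <- config$n_sample_factors
  widths <- c(p + s, rep(config$n_nodes_per_layer, config$n_hidden_layers), 1L)
  with_seed(config$seed, {
    W <- matrix(stats::rnorm(n_proteins * p, sd = 1 / sqrt(p)), n_proteins, p)
    H <- matrix(stats::rnorm(s * n_samples, sd = 1 / sqrt(s)), s, n_samples)
    layers <- lapply(seq_len(length(widths) - 1L), function(k) {
      fan_in <- widths[k]
      lim <- 1 / sqrt(fan_in)
      list(W = matrix(stats::runif(fan_in * widths[k + 1L], -lim, lim),
                      fan_in, widths[k + 1L]),
           b = numeric(widths[k + 1L]))
    })
    structure(list(W = W, H = H, layers = layers, config = config),
              class = "factor_model")
  })
}

#' @export
print.factor_model <- function(x, ...) {
  n_par <- length(x$W) + length(x$H) +
    sum(vapply(x$layers, function(l) length(l$W) + length(l$b), 0))
  cat(sprintf("factor_model: %d proteins x %d samples, p=%d, s=%d, %d hidden layer(s), %d parameters\n",
              nrow(x$W), ncol(x$H), ncol(x$W), nrow(x$H),
              length(x$layers) - 1L, n_par))
  invisible(x)
}

leaky_relu <- function(z, slope) ifelse(z > 0, z, slope * z)

# Forward pass for entry index vectors i, j. Returns predictions, and when
# keep = TRUE also the pre-/post-activation caches needed for backprop.
mlp_forward <- function(model, i, j, keep = FALSE) {
  slope <- model$config$leaky_slope
  A <- cbind(model$W[i, , drop = FALSE],
             t(model$H[, j, drop = FALSE]))
  L <- length(model$layers)
  As <- if (keep) vector("list", L) else NULL
  Zs <- if (keep) vector("list", L - 1L) else NULL
  for (k in seq_len(L - 1L)) {
    if (keep) As[[k]] <- A
    Z <- sweep(A %*% model$layers[[k]]$W, 2L, model$layers[[k]]$b, "+")
    if (keep) Zs[[k]] <- Z
    A <- leaky_relu(Z, slope)
  }
  if (keep) As[[L]] <- A
  out <- drop(A %*% model$layers[[L]]$W) + model$layers[[L]]$b
  if (keep) list(pred = out, As = As, Zs = Zs) else out
}

#' Predict a single entry
#'
#' Concatenates protein factor row `i` and sample factor column `j` and runs
#' them through the perceptron.
#'
#' @param model A [init_model()] / trained `factor_model`.
#' @param i Protein (row) index.
#' @param j Sample (column) index.
#' @return The predicted log-intensity.
#' @export
predict_entry <- function(model, i, j) {
  if (i < 1 || i > nrow(model$W)) abort("protein index %d out of range", i)
  if (j < 1 || j > ncol(model$H)) abort("sample index %d out of range", j)
  unname(mlp_forward(model, i, j))
}

#' Predict entries at arbitrary (protein, sample) index pairs
#'
#' @param model A `factor_model`.
#' @param i,j Equal-length index vectors.
#' @param chunk Entries evaluated per forward pass (memory control).
#' @return Numeric vector of predictions.
#' @export
predict_entries <- function(model, i, j, chunk = 200000L) {
  stopifnot(length(i) == length(j))
  out <- numeric(length(i))
  for (start in seq(1L, length(i), by = chunk)) {
    sel <- start:min(start + chunk - 1L, length(i))
    out[sel] <- mlp_forward(model, i[sel], j[sel])
  }
  out
}

#' Predict the full protein-by-sample matrix
#'
#' @param model A `factor_model`.
#' @return A numeric matrix of shape proteins x samples.
#' @export
predict_matrix <- function(model) {
  n <- nrow(model$W)
  m <- ncol(model$H)
  i <- rep(seq_len(n), times = m)
  j <- rep(seq_len(m), each = n)
  matrix(predict_entries(model, i, j), n, m)
}

# ---- Adam optimizer over the nested parameter list -------------------------

model_params <- function(model) {
  c(list(W = model$W, H = model$H),
    unlist(lapply(seq_along(model$layers), function(k) {
      stats::setNames(model$layers[[k]], paste0(c("W", "b"), k))
    }), recursive = FALSE))
}

set_model_params <- function(model, params) {
  model$W <- params$W
  model$H <- params$H
  for (k in seq_along(model$layers)) {
    model$layers[[k]]$W <- params[[paste0("W", k)]]
    model$layers[[k]]$b <- params[[paste0("b", k)]]
  }
  model
}

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

# Gradient of batch MSE w.r.t. every parameter. i, j, y are the batch entry
# indices and target values.
mlp_gradients <- function(model, i, j, y) {
  fw <- mlp_forward(model, i, j, keep = TRUE)
  B <- length(y)
  L <- length(model$layers)
  slope <- model$config$leaky_slope
  resid <- fw$pred - y
  loss <- mean(resid^2)
  grads <- vector("list", 2L * L + 2L)
  names(grads) <- c("W", "H", unlist(lapply(seq_len(L), function(k)
    paste0(c("W", "b"), k))))
  dout <- matrix(2 * resid / B, ncol = 1L)
  grads[[paste0("W", L)]] <- crossprod(fw$As[[L]], dout)
  grads[[paste0("b", L)]] <- sum(dout)
  dA <- dout %*% t(model$layers[[L]]$W)
  for (k in rev(seq_len(L - 1L))) {
    dZ <- dA * ifelse(fw$Zs[[k]] > 0, 1, slope)
    grads[[paste0("W", k)]] <- crossprod(fw$As[[k]], dZ)
    grads[[paste0("b", k)]] <- colSums(dZ)
    dA <- dZ %*% t(model$layers[[k]]$W)
  }
  p <- ncol(model$W)
  gW <- matrix(0, nrow(model$W), p)
  rs <- rowsum(dA[, seq_len(p), drop = FALSE], group = i)
  gW[as.integer(rownames(rs)), ] <- rs
  grads$W <- gW
  s <- nrow(model$H)
  gH <- matrix(0, s, ncol(model$H))
  rs <- rowsum(dA[, p + seq_len(s), drop = FALSE], group = j)
  gH[, as.integer(rownames(rs))] <- t(rs)
  grads$H <- gH
  list(grads = grads, loss = loss)
}

#' Epoch-level convergence check on the validation loss history
#'
#' Two stopping criteria, evaluated after each epoch on the validation MSE:
#' \describe{
#'   \item{tolerance}{The ratio (best loss so far minus current loss) over
#'     the best loss is computed; if it stays below `tolerance` for
#'     `patience` successive epochs, training stops. The difference is
#'     signed, so a worsening epoch also qualifies.}
#'   \item{wilcoxon}{Once at least 15 epochs are available, a one-sided
#'     Wilcoxon rank-sum test compares the five most recent validation MSEs
#'     against the five MSEs from epochs n-14 to n-10; a p-value below
#'     `wilcoxon_alpha` for the alternative "the older window is smaller"
#'     indicates the validation error has started to rise, and training
#'     stops.}
#' }
#'
#' @param val_history Numeric vector of per-epoch validation MSEs.
#' @param config A [model_config()] supplying `tolerance`, `patience` and
#'   `wilcoxon_alpha`.
#' @return A list with `stop` (logical), `reason` (`"tolerance"`,
#'   `"wilcoxon"` or `NA`), and `p_value` (rank-sum p, `NA` when not
#'   evaluated).
#' @export
check_convergence <- function(val_history, config = model_config()) {
  n <- length(val_history)
  if (n == 0L) abort("empty validation history")
  qualifies <- function(k) {
    best <- min(val_history[seq_len(k - 1L)])
    if (best <= 0) return(val_history[k] >= best)
    (best - val_history[k]) / best < config$tolerance
  }
  run <- 0L
  for (k in seq(2L, length.out = max(0L, n - 1L))) {
    run <- if (qualifies(k)) run + 1L else 0L
  }
  if (run >= config$patience) {
    return(list(stop = TRUE, reason = "tolerance", p_value = NA_real_))
  }
  if (n >= 15L) {
    w1 <- val_history[(n - 4L):n]
    w2 <- val_history[(n - 14L):(n - 10L)]
    p <- suppressWarnings(
      stats::wilcox.test(w2, w1, alternative = "less")$p.value)
    if (is.finite(p) && p < config$wilcoxon_alpha) {
      return(list(stop = TRUE, reason = "wilcoxon", p_value = p))
    }
    return(list(stop = FALSE, reason = NA_character_, p_value = p))
  }
  list(stop = FALSE, reason = NA_character_, p_value = NA_real_)
}

#' Train a factor model on the training partition
#'
#' Runs mini-batch gradient descent with the Adam optimizer on the batch
#' MSE, updating protein factors, sample factors and perceptron weights
#' jointly. Batches come from the biased low-intensity sampler (see
#' [biased_batches()]); one epoch comprises enough batches to cover the
#' training set in expectation. After each epoch the full validation MSE is
#' recorded and [check_convergence()] is consulted. The parameters from the
#' epoch with the lowest validation MSE are returned.
#'
#' @param model A freshly initialized `factor_model` (or `NULL` to
#'   initialize from `config`).
#' @param qm The [quant_matrix()] being completed.
#' @param masks `partition_masks` with non-empty train and validation masks.
#' @param config A [model_config()].
#' @param params [partition_params()] for the biased sampler's threshold
#'   distribution.
#' @param biased Use the biased low-intensity batch sampler (default);
#'   `FALSE` samples training entries uniformly.
#' @return A list with `model` (best-validation-epoch parameters) and `log`
#'   (a `training_log`: per-epoch `train_mse`, `val_mse`, `stop_reason`,
#'   `epochs_run`, `best_epoch`).
#' @export
train_model <- function(model = NULL, qm, masks, config = model_config(),
                        params = partition_params(), biased = TRUE) {
  if (is.null(model)) {
    model <- init_model(config, nrow(qm$values), ncol(qm$values))
  }
  config <- model$config
  train_idx <- which(masks$train)
  val_idx <- which(masks$val)
  if (length(train_idx) == 0L) abort("training mask is empty")
  if (length(val_idx) == 0L) abort("validation mask is empty")
  nr <- nrow(qm$values)
  vi <- ((val_idx - 1L) %% nr) + 1L
  vj <- ((val_idx - 1L) %/% nr) + 1L
  val_y <- qm$values[val_idx]
  dist <- threshold_distribution(qm$values, params)
  vals <- qm$values[train_idx]
  n_batches <- ceiling(length(train_idx) / config$batch_size)
  pars <- model_params(model)
  state <- adam_init(pars)
  train_mse <- numeric(0)
  val_mse <- numeric(0)
  best <- Inf
  best_pars <- pars
  best_epoch <- 0L
  stop_reason <- "max_epochs"
  with_seed(config$seed, {
    draw <- batch_index_stream(train_idx, vals, dist, biased)
    for (epoch in seq_len(config$max_epochs)) {
      losses <- numeric(n_batches)
      for (b in seq_len(n_batches)) {
        lin <- draw(config$batch_size)
        bi <- ((lin - 1L) %% nr) + 1L
        bj <- ((lin - 1L) %/% nr) + 1L
        model <- set_model_params(model, pars)
        g <- mlp_gradients(model, bi, bj, qm$values[lin])
        if (!is.finite(g$loss)) {
          abort("non-finite training loss at epoch %d, batch %d", epoch, b)
        }
        losses[b] <- g$loss
        upd <- adam_step(pars, g$grads, state, config$learning_rate)
        pars <- upd$params
        state <- upd$state
      }
      model <- set_model_params(model, pars)
      v_pred <- predict_entries(model, vi, vj)
      v_mse <- mean((v_pred - val_y)^2)
      if (!is.finite(v_mse)) abort("non-finite validation loss at epoch %d", epoch)
      train_mse <- c(train_mse, mean(losses))
      val_mse <- c(val_mse, v_mse)
      if (v_mse < best) {
        best <- v_mse
        best_pars <- pars
        best_epoch <- epoch
      }
      conv <- check_convergence(val_mse, config)
      if (conv$stop) {
        stop_reason <- conv$reason
        break
      }
    }
  })
  model <- set_model_params(model, best_pars)
  log <- structure(list(train_mse = train_mse, val_mse = val_mse,
                        stop_reason = stop_reason,
                        epochs_run = length(val_mse),
                        best_epoch = best_epoch),
                   class = "training_log")
  list(model = model, log = log)
}

#' @export
print.training_log <- function(x, ...) {
  cat(sprintf("training_log: %d epochs, stop=%s, best epoch %d (val MSE %.4g)\n",
              x$epochs_run, x$stop_reason, x$best_epoch,
              x$val_mse[x$best_epoch]))
  invisible(x)
}

#' Complete a quantification matrix from a prediction matrix
#'
#' @param qm The observed [quant_matrix()].
#' @param predictions Full prediction matrix of the same shape.
#' @param keep_observed Keep observed entries verbatim (default); `FALSE`
#'   replaces every entry with its prediction (reconstruction mode).
#' @return A complete `quant_matrix` (no missing entries).
#' @export
impute_matrix <- function(qm, predictions, keep_observed = TRUE) {
  if (!all(dim(predictions) == dim(qm$values))) abort("shape mismatch")
  miss <- is.na(qm$values)
  if (any(!is.finite(predictions[miss]))) {
    abort("non-finite prediction at a missing position")
  }
  values <- if (keep_observed) qm$values else predictions
  values[miss] <- predictions[miss]
  dimnames(values) <- dimnames(qm$values)
  quant_matrix(values, cohort = qm$samples$cohort,
               sample_type = qm$samples$sample_type,
               patient_id = qm$samples$patient_id, plex = qm$samples$plex)
}

#' Export learned embeddings as delimited tables
#'
#' Writes `<prefix>_protein_factors.tsv` (protein x factor) and
#' `<prefix>_sample_factors.tsv` (sample x factor) for downstream
#' visualization.
#'
#' @param model A trained `factor_model`.
#' @param qm The [quant_matrix()] the model was fit to (for identifiers).
#' @param prefix Output path prefix.
#' @return The two paths, invisibly.
#' @export
export_embeddings <- function(model, qm, prefix) {
  wp <- paste0(prefix, "_protein_factors.tsv")
  sp <- paste0(prefix, "_sample_factors.tsv")
  W <- data.frame(protein_id = rownames(qm$values), model$W,
                  check.names = FALSE)
  colnames(W)[-1L] <- paste0("factor_", seq_len(ncol(model$W)))
  utils::write.table(W, wp, sep = "\t", quote = FALSE, row.names = FALSE)
  H <- data.frame(sample_id = colnames(qm$values), t(model$H),
                  check.names = FALSE)
  colnames(H)[-1L] <- paste0("factor_", seq_len(nrow(model$H)))
  utils::write.table(H, sp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(wp, sp))
}
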