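#' Hyperparameter search space
#'
#' Defaults are the grid searched when fitting the full-scale model:
#' protein and sample factors in \{64, 128, 256, 512, 1024\}, 1/2/4 hidden
#' layers and 512/1024/2048 nodes per layer, for 5 x 5 x 3 x 3 = 225
#' combinations.
#'
#' @param protein_factors,sample_factors,hidden_layers,nodes_per_layer
#'   Candidate values for each hyperparameter.
#' @return A `hyperparam_grid` list.
#' @export
hyperparam_grid <- function(protein_factors = c(64, 128, 256, 512, 1024),
                            sample_factors = c(64, 128, 256, 512, 1024),
                            hidden_layers = c(1, 2, 4),
                            nodes_per_layer = c(512, 1024, 2048)) {
  stopifnot(length(protein_factors) > 0, length(sample_factors) > 0,
            length(hidden_layers) > 0, length(nodes_per_layer) > 0)
  structure(list(protein_factors = protein_factors,
                 sample_factors = sample_factors,
                 hidden_layers = hidden_layers,
                 nodes_per_layer = nodes_per_layer),
            class = "hyperparam_grid")
}

grid_size <- function(grid) {
  prod(lengths(grid[c("protein_factors", "sample_factors",
                      "hidden_layers", "nodes_per_layer")]))
}

#' Enumerate every configuration in a hyperparameter grid
#'
#' @param grid A [hyperparam_grid()].
#' @param base A [model_config()] supplying the non-searched settings
#'   (learning rate, batch size, stopping parameters, ...).
#' @return A list of [model_config()] objects in deterministic
#'   lexicographic order (protein factors vary fastest).
#' @export
enumerate_grid <- function(grid = hyperparam_grid(), base = model_config()) {
  combos <- expand.grid(protein_factors = grid$protein_factors,
                        sample_factors = grid$sample_factors,
                        hidden_layers = grid$hidden_layers,
                        nodes_per_layer = grid$nodes_per_layer,
                        KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(combos)), function(k) {
    cfg <- base
    cfg$n_protein_factors <- as.integer(combos$protein_factors[k])
    cfg$n_sample_factors <- as.integer(combos$sample_factors[k])
    cfg$n_hidden_layers <- as.integer(combos$hidden_layers[k])
    cfg$n_nodes_per_layer <- as.integer(combos$nodes_per_layer[k])
    cfg
  })
}

#' Sample configurations uniformly without replacement from the grid
#'
#' @param grid A [hyperparam_grid()].
#' @param n Number of configurations to draw.
#' @param seed RNG seed.
#' @param base Base [model_config()] (see [enumerate_grid()]).
#' @return A list of `n` [model_config()] objects.
#' @export
sample_configs <- function(grid = hyperparam_grid(), n = 10, seed = NULL,
                           base = model_config()) {
  total <- grid_size(grid)
  if (n > total) abort("cannot sample %d configs from a grid of %d", n, total)
  all_cfg <- enumerate_grid(grid, base)
  pick <- with_seed(seed, sample.int(total, n))
  all_cfg[pick]
}

#' Fit an ensemble of independently seeded models and average predictions
#'
#' Each member draws its own hyperparameters (unless `configs` is given),
#' derives its own seed (`seed` + member index), carves its own 10% MCAR
#' validation set out of the shared training mask, trains, and predicts the
#' full matrix. The ensemble prediction is the entrywise arithmetic mean of
#' the member predictions.
#'
#' @param qm The [quant_matrix()] to complete.
#' @param masks Shared `partition_masks` (train/test); each member makes
#'   its own validation split.
#' @param n_models Number of ensemble members (default 10).
#' @param seed Base RNG seed.
#' @param grid [hyperparam_grid()] to sample member configurations from.
#' @param base Base [model_config()] for non-searched settings.
#' @param configs Optional explicit list of [model_config()]s (overrides
#'   grid sampling; its length sets the ensemble size).
#' @param val_fraction MCAR validation fraction per member (default 0.10).
#' @param partition [partition_params()] for the biased batch sampler.
#' @param biased Use biased low-intensity batch selection (default `TRUE`).
#' @return An `ensemble_result`: `member_configs`, `member_predictions`,
#'   `member_logs`, `member_val_masks` and `averaged_prediction`.
#' @export
fit_ensemble <- function(qm, masks, n_models = 10, seed = NULL,
                         grid = hyperparam_grid(), base = model_config(),
                         configs = NULL, val_fraction = 0.10,
                         partition = partition_params(), biased = TRUE) {
  if (is.null(configs)) {
    stopifnot(n_models >= 1)
    configs <- sample_configs(grid, n_models, seed = seed, base = base)
  }
  n_models <- length(configs)
  preds <- vector("list", n_models)
  logs <- vector("list", n_models)
  vmasks <- vector("list", n_models)
  models <- vector("list", n_models)
  for (k in seq_len(n_models)) {
    member_seed <- if (is.null(seed)) NULL else as.integer(seed) + k
    cfg <- configs[[k]]
    cfg$seed <- member_seed
    configs[[k]] <- cfg
    m_masks <- mcar_validation_split(masks, val_fraction, seed = member_seed)
    vmasks[[k]] <- m_masks$val
    fit <- tryCatch(
      train_model(NULL, qm, m_masks, config = cfg, params = partition,
                  biased = biased),
      error = function(e) abort("ensemble member %d failed: %s", k,
                                conditionMessage(e)))
    models[[k]] <- fit$model
    logs[[k]] <- fit$log
    preds[[k]] <- predict_matrix(fit$model)
  }
  avg <- Reduce(`+`, preds) / n_models
  dimnames(avg) <- dimnames(qm$values)
  structure(list(member_configs = configs, member_predictions = preds,
                 member_logs = logs, member_val_masks = vmasks,
                 member_models = models, averaged_prediction = avg),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("ensemble_result: %d member model(s), %d x %d predictions\n",
              length(x$member_predictions),
              nrow(x$averaged_prediction), ncol(x$averaged_prediction)))
  invisible(x)
}
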