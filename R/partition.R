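#' Parameters of the MNAR partitioning procedure
#'
#' The partitioner draws, for every present entry, a random threshold from a
#' Normal distribution centered about a low quantile of the observed values,
#' with a standard deviation proportional to the observed standard deviation.
#' Entries falling below their threshold are candidates for the held-out test
#' set and enter a Bernoulli trial; everything else trains. This emulates
#' left-censored (intensity-dependent) missingness.
#'
#' @param center_quantile Quantile of present values at which the threshold
#'   distribution is centered (default 0.25, the 25th percentile).
#' @param sd_multiplier Threshold sd as a multiple of the sd of present
#'   values (default 1.1).
#' @param bernoulli_p Probability that a below-threshold entry is assigned
#'   to the test set (default 0.61).
#' @param target_test_fraction Desired share of present entries in the test
#'   set (default 0.20); used by [calibrate_bernoulli_p()].
#' @param seed RNG seed for the partition draw.
#' @return A `partition_params` list.
#' @export
partition_params <- function(center_quantile = 0.25, sd_multiplier = 1.1,
                             bernoulli_p = 0.61, target_test_fraction = 0.20,
                             seed = NULL) {
  stopifnot(center_quantile > 0, center_quantile < 1,
            sd_multiplier > 0,
            bernoulli_p >= 0, bernoulli_p <= 1,
            target_test_fraction >= 0, target_test_fraction < 1)
  structure(list(center_quantile = center_quantile,
                 sd_multiplier = sd_multiplier,
                 bernoulli_p = bernoulli_p,
                 target_test_fraction = target_test_fraction,
                 seed = seed),
            class = "partition_params")
}

# Threshold distribution (center, sd) over the present entries of a matrix.
threshold_distribution <- function(values, params) {
  present <- values[!is.na(values)]
  if (length(present) == 0L) abort("all entries are missing")
  list(center = unname(stats::quantile(present, params$center_quantile)),
       sd = params$sd_multiplier * stats::sd(present))
}

new_partition_masks <- function(train, val, test) {
  stopifnot(identical(dim(train), dim(val)), identical(dim(train), dim(test)))
  structure(list(train = train, val = val, test = test),
            class = "partition_masks")
}

#' @export
print.partition_masks <- function(x, ...) {
  cat(sprintf("partition_masks: %d train / %d val / %d test entries\n",
              sum(x$train), sum(x$val), sum(x$test)))
  invisible(x)
}

#' MNAR train/test partition of the present entries
#'
#' For each present entry `x`, a threshold `t` is drawn from
#' Normal(center, sd) where center is the `center_quantile` quantile and sd
#' is `sd_multiplier` times the standard deviation of all present values.
#' If `x < t` (the entry is low relative to its random cutoff) a
#' Bernoulli(`bernoulli_p`) trial sends it to the test set on success and to
#' the training set on failure; entries with `x >= t` always train. The
#' resulting test set is left-skewed relative to the training set, mimicking
#' intensity-dependent missingness. The validation mask is empty at this
#' stage; see [mcar_validation_split()].
#'
#' @param qm A [quant_matrix()] with at least one present entry.
#' @param params A [partition_params()]; its `seed` makes the draw
#'   deterministic.
#' @return A `partition_masks` object: logical matrices `train`, `val`,
#'   `test`, pairwise disjoint, whose union is the present-entry mask.
#' @export
mnar_partition <- function(qm, params = partition_params()) {
  v <- qm$values
  dist <- threshold_distribution(v, params)
  present <- !is.na(v)
  n <- sum(present)
  with_seed(params$seed, {
    thresholds <- stats::rnorm(n, dist$center, dist$sd)
    below <- v[present] < thresholds
    to_test <- below & (stats::runif(n) < params$bernoulli_p)
  })
  test <- matrix(FALSE, nrow(v), ncol(v), dimnames = dimnames(v))
  test[present] <- to_test
  train <- present & !test
  val <- matrix(FALSE, nrow(v), ncol(v), dimnames = dimnames(v))
  new_partition_masks(train, val, test)
}

#' Calibrate the Bernoulli success probability for a target test share
#'
#' Computes, analytically per present entry, the probability that the entry
#' falls below its random Normal threshold, `P(x < T) = 1 - pnorm((x -
#' center)/sd)`; the mean of these probabilities is the expected fraction of
#' test candidates. The Bernoulli probability is then `target` divided by
#' that fraction, clipped to [0, 1].
#'
#' @param qm A [quant_matrix()].
#' @param params A [partition_params()] supplying the threshold
#'   distribution.
#' @param target Desired expected test fraction (defaults to
#'   `params$target_test_fraction`).
#' @return The calibrated Bernoulli probability.
#' @export
calibrate_bernoulli_p <- function(qm, params = partition_params(),
                                  target = params$target_test_fraction) {
  stopifnot(target >= 0, target < 1)
  dist <- threshold_distribution(qm$values, params)
  x <- qm$values[!is.na(qm$values)]
  p_below <- if (dist$sd > 0) {
    mean(stats::pnorm(x, dist$center, dist$sd, lower.tail = FALSE))
  } else mean(x < dist$center)
  if (target == 0) return(0)
  if (target > p_below) {
    abort(paste0("target test fraction %.3f unreachable: at most %.3f of ",
                 "entries fall below their thresholds in expectation"),
          target, p_below)
  }
  min(1, target / p_below)
}

#' Move an MCAR validation subset out of the training mask
#'
#' Selects `floor(fraction * n_train)` training entries uniformly at random
#' (missing-completely-at-random, so the validation set has the same
#' intensity distribution as the training set) and moves them to the
#' validation mask. The test mask is untouched.
#'
#' @param masks A `partition_masks` object from [mnar_partition()].
#' @param fraction Fraction of training entries to move (default 0.10).
#' @param seed RNG seed.
#' @return Updated `partition_masks`.
#' @export
mcar_validation_split <- function(masks, fraction = 0.10, seed = NULL) {
  if (fraction < 0 || fraction >= 1) abort("`fraction` must be in [0, 1)")
  idx <- which(masks$train)
  if (length(idx) == 0L) abort("training mask is empty")
  n_val <- floor(fraction * length(idx))
  if (n_val > 0) {
    chosen <- with_seed(seed, sample(idx, n_val))
    masks$train[chosen] <- FALSE
    masks$val[chosen] <- TRUE
  }
  masks
}

#' Biased (low-intensity-enriched) training batch sampler
#'
#' Training batches are drawn from the training entries with replacement,
#' with low-intensity entries preferentially selected: each uniformly drawn
#' candidate is accepted outright when its value falls below a fresh draw
#' from the same threshold distribution used by [mnar_partition()], and
#' accepted with probability 0.5 otherwise. Pooled over many batches the
#' sampled intensities are therefore left-shifted relative to the full
#' training set, matching the left-skewed test set the model must predict.
#'
#' @param qm A [quant_matrix()].
#' @param masks `partition_masks`; candidates come from the train mask only.
#' @param n_batches Number of batches to draw.
#' @param batch_size Entries per batch (default 128).
#' @param params [partition_params()] defining the threshold distribution.
#' @param seed RNG seed.
#' @param biased Set `FALSE` to disable the acceptance rule and sample
#'   uniformly (used to verify the sampler against the training
#'   distribution).
#' @return A list of `n_batches` integer matrices with columns `protein`
#'   and `sample`, each with `batch_size` rows.
#' @export
biased_batches <- function(qm, masks, n_batches, batch_size = 128,
                           params = partition_params(), seed = NULL,
                           biased = TRUE) {
  stopifnot(batch_size >= 1, n_batches >= 1)
  idx <- which(masks$train)
  if (length(idx) == 0L) abort("training mask is empty")
  vals <- qm$values[idx]
  dist <- threshold_distribution(qm$values, params)
  with_seed(seed, {
    draw <- batch_index_stream(idx, vals, dist, biased)
    lapply(seq_len(n_batches), function(b) {
      lin <- draw(batch_size)
      cbind(protein = ((lin - 1L) %% nrow(qm$values)) + 1L,
            sample = ((lin - 1L) %/% nrow(qm$values)) + 1L)
    })
  })
}

# Returns a function(n) yielding n linear indices sampled from `idx` with
# replacement under the rejection rule. Uses the current RNG stream.
batch_index_stream <- function(idx, vals, dist, biased = TRUE) {
  function(n) {
    if (!biased) return(idx[sample.int(length(idx), n, replace = TRUE)])
    out <- integer(0)
    while (length(out) < n) {
      need <- n - length(out)
      cand <- sample.int(length(idx), max(2L * need, 64L), replace = TRUE)
      thr <- stats::rnorm(length(cand), dist$center, dist$sd)
      accept <- vals[cand] < thr | stats::runif(length(cand)) < 0.5
      out <- c(out, idx[cand[accept]])
    }
    out[seq_len(n)]
  }
}

#' Write partition masks as a (protein, sample, split) triplet table
#'
#' @param masks `partition_masks`.
#' @param qm The [quant_matrix()] the masks refer to (for identifiers).
#' @param path Output path.
#' @param header Optional provenance comment lines.
#' @return `path`, invisibly.
#' @export
write_masks <- function(masks, qm, path, header = NULL) {
  rows <- lapply(c(train = "train", val = "val", test = "test"), function(sp) {
    w <- which(masks[[sp]], arr.ind = TRUE)
    if (nrow(w) == 0L) return(NULL)
    data.frame(protein_id = rownames(qm$values)[w[, 1L]],
               sample_id = colnames(qm$values)[w[, 2L]],
               split = sp, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read partition masks written by [write_masks()]
#'
#' @param path Path to the triplet table.
#' @param qm The [quant_matrix()] the masks refer to.
#' @return A `partition_masks` object.
#' @export
read_masks <- function(path, qm) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  template <- matrix(FALSE, nrow(qm$values), ncol(qm$values),
                     dimnames = dimnames(qm$values))
  masks <- list(train = template, val = template, test = template)
  i <- match(df$protein_id, rownames(qm$values))
  j <- match(df$sample_id, colnames(qm$values))
  if (anyNA(i) || anyNA(j)) abort("mask refers to unknown protein/sample ids")
  for (sp in c("train", "val", "test")) {
    sel <- df$split == sp
    masks[[sp]][cbind(i[sel], j[sel])] <- TRUE
  }
  new_partition_masks(masks$train, masks$val, masks$test)
}
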