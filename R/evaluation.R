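#' Held-out test-set mean squared error, overall and per cohort
#'
#' @param predictions Full prediction matrix (proteins x samples).
#' @param qm_truth The [quant_matrix()] holding the true values; truth must
#'   be present at every test entry.
#' @param test_mask Logical matrix marking the held-out entries.
#' @param by_cohort Also compute per-cohort MSEs (default `TRUE`).
#' @return An `eval_report` list: `overall_mse`, `n_test_entries`, and when
#'   `by_cohort` the named vectors `mse_by_cohort` and
#'   `n_test_entries_by_cohort` (a cohort with no test entries is `NA`, not
#'   zero).
#' @export
test_mse <- function(predictions, qm_truth, test_mask, by_cohort = TRUE) {
  stopifnot(all(dim(predictions) == dim(qm_truth$values)),
            all(dim(test_mask) == dim(qm_truth$values)))
  if (!any(test_mask)) abort("test mask is empty")
  if (anyNA(qm_truth$values[test_mask])) {
    abort("truth is missing at some test entries")
  }
  sq <- (predictions[test_mask] - qm_truth$values[test_mask])^2
  report <- list(overall_mse = mean(sq), n_test_entries = sum(test_mask))
  if (by_cohort) {
    cohorts <- unique(qm_truth$samples$cohort)
    mse <- stats::setNames(rep(NA_real_, length(cohorts)), cohorts)
    n <- stats::setNames(integer(length(cohorts)), cohorts)
    for (ch in cohorts) {
      cols <- qm_truth$samples$cohort == ch
      m <- test_mask[, cols, drop = FALSE]
      n[ch] <- sum(m)
      if (n[ch] > 0) {
        mse[ch] <- mean((predictions[, cols, drop = FALSE][m] -
                           qm_truth$values[, cols, drop = FALSE][m])^2)
      }
    }
    report$mse_by_cohort <- mse
    report$n_test_entries_by_cohort <- n
  }
  structure(report, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: overall test MSE %.4g over %d entries\n",
              x$overall_mse, x$n_test_entries))
  if (!is.null(x$mse_by_cohort)) {
    for (ch in names(x$mse_by_cohort)) {
      cat(sprintf("  %s: %.4g (n=%d)\n", ch, x$mse_by_cohort[ch],
                  x$n_test_entries_by_cohort[ch]))
    }
  }
  invisible(x)
}

#' Per-protein prediction residuals over the test entries
#'
#' @param predictions Full prediction matrix.
#' @param qm_truth The truth [quant_matrix()].
#' @param test_mask Logical held-out mask.
#' @param aggregate Aggregation across a protein's test entries:
#'   `"mean_abs"` (mean absolute residual, default) or `"rms"`.
#' @param signed If `TRUE`, return the signed mean residual instead (for
#'   residual scatter plots).
#' @return Named numeric vector, one value per protein with at least one
#'   test entry.
#' @export
per_protein_residual <- function(predictions, qm_truth, test_mask,
                                 aggregate = c("mean_abs", "rms"),
                                 signed = FALSE) {
  aggregate <- match.arg(aggregate)
  stopifnot(all(dim(predictions) == dim(qm_truth$values)))
  idx <- which(test_mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) abort("test mask is empty")
  res <- predictions[test_mask] - qm_truth$values[test_mask]
  prot <- rownames(qm_truth$values)[idx[, 1L]]
  agg <- if (signed) {
    tapply(res, prot, mean)
  } else if (aggregate == "mean_abs") {
    tapply(abs(res), prot, mean)
  } else {
    sqrt(tapply(res^2, prot, mean))
  }
  out <- as.numeric(agg)
  names(out) <- names(agg)
  out[order(match(names(out), rownames(qm_truth$values)))]
}

#' Fraction of proteins predicted more accurately by method A than B
#'
#' Restricted to proteins for which either method's residual exceeds
#' `min_residual` (so near-perfect proteins do not inflate the statistic);
#' ties count as "not better".
#'
#' @param residuals_a,residuals_b Named per-protein residual vectors (see
#'   [per_protein_residual()]); compared over their shared proteins.
#' @param min_residual Retention threshold on `max(res_a, res_b)`
#'   (default 0.25).
#' @return Fraction in [0, 1] of retained proteins with
#'   `res_a < res_b`; `NA` with a warning when no protein passes the
#'   filter. The number of retained proteins is attached as attribute `n`.
#' @export
fraction_better <- function(residuals_a, residuals_b, min_residual = 0.25) {
  shared <- intersect(names(residuals_a), names(residuals_b))
  if (length(shared) == 0L) abort("no shared proteins between residual sets")
  a <- residuals_a[shared]
  b <- residuals_b[shared]
  keep <- pmax(a, b) > min_residual
  if (!any(keep)) {
    warning("no protein has residual above the threshold; fraction undefined")
    return(structure(NA_real_, n = 0L))
  }
  structure(mean(a[keep] < b[keep]), n = sum(keep))
}
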