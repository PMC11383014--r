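#' Downshifted-Gaussian random-sampling imputation
#'
#' The Perseus-style baseline: for each sample column with observed mean
#' `mu` and standard deviation `sigma`, every missing entry is drawn i.i.d.
#' from Normal(mu - downshift * sigma, (width * sigma)^2). Imputations are
#' therefore centered about the low end of the observed distribution,
#' mimicking left-censored missingness.
#'
#' @param qm A [quant_matrix()].
#' @param width Imputation sd as a fraction of the column sd (default 0.3).
#' @param downshift Downshift of the imputation mean in column-sd units
#'   (default 1.8).
#' @param seed RNG seed.
#' @return A complete `quant_matrix`; observed entries are untouched.
#' @export
gaussian_sample_impute <- function(qm, width = 0.3, downshift = 1.8,
                                   seed = NULL) {
  v <- qm$values
  with_seed(seed, {
    for (j in seq_len(ncol(v))) {
      obs <- v[, j][!is.na(v[, j])]
      n_miss <- sum(is.na(v[, j]))
      if (n_miss == 0L) next
      if (length(obs) < 2L) {
        abort("column %s has %d observed value(s); need >= 2", colnames(v)[j],
              length(obs))
      }
      mu <- mean(obs)
      sigma <- stats::sd(obs)
      v[is.na(v[, j]), j] <- stats::rnorm(n_miss, mu - downshift * sigma,
                                          width * sigma)
    }
  })
  quant_matrix(v, cohort = qm$samples$cohort,
               sample_type = qm$samples$sample_type,
               patient_id = qm$samples$patient_id, plex = qm$samples$plex)
}

#' Column-minimum imputation
#'
#' Replaces every missing value with the lowest observed quantification of
#' its sample column.
#'
#' @param qm A [quant_matrix()].
#' @return A complete `quant_matrix`; observed entries are untouched.
#' @export
column_min_impute <- function(qm) {
  v <- qm$values
  for (j in seq_len(ncol(v))) {
    miss <- is.na(v[, j])
    if (!any(miss)) next
    if (all(miss)) abort("column %s is fully missing", colnames(v)[j])
    v[miss, j] <- min(v[, j], na.rm = TRUE)
  }
  quant_matrix(v, cohort = qm$samples$cohort,
               sample_type = qm$samples$sample_type,
               patient_id = qm$samples$patient_id, plex = qm$samples$plex)
}
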