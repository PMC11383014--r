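#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: p-values are multiplied by
#' m/rank, monotonicity is enforced from the largest rank down, and results
#' are capped at 1 and returned in input order. Delegates to
#' [stats::p.adjust()].
#'
#' @param p_values Numeric vector of p-values in [0, 1] (`NA` allowed and
#'   preserved).
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p_values) {
  ok <- is.na(p_values) | (p_values >= 0 & p_values <= 1)
  if (!all(ok)) abort("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties receive average ranks). Pairs
#' where either value is missing are dropped; fewer than 3 complete pairs
#' or a constant sequence yields `NA`.
#'
#' @param x,y Equal-length numeric vectors.
#' @return Correlation coefficient in [-1, 1], or `NA` when undefined.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) return(NA_real_)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
  stats::cor(x[ok], y[ok], method = "spearman")
}

#' Paired tumor vs non-tumor differential expression
#'
#' For each protein, tumor and non-tumor samples of the same patient are
#' paired and a two-sided paired t-test is run on the per-patient
#' differences (tumor minus non-tumor). Values are assumed to be on a
#' log2-like scale, so the fold change is the mean paired difference.
#' Proteins whose pre-imputation missing fraction exceeds `max_missing`
#' are excluded before testing; p-values are BH-adjusted across the tested
#' proteins. A protein is called up (down) when its adjusted p-value is
#' below `alpha` and its log2 fold change exceeds `lfc_cut` (falls below
#' `-lfc_cut`).
#'
#' In no-imputation mode (`completed` still contains missing values) a
#' patient pair is dropped for a protein when either member is missing;
#' proteins left with fewer than 2 pairs get `NA` p-values and do not count
#' toward the BH family.
#'
#' @param completed The (imputed or raw) [quant_matrix()] to test; needs
#'   `sample_type` and `patient_id` annotations.
#' @param pre_imputation The matrix before imputation, used for the
#'   missingness filter; defaults to `completed`.
#' @param alpha Adjusted-p threshold for a DE call (default 0.01).
#' @param lfc_cut Absolute log2-fold-change threshold (default 0.5).
#' @param max_missing Maximum tolerated pre-imputation missing fraction
#'   (default 0.5).
#' @return A `data.frame` (class `de_table`) with one row per protein kept
#'   by the missingness filter: `protein_id`, `log2_fold_change`,
#'   `t_statistic`, `p_value`, `adjusted_p`, `direction`
#'   (`up`/`down`/`none`), `n_pairs`, `pre_imputation_missing_fraction`.
#' @export
run_de <- function(completed, pre_imputation = completed, alpha = 0.01,
                   lfc_cut = 0.5, max_missing = 0.5) {
  s <- completed$samples
  if (all(is.na(s$sample_type))) abort("sample_type annotations required")
  if (all(is.na(s$patient_id))) abort("patient_id annotations required")
  tumor <- which(s$sample_type == "tumor" & !is.na(s$patient_id))
  normal <- which(s$sample_type == "non_tumor" & !is.na(s$patient_id))
  patients <- intersect(s$patient_id[tumor], s$patient_id[normal])
  if (length(patients) < 2L) abort("need >= 2 complete tumor/non-tumor pairs")
  t_cols <- tumor[match(patients, s$patient_id[tumor])]
  n_cols <- normal[match(patients, s$patient_id[normal])]
  if (!all(dim(pre_imputation$values) == dim(completed$values))) {
    abort("pre_imputation matrix shape differs from completed matrix")
  }
  miss_frac <- rowMeans(is.na(pre_imputation$values))
  keep <- miss_frac <= max_missing
  prot <- rownames(completed$values)[keep]
  tv <- completed$values[keep, t_cols, drop = FALSE]
  nv <- completed$values[keep, n_cols, drop = FALSE]
  d <- tv - nv
  res <- t(vapply(seq_along(prot), function(r) {
    dr <- d[r, ][!is.na(d[r, ])]
    if (length(dr) < 2L || stats::sd(dr) == 0) {
      lfc <- if (length(dr)) mean(dr) else NA_real_
      return(c(lfc, NA_real_, NA_real_, length(dr)))
    }
    tt <- stats::t.test(dr)
    c(mean(dr), unname(tt$statistic), tt$p.value, length(dr))
  }, numeric(4)))
  if (all(is.na(res[, 3L]))) abort("no protein with enough valid pairs")
  adj <- rep(NA_real_, length(prot))
  tested <- !is.na(res[, 3L])
  adj[tested] <- bh_adjust(res[tested, 3L])
  direction <- rep("none", length(prot))
  direction[!is.na(adj) & adj < alpha & res[, 1L] > lfc_cut] <- "up"
  direction[!is.na(adj) & adj < alpha & res[, 1L] < -lfc_cut] <- "down"
  out <- data.frame(protein_id = prot,
                    log2_fold_change = res[, 1L],
                    t_statistic = res[, 2L],
                    p_value = res[, 3L],
                    adjusted_p = adj,
                    direction = direction,
                    n_pairs = as.integer(res[, 4L]),
                    pre_imputation_missing_fraction = miss_frac[keep],
                    stringsAsFactors = FALSE)
  class(out) <- c("de_table", "data.frame")
  out
}

#' Read a CORUM-style complex membership table
#'
#' Expects a delimited table with columns `complex_id` and `protein_id`.
#'
#' @param path Path to the table (tab- or comma-separated).
#' @return Named list mapping complex id to a character vector of member
#'   proteins.
#' @export
read_complexes <- function(path) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!all(c("complex_id", "protein_id") %in% colnames(df))) {
    abort("complex table needs complex_id and protein_id columns")
  }
  split(df$protein_id, df$complex_id)
}

#' Within-complex versus background co-expression correlations
#'
#' Restricts the matrix to one cohort (tumor samples only, by default) and
#' to proteins whose pre-imputation missing fraction is below
#' `max_missing`, then computes the Spearman correlation across samples for
#' every unordered pair of proteins that share a complex (deduplicated
#' across complexes). An equally sized background set of uniformly sampled
#' protein pairs - excluding self-pairs and any within-complex pair - is
#' correlated the same way, and the two sets of coefficients are compared
#' with a Welch two-sample t-test.
#'
#' @param completed [quant_matrix()] to correlate (imputed, or raw with
#'   missing values, in which case pairwise-complete samples are used).
#' @param complexes Named list mapping complex id to member protein ids
#'   (see [read_complexes()]).
#' @param cohort Cohort label to analyze; `NULL` uses all samples.
#' @param tumor_only Restrict to tumor samples (default `TRUE`).
#' @param max_missing Pre-imputation missingness cutoff (default 0.5).
#' @param pre_imputation Matrix used for the missingness filter; defaults
#'   to `completed`.
#' @param seed RNG seed for background pair sampling.
#' @return A `complex_corr_report`: `within_correlations`,
#'   `background_correlations` (equal length), their means, and the
#'   comparison `p_value`.
#' @export
complex_correlations <- function(completed, complexes, cohort = NULL,
                                 tumor_only = TRUE, max_missing = 0.5,
                                 pre_imputation = completed, seed = NULL) {
  s <- completed$samples
  cols <- rep(TRUE, ncol(completed$values))
  if (!is.null(cohort)) cols <- cols & s$cohort == cohort
  if (tumor_only && any(!is.na(s$sample_type))) {
    cols <- cols & !is.na(s$sample_type) & s$sample_type == "tumor"
  }
  if (sum(cols) < 3L) abort("fewer than 3 samples after cohort/type filtering")
  miss_frac <- rowMeans(is.na(pre_imputation$values))
  keep <- rownames(completed$values)[miss_frac < max_missing]
  v <- completed$values[keep, cols, drop = FALSE]
  prot_index <- stats::setNames(seq_along(keep), keep)
  pair_key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  within <- unique(do.call(rbind, lapply(complexes, function(members) {
    m <- sort(prot_index[intersect(members, keep)])
    if (length(m) < 2L) return(NULL)
    cmb <- utils::combn(m, 2L)
    cbind(cmb[1L, ], cmb[2L, ])
  })))
  if (is.null(within) || nrow(within) == 0L) {
    abort("no complex retains >= 2 members after filtering")
  }
  within_keys <- pair_key(within[, 1L], within[, 2L])
  n_pairs <- nrow(within)
  n_prot <- length(keep)
  total_pairs <- n_prot * (n_prot - 1) / 2
  if (total_pairs - n_pairs < n_pairs) {
    abort("not enough non-complex pairs to match %d within-complex pairs",
          n_pairs)
  }
  background <- with_seed(seed, {
    got <- matrix(integer(0), 0L, 2L)
    seen <- character(0)
    while (nrow(got) < n_pairs) {
      need <- n_pairs - nrow(got)
      a <- sample.int(n_prot, 2L * need + 16L, replace = TRUE)
      b <- sample.int(n_prot, 2L * need + 16L, replace = TRUE)
      ok <- a != b
      a <- a[ok]; b <- b[ok]
      keys <- pair_key(a, b)
      fresh <- !(keys %in% within_keys) & !(keys %in% seen) & !duplicated(keys)
      got <- rbind(got, cbind(pmin(a, b)[fresh], pmax(a, b)[fresh]))
      seen <- c(seen, keys[fresh])
    }
    got[seq_len(n_pairs), , drop = FALSE]
  })
  corr_pairs <- function(pairs) {
    vapply(seq_len(nrow(pairs)), function(r) {
      spearman_cor(v[pairs[r, 1L], ], v[pairs[r, 2L], ])
    }, 0)
  }
  w_cor <- corr_pairs(within)
  b_cor <- corr_pairs(background)
  # the comparison needs >= 2 non-degenerate coefficients per set
  p_val <- tryCatch(stats::t.test(w_cor, b_cor)$p.value,
                    error = function(e) NA_real_)
  structure(list(within_correlations = w_cor,
                 background_correlations = b_cor,
                 mean_within = mean(w_cor, na.rm = TRUE),
                 mean_background = mean(b_cor, na.rm = TRUE),
                 p_value = p_val,
                 n_pairs = n_pairs),
            class = "complex_corr_report")
}

#' @export
print.complex_corr_report <- function(x, ...) {
  cat(sprintf(paste0("complex_corr_report: %d pairs; mean within %.3f vs ",
                     "background %.3f (p = %.3g)\n"),
              x$n_pairs, x$mean_within, x$mean_background, x$p_value))
  invisible(x)
}
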