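#' Specification of a synthetic multi-cohort quantification dataset
#'
#' The generator emulates the structure of multi-cohort TMT protein
#' quantifications on a reference-normalized log scale: a low-rank
#' protein-by-sample signal, correlated protein blocks standing in for
#' protein complexes, per-cohort and per-plex column offsets (residual
#' batch effects), tumor-vs-non-tumor shifts on planted proteins, additive
#' Gaussian noise, and intensity-dependent (left-censored, logistic)
#' missingness calibrated to a target missing fraction.
#'
#' @param n_cohorts Number of cohorts (default 4).
#' @param proteins_per_cohort Proteins measured per cohort (default 300).
#' @param samples_per_cohort Samples per cohort (default 40).
#' @param shared_protein_fraction Fraction of each cohort's panel drawn
#'   from a common core (default 1: all cohorts measure the same panel;
#'   lower values create structural missingness after joining).
#' @param latent_rank Rank of the shared low-rank signal (default 5).
#' @param factor_scale Standard deviation of the low-rank signal
#'   (default 1).
#' @param noise_sd Measurement noise sd (default 0.3).
#' @param cohort_offset_sd Sd of per-cohort column offsets (default 0.3).
#' @param plex_offset_sd Sd of per-plex column offsets (default 0.1).
#' @param n_plexes_per_cohort TMT plexes per cohort (default 4).
#' @param paired_patients_per_cohort Patients contributing a tumor +
#'   non-tumor pair; defaults to half the samples (every sample paired).
#' @param n_de_proteins Planted differentially expressed proteins
#'   (default 30).
#' @param de_log2_shift Log2 shift added to tumor columns of planted
#'   proteins (default 1).
#' @param de_direction `"up"` (all planted proteins shift up, default) or
#'   `"both"` (alternating signs).
#' @param n_complexes,complex_size,complex_loading Correlated protein
#'   blocks: number, members each, and loading on the shared block factor
#'   (defaults 10, 5, 0.8).
#' @param mnar_slope Slope of the logistic missingness curve (default 2).
#' @param target_missing_fraction Overall missing fraction of the joined
#'   matrix, structural plus censored (default 0.3).
#' @param seed RNG seed.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(n_cohorts = 4, proteins_per_cohort = 300,
                     samples_per_cohort = 40, shared_protein_fraction = 1,
                     latent_rank = 5, factor_scale = 1, noise_sd = 0.3,
                     cohort_offset_sd = 0.3, plex_offset_sd = 0.1,
                     n_plexes_per_cohort = 4,
                     paired_patients_per_cohort = NULL,
                     n_de_proteins = 30, de_log2_shift = 1,
                     de_direction = c("up", "both"),
                     n_complexes = 10, complex_size = 5,
                     complex_loading = 0.8, mnar_slope = 2,
                     target_missing_fraction = 0.3, seed = 1) {
  de_direction <- match.arg(de_direction)
  if (is.null(paired_patients_per_cohort)) {
    paired_patients_per_cohort <- samples_per_cohort %/% 2L
  }
  stopifnot(n_cohorts >= 1, proteins_per_cohort >= 1, samples_per_cohort >= 1,
            shared_protein_fraction >= 0, shared_protein_fraction <= 1,
            latent_rank >= 1, factor_scale > 0, noise_sd >= 0,
            cohort_offset_sd >= 0, plex_offset_sd >= 0,
            n_plexes_per_cohort >= 1,
            2 * paired_patients_per_cohort <= samples_per_cohort,
            n_de_proteins >= 0, n_complexes >= 0, complex_size >= 2,
            mnar_slope > 0,
            target_missing_fraction >= 0, target_missing_fraction < 1)
  structure(as.list(environment()), class = "sim_spec")
}

#' Simulate a multi-cohort quantification dataset with known ground truth
#'
#' Builds the complete truth matrix described in [sim_spec()], applies
#' left-censored missingness whose logistic midpoint is calibrated by
#' bisection so that the realized overall missing fraction (structural
#' missingness from partially overlapping protein panels plus censoring)
#' matches the target within 0.01, and returns both the observed
#' [quant_matrix()] and the full ground truth.
#'
#' @param spec A [sim_spec()].
#' @return A list with `observed` (a `quant_matrix` with missing values
#'   and full annotations) and `truth` (a `sim_truth` list: `values`
#'   complete truth matrix, `missing_mask`, `de_proteins` with `sign`,
#'   `complexes`, `samples` annotations).
#' @export
simulate_cohorts <- function(spec = sim_spec()) {
  with_seed(spec$seed, {
    core_n <- round(spec$shared_protein_fraction * spec$proteins_per_cohort)
    uniq_n <- spec$proteins_per_cohort - core_n
    core <- sprintf("P%04d", seq_len(core_n))
    panels <- vector("list", spec$n_cohorts)
    extra <- list()
    for (k in seq_len(spec$n_cohorts)) {
      own <- if (uniq_n > 0) sprintf("C%d_P%03d", k, seq_len(uniq_n)) else character(0)
      panels[[k]] <- c(core, own)
      extra[[k]] <- own
    }
    all_prot <- unique(unlist(panels))
    n_prot <- length(all_prot)
    cohorts <- sprintf("cohort%d", seq_len(spec$n_cohorts))
    n_samp <- spec$n_cohorts * spec$samples_per_cohort
    sample_id <- character(0)
    cohort <- character(0)
    sample_type <- character(0)
    patient_id <- character(0)
    plex <- character(0)
    for (k in seq_len(spec$n_cohorts)) {
      ids <- sprintf("%s_s%02d", cohorts[k], seq_len(spec$samples_per_cohort))
      st <- rep(NA_character_, spec$samples_per_cohort)
      pid <- rep(NA_character_, spec$samples_per_cohort)
      np <- spec$paired_patients_per_cohort
      if (np > 0) {
        st[seq_len(2 * np)] <- rep(c("tumor", "non_tumor"), np)
        pid[seq_len(2 * np)] <- rep(sprintf("%s_pt%02d", cohorts[k],
                                            seq_len(np)), each = 2)
      }
      if (2 * np < spec$samples_per_cohort) {
        st[(2 * np + 1):spec$samples_per_cohort] <- "tumor"
      }
      px <- sprintf("%s_plex%d", cohorts[k],
                    rep_len(seq_len(spec$n_plexes_per_cohort),
                            spec$samples_per_cohort))
      sample_id <- c(sample_id, ids)
      cohort <- c(cohort, rep(cohorts[k], spec$samples_per_cohort))
      sample_type <- c(sample_type, st)
      patient_id <- c(patient_id, pid)
      plex <- c(plex, px)
    }
    # low-rank signal; paired tumor/non-tumor samples share their patient's
    # latent factors, so paired differences carry only the planted shift
    # plus measurement noise
    unit <- ifelse(is.na(patient_id), sample_id, patient_id)
    unit_levels <- unique(unit)
    unit_of <- match(unit, unit_levels)
    U <- matrix(stats::rnorm(n_prot * spec$latent_rank), n_prot)
    V_units <- matrix(stats::rnorm(spec$latent_rank * length(unit_levels)),
                      spec$latent_rank)
    V <- V_units[, unit_of, drop = FALSE]
    truth <- (U %*% V) * (spec$factor_scale / sqrt(spec$latent_rank))
    rownames(truth) <- all_prot
    colnames(truth) <- sample_id
    # correlated complex blocks: members load on a shared per-sample factor
    complexes <- list()
    if (spec$n_complexes > 0) {
      needed <- spec$n_complexes * spec$complex_size
      pool <- sample(all_prot, min(needed, n_prot))
      groups <- split(pool, rep_len(seq_len(spec$n_complexes), length(pool)))
      for (g in seq_along(groups)) {
        members <- groups[[g]]
        if (length(members) < 2L) next
        f <- stats::rnorm(length(unit_levels))[unit_of]
        truth[members, ] <- truth[members, , drop = FALSE] +
          spec$complex_loading * matrix(f, length(members), n_samp,
                                        byrow = TRUE)
        complexes[[sprintf("complex%02d", g)]] <- members
      }
    }
    # batch structure: cohort and plex column offsets
    cohort_off <- stats::setNames(
      stats::rnorm(spec$n_cohorts, 0, spec$cohort_offset_sd), cohorts)
    plex_levels <- unique(plex)
    plex_off <- stats::setNames(
      stats::rnorm(length(plex_levels), 0, spec$plex_offset_sd), plex_levels)
    truth <- truth + matrix(cohort_off[cohort] + plex_off[plex],
                            n_prot, n_samp, byrow = TRUE)
    # planted differential expression on tumor columns
    de_proteins <- data.frame(protein_id = character(0), sign = numeric(0))
    if (spec$n_de_proteins > 0) {
      planted <- sample(all_prot, min(spec$n_de_proteins, n_prot))
      signs <- if (spec$de_direction == "up") rep(1, length(planted)) else
        rep_len(c(1, -1), length(planted))
      tumor_cols <- which(!is.na(sample_type) & sample_type == "tumor")
      truth[planted, tumor_cols] <- truth[planted, tumor_cols, drop = FALSE] +
        signs * spec$de_log2_shift
      de_proteins <- data.frame(protein_id = planted, sign = signs,
                                stringsAsFactors = FALSE)
    }
    truth <- truth + matrix(stats::rnorm(n_prot * n_samp, 0, spec$noise_sd),
                            n_prot, n_samp)
    # structural missingness: proteins outside a cohort's panel
    measured <- matrix(FALSE, n_prot, n_samp, dimnames = dimnames(truth))
    for (k in seq_len(spec$n_cohorts)) {
      measured[panels[[k]], cohort == cohorts[k]] <- TRUE
    }
    struct_frac <- 1 - mean(measured)
    if (struct_frac > spec$target_missing_fraction) {
      abort(paste0("target missing fraction %.3f below the structural ",
                   "fraction %.3f"), spec$target_missing_fraction, struct_frac)
    }
    censor_target <- (spec$target_missing_fraction - struct_frac) /
      (1 - struct_frac)
    x <- truth[measured]
    censored <- rep(FALSE, length(x))
    if (censor_target > 0) {
      # bisection on the logistic midpoint so E[missing] hits the target
      expected <- function(c0) mean(stats::plogis(-spec$mnar_slope * (x - c0)))
      lo <- min(x) - 10
      hi <- max(x) + 10
      for (iter in 1:60) {
        mid <- (lo + hi) / 2
        if (expected(mid) < censor_target) lo <- mid else hi <- mid
      }
      c0 <- (lo + hi) / 2
      censored <- stats::runif(length(x)) <
        stats::plogis(-spec$mnar_slope * (x - c0))
    }
    missing_mask <- !measured
    missing_mask[measured] <- censored
    observed_values <- truth
    observed_values[missing_mask] <- NA_real_
    observed <- quant_matrix(observed_values, cohort = cohort,
                             sample_type = sample_type,
                             patient_id = patient_id, plex = plex)
    truth_obj <- structure(list(values = truth, missing_mask = missing_mask,
                                de_proteins = de_proteins,
                                complexes = complexes,
                                samples = observed$samples,
                                spec = spec),
                           class = "sim_truth")
    list(observed = observed, truth = truth_obj)
  })
}

#' Uniform (missing-completely-at-random) entry mask
#'
#' @param values A matrix (or [quant_matrix()]).
#' @param fraction Fraction of entries to mask, in [0, 1).
#' @param seed RNG seed.
#' @return Logical matrix with `floor(fraction * n)` entries `TRUE`,
#'   selected uniformly.
#' @export
mcar_mask <- function(values, fraction, seed = NULL) {
  if (inherits(values, "quant_matrix")) values <- values$values
  if (fraction < 0 || fraction >= 1) abort("`fraction` must be in [0, 1)")
  mask <- matrix(FALSE, nrow(values), ncol(values),
                 dimnames = dimnames(values))
  n <- floor(fraction * length(values))
  if (n > 0) {
    mask[with_seed(seed, sample.int(length(values), n))] <- TRUE
  }
  mask
}

#' Write a simulated dataset to a directory
#'
#' Writes `observed.tsv` and `truth.tsv` (quantification tables),
#' `metadata.tsv` (sample annotations), `complexes.tsv` (complex
#' membership) and `de_proteins.tsv` (planted shifts).
#'
#' @param sim Result of [simulate_cohorts()].
#' @param dir Output directory (created if needed).
#' @param header Optional provenance comment lines.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, header = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_quant_table(sim$observed, file.path(dir, "observed.tsv"),
                    header = header)
  truth_qm <- quant_matrix(sim$truth$values,
                           cohort = sim$observed$samples$cohort,
                           sample_type = sim$observed$samples$sample_type,
                           patient_id = sim$observed$samples$patient_id,
                           plex = sim$observed$samples$plex)
  write_quant_table(truth_qm, file.path(dir, "truth.tsv"), header = header)
  utils::write.table(sim$observed$samples, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(sim$truth$complexes)) {
    cx <- data.frame(
      complex_id = rep(names(sim$truth$complexes),
                       lengths(sim$truth$complexes)),
      protein_id = unlist(sim$truth$complexes, use.names = FALSE),
      stringsAsFactors = FALSE)
    utils::write.table(cx, file.path(dir, "complexes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  utils::write.table(sim$truth$de_proteins, file.path(dir, "de_proteins.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
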