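#' Protein-by-sample quantification matrix
#'
#' The central container of the package: a numeric matrix of log-scale
#' protein intensities (rows = proteins, columns = de-multiplexed TMT
#' samples) in which `NA` marks a missing quantification, together with
#' per-sample annotations. Every sample carries a cohort label; tumor /
#' non-tumor status, patient identity (for pairing) and TMT plex are
#' optional.
#'
#' @param values Numeric matrix; `NA` = missing. Row and column names, if
#'   present, must agree with `protein_ids` / `sample_ids`.
#' @param protein_ids,sample_ids Character vectors of unique identifiers.
#'   Default to the dimnames of `values`.
#' @param cohort Cohort label per sample: either a single label recycled to
#'   all samples or a vector of length `ncol(values)`.
#' @param sample_type Optional per-sample vector with values `"tumor"` /
#'   `"non_tumor"` (`NA` allowed).
#' @param patient_id Optional per-sample patient identifier used to pair
#'   tumor with non-tumor samples.
#' @param plex Optional per-sample TMT plex identifier.
#' @return An object of class `quant_matrix` with elements `values`
#'   (named numeric matrix) and `samples` (data frame of annotations).
#' @examples
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("P", 1:3), c("s1", "s2")))
#' m[2, 1] <- NA
#' qm <- quant_matrix(m, cohort = "BRCA")
#' missing_fraction(qm)
#' @export
quant_matrix <- function(values, protein_ids = rownames(values),
                         sample_ids = colnames(values), cohort,
                         sample_type = NULL, patient_id = NULL, plex = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix")
  }
  if (is.null(protein_ids) || is.null(sample_ids)) {
    abort("protein and sample identifiers are required")
  }
  protein_ids <- as.character(protein_ids)
  sample_ids <- as.character(sample_ids)
  if (length(protein_ids) != nrow(values)) {
    abort("%d protein ids for %d rows", length(protein_ids), nrow(values))
  }
  if (length(sample_ids) != ncol(values)) {
    abort("%d sample ids for %d columns", length(sample_ids), ncol(values))
  }
  if (anyDuplicated(protein_ids)) {
    abort("duplicate protein id: %s",
          paste(unique(protein_ids[duplicated(protein_ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    abort("duplicate sample id: %s",
          paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (any(is.infinite(values) | is.nan(values))) {
    abort("`values` must contain only finite numbers or NA")
  }
  dimnames(values) <- list(protein_ids, sample_ids)
  recycle <- function(x, what) {
    if (is.null(x)) return(rep(NA_character_, length(sample_ids)))
    if (length(x) == 1L) x <- rep(x, length(sample_ids))
    if (length(x) != length(sample_ids)) {
      abort("`%s` must have one value per sample", what)
    }
    as.character(x)
  }
  if (missing(cohort) || is.null(cohort)) abort("every sample needs a cohort label")
  cohort <- recycle(cohort, "cohort")
  if (anyNA(cohort)) abort("every sample needs a cohort label")
  sample_type <- recycle(sample_type, "sample_type")
  ok <- is.na(sample_type) | sample_type %in% c("tumor", "non_tumor")
  if (!all(ok)) abort("`sample_type` values must be 'tumor' or 'non_tumor'")
  samples <- data.frame(
    sample_id = sample_ids,
    cohort = cohort,
    sample_type = sample_type,
    patient_id = recycle(patient_id, "patient_id"),
    plex = recycle(plex, "plex"),
    stringsAsFactors = FALSE
  )
  structure(list(values = values, samples = samples), class = "quant_matrix")
}

#' @export
print.quant_matrix <- function(x, ...) {
  cat(sprintf("quant_matrix: %d proteins x %d samples (%.1f%% missing)\n",
              nrow(x$values), ncol(x$values), 100 * missing_fraction(x)))
  cat("cohorts:", paste(unique(x$samples$cohort), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.quant_matrix <- function(x) dim(x$values)

protein_ids <- function(qm) rownames(qm$values)
sample_ids <- function(qm) colnames(qm$values)

#' Subset a quantification matrix
#'
#' @param qm A [quant_matrix()].
#' @param proteins,samples Row / column selectors (names, indices or logical).
#' @return A `quant_matrix` restricted to the selection.
#' @export
subset_quant <- function(qm, proteins = NULL, samples = NULL) {
  v <- qm$values
  if (!is.null(proteins)) v <- v[proteins, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  if (nrow(v) == 0L || ncol(v) == 0L) abort("subset is empty")
  s <- qm$samples[match(colnames(v), qm$samples$sample_id), , drop = FALSE]
  quant_matrix(v, cohort = s$cohort, sample_type = s$sample_type,
               patient_id = s$patient_id, plex = s$plex)
}

#' Fraction of missing entries
#'
#' @param qm A [quant_matrix()] (or a plain matrix).
#' @return The number of missing cells divided by the total number of cells.
#' @export
missing_fraction <- function(qm) {
  v <- if (inherits(qm, "quant_matrix")) qm$values else qm
  if (length(v) == 0L) abort("empty matrix")
  mean(is.na(v))
}

#' Hide entries of a quantification matrix
#'
#' Sets the entries flagged by `mask` to missing. Used when benchmarking:
#' the held-out test entries are hidden from an imputation method, which
#' is then scored on how well it recovers them.
#'
#' @param qm A [quant_matrix()].
#' @param mask Logical matrix of the same shape; `TRUE` entries become
#'   missing.
#' @return The masked `quant_matrix`.
#' @export
mask_entries <- function(qm, mask) {
  if (!all(dim(mask) == dim(qm$values))) abort("mask shape mismatch")
  v <- qm$values
  v[mask] <- NA_real_
  quant_matrix(v, cohort = qm$samples$cohort,
               sample_type = qm$samples$sample_type,
               patient_id = qm$samples$patient_id, plex = qm$samples$plex)
}

missing_tokens <- c("", "NA", "NaN", "nan", "na", "N/A")

# First non-comment line decides tab vs comma.
detect_sep <- function(path) {
  head <- readLines(path, n = 50L)
  head <- head[!startsWith(head, "#")]
  if (length(head) == 0L) abort("no data lines in %s", path)
  if (grepl("\t", head[1L])) "\t" else ","
}

#' Read a protein-by-sample quantification table
#'
#' Expects a delimited table whose first column holds protein identifiers and
#' whose header row holds sample identifiers. Blank cells and NA/NaN tokens
#' become missing values. Values are assumed to be already log-transformed
#' and reference-normalized; set `log2 = TRUE` to log2-transform raw-scale
#' intensities on read (zeros become missing).
#'
#' @param path Path to the table.
#' @param sep Field delimiter; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @param cohort Cohort label to attach to every sample (annotations can be
#'   refined later with [attach_metadata()]).
#' @param log2 If `TRUE`, apply `log2()` to the parsed values.
#' @return A [quant_matrix()].
#' @export
read_quant_table <- function(path, sep = NULL, cohort = "unspecified",
                             log2 = FALSE) {
  if (!file.exists(path)) abort("file not found: %s", path)
  if (is.null(sep)) sep <- detect_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", check.names = FALSE,
                           comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) abort("table needs a protein id column plus >= 1 sample")
  prot <- raw[[1L]]
  if (anyDuplicated(prot)) {
    abort("duplicate protein id in %s: %s", path,
          paste(unique(prot[duplicated(prot)]), collapse = ", "))
  }
  samp <- colnames(raw)[-1L]
  if (anyDuplicated(samp)) {
    abort("duplicate sample id in %s: %s", path,
          paste(unique(samp[duplicated(samp)]), collapse = ", "))
  }
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  is_missing <- cells %in% missing_tokens | is.na(cells)
  num <- suppressWarnings(as.numeric(cells))
  bad <- which(is.na(num) & !is_missing)
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(cells)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(cells)) + 1L
    abort("non-numeric value '%s' at protein %s, sample %s",
          cells[bad[1L]], prot[i], samp[j])
  }
  num[is_missing] <- NA_real_
  values <- matrix(num, nrow = nrow(cells), dimnames = list(prot, samp))
  if (log2) {
    values[!is.na(values) & values <= 0] <- NA
    values <- log2(values)
  }
  quant_matrix(values, cohort = cohort)
}

#' Write a quantification table
#'
#' Writes the matrix in the same layout [read_quant_table()] expects
#' (first column `protein_id`, one column per sample, empty cell = missing).
#'
#' @param qm A [quant_matrix()].
#' @param path Output path.
#' @param sep Field delimiter (default tab).
#' @param header Optional character vector of comment lines (written with a
#'   leading `#`) used for provenance stamping.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(qm, path, sep = "\t", header = NULL) {
  df <- data.frame(protein_id = protein_ids(qm), qm$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Attach sample metadata from a delimited table
#'
#' The metadata table must contain a `sample_id` column; recognized optional
#' columns are `cohort`, `sample_type`, `patient_id` and `plex`. Samples
#' absent from the table keep their current annotations.
#'
#' @param qm A [quant_matrix()].
#' @param path Path to the metadata table (tab- or comma-separated).
#' @return The annotated `quant_matrix`.
#' @export
attach_metadata <- function(qm, path) {
  sep <- detect_sep(path)
  meta <- utils::read.table(path, header = TRUE, sep = sep,
                            colClasses = "character", check.names = FALSE,
                            comment.char = "#", stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(meta)) abort("metadata needs a sample_id column")
  idx <- match(qm$samples$sample_id, meta$sample_id)
  for (col in intersect(c("cohort", "sample_type", "patient_id", "plex"),
                        colnames(meta))) {
    hit <- !is.na(idx)
    qm$samples[[col]][hit] <- meta[[col]][idx[hit]]
  }
  quant_matrix(qm$values, cohort = qm$samples$cohort,
               sample_type = qm$samples$sample_type,
               patient_id = qm$samples$patient_id, plex = qm$samples$plex)
}

#' Join per-cohort matrices into one quantification matrix
#'
#' Rows of the joined matrix are the union of the cohorts' protein sets (in
#' order of first appearance) and columns are the concatenated samples. A
#' protein that was not measured in a cohort is missing in all of that
#' cohort's columns. Sample ids are prefixed with their cohort label when
#' needed to keep them globally unique.
#'
#' @param matrices List of [quant_matrix()] objects, one per cohort.
#' @param labels Cohort labels, one per matrix (defaults to each matrix's
#'   own cohort annotation).
#' @return The joined `quant_matrix` with `cohort` set from `labels`.
#' @export
join_cohorts <- function(matrices, labels = NULL) {
  if (length(matrices) == 0L) abort("no matrices to join")
  stopifnot(all(vapply(matrices, inherits, TRUE, "quant_matrix")))
  if (is.null(labels)) {
    labels <- vapply(matrices, function(m) m$samples$cohort[1L], "")
  }
  if (length(labels) != length(matrices)) abort("one label per matrix required")
  all_samp <- unlist(lapply(matrices, sample_ids))
  if (anyDuplicated(all_samp)) {
    matrices <- Map(function(m, lab) {
      colnames(m$values) <- paste(lab, colnames(m$values), sep = ".")
      m$samples$sample_id <- colnames(m$values)
      m
    }, matrices, labels)
    all_samp <- unlist(lapply(matrices, sample_ids))
    if (anyDuplicated(all_samp)) abort("sample ids not unique even after prefixing")
  }
  prot <- unique(unlist(lapply(matrices, protein_ids)))
  values <- matrix(NA_real_, length(prot), length(all_samp),
                   dimnames = list(prot, all_samp))
  ann <- vector("list", length(matrices))
  for (k in seq_along(matrices)) {
    m <- matrices[[k]]
    values[protein_ids(m), sample_ids(m)] <- m$values
    s <- m$samples
    s$cohort <- labels[[k]]
    ann[[k]] <- s
  }
  ann <- do.call(rbind, ann)
  quant_matrix(values, cohort = ann$cohort, sample_type = ann$sample_type,
               patient_id = ann$patient_id, plex = ann$plex)
}

#' Default exclusion keywords for control / reference channels
#'
#' Sample ids containing any of these substrings (case-insensitive) denote
#' internal reference channels, QC runs or pooled samples rather than
#' biological samples, and are dropped by [filter_matrix()].
#' @export
default_exclude_keywords <- c("RefInt", "QC", "pool", "pooled", "reference",
                              "NCI", "NX", "ref")

#' Filter samples by id keywords and proteins by minimum presence
#'
#' First removes samples whose id contains any exclusion keyword
#' (case-insensitive substring match, so `"ref"` also catches `"RefInt"`),
#' then removes proteins quantified in fewer than `min_present` of the
#' remaining samples. Row and column order is otherwise preserved.
#'
#' @param qm A [quant_matrix()].
#' @param min_present Minimum number of present values a protein must have
#'   to be kept (default 18).
#' @param exclude_keywords Character vector of substrings flagging
#'   non-biological samples; defaults to [default_exclude_keywords].
#' @return The filtered `quant_matrix`.
#' @export
filter_matrix <- function(qm, min_present = 18,
                          exclude_keywords = default_exclude_keywords) {
  if (min_present < 0) abort("`min_present` must be >= 0")
  keep_s <- rep(TRUE, ncol(qm$values))
  for (kw in exclude_keywords) {
    keep_s <- keep_s & !grepl(kw, colnames(qm$values), ignore.case = TRUE,
                              fixed = FALSE)
  }
  if (!any(keep_s)) abort("keyword filtering removed every sample")
  v <- qm$values[, keep_s, drop = FALSE]
  keep_p <- rowSums(!is.na(v)) >= min_present
  if (!any(keep_p)) abort("presence filtering removed every protein")
  subset_quant(qm, proteins = which(keep_p), samples = which(keep_s))
}
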