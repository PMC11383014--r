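test_that("parsing maps blanks and NaN tokens to missing and round-trips", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\ts1\ts2",
               "P1\t1.5\t2.0",
               "P2\t\t3.25",
               "P3\tNaN\t-0.5"), path)
  qm <- read_quant_table(path, cohort = "A")
  expect_equal(dim(qm$values), c(3L, 2L))
  expect_equal(sum(is.na(qm$values)), 2L)
  expect_equal(qm$values["P1", "s2"], 2.0)

  # write-then-read identity on values, ids and missing mask
  out <- withr::local_tempfile(fileext = ".tsv")
  write_quant_table(qm, out, header = "fixture")
  back <- read_quant_table(out, cohort = "A")
  expect_equal(back$values, qm$values)
  expect_identical(is.na(back$values), is.na(qm$values))
})

test_that("duplicate ids and non-numeric cells are hard errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\ts1", "P1\t1", "P1\t2"), path)
  expect_error(read_quant_table(path, cohort = "A"), "duplicate protein")

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("protein_id,s1,s2", "P1,1.0,oops"), path2)
  expect_error(read_quant_table(path2, cohort = "A"), "P1.*s2")

  m <- matrix(1, 2, 2, dimnames = list(c("P1", "P1"), c("a", "b")))
  expect_error(quant_matrix(m, cohort = "A"), "duplicate protein")
})

test_that("join over identical protein sets adds no missingness", {
  a <- tiny_qm(5, 3, missing = 0, seed = 1, cohort = "A")
  b <- tiny_qm(5, 4, missing = 0, seed = 2, cohort = "B")
  colnames(b$values) <- paste0("t", 1:4)
  b$samples$sample_id <- colnames(b$values)
  j <- join_cohorts(list(a, b), c("A", "B"))
  expect_equal(dim(j$values), c(5L, 7L))
  expect_equal(missing_fraction(j), 0)
  expect_equal(j$samples$cohort, c(rep("A", 3), rep("B", 4)))
})

test_that("join takes the union of proteins with structural missingness", {
  mk <- function(prot, samp, cohort) {
    quant_matrix(matrix(seq_along(prot) + 0.0, length(prot), length(samp),
                        dimnames = list(prot, samp)), cohort = cohort)
  }
  a <- mk(c("P1", "P2"), c("a1", "a2"), "A")
  b <- mk(c("P2", "P3"), c("b1"), "B")
  j <- join_cohorts(list(a, b), c("A", "B"))
  expect_setequal(rownames(j$values), c("P1", "P2", "P3"))
  expect_true(all(is.na(j$values["P1", c("b1")])))
  expect_true(all(is.na(j$values["P3", c("a1", "a2")])))
  expect_false(anyNA(j$values["P2", ]))
  # per-cohort column subset recovers each input exactly
  expect_equal(j$values[rownames(a$values), colnames(a$values)], a$values)
  expect_equal(j$values[rownames(b$values), colnames(b$values), drop = FALSE],
               b$values)
})

test_that("joined missing fraction matches a brute-force cell count", {
  set.seed(42)
  cohorts <- lapply(1:10, function(k) {
    prot <- sprintf("P%02d", sort(sample(1:40, sample(10:30, 1))))
    m <- matrix(rnorm(length(prot) * 5), length(prot), 5,
                dimnames = list(prot, sprintf("c%d_s%d", k, 1:5)))
    m[sample(length(m), round(0.1 * length(m)))] <- NA
    quant_matrix(m, cohort = sprintf("c%d", k))
  })
  j <- join_cohorts(cohorts, sprintf("c%d", 1:10))
  brute <- sum(vapply(seq_len(nrow(j$values)), function(i)
    sum(is.na(j$values[i, ])), 0L))
  expect_equal(missing_fraction(j), brute / length(j$values))
})

test_that("presence filter keeps proteins at exactly the threshold", {
  set.seed(7)
  v <- matrix(rnorm(3 * 100), 3, 100,
              dimnames = list(c("at17", "at18", "full"),
                              sprintf("s%03d", 1:100)))
  v["at17", 18:100] <- NA  # 17 present
  v["at18", 19:100] <- NA  # 18 present
  qm <- quant_matrix(v, cohort = "A")
  f <- filter_matrix(qm, min_present = 18)
  expect_setequal(rownames(f$values), c("at18", "full"))
})

test_that("keyword exclusion removes reference/QC samples, case-insensitively", {
  set.seed(8)
  v <- matrix(rnorm(40 * 6), 40, 6,
              dimnames = list(sprintf("P%02d", 1:40),
                              c("pooled_ref_01", "QC_2", "tumor_1",
                                "normal_1", "RefInt_3", "tumor_2")))
  qm <- quant_matrix(v, cohort = "A")
  f <- filter_matrix(qm, min_present = 1)
  expect_setequal(colnames(f$values), c("tumor_1", "normal_1", "tumor_2"))
})

test_that("filter_matrix is idempotent and identity when nothing matches", {
  qm <- tiny_qm(10, 8, missing = 5, seed = 3)
  f1 <- filter_matrix(qm, min_present = 2, exclude_keywords = "zzz")
  f2 <- filter_matrix(f1, min_present = 2, exclude_keywords = "zzz")
  expect_identical(f1$values, f2$values)
  # nothing to drop at min_present = 0
  f0 <- filter_matrix(qm, min_present = 0, exclude_keywords = "zzz")
  expect_identical(f0$values, qm$values)
})

test_that("missing_fraction counts cells", {
  expect_equal(missing_fraction(tiny_qm(3, 4, missing = 0)), 0)
  expect_equal(missing_fraction(tiny_qm(3, 4, missing = 3)), 0.25)
  v <- matrix(NA_real_, 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_equal(missing_fraction(quant_matrix(v, cohort = "A")), 1)
})

test_that("metadata attaches annotations by sample id", {
  qm <- tiny_qm(4, 4, missing = 0)
  meta <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tcohort\tsample_type\tpatient_id\tplex",
               "s01\tB\ttumor\tpt1\tplex1",
               "s02\tB\tnon_tumor\tpt1\tplex1"), meta)
  qm2 <- attach_metadata(qm, meta)
  expect_equal(qm2$samples$sample_type[1:2], c("tumor", "non_tumor"))
  expect_equal(qm2$samples$cohort, c("B", "B", "cohortA", "cohortA"))
  expect_equal(qm2$samples$patient_id[1:2], c("pt1", "pt1"))
})

test_that("mask_entries hides exactly the flagged cells", {
  qm <- tiny_qm(5, 4, missing = 2, seed = 9)
  mask <- mcar_mask(qm$values, 0.25, seed = 1)
  hidden <- mask_entries(qm, mask)
  expect_true(all(is.na(hidden$values[mask])))
  keep <- !mask & !is.na(qm$values)
  expect_identical(hidden$values[keep], qm$values[keep])
})
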