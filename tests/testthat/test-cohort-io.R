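test_that("TSV expression loading preserves shape and declared transform", {
  v <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  path <- write_expr_tsv(v)
  ex <- read_expression(path, transform = "log2p1")
  expect_equal(dim(ex), c(3L, 2L))
  expect_equal(ex$transform, "log2p1")
  expect_equal(as.matrix(ex), v)
})

test_that("duplicate gene rows collapse by mean with a warning", {
  v <- matrix(c(2, 6, 1, 4, 8, 3), nrow = 3,
              dimnames = list(c("g1", "g1", "g2"), c("s1", "s2")))
  path <- write_expr_tsv(v)
  expect_warning(ex <- read_expression(path, "log2p1"), "duplicated gene")
  expect_equal(as.matrix(ex)["g1", ], c(s1 = 4, s2 = 6))
  expect_equal(as.matrix(ex)["g2", ], c(s1 = 1, s2 = 3))
})

test_that("negative values and duplicate sample ids are hard errors", {
  v <- matrix(c(1, -2, 3, 4), nrow = 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(expression_matrix(v, "linear_tpm"), "g2.*s1")
  v2 <- matrix(1:4, nrow = 2, dimnames = list(c("g1", "g2"), c("s1", "s1")))
  expect_error(expression_matrix(v2, "linear_tpm"), "duplicate sample")
})

test_that("MatrixMarket input with name files loads and matches TSV route", {
  set.seed(1)
  v <- matrix(round(runif(12, 0, 50), 3), nrow = 4,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  mtx <- tempfile(fileext = ".mtx")
  Matrix::writeMM(Matrix::Matrix(v, sparse = TRUE), mtx)
  rows <- tempfile(); writeLines(rownames(v), rows)
  cols <- tempfile(); writeLines(colnames(v), cols)
  ex <- read_expression(mtx, "linear_tpm", rows = rows, cols = cols)
  expect_equal(as.matrix(ex), v)
})

test_that("gzip-compressed TSVs round-trip bit-identically", {
  set.seed(42)
  v <- matrix(rlnorm(20, 1, 1), nrow = 5,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  ex <- expression_matrix(v, "linear_tpm")
  path <- tempfile(fileext = ".tsv.gz")
  write_expression(ex, path)
  ex2 <- read_expression(path, "linear_tpm")
  expect_identical(as.matrix(ex2), as.matrix(ex))
})

test_that("clinical loading collapses substages, fills sentinels, checks ranges", {
  tb <- tibble::tibble(
    sample_id = c("a", "b", "c"),
    gender = c("Female", "MALE", NA),
    cancer_type = "SYN1",
    stage = c("IIIb", "Stage IIa", "??")
  )
  clin <- validate_clinical(tb)
  expect_equal(clin$stage, c("III", "II", "unknown"))
  expect_equal(clin$gender, c("female", "male", "unknown"))
  expect_equal(clin$response, rep("none", 3))
  expect_equal(stage_to_ordinal(c("IIIb", "I", "nope")), c(3L, 1L, NA))
  expect_error(validate_clinical(dplyr::mutate(tb, os_time = c(1, -1, 2))),
               "negative os_time.*'b'")
  expect_error(validate_clinical(dplyr::mutate(tb, os_event = c(0, 1, 2))),
               "os_event")
  expect_error(validate_clinical(tb[, c("sample_id", "gender")]),
               "cancer_type")
})

test_that("response-evaluable filter keeps CR/PR/PD only and is idempotent", {
  clin <- validate_clinical(tiny_clinical(
    letters[1:5], response = c("CR", "PR", "SD", "PD", NA)))
  expect_message(out <- filter_response_evaluable(clin), "removed 2")
  expect_setequal(out$response, c("CR", "PR", "PD"))
  expect_identical(filter_response_evaluable(out), out)
  all_sd <- validate_clinical(tiny_clinical(letters[1:3], response = "SD"))
  expect_warning(expect_message(empty <- filter_response_evaluable(all_sd)),
                 "no response-evaluable")
  expect_equal(nrow(empty), 0)
})

test_that("cohort join restricts to the sorted sample intersection", {
  v <- matrix(seq_len(10) + 0, nrow = 2,
              dimnames = list(c("GA1", "GN1"), c("c", "a", "b", "d", "e")))
  panel <- tiny_panel()[c(1, 3), ]
  clin <- tiny_clinical(c("b", "e", "c", "z"))
  cohort <- join_cohort(expression_matrix(v, "log2p1"), clin, panel)
  expect_equal(colnames(cohort$expr$values), c("b", "c", "e"))
  expect_equal(cohort$clinical$sample_id, c("b", "c", "e"))
  expect_error(join_cohort(expression_matrix(v, "log2p1"),
                           tiny_clinical(c("x", "y")), panel),
               "no sample ids shared")
})

test_that("marker coverage: accepted with warning at threshold, error below", {
  genes <- c(paste0("A", 1:4), "GN1")
  v <- matrix(1, nrow = 5, ncol = 2, dimnames = list(genes, c("s1", "s2")))
  # adaptive type with 8 markers, 4 present -> exactly at 0.5 threshold
  panel <- tibble::tibble(
    cell_type = c(rep("Ta", 8), "Na"),
    gene = c(paste0("A", 1:8), "GN1"),
    compartment = c(rep("adaptive", 8), "innate")
  )
  clin <- tiny_clinical(c("s1", "s2"))
  expect_warning(cohort <- join_cohort(expression_matrix(v, "log2p1"), clin, panel),
                 "incomplete marker coverage")
  expect_equal(cohort$coverage$coverage[cohort$coverage$cell_type == "Ta"], 0.5)
  # zero present markers -> error naming the cell type
  panel0 <- dplyr::bind_rows(panel, tibble::tibble(
    cell_type = "Tb", gene = "NOPE", compartment = "adaptive"))
  expect_error(join_cohort(expression_matrix(v, "log2p1"), clin, panel0), "Tb")
})

test_that("panel validation enforces compartment rules", {
  expect_error(validate_panel(tibble::tibble(
    cell_type = "x", gene = "g", compartment = "weird")), "unknown compartment")
  expect_error(validate_panel(tibble::tibble(
    cell_type = c("x", "x"), gene = c("g1", "g2"),
    compartment = c("adaptive", "innate"))), "constant within")
  panel <- default_panel()
  expect_equal(length(unique(panel$cell_type)), 14)
  expect_equal(length(compartment_cell_types(panel, "adaptive")), 7)
  expect_equal(length(compartment_cell_types(panel, "innate")), 6)
})
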