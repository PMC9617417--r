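test_that("expression TSV round-trips value-exactly and keeps its scale", {
  v <- matrix(c(1, 3, 2, 4), 2, 2,
              dimnames = list(c("gA", "gB"), c("s1", "s2")))
  em <- expression_matrix(v, "fpkm")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(em, path)
  back <- read_expression(path, "fpkm")
  expect_identical(expr_values(back), v)
  expect_identical(expr_scale(back), "fpkm")
})

test_that("duplicate gene rows collapse by per-sample maximum with a warning", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "gA\t1\t9", "gA\t5\t2", "gB\t3\t3"), path)
  expect_warning(em <- read_expression(path, "counts"), "duplicated")
  expect_equal(expr_values(em)["gA", ], c(s1 = 5, s2 = 9))
  expect_equal(nrow(expr_values(em)), 2)
})

test_that("malformed and negative expression cells are rejected by location", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "gA\t1\toops", "gB\t3\t3"), path)
  expect_error(read_expression(path, "counts"), "gA.*s2")
  writeLines(c("gene_id\ts1", "gA\t-2"), path)
  expect_error(read_expression(path, "counts"), "negative")
})

test_that("expression_matrix enforces its invariants", {
  v <- matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(expression_matrix(unname(v) * 1, "counts"), "rownames")
  vv <- v; rownames(vv) <- c("a", "a")
  expect_error(expression_matrix(vv * 1, "counts"), "duplicate gene")
  vv <- v * 1; vv[1, 1] <- NA
  expect_error(expression_matrix(vv, "counts"), "finite")
})

test_that("clinical tables validate rows and required columns", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tos_days\tos_event",
               "s1\t100\t1", "s2\t250\t0", "s3\t40\t1"), path)
  expect_equal(nrow(read_clinical(path)), 3)

  writeLines(c("sample_id\tos_days\tos_event",
               "s1\t100\t1", "s2\t0\t1"), path)
  expect_message(df <- read_clinical(path), "non-positive")
  expect_equal(df$sample_id, "s1")

  writeLines(c("sample_id\tos_days\tos_event", "s1\t100\t2"), path)
  expect_error(read_clinical(path), "os_event")

  writeLines(c("sample_id\tos_days", "s1\t100"), path)
  expect_error(read_clinical(path), "os_event")
})

test_that("align_cohort restricts both objects to the shared samples", {
  v <- matrix(1:6, 2, 3, dimnames = list(c("g1", "g2"), c("A", "B", "C")))
  em <- expression_matrix(v * 1.0, "fpkm")
  clin <- data.frame(sample_id = c("B", "C", "D"), os_days = c(10, 20, 30),
                     os_event = c(1, 0, 1))
  expect_message(al <- align_cohort(em, clin), "2 shared")
  expect_identical(colnames(expr_values(al$expr)), c("B", "C"))
  expect_identical(al$clinical$sample_id, c("B", "C"))

  clin_same <- data.frame(sample_id = c("A", "B", "C"),
                          os_days = c(1, 2, 3), os_event = c(1, 1, 0))
  al2 <- suppressMessages(align_cohort(em, clin_same))
  expect_identical(expr_values(al2$expr), expr_values(em))

  clin_disjoint <- data.frame(sample_id = c("X", "Y"), os_days = c(1, 2),
                              os_event = c(1, 1))
  expect_error(align_cohort(em, clin_disjoint), "no samples shared")
})

test_that("annotation validation enforces class/role pairing and lncRNA flag", {
  df <- data.frame(gene_id = c("g1", "g2"), is_lncrna = c(TRUE, FALSE),
                   mhc1_coding = c(TRUE, FALSE),
                   regulator_class = c("none", "psi"),
                   regulator_role = c("none", "writer"))
  expect_silent(validate_annotation(df))
  bad <- df; bad$regulator_role[2] <- "none"
  expect_error(validate_annotation(bad), "exactly when")
  bad <- df; bad$is_lncrna[1] <- FALSE
  expect_error(validate_annotation(bad), "mhc1_coding")
})

test_that("the bundled regulator table is a valid annotation", {
  path <- system.file("extdata", "regulators.tsv", package = "nascore")
  ann <- read_annotation(path)
  expect_true(all(ann$regulator_class %in% c("psi", "m5C", "m1A")))
  expect_true(all(table(ann$regulator_class) >= 3))
})

test_that("config fingerprints are stable and configuration-sensitive", {
  c1 <- nas_config(seed = 1)
  c2 <- nas_config(seed = 2)
  expect_identical(config_fingerprint(c1), config_fingerprint(nas_config(seed = 1)))
  expect_false(identical(config_fingerprint(c1), config_fingerprint(c2)))
  expect_error(nas_config(k_range = 2:12), "k_range")
  expect_error(nas_config(split_fraction = 1.2))
})
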