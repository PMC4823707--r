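test_that("count tables round-trip through TSV with values, IDs and order intact", {
  m <- tiny_matrix()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(m, path)
  back <- read_count_table(path, group_map = setNames(as.character(sample_groups(m)),
                                                      colnames(counts(m))))
  expect_identical(counts(back), counts(m))
  expect_identical(sample_groups(back), sample_groups(m))
})

test_that("malformed tables are rejected with the offending cell named", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "miR-1\t3\t-3"), path)
  expect_error(read_count_table(path), "miR-1.*s2")

  writeLines(c("gene_id\ts1\ts2", "miR-21\t1\t2", "miR-21\t3\t4"), path)
  expect_error(read_count_table(path), "duplicate gene ID: miR-21")

  writeLines(c("gene_id\ts1\ts2", "miR-1\t1\tx"), path)
  expect_error(read_count_table(path), "non-numeric.*miR-1")

  writeLines(c("gene_id\ts1\ts2", "miR-1\t1\t2"), path)
  expect_error(read_count_table(path, group_map = c(s1 = "A", s9 = "B")),
               "s9")
})

test_that("group sidecar files attach labels and CSV format is accepted", {
  counts_path <- withr::local_tempfile(fileext = ".csv")
  groups_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id,s1,s2,s3", "miR-1,0,1,5", "miR-2,2,3,4"), counts_path)
  writeLines(c("s1\tA", "s2\tA", "s3\tB"), groups_path)
  m <- read_count_table(counts_path, format = "csv", group_map = groups_path)
  expect_equal(as.character(sample_groups(m)), c("A", "A", "B"))
  expect_equal(counts(m)["miR-2", "s2"], 3)
})

test_that("CPM normalization rescales every sample to one million", {
  v <- matrix(c(1, 3, 2, 2, 5e5, 5e5), nrow = 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  m <- normalize_cpm(count_matrix(v))
  expect_equal(counts(m)[, "s1"], c(g1 = 250000, g2 = 750000))
  # a column already at CPM scale is unchanged
  expect_equal(counts(m)[, "s3"], v[, "s3"])
  expect_equal(unname(colSums(counts(m))), rep(1e6, 3), tolerance = 1e-6)

  v0 <- matrix(c(1, 2, 0, 0), 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(normalize_cpm(count_matrix(v0)), "s2")
})

test_that("mean filtering keeps genes strictly above threshold and is idempotent", {
  v <- matrix(rep(c(5, 15), 6), nrow = 2,
              dimnames = list(c("low", "high"), paste0("s", 1:6)))
  m <- count_matrix(v, groups = rep(c("A", "B"), each = 3))
  f <- suppressMessages(filter_by_mean(m, 10))
  expect_identical(rownames(counts(f)), "high")
  f2 <- suppressMessages(filter_by_mean(f, 10))
  expect_identical(counts(f2), counts(f))
  # threshold 0 keeps everything positive
  expect_equal(nrow(counts(suppressMessages(filter_by_mean(m, 0)))), 2L)
})

test_that("per-group filtering requires the threshold in every group", {
  v <- matrix(c(rep(12, 3), rep(8, 3)), nrow = 1,
              dimnames = list("g", paste0("s", 1:6)))
  m <- count_matrix(v, groups = rep(c("A", "B"), each = 3))
  # pooled mean 10 is not > 10; per-group fails in B
  expect_equal(nrow(counts(suppressMessages(suppressWarnings(
    filter_by_mean(m, 10, per_group = TRUE))))), 0L)
  expect_equal(nrow(counts(suppressMessages(suppressWarnings(
    filter_by_mean(m, 9.9))))), 1L)
})

test_that("result tables are written with NA placeholders and a header", {
  df <- data.frame(gene_id = c("a", "b"), p_value = c(0.5, NA))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results_table(df, path)
  lines <- readLines(path)
  expect_equal(lines[1L], "gene_id\tp_value")
  expect_equal(lines[3L], "b\tNA")
  write_results_table(df[0, ], path)
  expect_equal(readLines(path), "gene_id\tp_value")
})

test_that("count_matrix enforces its invariants", {
  v <- matrix(1:4, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(count_matrix(v, groups = c("A")), "one group per sample")
  v2 <- v; rownames(v2) <- c("g1", "g1")
  expect_error(count_matrix(v2), "duplicate gene ID")
  v3 <- v; v3[2, 1] <- -1
  expect_error(count_matrix(v3), "negative value.*g2.*s1")
})
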