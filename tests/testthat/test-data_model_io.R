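test_that("a written dataset round-trips with ids, values and labels intact", {
  data <- make_toy_dataset(3, 4, 0)
  paths <- write_dataset_files(data)
  got <- read_dataset(paths$expr, paths$labels)
  expect_identical(got$gene_ids, data$gene_ids)
  expect_identical(got$sample_ids, data$sample_ids)
  expect_equal(got$values, data$values)
  expect_identical(as.character(got$labels), as.character(data$labels))
  expect_identical(dim(got$values), c(3L, 4L))
})

test_that("reader rejects malformed inputs with informative errors", {
  data <- make_toy_dataset(3, 4, 0)
  dir <- withr::local_tempdir()
  paths <- write_dataset_files(data, dir)

  # label file missing one sample
  lab <- read.table(paths$labels, sep = "\t")
  write.table(lab[-2, ], paths$labels, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  expect_error(read_dataset(paths$expr, paths$labels), "s02")

  # duplicated gene row
  paths <- write_dataset_files(data, dir)
  lines <- readLines(paths$expr)
  writeLines(c(lines, sub("^g03", "g01", lines[4])), paths$expr)
  expect_error(read_dataset(paths$expr, paths$labels), "g01")

  # non-numeric cell names the gene and sample
  paths <- write_dataset_files(data, dir)
  lines <- readLines(paths$expr)
  lines[3] <- sub("\t[0-9.-]+$", "\tnot_a_number", lines[3])
  writeLines(lines, paths$expr)
  expect_error(read_dataset(paths$expr, paths$labels), "g02.*s04")
})

test_that("dataset constructor enforces its invariants", {
  v <- matrix(1:6, 2, 3)
  expect_error(labeled_expression_dataset(v, c("g1", "g1"), c("a", "b", "c"),
                                          c("x", "x", "y")), "g1")
  expect_error(labeled_expression_dataset(v, c("g1", "g2"), c("a", "b", "c"),
                                          c("x", "x")), "label")
  v[1, 1] <- NA
  expect_error(labeled_expression_dataset(v, c("g1", "g2"), c("a", "b", "c"),
                                          c("x", "x", "y")), "missing")
})

test_that("restrict_dataset follows the requested gene and sample order", {
  data <- make_toy_dataset(4, 6, 0)
  sub <- restrict_dataset(data, genes = c("g03", "g01"),
                          samples = c("s05", "s02"))
  expect_identical(sub$gene_ids, c("g03", "g01"))
  expect_identical(rownames(sub$values), c("g03", "g01"))
  expect_equal(sub$values["g03", "s05"], data$values["g03", "s05"])
  expect_error(restrict_dataset(data, genes = "nope"), "nope")
})

test_that("selection reports write one gene per line plus a JSON sidecar", {
  fake <- structure(list(
    p_star = 0.02, k_star = 4L, fallback = FALSE,
    selected_genes = gene_list(sprintf("g%d", 1:5), "test"),
    av_curve = rep(0.9, 200), v_baseline = 0.85, test_accuracy = 0.9,
    seed = 7L, config = list(kernel = "linear")), class = "SelectionResult")
  path <- withr::local_tempfile()
  write_selection_report(fake, path)
  lines <- readLines(path)
  expect_length(lines[nzchar(lines)], 5)
  expect_identical(read_gene_list(path)$gene_ids, fake$selected_genes$gene_ids)
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$p_star, 0.02)
  expect_equal(side$n_selected, 5)

  # empty selection: empty list file plus sidecar, no error
  fake$selected_genes <- gene_list(character(0), "empty")
  expect_silent(write_selection_report(fake, path))
  expect_length(readLines(path), 0)
  expect_true(file.exists(paste0(path, ".json")))
})

test_that("MI matrices round-trip through labeled CSV", {
  m <- mi_matrix_new(matrix(c(0, 0.1, 0.1, 0), 2), c("gA", "gB"), 0.3, "grade1")
  path <- withr::local_tempfile(fileext = ".csv")
  write_mi_matrix(m, path)
  got <- read_mi_matrix(path)
  expect_identical(got$gene_ids, m$gene_ids)
  expect_equal(got$values, m$values)
  expect_equal(got$bandwidth_h, 0.3)
  expect_identical(got$condition_label, "grade1")

  # values preserved to >= 12 significant digits
  set.seed(1)
  A <- matrix(rnorm(25), 5)
  A <- (A + t(A)) / 2
  m2 <- mi_matrix_new(A, paste0("g", 1:5), 0.27, "")
  write_mi_matrix(m2, path)
  expect_lt(max(abs(read_mi_matrix(path)$values - A)),
            max(abs(A)) * 1e-12)
})

test_that("MI matrix reader rejects non-square and mislabeled files", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("gene_id,g1,g2", "g1,0,0.1", "g2,0.1,0", "g3,0.2,0.3"), path)
  expect_error(read_mi_matrix(path), "square")
  writeLines(c("gene_id,g1,g2", "g1,0,0.1", "gX,0.1,0"), path)
  expect_error(read_mi_matrix(path), "match")
  expect_error(mi_matrix_new(matrix(0, 3, 2), paste0("g", 1:3), 1), "square")
  expect_error(mi_matrix_new(matrix(c(0, 1, 0, 0), 2), c("a", "b"), 1),
               "symmetric")
})

test_that("MI statistics tables keep the contrast-report column order", {
  s <- structure(list(mean = 0.1, std = 0.2, n_positive = 3L, n_negative = 1L,
                      n_sign_diff = 2L, min = -0.1, max = 0.5),
                 class = "MIStatsRow")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mi_stats(list(condA = s), path)
  tab <- read.delim(path)
  expect_identical(colnames(tab),
                   c("condition", "mean", "std", "n_positive", "n_negative",
                     "n_sign_diff", "min", "max"))
  expect_equal(tab$n_sign_diff, 2L)
})
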