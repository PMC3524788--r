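test_that("the pair-count rule reproduces max(5, int(500/n + 0.5))", {
  expect_identical(r_rule(33), 15L)
  expect_identical(r_rule(50), 10L)
  expect_identical(r_rule(116), 5L)
  expect_identical(r_rule(500), 5L)
  expect_identical(r_rule(5), 100L)
})

test_that("train/test split is 5:1, stratified and seed-stable", {
  # 139 samples with the 38/90/11 class layout: round(139/6) = 23 held out
  set.seed(1)
  labels <- rep(c("grade1", "grade2", "grade3"), c(38, 90, 11))
  data <- labeled_expression_dataset(matrix(rnorm(2 * 139), 2),
                                     c("g1", "g2"),
                                     sprintf("s%03d", 1:139), labels)
  sp <- split_train_test(data, seed = 5)
  expect_length(sp$test_ids, 23)
  expect_length(sp$train_ids, 116)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)
  # every class present on both sides
  for (side in list(sp$train_ids, sp$test_ids))
    expect_setequal(unique(as.character(data$labels[side])),
                    c("grade1", "grade2", "grade3"))
  expect_identical(split_train_test(data, seed = 5)$test_ids, sp$test_ids)
  expect_false(identical(split_train_test(data, seed = 6)$test_ids,
                         sp$test_ids))

  # 12 balanced samples: 10/2 with one test sample per class
  small <- make_toy_dataset(2, 12, 0)
  sps <- split_train_test(small, seed = 2)
  expect_length(sps$test_ids, 2)
  expect_setequal(unique(as.character(small$labels[sps$test_ids])),
                  c("A", "B"))

  # a class with < 2 samples is rejected
  bad <- labeled_expression_dataset(matrix(rnorm(10), 2), c("g1", "g2"),
                                    paste0("s", 1:5),
                                    c("a", "a", "a", "a", "b"))
  expect_error(split_train_test(bad, 1), "fewer than 2")
})

test_that("training-validation pairs partition S at 4:1, stratified", {
  data <- make_toy_dataset(2, 50, 0)
  pairs <- make_tv_pairs(data, seed = 3)
  expect_length(pairs, 10)                     # r_rule(50)
  for (p in pairs) {
    expect_length(p$validation_ids, 10)        # round(50/5)
    expect_setequal(c(p$train_ids, p$validation_ids), data$sample_ids)
    expect_length(intersect(p$train_ids, p$validation_ids), 0)
    expect_equal(nlevels(droplevels(data$labels[p$train_ids])), 2)
    expect_equal(nlevels(droplevels(data$labels[p$validation_ids])), 2)
  }
  # pairs differ from each other but reproduce under the same seed
  expect_false(identical(pairs[[1]]$validation_ids, pairs[[2]]$validation_ids))
  expect_identical(make_tv_pairs(data, seed = 3)[[4]]$validation_ids,
                   pairs[[4]]$validation_ids)
})

test_that("gene-list unions drop duplicates the way step counts are reported", {
  l1 <- gene_list(sprintf("a%02d", 1:47))
  l2 <- gene_list(c(sprintf("a%02d", 1:2), sprintf("b%02d", 1:25)))
  u <- union_gene_lists(list(l1, l2))
  expect_length(u$gene_ids, 72)                # 47 + 27 - 2 duplicated
  expect_equal(attr(u, "n_duplicates"), 2)
  l3 <- gene_list(c(sprintf("a%02d", 1:4), sprintf("c%02d", 1:21)))
  expect_length(union_gene_lists(list(l1, l3))$gene_ids, 68)  # 47 + 25 - 4
  expect_length(union_gene_lists(list(gene_list(paste0("x", 1:3)),
                                      gene_list(paste0("y", 1:4))))$gene_ids, 7)
})

test_that("the integrated run is deterministic and internally consistent", {
  gen <- generate_labeled_expression(
    planted_signal_spec(40, 4, c(18, 18), effect_size = 2, seed = 21))
  res <- suppressWarnings(run_amfes(gen$data, seed = 31))
  res2 <- suppressWarnings(run_amfes(gen$data, seed = 31))
  expect_identical(res$selected_genes$gene_ids, res2$selected_genes$gene_ids)
  expect_identical(res$av_curve, res2$av_curve)
  expect_identical(res$test_accuracy, res2$test_accuracy)

  # av(p_i) is the arithmetic mean of per-pair validation accuracies
  av_check <- colMeans(res$per_pair_v, na.rm = TRUE)
  av_check[is.nan(av_check)] <- NA_real_
  expect_equal(res$av_curve, av_check)
  expect_true(res$fallback || res$av_curve[res$k_star] >= res$v_baseline)
  # selected genes are a subset of the originals
  expect_true(all(res$selected_genes$gene_ids %in% gen$data$gene_ids))
  expect_error(run_amfes(make_toy_dataset(3, 9, 0, seed = 1) |>
    (\(d) labeled_expression_dataset(d$values, d$gene_ids, d$sample_ids,
                                     rep(c("a", "b", "c"), 3)))(), seed = 1),
    "two classes")
})

test_that("label-independent data yields near-chance test accuracy and a lean selection", {
  accs <- numeric(4)
  lean <- logical(4)
  for (s in 1:4) {
    gen <- generate_labeled_expression(
      planted_signal_spec(60, 0, c(30, 30), effect_size = 0, seed = 500 + s))
    res <- suppressWarnings(run_amfes(gen$data, seed = 600 + s))
    accs[s] <- res$test_accuracy
    lean[s] <- length(res$selected_genes$gene_ids) <= 60 / 2 ||
      res$fallback || res$empty_final_fallback
  }
  expect_lte(abs(mean(accs) - 0.5), 0.15 + 1e-12)  # <= band, float-safe
  expect_true(any(lean))
})

test_that("hierarchical runs select per task and merge without duplicates", {
  set.seed(9)
  labels <- rep(c("c1", "c2", "c3"), c(20, 14, 14))
  vals <- matrix(rnorm(30 * 48), 30, 48)
  vals[1:3, labels != "c1"] <- vals[1:3, labels != "c1"] + 2.5  # c1 vs rest
  vals[4:6, labels == "c3"] <- vals[4:6, labels == "c3"] + 2.5  # c2 vs c3
  data <- labeled_expression_dataset(vals, sprintf("g%02d", 1:30),
                                     sprintf("s%02d", 1:48), labels)
  tasks <- list(hier_task("first", list(low = "c1", high = c("c2", "c3"))),
                hier_task("second", list(mid = "c2", top = "c3")))
  hres <- suppressWarnings(run_hierarchical(data, tasks, seed = 2))
  expect_named(hres$steps, c("first", "second"))
  expect_length(hres$union$gene_ids,
                sum(hres$per_step_counts) - attr(hres$union, "n_duplicates"))
  expect_false(anyDuplicated(hres$union$gene_ids) > 0)
  # second task never sees c1 samples
  second_ids <- c(hres$steps$second$split$train_ids,
                  hres$steps$second$split$test_ids)
  expect_true(all(as.character(data$labels[second_ids]) %in% c("c2", "c3")))
  expect_error(run_hierarchical(data, list(
    hier_task("bad", list(a = "c1", b = "nonexistent"))), seed = 1),
    "bad")
})
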