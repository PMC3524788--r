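#' Number of training-validation pairs for a training set of size n
#'
#' `r = max(5, int(500/n + 0.5))` — more pairs for smaller training sets so
#' the averaged accuracy curve stays stable.
#'
#' @param n number of training samples.
#' @return Integer r.
#' @export
r_rule <- function(n) {
  stopifnot(n >= 1)
  max(5L, as.integer(500 / n + 0.5))
}

# Stratified holdout: pick n_hold sample ids, allocated across classes by
# largest-remainder on class proportions (each class keeps >=1 sample on the
# retained side; held side gets >=1 from a class only if its quota says so,
# except every class with >=2 samples contributes when the quota rounds to 0
# for all).
stratified_holdout <- function(labels, n_hold, seed) {
  labels <- droplevels(factor(labels))
  ids <- names(labels)
  n <- length(labels)
  cls <- levels(labels)
  n_c <- tabulate(labels)
  quota <- n_hold * n_c / n
  base <- floor(quota)
  rem <- quota - base
  extra <- n_hold - sum(base)
  if (extra > 0) {
    ord <- order(-rem, seq_along(cls))
    base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1L
  }
  # never hold out a whole class
  over <- base > n_c - 1L
  if (any(over)) {
    surplus <- sum(base[over] - (n_c[over] - 1L))
    base[over] <- n_c[over] - 1L
    room <- which(!over & base < n_c - 1L)
    for (cc in room) {
      if (surplus <= 0) break
      add <- min(surplus, n_c[cc] - 1L - base[cc])
      base[cc] <- base[cc] + add
      surplus <- surplus - add
    }
  }
  with_seed(seed, {
    held <- character(0)
    for (ci in seq_along(cls)) {
      pool <- ids[labels == cls[ci]]
      if (base[ci] > 0)
        held <- c(held, sample(pool, base[ci]))
    }
    held
  })
}

#' Stratified train/test split at a heuristic 5:1 ratio
#'
#' The test side gets `round(n/6)` samples (at least 1), allocated across
#' classes proportionally (largest remainder), so small classes are present
#' on both sides whenever feasible.
#'
#' @param data a `LabeledExpressionDataset`.
#' @param seed integer seed.
#' @param test_frac fraction held out for testing (default 1/6).
#' @return Class `SplitPlan`: `train_ids`, `test_ids`, `seed`.
#' @export
split_train_test <- function(data, seed, test_frac = 1 / 6) {
  labels <- droplevels(data$labels)
  small <- names(which(table(labels) < 2))
  if (length(small))
    stop("class(es) with fewer than 2 samples: ", paste(small, collapse = ", "))
  n_test <- max(1L, round(length(labels) * test_frac))
  test_ids <- stratified_holdout(labels, n_test, seed)
  train_ids <- setdiff(data$sample_ids, test_ids)
  structure(list(train_ids = train_ids, test_ids = test_ids, seed = seed),
            class = "SplitPlan")
}

#' Split the training set into r stratified training-validation pairs
#'
#' Each pair holds out `round(|S|/5)` samples (at least 1) for validation,
#' stratified by class; the number of pairs follows [r_rule()].
#'
#' @param S_view `LabeledExpressionDataset` restricted to the training
#'   subset S.
#' @param seed integer seed (one sub-seed per pair).
#' @return List of `TrainValidationPair` objects (`pair_index`, `train_ids`,
#'   `validation_ids`).
#' @export
make_tv_pairs <- function(S_view, seed) {
  n <- length(S_view$sample_ids)
  if (n < 5) stop("need at least 5 training samples, got ", n)
  r <- r_rule(n)
  n_val <- max(1L, round(n / 5))
  seeds <- spawn_seeds(seed, paste0("pair", seq_len(r)))
  lapply(seq_len(r), function(q) {
    val <- stratified_holdout(S_view$labels, n_val, seeds[q])
    structure(list(pair_index = q,
                   train_ids = setdiff(S_view$sample_ids, val),
                   validation_ids = val),
              class = "TrainValidationPair")
  })
}

#' Configuration for the integrated selection protocol
#'
#' @param kernel,cost,gamma SVM settings, see [svm_params()].
#' @param m_min,m_max,conv_tol ranking-stage controls, see [score_stage()].
#' @param artificial_method probe construction, see
#'   [generate_artificial_genes()].
#' @param lookahead window width of the stopping rule, see
#'   [select_optimal_subset()].
#' @param test_frac train/test split fraction.
#' @return A list of class `amfes_config`.
#' @export
amfes_config <- function(kernel = "linear", cost = 1, gamma = NULL,
                         m_min = 10, m_max = 200, conv_tol = 0.01,
                         artificial_method = "permute", lookahead = 10,
                         test_frac = 1 / 6) {
  structure(list(svm = svm_params(kernel, cost, gamma),
                 m_min = m_min, m_max = m_max, conv_tol = conv_tol,
                 artificial_method = artificial_method,
                 lookahead = lookahead, test_frac = test_frac),
            class = "amfes_config")
}

#' Run the integrated adaptive feature-selection protocol
#'
#' Splits the samples 5:1 into training/testing, draws r stratified 4:1
#' training-validation pairs from the training subset, and for each pair:
#' augments the training component with probe genes, ranks genes by
#' recursive halving, assigns gene-indices, and scores all 200 nested
#' candidate subsets on the validation component. The per-pair accuracy
#' curves are averaged; the look-ahead stopping rule picks `p*`. A final
#' ranking on all training samples (fresh probes, dedicated seed stream)
#' turns `p*` into one unique gene subset, whose test accuracy is reported
#' alongside the all-gene baseline.
#'
#' @param data a `LabeledExpressionDataset` with exactly two classes.
#' @param config an [amfes_config()].
#' @param seed master integer seed; every random component draws from a
#'   labeled sub-stream of it.
#' @return Class `SelectionResult`: `p_star`, `k_star`, `fallback`,
#'   `selected_genes` (a `GeneList` in final rank order), `av_curve`,
#'   `per_pair_v` (r x 200), `v_baseline`, `test_accuracy`,
#'   `test_accuracy_all_genes`, `split`, `r`, `seed`, `config`.
#' @export
run_amfes <- function(data, config = amfes_config(), seed = 1) {
  stopifnot(inherits(data, "LabeledExpressionDataset"))
  if (nlevels(droplevels(data$labels)) != 2)
    stop("run_amfes expects exactly two classes; use run_hierarchical for more")
  seeds <- spawn_seeds(seed, c("split", "pairs", "pair_work", "final_art",
                               "final_rank"))
  split <- split_train_test(data, seeds["split"], config$test_frac)
  S_view <- restrict_dataset(data, samples = split$train_ids)
  pairs <- make_tv_pairs(S_view, seeds["pairs"])
  r <- length(pairs)
  work_seeds <- spawn_seeds(seeds["pair_work"],
                            c(paste0("art", seq_len(r)),
                              paste0("rank", seq_len(r))))
  vmat <- matrix(NA_real_, r, 200L)
  vbase <- numeric(r)
  for (q in seq_len(r)) {
    tr <- restrict_dataset(S_view, samples = pairs[[q]]$train_ids)
    va <- restrict_dataset(S_view, samples = pairs[[q]]$validation_ids)
    aug <- generate_artificial_genes(tr, work_seeds[paste0("art", q)],
                                     config$artificial_method)
    ranked <- recursive_rank(aug$data$gene_ids, aug$data, config$svm,
                             work_seeds[paste0("rank", q)],
                             m_min = config$m_min, m_max = config$m_max,
                             conv_tol = config$conv_tol)
    idx <- assign_gene_indices(ranked, aug$artificial$artificial_ids)
    cands <- build_candidate_subsets(idx)
    vmat[q, ] <- evaluate_candidates(cands, tr, va, config$svm)
    vbase[q] <- baseline_accuracy(tr, va, config$svm)
  }
  av <- colMeans(vmat, na.rm = TRUE)
  av[is.nan(av)] <- NA_real_
  v_baseline <- mean(vbase)
  sel <- select_optimal_subset(av, v_baseline, config$lookahead)

  # unique subset: re-rank with fresh probes on all of S
  augS <- generate_artificial_genes(S_view, seeds["final_art"],
                                    config$artificial_method)
  rankedS <- recursive_rank(augS$data$gene_ids, augS$data, config$svm,
                            seeds["final_rank"],
                            m_min = config$m_min, m_max = config$m_max,
                            conv_tol = config$conv_tol)
  idxS <- assign_gene_indices(rankedS, augS$artificial$artificial_ids)
  selected <- names(idxS)[unclass(idxS) <= sel$p_star + 1e-12]
  empty_final <- length(selected) == 0
  if (empty_final) selected <- data$gene_ids  # degenerate: keep everything

  T_view_sel <- restrict_dataset(data, genes = selected,
                                 samples = split$test_ids)
  model_sel <- train_svm(restrict_dataset(S_view, genes = selected),
                         config$svm)
  test_acc <- classification_accuracy(model_sel, T_view_sel)
  model_all <- train_svm(S_view, config$svm)
  test_acc_all <- classification_accuracy(
    model_all, restrict_dataset(data, samples = split$test_ids))

  structure(list(p_star = sel$p_star, k_star = sel$k, fallback = sel$fallback,
                 empty_final_fallback = empty_final,
                 selected_genes = gene_list(selected, "adaptive SVM selection"),
                 av_curve = av, per_pair_v = vmat, v_baseline = v_baseline,
                 test_accuracy = test_acc,
                 test_accuracy_all_genes = test_acc_all,
                 split = split, r = r, seed = seed, config = config),
            class = "SelectionResult")
}

#' @export
print.SelectionResult <- function(x, ...) {
  cat("SelectionResult: ", length(x$selected_genes$gene_ids),
      " genes selected at p* = ", format(x$p_star),
      if (x$fallback) " (fallback: full set)", "\n", sep = "")
  cat("baseline validation accuracy:", format(x$v_baseline),
      "| test accuracy:", format(x$test_accuracy),
      "(all genes:", format(x$test_accuracy_all_genes), ")\n")
  invisible(x)
}

#' Define one binary task of a hierarchical classification scheme
#'
#' @param name task label (used in reports and error messages).
#' @param groups named list of exactly two character vectors mapping the
#'   task's two classes to original label values; samples with other labels
#'   are dropped for this task.
#' @return A list of class `hier_task`.
#' @export
hier_task <- function(name, groups) {
  if (length(groups) != 2 || is.null(names(groups)))
    stop("groups must be a named list of exactly two label sets")
  structure(list(name = name, groups = groups), class = "hier_task")
}

#' Hierarchical multi-class selection by a sequence of binary tasks
#'
#' Runs the full selection protocol once per task (for example: class 1
#' versus the rest, then class 2 versus class 3 on the remaining samples)
#' and merges the per-task gene lists into a duplicate-free union.
#'
#' @param data a `LabeledExpressionDataset`.
#' @param tasks list of [hier_task()] objects.
#' @param config an [amfes_config()].
#' @param seed master seed (one sub-stream per task).
#' @return Class `HierarchicalResult`: `steps` (named `SelectionResult`
#'   list), `union` (a `GeneList` with `raw_sum`/`n_duplicates` attributes),
#'   `per_step_counts`.
#' @export
run_hierarchical <- function(data, tasks, config = amfes_config(), seed = 1) {
  stopifnot(length(tasks) >= 1)
  seeds <- spawn_seeds(seed, vapply(tasks, `[[`, "", "name"))
  steps <- list()
  for (t in seq_along(tasks)) {
    task <- tasks[[t]]
    g1 <- task$groups[[1]]
    g2 <- task$groups[[2]]
    lab <- as.character(data$labels)
    keep <- data$sample_ids[lab %in% c(g1, g2)]
    newlab <- ifelse(lab[match(keep, data$sample_ids)] %in% g1,
                     names(task$groups)[1], names(task$groups)[2])
    counts <- table(newlab)
    if (length(counts) < 2 || any(counts < 2))
      stop("task '", task$name, "' has fewer than 2 samples in a class")
    sub <- labeled_expression_dataset(data$values[, keep, drop = FALSE],
                                      data$gene_ids, keep, newlab)
    steps[[task$name]] <- run_amfes(sub, config, seeds[t])
  }
  union <- union_gene_lists(lapply(steps, `[[`, "selected_genes"),
                            "hierarchical union")
  structure(list(steps = steps, union = union,
                 per_step_counts = vapply(steps, function(s)
                   length(s$selected_genes$gene_ids), integer(1))),
            class = "HierarchicalResult")
}

#' @export
print.HierarchicalResult <- function(x, ...) {
  cat("HierarchicalResult:", length(x$steps), "steps\n")
  for (nm in names(x$steps))
    cat("  ", nm, ": ", x$per_step_counts[nm], " genes\n", sep = "")
  cat("union: ", length(x$union$gene_ids), " genes (",
      attr(x$union, "raw_sum"), " raw, ", attr(x$union, "n_duplicates"),
      " duplicates removed)\n", sep = "")
  invisible(x)
}
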