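#' Gene-index of each original gene from a probe-augmented ranking
#'
#' A gene's index is the proportion of artificial probe genes ranked
#' strictly above it: 0 means better than every probe, 1 means worse than
#' all of them. Probes are excluded from the output; the index is monotone
#' non-decreasing down the ranked list.
#'
#' @param ranked character vector of gene ids in descending rank order,
#'   containing both original genes and probes.
#' @param artificial_ids the probe gene ids.
#' @return Named numeric vector (class `GeneIndexAssignment`) over the
#'   original genes, in ranked order.
#' @export
assign_gene_indices <- function(ranked, artificial_ids) {
  is_art <- ranked %in% artificial_ids
  n_art <- sum(is_art)
  if (n_art == 0)
    stop("no artificial probe genes present in the ranking")
  above <- cumsum(is_art)
  idx <- (above / n_art)[!is_art]
  names(idx) <- ranked[!is_art]
  structure(idx, class = "GeneIndexAssignment")
}

#' Build the 200-candidate nested subset grid
#'
#' Subset-index `p_i = i * 0.005` for `i = 1..200`; candidate `B(p_i)`
#' contains the original genes whose gene-index is `<= p_i`. The candidates
#' are nested and `B(1.0)` is the full gene set.
#'
#' @param indices a `GeneIndexAssignment`.
#' @return Class `CandidateSubsets`: list with `i`, `p` and `sets` (a list of
#'   gene-id vectors in ranked order).
#' @export
build_candidate_subsets <- function(indices) {
  if (!length(indices)) stop("empty gene-index assignment")
  p <- seq_len(200L) * 0.005
  sets <- lapply(p, function(pi) names(indices)[unclass(indices) <= pi + 1e-12])
  structure(list(i = seq_len(200L), p = p, sets = sets),
            class = "CandidateSubsets")
}

#' Validation accuracy of every candidate subset
#'
#' Trains an SVM on the training component restricted to each candidate's
#' genes and scores it on the validation component. Empty candidates are
#' left `NA`; identical candidate gene sets (the grid is nested, so runs of
#' `p_i` share a set) are trained once and cached.
#'
#' @param candidates a `CandidateSubsets`.
#' @param train_view,validation_view `LabeledExpressionDataset` components
#'   of one training-validation pair.
#' @param params [svm_params()].
#' @return Numeric vector of length 200 of validation accuracies (`NA` for
#'   empty candidates).
#' @export
evaluate_candidates <- function(candidates, train_view, validation_view,
                                params = svm_params()) {
  v <- rep(NA_real_, 200L)
  cache <- new.env(parent = emptyenv())
  for (i in candidates$i) {
    genes <- candidates$sets[[i]]
    if (!length(genes)) next
    key <- paste(genes, collapse = "\r")
    if (is.null(cache[[key]])) {
      model <- train_svm(restrict_dataset(train_view, genes = genes), params)
      cache[[key]] <- classification_accuracy(
        model, restrict_dataset(validation_view, genes = genes))
    }
    v[i] <- cache[[key]]
  }
  v
}

#' Baseline validation accuracy (all genes)
#'
#' @inheritParams evaluate_candidates
#' @return Validation accuracy of an SVM trained on every gene.
#' @export
baseline_accuracy <- function(train_view, validation_view,
                              params = svm_params()) {
  model <- train_svm(train_view, params)
  classification_accuracy(model, validation_view)
}

#' Look-ahead selection of the optimal subset-index
#'
#' Scans the 200-grid for the first `k` whose (averaged) accuracy is at
#' least the baseline and at least every accuracy in the window
#' `k..k+window` (clipped at the grid end). Unset accuracies (empty
#' candidates) count as `-Inf`. If no index qualifies, the full gene set
#' (`p = 1.0`) is returned with `fallback = TRUE`.
#'
#' @param av numeric vector of length 200 of (averaged) validation
#'   accuracies; `NA` allowed.
#' @param v_baseline baseline accuracy in \[0, 1\].
#' @param window look-ahead width (default 10).
#' @return List with `k` (grid position), `p_star`, `accuracy` and
#'   `fallback`.
#' @export
select_optimal_subset <- function(av, v_baseline, window = 10) {
  if (length(av) != 200L)
    stop("expected a 200-point accuracy grid, got length ", length(av))
  avv <- ifelse(is.na(av), -Inf, av)
  for (k in seq_len(200L)) {
    win <- k:min(k + window, 200L)
    if (avv[k] >= v_baseline && avv[k] >= max(avv[win]))
      return(list(k = k, p_star = k * 0.005, accuracy = av[k],
                  fallback = FALSE))
  }
  list(k = 200L, p_star = 1.0, accuracy = av[200L], fallback = TRUE)
}
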