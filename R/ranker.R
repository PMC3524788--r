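#' Augment a dataset with artificial probe genes
#'
#' One probe per original gene. By default a probe is a label-independent
#' permutation of one original gene's values across samples: it keeps that
#' gene's marginal distribution but destroys any class association, which is
#' what makes the probes a null reference for the gene-index of the
#' selection step. Gaussian probes (matching each gene's mean/sd) are
#' available as an alternative.
#'
#' @param data a `LabeledExpressionDataset`.
#' @param seed integer seed; the augmentation is a pure function of
#'   (data, seed, method).
#' @param method `"permute"` (default) or `"gaussian"`.
#' @return A list with `data` (augmented dataset, probes appended after the
#'   original genes) and `artificial` (class `ArtificialGeneSet`:
#'   `artificial_ids`, `generation_seed`).
#' @export
generate_artificial_genes <- function(data, seed, method = c("permute", "gaussian")) {
  method <- match.arg(method)
  if (!length(data$gene_ids)) stop("dataset has no genes")
  art_ids <- paste0("art.", data$gene_ids)
  clash <- intersect(art_ids, data$gene_ids)
  if (length(clash))
    art_ids <- make.unique(c(data$gene_ids, art_ids))[-seq_along(data$gene_ids)]
  vals <- data$values
  art <- with_seed(seed, {
    if (method == "permute") {
      t(apply(vals, 1, sample))
    } else {
      mu <- rowMeans(vals)
      sdv <- apply(vals, 1, stats::sd)
      mu + sdv * matrix(stats::rnorm(length(vals)), nrow(vals), ncol(vals))
    }
  })
  aug <- labeled_expression_dataset(rbind(vals, art),
                                    c(data$gene_ids, art_ids),
                                    data$sample_ids,
                                    as.character(data$labels))
  list(data = aug,
       artificial = structure(list(artificial_ids = art_ids,
                                   generation_seed = seed),
                              class = "ArtificialGeneSet"))
}

#' Draw random half-size gene subsets for one ranking stage
#'
#' Each of the `m` subsets contains `floor(k/2)` genes sampled without
#' replacement (independently across subsets) from the stage's `k` genes.
#'
#' @param stage_genes character vector of the stage's gene ids (k >= 2).
#' @param m number of subsets.
#' @param seed integer seed.
#' @return List of `SubsetDraw` objects (`subset_id`, `member_genes`).
#' @export
draw_gene_subsets <- function(stage_genes, m, seed) {
  k <- length(stage_genes)
  if (k < 2) stop("need at least 2 genes to draw half-size subsets, got ", k)
  j <- k %/% 2L
  with_seed(seed, lapply(seq_len(m), function(i) {
    structure(list(subset_id = i, member_genes = sample(stage_genes, j)),
              class = "SubsetDraw")
  }))
}

#' Relative-change convergence criterion for ranking-score vectors
#'
#' `||theta_prev - theta_new||^2 / ||theta_prev||^2` (squared Euclidean
#' norms); defined as 0 when `theta_prev` is the zero vector.
#'
#' @param theta_prev,theta_new numeric score vectors of equal length.
#' @return The criterion value.
#' @export
ranking_convergence <- function(theta_prev, theta_new) {
  denom <- sum(theta_prev^2)
  if (denom == 0) return(0)
  sum((theta_prev - theta_new)^2) / denom
}

#' Score one ranking stage by averaged objective-drop weights
#'
#' Trains one SVM per random half-size subset; a gene's score is the mean of
#' its objective-drop weights over the subsets it was drawn into. Subsets are
#' added one at a time beyond `m_min` until the relative change of the score
#' vector falls below `conv_tol`, or `m_max` is reached (then the result is
#' flagged non-converged, with a warning). A gene never drawn into any subset
#' by the time the loop stops gets score 0 with a warning; with
#' `m >= m_min = 10` half-size draws this is vanishingly rare.
#'
#' @param stage_genes gene ids of the stage (k >= 2).
#' @param view `LabeledExpressionDataset` holding these genes (training
#'   component samples only).
#' @param params [svm_params()].
#' @param seed integer seed for the subset draws.
#' @param m_min,m_max minimum/maximum number of subsets.
#' @param conv_tol relative-change threshold (default 0.01).
#' @return Class `GeneScoreVector`: `stage_gene_ids`, `scores` (named),
#'   `m_used`, `converged`.
#' @export
score_stage <- function(stage_genes, view, params = svm_params(), seed = 1,
                        m_min = 10, m_max = 200, conv_tol = 0.01) {
  k <- length(stage_genes)
  if (k < 2) stop("a ranking stage needs at least 2 genes")
  draws <- draw_gene_subsets(stage_genes, m_max, seed)
  sums <- stats::setNames(numeric(k), stage_genes)
  cnts <- stats::setNames(integer(k), stage_genes)
  theta <- function() ifelse(cnts > 0, sums / pmax(cnts, 1L), 0)
  consume <- function(i) {
    genes <- draws[[i]]$member_genes
    model <- train_svm(restrict_dataset(view, genes = genes), params)
    w <- gene_weights(model)
    sums[genes] <<- sums[genes] + w[genes]
    cnts[genes] <<- cnts[genes] + 1L
  }
  for (i in seq_len(min(m_min, m_max))) consume(i)
  m <- min(m_min, m_max)
  theta_prev <- theta()
  converged <- FALSE
  while (m < m_max) {
    m <- m + 1L
    consume(m)
    theta_new <- theta()
    if (ranking_convergence(theta_prev, theta_new) < conv_tol) {
      converged <- TRUE
      theta_prev <- theta_new
      break
    }
    theta_prev <- theta_new
  }
  if (!converged && m >= m_max)
    warning("ranking-score vector did not converge within m_max = ", m_max,
            " subsets", call. = FALSE)
  if (any(cnts == 0))
    warning(sum(cnts == 0), " gene(s) never drawn into any subset; scored 0",
            call. = FALSE)
  structure(list(stage_gene_ids = stage_genes, scores = theta_prev,
                 m_used = m, converged = converged),
            class = "GeneScoreVector")
}

#' Recursive-halving gene ranking
#'
#' All genes are scored and sorted; then only the top `ceiling(k/2)` are
#' re-ranked while the bottom half keeps its current order below them; the
#' halving repeats until at most three genes remain to be ranked. Ties are
#' broken by the incoming order (stable sort), so the output is a
#' deterministic permutation of the input.
#'
#' @param genes gene ids to rank.
#' @param view `LabeledExpressionDataset` holding these genes.
#' @param params [svm_params()].
#' @param seed integer seed (one sub-seed is spawned per stage).
#' @param m_min,m_max,conv_tol stage-scoring controls, see [score_stage()].
#' @return Character vector of gene ids in descending rank order, with
#'   attribute `stages`: per-stage list of `k`, `m_used`, `converged`.
#' @export
recursive_rank <- function(genes, view, params = svm_params(), seed = 1,
                           m_min = 10, m_max = 200, conv_tol = 0.01) {
  genes <- as.character(genes)
  if (!length(genes)) stop("no genes to rank")
  n_stages <- max(1L, ceiling(log2(max(length(genes), 1))) + 1L)
  stage_seeds <- spawn_seeds(seed, paste0("stage", seq_len(n_stages)))
  frozen <- character(0)
  current <- genes
  stages <- list()
  s <- 1L
  repeat {
    k <- length(current)
    if (k == 1) {
      ordered <- current
      stages[[s]] <- list(k = k, m_used = 0L, converged = TRUE)
    } else {
      sv <- score_stage(current, view, params, stage_seeds[s],
                        m_min = m_min, m_max = m_max, conv_tol = conv_tol)
      ordered <- current[order(-sv$scores[current], seq_along(current))]
      stages[[s]] <- list(k = k, m_used = sv$m_used, converged = sv$converged)
    }
    if (k <= 3) {
      out <- c(ordered, frozen)
      break
    }
    top <- ceiling(k / 2)
    frozen <- c(ordered[(top + 1L):k], frozen)
    current <- ordered[seq_len(top)]
    s <- s + 1L
  }
  attr(out, "stages") <- stages
  out
}
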