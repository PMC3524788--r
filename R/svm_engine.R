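#' SVM training parameters
#'
#' @param kernel `"linear"` (default) or `"radial"`.
#' @param cost soft-margin regularization constant C.
#' @param gamma radial-kernel width; default `1/n_genes` at training time.
#' @return A list of class `svm_params`.
#' @export
svm_params <- function(kernel = c("linear", "radial"), cost = 1, gamma = NULL) {
  kernel <- match.arg(kernel)
  stopifnot(is.numeric(cost), cost > 0)
  structure(list(kernel = kernel, cost = cost, gamma = gamma),
            class = "svm_params")
}

kernel_matrix <- function(A, B, kernel, gamma) {
  if (kernel == "linear") return(A %*% t(B))
  # radial: exp(-gamma * ||a-b||^2)
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

dual_objective_from <- function(SV, coefs, kernel, gamma) {
  K <- kernel_matrix(SV, SV, kernel, gamma)
  sum(abs(coefs)) - 0.5 * drop(t(coefs) %*% K %*% coefs)
}

#' Train a binary support-vector classifier on a gene view
#'
#' Genes are standardized (mean 0, variance 1) using statistics of this
#' training view only; the centering/scaling is stored in the model and
#' reapplied to any data scored through [classification_accuracy()] or
#' `predict`. The value of the dual objective at the trained coefficients is
#' recomputed from the stored support vectors and kept in the model.
#'
#' @param view a `LabeledExpressionDataset` restricted to the genes and
#'   samples to train on; must contain both classes.
#' @param params an [svm_params()].
#' @return An object of class `SvmModel` with elements `support_vectors`
#'   (standardized coordinates), `dual_coefficients` (label-signed alphas),
#'   `bias`, `kernel`, `cost`, `gamma`, `trained_gene_ids`, `center`,
#'   `scale` and `objective_value`.
#' @export
train_svm <- function(view, params = svm_params()) {
  y <- droplevels(view$labels)
  if (nlevels(y) < 2)
    stop("training data contain a single class ('", levels(y), "')")
  if (length(view$gene_ids) < 1) stop("no genes to train on")
  X <- t(view$values)  # samples x genes
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (all(scl == 0))
    stop("every gene has zero variance in the training data")
  scl[scl == 0] <- 1
  Xs <- scale(X, center = ctr, scale = scl)
  attr(Xs, "scaled:center") <- NULL
  attr(Xs, "scaled:scale") <- NULL
  gamma <- params$gamma %||% (1 / ncol(Xs))
  fit <- e1071::svm(Xs, y, kernel = params$kernel, cost = params$cost,
                    gamma = gamma, scale = FALSE)
  SV <- unname(as.matrix(fit$SV))
  cf <- as.numeric(fit$coefs)
  obj <- dual_objective_from(SV, cf, params$kernel, gamma)
  structure(list(fit = fit, support_vectors = SV, dual_coefficients = cf,
                 bias = as.numeric(fit$rho), kernel = params$kernel,
                 cost = params$cost, gamma = gamma,
                 trained_gene_ids = view$gene_ids,
                 center = ctr, scale = scl,
                 objective_value = obj),
            class = "SvmModel")
}

#' @export
print.SvmModel <- function(x, ...) {
  cat("SvmModel:", x$kernel, "kernel, C =", x$cost, "|",
      length(x$trained_gene_ids), "genes,",
      nrow(x$support_vectors), "support vectors\n")
  cat("dual objective:", format(x$objective_value), "\n")
  invisible(x)
}

#' Dual objective of a trained SVM, optionally with one gene removed
#'
#' With `excluded_gene = NULL` the stored optimum is returned exactly. With a
#' gene id, the dual objective is re-evaluated at the *fixed* trained
#' coefficients on support vectors from which that gene's coordinate has been
#' dropped — no retraining. Because the coefficients are held fixed, dropping
#' a coordinate can only increase the dual value; the per-gene ranking weight
#' is the magnitude of that change.
#'
#' @param model an `SvmModel`.
#' @param excluded_gene gene id to drop, or `NULL`.
#' @return The dual objective value.
#' @export
dual_objective <- function(model, excluded_gene = NULL) {
  stopifnot(inherits(model, "SvmModel"))
  if (is.null(excluded_gene)) return(model$objective_value)
  g <- match(excluded_gene, model$trained_gene_ids)
  if (is.na(g)) stop("gene '", excluded_gene, "' is not in the trained gene set")
  SV <- model$support_vectors[, -g, drop = FALSE]
  dual_objective_from(SV, model$dual_coefficients, model$kernel, model$gamma)
}

#' Per-gene objective-drop weight
#'
#' The ranking weight of gene g is the absolute change in the dual objective
#' when g's coordinate is dropped from the support vectors at fixed dual
#' coefficients. For the linear kernel this equals half the squared primal
#' weight-vector component, `0.5 * w_g^2`.
#'
#' @param model an `SvmModel`.
#' @param gene a trained gene id.
#' @return A list of class `GeneWeight` with `gene_id` and `weight`.
#' @export
gene_weight <- function(model, gene) {
  w <- abs(dual_objective(model, NULL) - dual_objective(model, gene))
  structure(list(gene_id = gene, weight = w), class = "GeneWeight")
}

#' Objective-drop weights for every trained gene
#'
#' Fast path used by the ranker: for the linear kernel all weights are
#' `0.5 * w_g^2` with `w = t(SV) %*% coefs`, computed in one pass; for other
#' kernels each gene's dual objective is re-evaluated.
#'
#' @param model an `SvmModel`.
#' @return Named numeric vector of weights over `trained_gene_ids`.
#' @export
gene_weights <- function(model) {
  stopifnot(inherits(model, "SvmModel"))
  if (model$kernel == "linear") {
    w <- drop(t(model$support_vectors) %*% model$dual_coefficients)
    return(stats::setNames(0.5 * w^2, model$trained_gene_ids))
  }
  vapply(model$trained_gene_ids,
         function(g) abs(model$objective_value - dual_objective(model, g)),
         numeric(1))
}

#' @export
predict.SvmModel <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "LabeledExpressionDataset"))
  X <- t(newdata$values[object$trained_gene_ids, , drop = FALSE])
  Xs <- scale(X, center = object$center, scale = object$scale)
  attr(Xs, "scaled:center") <- NULL
  attr(Xs, "scaled:scale") <- NULL
  stats::predict(object$fit, Xs)
}

#' Classification accuracy of a trained model on labeled data
#'
#' @param model an `SvmModel`.
#' @param view a `LabeledExpressionDataset` containing the trained genes.
#' @return Fraction of samples whose predicted class equals the label.
#' @export
classification_accuracy <- function(model, view) {
  pred <- predict(model, view)
  mean(as.character(pred) == as.character(view$labels))
}
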