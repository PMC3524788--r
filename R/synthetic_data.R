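#' Specification of a planted-signal expression dataset
#'
#' Describes the simplest structure a margin-based selector must detect:
#' independent Gaussian noise genes plus a small set of informative genes
#' whose class means differ by `effect_size` noise standard deviations.
#'
#' @param n_genes total number of genes.
#' @param n_informative number of class-informative genes
#'   (`<= n_genes`).
#' @param n_samples_per_class length-2 integer vector of per-class sample
#'   counts.
#' @param effect_size class-mean shift of informative genes, in units of
#'   `noise_sd` (>= 0).
#' @param noise_sd Gaussian noise standard deviation (> 0).
#' @param seed integer seed.
#' @return A list of class `PlantedSignalSpec`.
#' @export
planted_signal_spec <- function(n_genes, n_informative, n_samples_per_class,
                                effect_size, noise_sd = 1, seed = 1) {
  stopifnot(n_informative <= n_genes, n_informative >= 0,
            length(n_samples_per_class) == 2, all(n_samples_per_class >= 1),
            effect_size >= 0, noise_sd > 0)
  structure(list(n_genes = as.integer(n_genes),
                 n_informative = as.integer(n_informative),
                 n_samples_per_class = as.integer(n_samples_per_class),
                 effect_size = effect_size, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "PlantedSignalSpec")
}

#' Generate a labeled expression dataset with planted informative genes
#'
#' Noise genes are independent `N(0, noise_sd^2)` in both classes;
#' informative genes additionally have their class-B mean shifted by
#' `effect_size * noise_sd`. Which genes carry the signal is drawn at
#' random (under the spec's seed) and returned for recall scoring.
#'
#' @param spec a [planted_signal_spec()].
#' @return List with `data` (a `LabeledExpressionDataset`, classes
#'   `"classA"`/`"classB"`) and `planted` (character vector of informative
#'   gene ids).
#' @export
generate_labeled_expression <- function(spec) {
  stopifnot(inherits(spec, "PlantedSignalSpec"))
  nA <- spec$n_samples_per_class[1]
  nB <- spec$n_samples_per_class[2]
  n <- nA + nB
  gene_ids <- sprintf("g%03d", seq_len(spec$n_genes))
  sample_ids <- sprintf("s%03d", seq_len(n))
  labels <- rep(c("classA", "classB"), c(nA, nB))
  with_seed(spec$seed, {
    vals <- matrix(stats::rnorm(spec$n_genes * n, sd = spec$noise_sd),
                   spec$n_genes, n)
    planted <- sort(sample(gene_ids, spec$n_informative))
    shift <- spec$effect_size * spec$noise_sd
    vals[match(planted, gene_ids), labels == "classB"] <-
      vals[match(planted, gene_ids), labels == "classB"] + shift
    list(data = labeled_expression_dataset(vals, gene_ids, sample_ids, labels),
         planted = planted)
  })
}

#' Draw a correlated bivariate-normal sample pair
#'
#' Unit variances, correlation `rho`; the fixture for checking the
#' kernel MI estimator against the Gaussian closed form
#' `-0.5 * log(1 - rho^2)`.
#'
#' @param rho correlation, `|rho| < 1`.
#' @param M sample count (>= 2).
#' @param seed integer seed.
#' @return List with numeric vectors `x` and `y` of length M.
#' @export
generate_correlated_pair <- function(rho, M, seed) {
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  stopifnot(M >= 2)
  with_seed(seed, {
    x <- stats::rnorm(M)
    y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(M)
    list(x = x, y = y)
  })
}

#' Generate a random toy network with two agent gene sets
#'
#' Erdos-Renyi graph on `n_nodes` with edge probability `edge_prob`, plus
#' two agent sets drawn at random from the nodes (always nonempty).
#'
#' @param n_nodes node count.
#' @param edge_prob edge probability in \[0, 1\].
#' @param agent_sizes length-2 vector of agent-set sizes.
#' @param seed integer seed.
#' @return List with `edges` (two-column data frame), `nodes`,
#'   `agent_sets` (named list `A1`, `A2`).
#' @export
generate_toy_network <- function(n_nodes, edge_prob, agent_sizes, seed) {
  stopifnot(n_nodes >= 2, edge_prob >= 0, edge_prob <= 1,
            length(agent_sizes) == 2, all(agent_sizes >= 1),
            all(agent_sizes <= n_nodes))
  nodes <- sprintf("n%03d", seq_len(n_nodes))
  with_seed(seed, {
    idx <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
    keep <- stats::runif(nrow(idx)) < edge_prob
    edges <- data.frame(node_a = nodes[idx[keep, 1]],
                        node_b = nodes[idx[keep, 2]],
                        stringsAsFactors = FALSE)
    agent_sets <- list(A1 = sample(nodes, agent_sizes[1]),
                       A2 = sample(nodes, agent_sizes[2]))
    list(edges = edges, nodes = nodes, agent_sets = agent_sets)
  })
}
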