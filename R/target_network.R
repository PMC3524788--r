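#' Build a background target network with named agent gene sets
#'
#' @param edges data frame (or two/three-column matrix) of undirected edges:
#'   columns node_a, node_b and optionally weight. Self-loops are rejected.
#' @param agent_sets named list of nonempty gene-id vectors; every agent
#'   gene must be in the node universe.
#' @param nodes optional extra node ids (lets isolated agent genes exist as
#'   degree-0 nodes).
#' @return Class `TargetNetwork`: `graph` (an igraph), `agent_sets`.
#' @export
build_background_network <- function(edges, agent_sets, nodes = NULL) {
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2) stop("edge list needs at least two columns")
  a <- as.character(edges[[1]])
  b <- as.character(edges[[2]])
  loops <- a == b
  if (any(loops))
    stop("self-loop(s) in edge list: ", paste(unique(a[loops]), collapse = ", "))
  universe <- unique(c(a, b, as.character(nodes %||% character(0))))
  if (!length(agent_sets) || is.null(names(agent_sets)))
    stop("agent_sets must be a named list")
  for (nm in names(agent_sets)) {
    gs <- as.character(agent_sets[[nm]])
    if (!length(gs)) stop("agent set '", nm, "' is empty")
    missing <- setdiff(gs, universe)
    if (length(missing))
      stop("agent gene(s) of '", nm, "' absent from the network: ",
           paste(missing, collapse = ", "))
    agent_sets[[nm]] <- gs
  }
  g <- igraph::graph_from_data_frame(data.frame(from = a, to = b),
                                     directed = FALSE,
                                     vertices = universe)
  if (ncol(edges) >= 3)
    igraph::E(g)$weight <- as.numeric(edges[[3]])
  structure(list(graph = g, agent_sets = agent_sets),
            class = "TargetNetwork")
}

#' @export
print.TargetNetwork <- function(x, ...) {
  cat("TargetNetwork:", igraph::vcount(x$graph), "nodes,",
      igraph::ecount(x$graph), "edges;",
      length(x$agent_sets), "agent sets (",
      paste(names(x$agent_sets), collapse = ", "), ")\n")
  invisible(x)
}

#' Node importance (IP) by principal-component integration of centralities
#'
#' Betweenness, closeness (on the undirected graph, isolated nodes scored 0)
#' and PageRank (damping 0.85) are z-scored, projected onto the first
#' principal component, and shifted so the minimum is a small positive
#' floor (1e-6): the topology score is an IP-weighted average and needs
#' strictly positive weights. The eigenvector sign is fixed so the loading
#' on closeness (falling back to betweenness, then PageRank) is
#' nonnegative, making the scores deterministic.
#'
#' @param net a `TargetNetwork`.
#' @param damping PageRank damping factor.
#' @return Class `IPVector`: `ip` (named positive numeric),
#'   `component_loadings` (named length-3), `centralities` (n x 3 matrix).
#' @export
ip_values <- function(net, damping = 0.85) {
  g <- net$graph
  n <- igraph::vcount(g)
  if (n == 0) stop("empty graph")
  btw <- igraph::betweenness(g, directed = FALSE)
  cls <- suppressWarnings(igraph::closeness(g, mode = "all", normalized = TRUE))
  cls[!is.finite(cls)] <- 0
  pr <- igraph::page_rank(g, damping = damping)$vector
  cen <- cbind(betweenness = btw, closeness = cls, pagerank = pr)
  z <- apply(cen, 2, function(col) {
    # a centrality that is constant up to floating-point noise (regular
    # graphs) must not be z-scored into amplified noise
    s <- stats::sd(col)
    if (s <= 1e-10 * (max(abs(col)) + 1)) rep(0, length(col))
    else (col - mean(col)) / s
  })
  if (all(z == 0)) {
    scores <- rep(0, n)
    loadings <- c(betweenness = 0, closeness = 0, pagerank = 0)
  } else {
    pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
    loadings <- pc$rotation[, 1]
    # deterministic sign: prefer nonnegative closeness loading
    ref <- if (abs(loadings["closeness"]) > 1e-12) loadings["closeness"]
           else if (abs(loadings["betweenness"]) > 1e-12) loadings["betweenness"]
           else loadings["pagerank"]
    if (ref < 0) loadings <- -loadings
    scores <- drop(z %*% loadings)
  }
  ip <- scores - min(scores) + 1e-6
  names(ip) <- igraph::V(g)$name
  structure(list(ip = ip, component_loadings = loadings, centralities = cen),
            class = "IPVector")
}

#' Topology score of an agent gene-set pair
#'
#' IP-weighted average of exponentially decayed minimum shortest-path
#' distances between the two sets, symmetrized:
#' `TS = 1/2 * [sum_i IP1_i exp(-min_j d(i,j)) / sum_i IP1_i +
#'              sum_j IP2_j exp(-min_i d(j,i)) / sum_j IP2_j]`.
#' Distances are unweighted shortest paths on the joint background network;
#' a gene present in both sets is at distance 0, and a gene with no path to
#' the other set contributes `exp(-Inf) = 0`. TS is symmetric under swapping
#' the sets, lies in (0, 1], and equals 1 exactly when every gene of each
#' set is at distance 0 from the other set.
#'
#' @param net a `TargetNetwork`.
#' @param agent_a,agent_b names of agent sets in `net`, or gene-id vectors.
#' @param ip an [ip_values()] result (computed from `net` if `NULL`).
#' @return The topology score.
#' @export
topology_score <- function(net, agent_a, agent_b, ip = NULL) {
  resolve <- function(a) {
    if (length(a) == 1 && a %in% names(net$agent_sets))
      net$agent_sets[[a]] else as.character(a)
  }
  A <- resolve(agent_a)
  B <- resolve(agent_b)
  if (!length(A) || !length(B)) stop("agent sets must be nonempty")
  missing <- setdiff(c(A, B), igraph::V(net$graph)$name)
  if (length(missing))
    stop("agent gene(s) absent from the network: ",
         paste(missing, collapse = ", "))
  if (is.null(ip)) ip <- ip_values(net)
  d <- igraph::distances(net$graph, v = A, to = B, weights = NA)
  half <- function(w, dmin) {
    e <- exp(-dmin)
    e[dmin == Inf] <- 0
    sum(w * e) / sum(w)
  }
  0.5 * (half(ip$ip[A], apply(d, 1, min)) +
         half(ip$ip[B], apply(d, 2, min)))
}

#' Agent score from a phenotype-similarity matrix
#'
#' `AS = sum_{i,j} P_ij / M` where `P_ij` is the similarity of phenotype i
#' of the first agent and phenotype j of the second, and M is the total
#' number of phenotypes.
#'
#' @param similarity numeric matrix (or vector) of pairwise phenotype
#'   similarities in \[0, 1\].
#' @param n_phenotypes M, the total number of phenotypes (>= 1).
#' @return The agent score.
#' @export
agent_score <- function(similarity, n_phenotypes) {
  if (length(n_phenotypes) != 1 || n_phenotypes < 1)
    stop("n_phenotypes must be a positive count")
  sim <- as.numeric(similarity)
  if (any(sim < 0 | sim > 1))
    stop("phenotype similarities must lie in [0, 1]")
  sum(sim) / n_phenotypes
}

#' Cosine similarity of two phenotype feature vectors
#'
#' @param u,v numeric vectors of equal length, not both zero.
#' @return Cosine of the angle between them.
#' @export
cosine_similarity <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity undefined for a zero vector")
  sum(u * v) / (nu * nv)
}

#' Synergy score
#'
#' @param ts topology score.
#' @param as_score agent score.
#' @return `ts * as_score`.
#' @export
synergy_score <- function(ts, as_score) {
  stopifnot(is.finite(ts), is.finite(as_score))
  ts * as_score
}

#' Score and rank agent-set pairs by synergy
#'
#' Computes TS, AS and SS = TS x AS for each requested pair and returns them
#' ranked by SS, descending, ties broken by pair name.
#'
#' @param net a `TargetNetwork`.
#' @param pairs two-column matrix/data frame of agent-set names, or a list
#'   of length-2 character vectors. Default: all unordered pairs of
#'   `net$agent_sets`.
#' @param similarities list (one element per pair) of phenotype-similarity
#'   matrices.
#' @param n_phenotypes vector (recycled) of phenotype counts per pair.
#' @return Class `AgentPairScores` data frame: `agent_a`, `agent_b`, `ts`,
#'   `as_`, `ss`, sorted by `ss` descending.
#' @export
rank_agent_pairs <- function(net, pairs = NULL, similarities, n_phenotypes) {
  if (is.null(pairs)) {
    nm <- names(net$agent_sets)
    if (length(nm) < 2) stop("need at least two agent sets")
    pairs <- t(utils::combn(nm, 2))
  }
  if (is.list(pairs) && !is.data.frame(pairs))
    pairs <- do.call(rbind, pairs)
  pairs <- as.matrix(pairs)
  np <- nrow(pairs)
  if (!is.list(similarities)) similarities <- list(similarities)
  if (length(similarities) != np)
    stop("need one similarity matrix per pair (", np, "), got ",
         length(similarities))
  n_phenotypes <- rep_len(n_phenotypes, np)
  ip <- ip_values(net)
  ts <- numeric(np)
  as_ <- numeric(np)
  for (i in seq_len(np)) {
    ts[i] <- topology_score(net, pairs[i, 1], pairs[i, 2], ip)
    as_[i] <- agent_score(similarities[[i]], n_phenotypes[i])
  }
  ss <- ts * as_
  out <- data.frame(agent_a = pairs[, 1], agent_b = pairs[, 2],
                    ts = ts, as_ = as_, ss = ss,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$ss, out$agent_a, out$agent_b), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("AgentPairScores", "data.frame")
  out
}
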