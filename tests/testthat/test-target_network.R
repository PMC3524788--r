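path3 <- function() {
  build_background_network(data.frame(a = c("a", "b"), b = c("b", "c")),
                           list(A1 = "a", A2 = "c"))
}

uniform_ip <- function(nodes) {
  structure(list(ip = setNames(rep(1, length(nodes)), nodes)),
            class = "IPVector")
}

test_that("background networks validate edges and agent sets", {
  net <- path3()
  expect_equal(igraph::vcount(net$graph), 3)
  expect_equal(igraph::ecount(net$graph), 2)
  expect_error(build_background_network(
    data.frame(a = "x", b = "x"), list(A = "x")), "self-loop")
  expect_error(build_background_network(
    data.frame(a = "a", b = "b"), list(A = "zz")), "zz")
  expect_error(build_background_network(
    data.frame(a = "a", b = "b"), list(A = character(0))), "empty")
  # isolated agent gene retained as a degree-0 node
  iso <- build_background_network(data.frame(a = "a", b = "b"),
                                  list(A = "a", B = "lonely"),
                                  nodes = "lonely")
  expect_equal(igraph::degree(iso$graph)[["lonely"]], 0)
})

test_that("hub of a star dominates the IP score, with closed-form centralities", {
  n <- 7
  edges <- data.frame(a = rep("hub", n - 1), b = paste0("leaf", 1:(n - 1)))
  net <- build_background_network(edges, list(A = "hub"))
  ipv <- ip_values(net)
  cen <- ipv$centralities
  # closed forms for a star on n nodes
  expect_equal(unname(cen["hub", "betweenness"]), (n - 1) * (n - 2) / 2)
  expect_equal(unname(cen["leaf1", "betweenness"]), 0)
  expect_equal(unname(cen["hub", "closeness"]), 1)          # normalized
  expect_true(all(cen["hub", ] > cen["leaf1", ]))
  expect_true(all(ipv$ip["hub"] > ipv$ip[paste0("leaf", 1:(n - 1))]))
  expect_true(all(ipv$ip > 0))
})

test_that("vertex-transitive cycles get equal IP; repeated runs are identical", {
  edges <- data.frame(a = paste0("n", 1:6),
                      b = paste0("n", c(2:6, 1)))
  net <- build_background_network(edges, list(A = "n1"))
  ipv <- ip_values(net)
  expect_lt(diff(range(ipv$ip)), 1e-9)
  expect_identical(ip_values(net)$ip, ipv$ip)
})

test_that("topology score collapses to 1 for identical sets and is symmetric", {
  gen <- generate_toy_network(12, 0.3, c(3, 4), seed = 5)
  net <- build_background_network(gen$edges, gen$agent_sets,
                                  nodes = gen$nodes)
  expect_equal(topology_score(net, "A1", "A1"), 1.0)
  expect_equal(topology_score(net, "A2", "A2"), 1.0)
  ts12 <- topology_score(net, "A1", "A2")
  expect_identical(ts12, topology_score(net, "A2", "A1"))
  expect_gt(ts12, 0)
  expect_lte(ts12, 1)
})

test_that("path endpoints at distance 2 score exp(-2) under uniform IP", {
  net <- path3()
  ts <- topology_score(net, "A1", "A2", ip = uniform_ip(c("a", "b", "c")))
  expect_equal(ts, exp(-2))
})

test_that("topology score decays as cross-set distances grow, vanishing when disconnected", {
  # nested paths: endpoints at distance 2 vs distance 4
  e5 <- data.frame(a = c("a", "b", "c", "d"), b = c("b", "c", "d", "e"))
  net5 <- build_background_network(e5, list(A1 = "a", A2 = "e"))
  ts4 <- topology_score(net5, "A1", "A2",
                        ip = uniform_ip(c("a", "b", "c", "d", "e")))
  expect_equal(ts4, exp(-4))
  expect_gt(exp(-2), ts4)
  # disconnected pair contributes exp(-Inf) = 0
  disc <- build_background_network(data.frame(a = c("a", "x"), b = c("b", "y")),
                                   list(A1 = "a", A2 = "x"))
  ts_disc <- topology_score(disc, "A1", "A2",
                            ip = uniform_ip(c("a", "b", "x", "y")))
  expect_equal(ts_disc, 0)
})

test_that("agent score is the similarity sum over the phenotype count", {
  expect_equal(agent_score(matrix(1, 1, 1), 1), 1.0)
  expect_equal(agent_score(matrix(0.6, 1, 1), 1), 0.6)
  expect_equal(agent_score(matrix(0, 3, 2), 4), 0)
  expect_equal(agent_score(matrix(c(0.2, 0.4, 0.1, 0.3), 2), 5), 0.2)
  expect_error(agent_score(matrix(0.5, 1, 1), 0), "positive")
  expect_error(agent_score(matrix(1.5, 1, 1), 1), "\\[0, 1\\]")
})

test_that("synergy multiplies topology and agent scores, bilinear in AS", {
  expect_equal(synergy_score(0.5, 0.4), 0.2)
  expect_equal(synergy_score(0.9, 0), 0)
  ts <- 0.37
  expect_equal(synergy_score(ts, 3 * 0.2), 3 * synergy_score(ts, 0.2))
})

test_that("pair ranking orders by synergy score like a brute-force sort", {
  gen <- generate_toy_network(10, 0.4, c(2, 2), seed = 8)
  sets <- list(P = gen$agent_sets$A1, Q = gen$agent_sets$A2,
               R = gen$nodes[1:2])
  net <- build_background_network(gen$edges, sets, nodes = gen$nodes)
  sims <- list(matrix(0.9, 1, 1), matrix(0.5, 1, 1), matrix(0.1, 1, 1))
  ranked <- rank_agent_pairs(net, similarities = sims, n_phenotypes = 1)
  expect_equal(nrow(ranked), 3)
  # brute-force: recompute each pair independently and sort
  ip <- ip_values(net)
  manual <- data.frame(
    key = c("P|Q", "P|R", "Q|R"),
    ss = c(topology_score(net, "P", "Q", ip) * 0.9,
           topology_score(net, "P", "R", ip) * 0.5,
           topology_score(net, "Q", "R", ip) * 0.1))
  manual <- manual[order(-manual$ss, manual$key), ]
  expect_equal(paste(ranked$agent_a, ranked$agent_b, sep = "|"), manual$key)
  expect_equal(ranked$ss, manual$ss)
  expect_equal(ranked$ss, ranked$ts * ranked$as_)
})

test_that("cosine similarity behaves on phenotype feature vectors", {
  expect_equal(cosine_similarity(c(1, 0), c(1, 0)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_error(cosine_similarity(c(0, 0), c(1, 0)), "zero vector")
})
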