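# hand-checkable fixtures exercising each metric definition

.net_from_edges <- function(nodes, from, to) {
  igraph::graph_from_data_frame(data.frame(from = from, to = to),
                                directed = TRUE,
                                vertices = data.frame(name = nodes))
}

test_that("a directed 3-chain reproduces hand-computed centralities", {
  g <- .net_from_edges(c("a", "b", "c"), c("a", "b"), c("b", "c"))
  nm <- node_metrics(g)
  expect_equal(nm$betweenness[nm$node == "b"], 0.5)   # 1 / ((3-1)(3-2))
  expect_equal(nm$betweenness[nm$node %in% c("a", "c")], c(0, 0))
  expect_equal(nm$closeness[nm$node == "a"], 1 / 3)   # d = 1 + 2
  # c reaches nothing: both distances replaced by n = 3
  expect_equal(nm$closeness[nm$node == "c"], 1 / 6)
  expect_equal(nm$degree, c(1, 2, 1))
})

test_that("an undirected triangle has clustering 1 everywhere", {
  g <- .net_from_edges(c("a", "b", "c"),
                       c("a", "b", "b", "c", "c", "a"),
                       c("b", "a", "c", "b", "a", "c"))
  expect_equal(node_metrics(g)$clustering, rep(1, 3))
})

test_that("degenerate small graphs follow the stated conventions", {
  g1 <- igraph::make_empty_graph(1, directed = TRUE)
  igraph::V(g1)$name <- "solo"
  m1 <- node_metrics(g1)
  expect_equal(m1$closeness, 0)
  expect_equal(m1$betweenness, 0)
  g2 <- .net_from_edges(c("a", "b"), "a", "b")
  expect_equal(node_metrics(g2)$betweenness, c(0, 0))
})

test_that("graph metrics match enumeration on 2-cycle and 4-chain", {
  cyc <- .net_from_edges(c("a", "b"), c("a", "b"), c("b", "a"))
  gm <- graph_metrics(cyc)
  expect_equal(gm$average_degree, 2)
  expect_equal(gm$average_path_length, 1)
  chain <- .net_from_edges(letters[1:4], letters[1:3], letters[2:4])
  expect_equal(graph_metrics(chain)$average_path_length, 10 / 6)
  expect_equal(graph_metrics(chain)$average_degree, 2 * 3 / 4)
})

test_that("average degree always equals 2E/n on generated networks", {
  withr::local_seed(801)
  for (rep in 1:10) {
    pw <- random_pathway(sprintf("g%d", rep), sample(3:10, 1))
    net <- build_reaction_network(pw, character())
    gm <- graph_metrics(net)
    expect_equal(gm$average_degree, 2 * gm$n_edges / gm$n_nodes)
  }
})

test_that("centralities and APL match exhaustive path enumeration on random digraphs", {
  withr::local_seed(802)
  for (rep in 1:40) {
    g <- random_digraph(sample(2:10, 1), stats::runif(1, 0.1, 0.5))
    ig <- digraph_as_igraph(g)
    nm <- node_metrics(ig)
    expect_equal(stats::setNames(nm$closeness, nm$node),
                 oracle_closeness(g$nodes, g$edges))
    expect_equal(stats::setNames(nm$betweenness, nm$node),
                 oracle_betweenness(g$nodes, g$edges), tolerance = 1e-12)
    expect_equal(suppressWarnings(graph_metrics(ig)$average_path_length),
                 oracle_apl(g$nodes, g$edges))
  }
})

test_that("closeness respects its bounds under the unreachable := n convention", {
  withr::local_seed(803)
  for (rep in 1:20) {
    n <- sample(2:10, 1)
    g <- random_digraph(n, stats::runif(1, 0, 0.6))
    clo <- node_metrics(digraph_as_igraph(g))$closeness
    expect_true(all(clo >= 1 / (n * (n - 1)) - 1e-12))
    expect_true(all(clo <= 1 / (n - 1) + 1e-12))
  }
})

test_that("betweenness is invariant under node relabelling", {
  withr::local_seed(804)
  g <- random_digraph(8, 0.3)
  base <- node_metrics(digraph_as_igraph(g))
  perm <- sample(g$nodes)
  relabel <- stats::setNames(perm, g$nodes)
  g2 <- list(nodes = unname(relabel[g$nodes]),
             edges = data.frame(from = unname(relabel[g$edges$from]),
                                to = unname(relabel[g$edges$to])))
  new <- node_metrics(digraph_as_igraph(g2))
  expect_equal(stats::setNames(new$betweenness, new$node)[unname(relabel[base$node])],
               stats::setNames(base$betweenness, unname(relabel[base$node])))
})

test_that("adding edges never decreases any node's degree", {
  withr::local_seed(805)
  g <- random_digraph(8, 0.2)
  deg1 <- stats::setNames(node_metrics(digraph_as_igraph(g))$degree, g$nodes)
  extra <- data.frame(from = "v01", to = "v05")
  g$edges <- unique(rbind(g$edges, extra))
  deg2 <- stats::setNames(node_metrics(digraph_as_igraph(g))$degree, g$nodes)
  expect_true(all(deg2[names(deg1)] >= deg1))
})

test_that("hub detection keeps the top fraction with ties included", {
  m <- data.frame(node = letters[1:10], degree = 10:1,
                  clustering = 0, closeness = 0, betweenness = 0)
  h <- detect_hubs(m, "degree", 0.2)
  expect_setequal(h$members, c("a", "b"))
  tied <- data.frame(node = letters[1:5], degree = c(5, 5, 5, 1, 1),
                     clustering = 0, closeness = 0, betweenness = 0)
  expect_setequal(detect_hubs(tied, "degree", 0.2)$members, c("a", "b", "c"))
  flat <- data.frame(node = letters[1:4], degree = rep(3, 4),
                     clustering = 0, closeness = 0, betweenness = 0)
  expect_message(hf <- detect_hubs(flat, "degree", 0.25), "every node")
  expect_setequal(hf$members, letters[1:4])
})

test_that("common hubs intersect per metric and across the union of metrics", {
  mk <- function(nodes) structure(list(metric = "degree", members = nodes,
                                       fraction = 0.2, cutoff_value = 1),
                                  class = "hub_set")
  same <- common_hubs(list(o1 = mk(c("x", "y")), o2 = mk(c("x", "y"))))
  expect_setequal(same$degree, c("x", "y"))
  expect_setequal(common_hubs(list(o1 = mk("x"), o2 = mk("y")))$degree,
                  character())
  orgs <- list(
    o1 = list(degree = mk("x"), betweenness = mk(c("y", "z"))),
    o2 = list(degree = mk("w"), betweenness = mk("z")))
  ch <- common_hubs(orgs)
  expect_equal(ch$degree, character(0))
  expect_equal(ch$betweenness, "z")
  expect_setequal(ch$any_metric, "z")
})

test_that("variation across contexts computes sd, z and flags from definitions", {
  mk <- function(deg) data.frame(node = c("R1", "R2"), degree = deg,
                                 clustering = 0, closeness = 0, betweenness = 0)
  same <- variation_across(list(a = mk(c(2, 3)), b = mk(c(2, 3))))
  expect_true(all(same$sd == 0))
  expect_false(any(same$flag_sd))
  ctx <- list(a = mk(c(2, 1)), b = mk(c(2, 1)), c = mk(c(10, 1)))
  vr <- variation_across(ctx, metrics = "degree")
  r1 <- vr[vr$node == "R1", ]
  expect_equal(r1$sd, stats::sd(c(2, 2, 10)))
  expect_equal(r1$max_abs_z, max(abs(c(2, 2, 10) - mean(c(2, 2, 10)))) /
                 stats::sd(c(2, 2, 10)))
  expect_true(r1$flag_sd)
  expect_false(vr$flag_sd[vr$node == "R2"])
  expect_error(variation_across(list(a = mk(c(1, 1)))), "two contexts")
})
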