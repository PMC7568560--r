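test_that("pairwise weights follow the product-over-team-size rule", {
  expect_equal(coauthorship_weight(0.2, 0.2, 10), 0.004)
  expect_equal(coauthorship_weight(0, 5, 3), 0)
  expect_error(coauthorship_weight(1, 1, 1), class = "trialnet_network_error")
  # neighborhood total for an n-author paper with equal scores s grows
  # linearly in n: n(n-1)/2 pairs x s^2/n
  for (n in c(3, 6, 12)) {
    s <- 0.4
    pairs <- utils::combn(n, 2)
    total <- sum(coauthorship_weight(rep(s, ncol(pairs)), s, n))
    expect_equal(total, n * (n - 1) / 2 * s^2 / n)
    expect_equal(total / (n - 1), s^2 / 2)  # linear growth in team size
  }
})

test_that("the multigraph has one edge per author pair per record", {
  corp <- toy_corpus()
  led <- impact_ledger(corp)
  net <- build_network(led, up_to_year = 1995)
  expect_equal(nrow(net$nodes), 3L)
  expect_equal(nrow(net$edges), 3L)

  full <- build_network(led, up_to_year = 2018)
  expect_equal(nrow(full$edges), 3 + 1 + 3)
  # r1 and r3 share Beta_Bob: one component plus none disjoint here
  corp2 <- trial_corpus(dplyr::bind_rows(
    make_record("p1", 2000, c("A_Al", "B_Bo"), citations = 10L),
    make_record("p2", 2001, c("C_Cy", "D_Dee"), citations = 10L)
  ))
  net2 <- build_network(impact_ledger(corp2), 2018)
  expect_equal(igraph::components(net2$graph)$no, 2L)
  expect_equal(largest_component_share(net2), 0.5)
})

test_that("cumulative networks nest across years and grow monotonically", {
  sim <- simulate_corpus(sim_config(seed = 13))
  led <- impact_ledger(sim$corpus,
                       config = sim_impact_config(sim$ground_truth$config))
  years <- c(1990, 2005, 2018)
  nets <- lapply(years, function(y) build_network(led, y))
  for (i in 1:2) {
    expect_true(all(nets[[i]]$nodes$canonical_key %in%
                      nets[[i + 1]]$nodes$canonical_key))
    expect_lte(nrow(nets[[i]]$edges), nrow(nets[[i + 1]]$edges))
  }
  expect_true(all(nets[[3]]$edges$from != nets[[3]]$edges$to))
  expect_true(all(nets[[3]]$edges$weight >= 0))
})

test_that("density counts distinct pairs over n(n-1)/2", {
  expect_equal(round(100 * link_density(30, 12), 1), 45.5)
  expect_equal(round(100 * link_density(697084, 29197), 2), 0.16)
  two <- make_network(tibble::tibble(from = "a", to = "b", weight = 1))
  expect_equal(net_density(two), 1.0)
  # duplicated pairs collapse
  dup <- make_network(tibble::tibble(from = c("a", "a", "b"),
                                     to = c("b", "b", "c"),
                                     weight = c(1, 2, 1)))
  expect_equal(net_density(dup), 2 / 3)
})

test_that("modularity matches direct evaluation of its definition", {
  # all nodes in one community: Q = 1 - 1 = 0
  tri <- make_network(
    tibble::tibble(from = c("a", "b", "c"), to = c("b", "c", "a"),
                   weight = c(1, 2, 3)),
    subspecialty = rep("x", 3))
  expect_equal(net_modularity(tri), 0)

  # two disconnected equal cliques partitioned by clique
  cliques <- make_network(
    tibble::tibble(from = c("a1", "a1", "a2", "b1", "b1", "b2"),
                   to = c("a2", "a3", "a3", "b2", "b3", "b3"),
                   weight = rep(1, 6)),
    subspecialty = rep(c("A", "B"), each = 3))
  expect_equal(net_modularity(cliques),
               oracle_modularity(cliques, cliques$nodes$subspecialty))
  expect_equal(net_modularity(cliques), 0.5)

  # random label shuffles average to about zero (the null has a small
  # negative finite-size bias, so the graph must not be tiny)
  set.seed(401)
  edges <- random_graph_edges(30, p = 0.4)
  labels <- sample(c("A", "B", "C"), 30, replace = TRUE)
  net <- make_network(edges, subspecialty = labels)
  qs <- replicate(300, {
    shuffled <- net
    shuffled$nodes$subspecialty <- sample(shuffled$nodes$subspecialty)
    net_modularity(shuffled)
  })
  expect_lt(abs(mean(qs)), 0.05)
})

test_that("assortativity matches the mixing-matrix formula", {
  # isolated same-category groups: perfect assortativity
  iso <- make_network(
    tibble::tibble(from = c("a1", "b1"), to = c("a2", "b2"),
                   weight = c(1, 3)),
    subspecialty = c("A", "A", "B", "B"),
    nodes = c("a1", "a2", "b1", "b2"))
  expect_equal(net_assortativity(iso), 1)

  # complete bipartite across two categories: perfect disassortativity
  bip <- make_network(
    tibble::tibble(from = c("a1", "a1", "a2", "a2"),
                   to = c("b1", "b2", "b1", "b2"), weight = rep(1, 4)),
    subspecialty = c("A", "A", "B", "B"),
    nodes = c("a1", "a2", "b1", "b2"))
  expect_equal(net_assortativity(bip), -1)

  set.seed(402)
  for (rep in 1:5) {
    edges <- random_graph_edges(8, p = 0.5)
    labels <- sample(c("A", "B", "C"), 8, replace = TRUE)
    net <- make_network(edges, subspecialty = labels)
    if (length(unique(labels)) < 2) next
    expect_equal(net_assortativity(net), oracle_assortativity(net, labels))
  }

  solo <- make_network(tibble::tibble(from = "a", to = "b", weight = 1),
                       subspecialty = c("A", "A"))
  expect_error(net_assortativity(solo), class = "trialnet_network_error")
})

test_that("betweenness matches exhaustive shortest-path enumeration", {
  path3 <- make_network(tibble::tibble(from = c("a", "b"), to = c("b", "c"),
                                       weight = c(1, 1)))
  b <- net_betweenness(path3)
  expect_equal(b$betweenness[b$canonical_key == "b"], 1)
  expect_equal(b$betweenness[b$canonical_key != "b"], c(0, 0))
  expect_equal(b$betweenness_norm[b$canonical_key == "b"], 1)

  star <- make_network(tibble::tibble(from = rep("hub", 4),
                                      to = paste0("leaf", 1:4),
                                      weight = runif(4) + 0.5))
  bs <- net_betweenness(star)
  expect_equal(bs$betweenness[bs$canonical_key == "hub"], choose(4, 2))
  expect_true(all(bs$betweenness[bs$canonical_key != "hub"] == 0))

  set.seed(403)
  for (rep in 1:5) {
    net <- make_network(random_graph_edges(8, p = 0.45))
    got <- net_betweenness(net)
    want <- oracle_betweenness(net)
    expect_equal(got$betweenness, unname(want[got$canonical_key]),
                 tolerance = 1e-10)
  }
})

test_that("pagerank is a probability vector matching power iteration", {
  one <- make_network(tibble::tibble(from = character(), to = character(),
                                     weight = numeric()), nodes = "only")
  expect_equal(net_pagerank(one)$pagerank, 1.0)

  two <- make_network(tibble::tibble(from = "a", to = "b", weight = 2))
  expect_equal(net_pagerank(two)$pagerank, c(0.5, 0.5))

  set.seed(404)
  for (rep in 1:5) {
    net <- make_network(random_graph_edges(8, p = 0.45))
    got <- net_pagerank(net)
    want <- oracle_pagerank(net)
    expect_equal(sum(got$pagerank), 1, tolerance = 1e-9)
    expect_equal(got$pagerank, unname(want[got$canonical_key]),
                 tolerance = 1e-8)
  }
})

test_that("homophily tallies matching co-authors by count or by weight", {
  # ego 'e' with 10 distinct co-authors, 8 sharing its label
  edges <- tibble::tibble(
    from = rep("e", 10), to = sprintf("n%02d", 1:10), weight = rep(1, 10))
  labels <- c("S", rep("S", 8), rep("T", 2))
  net <- make_network(edges, subspecialty = labels,
                      nodes = c("e", sprintf("n%02d", 1:10)))
  hom <- net_homophily(net, "subspecialty", "neighbors")
  expect_equal(hom$homophily[hom$canonical_key == "e"], 0.8)

  # all co-authors match
  all_match <- make_network(
    tibble::tibble(from = c("x", "x"), to = c("y", "z"), weight = c(1, 1)),
    subspecialty = rep("S", 3))
  expect_true(all(net_homophily(all_match, "subspecialty",
                                "neighbors")$homophily == 1))

  # outlinks mode: matched weight 3 of total 4
  wnet <- make_network(
    tibble::tibble(from = c("e", "e"), to = c("m", "u"), weight = c(3, 1)),
    subspecialty = c("S", "S", "T"), nodes = c("e", "m", "u"))
  whom <- net_homophily(wnet, "subspecialty", "outlinks")
  expect_equal(whom$homophily[whom$canonical_key == "e"], 0.75)

  # authors labelled None are excluded from the subspecialty analysis
  with_none <- make_network(
    tibble::tibble(from = c("a", "a"), to = c("b", "c"), weight = c(1, 1)),
    subspecialty = c("S", "S", "None"))
  hn <- net_homophily(with_none, "subspecialty", "neighbors")
  expect_false("c" %in% hn$canonical_key)
  expect_equal(hn$homophily[hn$canonical_key == "a"], 1)
})

test_that("concentration ranks by impact with deterministic tie-breaks", {
  edges <- tibble::tibble(from = c("a", "a", "b"), to = c("b", "c", "c"),
                          weight = rep(1, 3))
  uniform <- make_network(edges, impacts = rep(2, 3))
  res <- concentration(uniform, top_fraction = 0.34)
  expect_equal(res$n_top, 2L)  # ceil(0.34 x 3)
  expect_equal(res$share_impact, 2 / 3)

  skew <- make_network(edges, impacts = c(10, 0, 0))
  res2 <- concentration(skew, top_fraction = 0.4)
  expect_equal(res2$share_impact, 1.0)
  # top 2 by tie-break are a then b; they cover 4 of the 6 edge endpoints
  expect_equal(res2$share_links, 4 / 6)

  set.seed(405)
  net <- make_network(random_graph_edges(9, 0.4),
                      impacts = runif(9))
  res3 <- concentration(net, 0.3)
  k <- ceiling(0.3 * 9)
  ord <- order(-net$nodes$impact, net$nodes$canonical_key)
  top <- net$nodes$canonical_key[ord[1:k]]
  expect_equal(res3$share_links,
               mean(c(net$edges$from, net$edges$to) %in% top))
  expect_equal(res3$share_impact,
               sum(net$nodes$impact[net$nodes$canonical_key %in% top]) /
                 sum(net$nodes$impact))
})

test_that("metric ranges hold across random graphs", {
  set.seed(406)
  for (rep in 1:10) {
    n <- sample(4:9, 1)
    labels <- sample(c("A", "B"), n, replace = TRUE)
    net <- make_network(random_graph_edges(n, 0.5), subspecialty = labels)
    expect_gte(min(net_betweenness(net)$betweenness), 0)
    expect_equal(sum(net_pagerank(net)$pagerank), 1, tolerance = 1e-9)
    q <- net_modularity(net)
    expect_true(q >= -0.5 && q <= 1)
    if (length(unique(labels)) == 2) {
      r <- net_assortativity(net)
      expect_true(r >= -1 - 1e-12 && r <= 1 + 1e-12)
    }
  }
})

test_that("synthetic networks have heavier degree tails than ER controls", {
  ginis <- sapply(1:5, function(s) {
    sim <- simulate_corpus(sim_config(seed = 500 + s))
    led <- impact_ledger(sim$corpus,
                         config = sim_impact_config(sim$ground_truth$config))
    net <- build_network(led, up_to_year = 2018)
    deg <- igraph::degree(net$graph)
    er <- igraph::sample_gnm(igraph::vcount(net$graph),
                             igraph::ecount(net$graph))
    c(obs = gini(deg), er = gini(igraph::degree(er)))
  })
  expect_gt(mean(ginis["obs", ]), mean(ginis["er", ]))
})

test_that("graph export writes node attributes and weights", {
  corp <- toy_corpus()
  led <- impact_ledger(corp)
  net <- build_network(led, 2018, node_attrs = tibble::tibble(
    canonical_key = c("Alpha_Anna", "Beta_Bob"),
    gender = c("woman", "man"), subspecialty = c("breast", "lymphoma")))
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml")
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(back), nrow(net$nodes))
  expect_true("impact" %in% igraph::vertex_attr_names(back))
  expect_true("weight" %in% igraph::edge_attr_names(back))

  el <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, el, "edgelist")
  tab <- readr::read_tsv(el, show_col_types = FALSE)
  expect_equal(nrow(tab), igraph::ecount(net$graph))
})
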