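test_that("degree statistics match closed forms and hand sums", {
  tri <- triangle_graph()
  expect_equal(degree_stats(tri)$avg_degree, 2)
  star <- mknet(edge_tbl(rep("hub", 4), c("l1", "l2", "l3", "l4")))
  expect_equal(degree_stats(star)$avg_degree, 8 / 5)
  wnet <- mknet(edge_tbl(c("a", "a", "b"), c("b", "c", "c"), c(3L, 2L, 7L)))
  wd <- degree_stats(wnet)$nodes
  expect_equal(setNames(wd$weighted_degree, wd$term),
               c(a = 5, b = 10, c = 9))
  expect_error(degree_stats(mknet(edge_tbl(character(), character())[0, ])),
               "no nodes")
})

test_that("average path length counts steps over connected pairs only", {
  path3 <- mknet(edge_tbl(c("a", "b"), c("b", "c")))
  expect_equal(average_path_length(path3), 4 / 3)
  k4 <- mknet(edge_tbl(c("a", "a", "a", "b", "b", "c"),
                       c("b", "c", "d", "c", "d", "d")))
  expect_equal(average_path_length(k4), 1)
  two_edges <- mknet(edge_tbl(c("a", "c"), c("b", "d")))
  expect_equal(average_path_length(two_edges), 1)  # cross pairs excluded
  # agreement with a Floyd-Warshall oracle on random graphs
  for (s in 1:5) {
    net <- random_conet(7, 0.4, seed = s)
    if (nrow(net$edges) == 0) next
    expect_equal(average_path_length(net), path_length_oracle(net))
  }
})

test_that("average clustering follows the triangle count convention", {
  expect_equal(average_clustering(triangle_graph()), 1)
  star <- mknet(edge_tbl(rep("hub", 4), c("l1", "l2", "l3", "l4")))
  expect_equal(average_clustering(star), 0)
  # triangle plus pendant: (1 + 1 + 1/3 + 0) / 4
  tp <- mknet(edge_tbl(c("a", "a", "b", "c"), c("b", "c", "c", "d")))
  expect_equal(average_clustering(tp), (1 + 1 + 1 / 3 + 0) / 4)
})

test_that("betweenness matches exhaustive shortest-path enumeration", {
  path3 <- mknet(edge_tbl(c("a", "b"), c("b", "c")))
  b <- node_betweenness(path3)
  expect_equal(b$betweenness[b$term == "b"], 1)
  k4 <- mknet(edge_tbl(c("a", "a", "a", "b", "b", "c"),
                       c("b", "c", "d", "c", "d", "d")))
  expect_true(all(node_betweenness(k4)$betweenness == 0))
  for (s in 1:6) {
    net <- random_conet(6, 0.45, seed = 100 + s)
    got <- node_betweenness(net)
    oracle <- betweenness_oracle(net)
    expect_equal(setNames(got$betweenness, got$term), oracle,
                 tolerance = 1e-10)
  }
})

test_that("betweenness totals equal summed interior path lengths", {
  for (s in 1:3) {
    net <- random_conet(7, 0.4, seed = 200 + s)
    if (nrow(net$edges) == 0) next
    g <- as_igraph(net)
    d <- igraph::distances(g, weights = NA)
    interior <- d[upper.tri(d)] - 1
    interior <- sum(interior[is.finite(interior) & interior > 0])
    expect_equal(sum(node_betweenness(net)$betweenness), interior)
  }
})

test_that("weak components count isolates as singletons", {
  expect_equal(weak_components(triangle_graph()), 1)
  net <- mknet(edge_tbl(c("a", "c"), c("b", "d")), isolates = "e")
  expect_equal(weak_components(net), 3)
  filtered <- filter_edges(bridge_graph(), 2)
  expect_equal(weak_components(filtered), 6)
})

test_that("modularity matches the brute-force double-sum oracle", {
  tri <- triangle_graph()
  expect_equal(modularity_q(tri, setNames(c(1L, 1L, 1L), c("a", "b", "c"))), 0)
  expect_equal(modularity_q(tri, setNames(1:3, c("a", "b", "c"))), -1 / 3)
  bridge <- bridge_graph()
  memb <- tibble::tibble(term = letters[1:6], community = c(1, 1, 1, 2, 2, 2))
  expect_equal(modularity_q(bridge, memb), 5 / 14)
  withr::with_seed(77, {
    for (s in 1:4) {
      net <- random_conet(sample(4:8, 1), 0.5, seed = 300 + s)
      n <- nrow(net$nodes)
      for (r in 1:25) {
        memb <- setNames(sample.int(3, n, replace = TRUE), net$nodes$term)
        expect_equal(modularity_q(net, memb), modularity_oracle(net, memb),
                     tolerance = 1e-12)
      }
    }
  })
  expect_error(modularity_q(tri, setNames(1L, "a")), "cover")
})

test_that("modularity agrees with igraph on weighted partitions", {
  for (s in 1:4) {
    net <- random_conet(7, 0.5, max_w = 6, seed = 400 + s)
    if (nrow(net$edges) == 0) next
    memb <- withr::with_seed(s, sample.int(3, 7, replace = TRUE))
    names(memb) <- net$nodes$term
    g <- as_igraph(net)
    expect_equal(modularity_q(net, memb),
                 igraph::modularity(g, memb[igraph::V(g)$name],
                                    weights = igraph::E(g)$weight),
                 tolerance = 1e-12)
  }
})

test_that("louvain recovers planted structure and the brute-force optimum", {
  # two disjoint 5-cliques
  clique_edges <- function(terms) {
    idx <- combn(length(terms), 2)
    edge_tbl(terms[idx[1, ]], terms[idx[2, ]])
  }
  cl <- mknet(dplyr::bind_rows(clique_edges(paste0("x", 1:5)),
                               clique_edges(paste0("y", 1:5))))
  lv <- louvain(cl, seed = 1)
  memb <- setNames(lv$membership$community, lv$membership$term)
  expect_length(unique(memb), 2)
  expect_length(unique(memb[paste0("x", 1:5)]), 1)
  expect_length(unique(memb[paste0("y", 1:5)]), 1)

  # bridge graph: brute-force over all 203 partitions says Q* = 5/14
  bridge <- bridge_graph()
  best <- max(purrr::map_dbl(all_partitions(6), function(p) {
    modularity_oracle(bridge, setNames(p, letters[1:6]))
  }))
  expect_equal(best, 5 / 14)
  lv_b <- louvain(bridge, seed = 2)
  expect_equal(lv_b$modularity, 5 / 14)
  # reported Q equals modularity_q of the returned partition exactly
  expect_identical(lv_b$modularity, modularity_q(bridge, lv_b$membership))
})

test_that("louvain is deterministic per seed, Q >= singleton partition", {
  net <- random_conet(8, 0.5, max_w = 4, seed = 55)
  r1 <- louvain(net, seed = 9)
  r2 <- louvain(net, seed = 9)
  expect_identical(r1, r2)
  singletons <- setNames(seq_len(8), net$nodes$term)
  expect_gte(r1$modularity, modularity_q(net, singletons))
  # edgeless convention
  lonely <- mknet(edge_tbl(character(), character())[0, ], isolates = c("a", "b"))
  lv <- louvain(lonely, seed = 1)
  expect_equal(lv$modularity, 0)
  expect_equal(sort(lv$membership$community), 1:2)
})

test_that("map equation matches hand values and the entropy-form oracle", {
  tri <- triangle_graph()
  one <- tibble::tibble(term = c("a", "b", "c"), community = 1)
  expect_equal(map_equation(tri, one), log2(3))
  bridge <- bridge_graph()
  memb <- tibble::tibble(term = letters[1:6], community = c(1, 1, 1, 2, 2, 2))
  expect_equal(map_equation(bridge, memb), 2.32073, tolerance = 1e-5)
  # single-module L is the visit-rate entropy on any graph
  for (s in 1:4) {
    net <- random_conet(7, 0.5, max_w = 5, seed = 500 + s)
    if (nrow(net$edges) == 0) next
    single <- tibble::tibble(term = net$nodes$term, community = 1)
    expect_equal(map_equation(net, single),
                 map_equation_oracle(net, single), tolerance = 1e-12)
    parts <- withr::with_seed(s, sample.int(3, 7, replace = TRUE))
    memb <- tibble::tibble(term = net$nodes$term, community = parts)
    expect_equal(map_equation(net, memb), map_equation_oracle(net, memb),
                 tolerance = 1e-12)
  }
})

test_that("description-length minimisation prefers true modules", {
  clique_edges <- function(terms) {
    idx <- combn(length(terms), 2)
    edge_tbl(terms[idx[1, ]], terms[idx[2, ]])
  }
  # two 5-cliques plus a weak bridge
  cl <- mknet(dplyr::bind_rows(clique_edges(paste0("x", 1:5)),
                               clique_edges(paste0("y", 1:5)),
                               edge_tbl("x1", "y1")))
  res <- minimize_description_length(cl, seed = 1)
  expect_equal(length(unique(res$membership$community)), 2)
  single <- tibble::tibble(term = cl$nodes$term, community = 1)
  expect_lt(res$bits, map_equation(cl, single))
  expect_identical(res$bits, map_equation(cl, res$membership))
  # single edge: one module optimal (enumeration of both partitions)
  e1 <- mknet(edge_tbl("a", "b"))
  both <- map_equation(e1, tibble::tibble(term = c("a", "b"), community = 1:2))
  one <- map_equation(e1, tibble::tibble(term = c("a", "b"), community = 1))
  expect_lte(one, both)
  res1 <- minimize_description_length(e1, seed = 3)
  expect_equal(res1$bits, one)
  # determinism
  expect_identical(minimize_description_length(cl, seed = 4),
                   minimize_description_length(cl, seed = 4))
})

test_that("minimised L never exceeds the single-module L on test graphs", {
  for (s in 1:5) {
    net <- random_conet(8, 0.45, max_w = 4, seed = 600 + s)
    if (nrow(net$edges) == 0) next
    res <- minimize_description_length(net, seed = s)
    single <- tibble::tibble(term = net$nodes$term, community = 1)
    expect_lte(res$bits, map_equation(net, single) + 1e-12)
  }
})

test_that("metrics are invariant under node relabelling", {
  net <- random_conet(7, 0.5, max_w = 5, seed = 700)
  relabel <- setNames(paste0("node_", seq_len(7)), net$nodes$term)
  net2 <- conet(
    tibble::tibble(term = unname(relabel[net$nodes$term]),
                   category = net$nodes$category,
                   frequency = net$nodes$frequency),
    tibble::tibble(from = unname(relabel[net$edges$from]),
                   to = unname(relabel[net$edges$to]),
                   weight = net$edges$weight),
    mode = net$mode)
  expect_equal(average_path_length(net), average_path_length(net2))
  expect_equal(average_clustering(net), average_clustering(net2))
  expect_equal(degree_stats(net)$avg_degree, degree_stats(net2)$avg_degree)
  expect_equal(weak_components(net), weak_components(net2))
  memb1 <- tibble::tibble(term = net$nodes$term, community = rep(1:2, length.out = 7))
  memb2 <- tibble::tibble(term = unname(relabel[memb1$term]),
                          community = memb1$community)
  expect_equal(modularity_q(net, memb1), modularity_q(net2, memb2))
  expect_equal(map_equation(net, memb1), map_equation(net2, memb2))
})

test_that("network_report composes constituent metrics and finds the hub", {
  net <- mknet(edge_tbl(c("a", "a", "b"), c("b", "c", "c"), c(3L, 2L, 7L)))
  rep <- network_report(net, seed = 1)
  expect_equal(rep$n_nodes, 3L)
  expect_equal(rep$n_edges, 3L)
  expect_equal(rep$avg_degree, degree_stats(net)$avg_degree)
  expect_equal(rep$avg_path_length, average_path_length(net))
  expect_equal(rep$avg_clustering, average_clustering(net))
  expect_equal(rep$density, 1)
  expect_equal(rep$hub, "b")  # weighted degrees a=5, b=10, c=9
  # edgeless degenerate input
  lonely <- mknet(edge_tbl(character(), character())[0, ],
                  isolates = c("a", "b"))
  rep0 <- network_report(lonely, seed = 1)
  expect_equal(rep0$modularity, 0)
  expect_equal(rep0$description_length, 0)
  expect_true(is.na(rep0$avg_path_length))
  expect_equal(rep0$n_components, 2L)
})

test_that("the dominant-loading condition becomes the network hub", {
  co <- generate_cohort(cad_cohort_config(n_patients = 2000, seed = 17))
  rep <- network_report(build_monopartite(co, "comorbidity"), seed = 1)
  expect_equal(rep$hub, "Hypertension")
})
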