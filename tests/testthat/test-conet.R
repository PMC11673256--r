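test_that("monopartite weights and frequencies match hand enumeration", {
  co <- toy_cohort()
  net <- build_monopartite(co, "diagnosis")
  e <- dplyr::arrange(net$edges, from, to)
  expect_equal(e$from, c("A", "A"))
  expect_equal(e$to, c("B", "C"))
  expect_equal(e$weight, c(2L, 1L))
  freq <- setNames(net$nodes$frequency, net$nodes$term)
  expect_equal(freq[c("A", "B", "C")], c(A = 3L, B = 2L, C = 1L))
})

test_that("a record with k same-category terms adds all C(k,2) pairs once", {
  co <- new_cohort(tibble::tibble(
    record_id = "r1", sex = "male", age = 60L, admission_year = 2015L,
    diagnoses = "", comorbidities = "A;B;C"))
  net <- build_monopartite(co, "comorbidity")
  expect_equal(nrow(net$edges), 3)
  expect_true(all(net$edges$weight == 1))
  # singleton record: node present, no edges
  single <- new_cohort(tibble::tibble(
    record_id = "r1", sex = "male", age = 60L, admission_year = 2015L,
    diagnoses = "X", comorbidities = ""))
  snet <- build_monopartite(single, "diagnosis")
  expect_equal(snet$nodes$term, "X")
  expect_equal(nrow(snet$edges), 0)
})

test_that("bipartite cross counts match hand enumeration and conservation", {
  co <- toy_cohort()
  net <- build_bipartite(co)
  w <- setNames(net$edges$weight, paste(net$edges$from, net$edges$to))
  # r1 contributes AxH, AxD, BxH, BxD; r2 AxH, BxH; r3 nothing
  expect_equal(sum(net$edges$weight),
               sum(lengths(co$diagnoses) * lengths(co$comorbidities)))
  ah <- net$edges$weight[net$edges$from == "A" & net$edges$to == "H" |
                           net$edges$from == "H" & net$edges$to == "A"]
  expect_equal(ah, 2L)
  # record with an empty side contributes nodes but no edges
  expect_true("C" %in% net$nodes$term)
  expect_false("C" %in% c(net$edges$from, net$edges$to))
  # cross-category only
  cat_of <- setNames(net$nodes$category, net$nodes$term)
  expect_true(all(cat_of[net$edges$from] != cat_of[net$edges$to]))
})

test_that("monopartite conservation: total weight = sum over records of C(k,2)", {
  co <- generate_cohort(cad_cohort_config(n_patients = 120, seed = 8))
  for (cat in c("diagnosis", "comorbidity")) {
    net <- build_monopartite(co, cat)
    col <- if (cat == "diagnosis") co$diagnoses else co$comorbidities
    expect_equal(sum(net$edges$weight),
                 sum(purrr::map_dbl(col, ~ choose(length(.x), 2))))
    # every edge weight bounded by min endpoint frequency
    freq <- setNames(net$nodes$frequency, net$nodes$term)
    expect_true(all(net$edges$weight <=
                      pmin(freq[net$edges$from], freq[net$edges$to])))
  }
})

test_that("network construction is invariant to record and term order", {
  co <- generate_cohort(cad_cohort_config(n_patients = 50, seed = 14))
  shuffled <- co[rev(seq_len(nrow(co))), ]
  shuffled$diagnoses <- purrr::map(shuffled$diagnoses, rev)
  n1 <- build_monopartite(co, "diagnosis")
  n2 <- build_monopartite(new_cohort(shuffled), "diagnosis")
  expect_equal(dplyr::arrange(n1$edges, from, to),
               dplyr::arrange(n2$edges, from, to))
  expect_equal(dplyr::arrange(n1$nodes, term), dplyr::arrange(n2$nodes, term))
})

test_that("edge filtering keeps isolates and composes via max(t1, t2)", {
  net <- mknet(edge_tbl(c("a", "b", "c"), c("b", "c", "d"), c(2L, 5L, 9L)))
  expect_equal(nrow(filter_edges(net, 1)$edges), 3)   # identity threshold
  f5 <- filter_edges(net, 5)
  expect_equal(nrow(f5$edges), 2)
  expect_equal(nrow(f5$nodes), 4)                      # isolates retained
  f99 <- filter_edges(net, 99)
  expect_equal(nrow(f99$edges), 0)
  expect_equal(nrow(f99$nodes), 4)
  expect_equal(filter_edges(filter_edges(net, 2), 5)$edges,
               filter_edges(net, 5)$edges)
})

test_that("networks round-trip through edge/node CSV and export to XML formats", {
  co <- toy_cohort()
  net <- build_bipartite(co)
  ep <- withr::local_tempfile(fileext = ".csv")
  np <- withr::local_tempfile(fileext = ".csv")
  write_conet(net, ep, "edgelist")
  write_conet(net, np, "nodelist")
  back <- read_conet(ep, np, mode = "bipartite")
  expect_equal(dplyr::arrange(back$edges, from, to),
               dplyr::arrange(net$edges, from, to))
  expect_equal(dplyr::arrange(back$nodes, term),
               dplyr::arrange(net$nodes, term))
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_conet(net, gml, "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), nrow(net$nodes))
  expect_equal(igraph::ecount(g), nrow(net$edges))
  gexf <- withr::local_tempfile(fileext = ".gexf")
  write_conet(net, gexf, "gexf")
  txt <- readLines(gexf)
  expect_true(any(grepl("defaultedgetype=\"undirected\"", txt)))
  expect_equal(sum(grepl("<node id=", txt)), nrow(net$nodes))
  expect_equal(sum(grepl("<edge id=", txt)), nrow(net$edges))
})

test_that("invalid networks are rejected", {
  nodes <- tibble::tibble(term = c("a", "b"), category = "diagnosis",
                          frequency = 1L)
  expect_error(conet(nodes, edge_tbl("a", "a"), "diagnosis"), "self-loops")
  expect_error(conet(nodes, edge_tbl("a", "b", 0L), "diagnosis"), "positive")
  expect_error(conet(nodes, edge_tbl("a", "z"), "diagnosis"), "endpoints")
  bip_nodes <- tibble::tibble(term = c("a", "b"), category = "diagnosis",
                              frequency = 1L)
  expect_error(conet(bip_nodes, edge_tbl("a", "b"), "bipartite"),
               "diagnosis and a comorbidity")
})
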