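# Descriptive network metrics. Standard unweighted topology metrics are
# delegated to igraph; community structure comes from community.R.

#' Per-node degree statistics
#'
#' Degree is the number of incident edges; weighted degree the sum of
#' incident edge weights. Averages run over all nodes, isolates
#' included.
#'
#' @param network A non-empty [conet()].
#' @return List with `avg_degree`, `avg_weighted_degree`, and a tibble
#'   `nodes` (`term`, `degree`, `weighted_degree`).
#' @export
degree_stats <- function(network) {
  stopifnot(inherits(network, "conet"))
  if (nrow(network$nodes) == 0) abort("network has no nodes")
  g <- as_igraph(network)
  deg <- igraph::degree(g)
  wdeg <- igraph::strength(g, weights = igraph::E(g)$weight)
  nodes <- tibble(term = igraph::V(g)$name,
                  degree = as.integer(deg),
                  weighted_degree = as.numeric(wdeg))
  list(avg_degree = mean(nodes$degree),
       avg_weighted_degree = mean(nodes$weighted_degree),
       nodes = nodes)
}

#' Average shortest-path length (steps)
#'
#' Unweighted breadth-first shortest paths averaged over all connected
#' unordered node pairs; pairs in different components are excluded and
#' isolates contribute no pairs. Edge weights are co-occurrence counts,
#' not distances, so paths count steps.
#'
#' @param network A [conet()] with at least one edge.
#' @return Mean path length in steps.
#' @export
average_path_length <- function(network) {
  stopifnot(inherits(network, "conet"))
  if (nrow(network$edges) == 0) abort("network has no connected pair of nodes")
  igraph::mean_distance(as_igraph(network), weights = NA, directed = FALSE,
                        unconnected = TRUE)
}

#' Average local clustering coefficient
#'
#' Unweighted local clustering (triangles through a node divided by
#' its potential triangles); nodes of degree < 2 contribute 0; mean
#' over all nodes.
#'
#' @param network A non-empty [conet()].
#' @return Mean clustering coefficient in \[0, 1\].
#' @export
average_clustering <- function(network) {
  stopifnot(inherits(network, "conet"))
  if (nrow(network$nodes) == 0) abort("network has no nodes")
  cc <- igraph::transitivity(as_igraph(network), type = "localundirected",
                             isolates = "zero", weights = NA)
  mean(cc)
}

#' Betweenness centrality
#'
#' Brandes shortest-path betweenness on the unweighted undirected
#' graph: endpoints excluded, unnormalised, each unordered pair counted
#' once.
#'
#' @param network A [conet()].
#' @return Tibble `term`, `betweenness`.
#' @export
node_betweenness <- function(network) {
  stopifnot(inherits(network, "conet"))
  g <- as_igraph(network)
  b <- igraph::betweenness(g, directed = FALSE, weights = NA, normalized = FALSE)
  tibble(term = igraph::V(g)$name, betweenness = as.numeric(b))
}

#' Number of weakly connected components
#'
#' Isolated nodes count as singleton components.
#'
#' @param network A [conet()].
#' @return Integer component count.
#' @export
weak_components <- function(network) {
  stopifnot(inherits(network, "conet"))
  if (nrow(network$nodes) == 0) return(0L)
  igraph::components(as_igraph(network))$no
}

network_density <- function(network) {
  n <- nrow(network$nodes)
  m <- nrow(network$edges)
  if (network$mode == "bipartite") {
    n_dx <- sum(network$nodes$category == "diagnosis")
    n_cm <- n - n_dx
    if (n_dx == 0 || n_cm == 0) return(0)
    m / (n_dx * n_cm)
  } else {
    if (n < 2) return(0)
    2 * m / (n * (n - 1))
  }
}

#' One-row summary report of a network
#'
#' Assembles node/edge counts, average (weighted) degree, density,
#' component count, average path length and clustering, the modularity
#' of the seeded Louvain partition, the minimised two-level
#' map-equation description length, and the hub (node of maximal
#' weighted degree, ties alphabetical). Degenerate inputs degrade
#' gracefully: an edgeless network reports modularity 0, 0 bits and
#' `NA` path length.
#'
#' @param network A [conet()].
#' @param seed Seed forwarded to [louvain()] and
#'   [minimize_description_length()].
#' @param resolution Louvain resolution.
#' @return One-row tibble (class `conet_report` via its attributes
#'   carries both partitions).
#' @export
network_report <- function(network, seed = 1L, resolution = 1) {
  stopifnot(inherits(network, "conet"))
  n <- nrow(network$nodes)
  m <- nrow(network$edges)
  if (n == 0) {
    return(tibble(mode = network$mode, n_nodes = 0L, n_edges = 0L,
                  avg_degree = NA_real_, avg_weighted_degree = NA_real_,
                  density = NA_real_, n_components = 0L,
                  avg_path_length = NA_real_, avg_clustering = NA_real_,
                  modularity = NA_real_, n_communities = 0L,
                  description_length = NA_real_, n_modules = 0L,
                  hub = NA_character_))
  }
  ds <- degree_stats(network)
  lv <- louvain(network, resolution = resolution, seed = seed)
  dl <- minimize_description_length(network, seed = seed)
  hub_pool <- ds$nodes[order(-ds$nodes$weighted_degree, ds$nodes$term), ]
  out <- tibble(
    mode = network$mode,
    n_nodes = n,
    n_edges = m,
    avg_degree = ds$avg_degree,
    avg_weighted_degree = ds$avg_weighted_degree,
    density = network_density(network),
    n_components = weak_components(network),
    avg_path_length = if (m > 0) average_path_length(network) else NA_real_,
    avg_clustering = average_clustering(network),
    modularity = lv$modularity,
    n_communities = length(unique(lv$membership$community)),
    description_length = dl$bits,
    n_modules = length(unique(dl$membership$community)),
    hub = hub_pool$term[1]
  )
  attr(out, "louvain") <- lv$membership
  attr(out, "map_partition") <- dl$membership
  out
}
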