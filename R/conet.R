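#' Co-occurrence network container
#'
#' A `conet` bundles a node table (`term`, `category`, `frequency` =
#' number of records containing the term) and an edge table (`from`,
#' `to`, `weight` = number of records in which both endpoints appear
#' together) with a mode: `"diagnosis"` or `"comorbidity"`
#' (monopartite) or `"bipartite"` (diagnosis-comorbidity cross edges
#' only). Graphs are undirected, without self-loops, and monopartite
#' edges store `from < to` lexicographically.
#'
#' @param nodes Tibble with columns `term`, `category`, `frequency`.
#' @param edges Tibble with columns `from`, `to`, `weight`.
#' @param mode `"diagnosis"`, `"comorbidity"` or `"bipartite"`.
#' @return A `conet` object.
#' @export
conet <- function(nodes, edges, mode = c("diagnosis", "comorbidity", "bipartite")) {
  mode <- match.arg(mode)
  nodes <- as_tibble(nodes)[, c("term", "category", "frequency")]
  if (nrow(edges) == 0) {
    edges <- tibble(from = character(), to = character(), weight = integer())
  }
  edges <- as_tibble(edges)[, c("from", "to", "weight")]
  if (anyDuplicated(nodes$term)) abort("duplicate node terms")
  if (any(edges$from == edges$to)) abort("self-loops are not allowed")
  if (any(edges$weight <= 0)) abort("edge weights must be positive")
  if (!all(c(edges$from, edges$to) %in% nodes$term)) {
    abort("edge endpoints must be nodes")
  }
  if (mode == "bipartite") {
    cat_of <- setNames(nodes$category, nodes$term)
    if (any(cat_of[edges$from] == cat_of[edges$to])) {
      abort("bipartite edges must join a diagnosis and a comorbidity")
    }
  } else {
    swap <- edges$from > edges$to
    tmp <- edges$from[swap]
    edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
  }
  structure(list(mode = mode, nodes = nodes, edges = edges),
            class = "conet")
}

#' @export
print.conet <- function(x, ...) {
  cat(sprintf("<conet: %s mode, %d nodes, %d edges, total weight %d>\n",
              x$mode, nrow(x$nodes), nrow(x$edges), sum(x$edges$weight)))
  invisible(x)
}

count_pairs <- function(term_sets) {
  pairs <- purrr::map(term_sets, function(terms) {
    terms <- sort(terms)
    if (length(terms) < 2) return(NULL)
    idx <- combn(length(terms), 2)
    tibble(from = terms[idx[1, ]], to = terms[idx[2, ]])
  })
  pairs <- dplyr::bind_rows(pairs)
  if (nrow(pairs) == 0) {
    return(tibble(from = character(), to = character(), weight = integer()))
  }
  dplyr::count(pairs, .data$from, .data$to, name = "weight")
}

node_frequencies <- function(term_sets) {
  terms <- unlist(term_sets)
  if (length(terms) == 0) return(tibble(term = character(), frequency = integer()))
  counts <- table(terms)
  tibble(term = names(counts), frequency = as.integer(counts))
}

#' Build a monopartite co-occurrence network
#'
#' An edge joins two terms of the chosen category when they appear
#' together in at least one record; its weight is the number of records
#' in which both appear. Every record contributes at most 1 to each
#' pair (terms are sets within a record). Node frequency counts the
#' records containing the term; nodes that never co-occur remain as
#' isolates.
#'
#' @param cohort A cohort tibble (terms already canonical).
#' @param category `"diagnosis"` or `"comorbidity"`.
#' @return A [conet()].
#' @export
build_monopartite <- function(cohort, category = c("diagnosis", "comorbidity")) {
  category <- match.arg(category)
  cohort <- new_cohort(cohort)
  sets <- cohort[[term_column(category)]]
  nodes <- node_frequencies(sets)
  nodes$category <- category
  conet(nodes[, c("term", "category", "frequency")],
        count_pairs(sets), mode = category)
}

#' Build the bipartite diagnosis-comorbidity network
#'
#' For each record, every (diagnosis, comorbidity) pair present
#' increments the cross-edge by 1; the total edge weight equals
#' \eqn{\sum_r |D_r| \cdot |C_r|}. Same-category pairs never form
#' edges.
#'
#' @param cohort A cohort tibble.
#' @return A [conet()] with `mode = "bipartite"`.
#' @export
build_bipartite <- function(cohort) {
  cohort <- new_cohort(cohort)
  dx <- node_frequencies(cohort$diagnoses)
  dx$category <- "diagnosis"
  cm <- node_frequencies(cohort$comorbidities)
  cm$category <- "comorbidity"
  # terms can legitimately appear in both vocabularies (e.g. myocardial
  # infarction as diagnosis and as comorbidity); disambiguate node ids
  clash <- intersect(dx$term, cm$term)
  if (length(clash) > 0) {
    dx$term <- ifelse(dx$term %in% clash, paste0(dx$term, " [dx]"), dx$term)
    cm$term <- ifelse(cm$term %in% clash, paste0(cm$term, " [cm]"), cm$term)
  }
  rename_terms <- function(terms, suffix) {
    ifelse(terms %in% clash, paste0(terms, suffix), terms)
  }
  pairs <- purrr::map2(cohort$diagnoses, cohort$comorbidities, function(d, co) {
    if (length(d) == 0 || length(co) == 0) return(NULL)
    tidyr::expand_grid(from = rename_terms(d, " [dx]"),
                       to = rename_terms(co, " [cm]"))
  })
  pairs <- dplyr::bind_rows(pairs)
  edges <- if (nrow(pairs) == 0) {
    tibble(from = character(), to = character(), weight = integer())
  } else {
    dplyr::count(pairs, .data$from, .data$to, name = "weight")
  }
  nodes <- dplyr::bind_rows(dx[, c("term", "category", "frequency")],
                            cm[, c("term", "category", "frequency")])
  conet(nodes, edges, mode = "bipartite")
}

#' Filter edges by minimum weight
#'
#' Keeps exactly the edges with `weight >= min_weight`. All nodes are
#' retained — including nodes isolated by the filter, which then count
#' as singleton weakly connected components — and node frequencies are
#' unchanged.
#'
#' @param network A [conet()].
#' @param min_weight Positive integer threshold.
#' @return The filtered `conet`.
#' @export
filter_edges <- function(network, min_weight) {
  stopifnot(inherits(network, "conet"), min_weight >= 1)
  network$edges <- network$edges[network$edges$weight >= min_weight, ]
  network
}

#' Convert a co-occurrence network to igraph
#'
#' @param network A [conet()].
#' @return An undirected weighted [igraph::graph] with vertex
#'   attributes `category` and `frequency`.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "conet"))
  g <- igraph::graph_from_data_frame(
    d = network$edges, directed = FALSE,
    vertices = as.data.frame(network$nodes))
  if (igraph::ecount(g) > 0) {
    igraph::E(g)$weight <- network$edges$weight
  }
  g
}

#' Export a network to disk
#'
#' Writes the edge list and node list as CSV (`source`, `target`,
#' `weight`, `type` / `term`, `category`, `frequency`), or the whole
#' graph as GraphML (via igraph) or GEXF 1.2 for Gephi
#' interoperability.
#'
#' @param network A [conet()].
#' @param path Output path.
#' @param format `"edgelist"`, `"nodelist"`, `"graphml"` or `"gexf"`.
#' @return `path`, invisibly.
#' @export
write_conet <- function(network, path,
                        format = c("edgelist", "nodelist", "graphml", "gexf")) {
  format <- match.arg(format)
  stopifnot(inherits(network, "conet"))
  if (format == "edgelist") {
    readr::write_csv(tibble(source = network$edges$from,
                            target = network$edges$to,
                            weight = network$edges$weight,
                            type = network$mode), path, progress = FALSE)
  } else if (format == "nodelist") {
    readr::write_csv(network$nodes, path, progress = FALSE)
  } else if (format == "graphml") {
    igraph::write_graph(as_igraph(network), path, format = "graphml")
  } else {
    write_gexf(network, path)
  }
  invisible(path)
}

# minimal static GEXF 1.2 writer (undirected weighted graph)
write_gexf <- function(network, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub('"', "&quot;", x, fixed = TRUE)
  }
  ids <- setNames(seq_len(nrow(network$nodes)) - 1L, network$nodes$term)
  node_xml <- sprintf(
    '      <node id="%d" label="%s"><attvalues><attvalue for="0" value="%s"/><attvalue for="1" value="%d"/></attvalues></node>',
    ids, esc(network$nodes$term), esc(network$nodes$category),
    network$nodes$frequency)
  edge_xml <- if (nrow(network$edges) == 0) character() else sprintf(
    '      <edge id="%d" source="%d" target="%d" weight="%d"/>',
    seq_len(nrow(network$edges)) - 1L,
    ids[network$edges$from], ids[network$edges$to], network$edges$weight)
  xml <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">',
    sprintf('  <graph mode="static" defaultedgetype="undirected">'),
    '    <attributes class="node">',
    '      <attribute id="0" title="category" type="string"/>',
    '      <attribute id="1" title="frequency" type="integer"/>',
    '    </attributes>',
    '    <nodes>', node_xml, '    </nodes>',
    '    <edges>', edge_xml, '    </edges>',
    '  </graph>', '</gexf>')
  writeLines(xml, path, useBytes = TRUE)
  invisible(path)
}

#' Read a network back from edge + node CSV
#'
#' @param edge_path,node_path CSV paths written by [write_conet()].
#' @param mode Network mode.
#' @return A [conet()].
#' @export
read_conet <- function(edge_path, node_path,
                       mode = c("diagnosis", "comorbidity", "bipartite")) {
  mode <- match.arg(mode)
  edges <- readr::read_csv(edge_path, col_types = readr::cols(), progress = FALSE)
  nodes <- readr::read_csv(node_path, col_types = readr::cols(), progress = FALSE)
  conet(nodes,
        tibble(from = as.character(edges$source),
               to = as.character(edges$target),
               weight = as.integer(edges$weight)),
        mode = mode)
}
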