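# Shared fixtures and independent brute-force oracles.

# small hand-enumerable cohort: r1 {A,B}/{H,D}, r2 {A,B}/{H}, r3 {A,C}/{}
toy_cohort <- function() {
  new_cohort(tibble::tibble(
    record_id = c("r1", "r2", "r3"),
    sex = c("male", "male", "female"),
    age = c(55L, 63L, 71L),
    admission_year = c(2014L, 2016L, 2019L),
    city = c("Nanning", "Nanning", "Other"),
    diagnoses = list(c("A", "B"), c("A", "B"), c("A", "C")),
    comorbidities = list(c("H", "D"), "H", character())
  ))
}

# build a monopartite conet directly from an edge tibble
mknet <- function(edges, isolates = character(), mode = "diagnosis") {
  terms <- sort(unique(c(edges$from, edges$to, isolates)))
  conet(tibble::tibble(term = terms, category = mode,
                       frequency = rep(1L, length(terms))),
        edges, mode = mode)
}

edge_tbl <- function(from, to, weight = 1L) {
  tibble::tibble(from = from, to = to, weight = as.integer(weight))
}

# two triangles {a,b,c} and {d,e,f} joined by the bridge c-d, unit weights
bridge_graph <- function() {
  mknet(edge_tbl(c("a", "a", "b", "c", "d", "d", "e"),
                 c("b", "c", "c", "d", "e", "f", "f")))
}

triangle_graph <- function() {
  mknet(edge_tbl(c("a", "a", "b"), c("b", "c", "c")))
}

# round-half-up to 2 decimals, the printed-table convention
rhu2 <- function(x) sprintf("%.2f", sign(x) * floor(abs(x) * 100 + 0.5) / 100)

# ---- oracles -------------------------------------------------------------

# modularity as the literal double sum over ordered node pairs
modularity_oracle <- function(network, membership, resolution = 1) {
  terms <- network$nodes$term
  n <- length(terms)
  A <- matrix(0, n, n, dimnames = list(terms, terms))
  e <- network$edges
  for (i in seq_len(nrow(e))) {
    A[e$from[i], e$to[i]] <- A[e$from[i], e$to[i]] + e$weight[i]
    A[e$to[i], e$from[i]] <- A[e$to[i], e$from[i]] + e$weight[i]
  }
  k <- rowSums(A)
  W2 <- sum(A)
  comm <- if (is.data.frame(membership)) {
    setNames(membership$community, membership$term)[terms]
  } else membership[terms]
  q <- 0
  for (u in seq_len(n)) {
    for (v in seq_len(n)) {
      if (comm[u] == comm[v]) {
        q <- q + (A[u, v] - resolution * k[u] * k[v] / W2) / W2
      }
    }
  }
  unname(q)
}

# all set partitions of n elements as restricted growth strings
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxc) {
    i <- length(prefix) + 1
    if (i > n) {
      out[[length(out) + 1]] <<- prefix
      return()
    }
    for (c in seq_len(maxc + 1)) rec(c(prefix, c), max(maxc, c))
  }
  rec(integer(), 0L)
  out
}

# betweenness by exhaustive simple-path enumeration (pure R, no igraph)
betweenness_oracle <- function(network) {
  terms <- network$nodes$term
  n <- length(terms)
  adj <- setNames(vector("list", n), terms)
  e <- network$edges
  for (i in seq_len(nrow(e))) {
    adj[[e$from[i]]] <- c(adj[[e$from[i]]], e$to[i])
    adj[[e$to[i]]] <- c(adj[[e$to[i]]], e$from[i])
  }
  paths_between <- function(s, t) {
    found <- list()
    walk <- function(path) {
      last <- path[length(path)]
      if (last == t) {
        found[[length(found) + 1]] <<- path
        return()
      }
      for (nx in adj[[last]]) if (!nx %in% path) walk(c(path, nx))
    }
    walk(s)
    found
  }
  bw <- setNames(numeric(n), terms)
  for (si in seq_len(n - 1)) {
    for (ti in (si + 1):n) {
      ps <- paths_between(terms[si], terms[ti])
      if (length(ps) == 0) next
      lens <- lengths(ps)
      shortest <- ps[lens == min(lens)]
      for (p in shortest) {
        interior <- p[-c(1, length(p))]
        bw[interior] <- bw[interior] + 1 / length(shortest)
      }
    }
  }
  bw
}

# map equation via the literal entropy form L = q H(Q) + sum p_i H(P^i)
map_equation_oracle <- function(network, membership) {
  e <- network$edges
  W <- sum(e$weight)
  terms <- network$nodes$term
  strength <- setNames(numeric(length(terms)), terms)
  for (i in seq_len(nrow(e))) {
    strength[e$from[i]] <- strength[e$from[i]] + e$weight[i]
    strength[e$to[i]] <- strength[e$to[i]] + e$weight[i]
  }
  p_alpha <- strength / (2 * W)
  comm <- setNames(membership$community, membership$term)[terms]
  H <- function(p) {
    p <- p[p > 0]
    if (length(p) == 0) return(0)
    p <- p / sum(p)
    -sum(p * log2(p))
  }
  labels <- sort(unique(comm))
  q <- purrr::map_dbl(labels, function(l) {
    cross <- (comm[e$from] == l) != (comm[e$to] == l)
    sum(e$weight[cross]) / (2 * W)
  })
  module_term <- purrr::map_dbl(seq_along(labels), function(i) {
    l <- labels[i]
    probs <- c(q[i], p_alpha[comm == l])
    sum(probs) * H(probs)
  })
  sum(q) * H(q) + sum(module_term)
}

# average path length over connected pairs via Floyd-Warshall (steps)
path_length_oracle <- function(network) {
  terms <- network$nodes$term
  n <- length(terms)
  D <- matrix(Inf, n, n, dimnames = list(terms, terms))
  diag(D) <- 0
  e <- network$edges
  for (i in seq_len(nrow(e))) {
    D[e$from[i], e$to[i]] <- 1
    D[e$to[i], e$from[i]] <- 1
  }
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  }
  d <- D[upper.tri(D)]
  mean(d[is.finite(d)])
}

# seeded Erdos-Renyi style random weighted conet
random_conet <- function(n, p_edge, max_w = 5, seed = 1) {
  withr::with_seed(seed, {
    terms <- letters[seq_len(n)]
    pairs <- t(combn(terms, 2))
    keep <- runif(nrow(pairs)) < p_edge
    edges <- tibble::tibble(from = pairs[keep, 1], to = pairs[keep, 2],
                            weight = sample.int(max_w, sum(keep), replace = TRUE))
    mknet(edges, isolates = terms)
  })
}
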