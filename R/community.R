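# Community structure: weighted Newman-Girvan modularity, a seeded
# Louvain optimiser, and the two-level map equation with a Louvain-style
# minimiser. These are implemented here (rather than delegated) because
# the determinism and exact-value contracts of the analysis depend on
# them; igraph's implementations serve as independent cross-checks in
# the test suite.

# ---- internal graph representation ---------------------------------------
# nodes 1..n; `nb`/`wt` adjacency lists excluding self-loops; `self`
# per-node self-loop weight (arises from aggregation); `k` weighted
# degree (self-loops count twice); `W` total edge weight.

igraph_internal <- function(network) {
  terms <- network$nodes$term
  n <- length(terms)
  id <- setNames(seq_len(n), terms)
  e <- network$edges
  from_internal_edges(n, id[e$from], id[e$to], as.numeric(e$weight),
                      terms = terms)
}

from_internal_edges <- function(n, ei, ej, ew, terms = NULL) {
  nb <- vector("list", n)
  wt <- vector("list", n)
  self <- numeric(n)
  for (idx in seq_along(ei)) {
    i <- ei[idx]; j <- ej[idx]; w <- ew[idx]
    if (i == j) {
      self[i] <- self[i] + w
    } else {
      nb[[i]] <- c(nb[[i]], j); wt[[i]] <- c(wt[[i]], w)
      nb[[j]] <- c(nb[[j]], i); wt[[j]] <- c(wt[[j]], w)
    }
  }
  k <- purrr::map_dbl(wt, ~ sum(.x %||% 0)) + 2 * self
  W <- sum(ew)
  list(n = n, nb = nb, wt = wt, self = self, k = k, W = W, terms = terms)
}

# membership as integer vector over g's nodes -> aggregated graph
aggregate_graph <- function(g, comm) {
  labels <- sort(unique(comm))
  remap <- match(comm, labels)
  m <- length(labels)
  acc <- new.env(parent = emptyenv())
  add_edge <- function(i, j, w) {
    key <- if (i <= j) paste0(i, "_", j) else paste0(j, "_", i)
    acc[[key]] <- (acc[[key]] %||% 0) + w
  }
  for (i in seq_len(g$n)) {
    if (g$self[i] > 0) add_edge(remap[i], remap[i], g$self[i])
    nbi <- g$nb[[i]]
    for (t in seq_along(nbi)) {
      j <- nbi[t]
      if (i < j) add_edge(remap[i], remap[j], g$wt[[i]][t])
    }
  }
  keys <- ls(acc)
  if (length(keys) == 0) {
    return(list(graph = from_internal_edges(m, integer(), integer(), numeric()),
                remap = remap))
  }
  parts <- stringr::str_split_fixed(keys, "_", 2)
  list(graph = from_internal_edges(m, as.integer(parts[, 1]),
                                   as.integer(parts[, 2]),
                                   purrr::map_dbl(keys, ~ acc[[.x]])),
       remap = remap)
}

relabel_contiguous <- function(comm) {
  match(comm, unique(comm))
}

# ---- modularity ----------------------------------------------------------

#' Weighted Newman-Girvan modularity of a partition
#'
#' \deqn{Q = \sum_c \left[\frac{W_c}{W} -
#'   \gamma\left(\frac{S_c}{2W}\right)^2\right]}
#' with \eqn{W} the total edge weight, \eqn{W_c} the intra-community
#' weight, \eqn{S_c} the community's weighted-degree sum and
#' \eqn{\gamma} the resolution (default 1). An edgeless network scores
#' 0 by convention.
#'
#' @param network A [conet()].
#' @param membership Community assignment: a named integer vector
#'   (names = node terms) or a tibble with columns `term`,
#'   `community`. Every node must be assigned.
#' @param resolution Resolution parameter \eqn{\gamma}.
#' @return Modularity Q (scalar).
#' @export
modularity_q <- function(network, membership, resolution = 1) {
  stopifnot(inherits(network, "conet"))
  comm <- membership_vector(network, membership)
  W <- sum(network$edges$weight)
  if (W == 0) return(0)
  e <- network$edges
  strength <- setNames(numeric(nrow(network$nodes)), network$nodes$term)
  for (i in seq_len(nrow(e))) {
    strength[e$from[i]] <- strength[e$from[i]] + e$weight[i]
    strength[e$to[i]] <- strength[e$to[i]] + e$weight[i]
  }
  S_c <- tapply(strength, comm[names(strength)], sum)
  intra_c <- numeric(length(S_c))
  names(intra_c) <- names(S_c)
  same <- comm[e$from] == comm[e$to]
  if (any(same)) {
    ic <- tapply(e$weight[same], comm[e$from][same], sum)
    intra_c[names(ic)] <- ic
  }
  sum(intra_c / W - resolution * (S_c / (2 * W))^2)
}

membership_vector <- function(network, membership) {
  terms <- network$nodes$term
  if (is.data.frame(membership)) {
    stopifnot(all(c("term", "community") %in% names(membership)))
    comm <- setNames(membership$community, membership$term)
  } else {
    comm <- membership
  }
  missing_nodes <- setdiff(terms, names(comm))
  if (length(missing_nodes) > 0) {
    abort(paste0("partition does not cover node(s): ",
                 paste(missing_nodes, collapse = ", ")))
  }
  as.integer(comm[terms]) |> setNames(terms)
}

# ---- Louvain -------------------------------------------------------------

# one local-move phase; returns updated comm and whether anything moved
louvain_local_moves <- function(g, comm, resolution, order) {
  W2 <- 2 * g$W
  S <- numeric(max(comm))
  for (i in seq_len(g$n)) S[comm[i]] <- S[comm[i]] + g$k[i]
  moved_any <- FALSE
  repeat {
    moved <- FALSE
    for (i in order) {
      ci <- comm[i]
      nbi <- g$nb[[i]]
      if (length(nbi) == 0) next
      S[ci] <- S[ci] - g$k[i]
      # weight from i to each neighbouring community
      wc <- tapply(g$wt[[i]], comm[nbi], sum)
      cand <- as.integer(names(wc))
      # gain of joining community c (common factor 1/W dropped)
      gains <- as.numeric(wc) - resolution * S[cand] * g$k[i] / W2
      w_to_ci <- if (ci %in% cand) wc[[as.character(ci)]] else 0
      best_gain <- w_to_ci - resolution * S[ci] * g$k[i] / W2
      best_c <- ci
      for (t in seq_along(cand)) {
        if (gains[t] > best_gain + 1e-12) {
          best_gain <- gains[t]
          best_c <- cand[t]
        }
      }
      S[best_c] <- S[best_c] + g$k[i]
      if (best_c != ci) {
        comm[i] <- best_c
        moved <- TRUE
        moved_any <- TRUE
      }
    }
    if (!moved) break
  }
  list(comm = comm, moved = moved_any)
}

#' Louvain community detection (seeded, weighted)
#'
#' Greedy two-phase optimisation of weighted modularity: repeated local
#' node moves to the neighbouring community with the largest modularity
#' gain, followed by aggregation of communities into super-nodes, until
#' no further improvement. The node visit order is shuffled once per
#' level from `seed`, making the result fully deterministic for a given
#' seed; ties keep the first-encountered best community.
#'
#' @param network A [conet()].
#' @param resolution Resolution parameter (1 = classic modularity, the
#'   Gephi default).
#' @param seed Integer seed for the visit order.
#' @return List with `membership` (tibble `term`, `community`;
#'   community ids contiguous from 1) and `modularity` (Q of the
#'   returned partition, computed with [modularity_q()]).
#' @export
louvain <- function(network, resolution = 1, seed = 1L) {
  stopifnot(inherits(network, "conet"))
  terms <- network$nodes$term
  n <- length(terms)
  if (nrow(network$edges) == 0) {
    memb <- tibble(term = terms, community = seq_len(n))
    return(list(membership = memb, modularity = 0))
  }
  g <- igraph_internal(network)
  assign_orig <- seq_len(n)   # original node -> current super-node
  level_seed <- as.integer(seed)
  repeat {
    order <- withr::with_seed(level_seed, sample.int(g$n))
    res <- louvain_local_moves(g, seq_len(g$n), resolution, order)
    comm <- relabel_contiguous(res$comm)
    if (length(unique(comm)) == g$n) break
    agg <- aggregate_graph(g, comm)
    assign_orig <- agg$remap[assign_orig]
    g <- agg$graph
    level_seed <- level_seed + 1L
    if (!res$moved) break
  }
  comm_final <- relabel_contiguous(assign_orig)
  memb <- tibble(term = terms, community = comm_final)
  list(membership = memb, modularity = modularity_q(network, memb, resolution))
}

# ---- map equation --------------------------------------------------------

plogp <- function(x) {
  ifelse(x > 0, x * log2(x), 0)
}

# L from module aggregates: q = per-module exit probabilities,
# p = per-module visit-rate sums, node_term = sum_a plogp(p_a)
map_L <- function(q, p, node_term) {
  plogp(sum(q)) - 2 * sum(plogp(q)) + sum(plogp(q + p)) - node_term
}

#' Two-level map-equation description length
#'
#' Average per-step codelength (bits) of a random walk on the
#' undirected weighted network under a two-level coding induced by the
#' partition:
#' \deqn{L(M) = q_\curvearrowleft H(Q) + \sum_i p^i_\circlearrowright H(P^i)}
#' with node visit rates \eqn{p_\alpha = k_\alpha / 2W} (the stationary
#' distribution of the undirected walk, no teleportation) and module
#' exit probabilities \eqn{q_i = (\text{boundary weight of } i)/2W}.
#' A single-module partition has no exit terms and reduces to the
#' entropy of the visit-rate distribution (e.g. `log2(3)` bits for a
#' triangle). An edgeless network scores 0 bits.
#'
#' @inheritParams modularity_q
#' @return Description length in bits.
#' @export
map_equation <- function(network, membership) {
  stopifnot(inherits(network, "conet"))
  comm <- membership_vector(network, membership)
  W <- sum(network$edges$weight)
  if (W == 0) return(0)
  e <- network$edges
  strength <- setNames(numeric(nrow(network$nodes)), network$nodes$term)
  for (i in seq_len(nrow(e))) {
    strength[e$from[i]] <- strength[e$from[i]] + e$weight[i]
    strength[e$to[i]] <- strength[e$to[i]] + e$weight[i]
  }
  p_alpha <- strength / (2 * W)
  labels <- sort(unique(comm))
  S_c <- purrr::map_dbl(labels, ~ sum(strength[comm == .x]))
  cut_c <- purrr::map_dbl(labels, function(l) {
    cross <- xor(comm[e$from] == l, comm[e$to] == l)
    sum(e$weight[cross & (comm[e$from] == l | comm[e$to] == l)])
  })
  q <- cut_c / (2 * W)
  p <- S_c / (2 * W)
  map_L(q, p, sum(plogp(p_alpha)))
}

#' Minimise the map-equation description length
#'
#' Louvain-style search: seeded local moves that greedily reduce the
#' two-level description length, followed by aggregation, until no
#' move helps. Deterministic for a given seed. The reported bits equal
#' [map_equation()] of the returned partition exactly.
#'
#' @param network A [conet()].
#' @param seed Integer seed for the visit order.
#' @return List with `membership` (tibble `term`, `community`) and
#'   `bits`.
#' @export
minimize_description_length <- function(network, seed = 1L) {
  stopifnot(inherits(network, "conet"))
  terms <- network$nodes$term
  n <- length(terms)
  if (nrow(network$edges) == 0) {
    memb <- tibble(term = terms, community = seq_len(n))
    return(list(membership = memb, bits = 0))
  }
  g0 <- igraph_internal(network)
  node_term <- sum(plogp(g0$k / (2 * g0$W)))
  g <- g0
  assign_orig <- seq_len(n)
  level_seed <- as.integer(seed)
  repeat {
    order <- withr::with_seed(level_seed, sample.int(g$n))
    res <- mapeq_local_moves(g, order, node_term)
    comm <- relabel_contiguous(res$comm)
    if (length(unique(comm)) == g$n) break
    agg <- aggregate_graph(g, comm)
    assign_orig <- agg$remap[assign_orig]
    g <- agg$graph
    level_seed <- level_seed + 1L
    if (!res$moved) break
  }
  memb <- tibble(term = terms, community = relabel_contiguous(assign_orig))
  list(membership = memb, bits = map_equation(network, memb))
}

# local-move phase for the map equation; maintains per-module S (degree
# sums) and intra weights, recomputing L incrementally per candidate
mapeq_local_moves <- function(g, order, node_term) {
  W2 <- 2 * g$W
  comm <- seq_len(g$n)
  S <- g$k
  intra <- g$self
  q_of <- function(c) (S[c] - 2 * intra[c]) / W2
  p_of <- function(c) S[c] / W2
  q <- purrr::map_dbl(seq_len(g$n), q_of)
  p <- purrr::map_dbl(seq_len(g$n), p_of)
  L <- map_L(q, p, node_term)
  moved_any <- FALSE
  repeat {
    moved <- FALSE
    for (i in order) {
      nbi <- g$nb[[i]]
      if (length(nbi) == 0) next
      ci <- comm[i]
      wc <- tapply(g$wt[[i]], comm[nbi], sum)
      cand <- as.integer(names(wc))
      w_to_ci <- if (ci %in% cand) wc[[as.character(ci)]] else 0
      best_L <- L
      best_c <- ci
      for (t in seq_along(cand)) {
        c2 <- cand[t]
        if (c2 == ci) next
        w_to_c2 <- as.numeric(wc[t])
        # aggregates after moving i: ci loses, c2 gains
        S1 <- S[ci] - g$k[i]; in1 <- intra[ci] - w_to_ci - g$self[i]
        S2 <- S[c2] + g$k[i]; in2 <- intra[c2] + w_to_c2 + g$self[i]
        q1 <- (S1 - 2 * in1) / W2; p1 <- S1 / W2
        q2 <- (S2 - 2 * in2) / W2; p2 <- S2 / W2
        qs <- q; ps <- p
        qs[c(ci, c2)] <- c(q1, q2)
        ps[c(ci, c2)] <- c(p1, p2)
        keep <- ps > 0 | qs > 0
        L_new <- map_L(qs[keep], ps[keep], node_term)
        if (L_new < best_L - 1e-12) {
          best_L <- L_new
          best_c <- c2
        }
      }
      if (best_c != ci) {
        w_to_c2 <- wc[[as.character(best_c)]]
        S[ci] <- S[ci] - g$k[i]; intra[ci] <- intra[ci] - w_to_ci - g$self[i]
        S[best_c] <- S[best_c] + g$k[i]
        intra[best_c] <- intra[best_c] + w_to_c2 + g$self[i]
        q[ci] <- q_of(ci); p[ci] <- p_of(ci)
        q[best_c] <- q_of(best_c); p[best_c] <- p_of(best_c)
        comm[i] <- best_c
        L <- best_L
        moved <- TRUE
        moved_any <- TRUE
      }
    }
    if (!moved) break
  }
  list(comm = comm, moved = moved_any)
}
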