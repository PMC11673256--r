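#' Tidy a co-occurrence network
#'
#' `tidy()` returns the edge table (with endpoint categories);
#' `glance()` a one-row structural summary.
#'
#' @param x A [conet()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.conet <- function(x, ...) {
  cat_of <- setNames(x$nodes$category, x$nodes$term)
  tibble(from = x$edges$from, to = x$edges$to,
         weight = x$edges$weight,
         from_category = unname(cat_of[x$edges$from]),
         to_category = unname(cat_of[x$edges$to]))
}

#' @rdname tidy.conet
#' @export
glance.conet <- function(x, ...) {
  tibble(mode = x$mode,
         n_nodes = nrow(x$nodes),
         n_edges = nrow(x$edges),
         total_weight = sum(x$edges$weight),
         density = network_density(x),
         n_components = weak_components(x))
}
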