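#' Edge-weight-threshold sensitivity sweep
#'
#' Recomputes the full [network_report()] after filtering the network
#' at each threshold (`filter_edges(network, t)`), mirroring the
#' sensitivity analysis of co-occurrence networks under edge-weight
#' filtering: raising the threshold prunes edges, lowers average
#' degree and density, and fragments the graph into more weakly
#' connected components, while the hub (max weighted degree) is
#' expected to be stable for strongly dominant conditions.
#'
#' @param network A [conet()].
#' @param thresholds Strictly increasing positive integer thresholds
#'   (default `c(1, 2, 3, 5, 10)`, spanning unit weights up to the
#'   >= 10 regime used for the printed pair tables).
#' @param seed Seed forwarded to [network_report()].
#' @param resolution Louvain resolution.
#' @return A `conet_sweep`: tibble with a `min_weight` column followed
#'   by the report columns; attribute `hub_stable` is `TRUE` iff the
#'   hub term is identical across thresholds.
#' @export
threshold_sweep <- function(network, thresholds = c(1, 2, 3, 5, 10),
                            seed = 1L, resolution = 1) {
  stopifnot(inherits(network, "conet"), length(thresholds) > 0)
  thresholds <- as.integer(thresholds)
  if (any(thresholds < 1) || is.unsorted(thresholds, strictly = TRUE)) {
    abort("thresholds must be strictly increasing positive integers")
  }
  rows <- purrr::map_dfr(thresholds, function(t) {
    rep <- network_report(filter_edges(network, t), seed = seed,
                          resolution = resolution)
    dplyr::bind_cols(tibble(min_weight = t), rep)
  })
  hubs <- rows$hub
  attr(rows, "hub_stable") <- length(unique(hubs)) == 1 && !anyNA(hubs)
  class(rows) <- c("conet_sweep", class(rows))
  rows
}

#' Write a sensitivity sweep as CSV
#'
#' One row per threshold, one column per metric; `NA` path lengths
#' (edgeless networks) render literally as `"NA"`.
#'
#' @param sweep A [threshold_sweep()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
sweep_to_table <- function(sweep, path) {
  readr::write_csv(as_tibble(sweep), path, na = "NA", progress = FALSE)
  invisible(path)
}

#' @export
glance.conet_sweep <- function(x, ...) {
  tibble(n_thresholds = nrow(x),
         min_threshold = min(x$min_weight),
         max_threshold = max(x$min_weight),
         hub_stable = isTRUE(attr(x, "hub_stable")),
         hub_at_min = x$hub[which.min(x$min_weight)])
}

#' @export
tidy.conet_sweep <- function(x, ...) {
  as_tibble(x)
}
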