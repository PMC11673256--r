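# shared internal helpers

# trim + drop empties; terms inside a record behave as a set
clean_terms <- function(x) {
  x <- stringr::str_squish(x[!is.na(x)])
  unique(x[nzchar(x)])
}

# vectorised clean_terms over a list column: squish once on the
# flattened vector, then re-split preserving empty entries
clean_term_list <- function(sets) {
  lens <- lengths(sets)
  if (sum(lens) == 0) return(purrr::map(sets, ~ character()))
  flat <- stringr::str_squish(as.character(unlist(sets, use.names = FALSE)))
  idx <- factor(rep.int(seq_along(sets), lens), levels = seq_along(sets))
  out <- split(flat, idx)
  names(out) <- NULL
  purrr::map(out, ~ unique(.x[!is.na(.x) & nzchar(.x)]))
}

split_terms <- function(x, sep = ";") {
  purrr::map(stringr::str_split(x %||% "", stringr::fixed(sep)), clean_terms)
}

join_terms <- function(x, sep = ";") {
  purrr::map_chr(x, paste, collapse = sep)
}

# round-half-up at `digits`, the convention used by the rendered tables
# (base round() is round-half-even)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- rlang::`%||%`
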