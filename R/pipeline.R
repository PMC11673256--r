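#' Diagnosis-comorbidity pair table
#'
#' All diagnosis-comorbidity pairs of the bipartite network with
#' co-occurrence weight at or above a cutoff, in descending weight
#' order (ties alphabetical by diagnosis then comorbidity).
#'
#' @param bipartite A [conet()] with `mode = "bipartite"`.
#' @param min_weight Weight cutoff (default 10, the convention of the
#'   printed pair tables).
#' @return Tibble `diagnosis`, `comorbidity`, `weight`.
#' @export
pair_table <- function(bipartite, min_weight = 10) {
  stopifnot(inherits(bipartite, "conet"))
  if (bipartite$mode != "bipartite") abort("pair_table needs a bipartite network")
  cat_of <- setNames(bipartite$nodes$category, bipartite$nodes$term)
  e <- bipartite$edges
  dx_first <- cat_of[e$from] == "diagnosis"
  out <- tibble(
    diagnosis = ifelse(dx_first, e$from, e$to),
    comorbidity = ifelse(dx_first, e$to, e$from),
    weight = e$weight
  )
  out <- out[out$weight >= min_weight, ]
  dplyr::arrange(out, dplyr::desc(.data$weight), .data$diagnosis,
                 .data$comorbidity)
}

#' Partner-count degree tables of the bipartite network
#'
#' For each diagnosis, the number of distinct comorbidities it
#' co-occurs with (its unweighted bipartite degree), and symmetrically
#' for comorbidities; filtered to at least `min_partners` partners and
#' sorted descending (ties alphabetical). Nodes without cross-edges
#' have partner count 0.
#'
#' @param bipartite A [conet()] with `mode = "bipartite"`.
#' @param min_partners Minimum partner count to keep (default 10,
#'   matching the printed tables; use 0 to list every node).
#' @return List of two tibbles, `diagnoses` (`term`, `n_partners`) and
#'   `comorbidities`.
#' @export
degree_tables <- function(bipartite, min_partners = 10) {
  stopifnot(inherits(bipartite, "conet"))
  if (bipartite$mode != "bipartite") abort("degree_tables needs a bipartite network")
  cat_of <- setNames(bipartite$nodes$category, bipartite$nodes$term)
  e <- bipartite$edges
  count_side <- function(category) {
    terms <- bipartite$nodes$term[bipartite$nodes$category == category]
    ends <- c(e$from[cat_of[e$from] == category],
              e$to[cat_of[e$to] == category])
    counts <- table(factor(ends, levels = terms))
    out <- tibble(term = names(counts), n_partners = as.integer(counts))
    out <- out[out$n_partners >= min_partners, ]
    dplyr::arrange(out, dplyr::desc(.data$n_partners), .data$term)
  }
  list(diagnoses = count_side("diagnosis"),
       comorbidities = count_side("comorbidity"))
}

#' Configure the end-to-end pipeline
#'
#' @param input A cohort source: a path to a CSV/JSONL record file, an
#'   in-memory cohort tibble, or a `cohort_config` to simulate from.
#' @param term_map Optional path to a term-map CSV or an in-memory term
#'   map; applied before any statistics.
#' @param out_dir Output directory (created if needed).
#' @param modes Network modes to build.
#' @param thresholds Sensitivity-sweep thresholds.
#' @param pair_cutoff Weight cutoff for the pair table.
#' @param min_partners Partner cutoff for the degree tables.
#' @param top_k Ranks per stratum in the stratified tables.
#' @param conf_level Confidence level for rates and odds ratios.
#' @param correct_or Haldane-Anscombe correction flag.
#' @param seed Seed used for simulation (if any) and community
#'   detection; recorded in the manifest.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input, out_dir, term_map = NULL,
                            modes = c("diagnosis", "comorbidity", "bipartite"),
                            thresholds = c(1, 2, 3, 5, 10),
                            pair_cutoff = 10, min_partners = 10, top_k = 5,
                            conf_level = 0.95, correct_or = TRUE, seed = 1L) {
  stopifnot(conf_level > 0, conf_level < 1)
  modes <- match.arg(modes, several.ok = TRUE)
  structure(list(input = input, term_map = term_map, out_dir = out_dir,
                 modes = modes, thresholds = thresholds,
                 pair_cutoff = pair_cutoff, min_partners = min_partners,
                 top_k = top_k, conf_level = conf_level,
                 correct_or = correct_or, seed = as.integer(seed)),
            class = "pipeline_config")
}

resolve_cohort <- function(input, seed) {
  if (inherits(input, "cohort_config")) {
    input$seed <- seed
    generate_cohort(input)
  } else if (is.character(input) && length(input) == 1) {
    read_cohort(input)
  } else if (is.data.frame(input)) {
    new_cohort(input)
  } else {
    abort("input must be a file path, a cohort tibble or a cohort_config")
  }
}

#' Run the full analysis pipeline
#'
#' Executes, in order: load/simulate -> term normalization -> vocabulary
#' summary -> detection-rate/odds-ratio tables per category ->
#' stratified top-k tables -> pair and partner-count tables -> network
#' construction per mode (edge/node CSV + GraphML + GEXF) -> metric
#' reports -> threshold sweeps. Every artifact is listed in
#' `manifest.json` with an MD5 content hash alongside the seed and a
#' config snapshot, so equal config + seed gives hash-identical runs.
#' A stage failure aborts with the stage name.
#'
#' @param config A [pipeline_config()].
#' @return The manifest as a list (invisibly also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  emit <- function(name) files <<- c(files, name)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)), class = "comorbnet_pipeline_error")
    })
  }
  out <- function(name) file.path(config$out_dir, name)

  cohort <- stage("load", resolve_cohort(config$input, config$seed))
  raw <- cohort
  if (!is.null(config$term_map)) {
    tm <- if (is.character(config$term_map)) read_term_map(config$term_map)
          else new_term_map(config$term_map)
    cohort <- stage("normalize", apply_term_map(cohort, tm))
  }
  stage("write_cohort", {
    write_cohort(cohort, out("cohort_normalized.csv"), "csv")
    emit("cohort_normalized.csv")
    readr::write_csv(vocab_summary(raw, cohort), out("vocab_summary.csv"),
                     progress = FALSE)
    emit("vocab_summary.csv")
  })

  stage("stats", {
    for (cat in c("diagnosis", "comorbidity")) {
      tab <- condition_table(cohort, cat, conf_level = config$conf_level,
                             correct = config$correct_or)
      readr::write_csv(tab, out(paste0(cat, "_rates.csv")), na = "INF",
                       progress = FALSE)
      emit(paste0(cat, "_rates.csv"))
      for (strat in c("age_bin", "sex", "admission_year")) {
        top <- stratified_top_k(cohort, strat, cat, k = config$top_k)
        readr::write_csv(top, out(paste0(cat, "_top", config$top_k, "_",
                                         strat, ".csv")), progress = FALSE)
        emit(paste0(cat, "_top", config$top_k, "_", strat, ".csv"))
      }
    }
  })

  networks <- stage("networks", {
    nets <- list()
    for (mode in config$modes) {
      net <- if (mode == "bipartite") build_bipartite(cohort)
             else build_monopartite(cohort, mode)
      nets[[mode]] <- net
      write_conet(net, out(paste0(mode, "_edges.csv")), "edgelist")
      write_conet(net, out(paste0(mode, "_nodes.csv")), "nodelist")
      write_conet(net, out(paste0(mode, "_network.graphml")), "graphml")
      write_conet(net, out(paste0(mode, "_network.gexf")), "gexf")
      emit(paste0(mode, c("_edges.csv", "_nodes.csv",
                          "_network.graphml", "_network.gexf")))
    }
    nets
  })

  stage("pair_tables", {
    if ("bipartite" %in% names(networks)) {
      bp <- networks[["bipartite"]]
      readr::write_csv(pair_table(bp, config$pair_cutoff),
                       out("pair_table.csv"), progress = FALSE)
      emit("pair_table.csv")
      dt <- degree_tables(bp, config$min_partners)
      readr::write_csv(dt$diagnoses, out("diagnosis_partners.csv"),
                       progress = FALSE)
      readr::write_csv(dt$comorbidities, out("comorbidity_partners.csv"),
                       progress = FALSE)
      emit(c("diagnosis_partners.csv", "comorbidity_partners.csv"))
    }
  })

  stage("metrics", {
    reports <- purrr::map_dfr(networks, network_report, seed = config$seed)
    readr::write_csv(reports, out("network_metrics.csv"), na = "NA",
                     progress = FALSE)
    emit("network_metrics.csv")
  })

  stage("sensitivity", {
    sweeps <- list()
    for (mode in names(networks)) {
      sw <- threshold_sweep(networks[[mode]], config$thresholds,
                            seed = config$seed)
      sweeps[[mode]] <- sw
      sweep_to_table(sw, out(paste0(mode, "_sensitivity.csv")))
      emit(paste0(mode, "_sensitivity.csv"))
    }
    summary <- purrr::imap(sweeps, function(sw, mode) {
      list(hub_stable = isTRUE(attr(sw, "hub_stable")),
           hub_at_min = sw$hub[which.min(sw$min_weight)])
    })
    jsonlite::write_json(summary, out("sensitivity_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    emit("sensitivity_summary.json")
  })

  manifest <- list(
    seed = config$seed,
    config = config_snapshot(config),
    files = purrr::map(setNames(files, files), function(f) {
      list(md5 = unname(tools::md5sum(file.path(config$out_dir, f))))
    })
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

config_snapshot <- function(config) {
  list(
    input = if (is.character(config$input)) config$input
            else if (inherits(config$input, "cohort_config")) "cohort_config"
            else "in-memory cohort",
    modes = config$modes,
    thresholds = config$thresholds,
    pair_cutoff = config$pair_cutoff,
    min_partners = config$min_partners,
    top_k = config$top_k,
    conf_level = config$conf_level,
    correct_or = config$correct_or,
    seed = config$seed
  )
}
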