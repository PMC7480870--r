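#' Build the stringency grid of fate distributions
#'
#' Crosses every analysis axis — dataset (`ppi`/`curated`), inclusive paralog
#' tier (an LC cell contains all pairs, MC the MC-and-above pairs, HC only
#' HC pairs), filter level and criterion — and tabulates per-fate pair counts
#' and percentages. Percentages are computed over assigned pairs only
#' (`unassigned` is excluded from denominators); cells with zero classified
#' pairs are flagged `empty`.
#'
#' @param assignments Fate assignments from [classify_pairs()].
#' @return Tibble with one row per (dataset, tier, filter_level, criterion,
#'   fate): `n`, `pct`, `total_assigned`, `empty`.
#' @export
build_grid <- function(assignments) {
  if (is.null(assignments) || nrow(assignments) == 0) {
    stop("cannot build a stringency grid from an empty assignment set",
         call. = FALSE)
  }
  datasets <- sort(unique(assignments$dataset))
  levels_ <- unique(assignments$filter_level)
  criteria <- sort(unique(assignments$criterion))
  combos <- expand.grid(dataset = datasets, filter_level = levels_,
                        criterion = criteria, stringsAsFactors = FALSE)
  have <- assignments |>
    dplyr::distinct(.data$dataset, .data$filter_level, .data$criterion)
  gap <- dplyr::anti_join(combos, have,
                          by = c("dataset", "filter_level", "criterion"))
  if (nrow(gap)) {
    stop("assignments are missing axis combination(s): ",
         paste(sprintf("(%s, %s, %s)", gap$dataset, gap$filter_level,
                       gap$criterion), collapse = "; "),
         call. = FALSE)
  }
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    cmb <- combos[i, ]
    sub <- assignments[assignments$dataset == cmb$dataset &
                         assignments$filter_level == cmb$filter_level &
                         assignments$criterion == cmb$criterion, ,
                       drop = FALSE]
    for (cell in TIERS) {
      cs <- sub[tier_at_least(sub$tier, cell), , drop = FALSE]
      assigned <- cs[cs$fate != "unassigned", , drop = FALSE]
      total <- nrow(assigned)
      n_fate <- table(factor(assigned$fate, levels = FATES))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        dataset = cmb$dataset, tier = cell,
        filter_level = cmb$filter_level, criterion = cmb$criterion,
        fate = FATES, n = as.integer(n_fate),
        pct = if (total > 0) 100 * as.integer(n_fate) / total else NA_real_,
        total_assigned = total,
        empty = total == 0
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Run the complete fate-classification pipeline on one species' files
#'
#' Orchestrates paralog detection, PPI filtering, fate assignment, complex
#' counting and grid construction from a configuration naming the input
#' files, writing every intermediate table plus a JSON run manifest and a
#' per-stage log into `out_dir`. When no localization file is configured the
#' co-localization filter is skipped (the grid then has no `f3` level) and a
#' warning is logged. Outputs are sorted deterministically, so a rerun with
#' the same configuration is byte-identical.
#'
#' @param config A list (or path to a YAML file) with elements `hits`, `ppi`
#'   (file paths) and optionally `domains`, `localization`,
#'   `mobile_elements`, `complexes`, `ohnologs`, `lengths`, `species`, and
#'   `thresholds` (arguments for [tier_thresholds()]).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `pairs`, `edge_sets`, `assignments`,
#'   `grid`, and (when complexes are configured) `complex_counts`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  for (req in c("hits", "ppi")) {
    if (is.null(config[[req]])) {
      stop("pipeline configuration must name a '", req, "' file", call. = FALSE)
    }
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_lines <- character()
  log_ <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(log_lines, paste("FAILED at stage:", name)),
                 file.path(out_dir, "pipeline.log"))
      writeLines(name, file.path(out_dir, "FAILED"))
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  thresholds <- if (is.null(config$thresholds)) tier_thresholds() else
    do.call(tier_thresholds, config$thresholds)
  lengths_tbl <- if (!is.null(config$lengths))
    readr::read_tsv(config$lengths, col_types = "ci") else NULL
  domains <- if (!is.null(config$domains))
    readr::read_tsv(config$domains, col_types = "ccd") else NULL

  hits <- stage("paralog_detection", read_blast6(config$hits, lengths_tbl))
  pairs <- stage("paralog_detection",
                 assign_tiers(collapse_to_pairs(hits), domains, thresholds))
  log_("paralog_detection: %d hits -> %d pairs (LC %d, MC %d, HC %d)",
       nrow(hits), nrow(pairs), nrow(pairs),
       sum(tier_at_least(pairs$tier, "MC")),
       sum(pairs$tier == "HC"))
  if (!is.null(config$ohnologs)) {
    pairs <- stage("paralog_detection",
                   load_ohnolog_flags(config$ohnologs, pairs))
  }

  records <- stage("ppi_filtering", read_ppi_records(config$ppi))
  flagged <- if (!is.null(config$mobile_elements))
    readLines(config$mobile_elements) else character()
  localization <- if (!is.null(config$localization))
    readr::read_tsv(config$localization, col_types = "cc") else NULL
  if (is.null(localization)) {
    log_("ppi_filtering: WARNING no localization file; filter3 (co-localization) skipped, grid level f3 unavailable")
  }
  edge_sets <- stage("ppi_filtering",
                     filter_chain(records, flagged, localization))
  edge_sets <- lapply(edge_sets, extract_paralog_edges, pairs = pairs)
  counts <- vapply(edge_sets, nrow, integer(1))
  log_("ppi_filtering: %d records; paralog-involving edges %s",
       nrow(records),
       paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))

  complexes <- if (!is.null(config$complexes))
    read_complexes(config$complexes) else NULL
  if (!is.null(complexes) && !is.null(config$species)) {
    complexes <- complexes[is.na(complexes$species) |
                             complexes$species == config$species, ,
                           drop = FALSE]
  }

  assignments <- stage("fate_assignment",
                       classify_pairs(pairs, edge_sets, complexes))
  log_("fate_assignment: %d assignments over %d pairs",
       nrow(assignments), nrow(pairs))
  grid <- stage("reporting", build_grid(assignments))

  complex_counts <- NULL
  if (!is.null(complexes)) {
    complex_counts <- stage("complex_counting", count_complexes_by_fate(
      complexes, assignments[assignments$dataset == "curated", ]))
    log_("complex_counting: %d complexes, %d with >=1 paralog",
         nrow(complexes), count_paralog_membership(complexes, pairs))
  }

  readr::write_tsv(pairs, file.path(out_dir, "pairs.tsv"))
  for (lvl in names(edge_sets)) {
    readr::write_tsv(flatten_edges(edge_sets[[lvl]]),
                     file.path(out_dir, sprintf("edges_%s.tsv", lvl)))
  }
  readr::write_tsv(assignments, file.path(out_dir, "fates.tsv"))
  readr::write_tsv(grid, file.path(out_dir, "grid.tsv"))
  if (!is.null(complex_counts)) {
    readr::write_tsv(complex_counts, file.path(out_dir, "complex_counts.tsv"))
  }
  manifest <- list(
    inputs = config[intersect(names(config),
                              c("hits", "ppi", "domains", "localization",
                                "mobile_elements", "complexes", "ohnologs",
                                "lengths", "species"))],
    thresholds = unclass(thresholds),
    filter_levels = names(edge_sets),
    n_pairs = nrow(pairs),
    package_version = as.character(utils::packageVersion("duplofate"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  invisible(list(pairs = pairs, edge_sets = edge_sets,
                 assignments = assignments, grid = grid,
                 complex_counts = complex_counts))
}

# Serialize list-columns for the edges TSV.
flatten_edges <- function(edges) {
  tibble::tibble(
    protein_a = edges$protein_a,
    protein_b = edges$protein_b,
    databases = vapply(edges$databases, paste, character(1), collapse = ";"),
    method_classes = vapply(edges$method_classes, paste, character(1),
                            collapse = ";"),
    n_databases = edges$n_databases,
    bait_a = edges$bait_a,
    bait_b = edges$bait_b
  )
}

#' Run the full analysis on an in-memory synthetic scenario
#'
#' Convenience wrapper used throughout the test-suite and the worked
#' examples: detects pairs, filters edges, classifies fates and builds the
#' grid for one species of a scenario, then (for species B, when species-A
#' data exist) maps homomer-to-heteromer transitions and compares oligomeric
#' orders.
#'
#' @param scenario A `duplo_scenario` from [generate_scenario()].
#' @param species `"B"` (eukaryote-like, default) or `"A"`.
#' @param transitions Whether to run the cross-species transition mapping
#'   (species B only).
#' @return List with `pairs`, `edge_sets`, `assignments`, `grid`,
#'   `complex_counts`, and (if run) `transitions`.
#' @export
analyze_scenario <- function(scenario, species = "B", transitions = TRUE) {
  flagged <- scenario$proteins$id[scenario$proteins$retro &
                                    scenario$proteins$species == species]
  pairs <- assign_tiers(collapse_to_pairs(scenario$hits[[species]]),
                        scenario$domains)
  edge_sets <- filter_chain(scenario$ppi[[species]], flagged,
                            scenario$localization)
  edge_sets <- lapply(edge_sets, extract_paralog_edges, pairs = pairs)
  complexes <- scenario$complexes[scenario$complexes$species == species, ,
                                  drop = FALSE]
  assignments <- classify_pairs(pairs, edge_sets, complexes)
  res <- list(pairs = pairs, edge_sets = edge_sets,
              assignments = assignments, grid = build_grid(assignments),
              complex_counts = count_complexes_by_fate(
                complexes, assignments[assignments$dataset == "curated", ]))
  if (species == "B" && transitions) {
    res$transitions <- scenario_transitions(scenario, res)
  }
  res
}

# Cross-species transition mapping for a scenario, reusing the species-B
# analysis results.
scenario_transitions <- function(scenario, b_results) {
  a <- analyze_scenario_a(scenario)
  links <- reciprocal_links(scenario$interspecies$fwd,
                            scenario$interspecies$rev)
  links <- shared_domain_filter(
    links,
    scenario$domains[scenario$domains$protein_id %in%
                       scenario$proteins$id[scenario$proteins$species == "A"], ],
    scenario$domains)
  b_asg <- b_results$assignments
  b_sel <- b_asg[b_asg$dataset == "ppi" & b_asg$criterion == "stringent" &
                   b_asg$filter_level == last_level(b_asg), , drop = FALSE]
  trans <- map_transitions(links, a$homomers, a$pairs, b_sel)
  ords <- order_tables(scenario$complexes, b_results$pairs)
  compare_orders(trans, ords$a_orders, ords$b_orders)
}

analyze_scenario_a <- function(scenario) {
  pairs_a <- assign_tiers(collapse_to_pairs(scenario$hits$A),
                          scenario$domains)
  sets_a <- filter_chain(scenario$ppi$A, character(), scenario$localization)
  last <- sets_a[[length(sets_a)]]
  cpx_a <- scenario$complexes[scenario$complexes$species == "A", , drop = FALSE]
  list(pairs = pairs_a, edge_sets = sets_a,
       homomers = build_homomer_set(last, cpx_a))
}

last_level <- function(assignments) {
  lv <- unique(assignments$filter_level)
  lv[order(match(lv, FILTER_LEVELS))][length(lv)]
}
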