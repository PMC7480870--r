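#' Write a synthetic scenario to a directory of plain-text files
#'
#' Emits the exact file dialects the pipeline readers consume: per-species
#' 13-column BLAST tabular hit files (outfmt 6 plus a `qcovs` column), raw PPI
#' record TSVs, a domain annotation TSV, a localization TSV, a JSON complex
#' file, forward/reverse inter-species hit files, the ground truth as JSON and
#' the configuration as YAML. [read_scenario()] reconstructs an equal scenario
#' object from the directory.
#'
#' @param dir_path Directory to write into (created if absent).
#' @param scenario A `duplo_scenario` from [generate_scenario()].
#' @return Invisibly, the character vector of files written.
#' @export
write_scenario <- function(dir_path, scenario) {
  if (!dir.exists(dir_path)) {
    ok <- dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create scenario directory: ", dir_path, call. = FALSE)
  }
  p <- function(f) file.path(dir_path, f)

  cfg <- unclass(scenario$config)
  # yaml drops the names of atomic vectors; write the named ones as maps
  cfg$n_families_per_fate <- as.list(cfg$n_families_per_fate)
  cfg$fate_mix <- as.list(cfg$fate_mix)
  yaml::write_yaml(cfg, p("config.yaml"))

  readr::write_tsv(scenario$proteins, p("proteins.tsv"))
  readr::write_tsv(scenario$localization, p("localization.tsv"))
  readr::write_tsv(scenario$domains, p("domains.tsv"))
  readr::write_tsv(hits_to_blast6(scenario$hits$A), p("hits_A.blast6.tsv"),
                   col_names = FALSE)
  readr::write_tsv(hits_to_blast6(scenario$hits$B), p("hits_B.blast6.tsv"),
                   col_names = FALSE)
  readr::write_tsv(scenario$ppi$A, p("ppi_A.tsv"))
  readr::write_tsv(scenario$ppi$B, p("ppi_B.tsv"))
  readr::write_tsv(hits_to_blast6(scenario$interspecies$fwd),
                   p("interspecies_fwd.blast6.tsv"), col_names = FALSE)
  readr::write_tsv(hits_to_blast6(scenario$interspecies$rev),
                   p("interspecies_rev.blast6.tsv"), col_names = FALSE)
  write_complexes(scenario$complexes, p("complexes.json"))
  flagged <- scenario$proteins$id[scenario$proteins$retro]
  writeLines(flagged, p("mobile_elements.txt"))

  truth <- scenario$truth
  truth_json <- list(
    pairs = truth$pairs,
    proteins = truth$proteins,
    families = truth$families,
    edges = truth$edges,
    a_edges = truth$a_edges,
    injected_false_positive = truth$injected_false_positive,
    injected_mislocalized = truth$injected_mislocalized,
    n_transitions = truth$n_transitions
  )
  jsonlite::write_json(truth_json, p("truth.json"), dataframe = "columns",
                       na = "null", auto_unbox = TRUE, digits = NA)

  invisible(list.files(dir_path, full.names = TRUE))
}

#' Read a scenario back from a directory written by [write_scenario()]
#'
#' @param dir_path Directory containing the scenario files.
#' @return A `duplo_scenario` list equal to the one written.
#' @export
read_scenario <- function(dir_path) {
  p <- function(f) file.path(dir_path, f)
  if (!file.exists(p("config.yaml"))) {
    stop("not a scenario directory (missing config.yaml): ", dir_path,
         call. = FALSE)
  }
  cfg <- yaml::read_yaml(p("config.yaml"))
  cfg$n_families_per_fate <- unlist(cfg$n_families_per_fate)
  cfg$fate_mix <- unlist(cfg$fate_mix)
  cfg$identity_coverage_ranges <- lapply(cfg$identity_coverage_ranges,
                                         function(t) lapply(t, unlist))
  cfg <- do.call(scenario_config, c(
    cfg[c("seed", "n_families_per_fate", "fate_mix", "n_singletons",
          "n_databases", "p_false_positive_edge", "p_homomer_blind_method",
          "p_missing_direction", "n_compartments", "p_mislocalized_edge",
          "n_retrotransposon_families", "identity_coverage_ranges",
          "transition_fraction", "p_singleton_ortholog")]))

  tsv <- function(f, types) readr::read_tsv(p(f), col_types = types)
  proteins <- tsv("proteins.tsv", "ccil")
  localization <- tsv("localization.tsv", "cc")
  domains <- tsv("domains.tsv", "ccd")
  truth_raw <- jsonlite::read_json(p("truth.json"), simplifyVector = TRUE)

  truth <- list(
    pairs = as_truth_tbl(truth_raw$pairs, truth_pairs_template()),
    proteins = as_truth_tbl(truth_raw$proteins, truth_proteins_template()),
    families = as_truth_tbl(truth_raw$families, truth_families_template()),
    edges = as_truth_tbl(truth_raw$edges, edge_list_template()),
    a_edges = as_truth_tbl(truth_raw$a_edges, edge_list_template()),
    injected_false_positive = as_truth_tbl(truth_raw$injected_false_positive,
                                           edge_list_template()),
    injected_mislocalized = as_truth_tbl(truth_raw$injected_mislocalized,
                                         edge_list_template()),
    n_transitions = as.integer(truth_raw$n_transitions)
  )

  structure(list(
    config = cfg,
    proteins = proteins,
    domains = domains,
    hits = list(A = read_blast6(p("hits_A.blast6.tsv")),
                B = read_blast6(p("hits_B.blast6.tsv"))),
    ppi = list(A = read_ppi_records(p("ppi_A.tsv")),
               B = read_ppi_records(p("ppi_B.tsv"))),
    localization = localization,
    complexes = read_complexes(p("complexes.json")),
    interspecies = list(
      fwd = read_blast6(p("interspecies_fwd.blast6.tsv")),
      rev = read_blast6(p("interspecies_rev.blast6.tsv"))
    ),
    truth = truth
  ), class = "duplo_scenario")
}

#' Read a raw PPI record table
#'
#' Expects a TSV with columns `interactor_a`, `interactor_b`, `source_db`,
#' `bait_id`, `prey_id`, `method_class`, `evidence_class`.
#'
#' @param path Path to the TSV file.
#' @return Tibble of raw PPI records.
#' @export
read_ppi_records <- function(path) {
  readr::read_tsv(path, col_types = "ccccccc")
}

# Coerce a JSON-round-tripped data frame to the template's column types,
# supplying typed empty columns when the frame came back empty.
as_truth_tbl <- function(x, template) {
  if (is.null(x) || (is.list(x) && length(x) == 0)) return(template)
  x <- tibble::as_tibble(x)
  if (nrow(x) == 0) return(template)
  for (cn in names(template)) {
    x[[cn]] <- methods::as(x[[cn]], class(template[[cn]]))
  }
  x[names(template)]
}

truth_pairs_template <- function() {
  tibble::tibble(pair_id = character(), protein_a = character(),
                 protein_b = character(), family_id = character(),
                 fate = character(), tier = character(),
                 self_a = logical(), self_b = logical(), cross = logical(),
                 other_partner_a = logical(), other_partner_b = logical())
}

truth_proteins_template <- function() {
  tibble::tibble(id = character(), species = character(),
                 self_interacting = logical(), retro = logical())
}

truth_families_template <- function() {
  tibble::tibble(family_id = character(), fate = character(),
                 tier = character(), a_status = character(),
                 a_ids = character(), order_a = integer(),
                 order_b = integer(), order_relation = character())
}

edge_list_template <- function() {
  tibble::tibble(a = character(), b = character())
}
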