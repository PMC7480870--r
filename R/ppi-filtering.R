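#' Aggregate raw multi-database PPI records into undirected evidence edges
#'
#' Drops records whose evidence class is not `experimental` (predicted and
#' text-mining interactions are discarded), then groups the remainder by
#' unordered protein pair and unions the per-record evidence: the set of
#' source databases, the observed bait directions, and the detection-method
#' classes. Self-interactions are records with identical interactor ids and
#' become self-edges (`protein_a == protein_b`); their direction evidence is
#' `a_as_bait` by construction. Records without bait/prey ids contribute no
#' direction evidence but still count toward the database tally.
#'
#' @param records Tibble of raw records with columns `interactor_a`,
#'   `interactor_b`, `source_db`, `bait_id`, `prey_id`, `method_class`,
#'   `evidence_class`.
#' @return Tibble of evidence edges: `protein_a`, `protein_b` (sorted;
#'   equal for self-edges), `databases` (list of database names),
#'   `method_classes` (list), `n_databases`, `bait_a`, `bait_b` (logical
#'   direction evidence).
#' @export
compile_edges <- function(records) {
  known <- c("experimental", "predicted", "text_mining")
  bad <- setdiff(unique(records$evidence_class), known)
  if (length(bad)) {
    stop("unknown evidence_class value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  rec <- records[records$evidence_class == "experimental", , drop = FALSE]
  if (nrow(rec) == 0) return(empty_edges())
  rec <- rec |>
    dplyr::mutate(
      protein_a = pmin(.data$interactor_a, .data$interactor_b),
      protein_b = pmax(.data$interactor_a, .data$interactor_b),
      dir_a = !is.na(.data$bait_id) & .data$bait_id == .data$protein_a,
      dir_b = !is.na(.data$bait_id) & .data$bait_id == .data$protein_b &
        .data$protein_a != .data$protein_b
    )
  rec |>
    dplyr::group_by(.data$protein_a, .data$protein_b) |>
    dplyr::summarise(
      databases = list(sort(unique(.data$source_db))),
      method_classes = list(sort(unique(.data$method_class))),
      n_databases = dplyr::n_distinct(.data$source_db),
      bait_a = any(.data$dir_a) | .data$protein_a[1] == .data$protein_b[1],
      bait_b = any(.data$dir_b),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$protein_a, .data$protein_b)
}

empty_edges <- function() {
  tibble::tibble(protein_a = character(), protein_b = character(),
                 databases = list(), method_classes = list(),
                 n_databases = integer(), bait_a = logical(),
                 bait_b = logical())
}

#' Filter 1: remove edges touching mobile-element proteins
#'
#' Removes every edge with at least one endpoint in the flagged set
#' (retrotransposon-like mobile genetic elements). An empty flagged set
#' leaves the edge set unchanged.
#'
#' @param edges Evidence edges from [compile_edges()].
#' @param flagged_proteins Character vector of flagged protein ids.
#' @return The filtered edge tibble.
#' @export
filter1_mobile_elements <- function(edges, flagged_proteins = character()) {
  edges[!(edges$protein_a %in% flagged_proteins |
            edges$protein_b %in% flagged_proteins), , drop = FALSE]
}

#' Filter 2: multi-database, bidirectional-evidence filter
#'
#' Retains a non-self edge only if it is reported in at least two source
#' databases and was observed with both proteins as bait and as prey. For
#' self-edges the direction requirement is vacuous (one protein plays both
#' roles) and only the two-database condition applies.
#'
#' @param edges Evidence edges.
#' @return The filtered edge tibble.
#' @export
filter2_evidence <- function(edges) {
  is_self <- edges$protein_a == edges$protein_b
  keep <- edges$n_databases >= 2 &
    (is_self | (edges$bait_a & edges$bait_b))
  edges[keep, , drop = FALSE]
}

#' Filter 3: sub-cellular co-localization filter
#'
#' Removes a non-self edge when both proteins have known compartment
#' annotations and the annotation sets are disjoint. Proteins without
#' localization data are treated as compatible with everything, and
#' self-edges are always retained.
#'
#' @param edges Evidence edges.
#' @param localization Tibble with columns `protein_id`, `compartment`
#'   (one row per annotation; proteins may carry several compartments).
#' @return The filtered edge tibble.
#' @export
filter3_colocalization <- function(edges, localization) {
  if (nrow(edges) == 0) return(edges)
  loc <- localization |>
    dplyr::mutate(compartment = tolower(.data$compartment)) |>
    dplyr::distinct()
  comp_sets <- split(loc$compartment, loc$protein_id)
  sets_a <- comp_sets[edges$protein_a]
  sets_b <- comp_sets[edges$protein_b]
  disjoint <- mapply(function(x, y) {
    !is.null(x) && !is.null(y) && length(intersect(x, y)) == 0
  }, sets_a, sets_b, USE.NAMES = FALSE)
  is_self <- edges$protein_a == edges$protein_b
  edges[is_self | !disjoint, , drop = FALSE]
}

#' Restrict an edge set to edges involving paralogous proteins
#'
#' Keeps edges with at least one endpoint that appears in any paralogous
#' pair; edges from a paralog to a non-paralog are retained (they are the
#' evidence for the hetero-others fate).
#'
#' @param edges Evidence edges.
#' @param pairs Paralogous pairs from [assign_tiers()].
#' @return The restricted edge tibble.
#' @export
extract_paralog_edges <- function(edges, pairs) {
  paralogs <- unique(c(pairs$protein_a, pairs$protein_b))
  edges[edges$protein_a %in% paralogs | edges$protein_b %in% paralogs, ,
        drop = FALSE]
}

#' Edges detected exclusively by non-bait/prey method classes
#'
#' Keeps only pairs all of whose experimental records have method class
#' `other` (neither two-hybrid nor pulldown), then applies the two-database
#' and co-localization filters — but not the direction filter, which is
#' meaningless for such methods.
#'
#' @param records Raw PPI records.
#' @param localization Optional localization tibble for the co-localization
#'   step; skipped when `NULL`.
#' @return Evidence edge tibble for the method-exclusive subset.
#' @export
subset_non_baitprey_methods <- function(records, localization = NULL) {
  edges <- compile_edges(records)
  only_other <- vapply(edges$method_classes,
                       function(m) all(m == "other"), logical(1))
  edges <- edges[only_other & edges$n_databases >= 2, , drop = FALSE]
  if (!is.null(localization)) {
    edges <- filter3_colocalization(edges, localization)
  }
  edges
}

#' Apply the successive PPI filters, keeping each level
#'
#' Runs the three filters in their canonical order and returns all four edge
#' sets: `raw` (compiled evidence edges), `f1` (mobile elements removed),
#' `f2` (two-database, bait-and-prey evidence), `f3` (co-localization).
#' When `localization` is `NULL` the third filter is skipped and `f3` is
#' absent.
#'
#' @param records Raw PPI records.
#' @param flagged_proteins Mobile-element protein ids for filter 1.
#' @param localization Localization tibble for filter 3, or `NULL`.
#' @return Named list of edge tibbles.
#' @export
filter_chain <- function(records, flagged_proteins = character(),
                         localization = NULL) {
  raw <- compile_edges(records)
  f1 <- filter1_mobile_elements(raw, flagged_proteins)
  f2 <- filter2_evidence(f1)
  sets <- list(raw = raw, f1 = f1, f2 = f2)
  if (!is.null(localization)) {
    sets$f3 <- filter3_colocalization(f2, localization)
  }
  sets
}
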