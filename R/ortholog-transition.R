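#' Reciprocal cross-species homology links
#'
#' Builds one link per cross-species protein pair that is hit in both BLAST
#' directions below the e-value threshold. Reciprocity means mutual
#' sub-threshold hits by default; `strict_best_hit = TRUE` additionally
#' demands that each protein is the other's best (smallest e-value) hit.
#'
#' @param hits_ab Hits from species A queried against species B
#'   ([read_blast6()] output).
#' @param hits_ba Hits from species B queried against species A.
#' @param e_threshold E-value threshold (default `1e-5`, strict inequality).
#' @param strict_best_hit Require reciprocal *best* hits.
#' @return Tibble of links: `protein_a`, `protein_b`, `e_value_fwd`,
#'   `e_value_rev`, `reciprocal` (always `TRUE`).
#' @export
reciprocal_links <- function(hits_ab, hits_ba, e_threshold = 1e-5,
                             strict_best_hit = FALSE) {
  best <- function(h, qcol, scol) {
    h |>
      dplyr::filter(.data$e_value < e_threshold) |>
      dplyr::group_by(q = .data[[qcol]], s = .data[[scol]]) |>
      dplyr::summarise(e_value = min(.data$e_value), .groups = "drop")
  }
  fwd <- best(hits_ab, "query_id", "subject_id")
  rev_ <- best(hits_ba, "query_id", "subject_id")
  links <- dplyr::inner_join(
    fwd |> dplyr::rename(protein_a = "q", protein_b = "s",
                         e_value_fwd = "e_value"),
    rev_ |> dplyr::rename(protein_b = "q", protein_a = "s",
                          e_value_rev = "e_value"),
    by = c("protein_a", "protein_b"))
  if (strict_best_hit && nrow(links)) {
    best_of <- function(h) {
      h |>
        dplyr::group_by(.data$q) |>
        dplyr::slice_min(.data$e_value, n = 1, with_ties = TRUE) |>
        dplyr::ungroup()
    }
    bf <- best_of(fwd)
    br <- best_of(rev_)
    links <- links |>
      dplyr::semi_join(bf, by = c(protein_a = "q", protein_b = "s")) |>
      dplyr::semi_join(br, by = c(protein_b = "q", protein_a = "s"))
  }
  links |>
    dplyr::mutate(reciprocal = TRUE) |>
    dplyr::arrange(.data$protein_a, .data$protein_b)
}

#' Keep links whose proteins share at least one significant domain
#'
#' @param links Links from [reciprocal_links()].
#' @param domains_a,domains_b Domain tibbles (`protein_id`, `domain_id`,
#'   `p_value`) for the two species.
#' @param p_cutoff Significance cutoff for domain annotations.
#' @return Filtered links with an added `shared_domains` list-column.
#' @export
shared_domain_filter <- function(links, domains_a, domains_b,
                                 p_cutoff = 1e-5) {
  sig <- function(d) d[d$p_value < p_cutoff, c("protein_id", "domain_id")]
  da <- sig(domains_a)
  db <- sig(domains_b)
  shared <- links |>
    dplyr::inner_join(da, by = c(protein_a = "protein_id"),
                      relationship = "many-to-many") |>
    dplyr::inner_join(db, by = c(protein_b = "protein_id", "domain_id"),
                      relationship = "many-to-many") |>
    dplyr::group_by(.data$protein_a, .data$protein_b) |>
    dplyr::summarise(shared_domains = list(sort(unique(.data$domain_id))),
                     .groups = "drop")
  links |>
    dplyr::inner_join(shared, by = c("protein_a", "protein_b"))
}

#' Map prokaryote-homomer to eukaryote-heteromer transitions
#'
#' Identifies species-B paralogous pairs assigned `obligatory_hetero` or
#' `mixed` whose members link to a homomeric species-A protein, and classifies
#' each A-side unit as a singleton homomer (the A protein has no paralog) or
#' a paralogous homomeric pair. One record is emitted per distinct
#' (A-side unit, B-side pair) combination. By default one linked member of
#' the B pair suffices (divergent paralogs may lose detectable similarity
#' asymmetrically); `require_both_members = TRUE` demands links to both.
#'
#' @param links Cross-species links (after [shared_domain_filter()] and any
#'   manual accept/reject list the user applies).
#' @param a_homomers Character vector of homomeric species-A proteins, from
#'   [build_homomer_set()].
#' @param a_pairs Species-A paralogous pairs ([assign_tiers()] output), used
#'   to separate singletons from paralogous homomers.
#' @param b_assignments Species-B fate assignments; use the stringent
#'   criterion, PPI dataset rows at the filter level under study.
#' @param require_both_members Demand that both B-pair members link to the A
#'   protein.
#' @return Tibble of transition records: `a_side_type`
#'   (`"singleton"`/`"paralog_pair"`), `a_ids` (one id or `"id1|id2"`),
#'   `b_pair`, `b_fate`.
#' @export
map_transitions <- function(links, a_homomers, a_pairs, b_assignments,
                            require_both_members = FALSE) {
  bsel <- b_assignments[b_assignments$fate %in%
                          c("obligatory_hetero", "mixed"), , drop = FALSE]
  empty <- tibble::tibble(a_side_type = character(), a_ids = character(),
                          b_pair = character(), b_fate = character())
  if (nrow(bsel) == 0 || nrow(links) == 0) return(empty)
  hlinks <- links[links$protein_a %in% a_homomers, , drop = FALSE]
  if (nrow(hlinks) == 0) return(empty)

  b_long <- dplyr::bind_rows(
    tibble::tibble(b_pair = bsel$pair_id, b_fate = bsel$fate,
                   member = bsel$protein_a),
    tibble::tibble(b_pair = bsel$pair_id, b_fate = bsel$fate,
                   member = bsel$protein_b)
  )
  hit <- hlinks |>
    dplyr::inner_join(b_long, by = c(protein_b = "member"),
                      relationship = "many-to-many") |>
    dplyr::group_by(a_protein = .data$protein_a, .data$b_pair,
                    .data$b_fate) |>
    dplyr::summarise(n_members_linked = dplyr::n_distinct(.data$protein_b),
                     .groups = "drop")
  if (require_both_members) {
    hit <- hit[hit$n_members_linked >= 2, , drop = FALSE]
  }
  if (nrow(hit) == 0) return(empty)

  # resolve each linked A protein to its A-side unit(s)
  a_pair_long <- dplyr::bind_rows(
    tibble::tibble(a_protein = a_pairs$protein_a,
                   unit = pair_key(a_pairs$protein_a, a_pairs$protein_b)),
    tibble::tibble(a_protein = a_pairs$protein_b,
                   unit = pair_key(a_pairs$protein_a, a_pairs$protein_b))
  )
  hit <- hit |>
    dplyr::left_join(a_pair_long, by = "a_protein",
                     relationship = "many-to-many") |>
    dplyr::mutate(
      a_side_type = ifelse(is.na(.data$unit), "singleton", "paralog_pair"),
      a_ids = ifelse(is.na(.data$unit), .data$a_protein, .data$unit)
    )
  hit |>
    dplyr::distinct(.data$a_side_type, .data$a_ids, .data$b_pair,
                    .data$b_fate) |>
    dplyr::arrange(.data$a_ids, .data$b_pair)
}

#' Oligomeric orders of curated complexes
#'
#' Total subunit counts of complexes with fully known stoichiometry (CS and
#' PDB tiers); complexes with any unknown copy number yield `NA`.
#'
#' @param complexes Complex tibble.
#' @return Tibble `complex_id`, `tier`, `order` (total subunits),
#'   `members` (list of member ids).
#' @export
oligomeric_orders <- function(complexes) {
  tibble::tibble(
    complex_id = complexes$complex_id,
    tier = complexes$tier,
    order = vapply(complexes$members, function(m) {
      if (anyNA(m$copies)) NA_integer_ else as.integer(sum(m$copies))
    }, integer(1)),
    members = lapply(complexes$members, function(m) m$id)
  )
}

#' Compare ancestral and derived oligomeric orders
#'
#' Annotates transition records with the oligomeric order of the species-A
#' homomer and of the species-B heteromeric complex, and classifies the
#' relation: `retained` (both known and equal), `changed` (both known and
#' different), `unknown` otherwise. Orders come from stoichiometry-bearing
#' (CS/PDB-tier) complexes: the A-side order is looked up per A protein, the
#' B-side order per B pair.
#'
#' @param transitions Records from [map_transitions()].
#' @param a_orders Tibble `protein_id`, `order` (species-A homomer orders).
#' @param b_orders Tibble `pair_id`, `order` (species-B heteromer orders).
#' @return `transitions` with `order_a`, `order_b`, `order_relation` added.
#' @export
compare_orders <- function(transitions, a_orders, b_orders) {
  first_member <- vapply(strsplit(transitions$a_ids, "|", fixed = TRUE),
                         `[`, character(1), 1)
  oa <- a_orders$order[match(first_member, a_orders$protein_id)]
  ob <- b_orders$order[match(transitions$b_pair, b_orders$pair_id)]
  transitions |>
    dplyr::mutate(
      order_a = oa,
      order_b = ob,
      order_relation = dplyr::case_when(
        is.na(oa) | is.na(ob) ~ "unknown",
        oa == ob ~ "retained",
        .default = "changed"
      )
    )
}

#' Oligomeric-order lookup tables from a scenario's complexes
#'
#' Convenience builder for [compare_orders()]: per-protein homomer orders for
#' species A and per-pair heteromer orders for species B, taken from
#' stoichiometry-bearing complexes.
#'
#' @param complexes Complex tibble covering both species.
#' @param b_pairs Species-B pair tibble (for pair ids).
#' @return List with `a_orders` and `b_orders` tibbles.
#' @export
order_tables <- function(complexes, b_pairs) {
  ord <- oligomeric_orders(complexes)
  known <- ord[!is.na(ord$order), , drop = FALSE]
  a_rows <- known[vapply(known$members, length, integer(1)) == 1, , drop = FALSE]
  a_orders <- tibble::tibble(
    protein_id = vapply(a_rows$members, `[`, character(1), 1),
    order = a_rows$order
  ) |> dplyr::distinct(.data$protein_id, .keep_all = TRUE)

  two_mem <- known[vapply(known$members, length, integer(1)) == 2, , drop = FALSE]
  if (nrow(two_mem)) {
    keys <- vapply(two_mem$members, function(m) pair_key(m[1], m[2]), character(1))
    b_orders <- tibble::tibble(pair_id = keys, order = two_mem$order) |>
      dplyr::filter(.data$pair_id %in% b_pairs$pair_id) |>
      dplyr::distinct(.data$pair_id, .keep_all = TRUE)
  } else {
    b_orders <- tibble::tibble(pair_id = character(), order = integer())
  }
  list(a_orders = a_orders, b_orders = b_orders)
}
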