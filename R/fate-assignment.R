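#' Derive the interaction status of paralogous pairs from a PPI edge set
#'
#' For each pair, reads off: `self_a`/`self_b` (a self-edge exists on that
#' paralog), `cross` (an edge between the two paralogs exists), and
#' `other_partner_a`/`other_partner_b` (the paralog has an edge to a protein
#' that is neither itself nor any of its detected paralogs). "Any detected
#' paralog" is judged against `analysis_pairs`, the analysis-wide paralog set
#' (by default the most inclusive, LC-level set supplied), so a hetero-others
#' partner is a genuinely new interactor.
#'
#' @param pairs Tibble of pairs (columns `protein_a`, `protein_b`, and
#'   optionally `pair_id`, `tier`).
#' @param edges One filtered evidence edge set.
#' @param analysis_pairs Pair tibble defining who counts as a paralog of whom;
#'   defaults to `pairs`.
#' @return `pairs` with logical columns `self_a`, `self_b`, `cross`,
#'   `other_partner_a`, `other_partner_b` appended.
#' @export
interaction_status_ppi <- function(pairs, edges, analysis_pairs = pairs) {
  self_set <- unique(edges$protein_a[edges$protein_a == edges$protein_b])
  cross_keys <- pair_key(edges$protein_a, edges$protein_b)[
    edges$protein_a != edges$protein_b]
  op_set <- outside_partner_set(edges, analysis_pairs)
  pairs |>
    dplyr::mutate(
      self_a = .data$protein_a %in% self_set,
      self_b = .data$protein_b %in% self_set,
      cross = pair_key(.data$protein_a, .data$protein_b) %in% cross_keys,
      other_partner_a = .data$protein_a %in% op_set,
      other_partner_b = .data$protein_b %in% op_set
    )
}

# Proteins having at least one non-self edge to a non-paralog.
outside_partner_set <- function(edges, analysis_pairs) {
  nonself <- edges[edges$protein_a != edges$protein_b, , drop = FALSE]
  if (nrow(nonself) == 0) return(character())
  nb <- tibble::tibble(
    protein = c(nonself$protein_a, nonself$protein_b),
    partner = c(nonself$protein_b, nonself$protein_a)
  )
  paralog_of <- tibble::tibble(
    protein = c(analysis_pairs$protein_a, analysis_pairs$protein_b),
    partner = c(analysis_pairs$protein_b, analysis_pairs$protein_a)
  )
  nb <- dplyr::anti_join(nb, paralog_of, by = c("protein", "partner"))
  unique(nb$protein)
}

#' Single-pair interaction status from PPI edges
#'
#' Convenience wrapper around [interaction_status_ppi()] for one unordered
#' pair.
#'
#' @param pair Character vector of the two protein ids.
#' @param edges One filtered evidence edge set.
#' @param analysis_pairs Optional pair tibble defining the paralog universe;
#'   defaults to the pair itself.
#' @return One-row status tibble.
#' @export
derive_status_ppi <- function(pair, edges, analysis_pairs = NULL) {
  s <- pair_sort(pair[1], pair[2])
  tbl <- tibble::tibble(protein_a = s$a, protein_b = s$b)
  if (is.null(analysis_pairs)) analysis_pairs <- tbl
  interaction_status_ppi(tbl, edges, analysis_pairs)
}

#' Assign a divergence fate from an interaction status
#'
#' Implements the four-fate classification. Under the stringent criterion:
#' cross-interaction without self-interaction gives `obligatory_hetero`;
#' cross-interaction with at least one self-interactor gives `mixed`; no
#' cross-interaction with both paralogs self-interacting gives
#' `obligatory_homo`; no cross-interaction with exactly one self-interactor
#' and an outside (non-paralogous) partner on the *non*-self-interacting
#' paralog gives `hetero_others`; anything else is `unassigned`. The flexible
#' criterion differs only in that every no-cross case with at least one
#' self-interactor becomes `obligatory_homo` (hetero-others is never
#' emitted), which is precisely how hetero-others truths get absorbed into
#' obligatory homomers under flexible assignment.
#'
#' @param status Status tibble with logical columns `self_a`, `self_b`,
#'   `cross`, `other_partner_a`, `other_partner_b` (one or more rows).
#' @param criterion `"stringent"` or `"flexible"`.
#' @return Character vector of fates, one per status row.
#' @export
assign_fate <- function(status, criterion = c("stringent", "flexible")) {
  criterion <- match.arg(criterion)
  sa <- status$self_a
  sb <- status$self_b
  cr <- status$cross
  opa <- status$other_partner_a
  opb <- status$other_partner_b
  if (criterion == "stringent") {
    dplyr::case_when(
      cr & !sa & !sb ~ "obligatory_hetero",
      cr & (sa | sb) ~ "mixed",
      !cr & sa & sb ~ "obligatory_homo",
      !cr & sa & !sb & opb ~ "hetero_others",
      !cr & !sa & sb & opa ~ "hetero_others",
      .default = "unassigned"
    )
  } else {
    dplyr::case_when(
      cr & !sa & !sb ~ "obligatory_hetero",
      cr & (sa | sb) ~ "mixed",
      !cr & (sa | sb) ~ "obligatory_homo",
      .default = "unassigned"
    )
  }
}

validate_complexes <- function(complexes) {
  if (is.null(complexes) || nrow(complexes) == 0) return(invisible(complexes))
  bad_tier <- setdiff(unique(complexes$tier), COMPLEX_TIERS)
  if (length(bad_tier)) {
    stop("unknown complex tier(s): ", paste(bad_tier, collapse = ", "),
         call. = FALSE)
  }
  has_contacts <- vapply(complexes$contacts,
                         function(x) !is.null(x) && nrow(x) > 0, logical(1))
  if (any(has_contacts & complexes$tier != "PDB")) {
    stop("contact lists are only valid on PDB-tier complexes", call. = FALSE)
  }
  invisible(complexes)
}

# Evidence sets extracted once from a curated complex table.
curated_evidence <- function(complexes) {
  validate_complexes(complexes)
  pdb_self <- character()
  pdb_cross <- character()
  multi_copy_cs <- character()
  member_c <- character()
  co_keys <- character()
  for (i in seq_len(nrow(complexes))) {
    tier <- complexes$tier[i]
    mem <- complexes$members[[i]]
    con <- complexes$contacts[[i]]
    if (tier == "PDB") {
      if (!is.null(con) && nrow(con)) {
        selfc <- con$a[con$a == con$b]
        multi <- mem$id[!is.na(mem$copies) & mem$copies >= 2]
        pdb_self <- c(pdb_self, intersect(selfc, multi))
        hetc <- con[con$a != con$b, , drop = FALSE]
        pdb_cross <- c(pdb_cross, pair_key(hetc$a, hetc$b))
      }
    } else {
      if (tier == "CS") {
        multi_copy_cs <- c(multi_copy_cs, mem$id[!is.na(mem$copies) & mem$copies >= 2])
      } else {
        # C tier: known copy numbers honoured, unknown fall back to the
        # PPI self-edge rule alone
        member_c <- c(member_c, mem$id[is.na(mem$copies) | mem$copies >= 2])
      }
      if (nrow(mem) >= 2) {
        cmb <- utils::combn(sort(mem$id), 2)
        co_keys <- c(co_keys, pair_key(cmb[1, ], cmb[2, ]))
      }
    }
  }
  list(pdb_self = unique(pdb_self), pdb_cross = unique(pdb_cross),
       self_candidates = unique(c(multi_copy_cs, member_c)),
       co_membership = unique(co_keys))
}

#' Derive interaction statuses from curated complexes
#'
#' Applies the tier-specific homomer/heteromer evidence rules. PDB tier:
#' self-interaction requires copy number >= 2 together with a self-contact in
#' the structure; cross-interaction requires an inter-subunit contact between
#' the paralogs. CS tier: self requires copy number >= 2 *and* a PPI
#' self-edge; cross requires co-membership in a complex *and* a PPI
#' cross-edge. C tier: copy numbers are unknown (known ones are honoured), so
#' self falls back to membership plus a PPI self-edge; cross as in CS.
#' Outside-partner flags are read from the PPI edge set. The returned
#' `ppi_cross` column records whether a PPI cross-edge exists; curated
#' obligatory-homomer calls are vetoed downstream when it does.
#'
#' @param pairs Pair tibble (`protein_a`, `protein_b`, ...).
#' @param complexes Complex tibble (see [read_complexes()]).
#' @param filtered_edges The PPI edge set at the filter level under study.
#' @param analysis_pairs Paralog universe for the outside-partner test.
#' @return `pairs` with status columns plus `ppi_cross`.
#' @export
interaction_status_curated <- function(pairs, complexes, filtered_edges,
                                       analysis_pairs = pairs) {
  ev <- curated_evidence(complexes)
  ppi_self <- unique(filtered_edges$protein_a[
    filtered_edges$protein_a == filtered_edges$protein_b])
  ppi_cross_keys <- pair_key(filtered_edges$protein_a, filtered_edges$protein_b)[
    filtered_edges$protein_a != filtered_edges$protein_b]
  op_set <- outside_partner_set(filtered_edges, analysis_pairs)
  self_of <- function(x) {
    x %in% ev$pdb_self | (x %in% ev$self_candidates & x %in% ppi_self)
  }
  pairs |>
    dplyr::mutate(
      key = pair_key(.data$protein_a, .data$protein_b),
      ppi_cross = .data$key %in% ppi_cross_keys,
      self_a = self_of(.data$protein_a),
      self_b = self_of(.data$protein_b),
      cross = .data$key %in% ev$pdb_cross |
        (.data$key %in% ev$co_membership & .data$ppi_cross),
      other_partner_a = .data$protein_a %in% op_set,
      other_partner_b = .data$protein_b %in% op_set
    ) |>
    dplyr::select(-"key")
}

#' Single-pair curated interaction status
#'
#' @param pair Character vector of the two protein ids.
#' @param complexes Complex tibble.
#' @param filtered_edges PPI edge set used for the CS/C-tier cross-checks.
#' @param analysis_pairs Optional paralog universe.
#' @return One-row status tibble including `ppi_cross`.
#' @export
derive_status_curated <- function(pair, complexes, filtered_edges,
                                  analysis_pairs = NULL) {
  s <- pair_sort(pair[1], pair[2])
  tbl <- tibble::tibble(protein_a = s$a, protein_b = s$b)
  if (is.null(analysis_pairs)) analysis_pairs <- tbl
  interaction_status_curated(tbl, complexes, filtered_edges, analysis_pairs)
}

#' Classify paralogous pairs across datasets, filter levels and criteria
#'
#' Produces one fate assignment per pair for every combination of dataset
#' (`ppi`, and `curated` when complexes are supplied), filter level (one per
#' edge set), and criterion. Cross- and self-evidence are always read from
#' the same filter level being evaluated. In curated mode an
#' obligatory-homomer call is demoted to `unassigned` when the paralogs
#' cross-interact in the same-level PPI data. Unassigned pairs are recorded
#' (they are excluded from fate-fraction denominators by [build_grid()]).
#'
#' @param pairs Pair tibble from [assign_tiers()].
#' @param edge_sets Named list of evidence edge sets, e.g. from
#'   [filter_chain()].
#' @param complexes Optional complex tibble enabling the curated dataset.
#' @param criteria Criteria to evaluate.
#' @return Tibble with columns `pair_id`, `protein_a`, `protein_b`, `tier`,
#'   `dataset`, `filter_level`, `criterion`, `fate` and the status flags.
#' @export
classify_pairs <- function(pairs, edge_sets, complexes = NULL,
                           criteria = c("stringent", "flexible")) {
  out <- list()
  for (lvl in names(edge_sets)) {
    edges <- edge_sets[[lvl]]
    st_ppi <- interaction_status_ppi(pairs, edges, analysis_pairs = pairs)
    st_cur <- if (!is.null(complexes)) {
      interaction_status_curated(pairs, complexes, edges,
                                 analysis_pairs = pairs)
    }
    for (crit in criteria) {
      out[[length(out) + 1L]] <- st_ppi |>
        dplyr::mutate(dataset = "ppi", filter_level = lvl, criterion = crit,
                      fate = assign_fate(st_ppi, crit))
      if (!is.null(st_cur)) {
        fate <- assign_fate(st_cur, crit)
        fate[fate == "obligatory_homo" & st_cur$ppi_cross] <- "unassigned"
        out[[length(out) + 1L]] <- st_cur |>
          dplyr::select(-"ppi_cross") |>
          dplyr::mutate(dataset = "curated", filter_level = lvl,
                        criterion = crit, fate = fate)
      }
    }
  }
  dplyr::bind_rows(out) |>
    dplyr::select("pair_id", "protein_a", "protein_b", "tier", "dataset",
                  "filter_level", "criterion", "fate", "self_a", "self_b",
                  "cross", "other_partner_a", "other_partner_b") |>
    dplyr::arrange(.data$dataset, .data$filter_level, .data$criterion,
                   .data$pair_id)
}

#' Build the set of known homomeric proteins
#'
#' Union of proteins with a PPI self-edge and proteins satisfying the curated
#' homomer rule for their complex tier (PDB: copy number >= 2 plus a
#' self-contact; CS: copy number >= 2 plus a PPI self-edge; C: membership
#' plus a PPI self-edge).
#'
#' @param edges Filtered PPI evidence edges for one species.
#' @param complexes Optional complex tibble for the same species.
#' @return Character vector of homomeric protein ids.
#' @export
build_homomer_set <- function(edges, complexes = NULL) {
  ppi_self <- unique(edges$protein_a[edges$protein_a == edges$protein_b])
  if (is.null(complexes) || nrow(complexes) == 0) return(sort(ppi_self))
  ev <- curated_evidence(complexes)
  curated <- c(ev$pdb_self, intersect(ev$self_candidates, ppi_self))
  sort(unique(c(ppi_self, curated)))
}
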