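#' Read curated complex records from JSON
#'
#' The JSON dialect is an array of records
#' `{complex_id, species, tier, members: [{id, copies}], contacts: [[a,b], ...]}`
#' where `tier` is one of `C` (composition only; copy numbers may be null),
#' `CS` (composition plus stoichiometry) or `PDB` (composition,
#' stoichiometry and inter-subunit contacts). Contact lists are only valid on
#' PDB-tier records.
#'
#' @param path Path to the JSON file.
#' @return Tibble with list-columns `members` (tibble `id`, `copies`) and
#'   `contacts` (tibble `a`, `b`).
#' @export
read_complexes <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (length(raw) == 0) {
    return(tibble::tibble(complex_id = character(), species = character(),
                          tier = character(), members = list(),
                          contacts = list()))
  }
  rows <- lapply(raw, function(r) {
    members <- tibble::tibble(
      id = vapply(r$members, function(m) m$id, character(1)),
      copies = vapply(r$members, function(m)
        if (is.null(m$copies)) NA_integer_ else as.integer(m$copies),
        integer(1))
    )
    contacts <- if (length(r$contacts)) {
      tibble::tibble(
        a = vapply(r$contacts, function(ct) ct[[1]], character(1)),
        b = vapply(r$contacts, function(ct) ct[[2]], character(1))
      )
    } else {
      tibble::tibble(a = character(), b = character())
    }
    tibble::tibble(complex_id = r$complex_id,
                   species = r$species %||% NA_character_,
                   tier = r$tier,
                   members = list(members), contacts = list(contacts))
  })
  out <- dplyr::bind_rows(rows)
  validate_complexes(out)
  out
}

#' Write curated complex records to JSON
#'
#' @param complexes Complex tibble as returned by [read_complexes()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_complexes <- function(complexes, path) {
  recs <- lapply(seq_len(nrow(complexes)), function(i) {
    mem <- complexes$members[[i]]
    con <- complexes$contacts[[i]]
    list(
      complex_id = complexes$complex_id[i],
      species = complexes$species[i],
      tier = complexes$tier[i],
      members = lapply(seq_len(nrow(mem)), function(j) {
        list(id = mem$id[j],
             copies = if (is.na(mem$copies[j])) NULL else mem$copies[j])
      }),
      contacts = if (!is.null(con) && nrow(con))
        lapply(seq_len(nrow(con)), function(j) c(con$a[j], con$b[j]))
      else list()
    )
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

complex_membership <- function(complexes) {
  if (nrow(complexes) == 0) {
    return(tibble::tibble(complex_id = character(), protein = character()))
  }
  tibble::tibble(
    complex_id = rep(complexes$complex_id,
                     vapply(complexes$members, nrow, integer(1))),
    protein = unlist(lapply(complexes$members, function(m) m$id),
                     use.names = FALSE)
  )
}

#' Count unique complexes by the divergence fate of the pairs they contain
#'
#' For every (filter level, criterion, inclusive paralog tier) context, counts
#' the number of distinct complexes containing at least one paralogous pair
#' assigned each fate. A complex "contains" an obligatory-hetero or mixed
#' pair when both paralogs are subunits; for obligatory-homo and
#' hetero-others — fates whose defining complexes hold a single paralog — one
#' member suffices, so the two distinct homomeric complexes formed by an
#' obligatory-homo pair both count. A complex containing pairs of k distinct
#' fates contributes to k cells, so counts need not sum to the number of
#' complexes.
#'
#' @param complexes Complex tibble (one species).
#' @param assignments Fate assignments from [classify_pairs()], normally the
#'   `dataset == "curated"` rows.
#' @return Tibble keyed by `filter_level`, `criterion`, `tier`, `fate` with a
#'   `n_complexes` count.
#' @export
count_complexes_by_fate <- function(complexes, assignments) {
  mem <- complex_membership(complexes)
  asg <- assignments[assignments$fate != "unassigned", , drop = FALSE]
  grid_cells <- expand.grid(filter_level = unique(assignments$filter_level),
                            criterion = unique(assignments$criterion),
                            cell_tier = TIERS, stringsAsFactors = FALSE)
  res <- list()
  for (i in seq_len(nrow(grid_cells))) {
    g <- grid_cells[i, ]
    sub <- asg[asg$filter_level == g$filter_level &
                 asg$criterion == g$criterion &
                 tier_at_least(asg$tier, g$cell_tier), , drop = FALSE]
    for (f in setdiff(unique(sub$fate), "unassigned")) {
      pf <- sub[sub$fate == f, , drop = FALSE]
      both_needed <- f %in% c("obligatory_hetero", "mixed")
      in_a <- mem |> dplyr::inner_join(
        tibble::tibble(protein = pf$protein_a, pair = pf$pair_id),
        by = "protein", relationship = "many-to-many")
      in_b <- mem |> dplyr::inner_join(
        tibble::tibble(protein = pf$protein_b, pair = pf$pair_id),
        by = "protein", relationship = "many-to-many")
      cpx <- if (both_needed) {
        intersect(paste(in_a$complex_id, in_a$pair),
                  paste(in_b$complex_id, in_b$pair)) |>
          vapply(function(x) strsplit(x, " ")[[1]][1], character(1)) |>
          unique()
      } else {
        unique(c(in_a$complex_id, in_b$complex_id))
      }
      res[[length(res) + 1L]] <- tibble::tibble(
        filter_level = g$filter_level, criterion = g$criterion,
        tier = g$cell_tier, fate = f, n_complexes = length(cpx))
    }
  }
  if (!length(res)) {
    return(tibble::tibble(filter_level = character(), criterion = character(),
                          tier = character(), fate = character(),
                          n_complexes = integer()))
  }
  dplyr::bind_rows(res) |>
    dplyr::arrange(.data$filter_level, .data$criterion, .data$tier, .data$fate)
}

tier_at_least <- function(tier, cell) {
  match(tier, TIERS) >= match(cell, TIERS)
}

#' Count complexes containing at least one paralogous protein
#'
#' @param complexes Complex tibble.
#' @param pairs Paralogous pair tibble.
#' @return Integer count of distinct complexes intersecting the paralog set.
#' @export
count_paralog_membership <- function(complexes, pairs) {
  mem <- complex_membership(complexes)
  paralogs <- unique(c(pairs$protein_a, pairs$protein_b))
  length(unique(mem$complex_id[mem$protein %in% paralogs]))
}
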