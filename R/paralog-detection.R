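#' Read a BLAST tabular (outfmt 6) hit file
#'
#' Parses the standard 12-column tab-separated BLAST output
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`), optionally carrying query coverage as a 13th `qcovs`
#' column. When `qcovs` is absent, coverage is computed from the aligned query
#' span and a protein length table. Self-hits (query equal to subject) are
#' dropped; reciprocal and duplicate hits are retained (deduplication happens
#' in [collapse_to_pairs()]).
#'
#' @param path Path to the hit file (no header).
#' @param lengths Optional tibble with columns `protein_id`, `length`
#'   (residues), required when the file has no `qcovs` column.
#' @return Tibble of hits with columns `query_id`, `subject_id`,
#'   `percent_identity`, `alignment_length`, `e_value`, `query_coverage`.
#' @export
read_blast6 <- function(path, lengths = NULL) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  raw <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  if (nrow(raw) == 0) {
    return(tibble::tibble(query_id = character(), subject_id = character(),
                          percent_identity = numeric(),
                          alignment_length = integer(),
                          e_value = numeric(), query_coverage = numeric()))
  }
  if (!ncol(raw) %in% c(12L, 13L)) {
    stop(sprintf("malformed BLAST tabular file '%s': expected 12 or 13 columns, found %d",
                 path, ncol(raw)), call. = FALSE)
  }
  names(raw)[seq_along(cols)] <- cols
  has_qcovs <- ncol(raw) == 13L
  if (has_qcovs) names(raw)[13] <- "qcovs"

  num_cols <- c("pident", "length", "qstart", "qend", "evalue",
                if (has_qcovs) "qcovs")
  for (cn in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[cn]]))
    bad <- which(is.na(v) & !is.na(raw[[cn]]))
    if (length(bad)) {
      stop(sprintf("malformed BLAST tabular row at line %d of '%s': non-numeric '%s' in column %s",
                   bad[1], path, raw[[cn]][bad[1]], cn), call. = FALSE)
    }
    raw[[cn]] <- v
  }

  hits <- tibble::tibble(
    query_id = raw$qseqid,
    subject_id = raw$sseqid,
    percent_identity = raw$pident,
    alignment_length = as.integer(raw$length),
    e_value = raw$evalue
  )
  if (has_qcovs) {
    hits$query_coverage <- raw$qcovs
  } else {
    if (is.null(lengths)) {
      stop("BLAST file has no qcovs column; supply a protein length table to compute query coverage",
           call. = FALSE)
    }
    len <- setNames(lengths$length, lengths$protein_id)
    ql <- unname(len[hits$query_id])
    if (anyNA(ql)) {
      stop("length table is missing proteins: ",
           paste(unique(hits$query_id[is.na(ql)]), collapse = ", "),
           call. = FALSE)
    }
    hits$query_coverage <- 100 * (abs(raw$qend - raw$qstart) + 1) / ql
  }
  hits[hits$query_id != hits$subject_id, ]
}

#' Collapse directional homology hits into per-pair best statistics
#'
#' For each unordered protein pair, retains the statistics of the hit with the
#' smallest e-value; ties are broken by higher identity, then higher coverage,
#' then by lexicographic (query, subject) order.
#'
#' @param hits Tibble from [read_blast6()] (one species).
#' @return Tibble with one row per unordered pair: `protein_a`, `protein_b`
#'   (sorted), `identity`, `coverage`, `e_value`.
#' @export
collapse_to_pairs <- function(hits) {
  if (nrow(hits) == 0) {
    return(tibble::tibble(protein_a = character(), protein_b = character(),
                          identity = numeric(), coverage = numeric(),
                          e_value = numeric()))
  }
  hits |>
    dplyr::mutate(protein_a = pmin(.data$query_id, .data$subject_id),
                  protein_b = pmax(.data$query_id, .data$subject_id)) |>
    dplyr::arrange(.data$protein_a, .data$protein_b, .data$e_value,
                   dplyr::desc(.data$percent_identity),
                   dplyr::desc(.data$query_coverage),
                   .data$query_id, .data$subject_id) |>
    dplyr::group_by(.data$protein_a, .data$protein_b) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::transmute(.data$protein_a, .data$protein_b,
                     identity = .data$percent_identity,
                     coverage = .data$query_coverage,
                     e_value = .data$e_value)
}

#' Confidence-tier thresholds for paralog assignment
#'
#' Inclusive identity/coverage thresholds defining the three nested paralog
#' confidence tiers: low confidence (LC, >= 25% identity, >= 40% query
#' coverage), medium confidence (MC, >= 30%, >= 50%) and high confidence
#' (HC, >= 40%, >= 60%, plus identical significant domain content). Domain
#' annotations participate only when their p-value is below `domain_p_cutoff`.
#'
#' @param lc,mc,hc Numeric length-2 vectors `c(min_identity, min_coverage)`.
#' @param domain_p_cutoff Significance cutoff for domain annotations.
#' @param hc_requires_identical_domains Whether HC additionally demands equal
#'   domain-content multisets.
#' @return A list of class `tier_thresholds`.
#' @export
tier_thresholds <- function(lc = c(25, 40), mc = c(30, 50), hc = c(40, 60),
                            domain_p_cutoff = 1e-5,
                            hc_requires_identical_domains = TRUE) {
  th <- list(LC = lc, MC = mc, HC = hc,
             domain_p_cutoff = domain_p_cutoff,
             hc_requires_identical_domains = hc_requires_identical_domains)
  for (i in 1:2) {
    if (!(th$LC[i] <= th$MC[i] && th$MC[i] <= th$HC[i])) {
      stop("tier thresholds must be ordered LC <= MC <= HC component-wise",
           call. = FALSE)
    }
  }
  class(th) <- "tier_thresholds"
  th
}

# Multiset signature of a protein's significant domains: sorted ids with
# multiplicity, collapsed to one string.
domain_signatures <- function(domains, p_cutoff) {
  sig <- domains[domains$p_value < p_cutoff, , drop = FALSE]
  if (nrow(sig) == 0) {
    return(tibble::tibble(protein_id = character(), signature = character()))
  }
  sig |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(signature = paste(sort(.data$domain_id), collapse = ";"),
                     .groups = "drop")
}

#' Assign paralogous pairs to inclusive confidence tiers
#'
#' Labels each pair with its highest attained tier; pairs below the LC
#' thresholds are discarded. HC additionally requires the multisets of
#' significant domain identifiers (p-value below the cutoff) of the two
#' proteins to be equal; pairs meeting the HC identity/coverage thresholds
#' but differing in domain content stay at MC. Tiers are inclusive: every HC
#' pair is also an MC and LC pair, so downstream tier cells select
#' `tier >= cell tier`.
#'
#' @param pairs Tibble from [collapse_to_pairs()].
#' @param domains Tibble with columns `protein_id`, `domain_id`, `p_value`,
#'   or `NULL` when no domain data are available (HC is then unattainable and
#'   `same_domain_content` is `NA`).
#' @param thresholds A [tier_thresholds()].
#' @return Tibble of paralogous pairs with columns `pair_id`, `protein_a`,
#'   `protein_b`, `identity`, `coverage`, `e_value`, `tier`,
#'   `same_domain_content`.
#' @export
assign_tiers <- function(pairs, domains = NULL, thresholds = tier_thresholds()) {
  meets <- function(tier) {
    pairs$identity >= thresholds[[tier]][1] &
      pairs$coverage >= thresholds[[tier]][2]
  }
  lc <- meets("LC")
  mc <- meets("MC")
  hc <- meets("HC")
  if (is.null(domains)) {
    same_dom <- rep(NA, nrow(pairs))
  } else {
    sigs <- domain_signatures(domains, thresholds$domain_p_cutoff)
    sig_of <- setNames(sigs$signature, sigs$protein_id)
    sa <- unname(sig_of[pairs$protein_a])
    sb <- unname(sig_of[pairs$protein_b])
    sa[is.na(sa)] <- ""
    sb[is.na(sb)] <- ""
    same_dom <- sa == sb
  }
  if (thresholds$hc_requires_identical_domains) {
    hc <- hc & !is.na(same_dom) & same_dom
  }
  tier <- dplyr::case_when(hc ~ "HC", mc ~ "MC", lc ~ "LC",
                           .default = NA_character_)
  out <- pairs |>
    dplyr::mutate(pair_id = pair_key(.data$protein_a, .data$protein_b),
                  tier = tier,
                  same_domain_content = same_dom) |>
    dplyr::filter(!is.na(.data$tier)) |>
    dplyr::select("pair_id", "protein_a", "protein_b", "identity", "coverage",
                  "e_value", "tier", "same_domain_content") |>
    dplyr::arrange(.data$pair_id)
  out
}

#' Annotate pairs with whole-genome-duplication (ohnolog) status
#'
#' Flags pairs present in a two-column ohnolog pair list (either ordering
#' matches). Purely annotative; has no effect on tier assignment or fate
#' classification.
#'
#' @param path Path to a two-column TSV of protein id pairs (no header).
#' @param pairs Tibble from [assign_tiers()].
#' @return `pairs` with an added logical `ohnolog` column.
#' @export
load_ohnolog_flags <- function(path, pairs) {
  ohno <- readr::read_tsv(path, col_names = c("a", "b"), col_types = "cc")
  keys <- unique(pair_key(ohno$a, ohno$b))
  known <- unique(c(pairs$protein_a, pairs$protein_b))
  missing <- setdiff(unique(c(ohno$a, ohno$b)), known)
  if (length(missing) && nrow(ohno)) {
    warning("ohnolog list names ", length(missing),
            " protein id(s) absent from the pair set", call. = FALSE)
  }
  pairs |>
    dplyr::mutate(ohnolog = pair_key(.data$protein_a, .data$protein_b) %in% keys)
}
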