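#' Generate a synthetic two-species scenario with known ground truth
#'
#' Builds a complete, seeded scenario for validating the fate-classification
#' pipeline end to end: a species-B proteome containing paralogous families
#' with known divergence fates, all-vs-all homology hits placing each pair in
#' an intended confidence tier, multi-database PPI observations corrupted by
#' the configured biases, curated complex records at the three evidence tiers,
#' and a species-A proteome supplying homomeric orthologs (singletons or
#' obligatory-homomeric pairs) for a fraction of the heteromeric species-B
#' families, connected by reciprocal inter-species homology hits.
#'
#' Observation biases emulate the known pathologies of high-throughput PPI
#' data: homomer-blind detection methods (pulldown-like observations of
#' self-edges are lost), edges seen in only one bait/prey direction, spurious
#' single-database edges, and well-supported but cross-compartment false
#' edges. Mobile-element (retrotransposon-like) families of 18 near-identical
#' self-interacting proteins act as confounders; their pairs carry no truth
#' fate and are meant to be removed by the mobile-element filter.
#'
#' @param config A [scenario_config()].
#' @return A list of class `duplo_scenario` with elements `config`, `proteins`,
#'   `domains`, `hits` (per-species homology hit tables), `ppi` (per-species
#'   raw record tables), `localization`, `complexes`, `interspecies`
#'   (`fwd`/`rev` cross-species hit tables), and `truth` (see Details).
#'
#' @details The `truth` element holds: `pairs` (per-pair fate and interaction
#'   flags), `proteins` (self-interaction truth and mobile-element flags),
#'   `families` (species-A ortholog status and oligomeric orders),
#'   `edges`/`a_edges` (true undirected edge lists), `injected_false_positive`
#'   and `injected_mislocalized` (the spurious edges added by the biases), and
#'   `n_transitions` (count of injected homomer-to-heteromer transitions).
#' @export
generate_scenario <- function(config = scenario_config()) {
  validate_scenario_config(config)
  set.seed(config$seed)

  fam <- build_families(config)
  prot <- build_proteins(fam, config)
  dom <- build_domains(fam, prot)
  pairs_truth <- build_truth_pairs(fam, prot)
  hits_b <- build_intra_hits(pairs_truth, prot, config)

  edges_b <- build_truth_edges(pairs_truth, prot)
  ppi_b <- emit_ppi_records(edges_b, config)
  injected <- inject_noise_edges(edges_b, prot, config)
  ppi_b <- dplyr::bind_rows(ppi_b, injected$records)

  aside <- build_species_a(fam, pairs_truth, dom, config)
  complexes <- build_complexes(fam, pairs_truth, prot, aside, config)

  localization <- dplyr::bind_rows(
    prot |> dplyr::transmute(protein_id = .data$id,
                             compartment = paste0("c", .data$compartment)),
    aside$proteins |> dplyr::transmute(protein_id = .data$id,
                                       compartment = paste0("c", .data$compartment))
  )

  proteins <- dplyr::bind_rows(
    prot |> dplyr::select("id", "species", "compartment", "retro"),
    aside$proteins |> dplyr::select("id", "species", "compartment", "retro")
  )

  truth <- list(
    pairs = pairs_truth |>
      dplyr::select("pair_id", "protein_a", "protein_b", "family_id", "fate",
                    "tier", "self_a", "self_b", "cross",
                    "other_partner_a", "other_partner_b"),
    proteins = dplyr::bind_rows(
      prot |> dplyr::select("id", "species", "self_interacting", "retro"),
      aside$proteins |> dplyr::select("id", "species", "self_interacting", "retro")
    ),
    families = aside$families,
    edges = edges_b,
    a_edges = aside$edges,
    injected_false_positive = injected$false_positive,
    injected_mislocalized = injected$mislocalized,
    n_transitions = aside$n_transitions
  )

  structure(list(
    config = config,
    proteins = proteins,
    domains = dplyr::bind_rows(dom, aside$domains),
    hits = list(A = blast6_to_hits(aside$hits), B = blast6_to_hits(hits_b)),
    ppi = list(A = aside$ppi, B = ppi_b),
    localization = localization,
    complexes = complexes,
    interspecies = list(fwd = blast6_to_hits(aside$interspecies$fwd),
                        rev = blast6_to_hits(aside$interspecies$rev)),
    truth = truth
  ), class = "duplo_scenario")
}

# ---- internal builders ------------------------------------------------------

build_families <- function(config) {
  counts <- config$n_families_per_fate[FATES]
  fate <- rep(names(counts), counts)
  n <- length(fate)
  tibble::tibble(
    family_id = sprintf("fam%04d", seq_len(n)),
    fate = fate,
    tier = if (n) sample(TIERS, n, replace = TRUE) else character(),
    compartment = if (n) sample.int(config$n_compartments, n, replace = TRUE) else integer()
  )
}

build_proteins <- function(fam, config) {
  counter <- new.env()
  counter$i <- 0L
  next_ids <- function(k) {
    ids <- sprintf("B%05d", counter$i + seq_len(k))
    counter$i <- counter$i + k
    ids
  }
  n_fam <- nrow(fam)
  members <- tibble::tibble(
    id = next_ids(2L * n_fam),
    family_id = rep(fam$family_id, each = 2),
    role = rep(c("a", "b"), times = n_fam),
    compartment = rep(fam$compartment, each = 2),
    retro = FALSE
  )
  n_ho <- sum(fam$fate == "hetero_others")
  partners <- tibble::tibble(
    id = next_ids(n_ho),
    family_id = fam$family_id[fam$fate == "hetero_others"],
    role = "partner",
    compartment = fam$compartment[fam$fate == "hetero_others"],
    retro = FALSE
  )
  singles <- tibble::tibble(
    id = next_ids(config$n_singletons),
    family_id = NA_character_,
    role = "singleton",
    compartment = if (config$n_singletons)
      sample.int(config$n_compartments, config$n_singletons, replace = TRUE) else integer(),
    retro = FALSE
  )
  n_retro <- config$n_retrotransposon_families
  retro <- tibble::tibble(
    id = next_ids(18L * n_retro),
    family_id = rep(sprintf("retro%02d", seq_len(n_retro)), each = 18),
    role = "retro",
    compartment = 1L,
    retro = TRUE
  )
  prot <- dplyr::bind_rows(members, partners, singles, retro)
  prot$species <- "B"
  # singleton homomers: roughly half of the singletons self-interact
  prot$self_interacting <- prot$role == "retro" |
    (prot$role == "singleton" & runif(nrow(prot)) < 0.5)
  prot
}

build_domains <- function(fam, prot) {
  fam_dom <- tibble::tibble(
    family_id = c(fam$family_id,
                  unique(prot$family_id[prot$role == "retro"])),
    domain_id = sprintf("PF%05d", seq_len(nrow(fam) +
                                            length(unique(prot$family_id[prot$role == "retro"]))))
  )
  carriers <- prot |>
    dplyr::filter(.data$role %in% c("a", "b", "retro")) |>
    dplyr::inner_join(fam_dom, by = "family_id")
  partner_dom <- prot |>
    dplyr::filter(.data$role == "partner") |>
    dplyr::mutate(domain_id = sprintf("PFP%04d", dplyr::row_number()))
  dom <- dplyr::bind_rows(
    carriers |> dplyr::select("id", "domain_id"),
    partner_dom |> dplyr::select("id", "domain_id")
  )
  tibble::tibble(
    protein_id = dom$id,
    domain_id = dom$domain_id,
    p_value = signif(10^-runif(nrow(dom), 6, 20), 3)
  )
}

build_truth_pairs <- function(fam, prot) {
  if (nrow(fam) == 0) {
    return(tibble::tibble(
      pair_id = character(), family_id = character(), fate = character(),
      tier = character(), compartment = integer(), protein_a = character(),
      protein_b = character(), partner = character(), self_a = logical(),
      self_b = logical(), cross = logical(), other_partner_a = logical(),
      other_partner_b = logical()))
  }
  members <- prot |>
    dplyr::filter(.data$role %in% c("a", "b")) |>
    tidyr::pivot_wider(id_cols = "family_id", names_from = "role",
                       values_from = "id")
  partners <- prot |>
    dplyr::filter(.data$role == "partner") |>
    dplyr::select("family_id", partner = "id")
  pairs <- fam |>
    dplyr::inner_join(members, by = "family_id") |>
    dplyr::left_join(partners, by = "family_id")
  n <- nrow(pairs)
  pairs |>
    dplyr::mutate(
      protein_a = pmin(.data$a, .data$b),
      protein_b = pmax(.data$a, .data$b),
      pair_id = paste(.data$protein_a, .data$protein_b, sep = "|"),
      self_a = .data$fate %in% c("obligatory_homo", "mixed", "hetero_others"),
      # mixed: at least one self-interactor; the second one by a fair coin
      self_b = .data$fate == "obligatory_homo" |
        (.data$fate == "mixed" & runif(n) < 0.5),
      cross = .data$fate %in% c("obligatory_hetero", "mixed"),
      other_partner_a = FALSE,
      other_partner_b = .data$fate == "hetero_others"
    ) |>
    dplyr::select("pair_id", "family_id", "fate", "tier", "compartment",
                  "protein_a", "protein_b", "partner",
                  "self_a", "self_b", "cross",
                  "other_partner_a", "other_partner_b")
}

# Sample identity/coverage inside the band that makes `tier` the highest
# attained tier: [tier lower bound, next tier's lower bound), closed at both
# ends for HC.
sample_tier_band <- function(tier, ranges, axis, n) {
  lo <- vapply(TIERS, function(t) ranges[[t]][[axis]][1], numeric(1))
  hi_all <- ranges[["LC"]][[axis]][2]
  lower <- lo[tier]
  upper <- c(LC = lo[["MC"]] - 0.1, MC = lo[["HC"]] - 0.1, HC = hi_all)[tier]
  runif(n, lower, upper)
}

blast6_rows <- function(query, subject, identity, coverage, e_value) {
  len <- pmax(30L, as.integer(round(coverage / 100 * 400)))
  tibble::tibble(
    qseqid = query, sseqid = subject,
    pident = round(identity, 1),
    length = len,
    mismatch = as.integer(round((1 - identity / 100) * len)),
    gapopen = pmin(5L, as.integer(round((1 - identity / 100) * 10))),
    qstart = 1L, qend = len, sstart = 1L, send = len,
    evalue = signif(e_value, 3),
    bitscore = round(len * identity / 100 * 2, 1),
    qcovs = round(coverage, 1)
  )
}

# Parsed-hit view of a 13-column BLAST table (same schema as read_blast6).
blast6_to_hits <- function(raw) {
  tibble::tibble(
    query_id = raw$qseqid,
    subject_id = raw$sseqid,
    percent_identity = raw$pident,
    alignment_length = as.integer(raw$length),
    e_value = raw$evalue,
    query_coverage = raw$qcovs
  )
}

# Inverse of blast6_to_hits: rebuild the full 13-column dialect
# deterministically from the parsed fields, so write/read round-trips are
# exact.
hits_to_blast6 <- function(hits) {
  len <- hits$alignment_length
  id <- hits$percent_identity
  tibble::tibble(
    qseqid = hits$query_id, sseqid = hits$subject_id,
    pident = id,
    length = len,
    mismatch = as.integer(round((1 - id / 100) * len)),
    gapopen = pmin(5L, as.integer(round((1 - id / 100) * 10))),
    qstart = 1L, qend = len, sstart = 1L, send = len,
    evalue = hits$e_value,
    bitscore = round(len * id / 100 * 2, 1),
    qcovs = hits$query_coverage
  )
}

build_intra_hits <- function(pairs_truth, prot, config) {
  rng <- config$identity_coverage_ranges
  n <- nrow(pairs_truth)
  fam_hits <- NULL
  if (n) {
    identity <- numeric(n)
    coverage <- numeric(n)
    for (t in TIERS) {
      k <- pairs_truth$tier == t
      identity[k] <- sample_tier_band(t, rng, "identity", sum(k))
      coverage[k] <- sample_tier_band(t, rng, "coverage", sum(k))
    }
    ev <- 10^-runif(n, 10, 50)
    fam_hits <- dplyr::bind_rows(
      blast6_rows(pairs_truth$protein_a, pairs_truth$protein_b, identity, coverage, ev),
      blast6_rows(pairs_truth$protein_b, pairs_truth$protein_a, identity, coverage, ev)
    )
  }
  retro <- prot |> dplyr::filter(.data$retro)
  retro_hits <- NULL
  if (nrow(retro)) {
    combos <- retro |>
      dplyr::group_by(.data$family_id) |>
      dplyr::reframe(as.data.frame(t(utils::combn(.data$id, 2)),
                                   stringsAsFactors = FALSE))
    m <- nrow(combos)
    id_r <- runif(m, 85, 99)
    cov_r <- runif(m, 90, 100)
    ev_r <- 10^-runif(m, 50, 150)
    retro_hits <- dplyr::bind_rows(
      blast6_rows(combos$V1, combos$V2, id_r, cov_r, ev_r),
      blast6_rows(combos$V2, combos$V1, id_r, cov_r, ev_r)
    )
  }
  out <- dplyr::bind_rows(fam_hits, retro_hits)
  if (ncol(out) == 0) {
    out <- blast6_rows(character(), character(), numeric(), numeric(),
                       numeric())
  }
  out
}

build_truth_edges <- function(pairs_truth, prot) {
  selfs <- prot |>
    dplyr::filter(.data$self_interacting) |>
    dplyr::transmute(a = .data$id, b = .data$id)
  # retro/singleton self-edges above; family selfs from the truth flags
  fam_selfs <- dplyr::bind_rows(
    pairs_truth |> dplyr::filter(.data$self_a) |>
      dplyr::transmute(a = .data$protein_a, b = .data$protein_a),
    pairs_truth |> dplyr::filter(.data$self_b) |>
      dplyr::transmute(a = .data$protein_b, b = .data$protein_b)
  )
  crosses <- pairs_truth |>
    dplyr::filter(.data$cross) |>
    dplyr::transmute(a = .data$protein_a, b = .data$protein_b)
  partner_edges <- pairs_truth |>
    dplyr::filter(.data$fate == "hetero_others") |>
    dplyr::transmute(a = pmin(.data$protein_b, .data$partner),
                     b = pmax(.data$protein_b, .data$partner))
  dplyr::bind_rows(selfs, fam_selfs, crosses, partner_edges) |>
    dplyr::distinct()
}

# Expand true undirected edges into per-database, per-direction raw records,
# applying the missing-direction and homomer-blind biases.
emit_ppi_records <- function(edges, config) {
  if (!nrow(edges)) return(empty_ppi_records())
  dbs <- sprintf("DB%d", seq_len(config$n_databases))
  ed <- edges |>
    dplyr::mutate(
      is_self = .data$a == .data$b,
      miss = !.data$is_self & runif(dplyr::n()) < config$p_missing_direction,
      drop_a = .data$miss & runif(dplyr::n()) < 0.5
    )
  dir_rows <- dplyr::bind_rows(
    ed |> dplyr::filter(!(.data$miss & .data$drop_a)) |>
      dplyr::mutate(bait = .data$a, prey = .data$b),
    ed |> dplyr::filter(!.data$is_self, !(.data$miss & !.data$drop_a)) |>
      dplyr::mutate(bait = .data$b, prey = .data$a)
  )
  recs <- dir_rows[rep(seq_len(nrow(dir_rows)), each = length(dbs)), ]
  recs$source_db <- rep(dbs, times = nrow(dir_rows))
  n <- nrow(recs)
  blind <- runif(n) < config$p_homomer_blind_method
  recs$method_class <- ifelse(blind, "pulldown",
                              sample(c("two_hybrid", "other"), n, replace = TRUE))
  recs <- recs[!(blind & recs$is_self), ]
  tibble::tibble(
    interactor_a = recs$a, interactor_b = recs$b,
    source_db = recs$source_db,
    bait_id = recs$bait, prey_id = recs$prey,
    method_class = recs$method_class,
    evidence_class = "experimental"
  )
}

empty_ppi_records <- function() {
  tibble::tibble(interactor_a = character(), interactor_b = character(),
                 source_db = character(), bait_id = character(),
                 prey_id = character(), method_class = character(),
                 evidence_class = character())
}

empty_edge_list <- function() tibble::tibble(a = character(), b = character())

# Spurious edges: cross-compartment edges carry strong (two-database,
# both-direction) support and are the co-localization filter's job; false
# positives carry single-database, single-direction support and are the
# evidence filter's job. The two sets are kept disjoint from the truth and
# from each other.
inject_noise_edges <- function(edges_b, prot, config) {
  n_true <- nrow(edges_b)
  truth_keys <- pair_key(edges_b$a, edges_b$b)
  cand <- prot |> dplyr::filter(!.data$retro)
  dbs <- sprintf("DB%d", seq_len(config$n_databases))

  sample_pairs <- function(k, exclude_keys, need_diff_compartment) {
    if (k == 0 || nrow(cand) < 2) return(empty_edge_list())
    out <- empty_edge_list()
    tries <- 0L
    while (nrow(out) < k && tries < 20L) {
      i <- sample.int(nrow(cand), 3L * k, replace = TRUE)
      j <- sample.int(nrow(cand), 3L * k, replace = TRUE)
      ok <- i != j
      if (need_diff_compartment) {
        ok <- ok & cand$compartment[i] != cand$compartment[j]
      }
      draw <- tibble::tibble(a = pmin(cand$id[i], cand$id[j])[ok],
                             b = pmax(cand$id[i], cand$id[j])[ok]) |>
        dplyr::distinct() |>
        dplyr::filter(!pair_key(.data$a, .data$b) %in% exclude_keys)
      out <- dplyr::bind_rows(out, draw) |> dplyr::distinct()
      tries <- tries + 1L
    }
    utils::head(out, k)
  }

  n_mis <- rbinom(1, n_true, config$p_mislocalized_edge)
  mis <- sample_pairs(n_mis, truth_keys, need_diff_compartment = TRUE)
  n_fp <- rbinom(1, n_true, config$p_false_positive_edge)
  fp <- sample_pairs(n_fp, c(truth_keys, pair_key(mis$a, mis$b)),
                     need_diff_compartment = FALSE)

  mis_recs <- NULL
  if (nrow(mis)) {
    two_dbs <- replicate(nrow(mis), sample(dbs, 2), simplify = FALSE)
    mis_long <- mis[rep(seq_len(nrow(mis)), each = 4), ]
    mis_long$source_db <- unlist(lapply(two_dbs, function(d) c(d, d)))
    bait_first <- rep(c(TRUE, TRUE, FALSE, FALSE), times = nrow(mis))
    mis_recs <- tibble::tibble(
      interactor_a = mis_long$a, interactor_b = mis_long$b,
      source_db = mis_long$source_db,
      bait_id = ifelse(bait_first, mis_long$a, mis_long$b),
      prey_id = ifelse(bait_first, mis_long$b, mis_long$a),
      method_class = sample(c("two_hybrid", "other"), nrow(mis_long), replace = TRUE),
      evidence_class = "experimental"
    )
  }
  fp_recs <- NULL
  if (nrow(fp)) {
    fp_recs <- tibble::tibble(
      interactor_a = fp$a, interactor_b = fp$b,
      source_db = sample(dbs, nrow(fp), replace = TRUE),
      bait_id = fp$a, prey_id = fp$b,
      method_class = sample(c("two_hybrid", "pulldown", "other"),
                            nrow(fp), replace = TRUE),
      evidence_class = "experimental"
    )
  }
  list(records = dplyr::bind_rows(mis_recs, fp_recs),
       false_positive = fp, mislocalized = mis)
}

build_species_a <- function(fam, pairs_truth, dom_b, config) {
  hetero <- fam |> dplyr::filter(.data$fate %in% c("obligatory_hetero", "mixed"))
  n_trans <- round(config$transition_fraction * nrow(hetero))
  trans_fams <- if (n_trans > 0) sort(sample(hetero$family_id, n_trans)) else character()

  fam_a <- fam |>
    dplyr::mutate(a_status = dplyr::case_when(
      !.data$family_id %in% trans_fams ~ "absent",
      runif(dplyr::n()) < config$p_singleton_ortholog ~ "homomer_singleton",
      TRUE ~ "homomer_pair"
    ))

  trans <- fam_a |> dplyr::filter(.data$a_status != "absent")
  n_a <- sum(ifelse(trans$a_status == "homomer_singleton", 1L, 2L))
  a_ids_list <- vector("list", nrow(trans))
  counter <- 0L
  for (i in seq_len(nrow(trans))) {
    k <- if (trans$a_status[i] == "homomer_singleton") 1L else 2L
    a_ids_list[[i]] <- sprintf("A%05d", counter + seq_len(k))
    counter <- counter + k
  }
  trans$a_ids <- vapply(a_ids_list, paste, character(1), collapse = "|")

  # oligomeric orders: ancestral homodimer; the derived heteromer either
  # retains order 2 (1+1) or expands to 4/6/8 subunits
  n_t <- nrow(trans)
  retained <- runif(n_t) < 0.5
  trans$order_a <- rep(2L, n_t)
  trans$order_b <- ifelse(retained, 2L,
                          if (n_t) sample(c(4L, 6L, 8L), n_t, replace = TRUE) else integer())
  trans$order_relation <- ifelse(retained, "retained", "changed")

  proteins_a <- tibble::tibble(
    id = as.character(unlist(a_ids_list)),
    family_id = rep(trans$family_id, lengths(a_ids_list)),
    species = "A",
    compartment = rep(trans$compartment, lengths(a_ids_list)),
    retro = FALSE,
    self_interacting = TRUE
  )

  # domain sharing with the orthologous B family
  fam_dom <- dom_b |>
    dplyr::inner_join(
      pairs_truth |> dplyr::select(protein_id = "protein_a", "family_id"),
      by = "protein_id") |>
    dplyr::distinct(.data$family_id, .data$domain_id)
  domains_a <- proteins_a |>
    dplyr::inner_join(fam_dom, by = "family_id") |>
    dplyr::transmute(protein_id = .data$id, domain_id = .data$domain_id,
                     p_value = signif(10^-runif(dplyr::n(), 6, 20), 3))

  # intra-A homology hits for the paralogous A pairs
  pair_rows <- trans[trans$a_status == "homomer_pair", ]
  hits_a <- NULL
  a_pairs <- empty_edge_list()
  if (nrow(pair_rows)) {
    ids <- strsplit(pair_rows$a_ids, "|", fixed = TRUE)
    p1 <- vapply(ids, `[`, character(1), 1)
    p2 <- vapply(ids, `[`, character(1), 2)
    m <- length(p1)
    idn <- runif(m, 45, 90)
    cov <- runif(m, 70, 100)
    ev <- 10^-runif(m, 20, 80)
    hits_a <- dplyr::bind_rows(blast6_rows(p1, p2, idn, cov, ev),
                               blast6_rows(p2, p1, idn, cov, ev))
    a_pairs <- tibble::tibble(a = pmin(p1, p2), b = pmax(p1, p2))
  }

  edges_a <- tibble::tibble(a = proteins_a$id, b = proteins_a$id)
  ppi_a <- emit_ppi_records(edges_a, config)

  # reciprocal inter-species hits: every A ortholog hits both B pair members
  links <- proteins_a |>
    dplyr::inner_join(
      pairs_truth |>
        dplyr::select("family_id", "protein_a", "protein_b") |>
        tidyr::pivot_longer(c("protein_a", "protein_b"), values_to = "b_id") |>
        dplyr::select("family_id", "b_id"),
      by = "family_id", relationship = "many-to-many")
  fwd <- rev <- NULL
  if (nrow(links)) {
    m <- nrow(links)
    idn <- runif(m, 30, 60)
    cov <- runif(m, 50, 90)
    ev_f <- 10^-runif(m, 6, 50)
    ev_r <- 10^-runif(m, 6, 50)
    fwd <- blast6_rows(links$id, links$b_id, idn, cov, ev_f)
    rev <- blast6_rows(links$b_id, links$id, idn, cov, ev_r)
  }

  families <- fam_a |>
    dplyr::left_join(
      trans |> dplyr::select("family_id", "a_ids", "order_a", "order_b",
                             "order_relation"),
      by = "family_id") |>
    dplyr::select("family_id", "fate", "tier", "a_status", "a_ids",
                  "order_a", "order_b", "order_relation")

  list(
    proteins = proteins_a,
    domains = domains_a,
    hits = if (is.null(hits_a)) blast6_rows(character(), character(),
                                            numeric(), numeric(), numeric())
           else hits_a,
    ppi = ppi_a,
    edges = edges_a,
    a_pairs = a_pairs,
    interspecies = list(
      fwd = if (is.null(fwd)) blast6_rows(character(), character(),
                                          numeric(), numeric(), numeric()) else fwd,
      rev = if (is.null(rev)) blast6_rows(character(), character(),
                                          numeric(), numeric(), numeric()) else rev
    ),
    families = families,
    n_transitions = nrow(trans)
  )
}

build_complexes <- function(fam, pairs_truth, prot, aside, config) {
  rows <- list()
  add <- function(id, species, tier, members, copies, contacts = NULL) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      complex_id = id, species = species, tier = tier,
      members = list(tibble::tibble(id = members, copies = copies)),
      contacts = list(if (is.null(contacts))
        tibble::tibble(a = character(), b = character()) else contacts)
    )
  }
  fam_info <- pairs_truth |>
    dplyr::left_join(aside$families |>
                       dplyr::select("family_id", "a_status", "order_b"),
                     by = "family_id")
  n <- nrow(fam_info)
  tier_draw <- if (n) sample(COMPLEX_TIERS, n, replace = TRUE) else character()
  # heteromer complexes of transition families need stoichiometry on record
  tier_draw[!is.na(fam_info$a_status) & fam_info$a_status != "absent"] <-
    sample(c("CS", "PDB"),
           sum(!is.na(fam_info$a_status) & fam_info$a_status != "absent"),
           replace = TRUE)
  k <- 0L
  nid <- function() {
    k <<- k + 1L
    sprintf("cpxB%04d", k)
  }
  cp <- function(tier, x) if (tier == "C") NA_integer_ else as.integer(x)
  for (i in seq_len(n)) {
    f <- fam_info[i, ]
    tier <- tier_draw[i]
    a <- f$protein_a
    b <- f$protein_b
    if (f$fate == "obligatory_homo") {
      add(nid(), "B", tier, a, cp(tier, 2),
          if (tier == "PDB") tibble::tibble(a = a, b = a))
      add(nid(), "B", tier, b, cp(tier, 2),
          if (tier == "PDB") tibble::tibble(a = b, b = b))
    } else if (f$fate %in% c("obligatory_hetero", "mixed")) {
      half <- if (!is.na(f$order_b)) f$order_b / 2 else 1
      add(nid(), "B", tier, c(a, b), cp(tier, c(half, half)),
          if (tier == "PDB") tibble::tibble(a = a, b = b))
      if (f$fate == "mixed") {
        if (f$self_a) add(nid(), "B", tier, a, cp(tier, 2),
                          if (tier == "PDB") tibble::tibble(a = a, b = a))
        if (f$self_b) add(nid(), "B", tier, b, cp(tier, 2),
                          if (tier == "PDB") tibble::tibble(a = b, b = b))
      }
    } else if (f$fate == "hetero_others") {
      self_id <- a
      other_id <- b
      partner <- f$partner
      add(nid(), "B", tier, self_id, cp(tier, 2),
          if (tier == "PDB") tibble::tibble(a = self_id, b = self_id))
      add(nid(), "B", tier, c(other_id, partner), cp(tier, c(1, 1)),
          if (tier == "PDB") tibble::tibble(a = pmin(other_id, partner),
                                            b = pmax(other_id, partner)))
    }
  }
  # species-A homomer complexes (CS tier, homodimers)
  j <- 0L
  for (id in aside$proteins$id) {
    j <- j + 1L
    add(sprintf("cpxA%04d", j), "A", "CS", id, 2L)
  }
  if (!length(rows)) {
    return(tibble::tibble(complex_id = character(), species = character(),
                          tier = character(), members = list(),
                          contacts = list()))
  }
  dplyr::bind_rows(rows)
}
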