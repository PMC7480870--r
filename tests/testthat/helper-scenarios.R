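# Shared scenario builders and brute-force oracles.

# All observation biases off; no mobile-element confounders. Family counts
# default to the module-test scale; acceptance tests pass the full scale.
zero_noise_config <- function(seed, n_families = 40, n_databases = 3,
                              transition_fraction = 0.34) {
  scenario_config(
    seed = seed, n_families = n_families, n_databases = n_databases,
    p_false_positive_edge = 0, p_homomer_blind_method = 0,
    p_missing_direction = 0, p_mislocalized_edge = 0,
    n_retrotransposon_families = 0,
    transition_fraction = transition_fraction
  )
}

# Moderate noise for filter-property runs: spurious weak edges and
# cross-compartment edges on, homomer-blind and direction losses off so the
# truth pairs stay classifiable.
noisy_filter_config <- function(seed, n_families = 100) {
  scenario_config(
    seed = seed, n_families = n_families, n_databases = 3,
    p_false_positive_edge = 0.1, p_homomer_blind_method = 0,
    p_missing_direction = 0, p_mislocalized_edge = 0.1,
    n_retrotransposon_families = 1, transition_fraction = 0
  )
}

ppi_record <- function(a, b, db, bait = a, method = "two_hybrid",
                       evidence = "experimental") {
  tibble::tibble(interactor_a = a, interactor_b = b, source_db = db,
                 bait_id = bait, prey_id = setdiff(c(a, b), bait)[1] %||% a,
                 method_class = method, evidence_class = evidence)
}

`%||%` <- function(x, y) if (length(x) == 0 || is.null(x)) y else x

# Strong-evidence records for one undirected edge: both directions in two
# databases.
strong_records <- function(a, b, dbs = c("DB1", "DB2"), method = "two_hybrid") {
  if (a == b) {
    dplyr::bind_rows(lapply(dbs, function(d) ppi_record(a, a, d, method = method)))
  } else {
    dplyr::bind_rows(lapply(dbs, function(d) {
      dplyr::bind_rows(ppi_record(a, b, d, bait = a, method = method),
                       ppi_record(a, b, d, bait = b, method = method))
    }))
  }
}

edge_tbl <- function(...) {
  compile_edges(dplyr::bind_rows(...))
}

# Brute-force per-pair status derivation: explicit loops over the edge rows,
# independent of the join-based implementation.
naive_status <- function(a, b, edges, all_pairs) {
  has_edge <- function(x, y) {
    any((edges$protein_a == min(x, y)) & (edges$protein_b == max(x, y)))
  }
  paralogs_of <- function(x) {
    unique(c(all_pairs$protein_b[all_pairs$protein_a == x],
             all_pairs$protein_a[all_pairs$protein_b == x]))
  }
  outside <- function(x) {
    nb <- character()
    for (i in seq_len(nrow(edges))) {
      ea <- edges$protein_a[i]; eb <- edges$protein_b[i]
      if (ea == eb) next
      if (ea == x) nb <- c(nb, eb)
      if (eb == x) nb <- c(nb, ea)
    }
    length(setdiff(nb, c(x, paralogs_of(x)))) > 0
  }
  list(self_a = has_edge(a, a), self_b = has_edge(b, b),
       cross = has_edge(a, b),
       other_partner_a = outside(a), other_partner_b = outside(b))
}

# Brute-force tier re-derivation: scan every hit for the pair and apply the
# thresholds directly.
naive_tier <- function(a, b, hits, domains, th = tier_thresholds()) {
  rows <- hits[(hits$query_id == a & hits$subject_id == b) |
                 (hits$query_id == b & hits$subject_id == a), , drop = FALSE]
  if (nrow(rows) == 0) return(NA_character_)
  best <- rows[order(rows$e_value, -rows$percent_identity,
                     -rows$query_coverage, rows$query_id, rows$subject_id), ][1, ]
  sig <- function(x) {
    d <- domains$domain_id[domains$protein_id == x &
                             domains$p_value < th$domain_p_cutoff]
    paste(sort(d), collapse = ";")
  }
  idn <- best$percent_identity
  cov <- best$query_coverage
  if (idn >= th$HC[1] && cov >= th$HC[2] && sig(a) == sig(b)) return("HC")
  if (idn >= th$MC[1] && cov >= th$MC[2]) return("MC")
  if (idn >= th$LC[1] && cov >= th$LC[2]) return("LC")
  NA_character_
}

# Fate assignments for one (dataset, level, criterion) cell, joined to truth.
truth_vs_assigned <- function(scenario, results, dataset = "ppi",
                              level = "f3", criterion = "stringent") {
  asg <- results$assignments
  cell <- asg[asg$dataset == dataset & asg$filter_level == level &
                asg$criterion == criterion, ]
  dplyr::inner_join(scenario$truth$pairs, cell, by = "pair_id",
                    suffix = c("_truth", ""))
}
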