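status_row <- function(self_a = FALSE, self_b = FALSE, cross = FALSE,
                       other_partner_a = FALSE, other_partner_b = FALSE) {
  tibble::tibble(self_a = self_a, self_b = self_b, cross = cross,
                 other_partner_a = other_partner_a,
                 other_partner_b = other_partner_b)
}

test_that("PPI status derivation reads self, cross and outside partners", {
  pairs <- tibble::tibble(protein_a = "A", protein_b = "B")
  st <- interaction_status_ppi(pairs, edge_tbl(strong_records("A", "A"),
                                               strong_records("B", "B")))
  expect_true(st$self_a && st$self_b && !st$cross)

  st <- interaction_status_ppi(pairs, edge_tbl(strong_records("A", "B")))
  expect_true(st$cross && !st$self_a && !st$self_b &&
                !st$other_partner_a && !st$other_partner_b)

  st <- interaction_status_ppi(pairs, edge_tbl(strong_records("A", "A"),
                                               strong_records("B", "C")))
  expect_true(st$self_a && st$other_partner_b && !st$other_partner_a)

  # a paralog (in any analysis pair) never counts as an outside partner
  wide <- tibble::tibble(protein_a = c("A", "B"), protein_b = c("B", "C"))
  st <- interaction_status_ppi(pairs, edge_tbl(strong_records("B", "C")),
                               analysis_pairs = wide)
  expect_false(st$other_partner_b)
})

test_that("the single-pair wrapper matches the vectorised derivation", {
  edges <- edge_tbl(strong_records("A", "A"), strong_records("B", "C"))
  st <- derive_status_ppi(c("B", "A"), edges)
  expect_equal(st$protein_a, "A")
  expect_true(st$self_a)
  expect_true(st$other_partner_b)
})

test_that("fate assignment follows the stringent and flexible definitions", {
  ho <- status_row(self_a = TRUE, other_partner_b = TRUE)
  expect_equal(assign_fate(ho, "stringent"), "hetero_others")
  expect_equal(assign_fate(ho, "flexible"), "obligatory_homo")

  het <- status_row(cross = TRUE)
  expect_equal(assign_fate(het, "stringent"), "obligatory_hetero")
  expect_equal(assign_fate(het, "flexible"), "obligatory_hetero")

  expect_equal(assign_fate(status_row(), "stringent"), "unassigned")
  expect_equal(assign_fate(status_row(), "flexible"), "unassigned")

  one_self_no_partner <- status_row(self_a = TRUE)
  expect_equal(assign_fate(one_self_no_partner, "stringent"), "unassigned")
  expect_equal(assign_fate(one_self_no_partner, "flexible"), "obligatory_homo")
})

make_complex <- function(id, tier, members, copies, contacts = NULL) {
  tibble::tibble(complex_id = id, species = "B", tier = tier,
                 members = list(tibble::tibble(id = members,
                                               copies = as.integer(copies))),
                 contacts = list(if (is.null(contacts))
                   tibble::tibble(a = character(), b = character())
                   else contacts))
}

test_that("curated status applies the tier-specific evidence rules", {
  pairs <- tibble::tibble(protein_a = "A", protein_b = "B")
  no_edges <- edge_tbl(ppi_record("Z", "Z", "DB1"))

  # PDB: copy number >= 2 plus a self-contact suffices without PPI support
  pdb <- make_complex("c1", "PDB", "A", 2,
                      contacts = tibble::tibble(a = "A", b = "A"))
  st <- interaction_status_curated(pairs, pdb, no_edges)
  expect_true(st$self_a && !st$self_b && !st$cross)

  # CS: co-membership needs a PPI cross-edge to call cross
  cs <- make_complex("c2", "CS", c("A", "B"), c(1, 1))
  st <- interaction_status_curated(pairs, cs, no_edges)
  expect_false(st$cross)
  st <- interaction_status_curated(pairs, cs, edge_tbl(strong_records("A", "B")))
  expect_true(st$cross && !st$self_a && !st$self_b)

  # CS: multiple copies without a PPI self-edge is not homomer evidence
  cs2 <- make_complex("c3", "CS", "A", 2)
  st <- interaction_status_curated(pairs, cs2, no_edges)
  expect_false(st$self_a)
  st <- interaction_status_curated(pairs, cs2, edge_tbl(strong_records("A", "A")))
  expect_true(st$self_a)

  # C: unknown copy numbers fall back to membership plus a PPI self-edge
  ct <- make_complex("c4", "C", "A", NA)
  st <- interaction_status_curated(pairs, ct, edge_tbl(strong_records("A", "A")))
  expect_true(st$self_a)
  # a known single-copy membership in a C complex is honoured: not homomer
  # evidence, even with a PPI self-edge on record
  ct1 <- make_complex("c5", "C", "A", 1)
  st <- interaction_status_curated(pairs, ct1, edge_tbl(strong_records("A", "A")))
  expect_false(st$self_a)
})

test_that("contact lists outside the PDB tier are rejected", {
  bad <- make_complex("c1", "CS", c("A", "B"), c(1, 1),
                      contacts = tibble::tibble(a = "A", b = "B"))
  expect_error(interaction_status_curated(
    tibble::tibble(protein_a = "A", protein_b = "B"), bad,
    edge_tbl(ppi_record("Z", "Z", "DB1"))), "PDB")
})

test_that("curated obligatory-homo calls are vetoed by PPI cross-interaction", {
  pairs <- tibble::tibble(pair_id = "A|B", protein_a = "A", protein_b = "B",
                          tier = "HC")
  cpx <- dplyr::bind_rows(
    make_complex("c1", "PDB", "A", 2, tibble::tibble(a = "A", b = "A")),
    make_complex("c2", "PDB", "B", 2, tibble::tibble(a = "B", b = "B")))
  clean <- edge_tbl(strong_records("A", "A"), strong_records("B", "B"))
  with_cross <- edge_tbl(strong_records("A", "A"), strong_records("B", "B"),
                         strong_records("A", "B"))
  asg1 <- classify_pairs(pairs, list(f3 = clean), cpx)
  asg2 <- classify_pairs(pairs, list(f3 = with_cross), cpx)
  cur1 <- asg1[asg1$dataset == "curated" & asg1$criterion == "stringent", ]
  cur2 <- asg2[asg2$dataset == "curated" & asg2$criterion == "stringent", ]
  expect_equal(cur1$fate, "obligatory_homo")
  expect_equal(cur2$fate, "unassigned")
})

test_that("pairs absent from the PPI data are unassigned, and proteins may recur across pairs", {
  pairs <- tibble::tibble(pair_id = c("A|B", "A|C"),
                          protein_a = c("A", "A"), protein_b = c("B", "C"),
                          tier = c("LC", "LC"))
  edges <- edge_tbl(strong_records("A", "A"), strong_records("A", "B"),
                    strong_records("A", "C"))
  asg <- classify_pairs(pairs, list(f2 = edges))
  strg <- asg[asg$criterion == "stringent", ]
  expect_equal(strg$fate[strg$pair_id == "A|B"], "mixed")
  expect_equal(strg$fate[strg$pair_id == "A|C"], "mixed")

  lonely <- tibble::tibble(pair_id = "X|Y", protein_a = "X", protein_b = "Y",
                           tier = "LC")
  asg <- classify_pairs(lonely, list(f2 = edges))
  expect_true(all(asg$fate == "unassigned"))
})

test_that("the homomer set unions PPI self-edges with curated homomer evidence", {
  edges <- edge_tbl(strong_records("S", "S"), strong_records("T", "T"))
  cpx <- dplyr::bind_rows(
    make_complex("c1", "PDB", "P", 2, tibble::tibble(a = "P", b = "P")),
    make_complex("c2", "CS", "T", 2),
    make_complex("c3", "C", "U", NA))
  got <- build_homomer_set(edges, cpx)
  expect_setequal(got, c("S", "T", "P"))  # U lacks a PPI self-edge
})

test_that("criterion nesting holds on noisy scenarios", {
  sc <- generate_scenario(scenario_config(seed = 31, n_families = 80,
                                          n_databases = 3))
  res <- analyze_scenario(sc, transitions = FALSE)
  asg <- res$assignments
  for (ds in unique(asg$dataset)) {
    for (lvl in unique(asg$filter_level)) {
      s <- asg[asg$dataset == ds & asg$filter_level == lvl &
                 asg$criterion == "stringent", ]
      f <- asg[asg$dataset == ds & asg$filter_level == lvl &
                 asg$criterion == "flexible", ]
      expect_true(all(s$pair_id[s$fate == "obligatory_homo"] %in%
                        f$pair_id[f$fate == "obligatory_homo"]))
      expect_true(all(s$pair_id[s$fate == "hetero_others"] %in%
                        f$pair_id[f$fate == "obligatory_homo"]))
      expect_equal(s$pair_id[s$fate == "obligatory_hetero"],
                   f$pair_id[f$fate == "obligatory_hetero"])
      expect_equal(s$pair_id[s$fate == "mixed"], f$pair_id[f$fate == "mixed"])
    }
  }
})

test_that("classification agrees with a brute-force per-pair derivation", {
  sc <- generate_scenario(scenario_config(seed = 37, n_families = 10,
                                          n_databases = 3))
  res <- analyze_scenario(sc, transitions = FALSE)
  edges <- res$edge_sets$f3
  cell <- res$assignments[res$assignments$dataset == "ppi" &
                            res$assignments$filter_level == "f3" &
                            res$assignments$criterion == "stringent", ]
  for (i in seq_len(nrow(cell))) {
    ns <- naive_status(cell$protein_a[i], cell$protein_b[i], edges, res$pairs)
    expect_equal(cell$fate[i],
                 assign_fate(tibble::as_tibble(ns), "stringent"),
                 label = cell$pair_id[i])
    expect_equal(unlist(ns),
                 unlist(cell[i, c("self_a", "self_b", "cross",
                                  "other_partner_a", "other_partner_b")]),
                 label = cell$pair_id[i])
  }
})
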