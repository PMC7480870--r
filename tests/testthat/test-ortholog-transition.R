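hit_tbl <- function(q, s, e) {
  tibble::tibble(query_id = q, subject_id = s, percent_identity = 40,
                 alignment_length = 150L, e_value = e, query_coverage = 70)
}

test_that("reciprocal links demand mutual sub-threshold hits", {
  fwd <- hit_tbl(c("A1", "A2"), c("B1", "B2"), c(1e-10, 1e-4))
  rev <- hit_tbl(c("B1", "B2"), c("A1", "A2"), c(1e-8, 1e-4))
  links <- reciprocal_links(fwd, rev)
  expect_equal(nrow(links), 1L)
  expect_equal(links$protein_a, "A1")
  expect_equal(links$e_value_fwd, 1e-10)
  expect_true(links$reciprocal)

  # one-directional hit: no link
  links <- reciprocal_links(hit_tbl("A1", "B1", 1e-10), hit_tbl("B9", "A9", 1e-10))
  expect_equal(nrow(links), 0L)
})

test_that("links are symmetric up to the species-role swap", {
  fwd <- hit_tbl(c("A1", "A1"), c("B1", "B2"), c(1e-10, 1e-12))
  rev <- hit_tbl(c("B1", "B2"), c("A1", "A1"), c(1e-9, 1e-11))
  ab <- reciprocal_links(fwd, rev)
  ba <- reciprocal_links(rev, fwd)
  expect_setequal(paste(ab$protein_a, ab$protein_b),
                  paste(ba$protein_b, ba$protein_a))
})

test_that("strict best-hit reciprocity prunes non-best links", {
  fwd <- hit_tbl(c("A1", "A1"), c("B1", "B2"), c(1e-20, 1e-10))
  rev <- hit_tbl(c("B1", "B2"), c("A1", "A1"), c(1e-18, 1e-9))
  loose <- reciprocal_links(fwd, rev)
  strict <- reciprocal_links(fwd, rev, strict_best_hit = TRUE)
  expect_equal(nrow(loose), 2L)
  expect_equal(nrow(strict), 1L)
  expect_equal(strict$protein_b, "B1")
})

test_that("the shared-domain filter keeps only links with a common significant domain", {
  links <- tibble::tibble(protein_a = c("A1", "A2", "A3"),
                          protein_b = c("B1", "B2", "B3"),
                          e_value_fwd = 1e-10, e_value_rev = 1e-10,
                          reciprocal = TRUE)
  da <- tibble::tibble(protein_id = c("A1", "A1", "A2"),
                       domain_id = c("D1", "D2", "D1"),
                       p_value = c(1e-8, 1e-8, 1e-8))
  db <- tibble::tibble(protein_id = c("B1", "B2", "B2"),
                       domain_id = c("D2", "D9", "D1"),
                       p_value = c(1e-8, 1e-8, 1e-3))
  got <- shared_domain_filter(links, da, db)
  expect_equal(got$protein_a, "A1")
  expect_equal(got$shared_domains[[1]], "D2")
})

test_that("transition mapping classifies A-side units and demands B-side hetero fates", {
  links <- tibble::tibble(protein_a = c("A1", "A2", "A3", "A4"),
                          protein_b = c("B1", "B2", "B3", "B4"),
                          e_value_fwd = 1e-10, e_value_rev = 1e-10,
                          reciprocal = TRUE)
  a_pairs <- tibble::tibble(pair_id = "A3|A4", protein_a = "A3",
                            protein_b = "A4", tier = "LC")
  b_asg <- tibble::tibble(
    pair_id = c("B1|B2", "B3|B4", "B5|B6"),
    protein_a = c("B1", "B3", "B5"), protein_b = c("B2", "B4", "B6"),
    fate = c("obligatory_hetero", "mixed", "obligatory_homo"))

  got <- map_transitions(links, a_homomers = c("A1", "A3", "A4"),
                         a_pairs = a_pairs, b_assignments = b_asg)
  expect_equal(nrow(got), 2L)
  singleton <- got[got$b_pair == "B1|B2", ]
  expect_equal(singleton$a_side_type, "singleton")
  expect_equal(singleton$a_ids, "A1")
  pairrec <- got[got$b_pair == "B3|B4", ]
  expect_equal(pairrec$a_side_type, "paralog_pair")
  expect_equal(pairrec$a_ids, "A3|A4")
  expect_true(all(got$b_fate %in% c("obligatory_hetero", "mixed")))

  # a non-homomeric A protein yields no record
  got <- map_transitions(links, a_homomers = "A9", a_pairs = a_pairs,
                         b_assignments = b_asg)
  expect_equal(nrow(got), 0L)

  # both-member linkage can be demanded
  got <- map_transitions(links, a_homomers = "A1", a_pairs = a_pairs,
                         b_assignments = b_asg, require_both_members = TRUE)
  expect_equal(nrow(got), 0L)
})

test_that("order comparison distinguishes retained, changed and unknown", {
  trans <- tibble::tibble(a_side_type = "singleton",
                          a_ids = c("A1", "A1", "A1"),
                          b_pair = c("B1|B2", "B3|B4", "B5|B6"),
                          b_fate = "obligatory_hetero")
  a_orders <- tibble::tibble(protein_id = "A1", order = 2L)
  b_orders <- tibble::tibble(pair_id = c("B1|B2", "B3|B4"),
                             order = c(2L, 8L))
  got <- compare_orders(trans, a_orders, b_orders)
  expect_equal(got$order_relation, c("retained", "changed", "unknown"))
})

test_that("oligomeric orders sum known copy numbers and propagate unknowns", {
  cpxs <- dplyr::bind_rows(
    tibble::tibble(complex_id = "c1", species = "B", tier = "CS",
                   members = list(tibble::tibble(id = c("A", "B"),
                                                 copies = c(4L, 4L))),
                   contacts = list(tibble::tibble(a = character(),
                                                  b = character()))),
    tibble::tibble(complex_id = "c2", species = "B", tier = "C",
                   members = list(tibble::tibble(id = "X",
                                                 copies = NA_integer_)),
                   contacts = list(tibble::tibble(a = character(),
                                                  b = character()))))
  ord <- oligomeric_orders(cpxs)
  expect_equal(ord$order, c(8L, NA_integer_))
})

test_that("every scenario transition record satisfies its invariants", {
  sc <- generate_scenario(zero_noise_config(seed = 29, n_families = 40))
  res <- analyze_scenario(sc)
  tr <- res$transitions
  expect_true(all(tr$b_fate %in% c("obligatory_hetero", "mixed")))
  a_hom <- build_homomer_set(
    filter_chain(sc$ppi$A, character(), sc$localization)$f3,
    sc$complexes[sc$complexes$species == "A", ])
  first_a <- vapply(strsplit(tr$a_ids, "|", fixed = TRUE), `[`,
                    character(1), 1)
  expect_true(all(first_a %in% a_hom))
})
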