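write_blast6_file <- function(rows) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  readr::write_tsv(rows, path, col_names = FALSE)
  path
}

b6row <- function(q, s, id = 50, len = 200, e = 1e-20, cov = NULL,
                  qstart = 1, qend = len) {
  r <- tibble::tibble(q = q, s = s, id = id, len = len, mm = 10L, go = 1L,
                      qs = qstart, qe = qend, ss = 1L, se = len,
                      e = e, bits = 300)
  if (!is.null(cov)) r$cov <- cov
  r
}

test_that("blast6 parsing drops self-hits and keeps reciprocal duplicates", {
  f <- write_blast6_file(dplyr::bind_rows(
    b6row("P1", "P1", cov = 100),
    b6row("P1", "P2", id = 25.0, cov = 60),
    b6row("P2", "P1", id = 25.0, cov = 60)))
  hits <- read_blast6(f)
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$percent_identity, c(25, 25))

  only_self <- write_blast6_file(b6row("P1", "P1", cov = 100))
  expect_equal(nrow(read_blast6(only_self)), 0L)
})

test_that("coverage is computed from a length table when qcovs is absent", {
  f <- write_blast6_file(b6row("P1", "P2", len = 120, qstart = 1, qend = 120))
  lengths <- tibble::tibble(protein_id = c("P1", "P2"), length = c(200L, 300L))
  hits <- read_blast6(f, lengths)
  expect_equal(hits$query_coverage, 100 * 120 / 200)
  expect_error(read_blast6(f), "length table")
  expect_error(read_blast6(f, tibble::tibble(protein_id = "P2", length = 300L)),
               "missing proteins")
})

test_that("malformed rows are reported with their line number", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(c("P1", "P2", "50", "200", "10", "1", "1", "200", "1",
                       "200", "1e-20", "300", "80"), collapse = "\t"),
               paste(c("P3", "P4", "notanumber", "200", "10", "1", "1", "200",
                       "1", "200", "1e-20", "300", "80"), collapse = "\t")),
             path)
  expect_error(read_blast6(path), "line 2")
})

test_that("pair collapse keeps the smallest e-value with documented tie-breaks", {
  hits <- dplyr::bind_rows(
    tibble::tibble(query_id = "A", subject_id = "B", percent_identity = 30,
                   alignment_length = 100L, e_value = 1e-10,
                   query_coverage = 50),
    tibble::tibble(query_id = "B", subject_id = "A", percent_identity = 32,
                   alignment_length = 100L, e_value = 1e-8,
                   query_coverage = 55))
  got <- collapse_to_pairs(hits)
  expect_equal(nrow(got), 1L)
  expect_equal(got$identity, 30)

  tie <- dplyr::bind_rows(
    tibble::tibble(query_id = "A", subject_id = "B", percent_identity = 30,
                   alignment_length = 100L, e_value = 1e-8,
                   query_coverage = 50),
    tibble::tibble(query_id = "B", subject_id = "A", percent_identity = 35,
                   alignment_length = 100L, e_value = 1e-8,
                   query_coverage = 40))
  expect_equal(collapse_to_pairs(tie)$identity, 35)

  single <- hits[1, ]
  expect_equal(collapse_to_pairs(single)$coverage, 50)
})

test_that("tier assignment honours inclusive boundaries and the domain check", {
  pairs <- tibble::tibble(
    protein_a = c("A1", "B1", "C1"), protein_b = c("A2", "B2", "C2"),
    identity = c(25.0, 45, 24.9), coverage = c(40.0, 70, 90),
    e_value = c(1e-10, 1e-30, 1e-5))
  domains <- tibble::tibble(
    protein_id = c("B1", "B1", "B2"),
    domain_id = c("D1", "D2", "D1"),
    p_value = c(1e-8, 1e-8, 1e-8))
  got <- assign_tiers(pairs, domains)
  expect_equal(nrow(got), 2L)
  expect_equal(got$tier[got$protein_a == "A1"], "LC")
  # HC thresholds met but domain multisets differ: stays MC
  expect_equal(got$tier[got$protein_a == "B1"], "MC")
  expect_false(got$same_domain_content[got$protein_a == "B1"])

  # equal multisets (copy number matters): HC granted
  dom_eq <- tibble::tibble(protein_id = c("B1", "B2"),
                           domain_id = c("D1", "D1"),
                           p_value = c(1e-8, 1e-8))
  expect_equal(assign_tiers(pairs[2, ], dom_eq)$tier, "HC")
  # insignificant annotations do not participate
  dom_insig <- dplyr::bind_rows(dom_eq,
                                tibble::tibble(protein_id = "B1",
                                               domain_id = "D9",
                                               p_value = 1e-3))
  expect_equal(assign_tiers(pairs[2, ], dom_insig)$tier, "HC")
})

test_that("tier counts are nested and shrink monotonically as thresholds rise", {
  sc <- generate_scenario(scenario_config(seed = 13, n_families = 80))
  pairs <- collapse_to_pairs(sc$hits$B)
  tiers <- assign_tiers(pairs, sc$domains)
  n_lc <- nrow(tiers)
  n_mc <- sum(tiers$tier %in% c("MC", "HC"))
  n_hc <- sum(tiers$tier == "HC")
  expect_lte(n_hc, n_mc)
  expect_lte(n_mc, n_lc)

  stricter <- assign_tiers(pairs, sc$domains,
                           tier_thresholds(lc = c(30, 50), mc = c(35, 55),
                                           hc = c(45, 65)))
  expect_lte(nrow(stricter), n_lc)
  expect_lte(sum(stricter$tier == "HC"), n_hc)
})

test_that("tier assignment agrees with a brute-force re-derivation on small scenarios", {
  sc <- generate_scenario(zero_noise_config(seed = 17, n_families = 12))
  hits <- sc$hits$B
  tiers <- assign_tiers(collapse_to_pairs(hits), sc$domains)
  for (i in seq_len(nrow(tiers))) {
    expect_equal(tiers$tier[i],
                 naive_tier(tiers$protein_a[i], tiers$protein_b[i],
                            hits, sc$domains),
                 label = tiers$pair_id[i])
  }
})

test_that("ohnolog flags annotate without altering tiers", {
  pairs <- assign_tiers(tibble::tibble(
    protein_a = c("X1", "Y1"), protein_b = c("X2", "Y2"),
    identity = c(50, 50), coverage = c(80, 80), e_value = c(1e-30, 1e-30)))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("X2\tX1", path)
  got <- load_ohnolog_flags(path, pairs)
  expect_true(got$ohnolog[got$protein_a == "X1"])
  expect_false(got$ohnolog[got$protein_a == "Y1"])
  expect_equal(got$tier, pairs$tier)

  unknown <- withr::local_tempfile(fileext = ".tsv")
  writeLines("Z1\tZ2", unknown)
  expect_warning(load_ohnolog_flags(unknown, pairs), "absent")

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(), empty)
  expect_false(any(load_ohnolog_flags(empty, pairs)$ohnolog))
})
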