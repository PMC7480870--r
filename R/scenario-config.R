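#' Configuration for a synthetic two-species interaction scenario
#'
#' Builds a validated configuration for [generate_scenario()]. The generator
#' emulates a eukaryote-like species "B" whose proteome contains paralogous
#' families with known divergence fates, observed through multi-database PPI
#' records corrupted by configurable biases, plus a prokaryote-like species "A"
#' supplying homomeric orthologs for a fraction of the heteromeric families.
#'
#' Defaults encode the study conditions of the yeast/E. coli analysis the
#' package implements: seven PPI source databases, five retrotransposon-like
#' mobile-element families of 18 proteins each (90 flagged proteins), and
#' roughly one third of heteromeric families having a homomeric ortholog in
#' species A, of which about two thirds are singletons.
#'
#' @param seed Integer seed; the whole scenario is deterministic given it.
#' @param n_families_per_fate Named integer vector with one count per fate
#'   (see [divergence_fates()]). If `NULL`, counts are apportioned from
#'   `n_families` and `fate_mix`.
#' @param n_families Total number of truth families, used with `fate_mix`
#'   when `n_families_per_fate` is `NULL`.
#' @param fate_mix Named probabilities over the four fates; must sum to 1.
#' @param n_singletons Number of proteins without any paralog.
#' @param n_databases Number of PPI source databases (>= 2).
#' @param p_false_positive_edge Probability (relative to the number of true
#'   edges) of injecting a spurious single-database, single-direction edge.
#' @param p_homomer_blind_method Probability that a PPI observation comes from
#'   a method class (pulldown-like) that cannot report self-interactions;
#'   such observations of self-edges are silently lost.
#' @param p_missing_direction Probability that a non-self edge is observed in
#'   only one bait/prey direction.
#' @param n_compartments Number of sub-cellular compartments.
#' @param p_mislocalized_edge Probability (relative to true edges) of injecting
#'   a well-supported but cross-compartment false edge.
#' @param n_retrotransposon_families Number of mobile-element confounder
#'   families (18 near-identical, self-interacting proteins each).
#' @param identity_coverage_ranges Per-tier closed sampling ranges for percent
#'   identity and query coverage, nested consistently with the tier
#'   thresholds (HC range inside MC range inside LC range).
#' @param transition_fraction Fraction of heteromeric (obligatory_hetero or
#'   mixed) species-B families whose species-A ortholog is a homomer.
#' @param p_singleton_ortholog Probability that such a species-A homomer is a
#'   singleton rather than an obligatory-homomeric paralogous pair.
#'
#' @return A list of class `scenario_config`.
#' @seealso [generate_scenario()], [write_scenario()]
#' @export
scenario_config <- function(seed = 1L,
                            n_families_per_fate = NULL,
                            n_families = 200L,
                            fate_mix = c(obligatory_homo = 0.25,
                                         obligatory_hetero = 0.25,
                                         mixed = 0.25,
                                         hetero_others = 0.25),
                            n_singletons = 40L,
                            n_databases = 7L,
                            p_false_positive_edge = 0.05,
                            p_homomer_blind_method = 0.3,
                            p_missing_direction = 0.2,
                            n_compartments = 5L,
                            p_mislocalized_edge = 0.05,
                            n_retrotransposon_families = 5L,
                            identity_coverage_ranges = default_tier_ranges(),
                            transition_fraction = 0.34,
                            p_singleton_ortholog = 0.65) {
  if (is.null(n_families_per_fate)) {
    n_families_per_fate <- apportion_counts(n_families, fate_mix)
  }
  cfg <- list(
    seed = as.integer(seed),
    n_families_per_fate = n_families_per_fate,
    fate_mix = fate_mix,
    n_singletons = as.integer(n_singletons),
    n_databases = as.integer(n_databases),
    p_false_positive_edge = p_false_positive_edge,
    p_homomer_blind_method = p_homomer_blind_method,
    p_missing_direction = p_missing_direction,
    n_compartments = as.integer(n_compartments),
    p_mislocalized_edge = p_mislocalized_edge,
    n_retrotransposon_families = as.integer(n_retrotransposon_families),
    identity_coverage_ranges = identity_coverage_ranges,
    transition_fraction = transition_fraction,
    p_singleton_ortholog = p_singleton_ortholog
  )
  class(cfg) <- "scenario_config"
  validate_scenario_config(cfg)
  cfg
}

#' Default per-tier identity/coverage sampling ranges
#'
#' Full inclusive regions satisfying each tier's thresholds, so the HC range
#' is nested inside MC, which is nested inside LC.
#'
#' @return Named list with elements `LC`, `MC`, `HC`, each holding closed
#'   `identity` and `coverage` intervals (percent).
#' @export
default_tier_ranges <- function() {
  list(
    LC = list(identity = c(25, 100), coverage = c(40, 100)),
    MC = list(identity = c(30, 100), coverage = c(50, 100)),
    HC = list(identity = c(40, 100), coverage = c(60, 100))
  )
}

# Deterministic largest-remainder apportionment of n into counts ~ mix.
apportion_counts <- function(n, mix) {
  stopifnot(length(mix) == length(FATES))
  mix <- mix[FATES]
  raw <- n * mix
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  setNames(as.integer(counts), FATES)
}

validate_scenario_config <- function(cfg) {
  fail <- function(field, msg) {
    stop(sprintf("invalid scenario configuration: field '%s' %s", field, msg),
         call. = FALSE)
  }
  if (length(cfg$seed) != 1 || is.na(cfg$seed)) fail("seed", "must be a single integer")
  nf <- cfg$n_families_per_fate
  if (!all(FATES %in% names(nf))) fail("n_families_per_fate", "must name all four fates")
  if (any(nf < 0)) fail("n_families_per_fate", "must be non-negative")
  if (abs(sum(cfg$fate_mix) - 1) > 1e-9) fail("fate_mix", "must sum to 1")
  if (any(cfg$fate_mix < 0)) fail("fate_mix", "must be non-negative")
  probs <- c("p_false_positive_edge", "p_homomer_blind_method",
             "p_missing_direction", "p_mislocalized_edge",
             "transition_fraction", "p_singleton_ortholog")
  for (p in probs) {
    v <- cfg[[p]]
    if (length(v) != 1 || is.na(v) || v < 0 || v > 1) fail(p, "must be a probability in [0,1]")
  }
  counts <- c("n_singletons", "n_compartments", "n_retrotransposon_families")
  for (ct in counts) {
    if (cfg[[ct]] < 0) fail(ct, "must be >= 0")
  }
  if (cfg$n_compartments < 1) fail("n_compartments", "must be >= 1")
  if (cfg$n_databases < 2) fail("n_databases", "must be >= 2")
  rng <- cfg$identity_coverage_ranges
  if (!all(TIERS %in% names(rng))) {
    fail("identity_coverage_ranges", "must name tiers LC, MC, HC")
  }
  for (axis in c("identity", "coverage")) {
    lo <- vapply(TIERS, function(t) rng[[t]][[axis]][1], numeric(1))
    hi <- vapply(TIERS, function(t) rng[[t]][[axis]][2], numeric(1))
    if (any(diff(lo) < 0) || any(diff(hi) > 0) || any(lo > hi)) {
      fail("identity_coverage_ranges",
           sprintf("%s ranges must be nested (HC inside MC inside LC)", axis))
    }
  }
  invisible(cfg)
}
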