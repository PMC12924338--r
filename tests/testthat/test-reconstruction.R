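adi_evidence <- function() {
  tibble::tibble(
    species = "Lp",
    enzyme_id = c("arginine_deiminase", "ornithine_transcarbamylase",
                  "carbamate_kinase"),
    homolog_found = c(TRUE, TRUE, FALSE),
    best_hit_taxonomy = c("eukaryote", "eukaryote", "unknown"),
    consensus_class = c("other", "other", NA),
    consensus_rule = c("unanimity", "unanimity", NA))
}

adi_pathway <- tibble::tibble(
  pathway_id = "ADI",
  enzyme_id = c("arginine_deiminase", "ornithine_transcarbamylase",
                "carbamate_kinase"))

test_that("contaminant flagging downgrades exactly the prokaryote-only cells", {
  ev <- tibble::tibble(
    species = "sp",
    enzyme_id = c("e1", "e2", "e2", "e3"),
    homolog_found = c(TRUE, TRUE, TRUE, TRUE),
    best_hit_taxonomy = c("eukaryote", "prokaryote", "eukaryote",
                          "prokaryote"))
  fl <- flag_contaminants(ev)
  expect_equal(fl$contaminant_only, c(FALSE, FALSE, FALSE, TRUE))

  # randomized table: recount independently
  withr::local_seed(17)
  big <- tibble::tibble(
    species = sample(c("a", "b"), 200, replace = TRUE),
    enzyme_id = sample(sprintf("e%02d", 1:20), 200, replace = TRUE),
    homolog_found = sample(c(TRUE, FALSE), 200, replace = TRUE,
                           prob = c(0.8, 0.2)),
    best_hit_taxonomy = sample(c("eukaryote", "prokaryote", "unknown"),
                               200, replace = TRUE))
  fl2 <- flag_contaminants(big)
  for (i in seq_len(nrow(fl2))) {
    cell <- big[big$species == fl2$species[i] &
                  big$enzyme_id == fl2$enzyme_id[i], ]
    found <- cell[cell$homolog_found, ]
    expected <- nrow(found) > 0 &&
      all(found$best_hit_taxonomy == "prokaryote")
    expect_equal(fl2$contaminant_only[i], expected)
  }

  expect_error(flag_contaminants(dplyr::mutate(ev,
                                               best_hit_taxonomy = "viral")),
               "unknown best_hit_taxonomy")
})

test_that("matrix statuses follow the presence/consistency rules", {
  pw <- tibble::tibble(pathway_id = "x", enzyme_id = c("e1", "e2", "e3"),
                       expected_compartment = c("plastid", NA, NA))
  ev <- tibble::tibble(
    species = "sp",
    enzyme_id = c("e1", "e2", "e3"),
    homolog_found = c(TRUE, TRUE, TRUE),
    best_hit_taxonomy = "eukaryote",
    consensus_class = c("plastid", "unassigned", "mitochondrion"),
    consensus_rule = c("unanimity", "none", "unanimity"))
  m <- build_matrix(ev, pw)
  st <- setNames(m$status, m$enzyme_id)
  expect_equal(st[["e1"]], "present_consistent")   # matches expectation
  expect_equal(st[["e2"]], "present_unassigned")
  expect_equal(st[["e3"]], "present_consistent")   # no expectation declared

  # expectation conflict is present but not consistent
  ev$consensus_class[1] <- "mitochondrion"
  m2 <- build_matrix(ev, pw)
  expect_equal(m2$status[m2$enzyme_id == "e1"], "present_unassigned")
  expect_equal(m2$localization[m2$enzyme_id == "e1"], "mitochondrion")

  # truncated consensus
  ev$consensus_class[1] <- NA
  ev$consensus_rule[1] <- "truncated"
  m3 <- build_matrix(ev, pw)
  expect_equal(m3$status[m3$enzyme_id == "e1"], "present_truncated")

  # unknown enzyme in evidence is ignored with a warning
  expect_warning(build_matrix(dplyr::mutate(ev, enzyme_id = c("e1", "e2",
                                                              "zz")), pw),
                 "zz")
})

test_that("randomized pathway matrices equal an independent per-cell recount", {
  withr::local_seed(23)
  pw <- tibble::tibble(pathway_id = "p", enzyme_id = sprintf("e%02d", 1:8),
                       expected_compartment = sample(c("plastid",
                                                       "mitochondrion", NA),
                                                     8, replace = TRUE))
  for (rep in 1:10) {
    ev <- tibble::tibble(
      species = sample(c("s1", "s2"), 60, replace = TRUE),
      enzyme_id = sample(pw$enzyme_id, 60, replace = TRUE),
      homolog_found = sample(c(TRUE, FALSE), 60, replace = TRUE,
                             prob = c(0.85, 0.15)),
      best_hit_taxonomy = sample(c("eukaryote", "prokaryote", "unknown"),
                                 60, replace = TRUE),
      consensus_class = sample(c("plastid", "mitochondrion", "unassigned",
                                 NA), 60, replace = TRUE),
      consensus_rule = sample(c("unanimity", "none", "truncated"), 60,
                              replace = TRUE))
    m <- build_matrix(ev, pw)
    ev_flagged <- flag_contaminants(ev)
    ev_flagged <- dplyr::left_join(
      ev_flagged, pw[, c("enzyme_id", "expected_compartment")],
      by = "enzyme_id")
    for (i in seq_len(nrow(m))) {
      rows <- ev_flagged[ev_flagged$species == m$species[i] &
                           ev_flagged$enzyme_id == m$enzyme_id[i], ]
      expect_equal(m$status[i], oracle_cell_status(rows))
    }
    # independence from evidence row order
    m_shuf <- build_matrix(ev[sample(nrow(ev)), ], pw)
    expect_identical(as.data.frame(m_shuf), as.data.frame(m))
  }
})

test_that("pathway completeness reports the missing-enzyme logic", {
  m <- build_matrix(adi_evidence(), adi_pathway)
  comp <- pathway_completeness(m, adi_pathway)
  expect_equal(comp$fraction_present, 2 / 3)
  expect_false(comp$complete)
  expect_equal(comp$missing[[1]], "carbamate_kinase")

  # all present -> complete
  full <- dplyr::mutate(adi_evidence(), homolog_found = TRUE,
                        consensus_class = "other",
                        consensus_rule = "unanimity")
  comp2 <- pathway_completeness(build_matrix(full, adi_pathway), adi_pathway)
  expect_true(comp2$complete)
  expect_equal(comp2$fraction_present, 1)

  # no evidence found at all -> fraction 0
  none <- dplyr::mutate(adi_evidence(), homolog_found = FALSE)
  comp3 <- pathway_completeness(build_matrix(none, adi_pathway), adi_pathway)
  expect_equal(comp3$fraction_present, 0)

  # contaminant-only counts as absent; flipping it to eukaryotic
  # evidence can only increase the fraction
  prok <- dplyr::mutate(adi_evidence(),
                        best_hit_taxonomy = c("prokaryote", "eukaryote",
                                              "unknown"))
  f_prok <- pathway_completeness(build_matrix(prok, adi_pathway),
                                 adi_pathway)$fraction_present
  expect_equal(f_prok, 1 / 3)
  expect_lte(f_prok, comp$fraction_present)
})

test_that("the community filter applies the sub-1% rule with >= boundary", {
  tab <- tibble::tibble(
    lineage = c("l1", "l2", "l3", "l4"),
    culture = "c1",
    abundance = c(0.50, 0.30, 0.195, 0.005))
  kept <- filter_community(tab)
  expect_equal(nrow(kept), 3L)
  expect_false("l4" %in% kept$lineage)

  # exactly at threshold is retained
  edge <- tibble::tibble(lineage = c("a", "b"), culture = "c1",
                         abundance = c(0.99, 0.01))
  expect_equal(nrow(filter_community(edge)), 2L)

  # threshold 0 retains everything; above the max retains nothing
  expect_equal(nrow(filter_community(tab, threshold = 0)), 4L)
  expect_equal(nrow(filter_community(tab, threshold = 0.6)), 0L)
})

test_that("shared lineages are the post-filter intersection", {
  tab <- tibble::tibble(
    lineage = c("a", "b", "c", "b", "c", "d"),
    culture = rep(c("c1", "c2"), each = 3),
    abundance = rep(1 / 3, 6))
  expect_equal(shared_lineages(tab), c("b", "c"))

  disjoint <- tibble::tibble(lineage = c("a", "b"),
                             culture = c("c1", "c2"), abundance = 1)
  expect_equal(shared_lineages(disjoint), character(0))

  same <- tibble::tibble(lineage = rep(c("a", "b"), 2),
                         culture = rep(c("c1", "c2"), each = 2),
                         abundance = 0.5)
  expect_equal(shared_lineages(same), c("a", "b"))
})

test_that("the synthetic community round-trips through filter and intersection", {
  tab <- generate_community_table(n_lineages = 17, n_noise = 4,
                                  n_shared = 7, seed = 12)
  kept <- filter_community(tab)
  counts <- attr(kept, "retained_counts")
  expect_equal(unname(counts), c(13L, 13L))  # n_lineages - n_noise each
  expect_equal(shared_lineages(kept), sprintf("shared_%02d", 1:7))
})
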