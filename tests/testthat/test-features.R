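test_that("residue charge follows the K/R/D/E convention", {
  expect_equal(residue_charge(c("K", "R")), c(1L, 1L))
  expect_equal(residue_charge(c("D", "E")), c(-1L, -1L))
  expect_equal(residue_charge(c("H", "X", "A", "G")), rep(0L, 4))
  expect_equal(residue_charge("k"), 1L)  # case-insensitive
  expect_error(residue_charge("Z"), "illegal residue")
})

test_that("positional charge profile matches direct application and is mean-invariant", {
  recs <- tibble::tibble(sequence = "MRKDE")
  prof <- positional_charge_profile(recs, L = 5)
  expect_equal(prof$mean_charge, c(0, 1, 1, -1, -1))
  expect_equal(prof$n_contributing, rep(1L, 5))

  # duplicating every sequence leaves the profile unchanged
  dup <- tibble::tibble(sequence = rep(c("MRKDE", "MKKAA"), each = 3))
  single <- tibble::tibble(sequence = c("MRKDE", "MKKAA"))
  expect_equal(positional_charge_profile(dup, 5)$mean_charge,
               positional_charge_profile(single, 5)$mean_charge)

  expect_error(positional_charge_profile(recs, L = 0), "L must")
  expect_error(positional_charge_profile(recs[0, ], L = 3), "no sequences")
})

test_that("charge profile equals a double-loop recount on random sequences", {
  withr::local_seed(101)
  recs <- random_records(200, len_range = c(5L, 60L))
  prof <- positional_charge_profile(recs, L = 40)
  oracle <- oracle_profile(recs$sequence, 40)
  expect_equal(prof$mean_charge, oracle$mean_charge)
  expect_equal(prof$n_contributing, oracle$n_contributing)
})

test_that("profile of a union is the n-weighted average of the parts", {
  withr::local_seed(55)
  a <- random_records(40, len_range = c(30L, 50L))
  b <- random_records(60, len_range = c(30L, 50L))
  pa <- positional_charge_profile(a, 30)
  pb <- positional_charge_profile(b, 30)
  pu <- positional_charge_profile(dplyr::bind_rows(a, b), 30)
  weighted <- (pa$mean_charge * pa$n_contributing +
                 pb$mean_charge * pb$n_contributing) /
    (pa$n_contributing + pb$n_contributing)
  expect_equal(pu$mean_charge, weighted)
})

test_that("region charge summary reproduces hand-computed means", {
  recs <- tibble::tibble(sequence = "MKKKAAAAAAAAAA")
  rc <- region_charge_summary(recs, first_k = 4, central = c(5, 14))
  expect_equal(rc$first_k_mean, 0.75)
  expect_equal(rc$central_mean, 0)

  polya <- tibble::tibble(sequence = rep("MAAAAAAAAAAAAAAAAAAA", 4))
  # the leading M is uncharged too, so both regions are exactly zero
  rc2 <- region_charge_summary(polya, first_k = 5, central = c(10, 18))
  expect_equal(c(rc2$first_k_mean, rc2$central_mean), c(0, 0))

  expect_error(region_charge_summary(recs, first_k = 4, central = c(20, 30)),
               "no sequence covers")

  # random set agrees with a brute-force recount
  withr::local_seed(77)
  rnd <- random_records(50, len_range = c(40L, 60L))
  rc3 <- region_charge_summary(rnd, first_k = 10, central = c(15, 35))
  per_first <- vapply(rnd$sequence, function(s) {
    mean(vapply(1:10, function(p) oracle_charge(substr(s, p, p)), numeric(1)))
  }, numeric(1))
  per_cent <- vapply(rnd$sequence, function(s) {
    mean(vapply(15:35, function(p) oracle_charge(substr(s, p, p)),
                numeric(1)))
  }, numeric(1))
  expect_equal(rc3$first_k_mean, mean(per_first))
  expect_equal(rc3$central_mean, mean(per_cent))
})

test_that("FGLK scanning follows the distinct-letter grammar", {
  # hand enumeration: AFGL{F,G,L}, FGLK{F,G,L,K}, GLKA{G,L,K} are sites
  scan <- scan_glk_sites(tibble::tibble(id = "p", sequence = "AFGLKAAA"),
                         window = c(1, 8))
  expect_equal(scan$site_starts[[1]], c(1L, 2L, 3L))
  expect_equal(scan$n_sites, 3L)

  polya <- scan_glk_sites(tibble::tibble(id = "a",
                                         sequence = strrep("A", 50)),
                          window = c(1, 40))
  expect_equal(polya$n_sites, 0L)

  # window clipping warns
  expect_warning(
    scan_glk_sites(tibble::tibble(id = "s", sequence = "MFGLK"),
                   window = c(1, 40)),
    "clipped")
  expect_error(scan_glk_sites(tibble::tibble(sequence = "MKV"),
                              window = c(5, 2)), "invalid scan window")
})

test_that("FGLK scan equals a brute-force enumerator on 500 random strings", {
  withr::local_seed(202)
  # motif-letter-rich alphabet so sites actually occur
  recs <- random_records(500, len_range = c(10L, 60L),
                         letters = c("F", "G", "L", "K", "A", "S", "T", "P"))
  scan <- suppressWarnings(  # short sequences: expected clipping
    scan_glk_sites(recs, window = c(1, 40), include_partial = TRUE))
  for (i in seq_len(nrow(recs))) {
    expect_identical(scan$site_starts[[i]],
                     oracle_glk_starts(recs$sequence[i], c(1, 40)))
  }
  # enlarging the window never decreases the count
  narrow <- suppressWarnings(
    scan_glk_sites(recs, window = c(1, 20), include_partial = TRUE))
  expect_true(all(scan$n_sites >= narrow$n_sites))
})

test_that("GLK prevalence is the fraction of sequences with a site", {
  planted <- tibble::tibble(sequence = paste0("M", strrep("A", 10), "FGLK",
                                              strrep("A", 30)))
  expect_equal(glk_prevalence(planted, c(1, 40)), 1)
  polya <- tibble::tibble(sequence = rep(strrep("A", 60), 3))
  expect_equal(glk_prevalence(polya, c(1, 40), include_partial = TRUE), 0)
})

test_that("sentinel enrichment matches its formula, limit and oracle", {
  n <- 100
  recs <- tibble::tibble(sequence = rep("MAKVL", n))
  enr <- sentinel_enrichment(recs, k = 3, pseudocount = 0.5)
  # all sequences carry A at position 2 under a uniform background
  a2 <- enr$enrichment[enr$position == 2 & enr$residue == "A"]
  expect_equal(a2, log2(((n + 0.5) / (n + 10)) / 0.05))
  expect_lt(abs(a2 - log2(20)), 0.2)  # large-n limit

  # observed frequency equal to background -> enrichment ~ 0
  withr::local_seed(33)
  unif <- random_records(4000, len_range = c(3L, 3L), start_met = FALSE)
  e0 <- sentinel_enrichment(unif, k = 2, include_partial = TRUE)
  expect_true(all(abs(e0$enrichment[e0$position == 2]) < 0.3))

  # brute-force oracle within 1e-12
  rnd <- random_records(150, len_range = c(5L, 30L))
  bg <- stats::setNames(rep(0.05, 20), strsplit("ACDEFGHIKLMNPQRSTVWY",
                                                "")[[1]])
  enr2 <- sentinel_enrichment(rnd, background_frequencies = bg, k = 20,
                              pseudocount = 0.5)
  oracle <- oracle_enrichment(rnd$sequence, bg, 20, 0.5)
  for (p in 1:20) {
    got <- enr2$enrichment[enr2$position == p]
    names(got) <- enr2$residue[enr2$position == p]
    expect_equal(got[colnames(oracle)], oracle[p, ], tolerance = 1e-12)
  }

  # zero background frequency for an observed residue is an error
  bg0 <- bg; bg0["A"] <- 0; bg0["C"] <- 0.1
  expect_error(sentinel_enrichment(tibble::tibble(sequence = "MA"),
                                   background_frequencies = bg0, k = 2),
               "pseudocount")
})

test_that("partial sequences are excluded from feature cohorts by default", {
  recs <- tibble::tibble(sequence = c("MKKKK", "KKKKK"),
                         is_partial = c(FALSE, TRUE))
  prof <- positional_charge_profile(recs, 2)
  expect_equal(prof$n_contributing, c(1L, 1L))  # only the complete sequence
  expect_equal(prof$mean_charge[1], 0)          # its M, not the partial K
  both <- positional_charge_profile(recs, 2, include_partial = TRUE)
  expect_equal(both$mean_charge[1], 0.5)
})
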