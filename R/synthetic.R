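# Synthetic-data generators. They emulate the statistical structure the
# downstream analyses assume — presequence positional charge, FGLK sites,
# per-tool predictor error, sub-1% community noise, two-peak Raman spectra —
# so that every stage of the pipeline can be exercised and validated in a
# closed generator/analyzer loop.

#' Configuration for the labeled synthetic proteome
#'
#' Defaults encode the qualitative targeting-peptide structure the features
#' module is designed to detect: chloroplast transit peptides (cTP) are
#' relatively uncharged at the N-terminus and most positively charged in
#' their central third; mitochondrial transit peptides (mTP) are most
#' positively charged at the very beginning; both classes carry FGLK sites
#' (putative Toc-interaction motifs) in their N-terminal windows (first ~40
#' residues for plastid, ~20 for mitochondrial proteins).
#'
#' @param n_per_class Named counts for classes `plastid`, `mitochondrion`,
#'   `secretory`, `other`.
#' @param ctp_length_range,mtp_length_range Presequence length ranges
#'   (residues, after the initiator Met).
#' @param mature_length_range Mature-domain length range.
#' @param background_frequencies Named 20-vector of residue frequencies
#'   summing to 1 (default uniform; only charge, sentinels and FGLK sites are
#'   structured, so composition beyond that is deliberately featureless).
#' @param ctp_center_KR_boost Multiplicative K/R enrichment in the central
#'   third of a cTP; the same factor divides K/R in its first 10 residues.
#' @param mtp_start_KR_boost Multiplicative K/R enrichment in the first 10
#'   residues of an mTP.
#' @param glk_insert_prob_plastid,glk_insert_prob_mito Probability of
#'   planting one literal `FGLK` 4-mer in the first 40 / first 20 residues.
#' @param seed Integer seed; the proteome is a deterministic function of the
#'   config.
#' @return A list of class `proteome_config`.
#' @export
proteome_config <- function(n_per_class = c(plastid = 100, mitochondrion = 100,
                                            secretory = 100, other = 100),
                            ctp_length_range = c(40L, 70L),
                            mtp_length_range = c(20L, 60L),
                            mature_length_range = c(80L, 150L),
                            background_frequencies = NULL,
                            ctp_center_KR_boost = 3,
                            mtp_start_KR_boost = 3,
                            glk_insert_prob_plastid = 0.8,
                            glk_insert_prob_mito = 0.6,
                            seed = 1L) {
  if (is.null(background_frequencies)) {
    background_frequencies <- setNames(rep(1 / 20, 20), AA_LETTERS)
  }
  cfg <- list(
    n_per_class = n_per_class,
    ctp_length_range = as.integer(ctp_length_range),
    mtp_length_range = as.integer(mtp_length_range),
    mature_length_range = as.integer(mature_length_range),
    background_frequencies = background_frequencies,
    ctp_center_KR_boost = ctp_center_KR_boost,
    mtp_start_KR_boost = mtp_start_KR_boost,
    glk_insert_prob_plastid = glk_insert_prob_plastid,
    glk_insert_prob_mito = glk_insert_prob_mito,
    seed = as.integer(seed)
  )
  .validate_proteome_config(cfg)
  structure(cfg, class = "proteome_config")
}

.validate_proteome_config <- function(cfg) {
  need <- c("plastid", "mitochondrion", "secretory", "other")
  if (!all(need %in% names(cfg$n_per_class))) {
    abort(paste0("n_per_class must name counts for: ",
                 paste(need, collapse = ", ")))
  }
  if (any(cfg$n_per_class < 0)) abort("n_per_class counts must be >= 0")
  f <- cfg$background_frequencies
  if (!setequal(names(f), AA_LETTERS)) {
    abort("background_frequencies must name exactly the 20 standard residues")
  }
  if (abs(sum(f) - 1) > 1e-9) abort("background_frequencies must sum to 1")
  for (r in c("ctp_length_range", "mtp_length_range", "mature_length_range")) {
    if (length(cfg[[r]]) != 2L || cfg[[r]][1] > cfg[[r]][2] || cfg[[r]][1] < 1) {
      abort(paste0(r, " must be an increasing positive integer pair"))
    }
  }
  # charge regions and FGLK windows must fit inside the shortest presequence
  if (cfg$ctp_length_range[1] < 15L) {
    abort("ctp_length_range minimum must be >= 15 (central charged region)")
  }
  if (cfg$mtp_length_range[1] < 10L) {
    abort("mtp_length_range minimum must be >= 10 (charged start region)")
  }
  for (p in c("glk_insert_prob_plastid", "glk_insert_prob_mito")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) abort(paste0(p, " must lie in [0, 1]"))
  }
  if (cfg$ctp_center_KR_boost <= 0 || cfg$mtp_start_KR_boost <= 0) {
    abort("K/R boost factors must be positive")
  }
  invisible(cfg)
}

.boosted <- function(freqs, letters, factor) {
  freqs[letters] <- freqs[letters] * factor
  freqs / sum(freqs)
}

.sample_residues <- function(n, freqs) {
  if (n <= 0) return(character(0))
  sample(names(freqs), n, replace = TRUE, prob = freqs)
}

# one presequence (after Met) as a character vector
.make_ctp <- function(cfg) {
  len <- sample(seq(cfg$ctp_length_range[1], cfg$ctp_length_range[2]), 1L)
  bg <- cfg$background_frequencies
  low <- .boosted(bg, c("K", "R"), 1 / cfg$ctp_center_KR_boost)
  high <- .boosted(bg, c("K", "R"), cfg$ctp_center_KR_boost)
  mid <- seq(floor(len / 3) + 1L, ceiling(2 * len / 3))
  res <- .sample_residues(len, bg)
  res[1:10] <- .sample_residues(10L, low)
  res[mid] <- .sample_residues(length(mid), high)
  res
}

.make_mtp <- function(cfg) {
  len <- sample(seq(cfg$mtp_length_range[1], cfg$mtp_length_range[2]), 1L)
  res <- .sample_residues(len, cfg$background_frequencies)
  res[1:10] <- .sample_residues(
    10L, .boosted(cfg$background_frequencies, c("K", "R"),
                  cfg$mtp_start_KR_boost))
  res
}

.plant_glk <- function(res, window_end) {
  # res includes the leading Met at position 1; plant so the 4-mer starts
  # inside the window and fits in the sequence
  last <- min(window_end, length(res)) - 3L
  if (last < 2L) return(res)
  at <- sample(2:last, 1L)
  res[at:(at + 3L)] <- c("F", "G", "L", "K")
  res
}

#' Generate a labeled synthetic proteome
#'
#' Each protein is `M` + class-specific presequence + mature domain sampled
#' from the background frequencies: plastid proteins get a cTP (K/R-depleted
#' first 10 residues, K/R-boosted central third, optional planted FGLK in the
#' first 40), mitochondrial proteins an mTP (K/R-boosted first 10, optional
#' FGLK in the first 20), secretory proteins a hydrophobic A/L/V/F leader of
#' 15–25 residues, and `other` proteins a mature domain only. Background
#' FGLK occurrences are not suppressed, so measured prevalence is planting
#' probability plus background.
#'
#' @param cfg A [proteome_config()].
#' @return A list with `records` (tibble: `id`, `description`, `sequence`,
#'   `is_partial`) and `labels` (tibble: `protein_id`, `true_class`).
#' @export
#' @examples
#' sim <- generate_labeled_proteome(proteome_config(
#'   n_per_class = c(plastid = 2, mitochondrion = 2, secretory = 1, other = 1)))
#' sim$labels
generate_labeled_proteome <- function(cfg) {
  stopifnot(inherits(cfg, "proteome_config"))
  withr::local_seed(cfg$seed)
  bg <- cfg$background_frequencies
  classes <- c("plastid", "mitochondrion", "secretory", "other")
  rows <- purrr::map(classes, function(cls) {
    n <- cfg$n_per_class[[cls]]
    if (n == 0L) return(NULL)
    seqs <- vapply(seq_len(n), function(i) {
      mature <- .sample_residues(
        sample(seq(cfg$mature_length_range[1], cfg$mature_length_range[2]), 1L),
        bg)
      res <- switch(cls,
        plastid = {
          r <- c("M", .make_ctp(cfg), mature)
          if (runif(1) < cfg$glk_insert_prob_plastid) r <- .plant_glk(r, 40L)
          r
        },
        mitochondrion = {
          r <- c("M", .make_mtp(cfg), mature)
          if (runif(1) < cfg$glk_insert_prob_mito) r <- .plant_glk(r, 20L)
          r
        },
        secretory = c("M",
                      sample(c("A", "L", "V", "F"), sample(15:25, 1L),
                             replace = TRUE),
                      mature),
        other = c("M", mature)
      )
      paste(res, collapse = "")
    }, character(1))
    tibble(
      id = sprintf("%s_%04d", substr(cls, 1, 4), seq_len(n)),
      description = paste("synthetic", cls),
      sequence = seqs,
      is_partial = FALSE,
      true_class = cls
    )
  })
  all <- dplyr::bind_rows(rows)
  if (nrow(all) == 0L) {
    return(list(
      records = tibble(id = character(), description = character(),
                       sequence = character(), is_partial = logical()),
      labels = tibble(protein_id = character(), true_class = character())
    ))
  }
  list(
    records = all[, c("id", "description", "sequence", "is_partial")],
    labels = tibble(protein_id = all$id, true_class = all$true_class)
  )
}

#' Build a per-tool error model as a row-stochastic confusion table
#'
#' Rows give, for each true class, the distribution of labels a tool emits.
#' The convenience default puts `accuracy` on the diagonal and spreads the
#' remainder uniformly over the other emitted classes.
#'
#' @param tool_id Tool name.
#' @param classes True (gold) classes the model covers.
#' @param accuracy Diagonal probability, recycled over `classes`.
#' @param emitted Classes the tool can emit (defaults to `classes`).
#' @return Long tibble `tool_id`, `true_class`, `emitted`, `prob` of class
#'   `tool_error_model`; rows for one `true_class` sum to 1.
#' @export
tool_error_model <- function(tool_id,
                             classes = c("plastid", "mitochondrion",
                                         "secretory", "other"),
                             accuracy = 0.85,
                             emitted = classes) {
  accuracy <- rep_len(accuracy, length(classes))
  rows <- purrr::map2(classes, accuracy, function(cls, acc) {
    p <- setNames(rep(0, length(emitted)), emitted)
    others <- setdiff(emitted, cls)
    if (cls %in% emitted) {
      p[cls] <- acc
      p[others] <- (1 - acc) / length(others)
    } else {
      p[others] <- 1 / length(others)
    }
    tibble(tool_id = tool_id, true_class = cls, emitted = emitted,
           prob = unname(p))
  })
  out <- dplyr::bind_rows(rows)
  .validate_error_model(out)
  structure(out, class = c("tool_error_model", class(out)))
}

.validate_error_model <- function(model) {
  if (any(model$prob < 0)) abort("error model probabilities must be >= 0")
  sums <- tapply(model$prob, paste(model$tool_id, model$true_class), sum)
  if (any(abs(sums - 1) > 1e-9)) {
    abort("error model rows must sum to 1 per (tool, true class)")
  }
  invisible(model)
}

#' Simulate predictor calls from per-tool error models
#'
#' For each protein and each tool, the emitted class is drawn from the
#' tool's confusion row for the protein's gold class, independently across
#' proteins and tools. The emitted class doubles as the native label (an
#' identity vocabulary).
#'
#' @param labels Tibble `protein_id`, `true_class`.
#' @param models A `tool_error_model` or list of them (or one long tibble
#'   covering several tools).
#' @param seed Integer seed.
#' @return Calls tibble: `protein_id`, `tool_id`, `native_label`,
#'   `canonical`.
#' @export
generate_tool_calls <- function(labels, models, seed = 1L) {
  if (inherits(models, "data.frame")) models <- list(models)
  models <- dplyr::bind_rows(models)
  .validate_error_model(models)
  withr::local_seed(as.integer(seed))
  tools <- unique(models$tool_id)
  out <- purrr::map(tools, function(tid) {
    m <- models[models$tool_id == tid, ]
    missing <- setdiff(unique(labels$true_class), unique(m$true_class))
    if (length(missing)) {
      abort(paste0("error model for '", tid, "' lacks confusion row(s) for: ",
                   paste(missing, collapse = ", ")))
    }
    emitted <- vapply(labels$true_class, function(cls) {
      row <- m[m$true_class == cls, ]
      sample(row$emitted, 1L, prob = row$prob)
    }, character(1), USE.NAMES = FALSE)
    tibble(protein_id = labels$protein_id, tool_id = tid,
           native_label = emitted, canonical = emitted)
  })
  dplyr::bind_rows(out)
}

#' Configuration for a synthetic two-peak Raman spectrum
#'
#' The spectrum is a linear baseline plus two Gaussian bands on a regular
#' wavenumber axis: the CH2 deformation band at 1440 cm-1 with height 1 and
#' the C=C stretch band at 1656 cm-1 with height `true_ratio`, plus i.i.d.
#' Gaussian noise. `true_ratio` is therefore the ground-truth unsaturation
#' ratio the analysis should recover.
#'
#' @param center_cc,center_ch2 Band centers in cm-1.
#' @param width Gaussian sd of both bands, cm-1.
#' @param true_ratio Height of the 1656 band relative to the 1440 band
#'   (default 1.07, the regime of monounsaturated storage lipids).
#' @param baseline_intercept,baseline_slope Linear baseline parameters.
#' @param noise_sd Gaussian noise sd (intensity units).
#' @param wn_range,wn_step Axis range and step in cm-1.
#' @param seed Integer seed.
#' @return A list of class `spectrum_config`.
#' @export
spectrum_config <- function(center_cc = 1656, center_ch2 = 1440, width = 8,
                            true_ratio = 1.07,
                            baseline_intercept = 0.1, baseline_slope = 2e-4,
                            noise_sd = 0.01,
                            wn_range = c(1200, 1800), wn_step = 1,
                            seed = 1L) {
  cfg <- list(center_cc = center_cc, center_ch2 = center_ch2, width = width,
              true_ratio = true_ratio,
              baseline_intercept = baseline_intercept,
              baseline_slope = baseline_slope, noise_sd = noise_sd,
              wn_range = wn_range, wn_step = wn_step, seed = as.integer(seed))
  if (cfg$true_ratio <= 0) abort("true_ratio must be > 0")
  if (cfg$noise_sd < 0) abort("noise_sd must be >= 0")
  if (cfg$width <= 0) abort("width must be > 0")
  inside <- function(x) x >= cfg$wn_range[1] && x <= cfg$wn_range[2]
  if (!inside(cfg$center_cc) || !inside(cfg$center_ch2)) {
    abort("band centers must lie inside the wavenumber range")
  }
  structure(cfg, class = "spectrum_config")
}

#' Generate a synthetic Raman spectrum
#'
#' @param cfg A [spectrum_config()].
#' @return A tibble `wavenumber`, `intensity` of class `spectrum_tbl`.
#' @export
#' @examples
#' sp <- generate_spectrum(spectrum_config(noise_sd = 0))
#' unsaturation_ratio(baseline_correct(sp))
generate_spectrum <- function(cfg) {
  stopifnot(inherits(cfg, "spectrum_config"))
  withr::local_seed(cfg$seed)
  wn <- seq(cfg$wn_range[1], cfg$wn_range[2], by = cfg$wn_step)
  gauss <- function(center, height) {
    height * exp(-(wn - center)^2 / (2 * cfg$width^2))
  }
  intensity <- cfg$baseline_intercept + cfg$baseline_slope * wn +
    gauss(cfg$center_ch2, 1) + gauss(cfg$center_cc, cfg$true_ratio) +
    rnorm(length(wn), sd = cfg$noise_sd)
  structure(tibble(wavenumber = wn, intensity = intensity),
            class = c("spectrum_tbl", class(tibble())))
}

#' Generate a two-culture 16S relative-abundance table
#'
#' Emulates the community tables behind the sub-1% contaminant filter: each
#' culture carries `n_lineages` lineages in total, of which `n_noise` are
#' forced below 1% relative abundance (sample-bleed-like contaminants) while
#' the remaining `n_lineages - n_noise` genuine lineages all sit at or above
#' 1% by construction. `n_shared` of the genuine lineages are common to both
#' cultures; defaults mirror two sediment cultures that each retain 13
#' lineages after filtering and share 7 anaerobic/microaerophilic ones.
#'
#' @param n_lineages Total lineages per culture (noise included).
#' @param n_noise Sub-1% noise lineages per culture.
#' @param n_shared Genuine lineages shared between the two cultures.
#' @param cultures Length-2 character vector of culture ids.
#' @param seed Integer seed.
#' @return Long tibble `lineage`, `culture`, `abundance`; each culture's
#'   abundances sum to 1.
#' @export
generate_community_table <- function(n_lineages = 17L, n_noise = 4L,
                                     n_shared = 7L,
                                     cultures = c("culture_A", "culture_B"),
                                     seed = 1L) {
  if (n_lineages < 1L) abort("n_lineages must be >= 1")
  if (n_noise >= n_lineages) abort("n_noise must be below n_lineages")
  n_genuine <- n_lineages - n_noise
  if (n_shared > n_genuine) {
    abort("n_shared cannot exceed the genuine (above-threshold) lineages")
  }
  if (length(cultures) != 2L) abort("exactly two cultures are generated")
  withr::local_seed(as.integer(seed))
  shared <- sprintf("shared_%02d", seq_len(n_shared))
  n_uniq <- n_genuine - n_shared
  one_culture <- function(tag) {
    uniq <- if (n_uniq > 0) sprintf("%s_only_%02d", tag, seq_len(n_uniq))
            else character(0)
    noise <- if (n_noise > 0) sprintf("%s_noise_%02d", tag, seq_len(n_noise))
             else character(0)
    noise_ab <- if (n_noise > 0) runif(n_noise, 0.0005, 0.009) else numeric(0)
    mass <- 1 - sum(noise_ab)
    w <- runif(n_genuine)
    genuine_ab <- 0.01 + (mass - 0.01 * n_genuine) * w / sum(w)
    tibble(lineage = c(shared, uniq, noise), culture = tag,
           abundance = c(genuine_ab, noise_ab))
  }
  dplyr::bind_rows(purrr::map(cultures, one_culture))
}
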