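# End-to-end demonstration pipeline: simulate -> benchmark -> consensus ->
# presequence features -> pathway reconstruction -> community filter ->
# unsaturation ratio. Everything is a deterministic function of one seed;
# the CLI subcommands in inst/scripts/orgloc.R wrap the same stages.

# A weak distractor predictor that over-calls mitochondrion: every
# non-mitochondrial row leaks `fp_to_mito` probability mass into the
# mitochondrion column. Used to exercise the precision-floor filter.
.mito_fp_model <- function(tool_id = "predalgo", accuracy = 0.6,
                           fp_to_mito = 0.3,
                           classes = c("plastid", "mitochondrion",
                                       "secretory", "other")) {
  m <- tool_error_model(tool_id, classes = classes, accuracy = accuracy)
  out <- as_tibble(m)
  for (cls in setdiff(classes, "mitochondrion")) {
    idx <- out$true_class == cls
    rest <- idx & !out$emitted %in% c(cls, "mitochondrion")
    take <- fp_to_mito - out$prob[idx & out$emitted == "mitochondrion"][1]
    out$prob[idx & out$emitted == "mitochondrion"] <- fp_to_mito
    out$prob[rest] <- out$prob[rest] - take / sum(rest)
  }
  .validate_error_model(out)
  structure(out, class = c("tool_error_model", class(out)))
}

# default panel: two organellar-only tools plus one multiclass tool that
# can also emit membrane/peroxisome, plus the weak mito-overcalling tool
.default_tool_models <- function() {
  gold <- c("plastid", "mitochondrion", "secretory", "other")
  list(
    tool_error_model("targetp", classes = gold, accuracy = 0.88),
    tool_error_model("deeploc20", classes = gold, accuracy = 0.85),
    tool_error_model("deeploc21", classes = gold, accuracy = 0.85,
                     emitted = c(gold, "membrane", "peroxisome")),
    .mito_fp_model()
  )
}

#' Run the full synthetic-study pipeline into a directory
#'
#' Generates a labeled proteome and mock predictor calls, benchmarks the
#' tools and selects the top three by MCC over plastid + mitochondrion,
#' produces consensus localization calls, computes transit-peptide features
#' on the consensus plastid and mitochondrial cohorts, assembles a toy
#' arginine-deiminase pathway matrix, filters a two-culture community table,
#' and summarises unsaturation ratios over a spectra cohort. All outputs are
#' plain TSV/FASTA; the whole run is a deterministic function of `seed`.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed; stage substreams are derived from it.
#' @param n_per_class Proteins per gold class.
#' @param n_spectra Spectra in the Raman cohort.
#' @return Named character vector of the files written, invisibly.
#' @export
run_pipeline <- function(out_dir, seed = 1L,
                         n_per_class = c(plastid = 120, mitochondrion = 120,
                                         secretory = 120, other = 120),
                         n_spectra = 20L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  path <- function(f) file.path(out_dir, f)

  # simulate
  sim <- generate_labeled_proteome(
    proteome_config(n_per_class = n_per_class, seed = seed))
  calls <- generate_tool_calls(sim$labels, .default_tool_models(),
                               seed = seed + 1L)
  write_fasta(sim$records, path("proteome.fasta"))
  write_table(sim$labels, path("labels.tsv"))
  write_table(calls, path("calls.tsv"))

  # benchmark and tool selection (precision floor expels the
  # mito-overcalling tool before ranking)
  bench <- benchmark_tools(sim$labels, calls)
  ranking <- rank_tools(bench$metrics, "mcc",
                        classes = c("plastid", "mitochondrion"),
                        precision_floor = 0.7)
  top3 <- select_top_k(ranking, k = min(3L, nrow(ranking)))
  write_table(as_tibble(bench$metrics), path("metrics.tsv"))
  write_table(as_tibble(ranking), path("ranking.tsv"))

  # consensus
  cfg <- consensus_config(top3, multiclass_tool = "deeploc21")
  consensus <- batch_consensus(calls, cfg, records = sim$records)
  write_table(as_tibble(consensus), path("consensus.tsv"))
  write_table(consensus_summary(consensus), path("consensus_summary.tsv"))

  # presequence features on the consensus cohorts
  assigned <- function(cls) {
    ids <- consensus$protein_id[consensus$assigned == cls]
    sim$records[sim$records$id %in% ids, , drop = FALSE]
  }
  pla <- assigned("plastid")
  mit <- assigned("mitochondrion")
  if (nrow(pla) > 0) {
    write_table(as_tibble(positional_charge_profile(pla, L = 40L)),
                path("charge_profile_plastid.tsv"))
  }
  if (nrow(mit) > 0) {
    write_table(as_tibble(positional_charge_profile(mit, L = 40L)),
                path("charge_profile_mitochondrion.tsv"))
  }
  prevalence <- tibble(
    cohort = c("plastid", "mitochondrion"),
    window = c("1-40", "1-20"),
    n = c(nrow(pla), nrow(mit)),
    glk_prevalence = c(
      if (nrow(pla)) glk_prevalence(pla, c(1L, 40L)) else NA_real_,
      if (nrow(mit)) glk_prevalence(mit, c(1L, 20L)) else NA_real_)
  )
  write_table(prevalence, path("glk_prevalence.tsv"))

  # toy pathway reconstruction: the arginine-deiminase (ADI) pathway with
  # carbamate kinase missing, localized via the consensus of two simulated
  # plastid proteins
  carriers <- head(pla$id, 2)
  carrier_class <- consensus$assigned[match(carriers, consensus$protein_id)]
  cc <- rep("unassigned", 2)
  cc[seq_along(carrier_class)] <- carrier_class
  evidence <- tibble(
    species = rep(c("species_A", "species_B"), each = 3),
    enzyme_id = rep(c("arginine_deiminase", "ornithine_transcarbamylase",
                      "carbamate_kinase"), 2),
    homolog_found = rep(c(TRUE, TRUE, FALSE), 2),
    best_hit_taxonomy = rep(c("eukaryote", "eukaryote", "unknown"), 2),
    consensus_class = rep(c(cc[1], cc[2], NA), 2),
    consensus_rule = rep(c("unanimity", "unanimity", NA), 2)
  )
  pathways <- tibble(pathway_id = "ADI",
                     enzyme_id = c("arginine_deiminase",
                                   "ornithine_transcarbamylase",
                                   "carbamate_kinase"))
  pm <- build_matrix(evidence, pathways)
  comp <- pathway_completeness(pm, pathways)
  comp$missing <- vapply(comp$missing, paste, character(1), collapse = ";")
  write_table(as_tibble(pm), path("pathway_matrix.tsv"))
  write_table(comp, path("pathway_completeness.tsv"))

  # community filter
  community <- generate_community_table(seed = seed + 2L)
  retained <- filter_community(community)
  write_table(community, path("community.tsv"))
  write_table(as_tibble(retained), path("community_retained.tsv"))
  write_table(tibble(lineage = shared_lineages(retained)),
              path("community_shared.tsv"))

  # unsaturation-ratio cohort
  spectra <- purrr::map(seq_len(n_spectra), function(i) {
    generate_spectrum(spectrum_config(seed = seed + 100L + i))
  })
  summary <- cohort_ratio_summary(spectra)
  write_table(tibble(spectrum = seq_len(n_spectra),
                     ratio = summary$ratios[[1]]),
              path("spectra_ratios.tsv"))
  write_table(summary[, c("mean", "sd", "n")], path("ratio_summary.tsv"))

  files <- list.files(out_dir, full.names = TRUE)
  invisible(setNames(files, basename(files)))
}
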