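# Assembly of species x enzyme presence/localization matrices, the
# prokaryotic-contaminant downgrade, pathway-completeness calls, and the
# sub-1% community-abundance filter with shared-lineage comparison.

STATUS_LEVELS <- c("present_consistent", "present_unassigned",
                   "present_truncated", "contaminant_only", "absent")

#' Downgrade contaminant-only enzyme evidence
#'
#' Homolog hits whose best database matches are prokaryotic likely come from
#' the co-cultured bacteria rather than the alga. A (species, enzyme) cell
#' whose every found homolog has a prokaryotic best hit is downgraded to
#' `contaminant_only` and counts as absent in all pathway logic; a cell with
#' at least one eukaryotic (or unknown) homolog keeps its eukaryotic
#' evidence.
#'
#' @param evidence Tibble with one row per homolog: `species`, `enzyme_id`,
#'   `homolog_found`, `best_hit_taxonomy` (one of `eukaryote`, `prokaryote`,
#'   `unknown`) and optionally `consensus_class`, `consensus_rule`,
#'   `n_paralogs`.
#' @return `evidence` with a logical `contaminant_only` column.
#' @export
flag_contaminants <- function(evidence) {
  stopifnot(all(c("species", "enzyme_id", "homolog_found",
                  "best_hit_taxonomy") %in% names(evidence)))
  bad <- setdiff(unique(evidence$best_hit_taxonomy),
                 c("eukaryote", "prokaryote", "unknown", NA))
  if (length(bad)) {
    abort(paste0("unknown best_hit_taxonomy value(s): ",
                 paste(bad, collapse = ", ")))
  }
  evidence %>%
    group_by(.data$species, .data$enzyme_id) %>%
    mutate(contaminant_only =
             any(.data$homolog_found) &
             all(!.data$homolog_found |
                   .data$best_hit_taxonomy == "prokaryote")) %>%
    ungroup()
}

# status of one (species, enzyme) cell from its homolog rows
.cell_status <- function(rows) {
  found <- rows[rows$homolog_found, , drop = FALSE]
  if (nrow(found) == 0L) {
    return(list(status = "absent", localization = "unknown"))
  }
  if (isTRUE(found$contaminant_only[1])) {
    return(list(status = "contaminant_only", localization = "unknown"))
  }
  # only non-contaminant evidence supports localization
  if ("contaminant_only" %in% names(found)) {
    euk <- found[found$best_hit_taxonomy != "prokaryote", , drop = FALSE]
    if (nrow(euk) > 0L) found <- euk
  }
  cls <- found$consensus_class
  rule <- found$consensus_rule
  assigned <- !is.na(cls) & cls != "unassigned"
  expected <- found$expected_compartment
  consistent <- assigned & (is.na(expected) | cls == expected)
  per <- ifelse(consistent, "present_consistent",
         ifelse(assigned, "present_unassigned",      # assigned but conflicting
         ifelse(!is.na(rule) & rule == "truncated",
                "present_truncated", "present_unassigned")))
  status <- STATUS_LEVELS[min(match(per, STATUS_LEVELS))]
  loc <- sort(unique(cls[assigned]))
  list(status = status,
       localization = if (length(loc)) paste(loc, collapse = ";")
                      else "unknown")
}

#' Build the species x enzyme pathway matrix
#'
#' For every (species, enzyme) pair referenced by the pathway definitions,
#' assigns a status: `absent` (no homolog), `contaminant_only` (prokaryotic
#' hits only, treated as absent downstream), `present_truncated` (homolog
#' found but N-terminally truncated, so localization is inconclusive),
#' `present_unassigned` (found, but the consensus is unassigned — or assigned
#' to a compartment conflicting with the expectation), or
#' `present_consistent` (found and the consensus matches the expected
#' compartment, or any assignment when no expectation is declared). With
#' multiple paralogs per cell the most informative status wins and
#' `localization` lists every assigned compartment.
#'
#' @param evidence Evidence tibble (see [flag_contaminants()], which is
#'   applied automatically when its column is missing).
#' @param pathways Tibble `pathway_id`, `enzyme_id`, optional
#'   `expected_compartment`.
#' @return Tibble of class `pathway_matrix`: `species`, `enzyme_id`,
#'   `status`, `localization`.
#' @export
build_matrix <- function(evidence, pathways) {
  stopifnot(all(c("pathway_id", "enzyme_id") %in% names(pathways)))
  if (anyDuplicated(pathways[, c("pathway_id", "enzyme_id")])) {
    abort("duplicate enzyme within a pathway definition")
  }
  if (!"contaminant_only" %in% names(evidence)) {
    evidence <- flag_contaminants(evidence)
  }
  if (!"consensus_class" %in% names(evidence)) {
    evidence$consensus_class <- NA_character_
  }
  if (!"consensus_rule" %in% names(evidence)) {
    evidence$consensus_rule <- NA_character_
  }
  known <- unique(pathways$enzyme_id)
  stray <- setdiff(unique(evidence$enzyme_id), known)
  if (length(stray)) {
    warn(paste0("evidence for enzyme(s) not in any pathway ignored: ",
                paste(stray, collapse = ", ")))
    evidence <- evidence[evidence$enzyme_id %in% known, , drop = FALSE]
  }
  exp_map <- pathways %>%
    select("enzyme_id", dplyr::any_of("expected_compartment")) %>%
    distinct()
  if (!"expected_compartment" %in% names(exp_map)) {
    exp_map$expected_compartment <- NA_character_
  }
  species <- sort(unique(evidence$species))
  grid <- tidyr::expand_grid(species = species, enzyme_id = sort(known))
  evidence <- dplyr::left_join(evidence, exp_map, by = "enzyme_id")
  cells <- purrr::pmap(grid, function(species, enzyme_id) {
    rows <- evidence[evidence$species == species &
                       evidence$enzyme_id == enzyme_id, , drop = FALSE]
    st <- .cell_status(rows)
    tibble(species = species, enzyme_id = enzyme_id,
           status = st$status, localization = st$localization)
  })
  structure(dplyr::bind_rows(cells),
            class = c("pathway_matrix", class(tibble())))
}

#' Pathway completeness per species
#'
#' Completeness is the fraction of a pathway's enzymes with any `present_*`
#' status; `contaminant_only` counts as absent. A pathway missing any member
#' is incomplete (the arginine-deiminase pathway lacking carbamate kinase is
#' the canonical example: 2/3 present, non-functional).
#'
#' @param matrix A `pathway_matrix` from [build_matrix()].
#' @param pathways Pathway definition tibble.
#' @param pathway_id Optional single pathway to restrict to.
#' @return Tibble per (pathway, species): `pathway_id`, `species`,
#'   `n_enzymes`, `n_present`, `fraction_present`, `complete`, `missing`
#'   (list column of enzyme ids).
#' @export
pathway_completeness <- function(matrix, pathways, pathway_id = NULL) {
  if (!is.null(pathway_id)) {
    pathways <- pathways[pathways$pathway_id %in% pathway_id, , drop = FALSE]
    if (nrow(pathways) == 0L) abort("pathway not found in definitions")
  }
  joined <- dplyr::inner_join(
    pathways[, c("pathway_id", "enzyme_id")], matrix, by = "enzyme_id")
  joined %>%
    group_by(.data$pathway_id, .data$species) %>%
    summarise(
      n_enzymes = dplyr::n(),
      n_present = sum(startsWith(.data$status, "present")),
      fraction_present = .data$n_present / .data$n_enzymes,
      complete = .data$n_present == .data$n_enzymes,
      missing = list(sort(.data$enzyme_id[!startsWith(.data$status,
                                                      "present")])),
      .groups = "drop"
    )
}

#' Filter a community table at a relative-abundance threshold
#'
#' Lineages below the threshold in a culture are discarded for that culture
#' as likely contaminants (e.g. sample bleeding during sequencing). A
#' lineage at exactly the threshold is retained — the rule is "below
#' threshold is not considered".
#'
#' @param table Long tibble `lineage`, `culture`, `abundance`.
#' @param threshold Relative-abundance cutoff (default 0.01, i.e. 1%).
#' @return The retained rows, with attribute `retained_counts` (named
#'   per-culture counts; also available via [dplyr::count()]).
#' @export
filter_community <- function(table, threshold = 0.01) {
  stopifnot(all(c("lineage", "culture", "abundance") %in% names(table)))
  if (any(table$abundance < 0)) abort("abundances must be non-negative")
  sums <- tapply(table$abundance, table$culture, sum)
  if (any(abs(sums - 1) > 1e-6)) {
    warn("per-culture abundances do not sum to 1")
  }
  kept <- table[table$abundance >= threshold, , drop = FALSE]
  counts <- table(factor(kept$culture, levels = sort(unique(table$culture))))
  structure(kept, retained_counts = setNames(as.integer(counts),
                                             names(counts)))
}

#' Lineages shared between two cultures after filtering
#'
#' @param table A (filtered) community tibble.
#' @param cultures Length-2 vector of culture ids (default: the two present).
#' @return Sorted character vector of lineages present in both.
#' @export
shared_lineages <- function(table, cultures = NULL) {
  if (is.null(cultures)) cultures <- sort(unique(table$culture))
  if (length(cultures) != 2L) abort("exactly two cultures must be compared")
  a <- table$lineage[table$culture == cultures[1]]
  b <- table$lineage[table$culture == cultures[2]]
  sort(intersect(a, b))
}
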