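# The conservative consensus caller. A protein is assigned a compartment
# only when all selected predictors agree, so per-class precision can only
# improve over any single tool at the cost of recall; membrane and
# peroxisome, which only the multiclass tool can emit, are assigned when
# that tool calls them and every other tool says "other".

#' Consensus configuration
#'
#' @param selected_tools Ordered tool ids (typically [select_top_k()]
#'   output).
#' @param multiclass_tool The one tool in the panel whose vocabulary covers
#'   membrane and peroxisome; only it may trigger those assignments.
#' @param organellar_classes Classes assignable by unanimity. Membrane and
#'   peroxisome are excluded by construction; `other` is included so that a
#'   unanimous cytosolic call is itself an assignment.
#' @return A list of class `consensus_config`.
#' @export
consensus_config <- function(selected_tools,
                             multiclass_tool = selected_tools[length(selected_tools)],
                             organellar_classes = c("plastid", "mitochondrion",
                                                    "secretory", "other")) {
  if (!multiclass_tool %in% selected_tools) {
    abort("multiclass_tool must be one of the selected tools")
  }
  if (any(c("membrane", "peroxisome") %in% organellar_classes)) {
    abort("organellar_classes cannot include membrane or peroxisome")
  }
  bad <- setdiff(organellar_classes, canonical_classes(gold_only = TRUE))
  if (length(bad)) {
    abort(paste0("unknown organellar class(es): ", paste(bad, collapse = ", ")))
  }
  structure(list(selected_tools = selected_tools,
                 multiclass_tool = multiclass_tool,
                 organellar_classes = organellar_classes),
            class = "consensus_config")
}

# the rule cascade for one protein; calls is a named vector tool_id -> class
.consensus_one <- function(calls, cfg, is_partial) {
  if (is_partial) {
    return(list(assigned = "unassigned", rule_fired = "truncated",
                supporting_tools = character(0)))
  }
  votes <- calls[cfg$selected_tools]
  agreed <- unique(votes)
  if (length(agreed) == 1L && agreed %in% cfg$organellar_classes) {
    return(list(assigned = agreed, rule_fired = "unanimity",
                supporting_tools = cfg$selected_tools))
  }
  mc <- votes[[cfg$multiclass_tool]]
  others <- votes[setdiff(cfg$selected_tools, cfg$multiclass_tool)]
  if (mc %in% c("membrane", "peroxisome") && all(others == "other")) {
    return(list(assigned = mc, rule_fired = "multiclass_only",
                supporting_tools = cfg$multiclass_tool))
  }
  list(assigned = "unassigned", rule_fired = "none",
       supporting_tools = character(0))
}

#' Consensus localization call for one protein
#'
#' Rule cascade: (1) a truncated (N-terminally partial) protein is never
#' assigned; (2) if every selected tool emits the same class and that class
#' is assignable by unanimity, it is assigned; (3) else, if the multiclass
#' tool calls membrane or peroxisome while every other tool calls `other`,
#' the multiclass call stands; (4) otherwise the protein stays unassigned.
#'
#' @param protein_id Protein identifier.
#' @param calls Calls tibble restricted or not to this protein; exactly one
#'   call per selected tool must exist for `protein_id`.
#' @param cfg A [consensus_config()].
#' @param is_partial Is the protein's N-terminus incomplete?
#' @return One-row tibble `protein_id`, `assigned`, `rule_fired`,
#'   `supporting_tools` (comma-collapsed).
#' @export
#' @examples
#' calls <- tibble::tibble(protein_id = "p1",
#'                         tool_id = c("a", "b", "c"),
#'                         canonical = c("plastid", "plastid", "plastid"))
#' consensus_call("p1", calls, consensus_config(c("a", "b", "c")))
consensus_call <- function(protein_id, calls, cfg, is_partial = FALSE) {
  pc <- calls[calls$protein_id == protein_id, , drop = FALSE]
  missing <- setdiff(cfg$selected_tools, pc$tool_id)
  if (length(missing)) {
    abort(paste0("protein '", protein_id, "' lacks call(s) from tool(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(pc$tool_id[pc$tool_id %in% cfg$selected_tools])) {
    abort(paste0("protein '", protein_id, "' has duplicate tool calls"))
  }
  votes <- setNames(pc$canonical, pc$tool_id)
  res <- .consensus_one(votes, cfg, is_partial)
  tibble(protein_id = protein_id, assigned = res$assigned,
         rule_fired = res$rule_fired,
         supporting_tools = paste(res$supporting_tools, collapse = ","))
}

#' Consensus calls for a whole protein collection
#'
#' Applies [consensus_call()] to every protein appearing in `calls`
#' (restricted to the selected tools), in a deterministic order independent
#' of input row order. When `records` are supplied, their `is_partial` flag
#' routes truncated proteins to the `truncated` rule.
#'
#' @param calls Calls tibble covering every protein x selected tool.
#' @param cfg A [consensus_config()].
#' @param records Optional protein records tibble providing `is_partial`.
#' @return Tibble of class `consensus_calls`, one row per protein, sorted by
#'   `protein_id`, with a `class_counts` attribute (named per-class counts of
#'   assignments).
#' @export
batch_consensus <- function(calls, cfg, records = NULL) {
  stopifnot(inherits(cfg, "consensus_config"))
  sel <- calls[calls$tool_id %in% cfg$selected_tools, , drop = FALSE]
  proteins <- sort(unique(sel$protein_id))
  if (length(proteins) == 0L) {
    out <- tibble(protein_id = character(), assigned = character(),
                  rule_fired = character(), supporting_tools = character())
    return(structure(out, class = c("consensus_calls", class(out)),
                     class_counts = integer(0)))
  }
  partial <- setNames(rep(FALSE, length(proteins)), proteins)
  if (!is.null(records) && "is_partial" %in% names(records)) {
    known <- intersect(proteins, records$id)
    partial[known] <- setNames(records$is_partial, records$id)[known]
  }
  # wide layout: one row per protein, one column per tool
  wide <- sel %>%
    select("protein_id", "tool_id", "canonical") %>%
    tidyr::pivot_wider(names_from = "tool_id", values_from = "canonical")
  missing_any <- vapply(cfg$selected_tools, function(t) {
    !t %in% names(wide) || anyNA(wide[[t]])
  }, logical(1))
  if (any(missing_any)) {
    abort(paste0("missing call(s) from tool(s): ",
                 paste(cfg$selected_tools[missing_any], collapse = ", ")))
  }
  if (anyDuplicated(sel[, c("protein_id", "tool_id")])) {
    abort("duplicate (protein, tool) calls in input")
  }
  wide <- wide[match(proteins, wide$protein_id), , drop = FALSE]
  rows <- purrr::map(seq_along(proteins), function(i) {
    votes <- setNames(
      vapply(cfg$selected_tools, function(t) wide[[t]][i], character(1)),
      cfg$selected_tools)
    res <- .consensus_one(votes, cfg, partial[[i]])
    tibble(protein_id = proteins[i], assigned = res$assigned,
           rule_fired = res$rule_fired,
           supporting_tools = paste(res$supporting_tools, collapse = ","))
  })
  out <- dplyr::bind_rows(rows)
  counts <- table(factor(out$assigned, levels = canonical_classes()))
  structure(out, class = c("consensus_calls", class(tibble())),
            class_counts = setNames(as.integer(counts), names(counts)))
}

#' Per-class assignment counts of a consensus run
#'
#' @param consensus A `consensus_calls` tibble from [batch_consensus()].
#' @return Tibble `assigned`, `n`.
#' @export
consensus_summary <- function(consensus) {
  counts <- attr(consensus, "class_counts")
  if (is.null(counts)) {
    counts <- table(factor(consensus$assigned, levels = canonical_classes()))
    counts <- setNames(as.integer(counts), names(counts))
  }
  tibble(assigned = names(counts), n = unname(counts))
}
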