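# Readers/writers for every file the pipeline touches, plus the vocabulary
# mapping that reconciles heterogeneous predictor outputs.

#' Read protein sequences from a FASTA file
#'
#' Returns one row per record with the sequence uppercased and validated
#' against the 20 amino-acid letters plus `X`. A record is flagged
#' `is_partial` (N-terminus incomplete) when its first residue is not
#' methionine or when the word `partial` appears in the description;
#' downstream, partial sequences are excluded from feature cohorts and never
#' receive a consensus localization.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped).
#' @return A tibble with columns `id`, `description`, `sequence`,
#'   `is_partial`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 demo", "MKVLR"), f)
#' read_fasta(f)
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) {
                    abort(paste0("failed to parse FASTA '", path, "': ",
                                 conditionMessage(e)))
                  })
  if (length(set) == 0L) abort(paste0("FASTA file is empty: ", path))
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  sequence <- unname(toupper(as.character(set)))
  if (anyDuplicated(id)) {
    abort(paste0("duplicate record id in FASTA: ",
                 paste(unique(id[duplicated(id)]), collapse = ", ")))
  }
  for (i in seq_along(sequence)) {
    .validate_sequence(sequence[[i]], id[[i]])
  }
  tibble(
    id = id,
    description = description,
    sequence = sequence,
    is_partial = !startsWith(sequence, "M") |
      grepl("\\bpartial\\b", description, ignore.case = TRUE)
  )
}

.validate_sequence <- function(seq, id) {
  if (!nzchar(seq)) abort(paste0("empty sequence for record '", id, "'"))
  letters <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!letters %in% AA_ALLOWED)
  if (length(bad)) {
    abort(sprintf(
      "illegal character '%s' at position %d in record '%s'",
      letters[bad[1]], bad[1], id))
  }
  invisible(TRUE)
}

#' Write protein records to FASTA
#'
#' @param records Tibble as returned by [read_fasta()] (columns `id`,
#'   `sequence`, optionally `description`).
#' @param path Output path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  desc <- if ("description" %in% names(records)) records$description else ""
  set <- Biostrings::AAStringSet(records$sequence)
  names(set) <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# TSV schemas: required columns, their readr types, and the key whose
# duplication is an error.
.SCHEMAS <- list(
  labels = list(
    cols = c(protein_id = "c", true_class = "c"),
    key = "protein_id"
  ),
  calls = list(
    cols = c(protein_id = "c", tool_id = "c", native_label = "c"),
    optional = c(canonical = "c", score = "d"),
    key = c("protein_id", "tool_id")
  ),
  vocabulary = list(
    cols = c(tool_id = "c", native_label = "c", canonical = "c"),
    key = c("tool_id", "native_label")
  ),
  evidence = list(
    cols = c(species = "c", enzyme_id = "c", homolog_found = "l",
             best_hit_taxonomy = "c"),
    optional = c(consensus_class = "c", consensus_rule = "c",
                 n_paralogs = "i"),
    key = NULL
  ),
  abundance = list(
    cols = c(lineage = "c", culture = "c", abundance = "d"),
    key = c("lineage", "culture")
  ),
  spectrum = list(
    cols = c(wavenumber = "d", intensity = "d"),
    key = "wavenumber"
  )
)

#' Read a typed, validated TSV table
#'
#' Supported schemas: `labels` (`protein_id`, `true_class`), `calls`
#' (`protein_id`, `tool_id`, `native_label` and optional `canonical`,
#' `score`), `vocabulary`, `evidence`, `abundance` and `spectrum`. Missing
#' required columns, duplicate keys, out-of-vocabulary classes, abundances
#' outside \[0, 1\] and scores outside \[0, 1\] are errors.
#'
#' @param path Path to a tab-separated file with a header.
#' @param schema_name One of `names(orgloc:::.SCHEMAS)`.
#' @return A tibble typed according to the schema.
#' @export
read_table <- function(path, schema_name) {
  schema <- .SCHEMAS[[schema_name]]
  if (is.null(schema)) {
    abort(paste0("unknown schema '", schema_name, "'; available: ",
                 paste(names(.SCHEMAS), collapse = ", ")))
  }
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  missing <- setdiff(names(schema$cols), names(tbl))
  if (length(missing)) {
    abort(paste0("schema '", schema_name, "': missing column(s) ",
                 paste(missing, collapse = ", "), " in ", path))
  }
  types <- c(schema$cols, schema$optional %||% character())
  for (col in intersect(names(types), names(tbl))) {
    tbl[[col]] <- switch(types[[col]],
      c = as.character(tbl[[col]]),
      d = as.numeric(tbl[[col]]),
      i = as.integer(tbl[[col]]),
      l = as.logical(tbl[[col]])
    )
  }
  tbl <- tbl[, intersect(names(types), names(tbl)), drop = FALSE]
  if (!is.null(schema$key)) {
    keys <- do.call(paste, c(tbl[schema$key], sep = "\r"))
    if (anyDuplicated(keys)) {
      abort(paste0("schema '", schema_name, "': duplicate key (",
                   paste(schema$key, collapse = ", "), ") in ", path))
    }
  }
  .validate_table(tbl, schema_name)
  as_tibble(tbl)
}

.validate_table <- function(tbl, schema_name) {
  if (schema_name == "labels") {
    bad <- setdiff(unique(tbl$true_class), canonical_classes(gold_only = TRUE))
    if (length(bad)) {
      abort(paste0("labels: true_class value(s) outside the canonical gold ",
                   "vocabulary: ", paste(bad, collapse = ", ")))
    }
  }
  if (schema_name == "calls" && "score" %in% names(tbl)) {
    s <- tbl$score[!is.na(tbl$score)]
    if (any(s < 0 | s > 1)) abort("calls: score outside [0, 1]")
  }
  if (schema_name == "abundance") {
    if (any(is.na(tbl$abundance)) || any(tbl$abundance < 0) ||
        any(tbl$abundance > 1)) {
      abort("abundance: relative abundances must lie in [0, 1]")
    }
  }
  if (schema_name == "spectrum") {
    if (is.unsorted(tbl$wavenumber, strictly = TRUE)) {
      abort("spectrum: wavenumber axis must be strictly increasing")
    }
  }
  invisible(tbl)
}

#' Write a table as tab-separated UTF-8
#'
#' @param table A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path) {
  readr::write_tsv(table, path)
  invisible(path)
}

#' Map native predictor labels to the canonical vocabulary
#'
#' Each localization predictor has its own output vocabulary (e.g. TargetP's
#' `cTP`/`mTP`/`SP`/`noTP`); a vocabulary map declares, per tool, the
#' translation of every native label into [canonical_classes()]. Mapping is
#' total: any (tool, native label) pair absent from the map is an error.
#'
#' @param calls Tibble with `protein_id`, `tool_id`, `native_label`.
#' @param vmap Tibble with `tool_id`, `native_label`, `canonical`.
#' @return `calls` with a filled `canonical` column, input order preserved.
#' @export
#' @examples
#' calls <- tibble::tibble(protein_id = "p1", tool_id = "targetp",
#'                         native_label = "cTP")
#' vmap <- tibble::tibble(tool_id = "targetp", native_label = "cTP",
#'                        canonical = "plastid")
#' map_labels(calls, vmap)
map_labels <- function(calls, vmap) {
  stopifnot(all(c("protein_id", "tool_id", "native_label") %in% names(calls)))
  bad <- setdiff(unique(vmap$canonical), canonical_classes())
  if (length(bad)) {
    abort(paste0("vocabulary map targets unknown class(es): ",
                 paste(bad, collapse = ", ")))
  }
  mapped <- dplyr::left_join(
    dplyr::select(calls, -dplyr::any_of("canonical")),
    dplyr::distinct(vmap[, c("tool_id", "native_label", "canonical")]),
    by = c("tool_id", "native_label")
  )
  if (anyNA(mapped$canonical)) {
    miss <- dplyr::distinct(
      mapped[is.na(mapped$canonical), c("tool_id", "native_label")])
    abort(paste0(
      "unmapped native label(s): ",
      paste(sprintf("%s:'%s'", miss$tool_id, miss$native_label),
            collapse = ", ")))
  }
  mapped
}

`%||%` <- function(x, y) if (is.null(x)) y else x
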