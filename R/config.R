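# YAML simulation configs: one file mirrors the generator configurations
# field for field, so a whole synthetic study is reproducible from a small
# text document.

#' Load simulation configuration from YAML
#'
#' The file may contain any of three top-level keys, each mirroring the
#' corresponding constructor's arguments field for field:
#' `proteome` ([proteome_config()]), `spectrum` ([spectrum_config()]), and
#' `tools` — a list of entries with `tool_id`, and either `accuracy` (plus
#' optional `classes`, `emitted`) for the diagonal convenience form of
#' [tool_error_model()], or an explicit `confusion` list of
#' `{true_class, emitted, prob}` rows.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `proteome`, `spectrum`, `tools` (any of
#'   which may be `NULL` when absent from the file).
#' @export
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines(c("proteome:",
#'              "  n_per_class: {plastid: 5, mitochondrion: 5,",
#'              "                secretory: 2, other: 2}",
#'              "  seed: 9",
#'              "tools:",
#'              "  - tool_id: toolA",
#'              "    accuracy: 0.9"), f)
#' cfg <- load_simulation_config(f)
#' cfg$proteome$n_per_class
load_simulation_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- yaml::read_yaml(path)
  out <- list(proteome = NULL, spectrum = NULL, tools = NULL)
  if (!is.null(raw$proteome)) {
    p <- raw$proteome
    if (!is.null(p$n_per_class)) p$n_per_class <- unlist(p$n_per_class)
    if (!is.null(p$background_frequencies)) {
      p$background_frequencies <- unlist(p$background_frequencies)
    }
    for (r in c("ctp_length_range", "mtp_length_range",
                "mature_length_range")) {
      if (!is.null(p[[r]])) p[[r]] <- unlist(p[[r]])
    }
    out$proteome <- do.call(proteome_config, p)
  }
  if (!is.null(raw$spectrum)) {
    s <- raw$spectrum
    if (!is.null(s$wn_range)) s$wn_range <- unlist(s$wn_range)
    out$spectrum <- do.call(spectrum_config, s)
  }
  if (!is.null(raw$tools)) {
    out$tools <- lapply(raw$tools, function(t) {
      if (is.null(t$tool_id)) abort("each tools entry needs a tool_id")
      if (!is.null(t$confusion)) {
        rows <- dplyr::bind_rows(lapply(t$confusion, as_tibble))
        rows$tool_id <- t$tool_id
        rows <- rows[, c("tool_id", "true_class", "emitted", "prob")]
        .validate_error_model(rows)
        structure(rows, class = c("tool_error_model", class(rows)))
      } else {
        args <- t[intersect(names(t), c("tool_id", "classes", "accuracy",
                                        "emitted"))]
        if (!is.null(args$classes)) args$classes <- unlist(args$classes)
        if (!is.null(args$emitted)) args$emitted <- unlist(args$emitted)
        do.call(tool_error_model, args)
      }
    })
  }
  out
}
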