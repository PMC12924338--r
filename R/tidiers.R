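# broom-style tidiers for the benchmark objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a tool confusion matrix
#'
#' @param x A `tool_confusion` from [confusion_from_calls()].
#' @param ... Unused.
#' @return Long tibble `tool_id`, `gold`, `predicted`, `n`.
#' @export
tidy.tool_confusion <- function(x, ...) {
  df <- as.data.frame.table(x$matrix, responseName = "n",
                            stringsAsFactors = FALSE)
  tibble(tool_id = x$tool_id, gold = df$gold, predicted = df$predicted,
         n = as.integer(df$n))
}

#' Per-class metrics of a tool confusion matrix
#'
#' @inheritParams tidy.tool_confusion
#' @return The [compute_metrics()] tibble.
#' @export
glance.tool_confusion <- function(x, ...) compute_metrics(x)

#' Tidy a multi-tool benchmark
#'
#' @param x A `tool_benchmark` from [benchmark_tools()].
#' @param ... Unused.
#' @return The per-tool, per-class metrics tibble.
#' @export
tidy.tool_benchmark <- function(x, ...) as_tibble(x$metrics)

#' One-row-per-tool summary of a benchmark
#'
#' @inheritParams tidy.tool_benchmark
#' @return Tibble `tool_id`, `accuracy` (overall, from the confusion
#'   diagonal), `mean_mcc` (over the classes with a defined MCC).
#' @export
glance.tool_benchmark <- function(x, ...) {
  rows <- purrr::map(x$confusions, function(cm) {
    m <- cm$matrix
    shared <- intersect(rownames(m), colnames(m))
    diag_sum <- sum(vapply(shared, function(cls) m[cls, cls], numeric(1)))
    met <- x$metrics[x$metrics$tool_id == cm$tool_id, ]
    tibble(tool_id = cm$tool_id,
           n = cm$n_total,
           accuracy = diag_sum / sum(m),
           mean_mcc = mean(met$mcc, na.rm = TRUE))
  })
  dplyr::bind_rows(rows)
}
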