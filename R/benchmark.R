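# Scoring localization predictors against a gold standard: per-tool
# confusion matrices over the canonical classes, one-vs-rest metrics
# including MCC, and tool ranking/selection for the consensus.

#' Confusion matrix of one tool against the gold standard
#'
#' Rows are gold classes, columns are emitted classes plus an explicit
#' `no-call` column: a labeled protein with no call from the tool counts
#' against that tool's sensitivity (it is a false negative for its gold
#' class) rather than silently dropping out — the conservative convention.
#'
#' @param labels Tibble `protein_id`, `true_class`.
#' @param calls Calls tibble with `canonical` filled (see [map_labels()]).
#' @param tool_id Tool to score.
#' @return A list of class `tool_confusion` with elements `tool_id`,
#'   `matrix` (gold rows x predicted columns, integer counts) and `n_total`.
#' @export
confusion_from_calls <- function(labels, calls, tool_id) {
  stopifnot(all(c("protein_id", "true_class") %in% names(labels)))
  tc <- calls[calls$tool_id == tool_id, , drop = FALSE]
  if (anyDuplicated(tc$protein_id)) {
    dup <- unique(tc$protein_id[duplicated(tc$protein_id)])
    abort(paste0("duplicate call(s) from '", tool_id, "' for protein(s): ",
                 paste(head(dup, 5), collapse = ", ")))
  }
  pred <- setNames(tc$canonical, tc$protein_id)[labels$protein_id]
  pred[is.na(pred)] <- "no-call"
  gold_levels <- sort(unique(labels$true_class))
  pred_levels <- c(sort(unique(c(gold_levels, setdiff(pred, "no-call")))),
                   "no-call")
  m <- table(factor(labels$true_class, levels = gold_levels),
             factor(pred, levels = pred_levels))
  m <- matrix(as.integer(m), nrow = length(gold_levels),
              dimnames = list(gold = gold_levels, predicted = pred_levels))
  structure(list(tool_id = tool_id, matrix = m, n_total = nrow(labels)),
            class = "tool_confusion")
}

#' @export
print.tool_confusion <- function(x, ...) {
  cat("Confusion matrix for tool '", x$tool_id, "' (n = ", x$n_total,
      ")\n\n", sep = "")
  print(x$matrix)
  invisible(x)
}

#' One-vs-rest classification metrics per class
#'
#' For each gold class the confusion matrix is collapsed to binary counts
#' (TP, FP, FN, TN) and the usual derived statistics are reported:
#' sensitivity TP/(TP+FN), specificity TN/(TN+FP), precision TP/(TP+FP),
#' accuracy, and the Matthews correlation coefficient
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#' Ratios with a zero denominator are reported as `NA`, never as 0.
#'
#' @param cm A `tool_confusion` from [confusion_from_calls()].
#' @return Tibble of class `tool_metrics`, one row per gold class:
#'   `tool_id`, `class`, `tp`, `fp`, `fn`, `tn`, `sensitivity`,
#'   `specificity`, `precision`, `accuracy`, `f1`, `mcc`.
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "tool_confusion"))
  if (cm$n_total <= 0) abort("empty confusion matrix")
  m <- cm$matrix
  gold <- rownames(m)
  rows <- purrr::map(gold, function(cls) {
    tp <- if (cls %in% colnames(m)) m[cls, cls] else 0L
    fp <- if (cls %in% colnames(m)) sum(m[, cls]) - tp else 0L
    fn <- sum(m[cls, ]) - tp
    tn <- sum(m) - tp - fp - fn
    ratio <- function(num, den) if (den > 0) num / den else NA_real_
    denom <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
    mcc <- if (denom > 0) {
      (as.numeric(tp) * tn - as.numeric(fp) * fn) / denom
    } else NA_real_
    prec <- ratio(tp, tp + fp)
    sens <- ratio(tp, tp + fn)
    f1 <- if (!is.na(prec) && !is.na(sens) && (prec + sens) > 0) {
      2 * prec * sens / (prec + sens)
    } else NA_real_
    tibble(tool_id = cm$tool_id, class = cls,
           tp = as.integer(tp), fp = as.integer(fp),
           fn = as.integer(fn), tn = as.integer(tn),
           sensitivity = sens, specificity = ratio(tn, tn + fp),
           precision = prec,
           accuracy = (tp + tn) / sum(m),
           f1 = f1, mcc = mcc)
  })
  structure(dplyr::bind_rows(rows),
            class = c("tool_metrics", class(tibble())))
}

#' Benchmark a set of tools against the gold standard
#'
#' Convenience wrapper running [confusion_from_calls()] and
#' [compute_metrics()] for every tool present in `calls`.
#'
#' @inheritParams confusion_from_calls
#' @return A list of class `tool_benchmark`: `confusions` (named list of
#'   `tool_confusion`) and `metrics` (one `tool_metrics` tibble).
#' @export
benchmark_tools <- function(labels, calls) {
  tools <- sort(unique(calls$tool_id))
  confusions <- purrr::map(tools, ~confusion_from_calls(labels, calls, .x))
  names(confusions) <- tools
  metrics <- dplyr::bind_rows(purrr::map(confusions, compute_metrics))
  structure(list(confusions = confusions,
                 metrics = structure(metrics,
                                     class = c("tool_metrics",
                                               class(tibble())))),
            class = "tool_benchmark")
}

#' @export
print.tool_benchmark <- function(x, ...) {
  cat("Localization predictor benchmark:", length(x$confusions),
      "tool(s),", x$confusions[[1]]$n_total, "gold-standard proteins\n")
  print(glance.tool_benchmark(x))
  invisible(x)
}

#' Rank tools by a metric aggregated over classes
#'
#' The aggregate is the unweighted mean of the chosen metric over the
#' requested classes (default: MCC over plastid + mitochondrion, the two
#' classes the consensus is designed to protect). Ties are broken
#' lexicographically by `tool_id` for reproducibility. An optional per-class
#' precision floor discards tools whose precision drops below it in any
#' requested class before ranking — the mechanism by which a predictor with
#' too many mitochondrial false positives is excluded.
#'
#' @param metrics A `tool_metrics` tibble (e.g. `benchmark_tools()$metrics`).
#' @param metric_name One of `"mcc"`, `"accuracy"`, `"f1"`,
#'   `"sensitivity"`, `"precision"`, `"specificity"`.
#' @param classes Classes to aggregate over.
#' @param precision_floor Optional minimum per-class precision; `NULL`
#'   (default) disables the filter.
#' @return Tibble of class `tool_ranking`: `rank`, `tool_id`, `metric`,
#'   `aggregate`, in descending aggregate order.
#' @export
rank_tools <- function(metrics, metric_name = "mcc",
                       classes = c("plastid", "mitochondrion"),
                       precision_floor = NULL) {
  metric_name <- match.arg(metric_name,
                           c("mcc", "accuracy", "f1", "sensitivity",
                             "precision", "specificity"))
  sub <- metrics[metrics$class %in% classes, , drop = FALSE]
  missing <- setdiff(classes, unique(sub$class))
  if (length(missing)) {
    abort(paste0("metrics lack class(es): ", paste(missing, collapse = ", ")))
  }
  if (!is.null(precision_floor)) {
    ok <- tapply(sub$precision, sub$tool_id,
                 function(p) all(!is.na(p) & p >= precision_floor))
    sub <- sub[sub$tool_id %in% names(ok)[ok], , drop = FALSE]
    if (nrow(sub) == 0L) abort("precision floor excluded every tool")
  }
  agg <- sub %>%
    group_by(.data$tool_id) %>%
    summarise(aggregate = mean(.data[[metric_name]]), .groups = "drop") %>%
    arrange(dplyr::desc(.data$aggregate), .data$tool_id) %>%
    mutate(rank = dplyr::row_number(), metric = metric_name) %>%
    select("rank", "tool_id", "metric", "aggregate")
  structure(agg, class = c("tool_ranking", class(tibble())))
}

#' Select the top-k tools from a ranking
#'
#' @param ranking A `tool_ranking` from [rank_tools()].
#' @param k Number of tools (default 3, the consensus panel size).
#' @return Character vector of tool ids in rank order.
#' @export
select_top_k <- function(ranking, k = 3L) {
  if (k > nrow(ranking)) {
    abort(sprintf("k = %d exceeds the %d ranked tool(s)", k, nrow(ranking)))
  }
  ranking$tool_id[seq_len(k)]
}
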