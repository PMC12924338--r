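# ggplot2 displays for the main result types. Each autoplot() returns a
# plain ggplot the caller can restyle.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col geom_tile
#'   geom_point geom_vline labs scale_fill_gradient2 theme_minimal
#'   facet_wrap
#' @export
ggplot2::autoplot

#' Plot a positional charge profile
#'
#' @param object A `charge_profile` from [positional_charge_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.charge_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$position, y = .data$mean_charge)) +
    geom_line(color = "#2c7fb8") +
    geom_point(size = 0.8, color = "#2c7fb8") +
    labs(x = "Position from N-terminus", y = "Mean net charge",
         title = "Positional charge profile") +
    theme_minimal()
}

#' Heatmap of a position x residue enrichment table
#'
#' @param object An `enrichment_table` from [sentinel_enrichment()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.enrichment_table <- function(object, ...) {
  ggplot(object, aes(x = .data$position, y = .data$residue,
                     fill = .data$enrichment)) +
    geom_tile() +
    scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b",
                         midpoint = 0, name = "log2 enrichment") +
    labs(x = "Position from N-terminus", y = "Residue",
         title = "Position-specific residue enrichment") +
    theme_minimal()
}

#' Bar chart of per-class metrics for each tool
#'
#' @param object A `tool_metrics` tibble (e.g. `benchmark_tools()$metrics`).
#' @param metric Which metric column to display (default `"mcc"`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tool_metrics <- function(object, metric = "mcc", ...) {
  ggplot(object, aes(x = .data$class, y = .data[[metric]],
                     fill = .data$tool_id)) +
    geom_col(position = "dodge") +
    labs(x = NULL, y = toupper(metric), fill = "Tool",
         title = "Predictor benchmark") +
    theme_minimal()
}

#' Grid display of a pathway presence/localization matrix
#'
#' @param object A `pathway_matrix` from [build_matrix()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pathway_matrix <- function(object, ...) {
  pal <- c(present_consistent = "#1a9850", present_unassigned = "#fee08b",
           present_truncated = "#fdae61", contaminant_only = "#d73027",
           absent = "grey85")
  ggplot(object, aes(x = .data$species, y = .data$enzyme_id,
                     fill = .data$status)) +
    geom_tile(color = "white", linewidth = 0.4) +
    ggplot2::scale_fill_manual(values = pal, name = "Status") +
    labs(x = NULL, y = NULL, title = "Enzyme presence and localization") +
    theme_minimal()
}

#' Plot a spectrum with the unsaturation bands marked
#'
#' @param object A `spectrum_tbl` (or any tibble with `wavenumber`,
#'   `intensity`).
#' @param bands A [band_definition()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spectrum_tbl <- function(object, bands = band_definition(), ...) {
  ggplot(object, aes(x = .data$wavenumber, y = .data$intensity)) +
    geom_line() +
    geom_vline(xintercept = bands$centers, linetype = "dashed",
               color = "#d95f02") +
    labs(x = expression(Wavenumber ~ (cm^-1)), y = "Intensity (a.u.)",
         title = "Raman spectrum") +
    theme_minimal()
}
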