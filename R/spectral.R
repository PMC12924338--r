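# The lipid-unsaturation statistic: baseline-corrected band-intensity ratio
# I(1656)/I(1440) — C=C stretch over CH2 deformation — and cohort summaries.

#' Band definition for the unsaturation ratio
#'
#' @param centers Length-2 vector: the C=C and CH2 band centers in cm-1
#'   (numerator first).
#' @param half_width Search half-width around each center, cm-1: the band
#'   intensity is taken inside center +/- half_width.
#' @param anchors List of two length-2 ranges (cm-1) flanking both bands,
#'   used by [baseline_correct()]; they must not overlap the search
#'   windows.
#' @return A list of class `band_definition`.
#' @export
band_definition <- function(centers = c(1656, 1440), half_width = 10,
                            anchors = list(c(1250, 1330), c(1740, 1790))) {
  if (length(centers) != 2L) abort("exactly two band centers are required")
  if (half_width <= 0) abort("half_width must be > 0")
  if (length(anchors) != 2L ||
      any(vapply(anchors, length, integer(1)) != 2L)) {
    abort("anchors must be a list of two (low, high) ranges")
  }
  for (a in anchors) {
    if (a[1] >= a[2]) abort("anchor ranges must be increasing")
    for (ct in centers) {
      if (a[1] <= ct + half_width && a[2] >= ct - half_width) {
        abort("anchor windows must be disjoint from the band search windows")
      }
    }
  }
  structure(list(centers = centers, half_width = half_width,
                 anchors = anchors),
            class = "band_definition")
}

.check_spectrum <- function(spectrum) {
  stopifnot(all(c("wavenumber", "intensity") %in% names(spectrum)))
  if (nrow(spectrum) < 2L) abort("spectrum needs at least two points")
  if (is.unsorted(spectrum$wavenumber, strictly = TRUE)) {
    abort("wavenumber axis must be strictly increasing")
  }
  invisible(spectrum)
}

#' Subtract a linear two-anchor baseline
#'
#' Fits the straight line through the mean (wavenumber, intensity) of each
#' anchor window and subtracts it. A linear baseline of any slope is thereby
#' removed exactly; the band ratio becomes invariant to such baselines.
#'
#' @param spectrum Tibble `wavenumber`, `intensity`.
#' @param bands A [band_definition()] supplying the anchor windows.
#' @return The corrected spectrum (same class as the input).
#' @export
baseline_correct <- function(spectrum, bands = band_definition()) {
  .check_spectrum(spectrum)
  wn <- spectrum$wavenumber
  pts <- purrr::map(bands$anchors, function(a) {
    inside <- wn >= a[1] & wn <= a[2]
    if (!any(inside)) {
      abort(sprintf("baseline anchor %g-%g lies outside the axis (%g-%g)",
                    a[1], a[2], min(wn), max(wn)))
    }
    c(x = mean(wn[inside]), y = mean(spectrum$intensity[inside]))
  })
  slope <- (pts[[2]]["y"] - pts[[1]]["y"]) / (pts[[2]]["x"] - pts[[1]]["x"])
  intercept <- pts[[1]]["y"] - slope * pts[[1]]["x"]
  out <- spectrum
  out$intensity <- spectrum$intensity - (intercept + slope * wn)
  out
}

#' Lipid-unsaturation band-intensity ratio I(1656)/I(1440)
#'
#' The ratio of the C=C stretch band intensity to the CH2 deformation band
#' intensity, a proxy for fatty-acid double-bond content (values around 1
#' indicate predominantly monounsaturated acyl chains). By default the band
#' intensity is the local maximum within +/- `half_width` of the center
#' (`mode = "height"`); `mode = "area"` integrates the window by the
#' trapezoidal rule instead. The input should be baseline-corrected (see
#' [baseline_correct()]); the ratio is invariant to global intensity
#' scaling.
#'
#' @param spectrum Tibble `wavenumber`, `intensity` (baseline-corrected).
#' @param bands A [band_definition()].
#' @param mode `"height"` (default) or `"area"`.
#' @return A positive number.
#' @export
#' @examples
#' sp <- generate_spectrum(spectrum_config(noise_sd = 0, true_ratio = 1.07))
#' unsaturation_ratio(baseline_correct(sp))
unsaturation_ratio <- function(spectrum, bands = band_definition(),
                               mode = c("height", "area")) {
  mode <- match.arg(mode)
  .check_spectrum(spectrum)
  wn <- spectrum$wavenumber
  band_intensity <- function(center) {
    inside <- wn >= center - bands$half_width & wn <= center + bands$half_width
    if (!any(inside)) {
      abort(sprintf("band window %g +/- %g outside the axis",
                    center, bands$half_width))
    }
    y <- spectrum$intensity[inside]
    if (mode == "height") max(y)
    else {
      x <- wn[inside]
      sum(diff(x) * (head(y, -1) + y[-1]) / 2)
    }
  }
  num <- band_intensity(bands$centers[1])
  den <- band_intensity(bands$centers[2])
  if (den <= 0) {
    abort("non-positive denominator band intensity; is the spectrum baseline-corrected?")
  }
  num / den
}

#' Cohort summary of unsaturation ratios
#'
#' Applies baseline correction (optional) and [unsaturation_ratio()] to each
#' spectrum and reports the sample mean and sample standard deviation
#' (n - 1 denominator) over the cohort — the form in which a
#' "ratio = mean +/- sd (n = ...)" statement is made.
#'
#' @param spectra List of spectrum tibbles.
#' @param bands A [band_definition()].
#' @param correct_baseline Apply [baseline_correct()] first? Default `TRUE`.
#' @param mode Passed to [unsaturation_ratio()].
#' @return Tibble `mean`, `sd`, `n` (plus `ratios` list column).
#' @export
cohort_ratio_summary <- function(spectra, bands = band_definition(),
                                 correct_baseline = TRUE,
                                 mode = c("height", "area")) {
  mode <- match.arg(mode)
  if (length(spectra) < 1L) abort("at least one spectrum is required")
  ratios <- vapply(spectra, function(sp) {
    if (correct_baseline) sp <- baseline_correct(sp, bands)
    unsaturation_ratio(sp, bands, mode)
  }, numeric(1))
  tibble(mean = mean(ratios),
         sd = if (length(ratios) > 1L) stats::sd(ratios) else NA_real_,
         n = length(ratios),
         ratios = list(unname(ratios)))
}
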