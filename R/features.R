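# Transit-peptide validation features: positional charge profiles, FGLK-site
# scanning in N-terminal windows, and position-specific residue enrichment
# against a background composition. Sequences flagged is_partial are
# excluded from every feature cohort by default — an incomplete N-terminus
# has no interpretable presequence.

CHARGE_MAP <- c(K = 1L, R = 1L, D = -1L, E = -1L)

#' Formal charge of an amino-acid residue
#'
#' Convention at assumed physiological pH: K and R carry +1, D and E carry
#' -1, everything else (including H and the unknown residue X) carries 0.
#' Vectorised over residues.
#'
#' @param residue Character vector of single residue letters.
#' @return Integer vector in \{-1, 0, +1\}.
#' @export
#' @examples
#' residue_charge(c("K", "E", "H", "A"))
residue_charge <- function(residue) {
  residue <- toupper(residue)
  bad <- which(!residue %in% AA_ALLOWED)
  if (length(bad)) {
    abort(paste0("illegal residue letter: ",
                 paste(unique(residue[bad]), collapse = ", ")))
  }
  out <- unname(CHARGE_MAP[residue])
  out[is.na(out)] <- 0L
  out
}

.feature_cohort <- function(records, include_partial) {
  stopifnot(is.data.frame(records), "sequence" %in% names(records))
  if (!include_partial && "is_partial" %in% names(records)) {
    records <- records[!records$is_partial, , drop = FALSE]
  }
  records
}

#' Per-position mean net charge over a sequence collection
#'
#' `mean_charge[p]` averages [residue_charge()] at position `p` over all
#' sequences of length at least `p`; `n_contributing[p]` counts them, so the
#' profile degrades gracefully as shorter sequences drop out.
#'
#' @param records Protein records tibble (needs `sequence`; `is_partial`
#'   honoured when present).
#' @param L Maximum position (1-based).
#' @param include_partial Include N-terminally truncated sequences?
#' @return Tibble `position`, `mean_charge`, `n_contributing` of class
#'   `charge_profile`.
#' @export
#' @examples
#' recs <- tibble::tibble(sequence = "MRKDE")
#' positional_charge_profile(recs, L = 5)
positional_charge_profile <- function(records, L, include_partial = FALSE) {
  if (L < 1) abort("L must be >= 1")
  records <- .feature_cohort(records, include_partial)
  if (nrow(records) == 0L) abort("no sequences to profile")
  seqs <- records$sequence
  lens <- nchar(seqs)
  prof <- purrr::map(seq_len(L), function(p) {
    covering <- seqs[lens >= p]
    if (length(covering) == 0L) {
      return(tibble(position = p, mean_charge = NA_real_,
                    n_contributing = 0L))
    }
    tibble(position = p,
           mean_charge = mean(residue_charge(substr(covering, p, p))),
           n_contributing = length(covering))
  })
  structure(dplyr::bind_rows(prof),
            class = c("charge_profile", class(tibble())))
}

#' Mean net charge of the N-terminal and central regions
#'
#' For each sequence long enough to cover a region, the mean residue charge
#' over that region is computed; region means are then averaged over
#' sequences. Defaults probe the cTP expectation: an uncharged start
#' (first 10 residues) versus a positively charged centre (positions 15-35).
#'
#' @param records Protein records tibble.
#' @param first_k N-terminal region is positions `1..first_k`.
#' @param central Length-2 vector, central region (1-based, inclusive).
#' @param include_partial Include truncated sequences?
#' @return Tibble with one row: `first_k_mean`, `central_mean`,
#'   `n_first_k`, `n_central`.
#' @export
region_charge_summary <- function(records, first_k = 10L,
                                  central = c(15L, 35L),
                                  include_partial = FALSE) {
  if (first_k < 1 || central[1] < 1 || central[1] > central[2]) {
    abort("invalid region windows")
  }
  records <- .feature_cohort(records, include_partial)
  lens <- nchar(records$sequence)
  region_mean <- function(from, to) {
    covering <- records$sequence[lens >= to]
    if (length(covering) == 0L) {
      abort(sprintf("no sequence covers region %d-%d", from, to))
    }
    per_seq <- vapply(covering, function(s) {
      mean(residue_charge(strsplit(substr(s, from, to), "")[[1]]))
    }, numeric(1), USE.NAMES = FALSE)
    c(mean(per_seq), length(covering))
  }
  fk <- region_mean(1L, first_k)
  ce <- region_mean(central[1], central[2])
  tibble(first_k_mean = fk[1], central_mean = ce[1],
         n_first_k = as.integer(fk[2]), n_central = as.integer(ce[2]))
}

#' Scan N-terminal windows for FGLK sites
#'
#' Default grammar: a site is any length-4 subwindow whose start position
#' lies inside the scan window and which contains at least `min_distinct`
#' distinct letters from `motif_letters` (default 3 of \{F, G, L, K\}).
#' Overlapping sites are all reported; the subwindow may run past the window
#' end but must fit inside the sequence. Windows extending beyond a sequence
#' are clipped with a warning. The grammar is configurable because the
#' field's FGLK-site definitions vary.
#'
#' @param records Protein records tibble (needs `sequence`; `id` optional).
#' @param window Length-2 vector, 1-based inclusive scan window for site
#'   start positions.
#' @param motif_letters Motif alphabet.
#' @param min_distinct Minimum distinct motif letters in a subwindow.
#' @param site_length Subwindow length.
#' @param include_partial Include truncated sequences?
#' @return Tibble `protein_id`, `window_start`, `window_end`,
#'   `site_starts` (list column), `n_sites`, of class `glk_scan`.
#' @export
#' @examples
#' scan_glk_sites(tibble::tibble(id = "p", sequence = "MFGLKAAA"),
#'                window = c(1, 8))
scan_glk_sites <- function(records, window = c(1L, 40L),
                           motif_letters = c("F", "G", "L", "K"),
                           min_distinct = 3L, site_length = 4L,
                           include_partial = FALSE) {
  if (window[1] < 1 || window[1] > window[2]) abort("invalid scan window")
  records <- .feature_cohort(records, include_partial)
  ids <- if ("id" %in% names(records)) records$id
         else sprintf("seq_%d", seq_len(nrow(records)))
  clipped <- FALSE
  rows <- purrr::map(seq_len(nrow(records)), function(i) {
    s <- records$sequence[i]
    len <- nchar(s)
    last_start <- min(window[2], len - site_length + 1L)
    if (window[2] > len) clipped <<- TRUE
    starts <- integer(0)
    if (last_start >= window[1]) {
      for (p in window[1]:last_start) {
        sub <- strsplit(substr(s, p, p + site_length - 1L), "")[[1]]
        if (length(intersect(sub, motif_letters)) >= min_distinct) {
          starts <- c(starts, p)
        }
      }
    }
    tibble(protein_id = ids[i], window_start = window[1],
           window_end = window[2], site_starts = list(starts),
           n_sites = length(starts))
  })
  if (clipped) {
    warn("scan window extends beyond some sequences; clipped to sequence end")
  }
  structure(dplyr::bind_rows(rows), class = c("glk_scan", class(tibble())))
}

#' Fraction of sequences with at least one FGLK site in a window
#'
#' @inheritParams scan_glk_sites
#' @param ... Passed on to [scan_glk_sites()] (grammar options).
#' @return A single number in \[0, 1\].
#' @export
glk_prevalence <- function(records, window = c(1L, 40L),
                           include_partial = FALSE, ...) {
  records <- .feature_cohort(records, include_partial)
  if (nrow(records) == 0L) abort("no sequences to scan")
  scan <- scan_glk_sites(records, window = window,
                         include_partial = TRUE, ...)
  mean(scan$n_sites >= 1L)
}

#' Position-specific residue enrichment over a background
#'
#' For each position `p` in `1..k` and each of the 20 standard residues
#' `a`, reports
#' `log2( (count(a at p) + pseudocount) / (n_p + 20 * pseudocount) / background[a] )`
#' where `n_p` counts standard residues observed at `p` (X is ignored:
#' it matches no residue). Sentinel residues of a targeting-peptide class
#' show up as positive enrichment bands near the N-terminus.
#'
#' @param records Protein records tibble.
#' @param background_frequencies Named 20-vector summing to 1 (default
#'   uniform).
#' @param k Number of N-terminal positions to tabulate.
#' @param pseudocount Additive smoothing (> 0 keeps the table finite).
#' @param include_partial Include truncated sequences?
#' @return Long tibble `position`, `residue`, `enrichment`, `observed_count`,
#'   `n`, of class `enrichment_table`.
#' @export
sentinel_enrichment <- function(records, background_frequencies = NULL,
                                k = 40L, pseudocount = 0.5,
                                include_partial = FALSE) {
  if (k < 1) abort("k must be >= 1")
  if (pseudocount <= 0) abort("pseudocount must be > 0")
  if (is.null(background_frequencies)) {
    background_frequencies <- setNames(rep(1 / 20, 20), AA_LETTERS)
  }
  if (!setequal(names(background_frequencies), AA_LETTERS)) {
    abort("background_frequencies must cover exactly the 20 standard residues")
  }
  if (abs(sum(background_frequencies) - 1) > 1e-6) {
    abort("background_frequencies must sum to 1")
  }
  records <- .feature_cohort(records, include_partial)
  if (nrow(records) == 0L) abort("no sequences for enrichment")
  seqs <- records$sequence
  lens <- nchar(seqs)
  rows <- purrr::map(seq_len(k), function(p) {
    obs <- substr(seqs[lens >= p], p, p)
    obs <- obs[obs != "X"]
    zero_bg <- intersect(unique(obs),
                         names(background_frequencies)[background_frequencies == 0])
    if (length(zero_bg)) {
      abort(paste0("residue(s) ", paste(zero_bg, collapse = ", "),
                   " observed at position ", p,
                   " have zero background frequency; add a pseudocount to ",
                   "the background"))
    }
    counts <- table(factor(obs, levels = AA_LETTERS))
    n <- length(obs)
    tibble(
      position = p,
      residue = AA_LETTERS,
      observed_count = as.integer(counts),
      n = n,
      enrichment = log2(((as.integer(counts) + pseudocount) /
                           (n + 20 * pseudocount)) /
                          unname(background_frequencies[AA_LETTERS]))
    )
  })
  structure(dplyr::bind_rows(rows),
            class = c("enrichment_table", class(tibble())))
}
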