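# Independent brute-force oracles. These deliberately share no code with
# the package: plain loops and if-chains, so agreement is evidence the
# vectorised implementations count the same things.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
          "P", "Q", "R", "S", "T", "V", "W", "Y")

oracle_charge <- function(letter) {
  if (letter == "K" || letter == "R") return(1)
  if (letter == "D" || letter == "E") return(-1)
  0
}

oracle_profile <- function(seqs, L) {
  means <- numeric(L)
  counts <- integer(L)
  for (p in seq_len(L)) {
    total <- 0
    n <- 0
    for (s in seqs) {
      if (nchar(s) >= p) {
        total <- total + oracle_charge(substr(s, p, p))
        n <- n + 1
      }
    }
    counts[p] <- n
    means[p] <- if (n > 0) total / n else NA_real_
  }
  list(mean_charge = means, n_contributing = counts)
}

oracle_glk_starts <- function(seq, window, motif = c("F", "G", "L", "K"),
                              min_distinct = 3, site_len = 4) {
  starts <- integer(0)
  last <- min(window[2], nchar(seq) - site_len + 1)
  if (last < window[1]) return(starts)
  for (p in window[1]:last) {
    seen <- character(0)
    for (q in p:(p + site_len - 1)) {
      ch <- substr(seq, q, q)
      if (ch %in% motif && !(ch %in% seen)) seen <- c(seen, ch)
    }
    if (length(seen) >= min_distinct) starts <- c(starts, p)
  }
  starts
}

oracle_enrichment <- function(seqs, bg, k, psi) {
  out <- matrix(NA_real_, nrow = k, ncol = 20,
                dimnames = list(NULL, AA20))
  for (p in seq_len(k)) {
    counts <- setNames(rep(0, 20), AA20)
    n <- 0
    for (s in seqs) {
      if (nchar(s) >= p) {
        ch <- substr(s, p, p)
        if (ch != "X") {
          counts[ch] <- counts[ch] + 1
          n <- n + 1
        }
      }
    }
    for (a in AA20) {
      out[p, a] <- log2(((counts[[a]] + psi) / (n + 20 * psi)) / bg[[a]])
    }
  }
  out
}

oracle_confusion <- function(labels, calls, tool) {
  gold_levels <- sort(unique(labels$true_class))
  lookup <- list()
  for (i in seq_len(nrow(calls))) {
    if (calls$tool_id[i] == tool) {
      lookup[[calls$protein_id[i]]] <- calls$canonical[i]
    }
  }
  preds <- character(nrow(labels))
  for (i in seq_len(nrow(labels))) {
    p <- lookup[[labels$protein_id[i]]]
    preds[i] <- if (is.null(p)) "no-call" else p
  }
  pred_levels <- c(sort(unique(c(gold_levels,
                                 setdiff(preds, "no-call")))), "no-call")
  m <- matrix(0L, length(gold_levels), length(pred_levels),
              dimnames = list(gold = gold_levels, predicted = pred_levels))
  for (i in seq_len(nrow(labels))) {
    m[labels$true_class[i], preds[i]] <- m[labels$true_class[i], preds[i]] + 1L
  }
  m
}

# per-cell recount of the pathway-matrix status rules
oracle_cell_status <- function(rows) {
  found <- rows[rows$homolog_found, , drop = FALSE]
  if (nrow(found) == 0) return("absent")
  all_prok <- TRUE
  for (i in seq_len(nrow(found))) {
    if (found$best_hit_taxonomy[i] != "prokaryote") all_prok <- FALSE
  }
  if (all_prok) return("contaminant_only")
  found <- found[found$best_hit_taxonomy != "prokaryote", , drop = FALSE]
  best <- "absent"
  rank <- c(present_consistent = 1, present_unassigned = 2,
            present_truncated = 3, absent = 9)
  for (i in seq_len(nrow(found))) {
    cls <- found$consensus_class[i]
    rule <- found$consensus_rule[i]
    exp <- found$expected_compartment[i]
    st <- if (!is.na(cls) && cls != "unassigned") {
      if (is.na(exp) || cls == exp) "present_consistent"
      else "present_unassigned"
    } else if (!is.na(rule) && rule == "truncated") {
      "present_truncated"
    } else "present_unassigned"
    if (rank[[st]] < rank[[best]]) best <- st
  }
  best
}

random_records <- function(n, len_range = c(20L, 80L),
                           letters = AA20, start_met = TRUE) {
  seqs <- vapply(seq_len(n), function(i) {
    len <- sample(len_range[1]:len_range[2], 1)
    body <- paste(sample(letters, len, replace = TRUE), collapse = "")
    if (start_met) paste0("M", body) else body
  }, character(1))
  tibble::tibble(id = sprintf("r%04d", seq_len(n)),
                 description = "", sequence = seqs,
                 is_partial = !startsWith(seqs, "M"))
}

balanced_labels <- function(n_per_class,
                            classes = c("plastid", "mitochondrion",
                                        "secretory", "other")) {
  tibble::tibble(
    protein_id = sprintf("p%05d", seq_len(n_per_class * length(classes))),
    true_class = rep(classes, each = n_per_class)
  )
}

# consensus precision of a class when consensus output is scored as a tool
precision_of <- function(labels, pred_tbl, cls) {
  cm <- confusion_from_calls(labels, pred_tbl, unique(pred_tbl$tool_id))
  met <- compute_metrics(cm)
  met$precision[met$class == cls]
}
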