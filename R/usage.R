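#' Tally per-species CUG codons at labelled Leu/Ser positions
#'
#' For every species, counts its CUG codons (all rows, paralogs included)
#' that fall at columns labelled as Leu- or Ser-positions at each threshold.
#' A column carries at most one amino-acid label per threshold (the modal
#' residue is unique), so no codon is counted on both sides. Codons at
#' unlabelled columns contribute to the total only.
#'
#' @param sites A `cug_sites` table.
#' @param labels A `column_labels` table from [label_columns()].
#' @param species All species ids (so zero-CUG species appear).
#' @return Data frame of class `usage_tally`: `species_id`, `n_cug`, and
#'   `leu_count_<t>`, `leu_pct_<t>`, `ser_count_<t>`, `ser_pct_<t>` per
#'   threshold.
#' @export
tally_species <- function(sites, labels, species) {
  thresholds <- attr(labels, "thresholds")
  out <- cug_species_counts(sites, species)
  for (t in thresholds) {
    tt <- format(t)
    for (aa in c("leu", "ser")) {
      lab_cols <- labels$global_column[labels[[paste0(aa, "_", tt)]]]
      cnt <- vapply(species, function(sp) {
        sum(sites$species_id == sp & sites$global_column %in% lab_cols)
      }, 1L)
      out[[paste0(aa, "_count_", tt)]] <- unname(cnt)
      out[[paste0(aa, "_pct_", tt)]] <-
        ifelse(out$n_cug > 0, 100 * unname(cnt) / out$n_cug, 0)
    }
  }
  attr(out, "thresholds") <- thresholds
  class(out) <- c("usage_tally", "data.frame")
  out
}

#' Call the codon usage scheme per species
#'
#' Thresholds are evaluated from the most to the least stringent. At the
#' first threshold where the stronger side has at least `min_sites` CUG
#' codons, the species is called `standard` if its Leu-position count is at
#' least `margin` times its Ser-position count, `aycu` in the mirrored case,
#' and otherwise the next threshold is consulted. A species whose evidence
#' never separates is `ambiguous`; a species with no CUG codons at all is
#' `no_data`.
#'
#' @param tallies A `usage_tally` from [tally_species()].
#' @param min_sites Minimum codon count on the stronger side for a
#'   threshold to be decisive (default 1).
#' @param margin Required evidence ratio between the two sides (default 3).
#' @return Data frame of class `usage_calls`: the tally columns plus
#'   `call`, `decisive_threshold`, `evidence_ratio`.
#' @export
call_usage <- function(tallies, min_sites = 1L, margin = 3.0) {
  thresholds <- attr(tallies, "thresholds")
  n <- nrow(tallies)
  call <- rep("ambiguous", n)
  dec <- rep(NA_real_, n)
  ratio <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (tallies$n_cug[i] == 0L) {
      call[i] <- "no_data"
      next
    }
    for (t in thresholds) {
      tt <- format(t)
      leu <- tallies[[paste0("leu_count_", tt)]][i]
      ser <- tallies[[paste0("ser_count_", tt)]][i]
      if (max(leu, ser) < min_sites) next
      if (leu >= margin * ser) {
        call[i] <- "standard"
      } else if (ser >= margin * leu) {
        call[i] <- "aycu"
      } else {
        next
      }
      dec[i] <- t
      ratio[i] <- if (call[i] == "standard") {
        if (ser == 0) Inf else leu / ser
      } else {
        if (leu == 0) Inf else ser / leu
      }
      break
    }
  }
  out <- tallies
  out$call <- call
  out$decisive_threshold <- dec
  out$evidence_ratio <- ratio
  attr(out, "min_sites") <- min_sites
  attr(out, "margin") <- margin
  class(out) <- c("usage_calls", class(tallies))
  out
}

#' Pooled group statistics of CUG placement
#'
#' Groups species by their final call (`standard` vs `aycu`) and reports,
#' per threshold and amino acid, the pooled percentage
#' `100 * sum(counts) / sum(n_cug)` together with the per-species mean and
#' range of percentages (species with at least one CUG only). Groups with no
#' CUG codons report `NA`.
#'
#' @param calls A `usage_calls` table.
#' @return Data frame: `group`, `threshold`, `aa`, `n_species`,
#'   `total_cug`, `pooled_count`, `pooled_pct`, `mean_pct`, `min_pct`,
#'   `max_pct`.
#' @export
group_summary <- function(calls) {
  thresholds <- attr(calls, "thresholds")
  out <- list()
  for (grp in c("standard", "aycu")) {
    g <- calls[calls$call == grp & calls$n_cug > 0, , drop = FALSE]
    for (t in thresholds) {
      tt <- format(t)
      for (aa in c("leu", "ser")) {
        cnt <- g[[paste0(aa, "_count_", tt)]]
        pct <- g[[paste0(aa, "_pct_", tt)]]
        tot <- sum(g$n_cug)
        out[[length(out) + 1L]] <- data.frame(
          group = grp, threshold = t, aa = aa, n_species = nrow(g),
          total_cug = tot,
          pooled_count = sum(cnt),
          pooled_pct = if (tot > 0) 100 * sum(cnt) / tot else NA_real_,
          mean_pct = if (nrow(g)) mean(pct) else NA_real_,
          min_pct = if (nrow(g)) min(pct) else NA_real_,
          max_pct = if (nrow(g)) max(pct) else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
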