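#' Property-entropy conservation score of one alignment column
#'
#' Residues are grouped into chemical-property classes; the score is
#' \deqn{(1 - H/H_{max}) (1 - g)}
#' where `H` is the Shannon entropy (natural log) of the class distribution
#' among non-gap residues, `H_max = log(K)` for `K` classes, and `g` is the
#' fraction of gap-like symbols (`-` and `X`) in the column. A gap-free
#' column drawn from a single class scores exactly 1; a gap-free column
#' spread uniformly over all classes scores exactly 0. Gaps and unknown
#' residues are excluded from the distribution and penalise the score
#' multiplicatively -- they are never conflated with real residues.
#'
#' @param column Character vector of single residues (may contain `-`, `X`).
#' @param partition A [property_partition()].
#' @return Numeric score in `[0, 1]`.
#' @examples
#' property_entropy(rep("L", 10))             # 1
#' property_entropy(c("A", "F", "S", "K", "D", "G"))  # 0
#' @export
property_entropy <- function(column, partition = property_partition()) {
  s <- pe_score_matrix(matrix(column, ncol = 1), partition)
  if (is.na(s)) stop("property_entropy: column has no scorable residue (all gap/X)")
  s
}

# Vectorised scorer: one score per column of a character matrix
# (rows = sequences).  All-gap columns give NA rather than an error so that
# window smoothing can skip them.
pe_score_matrix <- function(mat, partition = property_partition()) {
  lookup <- attr(partition, "lookup")
  k <- length(partition)
  ncol_ <- ncol(mat)
  nrow_ <- nrow(mat)
  cls <- matrix(lookup[mat], nrow = nrow_, ncol = ncol_)
  gap_like <- is.na(cls)   # '-' and 'X' (and any non-standard symbol)
  out <- numeric(ncol_)
  for (j in seq_len(ncol_)) {
    cj <- cls[!gap_like[, j], j]
    n <- length(cj)
    if (n == 0L) {
      out[j] <- NA_real_
      next
    }
    p <- tabulate(cj, nbins = k) / n
    p <- p[p > 0]
    h <- -sum(p * log(p))
    out[j] <- (1 - h / log(k)) * (1 - sum(gap_like[, j]) / nrow_)
  }
  out
}

#' Window-smoothed conservation scores
#'
#' Each column's raw score is combined with the mean raw score of its
#' neighbours within distance `w` (the focal column excluded from the
#' neighbourhood mean):
#' `smoothed(c) = (1 - lambda) * raw(c) + lambda * mean(raw[neighbours])`.
#' Windows are truncated at the profile boundaries; `w = 0` returns the raw
#' scores unchanged. `NA` raw scores (unscorable all-gap columns) are
#' dropped from neighbourhood means and stay `NA` at their own position.
#'
#' @param raw Numeric vector of per-column raw scores.
#' @param w Non-negative integer window half-width.
#' @param lambda_weight Weight of the neighbourhood mean, in `[0, 1]`.
#' @return Numeric vector, same length as `raw`.
#' @export
window_score <- function(raw, w = 3L, lambda_weight = 0.5) {
  stopifnot(w >= 0, lambda_weight >= 0, lambda_weight <= 1)
  if (w == 0L || length(raw) == 1L) return(raw)
  n <- length(raw)
  out <- raw
  for (j in seq_len(n)) {
    nb <- max(1L, j - w):min(n, j + w)
    nb <- setdiff(nb, j)
    m <- mean(raw[nb], na.rm = TRUE)
    if (is.nan(m)) m <- raw[j]   # no scorable neighbour: fall back to raw
    out[j] <- (1 - lambda_weight) * raw[j] + lambda_weight * m
  }
  out
}

# Modal residue among non-gap entries of a character vector, with ties broken
# in favour of L, then S, then alphabetically.  Returns list(residue, fraction,
# n) or NULL when nothing is scorable.
modal_residue <- function(column) {
  keep <- !(column %in% c("-", "X"))
  col <- column[keep]
  if (length(col) == 0L) return(NULL)
  tab <- table(col)
  top <- names(tab)[tab == max(tab)]
  res <- if ("L" %in% top) "L" else if ("S" %in% top) "S" else sort(top)[1]
  list(residue = res, fraction = as.numeric(max(tab)) / length(col),
       n = length(col))
}

#' Focal-subalignment conservation score at one column
#'
#' Implements the focal protocol used for every leucine/serine position: the
#' alignment is cut down to the focal column plus `flank` columns on each
#' side (clipped to the column's family block, so windows never straddle the
#' artificial junction between concatenated families), rows that carry a CUG
#' codon at the focal column are removed, raw property-entropy scores are
#' computed on this subalignment only, window smoothing is applied inside it,
#' and the focal column's smoothed score is returned. Restricting scoring to
#' the subalignment guarantees locality: nothing outside the flank can move
#' the score.
#'
#' @param concat A `concat_alignment` (see [concatenate()]).
#' @param sites A CUG site table (see [extract_cug_sites()]); used to find
#'   the rows to drop at the focal column. May be an empty data frame.
#' @param column Global column index (1-based) in the concatenated alignment.
#' @param flank Columns kept on each side of the focal column.
#' @param w Window half-width for smoothing (0 = none).
#' @param lambda_weight Neighbourhood weight for [window_score()].
#' @param partition A [property_partition()].
#' @return List with `column`, `score`, `raw`, `modal_residue`,
#'   `modal_fraction`, `n_retained`, `gap_fraction`, `excluded_species`.
#' @export
focal_conservation <- function(concat, sites, column, flank = 15L, w = 3L,
                               lambda_weight = 0.5,
                               partition = property_partition()) {
  mat <- concat_matrix(concat)
  stopifnot(column >= 1L, column <= ncol(mat))
  blk <- concat$blocks
  b <- which(blk$start <= column & column <= blk$end)
  lo <- max(blk$start[b], column - flank)
  hi <- min(blk$end[b], column + flank)
  excl <- character(0)
  if (nrow(sites) > 0L) {
    here <- sites[sites$global_column == column, , drop = FALSE]
    # only rows present in the concatenated alignment can be removed from it
    excl <- unique(here$species_id[here$row_id %in% concat$chosen$row_id])
  }
  keep <- !(rownames(mat) %in% excl)
  sub <- mat[keep, lo:hi, drop = FALSE]
  focal_j <- column - lo + 1L
  mr <- modal_residue(sub[, focal_j])
  if (is.null(mr)) {
    stop("focal_conservation: all retained rows are gapped at column ", column)
  }
  raw <- pe_score_matrix(sub, partition)
  sm <- window_score(raw, w = w, lambda_weight = lambda_weight)
  list(column = column,
       score = sm[focal_j],
       raw = raw[focal_j],
       modal_residue = mr$residue,
       modal_fraction = mr$fraction,
       n_retained = sum(keep),
       gap_fraction = mean(sub[, focal_j] %in% c("-", "X")),
       excluded_species = excl)
}

#' Conservation profile over all leucine/serine columns
#'
#' Applies [focal_conservation()] at every global column where at least one
#' retained row (i.e. a row without a CUG at that column) carries an L or an
#' S, at both window settings (`w = 0` and `w = 3`). Columns with no
#' leucine and no serine are not scored -- they can never be called a Leu or
#' Ser position.
#'
#' @inheritParams focal_conservation
#' @return Data frame of class `conservation_profile`: one row per scored
#'   column with `global_column`, `family_id`, `local_column`, `n_retained`,
#'   `gap_fraction`, `score_w0`, `score_w3`, `modal_residue`,
#'   `modal_fraction`, `has_leu`, `has_ser`.
#' @export
conservation_profile <- function(concat, sites, flank = 15L,
                                 lambda_weight = 0.5,
                                 partition = property_partition()) {
  mat <- concat_matrix(concat)
  blk <- concat$blocks
  # which rows are removed at which column (chosen rows only)
  excl_by_col <- list()
  if (nrow(sites) > 0L) {
    s <- sites[sites$row_id %in% concat$chosen$row_id, , drop = FALSE]
    excl_by_col <- split(s$species_id, s$global_column)
  }
  rows <- vector("list", ncol(mat))
  for (column in seq_len(ncol(mat))) {
    colchars <- mat[, column]
    excl <- unique(excl_by_col[[as.character(column)]])
    keep <- !(rownames(mat) %in% excl)
    retained <- colchars[keep]
    if (!any(retained == "L") && !any(retained == "S")) next
    if (all(retained %in% c("-", "X"))) next
    b <- which(blk$start <= column & column <= blk$end)
    lo <- max(blk$start[b], column - flank)
    hi <- min(blk$end[b], column + flank)
    sub <- mat[keep, lo:hi, drop = FALSE]
    focal_j <- column - lo + 1L
    raw <- pe_score_matrix(sub, partition)
    sm3 <- window_score(raw, w = 3L, lambda_weight = lambda_weight)
    mr <- modal_residue(sub[, focal_j])
    rows[[column]] <- data.frame(
      global_column = column,
      family_id = blk$family_id[b],
      local_column = column - blk$start[b] + 1L,
      n_retained = nrow(sub),
      gap_fraction = mean(sub[, focal_j] %in% c("-", "X")),
      score_w0 = raw[focal_j],
      score_w3 = sm3[focal_j],
      modal_residue = mr$residue,
      modal_fraction = mr$fraction,
      has_leu = any(retained == "L"),
      has_ser = any(retained == "S"),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) {
    out <- data.frame(global_column = integer(0), family_id = character(0),
                      local_column = integer(0), n_retained = integer(0),
                      gap_fraction = numeric(0), score_w0 = numeric(0),
                      score_w3 = numeric(0), modal_residue = character(0),
                      modal_fraction = numeric(0), has_leu = logical(0),
                      has_ser = logical(0))
  }
  class(out) <- c("conservation_profile", "data.frame")
  out
}

#' Label conserved leucine/serine positions at a set of thresholds
#'
#' A column is a Leu-position (Ser-position) at level `t` iff its
#' conservation score is at least `t` and its modal residue among retained,
#' non-gap rows is L (S). Labels are nested across thresholds by
#' construction.
#'
#' @param profile A [conservation_profile()].
#' @param thresholds Numeric vector, evaluated as given (default
#'   `c(0.9, 0.8, 0.5)`).
#' @param which_score `"w3"` (default) or `"w0"`.
#' @return Data frame `column_labels`: `global_column`, `modal_residue`,
#'   `score`, and one logical column `leu_<t>` / `ser_<t>` per threshold.
#' @export
label_columns <- function(profile, thresholds = c(0.9, 0.8, 0.5),
                          which_score = c("w3", "w0")) {
  which_score <- match.arg(which_score)
  sc <- if (which_score == "w3") profile$score_w3 else profile$score_w0
  out <- data.frame(global_column = profile$global_column,
                    modal_residue = profile$modal_residue,
                    score = sc, stringsAsFactors = FALSE)
  for (t in thresholds) {
    out[[paste0("leu_", format(t))]] <- sc >= t & profile$modal_residue == "L"
    out[[paste0("ser_", format(t))]] <- sc >= t & profile$modal_residue == "S"
  }
  attr(out, "thresholds") <- thresholds
  attr(out, "which_score") <- which_score
  class(out) <- c("column_labels", "data.frame")
  out
}
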