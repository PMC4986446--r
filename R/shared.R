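#' Pairwise shared-CUG-position matrix
#'
#' Counts, for every species pair, the alignment columns at which both
#' species carry at least one CUG codon (positions, not codons: two
#' paralogs with CUG at the same column count once). The diagonal holds
#' each species' number of distinct CUG columns. In `"conserved_50"` mode
#' only columns whose focal conservation score is at least 0.5 are
#' considered; columns that could not be scored (no leucine or serine among
#' retained rows) never qualify.
#'
#' @param sites A `cug_sites` table.
#' @param species Species order for the matrix.
#' @param profile A `conservation_profile` (required for `conserved_50`).
#' @param mode `"all_columns"` or `"conserved_50"`.
#' @param which_score `"w3"` (default) or `"w0"` score for the 0.5 cut.
#' @return Symmetric integer matrix with `mode` attribute.
#' @export
shared_matrix <- function(sites, species, profile = NULL,
                          mode = c("all_columns", "conserved_50"),
                          which_score = c("w3", "w0")) {
  mode <- match.arg(mode)
  which_score <- match.arg(which_score)
  s <- sites
  if (mode == "conserved_50") {
    stopifnot(!is.null(profile))
    sc <- if (which_score == "w3") profile$score_w3 else profile$score_w0
    ok_cols <- profile$global_column[!is.na(sc) & sc >= 0.5]
    s <- s[s$global_column %in% ok_cols, , drop = FALSE]
  }
  colsets <- lapply(species, function(sp) {
    unique(s$global_column[s$species_id == sp])
  })
  names(colsets) <- species
  n <- length(species)
  m <- matrix(0L, n, n, dimnames = list(species, species))
  for (i in seq_len(n)) {
    m[i, i] <- length(colsets[[i]])
    if (i < n) {
      for (j in (i + 1L):n) {
        v <- length(intersect(colsets[[i]], colsets[[j]]))
        m[i, j] <- v
        m[j, i] <- v
      }
    }
  }
  attr(m, "mode") <- mode
  m
}

#' Combine the two shared-CUG matrices into one table / heatmap
#'
#' Upper triangle: shared positions restricted to >=50%-conserved columns;
#' lower triangle: shared positions over all columns; diagonal: per-species
#' distinct CUG columns (all-columns mode). Optionally renders a heatmap on
#' a `log10(1 + x)` colour scale (so zeros are admissible).
#'
#' @param m_all Matrix from [shared_matrix()] in `all_columns` mode.
#' @param m_cons Matrix in `conserved_50` mode, same species order.
#' @param png_path Optional path; if given, a PNG heatmap is written.
#' @return The combined matrix (invisible if plotted).
#' @export
combine_shared <- function(m_all, m_cons, png_path = NULL) {
  if (!identical(rownames(m_all), rownames(m_cons))) {
    stop("consistency error: species order differs between the two matrices")
  }
  comb <- m_all
  comb[upper.tri(comb)] <- m_cons[upper.tri(m_cons)]
  diag(comb) <- diag(m_all)
  if (!is.null(png_path)) {
    n <- nrow(comb)
    grDevices::png(png_path, width = 200 + 28 * n, height = 200 + 28 * n)
    op <- graphics::par(mar = c(8, 8, 2, 2))
    z <- log10(1 + comb[, rev(seq_len(n)), drop = FALSE])
    graphics::image(seq_len(n), seq_len(n), z,
                    col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                    axes = FALSE, xlab = "", ylab = "")
    graphics::axis(1, at = seq_len(n), labels = rownames(comb), las = 2,
                   cex.axis = 0.8)
    graphics::axis(2, at = seq_len(n), labels = rev(colnames(comb)), las = 2,
                   cex.axis = 0.8)
    graphics::box()
    graphics::par(op)
    grDevices::dev.off()
    return(invisible(comb))
  }
  comb
}
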