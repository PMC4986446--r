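#' Split a family alignment into single-subfamily alignments
#'
#' Family alignments keep homologous subfamilies (e.g. the three tubulins)
#' together; for concatenation each subfamily becomes its own alignment so
#' that one species contributes at most one ortholog per block.
#'
#' @param family An `aligned_family` whose rows carry a `subfamily` label.
#' @return Named list of `aligned_family` objects, one per subfamily.
#' @export
split_subfamilies <- function(family) {
  subs <- split(family$rows, family$rows$subfamily)
  out <- lapply(names(subs), function(sf) {
    aligned_family(sf, subs[[sf]], max_paralogs = .Machine$integer.max)
  })
  names(out) <- names(subs)
  out
}

#' Concatenate subfamily alignments into one supermatrix
#'
#' One sequence per species; species missing a family contribute an all-gap
#' segment for that block. When a species has several rows (paralogs) in one
#' family, `ortholog_policy` decides: `"longest"` (default) keeps the row
#' with the most non-gap residues (ties broken by row id), `"first"` keeps
#' the first row, `"strict"` raises a paralog error.
#'
#' @param families List of `aligned_family` objects (already split into
#'   subfamilies).
#' @param ortholog_policy `"longest"`, `"first"` or `"strict"`.
#' @return Object of class `concat_alignment`: `species` (order), `seqs`
#'   (named character vector), `blocks` (data frame `family_id`, `start`,
#'   `end`, 1-based inclusive), `chosen` (data frame `family_id`,
#'   `species_id`, `row_id` recording which paralog entered each block),
#'   `total_columns`.
#' @export
concatenate <- function(families,
                        ortholog_policy = c("longest", "first", "strict")) {
  ortholog_policy <- match.arg(ortholog_policy)
  stopifnot(length(families) > 0L)
  species <- sort(unique(unlist(lapply(families,
                                       function(f) f$rows$species_id))))
  pieces <- matrix("", nrow = length(species), ncol = length(families),
                   dimnames = list(species, NULL))
  blocks <- data.frame(family_id = vapply(families, `[[`, "", "family_id"),
                       start = integer(length(families)),
                       end = integer(length(families)),
                       stringsAsFactors = FALSE)
  chosen <- list()
  at <- 1L
  for (k in seq_along(families)) {
    fam <- families[[k]]
    blocks$start[k] <- at
    blocks$end[k] <- at + fam$n_columns - 1L
    at <- at + fam$n_columns
    gaprow <- strrep("-", fam$n_columns)
    for (sp in species) {
      rows <- fam$rows[fam$rows$species_id == sp, , drop = FALSE]
      if (nrow(rows) == 0L) {
        pieces[sp, k] <- gaprow
        next
      }
      if (nrow(rows) > 1L) {
        if (ortholog_policy == "strict") {
          stop("paralog error: species '", sp, "' has ", nrow(rows),
               " rows in family '", fam$family_id, "'")
        }
        if (ortholog_policy == "longest") {
          nongap <- nchar(gsub("-", "", rows$seq, fixed = TRUE))
          rows <- rows[order(-nongap, rows$row_id), , drop = FALSE]
          message("concatenate: family '", fam$family_id, "', species '", sp,
                  "': kept longest of ", nrow(rows), " paralogs (",
                  rows$row_id[1], ")")
        } else {
          message("concatenate: family '", fam$family_id, "', species '", sp,
                  "': kept first of ", nrow(rows), " paralogs (",
                  rows$row_id[1], ")")
        }
      }
      pieces[sp, k] <- rows$seq[1]
      chosen[[length(chosen) + 1L]] <-
        data.frame(family_id = fam$family_id, species_id = sp,
                   row_id = rows$row_id[1], stringsAsFactors = FALSE)
    }
  }
  seqs <- apply(pieces, 1L, paste0, collapse = "")
  structure(list(species = species, seqs = seqs, blocks = blocks,
                 chosen = do.call(rbind, chosen),
                 total_columns = at - 1L),
            class = "concat_alignment")
}

#' Species-by-column character matrix view of a concatenated alignment
#'
#' @param concat A `concat_alignment`.
#' @return Character matrix, rows named by species.
#' @export
concat_matrix <- function(concat) {
  m <- do.call(rbind, strsplit(concat$seqs[concat$species], ""))
  rownames(m) <- concat$species
  m
}

#' @export
print.concat_alignment <- function(x, ...) {
  cat("concat_alignment: ", length(x$species), " species x ",
      x$total_columns, " columns in ", nrow(x$blocks), " blocks\n", sep = "")
  invisible(x)
}

#' Extract every CUG site from a set of mapped families
#'
#' One record per CTG codon in any row -- paralogs are all inspected, not
#' just the row chosen for the concatenated alignment. Global columns are
#' assigned via the concatenation block table
#' (`global = block start + local - 1`).
#'
#' @param families List of `aligned_family` objects, in the order used for
#'   [concatenate()].
#' @param maps Named list of `codon_map` objects (names = row ids), e.g.
#'   from [map_family_codons()].
#' @param concat The matching `concat_alignment`.
#' @return Data frame of class `cug_sites`: `species_id`, `row_id`,
#'   `family_id`, `global_column`, `local_column`.
#' @export
extract_cug_sites <- function(families, maps, concat) {
  out <- list()
  for (fam in families) {
    b <- match(fam$family_id, concat$blocks$family_id)
    if (is.na(b)) stop("extract_cug_sites: family '", fam$family_id,
                       "' not in concatenation block table")
    start <- concat$blocks$start[b]
    for (i in seq_len(nrow(fam$rows))) {
      rid <- fam$rows$row_id[i]
      m <- maps[[rid]]
      if (is.null(m)) next
      e <- m$entries[m$entries$codon == "CTG", , drop = FALSE]
      if (nrow(e) == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        species_id = fam$rows$species_id[i], row_id = rid,
        family_id = fam$family_id,
        global_column = start + e$column - 1L,
        local_column = e$column, stringsAsFactors = FALSE)
    }
  }
  sites <- if (length(out)) do.call(rbind, out) else
    data.frame(species_id = character(0), row_id = character(0),
               family_id = character(0), global_column = integer(0),
               local_column = integer(0), stringsAsFactors = FALSE)
  rownames(sites) <- NULL
  class(sites) <- c("cug_sites", "data.frame")
  sites
}

#' Per-species CUG counts, including zero-CUG species
#'
#' @param sites A `cug_sites` table.
#' @param species Character vector of all species (zero-CUG species appear
#'   with count 0).
#' @return Data frame `species_id`, `n_cug`.
#' @export
cug_species_counts <- function(sites, species) {
  n <- vapply(species, function(sp) sum(sites$species_id == sp), 1L)
  data.frame(species_id = species, n_cug = unname(n),
             stringsAsFactors = FALSE)
}

#' Mask CUG-encoded residues with 'X'
#'
#' Replaces the residue at every (species, CUG column) cell of the
#' concatenated alignment by `X`, producing the codon-usage-agnostic
#' alignment used for unbiased tree inference. Only sites from the rows that
#' entered the concatenation are applicable (a paralog that was not chosen
#' has no cells in the supermatrix); sites from other rows are ignored. A
#' site pointing at a gap cell is a consistency error.
#'
#' @param concat A `concat_alignment`.
#' @param sites A `cug_sites` table.
#' @return A new `concat_alignment`, identical except for the masked cells.
#' @export
mask_cug <- function(concat, sites) {
  mat <- concat_matrix(concat)
  s <- sites[sites$row_id %in% concat$chosen$row_id, , drop = FALSE]
  s <- unique(s[, c("species_id", "global_column")])
  for (i in seq_len(nrow(s))) {
    cell <- mat[s$species_id[i], s$global_column[i]]
    if (cell == "-") {
      stop("consistency error: CUG site of '", s$species_id[i],
           "' at column ", s$global_column[i], " points at a gap cell")
    }
    mat[s$species_id[i], s$global_column[i]] <- "X"
  }
  out <- concat
  out$seqs <- apply(mat, 1L, paste0, collapse = "")
  out
}
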