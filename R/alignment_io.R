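#' Construct a protein family alignment object
#'
#' @param family_id Short family label (e.g. `"myosin-I"`).
#' @param rows Data frame with columns `row_id`, `species_id`, `seq`
#'   (aligned residue strings over the 20 amino acids, `-` and `X`) and
#'   optionally `subfamily` (defaults to `family_id`) and `has_cds`.
#' @param max_paralogs Maximum rows per species allowed in one family.
#' @return An object of class `aligned_family` with elements `family_id`,
#'   `rows`, `n_columns`.
#' @export
aligned_family <- function(family_id, rows, max_paralogs = 2L) {
  stopifnot(is.data.frame(rows),
            all(c("row_id", "species_id", "seq") %in% names(rows)))
  if (anyDuplicated(rows$row_id)) {
    stop("aligned_family '", family_id, "': duplicate row_id")
  }
  widths <- nchar(rows$seq)
  if (length(unique(widths)) > 1L) {
    stop("aligned_family '", family_id,
         "': rows have unequal aligned lengths (",
         paste(unique(widths), collapse = ", "), ")")
  }
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX-]", rows$seq)
  if (any(bad)) {
    stop("aligned_family '", family_id, "': illegal residue symbol in row ",
         rows$row_id[which(bad)[1]])
  }
  if (!"subfamily" %in% names(rows)) rows$subfamily <- family_id
  if (!"has_cds" %in% names(rows)) rows$has_cds <- TRUE
  per_sp <- table(paste(rows$species_id, rows$subfamily))
  if (any(per_sp > max_paralogs)) {
    stop("aligned_family '", family_id, "': species exceeds paralog allowance (",
         max_paralogs, "): ", names(per_sp)[which.max(per_sp)])
  }
  structure(list(family_id = family_id, rows = rows,
                 n_columns = if (nrow(rows)) widths[1] else 0L),
            class = "aligned_family")
}

#' @export
print.aligned_family <- function(x, ...) {
  cat("aligned_family '", x$family_id, "': ", nrow(x$rows), " rows x ",
      x$n_columns, " columns, ", length(unique(x$rows$species_id)),
      " species\n", sep = "")
  invisible(x)
}

# Parse "species<delim>protein" FASTA headers -> data.frame(row_id, species_id)
parse_headers <- function(headers, delimiter = "|") {
  pos <- regexpr(delimiter, headers, fixed = TRUE)
  if (any(pos < 0)) {
    stop("metadata error: header without '", delimiter, "' delimiter: ",
         headers[which(pos < 0)[1]])
  }
  data.frame(row_id = headers,
             species_id = substr(headers, 1L, pos - 1L),
             stringsAsFactors = FALSE)
}

#' Read a family alignment and its coding sequences
#'
#' Reads a protein multiple sequence alignment and the matching spliced CDS
#' from FASTA. Headers are `species<delimiter>protein`; the full header is
#' the row id and the part before the delimiter the species id. Aligned rows
#' without a CDS record are kept and flagged (`has_cds = FALSE`): they carry
#' no CUG evidence but still contribute to conservation. CDS records that
#' match no aligned row are dropped with a warning.
#'
#' @param alignment_path FASTA file of aligned protein sequences.
#' @param cds_path FASTA file of spliced coding sequences, or `NULL`.
#' @param family_id Family label.
#' @param delimiter Header delimiter between species and protein name.
#' @param max_paralogs Passed to [aligned_family()].
#' @return List with `family` (an `aligned_family`) and `cds` (data frame
#'   `row_id`, `cds`).
#' @export
read_family <- function(alignment_path, cds_path = NULL, family_id,
                        delimiter = "|", max_paralogs = 2L) {
  aln <- Biostrings::readBStringSet(alignment_path)
  seqs <- toupper(as.character(aln))
  meta <- parse_headers(names(aln), delimiter)
  widths <- nchar(seqs)
  if (length(unique(widths)) > 1L) {
    stop("alignment-format error in ", alignment_path,
         ": rows have unequal lengths")
  }
  rows <- data.frame(row_id = meta$row_id, species_id = meta$species_id,
                     seq = unname(seqs), stringsAsFactors = FALSE)
  cds <- data.frame(row_id = character(0), cds = character(0),
                    stringsAsFactors = FALSE)
  if (!is.null(cds_path)) {
    cset <- Biostrings::readBStringSet(cds_path)
    cds <- data.frame(row_id = names(cset),
                      cds = toupper(as.character(cset)),
                      stringsAsFactors = FALSE)
    orphan <- !(cds$row_id %in% rows$row_id)
    if (any(orphan)) {
      warning(sum(orphan), " CDS record(s) in ", cds_path,
              " match no aligned row; dropped")
      cds <- cds[!orphan, , drop = FALSE]
    }
  }
  rows$has_cds <- rows$row_id %in% cds$row_id
  list(family = aligned_family(family_id, rows, max_paralogs = max_paralogs),
       cds = cds)
}

#' Write an alignment or sequence set as FASTA (wrapped at 60 columns)
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Write a concatenated alignment as relaxed PHYLIP
#'
#' Header line `ntaxa ncolumns`, then one `name<TAB>sequence` line per
#' species (relaxed: names are not truncated to 10 characters).
#'
#' @param concat A `concat_alignment`.
#' @param path Output path.
#' @export
write_phylip <- function(concat, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(length(concat$species), concat$total_columns), con)
  writeLines(paste(concat$species, concat$seqs[concat$species], sep = "\t"),
             con)
  invisible(path)
}
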