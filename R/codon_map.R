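# Translation tables.  The standard code comes from Biostrings; the
# alternative yeast codon usage (AYCU) differs only at CTG (serine, not
# leucine).
genetic_code_table <- function(code = c("standard", "aycu")) {
  code <- match.arg(code)
  gc <- Biostrings::GENETIC_CODE
  if (code == "aycu") gc[["CTG"]] <- "S"
  gc
}

translate_codon <- function(codon, table) {
  if (grepl("N", codon, fixed = TRUE)) return("X")
  unname(table[[codon]])
}

#' Map codons of a coding sequence onto alignment columns
#'
#' Walks the spliced CDS and the aligned (gapped) protein row in lockstep:
#' every ungapped residue receives exactly one codon and the alignment
#' column it occupies. A single trailing stop codon is trimmed; internal
#' stops are a frame error. Under the default `"wildcard"` setting a CTG
#' codon is allowed to sit under any residue, so the mapping never presumes
#' a CUG translation -- downstream usage calls are therefore independent of
#' any provisional code. `"standard"` / `"aycu"` instead validate CTG as
#' leucine / serine. The coordinates produced are identical under all three
#' settings whenever the mapping exists; the setting only changes
#' validation. Codons containing `N` must sit under an `X` residue and are
#' never CUG sites.
#'
#' @param family An `aligned_family`.
#' @param row_id Row to map.
#' @param cds The coding sequence (string over A,C,G,T,N) for that row.
#' @param genetic_code `"wildcard"` (default), `"standard"` or `"aycu"`.
#' @return Object of class `codon_map`: list with `row_id` and `entries`, a
#'   data frame (`codon_index`, `codon`, `column`), 1-based.
#' @export
map_codons <- function(family, row_id, cds,
                       genetic_code = c("wildcard", "standard", "aycu")) {
  genetic_code <- match.arg(genetic_code)
  i <- match(row_id, family$rows$row_id)
  if (is.na(i)) stop("map_codons: row '", row_id, "' not in family")
  aligned <- strsplit(family$rows$seq[i], "")[[1]]
  if (nchar(cds) %% 3L != 0L) {
    stop("frame error: CDS length for '", row_id, "' not divisible by 3")
  }
  codons <- substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
  std <- genetic_code_table("standard")
  aa <- vapply(codons, translate_codon, "", table = std)
  n <- length(codons)
  if (n > 0L && aa[n] == "*") {   # trailing stop
    codons <- codons[-n]
    aa <- aa[-n]
  }
  if (any(aa == "*")) {
    stop("frame error: internal stop codon at codon ", which(aa == "*")[1],
         " of '", row_id, "'")
  }
  cols <- which(aligned != "-")
  if (length(cols) != length(codons)) {
    stop("mapping error: '", row_id, "' has ", length(cols),
         " aligned residues but ", length(codons), " codons")
  }
  if (genetic_code != "standard") {
    tab <- genetic_code_table(if (genetic_code == "aycu") "aycu" else "standard")
    aa_check <- vapply(codons, translate_codon, "", table = tab)
  } else {
    aa_check <- aa
  }
  res <- aligned[cols]
  ok <- res == aa_check | res == "X" |
    (genetic_code == "wildcard" & codons == "CTG")
  ok[aa_check == "X" & res != "X"] <- FALSE   # N-codon must map to 'X'
  if (!all(ok)) {
    j <- which(!ok)[1]
    stop("mapping error in '", row_id, "': codon ", j, " (", codons[j],
         " -> ", aa_check[j], ") does not match aligned residue '", res[j],
         "' at column ", cols[j])
  }
  structure(list(row_id = row_id,
                 entries = data.frame(codon_index = seq_along(codons),
                                      codon = unname(codons),
                                      column = cols,
                                      stringsAsFactors = FALSE)),
            class = "codon_map")
}

#' Map every row of a family that has a coding sequence
#'
#' @param fam_data A list as returned by [read_family()] (elements `family`
#'   and `cds`), or a list with those names from the simulator.
#' @inheritParams map_codons
#' @return Named list of `codon_map` objects (one per row with a CDS).
#' @export
map_family_codons <- function(fam_data,
                              genetic_code = c("wildcard", "standard", "aycu")) {
  genetic_code <- match.arg(genetic_code)
  cds <- fam_data$cds
  maps <- lapply(seq_len(nrow(cds)), function(i) {
    map_codons(fam_data$family, cds$row_id[i], cds$cds[i],
               genetic_code = genetic_code)
  })
  names(maps) <- cds$row_id
  maps
}
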