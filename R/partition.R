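#' Amino-acid property partition
#'
#' The conservation score groups the 20 standard residues into disjoint
#' chemical-property classes and measures the entropy of a column over those
#' classes. The default partition has six classes --
#' aliphatic/small-hydrophobic \{A,V,L,I,M,C\}, aromatic \{F,W,Y,H\},
#' polar-uncharged \{S,T,N,Q\}, basic \{K,R\}, acidic \{D,E\} and
#' conformationally special \{G,P\} -- chosen so that leucine and serine fall
#' in different classes, which is what makes the score discriminate the two
#' candidate CUG translations.
#'
#' @param classes Named list of character vectors of single-letter residue
#'   codes. Must cover the 20 standard residues exactly once.
#' @return An object of class `property_partition`: the validated list, with
#'   a `lookup` attribute mapping residue -> class index.
#' @examples
#' pp <- property_partition()
#' attr(pp, "lookup")[["L"]] != attr(pp, "lookup")[["S"]]
#' @export
property_partition <- function(classes = list(
                                 aliphatic = c("A", "V", "L", "I", "M", "C"),
                                 aromatic  = c("F", "W", "Y", "H"),
                                 polar     = c("S", "T", "N", "Q"),
                                 basic     = c("K", "R"),
                                 acidic    = c("D", "E"),
                                 special   = c("G", "P"))) {
  stopifnot(is.list(classes), length(classes) >= 2)
  res <- unlist(classes, use.names = FALSE)
  if (anyDuplicated(res)) {
    stop("property partition: residue assigned to more than one class")
  }
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (!setequal(res, aa20)) {
    stop("property partition: classes must cover the 20 standard residues exactly")
  }
  lookup <- integer(0)
  for (i in seq_along(classes)) {
    lookup[classes[[i]]] <- i
  }
  structure(classes, lookup = lookup, class = "property_partition")
}

#' Read a property partition from a plain-text file
#'
#' One class per line: `class_name: RESIDUES` (e.g. `basic: KR`).
#'
#' @param path File path.
#' @return A [property_partition()].
#' @export
read_property_partition <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, ":", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad)) stop("partition file: each line must be 'name: RESIDUES'")
  nm <- vapply(parts, function(p) trimws(p[[1]]), "")
  cls <- lapply(parts, function(p) strsplit(gsub("\\s", "", p[[2]]), "")[[1]])
  names(cls) <- nm
  property_partition(cls)
}
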