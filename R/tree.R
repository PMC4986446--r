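#' Annotate a species tree with usage calls and CUG counts
#'
#' Decorates every matched tip label of a newick tree with the species'
#' codon-usage call and total CUG count, as
#' `label|call|n_cug`. Topology and branch lengths are untouched; tips
#' without a call are left undecorated and listed in a warning. Branch
#' rendering (width/colour by count) is left to downstream viewers -- the
#' counts travel with the tips.
#'
#' @param tree A `phylo` object or path to a newick file.
#' @param calls A `usage_calls` table.
#' @param tip_map Optional named character vector mapping tip label ->
#'   species id (for trees whose labels are not species ids).
#' @param out_path Optional path to write the annotated newick.
#' @return List with `tree` (annotated `phylo`), `table` (tip, species,
#'   call, n_cug), `unmatched` (character vector).
#' @export
annotate_tree <- function(tree, calls, tip_map = NULL, out_path = NULL) {
  if (is.character(tree)) tree <- ape::read.tree(tree)
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label)) {
    stop("tree error: duplicate tip labels")
  }
  tips <- tree$tip.label
  species <- if (is.null(tip_map)) tips else {
    ifelse(tips %in% names(tip_map), tip_map[tips], tips)
  }
  i <- match(species, calls$species_id)
  matched <- !is.na(i)
  if (any(!matched)) {
    warning("annotate_tree: ", sum(!matched),
            " tip(s) without a usage call: ",
            paste(tips[!matched], collapse = ", "))
  }
  lab <- tips
  lab[matched] <- paste(tips[matched], calls$call[i[matched]],
                        calls$n_cug[i[matched]], sep = "|")
  out <- tree
  out$tip.label <- lab
  tab <- data.frame(tip = tips, species_id = species,
                    call = ifelse(matched, calls$call[i], NA_character_),
                    n_cug = ifelse(matched, calls$n_cug[i], NA_integer_),
                    stringsAsFactors = FALSE)
  if (!is.null(out_path)) ape::write.tree(out, out_path)
  list(tree = out, table = tab, unmatched = tips[!matched])
}

#' Strip tip annotations added by [annotate_tree()]
#'
#' @param tree Annotated `phylo` object.
#' @return The tree with original tip labels.
#' @export
strip_tree_annotations <- function(tree) {
  tree$tip.label <- sub("\\|.*$", "", tree$tip.label)
  tree
}
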