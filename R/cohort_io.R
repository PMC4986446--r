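#' Write a simulated cohort in the formats the pipeline reads
#'
#' One `<family>_aln.fasta` / `<family>_cds.fasta` pair per family, the
#' truth tables as tab-separated files, and the configuration as a plain
#' `key = value` file.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (fd in cohort$families) {
    fid <- fd$family$family_id
    aln <- fd$family$rows$seq
    names(aln) <- fd$family$rows$row_id
    write_fasta(aln, file.path(dir, paste0(fid, "_aln.fasta")))
    cds <- fd$cds$cds
    names(cds) <- fd$cds$row_id
    write_fasta(cds, file.path(dir, paste0(fid, "_cds.fasta")))
  }
  if (!is.null(cohort$truth)) {
    write_tsv(cohort$truth$species, file.path(dir, "truth_species.tsv"))
    write_tsv(cohort$truth$sites, file.path(dir, "truth_sites.tsv"))
  }
  if (!is.null(cohort$config)) {
    cfg <- cohort$config
    lines <- vapply(names(cfg), function(k) {
      paste0(k, " = ", paste(cfg[[k]], collapse = ","))
    }, "")
    writeLines(lines, file.path(dir, "sim_config.txt"))
  }
  invisible(dir)
}

#' Read every family alignment/CDS pair from a directory
#'
#' Scans `dir` for `<family>_aln.fasta` files and pairs each with its
#' `<family>_cds.fasta` (if present).
#'
#' @param dir Input directory.
#' @param delimiter FASTA header delimiter, see [read_family()].
#' @return List of `list(family, cds)` pairs, ready for [run_pipeline()].
#' @export
read_family_dir <- function(dir, delimiter = "|") {
  aln_files <- sort(list.files(dir, pattern = "_aln\\.fasta$",
                               full.names = TRUE))
  if (length(aln_files) == 0L) {
    stop("input error: no '*_aln.fasta' files in ", dir)
  }
  lapply(aln_files, function(af) {
    fid <- sub("_aln\\.fasta$", "", basename(af))
    cf <- file.path(dir, paste0(fid, "_cds.fasta"))
    read_family(af, if (file.exists(cf)) cf else NULL, family_id = fid,
                delimiter = delimiter)
  })
}
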