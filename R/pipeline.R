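#' Pipeline run configuration
#'
#' Collects the free parameters of the analysis: the labelling thresholds
#' (most to least stringent), the focal flank width, the smoothing window
#' and its weight, the property partition, and the usage-call rule.
#'
#' @param thresholds Conservation thresholds, strictly decreasing.
#' @param flank Focal subalignment half-width in columns.
#' @param window Window half-width for score smoothing (0 disables).
#' @param lambda_weight Neighbourhood weight in [window_score()].
#' @param which_score Score used for labelling and the conserved-50 matrix.
#' @param partition A [property_partition()].
#' @param min_sites,margin Usage-call rule, see [call_usage()].
#' @param ortholog_policy Paralog resolution for [concatenate()].
#' @param delimiter FASTA header delimiter.
#' @return List of class `run_config`.
#' @export
run_config <- function(thresholds = c(0.9, 0.8, 0.5), flank = 15L,
                       window = 3L, lambda_weight = 0.5,
                       which_score = c("w3", "w0"),
                       partition = property_partition(),
                       min_sites = 1L, margin = 3.0,
                       ortholog_policy = "longest", delimiter = "|") {
  which_score <- match.arg(which_score)
  if (any(diff(thresholds) >= 0)) {
    stop("run_config: thresholds must be strictly decreasing")
  }
  if (flank < 1L) stop("run_config: flank must be >= 1")
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

# tab-separated writer with a reproducible comment header (no timestamps,
# so reruns are byte-identical)
write_tsv <- function(df, path, config_note = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  ver <- as.character(utils::packageVersion("cugusage"))
  writeLines(paste0("# cugusage ", ver,
                    if (!is.null(config_note)) paste0("; ", config_note)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full assignment pipeline on a set of families
#'
#' Executes map -> concatenate -> extract CUG sites -> focal conservation ->
#' label -> tally -> call -> group summary -> shared matrices -> mask, and
#' (optionally) writes every stage table under `out_dir`. All randomness in
#' the package lives in the simulator; given fixed inputs the bundle is
#' deterministic and reruns produce byte-identical files.
#'
#' @param families List of `list(family, cds)` pairs, e.g.
#'   `simulate_cohort()$families` or repeated [read_family()] results.
#' @param config A [run_config()].
#' @param out_dir Output directory (created), or `NULL` to skip writing.
#' @param write_png Also render the shared-matrix heatmap as PNG.
#' @return Report bundle: list with `concat`, `sites`, `species_counts`,
#'   `profile`, `labels`, `tallies`, `calls`, `groups`, `shared_all`,
#'   `shared_cons`, `shared_combined`, `masked`, `histogram`.
#' @export
run_pipeline <- function(families, config = run_config(), out_dir = NULL,
                         write_png = FALSE) {
  if (length(families) == 0L) stop("input error: no families given")
  subfams <- list()
  maps <- list()
  for (fd in families) {
    maps <- c(maps, map_family_codons(fd, genetic_code = "wildcard"))
    subfams <- c(subfams, unname(split_subfamilies(fd$family)))
  }
  concat <- concatenate(subfams, ortholog_policy = config$ortholog_policy)
  sites <- extract_cug_sites(subfams, maps, concat)
  counts <- cug_species_counts(sites, concat$species)
  profile <- conservation_profile(concat, sites, flank = config$flank,
                                  lambda_weight = config$lambda_weight,
                                  partition = config$partition)
  labels <- label_columns(profile, thresholds = config$thresholds,
                          which_score = config$which_score)
  tallies <- tally_species(sites, labels, concat$species)
  calls <- call_usage(tallies, min_sites = config$min_sites,
                      margin = config$margin)
  groups <- group_summary(calls)
  m_all <- shared_matrix(sites, concat$species, mode = "all_columns")
  m_cons <- shared_matrix(sites, concat$species, profile = profile,
                          mode = "conserved_50",
                          which_score = config$which_score)
  masked <- mask_cug(concat, sites)
  hist <- conservation_histogram(profile, sites,
                                 which_score = config$which_score)
  bundle <- list(concat = concat, sites = sites, species_counts = counts,
                 profile = profile, labels = labels, tallies = tallies,
                 calls = calls, groups = groups, shared_all = m_all,
                 shared_cons = m_cons,
                 shared_combined = combine_shared(m_all, m_cons),
                 masked = masked, histogram = hist, config = config)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir, write_png = write_png)
  invisible(bundle)
}

#' Write a pipeline bundle to disk
#'
#' @param bundle Result of [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @param write_png Also write the heatmap PNG.
#' @export
write_bundle <- function(bundle, out_dir, write_png = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- bundle$config
  note <- paste0("thresholds=", paste(cfg$thresholds, collapse = "/"),
                 "; flank=", cfg$flank, "; window=", cfg$window,
                 "; lambda=", cfg$lambda_weight, "; score=", cfg$which_score,
                 "; min_sites=", cfg$min_sites, "; margin=", cfg$margin)
  p <- function(f) file.path(out_dir, f)
  write_tsv(bundle$concat$blocks, p("blocks.tsv"), note)
  write_tsv(bundle$sites, p("cug_sites.tsv"), note)
  write_tsv(bundle$species_counts, p("cug_species_counts.tsv"), note)
  write_tsv(bundle$profile, p("conservation_profile.tsv"), note)
  write_tsv(as.data.frame(bundle$calls), p("usage_calls.tsv"), note)
  write_tsv(bundle$groups, p("group_summary.tsv"), note)
  comb <- data.frame(species = rownames(bundle$shared_combined),
                     bundle$shared_combined, check.names = FALSE)
  write_tsv(comb, p("shared_matrix.tsv"), note)
  write_tsv(bundle$histogram, p("conservation_histogram.tsv"), note)
  write_fasta(bundle$masked$seqs, p("masked_concat.fasta"))
  write_phylip(bundle$masked, p("masked_concat.phy"))
  if (write_png) {
    combine_shared(bundle$shared_all, bundle$shared_cons,
                   png_path = p("shared_matrix.png"))
  }
  invisible(out_dir)
}

#' Conservation histograms of Leu/Ser columns and their CUG load
#'
#' Bins scored columns by conservation into width-0.1 half-bounded bins
#' (`[0,0.1), ..., [0.9,1.0]`, with 1.0 in the top bin). For each amino
#' acid (columns containing at least one leucine / serine among retained
#' rows) three series are reported per bin: the number of such columns, the
#' number that carry at least one CUG codon, and the total CUG codons at
#' them.
#'
#' @param profile A `conservation_profile`.
#' @param sites A `cug_sites` table.
#' @param which_score `"w3"` or `"w0"`.
#' @return Data frame: `aa`, `bin_lo`, `bin_hi`, `n_columns`,
#'   `n_cug_columns`, `n_cug_codons`.
#' @export
conservation_histogram <- function(profile, sites,
                                   which_score = c("w3", "w0")) {
  which_score <- match.arg(which_score)
  sc <- if (which_score == "w3") profile$score_w3 else profile$score_w0
  bin <- pmin(floor(sc * 10), 9)  # 1.0 joins the top bin
  cug_per_col <- table(sites$global_column)
  out <- list()
  for (aa in c("L", "S")) {
    qual <- if (aa == "L") profile$has_leu else profile$has_ser
    for (b in 0:9) {
      in_bin <- qual & bin == b
      cols <- profile$global_column[in_bin]
      ncug <- cug_per_col[as.character(cols)]
      ncug <- sum(ncug[!is.na(ncug)])
      out[[length(out) + 1L]] <- data.frame(
        aa = aa, bin_lo = b / 10, bin_hi = (b + 1) / 10,
        n_columns = sum(in_bin),
        n_cug_columns = sum(cols %in% sites$global_column),
        n_cug_codons = ncug, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
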