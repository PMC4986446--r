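#' Simulation configuration
#'
#' Defaults describe a cohort with the structure the analysis assumes: two
#' flat clades -- one translating CUG as leucine (standard code), one as
#' serine (AYCU) -- whose CUG codons sit preferentially at conserved
#' leucine and serine columns respectively, with clade-ancestral placements
#' inherited (hence shared) within each clade and none across clades at
#' conserved columns, a small minority of species-specific "stray" CUGs at
#' unconserved columns, occasional gap blocks emulating low-coverage
#' genomes, and one species without any CUG codon.
#'
#' @param seed RNG seed (all randomness flows from it).
#' @param n_species_std,n_species_aycu Species per clade.
#' @param n_families Number of protein families.
#' @param columns_per_family Alignment columns per family.
#' @param frac_leu,frac_ser,frac_other Fractions of columns designated
#'   conserved-leucine, conserved-serine and conserved-other; the remainder
#'   is variable (each species draws a uniform residue).
#' @param noise Per-species substitution probability at conserved columns.
#' @param p_place_std Clade-level CUG placement rate at conserved-Leu
#'   columns (standard clade).
#' @param p_place_aycu Same at conserved-Ser columns (AYCU clade); lower
#'   than `p_place_std`, mirroring the sparser CUG usage of serine-clade
#'   genomes.
#' @param p_loss Per-species probability of losing an inherited clade CUG.
#' @param stray_rate Per-species, per-variable-column probability of a
#'   species-specific CUG (encoding the species' own CUG translation).
#' @param gap_rate Per-row probability of one contiguous gap block.
#' @param gap_len Range (min, max) of gap-block length in columns.
#' @param n_no_cug Number of standard-clade species stripped of all CUG
#'   codons (synonymous recoding; emulates species with zero CUGs).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_species_std = 12L, n_species_aycu = 12L,
                       n_families = 2L, columns_per_family = 500L,
                       frac_leu = 0.10, frac_ser = 0.10, frac_other = 0.40,
                       noise = 0.02, p_place_std = 0.15,
                       p_place_aycu = 0.08, p_loss = 0.15,
                       stray_rate = 0.002, gap_rate = 0.15,
                       gap_len = c(20L, 80L), n_no_cug = 1L) {
  cfg <- as.list(environment())
  probs <- c(frac_leu, frac_ser, frac_other, noise, p_place_std,
             p_place_aycu, p_loss, stray_rate, gap_rate)
  if (any(probs < 0 | probs > 1)) stop("sim_config: probabilities must be in [0,1]")
  if (frac_leu + frac_ser + frac_other > 1) {
    stop("sim_config: designated column fractions sum to more than 1")
  }
  n_leu <- round(frac_leu * columns_per_family)
  n_ser <- round(frac_ser * columns_per_family)
  if (n_leu + n_ser == 0L) {
    stop("sim_config: no eligible conserved Leu/Ser columns (infeasible)")
  }
  class(cfg) <- "sim_config"
  cfg
}

# synonymous codon sets under the standard code, with CTG removed from the
# leucine set so that back-translation never creates an accidental CUG site
synonym_sets <- function() {
  gc <- genetic_code_table("standard")
  syn <- split(names(gc), unname(gc))
  syn$L <- setdiff(syn$L, "CTG")
  syn
}

#' Simulate a two-clade cohort with ground truth
#'
#' Generates protein family alignments plus back-translated coding
#' sequences, together with a truth table recording every CUG site (its
#' column class and whether it is clade-inherited) and every species' true
#' code. Conserved columns carry their designated residue in all species up
#' to the substitution noise; clade-ancestral CUG placements are drawn once
#' per clade per eligible column and then inherited with per-species loss,
#' so sharing arises within clades and never across them at conserved
#' columns. Stray CUGs live only at variable columns. All outputs pass
#' [map_codons()] validation under the wildcard code, and the whole cohort
#' is deterministic given the seed.
#'
#' @param config A [sim_config()].
#' @return List with `families` (list of `list(family, cds)` per family),
#'   `truth` (`species` and `sites` data frames), `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  syn <- synonym_sets()
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  other18 <- setdiff(aa20, c("L", "S"))
  sp_std <- sprintf("std%02d", seq_len(config$n_species_std))
  sp_aycu <- sprintf("aycu%02d", seq_len(config$n_species_aycu))
  species <- c(sp_std, sp_aycu)
  nsp <- length(species)
  is_std <- species %in% sp_std
  no_cug_sp <- sp_std[seq_len(min(config$n_no_cug, length(sp_std)))]
  C <- config$columns_per_family
  n_leu <- round(config$frac_leu * C)
  n_ser <- round(config$frac_ser * C)
  n_oth <- round(config$frac_other * C)
  truth_sites <- list()
  families <- vector("list", config$n_families)
  for (f in seq_len(config$n_families)) {
    fam_id <- sprintf("fam%d", f)
    cls <- sample(c(rep("leu", n_leu), rep("ser", n_ser),
                    rep("other", n_oth), rep("var", C - n_leu - n_ser - n_oth)))
    consensus <- character(C)
    consensus[cls == "leu"] <- "L"
    consensus[cls == "ser"] <- "S"
    consensus[cls == "other"] <- sample(other18, sum(cls == "other"),
                                        replace = TRUE)
    # residues: conserved columns follow the consensus with noise; variable
    # columns are uniform per species
    res <- matrix("", nrow = nsp, ncol = C, dimnames = list(species, NULL))
    for (j in seq_len(C)) {
      if (cls[j] == "var") {
        res[, j] <- sample(aa20, nsp, replace = TRUE)
      } else {
        res[, j] <- consensus[j]
        hit <- stats::runif(nsp) < config$noise
        if (any(hit)) {
          res[hit, j] <- sample(setdiff(aa20, consensus[j]), sum(hit),
                                replace = TRUE)
        }
      }
    }
    # clade-ancestral CUG placements, inherited with loss
    cug <- matrix(FALSE, nrow = nsp, ncol = C, dimnames = list(species, NULL))
    inherited <- cug
    anc_std <- which(cls == "leu")[stats::runif(n_leu) < config$p_place_std]
    anc_aycu <- which(cls == "ser")[stats::runif(n_ser) < config$p_place_aycu]
    for (j in anc_std) {
      keep <- is_std & stats::runif(nsp) >= config$p_loss
      cug[keep, j] <- TRUE
      inherited[keep, j] <- TRUE
      res[keep, j] <- "L"   # a CUG cell always carries its translation
    }
    for (j in anc_aycu) {
      keep <- !is_std & stats::runif(nsp) >= config$p_loss
      cug[keep, j] <- TRUE
      inherited[keep, j] <- TRUE
      res[keep, j] <- "S"
    }
    # species-specific stray CUGs at variable columns only
    var_cols <- which(cls == "var")
    for (i in seq_len(nsp)) {
      hit <- var_cols[stats::runif(length(var_cols)) < config$stray_rate]
      cug[i, hit] <- TRUE
      res[i, hit] <- if (is_std[i]) "L" else "S"
    }
    cug[species %in% no_cug_sp, ] <- FALSE
    inherited[species %in% no_cug_sp, ] <- FALSE
    # gap blocks emulating low-coverage rows
    gap <- matrix(FALSE, nrow = nsp, ncol = C)
    for (i in seq_len(nsp)) {
      if (stats::runif(1) < config$gap_rate) {
        len <- min(sample(config$gap_len[1]:config$gap_len[2], 1L), C - 1L)
        start <- sample(seq_len(C - len + 1L), 1L)
        gap[i, start:(start + len - 1L)] <- TRUE
      }
    }
    res[gap] <- "-"
    cug[gap] <- FALSE
    # back-translate row by row; append a trailing stop codon
    rows <- data.frame(row_id = paste0(species, "|", fam_id),
                       species_id = species,
                       seq = apply(res, 1L, paste0, collapse = ""),
                       stringsAsFactors = FALSE)
    cdss <- character(nsp)
    for (i in seq_len(nsp)) {
      jj <- which(!gap[i, ])
      codons <- vapply(jj, function(j) {
        if (cug[i, j]) "CTG" else {
          s <- syn[[res[i, j]]]
          s[sample.int(length(s), 1L)]
        }
      }, "")
      cdss[i] <- paste0(paste0(codons, collapse = ""), "TAA")
    }
    families[[f]] <- list(
      family = aligned_family(fam_id, rows),
      cds = data.frame(row_id = rows$row_id, cds = cdss,
                       stringsAsFactors = FALSE))
    idx <- which(cug, arr.ind = TRUE)
    if (nrow(idx)) {
      truth_sites[[f]] <- data.frame(
        species_id = species[idx[, 1]], family_id = fam_id,
        local_column = unname(idx[, 2]),
        column_class = c(leu = "conserved-Leu", ser = "conserved-Ser",
                         other = "conserved-other",
                         var = "variable")[cls[idx[, 2]]],
        inherited = inherited[idx], stringsAsFactors = FALSE)
    }
  }
  sites <- if (length(truth_sites)) do.call(rbind, truth_sites) else
    data.frame(species_id = character(0), family_id = character(0),
               local_column = integer(0), column_class = character(0),
               inherited = logical(0))
  rownames(sites) <- NULL
  sp_truth <- data.frame(
    species_id = species,
    true_code = ifelse(is_std, "standard", "aycu"),
    clade = ifelse(is_std, "std", "aycu"),
    n_cug_true = vapply(species, function(sp) sum(sites$species_id == sp), 1L),
    stringsAsFactors = FALSE)
  rownames(sp_truth) <- NULL
  list(families = families, truth = list(species = sp_truth, sites = sites),
       config = config)
}

#' A tiny fixed worked example with hand-checkable structure
#'
#' Eight species (four per clade), one family of 36 columns, built from
#' literal sequences (no randomness, byte-stable across runs). Conserved
#' leucine columns 3, 9, 15 and conserved serine columns 21, 27, 33 are
#' flanked by a fixed conserved background; the standard clade carries CUGs
#' at columns 3 and 9, the AYCU clade at columns 21 and 27, species `stdD`
#' carries none, and `aycuD` has one stray CUG at variable column 18.
#'
#' @return List with `families` (as in [simulate_cohort()]) and `truth`.
#' @export
worked_example <- function() {
  # 36 columns: conserved background 'A' except
  #  col 3,9,15 = L; col 21,27,33 = S; col 18 variable; col 6,24 = G
  base <- strsplit("AALAAGAALAAAAALAAVAASAAGAASAAAAASAAA", "")[[1]]
  stopifnot(length(base) == 36)
  species <- c(paste0("std", LETTERS[1:4]), paste0("aycu", LETTERS[1:4]))
  res <- matrix(rep(base, each = 8L), nrow = 8L,
                dimnames = list(species, NULL))
  res[, 18] <- c("V", "I", "T", "K", "E", "F", "S", "S")  # variable column
  cug <- matrix(FALSE, 8L, 36L, dimnames = list(species, NULL))
  cug[c("stdA", "stdB", "stdC"), 3] <- TRUE
  cug[c("stdA", "stdB"), 9] <- TRUE
  cug[c("aycuA", "aycuB", "aycuC"), 21] <- TRUE
  cug[c("aycuA", "aycuB"), 27] <- TRUE
  cug["aycuD", 18] <- TRUE                  # stray at a variable column
  res["aycuD", 18] <- "S"
  # fixed synonymous codons keep the example byte-stable
  codon_for <- c(A = "GCT", L = "TTA", S = "TCT", G = "GGT", V = "GTT",
                 I = "ATT", T = "ACT", K = "AAA", E = "GAA", F = "TTT")
  cdss <- vapply(species, function(sp) {
    codons <- ifelse(cug[sp, ], "CTG", codon_for[res[sp, ]])
    paste0(paste0(codons, collapse = ""), "TAA")
  }, "")
  rows <- data.frame(row_id = paste0(species, "|toy"), species_id = species,
                     seq = apply(res, 1L, paste0, collapse = ""),
                     stringsAsFactors = FALSE)
  fam <- list(family = aligned_family("toy", rows),
              cds = data.frame(row_id = rows$row_id, cds = unname(cdss),
                               stringsAsFactors = FALSE))
  idx <- which(cug, arr.ind = TRUE)
  sites <- data.frame(
    species_id = species[idx[, 1]], family_id = "toy",
    local_column = unname(idx[, 2]),
    column_class = ifelse(idx[, 2] == 18, "variable",
                          ifelse(idx[, 2] %in% c(3, 9, 15),
                                 "conserved-Leu", "conserved-Ser")),
    inherited = idx[, 2] != 18, stringsAsFactors = FALSE)
  sites <- sites[order(sites$species_id, sites$local_column), ]
  rownames(sites) <- NULL
  sp_truth <- data.frame(
    species_id = species,
    true_code = ifelse(startsWith(species, "std"), "standard", "aycu"),
    clade = ifelse(startsWith(species, "std"), "std", "aycu"),
    n_cug_true = vapply(species, function(sp) sum(sites$species_id == sp), 1L),
    stringsAsFactors = FALSE)
  rownames(sp_truth) <- NULL
  list(families = list(fam), truth = list(species = sp_truth, sites = sites))
}
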