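# Independent oracles, kept deliberately naive and separate from the
# implementation paths they check.

# brute-force property-entropy score: tabulate classes by hand, natural log
oracle_property_entropy <- function(column, partition = property_partition()) {
  gap <- sum(column == "-" | column == "X")
  res <- column[column != "-" & column != "X"]
  cls <- vapply(res, function(a) {
    for (k in seq_along(partition)) if (a %in% partition[[k]]) return(k)
    stop("unknown residue ", a)
  }, 1L)
  h <- 0
  for (k in unique(cls)) {
    p <- sum(cls == k) / length(cls)
    h <- h - p * log(p)
  }
  (1 - h / log(length(partition))) * (1 - gap / length(column))
}

# random alignment column over residues + gaps
random_column <- function(n, gap_prob = 0.2) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  ifelse(stats::runif(n) < gap_prob,
         sample(c("-", "X"), n, replace = TRUE),
         sample(aa, n, replace = TRUE))
}

# naive reimplementation of the usage-call decision tree
oracle_call <- function(leu, ser, n_cug, thresholds = c(0.9, 0.8, 0.5),
                        min_sites = 1, margin = 3) {
  if (n_cug == 0) return("no_data")
  for (k in seq_along(thresholds)) {
    l <- leu[k]; s <- ser[k]
    if (max(l, s) < min_sites) next
    if (l >= margin * s) return("standard")
    if (s >= margin * l) return("aycu")
  }
  "ambiguous"
}

# tiny three-species family used across tests
toy_family <- function() {
  rows <- data.frame(
    row_id = c("sp1|myo1", "sp2|myo1", "sp3|myo1"),
    species_id = c("sp1", "sp2", "sp3"),
    seq = c("MLLSAAKKDEFG", "MLLSAAKKDEFG", "ML-SAAKKDEFG"),
    stringsAsFactors = FALSE)
  aligned_family("myo1", rows)
}

# back-translate an ungapped residue string with fixed codons (CTG where asked)
toy_cds <- function(residues, ctg_at = integer(0)) {
  codon_for <- c(M = "ATG", L = "TTA", S = "TCT", A = "GCT", K = "AAA",
                 D = "GAT", E = "GAA", F = "TTT", G = "GGT", V = "GTT",
                 I = "ATT", T = "ACT")
  res <- strsplit(residues, "")[[1]]
  codons <- codon_for[res]
  codons[ctg_at] <- "CTG"
  paste0(codons, collapse = "")
}
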