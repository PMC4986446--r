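test_that("family FASTA read-back preserves residues, order and metadata", {
  fam <- toy_family()
  aln_path <- withr::local_tempfile(fileext = ".fasta")
  seqs <- fam$rows$seq
  names(seqs) <- fam$rows$row_id
  write_fasta(seqs, aln_path)
  rd <- read_family(aln_path, NULL, family_id = "myo1")
  expect_equal(rd$family$n_columns, 12L)
  expect_equal(rd$family$rows$row_id, fam$rows$row_id)
  expect_equal(rd$family$rows$species_id, c("sp1", "sp2", "sp3"))
  expect_equal(rd$family$rows$seq, fam$rows$seq)
  expect_false(any(rd$family$rows$has_cds))
})

test_that("malformed alignments and headers are rejected", {
  p <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(c("sp1|a" = "MKLV", "sp2|a" = "MKL"), p)
  expect_error(read_family(p, NULL, "fam"), "unequal")
  write_fasta(c("sp1_noDelim" = "MKLV"), p)
  expect_error(read_family(p, NULL, "fam"), "metadata")
})

test_that("orphan CDS records are dropped with a warning", {
  aln <- withr::local_tempfile(fileext = ".fasta")
  cds <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(c("sp1|a" = "MKLV"), aln)
  write_fasta(c("sp1|a" = toy_cds("MKLV"), "spX|a" = toy_cds("MKLV")), cds)
  expect_warning(rd <- read_family(aln, cds, "fam"), "1 CDS record")
  expect_equal(nrow(rd$cds), 1L)
  expect_true(all(rd$family$rows$has_cds))
})

test_that("map_codons assigns one codon per ungapped residue across a gap", {
  rows <- data.frame(row_id = "sp1|a", species_id = "sp1", seq = "M-LS",
                     stringsAsFactors = FALSE)
  fam <- aligned_family("a", rows)
  m <- map_codons(fam, "sp1|a", "ATGCTGAGC")
  expect_equal(m$entries$codon, c("ATG", "CTG", "AGC"))
  expect_equal(m$entries$column, c(1L, 3L, 4L))
  expect_equal(m$entries$codon_index, 1:3)
  # trailing stop is trimmed
  m2 <- map_codons(fam, "sp1|a", "ATGCTGAGCTAA")
  expect_equal(m2$entries, m$entries)
})

test_that("genetic code setting affects validation only, never coordinates", {
  rows <- data.frame(row_id = c("l|a", "s|a"), species_id = c("l", "s"),
                     seq = c("M-LS", "M-SS"), stringsAsFactors = FALSE)
  fam <- aligned_family("a", rows)
  cds <- "ATGCTGAGC"
  # CUG-as-leucine row: valid under wildcard and standard, same coordinates
  expect_equal(map_codons(fam, "l|a", cds, "wildcard")$entries,
               map_codons(fam, "l|a", cds, "standard")$entries)
  expect_error(map_codons(fam, "l|a", cds, "aycu"), "mapping error")
  # CUG-as-serine row: valid under wildcard and aycu, same coordinates
  expect_equal(map_codons(fam, "s|a", cds, "wildcard")$entries,
               map_codons(fam, "s|a", cds, "aycu")$entries)
  expect_error(map_codons(fam, "s|a", cds, "standard"),
               "codon 2.*does not match")
})

test_that("frame, stop and N-codon rules are enforced", {
  rows <- data.frame(row_id = "sp|a", species_id = "sp", seq = "MXL",
                     stringsAsFactors = FALSE)
  fam <- aligned_family("a", rows)
  expect_error(map_codons(fam, "sp|a", "ATGCT"), "frame error")
  expect_error(map_codons(fam, "sp|a", "ATGTAACTT"), "internal stop")
  # codon with N maps to X, never to a residue
  m <- map_codons(fam, "sp|a", "ATGANACTT")
  expect_equal(m$entries$codon[2], "ANA")
  rows2 <- data.frame(row_id = "sp|a", species_id = "sp", seq = "MKL",
                      stringsAsFactors = FALSE)
  fam2 <- aligned_family("a", rows2)
  expect_error(map_codons(fam2, "sp|a", "ATGANACTT"), "mapping error")
})

test_that("concatenation tiles blocks, gap-fills missing species", {
  f1 <- aligned_family("f1", data.frame(
    row_id = paste0(c("sp1", "sp2", "sp3"), "|f1"),
    species_id = c("sp1", "sp2", "sp3"),
    seq = rep(strrep("A", 10), 3), stringsAsFactors = FALSE))
  f2 <- aligned_family("f2", data.frame(
    row_id = paste0(c("sp1", "sp2"), "|f2"),
    species_id = c("sp1", "sp2"),
    seq = rep(strrep("K", 8), 2), stringsAsFactors = FALSE))
  cc <- concatenate(list(f1, f2))
  expect_equal(cc$total_columns, 18L)
  expect_equal(unname(nchar(cc$seqs)), rep(18L, 3))
  expect_equal(substr(cc$seqs[["sp3"]], 11, 18), strrep("-", 8))
  expect_equal(cc$blocks$start, c(1L, 11L))
  expect_equal(cc$blocks$end, c(10L, 18L))
})

test_that("paralog policy: strict errors, longest keeps the fuller row", {
  fam <- aligned_family("f", data.frame(
    row_id = c("sp1|p1", "sp1|p2"), species_id = "sp1",
    seq = c("AAAA--", "AAAAAA"), stringsAsFactors = FALSE))
  expect_error(concatenate(list(fam), "strict"), "paralog error")
  cc <- suppressMessages(concatenate(list(fam), "longest"))
  expect_equal(cc$chosen$row_id, "sp1|p2")
  expect_equal(unname(cc$seqs["sp1"]), "AAAAAA")
})

test_that("CUG sites are found per codon, with zero-CUG species retained", {
  rows <- data.frame(
    row_id = c("sp1|a", "sp2|a", "sp2|b"),
    species_id = c("sp1", "sp2", "sp2"),
    seq = c("MLLSAA", "MLLSAA", "MLLSAA"), stringsAsFactors = FALSE)
  fam <- aligned_family("a", rows, max_paralogs = 2L)
  cds <- data.frame(row_id = rows$row_id,
                    cds = c(toy_cds("MLLSAA", ctg_at = c(2, 6)),
                            toy_cds("MLLSAA", ctg_at = 2),
                            toy_cds("MLLSAA", ctg_at = 2)),
                    stringsAsFactors = FALSE)
  # paralog rows share column 2; codon 6 of sp1 is CTG coding alanine? no:
  # ctg_at marks codon positions replaced by CTG; codon 6 codes A, so use
  # the wildcard mapping (translation deferred) -- this is exactly why
  # mapping must not presume a code
  maps <- map_family_codons(list(family = fam, cds = cds))
  cc <- suppressMessages(concatenate(list(fam)))
  sites <- extract_cug_sites(list(fam), maps, cc)
  expect_equal(nrow(sites), 4L)
  expect_equal(sum(sites$species_id == "sp1"), 2L)
  # sp2 paralogs: 2 sites, 1 distinct column
  s2 <- sites[sites$species_id == "sp2", ]
  expect_equal(nrow(s2), 2L)
  expect_equal(length(unique(s2$global_column)), 1L)
  counts <- cug_species_counts(sites, c("sp1", "sp2", "sp3"))
  expect_equal(counts$n_cug, c(2L, 2L, 0L))
  # count conservation: per-species counts sum to the site total
  expect_equal(sum(counts$n_cug), nrow(sites))
})

test_that("masking replaces exactly the CUG cells and is idempotent", {
  co <- simulate_cohort(sim_config(seed = 42, n_species_std = 4,
                                   n_species_aycu = 4, n_families = 1,
                                   columns_per_family = 80))
  fams <- lapply(co$families, function(fd) fd$family)
  maps <- do.call(c, lapply(co$families, map_family_codons))
  cc <- concatenate(fams)
  sites <- extract_cug_sites(fams, maps, cc)
  masked <- mask_cug(cc, sites)
  m0 <- concat_matrix(cc)
  m1 <- concat_matrix(masked)
  ndiff <- sum(m0 != m1)
  chosen_sites <- sites[sites$row_id %in% cc$chosen$row_id, ]
  expect_equal(ndiff,
               nrow(unique(chosen_sites[, c("species_id", "global_column")])))
  expect_true(all(m1[m0 != m1] == "X"))
  # idempotent
  expect_identical(mask_cug(masked, sites)$seqs, masked$seqs)
  # empty site table is the identity
  empty <- sites[0, ]
  expect_identical(mask_cug(cc, empty)$seqs, cc$seqs)
})

test_that("masking commutes with concatenation", {
  co <- simulate_cohort(sim_config(seed = 7, n_species_std = 3,
                                   n_species_aycu = 3, n_families = 2,
                                   columns_per_family = 60, gap_rate = 0))
  fams <- lapply(co$families, function(fd) fd$family)
  maps <- do.call(c, lapply(co$families, map_family_codons))
  cc <- concatenate(fams)
  sites <- extract_cug_sites(fams, maps, cc)
  mask_then <- mask_cug(cc, sites)$seqs
  # concatenate each family alone, mask it, then paste the pieces
  pieces <- lapply(fams, function(f) {
    cc1 <- concatenate(list(f))
    s1 <- extract_cug_sites(list(f), maps, cc1)
    mask_cug(cc1, s1)$seqs
  })
  then_mask <- paste0(pieces[[1]][cc$species], pieces[[2]][cc$species])
  expect_equal(unname(mask_then[cc$species]), then_mask)
})

test_that("phylip writer emits a parseable relaxed matrix", {
  co <- worked_example()
  cc <- concatenate(list(co$families[[1]]$family))
  p <- withr::local_tempfile(fileext = ".phy")
  write_phylip(cc, p)
  lines <- readLines(p)
  expect_equal(lines[1], paste(length(cc$species), cc$total_columns))
  expect_equal(length(lines), 1 + length(cc$species))
})
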