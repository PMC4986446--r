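test_that("property entropy hits its closed-form anchors", {
  # single class, gap-free
  expect_identical(property_entropy(rep("L", 10)), 1)
  # one residue from each of the six classes: maximal entropy
  expect_identical(property_entropy(c("A", "F", "S", "K", "D", "G")), 0)
  # [L,L,L,S]: 1 - H(3/4, 1/4)/log 6, frozen from the brute-force oracle
  expect_equal(property_entropy(c("L", "L", "L", "S")),
               0.68615478010501074, tolerance = 1e-15)
  # gap penalty is multiplicative; 'X' counts as gap-like, not as a residue
  expect_equal(property_entropy(c("L", "L", "-", "-")), 0.5)
  expect_equal(property_entropy(c("L", "L", "X", "-")), 0.5)
  expect_error(property_entropy(c("-", "X")), "all gap")
})

test_that("property entropy matches the brute-force oracle on random columns", {
  set.seed(101)
  pp <- property_partition()
  for (i in 1:300) {
    col <- random_column(sample(2:40, 1))
    if (all(col %in% c("-", "X"))) next
    s <- property_entropy(col, pp)
    expect_equal(s, oracle_property_entropy(col, pp), tolerance = 1e-12)
    expect_gte(s, 0)
    expect_lte(s, 1)
    # depends only on the column multiset
    expect_identical(property_entropy(sample(col), pp), s)
  }
})

test_that("moving a residue into the modal class never lowers the score", {
  set.seed(202)
  pp <- property_partition()
  lookup <- attr(pp, "lookup")
  for (i in 1:200) {
    col <- random_column(sample(3:30, 1), gap_prob = 0.1)
    res_idx <- which(!(col %in% c("-", "X")))
    if (length(res_idx) < 2) next
    cls <- lookup[col[res_idx]]
    modal_class <- as.integer(names(which.max(table(cls))))
    before <- property_entropy(col, pp)
    j <- sample(res_idx, 1)
    col[j] <- pp[[modal_class]][1]
    expect_gte(property_entropy(col, pp), before - 1e-12)
  }
})

test_that("window smoothing: identity at w=0, fixed points, hand value, bounds", {
  raw <- c(0.2, 0.9, 0.4, 1.0, 0.0)
  expect_identical(window_score(raw, w = 0L), raw)
  expect_equal(window_score(rep(0.7, 9), w = 3L), rep(0.7, 9))
  # [1,0,1], w=1, lambda=0.5: middle = 0.5*0 + 0.5*1
  expect_equal(window_score(c(1, 0, 1), w = 1L, lambda_weight = 0.5)[2], 0.5)
  # smoothed value stays within the raw range of its window
  set.seed(303)
  for (i in 1:50) {
    r <- runif(sample(4:40, 1))
    sm <- window_score(r, w = 3L, lambda_weight = 0.5)
    for (j in seq_along(r)) {
      win <- r[max(1, j - 3):min(length(r), j + 3)]
      expect_gte(sm[j], min(win) - 1e-12)
      expect_lte(sm[j], max(win) + 1e-12)
    }
  }
})

test_that("focal scoring removes CUG rows and equals the reduced-column oracle", {
  wx <- worked_example()
  fams <- list(wx$families[[1]]$family)
  maps <- map_family_codons(wx$families[[1]])
  cc <- concatenate(fams)
  sites <- extract_cug_sites(fams, maps, cc)
  # column 3: stdA-C carry CUG there and must be removed
  f <- focal_conservation(cc, sites, column = 3)
  expect_setequal(f$excluded_species, c("stdA", "stdB", "stdC"))
  expect_equal(f$n_retained, 5L)
  expect_equal(f$score, 1.0)   # flank fully conserved after removal
  # w=0 score equals the hand-reduced column's property entropy
  f0 <- focal_conservation(cc, sites, column = 3, w = 0L)
  mat <- concat_matrix(cc)
  reduced <- mat[setdiff(rownames(mat), f$excluded_species), 3]
  expect_equal(f0$score, oracle_property_entropy(reduced))
})

test_that("flank as wide as the alignment reproduces the global column score", {
  wx <- worked_example()
  fams <- list(wx$families[[1]]$family)
  cc <- concatenate(fams)
  empty_sites <- extract_cug_sites(fams, list(), cc)
  mat <- concat_matrix(cc)
  f <- focal_conservation(cc, empty_sites, column = 18, flank = 1000L,
                          w = 0L)
  expect_equal(f$score, oracle_property_entropy(mat[, 18]))
})

test_that("focal scores are local: columns outside the flank have no influence", {
  set.seed(404)
  co <- simulate_cohort(sim_config(seed = 5, n_species_std = 5,
                                   n_species_aycu = 5, n_families = 1,
                                   columns_per_family = 120))
  fams <- lapply(co$families, function(fd) fd$family)
  maps <- do.call(c, lapply(co$families, map_family_codons))
  cc <- concatenate(fams)
  sites <- extract_cug_sites(fams, maps, cc)
  prof <- conservation_profile(cc, sites)
  for (i in 1:20) {
    focal <- sample(prof$global_column, 1)
    before <- focal_conservation(cc, sites, focal)
    # scramble a column outside the +/-15 flank
    far <- setdiff(seq_len(cc$total_columns),
                   (focal - 15):(focal + 15))
    j <- sample(far, 1)
    mat <- concat_matrix(cc)
    mat[, j] <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                       nrow(mat), replace = TRUE)
    cc2 <- cc
    cc2$seqs <- apply(mat, 1L, paste0, collapse = "")
    after <- focal_conservation(cc2, sites, focal)
    expect_identical(after$score, before$score)
  }
})

test_that("column labels follow modal residue and nest across thresholds", {
  prof <- data.frame(
    global_column = 1:3, family_id = "f", local_column = 1:3,
    n_retained = 10L, gap_fraction = 0,
    score_w0 = c(0.95, 0.55, 0.95), score_w3 = c(0.95, 0.55, 0.95),
    modal_residue = c("L", "S", "A"), modal_fraction = 1,
    has_leu = TRUE, has_ser = TRUE, stringsAsFactors = FALSE)
  class(prof) <- c("conservation_profile", "data.frame")
  lab <- label_columns(prof)
  expect_true(all(unlist(lab[1, c("leu_0.9", "leu_0.8", "leu_0.5")])))
  expect_equal(unlist(lab[2, c("ser_0.9", "ser_0.8", "ser_0.5")]),
               c(ser_0.9 = FALSE, ser_0.8 = FALSE, ser_0.5 = TRUE))
  # conserved but neither L nor S modal: no label at any level
  expect_false(any(unlist(lab[3, -(1:3)])))
  # nesting on generator output
  co <- simulate_cohort(sim_config(seed = 3, n_species_std = 6,
                                   n_species_aycu = 6, n_families = 1,
                                   columns_per_family = 150))
  b <- run_pipeline(co$families)
  lb <- b$labels
  expect_true(all(!lb$leu_0.9 | lb$leu_0.8))
  expect_true(all(!lb$leu_0.8 | lb$leu_0.5))
  expect_true(all(!lb$ser_0.9 | lb$ser_0.8))
  expect_true(all(!lb$ser_0.8 | lb$ser_0.5))
})
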