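# Peptide enumeration, composite affinities, best epitopes, CCF and the
# expression filter.

test_that("peptide enumeration yields the forced window counts", {
  prot <- paste(rep("A", 60), collapse = "")
  pep <- enumerate_peptides(prot, 30, "missense", mut_residue = "W")
  # central missense: L windows per length -> 8+9+10+11+15 = 53
  expect_equal(nrow(pep), 53)
  expect_equal(sum(pep$length %in% 8:11), 38)
  expect_true(all(grepl("W", pep$mut_peptide)))
  expect_true(all(nchar(pep$mut_peptide) == pep$length))
  expect_true(all(nchar(pep$wt_peptide) == pep$length))

  # N-terminal missense: exactly one window per length
  pep1 <- enumerate_peptides(prot, 1, "missense", mut_residue = "W")
  expect_equal(nrow(pep1), 5)
  expect_equal(pep1$start, rep(1L, 5))
})

test_that("frameshift enumeration matches a brute-force window oracle", {
  set.seed(41)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  prot <- paste(sample(aa, 40, replace = TRUE), collapse = "")
  tail <- paste(sample(aa, 12, replace = TRUE), collapse = "")
  pos <- 25
  pep <- enumerate_peptides(prot, pos, "frameshift", mut_tail = tail)
  expect_true(all(is.na(pep$wt_peptide)))
  mut_prot <- paste0(substr(prot, 1, pos - 1), tail)
  for (len in c(8, 9, 10, 11, 15)) {
    # oracle: every window of the mutant protein touching a novel residue
    oracle <- 0
    for (s in seq_len(nchar(mut_prot) - len + 1)) {
      if (s + len - 1 >= pos) oracle <- oracle + 1
    }
    expect_equal(sum(pep$length == len), oracle)
  }
  expect_error(enumerate_peptides(prot, 99, "missense",
                                  mut_residue = "W"), "outside")
})

test_that("composite affinity is the predictor median", {
  expect_equal(composite_affinity(c(100, 200, 300, 400, 500)), 300)
  expect_equal(composite_affinity(c(50, 150)), 100)
  expect_equal(composite_affinity(42), 42)
})

test_that("best epitope takes the argmin with deterministic tie-breaks", {
  pairs <- tibble::tibble(mut_median = c(400, 40),
                          ratio = c(0.5, 0.9),
                          mut_peptide = c("AAAA", "CCCC"))
  expect_equal(best_epitope(pairs)$mut_median, 40)
  ties <- tibble::tibble(mut_median = c(40, 40),
                         ratio = c(0.5, 0.1),
                         mut_peptide = c("AAAA", "CCCC"))
  expect_equal(best_epitope(ties)$ratio, 0.1)
  lex <- tibble::tibble(mut_median = c(40, 40), ratio = c(0.1, 0.1),
                        mut_peptide = c("DDDD", "AAAA"))
  expect_equal(best_epitope(lex)$mut_peptide, "AAAA")

  # brute-force argmin oracle on random pairs
  set.seed(43)
  rnd <- tibble::tibble(mut_median = sample(seq(10, 1000, 10), 100,
                                            replace = TRUE),
                        ratio = runif(100),
                        mut_peptide = replicate(100, paste(
                          sample(LETTERS, 9, TRUE), collapse = "")))
  picked <- best_epitope(rnd)
  oracle <- rnd[order(rnd$mut_median, rnd$ratio, rnd$mut_peptide), ][1, ]
  expect_equal(picked, oracle)
})

test_that("binder calls respect the cutoff boundary and monotonicity", {
  pairs <- tibble::tibble(
    mutation_id = c("m1", "m2", "m3"),
    mut_median = c(499, 501, 200), ratio = c(1, 1, 1),
    mut_peptide = c("AAA", "CCC", "DDD"))
  calls <- call_neoantigens(pairs)
  expect_equal(calls$neoantigenic, c(TRUE, FALSE, TRUE))
  # lowering the cutoff never increases the burden
  burdens <- vapply(c(1000, 500, 300, 100), function(cut) {
    sum(call_neoantigens(pairs, cut)$neoantigenic)
  }, numeric(1))
  expect_true(all(diff(burdens) <= 0))
})

test_that("simulated binder fraction is recovered from affinity tables", {
  set.seed(47)
  aff <- simulate_affinities(sprintf("m%04d", 1:1000), p_binder = 0.66)
  # recompute composite medians from predictor columns, then call
  pred_cols <- grep("^predictor_", names(aff$affinities))
  recomputed <- apply(as.matrix(aff$affinities[, pred_cols]), 1,
                      composite_affinity)
  expect_equal(recomputed, aff$affinities$mut_median)
  calls <- call_neoantigens(aff$affinities)
  # calls agree with the generator's truth row by row, so the recovered
  # fraction equals the realized binder fraction exactly
  truth <- aff$truth[match(calls$mutation_id, aff$truth$mutation_id), ]
  expect_equal(calls$neoantigenic, truth$true_binder)
  expect_equal(mean(calls$neoantigenic), mean(aff$truth$true_binder))
  # and the generator is calibrated: realized fraction within 3 s.e.
  expect_lt(abs(mean(aff$truth$true_binder) - 0.66),
            3 * sqrt(0.66 * 0.34 / 1000))
})

test_that("neoepitope ratio is scale invariant and guards synonymy", {
  m <- c(100, 250, 400)
  ratio <- composite_affinity(m) / composite_affinity(m * 2)
  ratio_scaled <- composite_affinity(m * 7) / composite_affinity(m * 14)
  expect_equal(ratio, ratio_scaled)
  # identical mutant and wild-type peptides force ratio 1
  expect_equal(composite_affinity(m) / composite_affinity(m), 1)
})

test_that("the simplified CCF closed form behaves and caps", {
  one <- estimate_ccf(0.5, 1, 2, 1)
  expect_equal(one$ccf, 1)
  expect_true(one$clonal)
  half <- estimate_ccf(0.125, 0.5, 2, 1)
  expect_equal(half$ccf, 0.5)
  expect_false(half$clonal)
  capped <- estimate_ccf(0.9, 1, 2, 1)
  expect_equal(capped$ccf, 1)
  expect_equal(capped$ccf_raw, 1.8)
  expect_error(estimate_ccf(0.5, 0), "purity")
})

test_that("CCF recovery error is small at realistic depth", {
  set.seed(53)
  n <- 500
  purity <- runif(n, 0.8, 0.99)
  truth <- runif(n, 0.2, 1)
  draws <- vapply(seq_len(n), function(i) {
    d <- sample_allele_fraction(truth[i], purity[i], 2, 100)
    d$t_alt_count / d$t_depth
  }, numeric(1))
  est <- estimate_ccf(draws, purity, 2, 1)
  expect_lt(median(abs(est$ccf - truth)), 0.1)
})

test_that("clonality contrast recovers enrichment and the null", {
  # built-in enrichment
  set.seed(59)
  neo <- runif(2000) < 0.66
  clonal <- ifelse(neo, runif(2000) < 0.20, runif(2000) < 0.11)
  res <- clonal_neoantigen_contrast(neo, clonal)
  expect_gt(res$clonal_fraction_neo, res$clonal_fraction_other)
  expect_lt(res$p_value, 0.01)

  # degenerate: everything clonal
  allc <- clonal_neoantigen_contrast(rep(c(TRUE, FALSE), 10),
                                     rep(TRUE, 20))
  expect_equal(allc$clonal_fraction_neo, 1)
  expect_equal(allc$clonal_fraction_other, 1)
  expect_equal(allc$p_value, 1)

  # independence null keeps type-I error near nominal
  hits <- replicate(200, {
    neo0 <- runif(300) < 0.5; cl0 <- runif(300) < 0.15
    clonal_neoantigen_contrast(neo0, cl0)$p_value < 0.05
  })
  expect_lt(abs(mean(hits) - 0.05), 0.04)
})

test_that("expression filter drops the bottom quartile deterministically", {
  mat <- matrix(c(1, 2, 3, 4), nrow = 4,
                dimnames = list(c("G1", "G2", "G3", "G4"), "S1"))
  res <- expression_filter(mat, c("G3", "G4"))
  expect_equal(res$dropped_genes, "G1")
  expect_equal(res$overlap_fraction, 1)

  # ties at the cutoff break by gene name; equals a sort oracle
  set.seed(61)
  g <- 40
  means <- sample(c(1, 2, 5, 9), g, replace = TRUE)
  mat2 <- matrix(rep(means, 3), nrow = g,
                 dimnames = list(sprintf("G%02d", seq_len(g)), NULL))
  res2 <- expression_filter(mat2, sprintf("G%02d", 1:10))
  ord <- order(means, rownames(mat2))
  oracle_drop <- rownames(mat2)[ord][seq_len(floor(0.25 * g))]
  expect_equal(res2$dropped_genes, oracle_drop)
})

test_that("simulated expression placement reproduces the overlap fraction", {
  set.seed(67)
  neo_genes <- sprintf("NG%03d", 1:200)
  mat <- simulate_expression(800, neo_genes, p_expressed = 0.76)
  res <- expression_filter(mat, neo_genes)
  expect_lt(abs(res$overlap_fraction - 0.76), 0.08)
})
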