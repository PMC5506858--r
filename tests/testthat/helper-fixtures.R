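# Small in-code fixtures shared across the suite.

make_mutations <- function(sample_id = "S1", patient_id = "P1",
                           gene = "GENE0001", chrom = "1",
                           pos = NULL, ref = "C", alt = "T",
                           classification = "missense",
                           t_alt_count = 10L, t_depth = 40L) {
  n <- max(lengths(list(sample_id, gene, chrom, pos, ref, alt,
                        classification, t_alt_count, t_depth)))
  if (is.null(pos)) pos <- seq_len(n) * 1000L
  validate_mutations(tibble::tibble(
    sample_id = rep_len(sample_id, n),
    patient_id = rep_len(patient_id, n),
    gene = rep_len(gene, n),
    chrom = rep_len(chrom, n),
    pos = rep_len(as.integer(pos), n),
    ref = rep_len(ref, n),
    alt = rep_len(alt, n),
    classification = rep_len(classification, n),
    t_alt_count = rep_len(as.integer(t_alt_count), n),
    t_depth = rep_len(as.integer(t_depth), n)
  ))
}

make_segments <- function(sample_id = "S1", chrom = "1",
                          start = 1, end = 1e6, n_probes = 100L,
                          log2_ratio = 0) {
  n <- max(lengths(list(sample_id, chrom, start, end, log2_ratio)))
  validate_segments(tibble::tibble(
    sample_id = rep_len(sample_id, n),
    chrom = rep_len(chrom, n),
    start = rep_len(start, n),
    end = rep_len(end, n),
    n_probes = rep_len(as.integer(n_probes), n),
    log2_ratio = rep_len(log2_ratio, n)
  ))
}

make_junctions <- function(sample_id = "S1", chromA = "1",
                           posA = 1000L, strandA = "+",
                           chromB = "1", posB = 5000L, strandB = "-",
                           sv_class = NA_character_,
                           homology_len = 0L, insertion_len = 0L) {
  n <- max(lengths(list(sample_id, chromA, posA, chromB, posB,
                        strandA, strandB, homology_len,
                        insertion_len)))
  validate_junctions(tibble::tibble(
    sample_id = rep_len(sample_id, n),
    chromA = rep_len(chromA, n),
    posA = rep_len(as.integer(posA), n),
    strandA = rep_len(strandA, n),
    chromB = rep_len(chromB, n),
    posB = rep_len(as.integer(posB), n),
    strandB = rep_len(strandB, n),
    sv_class = rep_len(sv_class, n),
    homology_len = rep_len(as.integer(homology_len), n),
    insertion_len = rep_len(as.integer(insertion_len), n),
    repeatA = rep_len(FALSE, n),
    repeatB = rep_len(FALSE, n)
  ))
}

make_meta <- function(sample_id = "S1", patient_id = "P1",
                      resection_index = NULL, grade = "II",
                      histology = "fibroblastic",
                      radiation_status = "naive", purity = 0.9,
                      ploidy = 2, mean_coverage = 100) {
  n <- max(lengths(list(sample_id, patient_id, grade, histology,
                        purity, mean_coverage)))
  if (is.null(resection_index)) resection_index <- seq_len(n)
  validate_sample_meta(tibble::tibble(
    sample_id = rep_len(sample_id, n),
    patient_id = rep_len(patient_id, n),
    resection_index = rep_len(as.integer(resection_index), n),
    grade = rep_len(grade, n),
    histology = rep_len(histology, n),
    radiation_status = rep_len(radiation_status, n),
    purity = rep_len(purity, n),
    ploidy = rep_len(ploidy, n),
    mean_coverage = rep_len(mean_coverage, n)
  ))
}

# all permutations of 1..n as a matrix (rows are orderings)
all_perms <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- all_perms(n - 1)
  out <- NULL
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow = nrow(sub))))
  }
  unname(out)
}

# independent two-sided Fisher oracle: enumerate the hypergeometric
# support and sum probabilities no larger than the observed table's
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  pobs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}
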