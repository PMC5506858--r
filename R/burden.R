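# Per-sample mutation burden, allelic-fraction filtering, the six-class
# substitution spectrum and grouped comparisons.

#' Allelic-fraction filter
#'
#' Discards mutations with allele fraction below `min_af` (default 0.1),
#' the filter applied before driver and recurrence analyses.  The
#' boundary is kept: only fractions strictly less than the threshold are
#' removed.  Burden counts are reported unfiltered by default (see
#' [burden_table()]).
#'
#' @param mutations mutation tibble with `allele_fraction`.
#' @param min_af minimum allele fraction retained (default 0.1).
#' @param quiet suppress the message reporting how many records were
#'   removed.
#' @return filtered tibble.
#' @export
af_filter <- function(mutations, min_af = 0.1, quiet = FALSE) {
  keep <- mutations$allele_fraction >= min_af
  keep[is.na(keep)] <- FALSE
  if (min_af <= 0) keep <- rep(TRUE, nrow(mutations))
  if (!quiet) {
    message(sum(!keep), " of ", nrow(mutations),
            " mutations removed at AF < ", min_af)
  }
  mutations[keep, , drop = FALSE]
}

#' Nonsynonymous mutation burden of one sample
#'
#' Counts records in the nonsynonymous classification set (missense,
#' nonsense, splice_site, frameshift_indel, inframe_indel).
#'
#' @param mutations mutation tibble.
#' @param sample_id optional sample to count; by default all records are
#'   assumed to belong to one sample.
#' @return integer count.
#' @export
nonsyn_burden <- function(mutations, sample_id = NULL) {
  if (!is.null(sample_id)) {
    mutations <- mutations[mutations$sample_id == sample_id, , drop = FALSE]
  }
  sum(mutations$classification %in% nonsynonymous_classes())
}

#' @keywords internal
is_snv <- function(ref, alt) {
  nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    ref != alt
}

#' Six-class substitution spectrum
#'
#' Collapses every SNV to its pyrimidine-reference representation (a G>A
#' change is counted as C>T on the opposite strand, and so on) and
#' returns the fraction of substitutions in each of the six classes
#' C>A, C>G, C>T, T>A, T>C, T>G.  Indels and multi-nucleotide changes
#' are excluded.  With no SNVs all fractions are `NA`.
#'
#' @param mutations mutation tibble.
#' @return named numeric vector of six fractions summing to 1.
#' @export
spectrum6 <- function(mutations) {
  classes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  snv <- mutations[is_snv(mutations$ref, mutations$alt), , drop = FALSE]
  if (nrow(snv) == 0) {
    return(stats::setNames(rep(NA_real_, 6), classes))
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  flip <- snv$ref %in% c("A", "G")
  ref <- ifelse(flip, comp[snv$ref], snv$ref)
  alt <- ifelse(flip, comp[snv$alt], snv$alt)
  counts <- table(factor(paste0(ref, ">", alt), levels = classes))
  stats::setNames(as.numeric(counts) / nrow(snv), classes)
}

#' Per-sample burden table
#'
#' One row per sample with total and nonsynonymous mutation counts, mean
#' allele fraction, the six spectrum fractions and a hypermutator flag.
#' Samples with burden above `Q3 + 3 * IQR` of the cohort's
#' nonsynonymous counts are flagged (not removed); the analyses retain
#' hypermutators.
#'
#' @param mutations cohort mutation tibble.
#' @param filtered apply the AF >= 0.1 filter before counting
#'   (default `FALSE`: burden is reported on unfiltered calls).
#' @param min_af threshold used when `filtered = TRUE`.
#' @return tibble with columns `sample_id`, `n_nonsyn`, `n_total`,
#'   `mean_af`, the six `spectrum_*` fractions and `hypermutator`.
#' @export
burden_table <- function(mutations, filtered = FALSE, min_af = 0.1) {
  if (filtered) mutations <- af_filter(mutations, min_af, quiet = TRUE)
  samples <- unique(mutations$sample_id)
  rows <- lapply(samples, function(s) {
    m <- mutations[mutations$sample_id == s, , drop = FALSE]
    spec <- spectrum6(m)
    tibble::tibble(
      sample_id = s,
      n_nonsyn = nonsyn_burden(m),
      n_total = nrow(m),
      mean_af = mean(m$allele_fraction, na.rm = TRUE),
      spectrum_CA = spec[["C>A"]], spectrum_CG = spec[["C>G"]],
      spectrum_CT = spec[["C>T"]], spectrum_TA = spec[["T>A"]],
      spectrum_TC = spec[["T>C"]], spectrum_TG = spec[["T>G"]]
    )
  })
  out <- dplyr::bind_rows(rows)
  q <- stats::quantile(out$n_nonsyn, c(0.25, 0.75), names = FALSE)
  out$hypermutator <- out$n_nonsyn > q[2] + 3 * (q[2] - q[1])
  out
}

#' Two-group comparison of continuous values
#'
#' Two-sided comparison of a numeric vector between two groups, by
#' Wilcoxon rank-sum (default, used for sparse or outlier-prone data)
#' or Student's t-test.
#'
#' @param values numeric vector.
#' @param labels logical or two-level vector defining the groups.
#' @param test `"wilcoxon"` or `"t"`.
#' @return list with `statistic` and `p_value`.
#' @export
compare_groups <- function(values, labels, test = c("wilcoxon", "t")) {
  test <- match.arg(test)
  groups <- split(values, labels)
  if (length(groups) != 2) {
    stop("labels must define exactly two groups", call. = FALSE)
  }
  res <- if (test == "wilcoxon") {
    suppressWarnings(stats::wilcox.test(groups[[1]], groups[[2]],
                                        exact = FALSE))
  } else {
    stats::t.test(groups[[1]], groups[[2]])
  }
  list(statistic = unname(res$statistic), p_value = res$p.value)
}
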