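# Driver-status classification, co-occurrence testing and the binomial
# power model for detection of recurrently mutated genes.

#' Default canonical non-NF2 meningioma driver genes
#'
#' TRAF7, KLF4, AKT1 and SMO are the four most frequently mutated non-NF2
#' meningioma drivers; the remainder are additional published drivers.
#'
#' @return character vector of gene symbols.
#' @export
canonical_driver_genes <- function() {
  c("TRAF7", "KLF4", "AKT1", "SMO", "PIK3CA", "SUFU", "SMARCB1",
    "POLR2A", "BAP1")
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact test of association for the table
#' \preformatted{  a  b
#'   c  d}
#' The p-value sums hypergeometric probabilities of all tables (with the
#' observed margins) no more probable than the observed one.  The sample
#' odds ratio `(a*d)/(b*c)` is reported; when a margin is zero the odds
#' ratio is undefined (`NA`) and p is 1.
#'
#' @param a,b,c,d nonnegative integer cell counts.
#' @return list with `odds_ratio`, `p_value` and `direction`
#'   (`"co-occurring"` for OR > 1, `"exclusive"` for OR < 1, `"none"`
#'   otherwise or when undefined).
#' @export
fisher_association <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0)) stop("cell counts must be nonnegative", call. = FALSE)
  tab <- matrix(counts, nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(odds_ratio = NA_real_, p_value = 1, direction = "none"))
  }
  p <- stats::fisher.test(tab)$p.value
  or <- if (b == 0 || c == 0) NA_real_ else (a * d) / (b * c)
  direction <- "none"
  if ((b == 0 || c == 0) && a > 0 && d > 0) {
    direction <- "co-occurring"          # OR diverges upward
  } else if ((a == 0 || d == 0) && b > 0 && c > 0) {
    direction <- "exclusive"             # OR collapses to zero
  } else if (!is.na(or) && or > 1) {
    direction <- "co-occurring"
  } else if (!is.na(or) && or < 1) {
    direction <- "exclusive"
  }
  list(odds_ratio = or, p_value = min(1, p), direction = direction)
}

#' Per-sample driver status flags
#'
#' Derives the canonical driver flags used for co-occurrence testing.
#' Mutation-based flags use only allelic-fraction-filtered (AF >= 0.1 by
#' default, see [af_filter()]) nonsynonymous records; the chromosome-22
#' flag comes from arm calls.
#'
#' @param mutations mutation tibble (will be AF-filtered here).
#' @param arm_calls tibble from [call_arm_events()].
#' @param meta sample metadata.
#' @param canonical_genes non-NF2 driver gene list
#'   (default [canonical_driver_genes()]).
#' @param min_af allelic-fraction filter threshold (default 0.1).
#' @return tibble with columns `sample_id`, `nf2_mutant`, `chr22_loss`,
#'   `canonical_non_nf2`, `tert_promoter`.
#' @export
driver_status <- function(mutations, arm_calls, meta,
                          canonical_genes = canonical_driver_genes(),
                          min_af = 0.1) {
  mut <- af_filter(mutations, min_af = min_af, quiet = TRUE)
  nonsyn <- mut[mut$classification %in% nonsynonymous_classes(), ,
                drop = FALSE]
  loss22 <- chr22_loss(arm_calls)
  tibble::tibble(
    sample_id = meta$sample_id,
    nf2_mutant = vapply(meta$sample_id, function(s) {
      any(nonsyn$sample_id == s & nonsyn$gene == "NF2")
    }, logical(1), USE.NAMES = FALSE),
    chr22_loss = vapply(meta$sample_id, function(s) {
      hit <- loss22$chr22_loss[loss22$sample_id == s]
      if (length(hit) == 0 || is.na(hit[1])) FALSE else hit[1]
    }, logical(1), USE.NAMES = FALSE),
    canonical_non_nf2 = vapply(meta$sample_id, function(s) {
      any(nonsyn$sample_id == s & nonsyn$gene %in% canonical_genes)
    }, logical(1), USE.NAMES = FALSE),
    tert_promoter = vapply(meta$sample_id, function(s) {
      any(mut$sample_id == s & mut$gene == "TERT" &
            mut$classification == "noncoding")
    }, logical(1), USE.NAMES = FALSE)
  )
}

#' Pairwise driver co-occurrence matrix
#'
#' Tests each pair of driver flags with [fisher_association()] and
#' reports the direction of association together with raw p-values and
#' Benjamini-Hochberg q-values.
#'
#' @param statuses tibble from [driver_status()].
#' @param flags names of the logical columns to test pairwise.
#' @return tibble with one row per unordered flag pair: `flag_a`,
#'   `flag_b`, `odds_ratio`, `p_value`, `q_value`, `direction`.
#' @export
cooccurrence_matrix <- function(statuses,
                                flags = c("nf2_mutant", "chr22_loss",
                                          "canonical_non_nf2")) {
  pairs <- utils::combn(flags, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    x <- statuses[[pairs[1, i]]]
    y <- statuses[[pairs[2, i]]]
    ft <- fisher_association(sum(x & y), sum(x & !y),
                             sum(!x & y), sum(!x & !y))
    tibble::tibble(flag_a = pairs[1, i], flag_b = pairs[2, i],
                   odds_ratio = ft$odds_ratio, p_value = ft$p_value,
                   direction = ft$direction)
  })
  out <- dplyr::bind_rows(rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out[, c("flag_a", "flag_b", "odds_ratio", "p_value", "q_value",
          "direction")]
}

#' Binomial detection power
#'
#' Probability of observing at least `k` mutated patients in a cohort of
#' `n` when the true per-patient mutation rate of a gene is `p`:
#' the exact binomial tail `P(X >= k | n, p)`.
#'
#' @param n cohort size (patients).
#' @param k detection threshold (minimum mutated patients).
#' @param p per-patient mutation rate in `[0, 1]`.
#' @return detection power in `[0, 1]`.
#' @export
power_at_rate <- function(n, k, p) {
  if (k <= 0) return(rep(1, length(p)))
  stats::pbinom(k - 1, size = n, prob = p, lower.tail = FALSE)
}

#' Mutation rate detectable at a given power
#'
#' Inverts [power_at_rate()]: finds the per-patient mutation rate at
#' which a gene mutated in at least `k` of `n` patients is detected with
#' probability `target_power`.  The binomial tail is continuous and
#' strictly increasing in `p` for `k >= 1`, so the root is unique; it is
#' located by bisection until the power mismatch falls below `1e-10`.
#'
#' The whole-percent summary is the smallest integer percent at which the
#' target power is reached, i.e. the rate such that genes mutated in "at
#' least that percent" of patients are detected at the target power.
#'
#' @param n cohort size (patients).
#' @param k detection threshold, `k >= 1`.
#' @param target_power target detection probability in (0, 1).
#' @return list with `rate` (exact root) and `percent` (whole-percent
#'   summary).
#' @export
detectable_rate <- function(n, k, target_power) {
  stopifnot(k >= 1, target_power > 0, target_power < 1)
  lo <- 0; hi <- 1
  repeat {
    mid <- (lo + hi) / 2
    pw <- power_at_rate(n, k, mid)
    if (abs(pw - target_power) < 1e-10 || (hi - lo) < 1e-15) break
    if (pw < target_power) lo <- mid else hi <- mid
  }
  pct <- ceiling(mid * 100 - 1e-9)
  if (power_at_rate(n, k, pct / 100) < target_power) pct <- pct + 1
  list(rate = mid, percent = pct)
}
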