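# Arm-level somatic copy-number analysis: percent genome disrupted,
# arm-event calling, chromosome-22-loss detection and cohort incidence.

#' Chromosome arm coordinate tables
#'
#' Loads the chromosome-arm definition table used for arm-level event
#' calling.  `"hg19"` ships cytoband-derived arm boundaries (1-based
#' inclusive, centromeres excluded); `"toy"` is a tiny two-chromosome
#' table used in examples and tests.
#'
#' @param genome `"hg19"` or `"toy"`.
#' @return tibble with columns `chrom`, `arm`, `start`, `end`.
#' @export
load_arms <- function(genome = c("hg19", "toy")) {
  genome <- match.arg(genome)
  path <- system.file("extdata", paste0("arms_", genome, ".tsv"),
                      package = "meningiomics", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    chrom = readr::col_character(),
                    arm = readr::col_character(),
                    start = readr::col_double(),
                    end = readr::col_double()))
}

#' Percent of the autosomal genome disrupted by copy-number alteration
#'
#' The disruption metric is the percentage of the covered autosomal
#' genome whose segment mean departs from copy-neutral by at least
#' `amp_threshold` in absolute log2 ratio:
#' `100 * sum(length of autosomal segments with |log2| >= threshold) /
#' sum(length of all autosomal segments)`.  Sex chromosomes are excluded
#' because cohorts mix sexes.
#'
#' @param segments segment tibble (one sample; see [read_segments()]).
#' @param amp_threshold absolute log2-ratio cutoff for calling a segment
#'   altered (default 0.2).
#' @return disruption as a percentage in `[0, 100]`.
#' @export
percent_genome_disrupted <- function(segments, amp_threshold = 0.2) {
  seg <- segments[segments$chrom %in% autosomes(), , drop = FALSE]
  if (nrow(seg) == 0) {
    stop("no autosomal segments: cannot compute percent genome disrupted",
         call. = FALSE)
  }
  len <- seg$end - seg$start + 1
  altered <- abs(seg$log2_ratio) >= amp_threshold
  100 * sum(len[altered]) / sum(len)
}

#' @keywords internal
arm_overlap_lengths <- function(segments, arm_row, amp_threshold) {
  seg <- segments[segments$chrom == arm_row$chrom, , drop = FALSE]
  if (nrow(seg) == 0) {
    return(c(covered = 0, gain = 0, loss = 0))
  }
  ov_start <- pmax(seg$start, arm_row$start)
  ov_end <- pmin(seg$end, arm_row$end)
  len <- pmax(0, ov_end - ov_start + 1)
  c(covered = sum(len),
    gain = sum(len[seg$log2_ratio >= amp_threshold]),
    loss = sum(len[seg$log2_ratio <= -amp_threshold]))
}

#' Call arm-level copy-number events
#'
#' An arm is called `gain` (`loss`) when at least `frac_threshold` of its
#' covered length carries a segment mean at or above `+amp_threshold`
#' (at or below `-amp_threshold`); otherwise it is `neutral`.  The
#' altered fraction (the larger of the gained and lost fractions) is
#' reported for every arm regardless of call.
#'
#' @param segments segment tibble, possibly spanning several samples.
#' @param arms arm definition table from [load_arms()].
#' @param amp_threshold log2-ratio cutoff (default 0.2).
#' @param frac_threshold minimum altered fraction of covered arm length
#'   for a non-neutral call (default 0.8).
#' @return tibble with one row per sample and arm: `sample_id`, `chrom`,
#'   `arm`, `call`, `altered_fraction`, `covered_bp`.  Arms with no
#'   coverage in a sample are omitted.
#' @export
call_arm_events <- function(segments, arms, amp_threshold = 0.2,
                            frac_threshold = 0.8) {
  samples <- unique(segments$sample_id)
  res <- vector("list", length(samples))
  for (si in seq_along(samples)) {
    seg <- segments[segments$sample_id == samples[si], , drop = FALSE]
    rows <- vector("list", nrow(arms))
    for (ai in seq_len(nrow(arms))) {
      lens <- arm_overlap_lengths(seg, arms[ai, ], amp_threshold)
      if (lens[["covered"]] == 0) next
      gain_frac <- lens[["gain"]] / lens[["covered"]]
      loss_frac <- lens[["loss"]] / lens[["covered"]]
      call <- "neutral"
      if (gain_frac >= frac_threshold && gain_frac >= loss_frac) {
        call <- "gain"
      } else if (loss_frac >= frac_threshold) {
        call <- "loss"
      }
      rows[[ai]] <- tibble::tibble(
        sample_id = samples[si],
        chrom = arms$chrom[ai],
        arm = arms$arm[ai],
        call = call,
        altered_fraction = max(gain_frac, loss_frac),
        covered_bp = lens[["covered"]]
      )
    }
    res[[si]] <- dplyr::bind_rows(rows)
  }
  dplyr::bind_rows(res)
}

#' Chromosome 22 loss status per sample
#'
#' A sample is flagged as chromosome-22-lost when its 22q arm call is
#' `loss`.  Samples without a 22q call (no coverage) are reported `NA`.
#'
#' @param arm_calls tibble from [call_arm_events()].
#' @return tibble with columns `sample_id`, `chr22_loss`.
#' @export
chr22_loss <- function(arm_calls) {
  samples <- unique(arm_calls$sample_id)
  q22 <- arm_calls[arm_calls$chrom == "22" & arm_calls$arm == "q", ,
                   drop = FALSE]
  tibble::tibble(
    sample_id = samples,
    chr22_loss = vapply(samples, function(s) {
      row <- q22[q22$sample_id == s, , drop = FALSE]
      if (nrow(row) == 0) return(NA)
      row$call[1] == "loss"
    }, logical(1), USE.NAMES = FALSE)
  )
}

#' Cohort-level arm gain/loss incidence
#'
#' Percent incidence of gains and losses per arm across a cohort.
#' Histologies with known atypical genomic profiles (angiomatous
#' meningioma by default, which shows frequent broad gains) are excluded
#' from the denominator.
#'
#' @param arm_calls tibble from [call_arm_events()] over the cohort.
#' @param meta sample metadata (see [read_sample_meta()]).
#' @param exclude_histology character vector of histologies to drop.
#' @return tibble ordered by genome position with columns `chrom`, `arm`,
#'   `n_samples`, `gain_pct`, `loss_pct`.
#' @export
arm_incidence <- function(arm_calls, meta,
                          exclude_histology = "angiomatous") {
  keep <- meta$sample_id[!(meta$histology %in% exclude_histology)]
  calls <- arm_calls[arm_calls$sample_id %in% keep, , drop = FALSE]
  if (nrow(calls) == 0) {
    stop("no samples remain after histology exclusion", call. = FALSE)
  }
  chrom_rank <- stats::setNames(seq_along(c(as.character(1:22), "X", "Y")),
                                c(as.character(1:22), "X", "Y"))
  calls |>
    dplyr::group_by(.data$chrom, .data$arm) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      gain_pct = 100 * mean(.data$call == "gain"),
      loss_pct = 100 * mean(.data$call == "loss"),
      .groups = "drop"
    ) |>
    dplyr::arrange(chrom_rank[.data$chrom], .data$arm)
}
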