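# Neoantigen analysis: peptide enumeration, composite median affinity,
# best-epitope selection, binder calling, a simplified cancer cell
# fraction model and the expression filter.

#' Enumerate mutant/wild-type peptide windows
#'
#' For a missense change, returns every window of each requested length
#' that contains the altered residue; windows that would run past either
#' protein terminus are dropped.  For a frameshift, the mutant protein
#' is the wild-type prefix followed by `mut_tail`, every window
#' containing at least one novel residue is returned, and the wild-type
#' peptide is absent (`NA`).  Class I presentation uses lengths 8-11 and
#' class II length 15.
#'
#' @param protein wild-type protein sequence (single string).
#' @param pos 1-based protein position of the first altered residue.
#' @param alt_type `"missense"` or `"frameshift"`.
#' @param mut_residue replacement residue (missense).
#' @param mut_tail novel downstream sequence from `pos` on (frameshift).
#' @param lengths peptide lengths to enumerate.
#' @param hla_alleles optional allele names; windows are replicated per
#'   allele.
#' @return tibble with columns `hla_allele`, `length`, `start` (in the
#'   mutant protein), `mut_peptide`, `wt_peptide`.
#' @export
enumerate_peptides <- function(protein, pos,
                               alt_type = c("missense", "frameshift"),
                               mut_residue = NULL, mut_tail = NULL,
                               lengths = c(8L, 9L, 10L, 11L, 15L),
                               hla_alleles = "HLA-A*02:01") {
  alt_type <- match.arg(alt_type)
  wt <- strsplit(protein, "")[[1]]
  if (pos < 1 || pos > length(wt)) {
    stop("mutation position falls outside the protein", call. = FALSE)
  }
  if (alt_type == "missense") {
    if (is.null(mut_residue) || nchar(mut_residue) != 1) {
      stop("missense requires a single mut_residue", call. = FALSE)
    }
    mut <- wt
    mut[pos] <- mut_residue
    altered <- pos
  } else {
    if (is.null(mut_tail) || nchar(mut_tail) == 0) {
      stop("frameshift requires a nonempty mut_tail", call. = FALSE)
    }
    mut <- c(wt[seq_len(pos - 1)], strsplit(mut_tail, "")[[1]])
    altered <- seq(pos, length(mut))
  }
  rows <- list()
  for (len in lengths) {
    lo <- max(1L, min(altered) - len + 1L)
    hi <- min(max(altered), length(mut) - len + 1L)
    if (hi < lo) next
    for (start in seq(lo, hi)) {
      win <- seq(start, start + len - 1L)
      mut_pep <- paste(mut[win], collapse = "")
      wt_pep <- if (alt_type == "missense" && max(win) <= length(wt)) {
        paste(wt[win], collapse = "")
      } else {
        NA_character_
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        length = len, start = start,
        mut_peptide = mut_pep, wt_peptide = wt_pep)
    }
  }
  windows <- dplyr::bind_rows(rows)
  out <- dplyr::bind_rows(lapply(hla_alleles, function(al) {
    dplyr::mutate(windows, hla_allele = al)
  }))
  out[, c("hla_allele", "length", "start", "mut_peptide", "wt_peptide")]
}

#' Composite binding affinity
#'
#' The composite measure of binding strength across prediction
#' algorithms is the median of the per-predictor affinities (nM); an
#' even count averages the central two.
#'
#' @param affinities numeric vector of per-predictor nM values.
#' @return the median affinity.
#' @export
composite_affinity <- function(affinities) {
  if (length(affinities) == 0) stop("no affinities supplied", call. = FALSE)
  stats::median(affinities)
}

#' Best epitope of a mutation
#'
#' Among all peptide pairs (all HLA alleles and lengths) of one
#' mutation, selects the pair with the minimum mutant composite
#' affinity; ties are broken by lower neoepitope ratio, then by
#' lexicographically smaller mutant peptide, so the choice is
#' deterministic.
#'
#' @param pairs tibble with columns `mut_median`, `ratio`,
#'   `mut_peptide` (one row per peptide pair of a single mutation).
#' @return the selected row (single-row tibble).
#' @export
best_epitope <- function(pairs) {
  if (nrow(pairs) == 0) stop("no peptide pairs supplied", call. = FALSE)
  ord <- order(pairs$mut_median, pairs$ratio, pairs$mut_peptide)
  pairs[ord[1], , drop = FALSE]
}

#' Call neoantigenic mutations
#'
#' A mutation is predicted neoantigenic when its best epitope's mutant
#' composite affinity is at or below `binder_cutoff` nM (500 nM by
#' convention).
#'
#' @param pairs tibble of peptide pairs for many mutations, with a
#'   `mutation_id` column plus `mut_median`, `ratio`, `mut_peptide`.
#' @param binder_cutoff nM threshold (default 500).
#' @return tibble with one row per mutation: `mutation_id`, the best
#'   pair's columns, and `neoantigenic`.
#' @export
call_neoantigens <- function(pairs, binder_cutoff = 500) {
  ids <- unique(pairs$mutation_id)
  best <- dplyr::bind_rows(lapply(ids, function(id) {
    best_epitope(pairs[pairs$mutation_id == id, , drop = FALSE])
  }))
  best$neoantigenic <- best$mut_median <= binder_cutoff
  best
}

#' Per-sample neoantigen burden
#'
#' @param calls tibble from [call_neoantigens()], with `sample_id` and
#'   `mutation_id` columns.
#' @param n_nonsyn named vector or single count of nonsynonymous
#'   mutations per sample, the denominator of the neoantigenic fraction.
#' @return tibble with `sample_id`, `neo_burden`, `neo_fraction`
#'   (`NA` when the denominator is zero).
#' @export
neoantigen_burden <- function(calls, n_nonsyn) {
  samples <- unique(calls$sample_id)
  rows <- lapply(samples, function(s) {
    burden <- sum(calls$neoantigenic[calls$sample_id == s])
    denom <- if (length(n_nonsyn) == 1 && is.null(names(n_nonsyn))) {
      n_nonsyn
    } else {
      unname(n_nonsyn[s])
    }
    tibble::tibble(sample_id = s, neo_burden = burden,
                   neo_fraction = if (!is.na(denom) && denom > 0) {
                     burden / denom
                   } else {
                     NA_real_
                   })
  })
  dplyr::bind_rows(rows)
}

#' Simplified cancer cell fraction estimate
#'
#' Closed-form CCF from the observed allele fraction, tumor purity,
#' local total copy number and mutation multiplicity:
#' `ccf = af * (purity * local_cn + (1 - purity) * 2) /
#' (purity * multiplicity)`, capped at 1 with the pre-cap value kept in
#' `ccf_raw`.  A mutation is clonal when its capped CCF reaches
#' `clonal_cutoff`.
#'
#' @param allele_fraction observed allele fraction(s).
#' @param purity tumor purity in (0, 1].
#' @param local_cn local total copy number (default 2).
#' @param multiplicity mutated-allele copies (default 1).
#' @param clonal_cutoff CCF at or above which a mutation is called
#'   clonal (default 0.9).
#' @return tibble with `ccf_raw`, `ccf` and `clonal`.
#' @export
estimate_ccf <- function(allele_fraction, purity, local_cn = 2,
                         multiplicity = 1, clonal_cutoff = 0.9) {
  if (any(purity <= 0)) stop("purity must be positive", call. = FALSE)
  raw <- allele_fraction * (purity * local_cn + (1 - purity) * 2) /
    (purity * multiplicity)
  ccf <- pmin(raw, 1)
  tibble::tibble(ccf_raw = raw, ccf = ccf, clonal = ccf >= clonal_cutoff)
}

#' Clonality contrast between neoantigenic and other mutations
#'
#' Compares the fraction of clonal mutations between predicted
#' neoantigens and the remaining mutations with Fisher's exact test.
#'
#' @param neoantigenic logical vector, one per mutation.
#' @param clonal logical vector, one per mutation.
#' @return list with `clonal_fraction_neo`, `clonal_fraction_other`,
#'   `odds_ratio`, `p_value`.
#' @export
clonal_neoantigen_contrast <- function(neoantigenic, clonal) {
  stopifnot(length(neoantigenic) == length(clonal))
  a <- sum(neoantigenic & clonal); b <- sum(neoantigenic & !clonal)
  c <- sum(!neoantigenic & clonal); d <- sum(!neoantigenic & !clonal)
  ft <- fisher_association(a, b, c, d)
  list(
    clonal_fraction_neo = if (a + b > 0) a / (a + b) else NA_real_,
    clonal_fraction_other = if (c + d > 0) c / (c + d) else NA_real_,
    odds_ratio = ft$odds_ratio, p_value = ft$p_value
  )
}

#' Expression filter and neoantigen-gene overlap
#'
#' Ranks genes by their cross-sample mean expression, removes the bottom
#' 25% (the floor of `drop_fraction * G` genes; ties at the cutoff are
#' broken by gene-name order), and reports the fraction of
#' neoantigen-bearing genes that remain expressed.
#'
#' @param expression numeric matrix or data frame, genes in rows (row
#'   names are gene symbols), samples in columns.
#' @param neo_genes character vector of genes carrying proposed
#'   neoantigens.
#' @param drop_fraction fraction of lowest-expressed genes removed
#'   (default 0.25).
#' @return list with `retained_genes`, `dropped_genes` and
#'   `overlap_fraction`.
#' @export
expression_filter <- function(expression, neo_genes,
                              drop_fraction = 0.25) {
  mat <- as.matrix(expression)
  if (is.null(rownames(mat))) {
    stop("expression matrix must have gene row names", call. = FALSE)
  }
  means <- rowMeans(mat)
  ord <- order(means, rownames(mat))
  n_drop <- floor(drop_fraction * nrow(mat))
  dropped <- rownames(mat)[ord][seq_len(n_drop)]
  retained <- setdiff(rownames(mat), dropped)
  overlap <- if (length(neo_genes) > 0) {
    length(intersect(unique(neo_genes), retained)) /
      length(unique(neo_genes))
  } else {
    NA_real_
  }
  list(retained_genes = retained, dropped_genes = dropped,
       overlap_fraction = overlap)
}
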