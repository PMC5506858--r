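# Multi-sample heterogeneity: ubiquitous/shared/private partitioning,
# pairwise overlap, discovery curves, detection-power filtering,
# neighbor-joining phylogenies of serial resections and topology calls.

#' Gene-independent mutation identity
#'
#' A mutation is identified across samples by the exact tuple
#' (chrom, pos, ref, alt).
#'
#' @param mutations mutation tibble.
#' @return character vector of keys, one per row.
#' @export
mutation_key <- function(mutations) {
  paste(mutations$chrom, mutations$pos, mutations$ref, mutations$alt,
        sep = ":")
}

#' Sample-by-mutation presence matrix
#'
#' @param mutations mutation tibble for one patient.
#' @param samples sample ids to include as rows; defaults to the samples
#'   present in `mutations`.  Supplying the full resection list ensures
#'   samples with no calls still appear.
#' @return logical matrix, samples x distinct mutation keys.
#' @export
presence_matrix <- function(mutations, samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(mutations$sample_id))
  keys <- sort(unique(mutation_key(mutations)))
  mat <- matrix(FALSE, nrow = length(samples), ncol = length(keys),
                dimnames = list(samples, keys))
  if (nrow(mutations) > 0) {
    k <- mutation_key(mutations)
    ok <- mutations$sample_id %in% samples
    mat[cbind(match(mutations$sample_id[ok], samples), match(k[ok], keys))] <- TRUE
  }
  mat
}

#' Partition a patient's mutations into ubiquitous, shared and private
#'
#' Each distinct mutation is assigned to exactly one category by the
#' number of the patient's samples that carry it: all samples
#' (ubiquitous), more than one but not all (shared), or exactly one
#' (private).  Requires at least two samples; a single-sample patient is
#' flagged unanalyzable.
#'
#' @param mutations mutation tibble for one patient.
#' @param samples optional full sample list (see [presence_matrix()]).
#' @return list with `analyzable`, `n_ubiquitous`, `n_shared`,
#'   `n_private`, `n_total` and the logical `presence` matrix.
#' @export
partition_mutations <- function(mutations, samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(mutations$sample_id))
  if (length(samples) < 2) {
    return(list(analyzable = FALSE, n_ubiquitous = NA_integer_,
                n_shared = NA_integer_, n_private = NA_integer_,
                n_total = NA_integer_, presence = NULL))
  }
  mat <- presence_matrix(mutations, samples)
  counts <- colSums(mat)
  list(
    analyzable = TRUE,
    n_ubiquitous = sum(counts == length(samples)),
    n_shared = sum(counts > 1 & counts < length(samples)),
    n_private = sum(counts == 1),
    n_total = ncol(mat),
    presence = mat
  )
}

#' Pairwise shared-mutation fraction
#'
#' Overlap between two samples' mutation sets.  The default denominator
#' is the union (Jaccard index), which is symmetric and bounded in
#' `[0, 1]`; `"min"` divides by the smaller set and `"first"` by set A.
#'
#' @param keys_a,keys_b character vectors of mutation keys.
#' @param denominator `"union"`, `"min"` or `"first"`.
#' @return shared fraction; `NA` when the denominator is empty.
#' @export
pairwise_shared_fraction <- function(keys_a, keys_b,
                                     denominator = c("union", "min",
                                                     "first")) {
  denominator <- match.arg(denominator)
  a <- unique(keys_a); b <- unique(keys_b)
  inter <- length(intersect(a, b))
  den <- switch(denominator,
                union = length(union(a, b)),
                min = min(length(a), length(b)),
                first = length(a))
  if (den == 0) return(NA_real_)
  inter / den
}

#' Per-patient average shared fraction
#'
#' The overlap of shared mutations over all unordered pairs of a
#' patient's samples, averaged per patient.
#'
#' @param mutations mutation tibble for one patient.
#' @param samples optional full sample list.
#' @param denominator passed to [pairwise_shared_fraction()].
#' @return mean shared fraction over all sample pairs; `NA` for
#'   single-sample patients.
#' @export
per_patient_average <- function(mutations, samples = NULL,
                                denominator = "union") {
  if (is.null(samples)) samples <- sort(unique(mutations$sample_id))
  if (length(samples) < 2) return(NA_real_)
  keys <- lapply(samples, function(s) {
    mutation_key(mutations[mutations$sample_id == s, , drop = FALSE])
  })
  pairs <- utils::combn(length(samples), 2)
  vals <- vapply(seq_len(ncol(pairs)), function(i) {
    pairwise_shared_fraction(keys[[pairs[1, i]]], keys[[pairs[2, i]]],
                             denominator)
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

#' Cumulative event-discovery curve
#'
#' For m = 1..k samples, the expected fraction of all of the patient's
#' distinct events recovered by examining m samples, averaged over every
#' size-m subset of samples.  The curve is monotone nondecreasing and
#' reaches 1 at m = k.
#'
#' @param mutations mutation tibble for one patient (or any table with
#'   `sample_id` plus key columns).
#' @param samples optional full sample list.
#' @return tibble with columns `n_samples` and `fraction`.
#' @export
discovery_curve <- function(mutations, samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(mutations$sample_id))
  mat <- presence_matrix(mutations, samples)
  total <- ncol(mat)
  k <- length(samples)
  fractions <- vapply(seq_len(k), function(m) {
    subsets <- utils::combn(k, m)
    mean(vapply(seq_len(ncol(subsets)), function(i) {
      rows <- mat[subsets[, i], , drop = FALSE]
      sum(colSums(rows) > 0) / total
    }, numeric(1)))
  }, numeric(1))
  tibble::tibble(n_samples = seq_len(k), fraction = fractions)
}

#' Expected clonal allele fraction
#'
#' Expected allele fraction of a clonal (CCF = 1) mutation given tumor
#' purity, local total copy number and mutation multiplicity:
#' `purity * multiplicity / (purity * local_cn + (1 - purity) * 2)`.
#'
#' @param purity tumor purity in (0, 1].
#' @param local_cn local total copy number in the tumor (default 2).
#' @param multiplicity mutated-allele copies (default 1).
#' @return expected allele fraction.
#' @export
expected_clonal_af <- function(purity, local_cn = 2, multiplicity = 1) {
  purity * multiplicity / (purity * local_cn + (1 - purity) * 2)
}

#' Probability of detecting a mutation at a given depth
#'
#' Detection is modeled as observing at least `min_alt` mutant reads
#' from `Binomial(depth, expected_af)`, the standard minimum-alt-read
#' calling heuristic.
#'
#' @param depth sequencing depth at the site.
#' @param expected_af expected allele fraction.
#' @param min_alt minimum alt reads for a call (default 3).
#' @return detection probability.
#' @export
mutation_detection_power <- function(depth, expected_af, min_alt = 3) {
  stats::pbinom(min_alt - 1, size = round(depth), prob = expected_af,
                lower.tail = FALSE)
}

#' Mutations powered for detection in every sample of a patient
#'
#' A mutation enters the phylogeny only if, in every one of the
#' patient's samples, a clonal mutation at that site would be detected
#' with probability at least `power_threshold`.  The expected allele
#' fraction per sample comes from [expected_clonal_af()] using that
#' sample's purity; depth is the observed `t_depth` where the mutation
#' was called and the sample's `mean_coverage` otherwise.
#'
#' @param mutations mutation tibble for one patient.
#' @param meta metadata rows for the patient's samples (needs `purity`
#'   and `mean_coverage`).
#' @param power_threshold minimum per-sample detection power
#'   (default 0.95).
#' @param min_alt minimum alt reads for a call (default 3).
#' @param local_cn,multiplicity passed to [expected_clonal_af()].
#' @return character vector of powered mutation keys.
#' @export
powered_set <- function(mutations, meta, power_threshold = 0.95,
                        min_alt = 3, local_cn = 2, multiplicity = 1) {
  samples <- meta$sample_id
  if (anyNA(meta$purity)) {
    stop("sample purity missing from metadata; detection power needs ",
         "purity for every sample", call. = FALSE)
  }
  keys <- sort(unique(mutation_key(mutations)))
  if (length(keys) == 0) return(character())
  mk <- mutation_key(mutations)
  ok <- vapply(keys, function(key) {
    all(vapply(seq_along(samples), function(si) {
      s <- samples[si]
      hit <- which(mk == key & mutations$sample_id == s)
      depth <- if (length(hit) > 0) {
        mutations$t_depth[hit[1]]
      } else {
        meta$mean_coverage[si]
      }
      af <- expected_clonal_af(meta$purity[si], local_cn, multiplicity)
      mutation_detection_power(depth, af, min_alt) >= power_threshold
    }, logical(1)))
  }, logical(1))
  keys[ok]
}

#' @keywords internal
jaccard_distance_matrix <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      inter <- sum(mat[i, ] & mat[j, ])
      uni <- sum(mat[i, ] | mat[j, ])
      d[i, j] <- d[j, i] <- if (uni == 0) 0 else 1 - inter / uni
    }
  }
  d
}

#' Build a patient phylogeny from shared mutation overlap
#'
#' Pairwise distances between samples are 1 minus the Jaccard index of
#' their mutation sets (restricted to a powered set upstream, see
#' [powered_set()]).  The tree is built by neighbor joining, rooted by
#' an all-absent germline outgroup, and negative NJ branch lengths are
#' clamped to zero.  Samples are ordered lexicographically before
#' joining so the result does not depend on input order.
#'
#' @param presence logical sample-by-mutation matrix
#'   (see [presence_matrix()]).
#' @return list with `tree` (an `ape::phylo`, rooted at `"germline"`)
#'   and `newick` (its Newick text).
#' @export
build_tree <- function(presence) {
  if (nrow(presence) < 2) {
    stop("at least two samples are required to build a tree", call. = FALSE)
  }
  presence <- presence[order(rownames(presence)), , drop = FALSE]
  aug <- rbind(presence, germline = rep(FALSE, ncol(presence)))
  d <- jaccard_distance_matrix(aug)
  tree <- ape::nj(stats::as.dist(d))
  tree$edge.length[tree$edge.length < 0] <- 0
  tree <- ape::root(tree, outgroup = "germline", resolve.root = TRUE)
  list(tree = tree, newick = ape::write.tree(tree))
}

#' Classify recurrence topology from a patient tree
#'
#' Distinguishes linear clonal succession (each recurrence derives from
#' the previously resected tumor, so chronological neighbors are the
#' closest relatives) from branched outgrowth of a geographically
#' heterogeneous primary (closest relatives are chronologically
#' non-adjacent).  For each chronologically consecutive sample pair the
#' pair is scored as adjacent when either member's nearest neighbor(s)
#' in patristic tree distance (ties included, germline excluded)
#' contain the other.  `adjacency_score` is the fraction of consecutive
#' pairs so scored; the call is `linear` when the score is at least 0.5
#' and `branched` otherwise.
#'
#' @param tree rooted `phylo` from [build_tree()].
#' @param chronology sample ids in resection order.
#' @return list with `topology_call` and `adjacency_score`.
#' @export
classify_topology <- function(tree, chronology) {
  stopifnot(length(chronology) >= 2)
  dmat <- ape::cophenetic.phylo(tree)
  leaves <- setdiff(rownames(dmat), "germline")
  if (!all(chronology %in% leaves)) {
    stop("chronology contains samples absent from the tree", call. = FALSE)
  }
  dmat <- dmat[chronology, chronology, drop = FALSE]
  nn <- lapply(seq_along(chronology), function(i) {
    d <- dmat[i, -i]
    names(d)[d <= min(d) + 1e-9]
  })
  names(nn) <- chronology
  adjacent <- vapply(seq_len(length(chronology) - 1), function(r) {
    a <- chronology[r]; b <- chronology[r + 1]
    (b %in% nn[[a]]) || (a %in% nn[[b]])
  }, logical(1))
  score <- mean(adjacent)
  list(topology_call = if (score >= 0.5) "linear" else "branched",
       adjacency_score = score)
}

#' Driver vs passenger sharing across paired assays
#'
#' Builds the 2x2 table of shared/unshared status by driver status
#' across paired assays of the same tumor and tests it with
#' [fisher_association()].
#'
#' @param shared logical vector: was the mutation recovered in both
#'   assays?
#' @param is_driver logical vector: does the mutation hit a driver gene?
#' @return list with the 2x2 `counts` (drivers shared/unshared,
#'   passengers shared/unshared), `odds_ratio` and `p_value`.
#' @export
driver_vs_passenger_overlap <- function(shared, is_driver) {
  if (length(shared) != length(is_driver)) {
    stop("shared and is_driver must have equal length", call. = FALSE)
  }
  if (!any(is_driver)) {
    stop("no driver mutations supplied; check the driver gene list",
         call. = FALSE)
  }
  a <- sum(is_driver & shared); b <- sum(is_driver & !shared)
  c <- sum(!is_driver & shared); d <- sum(!is_driver & !shared)
  ft <- fisher_association(a, b, c, d)
  list(counts = matrix(c(a, b, c, d), 2, byrow = TRUE,
                       dimnames = list(c("driver", "passenger"),
                                       c("shared", "unshared"))),
       odds_ratio = ft$odds_ratio, p_value = ft$p_value)
}
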