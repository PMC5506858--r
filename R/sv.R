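# Rearrangement analysis: linkage of junctions into simple vs complex
# events, composition summaries and repair-mechanism classification.

#' Link rearrangement junctions into event clusters
#'
#' Within each sample, junctions are nodes of a graph with an edge
#' whenever any breakend of one junction lies within `window` bp of any
#' breakend of another on the same chromosome; connected components are
#' the event clusters.  Clusters with at least `min_complex_size` linked
#' junctions are complex events (catastrophic rearrangement such as
#' chromothripsis or chromoplexy); smaller clusters are simple.
#'
#' @param junctions junction tibble (see [read_junctions()]); may span
#'   several samples, which are clustered independently.
#' @param window linkage window in bp (default 10000).
#' @param min_complex_size minimum linked junctions for a complex event
#'   (default 4).
#' @return the input tibble with added columns `cluster_id` (unique
#'   across samples), `cluster_size`, `n_chromosomes` and `complexity`
#'   (`"simple"`/`"complex"`).  Clusters partition each sample's
#'   junctions.
#' @export
link_junctions <- function(junctions, window = 10000,
                           min_complex_size = 4) {
  if (window < 0) stop("window must be nonnegative", call. = FALSE)
  n <- nrow(junctions)
  cluster <- integer(n)
  next_id <- 0L
  for (s in unique(junctions$sample_id)) {
    idx <- which(junctions$sample_id == s)
    comp <- junction_components(junctions[idx, , drop = FALSE], window)
    cluster[idx] <- comp + next_id
    next_id <- next_id + max(comp)
  }
  out <- junctions
  out$cluster_id <- cluster
  sizes <- table(cluster)
  out$cluster_size <- as.integer(sizes[as.character(cluster)])
  out$n_chromosomes <- vapply(cluster, function(cl) {
    rows <- out[out$cluster_id == cl, , drop = FALSE]
    length(unique(c(rows$chromA, rows$chromB)))
  }, integer(1))
  out$complexity <- ifelse(out$cluster_size >= min_complex_size,
                           "complex", "simple")
  out
}

# Union-find over one sample's junctions.  Components are relabeled in
# order of first appearance, so the labels are deterministic for a given
# row order; cluster membership itself is order-invariant.
#' @keywords internal
junction_components <- function(junctions, window) {
  n <- nrow(junctions)
  if (n == 0) return(integer())
  ends <- rbind(
    data.frame(j = seq_len(n), chrom = junctions$chromA,
               pos = junctions$posA),
    data.frame(j = seq_len(n), chrom = junctions$chromB,
               pos = junctions$posB)
  )
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  for (chrom in unique(ends$chrom)) {
    e <- ends[ends$chrom == chrom, , drop = FALSE]
    e <- e[order(e$pos), , drop = FALSE]
    if (nrow(e) < 2) next
    for (i in seq_len(nrow(e) - 1)) {
      # sorted by position: linking each breakend to its successor within
      # the window yields the same components as all-pairs linkage
      if (e$pos[i + 1] - e$pos[i] <= window) {
        ra <- find(e$j[i]); rb <- find(e$j[i + 1])
        if (ra != rb) parent[ra] <- rb
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Rearrangement composition summary
#'
#' Fractions of junctions in each structural class (deletion,
#' duplication, inversion, translocation) overall and within the simple
#' and complex strata, plus per-cluster chromosome counts.  An empty
#' stratum yields `NA` fractions rather than zeros.
#'
#' @param junctions clustered junction tibble from [link_junctions()].
#' @return list with `by_class` (tibble of fractions per stratum),
#'   `clusters` (per-cluster summary) and counts `n_junctions`,
#'   `n_complex_junctions`, `complex_fraction`.
#' @export
composition_stats <- function(junctions) {
  classes <- c("deletion", "duplication", "inversion", "translocation")
  frac <- function(rows) {
    if (nrow(rows) == 0) {
      return(stats::setNames(rep(NA_real_, 4), classes))
    }
    counts <- table(factor(rows$sv_class, levels = classes))
    stats::setNames(as.numeric(counts) / nrow(rows), classes)
  }
  if (nrow(junctions) == 0) {
    by_class <- tibble::tibble(stratum = c("overall", "simple", "complex"),
                               deletion = NA_real_, duplication = NA_real_,
                               inversion = NA_real_,
                               translocation = NA_real_)
    return(list(by_class = by_class, clusters = tibble::tibble(),
                n_junctions = 0L, n_complex_junctions = 0L,
                complex_fraction = NA_real_))
  }
  simple <- junctions[junctions$complexity == "simple", , drop = FALSE]
  complexj <- junctions[junctions$complexity == "complex", , drop = FALSE]
  strata <- list(overall = junctions, simple = simple, complex = complexj)
  by_class <- dplyr::bind_rows(lapply(names(strata), function(nm) {
    tibble::as_tibble(c(list(stratum = nm), as.list(frac(strata[[nm]]))))
  }))
  clusters <- junctions |>
    dplyr::group_by(.data$sample_id, .data$cluster_id) |>
    dplyr::summarise(
      n_junctions = dplyr::n(),
      n_chromosomes = length(unique(c(.data$chromA, .data$chromB))),
      complexity = .data$complexity[1],
      .groups = "drop"
    )
  list(by_class = by_class, clusters = clusters,
       n_junctions = nrow(junctions),
       n_complex_junctions = nrow(complexj),
       complex_fraction = nrow(complexj) / nrow(junctions))
}

#' Classify the repair mechanism of rearrangement junctions
#'
#' Deterministic decision table over the junction-context features,
#' following the conventional microhomology/insertion cuts: a templated
#' insertion of at least `mmbir_min_ins` bp indicates microhomology-
#' mediated break-induced replication (MMBIR); otherwise microhomology
#' of at least `mmej_min_hom` bp indicates microhomology-mediated end
#' joining (MMEJ); otherwise (homology <= 2 bp, insertion < 10 bp)
#' non-homologous end joining (NHEJ).  Junctions with missing features
#' are `unclassified`.
#'
#' @param junctions junction tibble.
#' @param mmej_min_hom minimum microhomology for MMEJ (default 3 bp).
#' @param mmbir_min_ins minimum insertion for MMBIR (default 10 bp).
#' @return character vector of mechanism labels, one per junction.
#' @export
classify_mechanism <- function(junctions, mmej_min_hom = 3,
                               mmbir_min_ins = 10) {
  hom <- junctions$homology_len
  ins <- junctions$insertion_len
  out <- rep("unclassified", nrow(junctions))
  valid <- !is.na(hom) & !is.na(ins) & hom >= 0 & ins >= 0
  out[valid & ins >= mmbir_min_ins] <- "MMBIR"
  out[valid & ins < mmbir_min_ins & hom >= mmej_min_hom] <- "MMEJ"
  out[valid & ins < mmbir_min_ins & hom < mmej_min_hom] <- "NHEJ"
  out
}

#' Cohort mechanism profile
#'
#' Per-group fractions of junctions attributed to each repair mechanism,
#' with the combined MMEJ+NHEJ end-joining fraction also reported.
#'
#' @param junctions junction tibble.
#' @param groups grouping vector (e.g. tumor grade), one value per
#'   junction; a single cohort-wide group by default.
#' @param ... passed to [classify_mechanism()].
#' @return tibble with columns `group`, `n`, `MMEJ`, `NHEJ`, `MMBIR`,
#'   `unclassified`, `mmej_nhej`.
#' @export
mechanism_profile <- function(junctions,
                              groups = rep("all", nrow(junctions)), ...) {
  mech <- classify_mechanism(junctions, ...)
  levels <- c("MMEJ", "NHEJ", "MMBIR", "unclassified")
  rows <- lapply(unique(groups), function(g) {
    m <- mech[groups == g]
    counts <- table(factor(m, levels = levels))
    fr <- as.numeric(counts) / length(m)
    tibble::tibble(group = g, n = length(m),
                   MMEJ = fr[1], NHEJ = fr[2], MMBIR = fr[3],
                   unclassified = fr[4], mmej_nhej = fr[1] + fr[2])
  })
  dplyr::bind_rows(rows)
}
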