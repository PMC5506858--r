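# Synthetic tumor-evolution cohort generator.
#
# Emits cohorts in the same tabular formats the analyses consume
# (mutations, segments, junctions, metadata, affinity and expression
# tables) together with full ground-truth tables: per-mutation clone
# assignment and true CCF per sample, per-junction repair mechanism and
# event membership, per-arm true events and the true clone-tree
# topology.  Everything is deterministic given the config seed.

#' Simulation configuration
#'
#' Builds and validates the configuration driving [simulate_cohort()].
#' Defaults emulate the statistical structure of a high-grade meningioma
#' cohort: a mean of 23 nonsynonymous mutations per grade II-III sample
#' with a C>T-dominated substitution spectrum, high tumor purity,
#' chromosome 22q loss in 56% of samples co-occurring with NF2 mutation
#' (75% of 22q-lost vs 5% of 22q-intact samples carry one), canonical
#' non-NF2 drivers anti-correlated with NF2/22q events, a rearrangement
#' mechanism mixture dominated by end joining (MMEJ 0.45, NHEJ 0.45,
#' MMBIR 0.10), and lognormal peptide affinities calibrated so 66% of
#' mutations are binders at 500 nM.
#'
#' @param n_patients number of patients.
#' @param samples_per_patient regions/serial resections per patient.
#' @param clones_per_patient clones in single-sample patients'
#'   phylogenies (multi-sample patients get one dominant clone per
#'   sample plus, for branched topologies, a founder).
#' @param topology `"linear"`, `"branched"` or `"random"` (per-patient
#'   coin flip).
#' @param burden_mean_by_grade mean total mutation count per sample by
#'   grade.
#' @param mutations_per_clone optional Poisson mean of mutations per
#'   clone, overriding the burden-derived allocation.
#' @param private_per_sample Poisson mean of subclonal sample-private
#'   passenger mutations.
#' @param grade_probs sampling probabilities of grades I/II/III.
#' @param purity_range uniform range of tumor purity.
#' @param coverage_mean mean sequencing depth (reads).
#' @param dominant_ccf cancer cell fraction of the dominant clone's own
#'   mutations.
#' @param spectrum_weights six pyrimidine-context substitution weights.
#' @param mechanism_mixture probabilities over MMEJ/NHEJ/MMBIR; must sum
#'   to 1.
#' @param simple_sv_rate Poisson mean of isolated junctions per sample.
#' @param complex_event_rate Poisson mean of complex events per sample.
#' @param complex_size_mean mean junctions per complex event (>= 4).
#' @param chr22_loss_rate probability of chromosome 22q loss per
#'   patient.
#' @param nf2_given_loss,nf2_given_no_loss probability of an NF2
#'   mutation given 22q status.
#' @param canonical_given_driver,canonical_given_none probability of a
#'   canonical non-NF2 driver given presence/absence of an NF2/22q
#'   event.
#' @param arm_rates tibble of per-arm gain/loss probabilities
#'   (default [default_arm_rates()]); 22q is handled by
#'   `chr22_loss_rate`.
#' @param p_binder probability that a mutation's best epitope binds at
#'   500 nM.
#' @param n_genes size of the gene universe for the expression matrix.
#' @param p_expressed fraction of neoantigen-bearing genes placed above
#'   the bottom-quartile expression cutoff.
#' @param seed integer RNG seed.
#' @return validated `sim_config` list.
#' @export
sim_config <- function(n_patients = 10,
                       samples_per_patient = 1,
                       clones_per_patient = 3,
                       topology = c("random", "linear", "branched"),
                       burden_mean_by_grade = c(I = 7, II = 23, III = 23),
                       mutations_per_clone = NULL,
                       private_per_sample = 3,
                       grade_probs = c(I = 0.2, II = 0.6, III = 0.2),
                       purity_range = c(0.8, 0.99),
                       coverage_mean = 100,
                       dominant_ccf = 1,
                       spectrum_weights = c("C>A" = 0.08, "C>G" = 0.06,
                                            "C>T" = 0.45, "T>A" = 0.07,
                                            "T>C" = 0.26, "T>G" = 0.08),
                       mechanism_mixture = c(MMEJ = 0.45, NHEJ = 0.45,
                                             MMBIR = 0.10),
                       simple_sv_rate = 5,
                       complex_event_rate = 0.4,
                       complex_size_mean = 8,
                       chr22_loss_rate = 0.56,
                       nf2_given_loss = 0.75,
                       nf2_given_no_loss = 0.05,
                       canonical_given_driver = 0.02,
                       canonical_given_none = 0.35,
                       arm_rates = default_arm_rates(),
                       p_binder = 0.66,
                       n_genes = 400,
                       p_expressed = 0.76,
                       seed = 1L) {
  topology <- match.arg(topology)
  cfg <- list(
    n_patients = n_patients, samples_per_patient = samples_per_patient,
    clones_per_patient = clones_per_patient, topology = topology,
    burden_mean_by_grade = burden_mean_by_grade,
    mutations_per_clone = mutations_per_clone,
    private_per_sample = private_per_sample,
    grade_probs = grade_probs, purity_range = purity_range,
    coverage_mean = coverage_mean, dominant_ccf = dominant_ccf,
    spectrum_weights = spectrum_weights,
    mechanism_mixture = mechanism_mixture,
    simple_sv_rate = simple_sv_rate,
    complex_event_rate = complex_event_rate,
    complex_size_mean = complex_size_mean,
    chr22_loss_rate = chr22_loss_rate,
    nf2_given_loss = nf2_given_loss,
    nf2_given_no_loss = nf2_given_no_loss,
    canonical_given_driver = canonical_given_driver,
    canonical_given_none = canonical_given_none,
    arm_rates = arm_rates,
    p_binder = p_binder, n_genes = n_genes, p_expressed = p_expressed,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
}

#' @keywords internal
validate_sim_config <- function(cfg) {
  if (abs(sum(cfg$mechanism_mixture) - 1) > 1e-8) {
    stop("mechanism_mixture must sum to 1", call. = FALSE)
  }
  rates <- c(cfg$simple_sv_rate, cfg$complex_event_rate,
             cfg$chr22_loss_rate, cfg$arm_rates$gain_rate,
             cfg$arm_rates$loss_rate)
  if (any(rates < 0)) stop("all rates must be >= 0", call. = FALSE)
  if (cfg$complex_size_mean < 4) {
    stop("complex_size_mean must be >= 4", call. = FALSE)
  }
  if (any(cfg$purity_range <= 0) || any(cfg$purity_range > 1)) {
    stop("purity_range must lie in (0, 1]", call. = FALSE)
  }
  if (is.null(cfg$mutations_per_clone) &&
      any(cfg$burden_mean_by_grade < cfg$clones_per_patient)) {
    stop("impossible config: more clones than expected mutations ",
         "per sample", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Default per-arm alteration rates
#'
#' Gain/loss probabilities per chromosome arm reflecting the recurrent
#' arm events of high-grade meningioma: frequent losses of 1p, 6q, 10q,
#' 14q and 18q, gains of 17q and 20q, and a low background rate
#' elsewhere.  Chromosome 22q is governed separately by the
#' `chr22_loss_rate` config field.
#'
#' @return tibble with columns `chrom`, `arm`, `gain_rate`, `loss_rate`.
#' @export
default_arm_rates <- function() {
  arms <- expand.grid(chrom = as.character(1:22), arm = c("p", "q"),
                      stringsAsFactors = FALSE)
  arms <- arms[order(as.integer(arms$chrom), arms$arm), ]
  out <- tibble::tibble(chrom = arms$chrom, arm = arms$arm,
                        gain_rate = 0.01, loss_rate = 0.02)
  set_rate <- function(df, chrom, arm, gain, loss) {
    i <- df$chrom == chrom & df$arm == arm
    df$gain_rate[i] <- gain; df$loss_rate[i] <- loss
    df
  }
  out <- set_rate(out, "1", "p", 0.01, 0.25)
  out <- set_rate(out, "6", "q", 0.01, 0.15)
  out <- set_rate(out, "10", "q", 0.01, 0.15)
  out <- set_rate(out, "14", "q", 0.01, 0.12)
  out <- set_rate(out, "18", "q", 0.01, 0.15)
  out <- set_rate(out, "17", "q", 0.10, 0.01)
  out <- set_rate(out, "20", "q", 0.10, 0.01)
  out <- set_rate(out, "22", "p", 0.00, 0.00)
  out <- set_rate(out, "22", "q", 0.00, 0.00)
  out
}

#' Draw sequencing counts for a mutation
#'
#' Inverts the simplified CCF model: the expected allele fraction is
#' `true_ccf * purity * multiplicity /
#' (purity * local_cn + (1 - purity) * 2)` and the alt count is drawn
#' binomially at that fraction from the given depth.
#'
#' @param true_ccf true cancer cell fraction in `[0, 1]`.
#' @param purity tumor purity in (0, 1].
#' @param local_cn local total copy number; must be positive when
#'   `true_ccf > 0`.
#' @param depth sequencing depth (reads, >= 1).
#' @param multiplicity mutated-allele copies (default 1).
#' @return list with `t_alt_count`, `t_depth` and `expected_af`.
#' @export
sample_allele_fraction <- function(true_ccf, purity, local_cn, depth,
                                   multiplicity = 1) {
  if (purity <= 0 || purity > 1) stop("purity must be in (0, 1]",
                                      call. = FALSE)
  if (depth < 1) stop("depth must be >= 1", call. = FALSE)
  if (local_cn == 0 && true_ccf > 0) {
    stop("local copy number 0 with nonzero CCF", call. = FALSE)
  }
  af <- true_ccf * purity * multiplicity /
    (purity * local_cn + (1 - purity) * 2)
  list(t_alt_count = stats::rbinom(1, depth, af),
       t_depth = as.integer(depth), expected_af = af)
}

#' Draw junction-context features for a repair mechanism
#'
#' Generator decision table mirroring the classifier cuts: MMEJ
#' junctions carry 3-20 bp of microhomology and no insertion; NHEJ
#' junctions carry at most 2 bp of homology or a templated insertion
#' below 10 bp (never both); MMBIR junctions carry an insertion of at
#' least 10 bp.
#'
#' @param mechanism character vector over MMEJ/NHEJ/MMBIR.
#' @return tibble with `homology_len` and `insertion_len`, one row per
#'   mechanism.
#' @export
simulate_junction_features <- function(mechanism) {
  n <- length(mechanism)
  hom <- integer(n); ins <- integer(n)
  for (i in seq_len(n)) {
    if (mechanism[i] == "MMEJ") {
      hom[i] <- sample(3:20, 1)
    } else if (mechanism[i] == "NHEJ") {
      if (stats::runif(1) < 0.6) {
        hom[i] <- sample(0:2, 1)
      } else {
        ins[i] <- sample(0:9, 1)
      }
    } else if (mechanism[i] == "MMBIR") {
      ins[i] <- 10L + stats::rpois(1, 8)
    } else {
      stop("unknown mechanism: ", mechanism[i], call. = FALSE)
    }
  }
  tibble::tibble(homology_len = hom, insertion_len = ins)
}

# ---- internal helpers ------------------------------------------------

# clone tree of one patient: returns list(parent, dominant) where
# dominant[r] is the dominant clone of resection r
#' @keywords internal
make_clone_tree <- function(n_samples, n_clones, topology) {
  if (n_samples == 1) {
    parent <- c(0L, seq_len(max(n_clones - 1, 0)))
    return(list(parent = parent, dominant = length(parent),
                topology = "linear"))
  }
  if (topology == "linear") {
    parent <- c(0L, seq_len(n_samples - 1))
    list(parent = parent, dominant = seq_len(n_samples),
         topology = "linear")
  } else {
    # founder plus two sibling lineages; successive resections alternate
    # between lineages (outgrowth of geographically distinct subclones)
    parent <- integer(n_samples + 1)
    parent[1] <- 0L
    dominant <- integer(n_samples)
    lastA <- 1L; lastB <- 1L
    for (r in seq_len(n_samples)) {
      clone <- r + 1L
      if (r %% 2 == 1) {
        parent[clone] <- lastA; lastA <- clone
      } else {
        parent[clone] <- lastB; lastB <- clone
      }
      dominant[r] <- clone
    }
    list(parent = parent, dominant = dominant, topology = "branched")
  }
}

#' @keywords internal
clone_ancestry <- function(parent, clone) {
  path <- clone
  while (parent[clone] != 0L) {
    clone <- parent[clone]
    path <- c(clone, path)
  }
  path
}

# draw ref/alt pair from the six-class pyrimidine spectrum, presenting
# half of the draws on the purine strand
#' @keywords internal
draw_substitution <- function(n, weights) {
  classes <- names(weights)
  pick <- sample(classes, n, replace = TRUE, prob = weights)
  ref <- substr(pick, 1, 1)
  alt <- substr(pick, 3, 3)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  flip <- stats::runif(n) < 0.5
  tibble::tibble(ref = ifelse(flip, comp[ref], ref),
                 alt = ifelse(flip, comp[alt], alt))
}

# isolated position at least margin bp from previously used positions;
# NULL when the chromosome is saturated
#' @keywords internal
place_isolated <- function(occupied, chrom, chrom_len, margin = 1e7,
                           tries = 50) {
  used <- occupied[[chrom]]
  for (i in seq_len(tries)) {
    pos <- round(stats::runif(1, margin, chrom_len - margin))
    if (is.null(used) || all(abs(used - pos) > margin)) return(pos)
  }
  NULL
}

# draw a chromosome together with an isolated position, retrying over
# chromosomes when one is saturated
#' @keywords internal
pick_chrom_pos <- function(occupied, chrom_len, margin = 1e7,
                           exclude = character()) {
  pool <- setdiff(autosomes(), exclude)
  for (i in 1:300) {
    ch <- sample(pool, 1)
    pos <- place_isolated(occupied, ch, chrom_len[[ch]], margin)
    if (!is.null(pos)) return(list(chrom = ch, pos = pos))
  }
  stop("could not place an isolated breakend on any chromosome",
       call. = FALSE)
}

#' Simulate a synthetic meningioma cohort
#'
#' Generates a full cohort under the configured tumor-evolution model:
#' per-patient clone trees (linear clonal succession or branched
#' outgrowth of sibling lineages), per-clone mutations carried along
#' ancestries without back-mutation (infinite-sites, multiplicity 1),
#' purity- and depth-driven allele fractions with a 3-alt-read
#' detection threshold, arm-level copy-number events assigned to clones
#' (22q loss coupled to NF2 status), clustered complex and isolated
#' simple rearrangement junctions with mechanism-dependent
#' microhomology/insertion features, lognormal peptide-affinity tables
#' and a gene-expression matrix.
#'
#' @param config a [sim_config()] object.
#' @return list with tibbles `mutations`, `segments`, `junctions`,
#'   `meta`, `affinities`, `expression` (matrix), and `truth`, a list of
#'   ground-truth tables (`mutation_truth`, `arm_truth`,
#'   `junction_truth`, `clone_trees`, `patients`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  arms <- load_arms("hg19")
  chrom_len <- tapply(arms$end, arms$chrom, max)

  mut_rows <- list(); seg_rows <- list(); jx_rows <- list()
  meta_rows <- list(); mtruth_rows <- list(); atruth_rows <- list()
  jtruth_rows <- list(); tree_rows <- list(); pat_rows <- list()
  event_counter <- 0L

  for (pi in seq_len(config$n_patients)) {
    pid <- sprintf("P%03d", pi)
    grade <- sample(names(config$grade_probs), 1,
                    prob = config$grade_probs)
    purity <- stats::runif(1, config$purity_range[1],
                           config$purity_range[2])
    n_samples <- config$samples_per_patient
    topo <- if (config$topology == "random") {
      sample(c("linear", "branched"), 1)
    } else {
      config$topology
    }
    n_clones <- if (n_samples == 1) config$clones_per_patient else NA
    tree <- make_clone_tree(n_samples, n_clones, topo)
    n_clones <- length(tree$parent)

    # driver structure
    loss22 <- stats::runif(1) < config$chr22_loss_rate
    nf2 <- stats::runif(1) < if (loss22) config$nf2_given_loss else
      config$nf2_given_no_loss
    canonical <- stats::runif(1) <
      if (nf2 || loss22) config$canonical_given_driver else
        config$canonical_given_none

    # per-clone mutations
    # burden_mean_by_grade targets the NONSYNONYMOUS count; scale the
    # total so that thinning by the nonsynonymous class probability
    # leaves a Poisson with the configured mean
    nonsyn_frac <- 0.78
    mu_clone <- if (!is.null(config$mutations_per_clone)) {
      config$mutations_per_clone
    } else {
      config$burden_mean_by_grade[[grade]] / nonsyn_frac / n_clones
    }
    n_per_clone <- stats::rpois(n_clones, mu_clone)
    clone_of <- rep(seq_len(n_clones), n_per_clone)
    n_mut <- length(clone_of)
    sub <- draw_substitution(n_mut, config$spectrum_weights)
    muts <- tibble::tibble(
      mut_idx = seq_len(n_mut),
      clone = clone_of,
      chrom = sample(as.character(1:22), n_mut, replace = TRUE),
      pos = 1e6L + sample.int(190000000L, n_mut),
      ref = sub$ref, alt = sub$alt,
      classification = sample(
        c("missense", "nonsense", "splice_site", "frameshift_indel",
          "inframe_indel", "silent", "noncoding"),
        n_mut, replace = TRUE,
        prob = c(0.58, 0.05, 0.05, 0.07, 0.03, 0.15, 0.07)),
      gene = sprintf("GENE%04d", sample(seq_len(2000), n_mut,
                                        replace = TRUE))
    )
    if (nf2) {
      muts <- dplyr::bind_rows(muts, tibble::tibble(
        mut_idx = n_mut + 1L, clone = 1L, chrom = "22",
        pos = 29999544L + sample.int(95045L, 1), ref = "C", alt = "T",
        classification = sample(c("frameshift_indel", "nonsense",
                                  "splice_site"), 1),
        gene = "NF2"))
    }
    if (canonical) {
      muts <- dplyr::bind_rows(muts, tibble::tibble(
        mut_idx = nrow(muts) + 1L, clone = 1L,
        chrom = sample(as.character(1:20), 1),
        pos = 1e6L + sample.int(190000000L, 1), ref = "G", alt = "A",
        classification = "missense",
        gene = sample(c("TRAF7", "KLF4", "AKT1", "SMO"), 1)))
    }

    # arm events assigned to clones (22q loss on the founder)
    events <- list()
    if (loss22) {
      events[[1]] <- tibble::tibble(chrom = "22", arm = "q",
                                    event = "loss", clone = 1L)
    }
    for (ai in seq_len(nrow(config$arm_rates))) {
      r <- config$arm_rates[ai, ]
      u <- stats::runif(1)
      ev <- if (u < r$loss_rate) "loss"
      else if (u < r$loss_rate + r$gain_rate) "gain"
      else NA_character_
      if (!is.na(ev)) {
        cl <- if (stats::runif(1) < 0.7 || n_clones == 1) 1L else
          sample(2:n_clones, 1)
        events[[length(events) + 1]] <-
          tibble::tibble(chrom = r$chrom, arm = r$arm, event = ev,
                         clone = cl)
      }
    }
    events <- dplyr::bind_rows(events)

    pat_rows[[pi]] <- tibble::tibble(
      patient_id = pid, grade = grade, purity = purity,
      topology = tree$topology, chr22_loss = loss22, nf2_mutant = nf2,
      canonical_non_nf2 = canonical)
    tree_rows[[pi]] <- tibble::tibble(
      patient_id = pid, clone = seq_len(n_clones),
      parent = tree$parent, topology = tree$topology)

    # per-sample emission
    for (r in seq_len(n_samples)) {
      sid <- sprintf("%s_S%d", pid, r)
      dom <- tree$dominant[r]
      anc <- clone_ancestry(tree$parent, dom)
      meta_rows[[length(meta_rows) + 1]] <- tibble::tibble(
        sample_id = sid, patient_id = pid, resection_index = r,
        grade = grade, histology = "fibroblastic",
        radiation_status = sample(c("naive", "radiation_induced",
                                    "post_adjuvant_RT"), 1,
                                  prob = c(0.7, 0.15, 0.15)),
        purity = purity, ploidy = 2,
        mean_coverage = config$coverage_mean)

      sample_arm_events <- if (nrow(events) > 0) {
        events[events$clone %in% anc, , drop = FALSE]
      } else {
        events
      }
      if (nrow(sample_arm_events) > 0) {
        atruth_rows[[length(atruth_rows) + 1]] <- tibble::tibble(
          sample_id = sid, chrom = sample_arm_events$chrom,
          arm = sample_arm_events$arm, event = sample_arm_events$event)
      }

      # segments: every autosomal arm, split into 1-3 segments
      sc <- list(chrom = character(), start = numeric(),
                 end = numeric(), log2 = numeric())
      for (ai in seq_len(nrow(arms))) {
        if (!(arms$chrom[ai] %in% autosomes())) next
        hit <- nrow(sample_arm_events) > 0 &&
          any(sample_arm_events$chrom == arms$chrom[ai] &
                sample_arm_events$arm == arms$arm[ai])
        base <- if (!hit) stats::rnorm(1, 0, 0.03) else {
          ev <- sample_arm_events$event[
            sample_arm_events$chrom == arms$chrom[ai] &
              sample_arm_events$arm == arms$arm[ai]][1]
          if (ev == "loss") stats::rnorm(1, -0.6, 0.05) else
            stats::rnorm(1, 0.45, 0.05)
        }
        n_seg <- sample(1:3, 1)
        cuts <- sort(unique(c(arms$start[ai] - 1,
                              if (n_seg > 1) round(stats::runif(
                                n_seg - 1, arms$start[ai],
                                arms$end[ai])),
                              arms$end[ai])))
        starts <- cuts[-length(cuts)] + 1
        ends <- cuts[-1]
        keep <- ends >= starts
        sc$chrom <- c(sc$chrom, rep(arms$chrom[ai], sum(keep)))
        sc$start <- c(sc$start, starts[keep])
        sc$end <- c(sc$end, ends[keep])
        sc$log2 <- c(sc$log2,
                     round(base + stats::rnorm(sum(keep), 0, 0.02), 4))
      }
      seg_rows[[length(seg_rows) + 1]] <- tibble::tibble(
        sample_id = sid, chrom = sc$chrom, start = sc$start,
        end = sc$end,
        n_probes = pmax(10L, as.integer((sc$end - sc$start) / 1e5)),
        log2_ratio = sc$log2)

      # mutations: clones on the dominant ancestry, plus sample-private
      # subclonal passengers
      present <- muts[muts$clone %in% anc, , drop = FALSE]
      ccf <- ifelse(present$clone == dom & length(anc) > 1,
                    config$dominant_ccf, 1)
      n_priv <- stats::rpois(1, config$private_per_sample)
      if (n_priv > 0) {
        subp <- draw_substitution(n_priv, config$spectrum_weights)
        priv <- tibble::tibble(
          mut_idx = max(muts$mut_idx, 0L) + 1000L * r + seq_len(n_priv),
          clone = NA_integer_,
          chrom = sample(as.character(1:22), n_priv, replace = TRUE),
          pos = 1e6L + sample.int(190000000L, n_priv),
          ref = subp$ref, alt = subp$alt,
          classification = sample(
            c("missense", "silent", "noncoding"), n_priv,
            replace = TRUE, prob = c(0.7, 0.2, 0.1)),
          gene = sprintf("GENE%04d", sample(seq_len(2000), n_priv,
                                            replace = TRUE)))
        present <- dplyr::bind_rows(present, priv)
        ccf <- c(ccf, stats::runif(n_priv, 0.3, 0.7))
      }
      if (nrow(present) > 0) {
        local_cn <- ifelse(present$chrom == "22" & loss22, 1L, 2L)
        depth <- pmax(1L, stats::rpois(nrow(present),
                                       config$coverage_mean))
        af <- ccf * purity / (purity * local_cn + (1 - purity) * 2)
        alt_count <- stats::rbinom(nrow(present), depth, af)
        detected <- alt_count >= 3
        mtruth_rows[[length(mtruth_rows) + 1]] <- tibble::tibble(
          patient_id = pid, sample_id = sid,
          chrom = present$chrom, pos = present$pos,
          ref = present$ref, alt = present$alt,
          clone = present$clone, true_ccf = ccf,
          expected_af = af, detected = detected)
        if (any(detected)) {
          mut_rows[[length(mut_rows) + 1]] <- tibble::tibble(
            sample_id = sid, patient_id = pid,
            gene = present$gene[detected],
            chrom = present$chrom[detected],
            pos = present$pos[detected],
            ref = present$ref[detected], alt = present$alt[detected],
            classification = present$classification[detected],
            t_alt_count = alt_count[detected],
            t_depth = depth[detected],
            allele_fraction = alt_count[detected] / depth[detected])
        }
      }

      # rearrangement junctions
      occupied <- list()
      reserve <- function(chrom, pos) {
        occupied[[chrom]] <<- c(occupied[[chrom]], pos)
      }
      emit_junction <- function(cA, pA, sA, cB, pB, sB, mech, event_id,
                                complex) {
        feat <- simulate_junction_features(mech)
        cls <- if (cA != cB) "translocation" else
          sv_class_from_strands(sA, sB)
        jx_rows[[length(jx_rows) + 1]] <<- list(
          sample_id = sid, chromA = cA, posA = as.integer(pA),
          strandA = sA, chromB = cB, posB = as.integer(pB),
          strandB = sB, sv_class = cls,
          homology_len = feat$homology_len,
          insertion_len = feat$insertion_len,
          repeatA = stats::runif(1) < 0.15,
          repeatB = stats::runif(1) < 0.15)
        jtruth_rows[[length(jtruth_rows) + 1]] <<- list(
          sample_id = sid, mechanism = mech, event_id = event_id,
          complex = complex)
      }
      n_complex <- stats::rpois(1, config$complex_event_rate)
      for (ei in seq_len(n_complex)) {
        event_counter <- event_counter + 1L
        size <- 4L + stats::rpois(1, config$complex_size_mean - 4)
        n_chr <- max(1L, min(size, 6L, 1L + stats::rpois(1, 3)))
        cs <- character(0)
        cursor <- numeric(0)
        for (ci in seq_len(n_chr)) {
          hit <- pick_chrom_pos(occupied, chrom_len, exclude = cs)
          occupied[[hit$chrom]] <- c(occupied[[hit$chrom]], hit$pos,
                                     hit$pos + 1.2e6)
          cs <- c(cs, hit$chrom)
          cursor[hit$chrom] <- hit$pos
        }
        advance <- function(ch) {
          cursor[ch] <<- cursor[ch] + round(stats::runif(1, 100, 8000))
          cursor[ch]
        }
        mechs <- sample(names(config$mechanism_mixture), size,
                        replace = TRUE, prob = config$mechanism_mixture)
        for (j in seq_len(size)) {
          cA <- cs[(j - 1) %% n_chr + 1]; cB <- cs[j %% n_chr + 1]
          emit_junction(cA, advance(cA), sample(c("+", "-"), 1),
                        cB, advance(cB), sample(c("+", "-"), 1),
                        mechs[j], event_counter, TRUE)
        }
      }
      n_simple <- stats::rpois(1, config$simple_sv_rate)
      for (ji in seq_len(n_simple)) {
        event_counter <- event_counter + 1L
        mech <- sample(names(config$mechanism_mixture), 1,
                       prob = config$mechanism_mixture)
        if (stats::runif(1) < 0.21) {
          hitA <- pick_chrom_pos(occupied, chrom_len)
          reserve(hitA$chrom, hitA$pos)
          hitB <- pick_chrom_pos(occupied, chrom_len,
                                 exclude = hitA$chrom)
          reserve(hitB$chrom, hitB$pos)
          emit_junction(hitA$chrom, hitA$pos, sample(c("+", "-"), 1),
                        hitB$chrom, hitB$pos, sample(c("+", "-"), 1),
                        mech, event_counter, FALSE)
        } else {
          hit <- pick_chrom_pos(occupied, chrom_len)
          ch <- hit$chrom; pA <- hit$pos
          reserve(ch, pA)
          span <- round(stats::runif(1, 5e4, 2e6))
          reserve(ch, pA + span)
          cls <- sample(c("deletion", "duplication", "inversion"), 1,
                        prob = c(0.45, 0.2, 0.35))
          strands <- switch(cls,
                            deletion = c("+", "-"),
                            duplication = c("-", "+"),
                            inversion = sample(list(c("+", "+"),
                                                    c("-", "-")), 1)[[1]])
          emit_junction(ch, pA, strands[1], ch, pA + span, strands[2],
                        mech, event_counter, FALSE)
        }
      }
    }
  }

  mutations <- dplyr::bind_rows(mut_rows)
  meta <- dplyr::bind_rows(meta_rows)
  truth <- list(
    mutation_truth = dplyr::bind_rows(mtruth_rows),
    arm_truth = dplyr::bind_rows(atruth_rows),
    junction_truth = dplyr::bind_rows(jtruth_rows),
    clone_trees = dplyr::bind_rows(tree_rows),
    patients = dplyr::bind_rows(pat_rows)
  )

  # peptide affinities for detected nonsynonymous mutations
  nonsyn <- mutations[mutations$classification %in%
                        nonsynonymous_classes(), , drop = FALSE]
  mut_ids <- unique(paste(nonsyn$sample_id, mutation_key(nonsyn),
                          sep = "|"))
  aff <- simulate_affinities(mut_ids, p_binder = config$p_binder)
  aff$affinities$sample_id <-
    sub("\\|.*$", "", aff$affinities$mutation_id)

  # expression matrix over the gene universe, with neoantigen genes
  # placed above/below the bottom-quartile cutoff
  binder_genes <- unique(nonsyn$gene[
    paste(nonsyn$sample_id, mutation_key(nonsyn), sep = "|") %in%
      aff$truth$mutation_id[aff$truth$true_binder]])
  expression <- simulate_expression(config$n_genes, binder_genes,
                                    p_expressed = config$p_expressed)

  list(mutations = mutations,
       segments = dplyr::bind_rows(seg_rows),
       junctions = dplyr::bind_rows(jx_rows),
       meta = meta,
       affinities = aff$affinities,
       expression = expression,
       truth = c(truth, list(affinity_truth = aff$truth)))
}

#' Simulate peptide-affinity tables
#'
#' Fabricates per-predictor binding affinities for each mutation:
#' the best epitope's mutant composite affinity is drawn from a
#' lognormal calibrated so that a fraction `p_binder` of mutations bind
#' at `binder_cutoff` nM; decoy pairs receive strictly larger medians.
#' Per-predictor values are scaled multiplicative jitter around each
#' pair's median (so the recomputed composite equals the drawn median
#' exactly), and wild-type medians are the mutant median divided by a
#' lognormal neoepitope ratio.
#'
#' @param mutation_ids character vector of mutation identifiers.
#' @param p_binder target binder fraction at the cutoff.
#' @param binder_cutoff nM cutoff defining a binder (default 500).
#' @param sdlog lognormal spread of best-epitope affinities.
#' @param n_decoys additional non-best pairs per mutation.
#' @param n_predictors predictors feeding each composite median.
#' @return list with `affinities` (long tibble: `mutation_id`,
#'   `hla_allele`, `length`, `mut_peptide`, `wt_peptide`, per-predictor
#'   columns, `mut_median`, `wt_median`, `ratio`) and `truth`
#'   (`mutation_id`, `best_median`, `true_binder`).
#' @export
simulate_affinities <- function(mutation_ids, p_binder = 0.66,
                                binder_cutoff = 500, sdlog = 1.5,
                                n_decoys = 3, n_predictors = 5) {
  meanlog <- log(binder_cutoff) - stats::qnorm(p_binder) * sdlog
  n <- length(mutation_ids)
  alleles <- c("HLA-A*02:01", "HLA-B*07:02")
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  n_pairs_per <- 1L + n_decoys
  np <- n * n_pairs_per

  best <- stats::rlnorm(n, meanlog, sdlog)
  # pair medians: column 1 is the best epitope, decoys strictly larger
  medians <- matrix(0, nrow = n, ncol = n_pairs_per)
  medians[, 1] <- best
  if (n_decoys > 0) {
    medians[, -1] <- best * exp(matrix(stats::runif(n * n_decoys,
                                                    0.2, 3), n))
  }
  m <- as.vector(t(medians))
  id <- rep(mutation_ids, each = n_pairs_per)
  len <- sample(c(8L, 9L, 10L, 11L, 15L), np, replace = TRUE)
  ratio <- stats::rlnorm(np, 0, 0.5)
  wt <- m / ratio

  # predictor values: multiplicative jitter rescaled so the row median
  # equals the drawn pair median exactly
  jitter_scaled <- function(target) {
    f <- matrix(stats::rlnorm(np * n_predictors, 0, 0.4), nrow = np)
    f / apply(f, 1, stats::median) * target
  }
  vals <- jitter_scaled(m)
  colnames(vals) <- paste0("predictor_", seq_len(n_predictors))

  mut_pep <- vapply(len, function(l) {
    paste(sample(aa, l, replace = TRUE), collapse = "")
  }, character(1))
  wt_pep <- mut_pep
  for (i in seq_len(np)) {
    p <- sample.int(len[i], 1)
    substr(wt_pep[i], p, p) <- sample(setdiff(aa,
                                              substr(mut_pep[i], p, p)),
                                      1)
  }

  affinities <- tibble::tibble(
    mutation_id = id,
    hla_allele = sample(alleles, np, replace = TRUE),
    length = len, mut_peptide = mut_pep, wt_peptide = wt_pep,
    mut_median = m, wt_median = wt, ratio = m / wt)
  affinities <- dplyr::bind_cols(affinities, tibble::as_tibble(vals))
  list(affinities = affinities,
       truth = tibble::tibble(mutation_id = mutation_ids,
                              best_median = best,
                              true_binder = best <= binder_cutoff))
}

#' Simulate a gene-expression matrix
#'
#' Lognormal per-gene mean expression with per-sample multiplicative
#' noise.  Genes carrying proposed neoantigens are placed above the
#' bottom-quartile cutoff with probability `p_expressed`, so the
#' expression-filter overlap is recoverable against truth.
#'
#' @param n_genes total genes (filler genes are added around the
#'   neoantigen genes).
#' @param neo_genes gene symbols carrying neoantigens.
#' @param n_samples expression-profile count.
#' @param p_expressed probability a neoantigen gene lands above the
#'   bottom-quartile cutoff.
#' @param drop_fraction fraction removed by the expression filter.
#' @return numeric matrix (genes x samples) with gene row names.
#' @export
simulate_expression <- function(n_genes, neo_genes, n_samples = 8,
                                p_expressed = 0.76,
                                drop_fraction = 0.25) {
  neo_genes <- unique(neo_genes)
  filler <- setdiff(sprintf("FILLER%04d", seq_len(n_genes)), neo_genes)
  genes <- c(neo_genes, filler)
  g <- length(genes)
  means <- sort(stats::rlnorm(g, 5, 1))  # ascending
  n_drop <- floor(drop_fraction * g)
  low_slots <- seq_len(n_drop)
  high_slots <- seq(n_drop + 1, g)
  slot <- rep(NA_integer_, g)
  free_low <- low_slots; free_high <- high_slots
  for (i in seq_along(neo_genes)) {
    if (stats::runif(1) < p_expressed && length(free_high) > 0) {
      k <- free_high[sample.int(length(free_high), 1)]
      free_high <- setdiff(free_high, k)
    } else {
      k <- free_low[sample.int(length(free_low), 1)]
      free_low <- setdiff(free_low, k)
    }
    slot[i] <- k
  }
  slot[is.na(slot)] <- sample(c(free_low, free_high))
  gene_means <- means[slot]
  mat <- matrix(gene_means, nrow = g, ncol = n_samples) *
    matrix(stats::rlnorm(g * n_samples, 0, 0.1), nrow = g)
  rownames(mat) <- genes
  colnames(mat) <- sprintf("EXPR_S%02d", seq_len(n_samples))
  mat
}

#' Write a simulated cohort to standard-format files
#'
#' Writes the mutation, segment, junction and metadata tables in their
#' interchange formats plus the affinity, expression and truth tables
#' as TSV.
#'
#' @param cohort list from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mutations(cohort$mutations, file.path(dir, "mutations.tsv"))
  write_segments(cohort$segments, file.path(dir, "segments.seg"))
  write_junctions(cohort$junctions, file.path(dir, "junctions.bedpe"))
  write_sample_meta(cohort$meta, file.path(dir, "sample_meta.tsv"))
  readr::write_tsv(cohort$affinities, file.path(dir, "affinities.tsv"))
  expr <- tibble::as_tibble(cohort$expression, rownames = "gene")
  readr::write_tsv(expr, file.path(dir, "expression.tsv"))
  for (nm in names(cohort$truth)) {
    readr::write_tsv(cohort$truth[[nm]],
                     file.path(dir, paste0("truth_", nm, ".tsv")))
  }
  invisible(dir)
}
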