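# End-to-end orchestration: run every analysis stage over a cohort and
# emit a report directory of TSVs mirroring the figure-level statistics.

#' @keywords internal
config_hash <- function(params) {
  rlang::hash(params)
}

#' @keywords internal
write_report_tsv <- function(df, path, hash) {
  version <- as.character(utils::packageVersion("meningiomics"))
  header <- sprintf("# meningiomics %s config=%s", version, hash)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run all analyses over a cohort
#'
#' Orchestrates the full downstream pipeline: burden and spectrum,
#' percent genome disrupted and arm-level events, driver status and
#' co-occurrence, detection power, multi-sample heterogeneity and
#' phylogeny for patients with two or more samples, rearrangement
#' clustering and mechanism profile, and neoantigen calling.  Each
#' stage failure aborts with the stage name.  Every output file starts
#' with a comment line naming the package version and the configuration
#' hash, and the run is deterministic for a given cohort and parameter
#' set.
#'
#' @param cohort list with `mutations`, `segments`, `junctions`, `meta`
#'   and optionally `affinities` (e.g. from [simulate_cohort()] or
#'   assembled from the readers).
#' @param out_dir report directory, created if needed.
#' @param params named list of stage parameter overrides:
#'   `min_af`, `amp_threshold`, `frac_threshold`, `window`,
#'   `min_complex_size`, `binder_cutoff`, `power_n`, `power_k`,
#'   `genome`.
#' @return invisibly, a list of the stage result tables (also written
#'   under `out_dir`).
#' @export
run_all <- function(cohort, out_dir, params = list()) {
  defaults <- list(min_af = 0.1, amp_threshold = 0.2,
                   frac_threshold = 0.8, window = 10000,
                   min_complex_size = 4, binder_cutoff = 500,
                   power_n = 115, power_k = 15, genome = "hg19")
  params <- utils::modifyList(defaults, params)
  hash <- config_hash(params)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  res <- list()

  res$burden <- stage("burden", burden_table(cohort$mutations))
  write_report_tsv(res$burden, file.path(out_dir, "burden.tsv"), hash)

  res$disruption <- stage("scna", {
    samples <- unique(cohort$segments$sample_id)
    tibble::tibble(
      sample_id = samples,
      percent_disrupted = vapply(samples, function(s) {
        percent_genome_disrupted(
          cohort$segments[cohort$segments$sample_id == s, ],
          params$amp_threshold)
      }, numeric(1)))
  })
  arms <- load_arms(params$genome)
  res$arm_calls <- stage("scna", call_arm_events(
    cohort$segments, arms, params$amp_threshold, params$frac_threshold))
  res$arm_incidence <- stage("scna", arm_incidence(
    res$arm_calls, cohort$meta))
  write_report_tsv(res$disruption, file.path(out_dir, "disruption.tsv"),
                   hash)
  write_report_tsv(res$arm_calls, file.path(out_dir, "arm_calls.tsv"),
                   hash)
  write_report_tsv(res$arm_incidence,
                   file.path(out_dir, "arm_incidence.tsv"), hash)

  res$driver_status <- stage("assoc", driver_status(
    cohort$mutations, res$arm_calls, cohort$meta,
    min_af = params$min_af))
  res$cooccurrence <- stage("assoc",
                            cooccurrence_matrix(res$driver_status))
  pw95 <- detectable_rate(params$power_n, params$power_k, 0.95)
  pw50 <- detectable_rate(params$power_n, params$power_k, 0.50)
  res$power <- tibble::tibble(
    n = params$power_n, k = params$power_k,
    target_power = c(0.95, 0.50),
    rate = c(pw95$rate, pw50$rate),
    percent = c(pw95$percent, pw50$percent))
  write_report_tsv(res$driver_status,
                   file.path(out_dir, "driver_status.tsv"), hash)
  write_report_tsv(res$cooccurrence,
                   file.path(out_dir, "cooccurrence.tsv"), hash)
  write_report_tsv(res$power, file.path(out_dir, "power.tsv"), hash)

  res$heterogeneity <- stage("het", {
    multi <- cohort$meta |>
      dplyr::count(.data$patient_id) |>
      dplyr::filter(.data$n >= 2)
    if ("purity" %in% names(cohort$meta) &&
        anyNA(cohort$meta$purity[cohort$meta$patient_id %in%
                                   multi$patient_id])) {
      stop("purity missing for multi-sample patient(s); supply purity ",
           "in the sample metadata")
    }
    rows <- lapply(multi$patient_id, function(pid) {
      meta_p <- cohort$meta[cohort$meta$patient_id == pid, ]
      mut_p <- cohort$mutations[cohort$mutations$patient_id == pid, ]
      part <- partition_mutations(mut_p, meta_p$sample_id)
      keys <- powered_set(mut_p, meta_p)
      mut_pow <- mut_p[mutation_key(mut_p) %in% keys, , drop = FALSE]
      topo <- NA_character_; score <- NA_real_; newick <- NA_character_
      if (length(keys) > 0 && nrow(meta_p) >= 2) {
        pres <- presence_matrix(mut_pow, meta_p$sample_id)
        bt <- build_tree(pres)
        chron <- meta_p$sample_id[order(meta_p$resection_index)]
        cl <- classify_topology(bt$tree, chron)
        topo <- cl$topology_call; score <- cl$adjacency_score
        newick <- bt$newick
      }
      tibble::tibble(
        patient_id = pid, n_samples = nrow(meta_p),
        n_ubiquitous = part$n_ubiquitous, n_shared = part$n_shared,
        n_private = part$n_private,
        shared_fraction = per_patient_average(mut_p, meta_p$sample_id),
        n_powered = length(keys), topology_call = topo,
        adjacency_score = score, newick = newick)
    })
    dplyr::bind_rows(rows)
  })
  if (nrow(res$heterogeneity) > 0) {
    write_report_tsv(res$heterogeneity,
                     file.path(out_dir, "heterogeneity.tsv"), hash)
    writeLines(stats::na.omit(res$heterogeneity$newick),
               file.path(out_dir, "trees.nwk"))
  }

  res$sv <- stage("sv", {
    if (nrow(cohort$junctions) > 0) {
      linked <- link_junctions(cohort$junctions, params$window,
                               params$min_complex_size)
      comp <- composition_stats(linked)
      grade_of <- stats::setNames(cohort$meta$grade,
                                  cohort$meta$sample_id)
      mech <- mechanism_profile(linked,
                                groups = grade_of[linked$sample_id])
      list(linked = linked, composition = comp, mechanisms = mech)
    } else {
      list(linked = cohort$junctions,
           composition = composition_stats(
             dplyr::mutate(cohort$junctions, complexity = character())),
           mechanisms = tibble::tibble())
    }
  })
  if (nrow(res$sv$linked) > 0) {
    write_report_tsv(res$sv$linked, file.path(out_dir, "sv_clusters.tsv"),
                     hash)
    write_report_tsv(res$sv$composition$by_class,
                     file.path(out_dir, "sv_composition.tsv"), hash)
    write_report_tsv(res$sv$mechanisms,
                     file.path(out_dir, "sv_mechanisms.tsv"), hash)
  }

  res$neoantigens <- stage("neo", {
    if (is.null(cohort$affinities) || nrow(cohort$affinities) == 0) {
      NULL
    } else {
      calls <- call_neoantigens(cohort$affinities,
                                params$binder_cutoff)
      if (!"sample_id" %in% names(calls)) {
        calls$sample_id <- sub("\\|.*$", "", calls$mutation_id)
      }
      nonsyn <- vapply(
        unique(calls$sample_id),
        function(s) nonsyn_burden(cohort$mutations, s), integer(1))
      neoantigen_burden(calls, nonsyn)
    }
  })
  if (!is.null(res$neoantigens)) {
    write_report_tsv(res$neoantigens,
                     file.path(out_dir, "neoantigens.tsv"), hash)
  }

  res$summary <- stage("summary", {
    per_grade <- cohort$meta |>
      dplyr::left_join(res$burden, by = "sample_id") |>
      dplyr::left_join(res$disruption, by = "sample_id") |>
      dplyr::group_by(.data$grade) |>
      dplyr::summarise(
        n_samples = dplyr::n(),
        mean_nonsyn_burden = mean(.data$n_nonsyn, na.rm = TRUE),
        mean_percent_disrupted = mean(.data$percent_disrupted,
                                      na.rm = TRUE),
        .groups = "drop")
    per_grade
  })
  write_report_tsv(res$summary, file.path(out_dir, "summary.tsv"), hash)

  invisible(res)
}
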