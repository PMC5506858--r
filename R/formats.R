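# Tabular formats and record validation.
#
# All coordinates are 1-based inclusive internally.  BEDPE, which is 0-based
# half-open, is converted at the boundary on read and write.  Chromosome
# names are normalized by stripping any "chr" prefix; autosomes 1-22 plus
# X and Y are accepted.

#' Mutation classification vocabulary
#'
#' Somatic calls are normalized to a fixed seven-level classification.
#' "Nonsynonymous" comprises the protein-altering classes: missense,
#' nonsense, splice_site, frameshift_indel and inframe_indel; silent and
#' noncoding changes are excluded.
#'
#' @return `mutation_classes()` returns all seven class labels;
#'   `nonsynonymous_classes()` the protein-altering subset.
#' @export
mutation_classes <- function() {
  c("missense", "nonsense", "splice_site", "frameshift_indel",
    "inframe_indel", "silent", "noncoding")
}

#' @rdname mutation_classes
#' @export
nonsynonymous_classes <- function() {
  c("missense", "nonsense", "splice_site", "frameshift_indel",
    "inframe_indel")
}

#' Normalize chromosome names
#'
#' Strips a leading "chr" prefix and validates against autosomes 1-22 and
#' the sex chromosomes X and Y.
#'
#' @param chrom character vector of chromosome names.
#' @return character vector of normalized names.
#' @export
normalize_chrom <- function(chrom) {
  out <- sub("^chr", "", as.character(chrom))
  ok <- out %in% c(as.character(1:22), "X", "Y")
  if (!all(ok)) {
    stop("unrecognized chromosome name(s): ",
         paste(unique(out[!ok]), collapse = ", "), call. = FALSE)
  }
  out
}

#' @keywords internal
autosomes <- function() as.character(1:22)

# Map common MAF-style variant classification spellings onto the internal
# vocabulary.  Unknown labels are an error rather than silently coerced.
#' @keywords internal
normalize_classification <- function(x) {
  key <- tolower(gsub("[ _']", "", as.character(x)))
  map <- c(
    missense = "missense", missensemutation = "missense",
    nonsense = "nonsense", nonsensemutation = "nonsense",
    nonstopmutation = "nonsense",
    splicesite = "splice_site",
    frameshiftindel = "frameshift_indel", frameshiftdel = "frameshift_indel",
    frameshiftins = "frameshift_indel",
    inframeindel = "inframe_indel", inframedel = "inframe_indel",
    inframeins = "inframe_indel",
    silent = "silent", synonymous = "silent",
    noncoding = "noncoding", intron = "noncoding", utr3 = "noncoding",
    utr5 = "noncoding", igr = "noncoding", rna = "noncoding",
    "3utr" = "noncoding", "5utr" = "noncoding"
  )
  out <- unname(map[key])
  if (anyNA(out)) {
    stop("unrecognized mutation classification(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  out
}

#' @keywords internal
check_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("file '", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

#' Read a somatic mutation table
#'
#' Reads a MAF-like tab-separated table of somatic SNV/indel calls, one row
#' per mutation per sample.  Required columns: `sample_id`, `patient_id`,
#' `gene`, `chrom`, `pos`, `ref`, `alt`, `classification`, `t_alt_count`,
#' `t_depth`.  The allele fraction is recomputed as
#' `t_alt_count / t_depth`; rows with `t_alt_count > t_depth` raise a
#' validation error naming the offending line.
#'
#' @param path path to a tab-separated file with a header line.
#' @return a tibble of validated mutation records with an
#'   `allele_fraction` column.
#' @export
read_mutations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  check_columns(df, c("sample_id", "patient_id", "gene", "chrom", "pos",
                      "ref", "alt", "classification", "t_alt_count",
                      "t_depth"), path)
  df$pos <- as.integer(df$pos)
  df$t_alt_count <- as.integer(df$t_alt_count)
  df$t_depth <- as.integer(df$t_depth)
  validate_mutations(
    tibble::tibble(
      sample_id = df$sample_id,
      patient_id = df$patient_id,
      gene = df$gene,
      chrom = normalize_chrom(df$chrom),
      pos = df$pos,
      ref = df$ref,
      alt = df$alt,
      classification = normalize_classification(df$classification),
      t_alt_count = df$t_alt_count,
      t_depth = df$t_depth
    )
  )
}

#' Validate mutation records
#'
#' Enforces the record invariants (`t_alt_count <= t_depth`, `pos >= 1`)
#' and (re)computes `allele_fraction`.  Data rows are never silently
#' dropped: a violation is an error carrying the 1-based data row number.
#'
#' @param df tibble with the mutation columns (see [read_mutations()]).
#' @return the validated tibble with `allele_fraction` populated.
#' @export
validate_mutations <- function(df) {
  bad <- which(df$t_alt_count > df$t_depth)
  if (length(bad) > 0) {
    stop("t_alt_count exceeds t_depth at data row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(df$pos < 1)) {
    stop("pos must be >= 1 at data row(s): ",
         paste(which(df$pos < 1), collapse = ", "), call. = FALSE)
  }
  if (any(df$t_depth < 0) || any(df$t_alt_count < 0)) {
    stop("read counts must be nonnegative", call. = FALSE)
  }
  df$allele_fraction <- ifelse(df$t_depth > 0,
                               df$t_alt_count / df$t_depth, NA_real_)
  tibble::as_tibble(df)
}

#' Write a somatic mutation table
#'
#' @param mutations tibble as returned by [read_mutations()].
#' @param path output path; a tab-separated UTF-8 file with a header line.
#' @return `path`, invisibly.
#' @export
write_mutations <- function(mutations, path) {
  cols <- c("sample_id", "patient_id", "gene", "chrom", "pos", "ref", "alt",
            "classification", "t_alt_count", "t_depth", "allele_fraction")
  readr::write_tsv(mutations[, cols], path)
  invisible(path)
}

#' Read a segmented copy-number (SEG) file
#'
#' Expects tab-separated columns `sample_id`, `chrom`, `start`, `end`,
#' `n_probes`, `log2_ratio` (the classic SEG headers `ID`, `loc.start`,
#' `loc.end`, `num.mark`, `seg.mean` are accepted as aliases).  Segments
#' are sorted per sample and chromosome and checked for overlap; start and
#' end are 1-based inclusive.
#'
#' @param path path to a SEG-format file.
#' @return a tibble of segment records.
#' @export
read_segments <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  aliases <- c(ID = "sample_id", Sample = "sample_id", chromosome = "chrom",
               loc.start = "start", loc.end = "end", num.mark = "n_probes",
               seg.mean = "log2_ratio")
  hit <- names(df) %in% names(aliases)
  names(df)[hit] <- aliases[names(df)[hit]]
  check_columns(df, c("sample_id", "chrom", "start", "end", "n_probes",
                      "log2_ratio"), path)
  out <- tibble::tibble(
    sample_id = df$sample_id,
    chrom = if (nrow(df) > 0) normalize_chrom(df$chrom) else character(),
    start = as.numeric(df$start),
    end = as.numeric(df$end),
    n_probes = as.integer(df$n_probes),
    log2_ratio = as.numeric(df$log2_ratio)
  )
  validate_segments(out)
}

#' Validate copy-number segments
#'
#' Checks `start <= end` and that segments of one sample on one chromosome
#' do not overlap; returns the segments sorted by sample, chromosome and
#' start.
#'
#' @param df tibble with segment columns.
#' @return sorted, validated tibble.
#' @export
validate_segments <- function(df) {
  if (any(df$start > df$end)) {
    stop("segment start > end at data row(s): ",
         paste(which(df$start > df$end), collapse = ", "), call. = FALSE)
  }
  df <- dplyr::arrange(tibble::as_tibble(df), .data$sample_id,
                       .data$chrom, .data$start)
  grp <- split(seq_len(nrow(df)), paste(df$sample_id, df$chrom))
  for (idx in grp) {
    if (length(idx) < 2) next
    s <- df$start[idx]; e <- df$end[idx]
    ov <- which(s[-1] <= e[-length(e)])
    if (length(ov) > 0) {
      i <- idx[ov[1]]; j <- idx[ov[1] + 1]
      stop(sprintf(
        "overlapping segments for sample %s chrom %s: [%d,%d] and [%d,%d]",
        df$sample_id[i], df$chrom[i], df$start[i], df$end[i],
        df$start[j], df$end[j]), call. = FALSE)
    }
  }
  df
}

#' Write a segmented copy-number file
#'
#' @param segments tibble as returned by [read_segments()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  cols <- c("sample_id", "chrom", "start", "end", "n_probes", "log2_ratio")
  readr::write_tsv(segments[, cols], path)
  invisible(path)
}

# Strand-pair decision table for intrachromosomal junction classes.
#' @keywords internal
sv_class_from_strands <- function(strandA, strandB) {
  dplyr::case_when(
    strandA == "+" & strandB == "-" ~ "deletion",
    strandA == "-" & strandB == "+" ~ "duplication",
    TRUE ~ "inversion"
  )
}

#' Read rearrangement junctions (BEDPE)
#'
#' Reads a BEDPE table with the junction-context extension columns
#' `HOMLEN` (bp of breakpoint microhomology), `INSLEN` (bp of templated
#' junction insertion), `REPEAT_A`/`REPEAT_B` (repeat-element overlap
#' flags), plus `sample_id`.  BEDPE coordinates are 0-based half-open and
#' are converted to 1-based breakend positions on ingest
#' (`posA = start1 + 1`).  When the optional `SVCLASS` column is absent,
#' interchromosomal junctions are translocations and intrachromosomal
#' classes follow the strand pair: +/- deletion-type, -/+
#' duplication-type, +/+ or -/- inversion-type.
#'
#' @param path path to the BEDPE file.
#' @return a tibble of junction records with columns `sample_id`,
#'   `chromA`, `posA`, `strandA`, `chromB`, `posB`, `strandB`, `sv_class`,
#'   `homology_len`, `insertion_len`, `repeatA`, `repeatB`.
#' @export
read_junctions <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  check_columns(df, c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                      "strand1", "strand2", "HOMLEN", "INSLEN",
                      "REPEAT_A", "REPEAT_B", "sample_id"), path)
  out <- tibble::tibble(
    sample_id = df$sample_id,
    chromA = if (nrow(df) > 0) normalize_chrom(df$chrom1) else character(),
    posA = as.integer(df$start1) + 1L,
    strandA = df$strand1,
    chromB = if (nrow(df) > 0) normalize_chrom(df$chrom2) else character(),
    posB = as.integer(df$start2) + 1L,
    strandB = df$strand2,
    sv_class = if ("SVCLASS" %in% names(df)) df$SVCLASS else NA_character_,
    homology_len = as.integer(df$HOMLEN),
    insertion_len = as.integer(df$INSLEN),
    repeatA = as.logical(toupper(df$REPEAT_A)),
    repeatB = as.logical(toupper(df$REPEAT_B))
  )
  validate_junctions(out)
}

#' Validate junction records
#'
#' Derives missing `sv_class` values from the chromosome pair and strand
#' orientation, and enforces the record invariants: a junction is a
#' translocation exactly when its breakends lie on different chromosomes,
#' and microhomology and templated insertion are mutually exclusive
#' (`homology_len` and `insertion_len` cannot both be positive).
#'
#' @param df tibble with junction columns.
#' @return validated tibble.
#' @export
validate_junctions <- function(df) {
  df <- tibble::as_tibble(df)
  inter <- df$chromA != df$chromB
  derived <- ifelse(inter, "translocation",
                    sv_class_from_strands(df$strandA, df$strandB))
  df$sv_class <- ifelse(is.na(df$sv_class), derived, df$sv_class)
  bad <- which((df$sv_class == "translocation") != inter)
  if (length(bad) > 0) {
    stop("sv_class inconsistent with chromosome pair at data row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  both <- which(df$homology_len > 0 & df$insertion_len > 0)
  if (length(both) > 0) {
    stop("homology_len and insertion_len both positive at data row(s): ",
         paste(both, collapse = ", "), call. = FALSE)
  }
  if (any(df$homology_len < 0, na.rm = TRUE) ||
      any(df$insertion_len < 0, na.rm = TRUE)) {
    stop("junction feature lengths must be nonnegative", call. = FALSE)
  }
  df
}

#' Write rearrangement junctions (BEDPE)
#'
#' Inverse of [read_junctions()]: 1-based breakend positions are converted
#' back to 0-based half-open BEDPE intervals of width 1.
#'
#' @param junctions tibble as returned by [read_junctions()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_junctions <- function(junctions, path) {
  out <- tibble::tibble(
    chrom1 = junctions$chromA,
    start1 = junctions$posA - 1L,
    end1 = junctions$posA,
    chrom2 = junctions$chromB,
    start2 = junctions$posB - 1L,
    end2 = junctions$posB,
    name = sprintf("junction_%d", seq_len(nrow(junctions))),
    score = ".",
    strand1 = junctions$strandA,
    strand2 = junctions$strandB,
    SVCLASS = junctions$sv_class,
    HOMLEN = junctions$homology_len,
    INSLEN = junctions$insertion_len,
    REPEAT_A = junctions$repeatA,
    REPEAT_B = junctions$repeatB,
    sample_id = junctions$sample_id
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read sample/patient metadata
#'
#' Tab-separated table with columns `sample_id`, `patient_id`,
#' `resection_index` (chronological, unique within patient), `grade`
#' (I/II/III), `histology`, `radiation_status` (naive, radiation_induced,
#' post_adjuvant_RT), `purity` in (0,1], `ploidy`, `mean_coverage`.
#'
#' @param path path to the metadata file.
#' @return a validated tibble.
#' @export
read_sample_meta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  check_columns(df, c("sample_id", "patient_id", "resection_index", "grade",
                      "histology", "radiation_status", "purity", "ploidy",
                      "mean_coverage"), path)
  out <- tibble::tibble(
    sample_id = df$sample_id,
    patient_id = df$patient_id,
    resection_index = as.integer(df$resection_index),
    grade = df$grade,
    histology = df$histology,
    radiation_status = df$radiation_status,
    purity = as.numeric(df$purity),
    ploidy = as.numeric(df$ploidy),
    mean_coverage = as.numeric(df$mean_coverage)
  )
  validate_sample_meta(out)
}

#' Validate sample metadata
#'
#' @param df tibble with metadata columns.
#' @return the validated tibble.
#' @export
validate_sample_meta <- function(df) {
  if (any(df$purity <= 0 | df$purity > 1)) {
    stop("purity must lie in (0, 1]", call. = FALSE)
  }
  if (!all(df$grade %in% c("I", "II", "III"))) {
    stop("grade must be one of I, II, III", call. = FALSE)
  }
  if (!all(df$radiation_status %in%
           c("naive", "radiation_induced", "post_adjuvant_RT"))) {
    stop("unrecognized radiation_status value(s)", call. = FALSE)
  }
  dup <- df |>
    dplyr::count(.data$patient_id, .data$resection_index) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("resection_index not unique within patient: ",
         paste(dup$patient_id, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Write sample metadata
#'
#' @param meta tibble as returned by [read_sample_meta()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_meta <- function(meta, path) {
  cols <- c("sample_id", "patient_id", "resection_index", "grade",
            "histology", "radiation_status", "purity", "ploidy",
            "mean_coverage")
  readr::write_tsv(meta[, cols], path)
  invisible(path)
}
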