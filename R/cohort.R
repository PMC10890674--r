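# Validated-variant table parsing, PolyPhen-2 triage, and the per-cohort
# summary tables (mutation counts, patient and chromosome distributions,
# damage-class tallies).

CHROM_LEVELS <- c(as.character(1:22), "X")
PP2_CLASSES <- c("probably_damaging", "possibly_damaging", "benign")

#' Study cohort sizes and patient counts
#'
#' The per-cohort constants of the three-cohort schizophrenia trio study
#' this package ships a validated-variant fixture for: number of analysed
#' trio families, and the number of patients carrying exactly one versus
#' two or more validated de novo mutations. These printed counts are
#' needed for the patient-distribution table because the variant fixture
#' carries no patient identifiers.
#'
#' @return A tibble with columns `cohort`, `n_families`,
#'   `n_patients_with_1`, `n_patients_with_2plus`.
#' @export
sz_cohort_families <- function() {
  tibble(
    cohort = c("Algerian", "French", "Japanese"),
    n_families = c(75L, 45L, 61L),
    n_patients_with_1 = c(27L, 14L, 19L),
    n_patients_with_2plus = c(3L, 3L, 6L))
}

#' Path to the packaged validated de novo variant table
#'
#' A tab-separated table of 88 Sanger-validated de novo mutations from
#' three schizophrenia trio cohorts (Algerian, French, Japanese):
#' cohort, gene, chromosome, position, the three trio genotypes, and the
#' PolyPhen-2 score and predicted class.
#'
#' @return Path to the TSV file.
#' @export
sz_variant_fixture <- function() {
  system.file("extdata", "sz_trio_denovo_variants.tsv", package = "trionet",
              mustWork = TRUE)
}

normalize_chromosome <- function(x) {
  sub("^chr", "", trimws(x))
}

normalize_position <- function(x) {
  suppressWarnings(as.integer(sub("^chr[0-9XYM]+:", "", trimws(x))))
}

normalize_pp2_class <- function(x) {
  gsub(" ", "_", trimws(tolower(x)))
}

#' Read a validated trio-variant table
#'
#' Parses a tab-separated variant table with columns Cohort, Gene,
#' Chromosome, Position, Father, Mother, Patient, PPH2 Score, PPH2
#' Prediction (an optional Patient ID column is carried through).
#' Chromosome labels are normalized (`"chr10"` and `"10"` are the same
#' chromosome) and positions may be plain integers or `"chr5:102489584"`
#' style locus strings. Rows failing validation (malformed genotypes,
#' scores outside \[0, 1\], unknown chromosome) are dropped with a warning
#' naming their line numbers; a missing column is an error.
#'
#' @param path Path to the TSV file (lines starting with `#` are
#'   comments). Defaults to the packaged fixture.
#' @return A tibble with columns `cohort`, `gene`, `chromosome`,
#'   `position`, `father`, `mother`, `patient`, `pph2_score`,
#'   `pph2_class` (underscore-normalized).
#' @export
#' @examples
#' variants <- read_variant_table()
#' nrow(variants)  # 88
read_variant_table <- function(path = sz_variant_fixture()) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         comment = "#", progress = FALSE)
  names(raw) <- tolower(gsub("[ .]+", "_", trimws(names(raw))))
  required <- c("cohort", "gene", "chromosome", "position", "father",
                "mother", "patient", "pph2_score", "pph2_prediction")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    abort(sprintf("Variant table lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (nrow(raw) == 0L) {
    return(tibble(cohort = character(0), gene = character(0),
                  chromosome = character(0), position = integer(0),
                  father = character(0), mother = character(0),
                  patient = character(0), pph2_score = numeric(0),
                  pph2_class = character(0)))
  }
  out <- tibble(
    cohort = trimws(raw$cohort),
    gene = trimws(raw$gene),
    chromosome = normalize_chromosome(raw$chromosome),
    position = normalize_position(raw$position),
    father = trimws(raw$father),
    mother = trimws(raw$mother),
    patient = trimws(raw$patient),
    pph2_score = suppressWarnings(as.numeric(raw$pph2_score)),
    pph2_class = normalize_pp2_class(raw$pph2_prediction))
  if ("patient_id" %in% names(raw)) out$patient_id <- trimws(raw$patient_id)

  gt_ok <- function(x) grepl("^[ACGT]/[ACGT]$", x)
  valid <- out$chromosome %in% CHROM_LEVELS &
    !is.na(out$position) & out$position >= 1 &
    gt_ok(out$father) & gt_ok(out$mother) & gt_ok(out$patient) &
    !is.na(out$pph2_score) & out$pph2_score >= 0 & out$pph2_score <= 1 &
    out$pph2_class %in% PP2_CLASSES
  if (any(!valid)) {
    warn(sprintf("Dropped %d malformed row(s) at line(s): %s",
                 sum(!valid),
                 paste(which(!valid) + 1L, collapse = ", ")))
    out <- out[valid, ]
  }
  out
}

#' Triage PolyPhen-2 scores into damage classes
#'
#' Scores strictly above `t_probably` are `probably_damaging`, scores in
#' `(t_benign, t_probably]` are `possibly_damaging`, and the rest are
#' `benign`. The default cut points (0.94 and 0.446) reproduce the class
#' boundaries observed in the packaged validated-variant table (0.947 is
#' probably damaging while 0.929 is possibly; 0.478 is possibly while
#' 0.414 is benign) and differ from the predictor's published
#' HumDiv/HumVar cut-offs; both are configurable.
#'
#' @param score Numeric vector of scores in \[0, 1\].
#' @param t_probably Lower bound (exclusive) of the probably-damaging
#'   class.
#' @param t_benign Upper bound (inclusive) of the benign class.
#' @return Character vector of classes.
#' @export
#' @examples
#' pp2_classify(c(1, 0.929, 0.414))
pp2_classify <- function(score, t_probably = 0.94, t_benign = 0.446) {
  if (any(is.na(score)) || any(score < 0) || any(score > 1)) {
    abort("PolyPhen-2 scores must lie in [0, 1].")
  }
  ifelse(score > t_probably, "probably_damaging",
         ifelse(score > t_benign, "possibly_damaging", "benign"))
}

check_cohorts <- function(records, n_families) {
  unknown <- setdiff(unique(records$cohort), names(n_families))
  if (length(unknown)) {
    abort(sprintf("Unknown cohort(s): %s", paste(unknown, collapse = ", ")))
  }
}

default_families <- function() {
  fam <- sz_cohort_families()
  setNames(fam$n_families, fam$cohort)
}

#' Per-cohort mutation and chromosome tallies
#'
#' Counts validated mutations and distinct mutation-bearing chromosomes
#' per cohort and overall (the overall chromosome count is the size of
#' the union, not the sum). When the records carry a `patient_id` column,
#' patients with at least one mutation are counted as well.
#'
#' @param records Variant records from [read_variant_table()].
#' @param n_families Named integer vector of analysed families per
#'   cohort; defaults to the packaged study's counts.
#' @return A tibble with one row per cohort plus a `Total` row:
#'   `cohort`, `n_families`, `n_mutations`, `n_chromosomes` (and
#'   `n_patients_with` when patient ids are available).
#' @export
tally_mutations <- function(records, n_families = default_families()) {
  records <- as_tibble(records)
  check_cohorts(records, n_families)
  cohorts <- names(n_families)
  per <- purrr::map_dfr(cohorts, function(co) {
    r <- records[records$cohort == co, ]
    tibble(cohort = co,
           n_families = unname(n_families[co]),
           n_mutations = nrow(r),
           n_chromosomes = length(unique(r$chromosome)))
  })
  total <- tibble(cohort = "Total",
                  n_families = sum(n_families),
                  n_mutations = nrow(records),
                  n_chromosomes = length(unique(records$chromosome)))
  out <- bind_rows(per, total)
  if ("patient_id" %in% names(records)) {
    n_pat <- c(vapply(cohorts, function(co) {
      length(unique(records$patient_id[records$cohort == co]))
    }, integer(1)), length(unique(records$patient_id)))
    out$n_patients_with <- n_pat
  }
  out
}

#' Chromosome-multiplicity distribution as percentages
#'
#' For each cohort, counts chromosomes carrying exactly one, exactly two,
#' and three or more mutations, and expresses each count as a percentage
#' of the chromosome denominator (23 by default: 22 autosomes plus X),
#' rounded half away from zero. The "any" percentage is computed from the
#' unrounded total count, so it may differ from the sum of the rounded
#' components by one point.
#'
#' @inheritParams tally_mutations
#' @param denominator Number of chromosomes in the denominator.
#' @return A tibble per cohort: the three multiplicity counts
#'   (`n_chrom_1`, `n_chrom_2`, `n_chrom_3plus`) and the corresponding
#'   percentages `pct_1`, `pct_2`, `pct_3plus`, `pct_any`.
#' @export
chromosome_distribution <- function(records, denominator = 23) {
  records <- as_tibble(records)
  if (denominator < 1) abort("`denominator` must be at least 1.")
  cohorts <- unique(records$cohort)
  purrr::map_dfr(cohorts, function(co) {
    counts <- table(records$chromosome[records$cohort == co])
    n1 <- sum(counts == 1)
    n2 <- sum(counts == 2)
    n3 <- sum(counts >= 3)
    tibble(cohort = co,
           n_chrom_1 = n1, n_chrom_2 = n2, n_chrom_3plus = n3,
           pct_1 = round_half_up(100 * n1 / denominator),
           pct_2 = round_half_up(100 * n2 / denominator),
           pct_3plus = round_half_up(100 * n3 / denominator),
           pct_any = round_half_up(100 * (n1 + n2 + n3) / denominator))
  })
}

#' Patient-level mutation distribution as percentages
#'
#' Percentages of families whose proband carries exactly one, two or
#' more, and at least one validated mutation, rounded half away from
#' zero; the "any" percentage is computed from the unrounded sum of the
#' underlying counts. When `x` is a variant table with a `patient_id`
#' column, the counts are derived from the records; otherwise `x` must
#' carry the per-cohort counts directly (columns `cohort`,
#' `n_patients_with_1`, `n_patients_with_2plus`), as printed study tables
#' usually do.
#'
#' @param x Either variant records with `patient_id`, or a per-cohort
#'   count table; defaults to the packaged study's printed counts.
#' @param n_families Named vector of families per cohort.
#' @return A tibble per cohort: `pct_1`, `pct_2plus`, `pct_any`.
#' @export
patient_distribution <- function(x = sz_cohort_families(),
                                 n_families = default_families()) {
  x <- as_tibble(x)
  if ("patient_id" %in% names(x)) {
    counts <- x |>
      count(.data$cohort, .data$patient_id) |>
      group_by(.data$cohort) |>
      summarise(n_patients_with_1 = sum(.data$n == 1L),
                n_patients_with_2plus = sum(.data$n >= 2L),
                .groups = "drop")
  } else {
    needed <- c("cohort", "n_patients_with_1", "n_patients_with_2plus")
    if (!all(needed %in% names(x))) {
      abort("`x` must carry patient ids or per-cohort patient counts.")
    }
    counts <- x
  }
  check_cohorts(counts, n_families)
  fam <- unname(n_families[counts$cohort])
  with_any <- counts$n_patients_with_1 + counts$n_patients_with_2plus
  if (any(with_any > fam)) {
    abort("Patient counts exceed the number of families in some cohort.")
  }
  tibble(cohort = counts$cohort,
         pct_1 = round_half_up(100 * counts$n_patients_with_1 / fam),
         pct_2plus = round_half_up(100 * counts$n_patients_with_2plus / fam),
         pct_any = round_half_up(100 * with_any / fam))
}

#' Damage-class tally per cohort
#'
#' Cross-tabulates validated mutations by cohort and PolyPhen-2 damage
#' class, with a `Total` row. Classes come from the `pph2_class` column
#' when present, otherwise from [pp2_classify()] applied to the scores.
#'
#' @inheritParams tally_mutations
#' @return A tibble with columns `cohort`, `probably_damaging`,
#'   `possibly_damaging`, `benign`, `total`.
#' @export
pp2_tally <- function(records) {
  records <- as_tibble(records)
  cls <- if ("pph2_class" %in% names(records)) records$pph2_class
         else pp2_classify(records$pph2_score)
  cohorts <- unique(records$cohort)
  one_row <- function(name, classes) {
    tibble(cohort = name,
           probably_damaging = sum(classes == "probably_damaging"),
           possibly_damaging = sum(classes == "possibly_damaging"),
           benign = sum(classes == "benign"),
           total = length(classes))
  }
  bind_rows(
    purrr::map_dfr(cohorts, function(co) one_row(co, cls[records$cohort == co])),
    one_row("Total", cls))
}
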