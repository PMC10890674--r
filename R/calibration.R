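# Empirical calibration of the de novo filter: binned class-conditional
# feature densities (concordant vs discordant calibration sites), the
# naive-Bayes log Bayes factor, and threshold calibration to a target
# false-positive proportion.

#' Build class-conditional feature distributions from calibration sites
#'
#' Calibration sites are variant calls for which an orthogonal genotyping
#' technology gives a truth label: `concordant` calls (both technologies
#' agree, "true positives") and `discordant` calls ("false positives").
#' For each QC feature, sites are stratified by coverage (quartiles of the
#' `coverage` column by default) and split into heterozygous/homozygous
#' calls, and a binned empirical density is estimated per class in every
#' (feature, stratum, genotype class) cell, with Laplace smoothing so no
#' bin has zero mass. Cells in which either class is unobserved fall back
#' to the pooled (unstratified, class-collapsed) densities.
#'
#' @param calib A data frame with one row per calibration site: a `label`
#'   column (`"concordant"`/`"discordant"`), a `genotype_class` column
#'   (`"het"`/`"hom"`), a numeric `coverage` column (mean depth at the
#'   site), and one numeric column per QC feature (every remaining numeric
#'   column is treated as a feature).
#' @param bin_count Number of equal-width bins per feature (>= 2).
#' @param pseudocount Laplace pseudocount added to every bin (default 0.5).
#' @param n_strata Number of coverage strata (quantile cut points;
#'   default 4, i.e. quartiles).
#' @param features Optional character vector naming the feature columns;
#'   defaults to all numeric columns other than `coverage`.
#' @return An object of class `class_distributions` holding the binned
#'   densities, the shared bin edges per feature, and the coverage
#'   stratum breaks.
#' @export
build_class_distributions <- function(calib, bin_count = 20, pseudocount = 0.5,
                                      n_strata = 4, features = NULL) {
  calib <- as_tibble(calib)
  if (bin_count < 2) abort("`bin_count` must be at least 2.")
  if (pseudocount <= 0) abort("`pseudocount` must be positive.")
  for (col in c("label", "genotype_class", "coverage")) {
    if (!col %in% names(calib)) {
      abort(sprintf("`calib` lacks required column `%s`.", col))
    }
  }
  labs <- unique(calib$label)
  if (!all(c("concordant", "discordant") %in% labs)) {
    abort("Calibration data must contain both concordant and discordant sites.")
  }
  if (is.null(features)) {
    num <- vapply(calib, is.numeric, logical(1))
    features <- setdiff(names(calib)[num], "coverage")
  }
  if (!length(features)) abort("No feature columns found in `calib`.")

  probs <- seq(0, 1, length.out = n_strata + 1L)
  strata_breaks <- unique(quantile(calib$coverage, probs = probs, names = FALSE))
  strata <- coverage_stratum(calib$coverage, strata_breaks)

  edges <- lapply(setNames(features, features), function(f) {
    r <- range(calib[[f]], finite = TRUE)
    if (!all(is.finite(r))) abort(sprintf("Feature `%s` has no finite values.", f))
    if (r[1] == r[2]) r <- r + c(-0.5, 0.5)  # degenerate constant feature
    seq(r[1], r[2], length.out = bin_count + 1L)
  })

  smooth_density <- function(values, brk) {
    idx <- clamp_bin(findInterval(values, brk, rightmost.closed = TRUE),
                     bin_count)
    counts <- tabulate(idx, nbins = bin_count) + pseudocount
    counts / sum(counts)
  }

  cells <- list()
  for (f in features) {
    brk <- edges[[f]]
    x <- calib[[f]]
    is_conc <- calib$label == "concordant"
    # pooled fallback densities, always defined
    cells[[length(cells) + 1L]] <- tibble(
      feature = f, stratum = NA_integer_, genotype_class = "pooled",
      d_concordant = list(smooth_density(x[is_conc], brk)),
      d_discordant = list(smooth_density(x[!is_conc], brk)))
    for (s in seq_len(length(strata_breaks) - 1L)) {
      for (g in c("het", "hom")) {
        in_cell <- strata == s & calib$genotype_class == g
        if (!any(in_cell & is_conc) || !any(in_cell & !is_conc)) next
        cells[[length(cells) + 1L]] <- tibble(
          feature = f, stratum = s, genotype_class = g,
          d_concordant = list(smooth_density(x[in_cell & is_conc], brk)),
          d_discordant = list(smooth_density(x[in_cell & !is_conc], brk)))
      }
    }
  }

  structure(list(densities = bind_rows(cells), edges = edges,
                 strata_breaks = strata_breaks, bin_count = bin_count,
                 pseudocount = pseudocount, features = features),
            class = "class_distributions")
}

coverage_stratum <- function(coverage, breaks) {
  clamp_bin(findInterval(coverage, breaks, rightmost.closed = TRUE),
            length(breaks) - 1L)
}

clamp_bin <- function(idx, nbins) {
  pmin(pmax(idx, 1L), nbins)
}

#' @export
print.class_distributions <- function(x, ...) {
  cat(sprintf(
    "<class_distributions> %d feature(s), %d coverage strata, %d bins (pseudocount %.2g)\n",
    length(x$features), length(x$strata_breaks) - 1L, x$bin_count,
    x$pseudocount))
  cat("features:", paste(x$features, collapse = ", "), "\n")
  invisible(x)
}

lookup_cell <- function(dists, feature, stratum, gclass) {
  d <- dists$densities
  hit <- d$feature == feature & !is.na(d$stratum) & d$stratum == stratum &
    d$genotype_class == gclass
  if (!any(hit)) {  # fall back to pooled densities
    hit <- d$feature == feature & d$genotype_class == "pooled"
  }
  i <- which(hit)[1]
  list(conc = d$d_concordant[[i]], disc = d$d_discordant[[i]])
}

#' Naive-Bayes log Bayes factor for candidate sites
#'
#' Scores each site as the sum over QC features of the log ratio of the
#' concordant-class to discordant-class binned density evaluated at the
#' site's feature value, looked up in the site's coverage stratum and
#' heterozygous/homozygous cell. Natural log. A positive score favours a
#' genuine ("concordant-like") call. Feature values outside the calibrated
#' range use the nearest edge bin.
#'
#' @param sites A data frame with `coverage`, `genotype_class` and the
#'   calibrated feature columns; other columns pass through.
#' @param dists A `class_distributions` object from
#'   [build_class_distributions()].
#' @param features Features to score on; defaults to every calibrated
#'   feature. Naming a feature that was not calibrated is an error.
#' @return The input tibble with a `log_bf` column added.
#' @export
log_bayes_factor <- function(sites, dists, features = NULL) {
  if (!inherits(dists, "class_distributions")) {
    abort("`dists` must come from build_class_distributions().")
  }
  sites <- as_tibble(sites)
  features <- features %||% dists$features
  unknown <- setdiff(features, dists$features)
  if (length(unknown)) {
    abort(sprintf("Feature(s) not in the calibration: %s",
                  paste(unknown, collapse = ", ")))
  }
  missing_cols <- setdiff(c(features, "coverage", "genotype_class"),
                          names(sites))
  if (length(missing_cols)) {
    abort(sprintf("`sites` lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  n <- nrow(sites)
  lbf <- numeric(n)
  strata <- coverage_stratum(sites$coverage, dists$strata_breaks)
  for (f in features) {
    brk <- dists$edges[[f]]
    bins <- clamp_bin(findInterval(sites[[f]], brk, rightmost.closed = TRUE),
                      dists$bin_count)
    for (i in seq_len(n)) {
      cell <- lookup_cell(dists, f, strata[i], sites$genotype_class[i])
      lbf[i] <- lbf[i] + log(cell$conc[bins[i]]) - log(cell$disc[bins[i]])
    }
  }
  mutate(sites, log_bf = lbf)
}

#' Calibrate the log Bayes-factor acceptance threshold
#'
#' Finds the smallest threshold `t` such that among calibration sites with
#' `log_bf >= t`, the proportion of discordant ("false") sites is at most
#' `target_fp`. With `target_fp = 1` every site is acceptable and `-Inf`
#' is returned; when no threshold attains the target (e.g. the very top
#' scores are all discordant), `+Inf` is returned with a warning.
#'
#' @param log_bf Numeric vector of scores, or a data frame with `log_bf`
#'   and `label` columns.
#' @param label Labels parallel to `log_bf`: `"concordant"` (true) /
#'   `"discordant"` (false). Ignored when `log_bf` is a data frame.
#' @param target_fp Target false-positive proportion in (0, 1].
#' @return A single numeric threshold.
#' @export
calibrate_threshold <- function(log_bf, label = NULL, target_fp = 0.05) {
  if (is.data.frame(log_bf)) {
    label <- log_bf$label
    log_bf <- log_bf$log_bf
  }
  assert_scalar_number(target_fp, "target_fp")
  if (target_fp <= 0 || target_fp > 1) {
    abort("`target_fp` must lie in (0, 1].")
  }
  if (length(log_bf) != length(label)) {
    abort("`log_bf` and `label` lengths differ.")
  }
  if (length(unique(label)) < 2L) {
    abort("Calibration requires both concordant and discordant sites.")
  }
  if (target_fp == 1) return(-Inf)

  ord <- order(log_bf, decreasing = TRUE)
  is_false <- label[ord] == "discordant"
  # among the top-m sites (all with log_bf >= log_bf[ord][m]) the FP
  # proportion is cum_false[m] / m; scan from the loosest threshold up
  cum_fp <- cumsum(is_false) / seq_along(is_false)
  sorted_scores <- log_bf[ord]
  # candidate thresholds: -Inf (accept all) then each distinct score; the
  # accepted set for t = score[m] is the top block ending at the last tie
  last_of_block <- !duplicated(sorted_scores, fromLast = TRUE)
  ok_all <- cum_fp[length(cum_fp)] <= target_fp
  if (ok_all) return(-Inf)
  blocks <- which(last_of_block)
  ok <- blocks[cum_fp[blocks] <= target_fp]
  if (!length(ok)) {
    warn("No threshold attains the target false-positive proportion; returning +Inf.")
    return(Inf)
  }
  # smallest threshold = the loosest acceptable block (largest block index)
  sorted_scores[max(ok)]
}
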