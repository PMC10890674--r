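# Bayesian de novo candidate detection from per-member read counts.
#
# Genotypes are coded by alternate-allele dosage: RR = 0, RA = 1, AA = 2.
# Reads are modelled as independent draws with alt-allele probability
# error_rate, 0.5, 1 - error_rate respectively.

GT_LEVELS <- c("RR", "RA", "AA")

#' Log-likelihood of read counts given a genotype
#'
#' Binomial read-sampling model: each of `depth` reads supports the
#' alternate allele with probability `error_rate` (genotype RR), `0.5`
#' (RA), or `1 - error_rate` (AA). With zero depth the likelihood is 1
#' (log 0): no reads carry no information.
#'
#' @param depth,alt_count Non-negative integer vectors of total and
#'   alternate-supporting read counts, `alt_count <= depth`.
#' @param genotype Character vector over `"RR"`, `"RA"`, `"AA"`.
#' @param error_rate Per-read sequencing error probability in (0, 0.5).
#' @return Numeric vector of log-likelihoods (natural log).
#' @export
#' @examples
#' genotype_log_likelihood(10, 5, "RA")          # log choose(10,5) + 10*log(.5)
#' genotype_log_likelihood(20, 0, "RR", 0.005)   # 20 * log(0.995)
genotype_log_likelihood <- function(depth, alt_count, genotype,
                                    error_rate = 0.005) {
  assert_scalar_number(error_rate, "error_rate")
  if (error_rate <= 0 || error_rate >= 0.5) {
    abort("`error_rate` must lie strictly between 0 and 0.5.")
  }
  if (any(depth < 0) || any(alt_count < 0)) {
    abort("Read counts must be non-negative.")
  }
  if (any(alt_count > depth)) {
    abort("`alt_count` cannot exceed `depth`.")
  }
  bad <- setdiff(unique(genotype), GT_LEVELS)
  if (length(bad)) {
    abort(sprintf("Unknown genotype code(s): %s", paste(bad, collapse = ", ")))
  }
  p <- c(RR = error_rate, RA = 0.5, AA = 1 - error_rate)[genotype]
  dbinom(alt_count, depth, p, log = TRUE)
}

# All 27 (father, mother, proband) dosage configurations with their
# Mendelian status. Proband dosage is achievable iff it equals the sum of
# one transmissible allele from each parent (dosage 0 -> {0}, 1 -> {0,1},
# 2 -> {1}, as allele contribution).
trio_genotype_configs <- function() {
  cfg <- expand.grid(father = 0:2, mother = 0:2, proband = 0:2,
                     KEEP.OUT.ATTRS = FALSE)
  transmit <- list(`0` = 0L, `1` = 0:1, `2` = 1L)
  cfg$mendelian <- mapply(function(f, m, p) {
    any(outer(transmit[[as.character(f)]], transmit[[as.character(m)]], "+") == p)
  }, cfg$father, cfg$mother, cfg$proband)
  cfg$de_novo <- cfg$father == 0 & cfg$mother == 0 & cfg$proband > 0
  tibble::as_tibble(cfg)
}

# Per-member log-likelihood matrix (n sites x 3 genotypes)
member_loglik <- function(depth, alt, error_rate) {
  vapply(GT_LEVELS, function(g) {
    genotype_log_likelihood(depth, alt, rep(g, length(depth)), error_rate)
  }, numeric(length(depth)))
}

#' Detect candidate de novo sites in a trio
#'
#' For each site, the posterior odds of the de novo configuration (both
#' parents homozygous reference, proband carrying the alternate allele)
#' versus all Mendelian-consistent trio configurations are computed from
#' the binomial read model. The de novo configurations share prior mass
#' `denovo_prior`; the Mendelian-consistent configurations share the
#' complement uniformly; other Mendelian violations (dropout-like
#' configurations) receive no prior mass. A site is a candidate when the
#' posterior odds exceed 1.
#'
#' @param trio_sites A data frame with one row per site and columns
#'   `father_depth`, `father_alt`, `mother_depth`, `mother_alt`,
#'   `proband_depth`, `proband_alt`; any additional columns (site ids,
#'   coordinates) are carried through.
#' @param error_rate Per-read error probability, see
#'   [genotype_log_likelihood()].
#' @param denovo_prior Prior probability of a de novo mutation at a given
#'   site, in (0, 1).
#' @return A tibble of candidate sites (subset of the input rows) with
#'   added columns `log_posterior_odds`, `genotype_class` (`"het"` or
#'   `"hom"`, from the proband's maximum-likelihood genotype) and
#'   `min_depth` (minimum read depth across the trio).
#' @export
detect_candidates <- function(trio_sites, error_rate = 0.005,
                              denovo_prior = 1e-4) {
  assert_scalar_number(denovo_prior, "denovo_prior")
  if (denovo_prior <= 0 || denovo_prior >= 1) {
    abort("`denovo_prior` must lie strictly between 0 and 1.")
  }
  trio_sites <- as_tibble(trio_sites)
  needed <- c("father_depth", "father_alt", "mother_depth", "mother_alt",
              "proband_depth", "proband_alt")
  missing_cols <- setdiff(needed, names(trio_sites))
  if (length(missing_cols)) {
    abort(sprintf("`trio_sites` lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  n <- nrow(trio_sites)
  if (n == 0L) {
    return(mutate(trio_sites, log_posterior_odds = numeric(0),
                  genotype_class = character(0), min_depth = integer(0)))
  }

  lf <- member_loglik(trio_sites$father_depth, trio_sites$father_alt, error_rate)
  lm <- member_loglik(trio_sites$mother_depth, trio_sites$mother_alt, error_rate)
  lp <- member_loglik(trio_sites$proband_depth, trio_sites$proband_alt, error_rate)

  cfg <- trio_genotype_configs()
  n_mend <- sum(cfg$mendelian)
  log_prior <- ifelse(cfg$de_novo, log(denovo_prior / 2),
                      ifelse(cfg$mendelian, log((1 - denovo_prior) / n_mend),
                             -Inf))

  odds <- numeric(n)
  for (i in seq_len(n)) {
    ll <- lf[i, cfg$father + 1L] + lm[i, cfg$mother + 1L] +
      lp[i, cfg$proband + 1L] + log_prior
    odds[i] <- logsumexp(ll[cfg$de_novo]) - logsumexp(ll[cfg$mendelian])
  }

  pr_ml <- max.col(lp, ties.method = "first")  # 1=RR, 2=RA, 3=AA
  gclass <- ifelse(pr_ml == 3L, "hom", "het")

  out <- mutate(trio_sites,
                log_posterior_odds = odds,
                genotype_class = gclass,
                min_depth = pmin(.data$father_depth, .data$mother_depth,
                                 .data$proband_depth))
  filter(out, .data$log_posterior_odds > 0)
}

#' Filter candidate sites on Bayes factor and read depth
#'
#' Retains candidates with `log_bf >= bf_threshold` and minimum trio read
#' depth `>= depth_threshold` (both boundaries inclusive for retention;
#' sites are excluded when the log Bayes factor falls below 3 or the depth
#' below 20 under the defaults). Input order is preserved.
#'
#' @param sites A data frame with a `log_bf` column and either a
#'   `min_depth` column or the six per-member depth/alt columns used by
#'   [detect_candidates()].
#' @param bf_threshold Minimum natural-log Bayes factor (default 3).
#' @param depth_threshold Minimum read depth across the trio (default 20).
#' @return The retained subset, with `passed_filters = TRUE` added.
#' @export
filter_candidates <- function(sites, bf_threshold = 3, depth_threshold = 20) {
  sites <- as_tibble(sites)
  if (!"log_bf" %in% names(sites)) {
    abort("`sites` must have a `log_bf` column (see `log_bayes_factor()`).")
  }
  if (!"min_depth" %in% names(sites)) {
    depth_cols <- c("father_depth", "mother_depth", "proband_depth")
    if (!all(depth_cols %in% names(sites))) {
      abort("`sites` needs `min_depth` or per-member depth columns.")
    }
    sites$min_depth <- pmin(sites$father_depth, sites$mother_depth,
                            sites$proband_depth)
  }
  kept <- filter(sites, .data$log_bf >= bf_threshold,
                 .data$min_depth >= depth_threshold)
  mutate(kept, passed_filters = TRUE)
}
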