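# Trio genotype classification from unphased allele pairs ("G/A" strings).

parse_genotype <- function(x) {
  ok <- grepl("^[ACGT]/[ACGT]$", x)
  if (any(!ok)) {
    abort(sprintf("Malformed genotype string(s): %s",
                  paste(unique(x[!ok]), collapse = ", ")))
  }
  matrix(unlist(strsplit(x, "/", fixed = TRUE)), ncol = 2L, byrow = TRUE)
}

classify_one_trio <- function(fa, mo, pr) {
  # consistent if some (father transmission, mother transmission) pair
  # reproduces the proband's unordered allele pair
  pr_sorted <- sort(pr)
  for (a in fa) {
    for (b in mo) {
      if (identical(sort(c(a, b)), pr_sorted)) return("consistent")
    }
  }
  parental <- unique(c(fa, mo))
  novel <- setdiff(unique(pr), parental)
  if (pr[1] == pr[2] && pr[1] %in% novel) return("de_novo_hom")
  if (length(novel) == 1L && pr[1] != pr[2]) return("de_novo_het")
  "mendelian_violation_other"
}

#' Classify trio genotypes against Mendelian transmission
#'
#' Compares the proband's unphased genotype with every possible pair of
#' parental transmissions and assigns one of four classes:
#'
#' * `consistent` — some pair of parental alleles explains the proband;
#' * `de_novo_het` — the heterozygous proband carries exactly one allele
#'   absent from both parents (the classic de novo point mutation, e.g.
#'   parents G/G, G/G and proband G/A);
#' * `de_novo_hom` — the proband is homozygous for an allele absent from
#'   both parents (e.g. parents C/C, C/C and proband T/T, as seen for
#'   X-linked sites);
#' * `mendelian_violation_other` — transmission cannot explain the proband
#'   but no novel allele is present, the signature of allele dropout or a
#'   genotyping artifact rather than a new mutation (e.g. parents G/G, T/T
#'   and proband G/G).
#'
#' Chromosome labels are accepted for bookkeeping but do not alter the
#' classification: proband sex is unknown in the supported input, so sex
#' chromosomes are treated like autosomes.
#'
#' @param father,mother,proband Character vectors of genotypes written as
#'   unordered allele pairs over A/C/G/T, e.g. `"G/A"`. Recycled to a
#'   common length.
#' @param chromosome Optional chromosome labels (ignored; see Details).
#' @return A character vector of classes, one per trio.
#' @export
#' @examples
#' classify_trio_genotypes("G/G", "G/G", "G/A")  # de_novo_het
#' classify_trio_genotypes("G/G", "T/T", "G/G")  # mendelian_violation_other
classify_trio_genotypes <- function(father, mother, proband, chromosome = NULL) {
  n <- max(length(father), length(mother), length(proband))
  father <- rep_len(father, n)
  mother <- rep_len(mother, n)
  proband <- rep_len(proband, n)
  fa <- parse_genotype(father)
  mo <- parse_genotype(mother)
  pr <- parse_genotype(proband)
  vapply(seq_len(n), function(i) {
    classify_one_trio(fa[i, ], mo[i, ], pr[i, ])
  }, character(1))
}
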