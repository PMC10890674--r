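test_that("the packaged variant table parses to 88 normalized records", {
  v <- read_variant_table()
  expect_equal(nrow(v), 88L)
  expect_equal(unname(table(v$cohort)[c("Algerian", "French", "Japanese")]),
               c(35L, 21L, 32L), ignore_attr = TRUE)
  # chromosome labels are normalized whether or not they carry "chr"
  expect_true(all(v$chromosome %in% c(as.character(1:22), "X")))
  expect_false(any(grepl("^chr", v$chromosome)))
  # locus-style positions are parsed to integers
  expect_equal(v$position[v$gene == "HISPPD1"], 102489584L)
  expect_true(all(v$pph2_score >= 0 & v$pph2_score <= 1))
})

test_that("header-only input gives zero records and bad rows are rejected", {
  hdr <- paste("Cohort", "Gene", "Chromosome", "Position", "Father",
               "Mother", "Patient", "PPH2 Score", "PPH2 Prediction",
               sep = "\t")
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(hdr, empty)
  expect_equal(nrow(read_variant_table(empty)), 0L)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(hdr,
               "Algerian\tGENE1\t5\tchr5:100\tG/G\tG/G\tG/A\t1.2\tbenign",
               "Algerian\tGENE2\t5\tchr5:200\tG/G\tG/G\tG/A\t0.5\tpossibly damaging"),
             bad)
  expect_warning(v <- read_variant_table(bad), "line\\(s\\): 2")
  expect_equal(v$gene, "GENE2")

  missing_col <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Cohort\tGene", "Algerian\tGENE1"), missing_col)
  expect_error(read_variant_table(missing_col), "lacks column")
})

test_that("damage-class thresholds reproduce published boundary cases", {
  expect_equal(pp2_classify(1.0), "probably_damaging")
  expect_equal(pp2_classify(0.929), "possibly_damaging")
  expect_equal(pp2_classify(0.414), "benign")
  expect_equal(pp2_classify(0.0), "benign")
  expect_error(pp2_classify(1.2), "\\[0, 1\\]")
})

test_that("thresholds reproduce all 88 printed class labels, partition and order", {
  v <- read_variant_table()
  expect_equal(pp2_classify(v$pph2_score), v$pph2_class)
  # the three classes partition [0,1] and are monotone in the score
  grid <- seq(0, 1, by = 0.001)
  cls <- pp2_classify(grid)
  expect_true(all(cls %in% c("benign", "possibly_damaging",
                             "probably_damaging")))
  rank <- c(benign = 1, possibly_damaging = 2, probably_damaging = 3)
  expect_true(all(diff(rank[cls]) >= 0))
})

test_that("mutation tallies per cohort match the published table", {
  v <- read_variant_table()
  t3 <- tally_mutations(v)
  expect_equal(t3$n_mutations, c(35L, 21L, 32L, 88L))
  expect_equal(t3$n_chromosomes, c(18L, 14L, 16L, 22L))
  expect_equal(t3$n_families, c(75L, 45L, 61L, 181L))
  # record order does not matter
  t3_shuffled <- tally_mutations(v[withr::with_seed(1, sample(88)), ])
  expect_equal(t3, t3_shuffled)
  # empty input keeps the cohort skeleton with zeros
  t0 <- tally_mutations(v[0, ])
  expect_equal(t0$n_mutations, rep(0L, 4))
  expect_error(tally_mutations(dplyr::mutate(v, cohort = "Martian")),
               "Unknown cohort")
})

test_that("chromosome distribution percentages match the published table", {
  v <- read_variant_table()
  cd <- chromosome_distribution(v)
  alg <- cd[cd$cohort == "Algerian", ]
  expect_equal(c(alg$pct_1, alg$pct_2, alg$pct_3plus, alg$pct_any),
               c(52, 4, 22, 78))
  fr <- cd[cd$cohort == "French", ]
  expect_equal(c(fr$pct_1, fr$pct_2, fr$pct_3plus, fr$pct_any),
               c(39, 17, 4, 61))
  jp <- cd[cd$cohort == "Japanese", ]
  expect_equal(c(jp$pct_1, jp$pct_2, jp$pct_3plus, jp$pct_any),
               c(39, 4, 26, 70))
  # one record: a single chromosome, 1/23 rounds to 4
  one <- chromosome_distribution(v[1, ])
  expect_equal(c(one$pct_1, one$pct_2, one$pct_3plus, one$pct_any),
               c(4, 0, 0, 4))
  # pre-rounding, the multiplicity components sum exactly to "any"
  expect_equal(cd$n_chrom_1 + cd$n_chrom_2 + cd$n_chrom_3plus,
               tally_mutations(v)$n_chromosomes[1:3])
})

test_that("patient distribution percentages match the published table", {
  pd <- patient_distribution()
  expect_equal(pd$pct_any, c(40, 38, 41))
  expect_equal(pd$pct_1, c(36, 31, 31))
  expect_equal(pd$pct_2plus, c(4, 7, 10))
  # derived from per-record patient ids when they are present
  recs <- tibble::tibble(
    cohort = c("French", "French", "French"),
    patient_id = c("p1", "p1", "p2"))
  pd2 <- patient_distribution(recs, n_families = c(French = 10))
  expect_equal(pd2$pct_1, 10)     # one patient with a single mutation
  expect_equal(pd2$pct_2plus, 10) # one patient with two
  expect_equal(pd2$pct_any, 20)
  expect_error(
    patient_distribution(tibble::tibble(cohort = "French",
                                        n_patients_with_1 = 50,
                                        n_patients_with_2plus = 0),
                         n_families = c(French = 45)),
    "exceed")
  # zero patients round to zero
  pd0 <- patient_distribution(tibble::tibble(cohort = "French",
                                             n_patients_with_1 = 0,
                                             n_patients_with_2plus = 0),
                              n_families = c(French = 45))
  expect_equal(unlist(pd0[, -1]), c(pct_1 = 0, pct_2plus = 0, pct_any = 0))
})

test_that("damage-class tallies match the published table", {
  v <- read_variant_table()
  t6 <- pp2_tally(v)
  total <- t6[t6$cohort == "Total", ]
  expect_equal(c(total$probably_damaging, total$possibly_damaging,
                 total$benign, total$total), c(48L, 19L, 21L, 88L))
  alg <- t6[t6$cohort == "Algerian", ]
  expect_equal(c(alg$probably_damaging, alg$possibly_damaging, alg$benign),
               c(19L, 6L, 10L))
  # row sums equal the per-cohort mutation counts
  expect_equal(t6$total[match(c("Algerian", "French", "Japanese"),
                              t6$cohort)],
               c(35L, 21L, 32L))
  expect_equal(nrow(pp2_tally(v[0, ])), 1L)  # just the zero Total row
})

test_that("rounding is half away from zero", {
  expect_equal(round_half_up(c(0.5, 1.5, 2.5, -0.5, -1.5)),
               c(1, 2, 3, -1, -2))
  expect_equal(round_half_up(100 * 18 / 23), 78)
})
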