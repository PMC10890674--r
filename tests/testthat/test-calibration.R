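calib_frame <- function(label, value, coverage = 30, gclass = "het") {
  tibble::tibble(label = label, genotype_class = gclass,
                 coverage = coverage, qc = value)
}

test_that("identical class distributions give zero log Bayes factor", {
  calib <- calib_frame(rep(c("concordant", "discordant"), each = 50),
                       rep(seq(0, 1, length.out = 50), 2))
  d <- build_class_distributions(calib, bin_count = 5)
  scored <- log_bayes_factor(calib, d)
  expect_equal(scored$log_bf, rep(0, 100))
})

test_that("a single observed density ratio becomes its log", {
  # concordant mass 0.8 vs discordant 0.2 in one bin, mirrored in another:
  # two bins, no smoothing distortion beyond the shared pseudocount
  calib <- calib_frame(rep(c("concordant", "discordant"), c(100, 100)),
                       c(rep(0.1, 80), rep(0.9, 20),
                         rep(0.1, 20), rep(0.9, 80)))
  d <- build_class_distributions(calib, bin_count = 2, pseudocount = 1e-9,
                                 n_strata = 1)
  site <- calib_frame("concordant", 0.1)
  scored <- log_bayes_factor(site, d)
  expect_equal(scored$log_bf, log(0.8 / 0.2), tolerance = 1e-6)
})

test_that("log Bayes factor is additive over independent features", {
  # feature f1 carries ratio ~4 at the probe point, f2 carries ~1/2
  calib <- tibble::tibble(
    label = rep(c("concordant", "discordant"), c(100, 100)),
    genotype_class = "het", coverage = 30,
    f1 = c(rep(0.1, 80), rep(0.9, 20), rep(0.1, 20), rep(0.9, 80)),
    f2 = c(rep(0.1, 40), rep(0.9, 60), rep(0.1, 80), rep(0.9, 20)))
  d <- build_class_distributions(calib, bin_count = 2, pseudocount = 1e-9,
                                 n_strata = 1)
  probe <- tibble::tibble(label = "x", genotype_class = "het",
                          coverage = 30, f1 = 0.1, f2 = 0.1)
  both <- log_bayes_factor(probe, d)$log_bf
  only1 <- log_bayes_factor(probe, d, features = "f1")$log_bf
  only2 <- log_bayes_factor(probe, d, features = "f2")$log_bf
  expect_equal(both, only1 + only2)
  expect_equal(only1, log(0.8 / 0.2), tolerance = 1e-6)
  expect_equal(only2, log(0.4 / 0.8), tolerance = 1e-6)
})

test_that("unknown features and single-label calibration are rejected", {
  calib <- calib_frame(rep(c("concordant", "discordant"), each = 10),
                       rnorm(20))
  d <- build_class_distributions(calib, bin_count = 4)
  expect_error(log_bayes_factor(calib, d, features = "nope"), "nope")
  expect_error(build_class_distributions(calib_frame(rep("concordant", 10),
                                                     rnorm(10))),
               "both concordant and discordant")
})

test_that("binned densities match an independent histogram oracle", {
  sim <- simulate_calibration_features(sim_config(
    seed = 9, n_calib = 2000,
    calib_features = tibble::tibble(feature = "qc", conc_mean = 0,
                                    conc_sd = 1, disc_mean = 2,
                                    disc_sd = 1.5)))
  bins <- 15
  pc <- 0.5
  d <- build_class_distributions(sim, bin_count = bins, pseudocount = pc,
                                 n_strata = 1)
  pooled <- d$densities[d$densities$genotype_class == "pooled", ]
  edges <- d$edges$qc
  for (lab in c("concordant", "discordant")) {
    x <- sim$qc[sim$label == lab]
    counts <- hist(pmin(pmax(x, edges[1]), edges[length(edges)]),
                   breaks = edges, plot = FALSE)$counts
    oracle <- (counts + pc) / sum(counts + pc)
    got <- pooled[[paste0("d_", substr(lab, 1, 4), "ordant")]][[1]]
    expect_equal(got, oracle, tolerance = 1e-12)
    expect_true(all(got > 0))
    expect_equal(sum(got), 1)
  }
})

test_that("stratified cells fall back to pooled densities when empty", {
  calib <- tibble::tibble(
    label = rep(c("concordant", "discordant"), each = 40),
    genotype_class = "het",  # no hom records at all
    coverage = rep(c(10, 50), 40),
    qc = rnorm(80))
  d <- build_class_distributions(calib, bin_count = 5)
  site <- tibble::tibble(genotype_class = "hom", coverage = 30, qc = 0)
  expect_silent(scored <- log_bayes_factor(site, d))
  expect_true(is.finite(scored$log_bf))
})

test_that("threshold calibration handles separable and degenerate cases", {
  # perfectly separated classes, few enough true sites that a single
  # false acceptance would already exceed the target: the returned
  # threshold sits between the classes and realizes zero false positives
  withr::with_seed(17, {
    scores <- c(rnorm(15, 10, 0.1), rnorm(50, -10, 0.1))
    labels <- rep(c("concordant", "discordant"), c(15, 50))
  })
  t <- calibrate_threshold(scores, labels, target_fp = 0.05)
  accepted <- scores >= t
  expect_equal(mean(labels[accepted] == "discordant"), 0)
  expect_true(t > -5 && t <= 10.5)
  # the smallest-threshold rule never exceeds the target, whatever the mix
  withr::with_seed(18, {
    scores2 <- c(rnorm(50, 10, 0.1), rnorm(50, -10, 0.1))
    labels2 <- rep(c("concordant", "discordant"), each = 50)
  })
  t2 <- calibrate_threshold(scores2, labels2, target_fp = 0.05)
  expect_lte(mean(labels2[scores2 >= t2] == "discordant"), 0.05)
  # target 1: accept everything
  expect_equal(calibrate_threshold(scores, labels, target_fp = 1), -Inf)
  # unattainable: the single top score is discordant
  expect_warning(
    t2 <- calibrate_threshold(c(10, 1), c("discordant", "concordant"),
                              target_fp = 0.05),
    "No threshold")
  expect_equal(t2, Inf)
  expect_error(calibrate_threshold(scores, rep("concordant", length(scores))),
               "both concordant and discordant")
})

test_that("held-out false-positive proportion tracks the target", {
  sim <- simulate_labeled_scores(n = 10000, seed = 31)
  withr::with_seed(32, train_idx <- sample(nrow(sim), nrow(sim) / 2))
  t <- calibrate_threshold(sim[train_idx, ], target_fp = 0.05)
  held <- sim[-train_idx, ]
  accepted <- held$log_bf >= t
  fp <- mean(held$label[accepted] == "discordant")
  # binomial 99% CI around the target at the realized acceptance count
  half_width <- 2.576 * sqrt(0.05 * 0.95 / sum(accepted))
  expect_lt(abs(fp - 0.05), half_width + 0.005)
  # quantile oracle: the threshold sits near the mixture quantile at
  # which the discordant tail is 5% of the accepted mass
  expect_true(t > 1 && t < 3)
})
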