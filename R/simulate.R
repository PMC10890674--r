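# Synthetic-data generators: trio read counts with planted de novo
# events, labeled calibration features, weighted likelihood networks with
# planted modules, genomic events, and annotation collections with an
# injected enriched term. Every generator is a pure function of its
# configuration: a single root seed is split deterministically per
# generator, so reruns are byte-identical and the stages remain jointly
# reproducible.

SEED_OFFSETS <- c(trio = 101, calib = 202, network = 303, events = 404,
                  annot = 505, scores = 606)

#' Simulation configuration
#'
#' Collects all tunable parameters of the synthetic-data generators with
#' defaults sized like a desk-scale trio study: roughly 40x mean exome
#' coverage, a 0.5% per-read error rate, about ten true de novo events
#' per thousand candidate sites, and a likelihood network of 150 genes
#' with a planted 12-gene module whose edge weights are boosted
#' three-fold over the exponential background.
#'
#' @param seed Integer root seed; each generator derives its own sub-seed
#'   from it.
#' @param n_sites Number of trio sites to simulate.
#' @param mean_depth Mean per-member read depth (Poisson rate).
#' @param error_rate Per-read sequencing error probability.
#' @param denovo_rate Probability that a site carries a planted de novo
#'   mutation.
#' @param maf Population alternate-allele frequency used for inherited
#'   (non de novo) variation.
#' @param n_calib Number of labeled calibration sites.
#' @param calib_features Data frame describing the per-feature Gaussian
#'   class parameters: `feature`, `conc_mean`, `conc_sd`, `disc_mean`,
#'   `disc_sd`.
#' @param prop_discordant Proportion of discordant calibration sites.
#' @param n_genes,p_edge,weight_scale Likelihood-network size, background
#'   edge probability, and exponential weight scale.
#' @param module_size,module_multiplier Planted-module size and edge
#'   weight multiplier (1 = no planted signal).
#' @param n_snv,n_multi,genes_per_multi Event counts: single-gene SNV
#'   events, multi-gene (CNV/GWAS-locus-like) events, genes per
#'   multi-gene event.
#' @param universe_size,n_terms,term_size_range Annotation universe size,
#'   number of terms, and the uniform range of term sizes.
#' @param list_size,enrichment_factor Companion gene-list size and the
#'   sampling weight multiplier applied to the designated enriched term's
#'   genes (1 = no enrichment).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_sites = 1000L, mean_depth = 40, error_rate = 0.005,
                       denovo_rate = 0.01, maf = 0.2,
                       n_calib = 2000L,
                       calib_features = tibble(
                         feature = c("qual", "strand_bias"),
                         conc_mean = c(0, 0), conc_sd = c(1, 1),
                         disc_mean = c(2, 2), disc_sd = c(1, 1)),
                       prop_discordant = 0.5,
                       n_genes = 150L, p_edge = 0.05, weight_scale = 1,
                       module_size = 12L, module_multiplier = 3,
                       n_snv = 48L, n_multi = 6L, genes_per_multi = 3L,
                       universe_size = 2000L, n_terms = 50L,
                       term_size_range = c(10L, 100L),
                       list_size = 100L, enrichment_factor = 5) {
  cfg <- list(seed = as.integer(seed), n_sites = n_sites,
              mean_depth = mean_depth, error_rate = error_rate,
              denovo_rate = denovo_rate, maf = maf, n_calib = n_calib,
              calib_features = as_tibble(calib_features),
              prop_discordant = prop_discordant, n_genes = n_genes,
              p_edge = p_edge, weight_scale = weight_scale,
              module_size = module_size, module_multiplier = module_multiplier,
              n_snv = n_snv, n_multi = n_multi,
              genes_per_multi = genes_per_multi,
              universe_size = universe_size, n_terms = n_terms,
              term_size_range = term_size_range, list_size = list_size,
              enrichment_factor = enrichment_factor)
  for (p in c("error_rate", "denovo_rate", "maf", "p_edge", "prop_discordant")) {
    assert_scalar_number(cfg[[p]], p, 0, 1)
  }
  for (p in c("n_sites", "n_calib", "n_genes", "module_size", "universe_size",
              "n_terms", "list_size")) {
    assert_scalar_number(cfg[[p]], p, lower = 1)
  }
  structure(cfg, class = "sim_config")
}

sim_seed <- function(config, which) {
  derive_seed(config$seed, SEED_OFFSETS[[which]])
}

#' Simulate trio read counts with planted de novo mutations
#'
#' Per-member depths are Poisson(`mean_depth`); alternate-read counts are
#' binomial given the trio genotypes. A fraction `denovo_rate` of sites
#' carries a planted de novo event (both parents homozygous reference,
#' proband heterozygous); the remainder segregates an inherited variant
#' with population allele frequency `maf` under Hardy-Weinberg and
#' Mendelian transmission.
#'
#' @param config A [sim_config()].
#' @return A list with `sites` (tibble of per-member `*_depth`/`*_alt`
#'   columns plus `site_id`, `chrom`, `pos`) and `truth` (tibble:
#'   `site_id`, `is_denovo`, and the simulated dosages). The root seed is
#'   recorded as an attribute on both.
#' @export
simulate_trio_reads <- function(config = sim_config()) {
  withr::with_seed(sim_seed(config, "trio"), {
    n <- config$n_sites
    is_denovo <- runif(n) < config$denovo_rate
    q <- config$maf
    gt_pop <- function(m) {  # HWE dosage draw
      sample(0:2, m, replace = TRUE,
             prob = c((1 - q)^2, 2 * q * (1 - q), q^2))
    }
    father <- ifelse(is_denovo, 0L, gt_pop(n))
    mother <- ifelse(is_denovo, 0L, gt_pop(n))
    transmit <- function(g) ifelse(g == 0L, 0L,
                                   ifelse(g == 2L, 1L, rbinom(n, 1L, 0.5)))
    proband <- ifelse(is_denovo, 1L, transmit(father) + transmit(mother))
    draw <- function(dosage) {
      depth <- rpois(n, config$mean_depth)
      p <- c(config$error_rate, 0.5, 1 - config$error_rate)[dosage + 1L]
      list(depth = depth, alt = rbinom(n, depth, p))
    }
    fa <- draw(father); mo <- draw(mother); pr <- draw(proband)
    sites <- tibble(
      site_id = sprintf("S%05d", seq_len(n)),
      chrom = as.character(rep_len(1:22, n)),
      pos = seq_len(n) * 1000L,
      father_depth = fa$depth, father_alt = fa$alt,
      mother_depth = mo$depth, mother_alt = mo$alt,
      proband_depth = pr$depth, proband_alt = pr$alt)
    truth <- tibble(site_id = sites$site_id, is_denovo = is_denovo,
                    father_dosage = father, mother_dosage = mother,
                    proband_dosage = proband)
    attr(sites, "seed") <- config$seed
    attr(truth, "seed") <- config$seed
    list(sites = sites, truth = truth)
  })
}

#' Simulate a labeled calibration set of QC features
#'
#' Emulates the chip-versus-exome concordance classes used to train the
#' de novo filter: each site gets a concordant/discordant label, a
#' Poisson coverage draw, a het/hom genotype class, and one Gaussian
#' value per QC feature with class-specific location and scale taken from
#' `config$calib_features`.
#'
#' @inheritParams simulate_trio_reads
#' @return A tibble with columns `label`, `genotype_class`, `coverage`,
#'   and one column per feature.
#' @export
simulate_calibration_features <- function(config = sim_config()) {
  withr::with_seed(sim_seed(config, "calib"), {
    n <- config$n_calib
    label <- ifelse(runif(n) < config$prop_discordant,
                    "discordant", "concordant")
    out <- tibble(
      label = label,
      genotype_class = sample(c("het", "hom"), n, replace = TRUE),
      coverage = rpois(n, config$mean_depth))
    for (i in seq_len(nrow(config$calib_features))) {
      f <- config$calib_features[i, ]
      mu <- ifelse(label == "concordant", f$conc_mean, f$disc_mean)
      sdv <- ifelse(label == "concordant", f$conc_sd, f$disc_sd)
      out[[f$feature]] <- rnorm(n, mu, sdv)
    }
    attr(out, "seed") <- config$seed
    out
  })
}

#' Simulate labeled log Bayes-factor scores
#'
#' Draws scores for a mixture of true ("concordant") and false
#' ("discordant") candidate sites from two Gaussians, the study condition
#' used to exercise threshold calibration: true scores from
#' Normal(`mean_true`, `sd_true`), false scores from Normal(`mean_false`,
#' `sd_false`), in proportion `prop_true`.
#'
#' @param n Number of sites.
#' @param mean_true,sd_true True-class score distribution (default
#'   Normal(4, 1)).
#' @param mean_false,sd_false False-class score distribution (default
#'   Normal(0, 1)).
#' @param prop_true Proportion of true sites (default 0.5).
#' @param seed Integer seed.
#' @return A tibble with columns `log_bf` and `label`.
#' @export
simulate_labeled_scores <- function(n = 10000L, mean_true = 4, sd_true = 1,
                                    mean_false = 0, sd_false = 1,
                                    prop_true = 0.5, seed = 1L) {
  withr::with_seed(derive_seed(seed, SEED_OFFSETS[["scores"]]), {
    is_true <- runif(n) < prop_true
    tibble(
      log_bf = ifelse(is_true, rnorm(n, mean_true, sd_true),
                      rnorm(n, mean_false, sd_false)),
      label = ifelse(is_true, "concordant", "discordant"))
  })
}

#' Simulate a likelihood network with a planted module
#'
#' Background edges appear independently with probability `p_edge` and
#' carry exponential weights with scale `weight_scale`. A randomly placed
#' module of `module_size` genes is made fully connected, its edge
#' weights multiplied by `module_multiplier` (a multiplier of 1 plants no
#' detectable signal).
#'
#' @inheritParams simulate_trio_reads
#' @return A list with `network` (a [likelihood_network()]) and `module`
#'   (character vector of planted genes).
#' @export
simulate_likelihood_network <- function(config = sim_config()) {
  withr::with_seed(sim_seed(config, "network"), {
    genes <- sprintf("G%04d", seq_len(config$n_genes))
    pairs <- utils::combn(genes, 2L)
    on <- runif(ncol(pairs)) < config$p_edge
    edges <- tibble(gene_a = pairs[1, on], gene_b = pairs[2, on],
                    weight = rexp(sum(on), rate = 1 / config$weight_scale))
    module <- sort(sample(genes, config$module_size))
    mod_pairs <- utils::combn(module, 2L)
    mod_edges <- tibble(
      gene_a = mod_pairs[1, ], gene_b = mod_pairs[2, ],
      weight = config$module_multiplier *
        rexp(ncol(mod_pairs), rate = 1 / config$weight_scale))
    # module edges replace any background edge on the same pair
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    edges <- edges[!key(edges$gene_a, edges$gene_b) %in%
                     key(mod_edges$gene_a, mod_edges$gene_b), ]
    net <- likelihood_network(bind_rows(edges, mod_edges), nodes = genes)
    list(network = net, module = module)
  })
}

#' Simulate genomic events over a gene universe
#'
#' Draws `n_snv` single-gene SNV events and `n_multi` multi-gene events
#' (CNV/GWAS-locus-like, `genes_per_multi` genes sampled without
#' replacement within each event). Genes named in `include` are
#' guaranteed to appear, each as one SNV event, replacing that many
#' random SNV draws — used to plant module genes among noise events.
#'
#' @param genes Character vector of available gene symbols.
#' @param config A [sim_config()].
#' @param include Genes that must each get an SNV event (default none).
#' @return A tibble with columns `event_id`, `type`, `genes` (list).
#' @export
simulate_events <- function(genes, config = sim_config(), include = NULL) {
  withr::with_seed(sim_seed(config, "events"), {
    include <- unique(include)
    if (length(include) > config$n_snv) {
      abort("`include` has more genes than there are SNV events.")
    }
    pool <- setdiff(genes, include)
    snv_genes <- c(include,
                   sample(pool, config$n_snv - length(include)))
    snv <- tibble(type = "SNV", genes = as.list(snv_genes))
    multi <- if (config$n_multi > 0) {
      tibble(type = "CNV",
             genes = replicate(config$n_multi,
                               sample(genes, config$genes_per_multi),
                               simplify = FALSE))
    } else {
      tibble(type = character(0), genes = list())
    }
    out <- bind_rows(snv, multi)
    out$event_id <- sprintf("E%03d", seq_len(nrow(out)))
    out <- select(out, "event_id", "type", "genes")
    attr(out, "seed") <- config$seed
    out
  })
}

#' Simulate an annotation collection with one enriched term
#'
#' Builds a gene universe, draws `n_terms` annotation terms with sizes
#' uniform over `term_size_range`, and samples a companion gene list in
#' which the genes of one designated term are over-represented: members
#' of the enriched term get sampling weight `enrichment_factor`, all
#' other genes weight 1.
#'
#' @inheritParams simulate_trio_reads
#' @return A list with `collection` (tibble: `term_id`, `term_name`,
#'   `ontology`, `genes`), `gene_list`, `universe`, and `enriched_term`
#'   (the designated term id).
#' @export
simulate_annotation_sets <- function(config = sim_config()) {
  withr::with_seed(sim_seed(config, "annot"), {
    universe <- sprintf("U%05d", seq_len(config$universe_size))
    sizes <- sample(config$term_size_range[1]:config$term_size_range[2],
                    config$n_terms, replace = TRUE)
    collection <- tibble(
      term_id = sprintf("T%04d", seq_len(config$n_terms)),
      term_name = sprintf("synthetic term %d", seq_len(config$n_terms)),
      ontology = sample(c("BP", "CC", "MF"), config$n_terms, replace = TRUE),
      genes = lapply(sizes, function(s) sample(universe, s)))
    enriched_term <- collection$term_id[1]
    w <- rep(1, config$universe_size)
    w[universe %in% collection$genes[[1]]] <- config$enrichment_factor
    gene_list <- sample(universe, config$list_size, prob = w)
    list(collection = collection, gene_list = gene_list,
         universe = universe, enriched_term = enriched_term)
  })
}
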