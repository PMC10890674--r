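# Shared builders and independent oracles used across test files.

snv_events <- function(genes, ids = sprintf("E%03d", seq_along(genes))) {
  tibble::tibble(event_id = ids, type = "SNV", genes = as.list(genes))
}

# 8-node toy network: a weight-5 triangle (a, b, c) planted among
# unit-weight noise edges.
planted_triangle_network <- function() {
  likelihood_network(tibble::tibble(
    gene_a = c("a", "a", "b", "a", "b", "c", "d", "e", "f", "g"),
    gene_b = c("b", "c", "c", "d", "e", "f", "e", "f", "g", "h"),
    weight = c(5, 5, 5, 1, 1, 1, 1, 1, 1, 1)))
}

# Edge-weight lookup independent of the likelihood_network class
edge_weight_lookup <- function(edges) {
  key <- paste(pmin(edges$gene_a, edges$gene_b),
               pmax(edges$gene_a, edges$gene_b))
  stats::setNames(edges$weight, key)
}

oracle_cluster_score <- function(genes, edges) {
  if (length(genes) < 2) return(0)
  w <- edge_weight_lookup(edges)
  total <- 0
  cmb <- utils::combn(sort(genes), 2L)
  for (j in seq_len(ncol(cmb))) {
    k <- paste(cmb[1, j], cmb[2, j])
    if (k %in% names(w)) total <- total + w[[k]]
  }
  total
}

# Exhaustive search oracle: best score over all ways of picking k events
# and one gene from each picked event.
oracle_exhaustive_best <- function(events, edges, k) {
  n <- nrow(events)
  best <- -Inf
  best_genes <- NULL
  for (idx in utils::combn(n, k, simplify = FALSE)) {
    gene_choices <- expand.grid(events$genes[idx], stringsAsFactors = FALSE)
    for (r in seq_len(nrow(gene_choices))) {
      genes <- unlist(gene_choices[r, ], use.names = FALSE)
      if (anyDuplicated(genes)) next
      s <- oracle_cluster_score(genes, edges)
      if (s > best) {
        best <- s
        best_genes <- genes
      }
    }
  }
  list(score = best, genes = sort(best_genes))
}

# Per-site de novo decision by direct enumeration of all 27 trio dosage
# configurations, written independently of the package internals.
oracle_denovo_odds <- function(fd, fa, md, ma, pd, pa,
                               error_rate = 0.005, prior = 1e-4) {
  p_alt <- c(error_rate, 0.5, 1 - error_rate)
  lik <- function(depth, alt, g) dbinom(alt, depth, p_alt[g + 1])
  can_transmit <- function(g) switch(g + 1, 0L, c(0L, 1L), 1L)
  num <- 0
  den <- 0
  mendelian_cells <- 0L
  for (f in 0:2) for (m in 0:2) for (p in 0:2) {
    if (any(outer(can_transmit(f), can_transmit(m), "+") == p)) {
      mendelian_cells <- mendelian_cells + 1L
    }
  }
  for (f in 0:2) for (m in 0:2) for (p in 0:2) {
    l <- lik(fd, fa, f) * lik(md, ma, m) * lik(pd, pa, p)
    mendelian <- any(outer(can_transmit(f), can_transmit(m), "+") == p)
    if (f == 0 && m == 0 && p > 0) {
      num <- num + l * prior / 2
    } else if (mendelian) {
      den <- den + l * (1 - prior) / mendelian_cells
    }
  }
  log(num) - log(den)
}

# Transmission-based genotype classifier, coded from the definitions
# rather than the package's implementation.
oracle_classify <- function(fg, mg, pg) {
  fa <- strsplit(fg, "/")[[1]]
  mo <- strsplit(mg, "/")[[1]]
  pr <- sort(strsplit(pg, "/")[[1]])
  for (x in fa) for (y in mo) {
    if (identical(sort(c(x, y)), pr)) return("consistent")
  }
  novel <- setdiff(pr, c(fa, mo))
  if (pr[1] == pr[2] && all(pr %in% novel)) return("de_novo_hom")
  if (length(unique(novel)) == 1 && pr[1] != pr[2]) return("de_novo_het")
  "mendelian_violation_other"
}

random_genotype <- function(n, alleles = c("A", "C", "G", "T")) {
  paste(sample(alleles, n, replace = TRUE),
        sample(alleles, n, replace = TRUE), sep = "/")
}
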