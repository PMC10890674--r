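# Greedy search for a cohesive gene cluster in a weighted gene-gene
# phenotypic likelihood network, with permutation-based significance.
#
# Events are the search units: an SNV contributes one gene, a CNV or GWAS
# locus a set of genes of which at most one may enter a cluster.

#' Construct a weighted gene likelihood network
#'
#' The edge weight encodes the evidence that two genes share a phenotype.
#' The graph is undirected, without self-edges; an absent edge has weight
#' zero.
#'
#' @param edges A data frame with columns `gene_a`, `gene_b`, `weight`
#'   (one row per undirected edge; duplicate pairs are summed).
#' @param nodes Optional character vector of node names; defaults to the
#'   genes appearing in `edges`, and may add isolated nodes.
#' @return An object of class `likelihood_network`.
#' @export
likelihood_network <- function(edges, nodes = NULL) {
  edges <- as_tibble(edges)
  for (col in c("gene_a", "gene_b", "weight")) {
    if (!col %in% names(edges)) {
      abort(sprintf("`edges` lacks required column `%s`.", col))
    }
  }
  if (any(edges$gene_a == edges$gene_b)) {
    abort("Self-edges are not allowed in a likelihood network.")
  }
  nodes <- sort(unique(c(nodes, edges$gene_a, edges$gene_b)))
  idx <- setNames(seq_along(nodes), nodes)
  i <- idx[edges$gene_a]
  j <- idx[edges$gene_b]
  w <- Matrix::sparseMatrix(
    i = pmin(i, j), j = pmax(i, j), x = edges$weight,
    dims = c(length(nodes), length(nodes)), symmetric = TRUE)
  structure(list(nodes = nodes, weights = w, edges = edges),
            class = "likelihood_network")
}

#' @export
print.likelihood_network <- function(x, ...) {
  cat(sprintf("<likelihood_network> %d genes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

check_network <- function(network) {
  if (!inherits(network, "likelihood_network")) {
    abort("`network` must be a likelihood_network (see likelihood_network()).")
  }
  network
}

network_degree <- function(network) {
  Matrix::rowSums(network$weights != 0)
}

#' Score of a gene cluster
#'
#' The cluster score is the weighted sum of the network edges among the
#' cluster's genes. Empty and singleton clusters score 0.
#'
#' @param genes Character vector of gene symbols, all present in the
#'   network.
#' @param network A [likelihood_network()].
#' @return A single numeric score.
#' @export
cluster_score <- function(genes, network) {
  check_network(network)
  unknown <- setdiff(genes, network$nodes)
  if (length(unknown)) {
    abort(sprintf("Gene(s) not in the network: %s",
                  paste(unknown, collapse = ", ")))
  }
  if (length(genes) < 2L) return(0)
  i <- match(genes, network$nodes)
  sum(network$weights[i, i]) / 2
}

check_events <- function(events) {
  events <- as_tibble(events)
  for (col in c("event_id", "type", "genes")) {
    if (!col %in% names(events)) {
      abort(sprintf("`events` lacks required column `%s`.", col))
    }
  }
  if (!is.list(events$genes)) events$genes <- as.list(events$genes)
  sizes <- lengths(events$genes)
  if (any(sizes == 0L)) abort("Every event must carry at least one gene.")
  if (any(events$type == "SNV" & sizes != 1L)) {
    abort("SNV events must carry exactly one gene.")
  }
  if (anyDuplicated(events$event_id)) abort("Duplicate event ids.")
  events
}

# Dense weight submatrix over the event genes present in the network,
# with the per-gene event index. Genes appearing in several events are
# attributed to the first carrying event.
event_gene_table <- function(events, network) {
  genes <- unlist(events$genes, use.names = FALSE)
  event_of <- rep(seq_len(nrow(events)), lengths(events$genes))
  keep <- genes %in% network$nodes & !duplicated(genes)
  genes <- genes[keep]
  event_of <- event_of[keep]
  if (!length(genes)) abort("No event gene is present in the network.")
  ord <- order(genes)  # lexicographic, so ties resolve to smallest symbol
  genes <- genes[ord]
  event_of <- event_of[ord]
  W <- as.matrix(network$weights[match(genes, network$nodes),
                                 match(genes, network$nodes)])
  dimnames(W) <- list(genes, genes)
  list(genes = genes, event_of = event_of, W = W)
}

#' Greedy cluster search over genomic events
#'
#' Starting from every event gene as a seed, the search repeatedly adds
#' the gene (drawn from events not yet represented in the growing set)
#' whose connection to the current set yields the largest score increase,
#' and records the best-scoring set of every size `k <= k_max` across all
#' seeds. At most one gene per event ever enters a set, so a multi-gene
#' CNV/GWAS locus contributes a single gene. Score ties during growth are
#' broken by the lexicographically smallest gene symbol, making the search
#' fully deterministic.
#'
#' @param events A data frame with columns `event_id`, `type`
#'   (`"SNV"`/`"CNV"`/`"GWAS"`), and `genes` (list column of gene-symbol
#'   vectors; SNV events carry exactly one gene). Genes absent from the
#'   network are ignored.
#' @param network A [likelihood_network()].
#' @param k_max Largest cluster size to record (>= 2).
#' @return A tibble of class `greedy_clusters` with one row per cluster
#'   size: `k`, `score`, `genes` (list), `event_ids` (list).
#' @export
greedy_search <- function(events, network, k_max = 8) {
  check_network(network)
  events <- check_events(events)
  if (k_max < 2) abort("`k_max` must be at least 2.")
  if (nrow(events) == 0L) {
    out <- tibble(k = integer(0), score = numeric(0), genes = list(),
                  event_ids = list())
    class(out) <- c("greedy_clusters", class(out))
    return(out)
  }
  tab <- event_gene_table(events, network)
  k_max <- min(k_max, nrow(events), length(unique(tab$event_of)))

  n <- length(tab$genes)
  best_score <- rep(-Inf, k_max)
  best_set <- vector("list", k_max)

  for (seed in seq_len(n)) {
    sel <- seed
    used_events <- tab$event_of[seed]
    # connection of every gene to the current set
    conn <- tab$W[, seed]
    score <- 0
    if (score > best_score[1]) {
      best_score[1] <- score
      best_set[[1]] <- sel
    }
    k <- 1L
    while (k < k_max) {
      avail <- which(!(tab$event_of %in% used_events))
      if (!length(avail)) break
      inc <- conn[avail]
      pick <- avail[which.max(inc)]  # genes sorted, so first max = smallest symbol
      score <- score + conn[pick]
      sel <- c(sel, pick)
      used_events <- c(used_events, tab$event_of[pick])
      conn <- conn + tab$W[, pick]
      k <- k + 1L
      if (score > best_score[k]) {
        best_score[k] <- score
        best_set[[k]] <- sel
      }
    }
  }

  found <- which(is.finite(best_score))
  out <- tibble(
    k = found,
    score = best_score[found],
    genes = lapply(best_set[found], function(i) tab$genes[i]),
    event_ids = lapply(best_set[found], function(i) {
      events$event_id[tab$event_of[i]]
    }))
  class(out) <- c("greedy_clusters", class(out))
  out
}

# Structure-matched random events: same number of events, same number of
# genes per event, genes drawn from the network (optionally matched on
# weighted-degree decile).
randomize_events <- function(events, network, match = c("uniform", "degree")) {
  match <- match.arg(match)
  sizes <- lengths(events$genes)
  nodes <- network$nodes
  if (match == "uniform") {
    new_genes <- lapply(sizes, function(s) sample(nodes, s))
  } else {
    deg <- network_degree(network)
    brk <- unique(quantile(deg, probs = seq(0, 1, 0.1), names = FALSE))
    bin <- clamp_bin(findInterval(deg, brk, rightmost.closed = TRUE),
                     length(brk) - 1L)
    by_bin <- split(nodes, bin)
    orig_bin <- lapply(events$genes, function(g) {
      bin[match(g, nodes)]
    })
    new_genes <- lapply(orig_bin, function(b) {
      b[is.na(b)] <- sample(unique(bin), sum(is.na(b)), replace = TRUE)
      vapply(b, function(bb) sample(by_bin[[as.character(bb)]], 1L),
             character(1))
    })
  }
  mutate(events, genes = new_genes)
}

# Best greedy score for every size 2..k_max over n_perm structure-matched
# random event sets; one matrix row per permutation.
null_score_matrix <- function(events, network, k_max, n_perm,
                              match = "uniform") {
  out <- matrix(0, nrow = n_perm, ncol = k_max)
  for (b in seq_len(n_perm)) {
    perm <- randomize_events(events, network, match = match)
    res <- greedy_search(perm, network, k_max = k_max)
    out[b, res$k] <- res$score
  }
  out
}

#' Permutation null distribution of the best cluster score
#'
#' Each permutation replaces every event's gene set with a random set of
#' network genes of the same size (preserving the number of events and
#' genes per event), reruns the greedy search, and records the best score
#' at size `k`. Deterministic given `seed`.
#'
#' @inheritParams greedy_search
#' @param k Cluster size whose null scores are wanted (2 <= k <= number
#'   of events).
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param match `"uniform"` draws replacement genes uniformly;
#'   `"degree"` matches each replaced gene's weighted-degree decile.
#' @return Numeric vector of `n_perm` null scores.
#' @export
null_distribution <- function(events, network, k, n_perm = 100, seed = NULL,
                              match = c("uniform", "degree")) {
  check_network(network)
  events <- check_events(events)
  match <- match.arg(match)
  if (n_perm < 1) abort("`n_perm` must be at least 1.")
  if (k > nrow(events)) {
    abort(sprintf("Cluster size k = %d exceeds the number of events (%d).",
                  k, nrow(events)))
  }
  run <- function() null_score_matrix(events, network, k, n_perm, match)[, k]
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Permutation z-score and empirical p-value
#'
#' `p_raw` uses the add-one counting rule `(1 + #(null >= observed)) /
#' (1 + n_perm)`, so it can never be exactly zero; `z` is the observed
#' score standardized by the null mean and standard deviation (defined as
#' 0 when the null is degenerate).
#'
#' @param observed Observed cluster score.
#' @param null Numeric vector of null scores.
#' @return A one-row tibble with columns `z` and `p_raw`.
#' @export
significance <- function(observed, null) {
  if (!length(null)) abort("`null` must be non-empty.")
  s <- sd(null)
  z <- if (is.na(s) || s == 0) 0 else (observed - mean(null)) / s
  p_raw <- (1 + sum(null >= observed)) / (1 + length(null))
  tibble(z = z, p_raw = p_raw)
}

#' Best cluster across sizes with permutation significance
#'
#' Runs the greedy search for the observed events, builds the permutation
#' null for every size `2..k_max` from a common set of permutations,
#' computes the empirical p-value and z-score per size, adjusts the
#' p-values across the tested sizes (Bonferroni), and selects the size
#' with minimal adjusted p-value, breaking ties by maximal z-score (then
#' by smaller size).
#'
#' @inheritParams null_distribution
#' @param k_max Largest cluster size to test.
#' @return An object of class `cluster_result`: the selected cluster
#'   (genes, event assignment, score, `z`, `p_raw`, `p_adj`, size `k`),
#'   the per-size table (`by_k`), the null scores of the selected size,
#'   and the run parameters. Use [tidy()] for the gene-level assignment
#'   and [glance()] for the one-row summary.
#' @export
best_network <- function(events, network, k_max = 8, n_perm = 100,
                         seed = NULL, match = c("uniform", "degree")) {
  check_network(network)
  events <- check_events(events)
  match <- match.arg(match)
  observed <- greedy_search(events, network, k_max = k_max)
  k_cap <- max(observed$k)

  run_null <- function() {
    null_score_matrix(events, network, k_cap, n_perm, match)
  }
  nulls <- if (is.null(seed)) run_null() else withr::with_seed(seed, run_null())

  tested <- observed$k[observed$k >= 2L]
  m <- length(tested)
  by_k <- purrr::map_dfr(tested, function(k) {
    obs_k <- observed$score[observed$k == k]
    sig <- significance(obs_k, nulls[, k])
    tibble(k = k, score = obs_k, z = sig$z, p_raw = sig$p_raw,
           p_adj = min(1, sig$p_raw * m))
  })
  # minimal adjusted p, ties by maximal z, then smallest k
  ord <- order(by_k$p_adj, -by_k$z, by_k$k)
  pick <- by_k[ord[1], ]
  sel <- observed[observed$k == pick$k, ]

  structure(list(
    k = pick$k,
    genes = sel$genes[[1]],
    assignment = tibble(event_id = sel$event_ids[[1]], gene = sel$genes[[1]]),
    score = pick$score,
    z = pick$z,
    p_raw = pick$p_raw,
    p_adj = pick$p_adj,
    by_k = by_k,
    null_scores = nulls[, pick$k],
    n_perm = n_perm,
    k_max = k_max,
    seed = seed,
    match = match
  ), class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "<cluster_result> k = %d, score = %.4g, z = %.3g, p_raw = %.4g, p_adj = %.4g (%d permutations)\n",
    x$k, x$score, x$z, x$p_raw, x$p_adj, x$n_perm))
  cat("genes:", paste(x$genes, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname best_network
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @export
tidy.cluster_result <- function(x, ...) {
  x$assignment
}

#' @rdname best_network
#' @export
glance.cluster_result <- function(x, ...) {
  tibble(k = x$k, score = x$score, z = x$z, p_raw = x$p_raw, p_adj = x$p_adj,
         n_perm = x$n_perm, k_max = x$k_max)
}

#' Expand a cluster with its direct interactors for reporting
#'
#' The reported network around a selected cluster is the cluster's genes
#' together with their direct interactors from a physical protein-protein
#' interaction edge list (BioGRID-style), optionally restricted to genes
#' carrying given annotations (e.g. cytoskeleton and synapse GO classes).
#'
#' @param genes Character vector of selected cluster genes.
#' @param interactions A data frame with columns `gene_a`, `gene_b`.
#' @param keep_genes Optional character vector; interactors outside this
#'   set are dropped (`NULL` keeps all direct interactors).
#' @return A tibble with columns `gene` and `role`
#'   (`"selected"`/`"interactor"`).
#' @export
report_interactor_expansion <- function(genes, interactions,
                                        keep_genes = NULL) {
  interactions <- as_tibble(interactions)
  touching <- interactions$gene_a %in% genes | interactions$gene_b %in% genes
  partners <- setdiff(
    unique(c(interactions$gene_a[touching], interactions$gene_b[touching])),
    genes)
  if (!is.null(keep_genes)) partners <- intersect(partners, keep_genes)
  bind_rows(tibble(gene = sort(unique(genes)), role = "selected"),
            tibble(gene = sort(partners), role = "interactor"))
}
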