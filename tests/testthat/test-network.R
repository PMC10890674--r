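test_that("cluster scores sum the within-cluster edge weights", {
  net <- likelihood_network(tibble::tibble(
    gene_a = c("a", "a", "b"), gene_b = c("b", "c", "c"),
    weight = c(1, 2, 3)))
  expect_equal(cluster_score(character(0), net), 0)
  expect_equal(cluster_score("a", net), 0)
  expect_equal(cluster_score(c("a", "b"), net), 1)
  expect_equal(cluster_score(c("a", "b", "c"), net), 6)
  expect_error(cluster_score(c("a", "zz"), net), "zz")
  # invariance under relabeling
  relabeled <- likelihood_network(tibble::tibble(
    gene_a = c("x9", "x9", "y1"), gene_b = c("y1", "z", "z"),
    weight = c(1, 2, 3)))
  expect_equal(cluster_score(c("x9", "y1", "z"), relabeled), 6)
})

test_that("greedy search recovers a planted triangle and matches exhaustive search", {
  net <- planted_triangle_network()
  events <- snv_events(letters[1:8])
  res <- greedy_search(events, net, k_max = 3)
  expect_equal(sort(res$genes[[which(res$k == 3)]]), c("a", "b", "c"))
  oracle <- oracle_exhaustive_best(events, net$edges, 3)
  expect_equal(res$score[res$k == 3], oracle$score)
  expect_equal(sort(res$genes[[which(res$k == 3)]]), oracle$genes)
  # single SNV event: singleton cluster, score 0
  solo <- greedy_search(snv_events("a"), net, k_max = 3)
  expect_equal(solo$k, 1L)
  expect_equal(solo$score, 0)
})

test_that("multi-gene events contribute exactly one gene, the connected one", {
  net <- planted_triangle_network()
  events <- dplyr::bind_rows(
    snv_events(c("b", "c"), ids = c("Eb", "Ec")),
    tibble::tibble(event_id = "Ecnv", type = "CNV",
                   genes = list(c("a", "h"))))
  res <- greedy_search(events, net, k_max = 3)
  g3 <- res$genes[[which(res$k == 3)]]
  expect_setequal(g3, c("a", "b", "c"))  # picks a, not h, from the CNV
  oracle <- oracle_exhaustive_best(events, net$edges, 3)
  expect_equal(res$score[res$k == 3], oracle$score)
})

test_that("no cluster ever takes two genes from the same event", {
  withr::with_seed(77, {
    for (rep in 1:10) {
      sim <- simulate_likelihood_network(sim_config(
        seed = 700 + rep, n_genes = 30, p_edge = 0.3, module_size = 4))
      genes <- sim$network$nodes
      events <- tibble::tibble(
        event_id = sprintf("E%02d", 1:8),
        type = c(rep("SNV", 5), rep("CNV", 3)),
        genes = c(as.list(sample(genes, 5)),
                  replicate(3, sample(genes, 3), simplify = FALSE)))
      events$genes[6][[1]][1] <- events$genes[1][[1]]  # overlapping gene
      res <- greedy_search(events, sim$network, k_max = 6)
      for (i in seq_len(nrow(res))) {
        expect_equal(anyDuplicated(res$event_ids[[i]]), 0L)
        expect_equal(anyDuplicated(res$genes[[i]]), 0L)
      }
    }
  })
})

test_that("greedy scores never exceed the exhaustive optimum on small instances", {
  withr::with_seed(88, {
    for (rep in 1:12) {
      n <- sample(6:10, 1)
      genes <- paste0("g", seq_len(n))
      pairs <- utils::combn(genes, 2)
      on <- runif(ncol(pairs)) < 0.5
      edges <- tibble::tibble(gene_a = pairs[1, on], gene_b = pairs[2, on],
                              weight = rexp(sum(on)))
      net <- likelihood_network(edges, nodes = genes)
      events <- snv_events(genes)
      k <- sample(3:4, 1)
      res <- greedy_search(events, net, k_max = k)
      oracle <- oracle_exhaustive_best(events, edges, k)
      expect_lte(res$score[res$k == k], oracle$score + 1e-12)
    }
  })
})

test_that("null distributions are deterministic given a seed", {
  sim <- simulate_likelihood_network(sim_config(seed = 14, n_genes = 40,
                                                p_edge = 0.2))
  events <- snv_events(sample(sim$network$nodes, 10))
  n1 <- null_distribution(events, sim$network, k = 3, n_perm = 50, seed = 3)
  n2 <- null_distribution(events, sim$network, k = 3, n_perm = 50, seed = 3)
  expect_identical(n1, n2)
  expect_length(n1, 50)
  expect_error(null_distribution(events, sim$network, k = 11, n_perm = 5),
               "exceeds")
})

test_that("an all-zero network yields null scores of zero and p_adj 1", {
  net <- likelihood_network(tibble::tibble(
    gene_a = c("a", "b"), gene_b = c("b", "c"), weight = c(0, 0)),
    nodes = paste0(letters[1:6]))
  events <- snv_events(letters[1:5])
  expect_equal(null_distribution(events, net, k = 3, n_perm = 20, seed = 1),
               rep(0, 20))
  res <- best_network(events, net, k_max = 4, n_perm = 20, seed = 1)
  expect_equal(res$p_adj, 1)
  expect_equal(res$z, 0)
  expect_equal(res$score, 0)
})

test_that("significance follows the add-one counting rule and Gaussian tails", {
  null <- c(1, 2, 3)
  expect_equal(significance(0.5, null)$p_raw, 1)
  expect_equal(significance(10, rep(0, 99))$p_raw, 0.01)
  expect_equal(significance(5, rep(2, 10))$z, 0)  # degenerate null
  withr::with_seed(6, {
    null <- rnorm(10000)
    sig <- significance(2, null)
    expect_equal(sig$p_raw, pnorm(2, lower.tail = FALSE), tolerance = 0.15)
    expect_equal(sig$z, 2, tolerance = 0.1)
  })
})

test_that("adjusted p-values dominate raw ones and stay within [0, 1]", {
  sim <- simulate_likelihood_network(sim_config(seed = 21, n_genes = 40,
                                                p_edge = 0.15))
  events <- snv_events(sample(sim$network$nodes, 8))
  res <- best_network(events, sim$network, k_max = 5, n_perm = 40, seed = 2)
  expect_true(all(res$by_k$p_adj >= res$by_k$p_raw))
  expect_true(all(res$by_k$p_adj <= 1))
  expect_true(all(res$by_k$p_raw >= 1 / 41))
  # determinism of the full search
  res2 <- best_network(events, sim$network, k_max = 5, n_perm = 40, seed = 2)
  expect_equal(glance(res), glance(res2))
  expect_equal(tidy(res), tidy(res2))
})

test_that("the reporting expansion adds only annotated direct interactors", {
  interactions <- tibble::tibble(
    gene_a = c("a", "a", "b", "x"),
    gene_b = c("p", "q", "r", "y"))
  out <- report_interactor_expansion(c("a", "b"), interactions,
                                     keep_genes = c("p", "r"))
  expect_equal(out$gene[out$role == "selected"], c("a", "b"))
  expect_setequal(out$gene[out$role == "interactor"], c("p", "r"))
  all_in <- report_interactor_expansion("a", interactions)
  expect_setequal(all_in$gene[all_in$role == "interactor"], c("p", "q"))
})
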