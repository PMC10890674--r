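# Annotation-chart enrichment (hypergeometric / EASE), variant-type
# composition tests, and Venn-overlap statistics.

check_hyper_counts <- function(k, K, n, N_bg) {
  if (any(c(k, K, n, N_bg) < 0) || any(c(k, K, n, N_bg) != floor(c(k, K, n, N_bg)))) {
    abort("Counts must be non-negative integers.")
  }
  if (any(k > pmin(K, n)) || any(K > N_bg) || any(n > N_bg)) {
    abort("Inconsistent counts: need k <= min(K, n) and K, n <= N_bg.")
  }
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` where `X` is the overlap between a list of `n` genes and a
#' term of `K` genes drawn from a background of `N_bg` genes. Computed by
#' log-space summation of the probability mass function, so very small
#' tails are exact to machine precision.
#'
#' @param k Observed overlap.
#' @param K Term (category) size.
#' @param n Gene-list size.
#' @param N_bg Background universe size.
#' @return A probability (vectorized over the arguments).
#' @export
#' @examples
#' hypergeometric_tail(3, 10, 5, 100)
hypergeometric_tail <- function(k, K, n, N_bg) {
  args <- vctrs_recycle(k, K, n, N_bg)
  check_hyper_counts(args$a, args$b, args$c, args$d)
  mapply(function(k, K, n, N_bg) {
    if (k == 0) return(1)
    i <- k:min(K, n)
    lp <- lchoose(K, i) + lchoose(N_bg - K, n - i) - lchoose(N_bg, n)
    min(1, exp(logsumexp(lp)))
  }, args$a, args$b, args$c, args$d)
}

# minimal common-length recycling for 4 numeric args
vctrs_recycle <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  list(a = rep_len(a, n), b = rep_len(b, n), c = rep_len(c, n),
       d = rep_len(d, n))
}

#' EASE score (jackknifed hypergeometric tail)
#'
#' The conservative enrichment statistic used by DAVID's functional
#' annotation chart: the upper-tail hypergeometric probability with one
#' hit removed from the overlap, `P(X >= k - 1)`. An overlap of a single
#' gene can never be significant (`k <= 1` gives 1).
#'
#' @inheritParams hypergeometric_tail
#' @return A probability (vectorized).
#' @export
ease_score <- function(k, K, n, N_bg) {
  args <- vctrs_recycle(k, K, n, N_bg)
  check_hyper_counts(args$a, args$b, args$c, args$d)
  hypergeometric_tail(pmax(args$a - 1, 0), args$b, args$c, args$d)
}

check_collection <- function(collection) {
  collection <- as_tibble(collection)
  for (col in c("term_id", "genes")) {
    if (!col %in% names(collection)) {
      abort(sprintf("`collection` lacks required column `%s`.", col))
    }
  }
  if (!"term_name" %in% names(collection)) collection$term_name <- collection$term_id
  if (!"ontology" %in% names(collection)) collection$ontology <- NA_character_
  if (anyDuplicated(collection$term_id)) abort("Duplicate term ids in collection.")
  if (any(lengths(collection$genes) == 0L)) {
    abort("Every annotation term must have a non-empty gene set.")
  }
  collection
}

#' Functional annotation chart
#'
#' Tests each annotation term for over-representation in a gene list
#' against a background universe, DAVID-style. The default statistic is
#' the EASE score; `"fisher"` uses the plain one-sided hypergeometric
#' tail. Genes outside the background are dropped with a warning, and
#' only terms overlapping the list (`k >= 1`) are reported, sorted by raw
#' p-value. Multiple-testing adjustment is applied across all reported
#' terms.
#'
#' @param gene_list Character vector of gene symbols.
#' @param collection A data frame of annotation terms: `term_id`,
#'   optional `term_name` and `ontology`, and a `genes` list column (as
#'   returned by [read_gmt()]).
#' @param background Character vector: the gene universe.
#' @param method `"ease"` (default) or `"fisher"`.
#' @param adjust `"BH"` (default), `"bonferroni"`, or `"none"`.
#' @return A tibble with columns `term_id`, `term_name`, `ontology`, `k`
#'   (overlap), `K` (term size in background), `n` (list size), `N_bg`,
#'   `p_raw`, `p_adj`.
#' @export
annotation_chart <- function(gene_list, collection, background,
                             method = c("ease", "fisher"),
                             adjust = c("BH", "bonferroni", "none")) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  collection <- check_collection(collection)
  background <- unique(background)
  if (!length(background)) abort("`background` must be non-empty.")
  gene_list <- unique(gene_list)
  outside <- setdiff(gene_list, background)
  if (length(outside)) {
    warn(sprintf("%d gene(s) outside the background were dropped: %s",
                 length(outside),
                 paste(head(outside, 5), collapse = ", ")))
    gene_list <- intersect(gene_list, background)
  }
  n <- length(gene_list)
  N_bg <- length(background)
  stat <- if (method == "ease") ease_score else hypergeometric_tail

  res <- collection |>
    mutate(
      K = map_int(.data$genes, ~ length(intersect(unique(.x), background))),
      k = map_int(.data$genes, ~ length(intersect(unique(.x), gene_list))),
      n = n, N_bg = N_bg) |>
    filter(.data$k >= 1L, .data$K >= 1L)
  if (nrow(res) == 0L) {
    return(tibble(term_id = character(0), term_name = character(0),
                  ontology = character(0), k = integer(0), K = integer(0),
                  n = integer(0), N_bg = integer(0), p_raw = numeric(0),
                  p_adj = numeric(0)))
  }
  res |>
    mutate(p_raw = stat(.data$k, .data$K, .data$n, .data$N_bg),
           p_adj = p.adjust(.data$p_raw, method = adjust)) |>
    arrange(.data$p_raw, .data$term_id) |>
    select("term_id", "term_name", "ontology", "k", "K", "n", "N_bg",
           "p_raw", "p_adj")
}

#' One-sided composition test for a 2x2 table
#'
#' Fisher's exact test that a category (e.g. a GO class within a network)
#' is enriched for a tag (e.g. genes contributed by GWAS loci), given the
#' 2x2 table of in/out-category by tagged/untagged counts. One-sided in
#' the direction of over-representation of the tag in the category.
#'
#' @param category_counts A 2x2 numeric matrix or table, rows =
#'   in-category / out-category, columns = tagged / untagged.
#' @return A single p-value.
#' @export
#' @examples
#' composition_test(matrix(c(6, 2, 18, 46), nrow = 2))
composition_test <- function(category_counts) {
  m <- as.matrix(category_counts)
  if (!all(dim(m) == c(2L, 2L))) abort("`category_counts` must be 2x2.")
  if (any(m < 0) || any(m != floor(m))) abort("Counts must be non-negative integers.")
  if (sum(m) == 0) abort("All-zero table.")
  fisher.test(m, alternative = "greater")$p.value
}

#' Venn-partition overlaps with a reference gene set
#'
#' Computes the cardinality of every region of the Venn partition of the
#' named gene lists, and for each list the upper-tail hypergeometric
#' p-value of its overlap with a reference set (e.g. a GO class) given a
#' background universe size.
#'
#' @param lists Named list of character vectors (e.g. disease gene
#'   lists).
#' @param reference Character vector: the reference gene set.
#' @param n_background Background universe size, at least the size of the
#'   union of all lists and the reference.
#' @return A list with `regions` (tibble: `region`, `size`) over all
#'   non-empty combinations of the input lists, and `per_list` (tibble:
#'   `list`, `overlap`, `list_size`, `reference_size`, `p`).
#' @export
venn_overlap <- function(lists, reference, n_background) {
  if (is.null(names(lists)) || any(names(lists) == "")) {
    abort("`lists` must be a fully named list of gene vectors.")
  }
  lists <- lapply(lists, unique)
  reference <- unique(reference)
  universe_used <- length(unique(c(unlist(lists), reference)))
  if (n_background < universe_used) {
    abort("`n_background` is smaller than the union of the input sets.")
  }
  nm <- names(lists)
  all_genes <- unique(unlist(lists))
  membership <- vapply(lists, function(g) all_genes %in% g,
                       logical(length(all_genes)))
  if (length(all_genes) == 1L) membership <- matrix(membership, nrow = 1L)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(nm)),
                        KEEP.OUT.ATTRS = FALSE)
  names(combos) <- nm
  combos <- combos[rowSums(combos) > 0, , drop = FALSE]
  regions <- tibble(
    region = apply(combos, 1, function(r) paste(nm[as.logical(r)], collapse = "&")),
    size = vapply(seq_len(nrow(combos)), function(j) {
      r <- as.logical(combos[j, ])
      if (!length(all_genes)) return(0L)
      sum(apply(membership, 1, function(row) all(row == r)))
    }, integer(1)))
  regions$region <- unname(regions$region)
  per_list <- purrr::map_dfr(nm, function(name) {
    g <- lists[[name]]
    k <- length(intersect(g, reference))
    tibble(list = name, overlap = k, list_size = length(g),
           reference_size = length(reference),
           p = hypergeometric_tail(k, length(reference), length(g),
                                   n_background))
  })
  list(regions = regions, per_list = per_list)
}
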