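# Plain-text format readers and writers: variant tables, weighted edge
# lists, GMT annotation collections, gene lists, event tables, and trio
# VCF input. Writers prepend a '#' provenance header which all readers
# skip, so every format round-trips exactly.

provenance_header <- function(what, seed = NULL) {
  c(sprintf("# %s written by trionet %s", what,
            as.character(utils::packageVersion("trionet"))),
    if (!is.null(seed)) sprintf("# seed: %s", seed))
}

write_with_header <- function(df, path, what, seed = NULL) {
  writeLines(provenance_header(what, seed), path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' Write a variant table
#'
#' Inverse of [read_variant_table()]: writes the normalized schema so a
#' read/write/read cycle is the identity.
#'
#' @param records Variant records.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_variant_table <- function(records, path) {
  out <- as_tibble(records)
  out <- rename(out, Cohort = "cohort", Gene = "gene",
                Chromosome = "chromosome", Position = "position",
                Father = "father", Mother = "mother", Patient = "patient",
                `PPH2 Score` = "pph2_score")
  out$`PPH2 Prediction` <- gsub("_", " ", records$pph2_class)
  out$pph2_class <- NULL
  write_with_header(out, path, "variant table")
}

#' Read / write a weighted gene-gene edge list
#'
#' Three-column TSV (`gene_a`, `gene_b`, `weight`), the interchange
#' format for likelihood networks.
#'
#' @param path File path.
#' @return `read_edge_list()` returns a [likelihood_network()].
#' @export
read_edge_list <- function(path) {
  edges <- readr::read_tsv(path, comment = "#", progress = FALSE,
                           col_types = readr::cols(
                             gene_a = "c", gene_b = "c", weight = "d"))
  likelihood_network(edges)
}

#' @rdname read_edge_list
#' @param network A [likelihood_network()].
#' @param seed Optional seed recorded in the provenance header.
#' @export
write_edge_list <- function(network, path, seed = NULL) {
  check_network(network)
  write_with_header(network$edges[, c("gene_a", "gene_b", "weight")],
                    path, "edge list", seed)
}

#' Read / write GMT annotation collections
#'
#' Standard GMT: one term per line, tab-separated `term_id`,
#' description, then the member genes. The description field stores
#' `ontology|term_name` when an ontology is known, plain `term_name`
#' otherwise.
#'
#' @param path File path.
#' @return `read_gmt()` returns a tibble with columns `term_id`,
#'   `term_name`, `ontology`, `genes` (list).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) {
    return(tibble(term_id = character(0), term_name = character(0),
                  ontology = character(0), genes = list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3L
  if (any(bad)) {
    abort(sprintf("GMT line(s) with fewer than 3 fields: %s",
                  paste(which(bad), collapse = ", ")))
  }
  desc <- map_chr(fields, 2L)
  has_onto <- grepl("^(BP|CC|MF)\\|", desc)
  tibble(
    term_id = map_chr(fields, 1L),
    term_name = ifelse(has_onto, sub("^(BP|CC|MF)\\|", "", desc), desc),
    ontology = ifelse(has_onto, sub("\\|.*$", "", desc), NA_character_),
    genes = lapply(fields, function(f) f[-(1:2)]))
}

#' @rdname read_gmt
#' @param collection Annotation collection tibble.
#' @export
write_gmt <- function(collection, path) {
  collection <- check_collection(collection)
  desc <- ifelse(is.na(collection$ontology), collection$term_name,
                 paste(collection$ontology, collection$term_name, sep = "|"))
  lines <- vapply(seq_len(nrow(collection)), function(i) {
    paste(c(collection$term_id[i], desc[i], collection$genes[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write plain gene lists
#'
#' One gene symbol per line; `#` comments and blank lines are skipped.
#'
#' @param path File path.
#' @return `read_gene_list()` returns a character vector.
#' @export
read_gene_list <- function(path) {
  lines <- trimws(readLines(path))
  lines[!grepl("^#", lines) & nzchar(lines)]
}

#' @rdname read_gene_list
#' @param genes Character vector of gene symbols.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' Read / write genomic event tables
#'
#' TSV with columns `event_id`, `type`, `genes` (comma-separated within
#' the field).
#'
#' @param path File path.
#' @return `read_events()` returns the events tibble used by
#'   [greedy_search()].
#' @export
read_events <- function(path) {
  raw <- readr::read_tsv(path, comment = "#", progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  for (col in c("event_id", "type", "genes")) {
    if (!col %in% names(raw)) {
      abort(sprintf("Event table lacks column `%s`.", col))
    }
  }
  check_events(tibble(event_id = raw$event_id, type = raw$type,
                      genes = strsplit(raw$genes, ",", fixed = TRUE)))
}

#' @rdname read_events
#' @param events Events tibble.
#' @param seed Optional seed recorded in the provenance header.
#' @export
write_events <- function(events, path, seed = NULL) {
  events <- check_events(events)
  flat <- tibble(event_id = events$event_id, type = events$type,
                 genes = map_chr(events$genes, paste, collapse = ","))
  write_with_header(flat, path, "event table", seed)
}

#' Read trio read counts from a VCF
#'
#' Extracts per-member depth and alternate-read counts from a
#' three-sample VCF using the AD (allelic depth) FORMAT field, mapping
#' samples to pedigree roles through `pedigree`. Multi-allelic sites use
#' the first alternate allele. Requires the vcfR package.
#'
#' @param path Path to a VCF file.
#' @param pedigree Named character vector mapping roles to sample names:
#'   `c(father = ..., mother = ..., proband = ...)`.
#' @return A sites tibble as consumed by [detect_candidates()].
#' @export
read_trio_vcf <- function(path, pedigree) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("Reading VCF input requires the vcfR package.")
  }
  roles <- c("father", "mother", "proband")
  if (!all(roles %in% names(pedigree))) {
    abort("`pedigree` must name father, mother, and proband samples.")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")
  missing_samples <- setdiff(unname(pedigree[roles]), colnames(ad))
  if (length(missing_samples)) {
    abort(sprintf("Sample(s) not in VCF: %s",
                  paste(missing_samples, collapse = ", ")))
  }
  split_ad <- function(x) {
    parts <- strsplit(x, ",", fixed = TRUE)
    ref <- suppressWarnings(as.integer(map_chr(parts, 1L)))
    alt <- suppressWarnings(as.integer(vapply(parts, function(p) {
      if (length(p) >= 2L) p[2L] else "0"
    }, character(1))))
    ref[is.na(ref)] <- 0L
    alt[is.na(alt)] <- 0L
    list(depth = ref + alt, alt = alt)
  }
  fa <- split_ad(ad[, pedigree[["father"]]])
  mo <- split_ad(ad[, pedigree[["mother"]]])
  pr <- split_ad(ad[, pedigree[["proband"]]])
  fix <- vcfR::getFIX(v)
  tibble(
    site_id = paste0(fix[, "CHROM"], ":", fix[, "POS"]),
    chrom = normalize_chromosome(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    father_depth = fa$depth, father_alt = fa$alt,
    mother_depth = mo$depth, mother_alt = mo$alt,
    proband_depth = pr$depth, proband_alt = pr$alt)
}

#' Round-trip a file through its reader and writer
#'
#' Reads `path`, writes the in-memory content to a temporary file, reads
#' it back, and reports whether the two in-memory objects are identical.
#' A self-check that the plain-text interchange formats are lossless.
#'
#' @param path File path.
#' @param format One of `"variants"`, `"edges"`, `"gmt"`, `"genes"`,
#'   `"events"`.
#' @return `TRUE` when the round trip is exact.
#' @export
roundtrip_formats <- function(path,
                              format = c("variants", "edges", "gmt",
                                         "genes", "events")) {
  format <- match.arg(format)
  io <- switch(format,
    variants = list(read = read_variant_table, write = write_variant_table),
    edges = list(read = read_edge_list,
                 write = function(x, p) write_edge_list(x, p)),
    gmt = list(read = read_gmt, write = write_gmt),
    genes = list(read = read_gene_list, write = write_gene_list),
    events = list(read = read_events, write = function(x, p) write_events(x, p)))
  first <- io$read(path)
  tmp <- tempfile(fileext = paste0(".", format))
  on.exit(unlink(tmp))
  io$write(first, tmp)
  second <- io$read(tmp)
  if (format == "edges") {
    first <- first$edges
    second <- second$edges
  }
  attr(first, "seed") <- NULL
  attr(second, "seed") <- NULL
  isTRUE(all.equal(first, second, check.attributes = FALSE))
}
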