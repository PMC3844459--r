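#' Read a gene location file
#'
#' Four whitespace- or tab-delimited columns: gene symbol, chromosome label,
#' start and end position (1-based, inclusive). Chromosome labels are opaque
#' strings and must match the map file literally ("1" and "chr1" are
#' different labels).
#'
#' @param path Path to the gene file.
#' @return Tibble with `gene_symbol`, `chrom`, `start`, `end`, sorted by
#'   `(chrom, start)`.
#' @export
read_gene_file <- function(path) {
  if (!file.exists(path)) abort(paste0("gene file not found: ", path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(tibble::tibble(gene_symbol = character(), chrom = character(),
                          start = integer(), end = integer()))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  bad <- which(nf < 4L)
  if (length(bad) > 0L) {
    abort(sprintf("gene file line %d: expected 4 columns, found %d", bad[1], nf[bad[1]]))
  }
  rec <- t(vapply(fields, function(f) f[1:4], character(4)))
  start <- suppressWarnings(as.integer(rec[, 3L]))
  end <- suppressWarnings(as.integer(rec[, 4L]))
  if (anyNA(start) || anyNA(end)) {
    abort(sprintf("gene file line %d: non-integer coordinates",
                  which(is.na(start) | is.na(end))[1]))
  }
  bad <- which(start > end)
  if (length(bad) > 0L) {
    abort(sprintf("gene '%s': start (%d) > end (%d)", rec[bad[1], 1L],
                  start[bad[1]], end[bad[1]]))
  }
  if (anyDuplicated(rec[, 1L])) {
    abort(sprintf("duplicate gene symbol '%s' in gene file",
                  rec[duplicated(rec[, 1L]), 1L][1]))
  }
  tibble::tibble(gene_symbol = rec[, 1L], chrom = rec[, 2L],
                 start = start, end = end) |>
    dplyr::arrange(.data$chrom, .data$start)
}

#' Read a GMT-style pathway definition file
#'
#' One pathway per tab-delimited line: name, description (may be empty), then
#' gene symbols. Duplicate symbols within a pathway are dropped, preserving
#' first occurrence; pathways listing no genes are skipped with a warning.
#'
#' @param path Path to the pathway file.
#' @return Tibble with `pathway`, `description` and a list-column `genes` of
#'   character vectors.
#' @export
read_pathway_file <- function(path) {
  if (!file.exists(path)) abort(paste0("pathway file not found: ", path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  empty <- lengths(fields) < 3L
  if (any(empty)) {
    warn(sprintf("skipping %d pathway line(s) with no gene fields: %s",
                 sum(empty),
                 paste(head(vapply(fields[empty], `[`, character(1), 1L), 5L),
                       collapse = ", ")))
    fields <- fields[!empty]
  }
  tibble::tibble(
    pathway = vapply(fields, `[`, character(1), 1L),
    description = vapply(fields, `[`, character(1), 2L),
    genes = lapply(fields, function(f) unique(f[-(1:2)]))
  )
}

#' Write a pathway result table to TSV
#'
#' Columns: `pathway`, `n_genes_mapped`, `ES`, `p_perm`, `p_adjusted`,
#' `fdr_q`; rows sorted by `p_perm` ascending with ties broken by pathway
#' name.
#'
#' @param results A `pathway_pdt` fit or its tidy results tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  if (inherits(results, "pathway_pdt")) results <- results$results
  out <- results |>
    dplyr::transmute(
      pathway = .data$pathway,
      n_genes_mapped = .data$n_genes,
      ES = .data$es,
      p_perm = .data$p_perm,
      p_adjusted = .data$p_adjusted,
      fdr_q = .data$fdr_q
    ) |>
    dplyr::arrange(.data$p_perm, .data$pathway)
  readr::write_tsv(out, path)
  invisible(path)
}
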