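#' Assign SNPs to genes with a kilobase window
#'
#' A SNP belongs to a gene when its position lies within
#' `[start - 1000 * window_kb, end + 1000 * window_kb]` on the same
#' chromosome label (literal string match). A SNP may be assigned to several
#' overlapping genes. Genes with no assigned SNP are dropped.
#'
#' @param snps Tibble of SNP metadata (`snp_index`, `snp_id`, `chrom`,
#'   `pos`), e.g. the `snps` element of a `ped_data` object.
#' @param genes Tibble from [read_gene_file()] (`gene_symbol`, `chrom`,
#'   `start`, `end`).
#' @param window_kb Window size in kb on each side of the gene; 5 by default
#'   (20 is the common alternative for capturing regulatory SNPs).
#' @param quiet Suppress informational messages.
#' @return Tibble with one row per (gene, SNP) assignment: `gene_symbol`,
#'   `snp_index`, `snp_id`.
#' @export
map_snps_to_genes <- function(snps, genes, window_kb = 5, quiet = FALSE) {
  stopifnot(window_kb >= 0)
  if (nrow(genes) == 0L) abort("gene table is empty: no genes to map SNPs to")
  pad <- as.integer(round(1000 * window_kb))
  map <- dplyr::inner_join(
    genes |> dplyr::select("gene_symbol", "chrom", "start", "end"),
    snps |> dplyr::select("snp_index", "snp_id", "chrom", "pos"),
    by = "chrom", relationship = "many-to-many"
  ) |>
    dplyr::filter(.data$pos >= .data$start - pad, .data$pos <= .data$end + pad) |>
    dplyr::select("gene_symbol", "snp_index", "snp_id") |>
    dplyr::arrange(.data$gene_symbol, .data$snp_index)
  if (nrow(map) == 0L) {
    abort("no SNP could be assigned to any gene (check that chromosome labels in the map and gene files agree literally)")
  }
  if (!quiet) {
    shared <- length(intersect(unique(genes$chrom), unique(snps$chrom)))
    if (shared == 0L) warn("no chromosome label shared between map and gene file")
    inform(sprintf("mapped %d SNPs to %d genes (window %g kb)",
                   dplyr::n_distinct(map$snp_index),
                   dplyr::n_distinct(map$gene_symbol), window_kb))
  }
  map
}

#' Reduce SNP statistics to one score per gene
#'
#' Each gene's score is the largest squared PDT statistic (`score =
#' "squared"`, the default, a 1-df chi-square-scale quantity) or largest
#' absolute statistic (`score = "abs"`) over its informative SNPs — the
#' best-SNP reduction matching the minimum single-SNP p-value.
#' Uninformative SNPs (permutation-invariant denominator of zero) are
#' excluded from the maximum, and genes whose SNPs are all uninformative are
#' dropped, so a monomorphic SNP can never represent a gene.
#'
#' @param gene_map Tibble from [map_snps_to_genes()].
#' @param stats A `pdt_stats` object or its `stats` tibble.
#' @param score `"squared"` for \eqn{z^2} (default) or `"abs"` for
#'   \eqn{|z|}. The two give identical rankings; enrichment-score values
#'   differ.
#' @return Tibble (`gene_symbol`, `r`, `best_snp_id`, `n_snps`) sorted by
#'   `r` descending, ties broken by `gene_symbol` ascending.
#' @export
gene_scores <- function(gene_map, stats, score = c("squared", "abs")) {
  score <- match.arg(score)
  if (inherits(stats, "pdt_stats")) stats <- stats$stats
  joined <- dplyr::inner_join(gene_map, stats, by = c("snp_index", "snp_id")) |>
    dplyr::filter(.data$informative)
  if (nrow(joined) == 0L) {
    abort("no gene has an informative SNP: nothing to rank")
  }
  joined$r_snp <- if (score == "squared") joined$z^2 else abs(joined$z)
  joined |>
    dplyr::group_by(.data$gene_symbol) |>
    dplyr::summarise(
      r = max(.data$r_snp),
      best_snp_id = .data$snp_id[which.max(.data$r_snp)],
      n_snps = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$r), .data$gene_symbol)
}
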