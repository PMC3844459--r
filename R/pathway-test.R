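#' Per-permutation sign matrix
#'
#' The permutation null exchanges transmitted and untransmitted alleles
#' within each family, which negates that family's PDT summand; SNPs on the
#' same chromosome share one sign so linkage disequilibrium is preserved.
#' This returns the deterministic sign draw (±1, families x chromosome
#' blocks) for one permutation seed — the exact stream the permutation
#' engine consumes, exposed so an explicit transmission-flipping oracle can
#' replay it.
#'
#' @param seed Integer seed for this permutation.
#' @param n_fam Number of families.
#' @param n_chrom Number of chromosome blocks.
#' @return Integer matrix of ±1, `n_fam` x `n_chrom`.
#' @export
sign_matrix <- function(seed, n_fam, n_chrom) {
  sign_matrix_cpp(as.numeric(seed), as.integer(n_fam), as.integer(n_chrom))
}

#' Apply a sign-flip permutation to PDT statistics
#'
#' Multiplies each family's PDT summand by its per-chromosome sign and
#' recomputes every SNP's statistic. The denominator
#' \eqn{\sqrt{\sum_i D_i^2}} is sign-invariant, so only the numerator moves.
#'
#' @param stats A `pdt_stats` object.
#' @param signs ±1 matrix, families x chromosome blocks (chromosomes in
#'   order of first appearance in the map), e.g. from [sign_matrix()].
#' @return Tibble (`snp_index`, `snp_id`, `z`) of permuted statistics;
#'   uninformative SNPs keep `z = 0`.
#' @export
permute_signs <- function(stats, signs) {
  stopifnot(inherits(stats, "pdt_stats"))
  chrom_block <- match(stats$stats$chrom, unique(stats$stats$chrom))
  stopifnot(nrow(signs) == nrow(stats$d_matrix),
            ncol(signs) >= max(chrom_block))
  num <- colSums(stats$d_matrix * signs[, chrom_block, drop = FALSE])
  z <- ifelse(stats$stats$informative, num / sqrt(stats$stats$sum_d2), 0)
  tibble::tibble(snp_index = stats$stats$snp_index,
                 snp_id = stats$stats$snp_id, z = z)
}

#' Family-based pathway association test
#'
#' Runs the full pathway analysis: per-SNP PDT statistics from nuclear
#' families, SNP-to-gene assignment within a ±`window_kb` kb window, best-SNP
#' gene scores, the weighted KS-like enrichment score per pathway, and a
#' within-family sign-flip permutation null (`K` permutations, one sign per
#' family per chromosome). Per-pathway permutation p-values are accompanied
#' by family-wise adjusted p-values (max-statistic over permutation-
#' normalised enrichment scores) and Benjamini-Hochberg FDR q-values.
#'
#' Across permutations the gene-to-SNP map, the ranked gene set, pathway
#' memberships and the per-SNP denominators are frozen; only the signs of
#' the family summands are redrawn, so gene and pathway sizes cannot bias
#' the null. Results are reproducible for a fixed `seed` and invariant to
#' `threads`: each permutation owns a seed derived from `seed` by index.
#'
#' @param ped A `ped_data` object, or a length-2 character vector
#'   `c(ped, map)` of file paths.
#' @param genes Gene table from [read_gene_file()], or a path.
#' @param pathways Pathway table from [read_pathway_file()], or a path.
#' @param window_kb SNP-to-gene window in kb (default 5; 20 is the common
#'   alternative).
#' @param K Number of permutations (default 2000; raise for finer p-value
#'   resolution).
#' @param w Gene-score weight exponent in the running sum (default 1).
#' @param seed Integer seed; if `NULL` one is drawn and reported so the run
#'   can be reproduced.
#' @param threads Number of worker processes for the permutation loop;
#'   results are identical for any value.
#' @param score Gene score: `"squared"` (\eqn{z^2}, default) or `"abs"`.
#' @param tie_rule `"ge"` (default): p = (1 + #\{ES* >= ES\})/(K + 1),
#'   conservative and never zero; `"gt"`: p = #\{ES* > ES\}/K, the strict
#'   exceedance proportion.
#' @param sign_by `"chromosome"` (default): one sign per family per
#'   chromosome, preserving within-chromosome LD; `"genome"`: a single sign
#'   per family.
#' @param min_genes,max_genes Pathway-size bounds after mapping; pathways
#'   outside `[min_genes, min(max_genes, N - 1)]` are skipped with a reason.
#' @param average Use avg-PDT family summands (see [pdt_snp_stats()]).
#' @param quiet Suppress progress messages.
#' @return An object of class `pathway_pdt` with elements `results` (tibble:
#'   `pathway`, `n_genes`, `es`, `nes`, `p_perm`, `p_adjusted`, `fdr_q`,
#'   sorted by `p_perm`), `skipped` (tibble of excluded pathways with
#'   reasons), `score_table`, `pathway_genes`, `es_perm` (pathways x K),
#'   `n_genes_ranked`, `K`, `seed`, and QC counts. See [tidy.pathway_pdt()],
#'   [glance.pathway_pdt()], [autoplot.pathway_pdt()].
#' @examples
#' sim <- simulate_families(sim_config(n_families = 30, n_chrom = 3,
#'                                     snps_per_chrom = 20, n_genes = 6,
#'                                     target_genes = 3, n_pathways = 2,
#'                                     seed = 11))
#' fit <- pathway_pdt(sim$ped, sim$genes, sim$pathways, K = 99, seed = 1,
#'                    quiet = TRUE)
#' tidy(fit)
#' @export
pathway_pdt <- function(ped, genes, pathways, window_kb = 5, K = 2000, w = 1,
                        seed = NULL, threads = 1,
                        score = c("squared", "abs"),
                        tie_rule = c("ge", "gt"),
                        sign_by = c("chromosome", "genome"),
                        min_genes = 2, max_genes = Inf,
                        average = FALSE, quiet = FALSE) {
  score <- match.arg(score)
  tie_rule <- match.arg(tie_rule)
  sign_by <- match.arg(sign_by)
  stopifnot(K >= 1, w >= 0, threads >= 1, min_genes >= 1)

  if (is.character(ped)) {
    stopifnot(length(ped) == 2L)
    ped <- read_ped_map(ped[1], ped[2], quiet = quiet)
  }
  if (is.character(genes)) genes <- read_gene_file(genes)
  if (is.character(pathways)) pathways <- read_pathway_file(pathways)
  stopifnot(inherits(ped, "ped_data"))

  if (is.null(seed)) {
    seed <- sample.int(.Machine$integer.max, 1L)
    inform(sprintf("no seed supplied; using seed = %d", seed))
  }

  st <- pdt_snp_stats(ped, average = average, quiet = quiet)
  gmap <- map_snps_to_genes(ped$snps, genes, window_kb = window_kb,
                            quiet = quiet)
  tab <- gene_scores(gmap, st, score = score)
  n_gene <- nrow(tab)

  # frozen structures for the permutation engine, genes in symbol order
  gene_order <- sort(tab$gene_symbol)
  info <- st$stats$informative
  col_of_snp <- cumsum(info)            # 1-based column in the informative subset
  gmap_info <- gmap[info[gmap$snp_index], , drop = FALSE]
  gene_snps0 <- lapply(gene_order, function(g) {
    as.integer(col_of_snp[gmap_info$snp_index[gmap_info$gene_symbol == g]] - 1L)
  })
  d_info <- st$d_matrix[, info, drop = FALSE]
  denom <- sqrt(st$stats$sum_d2[info])
  chrom_info <- st$stats$chrom[info]
  if (sign_by == "genome") {
    chrom0 <- rep(0L, length(chrom_info))
    n_chrom <- 1L
  } else {
    chrom0 <- match(chrom_info, unique(chrom_info)) - 1L
    n_chrom <- length(unique(chrom_info))
  }

  # admissible pathways, frozen membership
  max_h <- min(max_genes, n_gene - 1L)
  keep <- list(); skipped <- list()
  for (i in seq_len(nrow(pathways))) {
    nm <- pathways$pathway[i]
    gs <- intersect(pathways$genes[[i]], tab$gene_symbol)
    n_h <- length(gs)
    if (n_h < min_genes || n_h > max_h) {
      skipped[[length(skipped) + 1L]] <- tibble::tibble(
        pathway = nm,
        reason = sprintf("%d mapped gene(s) outside admissible range [%d, %d]",
                         n_h, as.integer(min_genes), as.integer(max_h)))
      next
    }
    if (sum(tab$r[tab$gene_symbol %in% gs]^w) <= 0) {
      skipped[[length(skipped) + 1L]] <- tibble::tibble(
        pathway = nm, reason = "all mapped genes score zero (N_R = 0)")
      next
    }
    keep[[length(keep) + 1L]] <- list(pathway = nm, genes = gs)
  }
  skipped <- if (length(skipped)) dplyr::bind_rows(skipped) else
    tibble::tibble(pathway = character(), reason = character())
  if (length(keep) == 0L) abort("no admissible pathway after gene mapping")
  if (!quiet && nrow(skipped) > 0L) {
    inform(sprintf("skipped %d pathway(s): %s", nrow(skipped),
                   paste(skipped$pathway, collapse = ", ")))
  }

  path_names <- vapply(keep, `[[`, character(1), "pathway")
  path_genes <- lapply(keep, `[[`, "genes")
  path_idx0 <- lapply(path_genes, function(g) match(g, gene_order) - 1L)

  es_obs <- vapply(path_genes, function(g) enrichment_score(tab, g, w = w),
                   numeric(1))

  # one seed per permutation: partition-invariant across workers
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  perm_seeds <- sample.int(.Machine$integer.max, K, replace = TRUE)

  run_chunk <- function(ix) {
    perm_es_kernel(d_info, chrom0, n_chrom, denom, gene_snps0, path_idx0,
                   w, score == "squared", as.numeric(perm_seeds[ix]))
  }
  if (threads > 1L && K > 1L) {
    chunks <- parallel::splitIndices(K, min(threads, K))
    es_perm <- do.call(cbind, parallel::mclapply(chunks, run_chunk,
                                                 mc.cores = threads))
  } else {
    es_perm <- run_chunk(seq_len(K))
  }
  rownames(es_perm) <- path_names

  if (tie_rule == "ge") {
    p_perm <- (1 + rowSums(es_perm >= es_obs)) / (K + 1)
  } else {
    p_perm <- rowSums(es_perm > es_obs) / K
  }

  # family-wise adjustment: max over pathways of permutation-normalised ES
  mu <- rowMeans(es_perm)
  sdv <- apply(es_perm, 1L, sd)
  degen <- sdv < 1e-12
  sdv[degen] <- 1
  nes_obs <- (es_obs - mu) / sdv
  nes_obs[degen] <- 0
  nes_perm <- (es_perm - mu) / sdv
  nes_perm[degen, ] <- 0
  max_nes <- apply(nes_perm, 2L, max)
  if (tie_rule == "ge") {
    p_adj <- vapply(nes_obs, function(x) (1 + sum(max_nes >= x)) / (K + 1),
                    numeric(1))
  } else {
    p_adj <- vapply(nes_obs, function(x) sum(max_nes > x) / K, numeric(1))
  }

  results <- tibble::tibble(
    pathway = path_names,
    n_genes = lengths(path_genes),
    es = es_obs,
    nes = nes_obs,
    p_perm = p_perm,
    p_adjusted = p_adj,
    fdr_q = p.adjust(p_perm, method = "BH")
  ) |>
    dplyr::arrange(.data$p_perm, .data$pathway)

  if (!quiet) {
    alpha_res <- 1 / (K + 1)
    if (alpha_res > 0.01) {
      inform(sprintf("K = %d gives p-value resolution %.4f; increase K for finer significance levels",
                     K, alpha_res))
    }
  }

  structure(
    list(results = results, skipped = skipped, score_table = tab,
         pathway_genes = stats::setNames(path_genes, path_names),
         es_perm = es_perm, n_genes_ranked = n_gene,
         n_families = nrow(st$d_matrix),
         n_snps = nrow(st$stats),
         n_snps_informative = sum(info),
         n_mendel_errors = st$n_mendel_errors,
         K = K, seed = seed, w = w, window_kb = window_kb,
         score = score, tie_rule = tie_rule, sign_by = sign_by),
    class = "pathway_pdt"
  )
}

# save/restore the global RNG state without assuming it exists
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_set <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.pathway_pdt <- function(x, ...) {
  cat(sprintf("<pathway_pdt> %d pathway(s), %d ranked genes, %d families, K = %d, seed = %d\n",
              nrow(x$results), x$n_genes_ranked, x$n_families, x$K, x$seed))
  print(x$results, ...)
  invisible(x)
}
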