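#' Tidy a pathway_pdt fit
#'
#' @param x A `pathway_pdt` object.
#' @param ... Unused.
#' @return The per-pathway results tibble: `pathway`, `n_genes`, `es`,
#'   `nes`, `p_perm`, `p_adjusted`, `fdr_q`.
#' @export
tidy.pathway_pdt <- function(x, ...) {
  x$results
}

#' One-row summary of a pathway_pdt fit
#'
#' @param x A `pathway_pdt` object.
#' @param ... Unused.
#' @return One-row tibble with dataset and run-level counts.
#' @export
glance.pathway_pdt <- function(x, ...) {
  tibble::tibble(
    n_families = x$n_families,
    n_snps = x$n_snps,
    n_snps_informative = x$n_snps_informative,
    n_genes_ranked = x$n_genes_ranked,
    n_pathways_tested = nrow(x$results),
    n_pathways_skipped = nrow(x$skipped),
    n_mendel_errors = x$n_mendel_errors,
    K = x$K,
    window_kb = x$window_kb,
    w = x$w,
    seed = x$seed
  )
}

#' Plot pathway significance
#'
#' Dot plot of \eqn{-\log_{10}} permutation p-values per pathway, sized by
#' the number of mapped genes and coloured by FDR significance.
#'
#' @param object A `pathway_pdt` object.
#' @param fdr_cutoff FDR threshold used for colouring (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pathway_pdt <- function(object, fdr_cutoff = 0.05, ...) {
  df <- object$results |>
    dplyr::mutate(
      neglog_p = -log10(.data$p_perm),
      significant = .data$fdr_q <= fdr_cutoff
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$neglog_p,
                                   y = stats::reorder(.data$pathway, .data$neglog_p))) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_genes,
                                     colour = .data$significant)) +
    ggplot2::scale_colour_manual(
      values = c("TRUE" = "#b2182b", "FALSE" = "grey40"),
      name = sprintf("FDR q ≤ %.2g", fdr_cutoff)) +
    ggplot2::labs(x = expression(-log[10] ~ "permutation p-value"),
                  y = NULL, size = "mapped genes") +
    ggplot2::theme_minimal()
}

#' Running-sum plot for one pathway
#'
#' Shows the enrichment running sum along the descending gene-score ranking,
#' with tick marks at pathway-gene positions; the maximum is the enrichment
#' score.
#'
#' @param fit A `pathway_pdt` object.
#' @param pathway Name of a tested pathway.
#' @return A ggplot object.
#' @export
plot_running_sum <- function(fit, pathway) {
  stopifnot(inherits(fit, "pathway_pdt"))
  if (!pathway %in% names(fit$pathway_genes)) {
    abort(sprintf("pathway '%s' was not tested", pathway))
  }
  genes <- fit$pathway_genes[[pathway]]
  rs <- enrichment_score(fit$score_table, genes, w = fit$w, running = TRUE)
  tab <- fit$score_table |>
    dplyr::arrange(dplyr::desc(.data$r), .data$gene_symbol)
  df <- tibble::tibble(rank = seq_along(rs), running = rs,
                       hit = tab$gene_symbol %in% genes)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$running)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::geom_rug(data = df[df$hit, ], sides = "b", colour = "#b2182b") +
    ggplot2::annotate("point", x = which.max(rs), y = max(rs),
                      colour = "#b2182b") +
    ggplot2::labs(title = pathway, x = "gene rank (score descending)",
                  y = "running enrichment sum") +
    ggplot2::theme_minimal()
}
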