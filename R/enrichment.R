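#' Weighted KS-like enrichment score for one pathway
#'
#' Walks the descending gene-score ranking once, adding
#' \eqn{r_j^w / N_R} at pathway genes (\eqn{N_R = \sum_{G_j \in P} r_j^w})
#' and subtracting \eqn{1/(N - N_H)} at the others, and returns the running
#' maximum of the signed sum — the enrichment score \eqn{ES(P)}. A pathway
#' concentrated at the top of the ranking approaches 1; the running sum
#' telescopes to 0 at the end of the list, so \eqn{ES \ge 0} always and
#' depleted pathways sit near 0.
#'
#' @param score_table Tibble from [gene_scores()] (re-sorted defensively by
#'   `r` descending, gene symbol ascending).
#' @param pathway_genes Character vector of gene symbols in the pathway;
#'   symbols absent from the table are ignored.
#' @param w Gene-score weight exponent; default 1.
#' @param running If `TRUE`, return the full running-sum vector (one value
#'   per ranked gene) instead of its maximum.
#' @return The enrichment score (scalar), or the running sum if
#'   `running = TRUE`.
#' @examples
#' tab <- tibble::tibble(gene_symbol = c("A", "B", "C", "D"),
#'                       r = c(4, 3, 2, 1))
#' enrichment_score(tab, c("A", "C"))  # 2/3
#' @export
enrichment_score <- function(score_table, pathway_genes, w = 1, running = FALSE) {
  stopifnot(w >= 0)
  tab <- score_table |>
    dplyr::arrange(dplyr::desc(.data$r), .data$gene_symbol)
  hit <- tab$gene_symbol %in% pathway_genes
  n <- nrow(tab)
  n_h <- sum(hit)
  if (n_h == 0L) abort("no pathway gene present in the score table")
  if (n_h == n) abort("pathway covers every ranked gene (miss increment undefined)")
  rw <- tab$r^w
  n_r <- sum(rw[hit])
  if (n_r <= 0) abort("pathway weighted score total N_R is zero")
  step <- ifelse(hit, rw / n_r, -1 / (n - n_h))
  rs <- cumsum(step)
  if (running) rs else max(rs)
}
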