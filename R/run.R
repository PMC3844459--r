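#' Run the full pathway analysis from files to a result table
#'
#' Thin orchestration over [read_ped_map()], [read_gene_file()],
#' [read_pathway_file()], [pathway_pdt()] and [write_results()]: reads the
#' four inputs, runs the test, writes the TSV and logs dataset counts to
#' stderr. This is what the command-line wrapper calls.
#'
#' @param ped,map,gene_file,pathway_file Input paths.
#' @param out Output TSV path.
#' @param ... Passed to [pathway_pdt()] (`window_kb`, `K`, `w`, `seed`,
#'   `threads`, `score`, `tie_rule`, `sign_by`, `min_genes`, `max_genes`,
#'   `average`, `quiet`).
#' @param score_dump Optional path: also write the gene score table
#'   (gene, score, best SNP, SNP count) for debugging.
#' @return The `pathway_pdt` fit, invisibly.
#' @export
ppdt_run <- function(ped, map, gene_file, pathway_file, out, ...,
                     score_dump = NULL) {
  for (p in c(ped, map, gene_file, pathway_file)) {
    if (!file.exists(p)) abort(paste0("input file not found: ", p))
  }
  t0 <- Sys.time()
  pd <- read_ped_map(ped, map)
  genes <- read_gene_file(gene_file)
  pathways <- read_pathway_file(pathway_file)
  fit <- pathway_pdt(pd, genes, pathways, ...)
  write_results(fit, out)
  if (!is.null(score_dump)) {
    readr::write_tsv(fit$score_table, score_dump)
  }
  inform(sprintf(
    "analysed %d families / %d SNPs / %d genes / %d pathways (%d skipped, %d Mendelian errors) in %.1f s; results in %s",
    fit$n_families, fit$n_snps, fit$n_genes_ranked, nrow(fit$results),
    nrow(fit$skipped), fit$n_mendel_errors,
    as.numeric(difftime(Sys.time(), t0, units = "secs")), out))
  invisible(fit)
}

#' Replicated simulation study of the pathway test
#'
#' Repeatedly simulates an ascertained family dataset and runs the full
#' pipeline, collecting the target pathway's permutation p-value from each
#' replicate — the building block for type-I-error and power estimation.
#' Replicate seeds are derived deterministically from `seed`.
#'
#' @param n_replicates Number of simulated datasets.
#' @param config A [sim_config()]; its `seed` field is overridden per
#'   replicate.
#' @param K Permutations per replicate.
#' @param window_kb,w Analysis parameters, see [pathway_pdt()].
#' @param seed Master seed for the study.
#' @param pathway Which pathway's p-value to collect (default `"target"`).
#' @return Tibble with `replicate`, `p_perm`, `es`.
#' @export
simulation_study <- function(n_replicates, config, K = 500, window_kb = 5,
                             w = 1, seed = 1, pathway = "target") {
  stopifnot(inherits(config, "sim_config"), n_replicates >= 1)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max, 2L * n_replicates),
                  ncol = 2L)
  res <- purrr::map(seq_len(n_replicates), function(r) {
    cfg <- config
    cfg$seed <- seeds[r, 1L]
    sim <- simulate_families(cfg)
    fit <- pathway_pdt(sim$ped, sim$genes, sim$pathways, window_kb = window_kb,
                       K = K, w = w, seed = seeds[r, 2L], quiet = TRUE)
    row <- fit$results[fit$results$pathway == pathway, ]
    tibble::tibble(replicate = r, p_perm = row$p_perm, es = row$es)
  })
  dplyr::bind_rows(res)
}
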