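#' Configuration for the nuclear-family simulator
#'
#' Defines an ascertained nuclear-family GWAS simulation: parental
#' haplotypes from a first-order Markov model with per-SNP minor-allele
#' frequency and adjacent-SNP correlation `rho`, Mendelian transmission of
#' one unrecombined haplotype per parent, sibling affection from an additive
#' logistic disease model, ascertainment on at least one affected sibling,
#' and optional masking of both parents' genotypes in a fraction of
#' families. Genes tile consecutive SNP blocks within chromosomes; the first
#' pathway ("target") holds `target_genes` genes spread across the genome
#' and the remaining pathways are size-matched random gene sets.
#'
#' Defaults follow the classic simulation design for this family of
#' methods: families of two parents and three siblings with at least one
#' affected, causal variants (when requested) at minor-allele frequency 0.2
#' with odds ratios around 1.2–1.3, and a 24-gene target pathway — at a
#' reduced marker scale of 10 chromosomes x 100 SNPs, 50 genes and 5
#' pathways so calibration studies run quickly.
#'
#' @param n_families Number of ascertained families (default 500).
#' @param n_sibs Siblings per family (default 3).
#' @param n_chrom,snps_per_chrom Marker panel dimensions.
#' @param maf_range Uniform range minor-allele frequencies are drawn from.
#' @param rho Adjacent-SNP haplotype correlation (first-order Markov LD).
#' @param n_genes Total genes tiled over the panel.
#' @param target_genes Genes in the target pathway (default 24).
#' @param n_pathways Total pathways including the target.
#' @param n_causal Causal SNPs, placed in distinct target-pathway genes
#'   (default 0: null model).
#' @param causal_or Per-allele odds ratio shared by all causal SNPs.
#' @param causal_maf Minor-allele frequency forced at causal SNPs
#'   (default 0.2).
#' @param prevalence Baseline disease probability for a zero-risk-allele
#'   genotype (default 0.1).
#' @param missing_parent_fraction Fraction of families whose two parents'
#'   genotypes are masked to missing (default 0).
#' @param snp_spacing_bp Base pairs between adjacent SNPs (default 2000).
#' @param max_redraws Batches of candidate families drawn before declaring
#'   ascertainment infeasible.
#' @param seed Integer seed (required for reproducibility; if `NULL` one is
#'   drawn).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_families = 500, n_sibs = 3, n_chrom = 10,
                       snps_per_chrom = 100, maf_range = c(0.1, 0.4),
                       rho = 0.6, n_genes = 50, target_genes = 24,
                       n_pathways = 5, n_causal = 0, causal_or = 1.2,
                       causal_maf = 0.2, prevalence = 0.1,
                       missing_parent_fraction = 0, snp_spacing_bp = 2000,
                       max_redraws = 200, seed = NULL) {
  stopifnot(n_families >= 1, n_sibs >= 1, n_chrom >= 1, snps_per_chrom >= 1,
            rho >= 0, rho < 1, n_genes >= 1, n_genes <= n_chrom * snps_per_chrom,
            target_genes >= 1, target_genes <= n_genes, n_pathways >= 1,
            n_causal >= 0, n_causal <= target_genes, causal_or > 0,
            causal_maf > 0, causal_maf < 1, prevalence > 0, prevalence < 1,
            missing_parent_fraction >= 0, missing_parent_fraction <= 1)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate an ascertained nuclear-family dataset
#'
#' @param config A [sim_config()].
#' @return A `fam_sim` object: list with `ped` (a `ped_data` usable directly
#'   by [pathway_pdt()]), `genes`, `pathways`, `causal_snps` (tibble of
#'   causal SNP IDs and odds ratios), and `config`. Identical configs give
#'   identical datasets.
#' @examples
#' sim <- simulate_families(sim_config(n_families = 10, n_chrom = 2,
#'                                     snps_per_chrom = 10, seed = 3))
#' sim$ped
#' @export
simulate_families <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(config$seed)

  n_snp <- config$n_chrom * config$snps_per_chrom
  chrom <- rep(as.character(seq_len(config$n_chrom)),
               each = config$snps_per_chrom)
  pos <- rep(seq_len(config$snps_per_chrom), times = config$n_chrom) *
    config$snp_spacing_bp
  snp_id <- sprintf("snp%05d", seq_len(n_snp))
  maf <- runif(n_snp, config$maf_range[1], config$maf_range[2])

  layout <- sim_gene_layout(config, chrom, pos, snp_id)
  if (config$n_causal > 0) maf[layout$causal_idx] <- config$causal_maf
  or_vec <- rep(config$causal_or, config$n_causal)

  fams <- draw_ascertained_families(config, maf, chrom, layout$causal_idx,
                                    or_vec)

  # mask both parents in a random fraction of families
  n_mask <- round(config$missing_parent_fraction * config$n_families)
  if (n_mask > 0) {
    masked <- sample(config$n_families, n_mask)
    par_rows <- which(fams$members$is_parent &
                        fams$members$family_id %in%
                          sprintf("fam%04d", masked))
    fams$dosage[par_rows, ] <- NA_integer_
  }

  snps <- tibble::tibble(snp_index = seq_len(n_snp), snp_id = snp_id,
                         chrom = chrom, pos = pos,
                         allele_a = "A", allele_b = "G")
  ped <- structure(list(members = fams$members, dosage = fams$dosage,
                        snps = snps), class = "ped_data")
  structure(
    list(ped = ped, genes = layout$genes, pathways = layout$pathways,
         causal_snps = tibble::tibble(snp_id = snp_id[layout$causal_idx],
                                      odds_ratio = or_vec),
         config = config),
    class = "fam_sim"
  )
}

# Tile genes over SNP blocks, pick the target pathway spread across the
# genome, put causal SNPs mid-gene in distinct target genes, and draw
# size-matched random background pathways.
sim_gene_layout <- function(config, chrom, pos, snp_id) {
  n_snp <- length(chrom)
  block <- floor(n_snp / config$n_genes)
  gene_first <- (seq_len(config$n_genes) - 1L) * block + 1L
  gene_last <- pmin(gene_first + block - 1L, n_snp)
  # keep blocks within one chromosome: clip at chromosome boundaries
  gene_last <- pmin(gene_last,
                    (ceiling(gene_first / config$snps_per_chrom)) *
                      config$snps_per_chrom)
  genes <- tibble::tibble(
    gene_symbol = sprintf("gene%03d", seq_len(config$n_genes)),
    chrom = chrom[gene_first],
    start = pos[gene_first],
    end = pos[gene_last]
  )
  target_i <- unique(round(seq(1, config$n_genes,
                               length.out = config$target_genes)))
  while (length(target_i) < config$target_genes) {
    target_i <- sort(union(target_i,
                           setdiff(seq_len(config$n_genes), target_i)[1]))
  }
  target_genes <- genes$gene_symbol[target_i]

  causal_idx <- integer(0)
  if (config$n_causal > 0) {
    host <- target_i[unique(round(seq(1, length(target_i),
                                      length.out = config$n_causal)))]
    while (length(host) < config$n_causal) {
      host <- sort(union(host, setdiff(target_i, host)[1]))
    }
    causal_idx <- (gene_first[host] + gene_last[host]) %/% 2L
  }

  bg <- lapply(seq_len(max(config$n_pathways - 1L, 0L)), function(i) {
    sort(sample(genes$gene_symbol, length(target_genes)))
  })
  pathways <- tibble::tibble(
    pathway = c("target", sprintf("background_%d",
                                  seq_len(max(config$n_pathways - 1L, 0L)))),
    description = c("target pathway",
                    rep("size-matched random gene set",
                        max(config$n_pathways - 1L, 0L))),
    genes = c(list(target_genes), bg)
  )
  list(genes = genes, pathways = pathways, target_genes = target_genes,
       causal_idx = causal_idx)
}

# Markov haplotypes: marginal Bernoulli(maf) per SNP, adjacent-indicator
# correlation rho within a chromosome (conditional probabilities clamped to
# [0, 1], which attenuates rho slightly at extreme frequency contrasts).
sim_haplotypes <- function(n_hap, maf, chrom, rho) {
  n_snp <- length(maf)
  h <- matrix(0L, nrow = n_hap, ncol = n_snp)
  new_chrom <- c(TRUE, chrom[-1] != chrom[-n_snp])
  for (s in seq_len(n_snp)) {
    p <- maf[s]
    if (new_chrom[s]) {
      pr <- rep(p, n_hap)
    } else {
      pp <- maf[s - 1]
      fac <- rho * sqrt(p * (1 - p) / (pp * (1 - pp)))
      pr <- pmin(pmax(p + fac * (h[, s - 1] - pp), 0), 1)
    }
    h[, s] <- rbinom(n_hap, 1L, pr)
  }
  h
}

draw_ascertained_families <- function(config, maf, chrom, causal_idx, or_vec) {
  n_keep <- 0L
  kept_dos <- list()
  batch <- max(config$n_families, 32L)
  tries <- 0L
  eta0 <- qlogis(config$prevalence)
  beta <- log(or_vec)

  while (n_keep < config$n_families) {
    tries <- tries + 1L
    if (tries > config$max_redraws) {
      abort(sprintf("ascertainment failed: no family with an affected sibling after %d batches (pathological configuration?)",
                    config$max_redraws))
    }
    hap <- sim_haplotypes(4L * batch, maf, chrom, config$rho)
    fa1 <- hap[seq(1, 4 * batch, by = 4), , drop = FALSE]
    fa2 <- hap[seq(2, 4 * batch, by = 4), , drop = FALSE]
    mo1 <- hap[seq(3, 4 * batch, by = 4), , drop = FALSE]
    mo2 <- hap[seq(4, 4 * batch, by = 4), , drop = FALSE]

    kid_dos <- vector("list", config$n_sibs)
    aff <- matrix(FALSE, nrow = batch, ncol = config$n_sibs)
    for (k in seq_len(config$n_sibs)) {
      pick_f <- rbinom(batch, 1L, 0.5)
      pick_m <- rbinom(batch, 1L, 0.5)
      hf <- fa1; hf[pick_f == 1L, ] <- fa2[pick_f == 1L, ]
      hm <- mo1; hm[pick_m == 1L, ] <- mo2[pick_m == 1L, ]
      dos <- hf + hm
      kid_dos[[k]] <- dos
      eta <- eta0
      if (length(causal_idx) > 0) {
        eta <- eta0 + as.vector(dos[, causal_idx, drop = FALSE] %*% beta)
      }
      aff[, k] <- rbinom(batch, 1L, plogis(eta)) == 1L
    }
    ok <- which(rowSums(aff) >= 1L)
    for (i in ok) {
      if (n_keep >= config$n_families) break
      n_keep <- n_keep + 1L
      kept_dos[[n_keep]] <- list(
        father = fa1[i, ] + fa2[i, ],
        mother = mo1[i, ] + mo2[i, ],
        kids = lapply(kid_dos, function(d) d[i, ]),
        aff = aff[i, ]
      )
    }
  }

  n_row_fam <- 2L + config$n_sibs
  members <- tibble::tibble(
    family_id = rep(sprintf("fam%04d", seq_len(config$n_families)),
                    each = n_row_fam),
    person_id = rep(c("1", "2", as.character(2L + seq_len(config$n_sibs))),
                    times = config$n_families),
    father_id = rep(c("0", "0", rep("1", config$n_sibs)),
                    times = config$n_families),
    mother_id = rep(c("0", "0", rep("2", config$n_sibs)),
                    times = config$n_families),
    sex = rep(c(1L, 2L, rep(NA_integer_, config$n_sibs)),
              times = config$n_families),
    affection = NA_character_,
    is_parent = rep(c(TRUE, TRUE, rep(FALSE, config$n_sibs)),
                    times = config$n_families)
  )
  members$sex[is.na(members$sex)] <- sample(1:2, sum(is.na(members$sex)),
                                            replace = TRUE)
  dosage <- matrix(NA_integer_, nrow = nrow(members), ncol = length(maf))
  affection <- character(nrow(members))
  for (i in seq_len(config$n_families)) {
    base <- (i - 1L) * n_row_fam
    f <- kept_dos[[i]]
    dosage[base + 1L, ] <- f$father
    dosage[base + 2L, ] <- f$mother
    affection[base + 1:2] <- "unknown"
    for (k in seq_len(config$n_sibs)) {
      dosage[base + 2L + k, ] <- f$kids[[k]]
      affection[base + 2L + k] <- if (f$aff[k]) "affected" else "unaffected"
    }
  }
  members$affection <- affection
  list(members = members, dosage = dosage)
}

#' @export
print.fam_sim <- function(x, ...) {
  cat(sprintf("<fam_sim> %d families (%d sibs), %d SNPs, %d genes, %d pathways, %d causal SNP(s), seed = %d\n",
              x$config$n_families, x$config$n_sibs, nrow(x$ped$snps),
              nrow(x$genes), nrow(x$pathways), nrow(x$causal_snps),
              x$config$seed))
  invisible(x)
}

#' Write a simulated dataset as PLINK ped/map files
#'
#' Dosages are written as allele pairs (`A A`, `A G`, `G G`; missing =
#' `0 0`) so that [read_ped_map()] recovers them exactly: `G` is the
#' lexicographically larger allele and therefore the counted `allele_b`.
#'
#' @param x A `fam_sim` or `ped_data` object.
#' @param ped_path,map_path Output paths.
#' @return Named list of the two paths, ready to feed into
#'   [read_ped_map()].
#' @export
write_ped_map <- function(x, ped_path, map_path) {
  ped <- if (inherits(x, "fam_sim")) x$ped else x
  stopifnot(inherits(ped, "ped_data"))
  geno_code <- c(`0` = "A A", `1` = "A G", `2` = "G G")
  pheno_code <- c(affected = "2", unaffected = "1", unknown = "0")

  g <- matrix("0 0", nrow = nrow(ped$dosage), ncol = ncol(ped$dosage))
  ok <- !is.na(ped$dosage)
  g[ok] <- geno_code[as.character(ped$dosage[ok])]
  lines <- paste(ped$members$family_id, ped$members$person_id,
                 ped$members$father_id, ped$members$mother_id,
                 ped$members$sex, pheno_code[ped$members$affection],
                 apply(g, 1L, paste, collapse = " "))
  readr::write_lines(lines, ped_path)
  readr::write_lines(paste(ped$snps$chrom, ped$snps$snp_id, 0, ped$snps$pos,
                           sep = "\t"),
                     map_path)
  list(ped = ped_path, map = map_path)
}

#' Write gene and pathway definition files
#'
#' @param x A `fam_sim` object.
#' @param gene_path,pathway_path Output paths.
#' @return Named list of the two paths.
#' @export
write_annotations <- function(x, gene_path, pathway_path) {
  stopifnot(inherits(x, "fam_sim"))
  readr::write_lines(paste(x$genes$gene_symbol, x$genes$chrom,
                           x$genes$start, x$genes$end, sep = "\t"),
                     gene_path)
  readr::write_lines(
    vapply(seq_len(nrow(x$pathways)), function(i) {
      paste(c(x$pathways$pathway[i], x$pathways$description[i],
              x$pathways$genes[[i]]), collapse = "\t")
    }, character(1)),
    pathway_path)
  list(genes = gene_path, pathways = pathway_path)
}

#' Simulate and write a complete dataset to disk
#'
#' Emits the four files the analysis consumes: PLINK ped/map, gene
#' locations, and GMT-style pathway definitions.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Named list of paths (`ped`, `map`, `genes`, `pathways`).
#' @export
simulate_dataset <- function(config, dir, prefix = "sim") {
  sim <- simulate_families(config)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- file.path(dir, paste0(prefix, c(".ped", ".map", ".genes.txt", ".gmt")))
  write_ped_map(sim, p[1], p[2])
  write_annotations(sim, p[3], p[4])
  list(ped = p[1], map = p[2], genes = p[3], pathways = p[4])
}
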