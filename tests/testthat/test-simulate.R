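test_that("identical configurations reproduce identical datasets", {
  cfg <- sim_config(n_families = 15, n_sibs = 3, n_chrom = 3,
                    snps_per_chrom = 10, n_genes = 6, target_genes = 3,
                    n_pathways = 3, missing_parent_fraction = 0.4, seed = 100)
  s1 <- simulate_families(cfg)
  s2 <- simulate_families(cfg)
  expect_identical(s1$ped$dosage, s2$ped$dosage)
  expect_identical(s1$ped$members, s2$ped$members)
  expect_identical(s1$pathways, s2$pathways)
})

test_that("generated children are Mendelian-consistent with their parents", {
  sim <- simulate_families(sim_config(n_families = 30, n_sibs = 3, n_chrom = 2,
                                      snps_per_chrom = 25, n_genes = 4,
                                      target_genes = 2, n_pathways = 2,
                                      seed = 101))
  st <- pdt_snp_stats(sim$ped, quiet = TRUE)
  expect_equal(st$n_mendel_errors, 0L)
  m <- sim$ped$members
  for (fid in unique(m$family_id)[1:5]) {
    rows <- which(m$family_id == fid)
    f <- sim$ped$dosage[rows[1], ]; mo <- sim$ped$dosage[rows[2], ]
    for (k in rows[-(1:2)]) {
      cc <- sim$ped$dosage[k, ]
      expect_true(all(cc >= (f == 2) + (mo == 2) & cc <= (f >= 1) + (mo >= 1)))
    }
  }
})

test_that("every emitted family carries at least one affected sibling", {
  sim <- simulate_families(sim_config(n_families = 50, n_sibs = 2, n_chrom = 1,
                                      snps_per_chrom = 10, n_genes = 2,
                                      target_genes = 1, n_pathways = 1,
                                      seed = 102))
  aff_by_fam <- tapply(sim$ped$members$affection == "affected",
                       sim$ped$members$family_id, any)
  expect_true(all(aff_by_fam))
})

test_that("founder allele frequencies recover the configured MAF", {
  cfg <- sim_config(n_families = 400, n_sibs = 2, n_chrom = 1,
                    snps_per_chrom = 10, n_genes = 2, target_genes = 1,
                    n_pathways = 1, seed = 103)
  sim <- simulate_families(cfg)
  founders <- sim$ped$dosage[sim$ped$members$is_parent, ]
  n_chr_obs <- 2 * nrow(founders)
  # per-SNP MAFs are drawn once from maf_range, then founders sample them
  phat <- colMeans(founders) / 2
  # recover the drawn MAFs deterministically from the config seed
  set.seed(cfg$seed)
  maf <- runif(10, cfg$maf_range[1], cfg$maf_range[2])
  se <- sqrt(maf * (1 - maf) / n_chr_obs)
  expect_true(all(abs(phat - maf) <= 3 * se))
})

test_that("masking leaves exactly the requested fraction of families parentless", {
  sim <- simulate_families(sim_config(n_families = 20, n_sibs = 3, n_chrom = 2,
                                      snps_per_chrom = 5, n_genes = 2,
                                      target_genes = 1, n_pathways = 1,
                                      missing_parent_fraction = 1, seed = 104))
  parents <- sim$ped$members$is_parent
  expect_true(all(is.na(sim$ped$dosage[parents, ])))
  expect_true(all(!is.na(sim$ped$dosage[!parents, ])))
  # with all parents missing the PDT runs on discordant sib pairs alone
  st <- pdt_snp_stats(sim$ped, quiet = TRUE)
  m <- sim$ped$members
  fid <- unique(m$family_id)[1]
  rows <- which(m$family_id == fid & !m$is_parent)
  aff <- rows[m$affection[rows] == "affected"]
  unaff <- rows[m$affection[rows] == "unaffected"]
  want <- 0
  for (a in aff) for (u in unaff) {
    want <- want + (sim$ped$dosage[a, 1] - sim$ped$dosage[u, 1])
  }
  expect_equal(unname(st$d_matrix[fid, 1]), want)

  half <- simulate_families(sim_config(n_families = 20, n_sibs = 3,
                                       n_chrom = 2, snps_per_chrom = 5,
                                       n_genes = 2, target_genes = 1,
                                       n_pathways = 1,
                                       missing_parent_fraction = 0.5,
                                       seed = 105))
  fam_missing <- tapply(rowSums(is.na(half$ped$dosage[half$ped$members$is_parent, ])) > 0,
                        half$ped$members$family_id[half$ped$members$is_parent],
                        all)
  expect_equal(sum(fam_missing), 10L)
})

test_that("null simulations give centred per-SNP statistics", {
  set.seed(1)
  zbar <- vapply(1:200, function(i) {
    sim <- simulate_families(sim_config(n_families = 20, n_sibs = 2,
                                        n_chrom = 1, snps_per_chrom = 5,
                                        n_genes = 1, target_genes = 1,
                                        n_pathways = 1,
                                        seed = 7000 + i))
    pdt_snp_stats(sim$ped, quiet = TRUE)$stats$z[1]
  }, numeric(1))
  se <- sd(zbar) / sqrt(length(zbar))
  expect_lt(abs(mean(zbar)), 3 * se)
})

test_that("causal variants under the additive model inflate their own statistics", {
  set.seed(2)
  z2_causal <- z2_null <- numeric(30)
  for (i in 1:30) {
    sim <- simulate_families(sim_config(n_families = 100, n_sibs = 3,
                                        n_chrom = 2, snps_per_chrom = 20,
                                        n_genes = 8, target_genes = 4,
                                        n_pathways = 2, n_causal = 3,
                                        causal_or = 1.5, seed = 8000 + i))
    st <- pdt_snp_stats(sim$ped, quiet = TRUE)
    causal <- st$stats$snp_id %in% sim$causal_snps$snp_id
    z2_causal[i] <- mean(st$stats$z[causal]^2)
    z2_null[i] <- mean(st$stats$z[!causal]^2)
  }
  expect_gt(mean(z2_causal), mean(z2_null))
})

test_that("gene and pathway layout respects the configuration", {
  sim <- simulate_families(sim_config(n_families = 10, n_sibs = 2, n_chrom = 5,
                                      snps_per_chrom = 20, n_genes = 20,
                                      target_genes = 8, n_pathways = 4,
                                      n_causal = 5, causal_or = 1.2,
                                      seed = 106))
  expect_equal(nrow(sim$genes), 20L)
  expect_equal(nrow(sim$pathways), 4L)
  expect_equal(sim$pathways$pathway[1], "target")
  expect_equal(lengths(sim$pathways$genes), rep(8L, 4))
  expect_true(all(sim$genes$start <= sim$genes$end))
  # causal SNPs sit inside target-pathway genes
  target_genes <- sim$genes[sim$genes$gene_symbol %in% sim$pathways$genes[[1]], ]
  causal_pos <- sim$ped$snps[sim$ped$snps$snp_id %in% sim$causal_snps$snp_id, ]
  hits <- vapply(seq_len(nrow(causal_pos)), function(i) {
    any(target_genes$chrom == causal_pos$chrom[i] &
          target_genes$start <= causal_pos$pos[i] &
          target_genes$end >= causal_pos$pos[i])
  }, logical(1))
  expect_true(all(hits))
})

test_that("annotation files round-trip through their readers", {
  sim <- simulate_families(sim_config(n_families = 5, n_sibs = 2, n_chrom = 2,
                                      snps_per_chrom = 10, n_genes = 4,
                                      target_genes = 2, n_pathways = 3,
                                      seed = 107))
  paths <- write_annotations(sim, tempfile(fileext = ".txt"),
                             tempfile(fileext = ".gmt"))
  genes <- read_gene_file(paths$genes)
  expect_setequal(genes$gene_symbol, sim$genes$gene_symbol)
  pw <- read_pathway_file(paths$pathways)
  expect_equal(pw$pathway, sim$pathways$pathway)
  expect_equal(pw$genes, sim$pathways$genes)
})

test_that("pathological ascertainment configurations fail loudly", {
  cfg <- sim_config(n_families = 5, n_sibs = 1, n_chrom = 1,
                    snps_per_chrom = 5, n_genes = 1, target_genes = 1,
                    n_pathways = 1, prevalence = 1e-4, max_redraws = 2,
                    seed = 108)
  expect_error(simulate_families(cfg), "ascertainment failed")
})
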