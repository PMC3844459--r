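#' Per-SNP pedigree disequilibrium test statistics
#'
#' Computes, for every SNP, each family's PDT contribution
#' \eqn{D = \sum_{triads} X_T + \sum_{DSPs} X_S} and the sum-PDT statistic
#' \eqn{Z = \sum_i D_i / \sqrt{\sum_i D_i^2}}, where a triad is two genotyped
#' parents plus a genotyped affected offspring
#' (\eqn{X_T = 2c - f - m}, allele-b dosages: transmitted minus untransmitted
#' copies), and a discordant sib pair (DSP) is a genotyped affected/unaffected
#' sibling pair (\eqn{X_S} = affected minus unaffected dosage). All affected
#' x unaffected pairs are scored. Families with missing parents keep their
#' DSPs; triads with a Mendelian-inconsistent dosage pattern contribute 0 and
#' are counted in the QC summary. Unknown-phenotype siblings join no unit.
#'
#' The family-by-SNP matrix of \eqn{D} values is retained: flipping the sign
#' of a family's \eqn{D} is equivalent to exchanging its transmitted and
#' untransmitted alleles, which is the whole permutation engine.
#'
#' @param ped A `ped_data` object from [read_ped_map()] or
#'   [simulate_families()].
#' @param average If `TRUE`, each family's \eqn{D} is divided by its number
#'   of scored units at that SNP (avg-PDT) before forming \eqn{Z}. Default
#'   `FALSE` (sum-PDT).
#' @param quiet Suppress the QC message.
#' @return An object of class `pdt_stats`: list with
#'   * `stats`: tibble (`snp_index`, `snp_id`, `chrom`, `pos`, `sum_d`,
#'     `sum_d2`, `z`, `informative`);
#'   * `d_matrix`: numeric matrix, families x SNPs;
#'   * `family_ids`: row names of `d_matrix`;
#'   * `n_mendel_errors`: count of triad-SNP combinations skipped as
#'     Mendelian-inconsistent.
#' @examples
#' sim <- simulate_families(sim_config(n_families = 20, n_chrom = 2,
#'                                     snps_per_chrom = 10, seed = 7))
#' st <- pdt_snp_stats(sim$ped)
#' st$stats
#' @export
pdt_snp_stats <- function(ped, average = FALSE, quiet = FALSE) {
  stopifnot(inherits(ped, "ped_data"))
  members <- ped$members
  dos <- ped$dosage
  # canonical (sorted) family order: the permutation engine assigns signs by
  # row, so results stay invariant to the row order of the input ped file
  fam_ids <- sort(unique(members$family_id))
  n_snp <- ncol(dos)

  d_matrix <- matrix(0, nrow = length(fam_ids), ncol = n_snp,
                     dimnames = list(fam_ids, ped$snps$snp_id))
  n_mendel <- 0L
  for (k in seq_along(fam_ids)) {
    rows <- which(members$family_id == fam_ids[k])
    fc <- family_d_vector(members[rows, ], dos[rows, , drop = FALSE])
    n_mendel <- n_mendel + fc$n_mendel
    d <- fc$d
    if (average) {
      u <- fc$units
      d <- ifelse(u > 0L, d / u, 0)
    }
    d_matrix[k, ] <- d
  }

  sum_d <- unname(colSums(d_matrix))
  sum_d2 <- unname(colSums(d_matrix^2))
  informative <- sum_d2 > 0
  z <- ifelse(informative, sum_d / sqrt(sum_d2), 0)

  if (!quiet) {
    x_snps <- unique(ped$snps$chrom[toupper(ped$snps$chrom) %in% c("X", "23", "CHRX")])
    if (length(x_snps) > 0L) {
      warn(sprintf("chromosome(s) %s processed with the autosomal PDT formula",
                   paste(x_snps, collapse = ", ")))
    }
    inform(sprintf("PDT: %d/%d SNPs informative; %d Mendelian-inconsistent triad genotype(s) skipped",
                   sum(informative), n_snp, n_mendel))
  }

  structure(
    list(
      stats = tibble::tibble(
        snp_index = ped$snps$snp_index,
        snp_id = ped$snps$snp_id,
        chrom = ped$snps$chrom,
        pos = ped$snps$pos,
        sum_d = sum_d,
        sum_d2 = sum_d2,
        z = z,
        informative = informative
      ),
      d_matrix = d_matrix,
      family_ids = fam_ids,
      n_mendel_errors = n_mendel
    ),
    class = "pdt_stats"
  )
}

# One family's D across all SNPs, plus unit counts and Mendelian QC tally.
family_d_vector <- function(fam, dos) {
  n_snp <- ncol(dos)
  d <- numeric(n_snp)
  units <- integer(n_snp)
  n_mendel <- 0L

  kids <- which(!fam$is_parent)
  aff <- kids[fam$affection[kids] == "affected"]
  unaff <- kids[fam$affection[kids] == "unaffected"]

  father_row <- which(fam$is_parent & fam$person_id == fam$father_id[kids[1]])
  mother_row <- which(fam$is_parent & fam$person_id == fam$mother_id[kids[1]])

  if (length(father_row) == 1L && length(mother_row) == 1L) {
    f <- dos[father_row, ]
    m <- dos[mother_row, ]
    mn <- (f == 2L) + (m == 2L)   # minimum transmissible b-count
    mx <- (f >= 1L) + (m >= 1L)   # maximum transmissible b-count
    for (a in aff) {
      cc <- dos[a, ]
      ok <- !is.na(cc) & !is.na(f) & !is.na(m)
      good <- ok & cc >= mn & cc <= mx
      d[good] <- d[good] + (2L * cc - f - m)[good]
      units <- units + good
      n_mendel <- n_mendel + sum(ok & !good)
    }
  }
  for (a in aff) {
    for (u in unaff) {
      diff <- dos[a, ] - dos[u, ]
      ok <- !is.na(diff)
      d[ok] <- d[ok] + diff[ok]
      units <- units + ok
    }
  }
  list(d = d, units = units, n_mendel = n_mendel)
}

#' Single family PDT contribution at one SNP
#'
#' Exposes the per-family summand \eqn{D} (the quantity whose sign flips
#' under the permutation null) for inspection and testing.
#'
#' @param ped A `ped_data` object.
#' @param family_id Family identifier.
#' @param snp SNP ID or 1-based SNP index.
#' @return Tibble with `family_id`, `snp_id`, `d`, `n_units` (scored triads +
#'   DSPs) and `n_mendel_errors`.
#' @export
pdt_family_contribution <- function(ped, family_id, snp) {
  stopifnot(inherits(ped, "ped_data"))
  s <- if (is.character(snp)) match(snp, ped$snps$snp_id) else as.integer(snp)
  if (is.na(s) || s < 1L || s > nrow(ped$snps)) abort("unknown SNP")
  rows <- which(ped$members$family_id == family_id)
  if (length(rows) == 0L) abort(sprintf("unknown family '%s'", family_id))
  fc <- family_d_vector(ped$members[rows, ], ped$dosage[rows, , drop = FALSE])
  tibble::tibble(
    family_id = family_id,
    snp_id = ped$snps$snp_id[s],
    d = fc$d[s],
    n_units = fc$units[s],
    n_mendel_errors = fc$n_mendel
  )
}

#' @export
print.pdt_stats <- function(x, ...) {
  cat(sprintf("<pdt_stats> %d families x %d SNPs (%d informative)\n",
              nrow(x$d_matrix), ncol(x$d_matrix), sum(x$stats$informative)))
  invisible(x)
}
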