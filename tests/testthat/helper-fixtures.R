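# In-code fixture builders and independent oracles shared across test files.

# Build a ped_data object directly from a member table and dosage matrix.
make_ped <- function(members, dosage, chrom = NULL, pos = NULL) {
  n_snp <- ncol(dosage)
  if (is.null(chrom)) chrom <- rep("1", n_snp)
  if (is.null(pos)) pos <- seq_len(n_snp) * 1000L
  members$is_parent <- members$father_id == "0" & members$mother_id == "0"
  structure(
    list(
      members = tibble::tibble(members),
      dosage = dosage,
      snps = tibble::tibble(
        snp_index = seq_len(n_snp),
        snp_id = sprintf("s%03d", seq_len(n_snp)),
        chrom = chrom, pos = pos,
        allele_a = "A", allele_b = "G"
      )
    ),
    class = "ped_data"
  )
}

# One nuclear family's member rows. parents: logical, include parent rows.
fam_members <- function(fid, n_kids, affection, parents = TRUE) {
  kid_ids <- as.character(2L + seq_len(n_kids))
  if (parents) {
    tibble::tibble(
      family_id = fid,
      person_id = c("1", "2", kid_ids),
      father_id = c("0", "0", rep("1", n_kids)),
      mother_id = c("0", "0", rep("2", n_kids)),
      sex = c(1L, 2L, rep(1L, n_kids)),
      affection = c("unknown", "unknown", affection)
    )
  } else {
    tibble::tibble(
      family_id = fid,
      person_id = kid_ids,
      father_id = rep("1", n_kids),
      mother_id = rep("2", n_kids),
      sex = rep(1L, n_kids),
      affection = affection
    )
  }
}

# Independent brute-force enumerator of a family's PDT summand at one SNP:
# loops explicitly over affected children (triads, both parents genotyped,
# Mendelian-consistent dosages only) and over all affected x unaffected
# sibling pairs.
brute_family_d <- function(f, m, kid_dos, kid_aff) {
  d <- 0L
  aff <- which(kid_aff == "affected")
  unaff <- which(kid_aff == "unaffected")
  if (!is.na(f) && !is.na(m)) {
    lo <- (f == 2) + (m == 2)
    hi <- (f >= 1) + (m >= 1)
    for (a in aff) {
      cc <- kid_dos[a]
      if (!is.na(cc) && cc >= lo && cc <= hi) d <- d + (2L * cc - f - m)
    }
  }
  for (a in aff) {
    for (u in unaff) {
      if (!is.na(kid_dos[a]) && !is.na(kid_dos[u])) {
        d <- d + (kid_dos[a] - kid_dos[u])
      }
    }
  }
  d
}

# Naive two-loop reference for the enrichment score: for every prefix i,
# re-sum hits and misses from scratch.
brute_enrichment_score <- function(r_sorted, hit, w) {
  n <- length(r_sorted)
  n_r <- sum(r_sorted[hit]^w)
  n_h <- sum(hit)
  best <- -Inf
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(i)) {
      if (hit[j]) s <- s + r_sorted[j]^w / n_r else s <- s - 1 / (n - n_h)
    }
    if (s > best) best <- s
  }
  best
}

# Random small nuclear family with arbitrary missingness for oracle checks.
random_family <- function(fid) {
  n_kids <- sample(2:4, 1)
  parents <- runif(1) < 0.7
  aff <- sample(c("affected", "unaffected", "unknown"), n_kids, replace = TRUE)
  mem <- fam_members(fid, n_kids, aff, parents = parents)
  dos <- matrix(sample(c(0:2, NA), nrow(mem), replace = TRUE), ncol = 1)
  list(members = mem, dosage = dos)
}

# Trio-only null dataset built straight from Mendelian transmission (no
# ascertainment): parents Binomial(2, p), child receives one allele from
# each parent uniformly.
random_trio_ped <- function(n_fam, n_snp = 1, p = 0.3) {
  members <- dplyr::bind_rows(lapply(seq_len(n_fam), function(i) {
    fam_members(sprintf("f%04d", i), 1, "affected")
  }))
  transmit <- function(par_dos) {
    # allele drawn from a parent with the given b-dosage
    ifelse(par_dos == 2, 1L, ifelse(par_dos == 0, 0L,
                                    rbinom(length(par_dos), 1, 0.5)))
  }
  dos <- matrix(NA_integer_, nrow = 3 * n_fam, ncol = n_snp)
  for (s in seq_len(n_snp)) {
    f <- rbinom(n_fam, 2, p)
    m <- rbinom(n_fam, 2, p)
    cc <- transmit(f) + transmit(m)
    dos[, s] <- as.integer(rbind(f, m, cc))
  }
  make_ped(members, dos)
}
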