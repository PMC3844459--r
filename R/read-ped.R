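#' Read PLINK ped/map files into a pedigree dataset
#'
#' Parses a whitespace-delimited PLINK pedigree file together with its marker
#' map and returns a `ped_data` object: a member table, a biallelic dosage
#' matrix (counted allele = `allele_b`, the lexicographically larger allele
#' observed at each SNP), and a SNP metadata table. Genotypes are recoded to
#' 0/1/2 copies of `allele_b`; `0 0` (or any half-missing record) becomes
#' `NA`.
#'
#' Every family must be a single nuclear family: all offspring share the same
#' two parent IDs, parent rows (when present) are founders, and at least one
#' offspring exists. Multi-generational pedigrees are rejected.
#'
#' @param ped_path Path to the `.ped` file (6 leading columns: family ID,
#'   individual ID, father ID, mother ID, sex, affection; then two allele
#'   columns per SNP).
#' @param map_path Path to the `.map` file (4 columns: chromosome, SNP ID,
#'   genetic distance in cM (ignored), base-pair position).
#' @param quiet Suppress informational messages.
#' @return An object of class `ped_data`: a list with elements
#'   * `members`: tibble with `family_id`, `person_id`, `father_id`,
#'     `mother_id`, `sex`, `affection` (`"affected"`, `"unaffected"`,
#'     `"unknown"`) and `is_parent`;
#'   * `dosage`: integer matrix, members x SNPs, counts of `allele_b`;
#'   * `snps`: tibble with `snp_index`, `snp_id`, `chrom`, `pos`,
#'     `allele_a`, `allele_b`.
#' @examples
#' sim <- simulate_families(sim_config(n_families = 4, n_chrom = 2,
#'                                     snps_per_chrom = 5, seed = 1))
#' paths <- write_ped_map(sim, tempfile(fileext = ".ped"),
#'                        tempfile(fileext = ".map"))
#' ped <- read_ped_map(paths$ped, paths$map)
#' ped$snps
#' @export
read_ped_map <- function(ped_path, map_path, quiet = FALSE) {
  if (!file.exists(ped_path)) abort(paste0("ped file not found: ", ped_path))
  if (!file.exists(map_path)) abort(paste0("map file not found: ", map_path))

  snps <- parse_map_file(map_path)
  m <- nrow(snps)

  lines <- readr::read_lines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort("ped file is empty")
  fields <- strsplit(trimws(lines), "[ \t]+")
  want <- 6L + 2L * m
  nf <- lengths(fields)
  bad <- which(nf != want)
  if (length(bad) > 0L) {
    abort(sprintf("ped line %d: expected %d fields (6 + 2 x %d SNPs), found %d",
                  bad[1], want, m, nf[bad[1]]))
  }
  rec <- matrix(unlist(fields), nrow = length(fields), byrow = TRUE)

  affection <- decode_affection(rec[, 6L])
  members <- tibble::tibble(
    family_id = rec[, 1L],
    person_id = rec[, 2L],
    father_id = rec[, 3L],
    mother_id = rec[, 4L],
    sex       = suppressWarnings(as.integer(rec[, 5L])),
    affection = affection
  )
  if (anyDuplicated(paste(members$family_id, members$person_id, sep = "\r"))) {
    dup <- members[duplicated(paste(members$family_id, members$person_id, sep = "\r")), ]
    abort(sprintf("duplicate individual '%s' in family '%s'",
                  dup$person_id[1], dup$family_id[1]))
  }

  a1 <- rec[, 6L + 2L * seq_len(m) - 1L, drop = FALSE]
  a2 <- rec[, 6L + 2L * seq_len(m), drop = FALSE]

  allele_a <- allele_b <- rep(NA_character_, m)
  dosage <- matrix(NA_integer_, nrow = nrow(rec), ncol = m)
  n_half_missing <- 0L
  for (s in seq_len(m)) {
    x1 <- a1[, s]; x2 <- a2[, s]
    obs <- setdiff(unique(c(x1, x2)), "0")
    if (length(obs) > 2L) {
      abort(sprintf("SNP '%s': more than two alleles observed (%s)",
                    snps$snp_id[s], paste(sort(obs), collapse = ", ")))
    }
    obs <- sort(obs)
    if (length(obs) >= 1L) allele_a[s] <- obs[1L]
    if (length(obs) == 2L) allele_b[s] <- obs[2L]
    miss <- x1 == "0" | x2 == "0"
    n_half_missing <- n_half_missing + sum(xor(x1 == "0", x2 == "0"))
    if (!is.na(allele_b[s])) {
      d <- (x1 == allele_b[s]) + (x2 == allele_b[s])
    } else {
      d <- integer(length(x1))
    }
    d[miss] <- NA_integer_
    dosage[, s] <- d
  }
  if (n_half_missing > 0L && !quiet) {
    warn(sprintf("%d half-missing genotype record(s) treated as missing",
                 n_half_missing))
  }
  snps$allele_a <- allele_a
  snps$allele_b <- allele_b

  members <- validate_nuclear(members)

  out <- structure(
    list(members = members, dosage = dosage, snps = snps),
    class = "ped_data"
  )
  if (!quiet) {
    inform(sprintf("read %d individuals in %d families, %d SNPs",
                   nrow(members), dplyr::n_distinct(members$family_id), m))
  }
  out
}

parse_map_file <- function(map_path) {
  lines <- readr::read_lines(map_path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  bad <- which(nf < 4L)
  if (length(bad) > 0L) {
    abort(sprintf("map line %d: expected 4 fields, found %d", bad[1], nf[bad[1]]))
  }
  rec <- t(vapply(fields, function(f) f[1:4], character(4)))
  pos <- suppressWarnings(as.integer(rec[, 4L]))
  if (anyNA(pos) || any(pos <= 0L)) {
    abort(sprintf("map line %d: position must be a positive integer",
                  which(is.na(pos) | pos <= 0L)[1]))
  }
  snp_id <- rec[, 2L]
  if (anyDuplicated(snp_id)) {
    abort(sprintf("duplicate SNP ID in map: '%s'", snp_id[duplicated(snp_id)][1]))
  }
  tibble::tibble(
    snp_index = seq_along(snp_id),
    snp_id = snp_id,
    chrom = rec[, 1L],
    pos = pos
  )
}

decode_affection <- function(x) {
  out <- rep(NA_character_, length(x))
  out[x == "2"] <- "affected"
  out[x == "1"] <- "unaffected"
  out[x %in% c("0", "-9")] <- "unknown"
  if (anyNA(out)) {
    abort(sprintf("unknown affection code '%s' (expected 2, 1, 0 or -9)",
                  x[is.na(out)][1]))
  }
  out
}

# Enforce the single-nuclear-family structure and flag parent rows.
validate_nuclear <- function(members) {
  members$is_parent <- FALSE
  for (fid in unique(members$family_id)) {
    i <- which(members$family_id == fid)
    fam <- members[i, ]
    kids <- fam$father_id != "0" | fam$mother_id != "0"
    if (!any(kids)) {
      abort(sprintf("family '%s': no offspring (at least one non-founder member required)", fid))
    }
    pairs <- unique(fam[kids, c("father_id", "mother_id")])
    if (nrow(pairs) > 1L) {
      abort(sprintf("family '%s' is not a single nuclear family: offspring name %d distinct parent pairs",
                    fid, nrow(pairs)))
    }
    parent_ids <- setdiff(unlist(pairs), "0")
    is_par <- fam$person_id %in% parent_ids
    if (any(is_par & kids)) {
      abort(sprintf("family '%s' is not a single nuclear family: member '%s' is both offspring and parent",
                    fid, fam$person_id[which(is_par & kids)[1]]))
    }
    stray <- !kids & !is_par
    if (any(stray)) {
      abort(sprintf("family '%s': member '%s' is neither a parent nor an offspring of the nuclear family",
                    fid, fam$person_id[which(stray)[1]]))
    }
    members$is_parent[i] <- is_par
  }
  members
}

#' @export
print.ped_data <- function(x, ...) {
  cat(sprintf("<ped_data> %d individuals, %d families, %d SNPs\n",
              nrow(x$members), dplyr::n_distinct(x$members$family_id),
              nrow(x$snps)))
  invisible(x)
}
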