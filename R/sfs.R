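# Outgroup polarization and derived site-frequency spectra.

#' Read per-SNP outgroup allele states
#'
#' TSV with columns `snp_id` and `outgroup_allele`: a single nucleotide,
#' two segregating nucleotides joined by "/" (e.g. "A/G"), or "NA"/"N" for
#' an ambiguous call.
#'
#' @param path file path.
#' @return data.frame (snp_id, outgroup_allele) of class `ancestral_states`.
#' @export
read_ancestral_states <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          na.strings = c("NA", ""))
  if (!all(c("snp_id", "outgroup_allele") %in% names(df)))
    stop("ancestral states need columns snp_id, outgroup_allele")
  ancestral_states(df$snp_id, df$outgroup_allele)
}

#' Construct an ancestral-states table
#'
#' @param snp_id character vector.
#' @param outgroup_allele per-SNP outgroup state (see
#'   [read_ancestral_states()] for the encoding).
#' @return data.frame of class `ancestral_states`.
#' @export
ancestral_states <- function(snp_id, outgroup_allele) {
  if (anyDuplicated(snp_id)) stop("duplicate SNP ids in ancestral states")
  df <- data.frame(snp_id = as.character(snp_id),
                   outgroup_allele = toupper(as.character(outgroup_allele)),
                   stringsAsFactors = FALSE)
  class(df) <- c("ancestral_states", "data.frame")
  df
}

#' Polarize SNPs against the outgroup
#'
#' For each SNP, determines the derived allele as the ingroup allele that
#' does not match the outgroup state. SNPs where the outgroup call is
#' ambiguous, segregates for the same two alleles as the ingroup
#' (trans-specific polymorphism), or carries a nucleotide absent from the
#' ingroup pair are assigned a non-`polarized` status and excluded from
#' spectra.
#'
#' @param g a `genotype_matrix`.
#' @param anc an `ancestral_states` table covering the SNPs of `g`.
#' @return data.frame: snp_id, status
#'   (polarized/ambiguous/trans_specific/other_allele), ancestral allele,
#'   derived allele, and `derived_is_alt` (logical; NA unless polarized).
#' @export
polarize <- function(g, anc) {
  stopifnot(inherits(g, "genotype_matrix"))
  m <- match(g$snp_ids, anc$snp_id)
  if (anyNA(m)) stop("ancestral states missing for some SNPs")
  out_allele <- anc$outgroup_allele[m]
  ref <- g$alleles$ref
  alt <- g$alleles$alt
  status <- character(length(out_allele))
  anc_allele <- der_allele <- rep(NA_character_, length(out_allele))
  der_is_alt <- rep(NA, length(out_allele))
  parsed <- strsplit(ifelse(is.na(out_allele), "N", out_allele), "/", fixed = TRUE)
  for (j in seq_along(out_allele)) {
    states <- unique(parsed[[j]])
    states <- states[states %in% c("A", "C", "G", "T")]
    ingroup <- c(ref[j], alt[j])
    if (length(states) == 0L) {
      status[j] <- "ambiguous"
    } else if (length(states) >= 2L) {
      status[j] <- if (setequal(states, ingroup)) "trans_specific" else "other_allele"
    } else if (!(states %in% ingroup)) {
      status[j] <- "other_allele"
    } else {
      status[j] <- "polarized"
      anc_allele[j] <- states
      der_allele[j] <- setdiff(ingroup, states)
      der_is_alt[j] <- der_allele[j] == alt[j]
    }
  }
  data.frame(snp_id = g$snp_ids, status = status,
             ancestral_allele = anc_allele, derived_allele = der_allele,
             derived_is_alt = der_is_alt, stringsAsFactors = FALSE)
}

# Derived-allele counts and haploid sample sizes for polarized SNPs within
# an accession set; HET and MISSING are dropped (haploid coding of inbreds).
derived_counts <- function(g, members, pol) {
  cn <- haploid_counts(g, members)
  keep <- pol$status == "polarized"
  k <- ifelse(pol$derived_is_alt, cn$x, cn$n - cn$x)
  data.frame(snp_id = g$snp_ids, k = as.integer(k), n = as.integer(cn$n),
             stringsAsFactors = FALSE)[keep & cn$n > 0, , drop = FALSE]
}

# Hypergeometric projection: expected weight of derived count j in a
# subsample of m chromosomes from a SNP with k derived of n observed.
project_weights <- function(k, n, m) {
  stats::dhyper(0:m, k, n - k, m)
}

#' Derived site-frequency spectrum of a population
#'
#' Each polarized SNP contributes to the bin of its derived-allele count
#' among the non-missing haploid calls of the population. With
#' `projection_n` set, ragged per-SNP sample sizes are down-projected to a
#' common size by hypergeometric expectation; SNPs observed in fewer than
#' `projection_n` chromosomes are dropped. Mass that projects to count 0 or
#' `projection_n` is reported separately as fixed-ancestral/fixed-derived.
#'
#' @param g a `genotype_matrix`.
#' @param members accession ids of the population.
#' @param anc an `ancestral_states` table (or a precomputed [polarize()]
#'   result).
#' @param projection_n common haploid sample size to project to; `NULL`
#'   (default) uses the minimum per-SNP sample size across retained SNPs.
#' @return An `sfs_result`: list with `n`, `counts` (expected SNP counts in
#'   bins 1..n-1), `proportions`, `fixed_ancestral`, `fixed_derived`,
#'   `n_snps_used` and the polarization exclusion tally.
#' @export
derived_sfs <- function(g, members, anc, projection_n = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  pol <- if (is.data.frame(anc) && "status" %in% names(anc)) anc else polarize(g, anc)
  excl <- table(factor(pol$status,
                       levels = c("polarized", "ambiguous", "trans_specific",
                                  "other_allele")))
  dc <- derived_counts(g, members, pol)
  dc <- dc[dc$k > 0 & dc$k < dc$n, , drop = FALSE]   # polymorphic in the sample
  if (nrow(dc) == 0L) stop("no polarized polymorphic SNPs")
  if (is.null(projection_n)) projection_n <- min(dc$n)
  if (projection_n < 2L) stop("projection_n must be >= 2")
  dc <- dc[dc$n >= projection_n, , drop = FALSE]
  if (nrow(dc) == 0L) stop("no SNP observed in >= projection_n chromosomes")
  bins <- numeric(projection_n + 1L)
  for (i in seq_len(nrow(dc)))
    bins <- bins + project_weights(dc$k[i], dc$n[i], projection_n)
  poly <- bins[2:projection_n]
  structure(list(n = projection_n,
                 counts = poly,
                 proportions = poly / sum(poly),
                 fixed_ancestral = bins[1L],
                 fixed_derived = bins[projection_n + 1L],
                 n_snps_used = nrow(dc),
                 exclusions = as.list(excl)),
            class = "sfs_result")
}

#' @export
print.sfs_result <- function(x, ...) {
  cat(sprintf("sfs_result: projection n=%d, %d SNPs; fixed anc %.1f, fixed der %.1f\n",
              x$n, x$n_snps_used, x$fixed_ancestral, x$fixed_derived))
  invisible(x)
}

#' Joint (2-D) derived site-frequency spectrum
#'
#' Histogram of derived-allele counts in two disjoint accession partitions,
#' over SNPs polarized and observed in at least the projection size in
#' both. Counts in each partition are hypergeometrically projected to
#' (`nA`, `nB`).
#'
#' @param g a `genotype_matrix`.
#' @param membersA,membersB disjoint accession sets.
#' @param anc an `ancestral_states` table or [polarize()] result.
#' @param nA,nB projection sizes for the two partitions (default: the
#'   per-partition minima over shared SNPs).
#' @return list of class `joint_sfs`: matrix `counts` with (nA+1) x (nB+1)
#'   bins 0..nA by 0..nB, plus `nA`, `nB`, `n_snps_used`.
#' @export
joint_derived_sfs <- function(g, membersA, membersB, anc, nA = NULL, nB = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (length(membersA) == 0L || length(membersB) == 0L) stop("empty partition")
  if (length(intersect(membersA, membersB))) stop("partitions must be disjoint")
  pol <- if (is.data.frame(anc) && "status" %in% names(anc)) anc else polarize(g, anc)
  dA <- derived_counts(g, membersA, pol)
  dB <- derived_counts(g, membersB, pol)
  shared <- intersect(dA$snp_id[dA$n > 0], dB$snp_id[dB$n > 0])
  dA <- dA[match(shared, dA$snp_id), ]; dB <- dB[match(shared, dB$snp_id), ]
  if (is.null(nA)) nA <- min(dA$n)
  if (is.null(nB)) nB <- min(dB$n)
  keep <- dA$n >= nA & dB$n >= nB
  dA <- dA[keep, ]; dB <- dB[keep, ]
  if (nrow(dA) == 0L) stop("no SNP observed at the requested projection sizes")
  counts <- matrix(0, nA + 1L, nB + 1L,
                   dimnames = list(0:nA, 0:nB))
  for (i in seq_len(nrow(dA))) {
    wA <- project_weights(dA$k[i], dA$n[i], nA)
    wB <- project_weights(dB$k[i], dB$n[i], nB)
    counts <- counts + outer(wA, wB)
  }
  structure(list(counts = counts, nA = nA, nB = nB, n_snps_used = nrow(dA)),
            class = "joint_sfs")
}

#' Equilibrium-neutral expected site-frequency spectrum
#'
#' Under the standard neutral model at mutation-drift equilibrium the
#' expected proportion of segregating sites with derived count i in a
#' sample of n chromosomes is (1/i) / H(n-1), H the harmonic number.
#'
#' @param n haploid sample size (>= 2).
#' @return Numeric vector of proportions over bins 1..n-1 (sums to 1).
#' @export
neutral_equilibrium_sfs <- function(n) {
  if (n < 2) stop("n must be >= 2")
  w <- 1 / seq_len(n - 1)
  w / sum(w)
}

#' Fold a derived spectrum into a minor-allele spectrum
#'
#' @param sfs an `sfs_result` or numeric vector over bins 1..n-1.
#' @param n sample size (required when `sfs` is a bare vector).
#' @return Numeric vector over minor-allele counts 1..floor(n/2).
#' @export
fold_sfs <- function(sfs, n = NULL) {
  if (inherits(sfs, "sfs_result")) { v <- sfs$counts; n <- sfs$n } else v <- sfs
  if (is.null(n)) stop("n required")
  half <- n %/% 2
  out <- numeric(half)
  for (i in seq_len(half)) {
    out[i] <- if (i == n - i) v[i] else v[i] + v[n - i]
  }
  out
}
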