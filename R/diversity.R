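# Per-population diversity summaries: percent pairwise diversity, F_IS,
# private SNPs and sliding-window diversity tracks.

# Per-SNP pairwise-difference probability under haploid coding of inbreds.
# Heterozygous and missing calls drop out; returns NA for SNPs monomorphic
# (or with < 2 haploid calls) within the accession set.
per_snp_diversity <- function(g, members, unbiased = TRUE) {
  cn <- haploid_counts(g, members)
  x <- cn$x; n <- cn$n
  p <- ifelse(n > 0, x / n, NA_real_)
  d <- 2 * p * (1 - p)
  if (unbiased) d <- d * n / pmax(n - 1, 1)
  d[n < 2 | x == 0 | x == n] <- NA_real_
  d
}

#' Average pairwise diversity within a population
#'
#' The probability that two randomly drawn accessions differ at a SNP,
#' averaged over SNPs polymorphic within the population. Heterozygous and
#' missing calls are treated as missing; each homozygous call contributes a
#' single haploid allele. Per SNP the estimate is 2p(1-p) with, by default,
#' the unbiased n/(n-1) small-sample factor (p the within-population alt
#' frequency from n haploid calls).
#'
#' @param g a `genotype_matrix`.
#' @param members accession ids of the population (>= 2).
#' @param unbiased apply the n/(n-1) correction (default TRUE).
#' @return Mean per-SNP diversity over SNPs polymorphic in the population.
#' @export
pairwise_diversity <- function(g, members, unbiased = TRUE) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (length(members) < 2L) stop("need at least 2 members")
  d <- per_snp_diversity(g, members, unbiased)
  if (all(is.na(d))) stop("no polymorphic SNP retained in this population")
  mean(d, na.rm = TRUE)
}

#' Sliding-window diversity track
#'
#' Averages per-SNP diversity in windows of `window_snps` consecutive SNPs
#' (map order) advancing by `step_snps`, never crossing a linkage group. A
#' group shorter than one window yields a single truncated window. Windows
#' are anchored at the mean cM of their SNPs.
#'
#' @param g a `genotype_matrix`.
#' @param members accession ids of the population.
#' @param map a `genetic_map` covering the SNPs of `g`.
#' @param window_snps window size in SNPs (default 10).
#' @param step_snps step in SNPs (default 5).
#' @param unbiased see [pairwise_diversity()].
#' @return data.frame: linkage_group, window index, cM anchor, n_snps, diversity.
#' @export
sliding_diversity <- function(g, members, map, window_snps = 10L, step_snps = 5L,
                              unbiased = TRUE) {
  stopifnot(inherits(g, "genotype_matrix"))
  map <- map[map$snp_id %in% g$snp_ids, , drop = FALSE]
  d <- per_snp_diversity(g, members, unbiased)[map$snp_id]
  out <- list()
  for (lg in unique(map$linkage_group)) {
    idx <- which(map$linkage_group == lg)
    S <- length(idx)
    starts <- if (S <= window_snps) 1L else seq(1L, S - window_snps + 1L, by = step_snps)
    for (w in seq_along(starts)) {
      sel <- idx[starts[w]:min(starts[w] + window_snps - 1L, S)]
      out[[length(out) + 1L]] <- data.frame(
        linkage_group = lg, window = w,
        position_cM = mean(map$position_cM[sel]),
        n_snps = length(sel),
        diversity = mean(d[sel], na.rm = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Within-population inbreeding coefficient F_IS
#'
#' Per SNP with expected heterozygosity H_e > 0, F_IS = 1 - H_o/H_e where
#' H_o is the observed heterozygote fraction among non-missing calls and
#' H_e = 2p(1-p) with p the allele frequency counting each genotype as two
#' alleles (heterozygotes contribute one of each). Returned as either the
#' unweighted mean of per-SNP ratios (default) or one minus the ratio of
#' mean H_o to mean H_e.
#'
#' @param g a `genotype_matrix`.
#' @param members accession ids (>= 2).
#' @param method `"mean_of_ratios"` (default) or `"ratio_of_means"`.
#' @return F_IS in [-1, 1] (1 when no heterozygote is observed).
#' @export
inbreeding_coefficient <- function(g, members,
                                   method = c("mean_of_ratios", "ratio_of_means")) {
  stopifnot(inherits(g, "genotype_matrix"))
  method <- match.arg(method)
  if (length(members) < 2L) stop("need at least 2 members")
  calls <- g$calls[members, , drop = FALSE]
  n_obs <- colSums(!is.na(calls))
  n_het <- colSums(calls == CALL_HET, na.rm = TRUE)
  alt_alleles <- colSums(calls, na.rm = TRUE)     # 0/1/2 doubles as allele count
  p <- ifelse(n_obs > 0, alt_alleles / (2 * n_obs), NA_real_)
  he <- 2 * p * (1 - p)
  ho <- ifelse(n_obs > 0, n_het / n_obs, NA_real_)
  keep <- !is.na(he) & he > 0
  if (!any(keep)) stop("no SNP with H_e > 0 in this population")
  if (method == "mean_of_ratios") {
    mean(1 - ho[keep] / he[keep])
  } else {
    1 - mean(ho[keep]) / mean(he[keep])
  }
}

#' Count private SNPs per group
#'
#' A SNP is private to a group when it is polymorphic (two haploid states
#' observed) within that group and monomorphic or entirely missing in every
#' other group. Works for the breeding-population partition as well as
#' coarser partitions (e.g. spring vs winter).
#'
#' @param g a `genotype_matrix`.
#' @param groups named list of accession-id vectors (>= 2 groups), e.g.
#'   from [partition_accessions()].
#' @return Named integer vector of private-SNP counts per group.
#' @export
private_snps <- function(g, groups) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (length(groups) < 2L) stop("need at least 2 groups")
  poly <- vapply(groups, function(members) {
    cn <- haploid_counts(g, members)
    cn$x > 0L & cn$x < cn$n
  }, logical(length(g$snp_ids)))
  # poly: SNPs x groups logical matrix
  n_poly <- rowSums(poly)
  counts <- colSums(poly & n_poly == 1L)
  names(counts) <- names(groups)
  counts
}

#' Per-population diversity summary table
#'
#' One row per population: number of polymorphic markers, average pairwise
#' diversity, mean F_IS, private-SNP count and sample size.
#'
#' @param g a `genotype_matrix`.
#' @param scheme a `population_scheme`.
#' @param unbiased see [pairwise_diversity()].
#' @return data.frame with one row per population.
#' @export
diversity_summary <- function(g, scheme, unbiased = TRUE) {
  groups <- partition_accessions(scheme, "population",
                                 accessions = g$accession_ids)
  priv <- private_snps(g, groups)
  rows <- lapply(names(groups), function(pop) {
    members <- groups[[pop]]
    cn <- haploid_counts(g, members)
    data.frame(population = pop,
               sample_size = length(members),
               n_markers_polymorphic = sum(cn$x > 0L & cn$x < cn$n),
               avg_pairwise_diversity = pairwise_diversity(g, members, unbiased),
               mean_F_IS = inbreeding_coefficient(g, members),
               private_snp_count = unname(priv[pop]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
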