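# Haploid Weir-Cockerham theta: per-SNP scans with empirical outlier
# thresholds, multi-locus pairwise F_ST, and dropout-bootstrap robustness.

#' Haploid Weir-Cockerham theta at a single SNP
#'
#' ANOVA estimator of F_ST for haploid allele counts from r populations.
#' With n_i haploid sample sizes, p_i allele frequencies and
#' pbar = sum(n_i p_i)/sum(n_i):
#' MSP = sum(n_i (p_i - pbar)^2) / (r - 1),
#' MSG = sum(n_i p_i (1 - p_i)) / sum(n_i - 1),
#' n_c = (sum(n_i) - sum(n_i^2)/sum(n_i)) / (r - 1), and
#' theta = (MSP - MSG) / (MSP + (n_c - 1) MSG), undefined when the
#' denominator vanishes (e.g. the SNP is monomorphic overall) or fewer than
#' two populations have data.
#'
#' @param x per-population haploid counts of the alternate allele.
#' @param n per-population haploid sample sizes (heterozygotes must already
#'   have been dropped).
#' @return list of class `fst_components`: r, n_i, p_i, nbar, n_c, MSP, MSG,
#'   theta (NA when undefined) and a `reason` when undefined.
#' @export
wc_theta_haploid <- function(x, n) {
  if (length(x) != length(n)) stop("x and n lengths differ")
  keep <- n > 0
  x <- x[keep]; n <- n[keep]
  r <- length(n)
  if (any(x < 0) || any(x > n)) stop("counts must satisfy 0 <= x <= n")
  base <- list(r = r, n_i = n, p_i = if (r) x / n else numeric(),
               nbar = if (r) mean(n) else NA_real_)
  if (r < 2L) {
    return(structure(c(base, list(n_c = NA_real_, MSP = NA_real_, MSG = NA_real_,
                                  theta = NA_real_, reason = "r<2")),
                     class = "fst_components"))
  }
  p <- x / n
  N <- sum(n)
  pbar <- sum(n * p) / N
  MSP <- sum(n * (p - pbar)^2) / (r - 1)
  MSG <- sum(n * p * (1 - p)) / sum(n - 1)
  n_c <- (N - sum(n^2) / N) / (r - 1)
  denom <- MSP + (n_c - 1) * MSG
  theta <- if (denom == 0) NA_real_ else (MSP - MSG) / denom
  reason <- if (denom == 0) "undefined_denominator" else NA_character_
  structure(c(base, list(n_c = n_c, MSP = MSP, MSG = MSG, theta = theta,
                         reason = reason)),
            class = "fst_components")
}

# Vectorized per-SNP theta over a SNPs x populations count layout.
# X, N: matrices (SNPs x groups) of alt counts and haploid sample sizes.
# Returns list(theta, num, den) where num/den are the per-SNP variance
# components a and a + MSG used for ratio-of-sums aggregation.
wc_theta_matrix <- function(X, N) {
  has <- N > 0
  r <- rowSums(has)
  Nsum <- rowSums(N)
  P <- ifelse(has, X / pmax(N, 1L), 0)
  pbar <- rowSums(N * P) / pmax(Nsum, 1L)
  MSP <- rowSums(N * (P - pbar)^2 * has) / pmax(r - 1, 1)
  MSG <- rowSums(N * P * (1 - P) * has) / pmax(rowSums((N - 1) * has), 1)
  n_c <- (Nsum - rowSums(N^2) / pmax(Nsum, 1L)) / pmax(r - 1, 1)
  denom <- MSP + (n_c - 1) * MSG
  theta <- ifelse(r >= 2 & denom != 0, (MSP - MSG) / denom, NA_real_)
  # ratio-of-sums components: a = (MSP - MSG)/n_c, total = a + MSG
  a <- ifelse(r >= 2 & n_c > 0, (MSP - MSG) / n_c, NA_real_)
  list(theta = theta, num = a, den = a + MSG, r = r)
}

# SNPs x groups haploid count matrices for a partition of accessions.
partition_counts <- function(g, groups) {
  X <- N <- matrix(0L, length(g$snp_ids), length(groups),
                   dimnames = list(g$snp_ids, names(groups)))
  for (k in seq_along(groups)) {
    cn <- haploid_counts(g, groups[[k]])
    X[, k] <- cn$x
    N[, k] <- cn$n
  }
  list(X = X, N = N)
}

#' Genome-wide F_ST outlier scan
#'
#' Computes per-SNP haploid Weir-Cockerham theta across the groups of a
#' partition, the empirical quantile threshold over defined thetas
#' (negatives retained), and the outlier set (theta >= threshold, ties
#' included). Also reports the multi-locus (ratio-of-sums) mean theta.
#'
#' @param g a `genotype_matrix`.
#' @param groups named list of accession-id vectors (>= 2 groups), e.g.
#'   from [partition_accessions()].
#' @param quantile empirical quantile defining outliers (default 0.975,
#'   i.e. the top 2.5%).
#' @return An `fst_scan`: data.frame `snps` (snp_id, theta, outlier),
#'   `threshold`, `mean_theta` (ratio of sums), `mean_theta_per_snp`
#'   (mean of per-SNP ratios), `quantile`, `n_defined`.
#' @export
fst_scan <- function(g, groups, quantile = 0.975) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (length(groups) < 2L) stop("need >= 2 groups")
  pc <- partition_counts(g, groups)
  comp <- wc_theta_matrix(pc$X, pc$N)
  defined <- !is.na(comp$theta)
  if (sum(defined) < 2L) stop("fewer than 2 SNPs with defined theta")
  threshold <- stats::quantile(comp$theta[defined], quantile, names = FALSE)
  outlier <- defined & comp$theta >= threshold
  structure(list(
    snps = data.frame(snp_id = g$snp_ids, theta = comp$theta,
                      outlier = outlier, stringsAsFactors = FALSE),
    threshold = threshold,
    mean_theta = sum(comp$num[defined]) / sum(comp$den[defined]),
    mean_theta_per_snp = mean(comp$theta[defined]),
    quantile = quantile,
    n_defined = sum(defined)),
    class = "fst_scan")
}

#' @export
print.fst_scan <- function(x, ...) {
  cat(sprintf("fst_scan: %d SNPs defined, mean theta %.3f, threshold(%.3f) = %.3f, %d outliers\n",
              x$n_defined, x$mean_theta, x$quantile, x$threshold,
              sum(x$snps$outlier)))
  invisible(x)
}

#' Pairwise multi-locus F_ST matrix between populations
#'
#' For each population pair, the Weir-Cockerham ratio-of-sums estimate:
#' per-SNP among-population and total variance components are summed over
#' SNPs before the ratio is taken. The matrix is symmetric with a zero
#' diagonal.
#'
#' @param g a `genotype_matrix`.
#' @param scheme a `population_scheme` (or a named list of accession sets).
#' @return Symmetric numeric matrix of pairwise F_ST values.
#' @export
pairwise_fst <- function(g, scheme) {
  groups <- if (inherits(scheme, "population_scheme"))
    partition_accessions(scheme, "population", accessions = g$accession_ids)
  else scheme
  if (length(groups) < 2L) stop("need >= 2 populations")
  pc <- partition_counts(g, groups)
  K <- length(groups)
  M <- matrix(0, K, K, dimnames = list(names(groups), names(groups)))
  for (a in seq_len(K - 1L)) for (b in (a + 1L):K) {
    comp <- wc_theta_matrix(pc$X[, c(a, b), drop = FALSE],
                            pc$N[, c(a, b), drop = FALSE])
    ok <- !is.na(comp$num) & !is.na(comp$den)
    M[a, b] <- M[b, a] <- sum(comp$num[ok]) / sum(comp$den[ok])
  }
  M
}

#' Bootstrap robustness of the F_ST outlier set
#'
#' Repeatedly drops a random fraction of SNPs (`drop_snps`) or of
#' accessions stratified by group (`drop_samples`), re-runs the outlier
#' scan at the same quantile, and records the fraction of the original
#' outliers recovered. In `drop_snps` mode recovery is measured among the
#' original outliers that were retained in the iteration.
#'
#' @param g a `genotype_matrix`.
#' @param groups named list of accession-id vectors defining the partition.
#' @param mode `"drop_snps"` or `"drop_samples"`.
#' @param drop_fraction fraction removed per iteration (default 0.20).
#' @param iterations number of bootstrap iterations (default 100).
#' @param quantile outlier quantile (default 0.975).
#' @param seed integer seed; recorded in the report.
#' @return A `bootstrap_report`: mode, drop_fraction, iterations, seed,
#'   per-iteration `recovery` and `mean_recovery`.
#' @export
bootstrap_outlier_recovery <- function(g, groups,
                                       mode = c("drop_snps", "drop_samples"),
                                       drop_fraction = 0.20, iterations = 100L,
                                       quantile = 0.975, seed = 1L) {
  mode <- match.arg(mode)
  if (drop_fraction <= 0 || drop_fraction >= 1) stop("drop_fraction in (0,1)")
  base <- fst_scan(g, groups, quantile)
  orig <- base$snps$snp_id[base$snps$outlier]
  set.seed(seed)
  recovery <- numeric(iterations)
  for (it in seq_len(iterations)) {
    repeat {
      if (mode == "drop_snps") {
        n_drop <- floor(drop_fraction * length(g$snp_ids))
        keep_snp <- sample(g$snp_ids, length(g$snp_ids) - n_drop)
        sub <- subset_genotypes(g, snps = sort(keep_snp))
        sub_groups <- groups
      } else {
        sub_groups <- lapply(groups, function(mem) {
          n_drop <- floor(drop_fraction * length(mem))
          sample(mem, length(mem) - n_drop)
        })
        sub <- g
      }
      if (all(lengths(sub_groups) >= 1L)) break   # resample if a group empties
    }
    res <- tryCatch(fst_scan(sub, sub_groups, quantile), error = function(e) NULL)
    if (is.null(res)) { recovery[it] <- NA_real_; next }
    new_out <- res$snps$snp_id[res$snps$outlier]
    ref <- if (mode == "drop_snps") intersect(orig, res$snps$snp_id) else orig
    recovery[it] <- if (length(ref) == 0L) NA_real_ else
      length(intersect(ref, new_out)) / length(ref)
  }
  structure(list(mode = mode, drop_fraction = drop_fraction,
                 iterations = iterations, seed = seed,
                 recovery = recovery,
                 mean_recovery = mean(recovery, na.rm = TRUE)),
            class = "bootstrap_report")
}

#' @export
print.bootstrap_report <- function(x, ...) {
  cat(sprintf("bootstrap_report: %s, drop %.0f%%, %d iterations, mean recovery %.3f\n",
              x$mode, 100 * x$drop_fraction, x$iterations, x$mean_recovery))
  invisible(x)
}

#' Write an F_ST scan as a per-SNP TSV track
#'
#' @param scan an `fst_scan`.
#' @param map a `genetic_map` (adds linkage_group and cM columns).
#' @param path output TSV path.
#' @export
write_fst_scan <- function(scan, map, path) {
  df <- scan$snps
  m <- match(df$snp_id, map$snp_id)
  df$linkage_group <- map$linkage_group[m]
  df$position_cM <- map$position_cM[m]
  data.table::fwrite(df[, c("snp_id", "linkage_group", "position_cM",
                            "theta", "outlier")], path, sep = "\t")
  invisible(path)
}
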