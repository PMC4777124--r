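# Haplotypes for inbreds, the PHS recent-selection scan, and windowed IBS
# segment sharing between populations.

#' Collapse inbred genotypes to haploid allele strings
#'
#' With near-complete inbreeding (F_IS ~ 0.98) each accession is treated as
#' a single haplotype: homozygous reference -> 0, homozygous alternate -> 1,
#' heterozygous and missing calls -> missing. This replaces statistical
#' phasing, which at these inbreeding levels adds noise rather than
#' information.
#'
#' @param g a `genotype_matrix`.
#' @param accessions optional subset of accessions.
#' @return A `haplotype_set`: matrix `h` (haplotypes x SNPs over
#'   \{0, 1, NA\}), `accession_ids`, `snp_ids`, `collapsed_inbred = TRUE`.
#' @export
collapse_to_haplotypes <- function(g, accessions = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  h <- haploid_codes(g, accessions)
  structure(list(h = h, accession_ids = rownames(h), snp_ids = colnames(h),
                 collapsed_inbred = TRUE),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("haplotype_set: %d haplotypes x %d SNPs (%.1f%% missing)\n",
              nrow(x$h), ncol(x$h), 100 * mean(is.na(x$h))))
  invisible(x)
}

# Shared-segment length (cM) around every focal SNP of one linkage group for
# one haplotype pair. Missing sites neither match nor break (skipped); the
# segment around a focal SNP runs between the nearest flanking mismatches,
# and its length is the cM span of the matching sites it contains.
share_profile_chrom <- function(a, b, cm) {
  S <- length(a)
  st <- a == b                        # NA where either haplotype is missing
  is_mm <- !is.na(st) & !st
  is_mt <- !is.na(st) & st
  d <- numeric(S)
  if (any(is_mt)) {
    seg <- cumsum(is_mm)              # segment id for non-mismatch positions
    gmin <- tapply(cm[is_mt], seg[is_mt], min)
    gmax <- tapply(cm[is_mt], seg[is_mt], max)
    key <- match(as.character(seg), names(gmin))
    span <- gmax[key] - gmin[key]
    d <- ifelse(is.na(span), 0, span)
  }
  d[is_mm] <- 0
  unname(d)
}

# Map-ordered SNP index split by linkage group, restricted to the SNPs of h.
map_chrom_index <- function(h, map) {
  map <- map[map$snp_id %in% h$snp_ids, , drop = FALSE]
  if (nrow(map) != length(h$snp_ids)) stop("map does not cover the SNP set")
  split(seq_len(nrow(map)), map$linkage_group)[unique(map$linkage_group)]
}

# Pair-by-SNP matrix of sharing lengths d_ijx, SNPs in map order.
pair_share_matrix <- function(h, map) {
  map <- map[map$snp_id %in% h$snp_ids, , drop = FALSE]
  H <- h$h[, map$snp_id, drop = FALSE]
  n <- nrow(H)
  pr <- utils::combn(n, 2L)
  chroms <- split(seq_len(nrow(map)), map$linkage_group)[unique(map$linkage_group)]
  D <- matrix(0, ncol(pr), nrow(map))
  for (p in seq_len(ncol(pr))) {
    a <- H[pr[1L, p], ]; b <- H[pr[2L, p], ]
    for (idx in chroms)
      D[p, idx] <- share_profile_chrom(a[idx], b[idx], map$position_cM[idx])
  }
  list(D = D, pairs = pr, snp_id = map$snp_id, map = map)
}

#' Shared haplotype length around a focal SNP for one accession pair
#'
#' Extends left and right from the focal SNP while the two haplotypes
#' match; missing sites are skipped (they neither match nor break); the
#' segment stops at the first mismatch or chromosome end. The length is
#' cM(rightmost matching site) - cM(leftmost matching site); a mismatch at
#' the focal SNP itself gives 0.
#'
#' @param h a `haplotype_set`.
#' @param i,j accession ids (or indices) of the pair.
#' @param x focal SNP id.
#' @param map a `genetic_map`.
#' @return Sharing length in cM.
#' @export
sharing_length <- function(h, i, j, x, map) {
  stopifnot(inherits(h, "haplotype_set"))
  if (is.character(i)) i <- match(i, h$accession_ids)
  if (is.character(j)) j <- match(j, h$accession_ids)
  if (is.na(i) || is.na(j) || i == j) stop("need two distinct accessions")
  lg <- map$linkage_group[match(x, map$snp_id)]
  if (is.na(lg)) stop("focal SNP not on the map")
  m <- map[map$linkage_group == lg & map$snp_id %in% h$snp_ids, , drop = FALSE]
  a <- h$h[i, m$snp_id]; b <- h$h[j, m$snp_id]
  d <- share_profile_chrom(a, b, m$position_cM)
  d[match(x, m$snp_id)]
}

#' Pairwise haplotype sharing (PHS) selection scan
#'
#' For every haplotype pair (i, j) the genome-wide mean and standard
#' deviation of sharing lengths d_ijx over all focal SNPs standardize the
#' per-site score Z_ijx. For focal SNP x and allele A carried by p >= 2
#' haplotypes,
#' PHS_xA = mean of Z_ijx over carrier pairs - mean of Z_ijx over all
#' pairs. Long, high-frequency sharing relative to the genome-wide
#' background signals recent selection. Outliers are the top (1 - quantile)
#' of PHS among entries whose carrier frequency reaches `min_freq`.
#'
#' @param h a `haplotype_set` (>= 4 haplotypes).
#' @param map a `genetic_map` covering the SNP set.
#' @param min_freq minimum focal-allele frequency for outlier eligibility
#'   (default 0.10).
#' @param quantile empirical outlier quantile (default 0.975).
#' @return A `phs_scan`: data.frame `scores` (snp_id, linkage_group,
#'   position_cM, allele, phs, carrier_freq, n_carriers, mean_share_cM,
#'   eligible, outlier), `threshold`, plus the pair statistics.
#' @export
phs_scan <- function(h, map, min_freq = 0.10, quantile = 0.975) {
  stopifnot(inherits(h, "haplotype_set"))
  n <- nrow(h$h)
  if (n < 4L) stop("need >= 4 haplotypes")
  psm <- pair_share_matrix(h, map)
  D <- psm$D
  dbar <- rowMeans(D)
  sigma <- apply(D, 1L, stats::sd)
  valid <- sigma > 0
  if (!all(valid))
    warning(sum(!valid), " haplotype pair(s) identical genome-wide excluded from Z")
  if (!any(valid)) stop("no pair with positive sharing variance")
  Z <- (D[valid, , drop = FALSE] - dbar[valid]) / sigma[valid]
  pairs <- psm$pairs[, valid, drop = FALSE]
  Dv <- D[valid, , drop = FALSE]
  H <- h$h[, psm$snp_id, drop = FALSE]
  all_mean <- colMeans(Z)
  S <- length(psm$snp_id)
  rows <- vector("list", 2L * S)
  for (s in seq_len(S)) {
    col <- H[, s]
    n_obs <- sum(!is.na(col))
    for (al in c(0L, 1L)) {
      carr <- !is.na(col) & col == al
      p <- sum(carr)
      if (p < 2L) next
      mask <- carr[pairs[1L, ]] & carr[pairs[2L, ]]
      if (!any(mask)) next
      phs <- mean(Z[mask, s]) - all_mean[s]
      rows[[2L * (s - 1L) + al + 1L]] <- data.frame(
        snp_id = psm$snp_id[s], allele = al, phs = phs,
        carrier_freq = p / n_obs, n_carriers = p,
        mean_share_cM = mean(Dv[mask, s]),
        stringsAsFactors = FALSE)
    }
  }
  scores <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  m <- match(scores$snp_id, psm$map$snp_id)
  scores$linkage_group <- psm$map$linkage_group[m]
  scores$position_cM <- psm$map$position_cM[m]
  scores$eligible <- scores$carrier_freq >= min_freq
  if (!any(scores$eligible)) stop("no focal allele reaches min_freq")
  threshold <- stats::quantile(scores$phs[scores$eligible], quantile, names = FALSE)
  scores$outlier <- scores$eligible & scores$phs >= threshold
  structure(list(scores = scores[, c("snp_id", "linkage_group", "position_cM",
                                     "allele", "phs", "carrier_freq",
                                     "n_carriers", "mean_share_cM",
                                     "eligible", "outlier")],
                 threshold = threshold, quantile = quantile,
                 min_freq = min_freq,
                 pair_mean = dbar, pair_sd = sigma, n_haplotypes = n),
            class = "phs_scan")
}

#' @export
print.phs_scan <- function(x, ...) {
  cat(sprintf("phs_scan: %d haplotypes, %d scored alleles, threshold(%.3f) = %.3f, %d outliers\n",
              x$n_haplotypes, nrow(x$scores), x$quantile, x$threshold,
              sum(x$scores$outlier)))
  invisible(x)
}

# Half-overlapping window starts/ends for one linkage group of S SNPs; the
# trailing partial window is merged into the last full one.
ibs_windows <- function(S, window_snps) {
  if (S <= window_snps) return(data.frame(start = 1L, end = S))
  step <- max(1L, window_snps %/% 2L)
  starts <- seq(1L, S - window_snps + 1L, by = step)
  ends <- starts + window_snps - 1L
  ends[length(ends)] <- S
  data.frame(start = starts, end = ends)
}

#' Windowed IBS segment sharing between two populations
#'
#' Windows of `window_snps` SNPs tile each linkage group with half-window
#' steps. Two haplotypes are window-IBS when, among jointly non-missing
#' positions, the mismatch fraction is at most `max_mismatch` (boundary
#' inclusive) and at least half the window is jointly non-missing. Per
#' window, the sharing frequency in each population is the fraction of its
#' haplotypes that are IBS to at least one haplotype of the other
#' population.
#'
#' @param hA,hB `haplotype_set`s of the two populations over the same SNP
#'   set.
#' @param map a `genetic_map`.
#' @param window_snps window size in SNPs, typically 50 or 100.
#' @param max_mismatch tolerated mismatch fraction (default 0.10).
#' @return data.frame: linkage_group, window, start/end cM, n_snps,
#'   freqA, freqB.
#' @export
ibs_sharing <- function(hA, hB, map, window_snps = 100L, max_mismatch = 0.10) {
  stopifnot(inherits(hA, "haplotype_set"), inherits(hB, "haplotype_set"))
  if (!identical(hA$snp_ids, hB$snp_ids)) stop("populations must share the SNP set")
  map <- map[map$snp_id %in% hA$snp_ids, , drop = FALSE]
  A <- hA$h[, map$snp_id, drop = FALSE]
  B <- hB$h[, map$snp_id, drop = FALSE]
  A1 <- (!is.na(A)) * (A == 1); A1[is.na(A1)] <- 0
  A0 <- (!is.na(A)) * (A == 0); A0[is.na(A0)] <- 0
  B1 <- (!is.na(B)) * (B == 1); B1[is.na(B1)] <- 0
  B0 <- (!is.na(B)) * (B == 0); B0[is.na(B0)] <- 0
  out <- list()
  for (lg in unique(map$linkage_group)) {
    idx <- which(map$linkage_group == lg)
    win <- ibs_windows(length(idx), window_snps)
    for (w in seq_len(nrow(win))) {
      cols <- idx[win$start[w]:win$end[w]]
      wlen <- length(cols)
      a1 <- A1[, cols, drop = FALSE]; a0 <- A0[, cols, drop = FALSE]
      b1 <- B1[, cols, drop = FALSE]; b0 <- B0[, cols, drop = FALSE]
      mism <- a1 %*% t(b0) + a0 %*% t(b1)
      joint <- (a1 + a0) %*% t(b1 + b0)
      ibs <- joint >= wlen / 2 & mism <= max_mismatch * joint
      out[[length(out) + 1L]] <- data.frame(
        linkage_group = lg, window = w,
        start_cM = map$position_cM[cols[1L]],
        end_cM = map$position_cM[cols[wlen]],
        n_snps = wlen,
        freqA = mean(apply(ibs, 1L, any)),
        freqB = mean(apply(ibs, 2L, any)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
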