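# Four-population test for gene flow: f4 with block-jackknife standard
# errors and the three-topology migration rule.

#' f4 statistic with block-jackknife standard error
#'
#' f4(A,B; C,D) is the mean over SNPs of (p_A - p_B)(p_C - p_D). Under a
#' tree ((A,B),(C,D)) with no gene flow its expectation is zero, so
#' significant departures in all three pairings of four populations
#' indicate migration rather than incomplete lineage sorting. The standard
#' error comes from a delete-one block jackknife over blocks of
#' `block_size` consecutive SNPs that never span linkage groups.
#'
#' @param freqs numeric matrix (SNPs x 4) of allele frequencies for
#'   populations A, B, C, D (rows with any NA are dropped).
#' @param map optional `genetic_map` whose row order matches `freqs`
#'   rows; used to keep jackknife blocks within linkage groups.
#' @param block_size_snps consecutive SNPs per jackknife block (default 75).
#' @return An `f4_result`: estimate, SE, z, two-sided normal p, n_snps,
#'   n_blocks, block_size.
#' @export
f4_statistic <- function(freqs, map = NULL, block_size_snps = 75L) {
  freqs <- as.matrix(freqs)
  if (ncol(freqs) != 4L) stop("freqs must have 4 columns (A, B, C, D)")
  if (!is.null(map)) {
    if (is.null(rownames(freqs))) {
      if (nrow(map) != nrow(freqs)) stop("map rows must match freqs rows")
      lg_all <- as.character(map$linkage_group)
    } else {
      m <- map[map$snp_id %in% rownames(freqs), , drop = FALSE]
      if (nrow(m) != nrow(freqs)) stop("map does not cover the freqs rows")
      freqs <- freqs[m$snp_id, , drop = FALSE]    # map order
      lg_all <- as.character(m$linkage_group)
    }
  } else lg_all <- rep("1", nrow(freqs))
  keep <- stats::complete.cases(freqs)
  lg <- lg_all[keep]
  freqs <- freqs[keep, , drop = FALSE]
  S <- nrow(freqs)
  terms <- (freqs[, 1L] - freqs[, 2L]) * (freqs[, 3L] - freqs[, 4L])
  # consecutive-SNP blocks within linkage groups
  block <- integer(S)
  nb <- 0L
  for (g in unique(lg)) {
    idx <- which(lg == g)
    b <- (seq_along(idx) - 1L) %/% block_size_snps
    # avoid a tiny trailing block: merge it into the previous one
    if (length(idx) > block_size_snps && sum(b == max(b)) < block_size_snps / 2)
      b[b == max(b)] <- max(b) - 1L
    block[idx] <- nb + b + 1L
    nb <- nb + max(b) + 1L
  }
  if (nb < 2L) stop("need >= 2 jackknife blocks")
  est <- mean(terms)
  tot <- sum(terms)
  bs <- tapply(terms, block, sum)
  bn <- tabulate(block, nb)
  loo <- (tot - bs) / (S - bn)           # delete-one-block estimates
  jk_mean <- mean(loo)
  se <- sqrt((nb - 1) / nb * sum((loo - jk_mean)^2))
  z <- if (se > 0) est / se else ifelse(est == 0, 0, sign(est) * Inf)
  structure(list(f4 = est, se = se, z = z,
                 p = 2 * stats::pnorm(-abs(z)),
                 n_snps = S, n_blocks = nb,
                 block_size = block_size_snps),
            class = "f4_result")
}

#' @export
print.f4_result <- function(x, ...) {
  cat(sprintf("f4 = %.5f (SE %.5f, z = %.2f, p = %.3g; %d SNPs, %d blocks)\n",
              x$f4, x$se, x$z, x$p, x$n_snps, x$n_blocks))
  invisible(x)
}

#' Per-population allele frequencies from haploid calls
#'
#' @param g a `genotype_matrix`.
#' @param groups named list of accession-id vectors.
#' @return Numeric matrix SNPs x groups of alternate-allele frequencies
#'   (NA where a group has no non-missing haploid call).
#' @export
group_frequencies <- function(g, groups) {
  pc <- partition_counts(g, groups)
  F <- pc$X / pc$N
  F[pc$N == 0L] <- NA_real_
  F
}

#' Three-topology migration test for a population quadruple
#'
#' Evaluates f4 for the three distinct unrooted pairings (A,B;C,D),
#' (A,C;B,D), (A,D;B,C) and infers gene flow only when all three depart
#' significantly from zero at `alpha` (two-sided): under a clean tree one
#' pairing matches the true topology and its f4 is expected to be zero.
#'
#' @param freqs SNPs x populations frequency matrix with column names.
#' @param quad character vector of 4 distinct population names (A, B, C, D).
#' @param map optional `genetic_map` matching the rows of `freqs`.
#' @param block_size_snps jackknife block size (default 75).
#' @param alpha significance level (default 0.05).
#' @return A `migration_verdict`: the quadruple, a data.frame `topologies`
#'   (topology, f4, se, z, p, significant) and `verdict`
#'   ("gene_flow"/"no_gene_flow").
#' @export
test_migration <- function(freqs, quad, map = NULL, block_size_snps = 75L,
                           alpha = 0.05) {
  if (length(quad) != 4L || anyDuplicated(quad))
    stop("need 4 distinct populations")
  if (!all(quad %in% colnames(freqs))) stop("unknown population in quadruple")
  pairings <- list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))
  rows <- lapply(pairings, function(pp) {
    r <- f4_statistic(freqs[, quad[pp], drop = FALSE], map, block_size_snps)
    data.frame(topology = sprintf("(%s,%s;%s,%s)", quad[pp[1]], quad[pp[2]],
                                  quad[pp[3]], quad[pp[4]]),
               f4 = r$f4, se = r$se, z = r$z, p = r$p,
               significant = is.finite(r$p) & r$p < alpha,
               stringsAsFactors = FALSE)
  })
  top <- do.call(rbind, rows)
  structure(list(quad = quad, topologies = top, alpha = alpha,
                 verdict = if (all(top$significant)) "gene_flow" else "no_gene_flow"),
            class = "migration_verdict")
}

#' @export
print.migration_verdict <- function(x, ...) {
  cat(sprintf("migration_verdict [%s]: %s\n", paste(x$quad, collapse = ","),
              x$verdict))
  print(x$topologies, row.names = FALSE)
  invisible(x)
}

#' Iterate the migration test over substitution sets
#'
#' Mirrors the topology-iteration procedure: a base quadruple whose slots
#' marked `"X"`, `"Y1"`, `"Y2"` are substituted by every candidate (X) or
#' candidate pair (Y1, Y2) from the supplied sets; each concrete quadruple
#' gets the three-topology test.
#'
#' @param freqs SNPs x populations frequency matrix with column names.
#' @param base character vector of 4 slots; fixed population names or the
#'   placeholders "X", "Y1", "Y2".
#' @param x_set candidate populations for "X".
#' @param y_set candidate populations for the ("Y1","Y2") pair (all
#'   unordered pairs are used).
#' @param ... passed to [test_migration()].
#' @return data.frame with one row per quadruple: the four populations,
#'   the three p-values and the verdict.
#' @export
iterate_migration_tests <- function(freqs, base, x_set = character(),
                                    y_set = character(), ...) {
  quads <- list()
  xs <- if ("X" %in% base) x_set else NA_character_
  ypairs <- if (all(c("Y1", "Y2") %in% base)) {
    if (length(y_set) < 2L) stop("need >= 2 candidates for the Y pair")
    utils::combn(y_set, 2L, simplify = FALSE)
  } else list(NA_character_)
  for (x in xs) for (yp in ypairs) {
    q <- base
    q[q == "X"] <- x
    q[q == "Y1"] <- yp[1L]
    q[q == "Y2"] <- yp[2L]
    if (anyDuplicated(q)) next
    quads[[length(quads) + 1L]] <- q
  }
  if (!length(quads)) stop("no admissible quadruple")
  rows <- lapply(quads, function(q) {
    v <- test_migration(freqs, q, ...)
    data.frame(A = q[1], B = q[2], C = q[3], D = q[4],
               p1 = v$topologies$p[1], p2 = v$topologies$p[2],
               p3 = v$topologies$p[3], verdict = v$verdict,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
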