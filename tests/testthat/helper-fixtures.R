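# Shared fixture builders. Everything is generated in code at test time.

# Genotype matrix from an integer call matrix (0/1/2/NA); alleles default
# to A (ref) / G (alt) at every SNP.
gm_from_calls <- function(calls, ref = "A", alt = "G") {
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("acc%02d", seq_len(nrow(calls)))
  if (is.null(colnames(calls)))
    colnames(calls) <- sprintf("snp%03d", seq_len(ncol(calls)))
  genotype_matrix(calls, data.frame(snp_id = colnames(calls),
                                    ref = rep_len(ref, ncol(calls)),
                                    alt = rep_len(alt, ncol(calls)),
                                    stringsAsFactors = FALSE))
}

# Uniform map: one linkage group per `per_group` SNPs, 1 cM spacing.
map_for <- function(g, per_group = ncol(g$calls), spacing = 1) {
  S <- length(g$snp_ids)
  lg <- paste0(ceiling(seq_len(S) / per_group), "H")
  pos <- (seq_len(S) - 1) %% per_group * spacing
  genetic_map(g$snp_ids, lg, pos)
}

# Fully homozygous genotype matrix from Balding-Nichols drift: K populations
# of n accessions drifted at c from a shared Beta(1.5, 1.5) ancestral
# frequency. Returns the matrix and the accession grouping.
bn_genotypes <- function(c, S = 2000L, K = 8L, n = 50L, seed = 1L) {
  set.seed(seed)
  pi <- pmin(pmax(stats::rbeta(S, 1.5, 1.5), 0.02), 0.98)
  calls <- NULL; accs <- character(); pops <- character()
  for (k in seq_len(K)) {
    p <- if (c < 1e-12) pi else
      stats::rbeta(S, pi * (1 - c) / c, (1 - pi) * (1 - c) / c)
    m <- matrix(2L * stats::rbinom(n * S, 1L, rep(p, each = n)), n, S)
    calls <- rbind(calls, m)
    accs <- c(accs, sprintf("P%02d_a%03d", k, seq_len(n)))
    pops <- c(pops, rep(sprintf("P%02d", k), n))
  }
  rownames(calls) <- accs
  colnames(calls) <- sprintf("s%04d", seq_len(S))
  list(g = gm_from_calls(calls), groups = split(accs, pops), pi = pi)
}

# Random small genotype matrix with optional missing/heterozygous calls.
random_gm <- function(n_acc, n_snp, p_het = 0, p_miss = 0, seed = 1L) {
  set.seed(seed)
  calls <- matrix(sample(c(0L, 2L), n_acc * n_snp, replace = TRUE), n_acc, n_snp)
  if (p_het > 0)
    calls[matrix(stats::runif(n_acc * n_snp) < p_het, n_acc, n_snp)] <- 1L
  if (p_miss > 0)
    calls[matrix(stats::runif(n_acc * n_snp) < p_miss, n_acc, n_snp)] <- NA_integer_
  gm_from_calls(calls)
}

# Two-population scheme over the accessions of g, split in half.
scheme_halves <- function(g, spike = c(2L, 6L), habit = c("spring", "winter")) {
  n <- length(g$accession_ids)
  pop <- rep(c("PA", "PB"), c(ceiling(n / 2), floor(n / 2)))
  population_scheme(g$accession_ids, pop,
                    data.frame(population = c("PA", "PB"), spike_type = spike,
                               growth_habit = habit, stringsAsFactors = FALSE))
}

# Independent textbook oracle for haploid theta: expand counts to 0/1
# haploid observations and run the one-way ANOVA decomposition from scratch.
wc_oracle <- function(x, n) {
  r <- length(n)
  vals <- unlist(mapply(function(xi, ni) c(rep(1, xi), rep(0, ni - xi)),
                        x, n, SIMPLIFY = FALSE))
  grp <- rep(seq_len(r), n)
  N <- sum(n)
  means <- tapply(vals, grp, mean)
  gm <- mean(vals)
  MSA <- sum(n * (means - gm)^2) / (r - 1)
  MSW <- sum((vals - means[grp])^2) / (N - r)
  n_c <- (N - sum(n^2) / N) / (r - 1)
  s2A <- (MSA - MSW) / n_c
  denom <- s2A + MSW
  if (denom == 0) NA_real_ else s2A / denom
}

# Count simulator for the censored-normal divergence model.
cn_counts <- function(cs, L = 600L, n = 80L, seed = 1L) {
  set.seed(seed)
  pi <- pmin(pmax(stats::rbeta(L, 1.5, 1.5), 0.05), 0.95)
  K <- length(cs)
  p <- t(vapply(cs, function(c) {
    if (c < 1e-12) return(pi)
    pmin(pmax(stats::rnorm(L, pi, sqrt(c * pi * (1 - pi))), 0), 1)
  }, numeric(L)))
  x <- matrix(stats::rbinom(K * L, n, p), K, L)
  rownames(x) <- sprintf("P%d", seq_len(K))
  nn <- matrix(n, K, L, dimnames = dimnames(x))
  tot <- colSums(x)
  keep <- tot > 0 & tot < K * n
  list(x = x[, keep, drop = FALSE], n = nn[, keep, drop = FALSE])
}

# Independent scalar walker for shared-segment length: the oracle used by
# the PHS brute-force tests (no code shared with the package internals).
share_length_brute <- function(a, b, cm, x) {
  S <- length(a)
  match_at <- function(k) {
    if (is.na(a[k]) || is.na(b[k])) return(NA)   # skip: neither match nor break
    a[k] == b[k]
  }
  if (isFALSE(match_at(x))) return(0)
  lo <- x
  for (k in x:1) {
    st <- match_at(k)
    if (isFALSE(st)) break
    lo <- k
  }
  hi <- x
  for (k in x:S) {
    st <- match_at(k)
    if (isFALSE(st)) break
    hi <- k
  }
  sites <- lo:hi
  sites <- sites[vapply(sites, function(k) isTRUE(match_at(k)), TRUE)]
  if (!length(sites)) return(0)
  cm[max(sites)] - cm[min(sites)]
}

# Brute-force PHS for every (focal SNP, allele) of a haplotype set: plain
# double loops over pairs, genome-wide standardization.
phs_brute <- function(H, map) {
  H <- H[, map$snp_id, drop = FALSE]
  n <- nrow(H); S <- ncol(H)
  pr <- utils::combn(n, 2L)
  D <- matrix(NA_real_, ncol(pr), S)
  for (p in seq_len(ncol(pr))) {
    i <- pr[1, p]; j <- pr[2, p]
    for (x in seq_len(S)) {
      on <- which(map$linkage_group == map$linkage_group[x])
      D[p, x] <- share_length_brute(H[i, on], H[j, on], map$position_cM[on],
                                    match(x, on))
    }
  }
  dbar <- rowMeans(D); sg <- apply(D, 1, stats::sd)
  ok <- sg > 0
  out <- list()
  for (x in seq_len(S)) for (al in 0:1) {
    carr <- which(!is.na(H[, x]) & H[, x] == al)
    if (length(carr) < 2L) next
    zc <- za <- c()
    for (p in seq_len(ncol(pr))) {
      if (!ok[p]) next
      z <- (D[p, x] - dbar[p]) / sg[p]
      za <- c(za, z)
      if (pr[1, p] %in% carr && pr[2, p] %in% carr) zc <- c(zc, z)
    }
    if (!length(zc)) next
    out[[length(out) + 1L]] <- data.frame(snp_id = map$snp_id[x], allele = al,
                                          phs = mean(zc) - mean(za))
  }
  do.call(rbind, out)
}
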