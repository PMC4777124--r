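test_that("polarization statuses follow the exclusion rules", {
  g <- random_gm(4, 5, seed = 1)                      # alleles A/G everywhere
  anc <- ancestral_states(g$snp_ids, c("A", "G", "A/G", "C", "N"))
  pol <- polarize(g, anc)
  expect_equal(pol$status,
               c("polarized", "polarized", "trans_specific", "other_allele",
                 "ambiguous"))
  expect_equal(pol$derived_allele[1:2], c("G", "A"))  # allele not in outgroup
  expect_true(all(is.na(pol$derived_allele[3:5])))
  # outgroup segregating for an off-panel nucleotide is also excluded
  pol2 <- polarize(g, ancestral_states(g$snp_ids, c("A/C", "T", "A", "G", "A")))
  expect_equal(pol2$status[1:2], c("other_allele", "other_allele"))
  # exclusion statuses partition the excluded set
  counts <- table(pol$status)
  expect_equal(sum(counts), length(g$snp_ids))
})

test_that("hypergeometric projection matches exhaustive subsampling", {
  for (n in c(5L, 8L)) for (k in 1:(n - 1)) for (m in 2:(n - 1)) {
    # enumerate every m-subset of n chromosomes carrying k derived alleles
    chroms <- c(rep(1L, k), rep(0L, n - k))
    subs <- utils::combn(n, m)
    cnt <- table(factor(colSums(matrix(chroms[subs], nrow = m)), levels = 0:m))
    expect_equal(breedscan:::project_weights(k, n, m),
                 as.numeric(cnt / ncol(subs)), tolerance = 1e-12)
  }
})

test_that("derived spectra bin SNPs by derived count", {
  # 6 haploid accessions; each SNP has exactly one derived (alt) copy
  calls <- diag(6L) * 2L
  g <- gm_from_calls(calls)
  anc <- ancestral_states(g$snp_ids, rep("A", 6))     # ref ancestral
  s <- derived_sfs(g, g$accession_ids, anc)
  expect_equal(s$n, 6L)
  expect_equal(s$proportions, c(1, 0, 0, 0, 0))
  expect_equal(s$fixed_ancestral + s$fixed_derived, 0)
  # no polarized polymorphic SNPs -> error
  g2 <- gm_from_calls(matrix(0L, 4, 3))
  expect_error(derived_sfs(g2, g2$accession_ids,
                           ancestral_states(g2$snp_ids, rep("A", 3))),
               "no polarized polymorphic")
})

test_that("a neutral 1/i spectrum is recovered from multinomial sampling", {
  set.seed(42)
  n <- 10L; S <- 6000L
  probs <- neutral_equilibrium_sfs(n)
  ks <- sample(seq_len(n - 1), S, replace = TRUE, prob = probs)
  calls <- vapply(ks, function(k) c(rep(2L, k), rep(0L, n - k)), integer(n))
  g <- gm_from_calls(calls)       # n accessions x S SNPs
  s <- derived_sfs(g, g$accession_ids, ancestral_states(g$snp_ids, rep("A", S)))
  expect_equal(s$proportions, probs, tolerance = 0.05)
})

test_that("neutral equilibrium spectrum is 1/i normalized", {
  expect_equal(neutral_equilibrium_sfs(4), c(6, 3, 2) / 11)
  expect_equal(neutral_equilibrium_sfs(2), 1)
  for (n in c(3, 7, 20))
    expect_equal(sum(neutral_equilibrium_sfs(n)), 1)
  expect_error(neutral_equilibrium_sfs(1))
})

test_that("folded derived spectrum equals the minor-allele spectrum", {
  b <- bn_genotypes(0.1, S = 400, K = 1, n = 9, seed = 3)
  g <- b$g
  anc <- ancestral_states(g$snp_ids, rep("A", 400))
  s <- derived_sfs(g, g$accession_ids, anc, projection_n = 9L)
  folded <- fold_sfs(s)
  # independent minor-allele spectrum from raw alt counts
  x <- colSums(g$calls == 2L); n <- colSums(!is.na(g$calls))
  keep <- x > 0 & x < n
  minor <- table(factor(pmin(x, n - x)[keep], levels = 1:4))
  expect_equal(unname(folded), as.numeric(minor))
})

test_that("joint spectra concentrate where they must and marginalize", {
  # two disjoint partitions with identical genotype content -> diagonal mass
  calls <- rbind(diag(4L) * 2L, diag(4L) * 2L)
  g <- gm_from_calls(calls)
  A <- g$accession_ids[1:4]; B <- g$accession_ids[5:8]
  anc <- ancestral_states(g$snp_ids, rep("A", 4))
  j <- joint_derived_sfs(g, A, B, anc)
  expect_equal(sum(diag(j$counts)), sum(j$counts))
  expect_error(joint_derived_sfs(g, A, A, anc), "disjoint")
  # fixed derived in A, absent in B -> corner bin (nA, 0)
  calls2 <- rbind(matrix(2L, 3, 2), matrix(0L, 3, 2))
  g2 <- gm_from_calls(calls2)
  j2 <- joint_derived_sfs(g2, g2$accession_ids[1:3], g2$accession_ids[4:6],
                          ancestral_states(g2$snp_ids, c("A", "A")))
  expect_equal(j2$counts["3", "0"], 2)
  expect_equal(sum(j2$counts), 2)
  # marginals equal the 1-D spectrum over the shared polymorphic SNP set
  b <- bn_genotypes(0.2, S = 300, K = 2, n = 8, seed = 6)
  anc3 <- ancestral_states(b$g$snp_ids, rep("A", 300))
  polyA <- breedscan:::haploid_counts(b$g, b$groups[[1]])
  keep <- polyA$x > 0 & polyA$x < polyA$n
  gsub <- subset_genotypes(b$g, snps = b$g$snp_ids[keep])
  ancs <- ancestral_states(gsub$snp_ids, rep("A", sum(keep)))
  j3 <- joint_derived_sfs(gsub, b$groups[[1]], b$groups[[2]], ancs,
                          nA = 8L, nB = 8L)
  s1 <- derived_sfs(gsub, b$groups[[1]], ancs, projection_n = 8L)
  expect_equal(unname(rowSums(j3$counts))[2:8], s1$counts, tolerance = 1e-12)
})

test_that("joint spectrum off-diagonal spread grows with drift", {
  spread <- function(c, seed) {
    set.seed(seed)
    S <- 500; n <- 12
    pi <- pmin(pmax(rbeta(S, 1.5, 1.5), 0.05), 0.95)
    pA <- rbeta(S, pi * (1 - c) / c, (1 - pi) * (1 - c) / c)
    pB <- rbeta(S, pi * (1 - c) / c, (1 - pi) * (1 - c) / c)
    callsA <- vapply(seq_len(S), function(j) 2L * rbinom(n, 1, pA[j]), integer(n))
    callsB <- vapply(seq_len(S), function(j) 2L * rbinom(n, 1, pB[j]), integer(n))
    g <- gm_from_calls(rbind(callsA, callsB))
    A <- g$accession_ids[1:n]; B <- g$accession_ids[(n + 1):(2 * n)]
    j <- joint_derived_sfs(g, A, B, ancestral_states(g$snp_ids, rep("A", S)),
                           nA = n, nB = n)
    w <- j$counts / sum(j$counts)
    idx <- expand.grid(a = 0:n, b = 0:n)
    sum(w * (idx$a - idx$b)^2) / n^2
  }
  expect_lt(spread(0.02, 11), spread(0.3, 11))
})
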