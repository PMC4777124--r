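test_that("pairwise diversity matches the unbiased per-SNP formula", {
  # one SNP, calls AA, AA, GG: p = 2/3, n = 3 -> (3/2) * 2 * (2/3) * (1/3) = 2/3
  g <- gm_from_calls(matrix(c(0L, 0L, 2L), 3, 1))
  expect_equal(pairwise_diversity(g, g$accession_ids), 2 / 3)
  # identical homozygous accessions: nothing polymorphic -> error path
  g2 <- gm_from_calls(matrix(0L, 2, 5))
  expect_error(pairwise_diversity(g2, g2$accession_ids), "no polymorphic")
  # arithmetic mean over per-SNP values (biased variant for round numbers):
  # SNP1 p=1/2 -> 0.5, SNP2 p=1/4 -> 0.375
  g3 <- gm_from_calls(cbind(c(0L, 2L, 0L, 2L), c(0L, 0L, 0L, 2L)))
  expect_equal(pairwise_diversity(g3, g3$accession_ids, unbiased = FALSE),
               (0.5 + 0.375) / 2)
})

test_that("pairwise diversity equals the exhaustive pair-average oracle", {
  for (seed in 1:6) {
    g <- random_gm(sample(3:6, 1), 25, seed = seed)
    d <- per_pair <- NULL
    # oracle: per SNP fraction of differing pairs among SNPs polymorphic
    calls <- g$calls
    poly <- apply(calls, 2, function(v) length(unique(v[v != 1])) == 2)
    calls <- calls[, poly, drop = FALSE]
    n <- nrow(calls)
    diffs <- 0; snps <- 0
    for (j in seq_len(ncol(calls))) {
      for (i1 in 1:(n - 1)) for (i2 in (i1 + 1):n)
        diffs <- diffs + (calls[i1, j] != calls[i2, j])
      snps <- snps + 1
    }
    oracle <- diffs / choose(n, 2) / snps
    expect_equal(pairwise_diversity(g, g$accession_ids), oracle,
                 tolerance = 1e-12)
  }
})

test_that("F_IS handles the boundary and textbook cases", {
  # no heterozygotes at all -> F_IS = 1
  g <- random_gm(8, 20, seed = 9)
  expect_equal(inbreeding_coefficient(g, g$accession_ids), 1)
  # AA, AG, GG, AG: H_o = 0.5, p = 0.5, H_e = 0.5 -> 0
  g2 <- gm_from_calls(matrix(c(0L, 1L, 2L, 1L), 4, 1))
  expect_equal(inbreeding_coefficient(g2, g2$accession_ids), 0)
  expect_equal(inbreeding_coefficient(g2, g2$accession_ids,
                                      method = "ratio_of_means"), 0)
})

test_that("F_IS recovers the inbreeding level of simulated populations", {
  # genotypes drawn with P(het) = 2p(1-p)(1-F): F_IS should estimate F
  sim_f <- function(F, n = 400, S = 300, seed = 1) {
    set.seed(seed)
    p <- runif(S, 0.2, 0.8)
    calls <- sapply(p, function(pp) {
      pr <- c((1 - pp)^2 + F * pp * (1 - pp),
              2 * pp * (1 - pp) * (1 - F),
              pp^2 + F * pp * (1 - pp))
      sample(0:2, n, replace = TRUE, prob = pr)
    })
    g <- gm_from_calls(calls)
    inbreeding_coefficient(g, g$accession_ids)
  }
  expect_equal(sim_f(0), 0, tolerance = 0.05)             # Hardy-Weinberg
  for (gen in c(2, 4))                                     # selfing: F = 1-(1/2)^g
    expect_equal(sim_f(1 - 0.5^gen, seed = gen), 1 - 0.5^gen, tolerance = 0.03)
})

test_that("private SNP counts follow the definition and ignore ordering", {
  # s1 polymorphic only in A; s2 polymorphic in A and B; s3 nowhere
  calls <- cbind(c(0L, 2L, 0L, 0L, 0L, 0L),
                 c(0L, 2L, 0L, 2L, 0L, 0L),
                 c(0L, 0L, 0L, 0L, 0L, 0L))
  g <- gm_from_calls(calls)
  grp <- list(A = g$accession_ids[1:2], B = g$accession_ids[3:4],
              C = g$accession_ids[5:6])
  expect_equal(private_snps(g, grp), c(A = 1L, B = 0L, C = 0L))
  perm <- private_snps(g, grp[c("C", "A", "B")])
  expect_equal(perm[names(grp)], c(A = 1L, B = 0L, C = 0L))
  # all SNPs polymorphic everywhere -> zero counts
  g2 <- gm_from_calls(rbind(diag(2L)[rep(1:2, 3), ] * 2L))
  grp2 <- list(A = g2$accession_ids[1:2], B = g2$accession_ids[3:4],
               C = g2$accession_ids[5:6])
  expect_equal(unname(private_snps(g2, grp2)), c(0L, 0L, 0L))
})

test_that("sliding windows tile linkage groups as documented", {
  g <- random_gm(6, 15, seed = 5)
  map <- map_for(g)                                  # one group, 15 SNPs
  tr <- sliding_diversity(g, g$accession_ids, map, window_snps = 10, step_snps = 5)
  expect_equal(nrow(tr), 2L)
  expect_equal(tr$n_snps, c(10L, 10L))               # ranks 1-10 and 6-15
  # window larger than the group -> one truncated window
  tr2 <- sliding_diversity(g, g$accession_ids, map, window_snps = 50)
  expect_equal(nrow(tr2), 1L)
  expect_equal(tr2$n_snps, 15L)
  # constant per-SNP diversity -> every window equals it
  gc <- gm_from_calls(matrix(rep(c(0L, 0L, 2L, 2L), 12), 4, 12))
  trc <- sliding_diversity(gc, gc$accession_ids, map_for(gc), 4, 2)
  expect_true(all(abs(trc$diversity - trc$diversity[1]) < 1e-12))
})

test_that("diversity_summary assembles the per-population table", {
  b <- bn_genotypes(0.15, S = 150, K = 3, n = 12, seed = 8)
  scheme <- population_scheme(
    unlist(b$groups), rep(names(b$groups), lengths(b$groups)),
    data.frame(population = names(b$groups), spike_type = 2L,
               growth_habit = "spring", stringsAsFactors = FALSE))
  tab <- diversity_summary(b$g, scheme)
  expect_equal(nrow(tab), 3L)
  expect_true(all(tab$avg_pairwise_diversity > 0 & tab$avg_pairwise_diversity <= 1))
  expect_true(all(tab$mean_F_IS == 1))       # fully homozygous fixture
  expect_true(sum(tab$private_snp_count) <= length(b$g$snp_ids))
})
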