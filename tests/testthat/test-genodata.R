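test_that("matrix TSV tokens map to the four call states and round-trip", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("accession\ts1\ts2",
               "a1\tAA\tCC",
               "a2\tGG\tCT",
               "a3\tAG\tNN",
               "a4\tNN\tTT"), tsv)
  g <- read_genotypes(tsv, "matrix_tsv")
  expect_equal(unname(g$calls[, "s1"]), c(0L, 2L, 1L, NA))
  expect_equal(g$alleles$ref, c("A", "C"))
  expect_equal(g$alleles$alt, c("G", "T"))
  out <- tempfile(fileext = ".tsv")
  write_genotypes_tsv(g, out)
  g2 <- read_genotypes(out, "matrix_tsv")
  expect_identical(g2$calls, g$calls)
  expect_identical(g2$alleles, g$alleles)
})

test_that("matrix TSV reader rejects malformed input", {
  bad <- tempfile()
  writeLines(c("accession\ts1", "a1\tAA", "a2\tGG", "a3\tCC"), bad)
  expect_error(read_genotypes(bad, "matrix_tsv"), ">2 alleles")
  writeLines(c("accession\ts1", "a1\tZZ"), bad)
  expect_error(read_genotypes(bad, "matrix_tsv"), "unknown call")
  writeLines(c("accession\ts1", "a1\tAA", "a1\tGG"), bad)
  expect_error(read_genotypes(bad, "matrix_tsv"), "duplicate accession")
  file.create(empty <- tempfile())
  expect_error(suppressWarnings(read_genotypes(empty, "matrix_tsv")))
})

test_that("VCF GT semantics and VCF round-trip", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "a1", "a2", "a3", "a4", sep = "\t"),
               paste("1H", "100", "s1", "A", "G", ".", "PASS", ".", "GT",
                     "0/0", "1/1", "./.", "0/1", sep = "\t")), vcf)
  g <- read_genotypes(vcf, "vcf")
  expect_equal(unname(g$calls[, "s1"]), c(0L, 2L, NA, 1L))
  g2 <- random_gm(6, 12, p_het = 0.1, p_miss = 0.1, seed = 4)
  out <- tempfile(fileext = ".vcf")
  write_genotypes_vcf(g2, out)
  g3 <- read_genotypes(out, "vcf")
  expect_identical(g3$calls, g2$calls)
  expect_identical(g3$alleles, g2$alleles)
  writeLines(c("##fileformat=VCFv4.2"), vcf)
  expect_error(read_genotypes(vcf, "vcf"), "#CHROM")
})

test_that("apply_qc removes by reason in the documented order", {
  # 8 accessions x 4 SNPs: s2 monomorphic, s3 >25% missing, a7 >25% missing,
  # a8 10% heterozygous (2/20 > 6.25% over its non-missing calls)
  calls <- matrix(0L, 8, 10,
                  dimnames = list(sprintf("a%d", 1:8), sprintf("s%d", 1:10)))
  calls[1:4, ] <- rep(c(0L, 2L), each = 2)        # keep SNPs polymorphic
  calls[5:8, ] <- rep(c(2L, 0L), each = 2)
  calls[, "s2"] <- 0L                             # monomorphic
  calls[1:3, "s3"] <- NA                          # 3/8 = 37.5% missing
  calls[7, c("s4", "s5", "s6")] <- NA             # 3/8 SNPs missing for a7
  calls[8, c("s9", "s10")] <- 1L                  # 2 hets
  g <- gm_from_calls(calls)
  res <- apply_qc(g, scheme = NULL)
  rs <- res$report$removed_snps
  expect_equal(rs$reason[rs$snp_id == "s2"], "monomorphic")
  expect_equal(rs$reason[rs$snp_id == "s3"], "missing")
  ra <- res$report$removed_accessions
  expect_equal(ra$reason[ra$accession == "a7"], "missing")
  expect_equal(ra$reason[ra$accession == "a8"], "heterozygosity")
  # removal counts partition both axes
  expect_equal(nrow(rs) + length(res$genotypes$snp_ids), length(g$snp_ids))
  expect_equal(nrow(ra) + length(res$genotypes$accession_ids),
               length(g$accession_ids))
})

test_that("clean matrices pass QC unchanged and QC is idempotent", {
  g <- random_gm(10, 30, seed = 2)
  res <- apply_qc(g, scheme = NULL)
  expect_identical(res$genotypes$calls, g$calls)
  expect_equal(nrow(res$report$removed_snps), 0L)
  expect_equal(nrow(res$report$removed_accessions), 0L)
  for (seed in 1:5) {
    g <- random_gm(12, 40, p_het = 0.03, p_miss = 0.15, seed = seed)
    scheme <- scheme_halves(g)
    r1 <- apply_qc(g, scheme)
    r2 <- apply_qc(r1$genotypes, scheme)
    expect_identical(r2$genotypes$calls, r1$genotypes$calls)
    expect_equal(nrow(r2$report$removed_snps), 0L)
    expect_equal(nrow(r2$report$removed_accessions), 0L)
  }
})

test_that("population size floor and curated exclusions are honored", {
  g <- random_gm(6, 20, seed = 3)
  scheme <- population_scheme(
    g$accession_ids, c("P1", "P1", "P1", "P1", "P1", "P2"),
    data.frame(population = c("P1", "P2"), spike_type = c(2L, 6L),
               growth_habit = "spring", stringsAsFactors = FALSE))
  res <- apply_qc(g, scheme)
  ra <- res$report$removed_accessions
  expect_equal(ra$reason[ra$accession == "acc06"], "small_population")
  res2 <- apply_qc(g, scheme = NULL, exclude = "acc01")
  expect_false("acc01" %in% res2$genotypes$accession_ids)
  expect_equal(res2$report$removed_accessions$reason[1], "excluded")
})

test_that("selfing heterozygosity expectation is (1/2)^g", {
  expect_equal(selfing_het_expectation(4), 0.0625)
  expect_equal(selfing_het_expectation(0), 1.0)
  expect_equal(selfing_het_expectation(1), 0.5)
  expect_error(selfing_het_expectation(-1))
  expect_error(selfing_het_expectation(1.5))
})

test_that("genotype_matrix validates its invariants", {
  calls <- matrix(c(0L, 3L), 1, 2,
                  dimnames = list("a1", c("s1", "s2")))
  al <- data.frame(snp_id = c("s1", "s2"), ref = "A", alt = "G")
  expect_error(genotype_matrix(calls, al), "0, 1, 2 or NA")
  calls[1, 2] <- 0L
  al$alt <- c("G", "A")
  expect_error(genotype_matrix(calls, al), "must differ")
})
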