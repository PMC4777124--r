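two_pop_config <- function(...) {
  pops <- data.frame(population = c("P1", "P2"), spike_type = c(2L, 6L),
                     growth_habit = c("spring", "winter"),
                     n_accessions = c(15L, 15L), c_pop = c(0.1, 0.2),
                     stringsAsFactors = FALSE)
  sim_config(pops, n_snps_per_group = 40L, linkage_groups = c("1H", "2H"),
             map_length_cM = 100, c_spike = 0, c_habit = 0, ...)
}

test_that("the generator is bit-identical under a fixed seed", {
  cfg <- two_pop_config(seed = 77L)
  s1 <- simulate_genotypes(cfg)
  s2 <- simulate_genotypes(cfg)
  expect_identical(s1$genotypes$calls, s2$genotypes$calls)
  expect_identical(s1$ancestral, s2$ancestral)
  expect_identical(s1$truth$pop_freq, s2$truth$pop_freq)
  s3 <- simulate_genotypes(cfg, seed = 78L)
  expect_false(identical(s1$genotypes$calls, s3$genotypes$calls))
})

test_that("realized moment drift tracks the configured c", {
  pops <- data.frame(population = c("P1", "P2"), spike_type = 2L,
                     growth_habit = "spring", n_accessions = 4L,
                     c_pop = c(0.10, 0.30))
  cfg <- sim_config(pops, n_snps_per_group = 1000L, linkage_groups = c("1H", "2H"),
                    c_spike = 0, c_habit = 0, missing_rate = 0, seed = 9L)
  sim <- simulate_genotypes(cfg)
  rc <- sim$truth$realized_c
  expect_lt(abs(rc["P1"] - 0.10), 0.15 * 0.10)
  expect_lt(abs(rc["P2"] - 0.30), 0.15 * 0.30)
})

test_that("emitted files round-trip through the readers losslessly", {
  cfg <- two_pop_config(seed = 31L)
  sim <- simulate_genotypes(cfg)
  dir <- tempfile()
  write_sim_bundle(sim, dir)
  g_tsv <- read_genotypes(file.path(dir, "genotypes.tsv"), "matrix_tsv")
  # TSV canonicalizes allele polarity; compare on diplotype content
  tmp <- tempfile(); write_genotypes_tsv(sim$genotypes, tmp)
  expect_identical(readLines(file.path(dir, "genotypes.tsv")), readLines(tmp))
  g_vcf <- read_genotypes(file.path(dir, "genotypes.vcf"), "vcf")
  expect_identical(g_vcf$calls[, sim$genotypes$snp_ids], sim$genotypes$calls)
  expect_identical(g_vcf$alleles$ref[match(sim$genotypes$snp_ids, g_vcf$snp_ids)],
                   sim$genotypes$alleles$ref)
  map <- read_genetic_map(file.path(dir, "map.tsv"))
  expect_equal(map$snp_id, sim$map$snp_id)
  expect_equal(map$position_cM, sim$map$position_cM, tolerance = 1e-9)
  sch <- read_population_scheme(file.path(dir, "populations.tsv"))
  expect_equal(sort(population_members(sch, "P1")),
               sort(population_members(sim$scheme, "P1")))
  anc <- read_ancestral_states(file.path(dir, "ancestral.tsv"))
  expect_equal(anc$outgroup_allele, sim$ancestral$outgroup_allele)
})

test_that("selfing leaves (1/2)^g residual heterozygosity in the F1-het loci", {
  pops <- data.frame(population = "P1", spike_type = 2L, growth_habit = "spring",
                     n_accessions = 60L, c_pop = 0.05)
  cfg <- sim_config(pops, n_snps_per_group = 400L, linkage_groups = c("1H", "2H"),
                    c_spike = 0, c_habit = 0, missing_rate = 0,
                    selfing_generations = 4L, seed = 17L)
  sim <- simulate_genotypes(cfg)
  het <- mean(sim$genotypes$calls == 1L)
  f1 <- mean(sim$truth$f1_het_fraction)
  expect_equal(het / f1, 0.0625, tolerance = 0.1)
})

test_that("truth carrier lists exactly describe implanted segments", {
  pops <- data.frame(population = c("D", "R"), spike_type = 2L,
                     growth_habit = "spring", n_accessions = c(16L, 16L),
                     c_pop = c(0.2, 0.2))
  sweeps <- data.frame(population = "R", linkage_group = "1H", center_cM = 50,
                       length_cM = 30, frequency = 0.25)
  mig <- data.frame(donor = "D", recipient = "R", linkage_group = "2H",
                    start_cM = 20, end_cM = 60, frequency = 0.3)
  cfg <- sim_config(pops, n_snps_per_group = 60L, linkage_groups = c("1H", "2H"),
                    map_length_cM = 100, c_spike = 0, c_habit = 0,
                    sweeps = sweeps, migrations = mig, missing_rate = 0.02,
                    seed = 23L)
  sim <- simulate_genotypes(cfg)
  for (tr in c(sim$truth$sweeps, sim$truth$migrations)) {
    expected <- 2L * tr$haplotype
    for (acc in tr$carriers) {
      got <- sim$genotypes$calls[acc, tr$snp_ids]
      ok <- !is.na(got)
      expect_equal(unname(got[ok]), unname(expected[ok]))
    }
  }
  sw <- sim$truth$sweeps[[1]]
  expect_gte(length(sw$carriers), round(0.25 * 16))
  span <- range(sim$map$position_cM[match(sw$snp_ids, sim$map$snp_id)])
  expect_gte(diff(span) + 1e-9, 0)     # segment within the stated bounds
  expect_true(all(abs(sim$map$position_cM[match(sw$snp_ids, sim$map$snp_id)] - 50)
                  <= 15 + 1e-9))
})

test_that("zero drift gives near-zero between-population theta", {
  pops <- data.frame(population = c("P1", "P2", "P3"), spike_type = 2L,
                     growth_habit = "spring", n_accessions = 20L, c_pop = 0)
  cfg <- sim_config(pops, n_snps_per_group = 500L, linkage_groups = "1H",
                    c_spike = 0, c_habit = 0, missing_rate = 0, seed = 41L)
  sim <- simulate_genotypes(cfg)
  grp <- partition_accessions(sim$scheme, "population")
  scan <- fst_scan(sim$genotypes, grp)
  expect_lt(abs(scan$mean_theta), 0.01)
})

test_that("the paper-shape preset reproduces the partition structure", {
  cfg <- emulate_paper_shape(accession_scale = 0.12, n_snps_per_group = 300L,
                             seed = 1L)
  expect_equal(nrow(cfg$populations), 16L)
  expect_equal(length(cfg$linkage_groups), 7L)
  expect_equal(cfg$selfing_generations, 4L)
  sim <- simulate_genotypes(cfg)
  g <- apply_qc(sim$genotypes, sim$scheme)$genotypes
  th <- vapply(c("population", "spike_type", "growth_habit"), function(by) {
    grp <- partition_accessions(sim$scheme, by, accessions = g$accession_ids)
    fst_scan(g, grp)$mean_theta
  }, 0)
  expect_equal(unname(th["population"]), 0.37, tolerance = 0.03 / 0.37)
  expect_equal(unname(th["spike_type"]), 0.23, tolerance = 0.03 / 0.23)
  expect_equal(unname(th["growth_habit"]), 0.17, tolerance = 0.03 / 0.17)
})

test_that("infeasible specs are rejected", {
  pops <- data.frame(population = "P1", spike_type = 2L, growth_habit = "spring",
                     n_accessions = 10L, c_pop = 0.1)
  expect_error(sim_config(pops, sweeps = data.frame(population = "P1",
                                                    linkage_group = "1H",
                                                    center_cM = 10, length_cM = 5,
                                                    frequency = 1.5)),
               "frequency > 1")
  cfg <- sim_config(pops, n_snps_per_group = 20L, linkage_groups = "1H",
                    map_length_cM = 50,
                    sweeps = data.frame(population = "P1", linkage_group = "7H",
                                        center_cM = 10, length_cM = 5,
                                        frequency = 0.3))
  expect_error(simulate_genotypes(cfg), "no SNP")
})
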