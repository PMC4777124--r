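# Seeded synthetic-data generator: hierarchically structured, highly selfed
# breeding populations with known drift, implanted sweeps and migrant
# segments, and machine-readable ground truth.

#' Build a simulation configuration
#'
#' The generated world: ancestral allele frequencies drawn from a
#' midfrequency-enriched Beta (emulating an ascertained SNP panel), a
#' spike-type effect and a growth-habit effect shared by all populations of
#' the same class (crossed on the logit scale, each sized by a
#' Balding-Nichols draw), population-level Balding-Nichols drift on top,
#' founder haplotypes at linkage equilibrium, explicit implanted sweep and
#' migrant haplotype segments, and genotypes produced by selfing from
#' heterozygous crosses so residual heterozygosity is (1/2)^generations.
#' Setting `c_spike = c_habit = 0` with a per-type `c_type` column in
#' `populations` reduces the hierarchy to plain type-then-population
#' nesting.
#'
#' @param populations data.frame: `population`, `spike_type` (2/6),
#'   `growth_habit` ("spring"/"winter"), `n_accessions`, `c_pop`
#'   (population-level drift), optional `c_type`.
#' @param n_snps_per_group SNPs per linkage group (recycled).
#' @param map_length_cM cM length per linkage group (recycled).
#' @param linkage_groups linkage-group labels.
#' @param c_spike,c_habit drift sizing the shared spike-type and
#'   growth-habit effects.
#' @param selfing_generations selfing rounds from the heterozygous cross
#'   (default 4, i.e. 6.25% residual heterozygosity).
#' @param ancestral_beta shape parameters of the ancestral-frequency Beta.
#' @param missing_rate per-call missing probability.
#' @param sweeps data.frame (or NULL): `population`, `linkage_group`,
#'   `center_cM`, `length_cM`, `frequency`.
#' @param migrations data.frame (or NULL): `donor`, `recipient`,
#'   `linkage_group`, `start_cM`, `end_cM`, `frequency`.
#' @param outgroup_rates named list: `flip`, `ambiguous`, `other`, `trans`
#'   (probabilities of a mispolarized, ambiguous, off-allele or
#'   trans-specific outgroup call).
#' @param drift_model `"beta"` (Balding-Nichols, default) or
#'   `"censored_normal"` (the divergence-model law).
#' @param sweep_donor `"minor"` (default): the implanted sweep haplotype is
#'   built from the locally rarer allele at each site, so its allelic
#'   states segregate near the target carrier frequency (an
#'   exotic-introgression-like haplotype); `"founder"`: a plain draw from
#'   the population frequencies.
#' @param seed default RNG seed used by [simulate_genotypes()].
#' @return list of class `sim_config`.
#' @export
sim_config <- function(populations,
                       n_snps_per_group = 60L,
                       map_length_cM = 150,
                       linkage_groups = paste0(seq_len(7), "H"),
                       c_spike = 0, c_habit = 0,
                       selfing_generations = 4L,
                       ancestral_beta = c(1.5, 1.5),
                       missing_rate = 0.02,
                       sweeps = NULL, migrations = NULL,
                       outgroup_rates = list(flip = 0.02, ambiguous = 0.03,
                                             other = 0.02, trans = 0.02),
                       drift_model = c("beta", "censored_normal"),
                       sweep_donor = c("minor", "founder"),
                       seed = 1L) {
  populations <- as.data.frame(populations, stringsAsFactors = FALSE)
  need <- c("population", "spike_type", "growth_habit", "n_accessions", "c_pop")
  if (!all(need %in% names(populations)))
    stop("populations needs columns ", paste(need, collapse = ", "))
  if (any(populations$c_pop < 0 | populations$c_pop >= 1)) stop("c_pop in [0,1)")
  if (any(populations$n_accessions < 2L)) stop("each population needs >= 2 accessions")
  if (!is.null(sweeps) && any(sweeps$frequency > 1)) stop("sweep frequency > 1")
  if (!is.null(migrations) && any(migrations$frequency > 1)) stop("migration frequency > 1")
  structure(list(
    populations = populations,
    n_snps_per_group = rep_len(as.integer(n_snps_per_group), length(linkage_groups)),
    map_length_cM = rep_len(as.numeric(map_length_cM), length(linkage_groups)),
    linkage_groups = as.character(linkage_groups),
    c_spike = c_spike, c_habit = c_habit,
    selfing_generations = as.integer(selfing_generations),
    ancestral_beta = ancestral_beta,
    missing_rate = missing_rate,
    sweeps = sweeps, migrations = migrations,
    outgroup_rates = outgroup_rates,
    drift_model = match.arg(drift_model),
    sweep_donor = match.arg(sweep_donor),
    seed = as.integer(seed)),
    class = "sim_config")
}

# One Balding-Nichols (or censored-normal) drift step away from base
# frequencies p0 with drift c.
drift_draw <- function(p0, c, model = "beta") {
  if (c < 1e-12) return(p0)
  if (model == "censored_normal") {
    p <- stats::rnorm(length(p0), p0, sqrt(c * p0 * (1 - p0)))
    return(pmin(pmax(p, 0), 1))
  }
  a <- p0 * (1 - c) / c
  b <- (1 - p0) * (1 - c) / c
  stats::rbeta(length(p0), a, b)
}

#' Generate a synthetic genotype bundle with ground truth
#'
#' See [sim_config()] for the generated world. All randomness is driven by
#' `seed`; the same seed gives bit-identical output.
#'
#' @param config a `sim_config`.
#' @param seed RNG seed (default: `config$seed`).
#' @return list with `genotypes` (`genotype_matrix`), `map`
#'   (`genetic_map`), `scheme` (`population_scheme`), `ancestral`
#'   (`ancestral_states`) and `truth` (class `sim_truth`: ancestral
#'   frequencies `pi`, per-population frequencies `pop_freq`, drift
#'   parameters, sweep and migrant carrier/SNP lists, realized moment
#'   drift, seed).
#' @export
simulate_genotypes <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  pops <- config$populations
  K <- nrow(pops)
  # -- genetic map
  lg <- rep(config$linkage_groups, config$n_snps_per_group)
  pos <- unlist(lapply(seq_along(config$linkage_groups), function(i)
    sort(stats::runif(config$n_snps_per_group[i], 0, config$map_length_cM[i]))))
  snp_id <- sprintf("%s_%04d", lg, unlist(lapply(config$n_snps_per_group, seq_len)))
  map <- genetic_map(snp_id, lg, pos)
  snp_id <- map$snp_id            # map order
  S <- nrow(map)
  # -- ancestral frequencies (pi = frequency of the derived = alt allele)
  pi <- stats::rbeta(S, config$ancestral_beta[1], config$ancestral_beta[2])
  pi <- pmin(pmax(pi, 0.01), 0.99)
  # -- shared spike-type and growth-habit effects (crossed, logit scale)
  spike_levels <- sort(unique(pops$spike_type))
  habit_levels <- sort(unique(pops$growth_habit))
  eff <- function(c) if (c > 0) qlogis(pmin(pmax(drift_draw(pi, c), 1e-6), 1 - 1e-6)) - qlogis(pi) else numeric(S) * 0
  spike_eff <- lapply(stats::setNames(spike_levels, spike_levels),
                      function(s) eff(config$c_spike))
  habit_eff <- lapply(stats::setNames(habit_levels, habit_levels),
                      function(h) eff(config$c_habit))
  # -- optional nested type-level drift
  type_key <- paste(pops$spike_type, pops$growth_habit, sep = "_")
  type_freq <- list()
  for (tk in unique(type_key)) {
    i <- match(tk, type_key)
    base <- stats::plogis(qlogis(pi) + spike_eff[[as.character(pops$spike_type[i])]] +
                            habit_eff[[pops$growth_habit[i]]])
    c_type <- if (!is.null(pops$c_type)) pops$c_type[i] else 0
    type_freq[[tk]] <- drift_draw(base, c_type, config$drift_model)
  }
  # -- population frequencies
  pop_freq <- matrix(NA_real_, K, S, dimnames = list(pops$population, snp_id))
  for (i in seq_len(K))
    pop_freq[i, ] <- drift_draw(type_freq[[type_key[i]]], pops$c_pop[i],
                                config$drift_model)
  # -- founder haplotype pairs (linkage-equilibrium baseline)
  acc_pop <- rep(pops$population, pops$n_accessions)
  n_acc <- length(acc_pop)
  acc_id <- sprintf("%s_acc%03d", acc_pop,
                    unlist(lapply(pops$n_accessions, seq_len)))
  H1 <- matrix(0L, n_acc, S, dimnames = list(acc_id, snp_id))
  H2 <- H1
  for (i in seq_len(K)) {
    rows <- which(acc_pop == pops$population[i])
    pf <- pop_freq[i, ]
    H1[rows, ] <- matrix(stats::rbinom(length(rows) * S, 1L, rep(pf, each = length(rows))),
                         length(rows), S)
    H2[rows, ] <- matrix(stats::rbinom(length(rows) * S, 1L, rep(pf, each = length(rows))),
                         length(rows), S)
  }
  # -- implant sweeps: overwrite the segment of a carrier fraction with one
  #    shared founder haplotype (both gametes, so selfing preserves it)
  truth_sweeps <- list()
  if (!is.null(config$sweeps)) for (k in seq_len(nrow(config$sweeps))) {
    sw <- config$sweeps[k, ]
    seg <- which(map$linkage_group == sw$linkage_group &
                   abs(map$position_cM - sw$center_cM) <= sw$length_cM / 2)
    if (!length(seg)) stop("sweep segment contains no SNP")
    rows <- which(acc_pop == sw$population)
    if (!length(rows)) stop("unknown sweep population ", sw$population)
    # the swept haplotype is built from the locally rarer allele at each
    # site, so its allelic states really segregate near the target carrier
    # frequency (a haplotype assembled from common alleles is invisible at
    # most of its own sites); with sweep_donor = "founder" a plain draw
    # from the population frequencies is used instead
    donor <- if (identical(config$sweep_donor, "founder"))
      stats::rbinom(length(seg), 1L, pop_freq[sw$population, seg])
    else as.integer(pop_freq[sw$population, seg] < 0.5)
    carriers <- sample(rows, max(2L, round(sw$frequency * length(rows))))
    H1[carriers, seg] <- matrix(donor, length(carriers), length(seg), byrow = TRUE)
    H2[carriers, seg] <- H1[carriers, seg]
    truth_sweeps[[k]] <- list(population = sw$population,
                              linkage_group = sw$linkage_group,
                              center_cM = sw$center_cM, length_cM = sw$length_cM,
                              frequency = sw$frequency,
                              snp_ids = snp_id[seg], haplotype = donor,
                              carriers = acc_id[carriers])
  }
  # -- implant migrant segments copied from a donor-population haplotype
  truth_migr <- list()
  if (!is.null(config$migrations)) for (k in seq_len(nrow(config$migrations))) {
    mg <- config$migrations[k, ]
    seg <- which(map$linkage_group == mg$linkage_group &
                   map$position_cM >= mg$start_cM & map$position_cM <= mg$end_cM)
    if (!length(seg)) stop("migrant segment contains no SNP")
    don_rows <- which(acc_pop == mg$donor)
    rec_rows <- which(acc_pop == mg$recipient)
    if (!length(don_rows) || !length(rec_rows)) stop("unknown migration population")
    donor <- H1[sample(don_rows, 1L), seg]
    carriers <- sample(rec_rows, max(2L, round(mg$frequency * length(rec_rows))))
    # the migrating haplotype also segregates in its source population
    # (that is where it came from); donor_frequency defaults to the
    # recipient target frequency
    don_freq <- if (is.null(mg$donor_frequency)) mg$frequency else mg$donor_frequency
    don_carriers <- sample(don_rows, max(2L, round(don_freq * length(don_rows))))
    H1[don_carriers, seg] <- matrix(donor, length(don_carriers), length(seg),
                                    byrow = TRUE)
    H2[don_carriers, seg] <- H1[don_carriers, seg]
    H1[carriers, seg] <- matrix(donor, length(carriers), length(seg), byrow = TRUE)
    H2[carriers, seg] <- H1[carriers, seg]
    truth_migr[[k]] <- list(donor = mg$donor, recipient = mg$recipient,
                            donor_carriers = acc_id[don_carriers],
                            linkage_group = mg$linkage_group,
                            start_cM = mg$start_cM, end_cM = mg$end_cM,
                            frequency = mg$frequency,
                            snp_ids = snp_id[seg], haplotype = unname(donor),
                            carriers = acc_id[carriers])
  }
  # -- selfing from the heterozygous cross: a locus heterozygous in the F1
  #    stays heterozygous with probability (1/2)^g, else fixes either way
  g <- config$selfing_generations
  p_het <- 0.5^g
  het_f1 <- H1 != H2
  calls <- H1 + H2                      # 0 or 2 where homozygous in the F1
  u <- matrix(stats::runif(n_acc * S), n_acc, S)
  stay_het <- het_f1 & u < p_het
  fix_alt <- het_f1 & !stay_het & (u > (p_het + (1 - p_het) / 2))
  calls[het_f1] <- 0L
  calls[stay_het] <- 1L
  calls[fix_alt] <- 2L
  # -- missingness
  if (config$missing_rate > 0)
    calls[matrix(stats::runif(n_acc * S) < config$missing_rate, n_acc, S)] <- NA_integer_
  # -- alleles and outgroup states (ref = ancestral, alt = derived)
  nuc <- c("A", "C", "G", "T")
  ref <- sample(nuc, S, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nuc, r), 1L), "")
  third <- vapply(seq_len(S), function(j) sample(setdiff(nuc, c(ref[j], alt[j])), 1L), "")
  rates <- config$outgroup_rates
  kind <- sample(c("ok", "flip", "ambiguous", "other", "trans"), S, replace = TRUE,
                 prob = c(1 - rates$flip - rates$ambiguous - rates$other - rates$trans,
                          rates$flip, rates$ambiguous, rates$other, rates$trans))
  out_allele <- ref
  out_allele[kind == "flip"] <- alt[kind == "flip"]
  out_allele[kind == "ambiguous"] <- "N"
  out_allele[kind == "other"] <- third[kind == "other"]
  out_allele[kind == "trans"] <- paste0(ref[kind == "trans"], "/", alt[kind == "trans"])
  gm <- genotype_matrix(calls, data.frame(snp_id = snp_id, ref = ref, alt = alt,
                                          stringsAsFactors = FALSE))
  scheme <- population_scheme(acc_id, acc_pop,
                              pops[, c("population", "spike_type", "growth_habit")])
  anc <- ancestral_states(snp_id, out_allele)
  realized_c <- rowMeans(sweep(sweep(pop_freq, 2L, pi)^2, 2L,
                               pi * (1 - pi), "/"))
  truth <- structure(list(
    pi = stats::setNames(pi, snp_id),
    type_freq = type_freq,
    pop_freq = pop_freq,
    c_pop = stats::setNames(pops$c_pop, pops$population),
    c_spike = config$c_spike, c_habit = config$c_habit,
    realized_c = realized_c,
    f1_het_fraction = stats::setNames(rowMeans(het_f1), acc_id),
    sweeps = truth_sweeps, migrations = truth_migr,
    outgroup_kind = stats::setNames(kind, snp_id),
    seed = seed),
    class = "sim_truth")
  list(genotypes = gm, map = map, scheme = scheme, ancestral = anc,
       truth = truth)
}

#' Preset configuration mirroring the shape of the real study system
#'
#' Sixteen breeding populations in a spike-type x growth-habit hierarchy
#' (eleven spring, five winter; Table-1-like sample sizes), ~2,500 SNPs on
#' seven ~150 cM linkage groups, four selfing generations. The shared
#' spike/habit effect sizes and population drift are calibrated so the
#' realized partition-level mean theta lands near 0.37 (among populations),
#' 0.23 (spike-type) and 0.17 (growth habit).
#'
#' @param accession_scale multiplier on the per-population sample sizes
#'   (default 1; tests use smaller values for speed, with a floor of 8).
#' @param n_snps_per_group SNPs per linkage group (default 357, ~2,500
#'   total).
#' @param seed default seed stored in the config.
#' @return A `sim_config`.
#' @export
emulate_paper_shape <- function(accession_scale = 1, n_snps_per_group = 357L,
                                seed = 1L) {
  pops <- data.frame(
    population = c("AB2", "BA2", "BAI2", "MT2", "N2", "WA2",
                   "AB6", "BA6", "MN6", "N6", "WA6",
                   "OR2", "UT2", "OR6", "UT6", "VT6"),
    spike_type = c(rep(2L, 6L), rep(6L, 5L), 2L, 2L, 6L, 6L, 6L),
    growth_habit = c(rep("spring", 11L), rep("winter", 5L)),
    n_accessions = pmax(8L, as.integer(round(accession_scale *
      c(239, 172, 60, 317, 353, 351, 142, 147, 386, 380, 32,
        73, 30, 268, 343, 320)))),
    c_pop = c(0.21, 0.31, 0.31, 0.21, 0.26, 0.21,
              0.21, 0.26, 0.36, 0.21, 0.21,
              0.26, 0.42, 0.26, 0.21, 0.26),
    stringsAsFactors = FALSE)
  sim_config(populations = pops,
             n_snps_per_group = n_snps_per_group,
             map_length_cM = 150,
             linkage_groups = paste0(seq_len(7), "H"),
             c_spike = 0.20, c_habit = 0.125,
             selfing_generations = 4L,
             ancestral_beta = c(1.5, 1.5),
             missing_rate = 0.03,
             seed = seed)
}

#' Write a simulated bundle to disk
#'
#' Emits the genotype matrix as diplotype TSV and plain-text VCF, the map,
#' population and ancestral-state TSVs, the ground truth as JSON and the
#' configuration as JSON.
#'
#' @param sim result of [simulate_genotypes()].
#' @param dir output directory (created if needed).
#' @export
write_sim_bundle <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes_tsv(sim$genotypes, file.path(dir, "genotypes.tsv"))
  write_genotypes_vcf(sim$genotypes, file.path(dir, "genotypes.vcf"), sim$map)
  data.table::fwrite(as.data.frame(sim$map), file.path(dir, "map.tsv"), sep = "\t")
  a <- sim$scheme$assignments
  info <- sim$scheme$populations[match(a$population, sim$scheme$populations$population), ]
  data.table::fwrite(data.frame(accession = a$accession, population = a$population,
                                spike_type = info$spike_type,
                                growth_habit = info$growth_habit),
                     file.path(dir, "populations.tsv"), sep = "\t")
  data.table::fwrite(as.data.frame(sim$ancestral), file.path(dir, "ancestral.tsv"),
                     sep = "\t")
  tr <- sim$truth
  tr$pop_freq <- NULL; tr$type_freq <- NULL; tr$pi <- NULL   # bulky; keep JSON small
  jsonlite::write_json(unclass(tr), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
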