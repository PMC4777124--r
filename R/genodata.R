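# Core data model: genotype matrices for selfed accessions, genetic maps,
# population schemes, and the QC filters applied before every downstream scan.

# Internal call encoding: 0 = homozygous reference, 1 = heterozygous,
# 2 = homozygous alternate, NA = missing.
CALL_HOM_REF <- 0L
CALL_HET <- 1L
CALL_HOM_ALT <- 2L

#' Construct a genotype matrix object
#'
#' The central container of the package: a calls matrix for inbred accessions
#' over biallelic SNPs, with per-SNP reference/alternate nucleotides. Calls
#' are coded 0 (homozygous reference), 1 (heterozygous), 2 (homozygous
#' alternate) and `NA` (missing).
#'
#' @param calls integer matrix, accessions in rows (rownames = accession ids),
#'   SNPs in columns (colnames = SNP ids), values in \{0, 1, 2, NA\}.
#' @param alleles data.frame with columns `snp_id`, `ref`, `alt` (single
#'   distinct nucleotides), one row per SNP in column order of `calls`.
#' @return An object of class `genotype_matrix` with fields `calls`,
#'   `accession_ids`, `snp_ids`, `alleles`.
#' @export
genotype_matrix <- function(calls, alleles) {
  if (!is.matrix(calls)) stop("`calls` must be a matrix")
  storage.mode(calls) <- "integer"
  acc <- rownames(calls)
  snp <- colnames(calls)
  if (is.null(acc) || is.null(snp)) stop("`calls` must have row and column names")
  if (anyDuplicated(acc)) stop("duplicate accession ids")
  if (anyDuplicated(snp)) stop("duplicate SNP ids")
  ok <- is.na(calls) | calls %in% c(CALL_HOM_REF, CALL_HET, CALL_HOM_ALT)
  if (!all(ok)) stop("calls must be 0, 1, 2 or NA")
  alleles <- as.data.frame(alleles, stringsAsFactors = FALSE)
  need <- c("snp_id", "ref", "alt")
  if (!all(need %in% names(alleles))) stop("`alleles` needs columns snp_id, ref, alt")
  alleles <- alleles[, need]
  if (nrow(alleles) != ncol(calls) || !identical(as.character(alleles$snp_id), snp))
    stop("`alleles` must match the SNP columns of `calls` in order")
  nuc <- c("A", "C", "G", "T")
  if (!all(alleles$ref %in% nuc) || !all(alleles$alt %in% nuc))
    stop("alleles must be single nucleotides A/C/G/T")
  if (any(alleles$ref == alleles$alt)) stop("ref and alt alleles must differ")
  structure(list(calls = calls, accession_ids = acc, snp_ids = snp,
                 alleles = alleles),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d accessions x %d SNPs (%.1f%% missing, %.2f%% het)\n",
              length(x$accession_ids), length(x$snp_ids),
              100 * mean(is.na(x$calls)),
              100 * mean(x$calls == CALL_HET, na.rm = TRUE)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix by accessions and/or SNPs
#'
#' @param g a `genotype_matrix`.
#' @param accessions,snps character vectors of ids to keep (default: all).
#' @return A `genotype_matrix` restricted to the requested rows/columns.
#' @export
subset_genotypes <- function(g, accessions = NULL, snps = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.null(accessions)) accessions <- g$accession_ids
  if (is.null(snps)) snps <- g$snp_ids
  if (!all(accessions %in% g$accession_ids)) stop("unknown accession id")
  if (!all(snps %in% g$snp_ids)) stop("unknown SNP id")
  calls <- g$calls[accessions, snps, drop = FALSE]
  alleles <- g$alleles[match(snps, g$alleles$snp_id), , drop = FALSE]
  rownames(alleles) <- NULL
  genotype_matrix(calls, alleles)
}

## ---------------------------------------------------------------------------
## File I/O

#' Read a genotype matrix
#'
#' Two formats are supported. `matrix_tsv` is a tab-separated table with
#' accessions in rows and SNPs in columns; each cell is a two-nucleotide
#' diplotype ("AA", "AG", "NN" for missing), mirroring T3-style exports.
#' Since this dialect carries no reference/alternate polarity, the
#' alphabetically smaller observed allele becomes the reference. `vcf` is a
#' plain-text VCF with diploid GT fields; 0/0 maps to homozygous reference,
#' 1/1 to homozygous alternate, 0/1 (or 1/0) to heterozygous and ./. to
#' missing.
#'
#' @param path file path.
#' @param format `"matrix_tsv"` or `"vcf"`.
#' @return A `genotype_matrix`.
#' @export
read_genotypes <- function(path, format = c("matrix_tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         matrix_tsv = read_genotypes_tsv(path),
         vcf = read_genotypes_vcf(path))
}

read_genotypes_tsv <- function(path) {
  dt <- tryCatch(
    data.table::fread(path, sep = "\t", header = TRUE, colClasses = "character",
                      data.table = FALSE),
    error = function(e) stop("could not parse matrix TSV: ", conditionMessage(e)))
  if (nrow(dt) == 0L || ncol(dt) < 2L) stop("empty or malformed genotype TSV")
  acc <- dt[[1L]]
  if (anyDuplicated(acc)) stop("duplicate accession ids in TSV")
  snp <- colnames(dt)[-1L]
  if (anyDuplicated(snp)) stop("duplicate SNP ids in TSV")
  raw <- as.matrix(dt[, -1L, drop = FALSE])
  rownames(raw) <- acc
  nuc <- c("A", "C", "G", "T")
  calls <- matrix(NA_integer_, nrow(raw), ncol(raw), dimnames = dimnames(raw))
  ref <- alt <- character(ncol(raw))
  for (j in seq_len(ncol(raw))) {
    cell <- toupper(raw[, j])
    cell[cell %in% c("NN", "NA", "", "--", "N")] <- NA
    a1 <- substr(cell, 1L, 1L)
    a2 <- substr(cell, 2L, 2L)
    bad <- !is.na(cell) & (nchar(cell) != 2L | !(a1 %in% nuc) | !(a2 %in% nuc))
    if (any(bad)) stop("unknown call token '", raw[which(bad)[1L], j],
                       "' at SNP ", snp[j])
    obs <- sort(unique(c(a1[!is.na(cell)], a2[!is.na(cell)])))
    if (length(obs) > 2L) stop(">2 alleles at SNP ", snp[j])
    if (length(obs) == 0L) obs <- c("A", "C")     # fully missing column
    if (length(obs) == 1L) obs <- c(obs, setdiff(nuc, obs)[1L])
    ref[j] <- obs[1L]; alt[j] <- obs[2L]
    code <- (a1 == alt[j]) + (a2 == alt[j])
    calls[, j] <- ifelse(is.na(cell), NA_integer_, as.integer(code))
  }
  genotype_matrix(calls, data.frame(snp_id = snp, ref = ref, alt = alt,
                                    stringsAsFactors = FALSE))
}

read_genotypes_vcf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty VCF file")
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1L) stop("malformed VCF: missing #CHROM header line")
  fields <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1L]]
  if (length(fields) < 10L) stop("VCF has no sample columns")
  acc <- fields[-(1:9)]
  if (anyDuplicated(acc)) stop("duplicate accession ids in VCF")
  body <- lines[-seq_len(hdr)]
  if (length(body) == 0L) stop("VCF has no variant records")
  rec <- strsplit(body, "\t", fixed = TRUE)
  nfield <- lengths(rec)
  if (any(nfield != length(fields))) stop("ragged VCF record")
  snp <- vapply(rec, `[[`, "", 3L)
  if (anyDuplicated(snp)) stop("duplicate SNP ids in VCF")
  ref <- toupper(vapply(rec, `[[`, "", 4L))
  alt <- toupper(vapply(rec, `[[`, "", 5L))
  if (any(grepl(",", alt, fixed = TRUE))) stop(">2 alleles at a SNP (multiallelic ALT)")
  calls <- matrix(NA_integer_, length(acc), length(snp),
                  dimnames = list(acc, snp))
  for (i in seq_along(rec)) {
    fmt <- strsplit(rec[[i]][9L], ":", fixed = TRUE)[[1L]]
    gt_idx <- match("GT", fmt)
    if (is.na(gt_idx)) stop("VCF record without GT field")
    sm <- rec[[i]][-(1:9)]
    gt <- vapply(strsplit(sm, ":", fixed = TRUE), `[[`, "", gt_idx)
    gt <- gsub("|", "/", gt, fixed = TRUE)
    code <- integer(length(gt))
    code[gt %in% c("0/0")] <- CALL_HOM_REF
    code[gt %in% c("1/1")] <- CALL_HOM_ALT
    code[gt %in% c("0/1", "1/0")] <- CALL_HET
    miss <- gt %in% c("./.", ".")
    unknown <- !miss & !gt %in% c("0/0", "1/1", "0/1", "1/0")
    if (any(unknown)) stop("unknown GT token '", gt[which(unknown)[1L]],
                           "' at SNP ", snp[i])
    code[miss] <- NA_integer_
    calls[, i] <- code
  }
  genotype_matrix(calls, data.frame(snp_id = snp, ref = ref, alt = alt,
                                    stringsAsFactors = FALSE))
}

#' Write a genotype matrix as diplotype TSV
#'
#' Inverse of `read_genotypes(format = "matrix_tsv")` up to allele polarity
#' (the TSV dialect does not record which allele is the reference).
#'
#' @param g a `genotype_matrix`.
#' @param path output file path.
#' @export
write_genotypes_tsv <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  out <- matrix("NN", nrow(g$calls), ncol(g$calls), dimnames = dimnames(g$calls))
  for (j in seq_len(ncol(g$calls))) {
    r <- g$alleles$ref[j]; a <- g$alleles$alt[j]
    tok <- c(paste0(r, r), paste0(r, a), paste0(a, a))
    cj <- g$calls[, j]
    out[!is.na(cj), j] <- tok[cj[!is.na(cj)] + 1L]
  }
  df <- data.frame(accession = rownames(out), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Write a genotype matrix as a minimal plain-text VCF
#'
#' Emits a VCFv4.2 file with diploid GT calls only (no INFO/QUAL content);
#' chromosome and position columns are taken from `map` when given, else
#' placeholders are used. Readable by `read_genotypes(format = "vcf")`.
#'
#' @param g a `genotype_matrix`.
#' @param path output file path.
#' @param map optional `genetic_map`; cM positions are scaled to integer
#'   coordinates (x 10000) for the POS column.
#' @export
write_genotypes_vcf <- function(g, path, map = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (!is.null(map)) {
    m <- map[match(g$snp_ids, map$snp_id), ]
    chrom <- as.character(m$linkage_group)
    pos <- as.integer(round(m$position_cM * 1e4)) + 1L
  } else {
    chrom <- rep("1", length(g$snp_ids))
    pos <- seq_along(g$snp_ids)
  }
  tok <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(g$calls), ncol(g$calls))
  idx <- !is.na(g$calls)
  gt[idx] <- tok[g$calls[idx] + 1L]
  rows <- vapply(seq_along(g$snp_ids), function(j) {
    paste(c(chrom[j], pos[j], g$snp_ids[j], g$alleles$ref[j], g$alleles$alt[j],
            ".", "PASS", ".", "GT", gt[, j]), collapse = "\t")
  }, "")
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", g$accession_ids), collapse = "\t"))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a genetic map
#'
#' Three-column TSV: `snp_id`, `linkage_group`, `position_cM`. The map is
#' sorted by (linkage group, cM) and drives every haplotype-length
#' computation in the package.
#'
#' @param path file path.
#' @return A `genetic_map` data.frame.
#' @export
read_genetic_map <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  need <- c("snp_id", "linkage_group", "position_cM")
  if (!all(need %in% names(df))) stop("genetic map needs columns ", paste(need, collapse = ", "))
  genetic_map(df$snp_id, df$linkage_group, df$position_cM)
}

#' Construct a genetic map
#'
#' @param snp_id character vector of SNP ids.
#' @param linkage_group linkage-group labels (e.g. "1H".."7H").
#' @param position_cM non-negative map positions in centimorgans.
#' @return A data.frame of class `genetic_map`, sorted by
#'   (linkage_group, position_cM).
#' @export
genetic_map <- function(snp_id, linkage_group, position_cM) {
  if (anyDuplicated(snp_id)) stop("duplicate SNP ids in map")
  if (any(position_cM < 0)) stop("negative cM position")
  df <- data.frame(snp_id = as.character(snp_id),
                   linkage_group = as.character(linkage_group),
                   position_cM = as.numeric(position_cM),
                   stringsAsFactors = FALSE)
  df <- df[order(df$linkage_group, df$position_cM), ]
  rownames(df) <- NULL
  class(df) <- c("genetic_map", "data.frame")
  df
}

#' Construct a population scheme
#'
#' Maps accessions to breeding populations and records per-population
#' metadata: spike-type (2- or 6-rowed) and growth habit (spring or winter).
#'
#' @param accession,population character vectors (accession -> population).
#' @param pop_info data.frame with columns `population`, `spike_type`
#'   (2 or 6), `growth_habit` ("spring"/"winter") and optionally `program`.
#' @return An object of class `population_scheme`.
#' @export
population_scheme <- function(accession, population, pop_info) {
  if (anyDuplicated(accession)) stop("accession assigned more than once")
  assignments <- data.frame(accession = as.character(accession),
                            population = as.character(population),
                            stringsAsFactors = FALSE)
  pop_info <- as.data.frame(pop_info, stringsAsFactors = FALSE)
  if (!all(c("population", "spike_type", "growth_habit") %in% names(pop_info)))
    stop("pop_info needs columns population, spike_type, growth_habit")
  if (!all(assignments$population %in% pop_info$population))
    stop("population without metadata")
  if (!all(pop_info$spike_type %in% c(2L, 6L))) stop("spike_type must be 2 or 6")
  if (!all(pop_info$growth_habit %in% c("spring", "winter")))
    stop("growth_habit must be 'spring' or 'winter'")
  if (is.null(pop_info$program)) pop_info$program <- pop_info$population
  structure(list(assignments = assignments, populations = pop_info),
            class = "population_scheme")
}

#' Read a population scheme from TSV
#'
#' Columns: `accession`, `population`, `spike_type`, `growth_habit`
#' (and optionally `program`).
#'
#' @param path file path.
#' @return A `population_scheme`.
#' @export
read_population_scheme <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  need <- c("accession", "population", "spike_type", "growth_habit")
  if (!all(need %in% names(df))) stop("scheme needs columns ", paste(need, collapse = ", "))
  info <- unique(df[, setdiff(names(df), "accession"), drop = FALSE])
  if (anyDuplicated(info$population)) stop("inconsistent population metadata")
  population_scheme(df$accession, df$population, info)
}

#' Accessions belonging to a population
#'
#' @param scheme a `population_scheme`.
#' @param pop population label.
#' @return Character vector of accession ids.
#' @export
population_members <- function(scheme, pop) {
  stopifnot(inherits(scheme, "population_scheme"))
  scheme$assignments$accession[scheme$assignments$population == pop]
}

#' Partition accessions by a grouping variable
#'
#' @param scheme a `population_scheme`.
#' @param by `"population"`, `"spike_type"` or `"growth_habit"`.
#' @param accessions optional subset of accessions to partition.
#' @return Named list of accession-id vectors, one per group.
#' @export
partition_accessions <- function(scheme,
                                 by = c("population", "spike_type", "growth_habit"),
                                 accessions = NULL) {
  by <- match.arg(by)
  a <- scheme$assignments
  if (!is.null(accessions)) a <- a[a$accession %in% accessions, , drop = FALSE]
  if (by == "population") {
    grp <- a$population
  } else {
    grp <- scheme$populations[[by]][match(a$population, scheme$populations$population)]
  }
  split(a$accession, as.character(grp))
}

## ---------------------------------------------------------------------------
## Quality control

#' Apply the standard quality-control filters
#'
#' Removes, in a fixed order: (1) monomorphic SNPs (fewer than two distinct
#' homozygous states among non-missing, non-heterozygous calls); (2) SNPs
#' with missing-call fraction above `max_missing`; (3) accessions with
#' missing fraction above `max_missing`; (4) accessions whose heterozygous
#' fraction (over non-missing calls) exceeds `max_het`, the expectation
#' after four generations of selfing; (5) accessions whose population falls
#' below two members. Because removing accessions can create newly
#' monomorphic SNPs, the pass sequence is iterated to a fixed point so the
#' filter is idempotent; each removal keeps the reason of its first pass.
#'
#' @param g a `genotype_matrix`.
#' @param scheme a `population_scheme` covering the accessions (population
#'   size floor is skipped when `NULL`).
#' @param max_missing maximum tolerated missing fraction, default 0.25;
#'   the comparison is strict (`>`).
#' @param max_het maximum tolerated heterozygous fraction, default 0.0625.
#' @param exclude optional accession ids removed up front by curation
#'   (reason "excluded").
#' @return list with `genotypes` (filtered `genotype_matrix`) and `report`
#'   (a `qc_report`: reason-tagged removals plus thresholds).
#' @export
apply_qc <- function(g, scheme = NULL, max_missing = 0.25, max_het = 0.0625,
                     exclude = character()) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (max_missing < 0 || max_missing > 1 || max_het < 0 || max_het > 1)
    stop("thresholds must lie in [0, 1]")
  removed_snps <- data.frame(snp_id = character(), reason = character(),
                             stringsAsFactors = FALSE)
  removed_acc <- data.frame(accession = character(), reason = character(),
                            stringsAsFactors = FALSE)
  keep_acc <- g$accession_ids
  keep_snp <- g$snp_ids
  if (length(exclude)) {
    drop <- intersect(keep_acc, exclude)
    removed_acc <- rbind(removed_acc,
                         data.frame(accession = drop, reason = "excluded",
                                    stringsAsFactors = FALSE))
    keep_acc <- setdiff(keep_acc, drop)
  }
  repeat {
    changed <- FALSE
    calls <- g$calls[keep_acc, keep_snp, drop = FALSE]
    # (1) monomorphic: < 2 distinct homozygous states
    hom_ref <- colSums(calls == CALL_HOM_REF, na.rm = TRUE)
    hom_alt <- colSums(calls == CALL_HOM_ALT, na.rm = TRUE)
    mono <- keep_snp[hom_ref == 0L | hom_alt == 0L]
    if (length(mono)) {
      removed_snps <- rbind(removed_snps,
                            data.frame(snp_id = mono, reason = "monomorphic",
                                       stringsAsFactors = FALSE))
      keep_snp <- setdiff(keep_snp, mono)
      calls <- calls[, keep_snp, drop = FALSE]
      changed <- TRUE
    }
    # (2) SNP missingness
    if (length(keep_snp)) {
      miss <- colMeans(is.na(calls))
      bad <- keep_snp[miss > max_missing]
      if (length(bad)) {
        removed_snps <- rbind(removed_snps,
                              data.frame(snp_id = bad, reason = "missing",
                                         stringsAsFactors = FALSE))
        keep_snp <- setdiff(keep_snp, bad)
        calls <- calls[, keep_snp, drop = FALSE]
        changed <- TRUE
      }
    }
    if (length(keep_snp) == 0L) stop("all SNPs removed by QC")
    # (3) accession missingness
    miss_a <- rowMeans(is.na(calls))
    bad <- keep_acc[miss_a > max_missing]
    if (length(bad)) {
      removed_acc <- rbind(removed_acc,
                           data.frame(accession = bad, reason = "missing",
                                      stringsAsFactors = FALSE))
      keep_acc <- setdiff(keep_acc, bad)
      calls <- calls[keep_acc, , drop = FALSE]
      changed <- TRUE
    }
    # (4) accession heterozygosity over non-missing calls
    if (length(keep_acc)) {
      nonmiss <- rowSums(!is.na(calls))
      hets <- rowSums(calls == CALL_HET, na.rm = TRUE)
      frac <- ifelse(nonmiss > 0, hets / nonmiss, 0)
      bad <- keep_acc[frac > max_het]
      if (length(bad)) {
        removed_acc <- rbind(removed_acc,
                             data.frame(accession = bad, reason = "heterozygosity",
                                        stringsAsFactors = FALSE))
        keep_acc <- setdiff(keep_acc, bad)
        calls <- calls[keep_acc, , drop = FALSE]
        changed <- TRUE
      }
    }
    if (length(keep_acc) == 0L) stop("all accessions removed by QC")
    # (5) population size floor
    if (!is.null(scheme)) {
      a <- scheme$assignments
      a <- a[a$accession %in% keep_acc, , drop = FALSE]
      sizes <- table(a$population)
      small <- names(sizes)[sizes < 2L]
      bad <- a$accession[a$population %in% small]
      if (length(bad)) {
        removed_acc <- rbind(removed_acc,
                             data.frame(accession = bad, reason = "small_population",
                                        stringsAsFactors = FALSE))
        keep_acc <- setdiff(keep_acc, bad)
        changed <- TRUE
      }
      if (length(keep_acc) == 0L) stop("all accessions removed by QC")
    }
    if (!changed) break
  }
  report <- structure(list(removed_snps = removed_snps,
                           removed_accessions = removed_acc,
                           thresholds = list(max_missing = max_missing,
                                             max_het = max_het)),
                      class = "qc_report")
  list(genotypes = subset_genotypes(g, keep_acc, keep_snp), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d SNPs and %d accessions removed (max_missing=%g, max_het=%g)\n",
              nrow(x$removed_snps), nrow(x$removed_accessions),
              x$thresholds$max_missing, x$thresholds$max_het))
  if (nrow(x$removed_snps)) print(table(x$removed_snps$reason))
  if (nrow(x$removed_accessions)) print(table(x$removed_accessions$reason))
  invisible(x)
}

#' Write a QC report to disk
#'
#' @param report a `qc_report`.
#' @param dir output directory; writes `qc_removed_snps.tsv`,
#'   `qc_removed_accessions.tsv` and `qc_summary.json`.
#' @export
write_qc_report <- function(report, dir) {
  stopifnot(inherits(report, "qc_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(report$removed_snps, file.path(dir, "qc_removed_snps.tsv"),
                     sep = "\t")
  data.table::fwrite(report$removed_accessions,
                     file.path(dir, "qc_removed_accessions.tsv"), sep = "\t")
  summary <- list(thresholds = report$thresholds,
                  n_removed_snps = nrow(report$removed_snps),
                  n_removed_accessions = nrow(report$removed_accessions),
                  snp_reasons = as.list(table(report$removed_snps$reason)),
                  accession_reasons = as.list(table(report$removed_accessions$reason)))
  jsonlite::write_json(summary, file.path(dir, "qc_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Expected residual heterozygosity after selfing
#'
#' Starting from a fully heterozygous individual, each selfing generation
#' halves the expected fraction of heterozygous loci, so after `generations`
#' rounds the expectation is (1/2)^generations; four generations give the
#' 6.25% threshold used by the QC heterozygosity filter.
#'
#' @param generations non-negative integer number of selfing generations.
#' @return Expected heterozygous fraction of loci.
#' @export
selfing_het_expectation <- function(generations) {
  if (any(generations < 0) || any(generations != floor(generations)))
    stop("`generations` must be a non-negative integer")
  0.5^generations
}

# Haploid allele coding used by diversity / SFS / FST: homozygous calls
# contribute one chromosome (0 = ref, 1 = alt), HET and MISSING drop out.
haploid_codes <- function(g, accessions = NULL) {
  calls <- if (is.null(accessions)) g$calls else g$calls[accessions, , drop = FALSE]
  h <- matrix(NA_integer_, nrow(calls), ncol(calls), dimnames = dimnames(calls))
  h[calls == CALL_HOM_REF] <- 0L
  h[calls == CALL_HOM_ALT] <- 1L
  h
}

# Per-SNP haploid alt counts (x) and sample sizes (n) for a set of accessions.
haploid_counts <- function(g, accessions = NULL) {
  h <- haploid_codes(g, accessions)
  list(x = colSums(h == 1L, na.rm = TRUE), n = colSums(!is.na(h)))
}
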