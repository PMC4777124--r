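# Bayesian estimation of per-population divergence from ancestral allele
# frequencies ("c") under the censored-normal drift model, via MCMC.

#' Haploid allele counts for the divergence model
#'
#' Builds the populations x loci count matrices the sampler consumes from a
#' genotype matrix, dropping loci monomorphic (or unobserved) across the
#' pooled groups.
#'
#' @param g a `genotype_matrix`.
#' @param groups named list of accession-id vectors (the populations).
#' @return list with matrices `x` (alt counts) and `n` (haploid sample
#'   sizes), populations in rows, retained loci in columns.
#' @export
nicholson_counts <- function(g, groups) {
  pc <- partition_counts(g, groups)
  X <- t(pc$X); N <- t(pc$N)
  tot_x <- colSums(X); tot_n <- colSums(N)
  keep <- tot_n > 0 & tot_x > 0 & tot_x < tot_n
  list(x = X[, keep, drop = FALSE], n = N[, keep, drop = FALSE])
}

#' Fit the divergence parameter c per population
#'
#' Model: each population i has latent allele frequencies
#' p_ij ~ N(pi_j, c_i pi_j (1 - pi_j)) censored to [0, 1] with point
#' masses at the bounds; observed haploid counts x_ij ~ Binomial(n_ij,
#' p_ij); pi_j and c_i carry uniform(0, 1) priors. A
#' Metropolis-within-Gibbs sweep updates every p_ij (censoring random
#' walk), every pi_j (Beta proposal with concentration `m`, the
#' two-component Dirichlet scale), and every c_i (log-scale random walk)
#' per iteration. Proposal scales adapt during burn-in only, so the
#' retained chain is Markovian. Deterministic for a fixed `seed`.
#'
#' @param counts list with matrices `x` and `n` (populations x loci), as
#'   from [nicholson_counts()].
#' @param burn_in discarded initial iterations (default 1000).
#' @param run_length retained iterations (default 10000).
#' @param m Dirichlet concentration of the ancestral-frequency proposal
#'   (default 10).
#' @param seed integer RNG seed.
#' @param prop_p_sd,prop_c_sd initial random-walk scales for p and log(c).
#' @return A `c_posterior`: matrix `samples` (run_length x populations),
#'   per-population `mean`, `median`, `ci` (central 95%), acceptance rates
#'   and the run settings.
#' @export
fit_nicholson_c <- function(counts, burn_in = 1000L, run_length = 10000L,
                            m = 10, seed = 1L,
                            prop_p_sd = 0.05, prop_c_sd = 0.4) {
  x <- as.matrix(counts$x); n <- as.matrix(counts$n)
  if (!all(dim(x) == dim(n))) stop("x and n dimensions differ")
  if (nrow(x) < 2L) stop("need >= 2 populations")
  if (ncol(x) < 50L) stop("need >= 50 polymorphic loci")
  if (any(x < 0) || any(x > n)) stop("counts must satisfy 0 <= x <= n")
  tot_x <- colSums(x); tot_n <- colSums(n)
  if (any(tot_x == 0 | tot_x == tot_n))
    stop("monomorphic loci present; build counts with nicholson_counts()")
  pops <- rownames(x)
  if (is.null(pops)) pops <- paste0("pop", seq_len(nrow(x)))
  set.seed(seed)
  fit <- .nicholson_mcmc(x, n, as.integer(burn_in), as.integer(run_length),
                         m, prop_p_sd, prop_c_sd, 1e-9)
  s <- fit$c_samples
  colnames(s) <- pops
  structure(list(
    samples = s,
    mean = colMeans(s),
    median = apply(s, 2, stats::median),
    ci = apply(s, 2, stats::quantile, probs = c(0.025, 0.975)),
    accept = list(p = stats::setNames(fit$accept_p, pops),
                  pi = fit$accept_pi,
                  c = stats::setNames(fit$accept_c, pops)),
    pi_mean = fit$pi_mean,
    burn_in = burn_in, run_length = run_length, m = m, seed = seed),
    class = "c_posterior")
}

#' @export
print.c_posterior <- function(x, ...) {
  cat(sprintf("c_posterior: %d retained samples, %d populations (m=%g, seed=%d)\n",
              nrow(x$samples), ncol(x$samples), x$m, x$seed))
  print(round(rbind(mean = x$mean, median = x$median, x$ci), 4))
  invisible(x)
}

#' Histogram density summary of a c posterior
#'
#' Fixed-grid (kernel-free) histogram of the retained samples per
#' population, for density plotting and export, plus order-statistic
#' summaries. Histogram masses sum to 1 per population.
#'
#' @param post a `c_posterior`.
#' @param bins number of histogram bins (default 50) over the pooled
#'   sample range.
#' @return list with `density` (data.frame: population, bin midpoint,
#'   mass) and `summary` (data.frame: min, q2.5, median, mean, q97.5, max).
#' @export
c_density_summary <- function(post, bins = 50L) {
  stopifnot(inherits(post, "c_posterior"))
  s <- post$samples
  rng <- range(s)
  if (rng[1] == rng[2]) rng <- rng + c(-1e-9, 1e-9)   # degenerate chain
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  dens <- do.call(rbind, lapply(colnames(s), function(pop) {
    h <- hist(s[, pop], breaks = breaks, plot = FALSE, include.lowest = TRUE)
    data.frame(population = pop, c = mids, mass = h$counts / sum(h$counts),
               stringsAsFactors = FALSE)
  }))
  summ <- do.call(rbind, lapply(colnames(s), function(pop) {
    v <- s[, pop]
    data.frame(population = pop, min = min(v),
               q2.5 = unname(stats::quantile(v, 0.025)),
               median = stats::median(v), mean = mean(v),
               q97.5 = unname(stats::quantile(v, 0.975)), max = max(v),
               stringsAsFactors = FALSE)
  }))
  list(density = dens, summary = summ)
}
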