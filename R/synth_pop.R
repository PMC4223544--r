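#' Simulation parameters for a synthetic founder panel
#'
#' The generator emulates the key property of dense SNP panels used for
#' haplotype-based fine mapping: LD that decays with genetic distance in a
#' population of medium effective size, with MAF-filtered biallelic SNPs.
#'
#' @param n_chromosomes chromosomes sampled into the returned panel
#'   (must not exceed \code{2 * effective_size}).
#' @param n_markers marker count before MAF filtering.
#' @param chrom_length_cM total genetic length; markers are equally spaced.
#' @param n_burnin_generations generations of random mating used to build
#'   up LD by drift and recombination.
#' @param effective_size diploid population size during burn-in.
#' @param maf_threshold MAF filter applied to the sampled panel.
#' @param seed integer RNG seed.
#' @return a \code{pop_sim_params} list.
#' @export
pop_sim_params <- function(n_chromosomes = 100, n_markers = 60,
                           chrom_length_cM = 6, n_burnin_generations = 200,
                           effective_size = 100, maf_threshold = 0.05,
                           seed = 1L) {
  stopifnot(n_chromosomes > 0, n_markers > 0, chrom_length_cM >= 0,
            n_burnin_generations >= 0, effective_size > 0,
            maf_threshold >= 0, maf_threshold <= 0.5,
            n_chromosomes <= 2 * effective_size)
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 n_markers = as.integer(n_markers),
                 chrom_length_cM = chrom_length_cM,
                 n_burnin_generations = as.integer(n_burnin_generations),
                 effective_size = as.integer(effective_size),
                 maf_threshold = maf_threshold,
                 seed = as.integer(seed)),
            class = "pop_sim_params")
}

## One meiosis: recombine a parent's two chromosomes into a gamete.
## Haldane model: Poisson crossover count with mean = map length in Morgans,
## uniform crossover placement, no interference; starting strand is random.
meiosis <- function(hap1, hap2, positions_cM) {
  L <- positions_cM[length(positions_cM)] - positions_cM[1L]
  n_xo <- stats::rpois(1L, L / 100)
  strand <- stats::rbinom(1L, 1L, 0.5)
  if (n_xo == 0L) {
    if (strand == 0L) return(hap1) else return(hap2)
  }
  xo <- sort(stats::runif(n_xo, min = positions_cM[1L],
                          max = positions_cM[length(positions_cM)]))
  phase <- (strand + findInterval(positions_cM, xo)) %% 2L
  ifelse(phase == 0L, hap1, hap2)
}

## One generation of random mating: N diploids, each child draws two
## distinct parents uniformly and one recombinant gamete from each.
random_mating_generation <- function(chrom, positions_cM) {
  N <- nrow(chrom) %/% 2L
  out <- matrix(0L, nrow = 2L * N, ncol = ncol(chrom))
  for (i in seq_len(N)) {
    par <- sample.int(N, 2L)
    p1 <- 2L * par[1L]; p2 <- 2L * par[2L]
    out[2L * i - 1L, ] <- meiosis(chrom[p1 - 1L, ], chrom[p1, ], positions_cM)
    out[2L * i, ]      <- meiosis(chrom[p2 - 1L, ], chrom[p2, ], positions_cM)
  }
  out
}

#' Generate a synthetic founder haplotype panel
#'
#' Initializes \code{2 * effective_size} chromosomes with independent
#' Bernoulli alleles (per-marker frequency drawn from U(0.1, 0.9)), runs
#' \code{n_burnin_generations} of random mating with Haldane recombination
#' so that drift builds distance-decaying LD, samples
#' \code{n_chromosomes} chromosomes and applies the MAF filter.
#' Deterministic given the seed.
#'
#' @param params a \code{\link{pop_sim_params}}.
#' @return a \code{haplotype_panel}.
#' @export
generate_founder_panel <- function(params) {
  stopifnot(inherits(params, "pop_sim_params"))
  set.seed(params$seed)
  m <- params$n_markers
  positions <- if (m == 1L) 0 else
    seq(0, params$chrom_length_cM, length.out = m)
  freqs <- stats::runif(m, 0.1, 0.9)
  chrom <- matrix(stats::rbinom(2L * params$effective_size * m, 1L,
                                rep(freqs, each = 2L * params$effective_size)),
                  nrow = 2L * params$effective_size, ncol = m)
  for (g in seq_len(params$n_burnin_generations))
    chrom <- random_mating_generation(chrom, positions)
  take <- sample.int(nrow(chrom), params$n_chromosomes)
  ## keep chromosome pairs arbitrary: sampled rows form the panel in order
  panel <- haplotype_panel(chrom[take, , drop = FALSE] [
                             seq_len(2L * (params$n_chromosomes %/% 2L)), ,
                             drop = FALSE],
                           positions)
  out <- maf_filter(panel, params$maf_threshold)
  if (n_markers(out) == 0L)
    stop("all markers lost to the MAF filter; use fewer burn-in generations ",
         "or a larger effective size")
  out
}

#' Pairwise r between two marker columns of a panel (biallelic LD)
#' @param panel a \code{haplotype_panel}.
#' @param i,j marker indices.
#' @return the correlation of allele indicators over chromosomes (0 when a
#'   marker is monomorphic).
#' @export
marker_r <- function(panel, i, j) {
  x <- panel$alleles[, i]; y <- panel$alleles[, j]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}
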