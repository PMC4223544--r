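#' QTL scenario: genotype effects and retention rule
#'
#' @param genotype_effects length-3 numeric vector: effect for genotypes
#'   a1a1, a1a2, a2a2 (e.g. \code{c(2, 0, -2)} or \code{c(0.5, 0, -0.5)}).
#' @param maf_retention_threshold minimum QTL MAF in the phenotyped
#'   generation for a gene-drop replicate to be retained (default 0.1,
#'   inclusive).
#' @param var_polygenic parental polygenic variance (default 0.5).
#' @param var_mendelian Mendelian-sampling variance (default 0.25).
#' @param var_env environmental variance (default 1).
#' @return a \code{qtl_scenario} list.
#' @export
qtl_scenario <- function(genotype_effects = c(2, 0, -2),
                         maf_retention_threshold = 0.1,
                         var_polygenic = 0.5, var_mendelian = 0.25,
                         var_env = 1) {
  stopifnot(length(genotype_effects) == 3L, var_polygenic >= 0,
            var_mendelian >= 0, var_env >= 0)
  structure(list(genotype_effects = as.numeric(genotype_effects),
                 maf_retention_threshold = maf_retention_threshold,
                 var_polygenic = var_polygenic,
                 var_mendelian = var_mendelian,
                 var_env = var_env),
            class = "qtl_scenario")
}

#' Gene-drop founder haplotypes through a pedigree
#'
#' Founders receive two chromosomes each, sampled uniformly with
#' replacement from the founder panel; every transmission to an offspring
#' draws one recombinant gamete per parent (Poisson crossover count with
#' mean equal to the map length in Morgans, uniform placement, no
#' interference).  Deterministic given the seed.
#'
#' @param founder_panel a \code{haplotype_panel} of founder chromosomes.
#' @param ped a \code{pedigree}.
#' @param seed integer RNG seed.
#' @param generation generation whose individuals form the returned
#'   panel (default: last generation).
#' @return list with \code{panel} (a \code{haplotype_panel} of the
#'   requested generation, individual ids from the pedigree),
#'   \code{ids} (their pedigree ids) and \code{all_alleles} (2N x m matrix
#'   over the whole pedigree, rows 2k-1/2k = individual k in pedigree
#'   order).
#' @export
gene_drop <- function(founder_panel, ped, seed = 1L,
                      generation = max(ped$generation)) {
  set.seed(seed)
  pos <- founder_panel$positions_cM
  m <- length(pos)
  N <- nrow(ped)
  alle <- matrix(0L, nrow = 2L * N, ncol = m)
  founder_rows <- nrow(founder_panel$alleles)
  for (k in seq_len(N)) {
    s <- ped$sire[k]; d <- ped$dam[k]
    if (is.na(s) || is.na(d)) {
      pick <- sample.int(founder_rows, 2L, replace = TRUE)
      alle[2L * k - 1L, ] <- founder_panel$alleles[pick[1L], ]
      alle[2L * k, ] <- founder_panel$alleles[pick[2L], ]
    } else {
      alle[2L * k - 1L, ] <- meiosis(alle[2L * s - 1L, ], alle[2L * s, ], pos)
      alle[2L * k, ] <- meiosis(alle[2L * d - 1L, ], alle[2L * d, ], pos)
    }
  }
  keep <- which(ped$generation == generation)
  rows <- as.vector(rbind(2L * keep - 1L, 2L * keep))
  panel <- haplotype_panel(alle[rows, , drop = FALSE], pos,
                           marker_ids = founder_panel$marker_ids,
                           individual_ids = ped$id[keep])
  list(panel = panel, ids = ped$id[keep], all_alleles = alle)
}

#' Simulate phenotypes with a hidden additive QTL
#'
#' Phenotype model: \code{y = polygenic + g_QTL + env}, where the
#' polygenic value propagates through the pedigree (founders ~
#' N(0, var_polygenic); non-founders = half the parents' sum plus a
#' Mendelian-sampling term ~ N(0, var_mendelian), which keeps the
#' polygenic variance stationary at var_polygenic when var_mendelian =
#' var_polygenic / 2) and env ~ N(0, var_env).  Only individuals of the
#' phenotyped generation receive phenotypes.
#'
#' @param ped a \code{pedigree}.
#' @param qtl_genotypes named integer vector (0/1/2 copies of allele
#'   coded 1) for the phenotyped individuals, names = pedigree ids.
#' @param scenario a \code{\link{qtl_scenario}}.
#' @param seed integer RNG seed.
#' @param generation phenotyped generation (default: last).
#' @return data.frame with \code{id}, \code{g} (QTL genotype effect) and
#'   \code{y}.
#' @export
simulate_phenotypes <- function(ped, qtl_genotypes, scenario, seed = 1L,
                                generation = max(ped$generation)) {
  set.seed(seed)
  N <- nrow(ped)
  poly <- numeric(N)
  for (k in seq_len(N)) {
    s <- ped$sire[k]; d <- ped$dam[k]
    poly[k] <- if (is.na(s) || is.na(d))
      stats::rnorm(1L, 0, sqrt(scenario$var_polygenic))
    else
      0.5 * (poly[s] + poly[d]) +
        stats::rnorm(1L, 0, sqrt(scenario$var_mendelian))
  }
  keep <- which(ped$generation == generation)
  ids <- ped$id[keep]
  geno <- qtl_genotypes[ids]
  if (any(is.na(geno)))
    stop("missing QTL genotype for phenotyped individual ",
         ids[which(is.na(geno))[1L]])
  g <- scenario$genotype_effects[geno + 1L]
  y <- poly[keep] + g + stats::rnorm(length(keep), 0, sqrt(scenario$var_env))
  data.frame(id = ids, g = g, y = y, stringsAsFactors = FALSE)
}

#' QTL genotypes (allele-1 copy counts) of a panel's individuals
#' @param panel a \code{haplotype_panel}.
#' @param qtl_marker_index QTL marker.
#' @return named integer vector (0/1/2) per individual.
#' @export
qtl_genotypes <- function(panel, qtl_marker_index) {
  a <- panel$alleles[, qtl_marker_index]
  n <- length(a) %/% 2L
  g <- a[seq(1L, 2L * n, by = 2L)] + a[seq(2L, 2L * n, by = 2L)]
  names(g) <- panel$individual_ids
  g
}

#' Should a gene-drop replicate be retained?
#'
#' A replicate is retained iff the QTL minor allele frequency among the
#' phenotyped generation's chromosomes is greater than or equal to the
#' threshold (inclusive).
#'
#' @param qtl a truth object from \code{\link{qtl_truth}} on the
#'   descendant panel, or a 0/1 allele vector.
#' @param threshold retention MAF (default 0.1).
#' @return logical.
#' @export
retain_replicate <- function(qtl, threshold = 0.1) {
  a <- if (is.list(qtl)) qtl$qtl_alleles else qtl
  p <- mean(a)
  min(p, 1 - p) >= threshold
}

#' Phenotypic variance explained by the QTL under HWE
#'
#' With genotype effects \code{(g0, g1, g2)} for 0/1/2 copies at allele
#' frequency \code{p} under Hardy-Weinberg equilibrium, the explained
#' fraction is \code{Var(g) / (Var(g) + var_rest)}, where the
#' non-QTL phenotypic variance is the parental-average polygenic part
#' (\code{var_polygenic / 2}), the Mendelian term and the environmental
#' variance (0.25 + 0.25 + 1 = 1.5 under the defaults).
#'
#' @param scenario a \code{\link{qtl_scenario}}.
#' @param allele_freq frequency of the allele counted by the genotype, in
#'   (0, 1).
#' @return fraction of phenotypic variance explained by the QTL.
#' @export
variance_explained <- function(scenario, allele_freq = 0.5) {
  if (allele_freq <= 0 || allele_freq >= 1)
    stop("allele_freq must be inside (0, 1)")
  p <- allele_freq
  w <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  g <- scenario$genotype_effects
  vg <- sum(w * g^2) - sum(w * g)^2
  var_rest <- scenario$var_polygenic / 2 + scenario$var_mendelian +
    scenario$var_env
  vg / (vg + var_rest)
}
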