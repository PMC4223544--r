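## Shared fixtures and independent oracles used across the test files.

## Random phased panel with markers at the given spacing; allele
## frequencies drawn per marker so panels are polymorphic but unstructured.
random_panel <- function(n_chrom = 12L, m = 8L, spacing = 0.1, seed = 1L) {
  set.seed(seed)
  freq <- runif(m, 0.2, 0.8)
  alle <- matrix(rbinom(n_chrom * m, 1L, rep(freq, each = n_chrom)),
                 nrow = n_chrom)
  ## guard against monomorphic columns (re-toggle one entry)
  for (j in seq_len(m)) {
    if (all(alle[, j] == alle[1L, j])) alle[1L, j] <- 1L - alle[1L, j]
  }
  haplotype_panel(alle, seq(0, by = spacing, length.out = m))
}

## Brute-force entrywise-1-norm distance (independent of d1_pairwise).
naive_d1 <- function(M, M_QTL) {
  tot <- 0
  n <- nrow(M)
  for (i in seq_len(n)) for (j in seq_len(n))
    tot <- tot + abs(M[i, j] - M_QTL[i, j])
  tot / n^2
}

## Independent kinship-recursion oracle for the additive relationship
## matrix: A = 2 * phi with phi the coancestry coefficients, computed by
## the classic recursive definition with memoisation (distinct code path
## from the iterative tabular construction in the package).
kinship_A <- function(ped) {
  n <- nrow(ped)
  phi <- matrix(NA_real_, n, n)
  get_phi <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    if (!is.na(phi[i, j])) return(phi[i, j])
    if (i == j) {
      s <- if (is.na(ped$sire[i])) 0L else ped$sire[i]
      d <- if (is.na(ped$dam[i])) 0L else ped$dam[i]
      v <- 0.5 * (1 + get_phi(s, d))
    } else {
      a <- max(i, j); b <- min(i, j)   # a is the later individual
      s <- if (is.na(ped$sire[a])) 0L else ped$sire[a]
      d <- if (is.na(ped$dam[a])) 0L else ped$dam[a]
      v <- 0.5 * (get_phi(b, s) + get_phi(b, d))
    }
    phi[i, j] <<- v; phi[j, i] <<- v
    v
  }
  for (i in seq_len(n)) for (j in i:n) get_phi(i, j)
  2 * phi
}

## Random small pedigree for property tests (parents precede offspring).
random_pedigree <- function(n = 12L, seed = 1L) {
  set.seed(seed)
  id <- paste0("i", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (k in 3:n) {
    if (runif(1) < 0.7) {
      pp <- sample(k - 1L, 2L)
      sire[k] <- id[pp[1L]]; dam[k] <- id[pp[2L]]
    }
  }
  pedigree(id, sire, dam)
}

## Monte-Carlo oracle for the coalescent IBD-probability model on a
## 2-marker window: simulates the generative process (geometric
## coalescence truncated at T, exponential IBD tract flanks, chance IBS
## outside the tract at marker homozygosity) and conditions on the
## observed IBS pattern.
mc_pibd <- function(ibs, d_morgan, hom, Ne, T, nsim = 1e5, seed = 1L) {
  set.seed(seed)
  tau <- rgeom(nsim, 1 / (2 * Ne)) + 1L      # coalescence generation
  ibd <- tau <= T
  K <- length(ibs)
  sim_ibs <- matrix(FALSE, nsim, K)
  for (k in seq_len(K)) {
    covered <- ibd & (rexp(nsim, rate = 2 * pmin(tau, .Machine$integer.max)) >
                        d_morgan[k])
    ## markers on independent flanks: tract length drawn per marker flank
    ## is valid here because the two markers lie on opposite sides of the
    ## tested point (one per flank)
    chance <- runif(nsim) < hom[k]
    sim_ibs[, k] <- covered | (!covered & chance)
  }
  match_pat <- rowSums(sim_ibs == matrix(ibs, nsim, K, byrow = TRUE)) == K
  sum(ibd & match_pat) / sum(match_pat)
}

## Independent Li-Jiang score oracle: explicit loops over IBS sets and
## runs spanning the tested position.
naive_score <- function(pat_a, pat_b, pos, i) {
  w <- pmax(0, 1 - abs(pos - i))
  ibs <- pat_a == pat_b
  raw <- sum(w[ibs])
  nl <- sum(pos < i)
  if (nl >= 1 && nl < length(ibs) && ibs[nl] && ibs[nl + 1]) {
    runs <- rle(ibs)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    k <- which(runs$values & starts <= nl & ends >= nl + 1)
    raw <- raw + sum(w[starts[k]:ends[k]])
  }
  raw / (2 * sum(w))
}

## Mean squared prediction error of a TP-style estimate table over the
## target SNPs of a panel, from first principles (frequency form of the
## normalized squared euclidean distance).
naive_etp <- function(panel, t, lookup) {
  m <- n_markers(panel)
  targets <- (t %/% 2 + 1):(m - t %/% 2)
  tot <- 0
  for (j in targets) {
    cd <- code_haplotypes(panel,
                          list(marker_indices = (j - t %/% 2):(j + t %/% 2),
                               tested_pos_cM = panel$positions_cM[j]),
                          exclude = j)
    al <- panel$alleles[, j]
    k <- length(cd$freqs)
    N1 <- sapply(seq_len(k), function(p) sum(al[cd$labels == p]))
    Np <- sapply(seq_len(k), function(p) sum(cd$labels == p))
    for (p in seq_len(k)) for (q in seq_len(k)) {
      pshare <- (N1[p] * N1[q] + (Np[p] - N1[p]) * (Np[q] - N1[q])) /
        (Np[p] * Np[q])
      s <- lookup(cd$patterns[p], cd$patterns[q])
      tot <- tot + cd$freqs[p] * cd$freqs[q] *
        (pshare * (s - 1)^2 + (1 - pshare) * s^2)
    }
  }
  tot / length(targets)
}

## Independent REML criterion evaluator (direct dense formula) used to
## cross-check EM fits against a derivative-free optimizer.
naive_reml_ll <- function(y, A, sigma2, Zh = NULL, H = NULL) {
  n <- length(y)
  X <- matrix(1, n, 1)
  V <- sigma2[length(sigma2)] * diag(n)
  k <- 1
  if (!is.null(Zh)) {
    V <- V + sigma2[1] * Zh %*% H %*% t(Zh)
    k <- 2
  }
  V <- V + sigma2[k] * A
  Vi <- solve(V)
  XtVX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtVX) %*% t(X) %*% Vi
  -0.5 * (determinant(V)$modulus + log(XtVX[1, 1]) +
            drop(t(y) %*% P %*% y))
}
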