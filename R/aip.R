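#' Allelic identity predictor similarity object
#'
#' Internal constructor shared by all predictors: a kappa x kappa symmetric
#' matrix \code{H} of predictions in [0, 1] over the distinct haplotypes
#' (or clusters) at a tested position, plus the length-2n label vector
#' linking chromosomes to rows of \code{H}.
#'
#' @param H kappa x kappa symmetric numeric matrix, entries in [0, 1].
#' @param labels integer vector (length 2n) of haplotype/cluster labels.
#' @param predictor predictor name.
#' @param position_cM tested position.
#' @return an \code{aip_similarity} object.
#' @export
aip_similarity <- function(H, labels, predictor, position_cM = NA_real_) {
  H <- as.matrix(H)
  if (max(abs(H - t(H))) > 1e-12) stop("H must be symmetric")
  if (any(H < -1e-12 | H > 1 + 1e-12)) stop("H entries must lie in [0, 1]")
  H <- pmin(pmax((H + t(H)) / 2, 0), 1)
  labels <- as.integer(labels)
  if (any(labels < 1L | labels > nrow(H))) stop("label out of range for H")
  structure(list(H = H, labels = labels, predictor = predictor,
                 position_cM = position_cM),
            class = "aip_similarity")
}

#' @method print aip_similarity
#' @export
print.aip_similarity <- function(x, ...) {
  cat("aip_similarity [", x$predictor, "] kappa =", nrow(x$H),
      "over", length(x$labels), "chromosomes\n")
  invisible(x)
}

#' Expand a haplotype-level similarity to the chromosome-level matrix
#'
#' \code{M[c1, c2] = H[label(c1), label(c2)]}: the 2n x 2n similarity
#' matrix over chromosomes implied by the haplotype (or cluster) level
#' matrix.
#'
#' @param x an \code{aip_similarity}, or a kappa x kappa matrix \code{H}.
#' @param labels chromosome labels (only when \code{x} is a bare matrix).
#' @return symmetric 2n x 2n matrix with entries in [0, 1].
#' @export
expand_to_M <- function(x, labels = NULL) {
  if (inherits(x, "aip_similarity")) {
    H <- x$H; labels <- x$labels
  } else {
    H <- as.matrix(x)
    if (is.null(labels)) stop("labels required when x is a bare matrix")
    labels <- as.integer(labels)
    if (any(labels < 1L | labels > nrow(H))) stop("label out of range for H")
  }
  H[labels, labels, drop = FALSE]
}

#' Single-marker IBS predictor
#'
#' Predicts 1 when a pair of chromosomes carries the same allele at the
#' tested marker and 0 otherwise; tested positions coincide with marker
#' positions for this predictor.
#'
#' @param panel a \code{haplotype_panel}.
#' @param marker_index tested marker.
#' @return an \code{aip_similarity} (kappa = 2, or 1 when monomorphic).
#' @export
ibs_m <- function(panel, marker_index) {
  a <- panel$alleles[, marker_index]
  seen <- unique(a)
  labels <- match(a, seen)
  aip_similarity(diag(length(seen)), labels, "ibs_m",
                 panel$positions_cM[marker_index])
}

#' Haplotype IBS predictor
#'
#' Predicts 1 iff both chromosome segments carry identical marker alleles
#' across the whole window; at the haplotype level this is the kappa x
#' kappa identity matrix.
#'
#' @param coding a window coding from \code{\link{code_haplotypes}}.
#' @return an \code{aip_similarity}.
#' @export
ibs_hap <- function(coding) {
  aip_similarity(diag(length(coding$freqs)), coding$labels, "ibs_hap",
                 coding$window$tested_pos_cM)
}

#' Li-Jiang haplotype similarity score
#'
#' For a pair of haplotypes the raw score is the weighted count of IBS
#' markers plus the weighted length of the longest run of consecutive IBS
#' markers that spans the tested position (i.e. contains both innermost
#' markers); each marker's weight is \code{max(0, 1 - |pos_m - i|)} in cM,
#' clipped at 0 beyond 1 cM.  Scores are normalized by the self score so
#' predictions lie in [0, 1].
#'
#' @param coding a window coding from \code{\link{code_haplotypes}}.
#' @return an \code{aip_similarity}.
#' @export
score_li_jiang <- function(coding) {
  pm <- coding$pattern_mat
  k <- nrow(pm)
  i <- coding$window$tested_pos_cM
  pos <- score_positions(coding)
  w <- pmax(0, 1 - abs(pos - i))
  nl <- sum(pos < i)                          # markers left of i
  self_raw <- 2 * sum(w)
  H <- matrix(1, k, k)
  if (k > 1) for (p in 1:(k - 1)) for (q in (p + 1):k) {
    ibs <- pm[p, ] == pm[q, ]
    raw <- sum(w[ibs])
    if (nl >= 1L && nl < length(ibs) && ibs[nl] && ibs[nl + 1L]) {
      lo <- nl
      while (lo > 1L && ibs[lo - 1L]) lo <- lo - 1L
      hi <- nl + 1L
      while (hi < length(ibs) && ibs[hi + 1L]) hi <- hi + 1L
      raw <- raw + sum(w[lo:hi])
    }
    H[p, q] <- H[q, p] <- if (self_raw > 0) raw / self_raw
                          else as.numeric(all(ibs))
  }
  aip_similarity(H, coding$labels, "score", i)
}

## cM positions of the markers used in a coding's patterns
score_positions <- function(coding) {
  if (!is.null(coding$positions_cM)) return(coding$positions_cM)
  stop("coding lacks marker positions; build it with code_haplotypes()")
}

#' Coalescent IBD probability predictor
#'
#' Conditional probability that a pair of chromosome segments is IBD at the
#' tested position, given the IBS status of the window's marker alleles.
#' The model: the two lineages coalesce \code{tau} generations ago with
#' probability \code{(1/2Ne)(1 - 1/2Ne)^(tau-1)} truncated at \code{T}
#' generations (no IBD beyond the base population); given coalescence, the
#' IBD tract around the tested point extends on each flank by an
#' exponential length with rate \code{2 tau} per Morgan (Haldane, no
#' interference).  Markers inside the tract are IBS with certainty;
#' markers outside are IBS by chance with probability equal to their
#' homozygosity.  Bayes inversion over the observed IBS pattern gives
#' P(IBD | pattern).  Results are cached per IBS pattern, since only the
#' pattern enters the computation.
#'
#' @param coding a window coding from \code{\link{code_haplotypes}}.
#' @param Ne ancestral effective population size (default 100).
#' @param T generations since the base population (default 100).
#' @return an \code{aip_similarity}.
#' @export
p_ibd <- function(coding, Ne = 100, T = 100) {
  stopifnot(Ne > 0, T > 0)
  pm <- coding$pattern_mat
  k <- nrow(pm)
  i <- coding$window$tested_pos_cM
  pos <- score_positions(coding)
  ## chance IBS = marker homozygosity from panel haplotype frequencies
  p1 <- as.numeric(coding$freqs %*% pm)
  hom <- p1^2 + (1 - p1)^2
  left <- which(pos < i); right <- which(pos >= i)
  left <- left[order(i - pos[left])]          # ascending distance from i
  right <- right[order(pos[right] - i)]
  dl <- (i - pos[left]) / 100                 # Morgans
  dr <- (pos[right] - i) / 100
  cache <- new.env(parent = emptyenv())
  H <- matrix(0, k, k)
  for (p in 1:k) for (q in p:k) {
    ibs <- pm[p, ] == pm[q, ]
    key <- paste(as.integer(ibs), collapse = "")
    val <- cache[[key]]
    if (is.null(val)) {
      val <- pibd_pattern(ibs[left], dl, hom[left],
                          ibs[right], dr, hom[right], Ne, T)
      cache[[key]] <- val
    }
    H[p, q] <- H[q, p] <- val
  }
  aip_similarity(H, coding$labels, "pibd", i)
}

## Analytic P(IBD at the focal point | IBS pattern) under the tract model.
pibd_pattern <- function(ibs_l, d_l, c_l, ibs_r, d_r, c_r, Ne, T) {
  tau <- seq_len(T)
  prior <- (1 / (2 * Ne)) * (1 - 1 / (2 * Ne))^(tau - 1)
  p_non <- (1 - 1 / (2 * Ne))^T
  side <- function(ibs, d, h) {
    K <- length(ibs)
    if (K == 0L) return(rep(1, length(tau)))
    cm <- ifelse(ibs, h, 1 - h)               # chance term per marker
    suffix <- rev(cumprod(rev(c(cm, 1))))     # prod of chance terms m>k
    ok <- c(TRUE, cumprod(ibs) > 0)           # all of s_1..s_k IBS
    edges <- exp(-2 * outer(tau, c(0, d)))    # survival to each boundary
    width <- cbind(edges[, 1:K, drop = FALSE] -
                   edges[, -1, drop = FALSE], edges[, K + 1L])
    as.numeric(width %*% (ok * suffix))
  }
  lik_ibd <- side(ibs_l, d_l, c_l) * side(ibs_r, d_r, c_r)
  lik_non <- prod(ifelse(c(ibs_l, ibs_r), c(c_l, c_r), 1 - c(c_l, c_r)))
  num <- sum(prior * lik_ibd)
  num / (num + p_non * lik_non)
}

#' Train the least-squares trained predictor (TP)
#'
#' Target SNPs are the middle markers of sliding windows of \code{t + 1}
#' loci.  For every unordered pair of flanking t-marker patterns observed
#' at one or more target SNPs, TP stores the frequency-weighted average of
#' the proportion of chromosome pairs carrying those patterns that share
#' the allele at the target SNP; this is the least-squares minimizer of
#' the mean squared prediction error over target SNPs.
#'
#' @param panel a \code{haplotype_panel}.
#' @param t flanking-marker count (even).
#' @param exclude marker indices never used as target SNPs nor flanking
#'   markers (e.g. a hidden QTL).
#' @return a \code{tp_table}: lookup environment plus global fallback mean.
#' @export
train_tp <- function(panel, t, exclude = integer(0)) {
  stopifnot(t %% 2L == 0L, n_markers(panel) >= t + 1L)
  use <- setdiff(seq_len(n_markers(panel)), exclude)
  sub <- subset_markers(panel, use)
  m <- n_markers(sub)
  if (m < t + 1L) stop("not enough markers after exclusions")
  num <- new.env(parent = emptyenv())
  den <- new.env(parent = emptyenv())
  targets <- (t %/% 2L + 1L):(m - t %/% 2L)
  for (j in targets) {
    coding <- code_haplotypes(sub,
                              list(marker_indices = (j - t %/% 2L):(j + t %/% 2L),
                                   tested_pos_cM = sub$positions_cM[j]),
                              exclude = j)
    ## joint counts of (pattern, target allele)
    al <- sub$alleles[, j]
    k <- length(coding$freqs)
    N1 <- as.numeric(tapply(al, coding$labels, sum))
    Np <- as.numeric(tabulate(coding$labels, nbins = k))
    N0 <- Np - N1
    f <- coding$freqs
    for (p in 1:k) for (q in p:k) {
      pshare <- (N1[p] * N1[q] + N0[p] * N0[q]) / (Np[p] * Np[q])
      key <- tp_key(coding$patterns[p], coding$patterns[q])
      w <- f[p] * f[q]
      num[[key]] <- (if (is.null(num[[key]])) 0 else num[[key]]) + w * pshare
      den[[key]] <- (if (is.null(den[[key]])) 0 else den[[key]]) + w
    }
  }
  keys <- ls(num)
  est <- new.env(parent = emptyenv())
  tot_num <- 0; tot_den <- 0
  for (key in keys) {
    est[[key]] <- num[[key]] / den[[key]]
    tot_num <- tot_num + num[[key]]
    tot_den <- tot_den + den[[key]]
  }
  structure(list(estimates = est, weights = den, t = as.integer(t),
                 n_targets = length(targets),
                 global_mean = tot_num / tot_den),
            class = "tp_table")
}

tp_key <- function(a, b) if (a <= b) paste(a, b, sep = "|") else
  paste(b, a, sep = "|")

#' @method print tp_table
#' @export
print.tp_table <- function(x, ...) {
  cat("tp_table: t =", x$t, ",", length(ls(x$estimates)),
      "pattern pairs from", x$n_targets, "target SNPs; global mean",
      format(x$global_mean, digits = 4), "\n")
  invisible(x)
}

#' Look up a trained-predictor estimate for one unordered pattern pair
#' @param table a \code{tp_table}.
#' @param pattern_a,pattern_b t-length 0/1 pattern strings.
#' @return the stored estimate, or the fallback (1 for identical unseen
#'   patterns, the training-weighted global mean otherwise).
#' @export
tp_lookup <- function(table, pattern_a, pattern_b) {
  v <- table$estimates[[tp_key(pattern_a, pattern_b)]]
  if (!is.null(v)) return(v)
  if (pattern_a == pattern_b) 1 else table$global_mean
}

#' Trained-predictor similarity at a tested position
#' @param table a \code{tp_table} from \code{\link{train_tp}}.
#' @param coding a window coding with the same window size \code{t}.
#' @return an \code{aip_similarity}.
#' @export
tp_predict <- function(table, coding) {
  k <- length(coding$freqs)
  H <- matrix(0, k, k)
  for (p in 1:k) for (q in p:k)
    H[p, q] <- H[q, p] <- tp_lookup(table, coding$patterns[p],
                                    coding$patterns[q])
  aip_similarity(H, coding$labels, "tp", coding$window$tested_pos_cM)
}

#' Ingest per-marker cluster assignments from an external clustering tool
#'
#' The file is a whitespace-delimited integer matrix, one row per
#' chromosome (2n rows) and one column per marker, with a header row of
#' marker ids.  At a tested marker, chromosomes in the same local cluster
#' are predicted identical (H = identity over distinct clusters).
#'
#' @param path cluster file path.
#' @param panel the matching \code{haplotype_panel}.
#' @return integer matrix of labels (2n x m) with marker ids as colnames.
#' @export
load_cluster_aip <- function(path, panel) {
  lab <- utils::read.table(path, header = TRUE, check.names = FALSE)
  lab <- as.matrix(lab)
  if (nrow(lab) != nrow(panel$alleles) || ncol(lab) != n_markers(panel))
    stop("cluster label matrix is ", nrow(lab), " x ", ncol(lab),
         " but the panel needs ", nrow(panel$alleles), " x ",
         n_markers(panel))
  storage.mode(lab) <- "integer"
  lab
}

#' Cluster-based predictor at one marker
#' @param cluster_labels label matrix from \code{\link{load_cluster_aip}}
#'   (or any 2n x m integer matrix).
#' @param panel the matching \code{haplotype_panel}.
#' @param marker_index tested marker.
#' @return an \code{aip_similarity} (identity over the local clusters).
#' @export
cluster_aip <- function(cluster_labels, panel, marker_index) {
  raw <- cluster_labels[, marker_index]
  seen <- unique(raw)
  labels <- match(raw, seen)
  aip_similarity(diag(length(seen)), labels, "cluster",
                 panel$positions_cM[marker_index])
}
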