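#' True allelic identity at a (hidden) QTL marker
#'
#' @param panel a \code{haplotype_panel}.
#' @param qtl_marker_index the marker playing the biallelic QTL.
#' @return list with \code{qtl_alleles} (length 2n), \code{M_QTL}
#'   (2n x 2n 0/1 identity-by-state matrix, diagonal 1),
#'   \code{qtl_pos_cM} and \code{qtl_index}.
#' @export
qtl_truth <- function(panel, qtl_marker_index) {
  a <- panel$alleles[, qtl_marker_index]
  M <- outer(a, a, function(x, y) as.numeric(x == y))
  list(qtl_alleles = a, M_QTL = M,
       qtl_pos_cM = panel$positions_cM[qtl_marker_index],
       qtl_index = as.integer(qtl_marker_index))
}

#' Matrix distance between a predictor similarity and the QTL truth
#'
#' The normalized entrywise 1-norm
#' \code{d1 = (1 / 4n^2) * sum |M - M_QTL|}, diagonal included.
#'
#' @param M 2n x 2n predictor similarity matrix.
#' @param M_QTL 2n x 2n true 0/1 identity matrix.
#' @return scalar distance in [0, 1].
#' @export
d1_pairwise <- function(M, M_QTL) {
  if (!all(dim(M) == dim(M_QTL))) stop("matrix shape mismatch")
  sum(abs(M - M_QTL)) / (nrow(M)^2)
}

#' Matrix distance from haplotype frequencies and allele-sharing proportions
#'
#' Frequency form of the matrix distance:
#' \code{d1 = sum_pq f_p f_q [ p_pq (1 - s_pq) + (1 - p_pq) s_pq ]}, where
#' \code{p_pq} is the proportion of chromosome pairs carrying patterns
#' (p, q) that share the allele at the QTL and \code{s_pq} the predictor's
#' prediction.  Identical to \code{\link{d1_pairwise}} of the expanded
#' matrices.
#'
#' @param freqs haplotype frequencies (length kappa).
#' @param H kappa x kappa prediction matrix.
#' @param p_share kappa x kappa allele-sharing proportion matrix.
#' @return scalar distance.
#' @export
d1_frequency <- function(freqs, H, p_share) {
  ff <- outer(freqs, freqs)
  sum(ff * (p_share * (1 - H) + (1 - p_share) * H))
}

#' Matrix distance from the joint haplotype x QTL-allele frequency table
#'
#' Joint-frequency form (biallelic truth locus):
#' \code{d1 = sum_pq (j_p1 j_q1 + j_p2 j_q2)(1 - s_pq) +
#'                  (j_p1 j_q2 + j_p2 j_q1) s_pq}.
#'
#' @param joint kappa x 2 joint frequency table (rows: haplotypes,
#'   columns: QTL alleles), summing to 1.
#' @param H kappa x kappa prediction matrix.
#' @return scalar distance.
#' @export
d1_joint <- function(joint, H) {
  joint <- as.matrix(joint)
  if (ncol(joint) != 2L)
    stop("d1_joint requires a biallelic truth locus; use d1_frequency for ",
         "more alleles")
  same <- joint[, 1L] %o% joint[, 1L] + joint[, 2L] %o% joint[, 2L]
  diff <- joint[, 1L] %o% joint[, 2L] + joint[, 2L] %o% joint[, 1L]
  sum(same * (1 - H) + diff * H)
}

#' Joint LD state between a window's haplotypes and a QTL
#'
#' Computes the joint haplotype x QTL-allele frequencies, the LD
#' coefficients \code{Delta_p = f(h_p, a1) - f(h_p) f(a1)}, the summary
#' measures \code{D2 = 2 sum Delta_p^2} and
#' \code{R = D2 / (H_i * H_QTL)} (0 when either heterozygosity is 0), and
#' the allele-sharing proportions \code{p_share} used by the
#' frequency form of the matrix distance.  The QTL marker is always
#' excluded from the window's haplotype patterns.
#'
#' @param panel a \code{haplotype_panel}.
#' @param window a window spec (or marker index vector).
#' @param qtl a truth object from \code{\link{qtl_truth}}.
#' @return list with \code{coding}, \code{joint}, \code{hap_marg},
#'   \code{allele_marg}, \code{delta}, \code{D2}, \code{H_i},
#'   \code{H_QTL}, \code{R}, \code{p_share}.
#' @export
ld_state <- function(panel, window, qtl) {
  coding <- code_haplotypes(panel, window, exclude = qtl$qtl_index)
  ld_state_from_coding(coding, qtl)
}

## LD state given an existing window coding (QTL already excluded).
ld_state_from_coding <- function(coding, qtl) {
  out <- ld_state_from_labels(coding$labels, length(coding$freqs), qtl)
  out$coding <- coding
  out
}

## LD state from bare class labels (haplotypes or clusters) at a position.
ld_state_from_labels <- function(labels, k, qtl) {
  a <- qtl$qtl_alleles
  n_chrom <- length(labels)
  N1 <- as.numeric(tapply(a, factor(labels, levels = seq_len(k)), sum))
  N1[is.na(N1)] <- 0
  Np <- as.numeric(tabulate(labels, nbins = k))
  joint <- cbind(a1 = (Np - N1) / n_chrom, a2 = N1 / n_chrom)
  ## allele "a1" is code 0, "a2" is code 1; order is immaterial to R/D2
  hap_marg <- rowSums(joint)
  allele_marg <- colSums(joint)
  delta <- joint[, 1L] - hap_marg * allele_marg[1L]
  D2 <- 2 * sum(delta^2)
  H_i <- 1 - sum(hap_marg^2)
  H_QTL <- 1 - sum(allele_marg^2)
  R <- if (H_i <= 0 || H_QTL <= 0) 0 else D2 / (H_i * H_QTL)
  p_share <- (joint[, 1L] %o% joint[, 1L] + joint[, 2L] %o% joint[, 2L]) /
    (hap_marg %o% hap_marg)
  list(joint = joint, hap_marg = hap_marg,
       allele_marg = allele_marg, delta = delta, D2 = D2,
       H_i = H_i, H_QTL = H_QTL, R = R, p_share = p_share)
}

#' LD profile of a region around a fixed SNP
#'
#' Slides a \code{window_size}-marker window across a
#' \code{region_size}-marker region centered on a fixed SNP (playing the
#' QTL) and records, for each of the \code{region_size - window_size + 1}
#' tested positions, the multiallelic LD between the window's haplotypes
#' and the SNP's alleles.  The fixed SNP is excluded from every window's
#' haplotype patterns.
#'
#' @param panel a \code{haplotype_panel}.
#' @param region_size odd region size so the SNP is its center marker.
#' @param window_size even sliding-window size.
#' @param fixed_snp panel marker index of the fixed SNP.
#' @return data.frame with \code{offset} (window number),
#'   \code{tested_pos_cM}, \code{dist_cM} (tested position minus SNP
#'   position), \code{R}, \code{D2}.
#' @export
ld_profile <- function(panel, region_size, window_size, fixed_snp) {
  if (region_size %% 2L != 1L) stop("region_size must be odd")
  if (window_size %% 2L != 0L) stop("window_size must be even")
  h <- (region_size - 1L) %/% 2L
  lo <- fixed_snp - h; hi <- fixed_snp + h
  if (lo < 1L || hi > n_markers(panel))
    stop("region of ", region_size, " markers around marker ", fixed_snp,
         " exceeds the panel")
  qtl <- qtl_truth(panel, fixed_snp)
  starts <- lo:(hi - window_size + 1L)
  out <- lapply(seq_along(starts), function(k) {
    idx <- starts[k]:(starts[k] + window_size - 1L)
    st <- ld_state(panel, window_spec(panel, idx), qtl)
    data.frame(offset = k,
               tested_pos_cM = st$coding$window$tested_pos_cM,
               dist_cM = st$coding$window$tested_pos_cM - qtl$qtl_pos_cM,
               R = st$R, D2 = st$D2)
  })
  do.call(rbind, out)
}

#' Enumerate the fixed-SNP regions of a panel
#'
#' Centers of every \code{region_size}-marker region that fits in the
#' panel: markers \code{(region_size+1)/2 .. m - (region_size-1)/2}, i.e.
#' \code{m - region_size + 1} regions.
#'
#' @param panel a \code{haplotype_panel}.
#' @param region_size odd region size.
#' @return integer vector of center marker indices.
#' @export
enumerate_regions <- function(panel, region_size) {
  if (region_size %% 2L != 1L) stop("region_size must be odd")
  m <- n_markers(panel)
  if (region_size > m) stop("region exceeds the panel")
  h <- (region_size - 1L) %/% 2L
  (h + 1L):(m - h)
}

#' Mean LD profile over all regions of a panel
#'
#' Applies \code{\link{ld_profile}} to every possible
#' \code{region_size}-marker region (\code{m - region_size + 1} regions)
#' and averages R and D2 per window offset.
#'
#' @inheritParams ld_profile
#' @return data.frame with \code{offset}, \code{mean_dist_cM},
#'   \code{mean_R}, \code{mean_D2}, and \code{n_regions} as an attribute.
#' @export
mean_ld_profiles <- function(panel, region_size, window_size) {
  centers <- enumerate_regions(panel, region_size)
  if (!length(centers)) stop("panel shorter than one region")
  acc <- NULL
  for (c0 in centers) {
    pr <- ld_profile(panel, region_size, window_size, c0)
    if (is.null(acc)) {
      acc <- pr[, c("offset", "dist_cM", "R", "D2")]
    } else {
      acc$dist_cM <- acc$dist_cM + pr$dist_cM
      acc$R <- acc$R + pr$R
      acc$D2 <- acc$D2 + pr$D2
    }
  }
  n <- length(centers)
  out <- data.frame(offset = acc$offset, mean_dist_cM = acc$dist_cM / n,
                    mean_R = acc$R / n, mean_D2 = acc$D2 / n)
  attr(out, "n_regions") <- n
  out
}

## Two-haplotype joint table at LD coefficient delta with fixed marginals.
two_hap_joint <- function(hap_marg, allele_marg, delta) {
  joint <- outer(hap_marg, allele_marg) +
    delta * matrix(c(1, -1, -1, 1), 2L, 2L)
  if (any(joint < -1e-12) || any(joint > 1 + 1e-12))
    stop("infeasible LD coefficient ", delta, " for the given marginals")
  pmin(pmax(joint, 0), 1)
}

#' Matrix distance as a quadratic in the LD coefficient (two haplotypes)
#'
#' With exactly two observed haplotypes and a biallelic truth locus the
#' matrix distance is an exact quadratic in the single LD coefficient
#' \code{Delta_1}.  The quadratic is recovered numerically: joint tables
#' with fixed marginals are built at three or more probe values of
#' \code{Delta_1}, the joint-form distance is evaluated at each, and the
#' interpolating quadratic is fitted exactly.  Its leading coefficient
#' equals \code{-4 s11 - 4 s22 + 8 s12}; for the haplotype-IBS predictor
#' (H = identity) it is -8.
#'
#' @param H2 2 x 2 prediction matrix.
#' @param hap_marg haplotype marginal frequencies (length 2, sum 1).
#' @param allele_marg truth-allele marginal frequencies (length 2, sum 1).
#' @param probe_deltas at least 3 distinct feasible Delta_1 values.
#' @return list with coefficients \code{a}, \code{b}, \code{c}, the
#'   \code{critical_value} \code{-b / 2a}, and the probe values.
#' @export
xi_two_hap <- function(H2, hap_marg, allele_marg,
                       probe_deltas = default_probes(hap_marg, allele_marg)) {
  H2 <- as.matrix(H2)
  stopifnot(all(dim(H2) == c(2L, 2L)), length(hap_marg) == 2L,
            length(allele_marg) == 2L)
  probe_deltas <- unique(probe_deltas)
  if (length(probe_deltas) < 3L)
    stop("need at least 3 distinct probe values of Delta_1")
  vals <- vapply(probe_deltas, function(d)
    d1_joint(two_hap_joint(hap_marg, allele_marg, d), H2), numeric(1L))
  V <- cbind(probe_deltas^2, probe_deltas, 1)
  coef <- unname(if (length(probe_deltas) == 3L) solve(V, vals)
                 else qr.coef(qr(V), vals))
  fit <- as.numeric(V %*% coef)
  if (max(abs(fit - vals)) > 1e-9)
    stop("quadratic interpolation failed (probes collinear or degenerate)")
  list(a = coef[1L], b = coef[2L], c = coef[3L],
       critical_value = -coef[2L] / (2 * coef[1L]),
       probes = probe_deltas, values = vals)
}

default_probes <- function(hap_marg, allele_marg) {
  ## feasibility: all four joint entries must stay in [0, 1]
  lo <- max(-hap_marg[1L] * allele_marg[1L], -hap_marg[2L] * allele_marg[2L])
  hi <- min(hap_marg[1L] * allele_marg[2L], hap_marg[2L] * allele_marg[1L])
  c(lo, (lo + hi) / 2, hi)
}

#' Matrix distance at complete LD for a two-haplotype predictor
#'
#' With equal marginals (0.5 / 0.5) the extreme feasible LD coefficients
#' are Delta_1 = -1/4 and +1/4, where LD between the two haplotypes and
#' the truth alleles is complete.  Evaluates the matrix distance at both
#' extremes, reports the lower bound \code{s12 / 2} attained by
#' near-identical haplotype pairs, and whether the distance vanishes
#' (which characterizes the haplotype-IBS predictor).
#'
#' @param H2 2 x 2 prediction matrix (diagonal 1 for the discrete
#'   predictors; \code{s12} is the off-diagonal prediction).
#' @return list with \code{value_minus}, \code{value_plus} (d1 at
#'   Delta_1 = -1/4 and 1/4), \code{bound} (\code{s12 / 2}) and
#'   \code{is_zero}.
#' @export
xi_bound_check <- function(H2) {
  H2 <- as.matrix(H2)
  marg <- c(0.5, 0.5)
  vm <- d1_joint(two_hap_joint(marg, marg, -0.25), H2)
  vp <- d1_joint(two_hap_joint(marg, marg, 0.25), H2)
  list(value_minus = vm, value_plus = vp, bound = H2[1L, 2L] / 2,
       is_zero = max(vm, vp) < 1e-12)
}

#' Matrix distance at every tested position of a region (d1 profile)
#'
#' For each sliding window over \code{region_markers} (QTL marker hidden
#' unless \code{include_qtl}), computes the predictor's similarity and its
#' matrix distance to the QTL truth via the frequency form.  For the
#' single-marker predictors (\code{ibs_m}, \code{cluster}) the tested
#' positions are the region's marker positions instead of window centers.
#'
#' @param panel a \code{haplotype_panel} (full marker set, QTL included).
#' @param qtl a truth object from \code{\link{qtl_truth}}.
#' @param predictor one of \code{"ibs_m"}, \code{"ibs_hap"},
#'   \code{"score"}, \code{"pibd"}, \code{"tp"}, \code{"cluster"}.
#' @param window_size even window size (window predictors).
#' @param region_markers marker indices scanned (default: all markers).
#' @param include_qtl keep the QTL marker observable (gold-standard mode).
#' @param tp_table trained table for \code{predictor = "tp"}.
#' @param cluster_labels label matrix for \code{predictor = "cluster"}.
#' @param Ne,T coalescent parameters for \code{predictor = "pibd"}.
#' @return data.frame with \code{position_cM}, \code{d1}, \code{R}.
#' @export
d1_profile <- function(panel, qtl, predictor, window_size = 6L,
                       region_markers = seq_len(n_markers(panel)),
                       include_qtl = FALSE, tp_table = NULL,
                       cluster_labels = NULL, Ne = 100, T = 100) {
  marker_based <- predictor %in% c("ibs_m", "cluster")
  region_markers <- sort(as.integer(region_markers))
  hidden <- if (include_qtl) region_markers
            else setdiff(region_markers, qtl$qtl_index)
  rows <- list()
  if (marker_based) {
    for (j in hidden) {
      sim <- if (predictor == "ibs_m") ibs_m(panel, j)
             else cluster_aip(cluster_labels, panel, j)
      st <- ld_state_from_labels(sim$labels, nrow(sim$H), qtl)
      rows[[length(rows) + 1L]] <-
        data.frame(position_cM = panel$positions_cM[j],
                   d1 = d1_frequency(st$hap_marg, sim$H, st$p_share),
                   R = st$R)
    }
  } else {
    if (length(hidden) < window_size) return(empty_d1_profile())
    for (s in seq_len(length(hidden) - window_size + 1L)) {
      idx <- hidden[s:(s + window_size - 1L)]
      win <- window_spec(panel, idx)
      coding <- code_haplotypes(panel, win)
      sim <- switch(predictor,
                    ibs_hap = ibs_hap(coding),
                    score = score_li_jiang(coding),
                    pibd = p_ibd(coding, Ne = Ne, T = T),
                    tp = tp_predict(tp_table, coding),
                    stop("unknown predictor: ", predictor))
      st <- ld_state_from_coding(coding, qtl)
      rows[[length(rows) + 1L]] <-
        data.frame(position_cM = win$tested_pos_cM,
                   d1 = d1_frequency(coding$freqs, sim$H, st$p_share),
                   R = st$R)
    }
  }
  if (!length(rows)) return(empty_d1_profile())
  do.call(rbind, rows)
}

empty_d1_profile <- function()
  data.frame(position_cM = numeric(0), d1 = numeric(0), R = numeric(0))

#' Matrix distance against multiallelic LD at every target SNP
#'
#' For every target SNP (middle marker of a sliding window of
#' \code{window_size + 1} loci), treats the SNP as a hidden biallelic QTL,
#' computes each requested predictor's matrix distance at the surrounding
#' window, and the multiallelic LD \code{R} between the window's
#' haplotypes and the SNP's alleles.  Marker-based predictors are
#' evaluated at the nearest flanking marker.
#'
#' @param panel a \code{haplotype_panel}.
#' @param window_size even flanking window size.
#' @param predictors character vector of predictor names.
#' @param tp_table optional pre-trained \code{tp_table}; trained on the
#'   panel when requested and missing.
#' @param cluster_labels label matrix for the cluster predictor.
#' @param Ne,T coalescent parameters for \code{"pibd"}.
#' @return data.frame with one row per target SNP: \code{target_snp},
#'   \code{position_cM}, \code{R}, and one \code{d1_<predictor>} column
#'   per predictor.
#' @export
distance_vs_ld <- function(panel, window_size = 6L,
                           predictors = c("ibs_hap", "score", "pibd", "tp"),
                           tp_table = NULL, cluster_labels = NULL,
                           Ne = 100, T = 100) {
  t <- as.integer(window_size)
  stopifnot(t %% 2L == 0L)
  m <- n_markers(panel)
  if ("tp" %in% predictors && is.null(tp_table))
    tp_table <- train_tp(panel, t)
  targets <- (t %/% 2L + 1L):(m - t %/% 2L)
  out <- vector("list", length(targets))
  for (k in seq_along(targets)) {
    j <- targets[k]
    qtl <- qtl_truth(panel, j)
    win <- list(marker_indices = (j - t %/% 2L):(j + t %/% 2L),
                tested_pos_cM = panel$positions_cM[j])
    coding <- code_haplotypes(panel, win, exclude = j)
    st <- ld_state_from_coding(coding, qtl)
    row <- data.frame(target_snp = j, position_cM = panel$positions_cM[j],
                      R = st$R)
    for (p in predictors) {
      if (p %in% c("ibs_m", "cluster")) {
        near <- c(j - 1L, j + 1L)
        near <- near[which.min(abs(panel$positions_cM[near] -
                                   panel$positions_cM[j]))]
        sim <- if (p == "ibs_m") ibs_m(panel, near)
               else cluster_aip(cluster_labels, panel, near)
        d1 <- d1_pairwise(expand_to_M(sim), qtl$M_QTL)
      } else {
        sim <- switch(p,
                      ibs_hap = ibs_hap(coding),
                      score = score_li_jiang(coding),
                      pibd = p_ibd(coding, Ne = Ne, T = T),
                      tp = tp_predict(tp_table, coding),
                      stop("unknown predictor: ", p))
        d1 <- d1_frequency(coding$freqs, sim$H, st$p_share)
      }
      row[[paste0("d1_", p)]] <- d1
    }
    out[[k]] <- row
  }
  do.call(rbind, out)
}
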