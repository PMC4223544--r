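## Build all predictor similarity matrices for a window of a panel.
all_sims <- function(panel, coding, tp_table) {
  list(ibs_hap(coding), score_li_jiang(coding),
       p_ibd(coding, Ne = 50, T = 50), tp_predict(tp_table, coding))
}

test_that("QTL truth matrices encode allele identity", {
  p <- haplotype_panel(cbind(c(0L, 0L, 1L, 1L)), 0.5)
  q <- qtl_truth(p, 1L)
  expect_equal(q$M_QTL, rbind(c(1, 1, 0, 0), c(1, 1, 0, 0),
                              c(0, 0, 1, 1), c(0, 0, 1, 1)))
  mono <- haplotype_panel(cbind(rep(1L, 4L)), 0.5)
  expect_equal(qtl_truth(mono, 1L)$M_QTL, matrix(1, 4, 4))
  pr <- random_panel(14L, 3L, seed = 5L)
  qr <- qtl_truth(pr, 2L)
  a <- pr$alleles[, 2]
  for (c1 in 1:14) for (c2 in 1:14)
    expect_equal(qr$M_QTL[c1, c2], as.numeric(a[c1] == a[c2]))
  expect_equal(diag(qr$M_QTL), rep(1, 14))
})

test_that("pairwise matrix distance matches the naive double sum", {
  M <- matrix(1, 2, 2)
  expect_equal(d1_pairwise(M, M), 0)
  expect_equal(d1_pairwise(matrix(1, 2, 2), diag(2)), 0.5)
  set.seed(6)
  A <- matrix(runif(64), 8, 8); B <- matrix(rbinom(64, 1, 0.5), 8, 8)
  expect_equal(d1_pairwise(A, B), naive_d1(A, B), tolerance = 1e-14)
  expect_error(d1_pairwise(matrix(0, 2, 2), matrix(0, 3, 3)), "mismatch")
})

test_that("the three matrix-distance formulations agree to 1e-12", {
  ## master oracle on random panels and all predictor types
  worst <- 0
  for (s in 1:50) {
    p <- random_panel(12L, 8L, spacing = 0.15, seed = s)
    qtl <- qtl_truth(p, 4L)
    tab <- train_tp(p, 6L, exclude = 4L)
    win <- list(marker_indices = 1:7, tested_pos_cM = p$positions_cM[4])
    st <- ld_state(p, win, qtl)
    cd <- st$coding
    for (sim in all_sims(p, cd, tab)) {
      M <- expand_to_M(sim)
      d_pw <- d1_pairwise(M, qtl$M_QTL)
      d_fr <- d1_frequency(cd$freqs, sim$H, st$p_share)
      d_jt <- d1_joint(st$joint, sim$H)
      worst <- max(worst, abs(d_pw - d_fr), abs(d_pw - d_jt))
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("joint-form distance behaves at complete LD and independence", {
  ## complete LD with haplotype IBS: distance 0
  expect_equal(d1_joint(rbind(c(0.5, 0), c(0, 0.5)), diag(2)), 0)
  ## degenerate one-haplotype case with perfect prediction
  expect_equal(d1_joint(rbind(c(1, 0)), matrix(1, 1, 1)), 0)
  ## independence: verified against the pairwise form on a constructed
  ## panel where the window and the QTL are unassociated
  alle <- cbind(rep(c(0L, 1L), each = 8L),          # window marker
                rep(c(0L, 1L), times = 8L))          # QTL, orthogonal
  p <- haplotype_panel(alle, c(0, 0.5))
  qtl <- qtl_truth(p, 2L)
  cd <- code_haplotypes(p, list(marker_indices = 1L, tested_pos_cM = 0.25))
  st <- ld_state_from <- ld_state(p, list(marker_indices = 1:2,
                                          tested_pos_cM = 0.25), qtl)
  expect_equal(st$joint, outer(st$hap_marg, st$allele_marg),
               ignore_attr = TRUE)
  H <- diag(2)
  expect_equal(d1_joint(st$joint, H),
               d1_pairwise(expand_to_M(H, st$coding$labels), qtl$M_QTL),
               tolerance = 1e-12)
  ## more than two truth alleles are refused
  expect_error(d1_joint(matrix(1 / 6, 2, 3), diag(2)), "biallelic")
})

test_that("LD state reproduces the printed hand example and its identities", {
  ## two haplotypes at 0.5/0.5, QTL alleles 0.5/0.5, perfect association
  alle <- cbind(rep(c(0L, 1L), each = 4L),
                rep(c(0L, 1L), each = 4L))
  p <- haplotype_panel(alle, c(0, 0.5))
  qtl <- qtl_truth(p, 2L)
  st <- ld_state(p, list(marker_indices = 1:2, tested_pos_cM = 0.25), qtl)
  expect_equal(abs(st$delta[1]), 0.25)
  expect_equal(st$D2, 0.25)
  expect_equal(st$H_i, 0.5)
  expect_equal(st$H_QTL, 0.5)
  expect_equal(st$R, 1)
  ## invariants on random panels
  for (s in 1:25) {
    p <- random_panel(16L, 7L, seed = 100L + s)
    qtl <- qtl_truth(p, 4L)
    st <- ld_state(p, list(marker_indices = 1:7,
                           tested_pos_cM = p$positions_cM[4]), qtl)
    expect_lt(abs(sum(st$delta)), 1e-12)
    expect_equal(st$D2, 2 * sum(st$delta^2))
    expect_gte(st$R, 0); expect_lte(st$R, 1 + 1e-12)
    expect_equal(sum(st$joint), 1, tolerance = 1e-12)
    expect_equal(rowSums(st$joint), st$hap_marg, ignore_attr = TRUE)
    expect_equal(colSums(st$joint), st$allele_marg, ignore_attr = TRUE)
    ## R is invariant to reversing chromosome order (haplotype relabeling)
    pr <- haplotype_panel(p$alleles[16:1, ], p$positions_cM)
    str <- ld_state(pr, list(marker_indices = 1:7,
                             tested_pos_cM = p$positions_cM[4]),
                    qtl_truth(pr, 4L))
    expect_equal(str$R, st$R, tolerance = 1e-12)
    ## R is invariant to flipping the QTL allele coding
    pf <- p; pf$alleles[, 4] <- 1L - pf$alleles[, 4]
    stf <- ld_state(pf, list(marker_indices = 1:7,
                             tested_pos_cM = p$positions_cM[4]),
                    qtl_truth(pf, 4L))
    expect_equal(stf$R, st$R, tolerance = 1e-12)
  }
})

test_that("LD profiles have the expected geometry and averages", {
  p <- random_panel(30L, 85L, spacing = 0.05, seed = 77L)
  pr <- ld_profile(p, 81L, 6L, fixed_snp = 43L)
  expect_equal(nrow(pr), 76L)
  expect_error(ld_profile(p, 80L, 6L, 43L), "odd")
  expect_error(ld_profile(p, 81L, 5L, 43L), "even")
  expect_error(ld_profile(p, 81L, 6L, 10L), "exceeds")
  ## unstructured panel: profiles stay small everywhere (R has a positive
  ## finite-sample bias, so compare against a loose cap)
  expect_lt(max(pr$R), 0.6)
  expect_lt(mean(pr$R), 0.35)
  ## single-region mean equals that region's profile
  p81 <- random_panel(20L, 81L, spacing = 0.05, seed = 78L)
  mp <- mean_ld_profiles(p81, 81L, 6L)
  expect_equal(attr(mp, "n_regions"), 1L)
  pr81 <- ld_profile(p81, 81L, 6L, fixed_snp = 41L)
  expect_equal(mp$mean_R, pr81$R)
  expect_equal(mp$mean_D2, pr81$D2)
  ## multi-region mean equals the brute-force average of region profiles
  pm <- random_panel(16L, 89L, spacing = 0.05, seed = 79L)
  mp2 <- mean_ld_profiles(pm, 81L, 6L)
  expect_equal(attr(mp2, "n_regions"), 9L)
  manual <- Reduce(`+`, lapply(41:49, function(c0)
    ld_profile(pm, 81L, 6L, c0)$R)) / 9
  expect_equal(mp2$mean_R, manual, tolerance = 1e-12)
})

test_that("the quadratic in the LD coefficient has the predicted leading term", {
  ## haplotype IBS: coefficient exactly -8
  xt <- xi_two_hap(diag(2), c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(xt$a, -8, tolerance = 1e-9)
  ## and for skewed marginals too
  xt2 <- xi_two_hap(diag(2), c(0.3, 0.7), c(0.6, 0.4))
  expect_equal(xt2$a, -8, tolerance = 1e-9)
  ## all-ones predictions: the quadratic term vanishes
  xt3 <- xi_two_hap(matrix(1, 2, 2), c(0.5, 0.5), c(0.5, 0.5))
  expect_lt(abs(xt3$a), 1e-9)
  ## random continuous predictors match the closed form -4s11 -4s22 +8s12
  set.seed(31)
  for (r in 1:25) {
    s11 <- runif(1); s22 <- runif(1); s12 <- runif(1)
    H <- matrix(c(s11, s12, s12, s22), 2, 2)
    hm <- runif(1, 0.2, 0.8); am <- runif(1, 0.2, 0.8)
    xt <- xi_two_hap(H, c(hm, 1 - hm), c(am, 1 - am))
    expect_equal(xt$a, -4 * s11 - 4 * s22 + 8 * s12, tolerance = 1e-9)
    ## the fitted quadratic reproduces d1 at a probe inside the range
    mid <- mean(range(xt$probes))
    expect_equal(xt$a * mid^2 + xt$b * mid + xt$c,
                 d1_joint(rbind(c(hm * am + mid, hm * (1 - am) - mid),
                                c((1 - hm) * am - mid,
                                  (1 - hm) * (1 - am) + mid)), H),
                 tolerance = 1e-9)
  }
  expect_error(xi_two_hap(diag(2), c(0.5, 0.5), c(0.5, 0.5),
                          probe_deltas = c(0, 0, 0.1)), "3 distinct")
})

test_that("complete-LD distances vanish only for haplotype IBS", {
  bc <- xi_bound_check(diag(2))
  expect_true(bc$is_zero)
  expect_equal(bc$value_minus, 0)
  expect_equal(bc$value_plus, 0)
  ## continuous predictor with s12 = 0.6: bounded below by 0.3
  bc2 <- xi_bound_check(matrix(c(1, 0.6, 0.6, 1), 2, 2))
  expect_false(bc2$is_zero)
  expect_gte(bc2$value_minus, 0.3 - 1e-12)
  expect_equal(bc2$bound, 0.3)
  ## symmetry of the two extremes
  set.seed(13)
  for (r in 1:10) {
    s12 <- runif(1)
    bc <- xi_bound_check(matrix(c(1, s12, s12, 1), 2, 2))
    expect_equal(bc$value_minus, bc$value_plus, tolerance = 1e-12)
    expect_gte(bc$value_minus, s12 / 2 - 1e-12)
  }
})

test_that("distance-vs-LD tables cover every target SNP and track LD", {
  p <- generate_founder_panel(pop_sim_params(n_chromosomes = 60L,
                                             n_markers = 60L,
                                             chrom_length_cM = 3,
                                             n_burnin_generations = 80L,
                                             effective_size = 40L,
                                             seed = 42L))
  m <- n_markers(p)
  tab <- distance_vs_ld(p, window_size = 6L,
                        predictors = c("ibs_hap", "ibs_m"))
  expect_equal(nrow(tab), m - 6L)
  expect_true(all(tab$d1_ibs_hap >= 0 & tab$d1_ibs_hap <= 1))
  expect_true(all(tab$R >= 0 & tab$R <= 1 + 1e-12))
  ## on an LD-rich panel, haplotype-IBS distance falls as LD rises
  expect_lt(cor(tab$R, tab$d1_ibs_hap, method = "spearman"), 0)
})

test_that("d1 profiles localize a strong-LD QTL and honor the gold mode", {
  p <- generate_founder_panel(pop_sim_params(n_chromosomes = 80L,
                                             n_markers = 40L,
                                             chrom_length_cM = 2,
                                             n_burnin_generations = 100L,
                                             effective_size = 50L,
                                             seed = 11L))
  m <- n_markers(p)
  qi <- (m + 1L) %/% 2L
  qtl <- qtl_truth(p, qi)
  dp <- d1_profile(p, qtl, "ibs_hap", window_size = 6L)
  expect_equal(nrow(dp), (m - 1L) - 6L + 1L)   # QTL hidden
  expect_true(all(dp$d1 >= 0 & dp$d1 <= 1))
  ## gold-standard mode at the QTL marker itself reaches distance 0
  dg <- d1_profile(p, qtl, "ibs_m", include_qtl = TRUE)
  expect_equal(min(dg$d1), 0)
  ## markers in complete LD with the QTL tie at 0, so the QTL must be
  ## among the minimizers (not necessarily the unique one)
  expect_true(qtl$qtl_pos_cM %in%
                dg$position_cM[dg$d1 <= min(dg$d1) + 1e-12])
})
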