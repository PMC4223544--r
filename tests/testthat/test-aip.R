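test_that("single-marker IBS equals the brute-force allele-equality matrix", {
  p <- random_panel(12L, 5L, seed = 4L)
  sim <- ibs_m(p, 3L)
  M <- expand_to_M(sim)
  a <- p$alleles[, 3L]
  expect_equal(M, outer(a, a, function(x, y) as.numeric(x == y)))
  expect_equal(M[1, 1], 1)
  expect_true(all(M %in% c(0, 1)))
  ## monomorphic marker: kappa = 1, all predictions 1
  mono <- haplotype_panel(matrix(0L, 4L, 2L), c(0, 0.1))
  expect_equal(expand_to_M(ibs_m(mono, 1L)), matrix(1, 4, 4))
})

test_that("haplotype IBS is the identity over distinct window patterns", {
  for (s in 1:20) {
    p <- random_panel(16L, 6L, seed = s)
    cd <- code_haplotypes(p, window_spec(p, 1:6))
    sim <- ibs_hap(cd)
    expect_equal(sim$H, diag(length(cd$freqs)))
    M <- expand_to_M(sim)
    brute <- outer(seq_len(16L), seq_len(16L), Vectorize(function(c1, c2)
      as.numeric(all(p$alleles[c1, 1:6] == p$alleles[c2, 1:6]))))
    expect_equal(M, brute)
  }
})

test_that("similarity score matches an independent IBS-run enumeration", {
  p <- random_panel(20L, 6L, spacing = 0.1, seed = 8L)
  cd <- code_haplotypes(p, window_spec(p, 1:6))
  sim <- score_li_jiang(cd)
  k <- length(cd$freqs)
  expect_equal(diag(sim$H), rep(1, k))    # identical haplotypes score 1
  for (pp in seq_len(k)) for (qq in seq_len(k)) {
    expect_equal(sim$H[pp, qq],
                 naive_score(cd$pattern_mat[pp, ], cd$pattern_mat[qq, ],
                             cd$positions_cM, cd$window$tested_pos_cM),
                 tolerance = 1e-12)
  }
  ## fully discordant pair scores 0
  p2 <- haplotype_panel(rbind(rep(0L, 6), rep(1L, 6)),
                        seq(0, 0.5, by = 0.1))
  cd2 <- code_haplotypes(p2, window_spec(p2, 1:6))
  expect_equal(score_li_jiang(cd2)$H[1, 2], 0)
  ## IBS at markers 1-3 only: run does not span the center, so only the
  ## weighted IBS-count term contributes
  pat <- rbind(c(0L, 1L, 0L, 1L, 0L, 1L),
               c(0L, 1L, 0L, 0L, 1L, 0L))
  p3 <- haplotype_panel(pat, seq(0, 0.5, by = 0.1))
  cd3 <- code_haplotypes(p3, window_spec(p3, 1:6))
  i <- cd3$window$tested_pos_cM
  w <- pmax(0, 1 - abs(p3$positions_cM - i))
  expect_equal(score_li_jiang(cd3)$H[1, 2], sum(w[1:3]) / (2 * sum(w)))
})

test_that("IBD probability is monotone, has correct limits, and matches Monte-Carlo", {
  ## exhaustive monotonicity under IBS-pattern dominance at t = 4:
  ## build codings realizing every IBS pattern against an all-0 haplotype
  pos <- c(0.0, 0.1, 0.2, 0.3)
  patterns <- expand.grid(rep(list(0:1), 4))
  vals <- numeric(16)
  for (r in seq_len(16)) {
    other <- 1L - as.integer(patterns[r, ])    # 0 where IBS with all-0
    alle <- rbind(rep(0L, 4), other)
    pp <- haplotype_panel(alle, pos)
    cd <- code_haplotypes(pp, window_spec(pp, 1:4))
    sim <- p_ibd(cd, Ne = 100, T = 100)
    vals[r] <- if (length(cd$freqs) == 1L) sim$H[1, 1] else sim$H[1, 2]
  }
  ibs_sets <- lapply(seq_len(16), function(r) which(patterns[r, ] == 1))
  for (a in seq_len(16)) for (b in seq_len(16)) {
    if (all(ibs_sets[[b]] %in% ibs_sets[[a]]) &&
        length(ibs_sets[[a]]) > length(ibs_sets[[b]]))
      expect_gte(vals[a], vals[b] - 1e-12)
  }
  ## all-IBS beats one mismatch strictly
  expect_gt(vals[16], max(vals[c(8, 12, 14, 15)]))
  ## huge Ne: IBD improbable
  p2 <- random_panel(10L, 4L, spacing = 0.1, seed = 3L)
  cd2 <- code_haplotypes(p2, window_spec(p2, 1:4))
  big <- p_ibd(cd2, Ne = 1e7, T = 100)
  expect_lt(max(big$H), 1e-3)
  ## 2-marker window vs the Monte-Carlo oracle of the same generative model
  pe <- haplotype_panel(rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L),
                              c(0L, 0L), c(0L, 1L)),
                        c(0, 0.4))
  cde <- code_haplotypes(pe, window_spec(pe, 1:2))
  sim <- p_ibd(cde, Ne = 100, T = 100)
  i <- cde$window$tested_pos_cM
  d <- abs(cde$positions_cM - i) / 100
  p1 <- as.numeric(cde$freqs %*% cde$pattern_mat)
  hom <- p1^2 + (1 - p1)^2
  for (case in list(c(TRUE, TRUE), c(TRUE, FALSE), c(FALSE, FALSE))) {
    pairs <- which(outer(seq_len(nrow(cde$pattern_mat)),
                         seq_len(nrow(cde$pattern_mat)),
                         Vectorize(function(a, b)
                           all((cde$pattern_mat[a, ] == cde$pattern_mat[b, ]) ==
                                 case))), arr.ind = TRUE)[1, ]
    mc <- mc_pibd(case, d, hom, Ne = 100, T = 100, nsim = 2e5, seed = 42)
    expect_lt(abs(sim$H[pairs[1], pairs[2]] - mc), 0.02)
  }
})

test_that("trained predictor reproduces single-target proportions and minimizes its loss", {
  ## one target SNP: the estimator reduces to the raw sharing proportion
  p <- random_panel(20L, 5L, seed = 12L)       # m = t + 1 with t = 4
  tab <- train_tp(p, 4L)
  cd <- code_haplotypes(p, list(marker_indices = 1:5,
                                tested_pos_cM = p$positions_cM[3]),
                        exclude = 3L)
  al <- p$alleles[, 3]
  k <- length(cd$freqs)
  for (pp in seq_len(k)) for (qq in seq_len(k)) {
    ca <- which(cd$labels == pp); cb <- which(cd$labels == qq)
    pshare <- mean(outer(al[ca], al[cb], "=="))
    expect_equal(tp_lookup(tab, cd$patterns[pp], cd$patterns[qq]), pshare,
                 tolerance = 1e-12)
  }
  ## weighted-average estimator equals a brute-force recomputation
  p2 <- random_panel(24L, 9L, seed = 13L)
  tab2 <- train_tp(p2, 4L)
  expect_equal(tab2$n_targets, n_markers(p2) - 4L)
  ## the stored estimates minimize the mean squared prediction error:
  ## random perturbations never decrease it
  base <- naive_etp(p2, 4L, function(a, b) tp_lookup(tab2, a, b))
  keys <- ls(tab2$estimates)
  set.seed(99)
  for (r in 1:60) {
    key <- sample(keys, 1)
    eps <- sample(c(-0.05, 0.05), 1)
    pert <- naive_etp(p2, 4L, function(a, b) {
      v <- tp_lookup(tab2, a, b)
      kk <- if (a <= b) paste(a, b, sep = "|") else paste(b, a, sep = "|")
      if (kk == key) min(max(v + eps, 0), 1) else v
    })
    expect_gte(pert, base - 1e-12)
  }
})

test_that("trained-predictor fallbacks cover unseen pattern pairs", {
  p <- random_panel(10L, 7L, seed = 21L)
  tab <- train_tp(p, 4L)
  ## find a 4-marker pattern that never occurred in training
  seen <- unique(unlist(strsplit(ls(tab$estimates), "|", fixed = TRUE)))
  all_pat <- apply(expand.grid(rep(list(0:1), 4)), 1, paste, collapse = "")
  unseen <- setdiff(all_pat, seen)[1]
  expect_false(is.na(unseen))
  expect_equal(tp_lookup(tab, unseen, unseen), 1)
  seen_other <- setdiff(seen, unseen)[1]
  expect_equal(tp_lookup(tab, unseen, seen_other), tab$global_mean)
  expect_true(tab$global_mean >= 0 && tab$global_mean <= 1)
  ## prediction matrices stay in [0, 1] and are symmetric
  cd <- code_haplotypes(p, window_spec(p, 2:5))
  sim <- tp_predict(tab, cd)
  expect_true(all(sim$H >= 0 & sim$H <= 1))
  expect_equal(sim$H, t(sim$H))
})

test_that("external cluster assignments expand to the expected matrices", {
  p <- random_panel(8L, 4L, seed = 31L)
  ## all chromosomes in one cluster: all-ones matrix
  lab1 <- matrix(1L, 8L, 4L)
  f <- file.path(tempdir(), "clust1.txt")
  write.table(rbind(p$marker_ids, lab1), f, quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  cl <- load_cluster_aip(f, p)
  expect_equal(expand_to_M(cluster_aip(cl, p, 2L)), matrix(1, 8, 8))
  ## labels equal to 1-marker haplotype labels reproduce ibs_m
  lab2 <- apply(p$alleles, 2L, function(a) match(a, unique(a)))
  f2 <- file.path(tempdir(), "clust2.txt")
  write.table(rbind(p$marker_ids, lab2), f2, quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  cl2 <- load_cluster_aip(f2, p)
  for (j in 1:4) {
    expect_equal(expand_to_M(cluster_aip(cl2, p, j)),
                 expand_to_M(ibs_m(p, j)))
  }
  ## random labels: M is 1 exactly where labels match
  set.seed(7)
  lab3 <- matrix(sample(1:3, 32L, TRUE), 8L, 4L)
  M <- expand_to_M(cluster_aip(lab3, p, 3L))
  expect_equal(M, outer(lab3[, 3], lab3[, 3],
                        function(x, y) as.numeric(x == y)))
  ## shape mismatch rejected
  bad <- file.path(tempdir(), "clustbad.txt")
  write.table(rbind(p$marker_ids[1:3], matrix(1L, 8L, 3L)), bad,
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  expect_error(load_cluster_aip(bad, p), "matrix is")
})

test_that("haplotype-level matrices expand correctly to chromosome level", {
  expect_equal(expand_to_M(diag(2), c(1L, 2L, 1L, 2L)),
               matrix(c(1, 0, 1, 0,
                        0, 1, 0, 1,
                        1, 0, 1, 0,
                        0, 1, 0, 1), 4, 4))
  expect_equal(expand_to_M(matrix(1, 1, 1), rep(1L, 6L)), matrix(1, 6, 6))
  set.seed(17)
  H <- matrix(runif(16), 4, 4); H <- (H + t(H)) / 2
  labels <- sample(1:4, 10L, TRUE)
  M <- expand_to_M(H, labels)
  for (c1 in 1:10) for (c2 in 1:10)
    expect_equal(M[c1, c2], H[labels[c1], labels[c2]])
  expect_error(expand_to_M(H, c(1L, 5L)), "out of range")
  expect_error(aip_similarity(matrix(c(1, 0.2, 0.4, 1), 2), c(1L, 2L), "x"),
               "symmetric")
  expect_error(aip_similarity(matrix(c(1, 2, 2, 1), 2), c(1L, 2L), "x"),
               "0, 1")
})
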