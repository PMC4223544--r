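#' Deterministic seed for a named random stream
#'
#' All randomness in a study is driven by one global integer seed; each
#' module draws from its own named stream so stages can be reproduced
#' independently.  The derived seed stays below 2^31.
#'
#' @param seed global integer seed.
#' @param name stream name (e.g. "founders", "mating", "recomb").
#' @param index optional integer index (replicate number, attempt, ...).
#' @return integer seed.
#' @export
stream_seed <- function(seed, name, index = 0L) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 48271 + h * 9631 +
              as.numeric(index) * 7919) %% 2147483647)
}

#' Study configuration
#'
#' Default scale: three LD scenarios calibrated (via marker spacing and
#' population history) so that the multiallelic LD between the 6-marker
#' window harboring the QTL and the QTL alleles averages about 0.52, 0.18
#' and 0.08 — the three LD levels of the study design; 100 founder
#' chromosomes distributed among 200 pedigree founders, 5 generations,
#' 200 phenotyped individuals and 30 gene-drop replicates per scenario,
#' with additive QTL effects (2, 0, -2).
#'
#' @param scenarios named list; each element a list with
#'   \code{spacing} (marker spacing, cM), a \code{target_R} (the LD
#'   level at which the QTL marker is chosen) and optionally
#'   \code{effective_size}, \code{burnin} and \code{n_markers}
#'   overriding the global values.
#' @param n_replicates gene-drop replicates per scenario.
#' @param predictors predictors to compare.
#' @param gold_standard also run the single-marker predictor with the QTL
#'   observable (the gold-standard mode).
#' @param n_founder_chromosomes chromosomes in the founder panel.
#' @param n_founders,n_generations,gen_size pedigree shape.
#' @param n_markers markers in the founder panel (before MAF filter);
#'   scenarios may override it.
#' @param region_cM genetic length of the region scanned around each
#'   simulated QTL (default 3 cM).
#' @param window_size haplotype window size t.
#' @param effects genotype effects (a1a1, a1a2, a2a2).
#' @param maf_retention QTL MAF retention threshold per replicate.
#' @param effective_size,burnin synthetic-population history.
#' @param Ne,T coalescent parameters of the IBD-probability predictor.
#' @param seed global seed.
#' @return a \code{study_config} list.
#' @export
study_config <- function(scenarios = list(
                           high = list(spacing = 0.03, burnin = 200L,
                                       n_markers = 160L, target_R = 0.52),
                           medium = list(spacing = 0.15, target_R = 0.18),
                           low = list(spacing = 0.25, effective_size = 200L,
                                      burnin = 60L, target_R = 0.08)),
                         n_replicates = 30L,
                         predictors = c("ibs_m", "ibs_hap", "score",
                                        "pibd", "tp"),
                         gold_standard = TRUE,
                         n_founder_chromosomes = 100L,
                         n_founders = 200L, n_generations = 5L,
                         gen_size = 200L,
                         n_markers = 120L, region_cM = 3,
                         window_size = 6L,
                         effects = c(2, 0, -2),
                         maf_retention = 0.1,
                         effective_size = 100L, burnin = 100L,
                         Ne = 100, T = 100, seed = 1L) {
  cfg <- list(scenarios = scenarios, n_replicates = as.integer(n_replicates),
              predictors = predictors, gold_standard = gold_standard,
              n_founder_chromosomes = as.integer(n_founder_chromosomes),
              n_founders = as.integer(n_founders),
              n_generations = as.integer(n_generations),
              gen_size = as.integer(gen_size),
              n_markers = as.integer(n_markers),
              region_cM = region_cM,
              window_size = as.integer(window_size),
              effects = as.numeric(effects),
              maf_retention = maf_retention,
              effective_size = as.integer(effective_size),
              burnin = as.integer(burnin),
              Ne = Ne, T = T, seed = as.integer(seed))
  stopifnot(cfg$window_size %% 2L == 0L,
            all(cfg$predictors %in% c("ibs_m", "ibs_hap", "score", "pibd",
                                      "tp", "cluster")),
            length(names(cfg$scenarios)) == length(cfg$scenarios))
  class(cfg) <- "study_config"
  cfg
}

#' Read a study configuration from a YAML file
#' @param path YAML file whose keys match \code{\link{study_config}}
#'   arguments; \code{scenarios} is a named mapping of spacings.
#' @return a \code{study_config}.
#' @export
read_study_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configs requires the yaml package")
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$scenarios)) raw$scenarios <- lapply(raw$scenarios, as.list)
  do.call(study_config, raw)
}

## Serialize a config deterministically and hash it (md5 of the dump).
config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  dump_lines <- utils::capture.output(utils::str(unclass(cfg), digits.d = 15))
  writeLines(dump_lines, f)
  unname(tools::md5sum(f))
}

write_stamped_tsv <- function(d, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_stamped_tsv <- function(path)
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)

#' Run one gene-drop replicate: scan + matrix-distance evaluation
#'
#' Gene-drops the founder panel through the pedigree (re-drawing, up to
#' \code{max_attempts}, until the QTL MAF retention rule is met),
#' simulates phenotypes, then for each predictor runs the RLRT scan
#' (QTL hidden) and the d1 profile against the QTL truth.
#'
#' @param founder_panel founder \code{haplotype_panel}.
#' @param ped a \code{pedigree}.
#' @param A_final relationship matrix of the phenotyped generation.
#' @param qtl_index QTL marker index in the founder panel.
#' @param scenario a \code{\link{qtl_scenario}}.
#' @param predictors predictor names.
#' @param region_markers scanned marker indices.
#' @param window_size window size t.
#' @param seed replicate seed.
#' @param gold_standard include the gold-standard observable-QTL mode
#'   (reported as predictor \code{"ibs_m_qtl"}).
#' @param Ne,T coalescent parameters for \code{"pibd"}.
#' @param max_attempts maximum gene-drop redraws for retention.
#' @return data.frame with one row per predictor: \code{predictor},
#'   \code{theta_ma}, \code{theta_re}, \code{min_d1}, \code{attempts}.
#' @export
run_replicate <- function(founder_panel, ped, A_final, qtl_index, scenario,
                          predictors, region_markers, window_size = 6L,
                          seed = 1L, gold_standard = TRUE,
                          Ne = 100, T = 100, max_attempts = 50L) {
  gd <- NULL
  attempt <- 0L
  repeat {
    attempt <- attempt + 1L
    if (attempt > max_attempts)
      stop("QTL MAF retention failed after ", max_attempts, " gene-drops")
    gd <- gene_drop(founder_panel, ped,
                    seed = stream_seed(seed, "genedrop", attempt))
    qtl <- qtl_truth(gd$panel, qtl_index)
    if (retain_replicate(qtl, scenario$maf_retention_threshold)) break
  }
  pheno <- simulate_phenotypes(ped, qtl_genotypes(gd$panel, qtl_index),
                               scenario,
                               seed = stream_seed(seed, "phenotype"))
  stopifnot(identical(pheno$id, gd$panel$individual_ids))
  y <- pheno$y
  A_eig <- eigen(as.matrix(A_final), symmetric = TRUE)
  h0 <- fit_reml(y, A_final, A_eig = A_eig)
  tp_table <- if ("tp" %in% predictors)
    train_tp(gd$panel, window_size, exclude = qtl_index) else NULL
  rows <- list()
  for (p in predictors) {
    sc <- scan_region(gd$panel, y, A_final, p, qtl_index = qtl_index,
                      window_size = window_size,
                      region_markers = region_markers,
                      tp_table = tp_table, Ne = Ne, T = T, h0_fit = h0,
                      A_eig = A_eig)
    dp <- d1_profile(gd$panel, qtl, p, window_size = window_size,
                     region_markers = region_markers,
                     tp_table = tp_table, Ne = Ne, T = T)
    tr <- theta_re(dp)
    rows[[p]] <- data.frame(predictor = p, theta_ma = sc$theta_ma,
                            theta_re = tr$theta_re, min_d1 = tr$min_d1,
                            attempts = attempt)
  }
  if (gold_standard) {
    sc <- scan_region(gd$panel, y, A_final, "ibs_m", qtl_index = qtl_index,
                      window_size = window_size,
                      region_markers = region_markers, include_qtl = TRUE,
                      h0_fit = h0, A_eig = A_eig)
    dp <- d1_profile(gd$panel, qtl, "ibs_m", region_markers = region_markers,
                     include_qtl = TRUE)
    tr <- theta_re(dp)
    rows[["ibs_m_qtl"]] <- data.frame(predictor = "ibs_m_qtl",
                                      theta_ma = sc$theta_ma,
                                      theta_re = tr$theta_re,
                                      min_d1 = tr$min_d1,
                                      attempts = attempt)
  }
  out <- do.call(rbind, rows)
  out$theta_qtl <- qtl$qtl_pos_cM
  rownames(out) <- NULL
  out
}

#' Run the full comparison study
#'
#' For each LD scenario: generates a founder panel, a pedigree and its
#' relationship matrix, then runs \code{n_replicates} gene-drop
#' replicates (common random numbers across predictors), summarizes the
#' mapping-accuracy and relative-efficiency criteria per predictor, and
#' finally computes the Spearman consistency between the two RMSEs across
#' all (predictor x scenario) points.  All outputs are reproducible from
#' the config seed; when \code{out_dir} is given, the config, per-scenario
#' replicate tables and summaries are written there (tables carry the
#' config hash; existing complete replicate tables are reused so an
#' interrupted run can resume).
#'
#' @param config a \code{\link{study_config}} or YAML path.
#' @param out_dir optional output directory.
#' @param quiet suppress progress messages.
#' @return list with \code{replicates} (all scenarios), \code{summary}
#'   (per scenario x predictor), \code{rho} (Spearman consistency),
#'   \code{config}, \code{hash}.
#' @export
run_study <- function(config = study_config(), out_dir = NULL,
                      quiet = FALSE) {
  if (is.character(config)) config <- read_study_config(config)
  stopifnot(inherits(config, "study_config"))
  hash <- config_hash(config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    writeLines(utils::capture.output(utils::str(unclass(config),
                                                digits.d = 15)),
               file.path(out_dir, "config.txt"))
  }
  scenario <- qtl_scenario(genotype_effects = config$effects,
                           maf_retention_threshold = config$maf_retention)
  ped <- generate_pedigree(config$n_founders, config$n_generations,
                           gen_size = config$gen_size,
                           seed = stream_seed(config$seed, "pedigree"))
  A <- build_A(ped)
  final <- ped$generation == max(ped$generation)
  A_final <- A[final, final]
  all_reps <- list()
  all_sum <- list()
  for (sc_name in names(config$scenarios)) {
    scn <- config$scenarios[[sc_name]]
    if (!is.list(scn)) scn <- list(spacing = scn)
    eff <- if (is.null(scn$effective_size)) config$effective_size
           else as.integer(scn$effective_size)
    burn <- if (is.null(scn$burnin)) config$burnin else as.integer(scn$burnin)
    nmk <- if (is.null(scn$n_markers)) config$n_markers
           else as.integer(scn$n_markers)
    rep_path <- if (!is.null(out_dir))
      file.path(out_dir, paste0("replicates_", sc_name, ".tsv")) else NULL
    half_cM <- config$region_cM / 2
    ht <- config$window_size %/% 2L
    ## draw a founder panel that can host the scan region (drift can leave
    ## too few common markers for an unlucky draw; redraw if so)
    founder_panel <- NULL
    for (draw in 1:20) {
      params <- pop_sim_params(
        n_chromosomes = min(config$n_founder_chromosomes, 2L * eff),
        n_markers = nmk,
        chrom_length_cM = scn$spacing * (nmk - 1L),
        n_burnin_generations = burn,
        effective_size = eff,
        maf_threshold = 0.05,
        seed = stream_seed(config$seed, paste0("founders_", sc_name), draw))
      fp_try <- generate_founder_panel(params)
      m <- n_markers(fp_try)
      pos <- fp_try$positions_cM
      ## QTL candidates: room for the region, window flanks, common allele
      cand <- which(pos >= pos[1L] + half_cM & pos <= pos[m] - half_cM)
      cand <- cand[cand > ht & cand <= m - ht]
      cand <- cand[maf(fp_try)[cand] >= config$maf_retention]
      ## the region around any candidate must hold at least one full window
      cand <- cand[vapply(cand, function(j)
        sum(abs(pos - pos[j]) <= half_cM) > config$window_size,
        logical(1L))]
      if (length(cand)) { founder_panel <- fp_try; break }
    }
    if (is.null(founder_panel))
      stop("no eligible QTL candidate markers in scenario ", sc_name)
    ## choose the QTL marker whose surrounding-window LD is closest to
    ## the scenario's target level (QTL SNPs are picked for their LD level)
    Rcand <- vapply(cand, function(j) {
      win <- list(marker_indices = (j - ht):(j + ht),
                  tested_pos_cM = pos[j])
      ld_state(founder_panel, win, qtl_truth(founder_panel, j))$R
    }, numeric(1L))
    target <- if (is.null(scn$target_R)) stats::median(Rcand) else scn$target_R
    qtl_index <- cand[which.min(abs(Rcand - target))]
    region <- which(abs(pos - pos[qtl_index]) <= half_cM)
    n_expected <- config$n_replicates *
      (length(config$predictors) + as.integer(config$gold_standard))
    if (!is.null(rep_path) && file.exists(rep_path) &&
        nrow(read_stamped_tsv(rep_path)) == n_expected) {
      reps <- read_stamped_tsv(rep_path)
    } else {
      reps <- lapply(seq_len(config$n_replicates), function(w) {
        if (!quiet) message("scenario ", sc_name, " replicate ", w)
        r <- run_replicate(founder_panel, ped, A_final, qtl_index, scenario,
                           config$predictors, region,
                           window_size = config$window_size,
                           seed = stream_seed(config$seed,
                                              paste0("rep_", sc_name), w),
                           gold_standard = config$gold_standard,
                           Ne = config$Ne, T = config$T)
        r$replicate <- w
        r
      })
      reps <- do.call(rbind, reps)
      if (!is.null(rep_path)) write_stamped_tsv(reps, rep_path, hash)
    }
    reps$scenario <- sc_name
    theta_qtl <- founder_panel$positions_cM[qtl_index]
    sm <- summarize_replicates(reps, theta_qtl)
    sm$scenario <- sc_name
    ## LD level at the window harboring the QTL, on the founder panel
    sm$R_qtl <- tryCatch({
      qtlF <- qtl_truth(founder_panel, qtl_index)
      win <- list(marker_indices = (qtl_index - config$window_size %/% 2L):
                    (qtl_index + config$window_size %/% 2L),
                  tested_pos_cM = founder_panel$positions_cM[qtl_index])
      ld_state(founder_panel, win, qtlF)$R
    }, error = function(e) NA_real_)
    all_reps[[sc_name]] <- reps
    all_sum[[sc_name]] <- sm
  }
  replicates <- do.call(rbind, all_reps)
  summary <- do.call(rbind, all_sum)
  rownames(replicates) <- rownames(summary) <- NULL
  ## consistency over the hidden-QTL predictors only (the gold-standard
  ## mode sees the causal marker and is reported separately)
  hid <- summary[summary$predictor != "ibs_m_qtl", ]
  rho <- if (nrow(hid) >= 3L) consistency(hid) else NA_real_
  if (!is.null(out_dir)) {
    write_stamped_tsv(summary, file.path(out_dir, "summary.tsv"), hash)
    write_stamped_tsv(data.frame(spearman_rho = rho),
                      file.path(out_dir, "consistency.tsv"), hash)
  }
  list(replicates = replicates, summary = summary, rho = rho,
       config = config, hash = hash)
}
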