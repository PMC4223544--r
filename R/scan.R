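#' Condition a similarity matrix to be usable as a covariance structure
#'
#' Continuous predictors (Score, TP) can produce similarity matrices that
#' are indefinite or nearly singular; negative eigenvalues are floored at
#' zero and a small ridge (1e-6) is added to the diagonal.
#'
#' @param H symmetric matrix.
#' @return the conditioned positive-definite matrix.
#' @export
condition_H <- function(H) {
  H <- (H + t(H)) / 2
  e <- eigen(H, symmetric = TRUE)
  if (min(e$values) < 0)
    H <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
  H + diag(1e-6, nrow(H))
}

#' Haplotype incidence matrix (copy counts per individual)
#'
#' Each individual's row counts how many of its two chromosomes carry each
#' haplotype/cluster label (entries 0/1/2, rows sum to 2).
#'
#' @param labels length-2n chromosome label vector in 1..kappa.
#' @param kappa number of classes (default \code{max(labels)}).
#' @return n x kappa incidence matrix.
#' @export
incidence_Z <- function(labels, kappa = max(labels)) {
  n <- length(labels) %/% 2L
  Z <- matrix(0, n, kappa)
  for (k in seq_len(n)) {
    Z[k, labels[2L * k - 1L]] <- Z[k, labels[2L * k - 1L]] + 1
    Z[k, labels[2L * k]] <- Z[k, labels[2L * k]] + 1
  }
  Z
}

#' EM-REML fit of the association mixed model
#'
#' Fits \code{y = 1 beta + Z_h h + u + e} (H1) or the no-QTL model
#' \code{y = 1 beta + u + e} (H0) by EM-REML, where
#' \code{h ~ N(0, H sigma_h^2)} is the random haplotype/cluster effect at
#' the tested position, \code{u ~ N(0, A sigma_u^2)} the polygenic effect
#' and \code{e ~ N(0, I sigma_e^2)}.  Iterates until the relative change
#' of the restricted log-likelihood is below \code{tol} or \code{maxit}
#' iterations; variances are floored at 1e-8.  Non-convergence is flagged
#' on the result, not raised.
#'
#' @param y numeric phenotype vector (n >= 3).
#' @param A n x n additive relationship matrix.
#' @param Zh optional n x kappa incidence matrix (H1 model).
#' @param H optional kappa x kappa covariance structure of h; conditioned
#'   with \code{\link{condition_H}} unless already positive definite.
#' @param tol relative restricted-log-likelihood convergence tolerance.
#' @param maxit maximum EM iterations.
#' @param init optional starting variances (sigma_h2 if \code{Zh} given,
#'   sigma_u2, sigma_e2); defaults to an equal split of the phenotypic
#'   variance.  Warm starts (e.g. from the cached H0 fit) shorten the EM
#'   path without changing the criterion.
#' @param A_eig optional cached \code{eigen(A, symmetric = TRUE)} (eigen
#'   engine only); avoids re-decomposing A across fits on the same data.
#' @param engine \code{"eigen"} (default; works in A's eigenbasis with a
#'   Woodbury correction for the low-rank haplotype term) or
#'   \code{"dense"} (textbook dense-matrix EM).  Both implement the same
#'   updates and criterion.
#' @return a \code{reml_fit} object: \code{sigma2} (named variance
#'   estimates), \code{loglik}, \code{trace}, \code{iterations},
#'   \code{converged}, \code{model} ("H0"/"H1").
#' @export
fit_reml <- function(y, A, Zh = NULL, H = NULL, tol = 1e-8, maxit = 500L,
                     init = NULL, A_eig = NULL, engine = c("eigen", "dense")) {
  engine <- match.arg(engine)
  y <- as.numeric(y)
  n <- length(y)
  if (n < 3L) stop("need at least 3 phenotyped individuals")
  if (any(!is.finite(y))) stop("phenotypes must be finite")
  X <- matrix(1, n, 1L)
  with_h <- !is.null(Zh)
  if (with_h) {
    Zh <- as.matrix(Zh)
    if (is.null(H)) H <- diag(ncol(Zh))
    H <- as.matrix(H)
    ev <- eigen((H + t(H)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-10) H <- condition_H(H)
  }
  n_comp <- 2L + as.integer(with_h)
  if (is.null(init)) {
    v0 <- stats::var(y)
    if (!is.finite(v0) || v0 <= 0) v0 <- 1
    init <- rep(v0 / n_comp, n_comp)
  } else {
    init <- pmax(as.numeric(init), 1e-8)
    if (length(init) != n_comp)
      stop("init must supply ", n_comp, " variances")
  }
  if (engine == "eigen") {
    if (is.null(A_eig)) A_eig <- eigen(as.matrix(A), symmetric = TRUE)
    if (min(A_eig$values) < -1e-6)
      stop("relationship matrix A is not positive semidefinite")
    lambda <- pmax(A_eig$values, 0)
    Q <- A_eig$vectors
    W <- if (with_h) crossprod(Q, Zh %*% t(chol(H)))
         else matrix(0, n, 0L)
    q <- c(if (with_h) ncol(Zh), n)
    res <- em_reml_eig_cpp(crossprod(Q, y), crossprod(Q, X), lambda, W,
                           init, q, tol = tol, maxit = as.integer(maxit))
  } else {
    A <- as.matrix(A)
    if (min(eigen(A, symmetric = TRUE, only.values = TRUE)$values) < -1e-6)
      stop("relationship matrix A is not positive semidefinite")
    G <- list()
    if (with_h) G <- c(G, list(Zh %*% H %*% t(Zh)))
    G <- c(G, list(A))
    q <- c(if (with_h) ncol(Zh), n)
    res <- em_reml_cpp(y, X, G, init, q, tol = tol, maxit = as.integer(maxit))
  }
  nm <- c(if (with_h) "sigma_h2", "sigma_u2", "sigma_e2")
  sigma2 <- as.numeric(res$sigma2)
  names(sigma2) <- nm
  structure(list(sigma2 = sigma2, loglik = res$loglik,
                 trace = as.numeric(res$trace),
                 iterations = res$iterations, converged = res$converged,
                 model = if (with_h) "H1" else "H0", n = n),
            class = "reml_fit")
}

#' @method print reml_fit
#' @export
print.reml_fit <- function(x, ...) {
  cat("EM-REML fit (", x$model, "), n =", x$n, "\n")
  print(signif(x$sigma2, 4))
  cat("restricted logLik:", format(x$loglik, digits = 8),
      if (x$converged) "(converged," else "(NOT converged,",
      x$iterations, "iterations )\n")
  invisible(x)
}

#' @method logLik reml_fit
#' @export
logLik.reml_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$sigma2) + 1L,
            class = "logLik")
}

#' Restricted log-likelihood at fixed variance components
#'
#' Evaluates the same REML criterion as \code{\link{fit_reml}} (constant
#' terms dropped) at user-supplied variances; useful to check fits against
#' independent optimizers or to profile a component.
#'
#' @inheritParams fit_reml
#' @param sigma2 variances, ordered (sigma_h2 if \code{Zh} given),
#'   sigma_u2, sigma_e2.
#' @return scalar restricted log-likelihood.
#' @export
reml_loglik <- function(y, A, sigma2, Zh = NULL, H = NULL) {
  y <- as.numeric(y)
  X <- matrix(1, length(y), 1L)
  G <- list()
  if (!is.null(Zh)) {
    if (is.null(H)) H <- diag(ncol(Zh))
    G <- c(G, list(as.matrix(Zh) %*% as.matrix(H) %*% t(as.matrix(Zh))))
  }
  G <- c(G, list(as.matrix(A)))
  reml_loglik_cpp(y, X, G, as.numeric(sigma2))
}

#' Restricted likelihood-ratio test at one tested position
#'
#' \code{lambda = max(0, 2 (ll_H1 - ll_H0))}: EM can leave the H1
#' restricted likelihood microscopically below H0's, so the statistic is
#' clipped at zero.
#'
#' @param fit_h1 a \code{reml_fit} of the H1 model.
#' @param fit_h0 a \code{reml_fit} of the H0 model on the same data.
#' @return the RLRT statistic.
#' @export
rlrt <- function(fit_h1, fit_h0) {
  max(0, 2 * (fit_h1$loglik - fit_h0$loglik))
}

#' Variance-component association scan over a region
#'
#' Fits the H0 model once, then the H1 model at every tested position of
#' the region and records the RLRT statistic.  Tested positions are
#' marker positions for the single-marker predictors (\code{ibs_m},
#' \code{cluster}) and window centers for the haplotype predictors.  The
#' QTL marker is hidden unless \code{include_qtl} (gold-standard mode).
#' The estimated QTL location is the argmax of the RLRT profile; exact
#' ties are resolved by averaging the tying positions.
#'
#' @param panel descendant \code{haplotype_panel} of the phenotyped
#'   individuals (same order as \code{y}).
#' @param y phenotypes.
#' @param A additive relationship matrix of the phenotyped individuals.
#' @param predictor predictor name.
#' @param qtl_index panel marker index of the (hidden) QTL; NULL if none.
#' @param window_size even window size for haplotype predictors.
#' @param region_markers marker indices scanned (default all).
#' @param include_qtl gold-standard mode: keep the QTL observable.
#' @param tp_table,cluster_labels,Ne,T predictor-specific inputs.
#' @param h0_fit optional cached H0 \code{reml_fit}.
#' @param tol,maxit EM-REML controls.
#' @param A_eig optional cached \code{eigen(A, symmetric = TRUE)}.
#' @return a \code{qtl_scan} object: data.frame \code{profile}
#'   (position_cM, lambda, sigma_h2, sigma_u2, sigma_e2, converged),
#'   \code{theta_ma}, \code{predictor}, \code{h0} fit.
#' @export
scan_region <- function(panel, y, A, predictor, qtl_index = NULL,
                        window_size = 6L,
                        region_markers = seq_len(n_markers(panel)),
                        include_qtl = FALSE, tp_table = NULL,
                        cluster_labels = NULL, Ne = 100, T = 100,
                        h0_fit = NULL, tol = 1e-8, maxit = 500L,
                        A_eig = NULL) {
  if (is.null(A_eig)) A_eig <- eigen(as.matrix(A), symmetric = TRUE)
  marker_based <- predictor %in% c("ibs_m", "cluster")
  region_markers <- sort(as.integer(region_markers))
  hidden <- if (include_qtl || is.null(qtl_index)) region_markers
            else setdiff(region_markers, qtl_index)
  if (is.null(h0_fit))
    h0_fit <- fit_reml(y, A, tol = tol, maxit = maxit, A_eig = A_eig)
  sims <- list()
  if (marker_based) {
    for (j in hidden)
      sims[[length(sims) + 1L]] <-
        if (predictor == "ibs_m") ibs_m(panel, j)
        else cluster_aip(cluster_labels, panel, j)
  } else {
    if ("tp" == predictor && is.null(tp_table))
      tp_table <- train_tp(panel, window_size, exclude = qtl_index)
    if (length(hidden) >= window_size)
      for (s in seq_len(length(hidden) - window_size + 1L)) {
        idx <- hidden[s:(s + window_size - 1L)]
        coding <- code_haplotypes(panel, window_spec(panel, idx))
        sims[[length(sims) + 1L]] <- switch(predictor,
          ibs_hap = ibs_hap(coding),
          score = score_li_jiang(coding),
          pibd = p_ibd(coding, Ne = Ne, T = T),
          tp = tp_predict(tp_table, coding),
          stop("unknown predictor: ", predictor))
      }
  }
  ## warm-start the first position from the H0 estimates, then chain each
  ## position from its neighbor's solution (adjacent windows are highly
  ## correlated); the EM criterion and convergence rule are unchanged.
  warm <- c(0.1 * sum(h0_fit$sigma2), h0_fit$sigma2)
  rows <- vector("list", length(sims))
  for (k in seq_along(sims)) {
    sim <- sims[[k]]
    Zh <- incidence_Z(sim$labels, nrow(sim$H))
    f1 <- fit_reml(y, A, Zh = Zh, H = sim$H, tol = tol, maxit = maxit,
                   init = warm, A_eig = A_eig)
    warm <- pmax(f1$sigma2, 0.01 * sum(h0_fit$sigma2))
    rows[[k]] <- data.frame(position_cM = sim$position_cM,
                            lambda = rlrt(f1, h0_fit),
                            sigma_h2 = f1$sigma2[["sigma_h2"]],
                            sigma_u2 = f1$sigma2[["sigma_u2"]],
                            sigma_e2 = f1$sigma2[["sigma_e2"]],
                            converged = f1$converged)
  }
  profile <- do.call(rbind, rows)
  structure(list(profile = profile,
                 theta_ma = argmax_position(profile$position_cM,
                                            profile$lambda),
                 predictor = predictor, h0 = h0_fit),
            class = "qtl_scan")
}

## argmax with exact ties (within 1e-12) averaged
argmax_position <- function(positions, values) {
  mx <- max(values)
  mean(positions[values >= mx - 1e-12])
}

#' @method print qtl_scan
#' @export
print.qtl_scan <- function(x, ...) {
  cat("qtl_scan [", x$predictor, "]:", nrow(x$profile),
      "tested positions; max RLRT", format(max(x$profile$lambda), digits = 4),
      "at theta_ma =", format(x$theta_ma, digits = 6), "cM\n")
  invisible(x)
}

#' @method plot qtl_scan
#' @export
plot.qtl_scan <- function(x, qtl_pos = NULL, ...) {
  graphics::plot(x$profile$position_cM, x$profile$lambda, type = "b",
                 xlab = "tested position (cM)", ylab = "RLRT",
                 main = paste("RLRT profile -", x$predictor), ...)
  if (!is.null(qtl_pos)) graphics::abline(v = qtl_pos, col = "red", lty = 2)
  graphics::abline(v = x$theta_ma, col = "blue", lty = 3)
  invisible(x)
}
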