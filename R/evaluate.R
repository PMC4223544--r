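#' Position minimizing the matrix-distance profile
#'
#' The relative-efficiency location estimate: the tested position where
#' the matrix distance to the QTL truth is smallest.  Exact ties (within
#' 1e-12) are resolved by the arithmetic mean of the tying positions.
#'
#' @param profile data.frame with columns \code{position_cM} and
#'   \code{d1} (e.g. from \code{\link{d1_profile}}).
#' @return list with \code{theta_re} and \code{min_d1}.
#' @export
theta_re <- function(profile) {
  if (!nrow(profile)) stop("empty d1 profile")
  mn <- min(profile$d1)
  list(theta_re = mean(profile$position_cM[profile$d1 <= mn + 1e-12]),
       min_d1 = mn)
}

#' Summarize mapping accuracy and relative efficiency over replicates
#'
#' Computes, per predictor, the four comparison criteria over N
#' replicates: \code{RMSE_ma = sqrt(mean((theta_ma - theta_QTL)^2))},
#' \code{RMSE_re} likewise for the distance-minimizing position,
#' \code{E_re = mean(min d1)} and \code{sigma_re}, the population
#' (1/N-normalized) standard deviation of the minimal distances.
#'
#' @param replicates data.frame with columns \code{predictor},
#'   \code{replicate}, \code{theta_ma}, \code{theta_re}, \code{min_d1}.
#' @param theta_qtl true QTL position (cM).
#' @return data.frame, one row per predictor: \code{RMSE_ma},
#'   \code{RMSE_re}, \code{E_re}, \code{sigma_re}, \code{n_replicates}.
#' @export
summarize_replicates <- function(replicates, theta_qtl) {
  stopifnot(nrow(replicates) >= 1L)
  out <- lapply(split(replicates, replicates$predictor), function(d) {
    data.frame(predictor = d$predictor[1L],
               RMSE_ma = sqrt(mean((d$theta_ma - theta_qtl)^2)),
               RMSE_re = sqrt(mean((d$theta_re - theta_qtl)^2)),
               E_re = mean(d$min_d1),
               sigma_re = sqrt(mean((d$min_d1 - mean(d$min_d1))^2)),
               n_replicates = nrow(d))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Pairwise relative-efficiency order between predictors
#'
#' Predictor P dominates P' when both (a) its distance-minimizing
#' position is closer to the QTL (replicate-averaged, via RMSE_re) and
#' (b) its minimal matrix distance is smaller (via E_re).  Pairs where
#' only one inequality holds are incomparable.
#'
#' @param summary a summary data.frame from
#'   \code{\link{summarize_replicates}} (>= 2 predictors).
#' @return data.frame of ordered pairs with columns \code{better},
#'   \code{worse}, \code{relation} ("dominates" or "incomparable").
#' @export
relative_efficiency_order <- function(summary) {
  stopifnot(nrow(summary) >= 2L)
  pairs <- utils::combn(seq_len(nrow(summary)), 2L)
  rows <- apply(pairs, 2L, function(ij) {
    a <- summary[ij[1L], ]; b <- summary[ij[2L], ]
    a_dom <- a$RMSE_re < b$RMSE_re && a$E_re < b$E_re
    b_dom <- b$RMSE_re < a$RMSE_re && b$E_re < a$E_re
    if (a_dom) data.frame(better = a$predictor, worse = b$predictor,
                          relation = "dominates")
    else if (b_dom) data.frame(better = b$predictor, worse = a$predictor,
                               relation = "dominates")
    else data.frame(better = a$predictor, worse = b$predictor,
                    relation = "incomparable")
  })
  do.call(rbind, rows)
}

#' Consistency of mapping accuracy with relative efficiency
#'
#' Spearman rank correlation between RMSE_ma and RMSE_re across
#' (predictor x scenario) points, measuring how well the
#' phenotype-free matrix-distance criterion tracks QTL mapping accuracy.
#'
#' @param summaries data.frame combining per-scenario summaries (columns
#'   \code{RMSE_ma} and \code{RMSE_re}; >= 3 rows).
#' @return Spearman's rho.
#' @export
consistency <- function(summaries) {
  if (nrow(summaries) < 3L)
    stop("need at least 3 (predictor x scenario) points")
  stats::cor(summaries$RMSE_ma, summaries$RMSE_re, method = "spearman")
}
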