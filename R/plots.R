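#' Plot a mean LD profile
#'
#' @param profile output of \code{\link{mean_ld_profiles}} (or one
#'   \code{\link{ld_profile}}).
#' @param measure \code{"R"} or \code{"D2"}.
#' @param ... passed to \code{plot}.
#' @return invisibly, the profile.
#' @export
plot_ld_profile <- function(profile, measure = c("R", "D2"), ...) {
  measure <- match.arg(measure)
  x <- if (!is.null(profile$mean_dist_cM)) profile$mean_dist_cM
       else profile$dist_cM
  y <- profile[[if (!is.null(profile$mean_R))
    paste0("mean_", measure) else measure]]
  graphics::plot(x, y, type = "b", xlab = "tested position - QTL (cM)",
                 ylab = paste("multiallelic", measure), ...)
  graphics::abline(v = 0, col = "red", lty = 2)
  invisible(profile)
}

#' Scatter of matrix distance against multiallelic LD with a LOESS trend
#'
#' @param tab output of \code{\link{distance_vs_ld}}.
#' @param predictor predictor column to plot (without the \code{d1_}
#'   prefix).
#' @param loess add a LOESS regression line.
#' @param ... passed to \code{plot}.
#' @return invisibly, the LOESS fit (or NULL).
#' @export
plot_distance_vs_ld <- function(tab, predictor = "ibs_hap", loess = TRUE,
                                ...) {
  y <- tab[[paste0("d1_", predictor)]]
  if (is.null(y)) stop("no d1 column for predictor ", predictor)
  graphics::plot(tab$R, y, xlab = "multiallelic LD (R)",
                 ylab = "matrix distance d1", main = predictor,
                 pch = 16, col = "#00000055", ...)
  fit <- NULL
  if (loess && nrow(tab) >= 10L) {
    fit <- stats::loess(y ~ R, data = data.frame(R = tab$R, y = y))
    ord <- order(tab$R)
    graphics::lines(tab$R[ord], stats::predict(fit)[ord], col = "red",
                    lwd = 2)
  }
  invisible(fit)
}
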