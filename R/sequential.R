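#' Refit marginal posterior ages as calibrations
#'
#' The sequential (two-step) dating device: the marginal posterior age of
#' each mapped node from a first analysis is refitted as a skew-t density by
#' maximum likelihood and attached as a calibration for the corresponding
#' node of a second analysis. The correlation structure of the step-1
#' posterior is deliberately discarded — the step-2 time prior is the product
#' of the fitted marginals, truncated to keep descendants younger than
#' ancestors by the joint time prior.
#'
#' @param trace a trace data frame from the first analysis.
#' @param node_map named character vector: names are trace columns (e.g.
#'   \code{"t_5"}), values are node numbers on the target tree.
#' @return Named list of \code{cal_st} calibrations keyed by target node
#'   number, with a \code{fits} attribute carrying the fit diagnostics.
#' @export
posterior_to_calibrations <- function(trace, node_map) {
  stopifnot(is.data.frame(trace), length(node_map) >= 1)
  missing_cols <- setdiff(names(node_map), names(trace))
  if (length(missing_cols))
    stop("unmapped node column(s): ", paste(missing_cols, collapse = ", "))
  cals <- list()
  fits <- list()
  for (col in names(node_map)) {
    x <- trace[[col]]
    fit <- fit_skew_t_ml(x)
    if (is.null(fit$calibration))
      stop("skew-t fit failed outright for ", col)
    fits[[col]] <- fit
    cals[[as.character(node_map[[col]])]] <- fit$calibration
  }
  attr(cals, "fits") <- fits
  cals
}

#' Infinite-sites regression
#'
#' Regression through the origin of posterior CI width on posterior mean age:
#' \code{a = sum(w t) / sum(t^2)}, with the Pearson correlation of the two
#' as the linearity measure. On an infinite-sites plot a straight line
#' through the origin indicates that fossil-calibration uncertainty, not
#' sequence data, limits dating precision; the slope is the CI width added
#' per unit of divergence time.
#'
#' @param t posterior mean ages (must not all be zero).
#' @param w 95\% CI widths (same length).
#' @return A list with \code{slope} and \code{R} (Pearson correlation;
#'   \code{NaN} with a warning when undefined).
#' @export
infinite_sites_regression <- function(t, w) {
  stopifnot(length(t) == length(w), length(t) >= 1)
  if (all(t == 0)) stop("all ages are zero")
  slope <- sum(w * t) / sum(t^2)
  R <- if (length(t) < 2 || stats::var(t) == 0 || stats::var(w) == 0) {
    warning("correlation undefined: no variation in ages or widths")
    NaN
  } else stats::cor(t, w)
  list(slope = slope, R = R)
}

#' Calibration density versus marginal prior report
#'
#' Samples the joint time prior by MCMC and compares, per calibrated node,
#' the 2.5/50/97.5\% quantiles of the user-specified calibration density
#' with those of the marginal prior the truncation machinery actually
#' induces. Interacting calibrations (e.g. a heavy-tailed density adjacent
#' to the root) can shift the marginal prior substantially away from the
#' user's density.
#'
#' @param ct a \code{calibrated_tree}.
#' @param tspec a \code{time_prior_spec}.
#' @param n prior samples.
#' @param seed integer seed.
#' @return A data frame with one row per internal node: calibration-density
#'   quantiles (NA for kernel-only nodes), marginal-prior quantiles, and
#'   \code{discrepancy}, the maximum relative quantile shift.
#' @export
prior_truncation_report <- function(ct, tspec, n = 20000, seed = 1) {
  tr <- sample_time_prior(ct, tspec, n = n, seed = seed)
  roles <- node_roles(ct)
  probs <- c(0.025, 0.5, 0.975)
  rows <- lapply(roles$internal, function(nd) {
    x <- tr[[paste0("t_", nd)]]
    mq <- stats::quantile(x, probs, names = FALSE)
    cal <- ct$calibrations[[as.character(nd)]]
    if (!is.null(cal) && cal$family != "FIXED") {
      cq <- qcal(cal, probs)
      disc <- max(abs(mq - cq) / cq)
    } else {
      cq <- rep(NA_real_, 3); disc <- NA_real_
    }
    data.frame(node = nd,
               family = if (is.null(cal)) "kernel" else cal$family,
               cal_q2.5 = cq[1], cal_q50 = cq[2], cal_q97.5 = cq[3],
               prior_q2.5 = mq[1], prior_q50 = mq[2], prior_q97.5 = mq[3],
               discrepancy = disc)
  })
  do.call(rbind, rows)
}
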