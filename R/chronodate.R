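#' Bayesian divergence-time estimation
#'
#' The package's main fitting function: runs the dating MCMC on a calibrated
#' tree, under a chosen clock model and likelihood mode, and returns a fitted
#' object with posterior summaries of node ages and rates.
#'
#' Time is measured in units of 100 My internally; rates are substitutions
#' per site per 100 My.
#'
#' @param tree a \code{calibrated_tree} (see [read_calibrated_newick()]);
#'   the root must carry a calibration density or fixed age.
#' @param alignment an \code{alignment}, or \code{NULL} for a prior-only run.
#' @param clock clock model name (\code{"ar"}, \code{"ir"}, \code{"sc"}) or a
#'   \code{clock_model} object.
#' @param subst a \code{subst_model} (default HKY+G with 4 categories).
#' @param time_prior a \code{time_prior_spec} (default birth-death with
#'   lambda = mu = 1, rho = 0: the conditional-uniform kernel).
#' @param mode \code{"exact"}, \code{"approx"} (quadratic branch-length
#'   approximation) or \code{"none"} (prior-only).
#' @param iterations,burnin,thin,seed MCMC settings (see [mcmc_config()]).
#' @return An object of class \code{"chronodate"}.
#' @examples
#' \donttest{
#' sim <- simulate_dataset(ntips = 4, clock = clock_model("sc"),
#'                         sm = subst_model("JC"), sites = 500, seed = 1,
#'                         mu = 0.05)
#' ct <- calibrated_tree(sim$phylo,
#'                       setNames(list(cal_fixed(1)), "5"))
#' fit <- chronodate(ct, sim$aln, clock = "sc", subst = subst_model("JC"),
#'                   iterations = 4000, seed = 1)
#' summary(fit)
#' }
#' @export
chronodate <- function(tree, alignment = NULL,
                       clock = c("ar", "ir", "sc"),
                       subst = subst_model("HKY", gamma_shape = 0.5, ncat = 4),
                       time_prior = time_prior_spec(),
                       mode = c("exact", "approx", "none"),
                       iterations = 20000, burnin = NULL, thin = NULL,
                       seed = 1) {
  if (is.character(clock)) clock <- clock_model(match.arg(clock))
  mode <- if (is.null(alignment)) "none" else match.arg(mode)
  lik <- switch(mode,
    none = likelihood_none(),
    exact = likelihood_exact(alignment, subst),
    approx = likelihood_approx(
      build_branch_approx(alignment, tree$phylo, subst)))
  cfg <- mcmc_config(iterations = iterations, burnin = burnin, thin = thin,
                     seed = seed)
  trace <- run_mcmc(tree, time_prior, clock, lik, cfg)
  structure(list(tree = tree, clock = clock, subst = subst,
                 time_prior = time_prior, mode = mode, config = cfg,
                 trace = trace, summary = summarize_trace(trace)),
            class = "chronodate")
}

#' @export
print.chronodate <- function(x, ...) {
  cat("Bayesian dating fit (", toupper(x$clock$model), " clock, ",
      x$mode, " likelihood)\n", sep = "")
  cat(nrow(x$trace), "posterior samples;",
      length(x$tree$phylo$tip.label), "tips\n")
  ages <- x$summary[grepl("^t_", x$summary$parameter), ]
  cat("Posterior mean node ages (100 My):\n")
  print(data.frame(node = sub("^t_", "", ages$parameter),
                   mean = signif(ages$mean, 4),
                   `2.5%` = signif(ages$q2.5, 4),
                   `97.5%` = signif(ages$q97.5, 4),
                   check.names = FALSE), row.names = FALSE)
  invisible(x)
}

#' @export
summary.chronodate <- function(object, ...) object$summary

#' @param object,x a \code{chronodate} fit.
#' @rdname chronodate
#' @export
coef.chronodate <- function(object, ...) {
  ages <- object$summary[grepl("^t_", object$summary$parameter), ]
  stats::setNames(ages$mean, ages$parameter)
}

#' @rdname chronodate
#' @param which \code{"ages"} for posterior age intervals vs mean (the
#'   infinite-sites style plot) or \code{"trace"} for the log-likelihood
#'   trace.
#' @param ... unused.
#' @export
plot.chronodate <- function(x, which = c("ages", "trace"), ...) {
  which <- match.arg(which)
  if (which == "trace") {
    graphics::plot(x$trace$Gen, x$trace$lnL, type = "l",
                   xlab = "iteration", ylab = "log-likelihood")
  } else {
    ages <- x$summary[grepl("^t_", x$summary$parameter), ]
    w <- ages$q97.5 - ages$q2.5
    graphics::plot(ages$mean, w, xlab = "posterior mean age (100 My)",
                   ylab = "95% CI width (100 My)", pch = 19)
    fit <- infinite_sites_regression(ages$mean, w)
    graphics::abline(0, fit$slope, lty = 2)
  }
  invisible(x)
}

#' Export a fitted timetree as annotated Newick
#'
#' Writes the topology with posterior mean node ages as branch lengths
#' (100 My) and the original calibrations as quoted node labels.
#'
#' @param fit a \code{chronodate} object.
#' @param file optional path.
#' @return The Newick string.
#' @export
timetree_newick <- function(fit, file = NULL) {
  stopifnot(inherits(fit, "chronodate"))
  ages <- numeric(length(fit$tree$phylo$tip.label) + fit$tree$phylo$Nnode)
  cf <- coef(fit)
  ages[as.integer(sub("^t_", "", names(cf)))] <- cf
  write_calibrated_newick(fit$tree, file = file, ages = ages)
}
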