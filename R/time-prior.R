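#' Birth-death prior on node ages
#'
#' Specification of the joint prior on node ages: calibrated nodes follow
#' their calibration densities, and the remaining internal node ages follow
#' the birth-death kernel conditional on the root age, with the
#' ancestor-older-than-descendant constraint enforced by truncation
#' (a \code{-Inf} log prior, i.e. rejection during MCMC, with no explicit
#' renormalization).
#'
#' With \code{lambda = mu = 1, rho = 0} the kernel is the uniform density on
#' \code{(0, t_root)}, the default used throughout.
#'
#' @param lambda per-lineage birth rate.
#' @param mu per-lineage death rate.
#' @param rho sampling fraction in \[0, 1\].
#' @return An object of class \code{"time_prior_spec"}.
#' @export
time_prior_spec <- function(lambda = 1, mu = 1, rho = 0) {
  stopifnot(lambda >= 0, mu >= 0, rho >= 0, rho <= 1)
  structure(list(lambda = lambda, mu = mu, rho = rho),
            class = "time_prior_spec")
}

#' Birth-death kernel density of a non-root node age
#'
#' Density of an uncalibrated internal node age conditional on the root age,
#' under a birth-death process with sampling. Closed forms are used for all
#' parameter combinations, including the \code{rho = 0} limits.
#'
#' @param spec a \code{time_prior_spec}.
#' @param t node age(s) in (0, t_root).
#' @param t_root root age.
#' @param log return log density?
#' @return Density values; ages outside (0, t_root) have density 0
#'   (log density \code{-Inf}).
#' @export
bd_kernel_density <- function(spec, t, t_root, log = FALSE) {
  stopifnot(inherits(spec, "time_prior_spec"), t_root > 0)
  lam <- spec$lambda; mu <- spec$mu; rho <- spec$rho
  g <- numeric(length(t))
  inside <- t > 0 & t < t_root
  ti <- t[inside]
  if (abs(lam - mu) < 1e-12) {
    g[inside] <- if (rho == 0) 1 / t_root
      else (1 + rho * lam * t_root) / (t_root * (1 + rho * lam * ti)^2)
  } else {
    d <- lam - mu
    D <- function(x) d * exp(-d * x) + rho * lam * (1 - exp(-d * x))
    g[inside] <- d^2 * exp(-d * ti) * D(t_root) /
      (D(ti)^2 * (1 - exp(-d * t_root)))
  }
  if (log) ifelse(g > 0, base::log(g), -Inf) else g
}

## classify nodes of a calibrated tree once
node_roles <- function(ct) {
  n <- length(ct$phylo$tip.label)
  nn <- n + ct$phylo$Nnode
  root <- n + 1L
  internal <- (n + 1L):nn
  cal_ids <- as.integer(names(ct$calibrations))
  list(n = n, nn = nn, root = root, internal = internal,
       calibrated = cal_ids,
       free_kernel = setdiff(internal, c(root, cal_ids)),
       parents = tree_parents(ct$phylo),
       children = tree_children(ct$phylo))
}

root_is_constrained <- function(ct) {
  as.character(length(ct$phylo$tip.label) + 1L) %in% names(ct$calibrations)
}

#' Joint log prior of node ages
#'
#' Sum of log calibration densities over calibrated nodes plus the
#' birth-death kernel log density over uncalibrated non-root internal nodes,
#' conditional on the root age. Returns \code{-Inf} whenever any
#' ancestor-descendant age order is violated (truncation by rejection).
#' The root must carry a calibration density or fixed age.
#'
#' @param ct a \code{calibrated_tree}.
#' @param spec a \code{time_prior_spec}.
#' @param ages numeric vector of node ages indexed by ape node number (tips
#'   must be 0).
#' @param roles precomputed [node_roles] cache (internal use).
#' @return Log prior density (unnormalized across the truncation).
#' @export
joint_time_prior_logpdf <- function(ct, spec, ages, roles = node_roles(ct)) {
  if (!root_is_constrained(ct))
    stop("the root must carry a calibration density or fixed age")
  if (length(ages) != roles$nn || anyNA(ages[roles$internal]))
    stop("ages must assign a value to every node")
  if (any(ages < 0)) return(-Inf)
  ## ancestor > descendant everywhere
  e <- ct$phylo$edge
  if (any(ages[e[, 1]] <= ages[e[, 2]])) return(-Inf)
  lp <- 0
  for (nm in names(ct$calibrations)) {
    cal <- ct$calibrations[[nm]]
    a <- ages[as.integer(nm)]
    if (cal$family == "FIXED") {
      if (abs(a - cal$params$age) > 1e-12) return(-Inf)
    } else {
      lp <- lp + dcal(cal, a, log = TRUE)
    }
  }
  if (!is.finite(lp)) return(-Inf)
  if (length(roles$free_kernel))
    lp <- lp + sum(bd_kernel_density(spec, ages[roles$free_kernel],
                                     ages[roles$root], log = TRUE))
  lp
}

#' Sample the joint time prior
#'
#' Runs the MCMC sampler without sequence data (\code{likelihood_none()}) to
#' draw from the joint prior of node ages — the marginal priors this induces
#' at calibrated nodes can differ from the user-specified calibration
#' densities because of truncation.
#'
#' @param ct a \code{calibrated_tree} whose root is calibrated or fixed.
#' @param spec a \code{time_prior_spec}.
#' @param n number of retained samples.
#' @param seed integer seed.
#' @param ... further arguments passed to [mcmc_config()].
#' @return A trace data frame (one age column per internal node).
#' @export
sample_time_prior <- function(ct, spec, n = 10000, seed = 1, ...) {
  cfg <- mcmc_config(iterations = 3L * n, burnin = n, thin = 2L,
                     seed = seed, ...)
  run_mcmc(ct, spec, clock_model("sc"), likelihood_none(), cfg)
}
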