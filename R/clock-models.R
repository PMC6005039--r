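#' Molecular clock models
#'
#' Specification of the prior on branch substitution rates:
#' \describe{
#'   \item{sc}{Strict clock — a single rate \eqn{\mu_i} per locus.}
#'   \item{ir}{Independent log-normal rates — branch log-rates i.i.d.
#'     \eqn{N(\log\mu_i - \sigma_i^2/2, \sigma_i^2)}; the \eqn{-\sigma^2/2}
#'     correction makes the expected rate equal \eqn{\mu_i} at every
#'     timescale.}
#'   \item{ar}{Autocorrelated geometric Brownian rates — the rate assigned to
#'     a branch is the rate at its child node, which evolves from the parent
#'     node's rate over the branch duration \eqn{\Delta t}:
#'     \eqn{\log r \sim N(\log r_A - \sigma_i^2\Delta t/2,
#'     \sigma_i^2\Delta t)}, with the root rate equal to \eqn{\mu_i}. The
#'     log-rate variance grows with elapsed time, so closely related species
#'     behave almost clock-like while rates drift across deep divergences.}
#' }
#'
#' Across loci, the per-locus mean rates \eqn{\mu_i} follow a gamma-Dirichlet
#' prior: their average follows Gamma(\code{rate_prior}) and the proportions
#' follow a symmetric Dirichlet; likewise for the \eqn{\sigma_i^2}.
#'
#' @param model one of \code{"sc"}, \code{"ir"}, \code{"ar"}.
#' @param rate_prior c(shape, rate) of the gamma prior on the across-locus
#'   mean rate (default G(2, 40): mean 0.05 substitutions/site/100 My).
#' @param sigma2_prior c(shape, rate) of the gamma prior on the mean
#'   log-rate variance (default G(1, 10)); ignored under the strict clock.
#' @param dirichlet_alpha symmetric Dirichlet concentration for the
#'   across-locus partitioning.
#' @return An object of class \code{"clock_model"}.
#' @export
clock_model <- function(model = c("sc", "ir", "ar"), rate_prior = c(2, 40),
                        sigma2_prior = c(1, 10), dirichlet_alpha = 1) {
  model <- match.arg(model)
  stopifnot(length(rate_prior) == 2, all(rate_prior > 0),
            length(sigma2_prior) == 2, all(sigma2_prior > 0),
            dirichlet_alpha > 0)
  structure(list(model = model, rate_prior = rate_prior,
                 sigma2_prior = sigma2_prior,
                 dirichlet_alpha = dirichlet_alpha),
            class = "clock_model")
}

ldirichlet <- function(p, alpha) {
  k <- length(p)
  lgamma(k * alpha) - k * lgamma(alpha) + sum((alpha - 1) * log(p))
}

#' Gamma-Dirichlet log prior over locus rates
#'
#' Joint log density of the per-locus mean rates (and, for relaxed clocks,
#' per-locus log-rate variances): the across-locus average follows the gamma
#' prior and the proportions a symmetric Dirichlet, with the exact Jacobian
#' of the (average, proportions) to rates transform.
#'
#' @param spec a \code{clock_model}.
#' @param mu positive vector of per-locus mean rates.
#' @param sigma2 positive vector of per-locus variances (ignored for
#'   \code{"sc"}); must have the same length as \code{mu}.
#' @return Log density.
#' @export
locus_hyperprior_logpdf <- function(spec, mu, sigma2 = NULL) {
  stopifnot(inherits(spec, "clock_model"), all(mu > 0))
  gamma_dirichlet_lpdf <- function(x, a, b, alpha) {
    L <- length(x)
    xb <- mean(x)
    lp <- stats::dgamma(xb, a, b, log = TRUE)
    if (L > 1) {
      lp <- lp + ldirichlet(x / (L * xb), alpha) -
        L * log(L) - (L - 1) * log(xb)
    }
    lp
  }
  lp <- gamma_dirichlet_lpdf(mu, spec$rate_prior[1], spec$rate_prior[2],
                             spec$dirichlet_alpha)
  if (spec$model != "sc") {
    if (is.null(sigma2)) stop("sigma2 required for relaxed clocks")
    if (length(sigma2) != length(mu)) stop("length mismatch: mu vs sigma2")
    stopifnot(all(sigma2 > 0))
    lp <- lp + gamma_dirichlet_lpdf(sigma2, spec$sigma2_prior[1],
                                    spec$sigma2_prior[2],
                                    spec$dirichlet_alpha)
  }
  lp
}

#' Log prior of branch rates given the clock model
#'
#' @param spec a \code{clock_model}.
#' @param phylo the tree topology.
#' @param ages node ages indexed by node number.
#' @param rates matrix of branch rates (rows indexed by child node number,
#'   columns by locus); ignored under the strict clock.
#' @param mu per-locus mean rates.
#' @param sigma2 per-locus log-rate variances (relaxed clocks).
#' @return Log density of the rates given ages and hyperparameters. Under the
#'   strict clock the rates are a point mass at \code{mu} and the
#'   contribution is 0.
#' @export
branch_rate_logprior <- function(spec, phylo, ages, rates, mu,
                                 sigma2 = NULL) {
  stopifnot(inherits(spec, "clock_model"))
  if (spec$model == "sc") return(0)
  if (is.null(sigma2)) stop("sigma2 required for relaxed clocks")
  rk <- rates[phylo$edge[, 2], , drop = FALSE]
  if (anyNA(rk) || any(rk <= 0)) stop("branch rates must be positive")
  L <- length(mu)
  root <- length(phylo$tip.label) + 1L
  kids <- phylo$edge[, 2]
  pars <- phylo$edge[, 1]
  lp <- 0
  for (i in seq_len(L)) {
    if (spec$model == "ir") {
      lp <- lp + sum(stats::dlnorm(rates[kids, i],
                                   log(mu[i]) - sigma2[i] / 2,
                                   sqrt(sigma2[i]), log = TRUE))
    } else { # ar: geometric Brownian motion along branches
      r_parent <- ifelse(pars == root, mu[i], rates[pars, i])
      dt <- ages[pars] - ages[kids]
      v <- sigma2[i] * dt
      lp <- lp + sum(stats::dlnorm(rates[kids, i], log(r_parent) - v / 2,
                                   sqrt(v), log = TRUE))
    }
  }
  lp
}

#' Simulate branch rates under a clock model
#'
#' Simulator twin of [branch_rate_logprior()]. Hyperparameters are drawn
#' from their gamma-Dirichlet priors unless fixed values are supplied.
#'
#' @param spec a \code{clock_model}.
#' @param phylo tree topology.
#' @param ages node ages indexed by node number.
#' @param L number of loci.
#' @param seed integer seed (optional).
#' @param mu,sigma2 optional fixed hyperparameter vectors (length L).
#' @return A list with \code{mu}, \code{sigma2} and \code{rates} (matrix,
#'   rows = node numbers, columns = loci; row of a child node holds the rate
#'   of the branch above it).
#' @export
simulate_branch_rates <- function(spec, phylo, ages, L = 1, seed = NULL,
                                  mu = NULL, sigma2 = NULL) {
  stopifnot(inherits(spec, "clock_model"))
  if (!is.null(seed)) set.seed(seed)
  rgamma_dirichlet <- function(a, b, alpha) {
    xb <- stats::rgamma(1, a, b)
    g <- stats::rgamma(L, alpha, 1)
    L * xb * g / sum(g)
  }
  if (is.null(mu))
    mu <- rgamma_dirichlet(spec$rate_prior[1], spec$rate_prior[2],
                           spec$dirichlet_alpha)
  if (spec$model != "sc" && is.null(sigma2))
    sigma2 <- rgamma_dirichlet(spec$sigma2_prior[1], spec$sigma2_prior[2],
                               spec$dirichlet_alpha)
  nn <- length(phylo$tip.label) + phylo$Nnode
  root <- length(phylo$tip.label) + 1L
  rates <- matrix(NA_real_, nn, L)
  if (spec$model == "sc") {
    for (i in seq_len(L)) rates[, i] <- mu[i]
  } else if (spec$model == "ir") {
    for (i in seq_len(L))
      rates[, i] <- stats::rlnorm(nn, log(mu[i]) - sigma2[i] / 2,
                                  sqrt(sigma2[i]))
  } else { # ar
    e <- ape::reorder.phylo(phylo, "cladewise")$edge  # parents first
    for (i in seq_len(L)) {
      rates[root, i] <- mu[i]
      for (k in seq_len(nrow(e))) {
        par <- e[k, 1]; kid <- e[k, 2]
        v <- sigma2[i] * (ages[par] - ages[kid])
        rates[kid, i] <- stats::rlnorm(1, log(rates[par, i]) - v / 2,
                                       sqrt(v))
      }
    }
    rates[root, ] <- NA_real_  # root has no branch above it
  }
  list(mu = mu, sigma2 = sigma2, rates = rates)
}
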