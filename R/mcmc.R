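#' Likelihood sources for the dating MCMC
#'
#' The sampler can target the joint prior only (\code{likelihood_none}), the
#' exact Felsenstein likelihood (\code{likelihood_exact}), or the quadratic
#' branch-length approximation (\code{likelihood_approx}).
#'
#' @param aln an \code{alignment}.
#' @param sm a \code{subst_model}.
#' @param ba a \code{branch_approx} built by [build_branch_approx()].
#' @return An object of class \code{"lik_source"}.
#' @export
likelihood_none <- function() {
  structure(list(mode = "none", nloci = 1L), class = "lik_source")
}

#' @rdname likelihood_none
#' @export
likelihood_exact <- function(aln, sm) {
  stopifnot(inherits(aln, "alignment"), inherits(sm, "subst_model"))
  structure(list(mode = "exact", aln = aln, sm = sm,
                 nloci = length(aln$part_names)), class = "lik_source")
}

#' @rdname likelihood_none
#' @export
likelihood_approx <- function(ba) {
  stopifnot(inherits(ba, "branch_approx"))
  structure(list(mode = "approx", ba = ba, nloci = length(ba$parts)),
            class = "lik_source")
}

#' MCMC configuration
#'
#' @param iterations total iterations.
#' @param burnin iterations discarded (and used for step-size auto-tuning);
#'   default one quarter of the total.
#' @param thin sampling interval; default keeps at most 20,000 samples.
#' @param seed integer seed, recorded in the trace attributes.
#' @param beta likelihood power for power-posterior sampling (1 = posterior,
#'   0 = prior).
#' @param tune auto-tune proposal steps to 20-40\% acceptance during burn-in?
#' @return An object of class \code{"mcmc_config"}.
#' @export
mcmc_config <- function(iterations = 20000L, burnin = NULL, thin = NULL,
                        seed = 1L, beta = 1, tune = TRUE) {
  iterations <- as.integer(iterations)
  if (is.null(burnin)) burnin <- iterations %/% 4L
  burnin <- as.integer(burnin)
  stopifnot(iterations > burnin, burnin >= 0, beta >= 0, beta <= 1)
  if (is.null(thin))
    thin <- max(1L, as.integer(ceiling((iterations - burnin) / 20000)))
  structure(list(iterations = iterations, burnin = burnin,
                 thin = as.integer(thin), seed = as.integer(seed),
                 beta = beta, tune = tune), class = "mcmc_config")
}

## precompute per-partition pruning caches (patterns, tip CLVs)
make_lik_cache <- function(lik, phylo) {
  if (lik$mode != "exact") return(NULL)
  aln <- lik$aln
  ord <- match(phylo$tip.label, rownames(aln$seq))
  if (anyNA(ord))
    stop("unmatched tip(s): ",
         paste(phylo$tip.label[is.na(ord)], collapse = ", "))
  seqm <- aln$seq[ord, , drop = FALSE]
  po <- ape::reorder.phylo(phylo, "postorder")$edge
  parts <- lapply(seq_along(aln$part_names), function(p) {
    sp <- site_patterns(seqm[, aln$partition == p, drop = FALSE])
    tips <- lapply(seq_len(nrow(sp$patterns)),
                   function(i) tip_clv(sp$patterns[i, ]))
    list(tipclv = flatten_tips(tips), weights = sp$weights)
  })
  list(po = po, parts = parts, sm = lik$sm,
       n = length(phylo$tip.label), nn = length(phylo$tip.label) + phylo$Nnode)
}

## fast pruning against a cache; bl indexed by child node
cached_loglik_part <- function(cache, p, bl) {
  sm <- cache$sm
  part <- cache$parts[[p]]
  prune_loglik_cpp(part$tipclv, part$weights, cache$po, bl, sm$U, sm$Uinv,
                   sm$lambda, sm$freqs, sm$cat_rates, cache$n, cache$nn)
}

## branch lengths (child-node indexed) for locus i given a state
bl_locus <- function(state, phylo, clock, i) {
  kids <- phylo$edge[, 2]; pars <- phylo$edge[, 1]
  bl <- numeric(length(state$ages))
  dt <- state$ages[pars] - state$ages[kids]
  r <- if (clock$model == "sc") state$mu[i] else state$rates[kids, i]
  bl[kids] <- r * dt
  bl
}

lnL_locus <- function(state, phylo, clock, lik, cache, i) {
  if (lik$mode == "none") return(0)
  bl <- bl_locus(state, phylo, clock, i)
  if (lik$mode == "exact") return(cached_loglik_part(cache, i, bl))
  ap <- lik$ba$parts[[i]]
  if (is.null(ap$bhat)) return(0)
  bv <- bl[lik$ba$kids]
  d <- bv - ap$bhat
  ap$lnL0 + sum(ap$grad * d) + 0.5 * drop(t(d) %*% ap$hess %*% d)
}

## draw a topologically consistent initial state
init_state <- function(ct, tspec, clock, L) {
  roles <- node_roles(ct)
  phylo <- ct$phylo
  root_cal <- ct$calibrations[[as.character(roles$root)]]
  t_root <- if (root_cal$family == "FIXED") root_cal$params$age else
    qcal(root_cal, stats::runif(1, 0.2, 0.8))
  ages <- numeric(roles$nn)
  for (nd in postorder_nodes(phylo))
    ages[nd] <- max(ages[roles$children[[nd]]]) + stats::runif(1, 0.5, 1)
  ages[roles$internal] <- ages[roles$internal] / ages[roles$root] * t_root
  mu <- rep(clock$rate_prior[1] / clock$rate_prior[2], L)
  sigma2 <- if (clock$model == "sc") NULL else
    rep(clock$sigma2_prior[1] / clock$sigma2_prior[2], L)
  rates <- if (clock$model == "sc") NULL else
    matrix(rep(mu, each = roles$nn), roles$nn, L)
  list(ages = ages, mu = mu, sigma2 = sigma2, rates = rates)
}

#' Run the dating MCMC
#'
#' Metropolis-Hastings sampler over node ages, per-locus mean rates,
#' log-rate variances and (for relaxed clocks) per-branch rates, targeting
#' prior(ages) x prior(rates | ages) x likelihood^beta. Proposals are
#' sliding windows with reflection for ages (bounded by parent and child
#' ages), log-scale multipliers for rates and variances, and a whole-tree
#' rescale move (all ages x c, all rates / c) that leaves the strict-clock
#' likelihood invariant and helps mixing. Step sizes are auto-tuned to
#' 20-40\% acceptance during burn-in.
#'
#' @param ct a \code{calibrated_tree}; the root must be calibrated or fixed.
#' @param tspec a \code{time_prior_spec}.
#' @param clock a \code{clock_model}.
#' @param lik a \code{lik_source}.
#' @param cfg an \code{mcmc_config}.
#' @param init optional starting state (as returned in the trace's
#'   \code{final_state} attribute) for warm starts.
#' @return A data frame of class \code{"chrono_trace"}: columns \code{Gen},
#'   one age column \code{t_<node>} per internal node, \code{mu_<i>},
#'   \code{sigma2_<i>} (relaxed clocks) and \code{lnL}. Attributes:
#'   \code{final_state}, \code{acceptance}, \code{seed}.
#' @export
run_mcmc <- function(ct, tspec, clock, lik, cfg, init = NULL) {
  stopifnot(inherits(ct, "calibrated_tree"), inherits(tspec, "time_prior_spec"),
            inherits(clock, "clock_model"), inherits(lik, "lik_source"),
            inherits(cfg, "mcmc_config"))
  set.seed(cfg$seed)
  phylo <- ct$phylo
  roles <- node_roles(ct)
  if (!root_is_constrained(ct))
    stop("the root must carry a calibration density or fixed age")
  L <- lik$nloci
  relaxed <- clock$model != "sc"
  cache <- make_lik_cache(lik, phylo)
  kids <- phylo$edge[, 2]

  fixed_nodes <- as.integer(names(ct$calibrations))[
    vapply(ct$calibrations, function(c) c$family == "FIXED", logical(1))]
  free_ages <- setdiff(roles$internal, fixed_nodes)
  root_fixed <- roles$root %in% fixed_nodes

  components <- function(st) {
    lp_time <- joint_time_prior_logpdf(ct, tspec, st$ages, roles)
    if (!is.finite(lp_time))
      return(list(lp_time = -Inf, lp_hyper = -Inf, lp_rates = -Inf,
                  lnL = rep(-Inf, L)))
    lp_hyper <- locus_hyperprior_logpdf(clock, st$mu, st$sigma2)
    lp_rates <- branch_rate_logprior(clock, phylo, st$ages, st$rates,
                                     st$mu, st$sigma2)
    lnL <- vapply(seq_len(L), function(i)
      lnL_locus(st, phylo, clock, lik, cache, i), numeric(1))
    list(lp_time = lp_time, lp_hyper = lp_hyper, lp_rates = lp_rates,
         lnL = lnL)
  }
  total <- function(cmp) cmp$lp_time + cmp$lp_hyper + cmp$lp_rates +
    cfg$beta * sum(cmp$lnL)

  st <- init
  cmp <- if (!is.null(st)) components(st) else NULL
  tries <- 0
  while (is.null(cmp) || !is.finite(total(cmp))) {
    tries <- tries + 1
    if (tries > 100) stop("could not find a valid starting state")
    st <- init_state(ct, tspec, clock, L)
    cmp <- components(st)
  }

  steps <- c(age = 0.1, mu = 0.5, sigma2 = 0.5, rate = 0.5, rescale = 0.2)
  acc <- att <- steps * 0
  acc_tot <- att_tot <- steps * 0

  reflect <- function(x, lo, hi) {
    while (x < lo || x > hi) {
      if (x < lo) x <- 2 * lo - x
      if (x > hi) x <- 2 * hi - x
    }
    x
  }

  n_keep <- (cfg$iterations - cfg$burnin) %/% cfg$thin
  inodes <- roles$internal
  cn_age <- paste0("t_", inodes)
  cn_mu <- paste0("mu_", seq_len(L))
  cn_s2 <- if (relaxed) paste0("sigma2_", seq_len(L)) else character(0)
  out <- matrix(NA_real_, n_keep,
                1 + length(cn_age) + L + length(cn_s2) + 1,
                dimnames = list(NULL, c("Gen", cn_age, cn_mu, cn_s2, "lnL")))
  kept <- 0L

  for (it in seq_len(cfg$iterations)) {
    ## -- node ages
    for (j in free_ages) {
      lo <- max(st$ages[roles$children[[j]]])
      hi <- if (j == roles$root) Inf else st$ages[roles$parents[j]]
      t_new <- st$ages[j] + stats::runif(1, -steps["age"], steps["age"])
      t_new <- reflect(t_new, lo, if (is.finite(hi)) hi else Inf)
      st2 <- st; st2$ages[j] <- t_new
      lp_time2 <- joint_time_prior_logpdf(ct, tspec, st2$ages, roles)
      att["age"] <- att["age"] + 1
      if (is.finite(lp_time2)) {
        lp_rates2 <- if (clock$model == "ar")
          branch_rate_logprior(clock, phylo, st2$ages, st2$rates, st2$mu,
                               st2$sigma2) else cmp$lp_rates
        lnL2 <- vapply(seq_len(L), function(i)
          lnL_locus(st2, phylo, clock, lik, cache, i), numeric(1))
        dl <- (lp_time2 - cmp$lp_time) + (lp_rates2 - cmp$lp_rates) +
          cfg$beta * (sum(lnL2) - sum(cmp$lnL))
        if (log(stats::runif(1)) < dl) {
          st <- st2
          cmp$lp_time <- lp_time2; cmp$lp_rates <- lp_rates2; cmp$lnL <- lnL2
          acc["age"] <- acc["age"] + 1
        }
      }
    }
    ## -- locus mean rates
    for (i in seq_len(L)) {
      eps <- stats::runif(1, -steps["mu"], steps["mu"])
      st2 <- st; st2$mu[i] <- st$mu[i] * exp(eps)
      lp_hyper2 <- locus_hyperprior_logpdf(clock, st2$mu, st2$sigma2)
      lp_rates2 <- branch_rate_logprior(clock, phylo, st2$ages, st2$rates,
                                        st2$mu, st2$sigma2)
      lnL2 <- cmp$lnL
      if (!relaxed) lnL2[i] <- lnL_locus(st2, phylo, clock, lik, cache, i)
      dl <- (lp_hyper2 - cmp$lp_hyper) + (lp_rates2 - cmp$lp_rates) +
        cfg$beta * (sum(lnL2) - sum(cmp$lnL)) + eps
      att["mu"] <- att["mu"] + 1
      if (is.finite(dl) && log(stats::runif(1)) < dl) {
        st <- st2
        cmp$lp_hyper <- lp_hyper2; cmp$lp_rates <- lp_rates2; cmp$lnL <- lnL2
        acc["mu"] <- acc["mu"] + 1
      }
    }
    if (relaxed) {
      ## -- sigma2
      for (i in seq_len(L)) {
        eps <- stats::runif(1, -steps["sigma2"], steps["sigma2"])
        st2 <- st; st2$sigma2[i] <- st$sigma2[i] * exp(eps)
        lp_hyper2 <- locus_hyperprior_logpdf(clock, st2$mu, st2$sigma2)
        lp_rates2 <- branch_rate_logprior(clock, phylo, st2$ages, st2$rates,
                                          st2$mu, st2$sigma2)
        dl <- (lp_hyper2 - cmp$lp_hyper) + (lp_rates2 - cmp$lp_rates) + eps
        att["sigma2"] <- att["sigma2"] + 1
        if (is.finite(dl) && log(stats::runif(1)) < dl) {
          st <- st2
          cmp$lp_hyper <- lp_hyper2; cmp$lp_rates <- lp_rates2
          acc["sigma2"] <- acc["sigma2"] + 1
        }
      }
      ## -- branch rates
      for (i in seq_len(L)) for (k in kids) {
        eps <- stats::runif(1, -steps["rate"], steps["rate"])
        st2 <- st; st2$rates[k, i] <- st$rates[k, i] * exp(eps)
        lp_rates2 <- branch_rate_logprior(clock, phylo, st2$ages, st2$rates,
                                          st2$mu, st2$sigma2)
        lnL2 <- cmp$lnL
        lnL2[i] <- lnL_locus(st2, phylo, clock, lik, cache, i)
        dl <- (lp_rates2 - cmp$lp_rates) +
          cfg$beta * (lnL2[i] - cmp$lnL[i]) + eps
        att["rate"] <- att["rate"] + 1
        if (is.finite(dl) && log(stats::runif(1)) < dl) {
          st <- st2
          cmp$lp_rates <- lp_rates2; cmp$lnL <- lnL2
          acc["rate"] <- acc["rate"] + 1
        }
      }
    }
    ## -- whole-tree rescale (mixing move)
    if (!root_fixed) {
      eps <- stats::runif(1, -steps["rescale"], steps["rescale"])
      cc <- exp(eps)
      st2 <- st
      st2$ages[inodes] <- st$ages[inodes] * cc
      st2$mu <- st$mu / cc
      n_up <- length(inodes)
      n_down <- L
      if (relaxed) {
        st2$rates <- st$rates / cc
        n_down <- n_down + L * length(kids)
      }
      cmp2 <- components(st2)
      dl <- total(cmp2) - total(cmp) + (n_up - n_down) * eps
      att["rescale"] <- att["rescale"] + 1
      if (is.finite(dl) && log(stats::runif(1)) < dl) {
        st <- st2; cmp <- cmp2
        acc["rescale"] <- acc["rescale"] + 1
      }
    }
    ## -- adaptation during burn-in
    if (cfg$tune && it <= cfg$burnin && it %% 25 == 0) {
      for (cl in names(steps)) {
        if (att[cl] > 0) {
          r <- acc[cl] / att[cl]
          steps[cl] <- min(max(steps[cl] * exp(1.5 * (r - 0.3)), 1e-6), 1e3)
        }
      }
      acc_tot <- acc_tot + acc; att_tot <- att_tot + att
      acc[] <- 0; att[] <- 0
    }
    ## -- record
    if (it > cfg$burnin && (it - cfg$burnin) %% cfg$thin == 0) {
      kept <- kept + 1L
      row <- c(it, st$ages[inodes], st$mu,
               if (relaxed) st$sigma2 else NULL, sum(cmp$lnL))
      out[kept, ] <- row
    }
  }
  acc_tot <- acc_tot + acc; att_tot <- att_tot + att
  tr <- as.data.frame(out[seq_len(kept), , drop = FALSE])
  attr(tr, "final_state") <- st
  attr(tr, "acceptance") <- ifelse(att_tot > 0, acc_tot / att_tot, NA)
  attr(tr, "seed") <- cfg$seed
  class(tr) <- c("chrono_trace", "data.frame")
  tr
}

#' Effective sample size (initial positive sequence)
#'
#' Geyer's initial-positive-sequence estimator from the autocorrelation
#' function. A constant series has ESS equal to its length.
#'
#' @param x numeric vector.
#' @return Estimated effective sample size, capped at \code{length(x)}.
#' @export
ess <- function(x) {
  n <- length(x)
  if (n < 3 || stats::var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 2, 2000), plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  tau <- -1
  m <- 1
  while (m + 1 <= length(ac)) {
    g <- ac[m] + ac[m + 1]
    if (g < 0) break
    tau <- tau + 2 * g
    m <- m + 2
  }
  min(n, n / max(tau, 1))
}

#' Summarize a trace
#'
#' Posterior mean, equal-tailed 95\% credibility interval and effective
#' sample size per parameter column.
#'
#' @param trace a trace data frame (the \code{Gen} column is skipped).
#' @return A data frame with columns \code{parameter}, \code{mean},
#'   \code{q2.5}, \code{q97.5}, \code{ess}.
#' @export
summarize_trace <- function(trace) {
  stopifnot(is.data.frame(trace))
  if (nrow(trace) == 0) stop("empty trace")
  cols <- setdiff(names(trace), "Gen")
  data.frame(
    parameter = cols,
    mean = vapply(cols, function(c) mean(trace[[c]]), numeric(1)),
    q2.5 = vapply(cols, function(c)
      unname(stats::quantile(trace[[c]], 0.025)), numeric(1)),
    q97.5 = vapply(cols, function(c)
      unname(stats::quantile(trace[[c]], 0.975)), numeric(1)),
    ess = vapply(cols, function(c) ess(trace[[c]]), numeric(1)),
    row.names = NULL)
}

#' Compare two independent traces for convergence
#'
#' Per shared parameter, the absolute difference of means divided by the
#' pooled 95\% CI width; parameters exceeding 0.1 are flagged.
#'
#' @param trace1,trace2 traces from independent-seed runs of the same model.
#' @return A data frame with a logical \code{flag} column.
#' @export
convergence_check <- function(trace1, trace2) {
  if (!identical(sort(names(trace1)), sort(names(trace2))))
    stop("mismatched trace columns")
  s1 <- summarize_trace(trace1)
  s2 <- summarize_trace(trace2)
  s2 <- s2[match(s1$parameter, s2$parameter), ]
  w <- ((s1$q97.5 - s1$q2.5) + (s2$q97.5 - s2$q2.5)) / 2
  rel <- abs(s1$mean - s2$mean) / ifelse(w > 0, w, Inf)
  rel[w == 0 & abs(s1$mean - s2$mean) > 0] <- Inf
  data.frame(parameter = s1$parameter, rel_diff = rel, flag = rel > 0.1)
}

#' Generic 1-D Metropolis sampler
#'
#' Random-walk Metropolis on a scalar log target; used for tree-free targets
#' such as conjugate toys in thermodynamic-integration checks.
#'
#' @param logtarget function of one numeric argument returning a log density
#'   (\code{-Inf} outside the support).
#' @param init starting value (must have finite log target).
#' @param n retained samples.
#' @param step random-walk half-width.
#' @param burnin discarded initial iterations.
#' @param seed optional seed.
#' @return Numeric vector of \code{n} samples.
#' @export
mh_sample <- function(logtarget, init, n, step = 1, burnin = n %/% 4,
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- init
  lx <- logtarget(x)
  if (!is.finite(lx)) stop("initial value has zero target density")
  out <- numeric(n)
  for (it in seq_len(n + burnin)) {
    xp <- x + stats::runif(1, -step, step)
    lp <- logtarget(xp)
    if (is.finite(lp) && log(stats::runif(1)) < lp - lx) {
      x <- xp; lx <- lp
    }
    if (it > burnin) out[it - burnin] <- x
  }
  out
}
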