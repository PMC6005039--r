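test_that("the 1-D Metropolis kernel reproduces a gamma target", {
  x <- mh_sample(function(th) dgamma(th, 3, 2, log = TRUE), init = 1,
                 n = 1e5, step = 1.5, seed = 31)
  ## thin before the KS test: raw random-walk output is autocorrelated,
  ## which the test statistic's null distribution does not allow for
  xt <- x[seq(1, length(x), by = 20)]
  p <- suppressWarnings(ks.test(xt, function(q) pgamma(q, 3, 2))$p.value)
  expect_gt(p, 0.01)
  expect_lt(abs(mean(x) - 1.5), 5 * sqrt(3 / 4 / ess(x)))
})

test_that("trace summaries: constants, known laws, autocorrelated series", {
  ## constant column
  s <- summarize_trace(data.frame(x = rep(2.5, 100), lnL = rep(0, 100)))
  row <- s[s$parameter == "x", ]
  expect_equal(row$mean, 2.5)
  expect_equal(row$q97.5 - row$q2.5, 0)
  expect_equal(row$ess, 100)
  ## iid normal draws
  set.seed(32)
  z <- rnorm(1e5)
  sz <- summarize_trace(data.frame(z = z))
  expect_lt(abs(sz$mean), 3 / sqrt(1e5))
  expect_equal(sz$q2.5, -1.96, tolerance = 0.02)
  expect_equal(sz$q97.5, 1.96, tolerance = 0.02)
  ## AR(1): ESS ~ n (1 - phi) / (1 + phi)
  phi <- 0.9
  n <- 5e4
  e <- rnorm(n)
  x <- as.numeric(stats::filter(e, phi, method = "recursive"))
  expect_equal(ess(x), n * (1 - phi) / (1 + phi), tolerance = 0.2)
  expect_error(summarize_trace(data.frame(x = numeric(0))), "empty")
})

test_that("convergence check flags shifted chains and clears identical ones", {
  set.seed(33)
  tr1 <- data.frame(a = rnorm(2000), lnL = rnorm(2000))
  cc <- convergence_check(tr1, tr1)
  expect_false(any(cc$flag))
  tr2 <- tr1
  tr2$a <- tr2$a + 10 * (quantile(tr1$a, 0.975) - quantile(tr1$a, 0.025))
  expect_true(any(convergence_check(tr1, tr2)$flag))
  expect_error(convergence_check(tr1, data.frame(b = 1, lnL = 1)),
               "mismatch")
})

test_that("power 0 reproduces the prior-only chain exactly", {
  sim <- simulate_dataset(ntips = 4, clock = clock_model("sc"),
                          sm = subst_model("JC"), sites = 200, seed = 34,
                          mu = 0.2)
  ct <- calibrated_tree(sim$phylo, stats::setNames(list(cal_fixed(1)), "5"))
  cfg0 <- mcmc_config(iterations = 2000, burnin = 500, thin = 1, seed = 77,
                      beta = 0)
  tr_b0 <- run_mcmc(ct, time_prior_spec(), clock_model("sc"),
                    likelihood_exact(sim$aln, subst_model("JC")), cfg0)
  tr_pr <- run_mcmc(ct, time_prior_spec(), clock_model("sc"),
                    likelihood_none(), cfg0)
  cols <- c("t_5", "t_6", "t_7", "mu_1")
  expect_equal(tr_b0[cols], tr_pr[cols])
})

test_that("every retained sample satisfies ancestor-descendant ordering", {
  ct <- read_calibrated_newick("(((A,B)'G(2,8)',C),D);")
  n <- 4
  ct$calibrations[[as.character(n + 1)]] <- cal_b(0.8, 1.2, 0.025, 0.025)
  ct <- calibrated_tree(ct$phylo, ct$calibrations)
  tr <- sample_time_prior(ct, time_prior_spec(), n = 4000, seed = 35)
  ## topology: 5 = root, 6 above 7
  expect_true(all(tr$t_5 > tr$t_6))
  expect_true(all(tr$t_6 > tr$t_7))
  expect_true(all(tr$t_7 > 0))
})

test_that("strict-clock likelihood is invariant under the rescale move", {
  sim <- simulate_dataset(ntips = 4, clock = clock_model("sc"),
                          sm = subst_model("JC"), sites = 100, seed = 36,
                          mu = 0.25)
  sm <- subst_model("JC")
  for (cc in c(0.5, 1.3, 2)) {
    ll1 <- exact_loglik(sim$aln, sim$phylo,
                        bl_from_ages(sim$phylo, sim$ages, 0.25), sm)
    ll2 <- exact_loglik(sim$aln, sim$phylo,
                        bl_from_ages(sim$phylo, sim$ages * cc, 0.25 / cc), sm)
    expect_equal(ll1, ll2, tolerance = 1e-10)
  }
})

test_that("impossible constraints fail after bounded re-initialization", {
  ct <- read_calibrated_newick("((A,B),C);")
  cals <- stats::setNames(list(cal_fixed(1), cal_fixed(2)), c("4", "5"))
  ct <- calibrated_tree(ct$phylo, cals)  # child fixed older than root
  expect_error(run_mcmc(ct, time_prior_spec(), clock_model("sc"),
                        likelihood_none(), mcmc_config(iterations = 100,
                                                       burnin = 10)),
               "starting state")
})

test_that("independent seeds agree on the strict-clock benchmark", {
  sim <- simulate_dataset(ntips = 4, clock = clock_model("sc"),
                          sm = subst_model("JC"), sites = 500, seed = 37,
                          mu = 0.2)
  ct <- calibrated_tree(sim$phylo, stats::setNames(list(cal_fixed(1)), "5"))
  lik <- likelihood_exact(sim$aln, subst_model("JC"))
  cfg1 <- mcmc_config(iterations = 6000, burnin = 1500, seed = 1)
  cfg2 <- mcmc_config(iterations = 6000, burnin = 1500, seed = 2)
  tr1 <- run_mcmc(ct, time_prior_spec(), clock_model("sc"), lik, cfg1)
  tr2 <- run_mcmc(ct, time_prior_spec(), clock_model("sc"), lik, cfg2)
  cc <- convergence_check(tr1, tr2)
  expect_false(any(cc$flag[cc$parameter != "lnL"]))
})
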