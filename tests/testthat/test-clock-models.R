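balanced4 <- function(root_age = 1, inner = c(0.4, 0.6)) {
  phylo <- ape::read.tree(text = "((A,B),(C,D));")
  list(phylo = phylo, ages = c(0, 0, 0, 0, root_age, inner))
}

test_that("independent log-normal rates have mean mu at every timescale", {
  tr <- balanced4()
  set.seed(5)
  r <- replicate(2e4, simulate_branch_rates(
    clock_model("ir"), tr$phylo, tr$ages, mu = 1, sigma2 = 0.04)$rates[1, 1])
  se <- sd(r) / sqrt(length(r))
  expect_lt(abs(mean(r) - 1), 3 * se)
})

test_that("autocorrelated rates: continuity limit and variance additivity", {
  ## tiny elapsed time: child rate collapses onto the parent rate
  tr <- balanced4(root_age = 1, inner = c(1 - 1e-8, 1 - 1e-8))
  set.seed(6)
  out <- simulate_branch_rates(clock_model("ar"), tr$phylo, tr$ages,
                               mu = 0.7, sigma2 = 0.5)
  expect_equal(unname(out$rates[6, 1]), 0.7, tolerance = 1e-3)
  ## log-rate variance adds along a two-branch path (caterpillar tip)
  cat3 <- ape::read.tree(text = "((A,B),C);")
  ages3 <- c(0, 0, 0, 1, 0.6)  # path root -> node5 (0.4) -> tip A (0.6)
  s2 <- 0.3
  set.seed(7)
  ra <- replicate(3e4, simulate_branch_rates(
    clock_model("ar"), cat3, ages3, mu = 1, sigma2 = s2)$rates[1, 1])
  v <- var(log(ra))
  expect_equal(v, s2 * 1.0, tolerance = 0.05)  # 0.4 + 0.6 elapsed
})

test_that("sister-branch log-rates correlate through their shared path", {
  ## under geometric Brownian motion the sister log-rates share the
  ## root-to-parent path: cov = sigma2 * (root_age - parent_age), and both
  ## variances are sigma2 * root_age, so cor = 1 - parent_age / root_age
  set.seed(8)
  cor_at <- function(parent_age) {
    tr <- balanced4(root_age = 1, inner = c(parent_age, 0.5))
    sims <- replicate(5e3, simulate_branch_rates(
      clock_model("ar"), tr$phylo, tr$ages, mu = 1,
      sigma2 = 0.4)$rates[c(1, 2), 1])
    cor(log(sims[1, ]), log(sims[2, ]))
  }
  near_tips <- cor_at(0.2)
  near_root <- cor_at(0.9)
  expect_gt(near_tips, 0)
  expect_gt(near_root, 0)
  expect_gt(near_tips, near_root)
  expect_equal(near_tips, 0.8, tolerance = 0.1)
  expect_equal(near_root, 0.1, tolerance = 0.5)
})

test_that("strict clock is the small-variance limit of both relaxed clocks", {
  tr <- balanced4()
  set.seed(9)
  for (m in c("ir", "ar")) {
    out <- simulate_branch_rates(clock_model(m), tr$phylo, tr$ages,
                                 mu = 0.3, sigma2 = 1e-6)
    r <- out$rates[tr$phylo$edge[, 2], 1]
    expect_lt(max(abs(r - 0.3) / 0.3), 0.01, label = m)
  }
})

test_that("gamma-Dirichlet hyperprior: collapse, symmetry, simulator mean", {
  cm <- clock_model("sc", rate_prior = c(2, 40))
  ## single locus reduces to the plain gamma
  expect_equal(locus_hyperprior_logpdf(cm, 0.07),
               dgamma(0.07, 2, 40, log = TRUE))
  ## permutation symmetry across loci
  cmr <- clock_model("ir", rate_prior = c(2, 40), sigma2_prior = c(1, 10))
  mu <- c(0.02, 0.07, 0.04); s2 <- c(0.1, 0.3, 0.2)
  expect_equal(locus_hyperprior_logpdf(cmr, mu, s2),
               locus_hyperprior_logpdf(cmr, rev(mu), rev(s2)))
  expect_error(locus_hyperprior_logpdf(cmr, mu, s2[1:2]), "mismatch")
  ## simulated mean rate honours the G(2, 40) mean of 0.05
  tr <- balanced4()
  set.seed(10)
  mus <- replicate(2e4, mean(simulate_branch_rates(
    clock_model("sc"), tr$phylo, tr$ages, L = 3)$mu))
  expect_lt(abs(mean(mus) - 0.05), 3 * sd(mus) / sqrt(length(mus)))
})

test_that("density and simulator agree for one-branch IR rates", {
  tr <- balanced4()
  set.seed(11)
  r <- replicate(2e4, simulate_branch_rates(
    clock_model("ir"), tr$phylo, tr$ages, mu = 1, sigma2 = 0.25)$rates[1, 1])
  qs <- quantile(r, seq(0.05, 0.95, by = 0.05))
  breaks <- c(0, qs, Inf)
  obs <- table(cut(r, breaks))
  pr <- diff(plnorm(breaks, -0.125, 0.5))
  expect_gt(suppressWarnings(chisq.test(obs, p = pr)$p.value), 0.01)
})

test_that("branch-rate log prior matches analytic forms", {
  tr <- balanced4()
  kids <- tr$phylo$edge[, 2]
  nn <- 7
  cm_ir <- clock_model("ir")
  rates <- matrix(NA_real_, nn, 1)
  rates[kids, 1] <- c(0.8, 1.2, 0.9, 1.1, 1.0, 1.05)
  lp <- branch_rate_logprior(cm_ir, tr$phylo, tr$ages, rates, 1, 0.04)
  expect_equal(lp, sum(dlnorm(rates[kids, 1], -0.02, 0.2, log = TRUE)))
  ## strict clock contributes nothing
  expect_equal(branch_rate_logprior(clock_model("sc"), tr$phylo, tr$ages,
                                    NULL, 1), 0)
  ## AR: manual recursion on the balanced tree
  cm_ar <- clock_model("ar")
  s2 <- 0.09
  lp_ar <- branch_rate_logprior(cm_ar, tr$phylo, tr$ages, rates, 1, s2)
  manual <- 0
  pars <- tr$phylo$edge[, 1]
  for (e in seq_along(kids)) {
    rp <- if (pars[e] == 5) 1 else rates[pars[e], 1]
    dt <- tr$ages[pars[e]] - tr$ages[kids[e]]
    manual <- manual + dlnorm(rates[kids[e], 1],
                              log(rp) - s2 * dt / 2, sqrt(s2 * dt),
                              log = TRUE)
  }
  expect_equal(lp_ar, manual)
})
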