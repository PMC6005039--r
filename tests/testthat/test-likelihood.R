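two_tip <- function() ape::read.tree(text = "(A:0.1,B:0.1);")

test_that("zero-distance identical sequences give log(1/4) per site", {
  aln <- make_alignment(matrix(c("A", "A"), 2, 1,
                               dimnames = list(c("A", "B"), NULL)))
  ll <- exact_loglik(aln, two_tip(), numeric(3), subst_model("JC"))
  expect_equal(ll, log(1 / 4))
})

test_that("two-tip JC matches the closed-form transition probability", {
  sm <- subst_model("JC")
  phy <- two_tip()
  set.seed(12)
  for (case in 1:10) {
    t_tot <- runif(1, 0.01, 1.5)
    same <- sample(c(TRUE, FALSE), 1)
    pair <- if (same) c("A", "A") else c("A", "G")
    aln <- make_alignment(matrix(pair, 2, 1,
                                 dimnames = list(c("A", "B"), NULL)))
    bl <- numeric(3); bl[1] <- t_tot * 0.3; bl[2] <- t_tot * 0.7
    p_same <- 1 / 4 + 3 / 4 * exp(-4 * t_tot / 3)
    expected <- if (same) log(p_same / 4) else log((1 - p_same) / 12)
    expect_equal(exact_loglik(aln, phy, bl, sm), expected,
                 tolerance = 1e-12)
  }
})

test_that("pruning equals brute-force ancestral-state enumeration", {
  sm <- subst_model("HKY", kappa = 3, freqs = c(0.3, 0.2, 0.3, 0.2),
                    gamma_shape = 0.7, ncat = 4)
  sim <- simulate_dataset(ntips = 4, clock = clock_model("sc"), sm = sm,
                          sites = 5, seed = 3, mu = 0.3)
  phy <- sim$phylo
  bl <- bl_from_ages(phy, sim$ages, 0.3)
  ll <- exact_loglik(sim$aln, phy, bl, sm)
  smap <- stats::setNames(1:4, c("A", "C", "G", "T"))
  seqm <- sim$aln$seq[match(phy$tip.label, rownames(sim$aln$seq)), ]
  brute <- 0
  for (s in 1:5) {
    lik <- 0
    for (k in 1:4) {
      P <- lapply(bl * sm$cat_rates[k], function(b) chronodate:::tpm(sm, b))
      for (i5 in 1:4) for (i6 in 1:4) for (i7 in 1:4) {
        ist <- c(NA, NA, NA, NA, i5, i6, i7)
        pr <- sm$freqs[i5]
        for (e in seq_len(nrow(phy$edge))) {
          kid <- phy$edge[e, 2]
          kst <- if (kid <= 4) smap[[seqm[kid, s]]] else ist[kid]
          pr <- pr * P[[kid]][ist[phy$edge[e, 1]], kst]
        }
        lik <- lik + pr / 4
      }
    }
    brute <- brute + log(lik)
  }
  expect_equal(ll, brute, tolerance = 1e-10)
})

test_that("HKY with kappa 1 and equal frequencies equals JC", {
  sim <- simulate_dataset(ntips = 4, clock = clock_model("sc"),
                          sm = subst_model("JC"), sites = 50, seed = 4,
                          mu = 0.2)
  bl <- bl_from_ages(sim$phylo, sim$ages, 0.2)
  expect_equal(exact_loglik(sim$aln, sim$phylo, bl, subst_model("HKY", 1)),
               exact_loglik(sim$aln, sim$phylo, bl, subst_model("JC")),
               tolerance = 1e-12)
})

test_that("likelihood is invariant to sliding the root along its edge", {
  ## pulley principle for reversible models: only the sum of the two
  ## root-adjacent branch lengths matters
  sm <- subst_model("HKY", kappa = 2, freqs = c(0.35, 0.15, 0.2, 0.3),
                    gamma_shape = 0.5, ncat = 4)
  sim <- simulate_dataset(ntips = 5, clock = clock_model("sc"), sm = sm,
                          sites = 40, seed = 5, mu = 0.3)
  phy <- sim$phylo
  bl <- bl_from_ages(phy, sim$ages, 0.3)
  root_kids <- phy$edge[phy$edge[, 1] == 6, 2]
  tot <- sum(bl[root_kids])
  ll <- exact_loglik(sim$aln, phy, bl, sm)
  for (f in c(0, 0.25, 0.9, 1)) {
    bl2 <- bl
    bl2[root_kids] <- c(f, 1 - f) * tot
    expect_equal(exact_loglik(sim$aln, phy, bl2, sm), ll, tolerance = 1e-9)
  }
})

test_that("multi-partition likelihood factorizes", {
  sm <- subst_model("JC")
  sim <- simulate_dataset(ntips = 4, clock = clock_model("sc"), sm = sm,
                          sites = c(30, 20), L = 2, seed = 6, mu = c(0.2, 0.2))
  bl <- bl_from_ages(sim$phylo, sim$ages, 0.2)
  joint <- exact_loglik(sim$aln, sim$phylo, cbind(bl, bl), sm)
  a1 <- make_alignment(sim$aln$seq[, sim$aln$partition == 1])
  a2 <- make_alignment(sim$aln$seq[, sim$aln$partition == 2])
  expect_equal(joint, exact_loglik(a1, sim$phylo, bl, sm) +
                 exact_loglik(a2, sim$phylo, bl, sm), tolerance = 1e-12)
})

test_that("unmatched tips are rejected", {
  aln <- make_alignment(matrix("A", 2, 1, dimnames = list(c("X", "B"), NULL)))
  expect_error(exact_loglik(aln, two_tip(), numeric(3), subst_model("JC")),
               "unmatched")
})

test_that("branch-length approximation is a faithful local surrogate", {
  ## well-separated node ages so no branch sits on the zero boundary
  sm <- subst_model("JC")
  phylo <- ape::read.tree(text = "((A,B),(C,D));")
  ages <- c(0, 0, 0, 0, 1, 0.55, 0.35)
  aln <- simulate_alignment(phylo, ages, rates = 0.3, sm = sm,
                            sites = 1000, seed = 13)
  sim <- list(phylo = phylo, ages = ages, aln = aln)
  truth <- bl_from_ages(sim$phylo, sim$ages, 0.3)
  ba <- build_branch_approx(sim$aln, sim$phylo, sm)
  ap <- ba$parts[[1]]
  expect_true(ap$ok)
  ## the approximation lives on the unrooted parameterization: the two
  ## root-adjacent lengths share one (summed) parameter
  truth_par <- as.numeric(rowsum(truth[ba$kids], ba$param_of))
  np <- length(truth_par)
  ## MLE within 3 approximate SE of the generating lengths
  se <- sqrt(diag(solve(-ap$hess)))
  expect_true(all(is.finite(se)))
  expect_true(all(abs(ap$bhat - truth_par) < 3 * se + 1e-3))
  ## optimality: tiny gradient, negative-semidefinite curvature
  expect_lt(max(abs(ap$grad)), 1e-4 * max(1, abs(ap$lnL0)))
  ev <- eigen((ap$hess + t(ap$hess)) / 2, symmetric = TRUE)$values
  expect_true(all(ev <= 1e-6 * max(abs(ev))))
  ## exact at the MLE (full root-pair sum placed on one side)
  par_to_bl <- function(pv) {
    bl <- numeric(7)
    bl[ba$kids] <- pv[ba$param_of]
    rk <- ba$kids[ba$param_of == np]
    bl[rk] <- c(pv[np], 0)
    bl
  }
  expect_equal(approx_loglik(ba, par_to_bl(ap$bhat)), ap$lnL0)
  ## close to exact within 2 SE of the MLE
  set.seed(14)
  for (i in 1:5) {
    pv <- pmax(ap$bhat + runif(np, -2, 2) * se, 1e-8)
    bl2 <- par_to_bl(pv)
    d <- abs(approx_loglik(ba, bl2) - exact_loglik(sim$aln, sim$phylo, bl2, sm))
    expect_lt(d, 1.0)
  }
  ## far away: may diverge from the exact value but stays finite
  expect_true(is.finite(approx_loglik(ba, par_to_bl(ap$bhat * 5))))
})
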