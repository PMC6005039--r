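# Shared fixtures, all built in code.

# 3-tip tree with the root age fixed: the single free node is uniform on
# (0, root) under the default birth-death kernel.
fixed_root_tree <- function(root_age = 1) {
  ct <- read_calibrated_newick("((A,B),C);")
  calibrated_tree(ct$phylo,
                  stats::setNames(list(cal_fixed(root_age)), "4"))
}

# Representative parameter sets, one per calibration family, drawn from the
# published calibration table for this kind of analysis.
example_calibrations <- function() {
  list(
    B  = cal_b(0.112, 0.28, 0.01, 0.10),
    L  = cal_l(0.337, 0.1, 2, 0.05),
    ST = cal_st(0.4754, 0.0632, 0.98, 22.85),
    S2N = cal_s2n(0.474, 0.65, 0.0365, -3400, 0.6502, 0.1375, 11409),
    G  = cal_gamma(36, 36.9)
  )
}

# Total integral of a calibration pdf over (0, Inf) by adaptive quadrature.
cal_integral <- function(d) {
  stats::integrate(function(t) dcal(d, t), 0, Inf, rel.tol = 1e-9,
                   subdivisions = 500L)$value
}

# Branch lengths (child-node indexed) implied by ages and one scalar rate.
bl_from_ages <- function(phylo, ages, rate) {
  bl <- numeric(length(phylo$tip.label) + phylo$Nnode)
  kids <- phylo$edge[, 2]
  bl[kids] <- rate * (ages[phylo$edge[, 1]] - ages[kids])
  bl
}
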