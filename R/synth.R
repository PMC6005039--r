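#' Simulate a random time-tree
#'
#' Random labeled topology by uniform pair merging, with the internal node
#' ages placed as sorted uniforms on (0, root age) — the same conditional
#' uniform kernel the default birth-death time prior assumes — assigned in
#' increasing order so every merge is older than the lineages it joins.
#'
#' @param ntips number of tips (>= 2); tips are at age 0.
#' @param root_age root age in 100 My.
#' @param seed integer seed.
#' @param tip_labels optional tip names (default \code{t1, t2, ...}).
#' @return A list with \code{phylo} (ape tree, branch lengths in 100 My) and
#'   \code{ages} (node ages indexed by node number).
#' @export
simulate_timetree <- function(ntips, root_age = 1, seed = NULL,
                              tip_labels = paste0("t", seq_len(ntips))) {
  stopifnot(ntips >= 2, root_age > 0)
  if (!is.null(seed)) set.seed(seed)
  nn <- 2L * ntips - 1L
  ages <- numeric(nn)
  node_ages <- if (ntips > 2)
    c(sort(stats::runif(ntips - 2, 0, root_age)), root_age) else root_age
  edge <- matrix(0L, 2L * ntips - 2L, 2)
  pool <- seq_len(ntips)  # active lineages (node ids)
  ## ape numbering: root must be ntips+1, so the oldest (last) merge gets id
  ## ntips+1 and the youngest gets 2*ntips-1.
  internal_ids <- rev(seq.int(ntips + 1L, nn))
  ke <- 0L
  for (k in seq_len(ntips - 1L)) {
    pair <- if (length(pool) > 2) sample(length(pool), 2) else c(1L, 2L)
    node <- internal_ids[k]
    ages[node] <- node_ages[k]
    for (ch in pool[pair]) {
      ke <- ke + 1L
      edge[ke, ] <- c(node, ch)
    }
    pool <- c(pool[-pair], node)
  }
  phylo <- structure(list(edge = edge,
                          tip.label = tip_labels,
                          Nnode = ntips - 1L), class = "phylo")
  phylo <- ape::reorder.phylo(phylo, "cladewise")
  pars <- tree_parents(phylo)
  phylo$edge.length <- ages[pars[phylo$edge[, 2]]] - ages[phylo$edge[, 2]]
  list(phylo = phylo, ages = ages)
}

#' Simulate an alignment on a time-tree
#'
#' Forward simulation under the substitution model used by the likelihood:
#' sites evolve independently down the tree with branch length = rate x
#' duration, optionally mixing rates over discrete-gamma categories, and an
#' optional missing-data mask.
#'
#' @param phylo tree topology.
#' @param ages node ages indexed by node number.
#' @param rates branch rates: scalar, vector indexed by child node, or matrix
#'   (node x locus) as from [simulate_branch_rates()].
#' @param sm a \code{subst_model}.
#' @param sites sites per locus (scalar or vector, one entry per locus).
#' @param seed integer seed.
#' @param mask_fraction fraction of cells replaced by \code{?}.
#' @return An \code{alignment} with one partition per locus.
#' @export
simulate_alignment <- function(phylo, ages, rates, sm, sites, seed = NULL,
                               mask_fraction = 0) {
  stopifnot(inherits(sm, "subst_model"))
  if (!is.null(seed)) set.seed(seed)
  n <- length(phylo$tip.label)
  nn <- n + phylo$Nnode
  if (!is.matrix(rates)) rates <- matrix(rates, nn, 1)
  L <- max(ncol(rates), length(sites))
  if (ncol(rates) == 1L && L > 1L)
    rates <- rates[, rep(1L, L), drop = FALSE]
  if (ncol(rates) != L) stop("rates has ", ncol(rates),
                             " loci but sites has ", length(sites))
  sites <- rep_len(sites, L)
  e <- ape::reorder.phylo(phylo, "cladewise")$edge
  bases <- c("A", "C", "G", "T")
  blocks <- vector("list", L)
  for (l in seq_len(L)) {
    ns <- sites[l]
    cat_of_site <- sample.int(sm$ncat, ns, replace = TRUE)
    states <- matrix(0L, nn, ns)
    states[n + 1L, ] <- sample.int(4, ns, replace = TRUE, prob = sm$freqs)
    Pk <- vector("list", sm$ncat)
    for (k in seq_len(nrow(e))) {
      par <- e[k, 1]; kid <- e[k, 2]
      b <- rates[kid, l] * (ages[par] - ages[kid])
      for (cc in seq_len(sm$ncat)) Pk[[cc]] <- tpm(sm, b * sm$cat_rates[cc])
      for (cc in seq_len(sm$ncat)) {
        idx <- which(cat_of_site == cc)
        if (!length(idx)) next
        ps <- states[par, idx]
        u <- stats::runif(length(idx))
        cum <- t(apply(Pk[[cc]], 1, cumsum))
        states[kid, idx] <- 1L +
          rowSums(u > cum[ps, , drop = FALSE][, 1:3, drop = FALSE])
      }
    }
    m <- matrix(bases[states[seq_len(n), , drop = FALSE]], n, ns)
    blocks[[l]] <- m
  }
  seqm <- do.call(cbind, blocks)
  rownames(seqm) <- phylo$tip.label
  if (mask_fraction > 0) {
    nmiss <- round(mask_fraction * length(seqm))
    seqm[sample.int(length(seqm), nmiss)] <- "?"
  }
  ends <- cumsum(sites)
  parts <- data.frame(name = paste0("p", seq_len(L)),
                      start = c(1, utils::head(ends, -1) + 1), end = ends)
  make_alignment(seqm, parts)
}

#' Simulation recipe: tree, rates and alignment in one call
#'
#' @param ntips,root_age tree shape.
#' @param clock a \code{clock_model} with the true hyperpriors.
#' @param sm a \code{subst_model}.
#' @param sites sites per locus.
#' @param L number of loci.
#' @param seed integer seed (drives tree, rates and sequences).
#' @param mu,sigma2 optional fixed true hyperparameters.
#' @return A list with \code{phylo}, \code{ages}, \code{rates} (the
#'   [simulate_branch_rates()] output) and \code{aln}.
#' @export
simulate_dataset <- function(ntips = 4, root_age = 1,
                             clock = clock_model("sc"),
                             sm = subst_model("JC"), sites = 1000, L = 1,
                             seed = 1, mu = NULL, sigma2 = NULL) {
  set.seed(seed)
  tt <- simulate_timetree(ntips, root_age)
  br <- simulate_branch_rates(clock, tt$phylo, tt$ages, L = L,
                              mu = mu, sigma2 = sigma2)
  rmat <- br$rates
  aln <- simulate_alignment(tt$phylo, tt$ages, rmat, sm, sites)
  list(phylo = tt$phylo, ages = tt$ages, rates = br, aln = aln)
}
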