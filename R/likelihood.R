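#' Nucleotide substitution models
#'
#' HKY (or its Jukes-Cantor special case) with optional discrete-gamma rate
#' variation across sites. Rate matrices are scaled to one expected
#' substitution per site per unit branch length, and the symmetrized
#' eigendecomposition is stored so transition probabilities are cheap to
#' evaluate at many branch lengths.
#'
#' @param model \code{"JC"} or \code{"HKY"}.
#' @param kappa transition/transversion rate ratio (HKY).
#' @param freqs base frequencies in order A, C, G, T; must sum to 1.
#' @param gamma_shape shape of the discrete-gamma distribution of site rates;
#'   \code{NULL} disables rate variation.
#' @param ncat number of discrete-gamma categories (mean-of-bin rates).
#' @return An object of class \code{"subst_model"}.
#' @export
subst_model <- function(model = c("HKY", "JC"), kappa = 2,
                        freqs = rep(0.25, 4), gamma_shape = NULL,
                        ncat = 4) {
  model <- match.arg(model)
  if (model == "JC") { kappa <- 1; freqs <- rep(0.25, 4) }
  stopifnot(kappa > 0, length(freqs) == 4, all(freqs > 0),
            abs(sum(freqs) - 1) < 1e-8, ncat >= 1)
  ## HKY rate matrix, order A C G T; transitions: A<->G, C<->T
  Q <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    ti <- (i + j == 4 && i != j && (i %in% c(1, 3))) # A(1)-G(3)
    tv2 <- (i %in% c(2, 4) && j %in% c(2, 4))        # C(2)-T(4)
    Q[i, j] <- freqs[j] * if (ti || tv2) kappa else 1
  }
  diag(Q) <- -rowSums(Q)
  Q <- Q / sum(-diag(Q) * freqs)  # mean rate 1
  sp <- sqrt(freqs)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
  cat_rates <- if (is.null(gamma_shape) || ncat == 1) 1 else
    discrete_gamma_rates(gamma_shape, ncat)
  structure(list(model = model, kappa = kappa, freqs = freqs,
                 gamma_shape = gamma_shape, ncat = length(cat_rates),
                 cat_rates = cat_rates, Q = Q,
                 U = diag(1 / sp) %*% eg$vectors,
                 Uinv = t(eg$vectors) %*% diag(sp),
                 lambda = eg$values),
            class = "subst_model")
}

## mean-of-bin discretization of Gamma(shape, shape) into k equal-mass bins
discrete_gamma_rates <- function(shape, k) {
  b <- stats::qgamma(seq(0, 1, length.out = k + 1), shape, shape)
  ## E[X; X in bin] = pgamma(b, shape+1, shape) for X ~ Gamma(shape, shape)
  r <- k * (stats::pgamma(b[-1], shape + 1, shape) -
            stats::pgamma(b[-(k + 1)], shape + 1, shape))
  r / mean(r)  # guard tiny numeric drift; mean is 1 analytically
}

## 4x4 transition probability matrix at branch length t
tpm <- function(sm, t) {
  P <- sm$U %*% (exp(sm$lambda * t) * sm$Uinv)
  P[P < 0] <- 0
  P
}

## compress an alignment partition into site patterns
site_patterns <- function(seqmat) {
  key <- apply(seqmat, 2, paste, collapse = "")
  tab <- table(key)
  idx <- match(names(tab), key)
  list(patterns = seqmat[, idx, drop = FALSE],
       weights = as.numeric(tab))
}

## tip conditional-likelihood matrices (npat x 4), '?' fully ambiguous
tip_clv <- function(pattern_row) {
  states <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  m <- matrix(0, length(pattern_row), 4)
  known <- pattern_row %in% names(states)
  m[cbind(which(known), states[pattern_row[known]])] <- 1
  m[!known, ] <- 1
  m
}

## flatten tip conditional likelihoods for the C++ pruning kernel
flatten_tips <- function(tips) {
  unlist(lapply(tips, function(m) as.numeric(t(m))), use.names = FALSE)
}

## Felsenstein pruning over one partition. bl: vector indexed by child node.
prune_loglik <- function(patterns, weights, phylo, bl, sm) {
  n <- length(phylo$tip.label)
  po <- ape::reorder.phylo(phylo, "postorder")$edge
  tips <- lapply(seq_len(n), function(i) tip_clv(patterns[i, ]))
  prune_loglik_cpp(flatten_tips(tips), weights, po, bl, sm$U, sm$Uinv,
                   sm$lambda, sm$freqs, sm$cat_rates, n,
                   n + phylo$Nnode)
}

#' Exact log-likelihood of an alignment on a tree
#'
#' Felsenstein pruning under HKY (or JC) with discrete-gamma rate mixing.
#' \code{?} and gaps are fully ambiguous, so taxa absent from a partition
#' contribute nothing to its likelihood. The total factorizes over
#' partitions.
#'
#' @param aln an \code{alignment}.
#' @param phylo tree topology; tip labels must match alignment row names.
#' @param bl branch lengths in expected substitutions/site: either a vector
#'   indexed by child node number, or a matrix with one column per partition.
#' @param sm a \code{subst_model}.
#' @return Total log-likelihood (sum over partitions).
#' @export
exact_loglik <- function(aln, phylo, bl, sm) {
  stopifnot(inherits(aln, "alignment"), inherits(sm, "subst_model"))
  ord <- match(phylo$tip.label, rownames(aln$seq))
  if (anyNA(ord))
    stop("unmatched tip(s): ",
         paste(phylo$tip.label[is.na(ord)], collapse = ", "))
  seqm <- aln$seq[ord, , drop = FALSE]
  nparts <- length(aln$part_names)
  if (is.matrix(bl)) stopifnot(ncol(bl) == nparts)
  total <- 0
  for (p in seq_len(nparts)) {
    sp <- site_patterns(seqm[, aln$partition == p, drop = FALSE])
    blp <- if (is.matrix(bl)) bl[, p] else bl
    if (anyNA(blp[phylo$edge[, 2]])) stop("branch lengths contain NA")
    if (any(blp[phylo$edge[, 2]] < 0)) return(-Inf)
    total <- total + prune_loglik(sp$patterns, sp$weights, phylo, blp, sm)
  }
  total
}

#' Quadratic approximation to the branch-length likelihood
#'
#' Maximizes the exact log-likelihood of each partition over branch lengths,
#' then stores the MLE, the gradient and Hessian (central finite differences)
#' and the optimum value, so the log-likelihood can later be evaluated as a
#' second-order Taylor expansion — the approximate-likelihood device used to
#' make dating MCMC cheap. The approximation degrades away from the MLE and
#' must not be used for marginal-likelihood (power posterior) computation.
#'
#' @param aln an \code{alignment} (one set of approximations per partition).
#' @param phylo tree topology.
#' @param sm a \code{subst_model}.
#' @param b0 optional starting branch lengths (single value or vector).
#' @return An object of class \code{"branch_approx"}: per-partition list of
#'   \code{bhat}, \code{grad}, \code{hess}, \code{lnL0}, \code{ok}, plus the
#'   edge child-node index and the edge-to-parameter map.
#' @details Under a reversible substitution model the two root-adjacent
#'   branch lengths enter the likelihood only through their sum (the pulley
#'   principle), so the expansion is built on the unrooted parameterization:
#'   the root pair shares one length parameter and rooted branch lengths are
#'   mapped onto it when the surrogate is evaluated.
#' @export
build_branch_approx <- function(aln, phylo, sm, b0 = 0.1) {
  stopifnot(inherits(aln, "alignment"))
  kids <- phylo$edge[, 2]
  root <- length(phylo$tip.label) + 1L
  ## unrooted parameterization: both root children map to one parameter
  is_root_edge <- phylo$edge[, 1] == root
  param_of <- integer(length(kids))
  param_of[!is_root_edge] <- seq_len(sum(!is_root_edge))
  param_of[is_root_edge] <- sum(!is_root_edge) + 1L
  nb <- max(param_of)
  ord <- match(phylo$tip.label, rownames(aln$seq))
  if (anyNA(ord)) stop("unmatched tips")
  seqm <- aln$seq[ord, , drop = FALSE]
  parts <- vector("list", length(aln$part_names))
  for (p in seq_along(parts)) {
    sp <- site_patterns(seqm[, aln$partition == p, drop = FALSE])
    variable <- sum(apply(sp$patterns, 2, function(col) {
      s <- unique(col[col %in% c("A", "C", "G", "T")]); length(s) > 1
    }) * sp$weights) > 0
    first_root <- which(is_root_edge)[1]
    f <- function(bv) {
      bl <- numeric(length(phylo$tip.label) + phylo$Nnode)
      bl[kids] <- bv[param_of]
      bl[kids[is_root_edge]] <- 0
      bl[kids[first_root]] <- bv[nb]  # whole root-pair sum on one side
      -prune_loglik(sp$patterns, sp$weights, phylo, bl, sm)
    }
    start <- rep_len(b0, nb)
    opt <- tryCatch(
      stats::optim(start, f, method = "L-BFGS-B", lower = 1e-8,
                   control = list(maxit = 500, factr = 1e7)),
      error = function(e) NULL)
    if (is.null(opt)) {
      parts[[p]] <- list(ok = FALSE)
      next
    }
    ok <- variable && opt$convergence == 0
    grad_hess <- function(bhat, fx) {
      ## step clamped so finite differences never probe negative lengths
      h <- pmin(pmax(abs(bhat), 1e-2) * 1e-4, pmax(bhat / 2, 1e-9))
      g <- numeric(nb); H <- matrix(0, nb, nb)
      for (i in seq_len(nb)) {
        ei <- numeric(nb); ei[i] <- h[i]
        fp <- f(bhat + ei); fmn <- f(bhat - ei)
        g[i] <- -(fp - fmn) / (2 * h[i])
        H[i, i] <- -(fp - 2 * fx + fmn) / h[i]^2
      }
      for (i in seq_len(nb)) for (j in seq_len(nb)) {
        if (j <= i) next
        ei <- numeric(nb); ei[i] <- h[i]
        ej <- numeric(nb); ej[j] <- h[j]
        H[i, j] <- H[j, i] <-
          -(f(bhat + ei + ej) - f(bhat + ei - ej) -
              f(bhat - ei + ej) + f(bhat - ei - ej)) / (4 * h[i] * h[j])
      }
      list(g = g, H = (H + t(H)) / 2)
    }
    bhat <- opt$par
    fx <- opt$value
    gh <- grad_hess(bhat, fx)
    ## Newton polish: L-BFGS-B stops with a loose gradient; a few damped
    ## Newton steps sharpen the optimum so the stored gradient is ~0
    for (step in 1:10) {
      if (max(abs(gh$g)) < 1e-6 * max(1, abs(fx)) || max(abs(gh$g)) < 1e-5)
        break
      dir <- tryCatch(solve(gh$H, gh$g), error = function(e) NULL)
      if (is.null(dir)) break
      lam <- 1
      repeat {
        cand <- pmax(bhat - lam * dir, 1e-8)
        fc <- f(cand)
        if (fc <= fx || lam < 1e-4) break
        lam <- lam / 2
      }
      if (fc > fx) break
      bhat <- cand; fx <- fc
      gh <- grad_hess(bhat, fx)
    }
    parts[[p]] <- list(bhat = bhat, grad = gh$g, hess = gh$H,
                       lnL0 = -fx, ok = ok)
  }
  structure(list(parts = parts, kids = kids, param_of = param_of),
            class = "branch_approx")
}

#' Evaluate the quadratic approximate log-likelihood
#'
#' Rooted branch lengths are collapsed onto the unrooted parameterization
#' (the root-adjacent pair sums into one parameter) before the second-order
#' Taylor expansion is evaluated.
#'
#' @param ba a \code{branch_approx}.
#' @param bl branch lengths: vector indexed by child node, or matrix with a
#'   column per partition.
#' @return Approximate log-likelihood summed over partitions.
#' @export
approx_loglik <- function(ba, bl) {
  stopifnot(inherits(ba, "branch_approx"))
  total <- 0
  for (p in seq_along(ba$parts)) {
    ap <- ba$parts[[p]]
    if (is.null(ap$bhat)) next
    bv <- if (is.matrix(bl)) bl[ba$kids, p] else bl[ba$kids]
    pv <- as.numeric(rowsum(bv, ba$param_of))
    if (length(pv) != length(ap$bhat)) stop("branch-length dimension mismatch")
    d <- pv - ap$bhat
    total <- total + ap$lnL0 + sum(ap$grad * d) +
      0.5 * drop(t(d) %*% ap$hess %*% d)
  }
  total
}
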