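#' Fossil calibration densities
#'
#' Constructors for the calibration-density families used to encode fossil
#' evidence on node ages. Ages are in units of 100 My throughout.
#'
#' Families:
#' \describe{
#'   \item{B}{Soft-bounded uniform: uniform mass \eqn{1 - p_L - p_U} between a
#'     minimum age \eqn{t_L} and maximum age \eqn{t_U}, with a power-density
#'     left tail carrying mass \eqn{p_L} below \eqn{t_L} and an exponential
#'     right tail carrying \eqn{p_U} above \eqn{t_U}; the tail parameters are
#'     chosen so the density is continuous at both bounds.}
#'   \item{L}{Truncated Cauchy above a minimum age \eqn{t_L}: Cauchy with
#'     location \eqn{t_L(1 + p)} and scale \eqn{c\,t_L} truncated to
#'     \eqn{(t_L, \infty)} carrying mass \eqn{1 - p_L}, plus a
#'     continuity-matched power tail below \eqn{t_L} carrying \eqn{p_L}.}
#'   \item{ST}{Skew-t with location \eqn{\xi}, scale \eqn{\omega}, shape
#'     \eqn{\alpha} and degrees of freedom \eqn{\nu}.}
#'   \item{S2N}{Mixture of two skew-normal components with mixing weight
#'     \eqn{w} on the first component.}
#'   \item{G}{Gamma with shape \eqn{a} and rate \eqn{b}.}
#'   \item{FIXED}{Point mass, used to fix a node age exactly.}
#' }
#'
#' @param t_L,t_U minimum and maximum age bounds (100 My).
#' @param p_L,p_U probabilities that the age violates the lower/upper bound.
#' @param p,c offset and spread factors of the truncated Cauchy: location is
#'   \code{t_L * (1 + p)}, scale is \code{c * t_L}.
#' @param xi,omega,alpha,nu skew-t location, scale, shape and df.
#' @param w,xi1,omega1,alpha1,xi2,omega2,alpha2 mixture weight and the two
#'   skew-normal (location, scale, shape) triples.
#' @param shape,rate gamma parameters (mean \code{shape/rate}).
#' @param age fixed node age.
#' @return An object of class \code{"calibration"}.
#' @examples
#' d <- cal_b(0.112, 0.28, 0.01, 0.10)
#' pcal(d, 0.112)   # 0.01 by construction
#' @name calibration
NULL

new_calibration <- function(family, params) {
  structure(list(family = family, params = params), class = "calibration")
}

#' @rdname calibration
#' @export
cal_b <- function(t_L, t_U, p_L = 0.025, p_U = 0.025) {
  stopifnot(t_L >= 0, t_U > t_L, p_L > 0, p_U > 0, p_L + p_U < 1)
  new_calibration("B", list(t_L = t_L, t_U = t_U, p_L = p_L, p_U = p_U))
}

#' @rdname calibration
#' @export
cal_l <- function(t_L, p = 0.1, c = 2, p_L = 0.05) {
  stopifnot(t_L > 0, p > 0, c > 0, p_L > 0, p_L < 1)
  new_calibration("L", list(t_L = t_L, p = p, c = c, p_L = p_L))
}

#' @rdname calibration
#' @export
cal_st <- function(xi, omega, alpha, nu) {
  stopifnot(omega > 0, nu > 0)
  new_calibration("ST", list(xi = xi, omega = omega, alpha = alpha, nu = nu))
}

#' @rdname calibration
#' @export
cal_s2n <- function(w, xi1, omega1, alpha1, xi2, omega2, alpha2) {
  stopifnot(w > 0, w <= 1, omega1 > 0, omega2 > 0)
  new_calibration("S2N", list(w = w, xi1 = xi1, omega1 = omega1,
                              alpha1 = alpha1, xi2 = xi2, omega2 = omega2,
                              alpha2 = alpha2))
}

#' @rdname calibration
#' @export
cal_gamma <- function(shape, rate) {
  stopifnot(shape > 0, rate > 0)
  new_calibration("G", list(a = shape, b = rate))
}

#' @rdname calibration
#' @export
cal_fixed <- function(age) {
  stopifnot(age > 0)
  new_calibration("FIXED", list(age = age))
}

#' @export
print.calibration <- function(x, ...) {
  cat(format_calibration(x), "\n")
  invisible(x)
}

#' Serialize / parse calibrations
#'
#' `format_calibration()` renders a calibration as the compact
#' `FAMILY(p1, p2, ...)` string used in annotated Newick files;
#' `parse_calibration()` is its inverse.
#'
#' @param x a calibration object.
#' @param text a string such as `"B(0.25, 0.337, 0.01, 0.1)"`.
#' @param digits significant digits used when formatting.
#' @return A string, or a calibration object.
#' @export
format_calibration <- function(x, digits = 8) {
  stopifnot(inherits(x, "calibration"))
  p <- unlist(x$params)
  sprintf("%s(%s)", x$family,
          paste(vapply(p, function(v) format(v, digits = digits, trim = TRUE),
                       character(1)), collapse = ", "))
}

#' @rdname format_calibration
#' @export
parse_calibration <- function(text) {
  text <- trimws(text)
  m <- regmatches(text, regexec("^([A-Za-z0-9]+)\\s*\\((.*)\\)$", text))[[1]]
  if (length(m) != 3)
    stop("cannot parse calibration string: ", sQuote(text))
  fam <- toupper(m[2])
  p <- as.numeric(strsplit(m[3], ",")[[1]])
  if (anyNA(p)) stop("non-numeric calibration parameter in ", sQuote(text))
  switch(fam,
    B  = { stopifnot(length(p) == 4); cal_b(p[1], p[2], p[3], p[4]) },
    L  = { if (length(p) == 1) cal_l(p[1])
           else if (length(p) == 2) cal_l(p[1], p[2])
           else if (length(p) == 3) cal_l(p[1], p[2], p[3])
           else { stopifnot(length(p) == 4); cal_l(p[1], p[2], p[3], p[4]) } },
    ST = { stopifnot(length(p) == 4); cal_st(p[1], p[2], p[3], p[4]) },
    S2N = { stopifnot(length(p) == 7)
            cal_s2n(p[1], p[2], p[3], p[4], p[5], p[6], p[7]) },
    G  = { stopifnot(length(p) == 2); cal_gamma(p[1], p[2]) },
    FIXED = { stopifnot(length(p) == 1); cal_fixed(p[1]) },
    stop("unknown calibration family ", sQuote(fam))
  )
}

## ---- skew-normal / skew-t primitives ------------------------------------

dsn <- function(x, xi = 0, omega = 1, alpha = 0, log = FALSE) {
  z <- (x - xi) / omega
  lv <- log(2) - log(omega) + stats::dnorm(z, log = TRUE) +
    stats::pnorm(alpha * z, log.p = TRUE)
  if (log) lv else exp(lv)
}

rsn <- function(n, xi = 0, omega = 1, alpha = 0) {
  delta <- alpha / sqrt(1 + alpha^2)
  u0 <- stats::rnorm(n); u1 <- stats::rnorm(n)
  z <- delta * abs(u0) + sqrt(1 - delta^2) * u1
  xi + omega * z
}

dst_ <- function(x, xi = 0, omega = 1, alpha = 0, nu = 1, log = FALSE) {
  z <- (x - xi) / omega
  lv <- log(2) - log(omega) + stats::dt(z, df = nu, log = TRUE) +
    stats::pt(alpha * z * sqrt((nu + 1) / (nu + z^2)), df = nu + 1,
              log.p = TRUE)
  if (log) lv else exp(lv)
}

rst_ <- function(n, xi = 0, omega = 1, alpha = 0, nu = 1) {
  z <- rsn(n, 0, 1, alpha)
  w <- stats::rchisq(n, df = nu) / nu
  xi + omega * z / sqrt(w)
}

## numeric cdf of a unimodal density on the real line
num_cdf <- function(dfun, q) {
  vapply(q, function(qi) {
    stats::integrate(dfun, -Inf, qi, rel.tol = 1e-10,
                     stop.on.error = FALSE)$value
  }, numeric(1))
}

num_quantile <- function(pfun, prob, lower, upper) {
  vapply(prob, function(p) {
    stats::uniroot(function(x) pfun(x) - p, lower = lower, upper = upper,
                   extendInt = "upX", tol = 1e-12)$root
  }, numeric(1))
}

## ---- B family internals --------------------------------------------------

b_pars <- function(p) {
  core <- (1 - p$p_L - p$p_U) / (p$t_U - p$t_L)
  ## left tail t^(theta1-1) power density on (0, t_L), continuous at t_L
  theta1 <- core * p$t_L / p$p_L
  ## right tail exponential, continuous at t_U
  theta2 <- core / p$p_U
  list(core = core, theta1 = theta1, theta2 = theta2)
}

## ---- L family internals --------------------------------------------------

l_pars <- function(p) {
  A <- p$t_L * (1 + p$p)          # Cauchy location
  s <- p$c * p$t_L                # Cauchy scale
  ## mass of the untruncated Cauchy above t_L
  norm <- 0.5 + atan(p$p / p$c) / pi
  f_tL <- (1 - p$p_L) / (pi * s * (1 + (p$p / p$c)^2) * norm)
  theta <- p$t_L * f_tL / p$p_L   # left power-tail exponent (continuity)
  list(A = A, s = s, norm = norm, theta = theta)
}

## ---- generic density interface ------------------------------------------

#' Calibration density functions
#'
#' Density, distribution function, quantile function and random sampling for
#' calibration densities. The cdf/quantile of the skew-t and skew-normal
#' mixture families are computed by adaptive quadrature and root finding.
#'
#' @param d a \code{calibration} object.
#' @param t age(s), in 100 My.
#' @param q probabilities in (0, 1).
#' @param n number of draws.
#' @param log return log density?
#' @return Numeric vector.
#' @export
dcal <- function(d, t, log = FALSE) {
  stopifnot(inherits(d, "calibration"))
  p <- d$params
  v <- switch(d$family,
    B = {
      bp <- b_pars(p)
      out <- numeric(length(t))
      lo <- t < p$t_L & t > 0
      mid <- t >= p$t_L & t <= p$t_U
      hi <- t > p$t_U
      out[lo] <- p$p_L * bp$theta1 * (t[lo] / p$t_L)^(bp$theta1 - 1) / p$t_L
      out[mid] <- bp$core
      out[hi] <- bp$core * exp(-bp$theta2 * (t[hi] - p$t_U))
      out
    },
    L = {
      lp <- l_pars(p)
      out <- numeric(length(t))
      lo <- t < p$t_L & t > 0
      hi <- t >= p$t_L
      out[lo] <- p$p_L * lp$theta * (t[lo] / p$t_L)^(lp$theta - 1) / p$t_L
      out[hi] <- (1 - p$p_L) /
        (pi * lp$s * (1 + ((t[hi] - lp$A) / lp$s)^2) * lp$norm)
      out
    },
    ST = dst_(t, p$xi, p$omega, p$alpha, p$nu),
    S2N = p$w * dsn(t, p$xi1, p$omega1, p$alpha1) +
      (1 - p$w) * dsn(t, p$xi2, p$omega2, p$alpha2),
    G = stats::dgamma(t, p$a, p$b),
    FIXED = ifelse(t == p$age, Inf, 0),
    stop("no density for family ", d$family)
  )
  if (log) log(v) else v
}

#' @rdname dcal
#' @export
pcal <- function(d, t) {
  stopifnot(inherits(d, "calibration"))
  p <- d$params
  switch(d$family,
    B = {
      bp <- b_pars(p)
      out <- numeric(length(t))
      lo <- t < p$t_L; mid <- t >= p$t_L & t <= p$t_U; hi <- t > p$t_U
      out[lo] <- p$p_L * pmax(t[lo] / p$t_L, 0)^bp$theta1
      out[mid] <- p$p_L + bp$core * (t[mid] - p$t_L)
      out[hi] <- 1 - p$p_U * exp(-bp$theta2 * (t[hi] - p$t_U))
      out
    },
    L = {
      lp <- l_pars(p)
      out <- numeric(length(t))
      lo <- t < p$t_L; hi <- t >= p$t_L
      out[lo] <- p$p_L * pmax(t[lo] / p$t_L, 0)^lp$theta
      Fc <- function(x) 0.5 + atan((x - lp$A) / lp$s) / pi
      out[hi] <- p$p_L + (1 - p$p_L) * (Fc(t[hi]) - Fc(p$t_L)) / lp$norm
      out
    },
    ST = num_cdf(function(x) dst_(x, p$xi, p$omega, p$alpha, p$nu), t),
    S2N = num_cdf(function(x) dcal(d, x), t),
    G = stats::pgamma(t, p$a, p$b),
    FIXED = as.numeric(t >= p$age),
    stop("no cdf for family ", d$family)
  )
}

#' @rdname dcal
#' @export
qcal <- function(d, q) {
  stopifnot(inherits(d, "calibration"), all(q > 0), all(q < 1))
  p <- d$params
  switch(d$family,
    B = {
      bp <- b_pars(p)
      out <- numeric(length(q))
      lo <- q < p$p_L; hi <- q > 1 - p$p_U; mid <- !lo & !hi
      out[lo] <- p$t_L * (q[lo] / p$p_L)^(1 / bp$theta1)
      out[mid] <- p$t_L + (q[mid] - p$p_L) / bp$core
      out[hi] <- p$t_U - log((1 - q[hi]) / p$p_U) / bp$theta2
      out
    },
    L = {
      lp <- l_pars(p)
      out <- numeric(length(q))
      lo <- q < p$p_L; hi <- !lo
      out[lo] <- p$t_L * (q[lo] / p$p_L)^(1 / lp$theta)
      Fc_tL <- 0.5 + atan(-p$p / p$c) / pi
      u <- Fc_tL + (q[hi] - p$p_L) / (1 - p$p_L) * lp$norm
      out[hi] <- lp$A + lp$s * tan(pi * (u - 0.5))
      out
    },
    ST = {
      spread <- p$omega * if (p$nu > 2) sqrt(p$nu / (p$nu - 2)) else 10
      num_quantile(function(x) pcal(d, x), q,
                   lower = p$xi - 20 * spread, upper = p$xi + 20 * spread)
    },
    S2N = {
      lo <- min(p$xi1 - 20 * p$omega1, p$xi2 - 20 * p$omega2)
      hi <- max(p$xi1 + 20 * p$omega1, p$xi2 + 20 * p$omega2)
      num_quantile(function(x) pcal(d, x), q, lower = lo, upper = hi)
    },
    G = stats::qgamma(q, p$a, p$b),
    FIXED = rep(p$age, length(q)),
    stop("no quantile for family ", d$family)
  )
}

#' @rdname dcal
#' @param seed optional integer seed for reproducible draws.
#' @export
rcal <- function(d, n, seed = NULL) {
  stopifnot(inherits(d, "calibration"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- d$params
  switch(d$family,
    B = qcal(d, stats::runif(n)),
    L = qcal(d, stats::runif(n)),
    ST = rst_(n, p$xi, p$omega, p$alpha, p$nu),
    S2N = {
      k <- stats::runif(n) < p$w
      out <- numeric(n)
      out[k] <- rsn(sum(k), p$xi1, p$omega1, p$alpha1)
      out[!k] <- rsn(sum(!k), p$xi2, p$omega2, p$alpha2)
      out
    },
    G = stats::rgamma(n, p$a, p$b),
    FIXED = rep(p$age, n),
    stop("no sampler for family ", d$family)
  )
}

## ---- fitting -------------------------------------------------------------

#' Fit a skew-t density by maximum likelihood
#'
#' Fits (location, scale, shape, df) of a skew-t density to a sample, as used
#' when marginal posterior node ages are refitted as calibrations for a second
#' dating analysis. Optimization is multi-start (a moment-based start plus
#' jittered restarts) over (xi, log omega, alpha, log nu) with df bounded in
#' \[2.1, 1e4\] so the fitted density has finite variance.
#'
#' @param x numeric sample of ages (at least 100 values recommended).
#' @param n_starts number of jittered restarts beyond the moment start.
#' @return A list with elements \code{calibration} (a \code{cal_st} object),
#'   \code{par}, \code{loglik} and \code{converged}. Non-convergence is
#'   flagged, never an error.
#' @export
fit_skew_t_ml <- function(x, n_starts = 4) {
  stopifnot(is.numeric(x), length(x) >= 2)
  m <- mean(x); s <- stats::sd(x)
  if (s < 1e-7 * max(abs(m), 1)) {
    ## (near-)degenerate sample: return a sharp symmetric density, flagged
    return(list(calibration = cal_st(m, max(s, 1e-12), 0, 1e3),
                par = c(xi = m, omega = max(s, 1e-12), alpha = 0, nu = 1e3),
                loglik = NA_real_, converged = FALSE))
  }
  sk <- mean(((x - m) / s)^3)
  nll <- function(par) {
    xi <- par[1]; omega <- exp(par[2]); alpha <- par[3]
    nu <- 2.1 + exp(par[4])
    if (nu > 1e4) nu <- 1e4
    v <- suppressWarnings(-sum(dst_(x, xi, omega, alpha, nu, log = TRUE)))
    if (is.finite(v)) v else .Machine$double.xmax / 2
  }
  starts <- list(c(m - sign(sk) * 0.5 * s, log(s), 2 * sign(sk) + (sk == 0),
                   log(20)),
                 c(m, log(s), 0, log(50)))  # symmetric start
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(20260924L)
  for (i in seq_len(n_starts)) {
    starts[[i + 2]] <- starts[[1]] +
      c(stats::rnorm(1, 0, 0.3 * s), stats::rnorm(1, 0, 0.3),
        stats::rnorm(1, 0, 1.5), stats::rnorm(1, 0, 1))
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv())
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(stats::optim(st, nll, method = "Nelder-Mead",
                                 control = list(maxit = 2000)),
                    error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    return(list(calibration = NULL, par = NULL, loglik = NA_real_,
                converged = FALSE))
  par <- c(xi = best$par[1], omega = exp(best$par[2]), alpha = best$par[3],
           nu = min(2.1 + exp(best$par[4]), 1e4))
  list(calibration = cal_st(par[1], par[2], par[3], par[4]),
       par = par, loglik = -best$value,
       converged = best$convergence == 0 && length(x) >= 100)
}

#' Fit a gamma density by moment matching
#'
#' Shape \code{a = mean^2/var} and rate \code{b = mean/var}, the shape/rate
#' parameterization with mean \code{a/b} and variance \code{a/b^2}.
#'
#' @param x positive numeric sample, at least 2 values.
#' @return A \code{cal_gamma} calibration.
#' @export
fit_gamma_moments <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 2, all(x > 0))
  v <- stats::var(x)
  if (v == 0) stop("zero variance: cannot moment-match a gamma density")
  m <- mean(x)
  cal_gamma(m^2 / v, m / v)
}
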