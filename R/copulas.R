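#' Bivariate linking copulas
#'
#' Constructor for the parametric bivariate copulas used to link items to the
#' latent factors: the bivariate normal (BVN) copula, the Student-t copula with
#' fixed degrees of freedom, the extreme-value Gumbel copula, its survival
#' (180-degree rotated) version, and the two single-margin reflections of the
#' Gumbel copula which cover negative dependence.
#'
#' The dependence parameter can be given either on the native scale (`par`) or
#' on the Kendall's tau scale (`tau`), which is comparable across families.
#' The degrees of freedom `nu` of the t copula are treated as a fixed family
#' attribute (typically chosen from a small grid such as 2, 3, 5), never as an
#' estimated parameter.  The shorthand family tags `"t2"`, `"t3"`, `"t5"`, ...
#' are accepted and parsed into `family = "t"` with the corresponding `nu`.
#'
#' @param family One of `"bvn"`, `"t"`, `"gumbel"`, `"sgumbel"`,
#'   `"gumbel_r1"`, `"gumbel_r2"`, or a shorthand like `"t5"`.
#' @param par Dependence parameter on the native scale: a correlation in
#'   `[-1, 1]` for `"bvn"`/`"t"`, a parameter `>= 1` for the Gumbel variants.
#' @param tau Alternative to `par`: Kendall's tau within the family's
#'   attainable range (`(-1, 1)` for bvn/t, `[0, 1)` for gumbel/sgumbel,
#'   `(-1, 0]` for the reflected variants).
#' @param nu Degrees of freedom (`"t"` family only), any positive real.
#'
#' @return An object of class `"bicop"`: a list with elements `family`, `par`
#'   and (for the t copula) `nu`.
#' @examples
#' bicop("gumbel", tau = 0.5)       # par = 2
#' bicop("t5", par = 0.42)          # t copula, nu = 5
#' @export
bicop <- function(family, par = NULL, tau = NULL, nu = NULL) {
  pf <- parse_family(family)
  family <- pf$family
  if (!is.null(pf$nu)) nu <- pf$nu
  if (family == "t") {
    if (is.null(nu)) stop("the t copula needs fixed degrees of freedom `nu`")
    if (!is.numeric(nu) || nu <= 0) stop("`nu` must be a positive real")
  } else {
    nu <- NULL
  }
  if (is.null(par) && is.null(tau)) {
    stop("supply either `par` or `tau`")
  }
  if (!is.null(tau)) {
    if (!is.null(par)) stop("supply only one of `par` and `tau`")
    par <- tau_to_par(family, tau)
  }
  check_par(family, par)
  structure(list(family = family, par = par, nu = nu), class = "bicop")
}

#' @export
print.bicop <- function(x, ...) {
  nu <- if (is.null(x$nu)) "" else sprintf(", nu = %g", x$nu)
  cat(sprintf("<bicop> %s copula, par = %.4f%s (tau = %.4f)\n",
              x$family, x$par, nu, par_to_tau(x)))
  invisible(x)
}

bicop_families <- c("bvn", "t", "gumbel", "sgumbel", "gumbel_r1", "gumbel_r2")

parse_family <- function(family) {
  stopifnot(is.character(family), length(family) == 1L)
  if (grepl("^t[0-9.]+$", family)) {
    return(list(family = "t", nu = as.numeric(sub("^t", "", family))))
  }
  family <- match.arg(family, bicop_families)
  list(family = family, nu = NULL)
}

check_par <- function(family, par) {
  stopifnot(is.numeric(par), length(par) == 1L, is.finite(par))
  ok <- switch(family,
    bvn = ,
    t = par >= -1 && par <= 1,
    par >= 1)
  if (!ok) {
    rng <- if (family %in% c("bvn", "t")) "[-1, 1]" else "[1, Inf)"
    stop(sprintf("parameter %g outside the %s copula domain %s", par, family, rng))
  }
  invisible(TRUE)
}

## integer codes shared with the C++ kernels
family_code <- function(family) {
  match(family, bicop_families)
}

## clamp away from 0/1 before log/quantile transforms; Gumbel-type conditional
## cdfs are undefined at the exact boundary
.u_eps <- 1e-10
clamp01 <- function(u) pmin(pmax(u, .u_eps), 1 - .u_eps)

## ---- Kendall's tau conversions ---------------------------------------------

#' Kendall's tau conversions
#'
#' Map a copula's dependence parameter to Kendall's tau and back.  For the BVN
#' and t copulas `tau = (2 / pi) * asin(par)`; for the Gumbel and survival
#' Gumbel copulas `tau = 1 - 1 / par`; for the 1- and 2-reflected Gumbel
#' copulas `tau = 1 / par - 1`.
#'
#' @param spec A [bicop()] object.
#' @param family Family tag, as in [bicop()].
#' @param tau Kendall's tau within the family's attainable range.
#' @return `par_to_tau()` returns tau; `tau_to_par()` the native parameter.
#' @export
par_to_tau <- function(spec) {
  stopifnot(inherits(spec, "bicop"))
  switch(spec$family,
    bvn = ,
    t = 2 / pi * asin(spec$par),
    gumbel = ,
    sgumbel = 1 - 1 / spec$par,
    gumbel_r1 = ,
    gumbel_r2 = 1 / spec$par - 1)
}

#' @rdname par_to_tau
#' @export
tau_to_par <- function(family, tau) {
  family <- parse_family(family)$family
  stopifnot(is.numeric(tau), length(tau) == 1L, is.finite(tau))
  bad_range <- function(rng) {
    stop(sprintf("tau = %g outside the %s copula's attainable range %s",
                 tau, family, rng))
  }
  switch(family,
    bvn = ,
    t = {
      if (tau <= -1 || tau >= 1) bad_range("(-1, 1)")
      sin(pi * tau / 2)
    },
    gumbel = ,
    sgumbel = {
      if (tau < 0 || tau >= 1) bad_range("[0, 1)")
      1 / (1 - tau)
    },
    gumbel_r1 = ,
    gumbel_r2 = {
      if (tau > 0 || tau <= -1) bad_range("(-1, 0]")
      1 / (1 + tau)
    })
}

## ---- reflections -----------------------------------------------------------

#' Reflect a bivariate copula
#'
#' `"survival"` reflects both uniform margins about 1/2 (the survival copula,
#' which flips the direction of tail asymmetry), `"reflect1"` reflects only the
#' first margin and `"reflect2"` only the second (both turn positive into
#' negative dependence).  The dependence parameter is carried over; for the
#' radially symmetric BVN/t families the single-margin reflections negate it.
#'
#' @param spec A [bicop()] object.
#' @param mode One of `"survival"`, `"reflect1"`, `"reflect2"`.
#' @return A [bicop()] object.
#' @export
reflect_bicop <- function(spec, mode = c("survival", "reflect1", "reflect2")) {
  stopifnot(inherits(spec, "bicop"))
  mode <- match.arg(mode)
  fam <- spec$family
  par <- spec$par
  new_fam <- switch(mode,
    survival = c(bvn = "bvn", t = "t", gumbel = "sgumbel", sgumbel = "gumbel",
                 gumbel_r1 = "gumbel_r2", gumbel_r2 = "gumbel_r1")[[fam]],
    reflect1 = c(bvn = "bvn", t = "t", gumbel = "gumbel_r1", sgumbel = "gumbel_r2",
                 gumbel_r1 = "gumbel", gumbel_r2 = "sgumbel")[[fam]],
    reflect2 = c(bvn = "bvn", t = "t", gumbel = "gumbel_r2", sgumbel = "gumbel_r1",
                 gumbel_r1 = "sgumbel", gumbel_r2 = "gumbel")[[fam]])
  if (fam %in% c("bvn", "t") && mode != "survival") par <- -par
  bicop(new_fam, par = par, nu = spec$nu)
}

## ---- Gumbel primitives (shared by the public wrappers) ---------------------

pgumbel_cop <- function(u1, u2, th) {
  x <- -log(clamp01(u1)); y <- -log(clamp01(u2))
  exp(-(x^th + y^th)^(1 / th))
}

## h(u | v) = d C(u, v) / d v
hgumbel_cop <- function(u, v, th) {
  x <- -log(clamp01(u)); y <- -log(clamp01(v))
  s <- x^th + y^th
  exp(-s^(1 / th) + y + (1 / th - 1) * log(s) + (th - 1) * log(y))
}

dgumbel_cop <- function(u1, u2, th) {
  u1 <- clamp01(u1); u2 <- clamp01(u2)
  x <- -log(u1); y <- -log(u2)
  s <- x^th + y^th
  exp(-s^(1 / th) + x + y + (2 / th - 2) * log(s) +
        (th - 1) * (log(x) + log(y))) * (1 + (th - 1) * s^(-1 / th))
}

hinv_gumbel_cop <- function(p, v, th) {
  ## safeguarded bisection; h is strictly increasing in u for fixed v
  lo <- rep(.u_eps, length(p))
  hi <- rep(1 - .u_eps, length(p))
  p <- pmin(pmax(p, .u_eps), 1 - .u_eps)
  for (i in seq_len(52)) {
    mid <- (lo + hi) / 2
    below <- hgumbel_cop(mid, v, th) < p
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  (lo + hi) / 2
}

## ---- public copula functions ----------------------------------------------

#' Copula distribution functions
#'
#' `pbicop()` is the copula cdf `C(u1, u2)`; `dbicop()` its density;
#' `hbicop()` the conditional cdf of the first coordinate given the second,
#' `h(u | v) = dC(u, v)/dv`; and `hinv_bicop()` the inverse of `hbicop()` in
#' its first argument.  All are vectorised over the probability arguments and
#' clamp them to `[1e-10, 1 - 1e-10]` before log/quantile transforms.
#'
#' @param u1,u2,u,v,p Numeric vectors of probabilities in `[0, 1]`.
#' @param spec A [bicop()] object.
#' @return A numeric vector.
#' @examples
#' g <- bicop("gumbel", par = 2)
#' pbicop(0.5, 0.5, g)                  # 0.5^(2^(1/2))
#' hinv_bicop(hbicop(0.37, 0.8, g), 0.8, g)  # 0.37
#' @export
pbicop <- function(u1, u2, spec) {
  stopifnot(inherits(spec, "bicop"))
  n <- max(length(u1), length(u2))
  u1 <- rep_len(u1, n); u2 <- rep_len(u2, n)
  th <- spec$par
  ## exact on the boundary of the unit square
  edge <- u1 <= .u_eps | u2 <= .u_eps | u1 >= 1 - .u_eps | u2 >= 1 - .u_eps
  if (any(edge)) {
    out <- numeric(n)
    out[edge] <- pmin(u1, u2)[edge] * (u1[edge] > .u_eps & u2[edge] > .u_eps)
    if (any(!edge)) {
      out[!edge] <- pbicop(u1[!edge], u2[!edge], spec)
    }
    return(out)
  }
  switch(spec$family,
    gumbel = pgumbel_cop(u1, u2, th),
    sgumbel = u1 + u2 - 1 + pgumbel_cop(1 - u1, 1 - u2, th),
    gumbel_r1 = u2 - pgumbel_cop(1 - u1, u2, th),
    gumbel_r2 = u1 - pgumbel_cop(u1, 1 - u2, th),
    bvn = pbvn_cop(u1, u2, th),
    t = pt_cop(u1, u2, th, spec$nu))
}

## BVN copula cdf via Gauss-Legendre integration of the closed-form
## conditional on the normal scale: C = int_{-8}^{qnorm(u2)} phi(z)
## Phi((qnorm(u1) - rho z)/sqrt(1-rho^2)) dz.  Smooth integrand, 96 nodes.
pbvn_cop <- function(u1, u2, rho) {
  if (abs(rho) >= 1 - 1e-12) {
    return(if (rho > 0) pmin(u1, u2) else pmax(u1 + u2 - 1, 0))
  }
  u1 <- clamp01(u1); u2 <- clamp01(u2)
  gl <- legendre_raw(96L)
  upper <- stats::qnorm(u2)
  lower <- -8.5
  half <- (upper - lower) / 2
  centre <- (upper + lower) / 2
  x1 <- stats::qnorm(u1)
  s <- sqrt(1 - rho^2)
  out <- numeric(length(u1))
  for (q in seq_along(gl$nodes)) {
    z <- centre + half * gl$nodes[q]
    out <- out + gl$weights[q] * stats::dnorm(z) * stats::pnorm((x1 - rho * z) / s)
  }
  pmax(out * half, 0)
}

## t copula cdf by composite Gauss-Legendre on the uniform scale of v
pt_cop <- function(u1, u2, rho, nu) {
  if (abs(rho) >= 1 - 1e-12) {
    return(if (rho > 0) pmin(u1, u2) else pmax(u1 + u2 - 1, 0))
  }
  u1 <- clamp01(u1); u2 <- clamp01(u2)
  gl <- legendre_raw(64L)
  out <- numeric(length(u1))
  brk <- cbind(0, u2 / 2, u2)
  for (piece in 1:2) {
    a <- brk[, piece]; b <- brk[, piece + 1L]
    half <- (b - a) / 2; centre <- (a + b) / 2
    for (q in seq_along(gl$nodes)) {
      v <- clamp01(centre + half * gl$nodes[q])
      out <- out + gl$weights[q] * half * ht_cop(u1, v, rho, nu)
    }
  }
  pmax(out, 0)
}

ht_cop <- function(u, v, rho, nu) {
  x <- stats::qt(clamp01(u), nu)
  y <- stats::qt(clamp01(v), nu)
  stats::pt((x - rho * y) * sqrt((nu + 1) / ((nu + y^2) * (1 - rho^2))), nu + 1)
}

#' @rdname pbicop
#' @export
hbicop <- function(u, v, spec) {
  stopifnot(inherits(spec, "bicop"))
  n <- max(length(u), length(v))
  u <- rep_len(u, n); v <- rep_len(v, n)
  th <- spec$par
  out <- switch(spec$family,
    bvn = {
      if (abs(th) >= 1 - 1e-12) th <- sign(th) * (1 - 1e-12)
      stats::pnorm((stats::qnorm(clamp01(u)) - th * stats::qnorm(clamp01(v))) /
                     sqrt(1 - th^2))
    },
    t = ht_cop(u, v, th, spec$nu),
    gumbel = hgumbel_cop(u, v, th),
    sgumbel = 1 - hgumbel_cop(1 - u, 1 - v, th),
    gumbel_r1 = 1 - hgumbel_cop(1 - u, v, th),
    gumbel_r2 = hgumbel_cop(u, 1 - v, th))
  pmin(pmax(out, 0), 1)
}

#' @rdname pbicop
#' @export
hinv_bicop <- function(p, v, spec) {
  stopifnot(inherits(spec, "bicop"))
  n <- max(length(p), length(v))
  p <- rep_len(p, n); v <- rep_len(v, n)
  p <- clamp01(p); v <- clamp01(v)
  th <- spec$par
  out <- switch(spec$family,
    bvn = stats::pnorm(sqrt(1 - th^2) * stats::qnorm(p) + th * stats::qnorm(v)),
    t = {
      y <- stats::qt(v, spec$nu)
      x <- th * y + sqrt((1 - th^2) * (spec$nu + y^2) / (spec$nu + 1)) *
        stats::qt(p, spec$nu + 1)
      stats::pt(x, spec$nu)
    },
    gumbel = hinv_gumbel_cop(p, v, th),
    sgumbel = 1 - hinv_gumbel_cop(1 - p, 1 - v, th),
    gumbel_r1 = 1 - hinv_gumbel_cop(1 - p, v, th),
    gumbel_r2 = hinv_gumbel_cop(p, 1 - v, th))
  pmin(pmax(out, 0), 1)
}

#' @rdname pbicop
#' @export
dbicop <- function(u1, u2, spec) {
  stopifnot(inherits(spec, "bicop"))
  n <- max(length(u1), length(u2))
  u1 <- clamp01(rep_len(u1, n)); u2 <- clamp01(rep_len(u2, n))
  th <- spec$par
  switch(spec$family,
    bvn = {
      x <- stats::qnorm(u1); y <- stats::qnorm(u2)
      if (abs(th) < 1e-14) return(rep(1, n))
      exp(-(th^2 * (x^2 + y^2) - 2 * th * x * y) / (2 * (1 - th^2))) /
        sqrt(1 - th^2)
    },
    t = {
      nu <- spec$nu
      x <- stats::qt(u1, nu); y <- stats::qt(u2, nu)
      lc <- lgamma((nu + 2) / 2) + lgamma(nu / 2) - 2 * lgamma((nu + 1) / 2) -
        0.5 * log(1 - th^2)
      exp(lc -
            (nu + 2) / 2 *
              log1p((x^2 - 2 * th * x * y + y^2) / (nu * (1 - th^2))) +
            (nu + 1) / 2 * (log1p(x^2 / nu) + log1p(y^2 / nu)))
    },
    gumbel = dgumbel_cop(u1, u2, th),
    sgumbel = dgumbel_cop(1 - u1, 1 - u2, th),
    gumbel_r1 = dgumbel_cop(1 - u1, u2, th),
    gumbel_r2 = dgumbel_cop(u1, 1 - u2, th))
}
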