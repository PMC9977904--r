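## Independent oracles used across the test suite.  These are deliberately
## naive (loops, direct quadrature, enumeration) and share no code with the
## package's engine.

## all outcomes of d items with K categories, one row per outcome
all_outcomes <- function(d, K) {
  as.matrix(expand.grid(rep(list(0:(K - 1)), d)))
}

## Gauss-Legendre nodes/weights on (0, 1) straight from statmod
gl01 <- function(n) {
  gq <- statmod::gauss.quad(n, kind = "legendre")
  list(x = (gq$nodes + 1) / 2, w = gq$weights / 2)
}

## one-factor copula model pmf: pi(y) = int prod_j [h_j(a_{y+1}|v) - h_j(a_y|v)] dv
onefactor_pmf_oracle <- function(y, acut, specs, nq = 35) {
  gl <- gl01(nq)
  K <- nrow(acut) + 1L
  out <- 0
  for (q in seq_len(nq)) {
    v <- gl$x[q]
    f <- 1
    for (j in seq_along(y)) {
      up <- if (y[j] == K - 1) 1 else hbicop(acut[y[j] + 1L, j], v, specs[[j]])
      lo <- if (y[j] == 0) 0 else hbicop(acut[y[j], j], v, specs[[j]])
      f <- f * (up - lo)
    }
    out <- out + gl$w[q] * f
  }
  out
}

## two-factor copula model pmf with copulas specs1 (to V1) and specs2
## (to V2 given V1)
twofactor_pmf_oracle <- function(y, acut, specs1, specs2, nq = 35) {
  gl <- gl01(nq)
  K <- nrow(acut) + 1L
  out <- 0
  for (q1 in seq_len(nq)) {
    v1 <- gl$x[q1]
    for (q2 in seq_len(nq)) {
      v2 <- gl$x[q2]
      f <- 1
      for (j in seq_along(y)) {
        up <- if (y[j] == K - 1) 1 else
          hbicop(hbicop(acut[y[j] + 1L, j], v1, specs1[[j]]), v2, specs2[[j]])
        lo <- if (y[j] == 0) 0 else
          hbicop(hbicop(acut[y[j], j], v1, specs1[[j]]), v2, specs2[[j]])
        f <- f * (up - lo)
      }
      out <- out + gl$w[q1] * gl$w[q2] * f
    }
  }
  out
}

## discretised-MVN rectangle probabilities (deterministic Miwa algorithm)
mvn_rectangle_oracle <- function(cells, alpha, R) {
  d <- ncol(cells)
  apply(cells, 1, function(y) {
    lo <- vapply(seq_len(d), function(j) c(-Inf, alpha[, j])[y[j] + 1L], 0)
    up <- vapply(seq_len(d), function(j) c(alpha[, j], Inf)[y[j] + 1L], 0)
    mvtnorm::pmvnorm(lower = lo, upper = up, corr = R,
                     algorithm = mvtnorm::Miwa(steps = 512))[1]
  })
}

## implied normal correlation matrix of an all-BVN bi-factor model
bifactor_corr <- function(theta, delta, grp) {
  d <- length(theta)
  gam <- delta * sqrt(1 - theta^2)
  R <- diag(d)
  for (i in seq_len(d - 1)) {
    for (j in (i + 1):d) {
      R[i, j] <- R[j, i] <- theta[i] * theta[j] +
        if (grp[i] == grp[j]) gam[i] * gam[j] else 0
    }
  }
  R
}

## draw n pairs from a bivariate copula (conditional-inverse construction)
r_bicop <- function(n, spec) {
  v <- stats::runif(n)
  u <- hinv_bicop(stats::runif(n), v, spec)
  cbind(u, v)
}

## discretise uniform draws by cutpoints a (vector, strictly increasing)
discretise <- function(u, a) {
  findInterval(u, c(0, a, 1), rightmost.closed = TRUE) - 1L
}
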