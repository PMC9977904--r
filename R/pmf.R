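## Nested Gauss-Legendre evaluation of joint and marginal probabilities.
##
## Everything is built from per-item "cell arrays": for item j, a K x
## (n_q * n_q) matrix P_j whose column c = q1 + n_q * (q2 - 1) holds the
## conditional cell probabilities f(y | v_{q2}, v_{q1}) (bi-factor: v_{q1} is
## the common-factor node, v_{q2} the group node) or f(y | v_{q2|q1})
## (second-order: dependent group nodes).  The joint pmf is then
##   sum_{q1} w_{q1} prod_g [ sum_{q2} w_{q2} prod_{j in g} P_j ],
## and any marginal over a subset of items simply drops the other items'
## factors (their cell probabilities sum to one).

.pmf_floor <- 1e-300

## conditional cell-probability arrays for all items
item_cell_arrays <- function(model, rule) {
  s <- model$struct
  K <- s$K; d <- s$d
  nq <- length(rule$nodes)
  v <- rule$nodes
  out <- vector("list", d)
  if (model$kind == "bifactor") {
    v2 <- rep(v, each = nq)   # group-factor node for column c
    for (j in seq_len(d)) {
      s1 <- spec_of(model$fam1[j], model$par1[j], model$nu1[j])
      s2 <- spec_of(model$fam2[j], model$par2[j], model$nu2[j])
      ## boundaries k = 1..K-1 at the common-factor nodes
      U <- matrix(hbicop(rep(model$cut[, j], nq), rep(v, each = K - 1), s1),
                  nrow = K - 1L)            # (K-1) x nq, columns = q1
      Ubig <- U[, rep(seq_len(nq), nq), drop = FALSE]  # (K-1) x (nq*nq)
      Tk <- matrix(hbicop(as.vector(Ubig),
                          rep(v2, each = K - 1L), s2), nrow = K - 1L)
      out[[j]] <- boundaries_to_cells(Tk, K)
    }
  } else {
    ## second-order: dependent group nodes v_{q2|q1} = C^{-1}(v_q2 | v_q1)
    vdep <- secondorder_nodes(model, rule)   # G-list of length nq*nq vectors
    for (j in seq_len(d)) {
      g <- s$item_group[j]
      s1 <- spec_of(model$fam1[j], model$par1[j], model$nu1[j])
      vg <- vdep[[g]]
      Tk <- matrix(hbicop(rep(model$cut[, j], times = length(vg)),
                          rep(vg, each = K - 1L), s1), nrow = K - 1L)
      out[[j]] <- boundaries_to_cells(Tk, K)
    }
  }
  out
}

secondorder_nodes <- function(model, rule) {
  nq <- length(rule$nodes)
  v1 <- rep(rule$nodes, times = nq)  # q1 fastest
  v2 <- rep(rule$nodes, each = nq)
  lapply(seq_len(model$struct$G), function(g) {
    s0 <- spec_of(model$fam2[g], model$par2[g], model$nu2[g])
    hinv_bicop(v2, v1, s0)
  })
}

boundaries_to_cells <- function(Tk, K) {
  ncol <- ncol(Tk)
  P <- matrix(0, nrow = K, ncol = ncol)
  if (K == 2L) {
    P[1, ] <- Tk[1, ]
    P[2, ] <- 1 - Tk[1, ]
  } else {
    P[1, ] <- Tk[1, ]
    P[2:(K - 1), ] <- Tk[-1, , drop = FALSE] - Tk[-(K - 1), , drop = FALSE]
    P[K, ] <- 1 - Tk[K - 1, ]
  }
  pmax(P, 0)
}

## inner weighted sum over q2 of an m x (nq*nq) matrix -> m x nq
inner_sum <- function(L, nq, w) {
  m <- nrow(L)
  dim(L) <- c(m * nq, nq)
  out <- L %*% w
  dim(out) <- c(m, nq)
  out
}

#' Joint pmf of a factor copula model
#'
#' Evaluates the joint probability of one or more response vectors under a
#' bi-factor or second-order copula model by nested Gauss-Legendre quadrature:
#' a one-dimensional outer integral over the common factor of a product of `G`
#' one-dimensional inner integrals over the group factors (the second-order
#' model uses dependent inner quadrature points with a one-factor copula
#' distribution, so no copula density factor is needed).
#'
#' @param model A [bifactor_model()] or [secondorder_model()].
#' @param y A length-`d` vector of categories in `0 .. K - 1`, or an
#'   `m x d` matrix of such rows.
#' @param n_q Number of quadrature points per dimension.
#' @return A numeric vector of probabilities (length `m`).
#' @export
model_pmf <- function(model, y, n_q = 25L) {
  stopifnot(inherits(model, "bifcop_model"))
  s <- model$struct
  if (is.vector(y)) y <- matrix(y, nrow = 1L)
  y <- as.matrix(y)
  if (ncol(y) != s$d) stop(sprintf("y must have d = %d columns", s$d))
  if (any(y < 0 | y > s$K - 1L)) stop("categories must lie in 0 .. K-1")
  rule <- legendre_rule(n_q)
  P <- item_cell_arrays(model, rule)
  pmf_from_arrays(P, y, s, rule)
}

pmf_from_arrays <- function(P, y, s, rule) {
  nq <- length(rule$nodes)
  m <- nrow(y)
  outer_prod <- matrix(1, m, nq)
  for (g in seq_len(s$G)) {
    items <- which(s$item_group == g)
    L <- P[[items[1]]][y[, items[1]] + 1L, , drop = FALSE]
    for (j in items[-1]) {
      L <- L * P[[j]][y[, j] + 1L, , drop = FALSE]
    }
    outer_prod <- outer_prod * inner_sum(L, nq, rule$weights)
  }
  as.vector(outer_prod %*% rule$weights)
}

#' Marginal probabilities of an item subset
#'
#' Marginal probability table over a subset of items, computed directly by
#' quadrature over the relevant factors only (never by summing the full
#' `K^d` joint table): items absent from `items` contribute a factor of one.
#'
#' @param model A [bifactor_model()] or [secondorder_model()].
#' @param items Integer vector of distinct item indices (any length up to
#'   `d`; the goodness-of-fit machinery uses up to 4).
#' @param n_q Number of quadrature points.
#' @return An array of dimension `rep(K, length(items))`; entry
#'   `[y1+1, y2+1, ...]` is `P(Y[items[1]] = y1, Y[items[2]] = y2, ...)`.
#' @export
model_margin <- function(model, items, n_q = 25L) {
  stopifnot(inherits(model, "bifcop_model"))
  if (anyDuplicated(items)) stop("`items` must be distinct")
  s <- model$struct
  rule <- legendre_rule(n_q)
  P <- item_cell_arrays(model, rule)
  margin_from_arrays(P, items, s, rule)
}

margin_from_arrays <- function(P, items, s, rule) {
  K <- s$K; nq <- length(rule$nodes)
  ord <- order(items)
  sorted <- items[ord]
  groups <- unique(s$item_group[sorted])
  tabs <- list()
  for (g in groups) {
    in_g <- sorted[s$item_group[sorted] == g]
    X <- P[[in_g[1]]]
    cells <- K
    for (j in in_g[-1]) {
      X <- X[rep(seq_len(cells), times = K), , drop = FALSE] *
        P[[j]][rep(seq_len(K), each = cells), , drop = FALSE]
      cells <- cells * K
    }
    tabs[[as.character(g)]] <- inner_sum(X, nq, rule$weights)  # cells x nq
  }
  X <- tabs[[1]]
  cells <- nrow(X)
  for (tg in tabs[-1]) {
    cg <- nrow(tg)
    X <- X[rep(seq_len(cells), times = cg), , drop = FALSE] *
      tg[rep(seq_len(cg), each = cells), , drop = FALSE]
    cells <- cells * cg
  }
  out <- as.vector(X %*% rule$weights)
  dim(out) <- rep(K, length(items))
  ## axes currently follow the group-major sorted order; permute back
  if (any(ord != seq_along(items))) {
    out <- aperm(out, order(ord))
  }
  out
}

#' Log-likelihood of a factor copula model
#'
#' Sum of log joint probabilities over the rows of a response matrix, with
#' each probability floored at `1e-300` before taking logs (conditionals of
#' Gumbel-type copulas can underflow for extreme cells).
#'
#' @inheritParams model_pmf
#' @param data Response matrix or data frame (`n x d`, categories
#'   `0 .. K - 1`).
#' @param use_cpp Use the compiled kernel (default); the pure-R path is the
#'   slow reference implementation.
#' @return The log-likelihood (a scalar).
#' @export
model_loglik <- function(model, data, n_q = 25L, use_cpp = TRUE) {
  y <- response_matrix(data, model$struct)
  if (use_cpp) {
    ll <- loglik_cpp(model, y, n_q = n_q, grad = FALSE)
    return(ll$loglik)
  }
  sum(log(pmax(model_pmf(model, y, n_q = n_q), .pmf_floor)))
}

## coerce a data frame / matrix of responses to an integer matrix and
## validate against the structure
response_matrix <- function(data, struct) {
  y <- as.matrix(as.data.frame(data))
  storage.mode(y) <- "integer"
  if (ncol(y) != struct$d) {
    stop(sprintf("data has %d columns but the structure has d = %d items",
                 ncol(y), struct$d))
  }
  if (anyNA(y)) stop("missing responses are not supported")
  if (any(y < 0L) || any(y > struct$K - 1L)) {
    stop("responses must be coded 0 .. K-1")
  }
  y
}
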