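## Limited-information M2 goodness of fit.
##
## Residual ordering convention (fixed for reproducibility): univariate block
## first, items in group-major order with categories 1..K-1 fastest; then the
## bivariate block over lexicographic pairs (j1 < j2) with the first item's
## category cycling fastest within each pair.  Category 0 is excluded
## throughout (its probabilities are determined by the others).

#' Residual dimension of the M2 statistic
#'
#' `s = d (K - 1) + choose(d, 2) (K - 1)^2`: the number of univariate plus
#' bivariate marginal residuals excluding category 0.  `m2_df()` gives the
#' degrees of freedom `s - q` of the reference chi-square for the standard
#' parameter counts `q = d (K + 1)` (bi-factor) and `q = d K + G`
#' (second-order).
#'
#' @param d Number of items.
#' @param K Number of categories.
#' @param G Number of groups.
#' @param model `"bifactor"` or `"secondorder"`.
#' @export
residual_dim <- function(d, K) {
  d * (K - 1) + choose(d, 2) * (K - 1)^2
}

#' @rdname residual_dim
#' @export
m2_df <- function(d, K, G, model = c("bifactor", "secondorder")) {
  model <- match.arg(model)
  q <- if (model == "bifactor") d * (K + 1) else d * K + G
  residual_dim(d, K) - q
}

## ---- residuals --------------------------------------------------------------

## observed univariate + bivariate proportions (category 0 excluded)
observed_p2 <- function(y, K) {
  n <- nrow(y); d <- ncol(y)
  uni <- as.vector(vapply(seq_len(d), function(j)
    tabulate(y[, j], nbins = K - 1L) / n, numeric(K - 1L)))
  pairs <- utils::combn(d, 2)
  biv <- lapply(seq_len(ncol(pairs)), function(p) {
    j1 <- pairs[1, p]; j2 <- pairs[2, p]
    tab <- table(factor(y[, j1], levels = 0:(K - 1)),
                 factor(y[, j2], levels = 0:(K - 1))) / n
    as.vector(tab[-1, -1])    # y1 fastest, category 0 dropped
  })
  c(uni, unlist(biv))
}

## model-based univariate + bivariate margins in the same order; the
## univariate margins are exactly the cutpoint gaps (uniform latent margins),
## so only the bivariate block needs quadrature
model_pi2 <- function(model, n_q = 25L) {
  s <- model$struct
  K <- s$K; d <- s$d
  rule <- legendre_rule(n_q)
  P <- item_cell_arrays(model, rule)
  uni <- as.vector(apply(unclass(model$cut), 2,
                         function(a) diff(c(a, 1))))
  pairs <- utils::combn(d, 2)
  biv <- lapply(seq_len(ncol(pairs)), function(p) {
    tab <- margin_from_arrays(P, pairs[, p], s, rule)
    as.vector(tab[-1, -1])
  })
  c(uni, unlist(biv))
}

#' Univariate and bivariate residuals of a fitted model
#'
#' @param fit A [fit_factor_copula()] result.
#' @param n_q Quadrature points for the model margins.
#' @return A tibble with the stacked residual index (`block`, `items`,
#'   `categories`), observed proportions `p`, model margins `pi` and the
#'   residual `p - pi`.
#' @export
residual_vector <- function(fit, n_q = fit$n_q) {
  stopifnot(inherits(fit, "bifcop_fit"))
  K <- fit$struct$K; d <- fit$struct$d
  p2 <- observed_p2(fit$data, K)
  pi2 <- model_pi2(fit$model, n_q = n_q)
  idx <- residual_index(d, K)
  dplyr::mutate(idx, p = p2, pi = pi2, residual = p2 - pi2)
}

residual_index <- function(d, K) {
  Km1 <- K - 1L
  uni <- tibble::tibble(block = "uni",
                        j1 = rep(seq_len(d), each = Km1), j2 = NA_integer_,
                        y1 = rep(seq_len(Km1), d), y2 = NA_integer_)
  pairs <- utils::combn(d, 2)
  biv <- tibble::tibble(
    block = "biv",
    j1 = rep(pairs[1, ], each = Km1^2),
    j2 = rep(pairs[2, ], each = Km1^2),
    y1 = rep(rep(seq_len(Km1), times = Km1), ncol(pairs)),
    y2 = rep(rep(seq_len(Km1), each = Km1), ncol(pairs)))
  dplyr::bind_rows(uni, biv)
}

## ---- Delta2: derivatives of the margins wrt the estimated parameters --------

## s x q Jacobian by central finite differences; columns ordered as
## [cutpoints (item-major, k fastest), free copula parameters (par1, par2)]
compute_delta2 <- function(fit, n_q = fit$n_q, step = 1e-5, check_rank = TRUE) {
  m <- fit$model
  s <- fit$struct
  K <- s$K; d <- s$d
  free <- fit$free
  n1 <- length(m$par1)
  fam_all <- c(m$fam1, m$fam2)
  pars_hat <- c(m$par1, m$par2)
  acut_hat <- unclass(m$cut)

  eval_pi2 <- function(acut, pars) {
    mm <- m
    mm$cut <- cutpoint_set(acut, s)
    mm$par1 <- pars[seq_len(n1)]
    mm$par2 <- pars[-seq_len(n1)]
    model_pi2(mm, n_q = n_q)
  }

  cols <- list()
  ## cutpoint columns
  for (j in seq_len(d)) {
    for (k in seq_len(K - 1L)) {
      ap <- acut_hat; am <- acut_hat
      h <- step
      ap[k, j] <- ap[k, j] + h
      am[k, j] <- am[k, j] - h
      cols[[length(cols) + 1L]] <-
        (eval_pi2(ap, pars_hat) - eval_pi2(am, pars_hat)) / (2 * h)
    }
  }
  ## copula parameter columns (free only)
  for (p in free) {
    par <- pars_hat[p]
    if (fam_all[p] %in% c("bvn", "t")) {
      h <- min(step, (1 - abs(par)) / 3); h <- max(h, 1e-8)
      lo <- max(par - h, -1 + 1e-10); hi <- min(par + h, 1 - 1e-10)
    } else {
      h <- min(step, (par - 1) / 3 + 1e-9); h <- max(h, 1e-8)
      lo <- max(par - h, 1 + 1e-12); hi <- par + h
    }
    pp <- pars_hat; pp[p] <- hi
    pm <- pars_hat; pm[p] <- lo
    cols[[length(cols) + 1L]] <-
      (eval_pi2(acut_hat, pp) - eval_pi2(acut_hat, pm)) / (hi - lo)
  }
  D <- do.call(cbind, cols)
  if (!check_rank) return(D)
  qr_D <- qr(D)
  if (qr_D$rank < ncol(D)) {
    deficient <- setdiff(seq_len(ncol(D)), qr_D$pivot[seq_len(qr_D$rank)])
    stop("Delta2 is rank deficient in columns ",
         paste(deficient, collapse = ", "),
         " (a sign of a non-identified parameterisation)")
  }
  D
}

## ---- Xi2: asymptotic covariance of the residual proportions -----------------

## covariance of sqrt(n) (p2 - pi2) assembled from model margins of up to
## four items; repeated items in a joint probability force equal categories
compute_xi2 <- function(fit, n_q = fit$n_q) {
  m <- fit$model
  s <- fit$struct
  K <- s$K; d <- s$d; Km1 <- K - 1L
  rule <- legendre_rule(n_q)
  P <- item_cell_arrays(m, rule)

  marg_cache <- new.env(parent = emptyenv())
  marg <- function(items) {            # sorted distinct items -> array
    key <- paste(items, collapse = ".")
    got <- marg_cache[[key]]
    if (is.null(got)) {
      got <- if (length(items) == 1L) {
        diff(c(0, m$cut[, items], 1))  # univariate margins are exact
      } else {
        margin_from_arrays(P, items, s, rule)
      }
      marg_cache[[key]] <- got
    }
    got
  }
  ## P(Y[items] = cats) allowing repeated items (0 on inconsistent categories)
  jp <- function(items, cats) {
    o <- order(items)
    items <- items[o]; cats <- cats[o]
    keep <- !duplicated(items)
    if (any(!keep)) {
      dup_ok <- all(vapply(which(!keep), function(i)
        cats[i] == cats[max(which(items[seq_len(i - 1)] == items[i]))], TRUE))
      if (!dup_ok) return(0)
      items <- items[keep]; cats <- cats[keep]
    }
    marg(items)[matrix(cats + 1L, 1)]
  }

  pairs <- utils::combn(d, 2)
  npair <- ncol(pairs)
  s_uni <- d * Km1
  s_tot <- s_uni + npair * Km1^2
  uni_idx <- cbind(j = rep(seq_len(d), each = Km1), y = rep(seq_len(Km1), d))
  biv_idx <- cbind(j1 = rep(pairs[1, ], each = Km1^2),
                   j2 = rep(pairs[2, ], each = Km1^2),
                   y1 = rep(rep(seq_len(Km1), times = Km1), npair),
                   y2 = rep(rep(seq_len(Km1), each = Km1), npair))

  Xi <- matrix(0, s_tot, s_tot)
  ## Xi11
  for (a in seq_len(s_uni)) {
    for (b in a:s_uni) {
      pa <- jp(uni_idx[a, 1], uni_idx[a, 2])
      pab <- jp(c(uni_idx[a, 1], uni_idx[b, 1]), c(uni_idx[a, 2], uni_idx[b, 2]))
      pb <- jp(uni_idx[b, 1], uni_idx[b, 2])
      Xi[a, b] <- Xi[b, a] <- pab - pa * pb
    }
  }
  ## Xi21
  for (r in seq_len(nrow(biv_idx))) {
    row <- s_uni + r
    pr <- jp(biv_idx[r, 1:2], biv_idx[r, 3:4])
    for (b in seq_len(s_uni)) {
      pj <- jp(uni_idx[b, 1], uni_idx[b, 2])
      p3 <- jp(c(biv_idx[r, 1:2], uni_idx[b, 1]),
               c(biv_idx[r, 3:4], uni_idx[b, 2]))
      Xi[row, b] <- Xi[b, row] <- p3 - pr * pj
    }
  }
  ## Xi22
  for (r1 in seq_len(nrow(biv_idx))) {
    row <- s_uni + r1
    pr1 <- jp(biv_idx[r1, 1:2], biv_idx[r1, 3:4])
    for (r2 in r1:nrow(biv_idx)) {
      col <- s_uni + r2
      pr2 <- jp(biv_idx[r2, 1:2], biv_idx[r2, 3:4])
      p4 <- jp(c(biv_idx[r1, 1:2], biv_idx[r2, 1:2]),
               c(biv_idx[r1, 3:4], biv_idx[r2, 3:4]))
      Xi[row, col] <- Xi[col, row] <- p4 - pr1 * pr2
    }
  }
  Xi
}

## ---- M2 ---------------------------------------------------------------------

#' Limited-information M2 statistic
#'
#' Quadratic form in the univariate and bivariate residual proportions,
#' `M2 = n (p2 - pi2)' C2 (p2 - pi2)` with
#' `C2 = Xi2^{-1} - Xi2^{-1} Delta2 (Delta2' Xi2^{-1} Delta2)^{-1} Delta2' Xi2^{-1}`,
#' where `Delta2` holds the first derivatives of the margins with respect to
#' the estimated parameters (computed by central finite differences) and
#' `Xi2` the asymptotic covariance of the residuals (assembled from model
#' margins of up to four items).  Under the fitted model `M2` is
#' asymptotically chi-square with `s - q` degrees of freedom; the
#' RMSEA2 transform `sqrt(max((M2 - df) / (n df), 0))` is attached.
#'
#' @param fit A [fit_factor_copula()] result.
#' @param n_q Quadrature points for the model margins.
#' @return A tibble of class `"bifcop_m2"` with `statistic`, `s`, `q`, `df`,
#'   `p_value`, `rmsea2`, `n`.
#' @export
m2_test <- function(fit, n_q = fit$n_q) {
  stopifnot(inherits(fit, "bifcop_fit"))
  res <- residual_vector(fit, n_q = n_q)
  r <- res$residual
  s_tot <- length(r)
  q <- fit$q
  df <- s_tot - q
  if (df <= 0) stop("M2 requires s - q > 0")
  Delta2 <- compute_delta2(fit, n_q = n_q)
  Xi2 <- compute_xi2(fit, n_q = n_q)
  ch <- tryCatch(chol(Xi2), error = function(e) NULL)
  if (is.null(ch)) {
    warning("Xi2 not positive definite; ridge-stabilised solve used")
    ridge <- 1e-10 * sum(diag(Xi2)) / s_tot
    ch <- chol(Xi2 + ridge * diag(s_tot))
  }
  u <- backsolve(ch, forwardsolve(t(ch), r))          # Xi2^{-1} r
  B <- backsolve(ch, forwardsolve(t(ch), Delta2))     # Xi2^{-1} Delta2
  S <- crossprod(Delta2, B)                           # Delta2' Xi2^{-1} Delta2
  w <- crossprod(Delta2, u)
  m2 <- fit$n * (sum(r * u) - drop(crossprod(w, solve(S, w))))
  m2 <- max(m2, 0)
  out <- tibble::tibble(
    statistic = m2, s = s_tot, q = q, df = df,
    p_value = stats::pchisq(m2, df, lower.tail = FALSE),
    rmsea2 = sqrt(max((m2 - df) / (fit$n * df), 0)),
    n = fit$n)
  class(out) <- c("bifcop_m2", class(out))
  out
}

#' Maximum bivariate discrepancies
#'
#' For every item pair, `n` times the largest absolute difference between the
#' observed and model-based bivariate cell proportions,
#' `D = n max_{y1, y2} |p - pi|`, with group-wise and overall averages
#' (within-group pairs per group; all pairs overall).
#'
#' @inheritParams m2_test
#' @return A list of class `"bifcop_discrepancy"` with tibbles `pairs`
#'   (per-pair `D`) and `summary` (average `D` per scope).
#' @export
max_discrepancy <- function(fit, n_q = fit$n_q) {
  stopifnot(inherits(fit, "bifcop_fit"))
  m <- fit$model; s <- fit$struct
  K <- s$K; n <- fit$n
  rule <- legendre_rule(n_q)
  P <- item_cell_arrays(m, rule)
  pairs <- utils::combn(s$d, 2)
  per_pair <- purrr::map_dfr(seq_len(ncol(pairs)), function(p) {
    j1 <- pairs[1, p]; j2 <- pairs[2, p]
    obs <- table(factor(fit$data[, j1], levels = 0:(K - 1)),
                 factor(fit$data[, j2], levels = 0:(K - 1))) / n
    mod <- margin_from_arrays(P, c(j1, j2), s, rule)
    same <- s$item_group[j1] == s$item_group[j2]
    tibble::tibble(j1 = j1, j2 = j2,
                   group = ifelse(same, s$item_group[j1], NA_integer_),
                   D = n * max(abs(obs - mod)))
  })
  by_group <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(per_pair, !is.na(.data$group)), .data$group),
    D = mean(.data$D), n_pairs = dplyr::n(), .groups = "drop")
  summary <- dplyr::bind_rows(
    tibble::tibble(scope = paste0("group", by_group$group), D = by_group$D,
                   n_pairs = by_group$n_pairs),
    tibble::tibble(scope = "all", D = mean(per_pair$D), n_pairs = nrow(per_pair)))
  structure(list(pairs = per_pair, summary = summary),
            class = "bifcop_discrepancy")
}

#' @export
print.bifcop_discrepancy <- function(x, ...) {
  cat("Maximum bivariate discrepancies (n * max |p - pi|)\n")
  print(x$summary)
  invisible(x)
}
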