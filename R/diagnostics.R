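## Tail-asymmetry diagnostics: polychoric correlations and semi-correlations
## (correlations of the underlying normal scores restricted to the joint
## lower / upper quadrant).

#' Theoretical semi-correlations of a bivariate copula
#'
#' Correlations of standard normal scores `Z1, Z2` whose copula is `spec`,
#' conditional on both lying in the upper (`rho_plus`) or lower (`rho_minus`)
#' quadrant.  Computed by 60-point product Gauss-Legendre quadrature of the
#' quadrant moment integrals on `(0, 8)` standard deviations; the lower
#' semi-correlation is the upper one of the survival copula.  For reflection
#' symmetric copulas (BVN, t) the two coincide; the Gumbel copula has
#' `rho_minus < rho_plus` and the survival Gumbel the reverse.
#'
#' @param spec A [bicop()] object.
#' @return A tibble with `rho_minus` and `rho_plus`.
#' @examples
#' theoretical_semicorr(bicop("bvn", par = 0.34))   # both ~ 0.16
#' @export
theoretical_semicorr <- function(spec) {
  stopifnot(inherits(spec, "bicop"))
  tibble::tibble(rho_minus = upper_semicorr(reflect_bicop(spec, "survival")),
                 rho_plus = upper_semicorr(spec))
}

## conditional cdf of the SECOND argument given the first
cond21 <- function(u2, u1, spec) {
  th <- spec$par
  switch(spec$family,
    gumbel_r1 = hgumbel_cop(u2, 1 - u1, th),
    gumbel_r2 = 1 - hgumbel_cop(1 - u2, u1, th),
    ## all remaining families are exchangeable
    hbicop(u2, u1, spec))
}

upper_semicorr <- function(spec) {
  gl <- legendre_raw(60L)
  z <- 4 * (gl$nodes + 1)          # (0, 8)
  wz <- 4 * gl$weights
  phi_z <- stats::dnorm(z)
  u <- stats::pnorm(z)
  surv <- 1 - cond21(rep(0.5, length(z)), u, spec)
  e0 <- pbicop(0.5, 0.5, spec)     # P(U1 > .5, U2 > .5) = C(.5, .5)
  e1 <- sum(wz * z * phi_z * surv)
  e2 <- sum(wz * z^2 * phi_z * surv)
  dens <- dbicop(rep(u, each = length(u)), rep(u, times = length(u)), spec)
  num_cross <- sum((rep(wz * z * phi_z, each = length(z)) *
                      rep(wz * z * phi_z, times = length(z))) * dens)
  (num_cross - e1^2 / e0) / (e2 - e1^2 / e0)
}

#' Polychoric correlation of a two-way ordinal table
#'
#' Two-step maximum likelihood under a discretised bivariate normal: the
#' normal-scale cutpoints are fixed at the marginal quantiles and the
#' correlation maximises the bivariate multinomial likelihood.
#'
#' @param tab A `K1 x K2` contingency table of counts (or a matrix).
#' @return The correlation estimate (clamped to `[-1 + 1e-6, 1 - 1e-6]`), or
#'   `NA` with a warning when a margin is degenerate.
#' @export
sample_polychoric <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  pr <- rowSums(tab) / n
  pc <- colSums(tab) / n
  if (sum(pr > 0) < 2 || sum(pc > 0) < 2) {
    warning("degenerate margin: polychoric correlation undefined")
    return(NA_real_)
  }
  a <- cumsum(pr)[-length(pr)]
  b <- cumsum(pc)[-length(pc)]
  a <- pmin(pmax(a, 1e-9), 1 - 1e-9)
  b <- pmin(pmax(b, 1e-9), 1 - 1e-9)
  negll <- function(rho) {
    P <- bvn_rectangles(a, b, rho)
    -sum(tab * log(pmax(P, 1e-12)))
  }
  opt <- stats::optimize(negll, c(-1 + 1e-6, 1 - 1e-6), tol = 1e-7)
  opt$minimum
}

## rectangle probabilities of a discretised BVN with uniform-scale cutpoints
## a (rows) and b (cols); returns a (length(a)+1) x (length(b)+1) matrix
bvn_rectangles <- function(a, b, rho) {
  ga <- c(0, a, 1)
  gb <- c(0, b, 1)
  na <- length(ga); nb <- length(gb)
  U1 <- rep(ga, times = nb); U2 <- rep(gb, each = na)
  Cv <- pmin(U1, U2)            # exact on the boundary of the unit square
  interior <- U1 > 0 & U1 < 1 & U2 > 0 & U2 < 1
  Cv[interior] <- pbvn_cop(U1[interior], U2[interior], rho)
  Cm <- matrix(Cv, na, nb)
  Cm[-1, -1] - Cm[-na, -1] - Cm[-1, -nb] + Cm[-na, -nb]
}

#' Sample semi-correlations of an ordinal item pair
#'
#' Sample versions of the semi-correlations: polychoric correlations computed
#' in the joint lower and upper quadrants.  Each item is median-split (the
#' "upper" side starts at the smallest category whose cumulative proportion
#' exceeds 0.5); the observations falling jointly in a quadrant are treated
#' as an ordinal sub-table with its own marginal cutpoints, and the ordinary
#' two-step polychoric estimate of that sub-table is the quadrant
#' correlation.  A quadrant in which either item shows fewer than two
#' categories yields `NA` with a warning.
#'
#' @param y1,y2 Integer response vectors coded `0 .. K - 1`.
#' @return A tibble with `rho` (full polychoric), `rho_minus`, `rho_plus`.
#' @export
sample_semicorr <- function(y1, y2) {
  stopifnot(length(y1) == length(y2))
  m1 <- median_split(y1)
  m2 <- median_split(y2)
  up <- y1 >= m1 & y2 >= m2
  lo <- y1 < m1 & y2 < m2
  tibble::tibble(
    rho = sample_polychoric(table(y1, y2)),
    rho_minus = quadrant_polychoric(y1[lo], y2[lo]),
    rho_plus = quadrant_polychoric(y1[up], y2[up]))
}

## smallest category whose cumulative proportion exceeds 1/2
median_split <- function(y) {
  p <- cumsum(tabulate(y + 1L, nbins = max(y) + 1L)) / length(y)
  min(which(p > 0.5)) - 1L
}

quadrant_polychoric <- function(y1, y2) {
  if (length(y1) < 10L || length(unique(y1)) < 2L || length(unique(y2)) < 2L) {
    warning("quadrant too sparse: semi-correlation undefined")
    return(NA_real_)
  }
  sample_polychoric(table(y1, y2))
}

#' Semi-correlation summary table
#'
#' Averages of the pairwise polychoric correlations and semi-correlations for
#' all item pairs and for the pairs within each group, together with the
#' theoretical semi-correlations of candidate copula families matched to the
#' observed average correlation (BVN/t at `par = rho_N`; Gumbel-type via
#' Kendall's tau).  Items with more probability in the joint lower (upper)
#' tail than a discretised MVN show `rho_minus` (`rho_plus`) above the BVN
#' row, suggesting tail-dependent linking copulas.
#'
#' @param data Response data frame/matrix coded `0 .. K - 1`.
#' @param groups Group sizes or assignment, as in [group_structure()].
#' @param K Number of categories (default `max(data) + 1`).
#' @param families Family tags for the theoretical rows.
#' @return A tibble with columns `scope` (`"all"` or `"group<g>"`), `source`
#'   (`"observed"` or a family tag), `rho`, `rho_minus`, `rho_plus`,
#'   `n_pairs`.
#' @export
semicorr_table <- function(data, groups, K = NULL,
                           families = c("bvn", "t5", "gumbel", "sgumbel")) {
  y0 <- as.matrix(as.data.frame(data))
  if (is.null(K)) K <- max(y0) + 1L
  struct <- as_group_structure(groups, K, labels = colnames(as.data.frame(data)))
  y <- response_matrix(data, struct)
  pairs <- utils::combn(struct$d, 2)
  per_pair <- purrr::map_dfr(seq_len(ncol(pairs)), function(p) {
    j1 <- pairs[1, p]; j2 <- pairs[2, p]
    sc <- suppressWarnings(sample_semicorr(y[, j1], y[, j2]))
    dplyr::mutate(sc, j1 = j1, j2 = j2,
                  same_group = struct$item_group[j1] == struct$item_group[j2],
                  group = ifelse(same_group, struct$item_group[j1], NA_integer_))
  })
  scopes <- c(list(all = per_pair),
              purrr::map(seq_len(struct$G), function(g)
                dplyr::filter(per_pair, !is.na(.data$group), .data$group == g)))
  names(scopes) <- c("all", paste0("group", seq_len(struct$G)))
  out <- purrr::imap_dfr(scopes, function(df, scope) {
    if (!nrow(df)) return(NULL)
    obs <- tibble::tibble(
      scope = scope, source = "observed",
      rho = mean(df$rho, na.rm = TRUE),
      rho_minus = mean(df$rho_minus, na.rm = TRUE),
      rho_plus = mean(df$rho_plus, na.rm = TRUE),
      n_pairs = nrow(df))
    theo <- purrr::map_dfr(families, function(f) {
      spec <- matched_spec(f, obs$rho)
      sc <- theoretical_semicorr(spec)
      tibble::tibble(scope = scope, source = f, rho = obs$rho,
                     rho_minus = sc$rho_minus, rho_plus = sc$rho_plus,
                     n_pairs = nrow(df))
    })
    dplyr::bind_rows(obs, theo)
  })
  out
}

## family spec matched to a polychoric correlation: BVN/t take the
## correlation itself, Gumbel-type go through Kendall's tau
matched_spec <- function(family, rho) {
  pf <- parse_family(family)
  if (pf$family %in% c("bvn", "t")) {
    bicop(family, par = rho)
  } else {
    bicop(family, tau = 2 / pi * asin(abs(rho)) *
            (if (pf$family %in% c("gumbel", "sgumbel")) 1 else -1))
  }
}
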