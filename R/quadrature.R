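## Gauss-Legendre rules.  legendre_raw() is the (-1, 1) rule straight from
## statmod; legendre_rule() is the affine map to (0, 1) used for the latent
## uniform factors (weights then sum to 1).

.legendre_cache <- new.env(parent = emptyenv())

legendre_raw <- function(n) {
  key <- as.character(n)
  if (is.null(.legendre_cache[[key]])) {
    .legendre_cache[[key]] <- statmod::gauss.quad(n, kind = "legendre")
  }
  .legendre_cache[[key]]
}

#' Gauss-Legendre quadrature rule on (0, 1)
#'
#' Nodes and weights of the `n_q`-point Gauss-Legendre rule affinely mapped to
#' the unit interval, used to integrate over the latent uniform factors.  With
#' `n_q = 25` (the default throughout the package) the nested quadrature
#' evaluation of the joint pmf is accurate well beyond the precision needed
#' for likelihood optimisation.
#'
#' @param n_q Number of quadrature points.
#' @return A list with `nodes` (increasing, in (0, 1)) and `weights`
#'   (positive, summing to 1).
#' @export
legendre_rule <- function(n_q = 25L) {
  stopifnot(n_q >= 2)
  gl <- legendre_raw(as.integer(n_q))
  list(nodes = (gl$nodes + 1) / 2, weights = gl$weights / 2)
}
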