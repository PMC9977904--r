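#' Simulate ordinal responses from a factor copula model
#'
#' Draws `n` independent response vectors from a bi-factor or second-order
#' copula model by exploiting the models' conditional-independence structure.
#' For the bi-factor model the common and group factors `V0, V1, ..., VG` are
#' iid uniform and each item is sampled from its `K` conditional cell
#' probabilities given `(V_g, V_0)`.  For the second-order model `V0` is
#' uniform, each group factor is drawn through the inverse conditional cdf of
#' its linking copula, `V_g = C^{-1}(W_g | V_0)` with `W_g` uniform, and each
#' item is sampled from its conditional cell probabilities given `V_g`.
#' Category sampling is by inverse cdf on the `K` conditional probabilities
#' (exact, no rejection).
#'
#' @param model A [bifactor_model()] or [secondorder_model()].
#' @param n Number of respondents.
#' @param seed Optional integer seed; when given, the draw is reproducible.
#' @return A tibble with `n` rows and `d` integer columns named after the
#'   items, categories coded `0 .. K - 1`.
#' @examples
#' m <- bifactor_model(c(2, 2), K = 3, common_family = "gumbel",
#'                     group_family = "gumbel", tau_theta = 0.5, tau_delta = 0.3)
#' simulate_responses(m, 5, seed = 1)
#' @export
simulate_responses <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "bifcop_model"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  s <- model$struct
  d <- s$d; K <- s$K; G <- s$G
  y <- matrix(0L, n, d)

  if (model$kind == "bifactor") {
    v0 <- stats::runif(n)
    vg <- matrix(stats::runif(n * G), n, G)
    for (j in seq_len(d)) {
      g <- s$item_group[j]
      s1 <- spec_of(model$fam1[j], model$par1[j], model$nu1[j])
      s2 <- spec_of(model$fam2[j], model$par2[j], model$nu2[j])
      ## conditional boundary cdfs at the n latent draws, (K-1) x n
      U <- matrix(hbicop(rep(model$cut[, j], times = n),
                         rep(v0, each = K - 1L), s1), nrow = K - 1L)
      Tk <- matrix(hbicop(as.vector(U), rep(vg[, g], each = K - 1L), s2),
                   nrow = K - 1L)
      y[, j] <- sample_cells(Tk, n)
    }
  } else {
    v0 <- stats::runif(n)
    vg <- matrix(0, n, G)
    for (g in seq_len(G)) {
      s0 <- spec_of(model$fam2[g], model$par2[g], model$nu2[g])
      vg[, g] <- hinv_bicop(stats::runif(n), v0, s0)
    }
    for (j in seq_len(d)) {
      g <- s$item_group[j]
      s1 <- spec_of(model$fam1[j], model$par1[j], model$nu1[j])
      Tk <- matrix(hbicop(rep(model$cut[, j], times = n),
                          rep(vg[, g], each = K - 1L), s1), nrow = K - 1L)
      y[, j] <- sample_cells(Tk, n)
    }
  }
  colnames(y) <- s$labels
  tibble::as_tibble(y)
}

## inverse-cdf category draw given the (K-1) x n conditional boundary cdfs
sample_cells <- function(Tk, n) {
  u <- stats::runif(n)
  cat <- integer(n)
  for (k in seq_len(nrow(Tk))) {
    cat <- cat + as.integer(u > Tk[k, ])
  }
  cat
}

#' Simulation designs of the small-sample studies
#'
#' Convenience constructors for the data-generating models used in the
#' package's simulation studies: `d` items equally split into `G` groups,
#' `K` equally weighted categories (`a_k = k / K`), and common Kendall's tau
#' values per group.  For the bi-factor design `tau_theta` and `tau_delta`
#' are per-group values recycled to the items of each group; for the
#' second-order design `tau_theta` is per group and `tau_delta` has one entry
#' per group (the group-to-common-factor taus).
#'
#' The default taus are the study values used throughout the package's
#' simulation experiments: bi-factor `tau_theta = (0.45, 0.55, 0.65, 0.75)`,
#' `tau_delta = (0.30, 0.35, 0.40, 0.50)`; second-order `tau_theta =
#' (0.4, 0.5, 0.6, 0.7)`, `tau_delta = (0.30, 0.35, 0.40, 0.45)`.
#'
#' @param d Total number of items (must be divisible by `G`).
#' @param G Number of groups.
#' @param K Categories.
#' @param family Copula family tag for all factors.
#' @param tau_theta,tau_delta Per-group Kendall's taus.
#' @return A `bifcop_model`.
#' @export
study_bifactor_model <- function(d = 16, G = 4, K = 3, family = "gumbel",
                                 tau_theta = c(0.45, 0.55, 0.65, 0.75),
                                 tau_delta = c(0.30, 0.35, 0.40, 0.50)) {
  stopifnot(d %% G == 0, length(tau_theta) == G, length(tau_delta) == G)
  struct <- group_structure(rep(d / G, G), K = K)
  bifactor_model(struct, common_family = family, group_family = family,
                 tau_theta = tau_theta[struct$item_group],
                 tau_delta = tau_delta[struct$item_group])
}

#' @rdname study_bifactor_model
#' @export
study_secondorder_model <- function(d = 16, G = 4, K = 3, family = "gumbel",
                                    tau_theta = c(0.4, 0.5, 0.6, 0.7),
                                    tau_delta = c(0.30, 0.35, 0.40, 0.45)) {
  stopifnot(d %% G == 0, length(tau_theta) == G, length(tau_delta) == G)
  struct <- group_structure(rep(d / G, G), K = K)
  secondorder_model(struct, group_family = family, top_family = family,
                    tau_theta = tau_theta[struct$item_group],
                    tau_delta = tau_delta)
}
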