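#' Bi-factor and second-order copula model objects
#'
#' `bifactor_model()` couples each item to a common factor `V0` (copulas with
#' parameters `theta`, one per item) and, conditionally on `V0`, to its
#' group-specific factor `Vg` (copulas with parameters `delta`, one per item).
#' `secondorder_model()` couples each item to its group factor `Vg` (`theta`,
#' one per item) and the group factors to a single second-order factor `V0`
#' through a one-factor copula (`delta`, one per group).  One copula family is
#' used per factor: families are never mixed within a factor.
#'
#' Parameters may be supplied on the native scale (`theta`, `delta`) or on the
#' Kendall's tau scale (`tau_theta`, `tau_delta`), the latter being
#' comparable across families.  Scalars are recycled.
#'
#' @param struct A [group_structure()] (or group sizes plus `K`).
#' @param K Category count, when `struct` is given as sizes.
#' @param common_family,group_family Family tags as in [bicop()].  For the
#'   bi-factor model `common_family` is the family of the item-to-`V0` copulas
#'   and `group_family` (scalar or length `G`) that of the item-to-`Vg given
#'   V0` copulas.  For the second-order model `group_family` is the family of
#'   the item-to-`Vg` copulas and `top_family` that of the `Vg`-to-`V0`
#'   copulas.
#' @param top_family Family of the group-to-common-factor copulas
#'   (second-order model).
#' @param theta,delta Native-scale dependence parameters (`theta`: length `d`;
#'   `delta`: length `d` for the bi-factor model, length `G` for the
#'   second-order model).
#' @param tau_theta,tau_delta The same parameters on the Kendall's tau scale.
#' @param cutpoints A [cutpoint_set()] or matrix; defaults to equally
#'   weighted categories `a_k = k / K`.
#' @return An object of class `"bifcop_model"`.
#' @examples
#' m <- bifactor_model(c(2, 2), K = 3, common_family = "gumbel",
#'                     group_family = "gumbel", tau_theta = 0.5, tau_delta = 0.3)
#' @export
bifactor_model <- function(struct, K = NULL, common_family = "bvn",
                           group_family = "bvn", theta = NULL, delta = NULL,
                           tau_theta = NULL, tau_delta = NULL,
                           cutpoints = NULL) {
  struct <- if (inherits(struct, "group_structure")) struct else
    group_structure(struct, K)
  d <- struct$d
  fam1 <- fam_rep(resolve_families(common_family, 1L), rep(1L, d))
  fam2 <- fam_rep(resolve_families(group_family, struct$G), struct$item_group)
  theta <- resolve_pars(theta, tau_theta, fam1, d, "theta")
  delta <- resolve_pars(delta, tau_delta, fam2, d, "delta")
  new_bifcop_model("bifactor", struct, fam1, theta, fam2, delta, cutpoints)
}

#' @rdname bifactor_model
#' @export
secondorder_model <- function(struct, K = NULL, group_family = "bvn",
                              top_family = "bvn", theta = NULL, delta = NULL,
                              tau_theta = NULL, tau_delta = NULL,
                              cutpoints = NULL) {
  struct <- if (inherits(struct, "group_structure")) struct else
    group_structure(struct, K)
  d <- struct$d; G <- struct$G
  fam1 <- fam_rep(resolve_families(group_family, G), struct$item_group)
  fam0 <- fam_rep(resolve_families(top_family, 1L), rep(1L, G))
  theta <- resolve_pars(theta, tau_theta, fam1, d, "theta")
  delta <- resolve_pars(delta, tau_delta, fam0, G, "delta")
  new_bifcop_model("secondorder", struct, fam1, theta, fam0, delta, cutpoints)
}

## normalise family tags ("t5" -> t with nu = 5); returns a character vector
## of families with a parallel "nu" attribute
resolve_families <- function(fams, len) {
  fams <- rep_len(fams, len)
  parsed <- lapply(fams, parse_family)
  structure(vapply(parsed, `[[`, "", "family"),
            nu = vapply(parsed, function(p) p$nu %||% NA_real_, 0))
}

## index a resolved family vector, carrying the nu attribute along
fam_rep <- function(fams, idx) {
  structure(as.character(fams)[idx], nu = attr(fams, "nu")[idx])
}

resolve_pars <- function(par, tau, fams, len, what) {
  nus <- attr(fams, "nu")
  if (is.null(par) && is.null(tau)) {
    stop(sprintf("supply `%s` or `tau_%s`", what, what))
  }
  if (!is.null(tau)) {
    tau <- rep_len(tau, len)
    par <- vapply(seq_len(len), function(i) tau_to_par(fams[[i]], tau[[i]]), 0)
  } else {
    par <- rep_len(par, len)
    for (i in seq_len(len)) check_par(fams[[i]], par[[i]])
  }
  par
}

new_bifcop_model <- function(kind, struct, fam1, par1, fam2, par2, cutpoints) {
  cut <- if (is.null(cutpoints)) default_cutpoints(struct) else
    cutpoint_set(cutpoints, struct)
  m <- structure(
    list(kind = kind, struct = struct, cut = cut,
         fam1 = as.character(fam1), nu1 = attr(fam1, "nu"), par1 = par1,
         fam2 = as.character(fam2), nu2 = attr(fam2, "nu"), par2 = par2),
    class = "bifcop_model")
  m
}

#' @export
print.bifcop_model <- function(x, ...) {
  s <- x$struct
  kind <- if (x$kind == "bifactor") "bi-factor" else "second-order"
  cat(sprintf("<bifcop_model> %s copula model: d = %d, G = %d, K = %d\n",
              kind, s$d, s$G, s$K))
  f1lab <- if (x$kind == "bifactor") "items -> V0" else "items -> Vg"
  f2lab <- if (x$kind == "bifactor") "items -> Vg | V0" else "Vg -> V0"
  cat(sprintf("  %s: %s, tau in [%.2f, %.2f]\n", f1lab,
              paste(unique(fam_tag(x$fam1, x$nu1)), collapse = "/"),
              min(model_taus(x)$tau1), max(model_taus(x)$tau1)))
  tau2 <- model_taus(x)$tau2
  cat(sprintf("  %s: %s, tau in [%.2f, %.2f]\n", f2lab,
              paste(unique(fam_tag(x$fam2, x$nu2)), collapse = "/"),
              min(tau2), max(tau2)))
  invisible(x)
}

fam_tag <- function(fam, nu) {
  ifelse(fam == "t", paste0("t", nu), fam)
}

spec_of <- function(fam, par, nu) {
  bicop(fam, par = par, nu = if (is.na(nu)) NULL else nu)
}

model_taus <- function(model) {
  tau1 <- vapply(seq_along(model$par1), function(i)
    par_to_tau(spec_of(model$fam1[i], model$par1[i], model$nu1[i])), 0)
  tau2 <- vapply(seq_along(model$par2), function(i)
    par_to_tau(spec_of(model$fam2[i], model$par2[i], model$nu2[i])), 0)
  list(tau1 = tau1, tau2 = tau2)
}

#' Gaussian factor loadings of an all-BVN model
#'
#' For a bi-factor model with BVN linking copulas, the items' underlying
#' normal scores follow the Gaussian bi-factor model with common-factor
#' loading `theta` and group-factor loading `gamma = delta * sqrt(1 -
#' theta^2)`.  For an all-BVN second-order model the loadings derive from the
#' hierarchical representation `theta_jg = beta_jg * beta_g`, `gamma_jg =
#' beta_jg * sqrt(1 - beta_g^2)`, where `beta_jg` is the item-to-group-factor
#' correlation and `beta_g` the group-to-common-factor correlation.
#'
#' @param model An all-BVN [bifactor_model()] or [secondorder_model()].
#' @return A tibble with one row per item: `item`, `group`, `theta`, `gamma`
#'   (and `beta_item`, `beta_group` for the second-order model).
#' @export
gaussian_loadings <- function(model) {
  stopifnot(inherits(model, "bifcop_model"))
  if (any(model$fam1 != "bvn") || any(model$fam2 != "bvn")) {
    stop("Gaussian loadings are only defined when all linking copulas are BVN")
  }
  s <- model$struct
  base <- tibble::tibble(item = s$labels, group = s$item_group)
  if (model$kind == "bifactor") {
    th <- model$par1
    dl <- model$par2
    dplyr::mutate(base, theta = th, gamma = dl * sqrt(1 - th^2))
  } else {
    beta_item <- model$par1
    beta_group <- model$par2[s$item_group]
    dplyr::mutate(base,
                  beta_item = beta_item,
                  beta_group = beta_group,
                  theta = beta_item * beta_group,
                  gamma = beta_item * sqrt(1 - beta_group^2))
  }
}
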