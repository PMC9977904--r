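#' Default copula candidate set
#'
#' Canonical candidate order used by the selection algorithm: BVN first (ties
#' are broken toward the earlier, simpler candidate), then Gumbel, survival
#' Gumbel, and t copulas with degrees of freedom 2, 3, 5.
#'
#' @export
default_candidates <- function() {
  c("bvn", "gumbel", "sgumbel", "t2", "t3", "t5")
}

#' Heuristic AIC-based copula family selection
#'
#' Assigns one bivariate copula family per factor of a bi-factor or
#' second-order copula model.  Starting from the all-BVN (Gaussian) model, the
#' algorithm sweeps the candidate families for the common-factor linkage
#' (items to `V0` for the bi-factor model; group factors to `V0` for the
#' second-order model), fixes the family with the lowest AIC, and then sweeps
#' each group factor `V1 .. VG` in turn the same way.  Families are never
#' mixed within a factor.  Every sweep refits all copula parameters (warm
#' started from the incumbent fit), so exactly
#' `1 + |candidates| * (G + 1)` models are fitted.
#'
#' The reflected Gumbel variants (which cover negative dependence) are added
#' to a factor's candidate list only when the average pairwise sample tau
#' relevant to that factor is negative, since the Gumbel copula itself covers
#' positive dependence only.
#'
#' @inheritParams fit_factor_copula
#' @param candidates Character vector of family tags in canonical order.
#' @param se Compute standard errors for the final fit?
#' @return An object of class `"bifcop_selection"`: a list with the final
#'   `fit`, the selected `families`, and the AIC `trail` tibble (one row per
#'   fitted model).
#' @export
select_families <- function(data, groups, K = NULL,
                            model = c("bifactor", "secondorder"),
                            candidates = default_candidates(),
                            n_q = 25L, se = FALSE, control = list()) {
  model_kind <- match.arg(model)
  stopifnot(length(candidates) >= 1)
  y0 <- as.matrix(as.data.frame(data))
  if (is.null(K)) K <- max(y0) + 1L
  struct <- as_group_structure(groups, K, labels = colnames(as.data.frame(data)))
  y <- response_matrix(data, struct)

  ## average pairwise sample taus per factor (negative-dependence screening)
  taus <- factor_sample_taus(y, struct)
  factor_cands <- function(avg_tau) {
    if (is.finite(avg_tau) && avg_tau < 0) {
      unique(c(candidates, "gumbel_r1", "gumbel_r2"))
    } else candidates
  }

  fit_with <- function(fams, start) {
    fit_factor_copula(y, struct, model = model_kind, families = fams,
                      n_q = n_q, se = FALSE, start = start, control = control)
  }
  warm <- function(fit, fams) {
    ## incumbent taus, clamped into the new families' ranges
    m <- fit$model
    f1 <- resolve_families(if (model_kind == "bifactor") fams$common else fams$group,
                           if (model_kind == "bifactor") 1L else struct$G)
    f1 <- if (model_kind == "bifactor") rep_len(as.character(f1), struct$d) else
      as.character(f1)[struct$item_group]
    n2 <- length(m$par2)
    f2tag <- if (model_kind == "bifactor") fams$group else fams$top
    f2 <- as.character(resolve_families(f2tag, if (model_kind == "bifactor") struct$G else 1L))
    f2 <- if (model_kind == "bifactor") f2[struct$item_group] else rep_len(f2, n2)
    list(tau_theta = clamp_tau(par_to_tau_vec(m$fam1, m$par1), f1),
         tau_delta = clamp_tau(par_to_tau_vec(m$fam2, m$par2), f2))
  }

  trail <- list()
  note <- function(step, family, fit, selected = FALSE) {
    trail[[length(trail) + 1L]] <<- tibble::tibble(
      step = step, family = family, logLik = fit$loglik, AIC = fit$aic,
      converged = fit$converged, selected = selected)
  }

  ## step 1: all-BVN baseline
  fams <- if (model_kind == "bifactor") {
    list(common = "bvn", group = rep("bvn", struct$G))
  } else {
    list(group = rep("bvn", struct$G), top = "bvn")
  }
  best <- fit_with(fams, start = NULL)
  note("baseline", "bvn", best)

  ## step 2: sweep the common-factor linkage
  sweep_slot <- function(fams, slot, g, cands, best, step_lab) {
    best_fit <- NULL; best_fam <- NULL
    for (cand in cands) {
      f <- fams
      if (is.null(g)) f[[slot]] <- cand else f[[slot]][g] <- cand
      fit <- tryCatch(fit_with(f, start = warm(best, f)),
                      error = function(e) {
                        warning(sprintf("candidate %s failed at %s: %s",
                                        cand, step_lab, conditionMessage(e)))
                        NULL
                      })
      if (is.null(fit)) next
      note(step_lab, cand, fit)
      if (is.null(best_fit) || fit$aic < best_fit$aic) {
        best_fit <- fit; best_fam <- cand
      }
    }
    if (is.null(best_fit)) {           # every candidate failed: keep BVN
      best_fam <- "bvn"
      f <- fams
      if (is.null(g)) f[[slot]] <- "bvn" else f[[slot]][g] <- "bvn"
      best_fit <- fit_with(f, start = warm(best, f))
    }
    list(fit = best_fit, fam = best_fam)
  }

  common_slot <- if (model_kind == "bifactor") "common" else "top"
  res <- sweep_slot(fams, common_slot, NULL, factor_cands(taus$common), best,
                    "common")
  fams[[common_slot]] <- res$fam
  best <- res$fit

  ## step 3: sweep each group factor
  for (g in seq_len(struct$G)) {
    res <- sweep_slot(fams, "group", g, factor_cands(taus$group[g]), best,
                      paste0("group", g))
    fams$group[g] <- res$fam
    best <- res$fit
  }

  trail <- dplyr::bind_rows(trail)
  sel_rows <- c("common", paste0("group", seq_len(struct$G)))
  chosen <- c(fams[[common_slot]], fams$group)
  trail$selected <- purrr::map2_lgl(trail$step, trail$family, function(st, fa) {
    i <- match(st, sel_rows)
    !is.na(i) && fa == chosen[i] &&
      trail$AIC[trail$step == st & trail$family == fa][1] ==
        min(trail$AIC[trail$step == st])
  })

  if (se) best <- add_standard_errors(best)
  structure(list(fit = best, families = fams, trail = trail,
                 candidates = candidates, model = model_kind,
                 struct = struct), class = "bifcop_selection")
}

## average pairwise sample taus: between-group pairs for the common factor,
## within-group pairs for each group factor (fast Spearman proxy would change
## the sign never; Kendall is exact but slower, so use Spearman-converted)
factor_sample_taus <- function(y, struct) {
  r <- suppressWarnings(stats::cor(y, method = "spearman"))
  r[!is.finite(r)] <- 0
  tau <- 2 / pi * asin(pmin(pmax(2 * sin(pi * r / 6), -1), 1))
  same <- outer(struct$item_group, struct$item_group, "==")
  ut <- upper.tri(tau)
  list(common = mean(tau[ut & !same]),
       group = vapply(seq_len(struct$G), function(g) {
         idx <- struct$item_group == g
         block <- tau[idx, idx, drop = FALSE]
         vals <- block[upper.tri(block)]
         if (!length(vals)) 0 else mean(vals)
       }, 0))
}

#' @export
print.bifcop_selection <- function(x, ...) {
  cat(sprintf("<bifcop_selection> %s model, %d fits\n", x$model, nrow(x$trail)))
  sel <- dplyr::filter(x$trail, .data$selected)
  for (i in seq_len(nrow(sel))) {
    cat(sprintf("  %-8s -> %-8s (AIC %.1f)\n", sel$step[i], sel$family[i],
                sel$AIC[i]))
  }
  invisible(x)
}

#' @export
tidy.bifcop_selection <- function(x, ...) x$trail

#' @export
glance.bifcop_selection <- function(x, ...) {
  glance(x$fit)
}
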