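#' Plot methods
#'
#' `autoplot.bifcop_fit()` shows the estimated Kendall's taus (with 95%
#' intervals when standard errors are available) by factor;
#' `autoplot.bifcop_selection()` shows the AIC trail of the family-selection
#' sweeps; `plot_semicorr()` compares observed average semi-correlations with
#' the theoretical values of candidate copula families.
#'
#' @param object A fitted object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name bifcop-plots
NULL

#' @rdname bifcop-plots
#' @export
autoplot.bifcop_fit <- function(object, ...) {
  td <- tidy(object)
  td$side <- ifelse(grepl("^theta", td$term), "theta (to common/group factor)",
                    "delta (second linkage)")
  p <- ggplot2::ggplot(td, ggplot2::aes(x = .data$tau, y = .data$term,
                                        colour = .data$factor)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~side, scales = "free_y") +
    ggplot2::labs(x = "Kendall's tau", y = NULL,
                  title = sprintf("%s copula model (%s)", object$kind,
                                  toupper(object$method)))
  if (!is.null(td$se_tau)) {
    p <- p + ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$tau - 1.96 * .data$se_tau,
                   xmax = .data$tau + 1.96 * .data$se_tau),
      height = 0.2, na.rm = TRUE)
  }
  p
}

#' @rdname bifcop-plots
#' @export
autoplot.bifcop_selection <- function(object, ...) {
  tr <- object$trail
  tr$step <- factor(tr$step, levels = unique(tr$step))
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$family, y = .data$AIC,
                                   shape = .data$selected)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~step, scales = "free_y") +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 1, `TRUE` = 16)) +
    ggplot2::labs(x = NULL, y = "AIC", title = "Copula family selection trail")
}

#' @rdname bifcop-plots
#' @param table A [semicorr_table()] result.
#' @export
plot_semicorr <- function(table, ...) {
  long <- tidyr::pivot_longer(table, c("rho_minus", "rho_plus"),
                              names_to = "tail", values_to = "value")
  long$tail <- ifelse(long$tail == "rho_minus", "lower", "upper")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$tail, y = .data$value,
                                     colour = .data$source,
                                     group = .data$source)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(linetype = 2) +
    ggplot2::facet_wrap(~scope) +
    ggplot2::labs(x = NULL, y = "semi-correlation",
                  title = "Observed vs theoretical semi-correlations")
}
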