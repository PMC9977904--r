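#' Read ordinal response data from CSV
#'
#' Reads a rectangular CSV with a header row of item labels and validates it
#' as ordinal item response data: no missing cells, integer codes within the
#' declared range.  A coding offset can be declared for data coded
#' `1 .. K` instead of `0 .. K - 1`.
#'
#' @param path CSV file path.
#' @param groups Group sizes, a per-item assignment (character), or a named
#'   list mapping group names to item labels (as in a config file).
#' @param K Number of categories; default `max(data) + 1` after the offset.
#' @param offset Value subtracted from the codes (e.g. 1 for `1 .. K` data).
#' @return A tibble of integer responses with a `"group_structure"`
#'   attribute.
#' @export
read_responses <- function(path, groups = NULL, K = NULL, offset = 0L) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!nrow(df)) stop("no rows in ", path)
  bad_cells <- which(is.na(as.matrix(df)), arr.ind = TRUE)
  if (nrow(bad_cells)) {
    stop("missing cells at (row, col): ",
         paste(utils::head(apply(bad_cells, 1, paste, collapse = ","), 10),
               collapse = "; "))
  }
  y <- as.matrix(df)
  if (!is.numeric(y)) stop("non-numeric responses in ", path)
  y <- y - offset
  if (any(y != round(y))) stop("responses must be integer codes")
  storage.mode(y) <- "integer"
  if (is.null(K)) K <- max(y) + 1L
  if (any(y < 0L | y > K - 1L)) {
    offenders <- colnames(y)[apply(y < 0L | y > K - 1L, 2, any)]
    stop("out-of-range codes in items: ", paste(offenders, collapse = ", "))
  }
  struct <- NULL
  if (!is.null(groups)) {
    if (is.list(groups)) {
      wanted <- unlist(groups, use.names = FALSE)
      unknown <- setdiff(wanted, colnames(y))
      if (length(unknown)) {
        stop("unknown items in group map: ", paste(unknown, collapse = ", "))
      }
      y <- y[, wanted, drop = FALSE]
      assign_chr <- rep(names(groups), lengths(groups))
      struct <- group_structure(assign_chr, K, labels = colnames(y))
    } else {
      struct <- as_group_structure(groups, K, labels = colnames(y))
    }
  }
  out <- tibble::as_tibble(y)
  attr(out, "group_structure") <- struct
  message(sprintf("read %d x %d responses from %s (K = %d)",
                  nrow(y), ncol(y), path, K))
  out
}

#' @rdname read_responses
#' @param data Response tibble/matrix to write.
#' @export
write_responses <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

## read a JSON or YAML run configuration
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is needed for YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(cfg$model)) cfg$model <- "bifactor"
  if (!cfg$model %in% c("bifactor", "secondorder")) {
    stop("config: model must be 'bifactor' or 'secondorder'")
  }
  if (is.null(cfg$groups)) stop("config: `groups` is required")
  cfg
}

## serialise a fit to a JSON-ready list (native + tau scales, diagnostics)
fit_report <- function(fit, seed = NULL, config = NULL) {
  td <- tidy(fit)
  list(
    model = fit$kind, method = fit$method,
    n = fit$n, d = fit$struct$d, G = fit$struct$G, K = fit$struct$K,
    logLik = fit$loglik, npar_copula = fit$npar_copula, q = fit$q,
    AIC = fit$aic, converged = fit$converged, n_q = fit$n_q,
    cutpoints = unclass(fit$cut),
    parameters = as.data.frame(td),
    manifest = list(
      seed = seed,
      config_hash = if (is.null(config)) NULL else rlang::hash(config),
      package = as.character(utils::packageVersion("bifcop")),
      r_version = R.version.string,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
}
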