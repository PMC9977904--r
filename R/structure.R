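#' Group structure of an item battery
#'
#' Describes how the `d` ordinal items split into `G` non-overlapping groups
#' (domains, testlets, facets) and how many response categories `K` they
#' share.  Items are kept in group-major order: all items of group 1 first,
#' then group 2, and so on; every flat parameter vector in the package follows
#' this ordering.
#'
#' @param groups Either a numeric vector of group sizes (e.g. `c(7, 5, 8)`)
#'   or a character/factor per-item group assignment of length `d`, which must
#'   be contiguous (group-major).
#' @param K Number of ordinal categories; responses are coded `0 .. K - 1`.
#' @param labels Optional item labels (length `d`).
#' @return An object of class `"group_structure"` with fields `G`, `sizes`,
#'   `d`, `K`, `item_group` (length-`d` integer vector) and `labels`.
#' @examples
#' group_structure(c(2, 2), K = 3)
#' @export
group_structure <- function(groups, K, labels = NULL) {
  stopifnot(is.numeric(K), length(K) == 1L, K >= 2)
  K <- as.integer(K)
  if (anyNA(groups)) stop("`groups` must not contain NA")
  if (is.character(groups) || is.factor(groups)) {
    ## per-item assignment, in order of first appearance
    item_group <- match(as.character(groups), unique(as.character(groups)))
    if (any(diff(item_group) < 0)) {
      stop("item-to-group assignment must be contiguous (group-major); ",
           "reorder the items first")
    }
    sizes <- as.integer(unname(table(item_group)))
  } else {
    sizes <- as.integer(groups)
    if (any(sizes < 1)) stop("group sizes must be >= 1")
    item_group <- rep(seq_along(sizes), sizes)
  }
  d <- length(item_group)
  if (!is.null(labels)) {
    stopifnot(length(labels) == d)
  } else {
    labels <- paste0("item", seq_len(d))
  }
  structure(
    list(G = length(sizes), sizes = sizes, d = d, K = K,
         item_group = item_group, labels = as.character(labels)),
    class = "group_structure")
}

#' @export
print.group_structure <- function(x, ...) {
  cat(sprintf("<group_structure> d = %d items in G = %d groups (%s), K = %d categories\n",
              x$d, x$G, paste(x$sizes, collapse = ", "), x$K))
  invisible(x)
}

as_group_structure <- function(groups, K, labels = NULL) {
  if (inherits(groups, "group_structure")) return(groups)
  group_structure(groups, K, labels)
}

#' Cutpoints on the uniform scale
#'
#' Per-item strictly increasing cutpoints `a[k]` in (0, 1), `k = 1 .. K - 1`,
#' discretising a latent U(0, 1) variable into `K` ordinal categories (with
#' implicit boundaries `a[0] = 0`, `a[K] = 1`).  The normal-scale cutpoints
#' are `alpha = qnorm(a)`.
#'
#' @param a A `(K - 1) x d` matrix (or a length-`(K - 1)` vector recycled to
#'   all items) of interior cutpoints.
#' @param struct A [group_structure()].
#' @return A `(K - 1) x d` matrix with class `"cutpoint_set"`.
#' @export
cutpoint_set <- function(a, struct) {
  d <- struct$d; K <- struct$K
  if (is.vector(a)) a <- matrix(a, nrow = K - 1L, ncol = d)
  a <- as.matrix(a)
  if (!all(dim(a) == c(K - 1L, d))) {
    stop(sprintf("cutpoints must be a (K-1) x d = %d x %d matrix", K - 1L, d))
  }
  if (any(a <= 0) || any(a >= 1)) stop("cutpoints must lie strictly in (0, 1)")
  if (K > 2L && any(apply(a, 2, function(col) any(diff(col) <= 0)))) {
    stop("cutpoints must be strictly increasing within each item")
  }
  colnames(a) <- struct$labels
  rownames(a) <- paste0("a", seq_len(K - 1L))
  class(a) <- c("cutpoint_set", class(a))
  a
}

## equally weighted categories: a_k = k / K
default_cutpoints <- function(struct) {
  cutpoint_set(seq_len(struct$K - 1L) / struct$K, struct)
}
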