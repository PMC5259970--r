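#' Distance multisets
#'
#' A `dms` (distance multiset) stores non-negative integer distances together
#' with their multiplicities. It is the container for the problem input `D` of
#' the partial digest problem and for every residual distance pool held by the
#' solvers. Internally it is a pair of parallel vectors: sorted distinct
#' `value`s and positive integer `count`s, which makes difference, disjoint
#' union and sub-multiset tests exact O(distinct-values) vector operations.
#'
#' @param x An integer vector (repeats express multiplicity), or an existing
#'   `dms`, which is returned unchanged.
#' @return An object of class `dms`.
#' @examples
#' D <- dms(c(1, 2, 2, 3, 5, 6, 7, 8, 8, 10))
#' dms_size(D)
#' dms_count(D, 8)
#' @export
dms <- function(x = integer()) {
  if (inherits(x, "dms")) return(x)
  if (is.list(x)) pdp_error("cannot build a distance multiset from a list",
                            "pdp_parse_error")
  if (length(x) == 0L) return(new_dms(integer(), integer()))
  if (anyNA(x)) pdp_error("distances must not be NA", "pdp_parse_error")
  if (is.double(x) && any(x != trunc(x)))
    pdp_error("distances must be whole numbers (fractional value found)",
              "pdp_parse_error")
  x <- as.integer(x)
  if (any(x < 0L))
    pdp_error("distances must be non-negative", "pdp_nonpositive_error")
  r <- rle(sort(x))
  new_dms(r$values, r$lengths)
}

new_dms <- function(value, count) {
  structure(list(value = as.integer(value), count = as.integer(count)),
            class = "dms")
}

#' @export
print.dms <- function(x, ...) {
  n <- dms_size(x)
  cat(sprintf("<distance multiset: %d elements, %d distinct>\n",
              n, length(x$value)))
  if (n > 0L) {
    elems <- dms_elements(x)
    shown <- utils::head(elems, 40L)
    cat("{", paste(shown, collapse = ", "),
        if (n > 40L) ", ..." else "", "}\n", sep = "")
  }
  invisible(x)
}

#' @rdname dms
#' @param D,L Distance multisets (or vectors coercible with [dms()]).
#' @export
dms_size <- function(D) sum(dms(D)$count)

#' @rdname dms
#' @export
dms_max <- function(D) {
  D <- dms(D)
  if (length(D$value) == 0L)
    pdp_error("empty multiset has no maximum", "pdp_empty_input_error")
  D$value[length(D$value)]
}

#' @rdname dms
#' @export
dms_elements <- function(D) {
  D <- dms(D)
  rep(D$value, D$count)
}

#' @rdname dms
#' @param x A single distance.
#' @export
dms_count <- function(D, x) {
  D <- dms(D)
  i <- match(as.integer(x), D$value)
  if (is.na(i)) 0L else D$count[i]
}

#' @rdname dms
#' @export
dms_equal <- function(D, L) {
  D <- dms(D); L <- dms(L)
  identical(D$value, L$value) && identical(D$count, L$count)
}

#' Multiset difference
#'
#' Computes `D \ L`: each distance keeps multiplicity
#' `max(C(D, x) - C(L, x), 0)`. `L` need not be a sub-multiset of `D`;
#' counts clamp at zero.
#'
#' @param D,L Distance multisets (or vectors coercible with [dms()]).
#' @return A `dms`.
#' @examples
#' dms_difference(dms(c(1, 2, 2, 3, 5, 6, 7, 8, 8, 10)), dms(10))
#' @export
dms_difference <- function(D, L) {
  D <- dms(D); L <- dms(L)
  if (length(L$value) == 0L || length(D$value) == 0L) return(D)
  i <- match(D$value, L$value)
  sub <- ifelse(is.na(i), 0L, L$count[i])
  cnt <- D$count - sub
  keep <- cnt > 0L
  new_dms(D$value[keep], cnt[keep])
}

#' Disjoint union (multiset sum)
#'
#' Multiplicities add: `C(result, x) = C(D, x) + C(L, x)`.
#'
#' @inheritParams dms_difference
#' @return A `dms`.
#' @export
dms_union <- function(D, L) {
  D <- dms(D); L <- dms(L)
  v <- sort(unique(c(D$value, L$value)))
  iD <- match(v, D$value); iL <- match(v, L$value)
  cnt <- ifelse(is.na(iD), 0L, D$count[iD]) + ifelse(is.na(iL), 0L, L$count[iL])
  new_dms(v, cnt)
}

#' Sub-multiset test
#'
#' `TRUE` iff `C(L, x) <= C(D, x)` for every distance `x`. This is the
#' feasibility ("bounding") test applied to every candidate point placement.
#'
#' @param L Candidate sub-multiset.
#' @param D Reference multiset.
#' @export
dms_is_subset <- function(L, D) {
  L <- dms(L); D <- dms(D)
  if (length(L$value) == 0L) return(TRUE)
  i <- match(L$value, D$value)
  !anyNA(i) && all(L$count <= D$count[i])
}

#' Distances from a point to a point set
#'
#' \eqn{\Delta(y, X) = \{|y - x| : x \in X\}} as a multiset. May contain 0
#' when `y` is itself a member of `X`.
#'
#' @param y A non-negative integer position.
#' @param X An integer point set (coerced with [as_pointset()]).
#' @return A `dms` with exactly `length(X)` elements (with multiplicity).
#' @examples
#' delta_point(8, c(0, 10))
#' @export
delta_point <- function(y, X) {
  y <- as_scalar_int(y, "y")
  if (y < 0L) pdp_error("y must be non-negative", "pdp_nonpositive_error")
  X <- as_pointset(X)
  dms(abs(y - X))
}

#' Difference multiset of a point set
#'
#' \eqn{\Delta X}: all `choose(n, 2)` pairwise absolute differences of the
#' points, with multiplicity. A point set solves a partial digest instance `D`
#' exactly when `delta_set(X)` equals `D`.
#'
#' @param X An integer point set with at least one point.
#' @return A `dms` with `length(X) * (length(X) - 1) / 2` elements.
#' @examples
#' delta_set(c(0, 2, 7, 8, 10))
#' @export
delta_set <- function(X) {
  X <- as_pointset(X)
  n <- length(X)
  if (n < 1L) pdp_error("point set must contain at least one point",
                        "pdp_empty_input_error")
  if (n == 1L) return(dms())
  d <- abs(outer(X, X, `-`))
  dms(d[upper.tri(d)])
}

#' Validate a point set
#'
#' Coerces to a strictly increasing vector of non-negative integers.
#'
#' @param x Numeric vector of distinct non-negative whole numbers.
#' @export
as_pointset <- function(x) {
  if (anyNA(x)) pdp_error("points must not be NA", "pdp_parse_error")
  if (is.double(x) && any(x != trunc(x)))
    pdp_error("points must be whole numbers", "pdp_parse_error")
  x <- sort(as.integer(x))
  if (length(x) && x[1L] < 0L)
    pdp_error("points must be non-negative", "pdp_nonpositive_error")
  if (anyDuplicated(x))
    pdp_error("points must be pairwise distinct", "pdp_duplicate_site_error")
  x
}

as_scalar_int <- function(x, what) {
  if (length(x) != 1L || is.na(x) || (is.double(x) && x != trunc(x)))
    pdp_error(sprintf("%s must be a single whole number", what),
              "pdp_parse_error")
  as.integer(x)
}
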