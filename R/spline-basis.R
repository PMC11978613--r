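#' Natural cubic spline basis on the age scale
#'
#' Defines a natural (restricted) cubic spline basis by its boundary and
#' interior knots.  The basis has \code{df = length(interior_knots) + 1}
#' columns (no intercept column), is cubic between knots, has continuous
#' first and second derivatives everywhere, and is linear beyond the
#' boundary knots.  The same construction is used for the fixed age
#' effects of every longitudinal marker submodel and for the log
#' baseline hazard of the survival submodel (with its own knots).
#'
#' @param boundary_knots numeric length 2, lower and upper boundary ages.
#' @param interior_knots ordered numeric vector of interior knot ages,
#'   strictly inside the boundary knots.
#' @return an object of class \code{"spline_basis"}.
#' @seealso \code{\link{eval_basis}}, \code{\link{spline_basis_from_data}}
#' @export
spline_basis <- function(boundary_knots, interior_knots) {
  boundary_knots <- as.numeric(boundary_knots)
  interior_knots <- as.numeric(interior_knots)
  if (length(boundary_knots) != 2L || diff(boundary_knots) <= 0)
    stop("`boundary_knots` must be two increasing ages", call. = FALSE)
  if (length(interior_knots) < 1L)
    stop("at least one interior knot is required (df >= 2)", call. = FALSE)
  if (is.unsorted(interior_knots, strictly = TRUE))
    stop("`interior_knots` must be strictly increasing", call. = FALSE)
  if (min(interior_knots) <= boundary_knots[1] ||
      max(interior_knots) >= boundary_knots[2])
    stop("interior knots must lie strictly inside the boundary knots",
         call. = FALSE)
  structure(list(boundary_knots = boundary_knots,
                 interior_knots = interior_knots,
                 df = length(interior_knots) + 1L),
            class = "spline_basis")
}

#' Place spline knots from observed ages
#'
#' Interior knots are placed at equally spaced quantiles of the supplied
#' ages; boundary knots at the 1st and 99th percentiles, clipped to the
#' screening age range [40, 74].  With the default \code{df = 5} this
#' gives four interior knots.
#'
#' @param ages numeric vector of observed ages (visit ages for a marker
#'   basis; event ages for the baseline-hazard basis).
#' @param df basis dimension (number of columns), default 5.
#' @param clip range to which boundary knots are clipped; use
#'   \code{c(-Inf, Inf)} to disable.
#' @return a \code{"spline_basis"}.
#' @export
spline_basis_from_data <- function(ages, df = 5L, clip = c(40, 74)) {
  ages <- ages[is.finite(ages)]
  if (df < 2L) stop("`df` must be at least 2", call. = FALSE)
  if (length(unique(ages)) < df + 2L)
    stop("too few distinct ages to place ", df + 1L, " knots", call. = FALSE)
  bk <- unname(quantile(ages, c(0.01, 0.99), type = 7))
  bk[1] <- max(bk[1], clip[1]); bk[2] <- min(bk[2], clip[2])
  if (diff(bk) <= 0) bk <- range(ages)
  n_int <- df - 1L
  probs <- seq_len(n_int) / (n_int + 1L)
  ik <- unname(quantile(ages, probs, type = 7))
  ik <- ik[ik > bk[1] & ik < bk[2]]
  ik <- unique(ik)
  if (length(ik) < n_int) {
    # fall back to equally spaced knots when the quantiles collapse
    ik <- seq(bk[1], bk[2], length.out = n_int + 2L)[-c(1L, n_int + 2L)]
  }
  spline_basis(bk, ik)
}

#' Evaluate a natural spline basis
#'
#' Returns the n x df basis matrix at the requested ages.  Evaluation
#' outside the boundary knots extrapolates linearly (the natural
#' constraint).
#'
#' @param basis a \code{"spline_basis"}.
#' @param ages numeric vector of ages.
#' @return numeric matrix with \code{length(ages)} rows and
#'   \code{basis$df} columns.
#' @export
eval_basis <- function(basis, ages) {
  stopifnot(inherits(basis, "spline_basis"))
  if (any(!is.finite(ages))) stop("`ages` must be finite", call. = FALSE)
  m <- splines::ns(ages, knots = basis$interior_knots,
                   Boundary.knots = basis$boundary_knots)
  m <- unclass(m)
  attributes(m)[setdiff(names(attributes(m)), "dim")] <- NULL
  m
}

#' @export
print.spline_basis <- function(x, ...) {
  cat("Natural spline basis: df =", x$df, "\n")
  cat("  boundary knots:", format(x$boundary_knots, digits = 4), "\n")
  cat("  interior knots:", format(x$interior_knots, digits = 4), "\n")
  invisible(x)
}
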