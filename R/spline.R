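#' Quadratic spline specification for growth trajectories
#'
#' Defines the quadratic (degree-2) B-spline basis over age in months used for
#' the class-specific mean curves. The default interior knots at 3.5 and 9
#' months capture the rapid weight-for-length gain over the first four months,
#' the deceleration between four and nine months, and the levelling-off
#' afterwards.
#'
#' @param knots Interior knot ages in months, strictly increasing and strictly
#'   inside the boundary.
#' @param boundary Length-2 numeric, the age range covered (months).
#' @return An object of class `spline_spec` with elements `degree` (always 2),
#'   `knots`, `boundary` and `n_basis` (= degree + 1 + number of interior
#'   knots).
#' @examples
#' spline_spec()            # knots at 3.5 and 9 months
#' spline_spec(c(2, 6, 12)) # three interior knots
#' @export
spline_spec <- function(knots = c(3.5, 9), boundary = c(0, 18)) {
  knots <- as.numeric(knots)
  if (anyDuplicated(knots)) stop("duplicate interior knots")
  if (is.unsorted(knots, strictly = TRUE)) stop("knots must be strictly increasing")
  if (length(knots) && (min(knots) <= boundary[1] || max(knots) >= boundary[2]))
    stop("knots must lie strictly inside the boundary")
  structure(
    list(degree = 2L, knots = knots, boundary = as.numeric(boundary),
         n_basis = 3L + length(knots)),
    class = "spline_spec")
}

#' @export
print.spline_spec <- function(x, ...) {
  cat("Quadratic spline basis on [", x$boundary[1], ",", x$boundary[2],
      "] months; interior knots:",
      if (length(x$knots)) paste(x$knots, collapse = ", ") else "none",
      "; basis dimension", x$n_basis, "\n")
  invisible(x)
}

#' Spline design matrix over age
#'
#' Builds the design matrix for ages in months. Two parameterizations of the
#' same column space are available: `"intercept"` (default) returns an explicit
#' intercept column followed by the normalized B-spline basis with its first
#' column dropped — the parameterization used in the mixture model so the
#' random intercept attaches to an interpretable constant; `"bspline"` returns
#' the raw normalized B-spline basis, whose rows sum to one (partition of
#' unity). Both span the space of piecewise quadratics with continuous first
#' derivative and contain the constant function.
#'
#' Ages outside the boundary are clamped to it with a warning.
#'
#' @param ages Numeric vector of ages (months).
#' @param spec A [spline_spec()].
#' @param form `"intercept"` or `"bspline"`.
#' @return Numeric matrix with `length(ages)` rows and `spec$n_basis` columns.
#' @export
basis_matrix <- function(ages, spec = spline_spec(), form = c("intercept", "bspline")) {
  form <- match.arg(form)
  stopifnot(inherits(spec, "spline_spec"))
  lo <- spec$boundary[1]; hi <- spec$boundary[2]
  if (any(ages < lo | ages > hi, na.rm = TRUE)) {
    warning("ages outside [", lo, ", ", hi, "] months clamped to the boundary")
    ages <- pmin(pmax(ages, lo), hi)
  }
  B <- splines::bs(ages, degree = 2, knots = spec$knots,
                   Boundary.knots = spec$boundary, intercept = TRUE)
  B <- unname(as.matrix(B))
  if (form == "bspline") return(B)
  X <- cbind(1, B[, -1, drop = FALSE])
  colnames(X) <- c("(Intercept)", paste0("bs", seq_len(ncol(X) - 1)))
  X
}

#' Select interior knots by least-squares fit of a population mean curve
#'
#' For every candidate knot tuple, fits a single population-mean quadratic
#' spline to all (age, outcome) points by ordinary least squares and returns
#' the tuple with the smallest residual sum of squares. Knot choice precedes
#' class discovery, so the criterion is deliberately computed on the one-class
#' marginal fit. Ties (within `tol` relative to the best RSS) are broken
#' toward the lexicographically smallest knot tuple.
#'
#' @param ages,y Observation ages (months) and outcomes (same length).
#' @param n_knots Number of interior knots to place, 2 or 3.
#' @param grid Candidate knot positions (months); tuples are all increasing
#'   combinations drawn from it. Default: 0.5-month steps on [1, 15].
#' @param boundary Age boundary passed to [spline_spec()].
#' @param tol Relative RSS tolerance within which candidates count as tied.
#' @return A `spline_spec` with an extra attribute `"rss"` (the achieved RSS).
#' @export
select_knots <- function(ages, y, n_knots = 2, grid = seq(1, 15, by = 0.5),
                         boundary = c(0, 18), tol = 1e-9) {
  stopifnot(length(ages) == length(y), n_knots %in% c(2, 3))
  if (length(ages) < 20) stop("need at least 20 observations to select knots")
  if (!length(grid)) stop("empty candidate grid")
  tuples <- utils::combn(sort(unique(grid)), n_knots)
  rss <- apply(tuples, 2, function(kn) {
    X <- basis_matrix(ages, spline_spec(kn, boundary))
    fit <- stats::lm.fit(X, y)
    sum(fit$residuals^2)
  })
  best <- min(rss)
  # candidates tied with the optimum; lexicographic order of combn output is
  # already sorted, so the first tied column is the lexicographically smallest
  tied <- which(rss <= best * (1 + tol) + tol)
  kn <- tuples[, tied[1]]
  out <- spline_spec(kn, boundary)
  attr(out, "rss") <- rss[tied[1]]
  out
}
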