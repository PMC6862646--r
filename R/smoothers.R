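# B-spline design matrices, random-walk penalties for Bayesian
# P-splines, and tensor-product bases for space-time interactions.

#' Equidistant B-spline basis
#'
#' Builds a B-spline design matrix on an equidistant knot grid spanning
#' the data range, with `degree` boundary-knot extensions on each side
#' (de Boor evaluation via [splines::splineDesign()]).  The basis has
#' `n_inner_knots + degree + 1` functions and satisfies the partition
#' of unity on the knot span.
#'
#' @param x numeric vector of evaluation points.
#' @param n_inner_knots number of interior knots (>= 1).
#' @param degree spline degree (>= 0); cubic (3) by default.
#' @param range optional c(min, max) knot span; defaults to range(x).
#'   Points outside the span are an error at construction time (they
#'   are clamped, with a warning, at prediction time only).
#' @return a `spline_basis`: list with `design`, `knots` (full extended
#'   sequence), `degree`, `n_basis`, `range`.
#' @export
bspline_basis <- function(x, n_inner_knots = 20L, degree = 3L,
                          range = NULL) {
  x <- as.numeric(x)
  if (anyNA(x)) stop("x contains NA")
  if (n_inner_knots < 1L) stop("n_inner_knots must be >= 1")
  if (degree < 0L) stop("degree must be >= 0")
  if (is.null(range)) range <- base::range(x)
  if (range[2] <= range[1]) stop("degenerate knot span")
  if (any(x < range[1] | x > range[2]))
    stop("x outside the knot span")
  # widen the span infinitesimally so boundary data stay strictly
  # inside under floating-point knot construction
  lo <- range[1] - 1e-8 * diff(range)
  hi <- range[2] + 1e-8 * diff(range)
  h <- (hi - lo) / (n_inner_knots + 1L)
  knots <- lo + h * seq(-degree, n_inner_knots + 1L + degree)
  n_basis <- n_inner_knots + degree + 1L
  design <- splines::splineDesign(knots, x, ord = degree + 1L,
                                  outer.ok = FALSE)
  if (length(unique(x)) < n_basis)
    message("fewer distinct x values (", length(unique(x)),
            ") than basis functions (", n_basis, ")")
  structure(list(design = design, knots = knots, degree = degree,
                 n_basis = n_basis, range = range),
            class = "spline_basis")
}

#' Evaluate a spline basis at new points
#'
#' Points outside the training knot span are clamped to the span with a
#' warning (prediction-time safety).
#'
#' @param basis a [bspline_basis()].
#' @param xnew numeric vector.
#' @return matrix with `basis$n_basis` columns.
#' @export
eval_basis <- function(basis, xnew) {
  stopifnot(inherits(basis, "spline_basis"))
  xnew <- as.numeric(xnew)
  lo <- basis$range[1]; hi <- basis$range[2]
  if (any(xnew < lo | xnew > hi)) {
    warning("evaluation points clamped to the knot span [",
            format(lo), ", ", format(hi), "]")
    xnew <- pmin(pmax(xnew, lo), hi)
  }
  splines::splineDesign(basis$knots, xnew, ord = basis$degree + 1L,
                        outer.ok = FALSE)
}

#' Random-walk penalty matrix for P-spline coefficients
#'
#' K = t(D) %*% D with D the order-th difference operator, the precision
#' structure of a random-walk prior of that order on the coefficients.
#' Its null space contains constants (order 1) and linear trends
#' (order 2), so the flat / linear limits are unpenalized.
#'
#' @param n_basis number of basis coefficients.
#' @param order difference order (1 or 2 in practice); must be <
#'   `n_basis`.
#' @return a `penalty_matrix`: list with `K`, `order`,
#'   `rank = n_basis - order`.
#' @export
rw_penalty <- function(n_basis, order = 2L) {
  if (order < 1L) stop("order must be >= 1")
  if (order >= n_basis) stop("order must be smaller than n_basis")
  D <- diag(n_basis)
  for (i in seq_len(order)) D <- diff(D)
  structure(list(K = crossprod(D), order = order,
                 rank = n_basis - order),
            class = "penalty_matrix")
}

#' Row-wise tensor-product basis
#'
#' Row-wise Kronecker product of two marginal design matrices evaluated
#' on the same observations: column (k, j) is the elementwise product
#' of marginal columns k (first margin, e.g. region indicators) and j
#' (second margin, e.g. a time P-spline).  If both marginals satisfy
#' the partition of unity so does the tensor basis.
#'
#' @param design_s n x K_s matrix (first margin; typically region
#'   indicator columns for areal data).
#' @param design_t n x K_t matrix (second margin).
#' @return a `tensor_basis`: list with `design` (n x K_s*K_t, first
#'   margin varying slowest), `dims = c(K_s, K_t)`.
#' @export
tensor_basis <- function(design_s, design_t) {
  design_s <- as.matrix(design_s)
  design_t <- as.matrix(design_t)
  if (nrow(design_s) != nrow(design_t))
    stop("marginal bases must be evaluated on the same observations")
  Ks <- ncol(design_s); Kt <- ncol(design_t)
  design <- design_s[, rep(seq_len(Ks), each = Kt), drop = FALSE] *
    design_t[, rep(seq_len(Kt), times = Ks), drop = FALSE]
  structure(list(design = design, dims = c(Ks, Kt)),
            class = "tensor_basis")
}

# Kronecker-sum penalty for the tensor block: marginal spatial precision
# acting along the first margin plus marginal RW penalty along the
# second; column order matches tensor_basis (first margin slowest).
.tensor_penalty <- function(K_s, K_t) {
  kronecker(K_s, diag(ncol(K_t))) + kronecker(diag(ncol(K_s)), K_t)
}
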