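# Sampled curves in the (rho1, rho2) parameter plane.

#' Construct a parametric curve object
#'
#' A sampled curve in the \eqn{(\rho_1,\rho_2)} plane together with the
#' parameter grid that generated it, a validity mask (points where the
#' defining equations have a real solution and denominators are away from
#' zero) and per-point residuals of the defining equations.
#'
#' @param kind one of \code{"constant_eigenvalue"}, \code{"envelope"},
#'   \code{"hopf"}, \code{"singular"}.
#' @param parameter_name name of the running parameter (\code{"lambda"},
#'   \code{"omega"}, \code{"rho1"} or \code{"rho2"}).
#' @param parameter numeric vector of parameter values.
#' @param rho1,rho2 numeric vectors of curve coordinates (NA where invalid).
#' @param branch \code{"plus"}, \code{"minus"} or \code{"linear"}.
#' @param valid logical mask.
#' @param residual numeric vector of defining-equation residuals.
#' @param eigenvalue_tag eigenvalue associated with the curve, if constant
#'   along it (constant-eigenvalue and singular kinds).
#' @param tol residual tolerance used for the validity mask.
#' @return an object of class \code{"parametric_curve"}.
#' @export
parametric_curve <- function(kind, parameter_name, parameter, rho1, rho2,
                             branch = "linear", valid = NULL, residual = NULL,
                             eigenvalue_tag = NA_real_, tol = 1e-8,
                             breaks = NULL) {
  kind <- match.arg(kind, c("constant_eigenvalue", "envelope", "hopf", "singular"))
  n <- length(parameter)
  stopifnot(length(rho1) == n, length(rho2) == n)
  if (is.null(valid)) valid <- is.finite(rho1) & is.finite(rho2)
  if (is.null(residual)) residual <- rep(NA_real_, n)
  if (is.null(breaks)) breaks <- rep(FALSE, max(n - 1L, 0L))
  structure(list(kind = kind, parameter_name = parameter_name,
                 parameter = parameter, rho1 = rho1, rho2 = rho2,
                 branch = branch, valid = valid, residual = residual,
                 eigenvalue_tag = eigenvalue_tag, tol = tol, breaks = breaks),
            class = "parametric_curve")
}

#' @export
print.parametric_curve <- function(x, ...) {
  cat(sprintf("parametric_curve: %s (%s branch), %d points (%d valid)\n",
              x$kind, x$branch, length(x$parameter), sum(x$valid)))
  invisible(x)
}

#' @export
as.data.frame.parametric_curve <- function(x, ...) {
  data.frame(kind = x$kind, branch = x$branch, parameter = x$parameter,
             rho1 = x$rho1, rho2 = x$rho2, valid = x$valid,
             residual = x$residual)
}

# consecutive valid-point segments of a curve, as a 4-column matrix
# (x0, y0, x1, y1); used for crossing counts in the phase diagram.
# Segments flagged as breaks (e.g. jumps across a pole of a rational
# parametrization) are dropped, as are abnormally long jumps relative to
# the typical step.
curve_segments <- function(curve) {
  ok <- curve$valid & is.finite(curve$rho1) & is.finite(curve$rho2)
  i <- which(ok[-length(ok)] & ok[-1L] & !curve$breaks)
  if (length(i) == 0L)
    return(matrix(numeric(0), ncol = 4L))
  segs <- cbind(curve$rho1[i], curve$rho2[i],
                curve$rho1[i + 1L], curve$rho2[i + 1L])
  if (nrow(segs) >= 3L) {
    len <- sqrt((segs[, 3] - segs[, 1])^2 + (segs[, 4] - segs[, 2])^2)
    # a segment much longer than both its neighbours is a jump between
    # disconnected arcs (e.g. a branch switch), not part of the curve
    nb <- pmin(c(len[-1L], Inf), c(Inf, len[-length(len)]))
    keep <- len <= pmax(8 * nb, 1e-300)
    if (nrow(segs) >= 10L)
      keep <- keep & len <= 50 * stats::median(len) + 1e-300
    segs <- segs[keep, , drop = FALSE]
  }
  segs
}
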