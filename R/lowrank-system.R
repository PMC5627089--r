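#' Construct a low-rank perturbation system
#'
#' Bundles a real square base matrix \code{M} with one or two perturbation
#' vector pairs \code{(f_i, g_i)} and defines the two-parameter family
#' \deqn{\tilde M(\rho_1,\rho_2) = M + \rho_1 f_1 g_1^T + \rho_2 f_2 g_2^T.}
#' All spectral-geometry functions in the package operate on this object.
#'
#' The sign convention is fixed once and for all: perturbation strengths
#' \eqn{\rho_i} multiply the outer products \eqn{f_i g_i^T} with a plus sign.
#' Model builders whose natural parametrisation carries a minus sign (for
#' example inhibitory feedback connections) fold that sign into \code{f}.
#'
#' @param base_matrix real square numeric matrix (N x N), all entries finite.
#' @param pairs list of one or two lists, each with components \code{f} and
#'   \code{g}, numeric vectors of length N.
#' @param scale optional positive scalar recorded with the system (informative
#'   only; builders that use a global rate factor fold it into the matrix and
#'   vectors themselves).
#' @param label short text label.
#' @return An object of class \code{"lowrank_system"} with components
#'   \code{base_matrix}, \code{pairs}, \code{scale}, \code{label}, \code{n}.
#' @export
lowrank_system <- function(base_matrix, pairs, scale = 1, label = "") {
  base_matrix <- as.matrix(base_matrix)
  if (!is.numeric(base_matrix) || nrow(base_matrix) != ncol(base_matrix))
    stop("base_matrix must be a square numeric matrix")
  if (!all(is.finite(base_matrix)))
    stop("base_matrix contains non-finite entries")
  n <- nrow(base_matrix)
  if (!is.list(pairs) || length(pairs) < 1L || length(pairs) > 2L)
    stop("pairs must be a list of 1 or 2 (f, g) pairs")
  pairs <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    if (is.null(p$f) || is.null(p$g))
      stop(sprintf("pair %d must have components f and g", i))
    f <- as.numeric(p$f); g <- as.numeric(p$g)
    if (length(f) != n || length(g) != n)
      stop(sprintf("pair %d: f and g must have length %d", i, n))
    if (!all(is.finite(f)) || !all(is.finite(g)))
      stop(sprintf("pair %d contains non-finite entries", i))
    list(f = f, g = g)
  })
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale <= 0)
    stop("scale must be a positive scalar")
  structure(list(base_matrix = base_matrix, pairs = pairs, scale = scale,
                 label = as.character(label)[1L], n = n),
            class = "lowrank_system")
}

#' Assemble the perturbed matrix at given parameter values
#'
#' @param system a \code{\link{lowrank_system}}.
#' @param rho1,rho2 perturbation strengths; \code{rho2} is ignored for
#'   rank-one systems.
#' @return The real matrix \eqn{M + \rho_1 f_1 g_1^T + \rho_2 f_2 g_2^T}.
#' @export
assemble_matrix <- function(system, rho1, rho2 = 0) {
  stopifnot(inherits(system, "lowrank_system"))
  m <- system$base_matrix
  p <- system$pairs
  m <- m + rho1 * tcrossprod(p[[1L]]$f, p[[1L]]$g)
  if (length(p) >= 2L) m <- m + rho2 * tcrossprod(p[[2L]]$f, p[[2L]]$g)
  m
}

#' @export
print.lowrank_system <- function(x, ...) {
  cat(sprintf("lowrank_system '%s': N = %d, rank-%d perturbation\n",
              x$label, x$n, length(x$pairs)))
  invisible(x)
}

#' Spectrum of the assembled matrix
#'
#' Convenience wrapper around \code{eigen} for the perturbed matrix.
#'
#' @inheritParams assemble_matrix
#' @return complex vector of eigenvalues, sorted by decreasing real part.
#' @export
system_spectrum <- function(system, rho1, rho2 = 0) {
  ev <- eigen(assemble_matrix(system, rho1, rho2), only.values = TRUE)$values
  ev[order(-Re(ev))]
}
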