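# Fixtures, system I/O, curve export, and helpers shared by the
# command-line entry points.

pkg_version_string <- function() {
  v <- tryCatch(as.character(utils::packageVersion("perturbspec")),
                error = function(e) NA_character_)
  if (is.na(v)) v <- "0.0.0.9000-dev"
  paste0("perturbspec-", v)
}

# ---------------------------------------------------------------------------
# Built-in fixtures

#' The 4 x 4 worked-example system
#'
#' Base matrix with tridiagonal-like coupling and square-root-of-two
#' feedback entries, perturbed by \eqn{\rho_1} at entry (1,4) and
#' \eqn{\rho_2} at entry (2,3) (both with a minus sign, folded into the
#' \code{f} vectors).  Its transcription is pinned by the origin spectrum
#' (-3, -2, -2, -1) and by the closed form of the characteristic function,
#' both asserted in the test suite.
#'
#' @return a \code{\link{lowrank_system}}.
#' @export
e27_system <- function() {
  s2 <- sqrt(2)
  base <- matrix(c(-2, -1,  0,  0,
                   -1, -2,  0,  0,
                    s2,  1, -2,  0,
                    1,  s2,  0, -2), 4, 4, byrow = TRUE)
  e <- function(i) { v <- numeric(4); v[i] <- 1; v }
  lowrank_system(base,
                 list(list(f = -e(1), g = e(4)),
                      list(f = -e(2), g = e(3))),
                 label = "E27")
}

#' Named built-in fixtures
#'
#' Returns one of the shipped model fixtures by name:
#' \describe{
#'   \item{E27}{the 4 x 4 worked example (\code{\link{e27_system}}).}
#'   \item{INTEGRATOR-NORMAL}{N = 6 discrete oculomotor integrator, normal
#'     wiring (\code{\link{build_discrete_integrator}}).}
#'   \item{INTEGRATOR-NYSTAGMUS}{same network with the nystagmus wiring.}
#'   \item{CONTINUUM-N12}{parameters of the N = 12 continuum integrator
#'     (\code{\link{continuum_params}}); not a \code{lowrank_system}.}
#'   \item{RS-CUBIC}{the cubic-front elliptic data at modulus \code{k}
#'     (\code{\link{elliptic_front}}); not a \code{lowrank_system}.}
#' }
#'
#' @param name fixture name (case-insensitive).
#' @param k elliptic modulus for \code{RS-CUBIC}.
#' @return the fixture object.
#' @export
builtin_fixture <- function(name, k = 0.6) {
  switch(toupper(name),
         "E27" = e27_system(),
         "INTEGRATOR-NORMAL" = build_discrete_integrator(wiring = "normal"),
         "INTEGRATOR-NYSTAGMUS" = build_discrete_integrator(wiring = "nystagmus"),
         "CONTINUUM-N12" = continuum_params(N = 12),
         "RS-CUBIC" = elliptic_front(k),
         stop(sprintf("unknown fixture '%s'", name)))
}

#' Seeded random test systems
#'
#' Reproducible random \code{\link{lowrank_system}} generators used by the
#' property-based tests.  \code{structure = "dependent_g"} makes the second
#' projection vector a multiple of the first, which forces the cross term
#' \eqn{Q} of the characteristic function to vanish identically;
#' \code{"selfadjoint_base"} draws a symmetric base matrix so the spectral
#' form of the characteristic function applies.
#'
#' @param seed integer seed.
#' @param N matrix dimension, between 2 and 16.
#' @param structure one of \code{"generic"}, \code{"dependent_g"},
#'   \code{"selfadjoint_base"}.
#' @return a rank-two \code{\link{lowrank_system}}.
#' @export
fixture_generator <- function(seed, N = 6L,
                              structure = c("generic", "dependent_g",
                                            "selfadjoint_base")) {
  structure <- match.arg(structure)
  stopifnot(N >= 2L, N <= 16L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  base <- matrix(stats::rnorm(N * N), N, N)
  if (structure == "selfadjoint_base") base <- (base + t(base)) / 2
  f1 <- stats::rnorm(N); g1 <- stats::rnorm(N)
  f2 <- stats::rnorm(N)
  g2 <- if (structure == "dependent_g") stats::runif(1, 0.5, 2) * g1
  else stats::rnorm(N)
  lowrank_system(base, list(list(f = f1, g = g1), list(f = f2, g = g2)),
                 label = sprintf("random-%s-seed%d", structure, seed))
}

# ---------------------------------------------------------------------------
# System save / load

system_to_document <- function(system) {
  list(label = system$label, scale = system$scale,
       base_matrix = unname(apply(system$base_matrix, 1L, identity,
                                  simplify = FALSE)),
       pairs = lapply(system$pairs, function(p) list(f = p$f, g = p$g)))
}

document_to_system <- function(doc) {
  for (fld in c("base_matrix", "pairs"))
    if (is.null(doc[[fld]]))
      stop(sprintf("system document: missing field '%s'", fld))
  base <- doc$base_matrix
  if (is.list(base)) {
    lens <- lengths(base)
    if (length(unique(lens)) != 1L)
      stop("system document: field 'base_matrix' rows have unequal lengths")
    base <- do.call(rbind, lapply(base, as.numeric))
  }
  base <- as.matrix(base)
  if (nrow(base) != ncol(base))
    stop("system document: field 'base_matrix' is not square")
  if (!all(is.finite(base)))
    stop("system document: field 'base_matrix' has non-finite entries")
  pairs <- lapply(seq_along(doc$pairs), function(i) {
    p <- doc$pairs[[i]]
    if (is.null(p$f))
      stop(sprintf("system document: missing field 'pairs[%d]$f'", i))
    if (is.null(p$g))
      stop(sprintf("system document: missing field 'pairs[%d]$g'", i))
    if (length(p$f) != nrow(base))
      stop(sprintf("system document: field 'pairs[%d]$f' has length %d, expected %d",
                   i, length(p$f), nrow(base)))
    if (length(p$g) != nrow(base))
      stop(sprintf("system document: field 'pairs[%d]$g' has length %d, expected %d",
                   i, length(p$g), nrow(base)))
    list(f = as.numeric(p$f), g = as.numeric(p$g))
  })
  lowrank_system(base, pairs,
                 scale = if (is.null(doc$scale)) 1 else doc$scale,
                 label = if (is.null(doc$label)) "" else doc$label)
}

#' Save a system to JSON or CSV
#'
#' JSON stores the full document (label, scale, base matrix, pairs) with
#' full precision.  CSV uses a labelled-row layout: one row per matrix row
#' (role \code{m}) followed by rows \code{f1}, \code{g1}, \code{f2},
#' \code{g2}.
#'
#' @param system a \code{\link{lowrank_system}}.
#' @param path output file; the extension selects the format
#'   (\code{.json} or \code{.csv}).
#' @return \code{path}, invisibly.
#' @export
save_system <- function(system, path) {
  stopifnot(inherits(system, "lowrank_system"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(system_to_document(system), path, auto_unbox = TRUE,
                         digits = I(17), pretty = TRUE)
  } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    rows <- rbind(system$base_matrix,
                  do.call(rbind, lapply(system$pairs,
                                        function(p) rbind(p$f, p$g))))
    role <- c(rep("m", system$n),
              paste0(rep(c("f", "g"), length(system$pairs)),
                     rep(seq_along(system$pairs), each = 2L)))
    df <- data.frame(role = role,
                     apply(rows, 2L, function(col) sprintf("%.17g", col)))
    names(df) <- c("role", paste0("v", seq_len(system$n)))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else stop("unsupported extension: use .json or .csv")
  invisible(path)
}

#' Load a system from JSON or CSV
#'
#' Accepts the documents written by \code{\link{save_system}} (or an
#' already-parsed list in the JSON layout) and validates dimensions,
#' finiteness and required fields with errors naming the offending field.
#'
#' @param path file path, or a list in the JSON document layout.
#' @return a \code{\link{lowrank_system}}.
#' @export
load_system <- function(path) {
  if (is.list(path)) return(document_to_system(path))
  stopifnot(is.character(path), length(path) == 1L, file.exists(path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                               simplifyMatrix = FALSE)
    if (is.data.frame(doc$pairs))
      doc$pairs <- lapply(seq_len(nrow(doc$pairs)), function(i)
        list(f = doc$pairs$f[[i]], g = doc$pairs$g[[i]]))
    document_to_system(doc)
  } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!"role" %in% names(df)) stop("system CSV: missing column 'role'")
    vals <- as.matrix(df[, setdiff(names(df), "role"), drop = FALSE])
    storage.mode(vals) <- "double"
    m <- vals[df$role == "m", , drop = FALSE]
    npairs <- sum(grepl("^f", df$role))
    pairs <- lapply(seq_len(npairs), function(i) {
      fi <- vals[df$role == paste0("f", i), ]
      gi <- vals[df$role == paste0("g", i), ]
      if (length(fi) == 0L)
        stop(sprintf("system CSV: missing row 'f%d'", i))
      if (length(gi) == 0L)
        stop(sprintf("system CSV: missing row 'g%d'", i))
      list(f = fi, g = gi)
    })
    document_to_system(list(base_matrix = m, pairs = pairs))
  } else stop("unsupported extension: use .json or .csv")
}

# ---------------------------------------------------------------------------
# Curve export

curves_to_frame <- function(curves) {
  if (inherits(curves, "parametric_curve")) curves <- list(curves)
  do.call(rbind, lapply(curves, as.data.frame))
}

#' Export parametric curves with a manifest
#'
#' Writes a flat table with columns \code{kind, branch, parameter, rho1,
#' rho2, valid, residual} (one row per sample over all supplied curves)
#' plus a JSON manifest \code{<path>.manifest.json} recording, per curve,
#' the parameter name, grid range and size, and the residual tolerance,
#' together with the package version string.  Numeric CSV fields are
#' rendered with 17 significant digits so that re-exports are
#' byte-identical; no timestamps are written.
#'
#' @param curves a \code{parametric_curve} or list of them.
#' @param path output file path.
#' @param format \code{"csv"} or \code{"json"}.
#' @return \code{path}, invisibly.
#' @export
export_curves <- function(curves, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (inherits(curves, "parametric_curve")) curves <- list(curves)
  stopifnot(all(vapply(curves, inherits, TRUE, "parametric_curve")))
  df <- curves_to_frame(curves)
  if (format == "csv") {
    out <- data.frame(kind = df$kind, branch = df$branch,
                      parameter = sprintf("%.17g", df$parameter),
                      rho1 = sprintf("%.17g", df$rho1),
                      rho2 = sprintf("%.17g", df$rho2),
                      valid = tolower(as.character(df$valid)),
                      residual = sprintf("%.17g", df$residual))
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(lapply(curves, function(cv)
      list(kind = cv$kind, branch = cv$branch,
           parameter_name = cv$parameter_name, parameter = cv$parameter,
           rho1 = cv$rho1, rho2 = cv$rho2, valid = cv$valid,
           residual = cv$residual, eigenvalue_tag = cv$eigenvalue_tag,
           tol = cv$tol, breaks = cv$breaks)),
      path, auto_unbox = TRUE, digits = I(17), pretty = TRUE, na = "null")
  }
  manifest <- list(
    version = pkg_version_string(), format = format, file = basename(path),
    curves = lapply(curves, function(cv)
      list(kind = cv$kind, branch = cv$branch,
           parameter_name = cv$parameter_name,
           n_points = length(cv$parameter),
           parameter_range = range(cv$parameter), tol = cv$tol)))
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' Import curves written by \code{\link{export_curves}}
#'
#' @param path a \code{.json} curve file.
#' @return list of \code{parametric_curve} objects.
#' @export
import_curves <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  lapply(doc, function(cv)
    parametric_curve(cv$kind, cv$parameter_name,
                     as.numeric(cv$parameter), as.numeric(cv$rho1),
                     as.numeric(cv$rho2), branch = cv$branch,
                     valid = as.logical(cv$valid),
                     residual = as.numeric(cv$residual),
                     eigenvalue_tag = if (is.null(cv$eigenvalue_tag))
                       NA_real_ else as.numeric(cv$eigenvalue_tag),
                     tol = cv$tol, breaks = as.logical(cv$breaks)))
}
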