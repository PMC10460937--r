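#' Simulation cell
#'
#' A periodic (or non-periodic) simulation cell.  The matrix rows are the
#' lattice vectors in Angstrom, following the common MD convention.
#'
#' @param matrix 3x3 numeric matrix; rows are lattice vectors (Angstrom).
#' @param periodic one of `"cubic"`, `"orthorhombic"`, `"parallelepiped"`,
#'   `"none"`.  Defaults to a shape inferred from the matrix.
#' @return An object of class `md_cell` with elements `matrix` and `periodic`.
#' @examples
#' cubic_cell(53)
#' @export
cell <- function(matrix, periodic = NULL) {
  m <- as.matrix(matrix)
  if (!is.numeric(m) || !identical(dim(m), c(3L, 3L)) || any(!is.finite(m)))
    stop("cell matrix must be a finite 3x3 numeric matrix")
  if (is.null(periodic)) periodic <- .infer_periodic(m)
  periodic <- match.arg(periodic,
                        c("cubic", "orthorhombic", "parallelepiped", "none"))
  if (periodic != "none" && det(m) <= 0)
    stop("degenerate cell: lattice matrix must have positive volume")
  if (periodic == "cubic" &&
      (any(m[row(m) != col(m)] != 0) || length(unique(diag(m))) != 1L))
    stop("cubic cell requires equal diagonal entries and zero off-diagonals")
  if (periodic == "orthorhombic" && any(m[row(m) != col(m)] != 0))
    stop("orthorhombic cell requires zero off-diagonal entries")
  structure(list(matrix = unname(m), periodic = periodic), class = "md_cell")
}

.infer_periodic <- function(m) {
  if (all(m == 0)) return("none")
  if (all(m[row(m) != col(m)] == 0)) {
    if (length(unique(diag(m))) == 1L) "cubic" else "orthorhombic"
  } else "parallelepiped"
}

#' @rdname cell
#' @param length edge length in Angstrom (cubic), or a length-3 vector of edge
#'   lengths (orthorhombic).
#' @export
cubic_cell <- function(length) {
  stopifnot(is.numeric(length), length(length) == 1L, length > 0)
  cell(diag(rep(length, 3)), "cubic")
}

#' @rdname cell
#' @export
ortho_cell <- function(length) {
  stopifnot(is.numeric(length), length(length) == 3L, all(length > 0))
  cell(diag(length), "orthorhombic")
}

#' @export
print.md_cell <- function(x, ...) {
  cat("<md_cell>", x$periodic, "\n")
  print(x$matrix)
  invisible(x)
}

is_periodic <- function(cl) inherits(cl, "md_cell") && cl$periodic != "none"

# Minimum perpendicular width of the cell (limits the usable cutoff: the
# nearest-image convention is unambiguous only below half this width).
min_cell_width <- function(cl) {
  m <- cl$matrix
  v <- abs(det(m))
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  areas <- c(sqrt(sum(cross(m[2, ], m[3, ])^2)),
             sqrt(sum(cross(m[1, ], m[3, ])^2)),
             sqrt(sum(cross(m[1, ], m[2, ])^2)))
  min(v / areas)
}

#' Minimum-image distance between two points
#'
#' Distance between `a` and `b` under the minimum image convention: the
#' minimum over lattice translations `T` of `|a - b + T|`.  For skewed cells
#' the fractional displacement is wrapped to `[-0.5, 0.5)` and the 27
#' surrounding images are searched, which is exact whenever distances of
#' interest are below half the smallest cell width.
#'
#' @param a,b numeric 3-vectors, Angstrom.
#' @param cl an [cell()] object.
#' @return scalar distance in Angstrom; symmetric in `a`, `b`.
#' @examples
#' minimum_image_distance(c(0, 0, 0), c(52, 0, 0), cubic_cell(53)) # 1
#' @export
minimum_image_distance <- function(a, b, cl) {
  stopifnot(inherits(cl, "md_cell"), length(a) == 3L, length(b) == 3L)
  d <- as.numeric(a) - as.numeric(b)
  if (!is_periodic(cl)) return(sqrt(sum(d * d)))
  sqrt(.min_image_dist2(matrix(d, nrow = 1L), cl))
}

# Squared minimum-image lengths of displacement rows `dx` (n x 3).
.min_image_dist2 <- function(dx, cl) {
  if (!is_periodic(cl)) return(rowSums(dx * dx))
  m <- cl$matrix
  if (cl$periodic %in% c("cubic", "orthorhombic")) {
    L <- diag(m)
    for (k in 1:3) dx[, k] <- dx[, k] - L[k] * round(dx[, k] / L[k])
    return(rowSums(dx * dx))
  }
  # triclinic: wrap fractional coordinates, then scan the 27 nearest images
  f <- dx %*% solve(m)
  f <- f - round(f)
  best <- rep(Inf, nrow(f))
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    cart <- sweep(f, 2L, c(i, j, k), "+") %*% m
    best <- pmin(best, rowSums(cart * cart))
  }
  best
}
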