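#' Unit cell
#'
#' Constructs a unit cell from lengths (Angstrom) and angles (degrees) and
#' precomputes the fractional-to-Cartesian matrix in the standard
#' orthogonalization convention (a along x, b in the xy-plane).
#'
#' @param a,b,c cell lengths in Angstrom (> 0)
#' @param alpha,beta,gamma cell angles in degrees, each in (0, 180)
#' @return an object of class `unit_cell` with elements `a,b,c,alpha,beta,
#'   gamma`, `frac2cart` (3x3), `cart2frac` (3x3) and `volume` (A^3)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  len <- c(a, b, c); ang <- c(alpha, beta, gamma)
  if (any(!is.finite(len)) || any(len <= 0))
    stop("unit cell lengths must be positive and finite")
  if (any(!is.finite(ang)) || any(ang <= 0) || any(ang >= 180))
    stop("unit cell angles must lie in (0, 180) degrees")
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180); sg <- sin(gamma * pi / 180)
  v2 <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (v2 <= 1e-12) stop("degenerate unit cell (zero volume)")
  v <- sqrt(v2)
  m <- matrix(c(a, b * cg, c * cb,
                0, b * sg, c * (ca - cb * cg) / sg,
                0, 0,      c * v / sg),
              nrow = 3, byrow = TRUE)
  structure(list(a = a, b = b, c = c,
                 alpha = alpha, beta = beta, gamma = gamma,
                 frac2cart = m, cart2frac = solve(m),
                 volume = a * b * c * v),
            class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell  %.3f %.3f %.3f  %.2f %.2f %.2f  (V = %.1f A^3)\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume))
  invisible(x)
}

#' Fractional/Cartesian conversion
#'
#' @param cell a [unit_cell()]
#' @param x coordinates: length-3 vector or n x 3 matrix
#' @return coordinates in the other frame, same shape as input
#' @export
frac_to_cart <- function(cell, x) .cell_apply(cell$frac2cart, x)

#' @rdname frac_to_cart
#' @export
cart_to_frac <- function(cell, x) .cell_apply(cell$cart2frac, x)

.cell_apply <- function(m, x) {
  if (is.matrix(x)) t(m %*% t(x)) else drop(m %*% x)
}

#' Symmetry operator list
#'
#' Explicit rotation/translation operator lists (default P1).  Operators are
#' applied to fractional coordinates as `R %*% x + t`.  The list must contain
#' the identity; closure is not checked, so user-supplied subsets are
#' accepted as-is.
#'
#' @param rotations list of 3x3 matrices with determinant +1 or -1
#' @param translations list of length-3 fractional translation vectors
#' @return object of class `symmetry_ops`
#' @export
symmetry_ops <- function(rotations = list(diag(3)),
                         translations = list(c(0, 0, 0))) {
  if (length(rotations) != length(translations))
    stop("rotations and translations must have equal length")
  has_id <- FALSE
  for (i in seq_along(rotations)) {
    r <- rotations[[i]]
    if (!all(dim(r) == c(3, 3))) stop("rotation matrices must be 3x3")
    d <- det(r)
    if (abs(abs(d) - 1) > 1e-8)
      stop("rotation determinant must be +1 or -1")
    if (max(abs(r - diag(3))) < 1e-12 &&
        max(abs(translations[[i]])) < 1e-12) has_id <- TRUE
  }
  if (!has_id) stop("operator list must contain the identity")
  structure(list(rotations = rotations, translations = translations),
            class = "symmetry_ops")
}

#' Number of symmetry operators
#' @param ops a [symmetry_ops()]
#' @export
n_ops <- function(ops) length(ops$rotations)
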