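#' COSMO dielectric scaling function
#'
#' `f(eps) = (eps - 1) / (eps + x)`, the factor scaling the ideal-conductor
#' screening charges to a finite dielectric.  `f(1) = 0` (vacuum, no
#' screening) and `f -> 1` in the conductor limit; the original COSMO
#' offset `x = 0.5` is the default.
#'
#' @param epsilon dielectric constant, >= 1 (1 = vacuum, ~4 protein
#'   interior, ~80 water)
#' @param x offset in the denominator
#' @return scalar (or vector) in \[0, 1)
#' @export
f_eps <- function(epsilon, x = 0.5) {
  if (any(epsilon < 1)) stop("dielectric constant must be >= 1")
  (epsilon - 1) / (epsilon + x)
}

#' COSMO cavity radii
#'
#' Published COSMO-optimized element radii from the shipped text table;
#' metals default to 2.0 Angstrom, other unlisted elements to 1.17 times
#' the generic 1.5 A fallback unless given explicitly.
#'
#' @param elements character vector of element symbols
#' @param metal_radius radius assigned to elements absent from the table
#'   (the metals), Angstrom
#' @return numeric vector of cavity radii, Angstrom
#' @export
cosmo_radii <- function(elements, metal_radius = 2.0) {
  path <- system.file("extdata", "cosmo_radii.txt", package = "qrlite")
  tb <- utils::read.table(path, comment.char = "#",
                          col.names = c("element", "radius"))
  r <- tb$radius[match(elements, tb$element)]
  r[is.na(r)] <- metal_radius
  r
}

#' Build a COSMO cavity
#'
#' Tessellates each atom's cavity sphere with a deterministic Fibonacci
#' spiral lattice of `n_points` near-uniform points, removes points buried
#' inside any other atom's sphere (binary keep/drop) and assigns each
#' surviving point the area `4 pi R^2 / n_points`.
#'
#' For overlapping spheres, segments from different atoms can approach
#' each other arbitrarily closely along the intersection seam, which makes
#' the collocation matrix of [cosmo_solve()] lose positive definiteness.
#' Seam pairs closer than `seam_frac` times the local segment radius are
#' therefore merged (area-conserving), which leaves isolated spheres
#' untouched.
#'
#' @param pos n x 3 matrix of atom positions (Angstrom)
#' @param radii per-atom cavity radii (Angstrom, > 0)
#' @param n_points points per sphere before burial removal
#' @param seam_frac merge threshold as a fraction of the segment radius
#'   `sqrt(area/pi)`; 0 disables seam cleanup
#' @return object of class `cosmo_cavity`: `centers` (m x 3, Angstrom),
#'   `areas` (A^2), `owner` (atom index per segment), `radii`, `n_points`
#' @export
build_cavity <- function(pos, radii, n_points = 590, seam_frac = 0.8) {
  pos <- matrix(pos, ncol = 3)
  n <- nrow(pos)
  if (length(radii) != n) stop("need one radius per atom")
  if (any(radii <= 0)) stop("cavity radii must be positive")
  if (n > 1) {
    dm <- as.matrix(stats::dist(pos))
    diag(dm) <- Inf
    if (any(dm < 1e-6)) stop("coincident atoms in cavity construction")
  }
  sph <- .fib_sphere(n_points)
  centers <- NULL; owner <- integer(0); areas <- numeric(0)
  for (i in seq_len(n)) {
    pts <- sweep(sph * radii[i], 2, pos[i, ], "+")
    keep <- rep(TRUE, nrow(pts))
    for (j in seq_len(n)) {
      if (j == i) next
      dj2 <- rowSums(sweep(pts, 2, pos[j, ])^2)
      keep <- keep & dj2 > radii[j]^2
    }
    if (!any(keep)) next   # fully buried atom: no segments
    centers <- rbind(centers, pts[keep, , drop = FALSE])
    owner <- c(owner, rep(i, sum(keep)))
    areas <- c(areas, rep(4 * pi * radii[i]^2 / n_points, sum(keep)))
  }
  if (is.null(centers)) stop("cavity has no exposed surface")
  if (seam_frac > 0 && n > 1) {
    keep <- .merge_seam(centers, areas, owner, seam_frac)
    centers <- centers[keep$alive, , drop = FALSE]
    areas <- keep$areas[keep$alive]
    owner <- owner[keep$alive]
  }
  cav <- structure(list(centers = centers, areas = areas, owner = owner,
                        radii = radii, n_points = n_points, pos = pos),
                   class = "cosmo_cavity")
  ## the segment interaction matrix depends only on the surface, so its
  ## Cholesky factor is computed once here and reused by every solve
  cav$chol <- .cavity_chol(cav)
  cav
}

.cavity_chol <- function(cavity) {
  segs <- cavity$centers / .qr$BOHR_A
  areas <- cavity$areas / .qr$BOHR_A^2
  A <- 1 / .pdist(segs, segs, diag_value = 1)
  diag(A) <- 1.07 * sqrt(4 * pi / areas)
  tryCatch(chol(A), error = function(e)
    stop("COSMO interaction matrix is not positive definite ",
         "(ill-conditioned cavity): ", conditionMessage(e)))
}

## Area-conserving seam cleanup: cross-owner segment pairs closer than
## frac * max(segment radius) are merged into the first member.  One pass
## over the pairs sorted by distance; centers never move, so no new close
## pairs appear.
.merge_seam <- function(centers, areas, owner, frac) {
  d <- .pdist(centers, centers, diag_value = Inf)
  d[outer(owner, owner, "==")] <- Inf
  rseg <- sqrt(areas / pi)
  thr <- outer(rseg, rseg, pmax) * frac
  bad <- which(d < thr & upper.tri(d), arr.ind = TRUE)
  alive <- rep(TRUE, length(areas))
  if (nrow(bad)) {
    bad <- bad[order(d[bad]), , drop = FALSE]
    for (t in seq_len(nrow(bad))) {
      k <- bad[t, 1]; l <- bad[t, 2]
      if (alive[k] && alive[l]) {
        areas[k] <- areas[k] + areas[l]
        alive[l] <- FALSE
      }
    }
  }
  list(alive = alive, areas = areas)
}

## deterministic Fibonacci spiral lattice on the unit sphere
.fib_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Total exposed cavity surface area
#' @param cavity a [build_cavity()] result
#' @export
cavity_area <- function(cavity) sum(cavity$areas)

#' Solve the COSMO screening-charge equations
#'
#' Apparent surface charges for fixed point-charge solutes:
#' `Phi_k = sum_i z_i / |r_k - x_i|`, `A_kl = 1 / |r_k - r_l|` (k != l),
#' `A_kk = 1.07 sqrt(4 pi / area_k)`, `q = -f(eps) A^-1 Phi` and
#' `dG_solv = Phi' q / 2`, all in atomic units internally and kJ/mol at
#' the interface.  The symmetric system is solved by Cholesky
#' factorization.
#'
#' @param cavity a [build_cavity()] result
#' @param charges per-atom point charges (e), positions taken from the
#'   cavity
#' @param epsilon dielectric constant >= 1
#' @return object of class `cosmo_solution`: `q` (segment charges, e),
#'   `dG` (kJ/mol, <= 0), `epsilon`, `f`, `phi` (segment potentials, au)
#' @export
cosmo_solve <- function(cavity, charges, epsilon) {
  f <- f_eps(epsilon)
  m <- nrow(cavity$centers)
  if (m < 1) stop("cavity has no segments")
  if (length(charges) != nrow(cavity$pos))
    stop("need one charge per cavity atom")
  segs <- cavity$centers / .qr$BOHR_A
  atoms <- cavity$pos / .qr$BOHR_A
  areas <- cavity$areas / .qr$BOHR_A^2
  ## solute potential at segments
  d <- .pdist(segs, atoms)
  if (any(d < 1e-8)) stop("segment coincides with a solute charge")
  phi <- drop((1 / d) %*% charges)
  if (f == 0) {
    return(structure(list(q = numeric(m), dG = 0, epsilon = epsilon,
                          f = 0, phi = phi), class = "cosmo_solution"))
  }
  ch <- if (!is.null(cavity$chol)) cavity$chol else .cavity_chol(cavity)
  q <- -f * backsolve(ch, forwardsolve(t(ch), phi))
  dG <- 0.5 * sum(phi * q) * .qr$HARTREE_KJ
  structure(list(q = q, dG = dG, epsilon = epsilon, f = f, phi = phi),
            class = "cosmo_solution")
}

#' @export
print.cosmo_solution <- function(x, ...) {
  cat(sprintf("COSMO solution: eps = %g, f = %.6f, sum q = %+.4f e, dG = %.3f kJ/mol\n",
              x$epsilon, x$f, sum(x$q), x$dG))
  invisible(x)
}

## pairwise distance matrix between rows of a (m x 3) and b (n x 3)
.pdist <- function(a, b, diag_value = NULL) {
  m <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  m[m < 0] <- 0
  m <- sqrt(m)
  if (!is.null(diag_value) && nrow(a) == nrow(b)) diag(m) <- diag_value
  m
}

#' Fixed-cavity COSMO gradient
#'
#' Analytic gradient of the solvation energy with respect to the solute
#' atom positions at fixed cavity geometry:
#' `dG/dx_i = sum_k q_k dPhi_k/dx_i` (the screening charges are already
#' variationally optimal, so no `dq` term survives).  The motion of the
#' cavity surface itself is neglected; refinement compensates by
#' rebuilding the cavity at every outer cycle.  Documented as approximate.
#'
#' @param cavity a [build_cavity()] result
#' @param charges per-atom point charges (e)
#' @param epsilon dielectric constant
#' @param solution optional precomputed [cosmo_solve()] result
#' @param rebuild add the finite-difference cavity-rebuild correction:
#'   the full gradient is then central differences of the energy with the
#'   surface reconstructed at every displaced geometry, which restores
#'   rigid-motion invariance at the cost of `6 n` extra solves
#' @param h finite-difference step for the rebuild correction (Angstrom)
#' @return n x 3 matrix of gradients, kJ/mol/Angstrom
#' @export
cosmo_gradient <- function(cavity, charges, epsilon, solution = NULL,
                           rebuild = FALSE, h = 1e-4) {
  if (rebuild) {
    n <- nrow(cavity$pos)
    gr <- matrix(0, n, 3)
    efun <- function(pos) {
      cav <- build_cavity(pos, cavity$radii, cavity$n_points)
      cosmo_solve(cav, charges, epsilon)$dG
    }
    for (i in seq_len(n)) for (c in 1:3) {
      pp <- cavity$pos; pp[i, c] <- pp[i, c] + h
      pm <- cavity$pos; pm[i, c] <- pm[i, c] - h
      gr[i, c] <- (efun(pp) - efun(pm)) / (2 * h)
    }
    return(gr)
  }
  if (is.null(solution)) solution <- cosmo_solve(cavity, charges, epsilon)
  n <- nrow(cavity$pos)
  gr <- matrix(0, n, 3)
  if (solution$f == 0) return(gr)
  segs <- cavity$centers / .qr$BOHR_A
  atoms <- cavity$pos / .qr$BOHR_A
  d <- .pdist(segs, atoms)
  ## dPhi_k/dx_i = z_i (r_k - x_i) / d^3 ... gradient wrt x_i is
  ## -z_i (x_i - r_k)/d^3; assemble per coordinate
  inv3 <- 1 / d^3
  for (c in 1:3) {
    diff <- outer(segs[, c], atoms[, c], "-")        # r_k - x_i
    gr[, c] <- colSums(solution$q * diff * inv3) * charges
  }
  gr * .qr$HARTREE_KJ / .qr$BOHR_A
}

#' Conductor-Born reference energy
#'
#' Analytic COSMO solvation energy of a single point charge centred in a
#' spherical cavity: `dG = -f(eps) q^2 / (2 R)`, in kJ/mol.  Used as the
#' validation oracle for the numerical solver.
#'
#' @param q charge (e)
#' @param radius cavity radius (Angstrom)
#' @param epsilon dielectric constant
#' @return kJ/mol
#' @export
born_energy <- function(q, radius, epsilon) {
  -f_eps(epsilon) * q^2 / (2 * radius / .qr$BOHR_A) * .qr$HARTREE_KJ
}

#' Born validation table
#'
#' Runs the numerical COSMO solver for a single centred charge against the
#' analytic conductor-Born value over a grid of dielectric constants.
#'
#' @param q charge (e)
#' @param radius cavity radius (Angstrom)
#' @param eps_grid dielectric constants
#' @param n_points segments on the sphere
#' @return data frame with `eps, dG_numeric, dG_analytic, rel_error,
#'   gauss_ratio` (`sum q / (-f(eps) q)`)
#' @export
cosmo_born_table <- function(q = 1, radius = 2.0,
                             eps_grid = c(1, 2, 4, 10, 20, 40, 80),
                             n_points = 2000) {
  cav <- build_cavity(matrix(0, 1, 3), radius, n_points)
  rows <- lapply(eps_grid, function(e) {
    sol <- cosmo_solve(cav, q, e)
    ana <- born_energy(q, radius, e)
    data.frame(eps = e, dG_numeric = sol$dG, dG_analytic = ana,
               rel_error = if (ana != 0) abs(sol$dG - ana) / abs(ana) else 0,
               gauss_ratio = if (e > 1) sum(sol$q) / (-f_eps(e) * q) else NA_real_)
  })
  do.call(rbind, rows)
}
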