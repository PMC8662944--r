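#' Region ("system 1") energy with the built-in classical surrogate
#'
#' Evaluates the energy the refinement uses in place of a quantum-chemical
#' calculation of system 1: bonded terms (from the region restraint
#' parameters), point-charge Coulomb interactions with standard 1-2/1-3
#' exclusions, optional Lennard-Jones terms, and the COSMO continuum
#' solvation energy at dielectric `epsilon`.  The vacuum gradient is
#' analytic; the solvation gradient is the fixed-cavity COSMO gradient.
#' Link-atom gradients are mapped back onto their parent atoms through the
#' chain rule of the placement `x_link = x_in + s (x_out - x_in)` by the
#' caller ([total_energy()]).
#'
#' The surrogate stands in for a QM backend behind the same contract; an
#' external program can be plugged in via [backend_contract()] /
#' [run_external_backend()].
#'
#' @param atoms atom table of the capped region (as from
#'   [place_link_atoms()]`$atoms`): needs `element, x, y, z, charge,
#'   radius`
#' @param params a [restraint_params()] whose indices refer to rows of
#'   `atoms` (the region-internal bonded terms of the surrogate)
#' @param epsilon dielectric constant (>= 1); `epsilon = 1` skips COSMO
#'   entirely and the solvation component is exactly zero
#' @param lj optional Lennard-Jones table, data frame `i, j, eps_kj,
#'   sigma` (pair list, kJ/mol and Angstrom); default none
#' @param cavity_points COSMO segments per atom sphere
#' @param cavity optional frozen [build_cavity()] object; when supplied it
#'   is used as-is (fixed-cavity mode for consistent inner-cycle
#'   gradients), otherwise a cavity is built from the current coordinates
#' @return object of class `region_energy_result`: `energy` (kJ/mol),
#'   `vacuum`, `solvation`, `gradient` (n x 3, kJ/mol/A, rows follow
#'   `atoms` including link atoms), `cavity` (NULL for vacuum)
#' @export
region_energy <- function(atoms, params = restraint_params(), epsilon = 1,
                          lj = NULL, cavity_points = 242, cavity = NULL) {
  n <- nrow(atoms)
  x <- as.matrix(atoms[, c("x", "y", "z")])
  z <- atoms$charge
  ## bonded part reuses the restraint machinery on a wrapper model
  Evac <- 0
  gr <- matrix(0, n, 3)
  if (n_terms(params) > 0) {
    shadow <- structure(list(atoms = atoms), class = "structure_model")
    tb <- mm_energy(shadow, params)
    Evac <- Evac + tb$energy
    gr <- gr + tb$grad
  }
  ## Coulomb with 1-2/1-3 exclusions derived from the bond list
  if (n > 1 && any(z != 0)) {
    excl <- .excl_12_13(params$bonds, n)
    d <- .pdist(x, x, diag_value = Inf)
    d[excl] <- Inf
    qq <- outer(z, z)
    Ec <- .qr$COULOMB_KJ * qq / d
    Ec[upper.tri(Ec, diag = TRUE)] <- 0   # count each pair once
    Evac <- Evac + sum(Ec[is.finite(Ec)])
    ## gradient: dE/dx_i = -k q_i q_j (x_i - x_j)/d^3 summed over j
    inv3 <- 1 / d^3
    inv3[!is.finite(inv3)] <- 0
    w <- .qr$COULOMB_KJ * qq * inv3
    for (c in 1:3) {
      diff <- outer(x[, c], x[, c], "-")
      gr[, c] <- gr[, c] - rowSums(w * diff)
    }
  }
  ## Lennard-Jones pair list
  if (!is.null(lj) && nrow(lj)) {
    dv <- x[lj$i, , drop = FALSE] - x[lj$j, , drop = FALSE]
    r <- sqrt(rowSums(dv^2))
    sr6 <- (lj$sigma / r)^6
    Evac <- Evac + sum(4 * lj$eps_kj * (sr6^2 - sr6))
    f <- 4 * lj$eps_kj * (-12 * sr6^2 + 6 * sr6) / r^2
    for (c in 1:3) {
      gr[, c] <- gr[, c] + .acc(n, lj$i, f * dv[, c]) -
        .acc(n, lj$j, f * dv[, c])
    }
  }
  Esolv <- 0
  cav <- NULL
  if (epsilon > 1 && any(z != 0)) {
    if (is.null(cavity)) {
      radii <- atoms$radius
      if (any(is.na(radii))) radii[is.na(radii)] <- cosmo_radii(atoms$element[is.na(radii)])
      cav <- build_cavity(x, radii, cavity_points)
    } else {
      ## frozen surface, but the solute charges follow the current atoms
      cav <- cavity
      cav$pos <- x
    }
    sol <- cosmo_solve(cav, z, epsilon)
    Esolv <- sol$dG
    gr <- gr + cosmo_gradient(cav, z, epsilon, solution = sol)
  }
  structure(list(energy = Evac + Esolv, vacuum = Evac, solvation = Esolv,
                 gradient = gr, cavity = cav, epsilon = epsilon),
            class = "region_energy_result")
}

#' @export
print.region_energy_result <- function(x, ...) {
  cat(sprintf("region energy: %.3f kJ/mol (vacuum %.3f + solvation %.3f, eps = %g)\n",
              x$energy, x$vacuum, x$solvation, x$epsilon))
  invisible(x)
}

## logical n x n matrix of excluded (1-2 and 1-3) pairs, plus diagonal
.excl_12_13 <- function(bonds, n) {
  excl <- diag(n) > 0
  if (!is.null(bonds) && nrow(bonds)) {
    adj <- matrix(FALSE, n, n)
    adj[cbind(bonds$i, bonds$j)] <- TRUE
    adj[cbind(bonds$j, bonds$i)] <- TRUE
    excl <- excl | adj              # 1-2
    two <- (adj %*% adj) > 0        # 1-3 (and self, already excluded)
    excl <- excl | two
  }
  excl
}

#' Declare an external region-energy backend
#'
#' A backend is any executable obeying the file contract: it receives an
#' XYZ-format coordinate file and the dielectric constant, and writes a
#' result file whose first line is `energy <value> <unit>` followed by one
#' `gx gy gz` line per atom (gradient, in `<gradient unit>`).  Units must
#' be declared here so results can be converted to kJ/mol and Angstrom;
#' backends must be deterministic for fixed input.
#'
#' @param command executable path
#' @param energy_unit `"kj/mol"` or `"hartree"`
#' @param gradient_unit `"kj/mol/A"` or `"hartree/bohr"`
#' @param args extra command-line arguments (character vector)
#' @return object of class `backend_contract`
#' @export
backend_contract <- function(command, energy_unit = c("kj/mol", "hartree"),
                             gradient_unit = c("kj/mol/A", "hartree/bohr"),
                             args = character(0)) {
  structure(list(command = command,
                 energy_unit = match.arg(energy_unit),
                 gradient_unit = match.arg(gradient_unit),
                 args = args),
            class = "backend_contract")
}

#' Run an external region-energy backend
#'
#' Writes the capped region as XYZ text, invokes the backend with the
#' input path, an output path and the dielectric constant as arguments,
#' parses the documented result file and converts units (1 hartree =
#' 2625.4996 kJ/mol, 1 bohr = 0.529177 A).
#'
#' @param contract a [backend_contract()]
#' @param atoms capped region atom table (element, x, y, z, charge)
#' @param epsilon dielectric constant passed through to the backend
#' @return a `region_energy_result` (vacuum/solvation split is not
#'   reported by external backends; `solvation` is NA)
#' @export
run_external_backend <- function(contract, atoms, epsilon = 1) {
  xyz <- tempfile(fileext = ".xyz")
  out <- tempfile(fileext = ".dat")
  on.exit(unlink(c(xyz, out)), add = TRUE)
  n <- nrow(atoms)
  writeLines(c(as.character(n), "region",
               sprintf("%-2s %15.8f %15.8f %15.8f",
                       atoms$element, atoms$x, atoms$y, atoms$z)), xyz)
  status <- suppressWarnings(system2(contract$command,
                    c(contract$args, xyz, out, format(epsilon)),
                    stdout = TRUE, stderr = TRUE))
  code <- attr(status, "status")
  if (!is.null(code) && code != 0)
    stop("backend exited with status ", code, ":\n",
         paste(status, collapse = "\n"))
  if (!file.exists(out)) stop("backend produced no result file")
  ln <- readLines(out, warn = FALSE)
  if (length(ln) < n + 1)
    stop("backend result file too short: expected ", n + 1,
         " lines, got ", length(ln))
  head <- strsplit(trimws(ln[1]), "\\s+")[[1]]
  if (tolower(head[1]) != "energy") stop("result file must start with 'energy <value> <unit>'")
  e <- as.numeric(head[2])
  g <- do.call(rbind, lapply(ln[2:(n + 1)], function(s)
    as.numeric(strsplit(trimws(s), "\\s+")[[1]][1:3])))
  if (any(!is.finite(e)) || any(!is.finite(g)))
    stop("NaN or non-numeric values in backend results")
  if (contract$energy_unit == "hartree") e <- e * .qr$HARTREE_KJ
  if (contract$gradient_unit == "hartree/bohr")
    g <- g * .qr$HARTREE_KJ / .qr$BOHR_A
  structure(list(energy = e, vacuum = NA_real_, solvation = NA_real_,
                 gradient = g, cavity = NULL, epsilon = epsilon),
            class = "region_energy_result")
}
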