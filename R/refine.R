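#' Refinement configuration
#'
#' All tunable knobs of a quantum-refinement run.  `w_A` balances the
#' X-ray target against the empirical restraints (`"auto"` = gradient-norm
#' matching via [auto_wA()], resolved once at the start of refinement;
#' explicit values override).  `w_MM` converts restraint (statistical)
#' units to energy units; the shipped default 1/3 follows the original
#' ComQum-style convention and should be reviewed per force field.
#'
#' @param mm_params [restraint_params()] for the whole model (E_MM),
#'   indices into the model atom table
#' @param region_params [restraint_params()] for the capped region
#'   surrogate (E_QM1 bonded terms), indices into the capped-region atom
#'   table of [place_link_atoms()]
#' @param w_A scalar or `"auto"`
#' @param w_MM positive scalar
#' @param epsilon dielectric constant for the region energy (>= 1)
#' @param target `"lsq"` or `"mlf"`
#' @param max_cycles outer refinement cycles
#' @param coord_tol convergence threshold on the max coordinate shift per
#'   cycle (Angstrom)
#' @param energy_tol convergence threshold on the energy change per cycle
#'   (kJ/mol)
#' @param occupancies length-2 `(p, 1-p)` for dual-conformation (2QM)
#'   refinement; fixed, never refined
#' @param seed random seed recorded with the run (the minimizer itself is
#'   deterministic)
#' @param cavity_points COSMO segments per atom sphere
#' @param lj optional Lennard-Jones pair table for the region surrogate
#' @param region_params_b capped-region parameters for conformer B in 2QM
#'   mode
#' @param b_sim weight of the bonded B-factor similarity restraint in
#'   [refine_adps()]
#' @param inner_iters quasi-Newton iterations per outer cycle
#' @param max_step per-coordinate trust radius of one outer cycle
#'   (Angstrom).  Within a cycle the COSMO cavity is frozen, and the
#'   fixed-cavity energy is unbounded as a charge approaches the frozen
#'   surface; bounding the inner step keeps the geometry where the frozen
#'   context is valid, and the cavity is rebuilt at the next cycle.
#' @return object of class `refinement_config`
#' @export
refinement_config <- function(mm_params = restraint_params(),
                              region_params = restraint_params(),
                              w_A = "auto", w_MM = 1 / 3, epsilon = 1,
                              target = c("lsq", "mlf"), max_cycles = 200,
                              coord_tol = 1e-3, energy_tol = 0.01,
                              occupancies = c(1, 0), seed = 1,
                              cavity_points = 242, lj = NULL,
                              region_params_b = restraint_params(),
                              b_sim = 0.1, inner_iters = 25,
                              max_step = 0.25) {
  target <- match.arg(target)
  if (!identical(w_A, "auto") && (!is.numeric(w_A) || w_A < 0))
    stop("w_A must be a non-negative number or \"auto\"")
  if (w_MM <= 0) stop("w_MM must be positive")
  if (epsilon < 1) stop("epsilon must be >= 1")
  if (coord_tol <= 0 || energy_tol <= 0)
    stop("convergence thresholds must be positive")
  p <- occupancies[1]
  if (p < 0 || p > 1) stop("occupancy p must lie in [0, 1]")
  structure(list(mm_params = mm_params, region_params = region_params,
                 region_params_b = region_params_b,
                 w_A = w_A, w_MM = w_MM, epsilon = epsilon, target = target,
                 max_cycles = max_cycles, coord_tol = coord_tol,
                 energy_tol = energy_tol, occupancies = c(p, 1 - p),
                 seed = seed, cavity_points = cavity_points, lj = lj,
                 b_sim = b_sim, inner_iters = inner_iters,
                 max_step = max_step),
            class = "refinement_config")
}

## evaluate the crystallographic target per config, optionally with a
## frozen mlf parameter set (smooth within an outer cycle)
.xray_target <- function(model, refl, config, mlf_params = NULL,
                         need_bgrad = FALSE) {
  if (config$target == "mlf")
    target_mlf(model, refl, params = mlf_params, need_bgrad = need_bgrad)
  else target_lsq(model, refl, need_bgrad = need_bgrad)
}

## region energy of one capped region; returns energy and gradient mapped
## back onto model atoms (link-atom chain rule), plus the capped result
.region_term <- function(model, region, config, which_params = "region_params",
                         cavity = NULL) {
  capped <- place_link_atoms(model, region)
  res <- region_energy(capped$atoms, config[[which_params]],
                       epsilon = config$epsilon, lj = config$lj,
                       cavity_points = config$cavity_points,
                       cavity = cavity)
  g <- matrix(0, n_atoms(model), 3)
  nreg <- length(region$indices)
  g[region$indices, ] <- res$gradient[seq_len(nreg), , drop = FALSE]
  nb <- nrow(region$boundary_bonds)
  if (nb) {
    gl <- res$gradient[nreg + seq_len(nb), , drop = FALSE]
    s <- rep_len(region$link_scale, nb)
    for (t in seq_len(nb)) {
      g[region$boundary_bonds[t, 1], ] <-
        g[region$boundary_bonds[t, 1], ] + (1 - s[t]) * gl[t, ]
      g[region$boundary_bonds[t, 2], ] <-
        g[region$boundary_bonds[t, 2], ] + s[t] * gl[t, ]
    }
  }
  list(energy = res$energy, grad = g, result = res, capped = capped)
}

#' Combined quantum-refinement energy
#'
#' `E_total = E_QM1(eps) + w_MM (E_MM - E_MM1 + w_A E_Xray)`: the region
#' energy replaces the region-internal restraints, which are subtracted to
#' avoid double counting, while the X-ray term keeps the model tied to the
#' data.  The assembled gradient covers mobile atoms only; frozen atoms
#' receive exactly zero.
#'
#' @param model a [structure_model()]
#' @param region a [region_selection()]
#' @param refl a [reflection_set()]
#' @param config a [refinement_config()] with numeric `w_A`
#' @param fixed optional list of frozen evaluation context (`cavity`,
#'   `mlf_params`) used inside minimization cycles
#' @return a `target_value` with `energy`, `grad` and the component
#'   breakdown `e_qm1, e_mm, e_mm1, e_xray, r_work, r_free`
#' @export
total_energy <- function(model, region, refl, config, fixed = list()) {
  if (identical(config$w_A, "auto"))
    stop("w_A is \"auto\"; resolve it first with auto_wA() ",
         "(refine_coordinates does this automatically)")
  qm <- .region_term(model, region, config, cavity = fixed$cavity)
  mm <- mm_energy(model, config$mm_params)
  mm1 <- mm_energy(model, config$mm_params, region = region)
  xr <- .xray_target(model, refl, config, mlf_params = fixed$mlf_params)
  E <- qm$energy + config$w_MM * (mm$energy - mm1$energy +
                                  config$w_A * xr$energy)
  g <- qm$grad + config$w_MM * (mm$grad - mm1$grad + config$w_A * xr$grad)
  g[!model$mobile, ] <- 0
  .new_target(E, g, extra = list(
    e_qm1 = qm$energy, e_mm = mm$energy, e_mm1 = mm1$energy,
    e_xray = xr$energy, r_work = xr$r_work, r_free = xr$r_free,
    e_solv = qm$result$solvation))
}

## Orthonormal basis of the non-rigid subspace of n atoms at coordinates
## x (n x 3): the complement of the 3 translations and up to 3 rotations
## about the centroid.  Used by dataless region optimization, where the
## exact (rebuilt-cavity) energy is invariant under rigid motions and any
## rigid component of the fixed-cavity gradient is discretization
## artifact.
.nonrigid_basis <- function(x) {
  n <- nrow(x)
  xc <- sweep(x, 2, colMeans(x))
  modes <- matrix(0, 3 * n, 6)
  for (c in 1:3) modes[seq(c, 3 * n, by = 3), c] <- 1  # translations
  for (i in seq_len(n)) {
    r <- xc[i, ]
    modes[3 * (i - 1) + 1:3, 4] <- c(0, -r[3], r[2])   # rotation about x
    modes[3 * (i - 1) + 1:3, 5] <- c(r[3], 0, -r[1])
    modes[3 * (i - 1) + 1:3, 6] <- c(-r[2], r[1], 0)
  }
  s <- svd(modes, nu = 3 * n, nv = 0)
  rank <- sum(s$d > 1e-8 * max(s$d))
  s$u[, (rank + 1):(3 * n), drop = FALSE]
}

## Shared outer-cycle driver: inner quasi-Newton runs against frozen
## context (cavity, mlf shell parameters) inside a per-cycle trust region,
## then the context is rebuilt and the cycle is accepted only if the
## rebuilt energy did not rise; a rejected cycle halves the trust radius.
## efun(model, fixed) must return a target_value; ctxfun(model) rebuilds
## the frozen context.  project_rigid removes rigid-body modes from the
## inner search space (dataless optimization only).
.cycle_minimize <- function(model, efun, ctxfun, mobile_idx, config,
                            project_rigid = FALSE) {
  trace <- list()
  converged <- FALSE
  step <- config$max_step %||% 0.25
  fixed <- ctxfun(model)
  prevE <- efun(model, fixed)$energy
  n_reject <- 0
  for (cycle in seq_len(config$max_cycles)) {
    x0 <- as.numeric(t(coords(model)[mobile_idx, , drop = FALSE]))
    P <- if (project_rigid)
      .nonrigid_basis(coords(model)[mobile_idx, , drop = FALSE]) else NULL
    to_model <- function(p) {
      xyz <- if (is.null(P)) matrix(p, ncol = 3, byrow = TRUE)
             else matrix(x0 + as.numeric(P %*% p), ncol = 3, byrow = TRUE)
      set_coords(model, xyz, mobile_idx)
    }
    fn <- function(p) efun(to_model(p), fixed)$energy
    gfn <- function(p) {
      g <- as.numeric(t(efun(to_model(p), fixed)$grad[mobile_idx, , drop = FALSE]))
      if (is.null(P)) g else as.numeric(crossprod(P, g))
    }
    p0 <- if (is.null(P)) x0 else numeric(ncol(P))
    opt <- stats::optim(p0, fn, gfn, method = "L-BFGS-B",
                        lower = p0 - step, upper = p0 + step,
                        control = list(maxit = config$inner_iters,
                                       factr = 1e4))
    cand <- to_model(opt$par)
    shift <- coords(cand)[mobile_idx, , drop = FALSE] -
      matrix(x0, ncol = 3, byrow = TRUE)
    max_shift <- if (nrow(shift)) max(sqrt(rowSums(shift^2))) else 0
    cand_fixed <- ctxfun(cand)
    tv <- efun(cand, cand_fixed)
    accepted <- tv$energy <= prevE + config$energy_tol
    trace[[cycle]] <- data.frame(
      cycle = cycle, e_total = tv$energy,
      e_qm1 = tv$e_qm1 %||% NA_real_, e_mm = tv$e_mm %||% NA_real_,
      e_mm1 = tv$e_mm1 %||% NA_real_, e_xray = tv$e_xray %||% NA_real_,
      r_work = tv$r_work %||% NA_real_, r_free = tv$r_free %||% NA_real_,
      max_grad = max(abs(tv$grad[mobile_idx, , drop = FALSE])),
      max_shift = max_shift, step = step, accepted = accepted)
    if (accepted) {
      edrop <- prevE - tv$energy
      model <- cand
      fixed <- cand_fixed
      n_reject <- 0
      if (max_shift < config$coord_tol || edrop < config$energy_tol) {
        converged <- TRUE
        break
      }
      prevE <- tv$energy
      step <- min(config$max_step %||% 0.25, step * 1.5)
    } else {
      n_reject <- n_reject + 1
      step <- step / 2
      if (step < config$coord_tol / 4 || n_reject >= 8) {
        ## trust radius collapsed: no downhill move exists at resolution
        converged <- TRUE
        break
      }
    }
  }
  list(model = model, trace = do.call(rbind, trace), converged = converged)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Refine coordinates against the combined energy
#'
#' Quasi-Newton (L-BFGS) minimization of [total_energy()] over the mobile
#' atoms, organized in outer cycles: at each cycle start the slowly varying
#' context (COSMO cavity, maximum-likelihood shell parameters) is frozen,
#' an inner L-BFGS run minimizes the then-smooth energy, and the context
#' is rebuilt.  Terminates when the per-cycle maximum coordinate shift
#' falls below `coord_tol` (or the energy change below `energy_tol`), or
#' at `max_cycles`.  Deterministic given the inputs; the seed is recorded
#' in the trace attributes.
#'
#' @inheritParams total_energy
#' @return list with `model` (refined), `trace` (one row per cycle:
#'   energies, R factors, max gradient and shift), `converged`, `w_A`
#' @export
refine_coordinates <- function(model, region, refl, config) {
  if (identical(config$w_A, "auto"))
    config$w_A <- auto_wA(model, refl, config$mm_params,
                          target = config$target)
  mobile_idx <- which(model$mobile)
  run_stage <- function(model, config) {
    ctxfun <- function(m) {
      fixed <- list()
      if (config$epsilon > 1) {
        qm <- .region_term(m, region, config)
        fixed$cavity <- qm$result$cavity
      }
      if (config$target == "mlf")
        fixed$mlf_params <- estimate_mlf_params(m, refl)
      fixed
    }
    efun <- function(m, fixed) total_energy(m, region, refl, config, fixed)
    .cycle_minimize(model, efun, ctxfun, mobile_idx, config)
  }
  res <- run_stage(model, config)
  attr(res$trace, "seed") <- config$seed
  res$w_A <- config$w_A
  res
}

#' Dual-conformation (2QM) refinement
#'
#' Refines two alternative conformations of the region simultaneously:
#' separate region energies for conformers A and B enter unweighted, the
#' restraint terms internal to either conformer are subtracted, and the
#' calculated structure factors sum both conformers' atoms weighted by
#' their fixed occupancies `(p, 1-p)` (set on the atom table; occupancies
#' are never refined).
#'
#' @param model a [structure_model()] whose `alt` tags partition the
#'   region atoms into conformers `"A"` and `"B"` (shared atoms: `""`)
#' @param region_a,region_b [region_selection()]s for the two conformers;
#'   `region_b` may be empty (`p = 1` then reduces exactly to
#'   single-conformer refinement)
#' @inheritParams total_energy
#' @return as [refine_coordinates()]
#' @export
refine_2qm <- function(model, region_a, region_b, refl, config) {
  p <- config$occupancies[1]
  ## fixed occupancies act only through Fcalc
  model$atoms$occ[model$atoms$alt == "A"] <- p
  model$atoms$occ[model$atoms$alt == "B"] <- 1 - p
  if (identical(config$w_A, "auto"))
    config$w_A <- auto_wA(model, refl, config$mm_params,
                          target = config$target)
  b_empty <- length(region_b$indices) == 0
  mobile_idx <- which(model$mobile)
  efun <- function(m, fixed) {
    qa <- .region_term(m, region_a, config, cavity = fixed$cavity_a)
    mm <- mm_energy(m, config$mm_params)
    mm1a <- mm_energy(m, config$mm_params, region = region_a)
    xr <- .xray_target(m, refl, config, mlf_params = fixed$mlf_params)
    E <- qa$energy + config$w_MM * (mm$energy - mm1a$energy +
                                    config$w_A * xr$energy)
    g <- qa$grad + config$w_MM * (mm$grad - mm1a$grad + config$w_A * xr$grad)
    e_qm1 <- qa$energy
    e_mm1 <- mm1a$energy
    if (!b_empty) {
      qb <- .region_term(m, region_b, config,
                         which_params = "region_params_b",
                         cavity = fixed$cavity_b)
      mm1b <- mm_energy(m, config$mm_params, region = region_b)
      E <- E + qb$energy - config$w_MM * mm1b$energy
      g <- g + qb$grad - config$w_MM * mm1b$grad
      e_qm1 <- e_qm1 + qb$energy
      e_mm1 <- e_mm1 + mm1b$energy
    }
    g[!m$mobile, ] <- 0
    .new_target(E, g, extra = list(
      e_qm1 = e_qm1, e_mm = mm$energy, e_mm1 = e_mm1,
      e_xray = xr$energy, r_work = xr$r_work, r_free = xr$r_free))
  }
  ctxfun <- function(m) {
    fixed <- list()
    if (config$epsilon > 1) {
      fixed$cavity_a <- .region_term(m, region_a, config)$result$cavity
      if (!b_empty)
        fixed$cavity_b <- .region_term(m, region_b, config,
                                       which_params = "region_params_b")$result$cavity
    }
    if (config$target == "mlf")
      fixed$mlf_params <- estimate_mlf_params(m, refl)
    fixed
  }
  res <- .cycle_minimize(model, efun, ctxfun, mobile_idx, config)
  attr(res$trace, "seed") <- config$seed
  res$w_A <- config$w_A
  res
}

#' Isotropic ADP (B-factor) refinement
#'
#' Post-coordinate stage: minimizes the X-ray target over the B factors of
#' the mobile atoms, with a similarity restraint `b_sim (B_i - B_j)^2`
#' between bonded atom pairs and a hard lower bound of 1 A^2.
#' Coordinates are untouched.
#'
#' @inheritParams total_energy
#' @return list with `model` (updated B factors) and `converged`
#' @export
refine_adps <- function(model, refl, config) {
  mob <- which(model$mobile)
  if (!length(mob)) {
    warning("all atoms frozen; ADP refinement is a no-op")
    return(list(model = model, converged = TRUE))
  }
  mlf_params <- if (config$target == "mlf")
    estimate_mlf_params(model, refl) else NULL
  bonds <- config$mm_params$bonds
  fn <- function(bv) {
    m <- model; m$atoms$b[mob] <- bv
    tv <- .xray_target(m, refl, config, mlf_params = mlf_params)
    E <- tv$energy
    if (!is.null(bonds) && nrow(bonds))
      E <- E + config$b_sim * sum((m$atoms$b[bonds$i] - m$atoms$b[bonds$j])^2)
    E
  }
  gfn <- function(bv) {
    m <- model; m$atoms$b[mob] <- bv
    tv <- .xray_target(m, refl, config, mlf_params = mlf_params,
                       need_bgrad = TRUE)
    g <- tv$bgrad
    if (!is.null(bonds) && nrow(bonds)) {
      d <- m$atoms$b[bonds$i] - m$atoms$b[bonds$j]
      g <- g + 2 * config$b_sim *
        (.acc(n_atoms(m), bonds$i, d) - .acc(n_atoms(m), bonds$j, d))
    }
    g[mob]
  }
  opt <- stats::optim(model$atoms$b[mob], fn, gfn, method = "L-BFGS-B",
                      lower = 1, control = list(maxit = 500, factr = 10,
                                                pgtol = 1e-10))
  model$atoms$b[mob] <- opt$par
  list(model = model, converged = opt$convergence == 0)
}
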