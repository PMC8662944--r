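#' Toy-crystal specification
#'
#' Parameters of the deterministic synthetic-data generator: a P1 cell
#' containing a small bonded, (typically) net-charged "active-site"
#' cluster plus uncharged environment atoms, with amplitudes computed from
#' the true model, optional Gaussian amplitude noise, seeded free-set
#' flags, and a start model perturbed to an exact target RMSD.
#'
#' @param cell lengths of an orthorhombic P1 cell (Angstrom)
#' @param region_size atoms in the charged cluster (2..7)
#' @param net_charge total cluster charge (e); spread uniformly
#' @param n_env uncharged environment atoms (frozen in refinement)
#' @param d_min resolution limit (Angstrom, > 0.5)
#' @param noise relative Gaussian sigma on the amplitudes (>= 0);
#'   `|Fobs| = |Ftrue| (1 + noise N(0,1))`, truncated at `0.1 |Ftrue|`,
#'   with `sigma = noise |Ftrue|` (1% of `|Ftrue|` when noise = 0)
#' @param free_frac free-set fraction
#' @param perturb start-model RMSD over the region atoms (Angstrom,
#'   achieved exactly by rescaling a random displacement)
#' @param geom_eps dielectric constant at which the data-generating
#'   cluster geometry is equilibrated (free optimization of the region
#'   surrogate).  The default 80 emulates a crystal grown from aqueous
#'   solution: the true conformation of a charged site is the solvated
#'   one, while the restraint ideal values stay at the vacuum geometry.
#'   Set 1 (or `net_charge = 0`) to keep the ideal geometry as truth.
#' @param seed mandatory integer seed; identical specs and seeds give
#'   bit-identical outputs
#' @return object of class `toy_spec`
#' @export
toy_spec <- function(cell = c(13, 14, 15), region_size = 5, net_charge = -5,
                     n_env = 14, d_min = 1.2, noise = 0.02,
                     free_frac = 0.05, perturb = 0.3, geom_eps = 80, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  if (d_min <= 0.5) stop("d_min must exceed 0.5 A")
  if (noise < 0) stop("noise must be >= 0")
  if (region_size < 2 || region_size > 7)
    stop("region_size must be between 2 and 7")
  if (geom_eps < 1) stop("geom_eps must be >= 1")
  structure(list(cell = cell, region_size = region_size,
                 net_charge = net_charge, n_env = n_env, d_min = d_min,
                 noise = noise, free_frac = free_frac, perturb = perturb,
                 geom_eps = geom_eps, seed = as.integer(seed)),
            class = "toy_spec")
}

## fixed ligand directions: tetrahedral set then axial caps
.toy_directions <- function() {
  rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1),
        c(0, 0, 1), c(0, 0, -1)) / c(sqrt(3), sqrt(3), sqrt(3), sqrt(3), 1, 1)
}

## unique-under-Friedel index list to resolution d_min
.toy_hkl <- function(cell, d_min) {
  hmax <- ceiling(c(cell$a, cell$b, cell$c) / d_min)
  g <- as.matrix(expand.grid(h = -hmax[1]:hmax[1], k = -hmax[2]:hmax[2],
                             l = -hmax[3]:hmax[3]))
  g <- g[!(g[, 1] == 0 & g[, 2] == 0 & g[, 3] == 0), ]
  keep <- g[, 1] > 0 | (g[, 1] == 0 & g[, 2] > 0) |
    (g[, 1] == 0 & g[, 2] == 0 & g[, 3] > 0)
  g <- g[keep, , drop = FALSE]
  g[d_spacing(cell, g) >= d_min, , drop = FALSE]
}

#' Generate a toy crystal
#'
#' Builds the true model (bonded cluster at the cell centre, ideal
#' geometry, plus environment atoms), emits matching restraint parameters
#' (zero energy at the true geometry), computes noisy amplitudes and free
#' flags, and produces a start model perturbed to the requested RMSD over
#' the region atoms.  The mobile mask covers the region only; the
#' environment is frozen by construction.
#'
#' @param spec a [toy_spec()]
#' @return list with `true` and `start` ([structure_model()]s), `refl`
#'   ([reflection_set()]), `region` ([region_selection()]), `mm_params`
#'   (model-indexed restraints), `region_params` (capped-region-indexed,
#'   identical here since the cluster is an island), `spec`
#' @export
make_toy_crystal <- function(spec) {
  set.seed(spec$seed)
  cell <- unit_cell(spec$cell[1], spec$cell[2], spec$cell[3])
  nreg <- spec$region_size
  if (nreg + spec$n_env < nreg) stop("region larger than atom count")
  centre <- c(cell$a, cell$b, cell$c) / 2
  dirs <- .toy_directions()[seq_len(nreg - 1), , drop = FALSE]
  blen <- 2.2
  xreg <- rbind(centre,
                sweep(dirs * blen, 2, centre, "+"))
  lig_elements <- c("S", "O", "S", "O", "N", "O")
  elements <- c("Fe", lig_elements[seq_len(nreg - 1)])
  ## restraint ideal values always refer to the vacuum (ideal) geometry
  bonds <- data.frame(i = 1L, j = 2:nreg, r0 = blen, k = 800)
  angles <- NULL
  if (nreg >= 3) {
    pr <- t(utils::combn(2:nreg, 2))
    th0 <- sapply(seq_len(nrow(pr)), function(t) {
      v1 <- xreg[pr[t, 1], ] - xreg[1, ]
      v2 <- xreg[pr[t, 2], ] - xreg[1, ]
      acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
    })
    angles <- data.frame(i = pr[, 1], j = 1L, k = pr[, 2],
                         theta0 = th0, ka = 150)
  }
  mm_params <- restraint_params(bonds = bonds, angles = angles)
  region <- region_selection(seq_len(nreg))
  ## data-generating geometry: equilibrate the charged cluster in solvent
  ## (crystals grow from solution, so the observed conformation is the
  ## solvated one; the restraints keep the vacuum ideal values)
  if (spec$net_charge != 0 && spec$geom_eps > 1) {
    xreg <- .equilibrate_cluster(cell, xreg, elements, spec, mm_params,
                                 region)
  }
  ## environment: seeded rejection sampling, min separation 2.8 A
  xenv <- matrix(0, 0, 3)
  env_el <- rep(c("C", "N", "O"), length.out = spec$n_env)
  while (nrow(xenv) < spec$n_env) {
    cand <- stats::runif(3) * c(cell$a, cell$b, cell$c)
    alld <- rbind(xreg, xenv)
    dmin_frac <- .min_image_dist(cell, cand, alld)
    if (min(dmin_frac) > 2.8) xenv <- rbind(xenv, cand)
  }
  x <- rbind(xreg, xenv)
  n <- nrow(x)
  atoms <- data.frame(
    element = c(elements, env_el),
    atomname = c(paste0(toupper(elements), seq_len(nreg)),
                 paste0(env_el, nreg + seq_len(spec$n_env))),
    resname = c(rep("CLU", nreg), rep("ENV", spec$n_env)),
    chain = "A",
    resno = c(rep(1L, nreg), 1L + seq_len(spec$n_env)),
    alt = "",
    x = x[, 1], y = x[, 2], z = x[, 3],
    occ = 1,
    b = c(rep(8, nreg), round(stats::runif(spec$n_env, 8, 15), 2)),
    charge = c(rep(spec$net_charge / nreg, nreg), rep(0, spec$n_env)),
    radius = NA_real_,
    stringsAsFactors = FALSE)
  atoms$radius <- cosmo_radii(atoms$element)
  mobile <- c(rep(TRUE, nreg), rep(FALSE, spec$n_env))
  true <- structure_model(cell, atoms, mobile = mobile)
  ## reflections from the true model
  hkl <- .toy_hkl(cell, spec$d_min)
  ftrue <- Mod(calc_structure_factors(true, hkl))
  fobs <- pmax(ftrue * (1 + spec$noise * stats::rnorm(nrow(hkl))),
               0.1 * ftrue)
  sigma <- if (spec$noise > 0) spec$noise * ftrue else 0.01 * ftrue
  free <- stats::runif(nrow(hkl)) < spec$free_frac
  refl <- reflection_set(hkl, fobs, sigma, free)
  ## start model: exact-RMSD perturbation of the region
  start <- true
  if (spec$perturb > 0) {
    delta <- matrix(stats::rnorm(3 * nreg), nreg, 3)
    delta <- delta * spec$perturb / sqrt(mean(rowSums(delta^2)))
    start <- set_coords(start, coords(true)[seq_len(nreg), ] + delta,
                        seq_len(nreg))
  }
  list(true = true, start = start, refl = refl, region = region,
       mm_params = mm_params, region_params = mm_params, spec = spec)
}

## free optimization of the cluster surrogate at the generating dielectric
.equilibrate_cluster <- function(cell, xreg, elements, spec, mm_params,
                                 region) {
  nreg <- nrow(xreg)
  atoms <- data.frame(
    element = elements, atomname = paste0("X", seq_len(nreg)),
    resname = "CLU", chain = "A", resno = 1L, alt = "",
    x = xreg[, 1], y = xreg[, 2], z = xreg[, 3],
    occ = 1, b = 8, charge = spec$net_charge / nreg,
    radius = cosmo_radii(elements), stringsAsFactors = FALSE)
  m <- structure_model(cell, atoms)
  cfg <- refinement_config(region_params = mm_params, w_A = 1,
                           epsilon = spec$geom_eps, coord_tol = 1e-4,
                           energy_tol = 1e-4)
  opt <- .optimize_region(m, region, cfg)
  coords(opt$model)
}

## minimum-image distances from point p to rows of xs (orthorhombic cell)
.min_image_dist <- function(cell, p, xs) {
  if (!nrow(xs)) return(Inf)
  lens <- c(cell$a, cell$b, cell$c)
  df <- sweep(xs, 2, p)
  for (c in 1:3) df[, c] <- df[, c] - round(df[, c] / lens[c]) * lens[c]
  sqrt(rowSums(df^2))
}

#' Generate a two-conformer toy fixture
#'
#' One shared scaffold (cluster centre plus three ligands) and two
#' alternative placements of a fourth ligand atom, tagged `alt = "A"` /
#' `"B"` with occupancies `p` and `1 - p`; amplitudes come from the
#' occupancy-weighted superposition.  Intended as the substrate for
#' [refine_2qm()].
#'
#' @param spec a [toy_spec()] (`region_size` is fixed at 5 by the
#'   construction: centre + 3 shared + 1 alternative)
#' @param p occupancy of conformer A, strictly inside (0, 1)
#' @return list with `true`, `start`, `refl`, `region_a`, `region_b`,
#'   `mm_params`, `region_params_a`, `region_params_b`, `spec`
#' @export
make_two_conformer_toy <- function(spec, p = 0.86) {
  if (p <= 0 || p >= 1) stop("occupancy p must lie strictly inside (0, 1)")
  set.seed(spec$seed)
  cell <- unit_cell(spec$cell[1], spec$cell[2], spec$cell[3])
  centre <- c(cell$a, cell$b, cell$c) / 2
  blen <- 2.2
  dirs <- .toy_directions()
  xsh <- rbind(centre, sweep(dirs[1:3, ] * blen, 2, centre, "+"))
  dirA <- dirs[4, ]
  rot <- c(cos(0.5), sin(0.5), 0)
  dirB <- dirA + 0.6 * rot
  dirB <- dirB / sqrt(sum(dirB^2))
  xA <- centre + blen * dirA
  xB <- centre + blen * dirB
  if (sqrt(sum((xA - xB)^2)) < 0.3)
    warning("conformer placements closer than 0.3 A: discrimination degenerate")
  env_el <- rep(c("C", "N", "O"), length.out = spec$n_env)
  xenv <- matrix(0, 0, 3)
  while (nrow(xenv) < spec$n_env) {
    cand <- stats::runif(3) * c(cell$a, cell$b, cell$c)
    alld <- rbind(xsh, xA, xB, xenv)
    if (min(.min_image_dist(cell, cand, alld)) > 2.8) xenv <- rbind(xenv, cand)
  }
  x <- rbind(xsh, xA, xB, xenv)
  qa <- spec$net_charge / 5
  atoms <- data.frame(
    element = c("Fe", "S", "O", "S", "O", "O", env_el),
    atomname = c("FE1", "S2", "O3", "S4", "OL", "OL",
                 paste0(env_el, 6 + seq_len(spec$n_env))),
    resname = c(rep("CLU", 6), rep("ENV", spec$n_env)),
    chain = "A",
    resno = c(rep(1L, 6), 1L + seq_len(spec$n_env)),
    alt = c("", "", "", "", "A", "B", rep("", spec$n_env)),
    x = x[, 1], y = x[, 2], z = x[, 3],
    occ = c(rep(1, 4), p, 1 - p, rep(1, spec$n_env)),
    b = c(rep(8, 6), round(stats::runif(spec$n_env, 8, 15), 2)),
    charge = c(rep(qa, 6), rep(0, spec$n_env)),
    radius = NA_real_,
    stringsAsFactors = FALSE)
  atoms$radius <- cosmo_radii(atoms$element)
  mobile <- c(rep(TRUE, 6), rep(FALSE, spec$n_env))
  true <- structure_model(cell, atoms, mobile = mobile)
  mkparams <- function(lig, x5) {
    ## capped-region indices: 1..4 shared, 5 = alternative ligand
    pr <- t(utils::combn(2:5, 2))
    xs <- rbind(xsh, x5)
    th0 <- sapply(seq_len(nrow(pr)), function(t) {
      v1 <- xs[pr[t, 1], ] - xs[1, ]
      v2 <- xs[pr[t, 2], ] - xs[1, ]
      acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
    })
    restraint_params(
      bonds = data.frame(i = 1L, j = 2:5, r0 = blen, k = 800),
      angles = data.frame(i = pr[, 1], j = 1L, k = pr[, 2],
                          theta0 = th0, ka = 150))
  }
  region_a <- region_selection(c(1:4, 5L))
  region_b <- region_selection(c(1:4, 6L))
  params_a <- mkparams("A", xA)
  params_b <- mkparams("B", xB)
  ## model-indexed restraints: both conformer bonds present
  prm <- t(utils::combn(2:4, 2))
  th0m <- sapply(seq_len(nrow(prm)), function(t) {
    v1 <- xsh[prm[t, 1], ] - xsh[1, ]
    v2 <- xsh[prm[t, 2], ] - xsh[1, ]
    acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  })
  mm_params <- restraint_params(
    bonds = data.frame(i = 1L, j = 2:6, r0 = blen, k = 800),
    angles = data.frame(i = prm[, 1], j = 1L, k = prm[, 2],
                        theta0 = th0m, ka = 150))
  hkl <- .toy_hkl(cell, spec$d_min)
  ftrue <- Mod(calc_structure_factors(true, hkl))
  fobs <- pmax(ftrue * (1 + spec$noise * stats::rnorm(nrow(hkl))),
               0.1 * ftrue)
  sigma <- if (spec$noise > 0) spec$noise * ftrue else 0.01 * ftrue
  free <- stats::runif(nrow(hkl)) < spec$free_frac
  refl <- reflection_set(hkl, fobs, sigma, free)
  start <- true
  if (spec$perturb > 0) {
    idx <- 1:6
    delta <- matrix(stats::rnorm(18), 6, 3)
    delta <- delta * spec$perturb / sqrt(mean(rowSums(delta^2)))
    start <- set_coords(start, coords(true)[idx, ] + delta, idx)
  }
  list(true = true, start = start, refl = refl,
       region_a = region_a, region_b = region_b,
       mm_params = mm_params, region_params_a = params_a,
       region_params_b = params_b, p = p, spec = spec)
}

#' The shipped charged-cluster demo fixture
#'
#' A net-charge -5 five-atom cluster (mimicking a small, highly charged
#' metallocluster active site) in a P1 cell with environment atoms, 1.2 A
#' data and 2% amplitude noise.  The start model is only lightly perturbed
#' (0.05 A), emulating re-refinement of an already deposited structure --
#' the setting in which the gradient-matched `w_A` weight is meaningful.
#' This is the substrate for the dielectric-trend demonstrations: the
#' data record the solvated conformation of the charged cluster, so a
#' vacuum region energy fights the data (high strain, high residual
#' difference density) while a solvated one agrees with them.
#'
#' @param seed integer seed (default 1)
#' @return as [make_toy_crystal()]
#' @export
demo_fixture <- function(seed = 1) {
  make_toy_crystal(toy_spec(net_charge = -5, region_size = 5,
                            d_min = 1.2, noise = 0.02, perturb = 0.05,
                            seed = seed))
}

#' Gaussian-noise density map
#'
#' A map whose samples are i.i.d. standard normal deviates, used to
#' calibrate the RSZD estimator (oversampling factor 1 by construction).
#'
#' @param cell a [unit_cell()]
#' @param dims grid dimensions (length 3)
#' @param seed integer seed
#' @return a `density_map`
#' @export
noise_map <- function(cell, dims = c(24, 24, 24), seed = 1) {
  set.seed(seed)
  rho <- array(stats::rnorm(prod(dims)), dim = dims)
  structure(list(rho = rho, dims = dims, cell = cell,
                 sigma = sqrt(mean(rho^2)), oversample = 1,
                 d_min = NA_real_, includes_free = NA),
            class = "density_map")
}
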