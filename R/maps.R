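#' Difference-density map synthesis
#'
#' Fourier synthesis of difference coefficients
#' `(w_o |Fo| - w_c k |Fc|) exp(i phi_c)` with model phases, on a regular
#' grid (FFT-based; the grid is chosen fine enough that no Miller index
#' aliases).  `weighting = "simple"` uses `w_o = w_c = 1`;
#' `"sigmaa"` uses the figure of merit `m` and `D` from the
#' maximum-likelihood shell estimates.  Free reflections are included in
#' the map (standard practice); the flag is recorded.
#'
#' @param model a [structure_model()]
#' @param refl a [reflection_set()]
#' @param grid_spacing target spacing in Angstrom; must be at most
#'   `d_min / 2.5` (default `d_min / 3`)
#' @param weighting `"simple"` or `"sigmaa"`
#' @return object of class `density_map`: `rho` (3-D array, e/A^3),
#'   `dims`, `cell`, `sigma` (map rms), `oversample` (grid points per
#'   independent datum), `d_min`, `includes_free`
#' @export
difference_map <- function(model, refl, grid_spacing = NULL,
                           weighting = c("simple", "sigmaa")) {
  weighting <- match.arg(weighting)
  cell <- model$cell
  dmin <- min(d_spacing(cell, refl$hkl))
  if (is.null(grid_spacing)) grid_spacing <- dmin / 3
  if (grid_spacing > dmin / 2.5)
    stop(sprintf("grid spacing %.3f A too coarse for d_min = %.3f A (need <= %.3f)",
                 grid_spacing, dmin, dmin / 2.5))
  fc <- calc_structure_factors(model, refl$hkl)
  k <- scale_k(refl, fc)
  phic <- Arg(fc)
  if (weighting == "simple") {
    amp <- refl$fobs - k * Mod(fc)
  } else {
    tv <- target_mlf(model, refl)
    if (is.null(tv$fom)) {
      warning("sigma-A estimates unavailable; using simple weighting")
      amp <- refl$fobs - k * Mod(fc)
    } else {
      amp <- tv$fom * refl$fobs - tv$D_scale * Mod(fc)
    }
  }
  coef <- amp * exp(1i * phic)
  lens <- c(cell$a, cell$b, cell$c)
  hmax <- apply(abs(refl$hkl), 2, max)
  dims <- pmax(ceiling(lens / grid_spacing), 2 * hmax + 2)
  arr <- array(0 + 0i, dim = dims)
  idx <- sweep(refl$hkl, 2, dims, "%%") + 1
  midx <- sweep(-refl$hkl, 2, dims, "%%") + 1
  for (r in seq_along(coef)) {
    arr[idx[r, 1], idx[r, 2], idx[r, 3]] <-
      arr[idx[r, 1], idx[r, 2], idx[r, 3]] + coef[r]
    arr[midx[r, 1], midx[r, 2], midx[r, 3]] <-
      arr[midx[r, 1], midx[r, 2], midx[r, 3]] + Conj(coef[r])
  }
  rho <- Re(stats::fft(arr)) / cell$volume
  structure(list(rho = rho, dims = dims, cell = cell,
                 sigma = sqrt(mean(rho^2)),
                 oversample = max(1, prod(dims) / (2 * nrow(refl$hkl))),
                 d_min = dmin, includes_free = TRUE),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("density map %d x %d x %d, sigma = %.4g, d_min = %.2f A\n",
              x$dims[1], x$dims[2], x$dims[3], x$sigma, x$d_min))
  invisible(x)
}

#' Write/read a CCP4-format map (binary mode 2)
#'
#' Minimal writer for visual inspection in standard crystallographic
#' viewers; axis order is x fastest, space group P1.
#'
#' @param map a [difference_map()] result
#' @param path output file
#' @export
write_ccp4 <- function(map, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  d <- map$dims
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)            # NC NR NS
  wi(2)            # MODE float32
  wi(c(0, 0, 0))   # start
  wi(d)            # sampling intervals
  wf(c(map$cell$a, map$cell$b, map$cell$c,
       map$cell$alpha, map$cell$beta, map$cell$gamma))
  wi(c(1, 2, 3))   # axis order
  wf(c(min(map$rho), max(map$rho), mean(map$rho)))
  wi(1)            # ISPG
  wi(0)            # NSYMBT
  wi(rep(0, 25))   # extra
  wi(c(0, 0, 0))   # origin
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)  # little-endian stamp
  wf(map$sigma)
  wi(0)            # NLABL
  writeBin(raw(200 * 4), con)
  wf(as.numeric(map$rho))
  invisible(path)
}

#' @rdname write_ccp4
#' @return for `read_ccp4`, a `density_map` (sigma recomputed; oversample
#'   unknown, set to 1)
#' @export
read_ccp4 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  if (mode != 2) stop("only mode-2 (float32) maps supported")
  ri(3); ri(3)
  cellpar <- rf(6)
  seek(con, 1024)
  rho <- array(rf(prod(d)), dim = d)
  structure(list(rho = rho, dims = d,
                 cell = unit_cell(cellpar[1], cellpar[2], cellpar[3],
                                  cellpar[4], cellpar[5], cellpar[6]),
                 sigma = sqrt(mean(rho^2)), oversample = 1,
                 d_min = NA_real_, includes_free = NA),
            class = "density_map")
}

#' Per-residue real-space difference-density Z scores
#'
#' For each validation group `(chain, resno, alt)`: collect the grid
#' points within `mask_radius` of the group's atoms (minimum-image
#' convention), sum the positive and negative density separately in units
#' of the map sigma, and convert each sum to a Z score against its
#' pure-noise expectation, accounting for real-space correlation through
#' the map oversampling factor:
#'
#'   Z+/- = max(0, (S+/- - n phi(0)) / sqrt((1/2 - phi(0)^2) n * os))
#'
#' where `n` is the masked point count and `os` the oversampling factor.
#' `RSZD = max(|Z+|, |Z-|)`.  This is an EDSTATS-inspired estimator, not
#' bit-compatible with it; it is calibrated so that pure noise gives
#' RSZD of order 0-1 while gross local defects exceed 3, the conventional
#' quality threshold.
#'
#' @param map a [difference_map()] result (same cell as the model)
#' @param model a [structure_model()]
#' @param residues optional data frame `chain, resno, alt` restricting the
#'   report (default: every group in the model)
#' @param mask_radius Angstrom (default 1.5)
#' @return data frame `chain, resno, alt, resname, n_points, rszd_pos,
#'   rszd_neg, rszd`
#' @export
rszd <- function(map, model, residues = NULL, mask_radius = 1.5) {
  a <- model$atoms
  grp <- unique(a[, c("chain", "resno", "alt")])
  if (!is.null(residues))
    grp <- merge(grp, residues[, intersect(names(residues),
                                           c("chain", "resno", "alt"))])
  d <- map$dims
  gx <- (seq_len(d[1]) - 1) / d[1]
  gy <- (seq_len(d[2]) - 1) / d[2]
  gz <- (seq_len(d[3]) - 1) / d[3]
  grid_frac <- cbind(rep(gx, times = d[2] * d[3]),
                     rep(rep(gy, each = d[1]), times = d[3]),
                     rep(gz, each = d[1] * d[2]))
  f2c <- model$cell$frac2cart
  rho <- as.numeric(map$rho)
  sig <- map$sigma
  os <- max(1, map$oversample)
  mu1 <- stats::dnorm(0)                 # E[max(Z,0)] per point
  v1 <- 0.5 - mu1^2                      # Var[max(Z,0)] per point
  out <- list()
  for (g in seq_len(nrow(grp))) {
    sel <- a$chain == grp$chain[g] & a$resno == grp$resno[g] &
      a$alt == grp$alt[g]
    if (!any(sel)) next
    af <- t(model$cell$cart2frac %*% t(coords(model)[sel, , drop = FALSE]))
    inmask <- rep(FALSE, nrow(grid_frac))
    for (i in seq_len(nrow(af))) {
      df <- sweep(grid_frac, 2, af[i, ])
      df <- df - round(df)               # minimum image
      dc <- df %*% t(f2c)
      inmask <- inmask | rowSums(dc^2) <= mask_radius^2
    }
    n <- sum(inmask)
    if (n == 0 || sig < 1e-12) {
      zp <- zn <- 0
    } else {
      r <- rho[inmask] / sig
      splus <- sum(r[r > 0])
      sminus <- -sum(r[r < 0])
      s0 <- sqrt(v1 * n * os)
      zp <- max(0, (splus - mu1 * n) / s0)
      zn <- max(0, (sminus - mu1 * n) / s0)
    }
    out[[g]] <- data.frame(
      chain = grp$chain[g], resno = grp$resno[g], alt = grp$alt[g],
      resname = a$resname[sel][1], n_points = n,
      rszd_pos = zp, rszd_neg = zn, rszd = max(abs(zp), abs(zn)))
  }
  do.call(rbind, out)
}

#' Strain energy of the refined region
#'
#' The region-energy difference between the crystallographically refined
#' geometry and the freely optimized one (no X-ray term, no environment
#' restraints), both evaluated as single points at the same dielectric
#' constant and settings, starting the free optimization from the refined
#' geometry.  Non-negative (within optimizer tolerance) for any converged
#' refinement.
#'
#' @param model refined [structure_model()]
#' @param region a [region_selection()]
#' @param config a [refinement_config()] (uses `region_params`, `epsilon`,
#'   `lj`, convergence settings)
#' @return list with `strain` (kJ/mol), `e_refined`, `e_free`,
#'   `free_model`
#' @export
strain_energy <- function(model, region, config) {
  e_ref <- .region_term(model, region, config)$energy
  free <- .optimize_region(model, region, config)
  if (!free$converged)
    stop("free region optimization did not converge; trace:\n",
         paste(utils::capture.output(print(utils::tail(free$trace, 3))),
               collapse = "\n"))
  e_free <- .region_term(free$model, region, config)$energy
  list(strain = e_ref - e_free, e_refined = e_ref, e_free = e_free,
       free_model = free$model)
}

## free (data-less) optimization of the region energy over region atoms
.optimize_region <- function(model, region, config) {
  m <- model
  m$mobile <- rep(FALSE, n_atoms(m))
  m$mobile[region$indices] <- TRUE
  efun <- function(mm, fixed) {
    qt <- .region_term(mm, region, config, cavity = fixed$cavity)
    g <- qt$grad
    g[!mm$mobile, ] <- 0
    .new_target(qt$energy, g, extra = list(e_qm1 = qt$energy))
  }
  ctxfun <- function(mm) {
    if (config$epsilon > 1)
      list(cavity = .region_term(mm, region, config)$result$cavity)
    else list()
  }
  .cycle_minimize(m, efun, ctxfun, which(m$mobile), config,
                  project_rigid = TRUE)
}

#' Dielectric-constant grid
#'
#' The scan scheme used for solvation studies: steps of 1 between 1 and
#' 20, then steps of 5 between 20 and 80, i.e. 32 values in total.
#'
#' @return integer vector of dielectric constants
#' @export
eps_grid_default <- function() c(1:20, seq(25, 80, by = 5))

#' Dielectric-constant scan
#'
#' For each dielectric constant: full coordinate refinement, ADP stage,
#' difference map, per-residue RSZD over the region's validation groups,
#' and strain energy.  Every row starts from the same input model; a
#' failing value marks its row failed and the scan continues.
#'
#' @param model starting [structure_model()]
#' @param region a [region_selection()]
#' @param refl a [reflection_set()]
#' @param config a [refinement_config()] (its `epsilon` is overridden by
#'   the grid)
#' @param eps_grid dielectric constants (default [eps_grid_default()])
#' @param adp run the post-refinement ADP stage (default TRUE)
#' @return data frame with one row per epsilon: `eps, sum_rszd, strain,
#'   r_work, r_free, failed`, with the per-residue RSZD tables in
#'   `attr(, "residues")`
#' @export
dielectric_scan <- function(model, region, refl, config,
                            eps_grid = eps_grid_default(), adp = TRUE) {
  region_groups <- unique(model$atoms[region$indices,
                                      c("chain", "resno", "alt")])
  rows <- list(); pertab <- list()
  for (e in eps_grid) {
    cfg <- config
    cfg$epsilon <- e
    row <- tryCatch({
      ref <- refine_coordinates(model, region, refl, cfg)
      cfg$w_A <- ref$w_A
      m2 <- if (adp) refine_adps(ref$model, refl, cfg)$model else ref$model
      map <- difference_map(m2, refl)
      zt <- rszd(map, m2, residues = region_groups)
      st <- strain_energy(m2, region, cfg)
      last <- ref$trace[nrow(ref$trace), ]
      pertab[[as.character(e)]] <- cbind(eps = e, zt)
      data.frame(eps = e, sum_rszd = sum(zt$rszd), strain = st$strain,
                 r_work = last$r_work, r_free = last$r_free, failed = FALSE)
    }, error = function(err) {
      warning("scan failed at eps = ", e, ": ", conditionMessage(err))
      data.frame(eps = e, sum_rszd = NA_real_, strain = NA_real_,
                 r_work = NA_real_, r_free = NA_real_, failed = TRUE)
    })
    rows[[as.character(e)]] <- row
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "residues") <- do.call(rbind, c(pertab, list(make.row.names = FALSE)))
  out
}
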