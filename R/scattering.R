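#' Atomic scattering factor table
#'
#' Published 4-Gaussian independent-atom coefficients,
#' `f(s) = sum_i a_i exp(-b_i s^2) + c` with `s = sin(theta)/lambda` in
#' 1/Angstrom, shipped as plain-text package data.  At `s = 0`, `f` equals
#' the atomic electron count to within 2%.
#'
#' @return matrix with rownames = element symbols and columns
#'   `a1..a4, b1..b4, c`
#' @export
form_factor_table <- function() {
  if (!is.null(.qr$ff_table)) return(.qr$ff_table)
  path <- system.file("extdata", "form_factors.txt", package = "qrlite")
  tb <- utils::read.table(path, comment.char = "#",
                          col.names = c("element", paste0("a", 1:4),
                                        paste0("b", 1:4), "c"))
  m <- as.matrix(tb[, -1])
  rownames(m) <- tb$element
  .qr$ff_table <- m
  m
}

## f(s) for a vector of s^2 values; el is a single element symbol
.ff_eval <- function(el, s2) {
  tab <- form_factor_table()
  if (!el %in% rownames(tab))
    stop("no scattering factors for element '", el, "'")
  p <- tab[el, ]
  p["a1"] * exp(-p["b1"] * s2) + p["a2"] * exp(-p["b2"] * s2) +
    p["a3"] * exp(-p["b3"] * s2) + p["a4"] * exp(-p["b4"] * s2) + p["c"]
}

## Core structure-factor engine (direct summation over atoms and symmetry
## operators).  Returns the complex F vector plus, when need_grad, the
## per-operator phase matrices needed for adjoint gradients.
##   F(h) = sum_ops sum_j occ_j f_j(s) exp(-B_j s^2) exp(2 pi i h.(R x_j + t))
## with s = sin(theta)/lambda = 1/(2 d_h).
.sf_engine <- function(model, hkl, need_grad = FALSE,
                       subset = seq_len(n_atoms(model))) {
  hkl <- matrix(as.integer(hkl), ncol = 3)
  a <- model$atoms[subset, , drop = FALSE]
  n <- nrow(a); m <- nrow(hkl)
  g <- hkl %*% model$cell$cart2frac
  s2 <- rowSums(g^2) / 4                       # (1/2d)^2
  cmat <- matrix(0, m, n)
  for (el in unique(a$element)) {
    j <- which(a$element == el)
    fv <- .ff_eval(el, s2)
    cmat[, j] <- fv
  }
  dw <- exp(-outer(s2, a$b))                   # m x n Debye-Waller
  cmat <- cmat * dw * rep(a$occ, each = m)
  xf <- t(model$cell$cart2frac %*% t(as.matrix(a[, c("x", "y", "z")])))
  A <- numeric(m); B <- numeric(m)
  phis <- if (need_grad) vector("list", n_ops(model$ops)) else NULL
  for (io in seq_len(n_ops(model$ops))) {
    R <- model$ops$rotations[[io]]; tt <- model$ops$translations[[io]]
    phi <- 2 * pi * (hkl %*% R %*% t(xf) +
                     as.numeric(hkl %*% R %*% tt))
    A <- A + rowSums(cmat * cos(phi))
    B <- B + rowSums(cmat * sin(phi))
    if (need_grad) phis[[io]] <- phi
  }
  list(F = complex(real = A, imaginary = B), A = A, B = B,
       cmat = cmat, s2 = s2, hkl = hkl, phis = phis, subset = subset)
}

#' Structure factors of a model
#'
#' Independent-atom direct summation with isotropic Debye-Waller factors,
#' `exp(-B s^2)` with `s = 1/(2d)`, over all atoms and symmetry operators.
#'
#' @param model a [structure_model()]
#' @param hkl n x 3 integer matrix of Miller indices
#' @return complex vector of structure factors, one per reflection
#' @export
calc_structure_factors <- function(model, hkl) {
  .sf_engine(model, hkl)$F
}

## Adjoint coordinate gradient: given tvec = dE/d|Fc| (per reflection),
## return the n_subset x 3 matrix dE/dx.  Frozen-atom zeroing is the
## caller's responsibility.
.sf_coord_grad <- function(sf, model, tvec) {
  Fa <- pmax(Mod(sf$F), 1e-30)
  n <- ncol(sf$cmat)
  gr <- matrix(0, n, 3)
  for (io in seq_along(sf$phis)) {
    R <- model$ops$rotations[[io]]
    G <- 2 * pi * (sf$hkl %*% R) %*% model$cell$cart2frac  # m x 3: dphi/dx
    phi <- sf$phis[[io]]
    P <- (tvec / Fa) * sf$cmat * (sf$B * cos(phi) - sf$A * sin(phi))
    gr <- gr + t(P) %*% G
  }
  gr
}

## Adjoint B-factor gradient: dE/dB per atom in the subset.
.sf_b_grad <- function(sf, model, tvec) {
  Fa <- pmax(Mod(sf$F), 1e-30)
  n <- ncol(sf$cmat)
  gb <- numeric(n)
  for (io in seq_along(sf$phis)) {
    phi <- sf$phis[[io]]
    Q <- (tvec / Fa) * (-sf$s2) * sf$cmat * (sf$A * cos(phi) + sf$B * sin(phi))
    gb <- gb + colSums(Q)
  }
  gb
}

#' Least-squares scale factor
#'
#' The scalar `k` minimizing `sum (|Fo| - k |Fc|)^2` over the working set:
#' `k = sum |Fo||Fc| / sum |Fc|^2`.
#'
#' @param refl a [reflection_set()]
#' @param fcalc complex or numeric calculated structure factors matching
#'   `refl` row for row
#' @return scalar scale factor
#' @export
scale_k <- function(refl, fcalc) {
  w <- !refl$free
  if (!any(w)) stop("empty working set")
  fc <- Mod(fcalc)[w]
  sum(refl$fobs[w] * fc) / sum(fc^2)
}

#' R factors
#'
#' `R = sum ||Fo| - k |Fc|| / sum |Fo|` over the working and free sets,
#' with `k` computed on the working set only and applied to both.
#'
#' @inheritParams scale_k
#' @return list with `r_work`, `r_free` (NA when the free set is empty)
#'   and `k`
#' @export
r_factors <- function(refl, fcalc) {
  k <- scale_k(refl, fcalc)
  fc <- k * Mod(fcalc)
  rfac <- function(sel) {
    if (!any(sel)) return(NA_real_)
    sum(abs(refl$fobs[sel] - fc[sel])) / sum(refl$fobs[sel])
  }
  list(r_work = rfac(!refl$free), r_free = rfac(refl$free), k = k)
}

.new_target <- function(energy, grad, bgrad = NULL, extra = list()) {
  structure(c(list(energy = energy, grad = grad, bgrad = bgrad), extra),
            class = "target_value")
}

#' @export
print.target_value <- function(x, ...) {
  cat(sprintf("target value: E = %.6g, max |grad| = %.3g\n",
              x$energy, if (length(x$grad)) max(abs(x$grad)) else 0))
  invisible(x)
}

#' Least-squares amplitude target
#'
#' `E = sum_work w_h (|Fo| - k |Fc|)^2` with `w_h = 1 / sigma_h^2` and the
#' working-set scale `k` of [scale_k()].  The coordinate gradient is
#' analytic and includes the chain rule through both `F` and `k`; free-set
#' reflections contribute nothing to energy or gradient, and frozen atoms
#' receive exactly zero gradient.
#'
#' @param model a [structure_model()]
#' @param refl a [reflection_set()]
#' @param need_bgrad also compute the per-atom B-factor gradient
#' @return a `target_value`: `energy`, `grad` (n x 3), optional `bgrad`,
#'   plus `fcalc`, `k`, `r_work`, `r_free`
#' @export
target_lsq <- function(model, refl, need_bgrad = FALSE) {
  sf <- .sf_engine(model, refl$hkl, need_grad = TRUE)
  fc <- Mod(sf$F)
  wk <- !refl$free
  k <- sum(refl$fobs[wk] * fc[wk]) / sum(fc[wk]^2)
  w <- 1 / refl$sigma^2
  resid <- refl$fobs - k * fc
  E <- sum(w[wk] * resid[wk]^2)
  ## dE/d|Fc|_j = -2 w_j k resid_j [work]  +  (dk/d|Fc|_j) * sum_w -2 w resid |Fc|
  S1 <- sum(refl$fobs[wk] * fc[wk]); S2 <- sum(fc[wk]^2)
  dEdk <- sum(-2 * w[wk] * resid[wk] * fc[wk])
  dkdf <- numeric(length(fc))
  dkdf[wk] <- (refl$fobs[wk] * S2 - 2 * fc[wk] * S1) / S2^2
  tvec <- numeric(length(fc))
  tvec[wk] <- -2 * w[wk] * k * resid[wk]
  tvec <- tvec + dEdk * dkdf
  gr <- .sf_coord_grad(sf, model, tvec)
  gr[!model$mobile, ] <- 0
  bg <- NULL
  if (need_bgrad) {
    bg <- .sf_b_grad(sf, model, tvec)
    bg[!model$mobile] <- 0
  }
  rr <- r_factors(refl, sf$F)
  .new_target(E, gr, bg,
              list(fcalc = sf$F, k = k, r_work = rr$r_work, r_free = rr$r_free))
}

#' Estimate maximum-likelihood shell parameters
#'
#' Partitions reflections into resolution shells (working count >= 20 per
#' shell, >= 3 shells) and estimates, per shell, the mean-square observed
#' and scaled-calculated amplitudes and `sigma_A` by moment matching
#' (`sigma_A = <Eo Ec>` on normalized amplitudes, clamped to
#' \[0.05, 0.999\]).  The returned object freezes `k`, the shell
#' normalizations and `sigma_A`, so that [target_mlf()] is a smooth
#' function of the coordinates; refinement re-estimates it every cycle.
#'
#' @param model a [structure_model()]
#' @param refl a [reflection_set()]
#' @param nshells requested number of resolution shells
#' @return object of class `mlf_params`, or `NULL` when the shell
#'   population is insufficient (callers then fall back to [target_lsq()])
#' @export
estimate_mlf_params <- function(model, refl, nshells = 8) {
  fc <- Mod(calc_structure_factors(model, refl$hkl))
  wk <- !refl$free
  k <- sum(refl$fobs[wk] * fc[wk]) / sum(fc[wk]^2)
  s2 <- 1 / d_spacing(model$cell, refl$hkl)^2
  if (any(!is.finite(s2))) stop("unsortable resolutions")
  ns <- nshells
  repeat {
    if (ns < 3) return(NULL)
    br <- stats::quantile(s2[wk], probs = seq(0, 1, length.out = ns + 1))
    br[1] <- -Inf; br[length(br)] <- Inf
    shell <- cut(s2, br, labels = FALSE)
    if (min(table(shell[wk])) >= 20) break
    ns <- ns - 1
  }
  So <- Sc <- sA <- numeric(ns)
  for (i in seq_len(ns)) {
    sel <- wk & shell == i
    So[i] <- mean(refl$fobs[sel]^2)
    Sc[i] <- mean((k * fc[sel])^2)
    eo <- refl$fobs[sel] / sqrt(So[i])
    ec <- k * fc[sel] / sqrt(Sc[i])
    sA[i] <- min(0.999, max(0.05, mean(eo * ec)))
  }
  structure(list(k = k, shell = shell, nshells = ns,
                 So = So, Sc = Sc, sigmaA = sA),
            class = "mlf_params")
}

#' Maximum-likelihood amplitude target (acentric Rice likelihood)
#'
#' Negative log-likelihood of the observed amplitudes under the acentric
#' Rice (Luzzati) model with per-shell `sigma_A` from moment matching, on
#' normalized amplitudes `Eo = |Fo|/sqrt(<Fo^2>)`,
#' `Ec = k|Fc|/sqrt(<(k Fc)^2>)`:
#'
#'   -log p = -log(2 Eo / e) + (Eo^2 + sA^2 Ec^2)/e - log I0(2 Eo sA Ec / e)
#'
#' with `e = 1 - sA^2`.  Shell parameters are held fixed during gradient
#' evaluation (see [estimate_mlf_params()]); when they cannot be estimated
#' the target falls back to [target_lsq()] with a warning.
#'
#' @inheritParams target_lsq
#' @param nshells resolution shells for the sigma-A estimate
#' @param params optional precomputed [estimate_mlf_params()] object
#' @return a `target_value` (as [target_lsq()]), plus `mlf_params`
#' @export
target_mlf <- function(model, refl, nshells = 8, params = NULL,
                       need_bgrad = FALSE) {
  if (is.null(params)) params <- estimate_mlf_params(model, refl, nshells)
  if (is.null(params)) {
    warning("insufficient shell population for mlf; falling back to lsq")
    return(target_lsq(model, refl, need_bgrad = need_bgrad))
  }
  sf <- .sf_engine(model, refl$hkl, need_grad = TRUE)
  fc <- Mod(sf$F)
  wk <- !refl$free
  sh <- params$shell
  sA <- params$sigmaA[sh]
  eps <- 1 - sA^2
  Eo <- refl$fobs / sqrt(params$So[sh])
  Ec <- params$k * fc / sqrt(params$Sc[sh])
  x <- 2 * Eo * sA * Ec / eps
  logI0 <- log(besselI(x, 0, expon.scaled = TRUE)) + x
  nll <- -log(2 * Eo / eps) + (Eo^2 + sA^2 * Ec^2) / eps - logI0
  E <- sum(nll[wk])
  ratio <- besselI(x, 1, expon.scaled = TRUE) /
           besselI(x, 0, expon.scaled = TRUE)
  dEc <- 2 * sA^2 * Ec / eps - (2 * Eo * sA / eps) * ratio
  tvec <- numeric(length(fc))
  tvec[wk] <- dEc[wk] * params$k / sqrt(params$Sc[sh[wk]])
  gr <- .sf_coord_grad(sf, model, tvec)
  gr[!model$mobile, ] <- 0
  bg <- NULL
  if (need_bgrad) {
    bg <- .sf_b_grad(sf, model, tvec)
    bg[!model$mobile] <- 0
  }
  rr <- r_factors(refl, sf$F)
  .new_target(E, gr, bg,
              list(fcalc = sf$F, k = rr$k, r_work = rr$r_work,
                   r_free = rr$r_free, mlf_params = params,
                   fom = ratio, D_scale = sA * sqrt(params$So[sh] / params$Sc[sh]) * params$k))
}

#' Automatic X-ray weight by gradient-norm matching
#'
#' `w_A = rms(grad E_restraints) / rms(grad E_Xray)` over the mobile atoms
#' at the current model, so that the two terms initially pull with
#' comparable force.  An explicit user-supplied `w_A` always overrides.
#'
#' @param model a [structure_model()]
#' @param refl a [reflection_set()]
#' @param params a [restraint_params()] for the restraint gradient
#' @param target `"lsq"` or `"mlf"`
#' @return scalar weight
#' @export
auto_wA <- function(model, refl, params, target = c("lsq", "mlf")) {
  target <- match.arg(target)
  tx <- if (target == "lsq") target_lsq(model, refl)
        else target_mlf(model, refl)
  tm <- mm_energy(model, params)
  mob <- model$mobile
  rms <- function(g) sqrt(mean(g[mob, , drop = FALSE]^2))
  gx <- rms(tx$grad)
  if (gx < 1e-12)
    stop("X-ray gradient norm is zero at the current model; ",
         "perturb the starting coordinates before calling auto_wA")
  rms(tm$grad) / gx
}
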