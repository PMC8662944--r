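#' Restraint parameters
#'
#' Empirical (molecular-mechanics) restraints: harmonic bonds and angles,
#' optional cosine torsions and a one-sided quadratic nonbonded repulsion.
#' Electrostatics are deliberately absent from the restraints; charged
#' interactions belong to the region energy.
#'
#' Atoms are referenced by index into the model's atom table.
#'
#' @param bonds data frame `i, j, r0, k` (r0 in Angstrom > 0, k in
#'   energy/A^2 >= 0)
#' @param angles data frame `i, j, k, theta0, ka` (theta0 in degrees in
#'   (0, 180\], ka in energy/rad^2 >= 0)
#' @param torsions data frame `i, j, k, l, n, phase, kt` (periodicity `n`,
#'   phase in degrees, kt >= 0); energy `kt * (1 + cos(n*phi - phase))`
#' @param repulsion data frame `i, j, d0, krep`: energy
#'   `krep * (d0 - r)^2` for `r < d0`, else 0
#' @return object of class `restraint_params`
#' @export
restraint_params <- function(bonds = NULL, angles = NULL, torsions = NULL,
                             repulsion = NULL) {
  empty <- function(cols) {
    df <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    df
  }
  if (is.null(bonds)) bonds <- empty(c("i", "j", "r0", "k"))
  if (is.null(angles)) angles <- empty(c("i", "j", "k", "theta0", "ka"))
  if (is.null(torsions)) torsions <- empty(c("i", "j", "k", "l", "n", "phase", "kt"))
  if (is.null(repulsion)) repulsion <- empty(c("i", "j", "d0", "krep"))
  if (nrow(bonds) && (any(bonds$k < 0) || any(bonds$r0 <= 0)))
    stop("bond force constants must be >= 0 and r0 > 0")
  if (nrow(angles) && (any(angles$ka < 0) ||
                       any(angles$theta0 <= 0 | angles$theta0 > 180)))
    stop("angle force constants must be >= 0 and theta0 in (0, 180]")
  if (nrow(torsions) && any(torsions$kt < 0))
    stop("torsion force constants must be >= 0")
  if (nrow(repulsion) && any(repulsion$krep < 0))
    stop("repulsion force constants must be >= 0")
  structure(list(bonds = bonds, angles = angles, torsions = torsions,
                 repulsion = repulsion),
            class = "restraint_params")
}

#' @export
print.restraint_params <- function(x, ...) {
  cat(sprintf("restraints: %d bonds, %d angles, %d torsions, %d repulsions\n",
              nrow(x$bonds), nrow(x$angles), nrow(x$torsions),
              nrow(x$repulsion)))
  invisible(x)
}

#' Total number of restraint terms
#' @param params a [restraint_params()]
#' @export
n_terms <- function(params) {
  nrow(params$bonds) + nrow(params$angles) + nrow(params$torsions) +
    nrow(params$repulsion)
}

.check_term_atoms <- function(params, natom) {
  chk <- function(df, cols, what) {
    if (!nrow(df)) return(invisible())
    idx <- unlist(df[cols])
    bad <- which(idx < 1 | idx > natom)
    if (length(bad))
      stop(what, " restraint references missing atom (term ",
           ((bad[1] - 1) %% nrow(df)) + 1, ")")
  }
  chk(params$bonds, c("i", "j"), "bond")
  chk(params$angles, c("i", "j", "k"), "angle")
  chk(params$torsions, c("i", "j", "k", "l"), "torsion")
  chk(params$repulsion, c("i", "j"), "repulsion")
}

#' Molecular-mechanics restraint energy
#'
#' `E_MM = sum k_b (r - r0)^2 + sum k_a (theta - theta0)^2 + torsions +
#' one-sided repulsion`, with analytic Cartesian gradients.  With
#' `region`, only the terms whose atoms all lie inside system 1 are
#' summed -- this is the `E_MM1` subtracted in the combined refinement
#' energy to avoid double counting (link atoms are not model atoms and
#' never appear in restraint terms).
#'
#' @param model a [structure_model()]
#' @param params a [restraint_params()]
#' @param region optional [region_selection()]; when given, restrict to
#'   region-internal terms (E_MM1)
#' @return a `target_value` with `energy` and `grad` (n x 3, all atoms;
#'   no frozen-atom zeroing here since E_MM also restrains the boundary)
#' @export
mm_energy <- function(model, params, region = NULL) {
  x <- coords(model)
  n <- nrow(x)
  .check_term_atoms(params, n)
  inside <- rep(TRUE, n)
  if (!is.null(region)) {
    inside <- rep(FALSE, n)
    inside[region$indices] <- TRUE
  }
  E <- 0
  gr <- matrix(0, n, 3)
  b <- params$bonds
  if (nrow(b)) {
    keep <- inside[b$i] & inside[b$j]
    b <- b[keep, , drop = FALSE]
    if (nrow(b)) {
      dv <- x[b$i, , drop = FALSE] - x[b$j, , drop = FALSE]
      r <- sqrt(rowSums(dv^2))
      E <- E + sum(b$k * (r - b$r0)^2)
      f <- 2 * b$k * (r - b$r0) / r
      for (c in 1:3) {
        gr[, c] <- gr[, c] + .acc(n, b$i, f * dv[, c]) - .acc(n, b$j, f * dv[, c])
      }
    }
  }
  a <- params$angles
  if (nrow(a)) {
    keep <- inside[a$i] & inside[a$j] & inside[a$k]
    a <- a[keep, , drop = FALSE]
    if (nrow(a)) {
      r1 <- x[a$i, , drop = FALSE] - x[a$j, , drop = FALSE]
      r2 <- x[a$k, , drop = FALSE] - x[a$j, , drop = FALSE]
      n1 <- sqrt(rowSums(r1^2)); n2 <- sqrt(rowSums(r2^2))
      ct <- pmin(1 - 1e-12, pmax(-1 + 1e-12, rowSums(r1 * r2) / (n1 * n2)))
      th <- acos(ct)
      th0 <- a$theta0 * pi / 180
      E <- E + sum(a$ka * (th - th0)^2)
      ## dE/dtheta, dtheta/dcos = -1/sin
      pref <- 2 * a$ka * (th - th0) * (-1 / sqrt(1 - ct^2))
      di <- (r2 / (n1 * n2) - r1 * ct / n1^2)
      dk <- (r1 / (n1 * n2) - r2 * ct / n2^2)
      for (c in 1:3) {
        gr[, c] <- gr[, c] + .acc(n, a$i, pref * di[, c]) +
          .acc(n, a$k, pref * dk[, c]) -
          .acc(n, a$j, pref * (di[, c] + dk[, c]))
      }
    }
  }
  tq <- params$torsions
  if (nrow(tq)) {
    keep <- inside[tq$i] & inside[tq$j] & inside[tq$k] & inside[tq$l]
    tq <- tq[keep, , drop = FALSE]
    for (t in seq_len(nrow(tq))) {
      res <- .torsion_term(x, tq$i[t], tq$j[t], tq$k[t], tq$l[t],
                           tq$n[t], tq$phase[t] * pi / 180, tq$kt[t])
      E <- E + res$E
      gr <- gr + res$gr
    }
  }
  rp <- params$repulsion
  if (nrow(rp)) {
    keep <- inside[rp$i] & inside[rp$j]
    rp <- rp[keep, , drop = FALSE]
    if (nrow(rp)) {
      dv <- x[rp$i, , drop = FALSE] - x[rp$j, , drop = FALSE]
      r <- sqrt(rowSums(dv^2))
      act <- r < rp$d0
      if (any(act)) {
        rpa <- rp[act, , drop = FALSE]
        ra <- r[act]; dva <- dv[act, , drop = FALSE]
        E <- E + sum(rpa$krep * (rpa$d0 - ra)^2)
        f <- -2 * rpa$krep * (rpa$d0 - ra) / ra
        for (c in 1:3) {
          gr[, c] <- gr[, c] + .acc(n, rpa$i, f * dva[, c]) -
            .acc(n, rpa$j, f * dva[, c])
        }
      }
    }
  }
  .new_target(E, gr)
}

## scatter-add: sum vals into a length-n vector at idx
.acc <- function(n, idx, vals) {
  out <- numeric(n)
  s <- tapply(vals, idx, sum)
  out[as.integer(names(s))] <- s
  out
}

## single cosine torsion term E = kt * (1 + cos(n phi - phase)), with
## gradient by the standard four-point formula
.torsion_term <- function(x, i, j, k, l, nper, phase, kt) {
  b1 <- x[j, ] - x[i, ]; b2 <- x[k, ] - x[j, ]; b3 <- x[l, ] - x[k, ]
  c1 <- .cross(b1, b2); c2 <- .cross(b2, b3)
  nb2 <- sqrt(sum(b2^2))
  phi <- atan2(sum(.cross(c1, c2) * b2) / nb2, sum(c1 * c2))
  E <- kt * (1 + cos(nper * phi - phase))
  dEdphi <- -kt * nper * sin(nper * phi - phase)
  ## dphi/dr by the standard four-point decomposition
  g1 <- -dEdphi * nb2 / sum(c1^2) * c1
  g4 <- dEdphi * nb2 / sum(c2^2) * c2
  t1 <- sum(b1 * b2) / nb2^2
  t3 <- sum(b3 * b2) / nb2^2
  g2 <- -(1 + t1) * g1 + t3 * g4
  g3 <- t1 * g1 - (1 + t3) * g4
  grm <- matrix(0, nrow(x), 3)
  grm[i, ] <- g1; grm[j, ] <- g2; grm[k, ] <- g3; grm[l, ] <- g4
  list(E = E, gr = grm, phi = phi)
}

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Read/write restraint parameter files
#'
#' Line-oriented text format, atoms referenced by `resname atomname`
#' (resolved against a model when loading):
#' \preformatted{
#' BOND resA atomA resB atomB r0 k
#' ANGL resA atomA resB atomB resC atomC theta0 ka
#' TORS resA atomA ... resD atomD n phase kt
#' REPU resA atomA resB atomB d0 krep
#' }
#' Duplicate term definitions: last wins, with a warning.
#'
#' @param path parameter file
#' @param model a [structure_model()] used to resolve `(resname, atomname)`
#'   pairs to atom indices (first match)
#' @return a [restraint_params()]
#' @export
load_params <- function(path, model) {
  ln <- readLines(path, warn = FALSE)
  ln <- trimws(ln)
  ln <- ln[ln != "" & !startsWith(ln, "#")]
  key <- paste(model$atoms$resname, model$atoms$atomname)
  find <- function(res, at) {
    i <- match(paste(res, at), key)
    if (is.na(i)) stop("restraint references unknown atom ", res, " ", at)
    i
  }
  bonds <- list(); angles <- list(); torsions <- list(); repul <- list()
  for (s in ln) {
    f <- strsplit(s, "\\s+")[[1]]
    kind <- toupper(f[1])
    if (kind == "BOND") {
      v <- as.numeric(f[6:7])
      if (v[2] < 0) stop("negative force constant in: ", s)
      bonds[[paste(f[2:5], collapse = " ")]] <-
        data.frame(i = find(f[2], f[3]), j = find(f[4], f[5]),
                   r0 = v[1], k = v[2])
    } else if (kind == "ANGL") {
      v <- as.numeric(f[8:9])
      if (v[2] < 0) stop("negative force constant in: ", s)
      angles[[paste(f[2:7], collapse = " ")]] <-
        data.frame(i = find(f[2], f[3]), j = find(f[4], f[5]),
                   k = find(f[6], f[7]), theta0 = v[1], ka = v[2])
    } else if (kind == "TORS") {
      v <- as.numeric(f[10:12])
      if (v[3] < 0) stop("negative force constant in: ", s)
      torsions[[paste(f[2:9], collapse = " ")]] <-
        data.frame(i = find(f[2], f[3]), j = find(f[4], f[5]),
                   k = find(f[6], f[7]), l = find(f[8], f[9]),
                   n = v[1], phase = v[2], kt = v[3])
    } else if (kind == "REPU") {
      v <- as.numeric(f[6:7])
      if (v[2] < 0) stop("negative force constant in: ", s)
      repul[[paste(f[2:5], collapse = " ")]] <-
        data.frame(i = find(f[2], f[3]), j = find(f[4], f[5]),
                   d0 = v[1], krep = v[2])
    } else {
      stop("unknown restraint record: ", kind)
    }
  }
  nlines <- sum(grepl("^(BOND|ANGL|TORS|REPU)", toupper(ln)))
  nkept <- length(bonds) + length(angles) + length(torsions) + length(repul)
  if (nkept < nlines)
    warning("duplicate restraint definitions: last occurrence wins")
  bind <- function(lst) if (length(lst)) do.call(rbind, unname(lst)) else NULL
  restraint_params(bind(bonds), bind(angles), bind(torsions), bind(repul))
}

#' @rdname load_params
#' @param params a [restraint_params()]
#' @export
write_params <- function(params, path, model) {
  nm <- function(i) paste(model$atoms$resname[i], model$atoms$atomname[i])
  out <- character(0)
  b <- params$bonds
  for (t in seq_len(nrow(b)))
    out <- c(out, sprintf("BOND %s %s %.12g %.12g", nm(b$i[t]), nm(b$j[t]),
                          b$r0[t], b$k[t]))
  a <- params$angles
  for (t in seq_len(nrow(a)))
    out <- c(out, sprintf("ANGL %s %s %s %.12g %.12g", nm(a$i[t]), nm(a$j[t]),
                          nm(a$k[t]), a$theta0[t], a$ka[t]))
  tq <- params$torsions
  for (t in seq_len(nrow(tq)))
    out <- c(out, sprintf("TORS %s %s %s %s %.12g %.12g %.12g",
                          nm(tq$i[t]), nm(tq$j[t]), nm(tq$k[t]), nm(tq$l[t]),
                          tq$n[t], tq$phase[t], tq$kt[t]))
  rp <- params$repulsion
  for (t in seq_len(nrow(rp)))
    out <- c(out, sprintf("REPU %s %s %.12g %.12g", nm(rp$i[t]), nm(rp$j[t]),
                          rp$d0[t], rp$krep[t]))
  writeLines(out, path)
  invisible(path)
}
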