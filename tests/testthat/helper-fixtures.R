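# Shared fixtures and oracles, all built in code.

# central finite differences of scalar function fn at x0
fd_gradient <- function(fn, x0, h = 1e-5) {
  g <- numeric(length(x0))
  for (i in seq_along(x0)) {
    xp <- x0; xp[i] <- xp[i] + h
    xm <- x0; xm[i] <- xm[i] - h
    g[i] <- (fn(xp) - fn(xm)) / (2 * h)
  }
  g
}

rel_err <- function(got, want) max(abs(got - want)) / max(abs(want), 1e-12)

# independent brute-force structure-factor oracle: plain per-atom loop,
# sharing no code with the package engine
brute_force_sf <- function(model, hkl) {
  ff <- form_factor_table()
  sapply(seq_len(nrow(hkl)), function(r) {
    h <- hkl[r, ]
    tot <- 0 + 0i
    for (io in seq_len(n_ops(model$ops))) {
      R <- model$ops$rotations[[io]]
      tt <- model$ops$translations[[io]]
      hr <- as.numeric(h %*% R)
      g <- as.numeric(hr %*% model$cell$cart2frac)
      s2 <- sum(g^2) / 4
      for (j in seq_len(nrow(model$atoms))) {
        a <- model$atoms[j, ]
        p <- ff[a$element, ]
        f0 <- sum(p[1:4] * exp(-p[5:8] * s2)) + p[9]
        xf <- as.numeric(model$cell$cart2frac %*% c(a$x, a$y, a$z))
        phase <- 2 * pi * (sum(hr * xf) + sum(h * (R %*% tt)))
        tot <- tot + a$occ * f0 * exp(-a$b * s2) * exp(1i * phase)
      }
    }
    tot
  })
}

# a small random P1 model with mixed elements
random_model <- function(n = 12, seed = 1, cell = unit_cell(9, 10, 11)) {
  set.seed(seed)
  els <- sample(c("C", "N", "O", "S", "Fe"), n, replace = TRUE)
  atoms <- data.frame(
    element = els, atomname = paste0(els, seq_len(n)), resname = "RND",
    chain = "A", resno = seq_len(n), alt = "",
    x = runif(n) * cell$a, y = runif(n) * cell$b, z = runif(n) * cell$c,
    occ = runif(n, 0.5, 1), b = runif(n, 2, 20),
    charge = 0, radius = 2, stringsAsFactors = FALSE)
  structure_model(cell, atoms)
}

# two-atom harmonic system held off its ideal bond length
harmonic_pair <- function(r = 1.6, r0 = 1.5, k = 1000) {
  cell <- unit_cell(10, 10, 10)
  atoms <- data.frame(element = c("C", "C"), atomname = c("C1", "C2"),
                      resname = "LIG", chain = "A", resno = 1L, alt = "",
                      x = c(4, 4 + r), y = 5, z = 5, occ = 1, b = 5,
                      charge = 0, radius = 2.0, stringsAsFactors = FALSE)
  list(model = structure_model(cell, atoms),
       region = region_selection(1:2),
       params = restraint_params(bonds = data.frame(i = 1L, j = 2L,
                                                    r0 = r0, k = k)))
}

# pack/unpack helpers for coordinate-space finite differences
pack_coords <- function(model, idx) as.numeric(t(coords(model)[idx, , drop = FALSE]))
with_coords <- function(model, p, idx) {
  set_coords(model, matrix(p, ncol = 3, byrow = TRUE), idx)
}
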