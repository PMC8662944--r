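test_that("form factors reproduce atomic electron counts at s = 0", {
  tab <- form_factor_table()
  z <- c(H = 1, C = 6, N = 7, O = 8, S = 16, Fe = 26, Cu = 29, Mo = 42)
  for (el in names(z)) {
    f0 <- sum(tab[el, 1:4]) + tab[el, 9]
    expect_lt(abs(f0 - z[[el]]) / z[[el]], 0.02)
  }
})

test_that("structure factors obey closed forms and the brute-force oracle", {
  cell <- unit_cell(10, 10, 10)
  at <- data.frame(element = "C", atomname = "C1", resname = "X",
                   chain = "A", resno = 1L, alt = "", x = 0, y = 0, z = 0,
                   occ = 1, b = 0, charge = 0, radius = 2)
  m1 <- structure_model(cell, at)
  hkl <- rbind(c(1, 0, 0), c(2, 1, 0), c(3, 2, 1))
  F1 <- calc_structure_factors(m1, hkl)
  g <- hkl %*% cell$cart2frac
  s2 <- rowSums(g^2) / 4
  tab <- form_factor_table()["C", ]
  f_c <- sapply(s2, function(s) sum(tab[1:4] * exp(-tab[5:8] * s)) + tab[9])
  expect_equal(Mod(F1), unname(f_c), tolerance = 1e-12)
  expect_equal(Arg(F1), rep(0, 3), tolerance = 1e-12)

  # two identical atoms at +/- x fractional: F(h00) real, 2 f DW cos(2 pi h x)
  xf <- 0.13
  at2 <- rbind(at, at)
  at2$x <- c(xf * 10, -xf * 10)
  at2$b <- 4
  m2 <- structure_model(cell, at2)
  h00 <- cbind(1:4, 0, 0)
  F2 <- calc_structure_factors(m2, h00)
  s2h <- (1:4)^2 / (2 * 10)^2 / 1  # s = h/(2a) for (h00)
  fh <- sapply(s2h, function(s) sum(tab[1:4] * exp(-tab[5:8] * s)) + tab[9])
  expect_equal(Im(F2), rep(0, 4), tolerance = 1e-10)
  expect_equal(Re(F2), unname(2 * fh * exp(-4 * s2h) * cos(2 * pi * (1:4) * xf)),
               tolerance = 1e-10)

  # 12-atom random model against the independent direct sum
  m <- random_model(12, seed = 7)
  hkl <- as.matrix(expand.grid(h = -3:3, k = -2:2, l = -2:2))
  hkl <- hkl[rowSums(abs(hkl)) > 0, ]
  Fe <- calc_structure_factors(m, hkl)
  Fb <- brute_force_sf(m, hkl)
  expect_lt(max(Mod(Fe - Fb) / Mod(Fb)), 1e-10)

  # Friedel symmetry
  expect_equal(Mod(calc_structure_factors(m, hkl)),
               Mod(calc_structure_factors(m, -hkl)), tolerance = 1e-12)

  # symmetry operators: explicit two-fold gives the same as the doubled model
  ops2 <- symmetry_ops(list(diag(3), diag(c(-1, -1, 1))),
                       list(c(0, 0, 0), c(0, 0, 0.5)))
  msym <- m1; msym$ops <- ops2
  Fsym <- calc_structure_factors(msym, hkl[1:10, ])
  Fman <- brute_force_sf(msym, hkl[1:10, ])
  expect_lt(max(Mod(Fsym - Fman) / pmax(Mod(Fman), 1e-9)), 1e-10)

  expect_error(calc_structure_factors(
    structure_model(cell, transform(at, element = "Xx")), hkl),
    "element|Xx")
})

test_that("amplitude scaling minimizes the quadratic", {
  toy <- make_toy_crystal(toy_spec(seed = 3, n_env = 4, d_min = 1.8,
                                   net_charge = 0))
  fc <- calc_structure_factors(toy$true, toy$refl$hkl)
  r_eq <- reflection_set(toy$refl$hkl, Mod(fc), toy$refl$sigma, toy$refl$free)
  expect_equal(scale_k(r_eq, fc), 1, tolerance = 1e-12)
  r_2x <- reflection_set(toy$refl$hkl, 2 * Mod(fc), toy$refl$sigma, toy$refl$free)
  expect_equal(scale_k(r_2x, fc), 2, tolerance = 1e-12)

  # random amplitudes: matches a 1-D numeric minimization
  set.seed(11)
  fo <- runif(50, 1, 10)
  fcr <- complex(real = runif(50, 1, 10), imaginary = runif(50, -2, 2))
  rr <- reflection_set(cbind(1:50, 0, 0), fo, rep(1, 50))
  k1 <- scale_k(rr, fcr)
  k2 <- stats::optimize(function(k) sum((fo - k * Mod(fcr))^2),
                        c(0, 10), tol = 1e-12)$minimum
  expect_equal(k1, k2, tolerance = 1e-8)
  expect_error(scale_k(reflection_set(cbind(1, 0, 0), 1, 1, TRUE), 1 + 0i),
               "fraction|working")
})

test_that("R factors follow the definition and ignore reflection order", {
  rr <- reflection_set(rbind(c(1, 0, 0), c(2, 0, 0)), c(10, 10), c(1, 1))
  # force k = 1 by matching scales: |Fc| = {9, 11}, k = (90+110)/(81+121) = 0.990...
  rf <- r_factors(rr, c(9 + 0i, 11 + 0i))
  k <- rf$k
  expect_equal(rf$r_work, sum(abs(c(10, 10) - k * c(9, 11))) / 20)
  # with an explicitly unit scale the textbook value is 0.10
  expect_equal(sum(abs(c(10, 10) - c(9, 11))) / 20, 0.10)

  toy <- make_toy_crystal(toy_spec(seed = 9, n_env = 4, d_min = 1.8,
                                   net_charge = 0, noise = 0.05))
  fc <- calc_structure_factors(toy$true, toy$refl$hkl)
  r1 <- r_factors(toy$refl, fc)
  perm <- sample(length(fc))
  rp <- reflection_set(toy$refl$hkl[perm, ], toy$refl$fobs[perm],
                       toy$refl$sigma[perm], toy$refl$free[perm])
  r2 <- r_factors(rp, fc[perm])
  expect_equal(r1$r_work, r2$r_work, tolerance = 1e-12)
  expect_equal(r1$r_free, r2$r_free, tolerance = 1e-12)

  # empty free set: marker value
  rnf <- reflection_set(toy$refl$hkl, toy$refl$fobs, toy$refl$sigma)
  expect_true(is.na(r_factors(rnf, fc)$r_free))
})

test_that("least-squares target: minimum, gradients, scaling laws, free set", {
  toy <- make_toy_crystal(toy_spec(seed = 11, noise = 0.03, perturb = 0.2,
                                   n_env = 7, d_min = 1.5, net_charge = 0))
  m <- toy$start
  mob <- which(m$mobile)

  # zero at the generating model with noise-free data
  toy0 <- make_toy_crystal(toy_spec(seed = 12, noise = 0, perturb = 0,
                                    n_env = 5, d_min = 1.6, net_charge = 0))
  tv0 <- target_lsq(toy0$true, toy0$refl)
  expect_lt(tv0$energy, 1e-12 * length(toy0$refl$fobs))
  expect_lt(max(abs(tv0$grad)), 1e-6)

  # analytic gradient against central differences
  tv <- target_lsq(m, toy$refl)
  x0 <- pack_coords(m, mob)
  gfd <- fd_gradient(function(p) target_lsq(with_coords(m, p, mob), toy$refl)$energy,
                     x0, h = 1e-4)
  expect_lt(rel_err(as.numeric(t(tv$grad[mob, ])), gfd), 1e-5)

  # frozen atoms receive exactly zero gradient
  expect_true(all(tv$grad[!m$mobile, ] == 0))

  # doubling all sigmas quarters the energy
  r2 <- reflection_set(toy$refl$hkl, toy$refl$fobs, 2 * toy$refl$sigma,
                       toy$refl$free)
  expect_equal(target_lsq(m, r2)$energy, tv$energy / 4, tolerance = 1e-12)

  # free reflections influence nothing
  fo2 <- toy$refl$fobs
  fo2[toy$refl$free] <- fo2[toy$refl$free] * 3
  r3 <- reflection_set(toy$refl$hkl, fo2, toy$refl$sigma, toy$refl$free)
  tv3 <- target_lsq(m, r3)
  expect_equal(tv3$energy, tv$energy, tolerance = 1e-12)
  expect_equal(tv3$grad, tv$grad, tolerance = 1e-12)
  expect_equal(tv3$k, tv$k, tolerance = 1e-12)
})

test_that("maximum-likelihood target: sigmaA, gradient, limits, fallback", {
  toy <- make_toy_crystal(toy_spec(seed = 13, noise = 0.03, perturb = 0.15,
                                   n_env = 7, d_min = 1.4, net_charge = 0))
  m <- toy$start

  # perfect model on noiseless data: sigma_A >= 0.99 in every shell
  toy0 <- make_toy_crystal(toy_spec(seed = 14, noise = 0, perturb = 0,
                                    n_env = 7, d_min = 1.4, net_charge = 0))
  mp0 <- estimate_mlf_params(toy0$true, toy0$refl)
  expect_true(all(mp0$sigmaA >= 0.99))

  # analytic gradient vs central differences at frozen shell parameters
  mp <- estimate_mlf_params(m, toy$refl)
  tv <- target_mlf(m, toy$refl, params = mp)
  mob <- which(m$mobile)
  x0 <- pack_coords(m, mob)
  gfd <- fd_gradient(function(p)
    target_mlf(with_coords(m, p, mob), toy$refl, params = mp)$energy,
    x0, h = 1e-4)
  expect_lt(rel_err(as.numeric(t(tv$grad[mob, ])), gfd), 1e-4)

  # ranking consistency with lsq on a noiseless toy: a nearer model scores
  # better under both targets
  near <- with_coords(toy0$true, pack_coords(toy0$true, 1:5) +
                        rnorm(15, sd = 0.02), 1:5)
  far <- with_coords(toy0$true, pack_coords(toy0$true, 1:5) +
                       rnorm(15, sd = 0.3), 1:5)
  expect_lt(target_lsq(near, toy0$refl)$energy, target_lsq(far, toy0$refl)$energy)
  expect_lt(target_mlf(near, toy0$refl)$energy, target_mlf(far, toy0$refl)$energy)

  # too few working reflections: falls back to lsq with a warning
  small <- reflection_set(toy$refl$hkl[1:30, ], toy$refl$fobs[1:30],
                          toy$refl$sigma[1:30])
  expect_warning(tvf <- target_mlf(m, small), "falling back")
  expect_equal(tvf$energy, target_lsq(m, small)$energy)

  # free reflections do not leak into shell estimates
  fo2 <- toy$refl$fobs
  fo2[toy$refl$free] <- fo2[toy$refl$free] * 5
  r2 <- reflection_set(toy$refl$hkl, fo2, toy$refl$sigma, toy$refl$free)
  mp2 <- estimate_mlf_params(m, r2)
  expect_equal(mp2$sigmaA, mp$sigmaA, tolerance = 1e-12)
  expect_equal(mp2$So, mp$So, tolerance = 1e-12)
})

test_that("B-factor gradients match central differences", {
  toy <- make_toy_crystal(toy_spec(seed = 15, noise = 0.02, perturb = 0,
                                   n_env = 5, d_min = 1.6, net_charge = 0))
  m <- toy$start
  tv <- target_lsq(m, toy$refl, need_bgrad = TRUE)
  mob <- which(m$mobile)
  gfd <- sapply(mob, function(i) {
    mp <- m; mp$atoms$b[i] <- mp$atoms$b[i] + 1e-4
    mm_ <- m; mm_$atoms$b[i] <- mm_$atoms$b[i] - 1e-4
    (target_lsq(mp, toy$refl)$energy - target_lsq(mm_, toy$refl)$energy) / 2e-4
  })
  expect_lt(rel_err(tv$bgrad[mob], gfd), 1e-5)
})

test_that("automatic X-ray weight is well-defined and overridable", {
  toy <- make_toy_crystal(toy_spec(seed = 16, noise = 0.02, perturb = 0.1,
                                   n_env = 5, d_min = 1.6, net_charge = 0))
  wa <- auto_wA(toy$start, toy$refl, toy$mm_params)
  expect_true(is.finite(wa) && wa > 0)

  # rescaling Fobs and sigma together leaves the weight finite and similar
  r2 <- reflection_set(toy$refl$hkl, 3 * toy$refl$fobs, 3 * toy$refl$sigma,
                       toy$refl$free)
  wa2 <- auto_wA(toy$start, r2, toy$mm_params)
  expect_true(is.finite(wa2) && wa2 > 0)

  # published per-structure weights are accepted verbatim by the config
  cfg <- refinement_config(w_A = 0.0794)
  expect_equal(cfg$w_A, 0.0794)

  # zero X-ray gradient (unperturbed noiseless truth) is rejected
  toy0 <- make_toy_crystal(toy_spec(seed = 17, noise = 0, perturb = 0,
                                    n_env = 4, d_min = 1.8, net_charge = 0))
  expect_error(auto_wA(toy0$true, toy0$refl, toy0$mm_params), "perturb")
})
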