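test_that("refinement configuration validates its fields", {
  expect_error(refinement_config(w_MM = 0), "w_MM")
  expect_error(refinement_config(epsilon = 0.5), "epsilon")
  expect_error(refinement_config(w_A = -1), "w_A")
  expect_error(refinement_config(occupancies = c(1.2, -0.2)), "occupancy")
  expect_error(refinement_config(coord_tol = 0), "positive")
  cfg <- refinement_config(occupancies = c(0.86, 0.14))
  expect_equal(cfg$occupancies, c(0.86, 0.14))
})

test_that("combined energy: weight limits, partition identity, auto guard", {
  toy <- make_toy_crystal(toy_spec(seed = 51, noise = 0.02, perturb = 0.1,
                                   n_env = 6, d_min = 1.6, net_charge = 0))
  cfg <- refinement_config(mm_params = toy$mm_params,
                           region_params = toy$region_params, w_A = 0.5)

  expect_error(total_energy(toy$start, toy$region, toy$refl,
                            refinement_config(w_A = "auto")), "auto_wA")

  tv <- total_energy(toy$start, toy$region, toy$refl, cfg)

  # w_MM -> 0 limit leaves the pure region energy
  cfg0 <- cfg; cfg0$w_MM <- 1e-12
  tv0 <- total_energy(toy$start, toy$region, toy$refl, cfg0)
  expect_equal(tv0$energy, tv$e_qm1, tolerance = 1e-6)

  # region = whole model: E_MM - E_MM1 = 0 exactly
  region_all <- region_selection(seq_len(n_atoms(toy$start)))
  cfga <- cfg; cfga$region_params <- toy$mm_params
  tva <- total_energy(toy$start, region_all, toy$refl, cfga)
  expect_equal(tva$e_mm, tva$e_mm1, tolerance = 1e-12)
  expect_equal(tva$energy,
               tva$e_qm1 + cfg$w_MM * cfg$w_A * tva$e_xray,
               tolerance = 1e-9)

  # frozen atoms get exactly zero assembled gradient
  expect_true(all(tv$grad[!toy$start$mobile, ] == 0))
})

test_that("assembled gradient (with link atoms and solvent) passes FD checks", {
  toy <- make_toy_crystal(toy_spec(seed = 52, noise = 0.03, perturb = 0.15,
                                   n_env = 3, d_min = 1.7))
  m <- toy$start
  # cut the region down so a boundary bond with a link atom exists:
  # atoms 1-4 inside, atom 5 outside, bond 1-5 crosses
  region <- region_selection(1:4, boundary_bonds = cbind(1L, 5L))
  m$mobile <- c(rep(TRUE, 5), rep(FALSE, n_atoms(m) - 5))
  rp <- restraint_params(
    bonds = data.frame(i = 1, j = 2:5, r0 = 2.2, k = 800))
  cfg <- refinement_config(mm_params = toy$mm_params, region_params = rp,
                           w_A = 0.3, epsilon = 4, cavity_points = 200)
  capped <- place_link_atoms(m, region)
  cav <- build_cavity(as.matrix(capped$atoms[, c("x", "y", "z")]),
                      capped$atoms$radius, 200)
  fixed <- list(cavity = cav)
  tv <- total_energy(m, region, toy$refl, cfg, fixed = fixed)
  mob <- which(m$mobile)
  x0 <- pack_coords(m, mob)
  gfd <- fd_gradient(function(p)
    total_energy(with_coords(m, p, mob), region, toy$refl, cfg,
                 fixed = fixed)$energy, x0, h = 1e-4)
  expect_lt(rel_err(as.numeric(t(tv$grad[mob, ])), gfd), 2e-4)
})

test_that("coordinate refinement recovers a perturbed structure", {
  toy <- make_toy_crystal(toy_spec(seed = 53, noise = 0, perturb = 0.3,
                                   net_charge = 0, n_env = 8, d_min = 1.4))
  cfg <- refinement_config(mm_params = toy$mm_params,
                           region_params = toy$region_params, w_A = "auto")
  res <- refine_coordinates(toy$start, toy$region, toy$refl, cfg)
  expect_true(res$converged)
  idx <- toy$region$indices
  rmsd <- sqrt(mean(rowSums((coords(res$model)[idx, ] -
                             coords(toy$true)[idx, ])^2)))
  expect_lt(rmsd, 0.02)
  expect_lt(res$trace$r_work[nrow(res$trace)], 0.01)

  # frozen environment is bit-identical
  env <- setdiff(seq_len(n_atoms(toy$true)), idx)
  expect_identical(coords(res$model)[env, ], coords(toy$start)[env, ])

  # energy non-increasing over accepted cycles
  acc <- res$trace[res$trace$accepted, ]
  if (nrow(acc) > 1)
    expect_true(all(diff(acc$e_total) <= cfg$energy_tol + 1e-9))
})

test_that("refinement from the generating model converges immediately", {
  toy <- make_toy_crystal(toy_spec(seed = 54, noise = 0, perturb = 0,
                                   net_charge = 0, n_env = 5, d_min = 1.6))
  cfg <- refinement_config(mm_params = toy$mm_params,
                           region_params = toy$region_params, w_A = 1)
  res <- refine_coordinates(toy$true, toy$region, toy$refl, cfg)
  expect_lte(nrow(res$trace), 2)
  expect_lt(max(res$trace$max_shift), 1e-4)
})

test_that("with w_A = 0 the data are ignored and the surrogate relaxes", {
  ## charged fixture: the data record the solvated geometry, so a vacuum
  ## surrogate without data lands at the (different) restraint ideal
  toy <- make_toy_crystal(toy_spec(seed = 55, noise = 0, perturb = 0.25,
                                   n_env = 5, d_min = 1.6))
  cfg <- refinement_config(mm_params = toy$mm_params,
                           region_params = toy$region_params, w_A = 0)
  tv0 <- total_energy(toy$start, toy$region, toy$refl, cfg)
  res <- refine_coordinates(toy$start, toy$region, toy$refl, cfg)
  last <- res$trace[nrow(res$trace), ]
  expect_lt(last$e_qm1 + last$e_mm - last$e_mm1,
            tv0$e_qm1 + tv0$e_mm - tv0$e_mm1)
  # the model relaxes to the restraint ideal, not to the data
  expect_gt(last$r_work, 0.02)
})

test_that("ADP refinement recovers B factors and respects the lower bound", {
  toy <- make_toy_crystal(toy_spec(seed = 56, noise = 0, perturb = 0,
                                   net_charge = 0, n_env = 6, d_min = 1.4))
  truth <- toy$true
  truth$atoms$b[1:5] <- c(6, 9, 12, 7, 10)
  fobs <- Mod(calc_structure_factors(truth, toy$refl$hkl))
  refl <- reflection_set(toy$refl$hkl, fobs, 0.01 * fobs, toy$refl$free)
  start <- truth
  start$atoms$b[1:5] <- 8
  cfg <- refinement_config(mm_params = toy$mm_params, w_A = 1, b_sim = 0.01)
  res <- refine_adps(start, refl, cfg)
  expect_true(res$converged)
  expect_lt(max(abs(res$model$atoms$b[1:5] - truth$atoms$b[1:5]) /
                truth$atoms$b[1:5]), 0.05)
  # coordinates untouched
  expect_identical(coords(res$model), coords(start))

  # one atom's data favour B < 1 while the rest anchor the scale: the
  # bound activates exactly
  low <- truth
  low$atoms$b[3] <- 0.4
  fobs2 <- Mod(calc_structure_factors(low, toy$refl$hkl))
  refl2 <- reflection_set(toy$refl$hkl, fobs2, 0.01 * fobs2, toy$refl$free)
  start2 <- low
  start2$atoms$b[3] <- 8
  res2 <- refine_adps(start2, refl2, cfg)
  expect_equal(res2$model$atoms$b[3], 1, tolerance = 1e-9)

  # all-frozen model: warning no-op
  frozen <- start
  frozen$mobile <- rep(FALSE, n_atoms(frozen))
  expect_warning(res3 <- refine_adps(frozen, refl, cfg), "frozen")
  expect_identical(res3$model$atoms$b, frozen$atoms$b)
})

test_that("dual-conformation refinement: degeneracy, weighting, recovery", {
  # p = 1 with empty conformer B equals single-conformer refinement
  toy <- make_toy_crystal(toy_spec(seed = 57, noise = 0.02, perturb = 0.12,
                                   net_charge = 0, n_env = 6, d_min = 1.5))
  cfg <- refinement_config(mm_params = toy$mm_params,
                           region_params = toy$region_params, w_A = 0.1,
                           occupancies = c(1, 0), max_cycles = 8)
  r1 <- refine_coordinates(toy$start, toy$region, toy$refl, cfg)
  r2 <- refine_2qm(toy$start, toy$region, region_selection(integer(0)),
                   toy$refl, cfg)
  expect_lt(max(abs(coords(r1$model) - coords(r2$model))), 1e-9)
  expect_lt(abs(r1$trace$e_total[nrow(r1$trace)] -
                r2$trace$e_total[nrow(r2$trace)]), 1e-9)

  # occupancy-weighted Fcalc equals the brute conformer sum
  tc <- make_two_conformer_toy(toy_spec(seed = 58, noise = 0, perturb = 0,
                                        n_env = 5, d_min = 1.6), p = 0.86)
  f_all <- calc_structure_factors(tc$true, tc$refl$hkl)
  mA <- tc$true
  mA$atoms <- mA$atoms[mA$atoms$alt != "B", ]
  mA$mobile <- rep(TRUE, nrow(mA$atoms))
  mB <- tc$true
  mB$atoms <- mB$atoms[mB$atoms$alt == "B", ]
  mB$mobile <- rep(TRUE, nrow(mB$atoms))
  f_sum <- calc_structure_factors(mA, tc$refl$hkl) +
    calc_structure_factors(mB, tc$refl$hkl)
  expect_lt(max(Mod(f_all - f_sum)), 1e-10)

  # noiseless two-conformer data: both geometries recovered
  tc2 <- make_two_conformer_toy(toy_spec(seed = 59, noise = 0, perturb = 0.2,
                                         net_charge = 0, n_env = 6,
                                         d_min = 1.4), p = 0.86)
  cfg2 <- refinement_config(mm_params = tc2$mm_params,
                            region_params = tc2$region_params_a,
                            region_params_b = tc2$region_params_b,
                            w_A = "auto", occupancies = c(0.86, 0.14),
                            max_cycles = 50)
  rr <- refine_2qm(tc2$start, tc2$region_a, tc2$region_b, tc2$refl, cfg2)
  for (idx in list(tc2$region_a$indices, tc2$region_b$indices)) {
    rmsd <- sqrt(mean(rowSums((coords(rr$model)[idx, ] -
                               coords(tc2$true)[idx, ])^2)))
    expect_lt(rmsd, 0.05)
  }
})
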