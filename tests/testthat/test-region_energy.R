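region_atoms <- function(x, elements = NULL, charge = 0, radius = 2) {
  x <- matrix(x, ncol = 3)
  n <- nrow(x)
  if (is.null(elements)) elements <- rep("C", n)
  data.frame(element = elements, atomname = paste0("A", seq_len(n)),
             resname = "REG", chain = "A", resno = 1L, alt = "",
             x = x[, 1], y = x[, 2], z = x[, 3], occ = 1, b = 5,
             charge = rep_len(charge, n), radius = rep_len(radius, n),
             stringsAsFactors = FALSE)
}

test_that("Coulomb term, exclusions and the vacuum limit", {
  # two +1 charges 10 A apart, vacuum: bare Coulomb
  at <- region_atoms(rbind(c(0, 0, 0), c(10, 0, 0)), charge = 1)
  re <- region_energy(at, epsilon = 1)
  expect_equal(re$energy, 1389.35458 / 10, tolerance = 1e-9)
  expect_identical(re$solvation, 0)
  expect_equal(re$energy, re$vacuum)

  # solvent screening: the pair interaction shrinks but stays repulsive,
  # and the solvation component is negative
  re80 <- region_energy(at, epsilon = 80, cavity_points = 800)
  single <- region_energy(at[1, ], epsilon = 80, cavity_points = 800)
  interaction <- re80$energy - 2 * single$energy
  expect_lt(re80$solvation, 0)
  expect_lt(re80$energy, re$energy)
  expect_gt(interaction, 0)
  expect_lt(interaction, 1389.35458 / 10)

  # 1-2 and 1-3 exclusions silence bonded-path Coulomb
  x3 <- rbind(c(0, 0, 0), c(2, 0, 0), c(4, 0, 0))
  at3 <- region_atoms(x3, charge = 1)
  chain <- restraint_params(bonds = data.frame(i = c(1, 2), j = c(2, 3),
                                               r0 = 2, k = 0))
  re3 <- region_energy(at3, chain, epsilon = 1)
  expect_equal(re3$energy, 0, tolerance = 1e-12)   # all pairs excluded
  # without bonds, all three pairs interact
  re3b <- region_energy(at3, epsilon = 1)
  expect_equal(re3b$energy,
               1389.35458 * (1 / 2 + 1 / 2 + 1 / 4), tolerance = 1e-9)
})

test_that("vacuum gradients: finite differences, translation and torque", {
  set.seed(41)
  x <- matrix(runif(12, 0, 6), 4, 3)
  at <- region_atoms(x, charge = c(-1, 1, -0.5, 0.5))
  params <- restraint_params(bonds = data.frame(i = 1, j = 2, r0 = 2, k = 300))
  lj <- data.frame(i = c(1, 3), j = c(3, 4), eps_kj = 0.8, sigma = 3.2)
  re <- region_energy(at, params, epsilon = 1, lj = lj)
  fn <- function(p) {
    a2 <- at
    xm <- matrix(p, ncol = 3, byrow = TRUE)
    a2$x <- xm[, 1]; a2$y <- xm[, 2]; a2$z <- xm[, 3]
    region_energy(a2, params, epsilon = 1, lj = lj)$energy
  }
  gfd <- fd_gradient(fn, as.numeric(t(x)), h = 1e-6)
  expect_lt(rel_err(as.numeric(t(re$gradient)), gfd), 1e-6)

  # net force and torque vanish for an isolated system
  expect_lt(max(abs(colSums(re$gradient))), 1e-9)
  torque <- colSums(t(sapply(1:4, function(i)
    c(x[i, 2] * re$gradient[i, 3] - x[i, 3] * re$gradient[i, 2],
      x[i, 3] * re$gradient[i, 1] - x[i, 1] * re$gradient[i, 3],
      x[i, 1] * re$gradient[i, 2] - x[i, 2] * re$gradient[i, 1]))))
  expect_lt(max(abs(torque)), 1e-9)
})

test_that("solvation monotonically stabilizes a net-charged region", {
  at <- region_atoms(rbind(c(0, 0, 0), c(2.2, 0, 0), c(0, 2.2, 0)),
                     elements = c("Fe", "S", "O"), charge = -5 / 3,
                     radius = NA)
  at$radius <- cosmo_radii(at$element)
  es <- sapply(c(1, 4, 20, 80), function(e)
    region_energy(at, epsilon = e, cavity_points = 300)$energy)
  expect_true(all(diff(es) < 0))
})

test_that("external backends: mock round trip, unit conversion, self-consistency", {
  at <- region_atoms(rbind(c(0, 0, 0), c(1.5, 0, 0)), charge = 0)

  # mock backend echoing a constant energy and zero gradient
  mock <- tempfile(fileext = ".sh")
  writeLines(c("#!/bin/sh",
               "out=\"$2\"",
               "n=$(head -1 \"$1\")",
               "echo \"energy 42.5 kj/mol\" > \"$out\"",
               "i=0; while [ $i -lt $n ]; do echo \"0 0 0\" >> \"$out\"; i=$((i+1)); done"),
             mock)
  Sys.chmod(mock, "0755")
  res <- run_external_backend(backend_contract(mock), at, epsilon = 1)
  expect_equal(res$energy, 42.5)
  expect_equal(res$gradient, matrix(0, 2, 3))

  # hartree/bohr declarations are converted
  mock2 <- tempfile(fileext = ".sh")
  writeLines(c("#!/bin/sh",
               "echo \"energy 1.0 hartree\" > \"$2\"",
               "echo \"1 0 0\" >> \"$2\"",
               "echo \"0 0 0\" >> \"$2\""), mock2)
  Sys.chmod(mock2, "0755")
  res2 <- run_external_backend(
    backend_contract(mock2, energy_unit = "hartree",
                     gradient_unit = "hartree/bohr"), at, epsilon = 1)
  expect_equal(res2$energy, 2625.4996, tolerance = 1e-9)
  expect_equal(res2$gradient[1, 1], 2625.4996 / 0.529177, tolerance = 1e-9)

  # failing backends are reported
  bad <- tempfile(fileext = ".sh")
  writeLines(c("#!/bin/sh", "exit 3"), bad)
  Sys.chmod(bad, "0755")
  expect_error(run_external_backend(backend_contract(bad), at), "status 3")

  # short gradient file
  short <- tempfile(fileext = ".sh")
  writeLines(c("#!/bin/sh", "echo \"energy 1 kj/mol\" > \"$2\""), short)
  Sys.chmod(short, "0755")
  expect_error(run_external_backend(backend_contract(short), at), "short")
  unlink(c(mock, mock2, bad, short))
})

test_that("the builtin surrogate wrapped as an external process matches itself", {
  at <- region_atoms(rbind(c(0, 0, 0), c(2.0, 0, 0), c(0, 2.0, 0)),
                     charge = c(-1, 0.5, 0.5))
  params <- restraint_params(bonds = data.frame(i = 1, j = 2:3, r0 = 2, k = 400))
  direct <- region_energy(at, params, epsilon = 1)

  wrap <- tempfile(fileext = ".R")
  writeLines(c(
    "args <- commandArgs(trailingOnly = TRUE)",
    "suppressMessages(library(qrlite))",
    "xyz <- read.table(args[1], skip = 2,",
    "  col.names = c('element', 'x', 'y', 'z'))",
    sprintf("at <- data.frame(element = xyz$element, atomname = paste0('A', seq_len(nrow(xyz))), resname = 'REG', chain = 'A', resno = 1L, alt = '', x = xyz$x, y = xyz$y, z = xyz$z, occ = 1, b = 5, charge = c(-1, 0.5, 0.5), radius = 2)"),
    "params <- restraint_params(bonds = data.frame(i = 1, j = 2:3, r0 = 2, k = 400))",
    "res <- region_energy(at, params, epsilon = as.numeric(args[3]))",
    "out <- c(sprintf('energy %.12f kj/mol', res$energy),",
    "  sprintf('%.12f %.12f %.12f', res$gradient[,1], res$gradient[,2], res$gradient[,3]))",
    "writeLines(out, args[2])"), wrap)
  ext <- run_external_backend(
    backend_contract("Rscript", args = wrap), at, epsilon = 1)
  expect_equal(ext$energy, direct$energy, tolerance = 1e-9)
  expect_equal(ext$gradient, direct$gradient, tolerance = 1e-9)
  unlink(wrap)
})
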