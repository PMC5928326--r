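test_that("point-charge dipole matches the closed form and converts to Debye", {
  m <- gen_toy_molecule("diatomic")  # q = -/+0.2 e, d = 0.1 nm
  d <- compute_dipole(m)
  expect_equal(d$components, c(0.02, 0, 0), tolerance = 1e-12)
  expect_equal(d$magnitude_debye, 0.9606, tolerance = 1e-4)

  m0 <- m
  m0$atoms$charge <- 0
  expect_equal(compute_dipole(m0)$components, c(0, 0, 0))
})

test_that("a neutral molecule's dipole is origin-independent", {
  set.seed(7)
  for (rep in 1:5) {
    q <- rnorm(5); q <- q - mean(q)
    atoms <- data.frame(index = 1:5, name = paste0("A", 1:5), charge = q,
                        charge_group = 1L, mass = runif(5, 1, 16),
                        x = rnorm(5, 0, 0.2), y = rnorm(5, 0, 0.2),
                        z = rnorm(5, 0, 0.2))
    m <- suppressWarnings(molecule_topology("rand", atoms))
    d1 <- compute_dipole(m, "center_of_geometry")
    d2 <- compute_dipole(m, "center_of_mass")
    expect_equal(d1$components, d2$components, tolerance = 1e-12)
  }
})

test_that("dipole is linear in the charges for fixed geometry", {
  m <- gen_toy_molecule("benzene_like")
  q1 <- rnorm(12); q1 <- q1 - mean(q1)
  q2 <- rnorm(12); q2 <- q2 - mean(q2)
  mu_of <- function(q) { mm <- m; mm$atoms$charge <- q
                         compute_dipole(mm)$components }
  expect_equal(mu_of(q1 + q2), mu_of(q1) + mu_of(q2), tolerance = 1e-12)
})

test_that("dipole angles follow the geometric definition", {
  expect_equal(dipole_angle(c(1, 0, 0), c(0, 1, 0)), 90)
  v <- c(0.3, -0.2, 0.5)
  expect_equal(dipole_angle(v, 2 * v), 0)
  expect_equal(dipole_angle(v, -v), 180)
  expect_error(dipole_angle(c(0, 0, 0), v), "undefined")
})

test_that("exactly solvable charge fits are recovered with theta ~ 0", {
  ## two-atom neutral molecule, bond 0.1 nm, target 0.05 e nm along the bond
  m <- gen_toy_molecule("diatomic")
  res <- fit_charges_to_dipole(m, charge_fit_spec(c(0.05, 0, 0)))
  expect_equal(res$charges, c(-0.5, 0.5), tolerance = 1e-10)
  expect_lt(res$theta_deg, 1e-6)
  expect_lt(res$residual_norm, 1e-12)

  ## target equal to the current dipole: zero shift is optimal
  res2 <- fit_charges_to_dipole(m, charge_fit_spec(compute_dipole(m)))
  expect_equal(max(abs(res2$shift)), 0, tolerance = 1e-12)
  expect_lt(res2$theta_deg, 1e-6)
})

test_that("constrained fit matches the 1e-3-step brute-force grid search", {
  m <- gen_toy_molecule("planar4", seed = 5)
  ## a target reachable with shifts well inside the +-0.05 e search cube
  delta_true <- c(0.02, -0.012, 0.018, -0.026)
  mt <- m; mt$atoms$charge <- mt$atoms$charge + delta_true
  target <- compute_dipole(mt)$components
  res <- fit_charges_to_dipole(m, charge_fit_spec(target))
  q_grid <- oracle_charge_grid(m, target, half_range = 0.05, step = 1e-3)
  expect_equal(res$charges, q_grid, tolerance = 2e-3)
  expect_lt(res$residual_norm, 1e-10)
  expect_lt(res$theta_deg, 1e-6)
})

test_that("group sums and net charge are conserved by any fit", {
  b <- gen_toy_molecule("benzene_like")
  res <- fit_charges_to_dipole(b, charge_fit_spec(c(0.02, 0.01, 0)))
  gs <- tapply(res$charges, b$atoms$charge_group, sum)
  expect_true(all(abs(gs) < 1e-6))
  expect_lt(abs(sum(res$charges)), 1e-6)
})

test_that("fitting never worsens theta when improvement is possible", {
  set.seed(21)
  for (rep in 1:5) {
    m <- gen_toy_molecule("planar4", seed = rep + 30)
    delta <- rnorm(4, 0, 0.02); delta <- delta - mean(delta)
    mt <- m; mt$atoms$charge <- mt$atoms$charge + delta
    target <- compute_dipole(mt)$components
    if (sqrt(sum(target^2)) < 1e-6) next
    theta0 <- tryCatch(dipole_angle(compute_dipole(m)$components, target),
                       error = function(e) NA)
    res <- fit_charges_to_dipole(m, charge_fit_spec(target))
    if (is.finite(theta0)) expect_lte(res$theta_deg, theta0 + 1e-9)
  }
})

test_that("frozen atoms stay fixed and overlap atoms obey both groups", {
  atoms <- data.frame(index = 1:3, name = c("A", "B", "C"),
                      charge = c(0.1, -0.1, 0.0),
                      charge_group = c(1L, 1L, 2L), mass = 12,
                      x = c(0, 0.12, 0.2), y = c(0, 0.05, -0.04), z = 0)
  m <- molecule_topology("overlap3", atoms)
  spec <- charge_fit_spec(c(0.01, 0.005, 0),
                          overlap = data.frame(atom = 2L, group = 2L),
                          group_targets = c("1" = 0, "2" = 0))
  res <- fit_charges_to_dipole(m, spec)
  q <- res$charges
  expect_lt(abs(q[1] + q[2]), 1e-6)        # group 1 (atoms 1, 2)
  expect_lt(abs(q[2] + q[3]), 1e-6)        # group 2 (atoms 2, 3 via overlap)

  m2 <- gen_toy_molecule("planar4", seed = 9)
  ## a target reachable by moving charge between the two free atoms only
  m2t <- m2; m2t$atoms$charge <- m2t$atoms$charge + c(0, 0, 0.01, -0.01)
  resf <- fit_charges_to_dipole(
    m2, charge_fit_spec(compute_dipole(m2t)$components, frozen = c(1L, 2L)))
  expect_equal(resf$charges[1:2], m2$atoms$charge[1:2], tolerance = 1e-10)
  expect_equal(resf$charges[3:4], m2t$atoms$charge[3:4], tolerance = 1e-8)
})

test_that("a shift-bound violation is flagged, infeasibility is an error", {
  m <- gen_toy_molecule("diatomic")
  expect_warning(
    res <- fit_charges_to_dipole(m, charge_fit_spec(c(0.2, 0, 0),
                                                    max_shift = 0.1)),
    "bound")
  expect_true(res$shift_exceeded)

  ## frozen atoms that contradict the group target cannot be satisfied
  spec_bad <- charge_fit_spec(c(0.05, 0, 0), frozen = c(1L, 2L),
                              group_targets = c("1" = 1))
  expect_error(fit_charges_to_dipole(m, spec_bad), "infeasible")
})
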