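test_that("block averages reduce to the grand mean for equal blocks", {
  x <- rnorm(100)
  expect_equal(block_average(x, 5)$mean, mean(x))
  cb <- block_average(rep(3.2, 50), 5)
  expect_equal(cb$sd, 0)
  expect_error(block_average(1:3, 5), "too short")
})

test_that("density follows the closed form and scales inversely with volume", {
  s <- energy_volume_series(time = 1:10, volume = rep(147.0, 10),
                            n_molecules = 1000L)
  d <- liquid_density(s, molar_mass = 78.11)
  expect_equal(d$mean, 1000 * 78.11 / (6.02214076e23 * 147.0e-21),
               tolerance = 1e-12)
  expect_equal(d$mean, 0.88234, tolerance = 1e-4)
  expect_equal(d$sd, 0)

  s2 <- energy_volume_series(time = 1:10, volume = rep(294.0, 10),
                             n_molecules = 1000L)
  expect_equal(liquid_density(s2, 78.11)$mean, d$mean / 2)
  s3 <- energy_volume_series(time = 1:2, volume = c(1, -1))
  expect_error(liquid_density(s3, 78.11), "positive")
})

test_that("stochastic density block mean stays within 3 SEM of truth", {
  gen <- gen_liquid_series(noise_v = 1e-3, n = 2000L, seed = 42)
  tr <- attr(gen, "truth")
  s <- gen[["T298.15_P1"]]
  d <- liquid_density(s, 78.11)
  sem <- tr$rho0 * 1e-3 / sqrt(2000)
  expect_lt(abs(d$mean - tr$rho0), 3 * sem + 1e-7)
})

test_that("enthalpy of vaporization arithmetic and shift invariance", {
  expect_equal(enthalpy_of_vaporization(0, -30 * 500, 500, T = 298.15),
               32.479, tolerance = 1e-4)
  expect_equal(enthalpy_of_vaporization(-12.5, -12.5 * 200, 200, T = 310),
               8.31446261815324 * 310 / 1000)
  base <- enthalpy_of_vaporization(-5, -35 * 100, 100)
  shifted <- enthalpy_of_vaporization(-5 + 7, (-35 + 7) * 100, 100)
  expect_equal(base, shifted)
})

test_that("finite-difference estimators are exact on their closed forms", {
  ## rho(T) = rho0 exp(-alpha (T - T0)) with alpha = 1e-3
  T0 <- 298.15; rho0 <- 0.88; alpha <- 1.0e-3
  Ts <- c(288.15, 308.15)
  rhoT <- rho0 * exp(-alpha * (Ts - T0))
  expect_equal(thermal_expansion(rhoT, Ts), 1.0e-3, tolerance = 1e-12)
  expect_equal(thermal_expansion(c(0.9, 0.9), Ts), 0)
  expect_equal(thermal_expansion(rev(rhoT), rev(Ts)),
               thermal_expansion(rhoT, Ts))

  ## rho(P) = rho0 exp(kappa (P - P0)), kappa = 1 GPa^-1 = 1e-4 bar^-1
  Ps <- c(0.9, 1.1)
  rhoP <- rho0 * exp(1e-4 * (Ps - 1))
  expect_equal(isothermal_compressibility(rhoP, Ps), 1.0, tolerance = 1e-9)
  expect_equal(isothermal_compressibility(c(0.9, 0.9), Ps), 0)
  expect_equal(isothermal_compressibility(rev(rhoP), Ps),
               -isothermal_compressibility(rhoP, Ps))

  ## U linear in T, slope 100 kJ/(mol K) per molecule
  expect_equal(heat_capacity(c(0, 2000), c(290, 310), n_molecules = 1L),
               1.0e5)
  expect_equal(heat_capacity(c(5, 5), c(290, 310)), 0)
  ## central form: the middle state is not used
  expect_equal(thermal_expansion(c(rhoT[1], 0.77, rhoT[2]),
                                 c(Ts[1], T0, Ts[2])),
               thermal_expansion(rhoT, Ts))
})

test_that("noisy generator series recover the response coefficients", {
  gen <- gen_liquid_series(alpha_true = 1.0e-3, kappa_true = 1.0,
                           cp_true = 130, noise_v = 1e-5, noise_u = 0.05,
                           n = 2000L, seed = 7)
  tr <- attr(gen, "truth")
  rho_at <- function(nm) liquid_density(gen[[nm]], 78.11)$mean

  a_hat <- thermal_expansion(c(rho_at("T288.15_P1"), rho_at("T308.15_P1")),
                             c(288.15, 308.15))
  se_lnrho <- 1e-5 / sqrt(2000)
  expect_lt(abs(a_hat - tr$alpha), 3 * sqrt(2) * se_lnrho / 20)

  k_hat <- isothermal_compressibility(
    c(rho_at("T298.15_P0.9"), rho_at("T298.15_P1.1")), c(0.9, 1.1))
  expect_lt(abs(k_hat - tr$kappa), 1e4 * 3 * sqrt(2) * se_lnrho / 0.2)

  U_at <- function(nm) mean(gen[[nm]]$Etot)
  cp_hat <- heat_capacity(c(U_at("T288.15_P1"), U_at("T308.15_P1")),
                          c(288.15, 308.15), n_molecules = 1000L)
  se_u <- 0.05 / sqrt(2000)
  expect_lt(abs(cp_hat - tr$cp), 1000 * 3 * sqrt(2) * se_u / 20)
})

test_that("dielectric fluctuation estimator matches its closed form", {
  s0 <- energy_volume_series(time = 1:100,
                             box_dipole = matrix(0, 100, 3),
                             volume = rep(30, 100))
  r0 <- dielectric_constant(s0)
  expect_equal(r0$epsilon, 1)

  s <- gen_box_dipole_series(sigma = 0.5, volume = 30, n = 30000L, seed = 5)
  r <- dielectric_constant(s, T = 298.15)
  eps_true <- attr(s, "truth")$epsilon
  expect_gt(eps_true, 2)  # a meaningful fluctuation signal
  expect_lt(abs(r$epsilon - eps_true) / (eps_true - 1), 0.05)
  expect_true(r$converged)
  expect_length(r$running_average, 30000L)

  ## doubling V at fixed fluctuations halves (epsilon - 1)
  r2 <- dielectric_constant(s, volume = 60, T = 298.15)
  expect_equal(r2$epsilon - 1, (r$epsilon - 1) / 2, tolerance = 1e-10)
})

test_that("energy drift is the normalized OLS slope with a 0.5 threshold", {
  t <- seq(0, 1998, by = 2)
  s0 <- energy_volume_series(time = t, Etot = rep(-5000, length(t)),
                             n_dof = 9000)
  r0 <- energy_drift(s0)
  expect_equal(r0$drift, 0)
  expect_true(r0$passes)

  ## slope of exactly 1.0 J/(mol ns DoF): 1e-6 * n_dof kJ/mol per ps
  s1 <- energy_volume_series(time = t, Etot = -5000 + 1e-6 * 9000 * t,
                             n_dof = 9000)
  r1 <- energy_drift(s1)
  expect_equal(r1$drift, 1.0, tolerance = 1e-9)
  expect_false(r1$passes)

  s2 <- energy_volume_series(time = t, Etot = 777 + 1e-6 * 9000 * t,
                             n_dof = 9000)
  expect_equal(energy_drift(s2)$drift, r1$drift, tolerance = 1e-9)

  s3 <- energy_volume_series(time = 1:5, Etot = rep(1, 5), n_dof = 10)
  expect_error(energy_drift(s3), "10 samples")
})
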