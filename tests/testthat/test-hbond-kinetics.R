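test_that("constructed geometries are detected by distance and angle", {
  ## acceptor N at 0.28 nm from donor O, H on the O->N axis
  make_frame <- function(r_da) {
    xyz <- rbind(c(1, 1, 1), c(1 + r_da, 1, 1), c(1.1, 1, 1))
    trajectory_frame(0, xyz, c(3, 3, 3))
  }
  donors <- data.frame(donor = 1L, hydrogen = 3L)
  det <- detect_hbonds(list(make_frame(0.28)), donors, acceptors = 2L)
  expect_true(det$bonds[1, 1])
  det2 <- detect_hbonds(list(make_frame(0.36)), donors, acceptors = 2L)
  expect_false(det2$bonds[1, 1])
  ## bent H breaks the 30-degree criterion
  xyz <- rbind(c(1, 1, 1), c(1.28, 1, 1), c(1, 1.1, 1))
  det3 <- detect_hbonds(list(trajectory_frame(0, xyz, c(3, 3, 3))),
                        donors, acceptors = 2L)
  expect_false(det3$bonds[1, 1])
  expect_error(detect_hbonds(list(make_frame(0.28)),
                             data.frame(donor = 1L, hydrogen = 99L),
                             acceptors = 2L),
               "topology")
})

test_that("vectorized detection equals the brute-force triple loop", {
  set.seed(99)
  for (rep in 1:20) {
    sys <- random_hbond_system(n_donors = 4, n_acceptors = 7, n_frames = 8,
                               box = 1.1)
    det <- detect_hbonds(sys$frames, sys$donors, sys$acceptors)
    oracle <- oracle_hbond_counts(sys$frames, sys$donors, sys$acceptors)
    expect_equal(unname(det$bonds), unname(oracle))
  }
})

test_that("occupancy statistics follow their definitions", {
  s1 <- hbond_time_series(c(1, 1, 1, 1, 1), dt = 2)
  o1 <- hbond_occupancy(s1)
  expect_equal(o1$Aver_HB, 1)
  expect_equal(o1$Percent, 100)
  s2 <- hbond_time_series(c(0, 2, 0, 2, 0, 2, 0, 2, 0, 2), dt = 2)
  o2 <- hbond_occupancy(s2)
  expect_equal(o2$Aver_HB, 1)
  expect_equal(o2$Percent, 50)
})

test_that("two-state Markov occupancy converges to the stationary value", {
  s <- suppressWarnings(gen_hbond_markov(2, 5, dt = 2, duration_ns = 250,
                                         seed = 12))
  p <- attr(s, "truth")$p
  occ <- hbond_occupancy(s)
  expect_lt(abs(occ$Percent - 100 * p), 1)
  sym <- suppressWarnings(gen_hbond_markov(3, 3, dt = 1, duration_ns = 100,
                                           seed = 4))
  expect_lt(abs(mean(sym$counts) - 0.5), 0.02)
})

test_that("completed bonded intervals are extracted with end censoring", {
  ind <- matrix(c(1, 1, 0, 1, 1, 1, 0, 0, 1), ncol = 1)
  iv <- bond_intervals(ind, dt = 2)
  expect_equal(iv, 6)   # only the middle 3-frame run is completed
  two <- cbind(c(0, 1, 1, 0, 0), c(0, 0, 1, 0, 1))
  expect_equal(sort(bond_intervals(two, dt = 1)), c(1, 2))
})

test_that("residence time recovers exponential interval means", {
  set.seed(31)
  iv <- rexp(1e4, 1 / 2.11)
  r <- residence_time(iv)
  expect_lt(abs(r$tau - 2.11) / 2.11, 0.05)
  expect_equal(r$lifetime * r$tau, 1)
  expect_equal(r$flag, "ok")
})

test_that("degenerate and under-sampled interval sets are flagged", {
  few <- residence_time(rexp(10, 1))
  expect_equal(few$flag, "insufficient_sampling")
  expect_true(is.na(few$tau))
  ## all intervals exactly one frame long: tau at most dt, flagged
  one_frame <- residence_time(rep(2, 500), dt = 2)
  expect_equal(one_frame$flag, "short_lived")
  expect_lte(one_frame$tau, 2)
})

test_that("Markov fixtures at the trajectory save interval recover tau", {
  for (tau_true in c(0.4, 2.11, 10)) {
    s <- suppressWarnings(gen_hbond_markov(tau_true, 5, dt = 2,
                                           duration_ns = 250,
                                           seed = 100 + round(10 * tau_true)))
    r <- residence_time(attr(s, "intervals"))
    expect_lt(abs(r$tau - tau_true) / tau_true, 0.05)
  }
})

test_that("the Eyring map reproduces known free energies and identities", {
  expect_equal(hbond_free_energy(2.11), 6.38, tolerance = 1e-3)
  expect_equal(hbond_free_energy(9.49), 10.11, tolerance = 1e-3)
  ## fixed point: tau = h / (kB T) gives dG = 0
  cst <- aromring_constants
  tau0 <- cst$h / (cst$kB * 298.15) * 1e12
  expect_equal(hbond_free_energy(tau0), 0, tolerance = 1e-12)
  ## doubling tau adds exactly RT ln 2
  expect_equal(hbond_free_energy(2.11) - hbond_free_energy(1.055),
               8.31446261815324 * 298.15 / 1000 * log(2), tolerance = 1e-12)
  ## strictly increasing
  taus <- c(0.1, 0.5, 2, 9, 40)
  expect_true(all(diff(hbond_free_energy(taus)) > 0))
  expect_error(hbond_free_energy(-1), "positive")
})
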