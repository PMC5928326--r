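## Deterministic synthetic-data generators with known ground truth for
## every estimator in the package. Each generator seeds the RNG itself and
## returns its true parameters alongside the data, so tests never re-derive
## them. Trajectories are generated directly in configuration space; no
## dynamics is integrated.

#' Two-state Markov hydrogen-bond indicator series
#'
#' Alternating exponential dwell times (bound with mean `tau_bound`,
#' unbound with mean `tau_free`), started from the stationary state and
#' discretized at the save interval `dt`. The stationary bound occupancy is
#' p = tau_bound / (tau_bound + tau_free). The continuous ground-truth
#' bound intervals are returned alongside the discretized series, since a
#' save interval comparable to the dwell times aliases the indicator (a
#' warning is raised when dt > min(tau)/2).
#'
#' @param tau_bound,tau_free Mean dwell times, ps.
#' @param dt Save interval, ps (default 2, a common trajectory stride).
#' @param duration_ns Total duration, ns.
#' @param seed RNG seed.
#' @return An `hbond_time_series` with attributes `intervals` (ground-truth
#'   completed bound dwell times, ps) and `truth`
#'   (list tau_bound, tau_free, p).
#' @export
gen_hbond_markov <- function(tau_bound, tau_free, dt = 2, duration_ns = 250,
                             seed = 1L) {
  if (tau_bound <= 0 || tau_free <= 0 || dt <= 0 || duration_ns <= 0)
    stop("all times must be positive")
  if (dt > min(tau_bound, tau_free) / 2)
    warning("save interval dt aliases the dwell times (dt > min(tau)/2); ",
            "use the ground-truth intervals for kinetics")
  set.seed(seed)
  dur <- duration_ns * 1000
  p <- tau_bound / (tau_bound + tau_free)
  start_bound <- stats::runif(1) < p
  n_guess <- ceiling(2.4 * dur / (tau_bound + tau_free)) + 100L
  means <- if (start_bound) c(tau_bound, tau_free) else c(tau_free, tau_bound)
  dwell <- stats::rexp(n_guess, 1) *
    rep_len(means, n_guess)
  while (sum(dwell) < dur) {
    extra <- stats::rexp(n_guess, 1) *
      rep_len(if (length(dwell) %% 2L == 0L) means else rev(means), n_guess)
    dwell <- c(dwell, extra)
  }
  cum <- cumsum(dwell)
  tgrid <- seq(0, dur, by = dt)
  idx <- findInterval(tgrid, cum) + 1L
  bound <- if (start_bound) idx %% 2L == 1L else idx %% 2L == 0L
  bound_idx <- if (start_bound) seq(1L, length(dwell), by = 2L)
               else seq(2L, length(dwell), by = 2L)
  ## completed bound intervals within the duration
  bound_idx <- bound_idx[cum[bound_idx] < dur & bound_idx > 1L]
  series <- hbond_time_series(as.integer(bound), dt, label = "markov")
  attr(series, "intervals") <- dwell[bound_idx]
  attr(series, "truth") <- list(tau_bound = tau_bound, tau_free = tau_free,
                                p = p)
  series
}

#' Liquid observable series with known response coefficients
#'
#' Generates one [energy_volume_series()] per thermodynamic state on the
#' grid `temperatures` x `pressures`, with volumes fluctuating around
#' V(T,P) = V0 exp(alpha (T - T0)) exp(-kappa (P - P0)) and total energies
#' around U(T) = n_molecules (u0 + cp (T - T0) / 1000), so that the
#' finite-difference estimators are exact on the noiseless means.
#'
#' @param rho0 Reference density at (T0, P0), g/cm^3.
#' @param molar_mass Molar mass, g/mol.
#' @param n_molecules Molecules per box (default 1000).
#' @param alpha_true Thermal expansion coefficient, 1/K.
#' @param kappa_true Isothermal compressibility, 1/GPa.
#' @param cp_true Heat capacity, J/(mol K).
#' @param u0 Reference total energy per molecule at T0, kJ/mol.
#' @param T0,P0 Reference state (298.15 K, 1 bar).
#' @param temperatures Simulated temperatures, K (default T0 + c(-10,0,10)).
#' @param pressures Simulated pressures, bar (default c(0.9, 1, 1.1)).
#' @param noise_v Relative SD of the volume fluctuations (default 1e-3,
#'   a typical NPT box-volume fluctuation for ~1000 molecules).
#' @param noise_u Absolute SD of the per-molecule energy noise, kJ/mol.
#' @param n Frames per state.
#' @param seed RNG seed.
#' @return List of series named `"T<K>_P<bar>"`, with attribute `truth`.
#' @export
gen_liquid_series <- function(rho0 = 0.88, molar_mass = 78.11,
                              n_molecules = 1000L, alpha_true = 1.0e-3,
                              kappa_true = 1.0, cp_true = 130,
                              u0 = -30, T0 = 298.15, P0 = 1,
                              temperatures = T0 + c(-10, 0, 10),
                              pressures = c(0.9, 1, 1.1),
                              noise_v = 1e-3, noise_u = 0.05,
                              n = 1000L, seed = 1L) {
  set.seed(seed)
  cst <- aromring_constants
  V0 <- n_molecules * molar_mass / (cst$N_A * rho0 * 1e-21)   # nm^3
  states <- expand.grid(T = temperatures, P = pressures)
  out <- list()
  for (i in seq_len(nrow(states))) {
    Tk <- states$T[i]; Pb <- states$P[i]
    Vmean <- V0 * exp(alpha_true * (Tk - T0)) *
      exp(-kappa_true * (Pb - P0) * 1e-4)        # kappa per GPa, P in bar
    V <- Vmean * exp(stats::rnorm(n, 0, noise_v))
    U <- n_molecules * (u0 + cp_true * (Tk - T0) / 1000) +
      n_molecules * stats::rnorm(n, 0, noise_u)
    out[[sprintf("T%g_P%g", Tk, Pb)]] <-
      energy_volume_series(time = seq_len(n) * 2, volume = V, Etot = U,
                           Epot = U, pressure = rep(Pb, n),
                           temperature = rep(Tk, n),
                           n_molecules = n_molecules)
  }
  attr(out, "truth") <- list(rho0 = rho0, alpha = alpha_true,
                             kappa = kappa_true, cp = cp_true, V0 = V0,
                             T0 = T0, P0 = P0)
  out
}

#' Box-dipole series with a known dielectric constant
#'
#' Components of M drawn i.i.d. normal with SD `sigma` (e nm), for which
#' the fluctuation formula gives epsilon = 1 + sigma^2 e^2 /
#' (eps0 V kB T) in consistent units.
#'
#' @param sigma Per-component SD of M, e nm.
#' @param volume Box volume, nm^3.
#' @param T Temperature, K.
#' @param n Number of frames.
#' @param seed RNG seed.
#' @return An [energy_volume_series()] with attribute `truth` (list with
#'   the closed-form `epsilon`).
#' @export
gen_box_dipole_series <- function(sigma, volume, T = 298.15, n = 30000L,
                                  seed = 1L) {
  set.seed(seed)
  M <- matrix(stats::rnorm(3L * n, 0, sigma), ncol = 3L)
  cst <- aromring_constants
  eps_true <- 1 + (cst$e^2 * 1e-18) * sigma^2 /
    (cst$eps0 * 1e-27 * cst$kB * volume * T)
  s <- energy_volume_series(time = seq_len(n), box_dipole = M,
                            volume = rep(volume, n))
  attr(s, "truth") <- list(epsilon = eps_true, sigma = sigma)
  s
}

#' Polynomial <dH/dlambda> curve with a closed-form integral
#'
#' dHdl(lambda) = sum_k coef\[k\] lambda^(k-1); the exact integral over
#' \[0,1\] is sum_k coef\[k\]/k.
#'
#' @param coef Polynomial coefficients, constant term first.
#' @param sem Per-window SEM (recycled).
#' @param lambdas Lambda grid (default the standard 25-window stage grid).
#' @return A [ti_curve()] with attribute `truth` (list `integral`).
#' @export
gen_ti_curve <- function(coef, sem = 0, lambdas = ti_lambda_schedule()$coulomb$lambdas) {
  dHdl <- vapply(lambdas, function(l) sum(coef * l^(seq_along(coef) - 1L)),
                 numeric(1))
  curve <- ti_curve(lambdas, dHdl, sem)
  attr(curve, "truth") <- list(integral = sum(coef / seq_along(coef)))
  curve
}

## Rigid 3-site water geometry: O-H 0.1 nm, H-O-H 109.47 deg (SPC).
spc_hydrogens <- function(O, u, w) {
  half <- 109.47 / 2 * pi / 180
  h1 <- O + 0.1 * (cos(half) * u + sin(half) * w)
  h2 <- O + 0.1 * (cos(half) * u - sin(half) * w)
  rbind(h1, h2)
}

#' Hydration shell of rigid waters around a reference atom
#'
#' Places `n_waters` 3-site waters with oxygens at distances drawn tightly
#' around `obd` from a central reference atom (plus optional uniform bulk
#' waters), with water dipoles oriented toward the reference
#' (`"inward"`, hydrogens facing the atom), away (`"outward"`) or
#' isotropically (`"random"`).
#'
#' @param n_waters Number of shell waters.
#' @param obd Shell radius, nm.
#' @param orientation_mode `"inward"`, `"outward"` or `"random"`.
#' @param n_frames Number of frames (re-randomized each frame).
#' @param n_bulk Additional uniformly placed bulk waters (default 0).
#' @param box Cubic box edge, nm.
#' @param shell_sd SD of the shell-distance jitter, nm.
#' @param seed RNG seed.
#' @return List `frames`, `ref` (atom index 1), `waters` (data.frame O,
#'   H1, H2), and `truth`.
#' @export
gen_hydration_shell <- function(n_waters, obd = 0.28,
                                orientation_mode = c("inward", "outward",
                                                     "random"),
                                n_frames = 10L, n_bulk = 0L, box = 4,
                                shell_sd = 0.004, seed = 1L) {
  orientation_mode <- match.arg(orientation_mode)
  set.seed(seed)
  ntot <- n_waters + n_bulk
  center <- rep(box / 2, 3)
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    xyz <- matrix(NA_real_, 1L + 3L * ntot, 3L)
    xyz[1, ] <- center
    for (i in seq_len(ntot)) {
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      O <- if (i <= n_waters)
        center + pmax(stats::rnorm(1, obd, shell_sd), 0.05) * u
      else stats::runif(3, 0, box)
      toward <- center - O; toward <- toward / sqrt(sum(toward^2))
      dipdir <- switch(orientation_mode,
                       inward = toward,
                       outward = -toward,
                       random = { v <- stats::rnorm(3); v / sqrt(sum(v^2)) })
      ## a unit vector perpendicular to the dipole direction
      w <- stats::rnorm(3)
      w <- w - sum(w * dipdir) * dipdir
      w <- w / sqrt(sum(w^2))
      H <- spc_hydrogens(O, dipdir, w)
      base <- 1L + 3L * (i - 1L)
      xyz[base + 1L, ] <- O
      xyz[base + 2L, ] <- H[1, ]
      xyz[base + 3L, ] <- H[2, ]
    }
    frames[[f]] <- trajectory_frame(time = (f - 1L) * 2, xyz,
                                    rep(box, 3))
  }
  base <- 1L + 3L * (seq_len(ntot) - 1L)
  list(frames = frames, ref = 1L,
       waters = data.frame(O = base + 1L, H1 = base + 2L, H2 = base + 3L),
       truth = list(obd = obd, n_shell = n_waters,
                    orientation_mode = orientation_mode))
}

#' Uniform ideal-gas frames
#'
#' Positions uniform in a cubic box; the pair distribution of such a gas is
#' flat, g(r) = 1, at every distance.
#'
#' @param n_particles Particles per frame.
#' @param box Cubic box edge, nm.
#' @param n_frames Number of frames.
#' @param seed RNG seed.
#' @return List of [trajectory_frame()] objects.
#' @export
gen_uniform_gas <- function(n_particles, box = 2.5, n_frames = 50L,
                            seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n_frames), function(f)
    trajectory_frame((f - 1L) * 2,
                     matrix(stats::runif(3L * n_particles, 0, box),
                            ncol = 3L),
                     rep(box, 3)))
}

#' Torsion profile generated from known dihedral terms
#'
#' @param params A [dihedral_params()].
#' @param noise Gaussian noise SD, kJ/mol (default 0).
#' @param angles Scan grid, degrees (default a 30-degree grid covering one
#'   period).
#' @param seed RNG seed (used only when `noise > 0`).
#' @return A [torsion_profile()] with attribute `truth` (the params).
#' @export
gen_torsion_profile <- function(params, noise = 0,
                                angles = seq(-180, 150, by = 30),
                                seed = 1L) {
  e <- evaluate_dihedral(params, angles)
  if (noise > 0) {
    set.seed(seed)
    e <- e + stats::rnorm(length(e), 0, noise)
  }
  p <- torsion_profile(angles, e)
  attr(p, "truth") <- params
  p
}

#' Toy molecules with known charge structure
#'
#' * `diatomic`: two atoms 0.1 nm apart, charges -0.2/+0.2 e, one group.
#' * `planar4`: four atoms in the z = 0 plane at random positions, random
#'   neutral charges, one charge group.
#' * `benzene_like`: six CH units on a hexagon (C ring radius 0.139 nm,
#'   H at 0.248 nm), six charge groups of (-0.1, +0.1) e each.
#'
#' @param kind `"diatomic"`, `"planar4"` or `"benzene_like"`.
#' @param seed RNG seed (used by `planar4`).
#' @return A [molecule_topology()] with coordinates attached.
#' @export
gen_toy_molecule <- function(kind = c("diatomic", "planar4",
                                      "benzene_like"), seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "diatomic") {
    atoms <- data.frame(index = 1:2, name = c("A", "B"),
                        charge = c(-0.2, 0.2), charge_group = c(1L, 1L),
                        mass = c(12.011, 12.011),
                        x = c(0, 0.1), y = 0, z = 0)
    return(molecule_topology("diatomic", atoms, bonds = cbind(1L, 2L)))
  }
  if (kind == "planar4") {
    set.seed(seed)
    q <- stats::rnorm(4); q <- round(q - mean(q), 3)
    q[4] <- -sum(q[1:3])
    atoms <- data.frame(index = 1:4, name = paste0("A", 1:4),
                        charge = q, charge_group = 1L, mass = 12.011,
                        x = stats::runif(4, -0.15, 0.15),
                        y = stats::runif(4, -0.15, 0.15), z = 0)
    return(molecule_topology("planar4", atoms))
  }
  ang <- (0:5) * pi / 3
  atoms <- data.frame(
    index = 1:12,
    name = c(rbind(paste0("C", 1:6), paste0("H", 1:6))),
    charge = rep(c(-0.1, 0.1), 6),
    charge_group = rep(1:6, each = 2L),
    mass = rep(c(12.011, 1.008), 6),
    x = c(rbind(0.139 * cos(ang), 0.248 * cos(ang))),
    y = c(rbind(0.139 * sin(ang), 0.248 * sin(ang))),
    z = 0)
  bonds <- cbind(seq(1, 11, 2), seq(2, 12, 2))
  molecule_topology("benzene_like", atoms, bonds = bonds)
}
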