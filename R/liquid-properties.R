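## Liquid-phase observables from simulation time series: block-averaged
## density, enthalpy of vaporization, finite-difference response properties
## (thermal expansion, heat capacity, isothermal compressibility), the
## dipole-fluctuation dielectric constant with a running-average convergence
## check, and the total-energy drift quality criterion.

#' Construct an energy/volume observable series
#'
#' @param time Time stamps, ps, strictly increasing.
#' @param Epot Total system potential energy, kJ/mol (optional).
#' @param volume Box volume, nm^3 (optional).
#' @param pressure Pressure, bar (optional).
#' @param temperature Temperature, K (optional).
#' @param Etot Total (potential + kinetic) energy, kJ/mol (optional).
#' @param box_dipole N x 3 matrix of the box dipole M, e nm (optional).
#' @param n_molecules Number of molecules in the box.
#' @param n_dof Number of degrees of freedom (for the drift criterion).
#' @return Object of class `energy_volume_series`.
#' @export
energy_volume_series <- function(time, Epot = NULL, volume = NULL,
                                 pressure = NULL, temperature = NULL,
                                 Etot = NULL, box_dipole = NULL,
                                 n_molecules = 1L, n_dof = NULL) {
  time <- as.numeric(time)
  if (!length(time)) stop("series is empty")
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (n_molecules < 1L) stop("n_molecules must be >= 1")
  chk <- function(x, nm) {
    if (!is.null(x) && NROW(x) != length(time))
      stop(nm, " length does not match time")
    x
  }
  structure(list(time = time, Epot = chk(Epot, "Epot"),
                 volume = chk(volume, "volume"),
                 pressure = chk(pressure, "pressure"),
                 temperature = chk(temperature, "temperature"),
                 Etot = chk(Etot, "Etot"),
                 box_dipole = chk(box_dipole, "box_dipole"),
                 n_molecules = as.integer(n_molecules), n_dof = n_dof),
            class = "energy_volume_series")
}

#' Block average of a series
#'
#' Splits the series into `n_blocks` contiguous equal-length blocks
#' (remainder frames dropped from the tail), and returns the mean of the
#' block means with their standard deviation.
#'
#' @param x Numeric vector.
#' @param n_blocks Number of blocks (default 5).
#' @return List `mean`, `sd` (SD over block means), `n_blocks`.
#' @export
block_average <- function(x, n_blocks = 5L) {
  x <- as.numeric(x)
  L <- length(x) %/% n_blocks
  if (L < 1L) stop("series too short for ", n_blocks, " blocks")
  x <- x[seq_len(L * n_blocks)]
  bm <- colMeans(matrix(x, nrow = L))
  list(mean = mean(bm), sd = stats::sd(bm), n_blocks = as.integer(n_blocks))
}

#' Block-averaged liquid density
#'
#' Per-frame density rho = n_molecules * M / (N_A * V), converted to g/cm^3,
#' then block-averaged.
#'
#' @param series An [energy_volume_series()] with a volume column.
#' @param molar_mass Molar mass, g/mol.
#' @param n_blocks Number of blocks (default 5).
#' @return List `mean`, `sd` (g/cm^3), `n_blocks`.
#' @export
liquid_density <- function(series, molar_mass, n_blocks = 5L) {
  if (is.null(series$volume)) stop("series has no volume column")
  if (any(series$volume <= 0)) stop("volume must be positive")
  ## nm^3 -> cm^3 is 1e-21
  rho <- series$n_molecules * molar_mass /
    (aromring_constants$N_A * series$volume * 1e-21)
  block_average(rho, n_blocks)
}

#' Enthalpy of vaporization
#'
#' dHvap = (<E_pot(g)> + RT) - <E_pot(l)>/n_molecules, with the gas-phase
#' energy already per molecule and RT in kJ/mol (2.479 at 298.15 K).
#'
#' @param Epot_gas Mean gas-phase potential energy per molecule, kJ/mol.
#' @param Epot_liquid Mean total liquid potential energy, kJ/mol.
#' @param n_molecules Molecules in the liquid box.
#' @param T Temperature, K.
#' @return Enthalpy of vaporization, kJ/mol.
#' @export
enthalpy_of_vaporization <- function(Epot_gas, Epot_liquid, n_molecules,
                                     T = 298.15) {
  if (n_molecules < 1L) stop("n_molecules must be >= 1")
  (Epot_gas + rt_kj(T)) - Epot_liquid / n_molecules
}

## Pick the two extreme states when three (T-dT, T, T+dT) are supplied:
## the finite difference then spans the full interval (central difference).
fd_endpoints <- function(val, at) {
  if (length(val) != length(at)) stop("value and state vectors differ in length")
  if (length(val) < 2L) stop("need at least two states")
  if (length(val) > 3L) stop("at most three states are supported")
  o <- order(at)
  list(v = val[o][c(1L, length(o))], s = at[o][c(1L, length(o))])
}

#' Thermal expansion coefficient by finite differences
#'
#' alpha_P = -(ln rho(T2) - ln rho(T1)) / (T2 - T1). With three states
#' (T - dT, T, T + dT) the outer pair is used (central difference).
#'
#' @param rho Densities at the states, g/cm^3 (length 2 or 3).
#' @param T Temperatures, K, same length.
#' @return alpha_P in 1/K.
#' @export
thermal_expansion <- function(rho, T) {
  if (any(rho <= 0)) stop("densities must be positive")
  e <- fd_endpoints(rho, T)
  if (e$s[1] == e$s[2]) stop("temperatures must differ")
  -(log(e$v[2]) - log(e$v[1])) / (e$s[2] - e$s[1])
}

#' Classical isobaric heat capacity by finite differences
#'
#' C_P = (<U>(T2) - <U>(T1)) / ((T2 - T1) * n_molecules) with U the total
#' (potential + kinetic) system energy in kJ/mol; returned in J/(mol K).
#' No quantum corrections are applied (classical estimator).
#'
#' @param U Mean total energies at the states, kJ/mol (length 2 or 3).
#' @param T Temperatures, K, same length.
#' @param n_molecules Molecules in the box.
#' @return C_P in J/(mol K).
#' @export
heat_capacity <- function(U, T, n_molecules = 1L) {
  e <- fd_endpoints(U, T)
  if (e$s[1] == e$s[2]) stop("temperatures must differ")
  1000 * (e$v[2] - e$v[1]) / ((e$s[2] - e$s[1]) * n_molecules)
}

#' Isothermal compressibility by finite differences
#'
#' kappa_T = (ln rho(P2) - ln rho(P1)) / (P2 - P1), converted to 1/GPa.
#' The sign convention is the physically positive one: a liquid whose
#' density rises with pressure gives kappa_T > 0. With three states the
#' outer pressure pair is used.
#'
#' @param rho Densities at the states, g/cm^3 (length 2 or 3).
#' @param P Pressures, bar, same length.
#' @return kappa_T in 1/GPa.
#' @export
isothermal_compressibility <- function(rho, P) {
  if (any(rho <= 0)) stop("densities must be positive")
  e <- fd_endpoints(rho, P)
  if (e$s[1] == e$s[2]) stop("pressures must differ")
  ## per bar -> per GPa is 1e4
  1e4 * (log(e$v[2]) - log(e$v[1])) / (e$s[2] - e$s[1])
}

#' Static dielectric constant from box-dipole fluctuations
#'
#' epsilon = 1 + (<M^2> - <M>^2) / (3 eps0 V kB T) under conducting
#' ("tin-foil") boundary conditions, with M in e nm and V in nm^3. A
#' running-average trace of the estimate is returned together with a
#' convergence flag: converged when the relative spread of the estimate
#' over the final 20 percent of the trace is below 2 percent. An
#' unconverged result is still returned, flagged `FALSE`.
#'
#' @param series An [energy_volume_series()] with a `box_dipole` matrix.
#' @param volume Box volume, nm^3 (default: mean of the series volume).
#' @param T Temperature, K.
#' @return List `epsilon`, `running_average` (per-frame trace), `converged`.
#' @export
dielectric_constant <- function(series, volume = NULL, T = 298.15) {
  M <- series$box_dipole
  if (is.null(M)) stop("series has no box-dipole column")
  M <- as.matrix(M)
  if (is.null(volume)) {
    if (is.null(series$volume)) stop("volume not given and not in series")
    volume <- mean(series$volume)
  }
  if (volume <= 0 || T <= 0) stop("volume and temperature must be positive")
  cst <- aromring_constants
  ## (e nm)^2 / (eps0 nm^3 kB) in K units:
  pref <- (cst$e^2 * 1e-18) / (3 * cst$eps0 * 1e-27 * cst$kB)
  n <- nrow(M)
  cm <- apply(M, 2L, cumsum) / seq_len(n)
  cm2 <- apply(M^2, 2L, cumsum) / seq_len(n)
  fluct <- rowSums(cm2 - cm^2)
  trace <- 1 + pref * fluct / (volume * T)
  eps <- trace[n]
  tail_idx <- seq.int(max(1L, ceiling(0.8 * n)), n)
  spread <- diff(range(trace[tail_idx])) / abs(eps)
  list(epsilon = eps, running_average = trace, converged = spread < 0.02)
}

#' Total-energy drift quality criterion
#'
#' Absolute slope of the ordinary least-squares line through total energy
#' (kJ/mol) vs time (ps), normalized per nanosecond and per degree of
#' freedom, in J/(mol ns DoF); compared against the 0.5 J/(mol ns DoF)
#' quality threshold.
#'
#' @param series An [energy_volume_series()] with `Etot` and `n_dof`.
#' @param threshold Acceptance threshold, J/(mol ns DoF) (default 0.5).
#' @return List `drift` (J/(mol ns DoF)), `passes` (logical), `slope`
#'   (raw OLS slope, kJ/mol per ps).
#' @export
energy_drift <- function(series, threshold = 0.5) {
  if (is.null(series$Etot)) stop("series has no total-energy column")
  if (is.null(series$n_dof)) stop("series has no degrees-of-freedom count")
  if (length(series$time) < 10L) stop("need at least 10 samples for a drift estimate")
  fit <- stats::lm.fit(cbind(1, series$time), series$Etot)
  slope <- fit$coefficients[2]          # kJ/mol per ps
  drift <- abs(slope) * 1e6 / series$n_dof   # -> J/mol per ns per DoF
  list(drift = unname(drift), passes = unname(drift < threshold),
       slope = unname(slope))
}
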