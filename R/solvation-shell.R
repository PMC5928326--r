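## Solvation-shell structure around a reference (hetero)atom: radial
## distribution functions, the optimal binding distance (first RDF peak)
## and coordination number (shell integral), water-orientation
## classification, and the per-site summary row assembler.

#' Radial distribution function around reference atoms
#'
#' Standard shell-histogram estimator: pair counts per radial bin,
#' normalized by the ideal-gas expectation at the bulk number density of
#' the selected species, with minimum-image distances on the orthorhombic
#' box. Several reference atoms may be given; the estimate averages over
#' all of them (pairs where reference equals a selected atom are skipped).
#'
#' @param frames List of [trajectory_frame()] objects.
#' @param ref Integer vector of reference atom indices (1-based).
#' @param sel Integer vector of selected atom indices (e.g., water oxygens
#'   or hydrogens).
#' @param bin Bin width, nm; must not exceed a quarter of the smallest box
#'   edge.
#' @param r_max Histogram range, nm (default: half the smallest box edge).
#' @return Object of class `rdf_curve`: `r` (bin midpoints, nm), `g`
#'   (dimensionless), `rho_N` (bulk number density of `sel`, 1/nm^3).
#' @export
compute_rdf <- function(frames, ref, sel, bin = 0.01, r_max = NULL) {
  if (!length(frames)) stop("need at least one frame")
  if (bin <= 0) stop("bin must be positive")
  box0 <- frames[[1]]$box
  if (bin > min(box0) / 4)
    stop("bin width exceeds a quarter of the box edge")
  if (is.null(r_max)) r_max <- min(box0) / 2
  edges <- seq(0, r_max, by = bin)
  if (edges[length(edges)] < r_max) edges <- c(edges, r_max)
  counts <- numeric(length(edges) - 1L)
  rho_sum <- 0
  for (fr in frames) {
    xyz <- fr$coordinates
    box <- fr$box
    V <- prod(box)
    rho_sum <- rho_sum + length(sel) / V
    for (a in ref) {
      s <- setdiff(sel, a)
      d <- minimum_image(xyz[s, , drop = FALSE] -
                         matrix(xyz[a, ], length(s), 3L, byrow = TRUE), box)
      r <- sqrt(rowSums(d^2))
      counts <- counts + .bincode_counts(r, edges)
    }
  }
  rho_N <- rho_sum / length(frames)
  shell_vol <- 4 / 3 * pi * diff(edges^3)
  norm <- length(frames) * length(ref) * rho_N * shell_vol
  g <- counts / norm
  structure(list(r = (edges[-1] + edges[-length(edges)]) / 2, g = g,
                 rho_N = rho_N, bin = bin, edges = edges),
            class = "rdf_curve")
}

.bincode_counts <- function(r, edges) {
  b <- findInterval(r[r < edges[length(edges)]], edges,
                    rightmost.closed = TRUE)
  tabulate(b, nbins = length(edges) - 1L)
}

#' Optimal binding distance and coordination number from an RDF
#'
#' The optimal binding distance (OBD) is the position of the first local
#' maximum of g(r) with g > 1 whose height is at least `prominence` times
#' the following local minimum; the coordination number is
#' CN = rho_N * integral of 4 pi r^2 g(r) dr from 0 to that minimum
#' (trapezoidal). When no peak qualifies the curve is flagged
#' `"no structured shell"` and the global maximum position is returned with
#' a warning.
#'
#' @param curve An [compute_rdf()] result.
#' @param prominence Required peak-to-minimum height ratio (default 1.05).
#' @return List `OBD` (nm), `CN`, `r_min` (integration limit, nm),
#'   `flag` (`"ok"` or `"no structured shell"`).
#' @export
obd_cn <- function(curve, prominence = 1.05) {
  g <- curve$g; r <- curve$r
  n <- length(g)
  if (n < 3L) stop("RDF curve too short")
  is_max <- c(FALSE, g[2:(n - 1)] > g[1:(n - 2)] & g[2:(n - 1)] >= g[3:n],
              FALSE)
  next_min <- function(i) {
    j <- i + 1L
    while (j < n && !(g[j] <= g[j - 1L] && g[j] <= g[j + 1L])) j <- j + 1L
    j
  }
  peak <- NA_integer_
  for (i in which(is_max & g > 1)) {
    j <- next_min(i)
    if (g[i] >= prominence * g[j]) { peak <- i; break }
  }
  flag <- "ok"
  if (is.na(peak)) {
    flag <- "no structured shell"
    warning("no qualifying RDF peak; reporting the global maximum position")
    peak <- which.max(g)
  }
  j <- next_min(peak)
  ## binwise shell integral rho_N * sum 4/3 pi (r2^3 - r1^3) g_i: with the
  ## histogram's piecewise-constant g this is exactly the mean pair count
  ## inside r_min, so a constructed shell of N waters integrates to N.
  edges <- if (!is.null(curve$edges)) curve$edges
           else c(r - curve$bin / 2, r[length(r)] + curve$bin / 2)
  shell_vol <- 4 / 3 * pi * diff(edges^3)
  cn <- curve$rho_N * sum(shell_vol[seq_len(j)] * g[seq_len(j)])
  list(OBD = r[peak], CN = cn, r_min = edges[j + 1L], flag = flag)
}

#' Average orientation of first-shell water molecules
#'
#' For every water whose oxygen lies within `shell_radius` of the reference
#' atom (minimum image), the cosine of the angle between the water dipole
#' direction (the H-O-H bisector of a rigid 3-site water) and the vector
#' from the water oxygen to the reference atom is accumulated. Mean
#' cos >= 0.25 classifies the shell `"H-oriented"` (hydrogens toward the
#' atom), mean cos <= -0.25 `"O-oriented"`, otherwise `"Undefined"`.
#'
#' @param frames List of [trajectory_frame()] objects.
#' @param ref Reference atom index.
#' @param waters data.frame with columns `O`, `H1`, `H2` (atom indices of
#'   each rigid 3-site water).
#' @param shell_radius Shell radius, nm.
#' @param threshold Classification threshold on the mean cosine
#'   (default 0.25).
#' @return List `orientation`, `mean_cos`, `n_observations`.
#' @export
water_orientation <- function(frames, ref, waters, shell_radius,
                              threshold = 0.25) {
  waters <- as.data.frame(waters)
  if (!all(c("O", "H1", "H2") %in% names(waters)))
    stop("waters needs columns O, H1, H2 (rigid 3-site water)")
  cosines <- numeric(0)
  for (fr in frames) {
    xyz <- fr$coordinates; box <- fr$box
    vref <- minimum_image(matrix(xyz[ref, ], nrow(waters), 3L, byrow = TRUE) -
                          xyz[waters$O, , drop = FALSE], box)
    d <- sqrt(rowSums(vref^2))
    inshell <- which(d <= shell_radius & d > 0)
    if (!length(inshell)) next
    h1 <- minimum_image(xyz[waters$H1[inshell], , drop = FALSE] -
                        xyz[waters$O[inshell], , drop = FALSE], box)
    h2 <- minimum_image(xyz[waters$H2[inshell], , drop = FALSE] -
                        xyz[waters$O[inshell], , drop = FALSE], box)
    dip <- h1 + h2
    dn <- sqrt(rowSums(dip^2))
    cosines <- c(cosines,
                 rowSums(dip * vref[inshell, , drop = FALSE]) /
                   (dn * d[inshell]))
  }
  if (!length(cosines)) stop("empty solvation shell")
  if (length(cosines) < 100L)
    warning("fewer than 100 in-shell water observations; ",
            "orientation estimate may be unstable")
  m <- mean(cosines)
  orientation <- if (m >= threshold) "H-oriented"
                 else if (m <= -threshold) "O-oriented"
                 else "Undefined"
  list(orientation = orientation, mean_cos = m,
       n_observations = length(cosines))
}

#' Assemble the per-site hydration summary row
#'
#' Combines occupancy, residence-time kinetics, the Eyring breakage free
#' energy, RDF-derived coordination number and optimal binding distance,
#' and the orientation class into one report row. The trajectory is split
#' into `n_blocks` contiguous equal blocks; SDs of tau, dG, CN and OBD come
#' from the block scatter, while the Aver_HB SD is over per-frame counts.
#' Sites with fewer completed bonded intervals than `min_events` get `NA`
#' in the kinetic columns (rendered as empty cells by [write_report()]).
#'
#' @param molecule Molecule name.
#' @param series An `hbond_time_series` for the site.
#' @param rdf Either one [compute_rdf()] curve or a list of per-block
#'   curves (block SDs are then reported).
#' @param orientation Result of [water_orientation()] or a plain class
#'   string; `NA` to omit.
#' @param n_blocks Number of blocks (default 5).
#' @param T Temperature for the Eyring map, K.
#' @param min_events Sampling threshold passed to [residence_time()].
#' @return One-row data.frame in the report column order.
#' @export
hbond_site_report <- function(molecule, series, rdf = NULL,
                              orientation = NA, n_blocks = 5L, T = 298.15,
                              min_events = 20L) {
  occ <- hbond_occupancy(series, n_blocks)
  rt_all <- residence_time(bond_intervals(series), min_events = min_events,
                           dt = series$dt)

  ## per-block residence times for the SD
  nf <- nrow(series$pair_bonds)
  L <- nf %/% n_blocks
  block_tau <- rep(NA_real_, n_blocks)
  for (b in seq_len(n_blocks)) {
    rows <- ((b - 1L) * L + 1L):(b * L)
    iv <- bond_intervals(series$pair_bonds[rows, , drop = FALSE],
                         dt = series$dt)
    bt <- residence_time(iv, min_events = max(3L, min_events %/% n_blocks),
                         dt = series$dt)
    block_tau[b] <- bt$tau
  }
  tau_sd <- if (sum(is.finite(block_tau)) >= 2L)
    stats::sd(block_tau[is.finite(block_tau)]) else NA_real_

  tau <- rt_all$tau
  have_kin <- rt_all$flag %in% c("ok", "short_lived") && is.finite(tau)
  dG <- if (have_kin) hbond_free_energy(tau, T) else NA_real_
  dG_sd <- if (have_kin && sum(is.finite(block_tau)) >= 2L)
    stats::sd(hbond_free_energy(block_tau[is.finite(block_tau)], T))
    else NA_real_

  cn <- obd <- cn_sd <- obd_sd <- NA_real_
  if (!is.null(rdf)) {
    curves <- if (inherits(rdf, "rdf_curve")) list(rdf) else rdf
    res <- lapply(curves, obd_cn)
    cn <- mean(vapply(res, `[[`, numeric(1), "CN"))
    obd <- mean(vapply(res, `[[`, numeric(1), "OBD"))
    if (length(res) >= 2L) {
      cn_sd <- stats::sd(vapply(res, `[[`, numeric(1), "CN"))
      obd_sd <- stats::sd(vapply(res, `[[`, numeric(1), "OBD"))
    }
  }
  orient <- if (is.list(orientation)) orientation$orientation
            else as.character(orientation)

  data.frame(Molecule = molecule, Atom = series$label,
             Aver_HB = occ$Aver_HB, Aver_HB_sd = occ$Aver_HB_sd,
             tau_HB = tau, tau_HB_sd = tau_sd,
             lifetime_HB = if (have_kin) 1 / tau else NA_real_,
             dG_HB = dG, dG_HB_sd = dG_sd,
             Percent = occ$Percent,
             CN = cn, CN_sd = cn_sd, OBD_HB = obd, OBD_HB_sd = obd_sd,
             Orientation = orient,
             stringsAsFactors = FALSE)
}
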