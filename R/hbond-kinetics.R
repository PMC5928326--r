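## Geometric hydrogen-bond detection on orthorhombic periodic boxes and the
## derived per-site statistics: occupancy, residence time (survival-function
## exponential fit over uninterrupted bonded intervals), lifetime = 1/tau,
## and the Eyring breakage free energy.

## Minimum-image displacement for an orthorhombic box: rows of `d` are
## displacement vectors, `box` the 3 edge lengths.
minimum_image <- function(d, box) {
  d <- matrix(d, ncol = 3L)
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

#' Geometric hydrogen-bond criteria
#'
#' @param r_max Maximum donor-acceptor distance, nm (default 0.35).
#' @param angle_max Maximum hydrogen-donor-acceptor angle, degrees
#'   (default 30).
#' @return Object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(r_max = 0.35, angle_max = 30) {
  if (r_max <= 0 || angle_max <= 0) stop("criteria must be positive")
  structure(list(r_max = r_max, angle_max = angle_max),
            class = "hbond_criteria")
}

#' Detect hydrogen bonds in a trajectory
#'
#' A bond exists in a frame iff the minimum-image donor-acceptor distance is
#' at most `r_max` and the H-D-A angle is at most `angle_max`. Distances use
#' the minimum-image convention on the orthorhombic box of each frame.
#'
#' @param frames List of [trajectory_frame()] objects.
#' @param donors data.frame with columns `donor` and `hydrogen` (1-based
#'   atom indices; every hydrogen must have its covalent donor listed).
#' @param acceptors Integer vector of acceptor atom indices.
#' @param criteria An [hbond_criteria()].
#' @return Object of class `hbond_detection`: `pairs` (data.frame donor,
#'   hydrogen, acceptor), `bonds` (n_frames x n_pairs logical matrix),
#'   `dt` (frame spacing, ps), `times`.
#' @export
detect_hbonds <- function(frames, donors, acceptors,
                          criteria = hbond_criteria()) {
  donors <- as.data.frame(donors)
  if (!all(c("donor", "hydrogen") %in% names(donors)))
    stop("donors needs columns 'donor' and 'hydrogen'")
  nat <- nrow(frames[[1]]$coordinates)
  idx <- c(donors$donor, donors$hydrogen, acceptors)
  if (any(idx < 1L | idx > nat))
    stop("topology error: atom index outside 1..", nat)
  pairs <- expand.grid(dh = seq_len(nrow(donors)),
                       acceptor = as.integer(acceptors))
  pairs <- data.frame(donor = donors$donor[pairs$dh],
                      hydrogen = donors$hydrogen[pairs$dh],
                      acceptor = pairs$acceptor)
  pairs <- pairs[pairs$donor != pairs$acceptor, , drop = FALSE]
  rownames(pairs) <- NULL
  cosmax <- cos(criteria$angle_max * pi / 180)
  bonds <- matrix(FALSE, length(frames), nrow(pairs))
  for (f in seq_along(frames)) {
    xyz <- frames[[f]]$coordinates
    box <- frames[[f]]$box
    da <- minimum_image(xyz[pairs$acceptor, , drop = FALSE] -
                        xyz[pairs$donor, , drop = FALSE], box)
    dh <- minimum_image(xyz[pairs$hydrogen, , drop = FALSE] -
                        xyz[pairs$donor, , drop = FALSE], box)
    rda <- sqrt(rowSums(da^2))
    rdh <- sqrt(rowSums(dh^2))
    cosang <- rowSums(da * dh) / (rda * rdh)
    bonds[f, ] <- rda <= criteria$r_max & cosang >= cosmax
  }
  times <- vapply(frames, `[[`, numeric(1), "time")
  dt <- if (length(times) > 1L) stats::median(diff(times)) else NA_real_
  structure(list(pairs = pairs, bonds = bonds, dt = dt, times = times),
            class = "hbond_detection")
}

#' Per-site hydrogen-bond count series
#'
#' Collapses an [detect_hbonds()] result to the per-frame bond count of one
#' site atom, acting as donor, acceptor, or both.
#'
#' @param detection An `hbond_detection`.
#' @param site 1-based atom index of the site.
#' @param role `"donor"`, `"acceptor"` or `"both"`.
#' @param label Site label for reports (default the index).
#' @return Object of class `hbond_time_series`: `counts` (per frame),
#'   `pair_bonds` (indicator matrix restricted to this site's pairs),
#'   `dt`, `site`, `role`.
#' @export
hbond_site_series <- function(detection, site, role = c("both", "donor",
                                                        "acceptor"),
                              label = NULL) {
  role <- match.arg(role)
  p <- detection$pairs
  sel <- switch(role,
                donor = p$donor == site,
                acceptor = p$acceptor == site,
                both = p$donor == site | p$acceptor == site)
  pb <- detection$bonds[, sel, drop = FALSE]
  structure(list(site = site, role = role,
                 label = if (is.null(label)) as.character(site) else label,
                 counts = rowSums(pb), pair_bonds = pb, dt = detection$dt),
            class = "hbond_time_series")
}

#' Construct an H-bond count series directly
#'
#' @param counts Non-negative integer per-frame bond counts (length >= 2).
#' @param dt Frame spacing, ps.
#' @param site,role,label Site metadata.
#' @return An `hbond_time_series`. The single count series doubles as its
#'   own one-pair indicator for interval extraction.
#' @export
hbond_time_series <- function(counts, dt, site = NA, role = "both",
                              label = "site") {
  counts <- as.integer(counts)
  if (length(counts) < 2L) stop("series must have length >= 2")
  if (any(counts < 0L)) stop("bond counts must be non-negative")
  structure(list(site = site, role = role, label = label, counts = counts,
                 pair_bonds = matrix(counts > 0L, ncol = 1L), dt = dt),
            class = "hbond_time_series")
}

#' H-bond occupancy statistics
#'
#' `Aver_HB` is the mean per-frame bond count with its SD over per-frame
#' values; `Percent` is the percentage of frames with at least one bond.
#'
#' @param series An `hbond_time_series`.
#' @param n_blocks Blocks for the block-mean SD (default 5), reported as
#'   `block_sd` for derived quantities.
#' @return List `Aver_HB`, `Aver_HB_sd`, `Percent`, `block_sd`.
#' @export
hbond_occupancy <- function(series, n_blocks = 5L) {
  cnt <- series$counts
  ba <- block_average(cnt, n_blocks)
  list(Aver_HB = mean(cnt), Aver_HB_sd = stats::sd(cnt),
       Percent = 100 * mean(cnt >= 1L), block_sd = ba$sd)
}

#' Extract completed bonded-interval durations from indicator series
#'
#' Runs of consecutive bonded frames are converted to durations (run length
#' times `dt`). Runs touching either end of the series are censored and
#' dropped, so only completed intervals are returned.
#'
#' @param x An `hbond_time_series`, or a logical/0-1 matrix with one column
#'   per donor-hydrogen/acceptor pair.
#' @param dt Frame spacing in ps (taken from the series if available).
#' @return Numeric vector of interval durations, ps.
#' @export
bond_intervals <- function(x, dt = NULL) {
  if (inherits(x, "hbond_time_series")) {
    if (is.null(dt)) dt <- x$dt
    x <- x$pair_bonds
  }
  x <- as.matrix(x)
  if (is.null(dt) || is.na(dt)) stop("frame spacing dt is required")
  out <- lapply(seq_len(ncol(x)), function(j) {
    r <- rle(as.logical(x[, j]))
    if (!length(r$lengths)) return(numeric(0))
    keep <- r$values
    ## censor runs touching the ends
    if (keep[1]) keep[1] <- FALSE
    if (keep[length(keep)]) keep[length(keep)] <- FALSE
    r$lengths[keep] * dt
  })
  unlist(out)
}

#' Residence time from bonded-interval durations
#'
#' Builds the bond survival function C(t) = sum_j max(L_j - t, 0) /
#' sum_j L_j (the uninterrupted-bond autocorrelation implied by the
#' interval durations L_j; exactly exp(-t/tau) in expectation for
#' exponential dwell times) and fits a single exponential to it by
#' log-linear least squares over C >= 0.01. The lifetime is 1/tau by
#' definition.
#'
#' @param intervals Completed bonded-interval durations, ps (e.g., from
#'   [bond_intervals()]), or ground-truth dwell times from a generator.
#' @param min_events Minimum number of completed intervals required
#'   (default 20); below it the estimate is suppressed and flagged, the way
#'   sparsely sampled sites are reported as "-" in summary tables.
#' @param dt Optional frame spacing, ps; an estimate with tau <= dt is
#'   flagged `short_lived`.
#' @return List `tau` (ps), `lifetime` (1/ps), `n_events`, `flag`
#'   (`"ok"`, `"insufficient_sampling"`, `"short_lived"` or `"degenerate"`).
#' @export
residence_time <- function(intervals, min_events = 20L, dt = NULL) {
  intervals <- intervals[is.finite(intervals) & intervals > 0]
  n <- length(intervals)
  if (n < min_events)
    return(list(tau = NA_real_, lifetime = NA_real_, n_events = n,
                flag = "insufficient_sampling"))
  tmax <- stats::quantile(intervals, 0.98, names = FALSE)
  tgrid <- seq(0, tmax, length.out = 200L)
  tot <- sum(intervals)
  surv <- vapply(tgrid, function(t) sum(pmax(intervals - t, 0)) / tot,
                 numeric(1))
  use <- surv >= 0.01 & tgrid > 0
  if (sum(use) < 2L)
    return(list(tau = NA_real_, lifetime = NA_real_, n_events = n,
                flag = "degenerate"))
  slope <- stats::lm.fit(cbind(tgrid[use]), log(surv[use]))$coefficients[1]
  if (!is.finite(slope) || slope >= 0)
    return(list(tau = NA_real_, lifetime = NA_real_, n_events = n,
                flag = "degenerate"))
  tau <- unname(-1 / slope)
  flag <- if (!is.null(dt) && is.finite(dt) && tau <= dt) "short_lived" else "ok"
  list(tau = tau, lifetime = 1 / tau, n_events = n, flag = flag)
}

#' Eyring free energy of hydrogen-bond breakage
#'
#' Inverts the first-order breakage rate k = 1/tau through the Eyring
#' equation k = (kB T / h) exp(-dG / RT):
#' dG = RT ln(tau kB T / h), with tau converted to seconds inside the
#' logarithm. Strictly increasing in tau; dG = 0 at tau = h/(kB T)
#' (about 1.6e-4 ps at 298.15 K).
#'
#' @param tau Residence time, ps (> 0).
#' @param T Temperature, K (default 298.15).
#' @return Free energy of breakage, kJ/mol.
#' @export
hbond_free_energy <- function(tau, T = 298.15) {
  if (any(!is.finite(tau) | tau <= 0)) stop("tau must be positive")
  cst <- aromring_constants
  rt_kj(T) * log(tau * 1e-12 * cst$kB * T / cst$h)
}
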