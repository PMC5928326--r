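## Independent brute-force oracles, deliberately written as plain loops so
## they share no code path with the vectorized implementations they check.

## Minimum-image distance between two points, written out longhand.
oracle_mic_dist <- function(a, b, box) {
  d <- numeric(3)
  for (k in 1:3) {
    dd <- b[k] - a[k]
    dd <- dd - box[k] * round(dd / box[k])
    d[k] <- dd
  }
  sqrt(sum(d^2))
}

oracle_mic_vec <- function(a, b, box) {
  d <- numeric(3)
  for (k in 1:3) {
    dd <- b[k] - a[k]
    d[k] <- dd - box[k] * round(dd / box[k])
  }
  d
}

## Triple loop over (frame, acceptor, donor-hydrogen): a bond exists iff
## r(D,A) <= r_max and the H-D-A angle <= angle_max. Pairs are enumerated
## acceptor-major (donor varying fastest) to line up with the detector's
## pair table.
oracle_hbond_counts <- function(frames, donors, acceptors, r_max = 0.35,
                                angle_max = 30) {
  res <- list()
  for (f in seq_along(frames)) {
    xyz <- frames[[f]]$coordinates
    box <- frames[[f]]$box
    row <- logical(0)
    for (a in acceptors) {
      for (i in seq_len(nrow(donors))) {
        if (donors$donor[i] == a) next
        da <- oracle_mic_vec(xyz[donors$donor[i], ], xyz[a, ], box)
        dh <- oracle_mic_vec(xyz[donors$donor[i], ],
                             xyz[donors$hydrogen[i], ], box)
        r <- sqrt(sum(da^2))
        ang <- acos(max(-1, min(1, sum(da * dh) /
                                  (r * sqrt(sum(dh^2)))))) * 180 / pi
        row <- c(row, r <= r_max && ang <= angle_max)
      }
    }
    res[[f]] <- row
  }
  do.call(rbind, res)
}

## Random toy system for the H-bond oracle comparison: a few donor-hydrogen
## units and acceptors scattered in a periodic box.
random_hbond_system <- function(n_donors = 5, n_acceptors = 8, n_frames = 10,
                                box = 1.2) {
  nat <- 2 * n_donors + n_acceptors
  frames <- lapply(seq_len(n_frames), function(f) {
    xyz <- matrix(runif(3 * nat, 0, box), ncol = 3)
    ## put each hydrogen close to its donor
    for (i in seq_len(n_donors))
      xyz[n_donors + i, ] <- xyz[i, ] + rnorm(3, 0, 0.04)
    trajectory_frame((f - 1) * 2, xyz, rep(box, 3))
  })
  list(frames = frames,
       donors = data.frame(donor = seq_len(n_donors),
                           hydrogen = n_donors + seq_len(n_donors)),
       acceptors = 2 * n_donors + seq_len(n_acceptors))
}

## Exhaustive grid search over the feasible charge simplex of a 4-atom,
## one-group, neutral molecule: shifts for atoms 1..3 on a step-1e-3 grid,
## atom 4 balancing the group sum. For a planar molecule the dipole map has
## a null direction, so the least-squares optimum is a one-parameter
## family; ties (up to the grid's objective quantization) are broken by the
## smallest total shift norm, the solution the constrained least-squares
## problem is defined to return.
oracle_charge_grid <- function(molecule, target, half_range = 0.05,
                               step = 1e-3) {
  a <- molecule$atoms
  r <- as.matrix(a[, c("x", "y", "z")])
  r0 <- colMeans(r)
  A <- t(sweep(r, 2, r0))
  q0 <- a$charge
  mu0 <- as.numeric(A %*% q0)
  b <- A[, 1:3, drop = FALSE] - A[, c(4, 4, 4), drop = FALSE]
  grid <- seq(-half_range, half_range, by = step)
  g <- expand.grid(d1 = grid, d2 = grid, d3 = grid)
  mx <- mu0[1] + b[1, 1] * g$d1 + b[1, 2] * g$d2 + b[1, 3] * g$d3 - target[1]
  my <- mu0[2] + b[2, 1] * g$d1 + b[2, 2] * g$d2 + b[2, 3] * g$d3 - target[2]
  mz <- mu0[3] + b[3, 1] * g$d1 + b[3, 2] * g$d2 + b[3, 3] * g$d3 - target[3]
  obj <- mx^2 + my^2 + mz^2
  ## stepping along a flat valley off-grid perturbs the objective by at
  ## most (sigma_max(b) * step)^2
  tol <- (norm(b, "2") * step)^2
  cand <- which(obj <= min(obj) + tol)
  shift2 <- g$d1[cand]^2 + g$d2[cand]^2 + g$d3[cand]^2 +
    (g$d1[cand] + g$d2[cand] + g$d3[cand])^2
  i <- cand[which.min(shift2)]
  delta <- c(g$d1[i], g$d2[i], g$d3[i])
  c(q0[1:3] + delta, q0[4] - sum(delta))
}
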