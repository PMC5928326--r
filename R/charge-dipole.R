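## Molecular dipoles from point charges, the QM<->MM dipole angle theta, and
## constrained adjustment of partial charges toward a target (QM) dipole
## under charge-group, frozen-atom and shift-size constraints.

#' Construct a dipole vector
#'
#' @param components Length-3 numeric vector in e nm.
#' @return Object of class `dipole_vector` with the components and the
#'   magnitude in Debye (1 e nm = 48.0321 D).
#' @export
dipole_vector <- function(components) {
  components <- as.numeric(components)
  if (length(components) != 3L || !all(is.finite(components)))
    stop("dipole components must be 3 finite numbers (e nm)")
  structure(list(components = components,
                 magnitude_debye = aromring_constants$enm_to_debye *
                   sqrt(sum(components^2))),
            class = "dipole_vector")
}

#' @export
print.dipole_vector <- function(x, ...) {
  cat(sprintf("dipole (%.5f, %.5f, %.5f) e nm  |mu| = %.4f D\n",
              x$components[1], x$components[2], x$components[3],
              x$magnitude_debye))
  invisible(x)
}

#' Molecular dipole moment from point charges
#'
#' mu = sum_i q_i (r_i - r_origin). For a neutral molecule the result is
#' independent of the origin; for ions the declared origin is used and
#' recorded in the result's `origin` attribute.
#'
#' @param molecule A [molecule_topology()] with coordinates attached.
#' @param origin `"center_of_geometry"` or `"center_of_mass"`.
#' @return A [dipole_vector()].
#' @export
compute_dipole <- function(molecule,
                           origin = c("center_of_geometry", "center_of_mass")) {
  origin <- match.arg(origin)
  a <- molecule$atoms
  if (!all(c("x", "y", "z") %in% names(a)) || anyNA(a[, c("x", "y", "z")]))
    stop("molecule has no coordinates; use set_coordinates()")
  if (!("charge" %in% names(a)) || anyNA(a$charge))
    stop("molecule has missing partial charges")
  r <- as.matrix(a[, c("x", "y", "z")])
  r0 <- if (origin == "center_of_geometry") colMeans(r)
        else colSums(r * a$mass) / sum(a$mass)
  mu <- colSums(sweep(r, 2L, r0) * a$charge)
  out <- dipole_vector(mu)
  attr(out, "origin") <- origin
  out
}

#' Angle between two dipole vectors, in degrees
#'
#' @param a,b [dipole_vector()] objects or length-3 numeric vectors (e nm).
#' @return Angle in \[0, 180\] degrees.
#' @export
dipole_angle <- function(a, b) {
  va <- if (inherits(a, "dipole_vector")) a$components else as.numeric(a)
  vb <- if (inherits(b, "dipole_vector")) b$components else as.numeric(b)
  na <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
  if (na < 1e-12 || nb < 1e-12)
    stop("dipole angle undefined for a (near-)zero vector")
  cr <- c(va[2] * vb[3] - va[3] * vb[2],
          va[3] * vb[1] - va[1] * vb[3],
          va[1] * vb[2] - va[2] * vb[1])
  ## atan2 form is well conditioned near 0 and 180 degrees
  atan2(sqrt(sum(cr^2)), sum(va * vb)) * 180 / pi
}

#' Specification for a constrained charge fit
#'
#' @param target_dipole [dipole_vector()] or length-3 vector (e nm): the QM
#'   reference dipole to reproduce.
#' @param frozen Integer vector of 1-based atom indices whose charges are
#'   held fixed.
#' @param group_targets Named numeric vector mapping charge-group id to its
#'   required (integer) charge sum in e. Defaults to the rounded current
#'   group sums of the molecule.
#' @param overlap Optional data.frame with columns `atom`, `group`: atoms
#'   shared by two superimposed charge groups. Each overlap atom enters its
#'   primary group's sum (via `charge_group`) and additionally the listed
#'   second group's sum, so both group constraints act on it.
#' @param max_shift Largest allowed per-atom charge change in e (default
#'   0.5); violations are reported, not enforced.
#' @return Object of class `charge_fit_spec`.
#' @export
charge_fit_spec <- function(target_dipole, frozen = integer(0),
                            group_targets = NULL, overlap = NULL,
                            max_shift = 0.5) {
  tv <- if (inherits(target_dipole, "dipole_vector")) target_dipole
        else dipole_vector(target_dipole)
  if (!is.null(overlap)) {
    overlap <- as.data.frame(overlap)
    if (!all(c("atom", "group") %in% names(overlap)))
      stop("overlap needs columns 'atom' and 'group'")
    if (length(intersect(overlap$atom, frozen)) &&
        !all(overlap$atom %in% frozen))
      stop("frozen and overlap atom sets must be disjoint or identical")
  }
  structure(list(target_dipole = tv, frozen = as.integer(frozen),
                 group_targets = group_targets, overlap = overlap,
                 max_shift = max_shift),
            class = "charge_fit_spec")
}

## Moore-Penrose pseudo-inverse via SVD.
pinv <- function(M, tol = 1e-10) {
  s <- svd(M)
  pos <- s$d > tol * max(s$d, 1)
  if (!any(pos)) return(matrix(0, ncol(M), nrow(M)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Fit partial charges to reproduce a target dipole
#'
#' Minimizes the squared norm of mu(q) - mu_target over per-atom charge
#' shifts, subject to (i) each charge group summing to its (integer) target
#' and (ii) frozen atoms unchanged. Solved as equality-constrained linear
#' least squares; among equally good solutions the minimal-norm shift is
#' returned, making the result deterministic even when the system is
#' underdetermined. The per-atom shift bound `max_shift` is checked a
#' posteriori: a violation produces a warning and sets the `shift_exceeded`
#' flag rather than failing.
#'
#' @param molecule A [molecule_topology()] with coordinates.
#' @param spec A [charge_fit_spec()].
#' @param origin Dipole origin convention, as in [compute_dipole()].
#' @return Object of class `charge_fit_result`: `charges` (fitted, e),
#'   `theta_deg` (angle between achieved and target dipole, degrees),
#'   `dipole_mm` (achieved [dipole_vector()]), `residual_norm` (e nm),
#'   `shift`, `shift_exceeded`.
#' @export
fit_charges_to_dipole <- function(molecule, spec,
                                  origin = c("center_of_geometry",
                                             "center_of_mass")) {
  origin <- match.arg(origin)
  a <- molecule$atoms
  n <- nrow(a)
  q0 <- a$charge
  r <- as.matrix(a[, c("x", "y", "z")])
  r0 <- if (origin == "center_of_geometry") colMeans(r)
        else colSums(r * a$mass) / sum(a$mass)
  A <- t(sweep(r, 2L, r0))                      # 3 x n; mu = A %*% q

  groups <- sort(unique(a$charge_group))
  group_members <- function(g) {
    members <- which(a$charge_group == g)
    if (!is.null(spec$overlap))
      members <- union(members,
                       match(spec$overlap$atom[spec$overlap$group == g],
                             a$index))
    members[!is.na(members)]
  }
  gt <- spec$group_targets
  if (is.null(gt)) {
    gt <- vapply(groups, function(g) round(sum(q0[group_members(g)])),
                 numeric(1))
    names(gt) <- groups
  }
  if (!all(as.character(groups) %in% names(gt)))
    stop("group_targets must cover every charge group: missing ",
         paste(setdiff(as.character(groups), names(gt)), collapse = ", "))

  ## Constraint rows: one per charge group (overlap atoms enter both their
  ## groups' rows), one per frozen atom.
  C <- matrix(0, 0, n); d <- numeric(0); row_lab <- character(0)
  for (g in groups) {
    members <- group_members(g)
    row <- numeric(n); row[members] <- 1
    C <- rbind(C, row)
    d <- c(d, gt[[as.character(g)]] - sum(q0[members]))
    row_lab <- c(row_lab, paste0("group ", g))
  }
  for (idx in spec$frozen) {
    pos <- match(idx, a$index)
    if (is.na(pos)) stop("frozen atom index ", idx, " not in molecule")
    row <- numeric(n); row[pos] <- 1
    C <- rbind(C, row); d <- c(d, 0)
    row_lab <- c(row_lab, paste0("frozen atom ", idx))
  }

  ## Minimum-norm particular solution of C delta = d; consistency check.
  delta_p <- as.numeric(pinv(C) %*% d)
  resid_c <- as.numeric(C %*% delta_p - d)
  if (any(abs(resid_c) > 1e-8))
    stop("infeasible charge constraints; conflicting rows: ",
         paste(row_lab[abs(resid_c) > 1e-8], collapse = ", "))

  ## Null space of C spans the admissible shift directions.
  sv <- svd(C, nv = n)
  small <- which(sv$d <= 1e-10 * max(sv$d, 1))
  keep <- c(small, setdiff(seq_len(n), seq_along(sv$d)))
  Z <- sv$v[, keep, drop = FALSE]

  b <- spec$target_dipole$components - as.numeric(A %*% q0)
  if (ncol(Z)) {
    G <- A %*% Z
    y <- as.numeric(pinv(G) %*% (b - as.numeric(A %*% delta_p)))
    delta <- delta_p + as.numeric(Z %*% y)
  } else delta <- delta_p

  q <- q0 + delta
  shift_exceeded <- any(abs(delta) > spec$max_shift + 1e-12)
  if (shift_exceeded)
    warning(sprintf("max |charge shift| %.3f e exceeds the %.3f e bound",
                    max(abs(delta)), spec$max_shift))
  mu <- as.numeric(A %*% q)
  dip <- dipole_vector(mu)
  theta <- if (sqrt(sum(mu^2)) < 1e-12 ||
               sqrt(sum(spec$target_dipole$components^2)) < 1e-12)
    NA_real_ else dipole_angle(dip, spec$target_dipole)
  structure(list(charges = q, theta_deg = theta, dipole_mm = dip,
                 residual_norm = sqrt(sum((mu - spec$target_dipole$components)^2)),
                 shift = delta, shift_exceeded = shift_exceeded),
            class = "charge_fit_result")
}

#' @export
print.charge_fit_result <- function(x, ...) {
  cat(sprintf("charge fit: theta = %s deg, |mu_MM| = %.4f D, residual %.3e e nm%s\n",
              ifelse(is.na(x$theta_deg), "NA", sprintf("%.4g", x$theta_deg)),
              x$dipole_mm$magnitude_debye, x$residual_norm,
              if (x$shift_exceeded) " [shift bound exceeded]" else ""))
  invisible(x)
}
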