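# Sampling geometry: rotation matrices, the spherical centre-of-mass grid,
# rotamer schemes, the body-frame rotation axes, frontal alignment, and the
# cylindrical grid variant for flat, elongated receptor surfaces.

#' Rotation about the x axis
#'
#' Sign convention: applied to a centre of mass starting on the positive z
#' axis at distance d, the ordinate after rotation is `y' = d * sin(theta)`.
#'
#' @param theta angle in radians.
#' @return 3 x 3 proper rotation matrix.
#' @export
rotation_x <- function(theta) {
  ct <- cos(theta); st <- sin(theta)
  matrix(c(1, 0, 0,
           0, ct, st,
           0, -st, ct), nrow = 3, byrow = TRUE)
}

#' Rotation about the z axis
#' @param phi angle in radians.
#' @return 3 x 3 proper rotation matrix.
#' @export
rotation_z <- function(phi) {
  cp <- cos(phi); sp <- sin(phi)
  matrix(c(cp, -sp, 0,
           sp, cp, 0,
           0, 0, 1), nrow = 3, byrow = TRUE)
}

#' Rotation about an arbitrary axis (Rodrigues form)
#' @param axis length-3 vector (need not be unit).
#' @param angle angle in radians.
#' @return 3 x 3 proper rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("zero rotation axis")
  u <- axis / n
  ct <- cos(angle); st <- sin(angle)
  ux <- matrix(c(0, -u[3], u[2],
                 u[3], 0, -u[1],
                 -u[2], u[1], 0), nrow = 3, byrow = TRUE)
  ct * diag(3) + st * ux + (1 - ct) * (u %o% u)
}

#' Build the spherical centre-of-mass grid
#'
#' The mobile protein's CM is swept over the sphere of radius `d` around the
#' fixed protein's CM so that neighbouring CMs are about `delta_d` apart:
#' `delta_theta = delta_d / d`, `n_theta = trunc(pi / delta_theta)` (truncation
#' keeps the spacing at or above the requested resolution), rings at
#' `theta_i = i * pi / n_theta` for `i = 0..n_theta`, and per ring
#' `n_phi_i = max(1, trunc(2 * pi / delta_phi_i))` with
#' `delta_phi_i = delta_d / (d * sin(theta_i))`.  Polar rings collapse to a
#' single point.  Every ring starts at `phi = 0`.
#'
#' @param d CM-CM distance of the starting structure (Angstrom).
#' @param delta_d requested spatial resolution (Angstrom, default 1).
#' @return A `GridSpec`: d, delta_d, delta_theta, n_theta, ring tables
#'   (thetas, delta_phis, n_phis), `total`, a per-point data frame `points`
#'   (theta, phi) and the CM coordinate matrix `cm` (total x 3).
#' @export
build_cm_grid <- function(d, delta_d = 1) {
  if (delta_d <= 0) stop("delta_d must be positive")
  if (delta_d > d) stop("delta_d must not exceed d")
  delta_theta <- delta_d / d
  n_theta <- trunc(pi / delta_theta)
  thetas <- (0:n_theta) * pi / n_theta
  sin_t <- sin(thetas)
  delta_phis <- ifelse(sin_t > 1e-12, delta_d / (d * sin_t), Inf)
  n_phis <- pmax(1L, trunc(2 * pi / delta_phis))
  theta_pt <- rep(thetas, n_phis)
  phi_pt <- unlist(lapply(n_phis, function(n) (0:(n - 1)) * 2 * pi / n))
  cm <- t(vapply(seq_along(theta_pt), function(i) {
    rotation_z(phi_pt[i]) %*% rotation_x(theta_pt[i]) %*% c(0, 0, d)
  }, numeric(3)))
  structure(list(d = d, delta_d = delta_d, delta_theta = delta_theta,
                 n_theta = n_theta, thetas = thetas, delta_phis = delta_phis,
                 n_phis = n_phis, total = sum(n_phis),
                 points = data.frame(theta = theta_pt, phi = phi_pt),
                 cm = cm, p_ref = c(0, 0, d)),
            class = "GridSpec")
}

#' @export
print.GridSpec <- function(x, ...) {
  cat("GridSpec: d =", x$d, "A, delta_d =", x$delta_d, "A,",
      x$n_theta + 1, "theta rings,", x$total, "CM placements\n")
  invisible(x)
}

#' Cylindrical centre-of-mass grid for flat, elongated surfaces
#'
#' Places mobile CMs on a cylinder around `axis`: translation levels spaced
#' `delta_d` apart spanning `[-extent/2, +extent/2]` (inclusive endpoints)
#' and, per ring, `max(1, trunc(2 * pi * radius / delta_d))` angular steps so
#' that neighbouring CMs are about `delta_d` apart.  The default axis is the
#' long axis of the fixed structure (the largest-spread principal axis of the
#' mass-weighted gyration tensor).
#'
#' @param fixed a `RigidStructure` (used for the default axis and centre).
#' @param axis unit 3-vector; default the long axis of `fixed`.
#' @param delta_d spacing between neighbouring CMs (Angstrom).
#' @param extent axial span of the grid (Angstrom).
#' @param radius cylinder radius: distance of the mobile CM from the axis.
#' @param center point on the axis; default the CM of `fixed`.
#' @return A `CylinderGrid` with per-point (level, alpha) and `cm` matrix.
#' @export
cylindrical_grid <- function(fixed, axis = NULL, delta_d = 1, extent, radius,
                             center = NULL) {
  if (extent <= 0) stop("extent must be positive")
  if (delta_d <= 0) stop("delta_d must be positive")
  if (is.null(axis)) axis <- principal_axis(fixed)
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("zero axis")
  axis <- axis / n
  if (is.null(center)) center <- center_of_mass(fixed)
  levels <- seq(-extent / 2, extent / 2, by = delta_d)
  n_alpha <- max(1L, trunc(2 * pi * radius / delta_d))
  alphas <- (0:(n_alpha - 1)) * 2 * pi / n_alpha
  # orthonormal frame completing the axis
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  pts <- expand.grid(alpha = alphas, level = levels)[, c("level", "alpha")]
  cm <- t(apply(pts, 1, function(p) {
    center + p[["level"]] * axis +
      radius * (cos(p[["alpha"]]) * e1 + sin(p[["alpha"]]) * e2)
  }))
  structure(list(axis = axis, radius = radius, center = center,
                 delta_d = delta_d, extent = extent, levels = levels,
                 n_alpha = n_alpha, alphas = alphas, points = pts,
                 cm = cm, total = nrow(pts),
                 p_ref = center + radius * e1, e1 = e1, e2 = e2),
            class = "CylinderGrid")
}

#' Long axis of a structure
#'
#' The principal axis of largest spatial spread: the eigenvector of the
#' mass-weighted gyration tensor with the largest eigenvalue.
#'
#' @param structure a `RigidStructure`.
#' @return Unit 3-vector.
#' @export
principal_axis <- function(structure) {
  xyz <- coords(structure)
  w <- structure$atoms$mass
  cm <- colSums(xyz * w) / sum(w)
  xc <- sweep(xyz, 2, cm)
  g <- crossprod(xc * sqrt(w / sum(w)))
  ev <- eigen(g, symmetric = TRUE)
  v <- ev$vectors[, 1]
  v / sqrt(sum(v^2))
}

#' Rotamer scheme
#'
#' Enumeration of the body rotations (chi, psi, xi) about the mobile CM.  The
#' full scheme covers chi, psi in `[0, 360)` and xi in `[0, 180)`; the reduced
#' composite scheme covers chi, psi in `[-45, 45)` with 5-degree steps and xi
#' in `[0, 360)` with 15-degree steps.  All intervals are half-open, which
#' makes the reduced scheme enumerate exactly 18 * 18 * 24 = 7,776 rotamers.
#'
#' @param mode `"full"` or `"reduced"`.
#' @param delta increment (degrees) for chi and psi (and xi in full mode
#'   unless `delta_xi` is given).
#' @param delta_xi increment for xi; defaults to `delta` (full) or 15
#'   (reduced).
#' @return A `RotamerScheme` with per-axis half-open ranges and increments.
#' @export
rotamer_scheme <- function(mode = c("full", "reduced"), delta = 5,
                           delta_xi = NULL) {
  mode <- match.arg(mode)
  if (mode == "full") {
    if (is.null(delta_xi)) delta_xi <- delta
    rng <- list(chi = c(0, 360), psi = c(0, 360), xi = c(0, 180))
  } else {
    if (is.null(delta_xi)) delta_xi <- 15
    rng <- list(chi = c(-45, 45), psi = c(-45, 45), xi = c(0, 360))
  }
  inc <- c(chi = delta, psi = delta, xi = delta_xi)
  for (ax in names(rng)) {
    w <- diff(rng[[ax]])
    if (abs(w / inc[[ax]] - round(w / inc[[ax]])) > 1e-9)
      stop("increment for ", ax, " (", inc[[ax]],
           " deg) does not divide its range width (", w, " deg)")
  }
  structure(list(mode = mode, chi_range = rng$chi, psi_range = rng$psi,
                 xi_range = rng$xi, delta_chi = delta, delta_psi = delta,
                 delta_xi = delta_xi),
            class = "RotamerScheme")
}

#' Number of rotamers in a scheme
#' @param scheme a `RotamerScheme`.
#' @return Integer count `n_chi * n_psi * n_xi` on the half-open ranges.
#' @export
rotamer_count <- function(scheme) {
  n <- function(rng, d) as.integer(round(diff(rng) / d))
  n(scheme$chi_range, scheme$delta_chi) *
    n(scheme$psi_range, scheme$delta_psi) *
    n(scheme$xi_range, scheme$delta_xi)
}

#' Enumerate the rotamers of a scheme
#'
#' Lexicographic order: chi outermost, xi innermost; deterministic.
#'
#' @param scheme a `RotamerScheme`.
#' @return Matrix (count x 3) of (chi, psi, xi) in degrees.
#' @export
enumerate_rotamers <- function(scheme) {
  vals <- function(rng, d) seq(rng[1], rng[2] - d, by = d)
  chi <- vals(scheme$chi_range, scheme$delta_chi)
  psi <- vals(scheme$psi_range, scheme$delta_psi)
  xi <- vals(scheme$xi_range, scheme$delta_xi)
  g <- expand.grid(xi = xi, psi = psi, chi = chi,
                   KEEP.OUT.ATTRS = FALSE)[, c("chi", "psi", "xi")]
  m <- as.matrix(g)
  dimnames(m) <- list(NULL, c("chi", "psi", "xi"))
  m
}

#' Body-frame rotation axes
#'
#' The chi axis is the normal `(A, B, C)` of the plane through the two CMs
#' and the mobile protein's reference (Fe) atom, with `A = y1 z2 - y2 z1`,
#' `B = x2 z1 - x1 z2`, `C = x1 y2 - y1 x2` for the CM-CM vector
#' `(x1, y1, z1)` and reference point `(x2, y2, z2)` (fixed CM at the
#' origin).  The xi axis lies along the CM-CM vector and the psi axis along
#' `(C y1 - B z1, A z1 - C x1, B x1 - A y1)`, perpendicular to both.
#'
#' @param cm_fixed fixed-protein CM (the frame is translated so this is the
#'   origin).
#' @param cm_mobile mobile-protein CM.
#' @param fe_position reference atom of the mobile cofactor (e.g. the heme
#'   Fe).
#' @return An `AxesFrame`: unit `chi_axis`, `psi_axis`, `xi_axis` and the
#'   plane coefficients A, B, C (D = 0).
#' @export
build_axes <- function(cm_fixed, cm_mobile, fe_position) {
  v1 <- cm_mobile - cm_fixed
  v2 <- fe_position - cm_fixed
  n <- c(v1[2] * v2[3] - v2[2] * v1[3],
         v2[1] * v1[3] - v1[1] * v2[3],
         v1[1] * v2[2] - v1[2] * v2[1])
  scale <- sqrt(sum(v1^2)) * sqrt(sum(v2^2))
  if (sqrt(sum(n^2)) <= 1e-9 * max(scale, 1))
    stop("the two CMs and the reference atom are collinear; ",
         "supply a fallback reference atom off the CM-CM line")
  psi <- c(n[3] * v1[2] - n[2] * v1[3],
           n[1] * v1[3] - n[3] * v1[1],
           n[2] * v1[1] - n[1] * v1[2])
  unit <- function(v) v / sqrt(sum(v^2))
  structure(list(A = n[1], B = n[2], C = n[3], D = 0,
                 chi_axis = unit(n), xi_axis = unit(v1),
                 psi_axis = unit(psi)),
            class = "AxesFrame")
}

# Frame used when the reference atom is (numerically) on the CM-CM line:
# xi along the CM-CM vector, chi any perpendicular, psi completing the set.
.fallback_axes <- function(cm_fixed, cm_mobile) {
  v1 <- cm_mobile - cm_fixed
  xi <- v1 / sqrt(sum(v1^2))
  ref <- if (abs(xi[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  chi <- ref - sum(ref * xi) * xi
  chi <- chi / sqrt(sum(chi^2))
  psi <- c(xi[2] * chi[3] - xi[3] * chi[2],
           xi[3] * chi[1] - xi[1] * chi[3],
           xi[1] * chi[2] - xi[2] * chi[1])
  structure(list(A = chi[1], B = chi[2], C = chi[3], D = 0,
                 chi_axis = chi, xi_axis = xi, psi_axis = psi),
            class = "AxesFrame")
}

#' Body rotation for a (chi, psi, xi) triple
#'
#' Rotations are applied about the mobile CM in the order chi (about the
#' plane normal), then psi, then xi (about the CM-CM axis); axes are fixed in
#' the reference frame (extrinsic composition).
#'
#' @param frame an `AxesFrame`.
#' @param chi,psi,xi angles in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
body_rotation <- function(frame, chi, psi, xi) {
  d2r <- pi / 180
  rotation_about_axis(frame$xi_axis, xi * d2r) %*%
    rotation_about_axis(frame$psi_axis, psi * d2r) %*%
    rotation_about_axis(frame$chi_axis, chi * d2r)
}

# K x 9 row-major rotation matrices for a rotamer table
.body_rotation_rows <- function(frame, rotamers) {
  rx <- matrix(0, nrow(rotamers), 9)
  for (k in seq_len(nrow(rotamers))) {
    R <- body_rotation(frame, rotamers[k, 1], rotamers[k, 2], rotamers[k, 3])
    rx[k, ] <- as.vector(t(R))
  }
  rx
}

# P x 9 row-major placement rotations for a grid
.placement_rotation_rows <- function(grid) {
  if (inherits(grid, "GridSpec")) {
    pts <- grid$points
    t(vapply(seq_len(nrow(pts)), function(i) {
      as.vector(t(rotation_z(pts$phi[i]) %*% rotation_x(pts$theta[i])))
    }, numeric(9)))
  } else if (inherits(grid, "CylinderGrid")) {
    t(vapply(seq_len(nrow(grid$points)), function(i) {
      as.vector(t(rotation_about_axis(grid$axis, grid$points$alpha[i])))
    }, numeric(9)))
  } else stop("unknown grid class")
}

#' Frontal alignment of the mobile cofactor
#'
#' Scans the full rotational space (default 5-degree increments) for the body
#' rotation that minimises the cofactor-cofactor minimal heavy-atom distance
#' with the mobile CM held at its starting position.  Applying the returned
#' rotation makes the mobile cofactor face the fixed protein, so that the
#' reduced rotational scheme can reach short electron-transfer distances from
#' every subsequent grid placement.  Ties keep the lexicographically smallest
#' (chi, psi, xi).
#'
#' @param mobile,fixed `RigidStructure`s in their starting pose.
#' @param cof_mobile,cof_fixed cofactor groups (names, `CofactorGroup`s or
#'   index vectors).
#' @param delta scan increment in degrees (default 5).
#' @return List with the best `chi`, `psi`, `xi` (degrees), the corresponding
#'   `rotation` matrix (about the mobile CM), the achieved `d_min`, and the
#'   `frame` of rotation axes.
#' @export
frontal_align <- function(mobile, fixed, cof_mobile, cof_fixed, delta = 5) {
  cm_f <- center_of_mass(fixed)
  cm_m <- center_of_mass(mobile)
  ia <- .cof_indices(fixed, cof_fixed)
  ib <- .cof_indices(mobile, cof_mobile)
  fe <- colMeans(coords(mobile)[ib, , drop = FALSE])
  frame <- tryCatch(build_axes(cm_f, cm_m, fe),
                    error = function(e) .fallback_axes(cm_f, cm_m))
  scheme <- rotamer_scheme("full", delta = delta)
  rot <- enumerate_rotamers(scheme)
  rows <- .body_rotation_rows(frame, rot)
  res <- cpp_frontal_scan(coords(fixed)[ia, , drop = FALSE],
                          sweep(coords(mobile)[ib, , drop = FALSE], 2, cm_m),
                          rows, cm_m)
  k <- res$best
  list(chi = rot[k, 1], psi = rot[k, 2], xi = rot[k, 3],
       rotation = matrix(rows[k, ], 3, 3, byrow = TRUE),
       d_min = res$d_min, frame = frame)
}
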