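# The docking loop: every grid CM x every rotamer, translate to steric
# contact, record the minimal cofactor edge-to-edge distance, keep the best
# rotamer per CM.  Binary and ternary (blocker-filtered) modes.

#' Minimal cofactor edge-to-edge distance
#'
#' Minimum Euclidean distance over all heavy-atom pairs, one atom from each
#' cofactor group.
#'
#' @param a_coords,b_coords coordinate matrices (n x 3, Angstrom).
#' @return Distance in Angstrom.
#' @export
min_cofactor_distance <- function(a_coords, b_coords) {
  a_coords <- rbind(a_coords)
  b_coords <- rbind(b_coords)
  if (nrow(a_coords) == 0L || nrow(b_coords) == 0L)
    stop("empty cofactor group")
  cpp_min_pair_dist(a_coords, b_coords)
}

#' Exhaustive binary conformational sampling
#'
#' Places the mobile protein at every grid CM, enumerates all body rotamers,
#' translates each rotamer to steric contact along the CM-CM line, and keeps
#' per CM the rotamer with the smallest cofactor edge-to-edge distance
#' (ties resolved to the lexicographically smallest (chi, psi, xi)).  CMs
#' where no rotamer reaches an accepted contact are omitted from the
#' solutions and counted in `n_no_contact`.
#'
#' When `frontal` is TRUE (the default for the reduced scheme) the mobile is
#' first rotated about its CM into the orientation minimising the
#' cofactor-cofactor distance at the grid reference position (frontal
#' alignment); that orientation is then carried with every placement, so the
#' cofactor keeps facing the fixed protein during the grid sweep.
#'
#' The engine is fully deterministic: identical inputs give bit-identical
#' maps.
#'
#' @param fixed,mobile `RigidStructure`s in their input poses.
#' @param grid a `GridSpec` or `CylinderGrid`.
#' @param scheme a `RotamerScheme`.
#' @param vdw a `VdwParams`.
#' @param cof_fixed,cof_mobile cofactor groups (name, `CofactorGroup`, or
#'   index vector).
#' @param frontal apply frontal alignment first; default TRUE for reduced
#'   schemes.
#' @param frontal_delta scan increment (degrees) of the frontal alignment.
#' @param verbose print a one-line summary.
#' @return A `DistanceMap`: `solutions` data frame (grid_index, placement
#'   coordinates in degrees or Angstrom, chi/psi/xi in degrees, r_contact,
#'   d_min, f_vdw, CM position), per-solution rigid transforms, and run
#'   metadata.
#' @export
sample_binary <- function(fixed, mobile, grid, scheme, vdw = vdw_params(),
                          cof_fixed, cof_mobile, frontal = NULL,
                          frontal_delta = 5, verbose = FALSE) {
  if (is.null(frontal)) frontal <- scheme$mode == "reduced"
  cm_f <- center_of_mass(fixed)
  cm_m <- center_of_mass(mobile)
  ia <- .cof_indices(fixed, cof_fixed)
  ib <- .cof_indices(mobile, cof_mobile)

  a_xyz <- sweep(coords(fixed), 2, cm_f)
  b_cent <- sweep(coords(mobile), 2, cm_m)

  # grid CM positions relative to the fixed CM
  p0 <- grid$cm
  p_ref <- grid$p_ref
  if (inherits(grid, "CylinderGrid")) {
    p0 <- sweep(p0, 2, cm_f)
    p_ref <- p_ref - cm_f
  }

  # frontal alignment at the grid reference position (original orientation)
  frontal_info <- NULL
  r_front <- diag(3)
  if (frontal) {
    mobile_ref <- apply_transform(mobile, translation = cm_f + p_ref - cm_m)
    fa <- frontal_align(mobile_ref, fixed, ib, ia, delta = frontal_delta)
    r_front <- fa$rotation
    frontal_info <- fa[c("chi", "psi", "xi", "d_min")]
  }
  b_front <- b_cent %*% t(r_front)

  # body-rotation axes from the pre-alignment cofactor reference point, so
  # the plane stays well-defined after the cofactor is rotated onto the
  # CM-CM line by the frontal alignment
  fe_ref <- colMeans(b_cent[ib, , drop = FALSE]) + p_ref
  frame <- tryCatch(build_axes(c(0, 0, 0), p_ref, fe_ref),
                    error = function(e) .fallback_axes(c(0, 0, 0), p_ref))

  rotamers <- enumerate_rotamers(scheme)
  r_body <- .body_rotation_rows(frame, rotamers)
  r_place <- .placement_rotation_rows(grid)

  res <- cpp_sample(a_xyz, .engine_radii(fixed, vdw),
                    .active_mask(fixed, vdw),
                    b_front, .engine_radii(mobile, vdw),
                    .active_mask(mobile, vdw),
                    ia - 1L, ib - 1L, r_place, p0, r_body,
                    vdw$s, vdw$k_vdw, vdw$nonbonded_cutoff,
                    vdw$energy_cutoff, vdw$step, vdw$tol)

  hit <- which(res$found)
  k <- res$best_rotamer[hit]
  u <- p0[hit, , drop = FALSE] /
    sqrt(rowSums(p0[hit, , drop = FALSE]^2))
  cm_sol <- sweep(u * res$r_contact[hit], 2, cm_f, "+")

  if (inherits(grid, "GridSpec")) {
    place_cols <- data.frame(theta = grid$points$theta[hit] * 180 / pi,
                             phi = grid$points$phi[hit] * 180 / pi)
  } else {
    place_cols <- data.frame(level = grid$points$level[hit],
                             alpha = grid$points$alpha[hit] * 180 / pi)
  }
  solutions <- cbind(
    data.frame(grid_index = hit),
    place_cols,
    data.frame(chi = rotamers[k, 1], psi = rotamers[k, 2],
               xi = rotamers[k, 3],
               r_contact = res$r_contact[hit], d_min = res$d_min[hit],
               f_vdw = res$f_vdw[hit],
               cm_x = cm_sol[, 1], cm_y = cm_sol[, 2], cm_z = cm_sol[, 3])
  )
  rownames(solutions) <- NULL

  transforms <- matrix(NA_real_, length(hit), 9)
  for (i in seq_along(hit)) {
    rp <- matrix(r_place[hit[i], ], 3, 3, byrow = TRUE)
    rb <- matrix(r_body[k[i], ], 3, 3, byrow = TRUE)
    transforms[i, ] <- as.vector(t(rp %*% rb %*% r_front))
  }

  map <- structure(list(
    solutions = solutions, transforms = transforms, u = u,
    grid = grid, scheme = scheme, vdw = vdw,
    frontal = frontal_info, r_front = r_front, frame = frame,
    fixed_label = fixed$label, mobile_label = mobile$label,
    fixed_cm = cm_f, mobile_cm = cm_m,
    n_placements = nrow(p0), n_no_contact = sum(!res$found)
  ), class = "DistanceMap")
  if (verbose)
    message("sample_binary: ", nrow(p0), " CM placements, ",
            nrow(rotamers), " rotamers per CM, ", nrow(solutions),
            " contact solutions (", map$n_no_contact, " contact-free CMs)")
  map
}

#' @export
print.DistanceMap <- function(x, ...) {
  cat("DistanceMap: ", nrow(x$solutions), "/", x$n_placements,
      " CMs with contact solutions (", x$mobile_label, " over ",
      x$fixed_label, ")\n", sep = "")
  if (nrow(x$solutions))
    cat("  d_min range: ", round(min(x$solutions$d_min), 2), " - ",
        round(max(x$solutions$d_min), 2), " A\n", sep = "")
  invisible(x)
}

#' Pose the mobile structure as in a stored docking solution
#'
#' Re-applies the full rigid transform of solution `i`, reproducing the
#' engine's contact pose exactly.
#'
#' @param map a `DistanceMap`.
#' @param mobile the mobile `RigidStructure` in its original input pose.
#' @param i solution row index.
#' @return The posed `RigidStructure`.
#' @export
pose_solution <- function(map, mobile, i) {
  stopifnot(i >= 1, i <= nrow(map$solutions))
  R <- matrix(map$transforms[i, ], 3, 3, byrow = TRUE)
  tr <- map$fixed_cm + map$solutions$r_contact[i] * map$u[i, ]
  xyz <- sweep(coords(mobile), 2, map$mobile_cm) %*% t(R)
  set_coords(mobile, sweep(xyz, 2, tr, "+"))
}

#' Ternary sampling with a pre-bound blocker
#'
#' Samples the mobile protein against `fixed` exactly as in the binary mode,
#' disregarding the blocker, then evaluates the mobile-blocker quartic
#' repulsion for every solution and removes those above
#' `vdw$energy_cutoff`.
#'
#' @param fixed receptor `RigidStructure`.
#' @param blocker a `RigidStructure` at its fixed pose (typically the best
#'   binary solution posed with [pose_solution()]).
#' @param mobile the second probe molecule.
#' @inheritParams sample_binary
#' @return A `DistanceMap` whose solutions carry an extra `f_vdw_blocker`
#'   column; `n_blocked` counts the removed solutions.
#' @export
sample_ternary <- function(fixed, blocker, mobile, grid, scheme,
                           vdw = vdw_params(), cof_fixed, cof_mobile,
                           frontal = NULL, frontal_delta = 5,
                           verbose = FALSE) {
  map <- sample_binary(fixed, mobile, grid, scheme, vdw, cof_fixed,
                       cof_mobile, frontal = frontal,
                       frontal_delta = frontal_delta, verbose = verbose)
  n <- nrow(map$solutions)
  eb <- numeric(n)
  for (i in seq_len(n)) {
    posed <- pose_solution(map, mobile, i)
    eb[i] <- vdw_energy(posed, blocker, vdw)
  }
  keep <- eb <= vdw$energy_cutoff
  map$solutions$f_vdw_blocker <- eb
  map$solutions <- map$solutions[keep, , drop = FALSE]
  rownames(map$solutions) <- NULL
  map$transforms <- map$transforms[keep, , drop = FALSE]
  map$u <- map$u[keep, , drop = FALSE]
  map$n_blocked <- sum(!keep)
  map$blocker_label <- blocker$label
  if (verbose)
    message("sample_ternary: removed ", map$n_blocked,
            " solution(s) clashing with the blocker")
  map
}
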