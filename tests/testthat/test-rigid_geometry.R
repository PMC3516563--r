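# Rotation conventions, grid construction, rotamer enumeration, axes frames,
# frontal alignment, cylindrical grids.

test_that("rotation matrices follow the stated sign conventions", {
  expect_equal(rotation_x(0), diag(3))
  # theta rotation must take the CM ordinate to y' = d * sin(theta)
  d <- 7
  expect_equal(as.vector(rotation_x(pi / 2) %*% c(0, 0, d)), c(0, d, 0),
               tolerance = 1e-12)
  for (th in c(0.3, 1.1, 2.5))
    expect_equal((rotation_x(th) %*% c(0, 0, d))[2], d * sin(th),
                 tolerance = 1e-12)
  # orthonormal, determinant one
  set.seed(42)
  for (ang in runif(10, -10, 10)) {
    for (R in list(rotation_x(ang), rotation_z(ang),
                   rotation_about_axis(rnorm(3), ang))) {
      expect_equal(R %*% t(R), diag(3), tolerance = 1e-12)
      expect_equal(det(R), 1, tolerance = 1e-12)
    }
  }
})

test_that("spherical CM grid reproduces the resolution arithmetic", {
  g <- build_cm_grid(10, 1)
  expect_equal(g$delta_theta, 0.1)
  expect_equal(g$n_theta, 31L)              # trunc(pi / 0.1)
  expect_equal(g$total, sum(g$n_phis))
  expect_equal(nrow(g$cm), g$total)
  # every CM on the sphere of radius d
  expect_lt(max(abs(sqrt(rowSums(g$cm^2)) - 10)), 1e-6)
  # degenerate grid: delta_d = d still legal
  g1 <- build_cm_grid(10, 10)
  expect_gte(g1$total, 1)
  expect_error(build_cm_grid(10, 0), "positive")
  expect_error(build_cm_grid(10, 11), "exceed")
})

test_that("nearest-neighbour CM spacing stays near delta_d away from poles", {
  g <- build_cm_grid(10, 1)
  interior <- g$points$theta > 2 * pi / g$n_theta &
    g$points$theta < pi - 2 * pi / g$n_theta
  cm <- g$cm
  nn <- vapply(which(interior), function(i) {
    dd <- sqrt(rowSums(sweep(cm, 2, cm[i, ])^2))
    min(dd[-i])
  }, numeric(1))
  expect_gte(min(nn), 0.5)
  expect_lte(max(nn), 1.6)
})

test_that("rotamer accounting matches the sampling protocols", {
  reduced <- rotamer_scheme("reduced")          # 5-deg chi/psi, 15-deg xi
  full5 <- rotamer_scheme("full", delta = 5)
  expect_identical(rotamer_count(reduced), 7776L)
  expect_identical(rotamer_count(full5), 186624L)
  expect_identical(rotamer_count(full5) / rotamer_count(reduced), 24)
  expect_identical(rotamer_count(rotamer_scheme("full", delta = 1)),
                   23328000L)
  expect_error(rotamer_scheme("full", delta = 7), "does not divide")
})

test_that("rotamer enumeration is lexicographic, half-open, deterministic", {
  full <- rotamer_scheme("full", delta = 5)
  rot <- enumerate_rotamers(full)
  expect_equal(nrow(rot), rotamer_count(full))
  expect_equal(unname(rot[1, ]), c(0, 0, 0))
  expect_equal(unname(rot[2, ]), c(0, 0, 5))   # xi varies fastest
  reduced <- enumerate_rotamers(rotamer_scheme("reduced"))
  expect_false(any(reduced[, "chi"] == 45))
  expect_false(any(reduced[, "psi"] == 45))
  expect_true(any(reduced[, "chi"] == -45))
  expect_identical(reduced, enumerate_rotamers(rotamer_scheme("reduced")))
})

test_that("axes frame solves the CM/CM/Fe plane", {
  fr <- build_axes(c(0, 0, 0), c(10, 0, 0), c(10, 0, 1))
  expect_equal(fr$chi_axis, c(0, -1, 0))
  expect_equal(fr$xi_axis, c(1, 0, 0))
  expect_equal(fr$psi_axis, c(0, 0, -1))
  # Fe on the CM-CM line has no defined plane
  expect_error(build_axes(c(0, 0, 0), c(10, 0, 0), c(5, 0, 0)), "collinear")
  # pairwise orthogonality for random non-degenerate geometries
  set.seed(7)
  for (i in 1:20) {
    fr <- build_axes(c(0, 0, 0), rnorm(3, sd = 10), rnorm(3, sd = 10))
    expect_lt(abs(sum(fr$chi_axis * fr$xi_axis)), 1e-9)
    expect_lt(abs(sum(fr$chi_axis * fr$psi_axis)), 1e-9)
    expect_lt(abs(sum(fr$xi_axis * fr$psi_axis)), 1e-9)
  }
})

test_that("frontal alignment matches an exhaustive plain-R scan", {
  toy <- small_toy(atoms_per_shell = 16)
  # oracle: enumerate the same coarse grid in R and take the best distance
  delta <- 30
  fa <- frontal_align(toy$mobile, toy$fixed, "cof", "cof", delta = delta)
  cm_m <- center_of_mass(toy$mobile)
  cof_m <- coords(toy$mobile)[toy$mobile$cofactors$cof$atom_indices, ,
                              drop = FALSE]
  cof_f <- coords(toy$fixed)[toy$fixed$cofactors$cof$atom_indices, ,
                             drop = FALSE]
  fe <- colMeans(cof_m)
  frame <- build_axes(center_of_mass(toy$fixed), cm_m, fe)
  rot <- enumerate_rotamers(rotamer_scheme("full", delta = delta))
  dists <- vapply(seq_len(nrow(rot)), function(k) {
    R <- body_rotation(frame, rot[k, 1], rot[k, 2], rot[k, 3])
    posed <- sweep(sweep(cof_m, 2, cm_m) %*% t(R), 2, cm_m, "+")
    bf_min_dist(cof_f, posed)
  }, numeric(1))
  expect_equal(fa$d_min, min(dists), tolerance = 1e-9)
  expect_equal(unname(c(fa$chi, fa$psi, fa$xi)),
               unname(rot[which.min(dists), ]))
  # the aligned cofactor points toward the fixed body: its direction is
  # within the rotational increment of the CM-CM axis
  aligned <- as.vector(fa$rotation %*% (colMeans(cof_m) - cm_m))
  axis_dir <- (center_of_mass(toy$fixed) - cm_m)
  cosang <- sum(aligned * axis_dir) /
    sqrt(sum(aligned^2) * sum(axis_dir^2))
  expect_gt(cosang, cos(1.5 * delta * pi / 180))
  # deterministic
  fa2 <- frontal_align(toy$mobile, toy$fixed, "cof", "cof", delta = delta)
  expect_identical(fa[c("chi", "psi", "xi", "d_min")],
                   fa2[c("chi", "psi", "xi", "d_min")])
})

test_that("an already-aligned mobile yields the identity triple", {
  # mobile cofactor exactly facing the fixed body along the CM-CM axis
  toy <- small_toy(atoms_per_shell = 16, cof_dir_a = c(0, 0, 1),
                   cof_dir_b = c(0, 0, -1))
  fa <- frontal_align(toy$mobile, toy$fixed, "cof", "cof", delta = 30)
  expect_equal(unname(c(fa$chi, fa$psi, fa$xi)), c(0, 0, 0))
})

test_that("cylindrical grid counts follow the arc-length arithmetic", {
  toy <- small_toy(atoms_per_shell = 16)
  g <- cylindrical_grid(toy$fixed, axis = c(0, 0, 1), delta_d = 1,
                        extent = 10, radius = 10)
  expect_equal(g$n_alpha, 62L)              # trunc(2 * pi * 10)
  expect_equal(length(g$levels), 11L)       # inclusive endpoints
  expect_equal(g$total, 62L * 11L)
  expect_error(cylindrical_grid(toy$fixed, axis = c(0, 0, 0), delta_d = 1,
                                extent = 10, radius = 10), "zero axis")
  # default axis is the long axis: stretch a body along x and check
  stretched <- apply_transform(toy$fixed, rotation = diag(c(1, 1, 1)))
  xyz <- coords(stretched); xyz[, 1] <- xyz[, 1] * 5
  stretched <- set_coords(stretched, xyz)
  ax <- principal_axis(stretched)
  expect_gt(abs(ax[1]), 0.99)
})

test_that("rigid transforms preserve intra-body distances", {
  set.seed(11)
  body <- random_body(30, seed = 11)
  d0 <- dist(coords(body))
  for (i in 1:5) {
    R <- random_rotation()
    moved <- apply_transform(body, R, rnorm(3, sd = 20), center = rnorm(3))
    expect_equal(as.vector(dist(coords(moved))), as.vector(d0),
                 tolerance = 1e-9)
  }
})
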