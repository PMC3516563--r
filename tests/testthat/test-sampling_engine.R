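# The docking loop: distances, map structure, oracle comparisons, ternary
# filtering, determinism.

test_that("min_cofactor_distance is an exhaustive pair minimum", {
  expect_equal(min_cofactor_distance(rbind(c(0, 0, 0)), rbind(c(3, 4, 0))),
               5)
  shared <- rbind(c(1, 1, 1))
  expect_equal(min_cofactor_distance(rbind(shared, c(9, 9, 9)), shared), 0)
  set.seed(31)
  xa <- matrix(rnorm(60), ncol = 3)
  xb <- matrix(rnorm(90, mean = 2), ncol = 3)
  expect_equal(min_cofactor_distance(xa, xb), bf_min_dist(xa, xb),
               tolerance = 1e-12)
  expect_error(min_cofactor_distance(xa[0, , drop = FALSE], xb), "empty")
})

toy <- small_toy(atoms_per_shell = 24, delta_d = 3, rot_delta = 15)
toy_grid <- build_cm_grid(toy$d0, delta_d = 3)
toy_scheme <- coarse_reduced_scheme()
toy_map <- sample_binary(toy$fixed, toy$mobile, toy_grid, toy_scheme,
                         vdw_params(), "cof", "cof")

test_that("binary map covers the grid and satisfies the pose contract", {
  s <- toy_map$solutions
  expect_lte(nrow(s), toy_grid$total)
  expect_equal(nrow(s) + toy_map$n_no_contact, toy_grid$total)
  expect_true(all(s$d_min > 0))
  expect_true(all(s$f_vdw > 0))
  expect_true(all(s$f_vdw <= vdw_params()$energy_cutoff))
})

test_that("global minimum matches the fixture's closed-form gap", {
  dmin <- min(toy_map$solutions$d_min)
  expect_gte(dmin, toy$expected_min_gap - 0.03)
  expect_lte(dmin, toy$expected_min_gap + toy$tolerance)
})

test_that("the sampling engine is deterministic", {
  again <- sample_binary(toy$fixed, toy$mobile, toy_grid, toy_scheme,
                         vdw_params(), "cof", "cof")
  expect_identical(toy_map$solutions, again$solutions)
  expect_identical(toy_map$transforms, again$transforms)
})

test_that("stored transforms reproduce d_min and f_vdw exactly", {
  s <- toy_map$solutions
  p <- vdw_params()
  idx_f <- toy$fixed$cofactors$cof$atom_indices
  idx_m <- toy$mobile$cofactors$cof$atom_indices
  for (i in seq(1, nrow(s), length.out = 8)) {
    i <- as.integer(i)
    posed <- pose_solution(toy_map, toy$mobile, i)
    expect_equal(vdw_energy(posed, toy$fixed, p), s$f_vdw[i],
                 tolerance = 1e-9)
    expect_equal(min_cofactor_distance(coords(toy$fixed)[idx_f, ,
                                                         drop = FALSE],
                                       coords(posed)[idx_m, , drop = FALSE]),
                 s$d_min[i], tolerance = 1e-9)
    # the posed CM sits at r_contact along the placement direction
    expect_equal(sqrt(sum((center_of_mass(posed) -
                             center_of_mass(toy$fixed))^2)),
                 s$r_contact[i], tolerance = 1e-9)
  }
})

test_that("dense random-rotation oracle never beats the engine meaningfully", {
  # at a handful of CMs, brute-force rotations + the public contact search
  # must not find a cofactor distance below the engine's per-CM best by
  # more than the discretization bound of the rotamer increments
  p <- vdw_params()
  idx_f <- toy$fixed$cofactors$cof$atom_indices
  idx_m <- toy$mobile$cofactors$cof$atom_indices
  cm_m <- center_of_mass(toy$mobile)
  cm_f <- center_of_mass(toy$fixed)
  set.seed(99)
  pick <- sample(seq_len(nrow(toy_map$solutions)), 3)
  for (i in pick) {
    u <- toy_map$u[i, ]
    start <- cm_f + u * toy$spec$separation
    oracle_best <- Inf
    for (k in 1:150) {
      R <- random_rotation()
      posed0 <- apply_transform(toy$mobile, R, start - cm_m, center = cm_m)
      res <- translate_to_contact(posed0, toy$fixed, direction = -u,
                                  params = p)
      if (!res$contact) next
      d <- min_cofactor_distance(
        coords(toy$fixed)[idx_f, , drop = FALSE],
        coords(res$structure)[idx_m, , drop = FALSE])
      oracle_best <- min(oracle_best, d)
    }
    expect_gte(oracle_best, toy_map$solutions$d_min[i] - toy$tolerance)
  }
})

test_that("ternary sampling with a distant blocker reduces to binary", {
  blocker <- apply_transform(toy$mobile, translation = c(500, 0, 0))
  tern <- sample_ternary(toy$fixed, blocker, toy$mobile, toy_grid,
                         toy_scheme, vdw_params(), "cof", "cof")
  expect_equal(tern$n_blocked, 0L)
  shared <- setdiff(names(tern$solutions), "f_vdw_blocker")
  expect_identical(tern$solutions[, shared], toy_map$solutions)
})

test_that("a blocker at the best site carves out its clash neighbourhood", {
  best <- which.min(toy_map$solutions$d_min)
  blocker <- pose_solution(toy_map, toy$mobile, best)
  tern <- sample_ternary(toy$fixed, blocker, toy$mobile, toy_grid,
                         toy_scheme, vdw_params(), "cof", "cof")
  p <- vdw_params()
  expect_gt(tern$n_blocked, 0L)
  expect_lte(nrow(tern$solutions), nrow(toy_map$solutions))
  # the blocked best CM is gone
  expect_false(toy_map$solutions$grid_index[best] %in%
                 tern$solutions$grid_index)
  # every retained solution independently satisfies the blocker cutoff
  for (i in seq_len(nrow(tern$solutions))) {
    posed <- pose_solution(tern, toy$mobile, i)
    expect_lte(vdw_energy(posed, blocker, p), p$energy_cutoff)
  }
})

test_that("swapping probe and receptor of a symmetric pair is reciprocal", {
  sym <- make_toy_pair(radius_a = 6, radius_b = 6, atoms_per_shell = 24,
                       cof_dir_a = c(0, 0, 1), cof_dir_b = c(0, 0, -1),
                       delta_d = 3, rot_delta = 15)
  grid <- build_cm_grid(sym$d0, delta_d = 3)
  fwd <- sample_binary(sym$fixed, sym$mobile, grid, toy_scheme,
                       vdw_params(), "cof", "cof")
  rev <- sample_binary(sym$mobile, sym$fixed, grid, toy_scheme,
                       vdw_params(), "cof", "cof")
  expect_equal(min(fwd$solutions$d_min), min(rev$solutions$d_min),
               tolerance = sym$tolerance)
})
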