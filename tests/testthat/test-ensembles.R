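# Ensemble aggregation and the tethered-domain conformer generator.

fake_map <- function(k_et) list(solutions = data.frame(
  d_min = 3.6 + (13 - log10(k_et)) / 1.4 * log(10), k_et = k_et))

test_that("ensemble aggregation computes Table-style statistics", {
  m10 <- fake_map(10^runif(30, 5, 9))
  same <- aggregate_ensemble(list(m10, m10, m10))
  expect_equal(same$sd_size, 0)
  expect_equal(same$mean_size, same$epitope_sizes[1])

  a <- fake_map(10^seq(6.1, 8, length.out = 10))   # 10 above threshold
  b <- fake_map(10^seq(6.1, 8, length.out = 20))   # 20 above threshold
  agg <- aggregate_ensemble(list(a, b))
  expect_equal(agg$mean_size, 15)
  expect_equal(agg$sd_size, sd(c(10, 20)))         # sample (n-1) convention
  expect_equal(agg$sd_size, 7.0711, tolerance = 1e-4)
  expect_gte(agg$mean_size, min(agg$epitope_sizes))
  expect_lte(agg$mean_size, max(agg$epitope_sizes))
  # pooled minimum equals the min of per-conformer minima
  expect_equal(agg$pooled_min_d, min(min(a$solutions$d_min),
                                     min(b$solutions$d_min)))
  # permutation invariance
  agg_rev <- aggregate_ensemble(list(b, a))
  expect_equal(sort(agg_rev$epitope_sizes), sort(agg$epitope_sizes))
  expect_equal(agg_rev$mean_size, agg$mean_size)
  expect_equal(agg_rev$pooled_min_d, agg$pooled_min_d)
  expect_error(aggregate_ensemble(list()), "empty")
})

md <- make_toy_multidomain(radius_a = 7, radius_b = 5, n_linker = 4,
                           atoms_per_shell = 24)

test_that("generated conformers keep the domains internally rigid", {
  set <- generate_linker_conformers(md$structure, md$domain_a, md$domain_b,
                                    md$linker, n = 6, seed = 3)
  expect_length(set$conformers, 6L)
  a_sel <- md$structure$atoms$resno %in% md$domain_a
  b_sel <- md$structure$atoms$resno %in% md$domain_b
  d_a0 <- dist(coords(md$structure)[a_sel, ])
  d_b0 <- dist(coords(md$structure)[b_sel, ])
  p <- vdw_params()
  for (conf in set$conformers) {
    expect_equal(as.vector(dist(coords(conf)[a_sel, ])), as.vector(d_a0),
                 tolerance = 1e-6)
    expect_equal(as.vector(dist(coords(conf)[b_sel, ])), as.vector(d_b0),
                 tolerance = 1e-6)
    # independent clash re-check of the accepted conformer
    xa <- coords(conf)[a_sel, ]; xb <- coords(conf)[b_sel, ]
    sub_a <- new_rigid_structure(conf$atoms[a_sel, ])
    sub_b <- new_rigid_structure(conf$atoms[b_sel, ])
    expect_lte(vdw_energy(sub_a, sub_b, p), p$energy_cutoff)
  }
})

test_that("conformer generation is seed-deterministic", {
  s1 <- generate_linker_conformers(md$structure, md$domain_a, md$domain_b,
                                   md$linker, n = 4, seed = 11)
  s2 <- generate_linker_conformers(md$structure, md$domain_a, md$domain_b,
                                   md$linker, n = 4, seed = 11)
  s3 <- generate_linker_conformers(md$structure, md$domain_a, md$domain_b,
                                   md$linker, n = 4, seed = 12)
  for (i in 1:4)
    expect_identical(coords(s1$conformers[[i]]), coords(s2$conformers[[i]]))
  expect_false(identical(coords(s1$conformers[[2]]),
                         coords(s3$conformers[[2]])))
})

test_that("an empty linker returns the input conformation only", {
  solid <- make_toy_multidomain(n_linker = 0, atoms_per_shell = 16)
  set <- generate_linker_conformers(solid$structure, solid$domain_a,
                                    solid$domain_b, solid$linker, n = 5,
                                    seed = 1)
  expect_length(set$conformers, 1L)
  expect_identical(coords(set$conformers[[1]]), coords(solid$structure))
})

test_that("domain mobility exposes the buried cofactor", {
  # with a short linker the inter-domain cleft is too narrow for the probe,
  # so in the extended conformation the second domain's cofactor (facing
  # the first domain) cannot be approached closely; over a torsion ensemble
  # the pooled shortest distance drops
  cleft <- make_toy_multidomain(radius_a = 7, radius_b = 5, n_linker = 2,
                                atoms_per_shell = 64)
  probe_spec <- make_toy_pair(radius_a = 5, radius_b = 5,
                              atoms_per_shell = 48)
  probe <- probe_spec$mobile
  scheme <- coarse_reduced_scheme()
  run_one <- function(receptor) {
    d <- sqrt(sum((center_of_mass(receptor) - center_of_mass(probe))^2))
    grid <- build_cm_grid(max(d, 26), delta_d = 6)
    m <- sample_binary(receptor, probe, grid, scheme, vdw_params(),
                       "cof", "cof")
    min(m$solutions$d_min)
  }
  closed <- run_one(cleft$structure)
  expect_gt(closed, probe_spec$expected_min_gap + 0.15)  # occluded
  set <- generate_linker_conformers(cleft$structure, cleft$domain_a,
                                    cleft$domain_b, cleft$linker, n = 5,
                                    seed = 5)
  open_min <- min(vapply(set$conformers, run_one, numeric(1)))
  expect_lt(open_min, closed - 0.1)
  # once open, the probe reaches the analytic cofactor-contact floor
  expect_lt(open_min, probe_spec$expected_min_gap + probe_spec$tolerance)
})

test_that("conformer sets survive a multi-model PDB round trip", {
  set <- generate_linker_conformers(md$structure, md$domain_a, md$domain_b,
                                    md$linker, n = 3, seed = 7)
  f <- tempfile(fileext = ".pdb")
  write_conformers(set, f)
  back <- read_conformers(f)
  expect_length(back$conformers, 3L)
  for (i in 1:3)
    expect_equal(coords(back$conformers[[i]]), coords(set$conformers[[i]]),
                 tolerance = 1e-3)  # PDB file precision
})
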