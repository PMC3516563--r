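# Shared test substrate: hand-built atom tables, random rigid bodies, and
# plain-R brute-force oracles kept independent of the compiled code paths.

# heavy atoms of the standard protoporphyrin-IX + Fe heme component
hem_atom_names <- c(
  "FE", "NA", "NB", "NC", "ND",
  "C1A", "C2A", "C3A", "C4A", "CMA", "CAA", "CBA", "CGA", "O1A", "O2A",
  "C1B", "C2B", "C3B", "C4B", "CMB", "CAB", "CBB",
  "C1C", "C2C", "C3C", "C4C", "CMC", "CAC", "CBC",
  "C1D", "C2D", "C3D", "C4D", "CMD", "CAD", "CBD", "CGD", "O1D", "O2D",
  "CHA", "CHB", "CHC", "CHD"
)

hem_elements <- function(names) {
  e <- substr(names, 1, 1)
  e[names == "FE"] <- "FE"
  e
}

trp_sidechain_ring <- c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2",
                        "CZ3", "CH2")

make_atoms <- function(names, elements, resname, resno, xyz,
                       hetero = FALSE, chain = "A", rmin = NULL,
                       serial_start = 1L) {
  n <- length(names)
  if (is.null(rmin)) rmin <- unname(default_radius_table()[elements])
  data.frame(serial = serial_start + seq_len(n) - 1L, name = names,
             element = elements, resname = resname,
             resno = if (length(resno) == 1L) rep(resno, n) else resno,
             chain = chain, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             mass = unname(redoxmap:::.element_masses[elements]),
             rmin = rmin, hetero = hetero, stringsAsFactors = FALSE)
}

# single-atom body with a chosen contact radius, centred at pos
point_body <- function(pos, rmin = 2.0, label = "pt") {
  new_rigid_structure(
    make_atoms("CA", "C", "GLY", 1L, rbind(pos), rmin = rmin),
    label = label)
}

# random blob of vdW-active atoms with random radii
random_body <- function(n, seed, center = c(0, 0, 0), spread = 4,
                        rmin_range = c(1.2, 2.2)) {
  set.seed(seed)
  xyz <- sweep(matrix(rnorm(3 * n, sd = spread), ncol = 3), 2, center, "+")
  rmin <- runif(n, rmin_range[1], rmin_range[2])
  new_rigid_structure(
    make_atoms(rep("CA", n), rep("C", n), "GLY", seq_len(n), xyz,
               rmin = rmin),
    label = paste0("rand", seed))
}

# plain-R quartic repulsion, double loop, no acceleration
bf_vdw_energy <- function(a, b, params) {
  xa <- coords(a); xb <- coords(b)
  ra <- a$atoms$rmin; rb <- b$atoms$rmin
  if (params$combine == "mean") { ra <- ra / 2; rb <- rb / 2 }
  ma <- if (params$reduced) a$reduced_mask else rep(TRUE, nrow(xa))
  mb <- if (params$reduced) b$reduced_mask else rep(TRUE, nrow(xb))
  e <- 0
  for (i in seq_len(nrow(xa))) {
    if (!ma[i]) next
    for (j in seq_len(nrow(xb))) {
      if (!mb[j]) next
      r <- sqrt(sum((xa[i, ] - xb[j, ])^2))
      if (r > params$nonbonded_cutoff) next
      q <- params$s * (ra[i] + rb[j])
      if (r < q) e <- e + (q^2 - r^2)^2
    }
  }
  params$k_vdw * e
}

bf_min_dist <- function(xa, xb) {
  min(apply(xa, 1, function(p)
    min(sqrt(rowSums(sweep(rbind(xb), 2, p)^2)))))
}

# uniform random rotation matrix (quaternion method), for oracle scans
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b),
           a^2 - b^2 - c^2 + d^2),
         nrow = 3, byrow = TRUE)
}

# small toy systems shared across test files
small_toy <- function(atoms_per_shell = 24, radius = 6, ...) {
  make_toy_pair(radius_a = radius, radius_b = radius,
                atoms_per_shell = atoms_per_shell, ...)
}

coarse_reduced_scheme <- function() rotamer_scheme("reduced", delta = 15,
                                                   delta_xi = 45)
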