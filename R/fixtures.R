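# Synthetic toy structures with analytic ground truth: quasi-uniform atom
# shells with a single protruding cofactor atom, and a tethered two-shell
# multidomain variant.  Everything the test substrate needs, no downloads.

# Deterministic Fibonacci-spiral points on a sphere; seed-stable across
# platforms because no RNG is involved (an optional azimuth offset makes
# different seeds distinguishable without changing the geometry class).
.fib_shell <- function(n, radius, azimuth_offset = 0) {
  i <- seq_len(n) - 1
  z <- 1 - 2 * (i + 0.5) / n
  rho <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  phi <- i * golden + azimuth_offset
  radius * cbind(rho * cos(phi), rho * sin(phi), z)
}

.shell_atoms <- function(xyz, chain, resno_start, atom_vdw,
                         serial_start = 1L) {
  n <- nrow(xyz)
  data.frame(
    serial = serial_start + seq_len(n) - 1L, name = "CA", element = "C",
    resname = "GLY", resno = resno_start + seq_len(n) - 1L, chain = chain,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    mass = 12.011, rmin = atom_vdw, hetero = FALSE,
    stringsAsFactors = FALSE
  )
}

.cof_atom <- function(pos, chain, resno, atom_vdw, serial) {
  data.frame(serial = serial, name = "FE", element = "FE", resname = "COF",
             resno = resno, chain = chain, x = pos[1], y = pos[2],
             z = pos[3], mass = 55.845, rmin = atom_vdw, hetero = TRUE,
             stringsAsFactors = FALSE)
}

#' Toy pair of atom shells with embedded single-atom cofactors
#'
#' Two quasi-uniform spherical atom shells (deterministic Fibonacci-spiral
#' placement) each carrying a single cofactor atom that protrudes
#' `cof_bump` Angstrom beyond the shell at a chosen surface direction.  All
#' atoms share one contact radius, so the minimal achievable
#' cofactor-cofactor distance when the bodies touch cofactor-to-cofactor is
#' known in closed form from the quartic onset:
#' `expected_min_gap = s * 2 * atom_vdw` (the protrusion guarantees the
#' cofactor pair is the first contact when the cofactors face each other).
#'
#' The returned `tolerance` is the documented discretization bound for a
#' sampling run at resolution `delta_d` and rotational increment
#' `rot_delta` degrees: lateral cofactor misalignments of up to
#' `eps_f = (radius_a + cof_bump) * delta_d / d0` (grid) and
#' `eps_m = (radius_b + cof_bump) * rot_delta_rad` (rotamers) inflate the
#' gap by at most their curvature and chord terms, plus twice the contact
#' bisection tolerance.
#'
#' @param radius_a,radius_b shell radii, Angstrom.
#' @param atoms_per_shell atoms per shell (>= 4).
#' @param atom_vdw shared contact radius, Angstrom.
#' @param cof_dir_a,cof_dir_b unit direction of each cofactor.
#' @param cof_bump cofactor protrusion beyond the shell, Angstrom.
#' @param separation starting CM-CM distance (default: shells 10 A apart).
#' @param s quartic radius scale assumed for the closed form.
#' @param delta_d,rot_delta sampling resolutions the tolerance is quoted
#'   for.
#' @param seed azimuth-offset seed (same seed, identical structures).
#' @return List: `fixed`, `mobile` (`RigidStructure`s with cofactor group
#'   `"cof"`), `expected_min_gap`, `tolerance`, `d0` and the echoed spec.
#' @export
make_toy_pair <- function(radius_a = 8, radius_b = 8, atoms_per_shell = 48,
                          atom_vdw = 1.7, cof_dir_a = c(0, 0, 1),
                          cof_dir_b = c(0, 0, -1), cof_bump = 0.8,
                          separation = NULL, s = 0.75, delta_d = 2,
                          rot_delta = 15, seed = 1) {
  stopifnot(radius_a > atom_vdw, radius_b > atom_vdw, atom_vdw > 0,
            atoms_per_shell >= 4)
  unit <- function(v) v / sqrt(sum(v^2))
  cof_dir_a <- unit(cof_dir_a); cof_dir_b <- unit(cof_dir_b)
  if (is.null(separation)) separation <- radius_a + radius_b + 10

  off_a <- (seed %% 97) * 0.05
  off_b <- (seed %% 89) * 0.07
  xa <- .fib_shell(atoms_per_shell, radius_a, off_a)
  xb <- sweep(.fib_shell(atoms_per_shell, radius_b, off_b), 2,
              c(0, 0, separation), "+")
  atoms_a <- rbind(.shell_atoms(xa, "A", 1L, atom_vdw),
                   .cof_atom(cof_dir_a * (radius_a + cof_bump), "A",
                             atoms_per_shell + 1L, atom_vdw,
                             atoms_per_shell + 1L))
  atoms_b <- rbind(.shell_atoms(xb, "B", 1L, atom_vdw),
                   .cof_atom(c(0, 0, separation) +
                               cof_dir_b * (radius_b + cof_bump), "B",
                             atoms_per_shell + 1L, atom_vdw,
                             atoms_per_shell + 1L))
  fixed <- new_rigid_structure(atoms_a, label = "toy-fixed")
  mobile <- new_rigid_structure(atoms_b, label = "toy-mobile")
  fixed$cofactors$cof <- structure(list(name = "cof",
                                        atom_indices = atoms_per_shell + 1L),
                                   class = "CofactorGroup")
  mobile$cofactors$cof <- structure(list(name = "cof",
                                         atom_indices = atoms_per_shell + 1L),
                                    class = "CofactorGroup")

  gap <- s * 2 * atom_vdw
  d0 <- radius_a + radius_b + 2 * cof_bump + gap  # CM-CM at facing contact
  eps_f <- (radius_a + cof_bump) * (delta_d / d0)
  eps_m <- (radius_b + cof_bump) * (rot_delta * pi / 180)
  tolerance <- 0.03 +
    eps_f^2 / (2 * (radius_a + cof_bump)) +
    eps_m^2 / (2 * (radius_b + cof_bump)) +
    (eps_f + eps_m)^2 / (2 * gap)

  list(fixed = fixed, mobile = mobile, expected_min_gap = gap,
       tolerance = tolerance, d0 = d0,
       spec = list(radius_a = radius_a, radius_b = radius_b,
                   atoms_per_shell = atoms_per_shell, atom_vdw = atom_vdw,
                   cof_dir_a = cof_dir_a, cof_dir_b = cof_dir_b,
                   cof_bump = cof_bump, separation = separation, s = s,
                   delta_d = delta_d, rot_delta = rot_delta, seed = seed))
}

#' Toy two-domain structure joined by a pseudo-linker
#'
#' Two atom shells connected along +x by a chain of `n_linker` CA
#' pseudo-residues at 3.8-Angstrom virtual-bond spacing.  The second
#' domain's cofactor points back towards the first domain, so it is
#' sterically occluded in this extended "closed" conformation and becomes
#' accessible once linker torsions swing the domain away.  Residue numbers
#' run along the chain so that the attachment-nearest shell atoms flank the
#' linker.
#'
#' @param radius_a,radius_b shell radii, Angstrom.
#' @param n_linker number of linker pseudo-residues (0 gives a single rigid
#'   body).
#' @param atoms_per_shell atoms per shell.
#' @param atom_vdw shared contact radius.
#' @param seed spiral azimuth seed.
#' @return List: `structure` (single-chain `RigidStructure` with cofactor
#'   group `"cof"`), and residue-number vectors `domain_a`, `linker`,
#'   `domain_b`.
#' @export
make_toy_multidomain <- function(radius_a = 7, radius_b = 5, n_linker = 4,
                                 atoms_per_shell = 32, atom_vdw = 1.7,
                                 seed = 1) {
  # zig-zag CA trace: 3.8 A virtual bonds with alternating lateral offset,
  # so consecutive pivot axes are non-collinear and torsions can swing the
  # second domain away from the first
  bond <- 3.8
  dy <- 1.2
  dx <- sqrt(bond^2 - (2 * dy)^2)
  off <- (seed %% 97) * 0.05
  xa <- .fib_shell(atoms_per_shell, radius_a, off)
  xa <- xa[order(xa[, 1]), , drop = FALSE]  # attachment (max x) last
  centre_b <- c(radius_a + (n_linker + 1) * dx + radius_b, 0, 0)
  xb <- sweep(.fib_shell(atoms_per_shell, radius_b, off + 0.3), 2,
              centre_b, "+")
  xb <- xb[order(xb[, 1]), , drop = FALSE]  # attachment (min x) first

  na <- atoms_per_shell
  atoms <- .shell_atoms(xa, "A", 1L, atom_vdw)
  if (n_linker > 0) {
    k <- seq_len(n_linker)
    lx <- cbind(radius_a + dx * k, dy * (-1)^k, 0)
    atoms <- rbind(atoms, .shell_atoms(lx, "A", na + 1L, atom_vdw,
                                       serial_start = na + 1L))
  }
  nb_start <- na + n_linker + 1L
  atoms_b <- .shell_atoms(xb, "A", nb_start, atom_vdw,
                          serial_start = nb_start)
  cof_pos <- centre_b + c(-(radius_b + 0.8), 0, 0)  # faces domain A
  cof <- .cof_atom(cof_pos, "A", nb_start + atoms_per_shell,
                   atom_vdw, nb_start + atoms_per_shell)
  atoms <- rbind(atoms, atoms_b, cof)
  st <- new_rigid_structure(atoms, label = "toy-multidomain")
  st$cofactors$cof <- structure(
    list(name = "cof", atom_indices = which(st$atoms$resname == "COF")),
    class = "CofactorGroup")
  list(structure = st,
       domain_a = 1:na,
       linker = if (n_linker > 0) (na + 1L):(na + n_linker) else integer(0),
       domain_b = nb_start:(nb_start + atoms_per_shell))
}
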