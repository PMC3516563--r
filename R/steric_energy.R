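# Quartic repulsive van der Waals energy and the translate-to-contact
# procedure that turns a grid placement into a rigid-body complex mimic.

#' Steric (quartic repulsion) parameters
#'
#' `f_vdW = k_vdw * sum_pairs max(0, (s * r_min_ij)^2 - r_ij^2)^2`, summed
#' over intermolecular heavy-atom pairs within `nonbonded_cutoff` that are
#' vdW-active under the reduced mask.  `r_min_ij` combines per-atom contact
#' radii by summation (`"sum"`, the default) or by the arithmetic mean of the
#' diameters (`"mean"`, i.e. the average of the two radii doubled is not
#' taken - the plain mean of the radii is used).
#'
#' @param s dimensionless radius scale (default 0.75).
#' @param k_vdw force constant, kcal/mol/A^4 (default 20).
#' @param nonbonded_cutoff pair-list cutoff, Angstrom (default 8.5, the upper
#'   end of the customary 5.5-8.5 range).
#' @param energy_cutoff accepted-contact energy ceiling, kcal/mol (default
#'   10; 300 for permissive runs).
#' @param reduced apply the reduced side-chain mask (default TRUE).
#' @param combine radius combination rule, `"sum"` or `"mean"`.
#' @param step inward step of the contact search, Angstrom.
#' @param tol bisection tolerance of the contact search, Angstrom.
#' @return A `VdwParams` list.
#' @export
vdw_params <- function(s = 0.75, k_vdw = 20, nonbonded_cutoff = 8.5,
                       energy_cutoff = 10, reduced = TRUE,
                       combine = c("sum", "mean"), step = 0.1, tol = 0.01) {
  combine <- match.arg(combine)
  stopifnot(s > 0, s <= 1, k_vdw > 0, nonbonded_cutoff > 0,
            energy_cutoff > 0, step > 0, tol > 0)
  structure(list(s = s, k_vdw = k_vdw, nonbonded_cutoff = nonbonded_cutoff,
                 energy_cutoff = energy_cutoff, reduced = reduced,
                 combine = combine, step = step, tol = tol),
            class = "VdwParams")
}

# Radii as used pairwise: under the "mean" rule r_ij = (r_i + r_j)/2, which
# equals summing half-radii, so halve per-atom radii once here.
.engine_radii <- function(structure, vdw) {
  r <- structure$atoms$rmin
  if (vdw$combine == "mean") r / 2 else r
}

#' Intermolecular quartic repulsive energy
#'
#' Evaluates the repulsive quartic potential between two posed structures.
#' Pairs are restricted to the non-bonded cutoff and, when
#' `params$reduced` is TRUE, to atoms active under the reduced side-chain
#' mask.  The result is non-negative and depends only on the relative pose.
#'
#' @param a,b `RigidStructure`s at their current poses.
#' @param params a `VdwParams`.
#' @return Energy in kcal/mol.
#' @export
vdw_energy <- function(a, b, params = vdw_params()) {
  cpp_vdw_energy(coords(a), .engine_radii(a, params), .active_mask(a, params),
                 coords(b), .engine_radii(b, params), .active_mask(b, params),
                 params$s, params$k_vdw, params$nonbonded_cutoff)
}

#' Translate a mobile structure to steric contact
#'
#' Moves `mobile` along `direction` (pointing from the mobile CM towards the
#' fixed CM) until the quartic repulsive energy lies in
#' `(0, energy_cutoff]`: the largest CM separation with positive energy,
#' located by inward 0.1-Angstrom stepping to the first positive-energy
#' position followed by bisection of the zero/positive boundary to 0.01
#' Angstrom (both configurable via `params`).  A mobile that starts
#' overlapped is receded first, so the result is independent of the starting
#' separation along the line.
#'
#' @param mobile,fixed `RigidStructure`s.
#' @param direction length-3 vector from the mobile towards the fixed CM.
#' @param params a `VdwParams`.
#' @return List with `contact` (logical), `r_contact` (CM separation,
#'   Angstrom), `energy` (kcal/mol), `displacement` (signed motion along
#'   `direction`) and `structure` (the posed mobile), or
#'   `contact = FALSE` when no positive energy is reachable on the line.
#' @export
translate_to_contact <- function(mobile, fixed, direction,
                                 params = vdw_params()) {
  n <- sqrt(sum(direction^2))
  if (n < 1e-12) stop("zero direction")
  e <- -direction / n  # receding direction (away from the fixed body)
  res <- cpp_contact_line(coords(fixed), .engine_radii(fixed, params),
                          .active_mask(fixed, params),
                          coords(mobile), .engine_radii(mobile, params),
                          .active_mask(mobile, params),
                          e, params$s, params$k_vdw, params$nonbonded_cutoff,
                          params$energy_cutoff, params$step, params$tol,
                          FALSE)
  if (!res$found) return(list(contact = FALSE, r_contact = NA_real_,
                              energy = NA_real_, displacement = NA_real_,
                              structure = NULL))
  posed <- apply_transform(mobile, translation = res$disp * e)
  r <- sqrt(sum((center_of_mass(posed) - center_of_mass(fixed))^2))
  list(contact = TRUE, r_contact = r, energy = res$energy,
       displacement = res$disp, structure = posed)
}
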