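# Multidomain and ensemble handling: conformer sets, ensemble aggregation of
# distance maps, and a simplified tethered-domain conformer generator.

#' Conformer set
#'
#' @param conformers list of `RigidStructure`s sharing atom identity.
#' @param provenance free-form provenance record (`"file"` or a list
#'   describing the generator call).
#' @return A `ConformerSet`.
#' @export
conformer_set <- function(conformers, provenance = "file") {
  stopifnot(length(conformers) >= 1L)
  n <- vapply(conformers, function(s) nrow(s$atoms), integer(1))
  if (length(unique(n)) != 1L)
    stop("conformers differ in atom count")
  nm <- lapply(conformers, function(s) s$atoms$name)
  if (!all(vapply(nm, identical, logical(1), nm[[1]])))
    stop("conformers differ in atom names")
  structure(list(conformers = conformers, provenance = provenance),
            class = "ConformerSet")
}

#' @export
print.ConformerSet <- function(x, ...) {
  cat("ConformerSet:", length(x$conformers), "conformer(s),",
      nrow(x$conformers[[1]]$atoms), "atoms each\n")
  invisible(x)
}

#' Read a multi-model PDB as a conformer set
#'
#' @param path multi-model PDB file (MODEL/ENDMDL records).
#' @param ... passed to [read_structure()].
#' @return A `ConformerSet`.
#' @export
read_conformers <- function(path, ...) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  n <- nrow(pdb$xyz)
  conformer_set(lapply(seq_len(n), function(m)
    read_structure(path, model = m, ...)), provenance = "file")
}

#' Aggregate distance maps over a receptor conformer ensemble
#'
#' Computes per-conformer epitope metrics and Table-style ensemble
#' statistics: mean and sample (n-1) standard deviation of the epitope
#' sizes, the pooled shortest cofactor distance, and the pooled upper-limit
#' rate.
#'
#' @param maps list of `DistanceMap`s, one per conformer.
#' @param et an `EtParams` used to annotate any map lacking rates.
#' @param threshold epitope rate threshold, 1/s.
#' @return An `EnsembleSummary`.
#' @export
aggregate_ensemble <- function(maps, et = et_params(), threshold = 1e6) {
  if (length(maps) == 0L) stop("empty ensemble")
  maps <- lapply(maps, function(m) {
    if (is.null(m$solutions$k_et)) map_rates(m, et) else m
  })
  metrics <- lapply(maps, epitope_metrics, threshold = threshold)
  sizes <- vapply(metrics, `[[`, numeric(1), "epitope_size")
  structure(list(
    per_conformer = metrics,
    epitope_sizes = sizes,
    mean_size = mean(sizes),
    sd_size = if (length(sizes) > 1L) sd(sizes) else 0,
    pooled_min_d = min(vapply(metrics, `[[`, numeric(1), "shortest_r")),
    pooled_upper_ket = max(vapply(metrics, `[[`, numeric(1),
                                  "upper_limit_ket")),
    threshold = threshold, n_conformers = length(maps)
  ), class = "EnsembleSummary")
}

#' @export
print.EnsembleSummary <- function(x, ...) {
  cat("EnsembleSummary over ", x$n_conformers, " conformer(s):\n",
      "  epitope size: ", round(x$mean_size, 1), " +/- ",
      round(x$sd_size, 1), "\n",
      "  pooled shortest r: ", round(x$pooled_min_d, 2), " A\n",
      "  pooled upper-limit k_ET: ",
      format(x$pooled_upper_ket, digits = 3), " 1/s\n", sep = "")
  invisible(x)
}

# backbone atoms of the linker in chain order, used as torsion pivots
.linker_pivots <- function(atoms, domain_a, domain_b, linker) {
  bb <- c("N", "CA", "C")
  ord <- order(atoms$resno, match(atoms$name, bb))
  # last backbone atom of domain A and first of domain B flank the pivots
  pick <- function(resnos) {
    i <- ord[atoms$resno[ord] %in% resnos & atoms$name[ord] %in% bb]
    i
  }
  c(tail(pick(domain_a), 1L), pick(linker), head(pick(domain_b), 1L))
}

#' Generate tethered two-domain conformers
#'
#' A simplified stand-in for torsion-angle simulated annealing: the two
#' domains are kept internally rigid while torsions about the consecutive
#' linker backbone bonds (N-CA, CA-C where present; virtual CA-CA bonds for
#' coarse chains) are drawn uniformly on `[0, 2 pi)`.  A draw is accepted
#' only if the domain-domain and domain-linker quartic repulsion energies do
#' not exceed `vdw$energy_cutoff`.  Deterministic under a fixed seed.
#'
#' @param structure a single-chain `RigidStructure`.
#' @param domain_a,domain_b,linker residue-number vectors; must be disjoint
#'   and cover the chain.  An empty `linker` returns the input conformation
#'   only.
#' @param n number of conformers (default 100).
#' @param seed RNG seed.
#' @param vdw a `VdwParams` (its `energy_cutoff` is the clash criterion).
#' @param max_attempts rejection-sampling budget.
#' @return A `ConformerSet` of `n` conformers (the generator is flagged as a
#'   simplified sampler in the provenance).
#' @export
generate_linker_conformers <- function(structure, domain_a, domain_b, linker,
                                       n = 100, seed = 1,
                                       vdw = vdw_params(),
                                       max_attempts = 100 * n) {
  atoms <- structure$atoms
  all_res <- sort(unique(atoms$resno))
  claimed <- c(domain_a, domain_b, linker)
  if (anyDuplicated(claimed))
    stop("domain and linker residue ranges overlap")
  if (!setequal(claimed, all_res))
    stop("domain and linker ranges must cover the chain")
  if (length(linker) == 0L)
    return(conformer_set(list(structure),
                         provenance = list(generated = TRUE, seed = seed,
                                           linker = linker, n = 1L)))

  pivots <- .linker_pivots(atoms, domain_a, domain_b, linker)
  if (length(pivots) < 2L) stop("no rotatable linker bonds found")

  in_a <- atoms$resno %in% domain_a
  in_b <- atoms$resno %in% domain_b
  in_l <- atoms$resno %in% linker
  mask <- structure$reduced_mask
  rad <- .engine_radii(structure, vdw)
  sub <- function(xyz, sel) xyz[sel, , drop = FALSE]
  clash_free <- function(xyz) {
    e_ab <- cpp_vdw_energy(sub(xyz, in_a), rad[in_a], mask[in_a],
                           sub(xyz, in_b), rad[in_b], mask[in_b],
                           vdw$s, vdw$k_vdw, vdw$nonbonded_cutoff)
    if (e_ab > vdw$energy_cutoff) return(FALSE)
    e_al <- cpp_vdw_energy(sub(xyz, in_a), rad[in_a], mask[in_a],
                           sub(xyz, in_l), rad[in_l], mask[in_l],
                           vdw$s, vdw$k_vdw, vdw$nonbonded_cutoff)
    if (e_al > vdw$energy_cutoff) return(FALSE)
    e_bl <- cpp_vdw_energy(sub(xyz, in_b), rad[in_b], mask[in_b],
                           sub(xyz, in_l), rad[in_l], mask[in_l],
                           vdw$s, vdw$k_vdw, vdw$nonbonded_cutoff)
    e_bl <= vdw$energy_cutoff
  }

  xyz0 <- coords(structure)
  ord_key <- atoms$resno * 10 + match(atoms$name, c("N", "CA", "C"),
                                      nomatch = 2L)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(seed)

  out <- vector("list", n)
  got <- 0L
  attempts <- 0L
  while (got < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("could not generate ", n, " clash-free conformers in ",
           max_attempts, " attempts (", got, " accepted)")
    xyz <- xyz0
    for (j in seq_len(length(pivots) - 1L)) {
      p1 <- xyz[pivots[j], ]
      p2 <- xyz[pivots[j + 1L], ]
      axis <- p2 - p1
      if (sum(axis^2) < 1e-12) next
      ang <- stats::runif(1, 0, 2 * pi)
      R <- rotation_about_axis(axis, ang)
      # everything after the proximal pivot rotates; the distal pivot lies
      # on the axis so including it is harmless
      rot_sel <- ord_key > ord_key[pivots[j]]
      xyz[rot_sel, ] <- sweep(sweep(xyz[rot_sel, , drop = FALSE], 2, p1) %*%
                                t(R), 2, p1, "+")
    }
    if (clash_free(xyz)) {
      got <- got + 1L
      out[[got]] <- set_coords(structure, xyz)
    }
  }
  conformer_set(out, provenance = list(generated = TRUE, seed = seed,
                                       linker = linker, n = n,
                                       attempts = attempts,
                                       sampler = "uniform-torsion rejection (simplified)"))
}
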