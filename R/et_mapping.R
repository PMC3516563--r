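# Distance-to-rate conversion (Moser-Dutton ruler with the Marcus activation
# term), functional-epitope metrics, and distribution diagnostics.

#' Electron-transfer rate parameters
#'
#' Constants of the non-adiabatic ET rate expression
#' `k_ET = k0 * exp(-beta * (r - r0)) * exp(-(dG + lambda)^2 /
#' (4 * lambda * kB * T))`.
#'
#' @param delta_G reaction free energy difference, eV.
#' @param lambda reorganization energy, eV (must be positive).
#' @param temperature Kelvin (default 298.15).
#' @param k0 nuclear frequency, 1/s (default 1e13).
#' @param beta electronic-coupling decay coefficient, 1/Angstrom (default
#'   1.4).
#' @param r0 van der Waals contact distance, Angstrom (default 3.6).
#' @param k_B Boltzmann constant, eV/K.
#' @return An `EtParams` list.
#' @export
et_params <- function(delta_G = 0, lambda = 1.0, temperature = 298.15,
                      k0 = 1e13, beta = 1.4, r0 = 3.6,
                      k_B = 8.617333e-5) {
  if (lambda <= 0) stop("reorganization energy lambda must be positive")
  if (temperature <= 0) stop("temperature must be positive")
  structure(list(delta_G = delta_G, lambda = lambda,
                 temperature = temperature, k0 = k0, beta = beta, r0 = r0,
                 k_B = k_B), class = "EtParams")
}

#' Non-adiabatic electron-transfer rate
#'
#' The distance-ruler rate: exponential decay of the electronic coupling
#' from the van der Waals contact distance `r0`, times the Marcus
#' activation (Franck-Condon) factor.  Distances below `r0` are clamped to
#' `r0` (the rate is capped at the activation-weighted `k0`) with a
#' warning, since the ruler is parameterised from contact outwards.
#' Vectorised over `r`.
#'
#' @param r edge-to-edge distance(s), Angstrom.
#' @param params an `EtParams`.
#' @return Rate(s) in 1/s.
#' @export
et_rate <- function(r, params = et_params()) {
  if (any(r < params$r0)) {
    warning("distance(s) below the contact distance r0 clamped to r0")
    r <- pmax(r, params$r0)
  }
  fc <- exp(-(params$delta_G + params$lambda)^2 /
              (4 * params$lambda * params$k_B * params$temperature))
  params$k0 * exp(-params$beta * (r - params$r0)) * fc
}

#' Annotate a distance map with ET rates
#'
#' Applies [et_rate()] to every solution's `d_min`; pure and
#' order-preserving.  Distances below `r0` are clamped as in [et_rate()];
#' clamped solutions are counted in `n_clamped`.
#'
#' @param map a `DistanceMap`.
#' @param params an `EtParams`.
#' @return The map with a `k_et` solutions column and `$et` set.
#' @export
map_rates <- function(map, params = et_params()) {
  d <- map$solutions$d_min
  map$n_clamped <- sum(d < params$r0)
  map$solutions$k_et <- suppressWarnings(et_rate(d, params))
  map$et <- params
  map
}

#' Functional-epitope summary metrics
#'
#' `epitope_size` counts the CMs whose best rotamer supports a rate above
#' `threshold`; `upper_limit_ket` is the map-wide maximum rate (the
#' upper-limit ET rate of the complex); `top_decile_mean` averages the top
#' 10 percent (by rate, `ceiling(0.1 * size)` solutions) of the
#' above-threshold set, reported as `NA` when the set is empty;
#' `shortest_r` is the smallest cofactor edge-to-edge distance on the map.
#'
#' @param map a rate-annotated `DistanceMap` (see [map_rates()]).
#' @param threshold rate threshold, 1/s (default 1e6).
#' @return An `EpitopeMetrics` list.
#' @export
epitope_metrics <- function(map, threshold = 1e6) {
  k <- map$solutions$k_et
  if (is.null(k)) stop("map has no rates; call map_rates() first")
  if (length(k) == 0L) stop("empty map")
  above <- k[k > threshold]
  size <- length(above)
  top <- if (size > 0L) {
    mean(sort(above, decreasing = TRUE)[seq_len(ceiling(0.1 * size))])
  } else NA_real_
  structure(list(upper_limit_ket = max(k), epitope_size = size,
                 top_decile_mean = top,
                 shortest_r = min(map$solutions$d_min),
                 threshold = threshold, n_solutions = length(k)),
            class = "EpitopeMetrics")
}

#' @export
print.EpitopeMetrics <- function(x, ...) {
  cat("EpitopeMetrics:\n",
      "  upper-limit k_ET: ", format(x$upper_limit_ket, digits = 3),
      " 1/s\n",
      "  epitope size (k_ET > ", format(x$threshold), "): ",
      x$epitope_size, " of ", x$n_solutions, " CMs\n",
      "  top-decile mean:  ", format(x$top_decile_mean, digits = 3),
      " 1/s\n",
      "  shortest r:       ", round(x$shortest_r, 2), " A\n", sep = "")
  invisible(x)
}

# left-closed binning from 0 shared by the histogram utilities
.bin_counts <- function(values, bin_width, n_bins = NULL) {
  if (bin_width <= 0) stop("bin_width must be positive")
  idx <- floor(values / bin_width)
  if (any(idx < 0)) stop("negative values cannot be binned from 0")
  if (is.null(n_bins)) n_bins <- max(idx) + 1L
  counts <- tabulate(idx + 1L, nbins = n_bins)
  data.frame(lower = (seq_len(n_bins) - 1L) * bin_width,
             upper = seq_len(n_bins) * bin_width,
             count = counts)
}

#' Histogram of cofactor distances over a map
#'
#' Left-closed bins `[i*w, (i+1)*w)` starting at 0; counts sum to the number
#' of solutions.
#'
#' @param map a `DistanceMap`.
#' @param bin_width bin width, Angstrom.
#' @return Data frame with `lower`, `upper`, `count`.
#' @export
distance_histogram <- function(map, bin_width = 1) {
  .bin_counts(map$solutions$d_min, bin_width)
}

#' Histogram of ET rates over a map
#'
#' Binned on `log10(k_ET)` by default (rates span many decades), analogous
#' to [distance_histogram()].
#'
#' @param map a rate-annotated `DistanceMap`.
#' @param bin_width bin width (log10 units by default).
#' @param log10 bin the decadic logarithm of the rate (default TRUE).
#' @return Data frame with `lower`, `upper`, `count`.
#' @export
rate_histogram <- function(map, bin_width = 1, log10 = TRUE) {
  k <- map$solutions$k_et
  if (is.null(k)) stop("map has no rates; call map_rates() first")
  .bin_counts(if (log10) log10(k) else k, bin_width)
}

#' Pearson correlation of distance occurrences between two maps
#'
#' Bins both maps' `d_min` values on a common left-closed grid from 0 and
#' returns the Pearson correlation of the per-bin counts.  Degenerate
#' (zero-variance) count vectors give `NA` with a warning.
#'
#' @param map_a,map_b `DistanceMap`s.
#' @param bin_width common bin width, Angstrom.
#' @return Pearson correlation coefficient, or `NA`.
#' @export
occurrence_correlation <- function(map_a, map_b, bin_width = 1) {
  da <- map_a$solutions$d_min
  db <- map_b$solutions$d_min
  n_bins <- floor(max(da, db) / bin_width) + 1L
  ca <- .bin_counts(da, bin_width, n_bins)$count
  cb <- .bin_counts(db, bin_width, n_bins)$count
  if (length(ca) < 2L || sd(ca) == 0 || sd(cb) == 0) {
    warning("zero-variance occurrence counts; correlation undefined")
    return(NA_real_)
  }
  cor(ca, cb)
}

#' Rate enhancement between two distances, in orders of magnitude
#'
#' `beta * (r_b - r_a) / ln(10)`: the decadic log of the rate ratio between
#' two geometries sharing the same driving force and reorganization energy
#' (the activation factor cancels).
#'
#' @param r_a,r_b edge-to-edge distances, Angstrom.
#' @param beta decay coefficient, 1/Angstrom (default 1.4).
#' @return Orders of magnitude (positive when `r_b > r_a`).
#' @export
log_enhancement <- function(r_a, r_b, beta = 1.4) {
  stopifnot(r_a > 0, r_b > 0)
  beta * (r_b - r_a) / log(10)
}
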