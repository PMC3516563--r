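# Run orchestration: configuration files, the three run types (binary,
# ternary, ensemble) and the TSV / pseudo-atom-PDB writers.

.default_config <- function() {
  list(
    grid = list(type = "spherical", delta_d = 1, d = NULL,
                extent = NULL, radius = NULL, axis = NULL),
    scheme = list(mode = "reduced", delta = 5, delta_xi = NULL),
    vdw = list(),
    et = list(),
    threshold = 1e6,
    cofactor_fixed = NULL, cofactor_mobile = NULL,
    output_dir = ".", label = "run", verbose = TRUE
  )
}

.merge_config <- function(user, defaults = .default_config()) {
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(user[[k]]) && is.list(defaults[[k]]))
      .merge_config(user[[k]], defaults[[k]]) else user[[k]]
  }
  defaults
}

#' Read a run configuration file
#'
#' YAML key/value configuration mirroring the arguments of [run_binary()],
#' [run_ternary()] and [run_ensemble()]; unspecified keys fall back to the
#' package defaults.
#'
#' @param path YAML file.
#' @return Configuration list.
#' @export
read_run_config <- function(path) {
  .merge_config(yaml::read_yaml(path))
}

.as_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    read_run_config(config)
  else .merge_config(config)
}

.config_objects <- function(cfg) {
  for (f in c("fixed", "mobile"))
    if (is.character(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("input file '", cfg[[f]], "' does not exist")
  fixed <- if (inherits(cfg$fixed, "RigidStructure")) cfg$fixed
           else read_structure(cfg$fixed)
  mobile <- if (inherits(cfg$mobile, "RigidStructure")) cfg$mobile
            else read_structure(cfg$mobile)
  if (is.null(cfg$cofactor_fixed) || is.null(cfg$cofactor_mobile))
    stop("cofactor_fixed and cofactor_mobile selections are required")
  vdw <- do.call(vdw_params, cfg$vdw)
  et <- do.call(et_params, cfg$et)
  scheme <- rotamer_scheme(cfg$scheme$mode, delta = cfg$scheme$delta,
                           delta_xi = cfg$scheme$delta_xi)
  list(fixed = fixed, mobile = mobile, vdw = vdw, et = et, scheme = scheme)
}

.config_grid <- function(cfg, fixed, mobile) {
  g <- cfg$grid
  if (identical(g$type, "cylindrical")) {
    cylindrical_grid(fixed, axis = g$axis, delta_d = g$delta_d,
                     extent = g$extent, radius = g$radius)
  } else {
    d <- g$d
    if (is.null(d))
      d <- sqrt(sum((center_of_mass(fixed) - center_of_mass(mobile))^2))
    build_cm_grid(d, g$delta_d)
  }
}

#' Write the solutions table of a map as TSV
#' @param map a `DistanceMap`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_solutions_tsv <- function(map, path) {
  write.table(format(map$solutions, digits = 10, trim = TRUE,
                     scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a solutions TSV back as a minimal map
#'
#' Returns a list with a `solutions` data frame, sufficient for the metric
#' and histogram utilities; used to verify TSV round-trips.
#'
#' @param path TSV written by [write_solutions_tsv()].
#' @return List with element `solutions`.
#' @export
read_solutions_tsv <- function(path) {
  list(solutions = read.table(path, header = TRUE, sep = "\t"))
}

#' Write epitope metrics as a two-column TSV
#' @param metrics an `EpitopeMetrics`.
#' @param path output file.
#' @param extra optional named list appended as additional rows.
#' @return `path`, invisibly.
#' @export
write_metrics_tsv <- function(metrics, path, extra = NULL) {
  vals <- c(unclass(metrics), extra)
  df <- data.frame(metric = names(vals),
                   value = vapply(vals, function(v)
                     format(v, digits = 10), character(1)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a pseudo-atom CM map as PDB
#'
#' One HETATM per solution CM with the B-factor column carrying `d_min` or
#' `log10(k_ET)`, for surface colouring in any molecular viewer.
#'
#' @param map a `DistanceMap` (rate-annotated for `value = "log10_ket"`).
#' @param path output file.
#' @param value which quantity to store in the B-factor column.
#' @return `path`, invisibly.
#' @export
write_map_pdb <- function(map, path, value = c("d_min", "log10_ket")) {
  value <- match.arg(value)
  s <- map$solutions
  b <- if (value == "d_min") s$d_min else log10(s$k_et)
  n <- nrow(s)
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(as.matrix(s[, c("cm_x", "cm_y",
                                                     "cm_z")]))),
                   type = rep("HETATM", n), resno = seq_len(n),
                   resid = rep("MAP", n), eleno = seq_len(n),
                   elety = rep("CM", n), chain = rep("X", n),
                   o = rep(1, n), b = round(b, 2),
                   elesy = rep("C", n))
  invisible(path)
}

.write_artifacts <- function(map, et, threshold, outdir, label,
                             extra_metrics = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  map <- map_rates(map, et)
  metrics <- epitope_metrics(map, threshold)
  f <- function(x) file.path(outdir, paste0(label, "_", x))
  files <- c(
    solutions = write_solutions_tsv(map, f("solutions.tsv")),
    metrics = write_metrics_tsv(metrics, f("metrics.tsv"),
                                extra = extra_metrics),
    dist_hist = {
      write.table(distance_histogram(map, 1), f("distance_histogram.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      f("distance_histogram.tsv")
    },
    rate_hist = {
      write.table(rate_histogram(map, 1), f("rate_histogram.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      f("rate_histogram.tsv")
    },
    map_dmin = write_map_pdb(map, f("map_dmin.pdb"), "d_min"),
    map_ket = write_map_pdb(map, f("map_ket.pdb"), "log10_ket")
  )
  list(map = map, metrics = metrics, files = files)
}

#' Run a binary-complex mapping
#'
#' Reads the configuration (list or YAML path), samples the mobile protein
#' over the fixed protein's surface, converts distances to ET rates and
#' writes the run artifacts: solutions TSV, metrics TSV, distance and rate
#' histograms, and pseudo-atom map PDBs coloured by distance and by rate.
#'
#' @param config configuration list or YAML file path.  Required keys:
#'   `fixed`, `mobile` (paths or `RigidStructure`s), `cofactor_fixed`,
#'   `cofactor_mobile` (selection strings); see [read_run_config()] for the
#'   optional blocks.
#' @return List with the rate-annotated `map`, the `metrics`, and the
#'   written `files`.
#' @export
run_binary <- function(config) {
  cfg <- .as_config(config)
  obj <- .config_objects(cfg)
  grid <- .config_grid(cfg, obj$fixed, obj$mobile)
  if (isTRUE(cfg$verbose))
    message("run_binary: grid of ", grid$total, " CMs, ",
            rotamer_count(obj$scheme), " rotamers per CM")
  map <- sample_binary(obj$fixed, obj$mobile, grid, obj$scheme, obj$vdw,
                       cfg$cofactor_fixed, cfg$cofactor_mobile,
                       verbose = isTRUE(cfg$verbose))
  if (isTRUE(cfg$verbose))
    message("run_binary: ", map$n_no_contact, " contact-free CM(s)")
  .write_artifacts(map, obj$et, cfg$threshold, cfg$output_dir, cfg$label)
}

#' Run a ternary-complex mapping
#'
#' As [run_binary()] but with a pre-bound blocker molecule (`config$blocker`,
#' path or `RigidStructure`, already at its bound pose): the second probe is
#' sampled disregarding the blocker and solutions clashing with it are
#' removed.
#'
#' @inheritParams run_binary
#' @return As [run_binary()]; the metrics TSV additionally records the
#'   number of blocked solutions.
#' @export
run_ternary <- function(config) {
  cfg <- .as_config(config)
  obj <- .config_objects(cfg)
  if (is.null(cfg$blocker)) stop("ternary run requires a blocker")
  blocker <- if (inherits(cfg$blocker, "RigidStructure")) cfg$blocker
             else read_structure(cfg$blocker)
  grid <- .config_grid(cfg, obj$fixed, obj$mobile)
  map <- sample_ternary(obj$fixed, blocker, obj$mobile, grid, obj$scheme,
                        obj$vdw, cfg$cofactor_fixed, cfg$cofactor_mobile,
                        verbose = isTRUE(cfg$verbose))
  .write_artifacts(map, obj$et, cfg$threshold, cfg$output_dir, cfg$label,
                   extra_metrics = list(n_blocked = map$n_blocked))
}

#' Run an ensemble mapping over receptor conformers
#'
#' Samples the mobile protein against every conformer of the receptor
#' (`config$conformers`: a multi-model PDB path or a `ConformerSet`) and
#' writes per-conformer metrics plus the ensemble summary (mean and sample
#' standard deviation of the epitope sizes, pooled shortest distance).
#'
#' @inheritParams run_binary
#' @return List with `maps` (per conformer), the `summary`
#'   (`EnsembleSummary`) and the written `files`.
#' @export
run_ensemble <- function(config) {
  cfg <- .as_config(config)
  obj <- .config_objects(cfg)
  conf <- cfg$conformers
  set <- if (inherits(conf, "ConformerSet")) conf
         else read_conformers(conf)
  maps <- lapply(seq_along(set$conformers), function(i) {
    fixed <- set$conformers[[i]]
    grid <- .config_grid(cfg, fixed, obj$mobile)
    m <- sample_binary(fixed, obj$mobile, grid, obj$scheme, obj$vdw,
                       cfg$cofactor_fixed, cfg$cofactor_mobile)
    map_rates(m, obj$et)
  })
  summ <- aggregate_ensemble(maps, obj$et, cfg$threshold)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  per <- data.frame(
    conformer = seq_along(maps),
    epitope_size = summ$epitope_sizes,
    upper_limit_ket = vapply(summ$per_conformer, `[[`, numeric(1),
                             "upper_limit_ket"),
    shortest_r = vapply(summ$per_conformer, `[[`, numeric(1), "shortest_r")
  )
  f_per <- file.path(cfg$output_dir, paste0(cfg$label, "_conformers.tsv"))
  write.table(format(per, digits = 10), f_per, sep = "\t", quote = FALSE,
              row.names = FALSE)
  f_sum <- file.path(cfg$output_dir,
                     paste0(cfg$label, "_ensemble_summary.tsv"))
  sum_df <- data.frame(
    metric = c("n_conformers", "mean_epitope_size", "sd_epitope_size",
               "pooled_min_d", "pooled_upper_ket"),
    value = format(c(summ$n_conformers, summ$mean_size, summ$sd_size,
                     summ$pooled_min_d, summ$pooled_upper_ket),
                   digits = 10))
  write.table(sum_df, f_sum, sep = "\t", quote = FALSE, row.names = FALSE)
  list(maps = maps, summary = summ,
       files = c(conformers = f_per, summary = f_sum))
}
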