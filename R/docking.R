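# Post-processing of multi-run docking results: greedy energy-ranked pose
# clustering, run-consistency checks, grid-box arithmetic, and binding
# free energy / inhibition constant / pKd conversions.

#' Build a pose ensemble table
#'
#' @param conformations List of N x 3 ligand heavy-atom coordinate
#'   matrices, all with the same atom count.
#' @param energy Binding free energies, kcal/mol (finite).
#' @param run_id Integer docking-run identifiers.
#' @return Object of class `pose_ensemble`: tibble with columns `pose`
#'   (1-based id), `energy`, `run_id` and list-column `conf`.
#' @export
pose_ensemble <- function(conformations, energy, run_id = seq_along(conformations)) {
  nat <- unique(map_int(conformations, nrow))
  if (length(nat) != 1) abort("all poses must have the same atom count")
  if (!all(is.finite(energy))) abort("pose energies must be finite")
  out <- tibble(pose = seq_along(conformations), energy = as.numeric(energy),
                run_id = as.integer(run_id), conf = conformations)
  structure(out, class = c("pose_ensemble", class(out)))
}

#' Cluster docking poses by RMSD tolerance
#'
#' Greedy energy-ranked clustering, the convention of docking virtual
#' screening tools: poses are visited in order of increasing energy (ties
#' broken by lower run id, then pose id); the first pose seeds cluster 1;
#' each subsequent pose joins the first existing cluster whose *seed* lies
#' within the RMSD tolerance, otherwise it seeds a new cluster.  Cluster
#' seeds are therefore each cluster's lowest-energy member and the cluster
#' list is energy-sorted.  RMSD is in-place by default (fixed receptor
#' frame); superimposed RMSD is available via `rmsd_mode`.
#'
#' @param poses A [pose_ensemble()].
#' @param tolerance RMSD tolerance, Angstrom (default 2.0).
#' @param rmsd_mode "in_place" (default) or "superimposed".
#' @return Object of class `cluster_result`: the pose tibble plus a
#'   `cluster` column, with a per-cluster summary in attribute `clusters`.
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @export
cluster_poses <- function(poses, tolerance = 2.0,
                          rmsd_mode = c("in_place", "superimposed")) {
  rmsd_mode <- match.arg(rmsd_mode)
  if (nrow(poses) == 0) abort("need at least one pose")
  dist_fun <- if (rmsd_mode == "in_place") {
    function(a, b) rmsd_in_place(a, b)
  } else {
    function(a, b) superpose(a, b)$rmsd
  }
  ord <- order(poses$energy, poses$run_id, poses$pose)
  seeds <- integer(0)           # row indices of cluster seeds
  assign <- integer(nrow(poses))
  for (r in ord) {
    placed <- FALSE
    for (ci in seq_along(seeds)) {
      if (dist_fun(poses$conf[[seeds[ci]]], poses$conf[[r]]) <= tolerance) {
        assign[r] <- ci
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      seeds <- c(seeds, r)
      assign[r] <- length(seeds)
    }
  }
  out <- mutate(poses, cluster = assign)
  summ <- out |>
    group_by(.data$cluster) |>
    summarise(size = n(), seed_pose = .data$pose[which.min(.data$energy)],
              min_energy = min(.data$energy), mean_energy = mean(.data$energy),
              .groups = "drop") |>
    arrange(.data$cluster)
  structure(out, clusters = summ, tolerance = tolerance,
            rmsd_mode = rmsd_mode,
            class = c("cluster_result", class(poses)))
}

#' @describeIn cluster_poses Per-cluster summary table (size, seed pose,
#'   minimum and mean energy), energy-ordered.
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @export
tidy.cluster_result <- function(x, ...) attr(x, "clusters")

#' @describeIn cluster_poses One-row summary: number of clusters, largest
#'   cluster size and fraction, best energy.
#' @export
glance.cluster_result <- function(x, ...) {
  cl <- attr(x, "clusters")
  tibble(n_poses = nrow(x), n_clusters = nrow(cl),
         largest_size = max(cl$size),
         largest_fraction = max(cl$size) / nrow(x),
         best_energy = min(cl$min_energy),
         tolerance = attr(x, "tolerance"))
}

#' @describeIn cluster_poses Pose energies grouped by cluster.
#' @param object A `cluster_result`.
#' @export
autoplot.cluster_result <- function(object, ...) {
  df <- as_tibble(object)[, c("pose", "energy", "cluster")]
  df$cluster <- factor(df$cluster)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cluster, y = .data$energy)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.6) +
    ggplot2::labs(x = "cluster (energy-ranked)",
                  y = "binding free energy (kcal/mol)")
}

#' Check docking run-to-run consistency
#'
#' Docking results are considered consistent when at least a given
#' fraction (default 70%) of the independent runs produced a best pose
#' within a strict RMSD cut (default < 0.5 Angstrom) of the overall best
#' energy pose.
#'
#' @param run_best List of per-run best-pose coordinate matrices.
#' @param reference Overall best-energy pose coordinates.
#' @param rmsd_cut Strict RMSD cut, Angstrom.
#' @param fraction Required fraction of runs.
#' @param rmsd_mode "in_place" or "superimposed".
#' @return One-row tibble: `n_runs`, `n_within`, `fraction`, `pass`.
#' @examples
#' ref <- matrix(rnorm(15), 5, 3)
#' consistency_check(list(ref, ref + 1), ref)
#' @export
consistency_check <- function(run_best, reference, rmsd_cut = 0.5,
                              fraction = 0.70,
                              rmsd_mode = c("in_place", "superimposed")) {
  rmsd_mode <- match.arg(rmsd_mode)
  if (length(run_best) == 0) abort("need at least one run")
  r <- map_dbl(run_best, function(p) {
    if (rmsd_mode == "in_place") rmsd_in_place(p, reference)
    else superpose(reference, p)$rmsd
  })
  n_within <- sum(r < rmsd_cut)   # strict inequality
  frac <- n_within / length(r)
  ok <- frac >= fraction
  tibble(n_runs = length(r), n_within = n_within, fraction = frac, pass = ok)
}

#' Convert a binding free energy to inhibition constant and pKd
#'
#' Converts a docking binding free energy (kcal/mol) at temperature T to
#' an inhibition constant `Ki = exp(dG / RT)` (molar) and binding affinity
#' `pKd = -log10(Ki) = -dG / (RT ln 10)`, with
#' R = 1.98720e-3 kcal/(mol K).  A negative (favourable) free energy gives
#' a positive pKd.
#'
#' @param delta_G Binding free energies, kcal/mol.
#' @param temperature Temperature, K (default 298.15).
#' @return Tibble (one row per input): `delta_G`, `K_i` (molar), `pKd`,
#'   `temperature`.
#' @examples
#' dg_to_pkd(-12.5)  # pKd 9.2 at 298.15 K
#' @export
dg_to_pkd <- function(delta_G, temperature = 298.15) {
  if (any(temperature <= 0)) abort("temperature must be positive")
  RT <- dockfit_constants()$R_kcal * temperature
  tibble(delta_G = delta_G, K_i = exp(delta_G / RT),
         pKd = -delta_G / (RT * log(10)), temperature = temperature)
}

#' Convert a pKd back to a binding free energy
#'
#' Exact inverse of [dg_to_pkd()]: `dG = -pKd * RT ln 10` kcal/mol.
#'
#' @param pKd Binding affinities.
#' @param temperature Temperature, K.
#' @return Binding free energies, kcal/mol.
#' @examples
#' pkd_to_dg(6.5)  # -8.9 kcal/mol
#' @export
pkd_to_dg <- function(pKd, temperature = 298.15) {
  if (any(temperature <= 0)) abort("temperature must be positive")
  RT <- dockfit_constants()$R_kcal * temperature
  -pKd * RT * log(10)
}

#' Adjust a binding affinity to another temperature
#'
#' Experimental catecholamine affinities are typically measured at
#' physiological temperature (310.15 K) while docking energies are
#' evaluated at 298.15 K.  Two documented adjustment modes are provided:
#' `"offset"` (default) adds a constant number of pKd units (default
#' +0.2, the conventional correction); `"rescale"` keeps the free energy
#' fixed and re-evaluates pKd at the target temperature, which for a
#' favourable (negative) free energy *lowers* the affinity.  The mode is
#' recorded in the result.
#'
#' @param report Tibble from [dg_to_pkd()] (columns `delta_G`, `pKd`,
#'   `temperature`).
#' @param target_temperature Target temperature, K.
#' @param mode "offset" or "rescale".
#' @param offset pKd units added in offset mode.
#' @return The report with updated `pKd`, `K_i`, `temperature` and a
#'   `mode` column.
#' @examples
#' temperature_adjusted_pkd(dg_to_pkd(-8.1))  # 5.9 -> 6.1
#' @export
temperature_adjusted_pkd <- function(report, target_temperature = 310.15,
                                     mode = c("offset", "rescale"),
                                     offset = 0.2) {
  mode <- match.arg(mode)
  out <- report
  if (mode == "offset") {
    out$pKd <- report$pKd + offset
  } else {
    RT <- dockfit_constants()$R_kcal * target_temperature
    out$pKd <- -report$delta_G / (RT * log(10))
  }
  out$K_i <- 10^(-out$pKd)
  out$temperature <- target_temperature
  out$mode <- mode
  out
}

#' Mean and spread of per-run binding free energies
#'
#' @param energies Best binding free energies of independent runs,
#'   kcal/mol.
#' @return One-row tibble: `mean`, `sd` (sample standard deviation; 0 for
#'   a single value), `n`.
#' @examples
#' mean_bfe(c(-7.0, -7.8))
#' @export
mean_bfe <- function(energies) {
  if (length(energies) == 0) abort("need at least one energy")
  tibble(mean = mean(energies),
         sd = if (length(energies) > 1) sd(energies) else 0,
         n = length(energies))
}

#' Docking grid-box edge and ligand-fit check
#'
#' The grid edge is `points * spacing` (e.g. 50 points at 0.375 Angstrom
#' resolution give an 18.75 Angstrom box).  When a ligand radius of
#' gyration is supplied, the edge-to-Rg ratio is compared against a
#' recommended lower bound (default 2.9).
#'
#' @param points Grid points per axis (>= 2).
#' @param spacing Grid spacing, Angstrom (> 0).
#' @param radius_of_gyration Optional ligand Rg, Angstrom.
#' @param min_ratio Required edge / Rg ratio.
#' @return One-row tibble: `edge` (Angstrom) and, when Rg is given,
#'   `ratio` and `fits`.
#' @examples
#' grid_edge(50, 0.375)  # 18.75
#' @export
grid_edge <- function(points, spacing, radius_of_gyration = NULL,
                      min_ratio = 2.9) {
  if (points < 2) abort("a grid needs at least 2 points per axis")
  if (spacing <= 0) abort("grid spacing must be positive")
  edge <- points * spacing
  if (is.null(radius_of_gyration)) return(tibble(edge = edge))
  ratio <- edge / radius_of_gyration
  tibble(edge = edge, ratio = ratio, fits = ratio >= min_ratio)
}
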