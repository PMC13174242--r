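# Synthetic-data generators: cell populations, donor cohorts and current
# traces with known ground truth. The generators are phenomenological at the
# sub-pulse level: they reproduce the statistical structure the downstream
# analysis assumes (three-region pulse shape, recovery-bin mixtures, group
# shifts), not channel hydrodynamics.

#' Recovery-time bin labels
#'
#' The five recovery classes used throughout: immediate recovery (0 ms),
#' three finite bins (50-60, 60-70, 70-120 ms) and "Inf" for cells still
#' deformed at the end of the 120 ms observation window.
#' @return character vector of length 5.
#' @export
recovery_bins <- function() {
  c("0ms", "50-60ms", "60-70ms", "70-120ms", "Inf")
}

#' Specification of a synthetic cell population
#'
#' Defines the distribution a simulated population is drawn from: free
#' diameters are truncated-normal (truncated just above the contraction
#' width so the applied strain is defined for every cell), wCDI is
#' truncated-normal with the given location/scale, and the recovery class is
#' drawn from a probability vector over the five bins of [recovery_bins()].
#'
#' The deformation ground truth uses an oblate-spheroid bulge model,
#' `L_deform = bulge_factor * sqrt(D_cell^3 / wc)`; `bulge_factor = 1` is
#' the volume-conserving spheroid, and the default 1.35 (with lognormal
#' jitter `bulge_sd`) makes the contraction sub-pulse deeper than the
#' node-pore sub-pulse across the physical size range, as observed pulses
#' are.
#'
#' @param group_label one of `"younger"`, `"older"`, `"high_risk"`.
#' @param mean_diameter_um,sd_diameter_um free-diameter distribution (um).
#' @param wcdi_location,wcdi_scale wCDI distribution (dimensionless).
#' @param recovery_distribution probability vector over the five recovery
#'   bins; must sum to 1.
#' @param n_cells number of cells (>= 1).
#' @param seed integer seed; mandatory, every generator is deterministic
#'   under a fixed seed.
#' @param mean_uflow,sd_uflow per-cell node-region flow velocity (um/ms).
#' @param bulge_factor,bulge_sd deformation bulge model (see Details).
#' @return an object of class `population_spec`.
#' @seealso [younger_population_spec()], [older_population_spec()],
#'   [high_risk_population_spec()] for the built-in group defaults.
#' @export
population_spec <- function(group_label = c("younger", "older", "high_risk"),
                            mean_diameter_um = 17.5,
                            sd_diameter_um = 1.0,
                            wcdi_location = 4.0,
                            wcdi_scale = 0.45,
                            recovery_distribution =
                              c(0.55, 0.20, 0.10, 0.10, 0.05),
                            n_cells = 100L,
                            seed = 1L,
                            mean_uflow = 15,
                            sd_uflow = 0.3,
                            bulge_factor = 1.35,
                            bulge_sd = 0.03) {
  group_label <- match.arg(group_label)
  if (length(n_cells) != 1L || !is.finite(n_cells) || n_cells < 1) {
    stopf("`n_cells` must be >= 1")
  }
  check_scalar_pos(sd_diameter_um, "sd_diameter_um")
  p <- recovery_distribution
  if (length(p) != 5L || any(p < 0) || abs(sum(p) - 1) > 1e-12) {
    stopf("`recovery_distribution` must be 5 non-negative probabilities summing to 1")
  }
  spec <- list(
    group_label = group_label,
    mean_diameter_um = mean_diameter_um, sd_diameter_um = sd_diameter_um,
    wcdi_location = wcdi_location, wcdi_scale = wcdi_scale,
    recovery_distribution = p, n_cells = as.integer(n_cells),
    seed = as.integer(seed),
    mean_uflow = mean_uflow, sd_uflow = sd_uflow,
    bulge_factor = bulge_factor, bulge_sd = bulge_sd
  )
  class(spec) <- "population_spec"
  spec
}

#' Built-in population defaults per group
#'
#' Synthetic stand-ins for the empirical feature distributions of each
#' donor group (which are not published at the per-cell level):
#' * younger: mean free diameter 17.5 um, chosen so the strain relation at
#'   the 10.5 um contraction width yields an average strain of ~0.4; fast
#'   recovery dominates; wCDI location 4.0 (softer).
#' * older: same size distribution, lower wCDI (stiffer) and most recovery
#'   mass on the 70-120 ms and infinite bins (slow-recovering fraction).
#' * high_risk: diameters ~0.5 um smaller than average risk, mechanics close
#'   to the older group.
#'
#' @param n_cells,seed passed to [population_spec()].
#' @param ... overrides forwarded to [population_spec()].
#' @return a `population_spec`.
#' @export
younger_population_spec <- function(n_cells = 100L, seed = 1L, ...) {
  population_spec("younger", mean_diameter_um = 17.5, wcdi_location = 4.0,
                  recovery_distribution = c(0.55, 0.20, 0.10, 0.10, 0.05),
                  n_cells = n_cells, seed = seed, ...)
}

#' @rdname younger_population_spec
#' @export
older_population_spec <- function(n_cells = 100L, seed = 1L, ...) {
  population_spec("older", mean_diameter_um = 17.5, wcdi_location = 3.2,
                  recovery_distribution = c(0.15, 0.15, 0.15, 0.30, 0.25),
                  n_cells = n_cells, seed = seed, ...)
}

#' @rdname younger_population_spec
#' @export
high_risk_population_spec <- function(n_cells = 100L, seed = 1L, ...) {
  population_spec("high_risk", mean_diameter_um = 17.0, wcdi_location = 3.3,
                  recovery_distribution = c(0.20, 0.15, 0.15, 0.25, 0.25),
                  n_cells = n_cells, seed = seed, ...)
}

# Truncated-normal sampler by rejection; lower truncation only.
rtruncnorm_lower <- function(n, mean, sd, lower) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0L) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw > lower
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

# Ground-truth recovery time drawn within a bin. Finite bins leave a 6 ms
# guard below the upper edge so that the 5 ms pitch of the post-contraction
# sensing train cannot push the measured recovery time across a bin
# boundary.
draw_recovery_time <- function(class) {
  n <- length(class)
  r <- numeric(n)
  r[class == "0ms"] <- 0
  r[class == "50-60ms"] <- stats::runif(sum(class == "50-60ms"), 50, 54)
  r[class == "60-70ms"] <- stats::runif(sum(class == "60-70ms"), 60, 64)
  r[class == "70-120ms"] <- stats::runif(sum(class == "70-120ms"), 70, 114)
  r[class == "Inf"] <- Inf
  r
}

#' Simulate a cell population with full ground truth
#'
#' Draws `n_cells` cells from a [population_spec()] and derives, through the
#' device-physics forward models, every quantity a real measurement would
#' produce: free diameter, wCDI, contraction transit time
#' (`dT_cont = Lc * D / (U * h * wCDI)`, the wCDI relation inverted),
#' deformation length and transverse deformation, recovery class and
#' ground-truth recovery time, per-cell flow velocity, applied strain, and
#' the true relative sub-pulse depths `dI_np` (via the blockade model) and
#' `dI_c` (via the oblate-spheroid volume ratio). Deterministic under the
#' spec's seed.
#'
#' @param spec a [population_spec()].
#' @param geometry an [nps_geometry()].
#' @return data frame with one row per cell and the population ground truth
#'   (`cell_id`, `group`, `D_cell_um`, `wCDI`, `dT_cont_ms`, `L_deform_um`,
#'   `delta_deform`, `recovery_class`, `recovery_time_ms`,
#'   `U_flow_um_per_ms`, `strain`, `dI_np`, `dI_c`).
#' @examples
#' pop <- simulate_population(younger_population_spec(n_cells = 20, seed = 7))
#' head(pop)
#' @export
simulate_population <- function(spec, geometry = nps_geometry()) {
  stopifnot(inherits(spec, "population_spec"), inherits(geometry, "nps_geometry"))
  wc <- geometry$contraction_width_um
  with_seed(spec$seed, {
    n <- spec$n_cells
    D <- rtruncnorm_lower(n, spec$mean_diameter_um, spec$sd_diameter_um,
                          lower = wc + 0.2)
    wcdi <- rtruncnorm_lower(n, spec$wcdi_location, spec$wcdi_scale, lower = 0.5)
    U <- rtruncnorm_lower(n, spec$mean_uflow, spec$sd_uflow, lower = 5)
    cls <- sample(recovery_bins(), n, replace = TRUE,
                  prob = spec$recovery_distribution)
    rtime <- draw_recovery_time(cls)
    gamma <- spec$bulge_factor * exp(stats::rnorm(n, 0, spec$bulge_sd))
    L_deform <- gamma * sqrt(D^3 / wc)
    dT_cont <- geometry$contraction_length_um * D /
      (U * geometry$channel_height_um * wcdi)
    V_contraction <- geometry$contraction_length_um * wc *
      geometry$channel_height_um
    dI_np <- forward_relative_blockade(D, geometry$De_um, geometry$L_eff_um)
    dI_c <- pi * wc * L_deform^2 / 6 / V_contraction
    data.frame(
      cell_id = sprintf("%s_%04d", spec$group_label, seq_len(n)),
      group = spec$group_label,
      D_cell_um = D,
      wCDI = wcdi,
      dT_cont_ms = dT_cont,
      L_deform_um = L_deform,
      delta_deform = L_deform / D,
      recovery_class = cls,
      recovery_time_ms = rtime,
      U_flow_um_per_ms = U,
      strain = (D - wc) / D,
      dI_np = dI_np,
      dI_c = dI_c,
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate a donor cohort
#'
#' Builds a cohort of donors split between the two chronological classes
#' (younger < 35 y, older > 50 y), each donor carrying cells drawn from the
#' corresponding group default of [younger_population_spec()] /
#' [older_population_spec()]. Donor ages are drawn uniformly within the
#' class's age range and per-donor seeds derive from the cohort seed.
#'
#' @param n_donors_per_group donors in each chronological class.
#' @param cells_per_donor cells simulated per donor.
#' @param seed cohort seed.
#' @param geometry an [nps_geometry()].
#' @return data frame of cells with `donor_id`, `age` and population ground
#'   truth columns.
#' @export
simulate_cohort <- function(n_donors_per_group = 9L, cells_per_donor = 75L,
                            seed = 1L, geometry = nps_geometry()) {
  ages_y <- with_seed(derive_seed(seed, "ages-younger"),
                      sample(22:34, n_donors_per_group, replace = TRUE))
  ages_o <- with_seed(derive_seed(seed, "ages-older"),
                      sample(51:75, n_donors_per_group, replace = TRUE))
  out <- list()
  for (i in seq_len(n_donors_per_group)) {
    for (grp in c("younger", "older")) {
      id <- sprintf("%s-%02d", if (grp == "younger") "Y" else "O", i)
      spec_fun <- if (grp == "younger") younger_population_spec else
        older_population_spec
      pop <- simulate_population(
        spec_fun(n_cells = cells_per_donor,
                 seed = derive_seed(seed, paste0("donor-", id))),
        geometry
      )
      pop$donor_id <- id
      pop$age <- if (grp == "younger") ages_y[i] else ages_o[i]
      pop$cell_id <- paste0(id, "_", seq_len(nrow(pop)))
      out[[id]] <- pop
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Acquisition settings for trace simulation
#'
#' @param sampling_rate_hz sampling rate (>= 1 kHz; default 10 kHz resolves
#'   ms-scale sub-pulses at low cost).
#' @param baseline_current baseline current in normalised units.
#' @param noise_sd Gaussian baseline-noise standard deviation (same units as
#'   the baseline; default 1e-4 of a unit baseline).
#' @param deform_excess fractional depth elevation of post-contraction
#'   sub-pulses while the cell is still deformed.
#' @return list of class `acquisition_spec`.
#' @export
acquisition_spec <- function(sampling_rate_hz = 10000,
                             baseline_current = 1.0,
                             noise_sd = 1e-4,
                             deform_excess = 0.35) {
  if (sampling_rate_hz < 1000) stopf("sampling rate must be >= 1 kHz")
  check_scalar_pos(baseline_current, "baseline_current")
  if (noise_sd < 0) stopf("`noise_sd` must be >= 0")
  structure(list(sampling_rate_hz = sampling_rate_hz,
                 baseline_current = baseline_current,
                 noise_sd = noise_sd,
                 deform_excess = deform_excess),
            class = "acquisition_spec")
}

# Piecewise-constant sub-pulse segments (start/duration/depth, ms) of one
# cell event, relative to the cell's channel entry at t = 0. Depths are
# relative blockades; the post-contraction train marks a pore as recovered
# when its entry time (since contraction exit) reaches the cell's
# ground-truth recovery time, with 0 ms meaning the first post pore is
# already recovered.
cell_event_segments <- function(cell, geometry, acq) {
  U <- cell$U_flow_um_per_ms
  node_ms <- geometry$node_length_um / U
  pore_ms <- geometry$pore_length_um / U
  pnode_ms <- geometry$post_node_length_um / U
  ppore_ms <- geometry$post_pore_length_um / U
  segs <- list()
  t <- 0
  for (k in seq_len(geometry$n_pre_pores)) {
    t <- t + node_ms
    segs[[length(segs) + 1L]] <- c(start = t, dur = pore_ms, depth = cell$dI_np)
    t <- t + pore_ms
  }
  t <- t + node_ms
  segs[[length(segs) + 1L]] <- c(start = t, dur = cell$dT_cont_ms,
                                 depth = cell$dI_c)
  t <- t + cell$dT_cont_ms
  exit_t <- t
  for (j in seq_len(geometry$n_post_pores)) {
    t <- t + pnode_ms
    since_exit <- t - exit_t
    depth <- if (since_exit >= cell$recovery_time_ms) {
      cell$dI_np
    } else {
      cell$dI_np * (1 + acq$deform_excess)
    }
    segs[[length(segs) + 1L]] <- c(start = t, dur = ppore_ms, depth = depth)
    t <- t + ppore_ms
  }
  list(segments = do.call(rbind, segs), duration_ms = t, exit_ms = exit_t)
}

#' Simulate a current trace for one or more cells
#'
#' Produces a sampled current-versus-time trace with the three-region pulse
#' structure of a mechano-NPS measurement: pre-contraction node-pore
#' sub-pulses of relative depth `dI_np`, one long contraction sub-pulse of
#' depth `dI_c` and duration `dT_cont`, and a train of post-contraction
#' sub-pulses whose depth relaxes back to `dI_np` once the cell's
#' ground-truth recovery time has elapsed (elevated by
#' `acq$deform_excess` while still deformed). Gaussian baseline noise is
#' added at the configured amplitude. Overlapping `entry_times_ms` make the
#' cells' blockades add, emulating coincident transits.
#'
#' @param cells data frame of cells from [simulate_population()] (requires
#'   `dI_np`, `dI_c`, `dT_cont_ms`, `recovery_time_ms`, `U_flow_um_per_ms`,
#'   and `D_cell_um` for the transit check).
#' @param geometry an [nps_geometry()].
#' @param acq an [acquisition_spec()].
#' @param entry_times_ms channel entry time of each cell (ms); default
#'   spaces cells 400 ms apart.
#' @param seed seed for the baseline noise.
#' @return data frame of class `nps_trace` with columns `time_ms`,
#'   `current`; the sampling rate, baseline and per-cell ground truth are
#'   attached as attributes (`sampling_rate_hz`, `baseline_current`,
#'   `ground_truth`).
#' @export
simulate_trace <- function(cells, geometry = nps_geometry(),
                           acq = acquisition_spec(),
                           entry_times_ms = NULL, seed = 1L) {
  stopifnot(inherits(geometry, "nps_geometry"), inherits(acq, "acquisition_spec"))
  cells <- as.data.frame(cells)
  if (nrow(cells) < 1L) stopf("need at least one cell")
  if (!is.null(cells$D_cell_um) &&
      any(cells$D_cell_um >= geometry$pore_width_um)) {
    stopf("cell diameter >= pore width (%g um): cannot transit the sensing pore",
          geometry$pore_width_um)
  }
  if (is.null(entry_times_ms)) {
    entry_times_ms <- 50 + (seq_len(nrow(cells)) - 1) * 400
  }
  stopifnot(length(entry_times_ms) == nrow(cells))

  events <- lapply(seq_len(nrow(cells)), function(i) {
    cell_event_segments(as.list(cells[i, ]), geometry, acq)
  })
  total_ms <- max(entry_times_ms +
                    vapply(events, `[[`, numeric(1), "duration_ms")) + 50
  dt <- 1000 / acq$sampling_rate_hz
  time_ms <- seq(0, total_ms, by = dt)
  current <- rep(acq$baseline_current, length(time_ms))
  for (i in seq_along(events)) {
    segs <- events[[i]]$segments
    t0 <- entry_times_ms[i]
    for (s in seq_len(nrow(segs))) {
      idx <- which(time_ms >= t0 + segs[s, "start"] &
                     time_ms < t0 + segs[s, "start"] + segs[s, "dur"])
      current[idx] <- current[idx] -
        segs[s, "depth"] * acq$baseline_current
    }
  }
  if (acq$noise_sd > 0) {
    current <- current + with_seed(derive_seed(seed, "trace-noise"),
                                   stats::rnorm(length(current), 0, acq$noise_sd))
  }
  tr <- data.frame(time_ms = time_ms, current = current)
  attr(tr, "sampling_rate_hz") <- acq$sampling_rate_hz
  attr(tr, "baseline_current") <- acq$baseline_current
  attr(tr, "ground_truth") <- cbind(cells, entry_time_ms = entry_times_ms)
  class(tr) <- c("nps_trace", "data.frame")
  tr
}

#' Read or write a current trace as CSV
#'
#' The on-disk format is a plain CSV with header `time_ms,current`
#' (normalised current). The sampling rate is recovered from the time grid
#' on read.
#'
#' @param trace an `nps_trace` data frame.
#' @param path file path.
#' @return `read_trace()` returns an `nps_trace`; `write_trace()` returns
#'   `path` invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace)[, c("time_ms", "current")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  tr <- utils::read.csv(path)
  if (!all(c("time_ms", "current") %in% names(tr))) {
    stopf("trace CSV must have columns `time_ms,current`")
  }
  dt <- diff(tr$time_ms)
  if (any(dt <= 0) || (max(dt) - min(dt)) > 1e-9 * mean(dt)) {
    stopf("trace must be uniformly sampled with strictly increasing time")
  }
  attr(tr, "sampling_rate_hz") <- 1000 / mean(dt)
  class(tr) <- c("nps_trace", "data.frame")
  tr
}
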