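# Pulse extraction: from a raw current trace to the four sub-pulse
# quantities (dI_np, dI_c, dT_cont, dT_r) per cell event.
#
# Detection is threshold-based (baseline - k * MAD) on a lightly smoothed
# copy of the trace; sub-pulse edges are then refined to the half-depth
# crossing of the smoothed signal, which for a centred moving average
# recovers the underlying step position to within one sample. Depths are
# medians of the unsmoothed plateau samples, so noiseless traces round-trip
# exactly.

smooth_trace <- function(current, n) {
  if (n <= 1L) return(current)
  sm <- stats::filter(current, rep(1 / n, n), sides = 2)
  sm <- as.numeric(sm)
  # pad the filter's NA margins with the raw signal
  na <- is.na(sm)
  sm[na] <- current[na]
  sm
}

#' Robust baseline estimate of a current trace
#'
#' Two-pass estimate: a crude baseline is taken as the median of the top
#' quartile of samples (sub-pulses only ever lower the current, so the upper
#' tail is pulse-free even when pulses occupy most of the trace); the noise
#' scale is estimated around it, and the final baseline is the median of all
#' samples within the noise band of the crude value.
#'
#' @param trace an `nps_trace` or data frame with `time_ms`, `current`.
#' @param k MAD multiplier delimiting the baseline band.
#' @return strictly positive baseline current (scalar).
#' @export
estimate_baseline <- function(trace, k = 5) {
  x <- trace$current
  if (length(x) < 100L) stopf("baseline estimation needs >= 100 samples")
  top <- x[x >= stats::quantile(x, 0.75)]
  b0 <- stats::median(top)
  sigma <- stats::mad(top)
  band <- x[x >= b0 - max(k * sigma, 1e-9 * abs(b0))]
  if (length(band) < 0.02 * length(x)) {
    stopf("no baseline region found (trace appears to be all pulse)")
  }
  b <- stats::median(band)
  if (b <= 0) stopf("estimated baseline is non-positive")
  b
}

# Refine one run's edges to the half-depth crossings of the smoothed trace.
refine_edges <- function(sm, i0, i1, baseline, depth) {
  half <- baseline - depth / 2
  j0 <- i0
  while (j0 > 1L && sm[j0 - 1L] < half) j0 <- j0 - 1L
  while (j0 <= i1 && sm[j0] >= half) j0 <- j0 + 1L
  j1 <- i1
  n <- length(sm)
  while (j1 < n && sm[j1 + 1L] < half) j1 <- j1 + 1L
  while (j1 >= j0 && sm[j1] >= half) j1 <- j1 - 1L
  c(j0, j1)
}

#' Detect and segment sub-pulses in a current trace
#'
#' Samples below `baseline - max(k * MAD, 1e-6 * baseline)` (on a smoothed
#' copy of the trace; window `smooth_ms`) form candidate sub-pulses; runs
#' separated by less than `event_gap_ms` are grouped into one cell event.
#' Each event with the expected number of sub-pulses for the geometry
#' (`n_pre + 1 + n_post`) is segmented into pre-contraction pore sub-pulses,
#' the contraction sub-pulse (the deepest, and tie-broken longest,
#' sub-pulse) and post-contraction sub-pulses. Events with extra sub-pulses
#' are flagged `"coincident"` (two cells in the channel) and events with
#' missing segments `"incomplete"`; neither is silently dropped.
#'
#' @param trace an `nps_trace` or data frame with `time_ms`, `current`.
#' @param geometry an [nps_geometry()].
#' @param k MAD multiplier for the detection threshold.
#' @param event_gap_ms minimum pulse-free gap separating two cell events.
#' @param smooth_ms moving-average window used for detection (the reported
#'   depths always come from unsmoothed samples).
#' @return list with `events` (event_id, n_subpulses, flag, t_start, t_end),
#'   `subpulses` (event_id, region, t_start_ms, t_end_ms, duration_ms,
#'   depth, n_samples) and the estimated `baseline`.
#' @export
detect_subpulses <- function(trace, geometry = nps_geometry(), k = 5,
                             event_gap_ms = 30, smooth_ms = 0.8) {
  x <- trace$current
  t <- trace$time_ms
  empty <- list(
    events = data.frame(event_id = integer(), n_subpulses = integer(),
                        flag = character(), t_start_ms = numeric(),
                        t_end_ms = numeric()),
    subpulses = data.frame(event_id = integer(), region = character(),
                           t_start_ms = numeric(), t_end_ms = numeric(),
                           duration_ms = numeric(), depth = numeric(),
                           n_samples = integer()),
    baseline = NA_real_, noise_sd = 0
  )
  if (length(x) < 100L) return(empty)
  dt <- t[2] - t[1]
  baseline <- estimate_baseline(trace, k = k)
  nwin <- max(1L, round(smooth_ms / dt))
  if (nwin %% 2L == 0L) nwin <- nwin + 1L  # odd window keeps edges symmetric
  sm <- smooth_trace(x, nwin)
  sigma0 <- stats::mad(x[x >= stats::quantile(x, 0.75)])
  in_band <- x >= baseline - 5 * sigma0 - 1e-9 * baseline
  noise_raw <- stats::mad(x[in_band])
  noise_sm <- stats::mad(sm[in_band])
  if (!is.finite(noise_raw)) noise_raw <- 0
  if (!is.finite(noise_sm)) noise_sm <- 0
  thr <- baseline - max(k * noise_sm, 1e-6 * baseline)

  below <- sm < thr
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(i0 = starts[r$values], i1 = ends[r$values])
  runs <- runs[runs$i1 - runs$i0 + 1L >= 2L, , drop = FALSE]
  if (nrow(runs) == 0L) {
    empty$baseline <- baseline
    return(empty)
  }

  margin <- nwin  # samples at each run edge contaminated by smoothing
  edges <- t(vapply(seq_len(nrow(runs)), function(i) {
    i0 <- runs$i0[i]; i1 <- runs$i1[i]
    plateau <- if (i1 - i0 + 1L > 3L * margin) {
      x[(i0 + margin):(i1 - margin)]
    } else {
      x[i0:i1]
    }
    refine_edges(sm, i0, i1, baseline, baseline - stats::median(plateau))
  }, integer(2)))
  # a deep pulse at low SNR can fragment into several threshold runs that
  # all refine to (parts of) the same extent: merge intervals that overlap
  # or nearly touch (anything closer than half the shortest node gap)
  min_gap <- max(2L, as.integer(round(0.5 / dt)))
  ord <- order(edges[, 1])
  merged <- list()
  cur <- edges[ord[1], ]
  for (i in ord[-1]) {
    if (edges[i, 1] <= cur[2] + min_gap) {
      cur[2] <- max(cur[2], edges[i, 2])
    } else {
      merged[[length(merged) + 1L]] <- cur
      cur <- edges[i, ]
    }
  }
  merged[[length(merged) + 1L]] <- cur

  sp <- lapply(merged, function(e) {
    n <- e[2] - e[1] + 1L
    # depth: trimmed mean of the raw (unsmoothed) plateau; raw pulse edges
    # are step-sharp, so trimming 2 samples per side removes edge-jitter
    # contamination while keeping sqrt(n) noise efficiency
    interior <- if (n >= 9L) x[(e[1] + 2L):(e[2] - 2L)] else x[e[1]:e[2]]
    depth <- baseline - mean(interior)
    data.frame(t_start_ms = t[e[1]], t_end_ms = t[e[2]] + dt,
               duration_ms = n * dt, depth = depth,
               n_samples = n, n_plateau = length(interior),
               plateau_sd = stats::sd(interior))
  })
  sp <- do.call(rbind, sp)
  sp <- sp[sp$depth > 0, , drop = FALSE]
  if (nrow(sp) == 0L) {
    empty$baseline <- baseline
    empty$noise_sd <- noise_raw
    return(empty)
  }

  gap_after <- c(diff(sp$t_start_ms) - sp$duration_ms[-nrow(sp)], Inf)
  event_id <- cumsum(c(1, utils::head(gap_after, -1) > event_gap_ms))
  sp$event_id <- as.integer(event_id)

  expected <- expected_subpulses(geometry)
  # a single transiting cell produces flat (rectangular) sub-pulses; two
  # cells in the channel stack their blockades, leaving sub-pulses with
  # stepped plateaus -- use that as the coincidence signature
  sd_thr <- max(2.5 * noise_raw, 2e-6 * baseline)
  ev <- do.call(rbind, lapply(split(sp, sp$event_id), function(s) {
    stacked <- any(s$plateau_sd > sd_thr, na.rm = TRUE)
    flag <- if (nrow(s) > expected || stacked) "coincident"
            else if (nrow(s) == expected) "ok"
            else "incomplete"
    data.frame(event_id = s$event_id[1], n_subpulses = nrow(s), flag = flag,
               t_start_ms = min(s$t_start_ms), t_end_ms = max(s$t_end_ms))
  }))
  rownames(ev) <- NULL

  sp$region <- NA_character_
  for (e_i in which(ev$flag == "ok")) {
    id <- ev$event_id[e_i]
    idx <- which(sp$event_id == id)
    # with the expected sub-pulse count, the contraction sits right after
    # the pre-contraction pores; sanity-check it is the deepest long
    # sub-pulse (it must block the narrower channel more than the pores)
    cand <- geometry$n_pre_pores + 1L
    if (sp$depth[idx[cand]] <= max(sp$depth[idx[seq_len(cand) - 1L]])) {
      ev$flag[e_i] <- "incomplete"
      next
    }
    sp$region[idx] <- ifelse(seq_along(idx) < cand, "pre",
                             ifelse(seq_along(idx) == cand, "contraction",
                                    "post"))
  }
  sp <- sp[, c("event_id", "region", "t_start_ms", "t_end_ms", "duration_ms",
               "depth", "n_samples", "n_plateau", "plateau_sd")]
  rownames(sp) <- NULL
  list(events = ev, subpulses = sp, baseline = baseline,
       noise_sd = noise_raw)
}

# Recovery time of one segmented event. Convention: 0 ms when the first
# post-contraction sub-pulse has already returned to the pre-contraction
# depth; otherwise the elapsed time from contraction exit to the entry of
# the first recovered sub-pulse; Inf when no sub-pulse entering within the
# observation window has recovered.
event_recovery_time <- function(post, dI_np, exit_ms, window_ms, tol,
                                noise_scale) {
  entries <- post$t_start_ms - exit_ms
  in_window <- entries <= window_ms
  n_eff <- if (!is.null(post$n_plateau)) post$n_plateau else post$n_samples
  tol_abs <- pmax(tol * dI_np, 3 * noise_scale / sqrt(pmax(n_eff, 1)))
  recovered <- abs(post$depth - dI_np) <= tol_abs
  hit <- which(recovered & in_window)
  if (length(hit) == 0L) return(Inf)
  if (hit[1] == 1L) return(0)
  entries[hit[1]]
}

#' Extract sub-pulse features from segmented cell events
#'
#' Converts each cleanly segmented event of [detect_subpulses()] into the
#' four sub-pulse quantities: `dI_np` (mean pre-contraction pore depth),
#' `dI_c` and `dT_cont_ms` (contraction depth and duration), and the
#' recovery time `dT_r_ms`, defined as the elapsed time from contraction
#' exit until a post-contraction sub-pulse first returns to within
#' `recovery_tol` of `dI_np` (0 when the first post sub-pulse has already
#' recovered, `Inf` when none recovers within `window_ms`). The recovery
#' tolerance has a noise-aware floor of three standard errors of the
#' sub-pulse depth estimate. Flagged (coincident/incomplete) events are
#' excluded from the feature table and reported in the `flags` attribute.
#'
#' @param detection result of [detect_subpulses()].
#' @param geometry an [nps_geometry()].
#' @param window_ms observation window for recovery (120 ms for this device
#'   geometry and flow rate).
#' @param recovery_tol relative tolerance on the return to `dI_np`.
#' @param noise_sd baseline noise scale used for the tolerance floor
#'   (estimated from the trace when `NULL`).
#' @return data frame `cell_id, I_baseline, dI_np, dI_c, dT_cont_ms,
#'   dT_r_ms, U_flow_um_per_ms` (depths in relative units; `dT_r_ms` uses
#'   `Inf` as the sentinel); excluded events in `attr(, "flags")`.
#' @export
extract_features <- function(detection, geometry = nps_geometry(),
                             window_ms = 120, recovery_tol = 0.02,
                             noise_sd = NULL) {
  ev <- detection$events
  sp <- detection$subpulses
  baseline <- detection$baseline
  ok <- ev$event_id[ev$flag == "ok"]
  flags <- ev[ev$flag != "ok", , drop = FALSE]
  if (is.null(noise_sd)) {
    noise_sd <- if (!is.null(detection$noise_sd)) detection$noise_sd else 0
  }
  out <- lapply(ok, function(id) {
    s <- sp[sp$event_id == id, , drop = FALSE]
    pre <- s[s$region == "pre", , drop = FALSE]
    con <- s[s$region == "contraction", , drop = FALSE]
    post <- s[s$region == "post", , drop = FALSE]
    if (nrow(pre) == 0L || nrow(con) != 1L) return(NULL)
    dI_np <- mean(pre$depth) / baseline
    if (nrow(post) == 0L) return(NULL)  # dT_r undefined; event flagged
    dT_r <- event_recovery_time(
      transform(post, depth = depth / baseline),
      dI_np, con$t_end_ms, window_ms, recovery_tol,
      noise_scale = noise_sd / baseline
    )
    data.frame(
      cell_id = sprintf("event_%03d", id),
      I_baseline = baseline,
      dI_np = dI_np,
      dI_c = con$depth / baseline,
      dT_cont_ms = con$duration_ms,
      dT_r_ms = dT_r,
      U_flow_um_per_ms = estimate_Uflow(pre$duration_ms, geometry),
      stringsAsFactors = FALSE
    )
  })
  dropped <- ok[vapply(out, is.null, logical(1))]
  if (length(dropped) > 0L) {
    flags <- rbind(flags, transform(ev[ev$event_id %in% dropped, ],
                                    flag = "missing-segments"))
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) {
    res <- data.frame(cell_id = character(), I_baseline = numeric(),
                      dI_np = numeric(), dI_c = numeric(),
                      dT_cont_ms = numeric(), dT_r_ms = numeric(),
                      U_flow_um_per_ms = numeric())
  }
  rownames(res) <- NULL
  attr(res, "flags") <- flags
  res
}

#' Full trace-to-phenotype pipeline
#'
#' Runs [detect_subpulses()], [extract_features()] and the device physics on
#' a raw trace, returning per-cell mechanophenotypes: free diameter from the
#' blockade model, wCDI, deformation length and transverse deformation,
#' recovery class and applied strain.
#'
#' @param trace an `nps_trace`.
#' @param geometry an [nps_geometry()].
#' @param window_ms,recovery_tol passed to [extract_features()].
#' @param noise_sd baseline noise scale (see [extract_features()]).
#' @return phenotype data frame (`cell_id`, `D_cell_um`, `wCDI`,
#'   `dT_cont_ms`, `L_deform_um`, `delta_deform`, `recovery_class`,
#'   `dT_r_ms`, `U_flow_um_per_ms`, `strain`).
#' @export
process_trace <- function(trace, geometry = nps_geometry(), window_ms = 120,
                          recovery_tol = 0.02, noise_sd = NULL) {
  det <- detect_subpulses(trace, geometry)
  feats <- extract_features(det, geometry, window_ms = window_ms,
                            recovery_tol = recovery_tol, noise_sd = noise_sd)
  phenotype_from_features(feats, geometry)
}

#' Derive mechanophenotypes from sub-pulse features
#'
#' Applies the device physics to a sub-pulse feature table: diameter by
#' inverting the blockade model, wCDI from the contraction transit, the
#' oblate-spheroid deformation from the contraction blockade, the recovery
#' class from the binned recovery time, and the per-cell applied strain.
#'
#' @param features output of [extract_features()] (or a CSV read back with
#'   the same columns).
#' @param geometry an [nps_geometry()].
#' @return phenotype data frame as in [process_trace()].
#' @export
phenotype_from_features <- function(features, geometry = nps_geometry()) {
  if (nrow(features) == 0L) {
    return(data.frame(cell_id = character(), D_cell_um = numeric(),
                      wCDI = numeric(), dT_cont_ms = numeric(),
                      L_deform_um = numeric(), delta_deform = numeric(),
                      recovery_class = character(), dT_r_ms = numeric(),
                      U_flow_um_per_ms = numeric(), strain = numeric()))
  }
  D <- diameter_from_blockade(features$dI_np, geometry$De_um,
                              geometry$L_eff_um)
  defo <- transverse_deformation(features$dI_c, geometry, D)
  wcdi <- compute_wCDI(D, features$dT_cont_ms, features$U_flow_um_per_ms,
                       geometry)
  data.frame(
    cell_id = features$cell_id,
    D_cell_um = D,
    wCDI = wcdi,
    dT_cont_ms = features$dT_cont_ms,
    L_deform_um = defo$L_deform_um,
    delta_deform = defo$delta_deform,
    recovery_class = recovery_bins()[bin_recovery_index(features$dT_r_ms)],
    dT_r_ms = features$dT_r_ms,
    U_flow_um_per_ms = features$U_flow_um_per_ms,
    strain = average_strain(D, geometry$contraction_width_um),
    stringsAsFactors = FALSE
  )
}
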