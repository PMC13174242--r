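#' Mechano-NPS device geometry
#'
#' Describes the microfluidic channel used for mechano-node-pore sensing: a
#' series of node/pore segments, a single narrow contraction channel that
#' applies a fixed average strain to transiting cells, and a post-contraction
#' recovery region segmented into short sensing pores. The defaults are the
#' dimensions of the device used to acquire the data this package models:
#' 50 x 85 um nodes, 700 x 22 um pores, a 3000 x 10.5 um contraction channel,
#' 22.3 um channel height and a 700 um recovery length, driven at 25 kPa with
#' a 1 V DC bias (the last two are metadata; the simulator works from transit
#' speeds, not hydrodynamics).
#'
#' `De_um` is the effective channel diameter of the sensing pore, an
#' empirical constant normally obtained by [calibrate_De()] from polystyrene
#' microspheres of known size; `L_eff_um` is the effective sensing length and
#' defaults to the pore length. The post-contraction recovery region is
#' modelled as `n_post_pores` short node/pore units so that the time at which
#' a cell's sub-pulses return to their pre-contraction magnitude is resolved
#' on a few-millisecond grid.
#'
#' @param node_length_um,node_width_um node dimensions (um).
#' @param pore_length_um,pore_width_um sensing-pore dimensions (um).
#' @param contraction_length_um,contraction_width_um contraction-channel
#'   dimensions (um); the width `wc` sets the applied strain.
#' @param channel_height_um channel height (um).
#' @param recovery_length_um nominal recovery-segment length (um, metadata).
#' @param n_pre_pores number of node/pore units ahead of the contraction.
#' @param post_node_length_um,post_pore_length_um,n_post_pores layout of the
#'   post-contraction sensing train.
#' @param De_um effective channel diameter (um, calibrated).
#' @param L_eff_um effective sensing length (um).
#' @param pressure_kPa,voltage_V acquisition metadata.
#' @return an object of class `nps_geometry` (a validated list).
#' @examples
#' geom <- nps_geometry()
#' geom$contraction_width_um
#' @export
nps_geometry <- function(node_length_um = 50,
                         node_width_um = 85,
                         pore_length_um = 700,
                         pore_width_um = 22,
                         contraction_length_um = 3000,
                         contraction_width_um = 10.5,
                         channel_height_um = 22.3,
                         recovery_length_um = 700,
                         n_pre_pores = 2L,
                         post_node_length_um = 20,
                         post_pore_length_um = 55,
                         n_post_pores = 24L,
                         De_um = 40,
                         L_eff_um = pore_length_um,
                         pressure_kPa = 25,
                         voltage_V = 1) {
  g <- list(
    node_length_um = node_length_um, node_width_um = node_width_um,
    pore_length_um = pore_length_um, pore_width_um = pore_width_um,
    contraction_length_um = contraction_length_um,
    contraction_width_um = contraction_width_um,
    channel_height_um = channel_height_um,
    recovery_length_um = recovery_length_um,
    n_pre_pores = as.integer(n_pre_pores),
    post_node_length_um = post_node_length_um,
    post_pore_length_um = post_pore_length_um,
    n_post_pores = as.integer(n_post_pores),
    De_um = De_um, L_eff_um = L_eff_um,
    pressure_kPa = pressure_kPa, voltage_V = voltage_V
  )
  lens <- c("node_length_um", "pore_length_um", "contraction_length_um",
            "contraction_width_um", "channel_height_um", "recovery_length_um",
            "post_node_length_um", "post_pore_length_um", "De_um", "L_eff_um")
  for (nm in lens) check_scalar_pos(g[[nm]], nm)
  if (g$contraction_width_um >= g$pore_width_um) {
    stopf("contraction width (%.3g) must be narrower than the pore width (%.3g)",
          g$contraction_width_um, g$pore_width_um)
  }
  if (g$n_pre_pores < 1L || g$n_post_pores < 1L) {
    stopf("the channel needs at least one pre- and one post-contraction pore")
  }
  class(g) <- "nps_geometry"
  g
}

#' @export
print.nps_geometry <- function(x, ...) {
  cat("mechano-NPS device geometry\n")
  cat(sprintf("  pore:        %g x %g um (x%d pre-contraction)\n",
              x$pore_length_um, x$pore_width_um, x$n_pre_pores))
  cat(sprintf("  contraction: %g x %g um, height %g um\n",
              x$contraction_length_um, x$contraction_width_um,
              x$channel_height_um))
  cat(sprintf("  recovery:    %d x (%g + %g) um sensing units\n",
              x$n_post_pores, x$post_node_length_um, x$post_pore_length_um))
  cat(sprintf("  effective:   De = %g um, L = %g um\n", x$De_um, x$L_eff_um))
  invisible(x)
}

#' Read or write a device geometry as YAML
#'
#' @param geometry an [nps_geometry()] object.
#' @param path file path.
#' @return `read_geometry()` returns an `nps_geometry`;
#'   `write_geometry()` returns `path` invisibly.
#' @export
write_geometry <- function(geometry, path) {
  stopifnot(inherits(geometry, "nps_geometry"))
  yaml::write_yaml(unclass(geometry), path)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  do.call(nps_geometry, yaml::read_yaml(path))
}

# Number of sub-pulses a single clean cell event should produce.
expected_subpulses <- function(geometry) {
  geometry$n_pre_pores + 1L + geometry$n_post_pores
}
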