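# Device physics: size from blockade, oblate-spheroid deformation, wCDI,
# strain and flow-velocity estimation.

# Pole of the size-correction factor: the blockade model diverges as
# D_cell -> De * (1/0.8)^(1/3).
blockade_pole <- function(De_um) De_um * (1 / 0.8)^(1 / 3)

#' Relative current blockade of a spherical cell in the sensing pore
#'
#' Size-to-signal model for resistive-pulse sensing: a cell of free diameter
#' `D_cell` in a channel of effective diameter `De` and effective length `L`
#' produces a relative current drop
#' \deqn{\Delta I/I = \frac{D_{cell}^3}{D_e^2 L}\,
#'       \frac{1}{1 - 0.8\,(D_{cell}/D_e)^3}.}
#' The correction factor accounts for the finite cell/channel size ratio and
#' diverges at \eqn{D_{cell} = D_e (1/0.8)^{1/3}}; diameters at or beyond the
#' pole are rejected.
#'
#' @param D_cell_um free cell diameter (um); vectorised.
#' @param De_um effective channel diameter (um).
#' @param L_um effective channel length (um).
#' @return dimensionless relative blockade \eqn{\Delta I/I}, strictly
#'   increasing in `D_cell_um`.
#' @seealso [diameter_from_blockade()] for the numerical inverse.
#' @examples
#' forward_relative_blockade(15, De_um = 20, L_um = 700)
#' @export
forward_relative_blockade <- function(D_cell_um, De_um, L_um) {
  check_scalar_pos(De_um, "De_um")
  check_scalar_pos(L_um, "L_um")
  if (any(!is.finite(D_cell_um)) || any(D_cell_um < 0)) {
    stopf("`D_cell_um` must be finite and non-negative")
  }
  pole <- blockade_pole(De_um)
  if (any(D_cell_um >= pole)) {
    stopf("D_cell >= %.4f um lies at/beyond the pole of the correction factor",
          pole)
  }
  ratio3 <- (D_cell_um / De_um)^3
  D_cell_um^3 / (De_um^2 * L_um) / (1 - 0.8 * ratio3)
}

#' Free cell diameter from a measured relative blockade
#'
#' Numerically inverts the blockade model by bisection: the forward relation
#' is strictly increasing on its domain, so the root is unique. Convergence
#' is to better than 1e-6 um.
#'
#' @param dI_over_I measured relative blockade (dimensionless); vectorised.
#' @param De_um effective channel diameter (um).
#' @param L_um effective channel length (um).
#' @return free cell diameter (um).
#' @examples
#' b <- forward_relative_blockade(15, 20, 700)
#' diameter_from_blockade(b, 20, 700)
#' @export
diameter_from_blockade <- function(dI_over_I, De_um, L_um) {
  check_scalar_pos(De_um, "De_um")
  check_scalar_pos(L_um, "L_um")
  if (any(!is.finite(dI_over_I)) || any(dI_over_I <= 0)) {
    stopf("`dI_over_I` must be finite and > 0 (empty-channel blockades are not invertible)")
  }
  eps <- 1e-9
  upper <- blockade_pole(De_um) - 1e-6
  max_blockade <- forward_relative_blockade(upper, De_um, L_um)
  if (any(dI_over_I >= max_blockade)) {
    stopf(paste0("blockade ratio not attainable: admissible range is ",
                 "(0, %.6g) for De = %g um, L = %g um"),
          max_blockade, De_um, L_um)
  }
  vapply(dI_over_I, function(b) {
    stats::uniroot(
      function(d) forward_relative_blockade(d, De_um, L_um) - b,
      lower = eps, upper = upper, tol = 1e-10
    )$root
  }, numeric(1))
}

#' Calibrate the effective channel diameter from microsphere blockades
#'
#' The effective diameter `De` is determined by running polystyrene
#' microspheres of known size through the device and minimising the squared
#' residual between the blockade model's predictions and the measured
#' relative blockades (one-dimensional bounded minimisation over `De`).
#' With a single noiseless measurement this reduces to exact inversion.
#'
#' @param microsphere_blockades measured relative blockades (> 0).
#' @param known_diameter_um microsphere diameter (um).
#' @param L_um effective channel length (um).
#' @return calibrated `De` (um).
#' @export
calibrate_De <- function(microsphere_blockades, known_diameter_um, L_um) {
  check_scalar_pos(known_diameter_um, "known_diameter_um")
  check_scalar_pos(L_um, "L_um")
  b <- microsphere_blockades
  if (length(b) < 1L || any(!is.finite(b)) || any(b <= 0)) {
    stopf("microsphere blockades must be positive finite values")
  }
  # De must exceed known_diameter / (1/0.8)^(1/3) for the model to be defined.
  lower <- known_diameter_um / (1 / 0.8)^(1 / 3) + 1e-6
  upper <- max(1000, 50 * known_diameter_um)
  obj <- function(De) {
    pred <- forward_relative_blockade(known_diameter_um, De, L_um)
    sum((pred - b)^2)
  }
  stats::optimize(obj, interval = c(lower, upper), tol = 1e-9)$minimum
}

#' Transverse deformation of a cell in the contraction channel
#'
#' Inside the contraction channel the cell is modelled as an oblate spheroid
#' of volume \eqn{V_{deform} = \pi w_c L_{deform}^2 / 6}. The relative
#' current drop in the contraction channel is taken as the volume ratio
#' \eqn{V_{deform}/V_{contraction}} with proportionality constant 1 and
#' \eqn{V_{contraction} = L_c w_c h}, which gives
#' \deqn{L_{deform} = \sqrt{6\,(\Delta I_c/I)\,V_{contraction} / (\pi w_c)}}
#' and the dimensionless transverse deformation
#' \eqn{\delta_{deform} = L_{deform}/D_{cell}}.
#'
#' @param dIc_over_I relative blockade in the contraction channel (>= 0);
#'   vectorised.
#' @param geometry an [nps_geometry()].
#' @param D_cell_um free cell diameter (um).
#' @return data frame with `L_deform_um` and `delta_deform`.
#' @export
transverse_deformation <- function(dIc_over_I, geometry, D_cell_um) {
  stopifnot(inherits(geometry, "nps_geometry"))
  if (any(!is.finite(dIc_over_I)) || any(dIc_over_I < 0)) {
    stopf("`dIc_over_I` must be finite and >= 0")
  }
  if (any(!is.finite(D_cell_um)) || any(D_cell_um <= 0)) {
    stopf("`D_cell_um` must be positive")
  }
  wc <- geometry$contraction_width_um
  V_contraction <- geometry$contraction_length_um * wc *
    geometry$channel_height_um
  L_deform <- sqrt(6 * dIc_over_I * V_contraction / (pi * wc))
  data.frame(L_deform_um = L_deform, delta_deform = L_deform / D_cell_um)
}

#' Whole-cell deformability index (wCDI)
#'
#' Dimensionless deformability measure, inversely related to cortical
#' tension / Young's modulus:
#' \deqn{wCDI = \frac{L_c}{U_{flow}\,h}\cdot\frac{D_{cell}}{\Delta T_{cont}}}
#' where \eqn{U_{flow}} is the fluid velocity in the node leading into the
#' contraction channel. Softer cells transit faster (smaller
#' \eqn{\Delta T_{cont}}), giving a larger wCDI; the \eqn{D_{cell}} factor
#' removes the trivial size dependence of transit time.
#'
#' @param D_cell_um free cell diameter (um); vectorised.
#' @param dT_cont_ms transit time through the contraction channel (ms);
#'   must be finite and positive.
#' @param U_flow_um_per_ms fluid velocity in the lead-in node (um/ms).
#' @param geometry an [nps_geometry()].
#' @return dimensionless wCDI.
#' @examples
#' compute_wCDI(15, 30, 15, nps_geometry())
#' @export
compute_wCDI <- function(D_cell_um, dT_cont_ms, U_flow_um_per_ms, geometry) {
  stopifnot(inherits(geometry, "nps_geometry"))
  if (any(!is.finite(dT_cont_ms)) || any(dT_cont_ms <= 0)) {
    stopf("`dT_cont_ms` must be finite and > 0 (contraction transit is always finite)")
  }
  if (any(!is.finite(D_cell_um)) || any(D_cell_um <= 0) ||
      any(!is.finite(U_flow_um_per_ms)) || any(U_flow_um_per_ms <= 0)) {
    stopf("diameters and flow velocities must be positive and finite")
  }
  (geometry$contraction_length_um /
     (U_flow_um_per_ms * geometry$channel_height_um)) *
    (D_cell_um / dT_cont_ms)
}

#' Average applied strain in the contraction channel
#'
#' \deqn{\varepsilon = (D_{cell} - w_c) / D_{cell}} for a cell wider than
#' the contraction channel; undefined (error) when the cell is not
#' compressed.
#'
#' @param D_cell_um free cell diameter (um); vectorised.
#' @param wc_um contraction-channel width (um).
#' @return strain in (0, 1).
#' @examples
#' average_strain(17.5, 10.5)  # ~0.4, the device's design strain
#' @export
average_strain <- function(D_cell_um, wc_um) {
  check_scalar_pos(wc_um, "wc_um")
  if (any(!is.finite(D_cell_um)) || any(D_cell_um <= wc_um)) {
    stopf("strain is undefined for D_cell <= wc (cell not compressed)")
  }
  (D_cell_um - wc_um) / D_cell_um
}

#' Flow velocity from pre-contraction pore transit times
#'
#' The node-region fluid velocity entering the contraction channel is
#' estimated as the pore length divided by the mean duration of the
#' pre-contraction pore sub-pulses.
#'
#' @param pre_durations_ms durations of pre-contraction pore sub-pulses (ms).
#' @param geometry an [nps_geometry()].
#' @return `U_flow` in um/ms.
#' @export
estimate_Uflow <- function(pre_durations_ms, geometry) {
  stopifnot(inherits(geometry, "nps_geometry"))
  if (length(pre_durations_ms) < 1L || any(!is.finite(pre_durations_ms)) ||
      any(pre_durations_ms <= 0)) {
    stopf("need at least one positive, finite pre-contraction sub-pulse duration")
  }
  geometry$pore_length_um / mean(pre_durations_ms)
}
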