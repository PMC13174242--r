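# Synthetic mass-cytometry (CyTOF-like) expression matrices: log-normal
# marker intensities with configurable per-marker group shifts, emulating a
# gated per-cell intensity table from a 27-marker HMEC panel.

#' Default 27-marker CyTOF panel
#'
#' Proteins and phospho-proteins covering lineage (keratins, CD markers),
#' cell-cycle regulation and signalling, mirroring a typical mammary
#' epithelial mass-cytometry panel.
#'
#' @return character vector of 27 marker names.
#' @export
cytof_panel <- function() {
  c("KRT14", "KRT19", "KRT7", "KRT5", "KRT8", "CD44", "CD271", "CD133",
    "CD24", "CD49f", "EpCAM", "pRb", "pS6", "p38", "GSK3", "mTOR", "pERK",
    "pAKT", "pSTAT3", "pCREB", "YAP1", "Ki67", "CyclinB1", "p21", "p16",
    "EZH2", "VIM")
}

#' Built-in group-shift maps for the CyTOF generator
#'
#' Synthetic stand-ins for the differential-expression structure between
#' groups: ageing shifts (`age_effects()`) raise pRb, CD44 and pS6 and lower
#' KRT19 in older cells; high-risk shifts (`hr_effects()`) alter p38, GSK3
#' and mTOR. Effect sizes are configuration, not constants.
#'
#' @return named numeric vector of log-unit shifts.
#' @export
age_effects <- function() {
  c(pRb = 0.8, CD44 = 0.7, pS6 = 0.6, KRT19 = -0.9, KRT14 = 0.5)
}

#' @rdname age_effects
#' @export
hr_effects <- function() {
  c(p38 = 0.6, GSK3 = -0.6, mTOR = 0.6, KRT14 = 0.5, pS6 = 0.4)
}

#' Simulate a CyTOF-like expression matrix
#'
#' Marker intensities are log-normal: for cell i in group g and marker m,
#' `intensity = exp(mu_m + shift[g, m] + N(0, sigma))`, where the per-marker
#' base levels `mu_m` are drawn once from `N(3, 0.5)` under the seed and
#' `shift` applies the configured log-unit effects in the listed groups
#' (the first group is the unshifted reference unless it has its own entry).
#'
#' @param markers marker panel (default [cytof_panel()], 27 markers).
#' @param groups character vector of group labels to generate.
#' @param effects named list mapping a group label to a named numeric vector
#'   of log-unit shifts (marker names must be in the panel). Empty list
#'   gives a null generator with equal group means.
#' @param n_per_group cells per group.
#' @param seed integer seed; deterministic output.
#' @param noise_sd within-group log-intensity standard deviation.
#' @param lineage,condition metadata labels attached to every cell.
#' @return data frame with `cell_id`, `lineage`, `group`, `condition` and
#'   one non-negative intensity column per marker.
#' @examples
#' m <- simulate_cytof(groups = c("younger", "older"),
#'                     effects = list(older = age_effects()),
#'                     n_per_group = 50, seed = 1)
#' dim(m)
#' @export
simulate_cytof <- function(markers = cytof_panel(),
                           groups = c("younger", "older"),
                           effects = list(),
                           n_per_group = 500L,
                           seed = 1L,
                           noise_sd = 0.5,
                           lineage = "luminal",
                           condition = "control") {
  if (length(markers) < 1L) stopf("panel must contain at least one marker")
  if (anyDuplicated(markers)) stopf("marker names must be unique")
  bad <- setdiff(unlist(lapply(effects, names)), markers)
  if (length(bad) > 0L) {
    stopf("effect references markers absent from the panel: %s",
          paste(bad, collapse = ", "))
  }
  if (!all(names(effects) %in% groups)) {
    stopf("effect group labels must be among `groups`")
  }
  with_seed(seed, {
    mu <- stats::rnorm(length(markers), mean = 3, sd = 0.5)
    names(mu) <- markers
    rows <- lapply(groups, function(g) {
      shift <- stats::setNames(numeric(length(markers)), markers)
      if (!is.null(effects[[g]])) {
        shift[names(effects[[g]])] <- effects[[g]]
      }
      logint <- matrix(stats::rnorm(n_per_group * length(markers), 0, noise_sd),
                       nrow = n_per_group)
      logint <- sweep(logint, 2, mu + shift, "+")
      intens <- exp(logint)
      colnames(intens) <- markers
      cbind(
        data.frame(cell_id = sprintf("%s_%05d", g, seq_len(n_per_group)),
                   lineage = lineage, group = g, condition = condition,
                   stringsAsFactors = FALSE),
        as.data.frame(intens)
      )
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
}
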