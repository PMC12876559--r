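# Two-regime least-squares estimation of the per-geometry loss coefficients
# Kv (viscous, linear in flow) and Kt (expansion, quadratic in flow) from
# (q, dp) samples, mirroring the split-at-Re-10 procedure: Kv from a
# through-origin fit of dp on h1(q) over the creeping-flow subset (Re < 10),
# Kt from a through-origin fit of the residual dp - Kv h1(q) on h2(q^2) over
# the inertial subset (Re >= 10).

#' Viscous and inertial flow terms of the lumped pressure-drop model
#'
#' \deqn{h_1(q) = 8\mu l_s q/(\pi a_0^4), \qquad
#'       h_2(q^2) = \tfrac12 \rho (q/(\pi a_0^2))^2.}
#'
#' @param q volumetric flow (m^3 s^-1), >= 0 (vectorized).
#' @param consts a \code{\link{fluid_constants}} object.
#' @return list with \code{h1q} and \code{h2q2} (both Pa).
#' @export
h_terms <- function(q, consts = fluid_constants()) {
  list(h1q = 8 * consts$mu * consts$ls * q / (pi * consts$a0^4),
       h2q2 = 0.5 * consts$rho * (q / (pi * consts$a0^2))^2)
}

#' Fit the loss coefficients for one geometry
#'
#' @param samples data.frame of flow samples for a single geometry (campaign
#'   schema: \code{re}, \code{q_m3s}, \code{dp_sten_pa}, \code{converged},
#'   \code{excluded}).
#' @param consts a \code{\link{fluid_constants}} object.
#' @param re_split Reynolds split between regimes; Re >= \code{re_split}
#'   belongs to the inertial (Kt) subset.
#' @param drop_flagged drop excluded / non-converged samples before fitting.
#' @return one-row data.frame: geometry_id, kv, kt, n_low, n_high.
#' @export
fit_loss_coefficients <- function(samples, consts = fluid_constants(),
                                  re_split = 10, drop_flagged = TRUE) {
  id <- if ("geometry_id" %in% names(samples)) samples$geometry_id[1] else NA
  if (drop_flagged) {
    samples <- samples[samples$converged & !samples$excluded, , drop = FALSE]
  }
  low <- samples[samples$re < re_split, , drop = FALSE]
  high <- samples[samples$re >= re_split, , drop = FALSE]
  if (nrow(low) < 1) {
    stop(sprintf("geometry %s: no usable low-Reynolds samples", id))
  }
  if (nrow(high) < 1) {
    stop(sprintf("geometry %s: no usable high-Reynolds samples", id))
  }
  hl <- h_terms(low$q_m3s, consts)
  kv <- sum(low$dp_sten_pa * hl$h1q) / sum(hl$h1q^2)
  hh <- h_terms(high$q_m3s, consts)
  resid <- high$dp_sten_pa - kv * hh$h1q
  kt <- sum(resid * hh$h2q2) / sum(hh$h2q2^2)
  if (kv < 0 || kt < 0) {
    warning(sprintf("geometry %s: negative fitted loss coefficient", id))
  }
  data.frame(geometry_id = id, kv = kv, kt = kt,
             n_low = nrow(low), n_high = nrow(high),
             stringsAsFactors = FALSE)
}

#' Fit loss coefficients for every geometry in a campaign table
#'
#' @param campaign campaign data.frame (one row per geometry x Reynolds).
#' @inheritParams fit_loss_coefficients
#' @return data.frame with one row per geometry.
#' @export
fit_loss_table <- function(campaign, consts = fluid_constants(),
                           re_split = 10, drop_flagged = TRUE) {
  ids <- unique(campaign$geometry_id)
  do.call(rbind, lapply(ids, function(g) {
    fit_loss_coefficients(campaign[campaign$geometry_id == g, , drop = FALSE],
                          consts, re_split, drop_flagged)
  }))
}

#' Join fitted loss coefficients with shape coefficients
#'
#' Builds the regression training table \code{id, alpha_1..alpha_k, kv, kt,
#' n_low, n_high}.
#'
#' @param loss data.frame from \code{\link{fit_loss_table}}.
#' @param alphas data.frame from \code{\link{project_cohort}}.
#' @return merged data.frame.
#' @export
merge_training_table <- function(loss, alphas) {
  out <- merge(alphas, loss, by.x = "id", by.y = "geometry_id", sort = TRUE)
  if (nrow(out) == 0) stop("no overlapping geometry ids")
  out
}
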