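# Desk-scale flow oracle producing reference (flow, pressure-drop) samples
# per geometry across the Reynolds campaign. The oracle's ground truth is a
# deterministic, geometry-dependent pair of loss coefficients: an
# integrated-Poiseuille viscous coefficient kv* and a Borda-Carnot
# sudden-expansion coefficient kt* at the minimal radius. With noise off the
# samples lie exactly in the lumped-model family
# dp_sten = kv* h1(q) + kt* h2(q^2), enabling exact parameter recovery
# downstream. Externally supplied (flow, pressure-drop) tables in the same
# schema can be used in place of the oracle.

#' Oracle configuration
#'
#' @param noise_sd standard deviation of multiplicative log-normal noise on
#'   the stenotic drop (dimensionless, 0 = noise-free).
#' @param mismatch_gain optional Reynolds-dependent model-mismatch amplitude;
#'   adds \code{mismatch_gain * (re/500) * kv_star * h1(q)} to the drop.
#' @param fail_prob probability a sample is marked non-converged.
#' @param seed integer seed for noise and failure draws.
#' @param dp_cap physiological exclusion cap on the stenotic drop (Pa,
#'   default 60 mmHg).
#' @return object of class \code{oracle_config}.
#' @export
oracle_config <- function(noise_sd = 0, mismatch_gain = 0, fail_prob = 0,
                          seed = 7L, dp_cap = mmhg_to_pa(60)) {
  stopifnot(noise_sd >= 0, fail_prob >= 0, fail_prob < 1, dp_cap > 0)
  structure(list(noise_sd = noise_sd, mismatch_gain = mismatch_gain,
                 fail_prob = fail_prob, seed = as.integer(seed),
                 dp_cap = dp_cap),
            class = "oracle_config")
}

#' Convert a Reynolds number to volumetric flow
#'
#' Inverts \eqn{Re = \rho v_{avg} D / \mu} with \eqn{v_{avg} = q/(\pi a_0^2)}
#' and \eqn{D = 2 a_0}, giving \eqn{q = Re\,\mu\,\pi a_0 / (2\rho)}.
#'
#' @param re Reynolds number(s), >= 0.
#' @param consts a \code{\link{fluid_constants}} object.
#' @return volumetric flow (m^3 s^-1).
#' @export
reynolds_to_flow <- function(re, consts = fluid_constants()) {
  if (any(re < 0)) stop("Reynolds number must be non-negative")
  re * consts$mu * pi * consts$a0 / (2 * consts$rho)
}

#' @rdname reynolds_to_flow
#' @param q volumetric flow (m^3 s^-1).
#' @export
flow_to_reynolds <- function(q, consts = fluid_constants()) {
  2 * consts$rho * q / (consts$mu * pi * consts$a0)
}

#' Poiseuille pressure drop in a straight tube at the reference radius
#'
#' \deqn{\Delta p = 8 \mu L q / (\pi a_0^4)}
#'
#' @param q volumetric flow (m^3 s^-1), >= 0.
#' @param length tube length (m), >= 0.
#' @param consts a \code{\link{fluid_constants}} object.
#' @return pressure drop (Pa).
#' @export
poiseuille_drop <- function(q, length, consts = fluid_constants()) {
  stopifnot(all(q >= 0), all(length >= 0))
  8 * consts$mu * length * q / (pi * consts$a0^4)
}

#' Ground-truth oracle loss coefficients for a geometry
#'
#' The viscous coefficient is the lesion-window average of the local
#' Poiseuille resistance ratio,
#' \eqn{k_v^* = (1/l_s)\int (a_0/a(z))^4 dz}, computed by trapezoidal
#' quadrature on the splined radius (20 subdivisions per mm) over the 10 mm
#' window centred on the lesion planes. The expansion coefficient is the
#' Borda-Carnot sudden-expansion value at the minimal radius,
#' \eqn{k_t^* = ((a_0/a_{min})^2 - 1)^2}.
#'
#' @param profile a \code{radius_profile}.
#' @param consts a \code{\link{fluid_constants}} object.
#' @param n_per_mm quadrature subdivisions per millimetre (>= 20).
#' @return list with \code{kv_star} and \code{kt_star}.
#' @export
oracle_coefficients <- function(profile, consts = fluid_constants(),
                                n_per_mm = 20L) {
  stopifnot(inherits(profile, "radius_profile"), n_per_mm >= 20)
  z <- profile$plane_z[1:20]
  r <- profile$radii[1:20]
  if (any(r <= 0)) stop("non-positive radius in profile")
  sf <- stats::splinefun(z, r, method = "natural")
  # lesion window: each lesion plane (6..15) owns its 1 mm cell
  z_lo <- z[6] - 0.5e-3
  z_hi <- z[15] + 0.5e-3
  npt <- as.integer(round((z_hi - z_lo) * 1e3) * n_per_mm) + 1L
  zz <- seq(z_lo, z_hi, length.out = npt)
  rr <- sf(zz)
  if (any(rr <= 0)) stop("splined radius non-positive inside lesion window")
  f <- (consts$a0 / rr)^4
  h <- diff(zz)
  integral <- sum((f[-1] + f[-length(f)]) / 2 * h)
  kv_star <- integral / consts$ls
  # minimal radius of the profile itself (the plane radii), not of the
  # lofting spline, which may undershoot between knots of sharp lesions
  a_min <- min(r)
  kt_star <- ((consts$a0 / a_min)^2 - 1)^2
  list(kv_star = kv_star, kt_star = kt_star)
}

# Clean (noise-free) stenotic drop for given truth coefficients and flows.
oracle_dp_clean <- function(kv_star, kt_star, q, consts) {
  ht <- h_terms(q, consts)
  kv_star * ht$h1q + kt_star * ht$h2q2
}

#' Simulate one reference pressure-drop sample
#'
#' Produces the oracle's stenotic drop for one geometry at one Reynolds
#' number, plus the Poiseuille baseline over \code{lext} and the total drop.
#' Optional multiplicative log-normal noise, a Reynolds-proportional mismatch
#' term, and random convergence failures emulate imperfections of a CFD
#' campaign. Samples whose stenotic drop exceeds \code{dp_cap} are flagged
#' (not removed).
#'
#' @param profile an extended \code{radius_profile} (21 planes).
#' @param re Reynolds number.
#' @param cfg an \code{\link{oracle_config}}.
#' @param consts a \code{\link{fluid_constants}} object.
#' @return one-row data.frame (a FlowSample): geometry_id, re, q_m3s,
#'   dp_total_pa, dp_pois_pa, dp_sten_pa, converged, excluded.
#' @export
simulate_pressure_drop <- function(profile, re, cfg = oracle_config(),
                                   consts = fluid_constants()) {
  if (!isTRUE(profile$has_extension)) {
    stop("simulate_pressure_drop expects an extended profile")
  }
  ko <- oracle_coefficients(profile, consts)
  with_local_seed(cfg$seed, {
    run_campaign_one(profile$id, ko, re, cfg, consts)
  })
}

# Vectorized over re; assumes caller manages the RNG state.
run_campaign_one <- function(id, ko, re, cfg, consts) {
  q <- reynolds_to_flow(re, consts)
  dp_sten <- oracle_dp_clean(ko$kv_star, ko$kt_star, q, consts)
  if (cfg$noise_sd > 0) {
    dp_sten <- dp_sten * exp(stats::rnorm(length(re), 0, cfg$noise_sd))
  }
  if (cfg$mismatch_gain != 0) {
    ht <- h_terms(q, consts)
    dp_sten <- dp_sten + cfg$mismatch_gain * (re / 500) * ko$kv_star * ht$h1q
  }
  dp_pois <- poiseuille_drop(q, consts$lext, consts)
  converged <- if (cfg$fail_prob > 0) {
    stats::runif(length(re)) >= cfg$fail_prob
  } else rep(TRUE, length(re))
  data.frame(geometry_id = if (is.null(id)) NA_character_ else id,
             re = re, q_m3s = q, dp_total_pa = dp_sten + dp_pois,
             dp_pois_pa = dp_pois, dp_sten_pa = dp_sten,
             converged = converged, excluded = dp_sten > cfg$dp_cap,
             stringsAsFactors = FALSE)
}

#' Run the full-factorial flow campaign
#'
#' One sample per (geometry, Reynolds number in \code{consts$re_list});
#' excluded and non-converged samples are retained but flagged. All
#' randomness is driven by \code{cfg$seed}.
#'
#' @param profiles list of extended \code{radius_profile}s (or non-extended;
#'   they are extended on the fly).
#' @param cfg an \code{\link{oracle_config}}.
#' @param consts a \code{\link{fluid_constants}} object.
#' @return campaign data.frame with n_geometries x length(re_list) rows and
#'   attribute \code{truth} (data.frame geometry_id, kv_star, kt_star).
#' @export
run_campaign <- function(profiles, cfg = oracle_config(),
                         consts = fluid_constants()) {
  if (length(profiles) == 0) stop("empty cohort")
  out <- with_local_seed(cfg$seed, {
    lapply(profiles, function(p) {
      if (!isTRUE(p$has_extension)) p <- append_cfd_extension(p, consts)
      ko <- oracle_coefficients(p, consts)
      df <- run_campaign_one(p$id, ko, consts$re_list, cfg, consts)
      attr(df, "truth") <- data.frame(geometry_id = p$id,
                                      kv_star = ko$kv_star,
                                      kt_star = ko$kt_star,
                                      stringsAsFactors = FALSE)
      df
    })
  })
  campaign <- do.call(rbind, out)
  rownames(campaign) <- NULL
  attr(campaign, "truth") <- do.call(rbind, lapply(out, attr, "truth"))
  campaign
}

#' Explicit-CFL time-step estimate
#'
#' \eqn{\Delta t = \Delta x_{min} / u}, documenting the time-step sizing of
#' the replaced high-fidelity flow stage.
#'
#' @param dx_min minimum cell size (m), > 0.
#' @param u_char characteristic velocity (m s^-1), > 0.
#' @return time step (s).
#' @export
cfl_time_step <- function(dx_min, u_char) {
  if (any(dx_min <= 0) || any(u_char <= 0)) {
    stop("dx_min and u_char must be positive")
  }
  dx_min / u_char
}
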