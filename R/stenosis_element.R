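# The deliverable 0D stenosis element: predicts the trans-lesional pressure
# drop from shape coefficients and flow via the two trained loss-coefficient
# regressors, exposes the resistance / under-relaxation coupling law used to
# embed the element in a pulse-wave network, computes FFR, and provides the
# classical geometry-based comparator of Heinen et al. for benchmarking.

#' Bundle the trained models into a stenosis element
#'
#' @param shape_model a fitted \code{shape_model}.
#' @param kv_model,kt_model trained \code{gpr_model}s for the viscous and
#'   expansion loss coefficients, trained on coefficient vectors of the same
#'   length as \code{shape_model$n_modes_kept}.
#' @param consts a \code{\link{fluid_constants}} object.
#' @return object of class \code{stenosis_bundle}.
#' @export
stenosis_bundle <- function(shape_model, kv_model, kt_model,
                            consts = fluid_constants()) {
  stopifnot(inherits(kv_model, "gpr_model"), inherits(kt_model, "gpr_model"))
  structure(list(shape_model = shape_model, kv_model = kv_model,
                 kt_model = kt_model, consts = consts),
            class = "stenosis_bundle")
}

#' Predict the pressure drop from shape coefficients and flow
#'
#' \eqn{\Delta p = \hat K_v h_1(q) + \hat K_t h_2(q^2)} with the GPR
#' posterior means; the predictive standard deviation is propagated from the
#' two per-coefficient standard deviations assuming independence:
#' \eqn{\sigma_{\Delta p} = \sqrt{(h_1\sigma_{K_v})^2 + (h_2\sigma_{K_t})^2}}.
#'
#' @param bundle a \code{\link{stenosis_bundle}}.
#' @param alpha shape-coefficient vector (or matrix of rows).
#' @param q volumetric flow (m^3 s^-1), >= 0 (scalar or one per alpha row).
#' @return list with \code{dp} (Pa), \code{dp_sigma} (Pa), \code{kv},
#'   \code{kt}, \code{kv_sigma}, \code{kt_sigma}.
#' @export
predict_dp <- function(bundle, alpha, q) {
  stopifnot(inherits(bundle, "stenosis_bundle"), all(q >= 0))
  A <- if (is.null(dim(alpha))) matrix(as.numeric(alpha), nrow = 1) else as.matrix(alpha)
  pv <- gpr_predict(bundle$kv_model, A)
  pt <- gpr_predict(bundle$kt_model, A)
  ht <- h_terms(q, bundle$consts)
  dp <- pv$mean * ht$h1q + pt$mean * ht$h2q2
  dp_sigma <- sqrt((ht$h1q * pv$sd)^2 + (ht$h2q2 * pt$sd)^2)
  list(dp = dp, dp_sigma = dp_sigma, kv = pv$mean, kt = pt$mean,
       kv_sigma = pv$sd, kt_sigma = pt$sd)
}

#' Geometry of the classical comparator stenosis model
#'
#' @param a0 reference radius (m); \code{a_s} minimal stenosis radius (m),
#'   0 < a_s <= a0; \code{ls} lesion length (m); \code{kv}, \code{kt} loss
#'   coefficients (explicit inputs to the comparator).
#' @param a_s,ls,kv,kt see above.
#' @return object of class \code{heinen_geometry}.
#' @export
heinen_geometry <- function(a0 = 1.5e-3, a_s = a0, ls = 1.0e-2,
                            kv = 1, kt = 1) {
  stopifnot(a_s > 0, a_s <= a0, ls > 0)
  structure(list(a0 = a0, a_s = a_s, ls = ls, kv = kv, kt = kt),
            class = "heinen_geometry")
}

#' Pressure drop of the geometry-based comparator model
#'
#' \deqn{\Delta p = K_v \frac{8\mu l_s}{\pi a_0^4} q +
#'   K_t \frac{\rho}{2\pi^2 a_0^4}\left(\left(\frac{a_0}{a_s}\right)^2 -
#'   1\right)^2 q^2,}
#' the classical lumped stenosis model whose loss coefficients derive from
#' the minimal/reference radii and lesion length alone (cosinusoidal lesion
#' assumption).
#'
#' @param geom a \code{\link{heinen_geometry}}.
#' @param q volumetric flow (m^3 s^-1), >= 0.
#' @param consts a \code{\link{fluid_constants}} object (for rho, mu).
#' @return pressure drop (Pa).
#' @export
heinen_dp <- function(geom, q, consts = fluid_constants()) {
  stopifnot(inherits(geom, "heinen_geometry"), all(q >= 0))
  lin <- geom$kv * 8 * consts$mu * geom$ls * q / (pi * geom$a0^4)
  quad <- geom$kt * consts$rho / (2 * pi^2 * geom$a0^4) *
    ((geom$a0 / geom$a_s)^2 - 1)^2 * q^2
  lin + quad
}

#' Under-relaxation state for the network coupling law
#'
#' @param alpha_relax smoothing factor in [0, 1): the updated smoothed flow
#'   magnitude keeps \code{alpha_relax} of its previous value and takes
#'   \code{1 - alpha_relax} of the current raw magnitude.
#' @param q_smoothed initial smoothed flow magnitude (m^3 s^-1, >= 0).
#' @return object of class \code{waveform_state}.
#' @export
waveform_state <- function(alpha_relax = 0.3, q_smoothed = 0) {
  stopifnot(alpha_relax >= 0, alpha_relax < 1, q_smoothed >= 0)
  structure(list(alpha_relax = alpha_relax, q_smoothed = q_smoothed),
            class = "waveform_state")
}

#' Advance the smoothed flow magnitude one step
#'
#' \eqn{q_{sm}^{n} = \alpha q_{sm}^{n-1} + (1-\alpha) |q^{n}|}; reversed flow
#' contributes by magnitude, damping near-zero and reversed systolic flow.
#'
#' @param state a \code{\link{waveform_state}}.
#' @param q_raw signed instantaneous flow (m^3 s^-1).
#' @return the updated \code{waveform_state}.
#' @export
smooth_flow <- function(state, q_raw) {
  stopifnot(inherits(state, "waveform_state"))
  state$q_smoothed <- state$alpha_relax * state$q_smoothed +
    (1 - state$alpha_relax) * abs(q_raw)
  state
}

#' Instantaneous resistance of the lumped stenosis element
#'
#' \eqn{R(q) = K_v 8\mu l_s/(\pi a_0^4) + K_t \rho/(2\pi^2 a_0^4)\, q_{sm}},
#' so that \eqn{R(q) q} reproduces the quadratic pressure-drop law when the
#' smoothed magnitude has converged to \eqn{|q|}.
#'
#' @param kv,kt loss coefficients.
#' @param q_smoothed smoothed flow magnitude (m^3 s^-1, >= 0).
#' @param consts a \code{\link{fluid_constants}} object.
#' @return resistance (Pa s m^-3).
#' @export
resistance <- function(kv, kt, q_smoothed, consts = fluid_constants()) {
  stopifnot(all(q_smoothed >= 0))
  kv * 8 * consts$mu * consts$ls / (pi * consts$a0^4) +
    kt * consts$rho / (2 * pi^2 * consts$a0^4) * q_smoothed
}

#' Fractional flow reserve from a pressure drop
#'
#' \eqn{FFR = 1 - \Delta p / P_{aorta}}; values below zero (drop exceeding
#' the aortic pressure) are reported, not clipped.
#'
#' @param dp pressure drop (Pa).
#' @param p_aorta mean aortic pressure (Pa, > 0; default 100 mmHg).
#' @return FFR (dimensionless).
#' @export
ffr_from_dp <- function(dp, p_aorta = mmhg_to_pa(100)) {
  if (any(p_aorta <= 0)) stop("p_aorta must be positive")
  1 - dp / p_aorta
}

#' Drive the stenosis element with a flow waveform
#'
#' Per time step: update the smoothed flow magnitude, form the resistance
#' \eqn{R(q_{sm})}, and take \eqn{\Delta P = R q} with the signed
#' instantaneous flow (reversed flow gives a reversed drop). FFR is the time
#' average of \eqn{(P_{aorta} - \Delta p)/P_{aorta}} over the series. The
#' smoothed magnitude is initialized at \eqn{|q_1|} to avoid an artificial
#' startup transient.
#'
#' @param kv,kt loss coefficients of the element (e.g. posterior means from
#'   \code{\link{predict_dp}}).
#' @param q_series signed flow time series (m^3 s^-1).
#' @param p_aorta aortic pressure: scalar or series (Pa).
#' @param alpha_relax under-relaxation smoothing factor.
#' @param consts a \code{\link{fluid_constants}} object.
#' @return list with \code{table} (data.frame t index, q, q_smoothed, dp_pa,
#'   ffr_running) and \code{ffr} (time-averaged FFR).
#' @export
run_waveform <- function(kv, kt, q_series, p_aorta = mmhg_to_pa(100),
                         alpha_relax = 0.3, consts = fluid_constants()) {
  n <- length(q_series)
  if (n < 1) stop("empty flow series")
  p_series <- rep_len(p_aorta, n)
  state <- waveform_state(alpha_relax, q_smoothed = abs(q_series[1]))
  q_sm <- numeric(n); dp <- numeric(n)
  for (i in seq_len(n)) {
    state <- smooth_flow(state, q_series[i])
    q_sm[i] <- state$q_smoothed
    dp[i] <- resistance(kv, kt, state$q_smoothed, consts) * q_series[i]
  }
  ffr_inst <- (p_series - dp) / p_series
  list(table = data.frame(step = seq_len(n), q = q_series, q_smoothed = q_sm,
                          dp_pa = dp, ffr_running = cumsum(ffr_inst) /
                            seq_len(n)),
       ffr = mean(ffr_inst))
}

#' Parameterized two-phase coronary-like flow waveform
#'
#' A simple diastole-dominant coronary flow fixture: suppressed (optionally
#' slightly reversed) flow during systole and elevated flow during diastole,
#' smoothly blended. Used to exercise the waveform-driven element; it is a
#' synthetic stand-in for pulse-wave-solver output, not a physiological
#' model.
#'
#' @param n_steps samples per cycle.
#' @param n_cycles number of cardiac cycles.
#' @param period cycle duration (s).
#' @param q_mean cycle-mean flow (m^3 s^-1).
#' @param systolic_fraction fraction of the cycle in systole.
#' @param reversal_depth systolic dip depth relative to \code{q_mean}
#'   (values > 1 produce transient flow reversal).
#' @return data.frame with \code{t_s} and \code{q_m3s}.
#' @export
coronary_waveform <- function(n_steps = 200L, n_cycles = 3L, period = 0.8,
                              q_mean = 3.33e-6, systolic_fraction = 0.35,
                              reversal_depth = 0.9) {
  t <- seq(0, n_cycles * period, length.out = n_steps * n_cycles)
  phase <- (t %% period) / period
  sys <- phase < systolic_fraction
  shape <- ifelse(sys,
                  1 - reversal_depth * sin(pi * phase / systolic_fraction)^2,
                  1 + 0.8 * sin(pi * (phase - systolic_fraction) /
                                  (1 - systolic_fraction))^2)
  q <- q_mean * shape / mean(shape)
  data.frame(t_s = t, q_m3s = q)
}
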