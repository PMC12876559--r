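# Pa per mmHg; deliberately the only place this constant appears.
.PA_PER_MMHG <- 133.322

#' Convert pressures between mmHg and Pa
#'
#' All internal computations use SI units (Pa); these helpers convert to and
#' from the clinical mmHg scale.
#'
#' @param x numeric vector of pressures.
#' @return numeric vector in the target unit.
#' @export
mmhg_to_pa <- function(x) x * .PA_PER_MMHG

#' @rdname mmhg_to_pa
#' @export
pa_to_mmhg <- function(x) x / .PA_PER_MMHG

#' Fluid and reference-geometry constants
#'
#' Bundles the constant physical and geometric parameters used throughout the
#' pipeline: blood density and viscosity, the healthy reference radius
#' \code{a0}, the nominal lesion length \code{ls} used in the viscous loss
#' term, the total straight (non-stenotic) length \code{lext} whose Poiseuille
#' drop is subtracted as baseline, the mean aortic pressure used for FFR, the
#' Reynolds-number campaign schedule, and the minimum cell size /
#' characteristic velocity for the CFL time-step utility.
#'
#' @param rho blood density (kg m^-3).
#' @param mu dynamic viscosity (Pa s).
#' @param a0 reference (healthy) vessel radius (m).
#' @param ls stenotic lesion length (m).
#' @param lext total straight non-stenotic length for baseline subtraction (m).
#' @param p_aorta mean aortic pressure (Pa).
#' @param re_list ordered vector of Reynolds numbers for the flow campaign.
#' @param dx_min minimum cell size for the CFL utility (m).
#' @param u_char characteristic velocity for the CFL utility (m s^-1).
#' @return an object of class \code{fluid_constants} (a named list).
#' @export
fluid_constants <- function(rho = 1060, mu = 0.0035, a0 = 1.5e-3, ls = 1.0e-2,
                            lext = 4.0e-2, p_aorta = mmhg_to_pa(100),
                            re_list = c(0.1, 1, 10, 50, 100, 150, 200, 250,
                                        300, 350, 400, 450, 500),
                            dx_min = 5.0e-5, u_char = 0.55) {
  stopifnot(rho > 0, mu > 0, a0 > 0, ls > 0, lext > 0, p_aorta > 0,
            dx_min > 0, u_char > 0)
  if (a0 >= lext) stop("a0 must be smaller than lext")
  if (length(re_list) < 1 || any(re_list <= 0) ||
      any(diff(re_list) <= 0)) {
    stop("re_list entries must be positive and strictly increasing")
  }
  structure(list(rho = rho, mu = mu, a0 = a0, ls = ls, lext = lext,
                 p_aorta = p_aorta, re_list = re_list,
                 dx_min = dx_min, u_char = u_char),
            class = "fluid_constants")
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library functions never perturb the
# user's RNG stream.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(abs(as.numeric(seed)) %% 2147483646))
  force(code)
}
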