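# Synthetic axisymmetric stenotic vessel geometries.
#
# Each vessel is described on 20 equidistant cross-sectional planes (1 mm
# apart; plane i sits at z = (i-1) mm). A single focal lesion occupies the
# central segment (planes 6-15): boundary planes s_sten/e_sten are drawn
# uniformly, the minimum-severity plane c_sten is placed inside by a truncated
# uniform draw, and the radius reduction follows a Gaussian taper with
# per-plane +/-10% noise. A 21st plane 30 mm downstream provides the
# cylindrical CFD outflow extension. Plane indices are 1-based throughout.

#' Truncate toward zero
#'
#' Integer truncation used to place the minimum-severity plane: floor for
#' non-negative arguments, ceiling for negative ones.
#'
#' @param x finite numeric vector.
#' @return integer-valued numeric vector.
#' @export
truncate_toward_zero <- function(x) {
  if (any(!is.finite(x))) stop("x must be finite")
  ifelse(x >= 0, floor(x), ceiling(x))
}

#' Draw lesion boundary planes, center plane and taper width
#'
#' Draws the stenosis boundary planes s_sten ~ U\{6..10\} and
#' e_sten ~ U\{11..15\}, the center-placement variate beta ~ U[0,1), and the
#' Gaussian taper width sigma ~ U[1,3], then computes the minimum-severity
#' plane c_sten = s_sten + 2 + T(beta (e_sten - s_sten - 3)) with T the
#' truncation of \code{\link{truncate_toward_zero}}. Uses the current RNG
#' state (seed at the call site for reproducibility).
#'
#' @return list with \code{s_sten}, \code{e_sten}, \code{beta},
#'   \code{c_sten}, \code{sigma}.
#' @export
sample_lesion_planes <- function() {
  s_sten <- sample(6:10, 1)
  e_sten <- sample(11:15, 1)
  beta <- stats::runif(1)
  sigma <- stats::runif(1, 1, 3)
  c_sten <- compute_center_plane(s_sten, e_sten, beta)
  list(s_sten = s_sten, e_sten = e_sten, beta = beta,
       c_sten = c_sten, sigma = sigma)
}

#' @rdname sample_lesion_planes
#' @param s_sten,e_sten lesion boundary plane indices.
#' @param beta center-placement draw in [0,1).
#' @export
compute_center_plane <- function(s_sten, e_sten, beta) {
  as.integer(s_sten + 2 + truncate_toward_zero(beta * (e_sten - s_sten - 3)))
}

#' Assemble generation parameters for one lesion geometry
#'
#' @param s_sev stenosis severity, fractional radius reduction in [0.3, 0.8]
#'   by default (any value in (0,1) is accepted).
#' @param s_sten,e_sten boundary plane indices (6..10 and 11..15).
#' @param beta center-placement draw in [0,1).
#' @param sigma Gaussian taper width in plane units, in [1,3].
#' @param eps length-20 vector of per-plane noise multipliers in [-0.1, 0.1];
#'   the entry at the center plane is forced to zero (the center plane always
#'   receives exactly the target reduction).
#' @param seed integer recorded for provenance.
#' @return object of class \code{generation_params}.
#' @export
generation_params <- function(s_sev, s_sten, e_sten, beta, sigma,
                              eps = rep(0, 20), seed = NA_integer_) {
  stopifnot(s_sev > 0, s_sev < 1,
            s_sten %in% 6:10, e_sten %in% 11:15,
            beta >= 0, beta < 1, sigma >= 1, sigma <= 3,
            length(eps) == 20, all(abs(eps) <= 0.1 + 1e-12))
  c_sten <- compute_center_plane(s_sten, e_sten, beta)
  eps[c_sten] <- 0
  structure(list(s_sev = s_sev, s_sten = as.integer(s_sten),
                 e_sten = as.integer(e_sten), beta = beta,
                 c_sten = c_sten, sigma = sigma, eps = eps,
                 seed = seed),
            class = "generation_params")
}

#' Build the per-plane radius profile of a stenotic vessel
#'
#' Planes outside the lesion region keep the reference radius a0. Within the
#' region (boundary planes s_sten..e_sten, extended to include the center
#' plane when it falls just outside), the radius follows a noisy Gaussian
#' reduction
#' \deqn{a_i = a_0 - (a_0 - a_s)\exp(-(i - c)^2/(2\sigma^2))(1 + \epsilon_i),}
#' with \eqn{a_s = (1 - S_{sev}) a_0} the minimal lesion radius. No noise is
#' applied at the center plane, which receives exactly \eqn{a_s}.
#'
#' @param params a \code{\link{generation_params}} object.
#' @param consts a \code{\link{fluid_constants}} object.
#' @return object of class \code{radius_profile} with fields \code{plane_z}
#'   (m), \code{radii} (m), \code{has_extension}, \code{params}, \code{a_s}.
#' @export
build_radius_profile <- function(params, consts = fluid_constants()) {
  stopifnot(inherits(params, "generation_params"))
  a0 <- consts$a0
  a_s <- (1 - params$s_sev) * a0
  planes <- 1:20
  z <- (planes - 1) * 1e-3
  radii <- rep(a0, 20)
  region <- seq(params$s_sten, max(params$e_sten, params$c_sten))
  g <- exp(-(region - params$c_sten)^2 / (2 * params$sigma^2))
  eps <- params$eps[region]
  eps[region == params$c_sten] <- 0
  radii[region] <- a0 - (a0 - a_s) * g * (1 + eps)
  radii[params$c_sten] <- a_s
  if (any(radii <= 0)) {
    stop("generated radius profile has non-positive radius; regenerate noise")
  }
  structure(list(plane_z = z, radii = radii, has_extension = FALSE,
                 params = params, a_s = a_s),
            class = "radius_profile")
}

#' Append the cylindrical CFD outflow extension
#'
#' Adds plane 21 with the reference radius at ten reference diameters
#' (30 mm with defaults) beyond plane 20, so that with the 5 mm straight
#' distal segment (planes 16-20) the total outlet extension is 35 mm.
#'
#' @param profile a 20-plane \code{radius_profile} without extension.
#' @param consts a \code{\link{fluid_constants}} object.
#' @return the extended 21-plane \code{radius_profile}.
#' @export
append_cfd_extension <- function(profile, consts = fluid_constants()) {
  stopifnot(inherits(profile, "radius_profile"))
  if (profile$has_extension) stop("profile already has a CFD extension")
  if (length(profile$radii) != 20) stop("expected a 20-plane profile")
  ext_len <- 10 * 2 * consts$a0
  profile$plane_z <- c(profile$plane_z, profile$plane_z[20] + ext_len)
  profile$radii <- c(profile$radii, consts$a0)
  profile$has_extension <- TRUE
  profile
}

#' Loft a radius profile into an axisymmetric surface mesh
#'
#' Interpolates the plane radii with a natural cubic spline and sweeps the
#' resulting radius function around the vessel axis, producing vertices on a
#' fixed (nz x ntheta) grid shared by all cohort members. The shared grid
#' gives exact template-to-target point correspondence for shape modeling.
#'
#' @param profile a \code{radius_profile}.
#' @param nz number of axial samples (default 4 per millimetre plus one).
#' @param ntheta number of circumferential samples (>= 8).
#' @param source_id identifier carried on the mesh.
#' @return object of class \code{tube_mesh} with fields \code{nz},
#'   \code{ntheta}, \code{z} (axial stations, m), \code{vertices}
#'   (nz*ntheta x 3 matrix, ring-major), \code{source_id}.
#' @export
loft_surface <- function(profile, nz = NULL, ntheta = 32L,
                         source_id = NA_character_) {
  stopifnot(inherits(profile, "radius_profile"), ntheta >= 8)
  z_knots <- profile$plane_z
  if (is.null(nz)) {
    nz <- as.integer(round((z_knots[length(z_knots)] - z_knots[1]) / 1e-3) * 4 + 1)
  }
  if (nz < length(z_knots)) stop("nz must be at least the number of planes")
  sf <- stats::splinefun(z_knots, profile$radii, method = "natural")
  z <- seq(z_knots[1], z_knots[length(z_knots)], length.out = nz)
  r <- sf(z)
  if (any(r <= 0)) stop("lofted spline produced non-positive radius")
  theta <- 2 * pi * (seq_len(ntheta) - 1) / ntheta
  ct <- cos(theta); st <- sin(theta)
  vertices <- cbind(x = as.vector(t(outer(r, ct))),
                    y = as.vector(t(outer(r, st))),
                    z = rep(z, each = ntheta))
  structure(list(nz = as.integer(nz), ntheta = as.integer(ntheta), z = z,
                 vertices = vertices, source_id = source_id),
            class = "tube_mesh")
}

#' Straight-tube template mesh
#'
#' The fixed lofting/shape-model template: a straight tube at the reference
#' radius spanning the 20-plane domain, on the same vertex grid as the
#' cohort meshes.
#'
#' @inheritParams loft_surface
#' @param consts a \code{\link{fluid_constants}} object.
#' @export
template_mesh <- function(consts = fluid_constants(), nz = NULL, ntheta = 32L) {
  params <- generation_params(s_sev = 0.5, s_sten = 6, e_sten = 15,
                              beta = 0, sigma = 2)
  prof <- build_radius_profile(params, consts)
  prof$radii <- rep(consts$a0, 20)
  loft_surface(prof, nz = nz, ntheta = ntheta, source_id = "template")
}

#' Generate a cohort of synthetic stenotic geometries
#'
#' Severities come from a seeded low-discrepancy stream
#' (\code{\link{sample_severities}}); the nuisance draws (boundary planes,
#' beta, sigma, per-plane noise) come from a separate seeded stream so the
#' severity distribution is invariant to nuisance settings. The whole cohort
#' is bitwise reproducible for a fixed seed. Radius profiles violating
#' positivity have their noise redrawn.
#'
#' @param n cohort size (>= 1).
#' @param seed integer seed.
#' @param consts a \code{\link{fluid_constants}} object.
#' @param lo,hi severity bounds.
#' @param ntheta,nz mesh grid resolution passed to \code{\link{loft_surface}}.
#' @param mesh logical; also loft a surface mesh per geometry (planes 1-20,
#'   no extension, as used for shape modeling).
#' @return list with \code{profiles} (list of \code{radius_profile}),
#'   \code{meshes} (list of \code{tube_mesh} or NULL), and \code{manifest}
#'   (data.frame: id, s_sev, s_sten, e_sten, c_sten, sigma, seed,
#'   profile_path, mesh_path).
#' @export
generate_cohort <- function(n, seed = 42L, consts = fluid_constants(),
                            lo = 0.3, hi = 0.8, ntheta = 32L, nz = NULL,
                            mesh = TRUE) {
  stopifnot(n >= 1)
  sev <- sample_severities(n, lo, hi, seed = seed)
  profiles <- vector("list", n)
  meshes <- if (mesh) vector("list", n) else NULL
  rows <- vector("list", n)
  with_local_seed(seed + 1L, {
    for (i in seq_len(n)) {
      planes <- sample_lesion_planes()
      repeat {
        eps <- stats::runif(20, -0.1, 0.1)
        params <- generation_params(sev[i], planes$s_sten, planes$e_sten,
                                    planes$beta, planes$sigma, eps = eps,
                                    seed = seed)
        prof <- try(build_radius_profile(params, consts), silent = TRUE)
        if (!inherits(prof, "try-error")) break
      }
      id <- sprintf("geom_%04d", i)
      prof$id <- id
      profiles[[i]] <- prof
      if (mesh) meshes[[i]] <- loft_surface(prof, nz = nz, ntheta = ntheta,
                                            source_id = id)
      rows[[i]] <- data.frame(id = id, s_sev = sev[i],
                              s_sten = planes$s_sten, e_sten = planes$e_sten,
                              c_sten = planes$c_sten, sigma = planes$sigma,
                              seed = seed, profile_path = NA_character_,
                              mesh_path = NA_character_,
                              stringsAsFactors = FALSE)
    }
  })
  manifest <- do.call(rbind, rows)
  list(profiles = profiles, meshes = meshes, manifest = manifest)
}

#' Write a radius profile as CSV (plane, z_mm, radius_mm; 1-based planes)
#' @param profile a \code{radius_profile}.
#' @param path output file path.
#' @export
write_profile_csv <- function(profile, path) {
  df <- data.frame(plane = seq_along(profile$radii),
                   z_mm = profile$plane_z * 1e3,
                   radius_mm = profile$radii * 1e3)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a radius profile from columnar text (plane, z_mm, radius_mm)
#' @param path CSV path as written by \code{\link{write_profile_csv}}.
#' @export
read_profile_csv <- function(path) {
  df <- utils::read.csv(path)
  structure(list(plane_z = df$z_mm * 1e-3, radii = df$radius_mm * 1e-3,
                 has_extension = nrow(df) > 20, params = NULL,
                 a_s = min(df$radius_mm) * 1e-3),
            class = "radius_profile")
}

#' Export a tube mesh as ASCII STL
#' @param mesh a \code{tube_mesh}.
#' @param path output file path.
#' @export
write_mesh_stl <- function(mesh, path) {
  v <- mesh$vertices; nt <- mesh$ntheta; nzz <- mesh$nz
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", mesh$source_id), con)
  idx <- function(iz, it) (iz - 1L) * nt + ((it - 1L) %% nt) + 1L
  tri <- character(0)
  emit <- function(a, b, c) {
    n <- c(0, 0, 1)  # placeholder normal; viewers recompute
    sprintf("facet normal %g %g %g\n outer loop\n  vertex %g %g %g\n  vertex %g %g %g\n  vertex %g %g %g\n endloop\nendfacet",
            n[1], n[2], n[3], v[a, 1], v[a, 2], v[a, 3],
            v[b, 1], v[b, 2], v[b, 3], v[c, 1], v[c, 2], v[c, 3])
  }
  for (iz in seq_len(nzz - 1L)) {
    for (it in seq_len(nt)) {
      a <- idx(iz, it); b <- idx(iz, it + 1L)
      c2 <- idx(iz + 1L, it); d <- idx(iz + 1L, it + 1L)
      tri <- c(tri, emit(a, b, d), emit(a, d, c2))
    }
  }
  writeLines(tri, con)
  writeLines("endsolid", con)
  invisible(path)
}
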