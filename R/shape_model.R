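# Statistical shape model: template alignment, per-vertex displacement
# fields, and PCA. Because the cohort is lofted on a common vertex grid,
# template-to-target correspondence is exact by construction, and the shape
# model operates on per-vertex displacement fields (flattened x-block /
# y-block / z-block). A geometry is encoded by its coefficient vector alpha.

#' Translate a mesh onto the template frame
#'
#' Pure translation alignment: the mesh is shifted so its minimum
#' z-coordinate is zero and its inlet-ring centroid (mean x, y of vertices at
#' the minimum z) matches the template's inlet centroid. No rotation or
#' scaling is applied.
#'
#' @param mesh,template \code{tube_mesh} objects.
#' @return the aligned \code{tube_mesh}.
#' @export
align_to_template <- function(mesh, template) {
  stopifnot(inherits(mesh, "tube_mesh"), inherits(template, "tube_mesh"))
  inlet <- function(m) {
    zmin <- min(m$vertices[, 3])
    ring <- m$vertices[abs(m$vertices[, 3] - zmin) < 1e-12, , drop = FALSE]
    if (nrow(ring) == 0) stop("empty inlet ring")
    c(mean(ring[, 1]), mean(ring[, 2]), zmin)
  }
  ci <- inlet(mesh); ct <- inlet(template)
  shift <- c(ct[1] - ci[1], ct[2] - ci[2], -ci[3])
  mesh$vertices <- sweep(mesh$vertices, 2, -shift)
  mesh$z <- mesh$z - ci[3]
  mesh
}

#' Template-to-target displacement field
#'
#' @param template,target \code{tube_mesh} objects on the same grid topology.
#' @return object of class \code{displacement_vector}: a numeric vector of
#'   length 3 Nv (x-block, y-block, z-block; metres) with attribute
#'   \code{source_id}.
#' @export
displacement_field <- function(template, target) {
  stopifnot(inherits(template, "tube_mesh"), inherits(target, "tube_mesh"))
  if (template$nz != target$nz || template$ntheta != target$ntheta) {
    stop("grid topology mismatch between template and target")
  }
  d <- target$vertices - template$vertices
  structure(c(d[, 1], d[, 2], d[, 3]), class = "displacement_vector",
            source_id = target$source_id)
}

# Stack a list of displacement vectors (or pass a matrix through) into an
# n x 3Nv data matrix.
as_displacement_matrix <- function(displacements) {
  if (is.matrix(displacements)) return(displacements)
  lens <- vapply(displacements, length, integer(1))
  if (length(unique(lens)) != 1) stop("displacement vectors differ in length")
  do.call(rbind, lapply(displacements, as.numeric))
}

#' Fit the statistical shape model by PCA
#'
#' Computes the sample mean displacement and the principal modes/variances of
#' the centered displacement matrix. When the ambient dimension exceeds the
#' cohort size the eigendecomposition is taken through the (n x n) Gram
#' matrix, otherwise through the SVD of the centered matrix; both routes give
#' identical modes. Mode signs are fixed so each mode's largest-magnitude
#' component is positive; variances use the (n - 1) denominator.
#'
#' @param displacements list of \code{displacement_vector}s (or an n x 3Nv
#'   matrix), at least two.
#' @param template the \code{tube_mesh} template the displacements refer to.
#' @param n_modes modes to retain for coefficient vectors: a count or
#'   \code{"auto"} (smallest number reaching \code{var_target} cumulative
#'   variance). All non-degenerate modes are stored regardless.
#' @param var_target cumulative-variance target for \code{"auto"}.
#' @return object of class \code{shape_model} with fields \code{template},
#'   \code{mean}, \code{modes} (3Nv x k, orthonormal columns),
#'   \code{variances}, \code{n_su}, \code{n_modes_kept}.
#' @export
fit_shape_model <- function(displacements, template = NULL, n_modes = 5L,
                            var_target = 0.90) {
  X <- as_displacement_matrix(displacements)
  n <- nrow(X)
  if (n < 2) stop("at least two shapes are required")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  if (ncol(X) > n) {
    G <- tcrossprod(Xc)
    eg <- eigen(G, symmetric = TRUE)
    pos <- which(eg$values > max(eg$values, 0) * 1e-12)
    sv <- sqrt(eg$values[pos])
    modes <- crossprod(Xc, eg$vectors[, pos, drop = FALSE]) %*%
      diag(1 / sv, length(pos))
    variances <- eg$values[pos] / (n - 1)
  } else {
    sv <- svd(Xc)
    pos <- which(sv$d > max(sv$d, 0) * 1e-8)
    modes <- sv$v[, pos, drop = FALSE]
    variances <- sv$d[pos]^2 / (n - 1)
  }
  # deterministic sign: largest-|.| component of each mode positive
  for (j in seq_len(ncol(modes))) {
    i <- which.max(abs(modes[, j]))
    if (modes[i, j] < 0) modes[, j] <- -modes[, j]
  }
  kept <- if (identical(n_modes, "auto")) {
    cum <- cumsum(variances) / sum(variances)
    which(cum >= var_target)[1]
  } else {
    min(as.integer(n_modes), ncol(modes))
  }
  structure(list(template = template, mean = mu, modes = modes,
                 variances = variances, n_su = n,
                 n_modes_kept = as.integer(kept)),
            class = "shape_model")
}

#' Project a displacement field onto the shape modes
#'
#' Shape coefficients are inner products of the centered displacement with
#' the orthonormal modes: \eqn{\alpha_m = \langle d - \bar d, \phi_m\rangle}.
#'
#' @param model a \code{shape_model}.
#' @param disp a displacement vector of matching length.
#' @param n_modes number of leading modes (default: the model's kept count).
#' @return numeric coefficient vector of class \code{shape_coefficients}.
#' @export
project <- function(model, disp, n_modes = model$n_modes_kept) {
  stopifnot(inherits(model, "shape_model"))
  if (length(disp) != length(model$mean)) stop("displacement length mismatch")
  if (n_modes > ncol(model$modes)) stop("n_modes exceeds available modes")
  alpha <- drop(crossprod(model$modes[, seq_len(n_modes), drop = FALSE],
                          as.numeric(disp) - model$mean))
  structure(alpha, class = "shape_coefficients",
            source_id = attr(disp, "source_id"))
}

#' Reconstruct a geometry from shape coefficients
#'
#' Rebuilds the displacement field as mean + sum(alpha_m phi_m), applies it to
#' the template, and (optionally) reports the largest per-vertex distance to
#' a target mesh in millimetres.
#'
#' @param model a \code{shape_model} carrying a template mesh.
#' @param alpha coefficient vector (length <= available modes).
#' @param target optional \code{tube_mesh} to measure reconstruction error
#'   against.
#' @return list with \code{mesh} (a \code{tube_mesh}), \code{max_error_mm}
#'   (largest per-vertex distance) and \code{rms_error_mm} (root-mean-square
#'   per-vertex distance; unlike the maximum, this is guaranteed
#'   non-increasing in the number of modes). Both NA when no target given.
#' @export
reconstruct <- function(model, alpha, target = NULL) {
  stopifnot(inherits(model, "shape_model"))
  k <- length(alpha)
  if (k > ncol(model$modes)) stop("alpha longer than available modes")
  d <- model$mean
  if (k > 0) {
    d <- d + drop(model$modes[, seq_len(k), drop = FALSE] %*% as.numeric(alpha))
  }
  tmpl <- model$template
  if (is.null(tmpl)) stop("shape model has no template mesh attached")
  nv <- nrow(tmpl$vertices)
  disp <- cbind(d[seq_len(nv)], d[nv + seq_len(nv)], d[2 * nv + seq_len(nv)])
  mesh <- tmpl
  mesh$vertices <- tmpl$vertices + disp
  mesh$source_id <- "reconstruction"
  err <- NA_real_
  rms <- NA_real_
  if (!is.null(target)) {
    dd <- sqrt(rowSums((mesh$vertices - target$vertices)^2))
    err <- max(dd) * 1e3
    rms <- sqrt(mean(dd^2)) * 1e3
  }
  list(mesh = mesh, max_error_mm = err, rms_error_mm = rms)
}

#' Per-mode and cumulative explained variance fractions
#'
#' @param model a fitted \code{shape_model}.
#' @return data.frame with columns \code{mode}, \code{fraction},
#'   \code{cumulative}.
#' @export
explained_variance <- function(model) {
  stopifnot(inherits(model, "shape_model"))
  fr <- model$variances / sum(model$variances)
  data.frame(mode = seq_along(fr), fraction = fr, cumulative = cumsum(fr))
}

#' Project a whole cohort into shape-coefficient rows
#'
#' Convenience wrapper: aligns (no-op for generator output), computes
#' displacement fields against the model template, and projects each onto the
#' kept modes.
#'
#' @param model a \code{shape_model}.
#' @param meshes list of \code{tube_mesh} objects.
#' @param ids geometry identifiers (default: mesh source ids).
#' @return data.frame \code{id, alpha_1..alpha_k}.
#' @export
project_cohort <- function(model, meshes, ids = NULL) {
  if (is.null(ids)) {
    ids <- vapply(meshes, function(m) as.character(m$source_id), character(1))
  }
  k <- model$n_modes_kept
  A <- t(vapply(meshes, function(m) {
    as.numeric(project(model, displacement_field(model$template, m), k))
  }, numeric(k)))
  colnames(A) <- paste0("alpha_", seq_len(k))
  cbind(data.frame(id = ids, stringsAsFactors = FALSE), as.data.frame(A))
}
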