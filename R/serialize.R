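# Portable JSON serialization for fitted models (schema-versioned; numbers
# written at full precision). Adequate for desk-scale models; large binary
# array formats are deliberately avoided to keep artifacts portable.

.SCHEMA_VERSION <- 1L

#' Save / load a fitted shape model as JSON
#'
#' @param model a \code{shape_model}.
#' @param path file path (conventionally \code{*.ssm.json}).
#' @export
write_shape_model <- function(model, path) {
  stopifnot(inherits(model, "shape_model"))
  tm <- model$template
  obj <- list(schema = .SCHEMA_VERSION, type = "shape_model",
              mean = model$mean, modes = model$modes,
              variances = model$variances, n_su = model$n_su,
              n_modes_kept = model$n_modes_kept,
              template = list(nz = tm$nz, ntheta = tm$ntheta, z = tm$z,
                              vertices = tm$vertices))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_shape_model
#' @export
read_shape_model <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(o$type, "shape_model")) stop("not a shape-model archive")
  verts <- as.matrix(o$template$vertices)
  colnames(verts) <- c("x", "y", "z")
  tmpl <- structure(list(nz = o$template$nz, ntheta = o$template$ntheta,
                         z = o$template$z, vertices = verts,
                         source_id = "template"),
                    class = "tube_mesh")
  structure(list(template = tmpl, mean = o$mean,
                 modes = as.matrix(o$modes),
                 variances = o$variances, n_su = o$n_su,
                 n_modes_kept = o$n_modes_kept),
            class = "shape_model")
}

#' Save / load a trained GP regressor as JSON
#'
#' @param model a \code{gpr_model}.
#' @param path file path (conventionally \code{*.gpr.json}).
#' @export
write_gpr_model <- function(model, path) {
  stopifnot(inherits(model, "gpr_model"))
  obj <- list(schema = .SCHEMA_VERSION, type = "gpr_model",
              kernel = unclass(model$kernel),
              transform = unclass(model$transform),
              feat_mu = model$feat_mu, feat_sd = model$feat_sd,
              X_feat = model$X_feat, y = model$y, y_bar = model$y_bar,
              target_name = model$target_name)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gpr_model
#' @export
read_gpr_model <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(o$type, "gpr_model")) stop("not a GPR archive")
  X <- as.matrix(o$X_feat)
  cfg <- kernel_config(o$kernel$family,
                       nu = if (is.null(o$kernel$nu)) 1.5 else o$kernel$nu,
                       c_scale = o$kernel$c_scale,
                       noise_var = o$kernel$noise_var,
                       length_scales = o$kernel$length_scales)
  if (o$kernel$family == "RBF") cfg$nu <- NULL
  tr <- feature_transform(o$transform$degree, o$transform$log_target,
                          o$transform$log_offset, o$transform$standardize)
  yt <- if (tr$log_target) log(o$y + tr$log_offset) else o$y
  K <- kernel_eval(cfg, X)
  L <- chol(K)
  alpha_dual <- backsolve(L, forwardsolve(t(L), yt - o$y_bar))
  structure(list(kernel = cfg, transform = tr, feat_mu = o$feat_mu,
                 feat_sd = o$feat_sd, X_feat = X, y = o$y, y_bar = o$y_bar,
                 L = L, alpha_dual = alpha_dual,
                 target_name = o$target_name),
            class = "gpr_model")
}
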