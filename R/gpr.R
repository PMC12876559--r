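# Exact Gaussian-process regression with a composite kernel
# C * k_base + white noise, where k_base is an RBF or Matern kernel with
# per-dimension (ARD) length scales. Targets may be log-transformed with a
# small offset; features may be polynomially enriched and are standardized
# with training statistics. Kernel hyperparameters are refined by maximizing
# the log marginal likelihood within box bounds.

.L_BOUNDS <- c(1e-3, 1e5)
.C_BOUNDS <- c(1e-1, 1e5)
.S2_BOUNDS <- c(1e-6, 1e1)

#' Kernel configuration for the composite GP kernel
#'
#' @param family kernel family, \code{"RBF"} or \code{"Matern"}.
#' @param nu Matern smoothness, one of 0.5, 1.5, 2.5 (Matern only).
#' @param c_scale constant scale factor C in [1e-1, 1e5].
#' @param noise_var white-kernel variance sigma^2 in [1e-6, 1e1].
#' @param length_scales per-dimension length-scale vector (recycled to the
#'   feature dimension at fit time), each in [1e-3, 1e5].
#' @return object of class \code{kernel_config}.
#' @export
kernel_config <- function(family = c("RBF", "Matern"), nu = 1.5,
                          c_scale = 1, noise_var = 1e-4,
                          length_scales = 1) {
  family <- match.arg(family)
  if (family == "Matern" && !nu %in% c(0.5, 1.5, 2.5)) {
    stop("nu must be one of 0.5, 1.5, 2.5")
  }
  stopifnot(c_scale >= .C_BOUNDS[1], c_scale <= .C_BOUNDS[2],
            noise_var >= .S2_BOUNDS[1], noise_var <= .S2_BOUNDS[2],
            all(length_scales >= .L_BOUNDS[1]),
            all(length_scales <= .L_BOUNDS[2]))
  structure(list(family = family, nu = if (family == "Matern") nu else NULL,
                 c_scale = c_scale, noise_var = noise_var,
                 length_scales = length_scales),
            class = "kernel_config")
}

#' Feature/target transform configuration
#'
#' @param degree polynomial feature enrichment degree (1, 2 or 3).
#' @param log_target natural-log transform the target (with offset).
#' @param log_offset small positive offset guarding the log domain.
#' @param standardize standardize features with training statistics.
#' @return object of class \code{feature_transform}.
#' @export
feature_transform <- function(degree = 1L, log_target = FALSE,
                              log_offset = 1e-6, standardize = TRUE) {
  stopifnot(degree %in% 1:3, log_offset > 0)
  structure(list(degree = as.integer(degree), log_target = log_target,
                 log_offset = log_offset, standardize = standardize),
            class = "feature_transform")
}

#' Polynomial feature enrichment of shape coefficients
#'
#' Degree 1 returns the input unchanged. Degree 2 appends all squares and all
#' pairwise interactions (i < j); degree 3 further appends all monomials of
#' total degree three (cubes, square-times-linear with i != j, and triple
#' products i < j < k). Ordering is fixed and deterministic.
#'
#' @param alpha numeric vector or matrix (rows = observations).
#' @param degree 1, 2 or 3.
#' @return matrix of enriched features with descriptive column names.
#' @export
polynomial_enrich <- function(alpha, degree = 1L) {
  if (is.null(dim(alpha))) alpha <- matrix(alpha, nrow = 1)
  alpha <- as.matrix(alpha)
  d <- ncol(alpha)
  if (d == 0) stop("empty coefficient vector")
  if (!degree %in% 1:3) stop("degree must be 1, 2 or 3")
  if (is.null(colnames(alpha))) colnames(alpha) <- paste0("a", seq_len(d))
  nm <- colnames(alpha)
  out <- alpha
  if (degree >= 2) {
    sq <- alpha^2
    colnames(sq) <- paste0(nm, "^2")
    out <- cbind(out, sq)
    if (d >= 2) {
      for (i in seq_len(d - 1)) for (j in seq(i + 1, d)) {
        v <- alpha[, i] * alpha[, j]
        out <- cbind(out, v)
        colnames(out)[ncol(out)] <- paste0(nm[i], "*", nm[j])
      }
    }
  }
  if (degree >= 3) {
    cu <- alpha^3
    colnames(cu) <- paste0(nm, "^3")
    out <- cbind(out, cu)
    for (i in seq_len(d)) for (j in seq_len(d)) {
      if (i != j) {
        v <- alpha[, i]^2 * alpha[, j]
        out <- cbind(out, v)
        colnames(out)[ncol(out)] <- paste0(nm[i], "^2*", nm[j])
      }
    }
    if (d >= 3) {
      for (i in seq_len(d - 2)) for (j in seq(i + 1, d - 1))
        for (k in seq(j + 1, d)) {
          v <- alpha[, i] * alpha[, j] * alpha[, k]
          out <- cbind(out, v)
          colnames(out)[ncol(out)] <- paste0(nm[i], "*", nm[j], "*", nm[k])
        }
    }
  }
  out
}

# Base (unscaled) kernel matrix from per-dimension scaled squared distances.
# r2 is the matrix of sum_d (dx_d / l_d)^2.
base_kernel <- function(r2, family, nu) {
  r <- sqrt(pmax(r2, 0))
  if (family == "RBF") return(exp(-r2 / 2))
  if (nu == 0.5) return(exp(-r))
  if (nu == 1.5) { s <- sqrt(3) * r; return((1 + s) * exp(-s)) }
  if (nu == 2.5) { s <- sqrt(5) * r; return((1 + s + s^2 / 3) * exp(-s)) }
  stop("unsupported nu")
}

#' Evaluate the composite kernel
#'
#' \eqn{K = C k_{base}(x_i, x_j) + \sigma^2 [i = j]}, where the white term is
#' added only on the diagonal of a symmetric training evaluation
#' (\code{X2 = NULL}), never on cross-covariances.
#'
#' @param cfg a \code{\link{kernel_config}}.
#' @param X feature matrix (rows = points).
#' @param X2 optional second feature matrix; when NULL, the symmetric
#'   training kernel (with white diagonal) is returned.
#' @return kernel matrix.
#' @export
kernel_eval <- function(cfg, X, X2 = NULL) {
  X <- as.matrix(X)
  d <- ncol(X)
  ell <- rep_len(cfg$length_scales, d)
  Xs <- sweep(X, 2, ell, "/")
  if (is.null(X2)) {
    r2 <- sq_dist(Xs, Xs)
    K <- cfg$c_scale * base_kernel(r2, cfg$family, cfg$nu)
    diag(K) <- diag(K) + cfg$noise_var
    K
  } else {
    X2 <- as.matrix(X2)
    if (ncol(X2) != d) stop("feature dimension mismatch")
    X2s <- sweep(X2, 2, ell, "/")
    r2 <- sq_dist(Xs, X2s)
    cfg$c_scale * base_kernel(r2, cfg$family, cfg$nu)
  }
}

# Pairwise squared Euclidean distances between rows of A and B.
sq_dist <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

# Negative log marginal likelihood and its gradient w.r.t.
# theta = c(log l_1..log l_d, log C, log s2). D2 is a list of per-dimension
# squared-difference matrices. Returns list(value, grad).
gp_nll <- function(theta, D2, y) {
  d <- length(D2)
  ell2 <- exp(2 * theta[seq_len(d)])
  C <- exp(theta[d + 1])
  s2 <- exp(theta[d + 2])
  fam <- attr(D2, "family"); nu <- attr(D2, "nu")
  n <- length(y)
  r2 <- matrix(0, n, n)
  for (k in seq_len(d)) r2 <- r2 + D2[[k]] / ell2[k]
  kb <- base_kernel(r2, fam, nu)
  K <- C * kb
  diag(K) <- diag(K) + s2
  L <- tryCatch(chol(K), error = function(e) {
    diag(K) <- diag(K) + 1e-10 * max(diag(K))
    chol(K)
  })
  a <- backsolve(L, forwardsolve(t(L), y))
  val <- 0.5 * sum(y * a) + sum(log(diag(L))) + 0.5 * n * log(2 * pi)
  Kinv <- chol2inv(L)
  Q <- tcrossprod(a) - Kinv   # dLML/dtheta = 0.5 tr(Q dK); NLL flips sign
  r <- sqrt(pmax(r2, 0))
  # dk_base/dlog(l_k) = w(r) * S_k with S_k = D2[[k]]/l_k^2
  w <- if (fam == "RBF") kb else if (nu == 0.5) {
    wr <- exp(-r) / r; wr[r == 0] <- 0; wr
  } else if (nu == 1.5) 3 * exp(-sqrt(3) * r) else {
    s <- sqrt(5) * r; (5 / 3) * (1 + s) * exp(-s)
  }
  grad <- numeric(d + 2)
  Cw <- C * w
  for (k in seq_len(d)) {
    grad[k] <- -0.5 * sum(Q * (Cw * (D2[[k]] / ell2[k])))
  }
  grad[d + 1] <- -0.5 * sum(Q * (C * kb))
  grad[d + 2] <- -0.5 * sum(diag(Q)) * s2
  list(value = val, grad = grad)
}

#' Fit an exact Gaussian-process regressor
#'
#' Applies the feature/target transforms, then refines the kernel
#' hyperparameters (per-dimension length scales, scale C, noise sigma^2) by
#' maximizing the log marginal likelihood with L-BFGS-B from the configured
#' starting values, within the search-space bounds, with seeded multi-start.
#'
#' @param X input matrix (rows = observations; raw shape coefficients).
#' @param y numeric targets.
#' @param cfg a \code{\link{kernel_config}} (starting values for C, sigma^2).
#' @param transform a \code{\link{feature_transform}}.
#' @param seed integer seed for restart jitter.
#' @param optimize refine hyperparameters by marginal likelihood (TRUE) or
#'   keep the configured values.
#' @param n_restarts number of optimizer starts (first start is the
#'   configured values; the rest are jittered).
#' @param target_name label ("kv", "kt", ...) carried on the model.
#' @param maxit,factr L-BFGS-B iteration cap and convergence factor
#'   (loosened inside cross-validation for speed).
#' @return object of class \code{gpr_model}.
#' @export
gpr_fit <- function(X, y, cfg = kernel_config(), transform = feature_transform(),
                    seed = 0L, optimize = TRUE, n_restarts = 3L,
                    target_name = NA_character_, maxit = 200L, factr = 1e8) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("at least two training rows are required")
  if (nrow(X) != length(y)) stop("X rows and y length differ")
  F <- polynomial_enrich(X, transform$degree)
  if (transform$standardize) {
    mu <- colMeans(F)
    sd <- apply(F, 2, stats::sd)
    sd[sd == 0 | !is.finite(sd)] <- 1
    F <- sweep(sweep(F, 2, mu), 2, sd, "/")
  } else {
    mu <- rep(0, ncol(F)); sd <- rep(1, ncol(F))
  }
  yt <- if (transform$log_target) {
    if (any(y + transform$log_offset <= 0)) {
      stop("log transform requires targets > -log_offset")
    }
    log(y + transform$log_offset)
  } else y
  ybar <- mean(yt)
  yc <- yt - ybar
  d <- ncol(F)
  D2 <- lapply(seq_len(d), function(k) {
    dx <- outer(F[, k], F[, k], "-"); dx * dx
  })
  attr(D2, "family") <- cfg$family
  attr(D2, "nu") <- cfg$nu
  theta0 <- c(log(rep_len(cfg$length_scales, d)), log(cfg$c_scale),
              log(cfg$noise_var))
  lower <- c(rep(log(.L_BOUNDS[1]), d), log(.C_BOUNDS[1]), log(.S2_BOUNDS[1]))
  upper <- c(rep(log(.L_BOUNDS[2]), d), log(.C_BOUNDS[2]), log(.S2_BOUNDS[2]))
  theta <- theta0
  if (optimize) {
    starts <- list(theta0)
    if (n_restarts > 1) {
      # further starts drawn log-uniform across the box bounds, but with
      # length scales near their unit initialization (standardized features)
      jit <- with_local_seed(seed, {
        lapply(seq_len(n_restarts - 1), function(i) {
          c(stats::runif(d, -1, 2),
            stats::runif(2, lower[d + 1:2], upper[d + 1:2]))
        })
      })
      starts <- c(starts, jit)
    }
    best <- NULL
    # fn and gr share one evaluation via a one-slot memo
    memo <- new.env(parent = emptyenv())
    nll_at <- function(th) {
      if (!is.null(memo$theta) && identical(th, memo$theta)) return(memo$res)
      memo$theta <- th
      memo$res <- gp_nll(th, D2, yc)
      memo$res
    }
    for (st in starts) {
      fit <- tryCatch(
        stats::optim(st,
                     fn = function(th) nll_at(th)$value,
                     gr = function(th) nll_at(th)$grad,
                     method = "L-BFGS-B", lower = lower, upper = upper,
                     control = list(maxit = maxit, factr = factr)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
    }
    if (is.null(best)) stop("marginal-likelihood optimization failed")
    theta <- best$par
  }
  ell <- pmin(pmax(exp(theta[seq_len(d)]), .L_BOUNDS[1]), .L_BOUNDS[2])
  C <- min(max(exp(theta[d + 1]), .C_BOUNDS[1]), .C_BOUNDS[2])
  s2 <- min(max(exp(theta[d + 2]), .S2_BOUNDS[1]), .S2_BOUNDS[2])
  cfg_fit <- kernel_config(cfg$family, nu = if (is.null(cfg$nu)) 1.5 else cfg$nu,
                           c_scale = C, noise_var = s2, length_scales = ell)
  if (cfg$family == "RBF") cfg_fit$nu <- NULL
  K <- kernel_eval(cfg_fit, F)
  L <- tryCatch(chol(K), error = function(e) {
    diag(K) <- diag(K) + 1e-10 * max(diag(K)); chol(K)
  })
  alpha_dual <- backsolve(L, forwardsolve(t(L), yc))
  structure(list(kernel = cfg_fit, transform = transform,
                 feat_mu = mu, feat_sd = sd, X_feat = F, y = y,
                 y_bar = ybar, L = L, alpha_dual = alpha_dual,
                 target_name = target_name),
            class = "gpr_model")
}

#' Predict with a fitted Gaussian-process regressor
#'
#' Returns the exact-GP posterior mean and predictive standard deviation
#' (including the white-noise variance). When the model was trained on
#' log-transformed targets, point predictions are mapped back with the
#' log-normal median \eqn{\exp(\mu) - \epsilon} by default (robust: the
#' log-normal mean's \eqn{\exp(\sigma^2/2)} factor inflates predictions
#' severely at high-uncertainty extrapolation points); the log-normal-mean
#' convention is available via \code{back_transform = "mean"}. The reported
#' standard deviation is the log-normal standard deviation in either case.
#'
#' @param model a fitted \code{gpr_model}.
#' @param X input matrix of raw shape coefficients (rows = queries).
#' @param transformed_scale return mean/sd on the (centered, possibly log)
#'   training scale instead of the original target scale.
#' @param back_transform point-prediction back-transform for log-trained
#'   models: \code{"median"} (default) or \code{"mean"}.
#' @return list with \code{mean} and \code{sd}.
#' @export
gpr_predict <- function(model, X, transformed_scale = FALSE,
                        back_transform = c("median", "mean")) {
  back_transform <- match.arg(back_transform)
  if (!inherits(model, "gpr_model")) stop("not a trained gpr_model")
  X <- as.matrix(X)
  F <- polynomial_enrich(X, model$transform$degree)
  if (ncol(F) != length(model$feat_mu)) stop("feature dimension mismatch")
  F <- sweep(sweep(F, 2, model$feat_mu), 2, model$feat_sd, "/")
  Kx <- kernel_eval(model$kernel, F, model$X_feat)   # m x n
  mu_t <- unname(drop(Kx %*% model$alpha_dual)) + model$y_bar
  v <- forwardsolve(t(model$L), t(Kx))
  var_t <- model$kernel$c_scale + model$kernel$noise_var - colSums(v^2)
  var_t <- pmax(var_t, 0)
  sd_t <- sqrt(var_t)
  if (transformed_scale) {
    return(list(mean = mu_t, sd = sd_t))
  }
  if (model$transform$log_target) {
    mean_o <- if (identical(back_transform, "mean")) {
      exp(mu_t + var_t / 2) - model$transform$log_offset
    } else {
      exp(mu_t) - model$transform$log_offset
    }
    sd_o <- sqrt(pmax(exp(var_t) - 1, 0)) * exp(mu_t + var_t / 2)
    list(mean = mean_o, sd = sd_o)
  } else {
    list(mean = mu_t, sd = sd_t)
  }
}

#' Mean squared error
#' @param y,yhat numeric vectors of equal length.
#' @export
mse <- function(y, yhat) {
  stopifnot(length(y) == length(yhat))
  mean((y - yhat)^2)
}
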