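test_that("alignment is a pure translation with idempotence", {
  tmpl <- template_mesh()
  coh <- small_cohort()
  m <- coh$meshes[[3]]
  expect_equal(align_to_template(m, tmpl)$vertices, m$vertices,
               tolerance = 1e-12)
  shifted <- m
  shifted$vertices <- sweep(m$vertices, 2, c(1e-3, 2e-3, 3e-3), "+")
  back <- align_to_template(shifted, tmpl)
  expect_equal(back$vertices, m$vertices, tolerance = 1e-12)
})

test_that("displacement fields are exact vertex differences and additive", {
  tmpl <- template_mesh()
  coh <- small_cohort()
  a <- coh$meshes[[1]]; b <- coh$meshes[[2]]
  expect_true(all(displacement_field(tmpl, tmpl) == 0))
  dTA <- displacement_field(tmpl, a)
  dAB <- displacement_field(a, b)
  dTB <- displacement_field(tmpl, b)
  expect_equal(as.numeric(dTA) + as.numeric(dAB), as.numeric(dTB),
               tolerance = 1e-15)

  # push one ring radially inward: only that ring's x/y entries move
  nv <- nrow(tmpl$vertices)
  pushed <- tmpl
  ring <- 5L
  idx <- (ring - 1L) * tmpl$ntheta + seq_len(tmpl$ntheta)
  r0 <- sqrt(rowSums(pushed$vertices[idx, 1:2]^2))
  pushed$vertices[idx, 1:2] <- pushed$vertices[idx, 1:2] * (1 - 1e-4 / r0)
  d <- as.numeric(displacement_field(tmpl, pushed))
  moved <- which(d != 0)
  expect_true(all(moved %in% c(idx, nv + idx)))
  mag <- sqrt(d[idx]^2 + d[nv + idx]^2)
  expect_equal(mag, rep(1e-4, tmpl$ntheta), tolerance = 1e-12)

  bad <- tmpl; bad$ntheta <- bad$ntheta + 1L
  expect_error(displacement_field(bad, tmpl), "topology")
})

test_that("PCA matches a brute-force covariance eigendecomposition", {
  set.seed(3)
  X <- matrix(rnorm(10 * 7), nrow = 10)
  sm <- fit_shape_model(X, n_modes = 6)
  # independent oracle: dense covariance eigendecomposition
  S <- stats::cov(X)
  eg <- eigen(S, symmetric = TRUE)
  k <- length(sm$variances)
  expect_equal(sm$variances, eg$values[seq_len(k)], tolerance = 1e-8)
  for (j in seq_len(k)) {
    v <- eg$vectors[, j]
    i <- which.max(abs(v)); if (v[i] < 0) v <- -v
    expect_equal(sm$modes[, j], v, tolerance = 1e-8)
  }
  # orthonormality and energy conservation
  G <- crossprod(sm$modes)
  expect_equal(G, diag(k), tolerance = 1e-8)
  expect_equal(sum(sm$variances),
               sum(apply(X, 2, stats::var)), tolerance = 1e-8)
})

test_that("rank, duplication invariance and full-basis reconstruction hold", {
  set.seed(4)
  X2 <- matrix(rnorm(2 * 9), nrow = 2)
  expect_length(fit_shape_model(X2, n_modes = 1)$variances, 1L)

  X <- matrix(rnorm(8 * 12), nrow = 8)
  sm <- fit_shape_model(X)
  smd <- fit_shape_model(rbind(X, X))
  fr <- sm$variances / sum(sm$variances)
  frd <- smd$variances / sum(smd$variances)
  expect_equal(fr, frd, tolerance = 1e-8)
  expect_equal(abs(sm$modes), abs(smd$modes), tolerance = 1e-7)

  # all-mode reconstruction reproduces every training vector
  k <- length(sm$variances)
  for (i in seq_len(nrow(X))) {
    a <- drop(crossprod(sm$modes, X[i, ] - sm$mean))
    rec <- sm$mean + drop(sm$modes %*% a)
    expect_lt(max(abs(rec - X[i, ])) / max(abs(X[i, ])), 1e-8)
  }
})

test_that("projection and reconstruction satisfy the GP/PCA identities", {
  fx <- small_displacements()
  sm <- fit_shape_model(fx$D, template = fx$template, n_modes = 5)
  expect_identical(sm$n_modes_kept, 5L)

  # alpha of the mean displacement is zero
  mean_disp <- sm$mean
  expect_equal(max(abs(project(sm, mean_disp))), 0, tolerance = 1e-10)
  # orthonormality makes mode coefficients literal
  d <- sm$mean + 2 * sm$modes[, 1]
  a <- project(sm, d, n_modes = 5)
  expect_equal(as.numeric(a), c(2, 0, 0, 0, 0), tolerance = 1e-8)

  # cohort-mean alpha vanishes (centering)
  A <- t(apply(fx$D, 1, function(r) as.numeric(project(sm, r))))
  expect_lt(max(abs(colMeans(A))), 1e-10)

  # project-reconstruct is idempotent
  d0 <- fx$D[7, ]
  a1 <- project(sm, d0)
  rec1 <- sm$mean + drop(sm$modes[, 1:5] %*% as.numeric(a1))
  a2 <- project(sm, rec1)
  expect_equal(as.numeric(a1), as.numeric(a2), tolerance = 1e-10)

  # alpha = 0 reconstructs the mean shape
  rec0 <- reconstruct(sm, numeric(0))
  nv <- nrow(fx$template$vertices)
  expect_equal(rec0$mesh$vertices,
               fx$template$vertices + cbind(sm$mean[1:nv],
                                            sm$mean[nv + 1:nv],
                                            sm$mean[2 * nv + 1:nv]),
               tolerance = 1e-12)

  # truncation monotonicity of the L2 reconstruction error
  target <- fx$cohort$meshes[[11]]
  dt <- fx$D[11, ]
  k_all <- ncol(sm$modes)
  ks <- unique(pmin(c(1, 2, 3, 5, 8, k_all), k_all))
  errs <- vapply(ks, function(k) {
    reconstruct(sm, project(sm, dt, n_modes = k), target)$rms_error_mm
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("explained variance normalizes and auto mode selection works", {
  fx <- small_displacements()
  sm <- fit_shape_model(fx$D, template = fx$template, n_modes = "auto",
                        var_target = 0.90)
  ev <- explained_variance(sm)
  expect_equal(sum(ev$fraction), 1, tolerance = 1e-12)
  expect_true(all(diff(ev$cumulative) >= -1e-15))
  expect_gte(ev$cumulative[sm$n_modes_kept], 0.90)
  if (sm$n_modes_kept > 1) {
    expect_lt(ev$cumulative[sm$n_modes_kept - 1], 0.90)
  }
  # single-direction data: first fraction is 1
  base <- rnorm(6)
  X1 <- outer(c(1, 2, 3, 4), base)
  expect_equal(explained_variance(fit_shape_model(X1))$fraction[1], 1,
               tolerance = 1e-12)
})
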