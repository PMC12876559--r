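test_that("polynomial enrichment has the documented order and counts", {
  a <- matrix(c(2, 3), nrow = 1, dimnames = list(NULL, c("a", "b")))
  expect_identical(polynomial_enrich(a, 1), a)
  e2 <- polynomial_enrich(a, 2)
  expect_identical(colnames(e2), c("a", "b", "a^2", "b^2", "a*b"))
  expect_identical(as.numeric(e2), c(2, 3, 4, 9, 6))
  # five shape coefficients: 5 linear + 5 squares + 10 interactions
  a5 <- matrix(rnorm(10 * 5), ncol = 5)
  expect_identical(ncol(polynomial_enrich(a5, 2)), 20L)
  # degree 3 adds all C(5+2,3) = 35 cubic monomials
  expect_identical(ncol(polynomial_enrich(a5, 3)), 55L)
  expect_error(polynomial_enrich(matrix(nrow = 1, ncol = 0), 2), "empty")
})

test_that("kernel identities: exponential form, RBF limit, white placement", {
  x <- matrix(seq(0, 2, by = 0.1), ncol = 1)
  cfg05 <- kernel_config("Matern", nu = 0.5, c_scale = 1, noise_var = 1e-6,
                         length_scales = 0.7)
  K <- kernel_eval(cfg05, x, x)
  r <- abs(outer(drop(x), drop(x), "-"))
  expect_lt(max(abs(K - exp(-r / 0.7))), 1e-12)

  # nu = 2.5 approximates the RBF for small scaled distances
  # (at r/l = 0.4 the relative gap is 4.3%; it reaches 6% by r/l = 0.5)
  cfg25 <- kernel_config("Matern", nu = 2.5, c_scale = 1, noise_var = 1e-6)
  cfgr <- kernel_config("RBF", c_scale = 1, noise_var = 1e-6)
  xs <- matrix(seq(0, 0.4, by = 0.05), ncol = 1)
  Km <- kernel_eval(cfg25, xs, xs); Kr <- kernel_eval(cfgr, xs, xs)
  expect_lt(max(abs(Km - Kr) / Kr), 0.05)

  # white noise on the training diagonal only, never on cross-covariance
  cfg <- kernel_config("RBF", c_scale = 2, noise_var = 0.5)
  Ktrain <- kernel_eval(cfg, xs)
  Kcross <- kernel_eval(cfg, xs, xs)
  expect_equal(diag(Ktrain), rep(2.5, nrow(xs)), tolerance = 1e-12)
  expect_equal(diag(Kcross), rep(2.0, nrow(xs)), tolerance = 1e-12)
  expect_identical(Ktrain - diag(0.5, nrow(xs)), Kcross)
  expect_error(kernel_eval(cfg, xs, cbind(xs, xs)), "dimension")
})

test_that("posterior mean and variance match the textbook formulas", {
  set.seed(11)
  X <- matrix(rnorm(10 * 2), ncol = 2)
  y <- sin(X[, 1]) + 0.3 * X[, 2]
  cfg <- kernel_config("Matern", nu = 1.5, c_scale = 1.7, noise_var = 1e-3,
                       length_scales = c(0.9, 1.4))
  tr <- feature_transform(1, FALSE, standardize = FALSE)
  m <- gpr_fit(X, y, cfg, tr, optimize = FALSE)
  Xs <- matrix(rnorm(6 * 2), ncol = 2)
  p <- gpr_predict(m, Xs)

  # brute-force oracle: direct solve, no Cholesky
  K <- kernel_eval(cfg, X)
  Ks <- kernel_eval(cfg, Xs, X)
  mu <- drop(Ks %*% solve(K, y - mean(y))) + mean(y)
  v <- cfg$c_scale + cfg$noise_var -
    diag(Ks %*% solve(K, t(Ks)))
  expect_equal(p$mean, mu, tolerance = 1e-8)
  expect_equal(p$sd, sqrt(pmax(v, 0)), tolerance = 1e-8)
})

test_that("fitting interpolates smooth targets and shrinks variance at data", {
  set.seed(12)
  X <- matrix(runif(40, -1, 1), ncol = 2)
  y <- 5 + 2 * X[, 1] - 3 * X[, 2]
  m <- gpr_fit(X, y, kernel_config("RBF", c_scale = 10, noise_var = 1e-6),
               feature_transform(1), seed = 2)
  p <- gpr_predict(m, X)
  expect_lt(max(abs(p$mean - y) / abs(y)), 1e-4)
  far <- gpr_predict(m, matrix(c(50, 50), ncol = 2))
  expect_gt(far$sd, max(p$sd))

  # duplicated rows are handled by the white-noise regularization
  Xd <- rbind(X, X[1:5, ]); yd <- c(y, y[1:5] + 0.01)
  expect_s3_class(gpr_fit(Xd, yd,
                          kernel_config("RBF", noise_var = 1e-2),
                          feature_transform(1), seed = 2,
                          n_restarts = 1), "gpr_model")

  # identical seeds give identical trained state
  m2 <- gpr_fit(X, y, kernel_config("RBF", c_scale = 10, noise_var = 1e-6),
                feature_transform(1), seed = 2)
  expect_identical(m$kernel$length_scales, m2$kernel$length_scales)
  expect_identical(m$alpha_dual, m2$alpha_dual)
})

test_that("log-target transform round-trips and guards its domain", {
  tr <- feature_transform(1, TRUE)
  y <- c(0.5, 3, 700)
  expect_equal(exp(log(y + tr$log_offset)) - tr$log_offset, y,
               tolerance = 1e-12)
  set.seed(13)
  X <- matrix(rnorm(16), ncol = 2)
  expect_error(gpr_fit(X, rep(-1, 8), kernel_config(), tr), "log")
  m <- gpr_fit(X, exp(rnorm(8)), kernel_config("RBF"), tr, seed = 1,
               n_restarts = 1)
  p <- gpr_predict(m, X)
  pm <- gpr_predict(m, X, back_transform = "mean")
  pl <- gpr_predict(m, X, transformed_scale = TRUE)
  expect_equal(p$mean, exp(pl$mean) - tr$log_offset, tolerance = 1e-12)
  expect_true(all(pm$mean >= p$mean))  # log-normal mean >= median
})

test_that("the MSE objective and CV search behave as specified", {
  expect_identical(mse(c(1, 2), c(1, 3)), 0.5)

  # a quadratic target makes degree-2 trials dominate the leaderboard
  set.seed(14)
  X <- matrix(runif(80, -2, 2), ncol = 2)
  y <- X[, 1]^2 + 0.05 * rnorm(40)
  sr <- hyperparameter_search(X, y, n_trials = 8, k = 3, seed = 7,
                              degrees = 1:2, n_startup = 4)
  expect_identical(nrow(sr$trials), 8L)
  top <- sr$trials$degree[order(sr$trials$cv_mse)][1:3]
  expect_gte(sum(top == 2), 2)
  expect_identical(sr$best$degree, sr$trials$degree[sr$best_index])

  # full determinism of the trial sequence and winner
  sr2 <- hyperparameter_search(X, y, n_trials = 8, k = 3, seed = 7,
                               degrees = 1:2, n_startup = 4)
  expect_identical(sr$trials, sr2$trials)
  expect_identical(sr$best_index, sr2$best_index)

  # random sampler is also seeded and valid
  sr3 <- hyperparameter_search(X, y, n_trials = 4, k = 3, seed = 7,
                               sampler = "random")
  expect_identical(nrow(sr3$trials), 4L)
  expect_error(hyperparameter_search(X[1:3, ], y[1:3], k = 5), "exceeds")
})

test_that("model archives round-trip through JSON", {
  set.seed(15)
  X <- matrix(rnorm(30), ncol = 3)
  y <- exp(X[, 1]) + 2
  m <- gpr_fit(X, y, kernel_config("Matern", nu = 1.5),
               feature_transform(2, TRUE), seed = 4, n_restarts = 1)
  path <- tempfile(fileext = ".gpr.json")
  write_gpr_model(m, path)
  m2 <- read_gpr_model(path)
  Xs <- matrix(rnorm(9), ncol = 3)
  expect_equal(gpr_predict(m2, Xs)$mean, gpr_predict(m, Xs)$mean,
               tolerance = 1e-8)
  expect_equal(gpr_predict(m2, Xs)$sd, gpr_predict(m, Xs)$sd,
               tolerance = 1e-8)

  fx <- small_displacements()
  sm <- fit_shape_model(fx$D, template = fx$template, n_modes = 3)
  sp <- tempfile(fileext = ".ssm.json")
  write_shape_model(sm, sp)
  sm2 <- read_shape_model(sp)
  d <- fx$D[4, ]
  expect_equal(as.numeric(project(sm2, d)), as.numeric(project(sm, d)),
               tolerance = 1e-9)
})
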