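test_that("truncation toward zero floors positives and ceils negatives", {
  expect_identical(truncate_toward_zero(2.7), 2)
  expect_identical(truncate_toward_zero(-1.8), -1)
  expect_identical(truncate_toward_zero(0), 0)
  expect_error(truncate_toward_zero(NaN), "finite")
})

test_that("severity sampling is stratified, bounded and reproducible", {
  s <- sample_severities(1024, 0.3, 0.8, seed = 42)
  expect_length(s, 1024)
  expect_true(all(s >= 0.3 & s < 0.8))
  bins <- table(cut(s, breaks = seq(0.3, 0.8, length.out = 11),
                    include.lowest = TRUE))
  expect_true(all(bins %in% c(102L, 103L)))
  expect_identical(s, sample_severities(1024, 0.3, 0.8, seed = 42))
  expect_false(identical(s, sample_severities(1024, 0.3, 0.8, seed = 43)))

  u <- sample_severities(2, 0, 1, seed = 1)
  expect_true(all(u >= 0 & u < 1))
  expect_false(u[1] == u[2])
  expect_error(sample_severities(1, 0.5, 0.5), "bounds")
})

test_that("center-plane placement matches brute-force enumeration of the rule", {
  # direct examples
  expect_identical(compute_center_plane(6, 15, 0.5), 11L)
  expect_identical(compute_center_plane(10, 11, 0.1), 12L)
  expect_identical(compute_center_plane(10, 11, 0.9), 11L)
  # independent brute-force oracle over a beta grid
  brute <- function(s, e, b) {
    x <- b * (e - s - 3)
    t <- if (x >= 0) floor(x) else ceiling(x)
    as.integer(s + 2 + t)
  }
  for (s in 6:10) for (e in 11:15) {
    for (b in seq(0, 0.999, by = 0.037)) {
      c_impl <- compute_center_plane(s, e, b)
      expect_identical(c_impl, brute(s, e, b))
      # admissible placement set implied by the rule
      gap <- e - s
      admissible <- if (gap >= 4) seq(s + 2L, e - 2L) else
        if (gap == 3) e - 1L else
        if (gap == 2) e else c(e, e + 1L)
      expect_true(c_impl %in% admissible)
    }
  }
})

test_that("radius profiles honor exact reductions and straight segments", {
  consts <- fluid_constants()
  p <- make_profile(s_sev = 0.5)
  expect_equal(p$radii[p$params$c_sten], 0.75e-3, tolerance = 0)
  expect_identical(p$radii[c(1:5, 16:20)], rep(consts$a0, 10))

  # hand-evaluated taper value: s_sev 0.6, c_sten 10, sigma 2 -> plane 8
  p2 <- make_profile(s_sev = 0.6, s_sten = 7, e_sten = 13, beta = 0.5,
                     sigma = 2)
  expect_identical(p2$params$c_sten, 10L)
  a8 <- consts$a0 - 0.6 * consts$a0 * exp(-4 / 8)
  expect_equal(p2$radii[8], a8, tolerance = 1e-12)
  expect_equal(p2$radii[8] * 1e3, 0.9541, tolerance = 1e-4)

  # flat limit: very wide taper pushes every lesion plane toward a_s
  p3 <- make_profile(s_sev = 0.5, sigma = 3)
  g <- exp(-(7:13 - p3$params$c_sten)^2 / (2 * 9))
  expect_true(all(abs(p3$radii[7:13] -
                        (consts$a0 - 0.75e-3 * g)) < 1e-15))

  # noise is never applied at the center plane
  eps <- rep(0.1, 20)
  p4 <- make_profile(s_sev = 0.7, eps = eps)
  expect_equal(p4$radii[p4$params$c_sten], (1 - 0.7) * consts$a0,
               tolerance = 1e-15)
})

test_that("the CFD extension adds a 30 mm cylinder giving a 35 mm outlet", {
  consts <- fluid_constants()
  p <- append_cfd_extension(make_profile(), consts)
  expect_length(p$radii, 21)
  expect_equal(p$plane_z[21], 49e-3)
  expect_equal(p$plane_z[21] - p$plane_z[20], 30e-3)
  expect_equal(p$plane_z[21] - p$plane_z[15], 35e-3)  # distal straight + cylinder
  expect_identical(p$radii[21], consts$a0)
  expect_error(append_cfd_extension(p, consts), "already")

  big <- fluid_constants(a0 = 3e-3)
  pb <- append_cfd_extension(make_profile(consts = big), big)
  expect_equal(pb$plane_z[21] - pb$plane_z[20], 60e-3)
})

test_that("lofting interpolates plane radii exactly and is deterministic", {
  consts <- fluid_constants()
  p <- make_profile()
  p$radii <- rep(consts$a0, 20)
  m <- loft_surface(p)
  r <- sqrt(m$vertices[, 1]^2 + m$vertices[, 2]^2)
  expect_true(all(abs(r - consts$a0) < 1e-12))

  p2 <- make_profile(s_sev = 0.7, sigma = 1.2)
  m2 <- loft_surface(p2)
  # mesh radii at the plane stations reproduce the knots
  iz <- round((p2$plane_z - p2$plane_z[1]) / diff(m2$z[1:2])) + 1
  for (k in seq_along(iz)) {
    ring <- m2$vertices[(iz[k] - 1) * m2$ntheta + seq_len(m2$ntheta), ]
    expect_true(all(abs(sqrt(ring[, 1]^2 + ring[, 2]^2) - p2$radii[k]) < 1e-9))
  }
  expect_identical(loft_surface(p2)$vertices, m2$vertices)
})

test_that("cohorts are reproducible, labeled, and severity-consistent", {
  coh <- small_cohort()
  coh2 <- generate_cohort(30, seed = 5L)
  expect_identical(coh$manifest, coh2$manifest)
  expect_identical(coh$meshes[[17]]$vertices, coh2$meshes[[17]]$vertices)
  expect_identical(anyDuplicated(coh$manifest$id), 0L)

  consts <- fluid_constants()
  for (i in seq_along(coh$profiles)) {
    p <- coh$profiles[[i]]
    s <- coh$manifest$s_sev[i]
    # center plane carries the exact target reduction
    expect_equal(p$radii[p$params$c_sten], (1 - s) * consts$a0,
                 tolerance = 1e-15)
    # +/-10% noise bounds the overshoot of the worst plane
    expect_lte(1 - min(p$radii) / consts$a0, 1.1 * s + 1e-12)
    expect_identical(p$radii[c(1:5, 16:20)], rep(consts$a0, 10))
    expect_identical(p$params$eps[p$params$c_sten], 0)
  }
})
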