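# Shared fixtures, memoized per session so expensive cohorts are built once.

.fixture_env <- new.env(parent = emptyenv())

memo_fixture <- function(key, builder) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- builder()
  .fixture_env[[key]]
}

# A deterministic noise-free lesion profile with known parameters.
make_profile <- function(s_sev = 0.6, s_sten = 7, e_sten = 13, beta = 0.5,
                         sigma = 2, eps = rep(0, 20),
                         consts = fluid_constants()) {
  build_radius_profile(
    generation_params(s_sev, s_sten, e_sten, beta, sigma, eps = eps),
    consts)
}

# Ad-hoc radius profile with a prescribed radius vector (for oracle tests).
raw_profile <- function(radii_m, extended = FALSE, id = "raw") {
  z <- (seq_along(radii_m) - 1) * 1e-3
  if (extended) z[length(z)] <- z[length(z) - 1] + 30e-3
  structure(list(plane_z = z, radii = radii_m, has_extension = extended,
                 params = NULL, a_s = min(radii_m), id = id),
            class = "radius_profile")
}

# Small cohort with meshes, shared across test files.
small_cohort <- function() {
  memo_fixture("cohort30", function() generate_cohort(30, seed = 5L))
}

# Displacement matrix and template for the small cohort.
small_displacements <- function() {
  memo_fixture("disp30", function() {
    coh <- small_cohort()
    tmpl <- template_mesh()
    D <- t(vapply(coh$meshes, function(m) {
      as.numeric(displacement_field(tmpl, m))
    }, numeric(3 * nrow(tmpl$vertices))))
    list(D = D, template = tmpl, cohort = coh)
  })
}

# Training table (alphas + fitted loss coefficients) for a medium cohort.
medium_table <- function() {
  memo_fixture("table60", function() {
    coh <- generate_cohort(60, seed = 9L)
    tmpl <- template_mesh()
    D <- t(vapply(coh$meshes, function(m) {
      as.numeric(displacement_field(tmpl, m))
    }, numeric(3 * nrow(tmpl$vertices))))
    sm <- fit_shape_model(D, template = tmpl, n_modes = 5)
    alphas <- project_cohort(sm, coh$meshes)
    camp <- run_campaign(coh$profiles, oracle_config())
    loss <- fit_loss_table(camp)
    list(cohort = coh, sm = sm, alphas = alphas, campaign = camp,
         table = merge_training_table(loss, alphas))
  })
}
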