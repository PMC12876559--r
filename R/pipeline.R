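# Full-workflow orchestration: generate cohort -> fit/project shape model ->
# flow campaign -> loss-coefficient fits -> geometry-level train/test split
# -> regressor training -> prediction and evaluation, with per-stage CSV
# artifacts and a machine-readable JSON summary. Every artifact is
# regenerable bit-identically from the configuration seeds.

#' Pipeline configuration
#'
#' @param n cohort size.
#' @param seed_cohort,seed_oracle,seed_split,seed_search stage seeds.
#' @param severity_lo,severity_hi severity window.
#' @param n_modes shape modes kept (count or \code{"auto"}).
#' @param noise_sd oracle log-normal noise.
#' @param train_frac fraction of geometries in the training set (floor).
#' @param n_trials,k_folds hyperparameter-search budget.
#' @param sampler \code{"tpe"} or \code{"random"}.
#' @param out_dir output root directory (created if missing).
#' @return object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(n = 100L, seed_cohort = 42L, seed_oracle = 7L,
                            seed_split = 1L, seed_search = 0L,
                            severity_lo = 0.3, severity_hi = 0.8,
                            n_modes = 5L, noise_sd = 0,
                            train_frac = 0.9, n_trials = 20L, k_folds = 5L,
                            sampler = "tpe", out_dir = tempfile("stenoshape_")) {
  stopifnot(train_frac > 0, train_frac < 1, n >= 10)
  structure(list(n = as.integer(n), seed_cohort = as.integer(seed_cohort),
                 seed_oracle = as.integer(seed_oracle),
                 seed_split = as.integer(seed_split),
                 seed_search = as.integer(seed_search),
                 severity_lo = severity_lo, severity_hi = severity_hi,
                 n_modes = n_modes, noise_sd = noise_sd,
                 train_frac = train_frac, n_trials = as.integer(n_trials),
                 k_folds = as.integer(k_folds), sampler = sampler,
                 out_dir = out_dir),
            class = "pipeline_config")
}

# Severity-decile-stratified split of geometry ids into train/test.
split_geometries <- function(manifest, train_frac, seed) {
  with_local_seed(seed, {
    dec <- cut(rank(manifest$s_sev, ties.method = "first"),
               breaks = 10, labels = FALSE)
    n_train <- floor(train_frac * nrow(manifest))
    train <- character(0)
    for (d in sort(unique(dec))) {
      ids <- manifest$id[dec == d]
      k <- round(length(ids) * train_frac)
      train <- c(train, sample(ids, k))
    }
    # adjust to the exact floor() count, deterministically
    if (length(train) > n_train) {
      train <- sample(train, n_train)
    } else if (length(train) < n_train) {
      pool <- setdiff(manifest$id, train)
      train <- c(train, sample(pool, n_train - length(train)))
    }
    list(train = sort(train), test = sort(setdiff(manifest$id, train)))
  })
}

#' Run the full modeling pipeline
#'
#' Executes all stages and writes, under \code{cfg$out_dir}:
#' \code{cohort/manifest.csv}, \code{ssm/alphas.csv},
#' \code{ssm/explained_variance.csv}, \code{campaign/campaign.csv},
#' \code{models/training_table.csv}, \code{models/trials_*.csv},
#' \code{eval/predictions.csv} and \code{summary.json}.
#'
#' @param cfg a \code{\link{pipeline_config}}.
#' @return the run directory, invisibly; the summary list as attribute
#'   \code{"summary"} and in-memory stage objects as attribute
#'   \code{"objects"}.
#' @export
run_full_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  out <- cfg$out_dir
  for (d in c("cohort", "ssm", "campaign", "models", "eval")) {
    dir.create(file.path(out, d), recursive = TRUE, showWarnings = FALSE)
  }
  consts <- fluid_constants()

  coh <- generate_cohort(cfg$n, seed = cfg$seed_cohort, consts = consts,
                         lo = cfg$severity_lo, hi = cfg$severity_hi)
  utils::write.csv(coh$manifest, file.path(out, "cohort", "manifest.csv"),
                   row.names = FALSE)

  tmpl <- template_mesh(consts)
  D <- t(vapply(coh$meshes, function(m) {
    as.numeric(displacement_field(tmpl, m))
  }, numeric(3 * nrow(tmpl$vertices))))
  sm <- fit_shape_model(D, template = tmpl, n_modes = cfg$n_modes)
  ev <- explained_variance(sm)
  utils::write.csv(ev, file.path(out, "ssm", "explained_variance.csv"),
                   row.names = FALSE)
  alphas <- project_cohort(sm, coh$meshes)
  utils::write.csv(alphas, file.path(out, "ssm", "alphas.csv"),
                   row.names = FALSE)

  ocfg <- oracle_config(noise_sd = cfg$noise_sd, seed = cfg$seed_oracle)
  campaign <- run_campaign(coh$profiles, ocfg, consts)
  utils::write.csv(campaign, file.path(out, "campaign", "campaign.csv"),
                   row.names = FALSE)

  loss <- fit_loss_table(campaign, consts)
  table <- merge_training_table(loss, alphas)
  utils::write.csv(table, file.path(out, "models", "training_table.csv"),
                   row.names = FALSE)

  sp <- split_geometries(coh$manifest, cfg$train_frac, cfg$seed_split)
  tr <- table[table$id %in% sp$train, ]
  te <- table[table$id %in% sp$test, ]
  acol <- grep("^alpha_", names(table), value = TRUE)
  kv_model <- train_coefficient_model(as.matrix(tr[acol]), tr$kv,
                                      target_name = "kv",
                                      n_trials = cfg$n_trials,
                                      k = cfg$k_folds,
                                      seed = cfg$seed_search,
                                      sampler = cfg$sampler)
  kt_model <- train_coefficient_model(as.matrix(tr[acol]), tr$kt,
                                      target_name = "kt",
                                      n_trials = cfg$n_trials,
                                      k = cfg$k_folds,
                                      seed = cfg$seed_search + 1L,
                                      sampler = cfg$sampler)
  utils::write.csv(attr(kv_model, "search")$trials,
                   file.path(out, "models", "trials_kv.csv"),
                   row.names = FALSE)
  utils::write.csv(attr(kt_model, "search")$trials,
                   file.path(out, "models", "trials_kt.csv"),
                   row.names = FALSE)

  bundle <- stenosis_bundle(sm, kv_model, kt_model, consts)
  pv <- gpr_predict(kv_model, as.matrix(te[acol]))
  pt <- gpr_predict(kt_model, as.matrix(te[acol]))
  kv_metrics <- c(r2 = r2_identity(te$kv, pv$mean),
                  unlist(rmse_and_calibration(te$kv, pv$mean, pv$sd)))
  kt_metrics <- c(r2 = r2_identity(te$kt, pt$mean),
                  unlist(rmse_and_calibration(te$kt, pt$mean, pt$sd)))

  # per-sample pressure-drop evaluation on usable test-set samples
  ctest <- campaign[campaign$geometry_id %in% sp$test &
                      campaign$converged & !campaign$excluded, ]
  idx <- match(ctest$geometry_id, te$id)
  ht <- h_terms(ctest$q_m3s, consts)
  dp_pred <- pv$mean[idx] * ht$h1q + pt$mean[idx] * ht$h2q2
  dp_sigma <- sqrt((ht$h1q * pv$sd[idx])^2 + (ht$h2q2 * pt$sd[idx])^2)
  dp_metrics <- c(r2 = r2_identity(ctest$dp_sten_pa, dp_pred),
                  unlist(rmse_and_calibration(ctest$dp_sten_pa, dp_pred,
                                              dp_sigma)))
  ffr_ref <- ffr_from_dp(ctest$dp_sten_pa, consts$p_aorta)
  ffr_pred <- ffr_from_dp(dp_pred, consts$p_aorta)
  agree <- ffr_agreement(ffr_ref, ffr_pred)
  ba <- bland_altman(ffr_ref, ffr_pred)
  preds <- data.frame(id = ctest$geometry_id, re = ctest$re,
                      dp_ref_pa = ctest$dp_sten_pa, dp_pred_pa = dp_pred,
                      dp_sigma_pa = dp_sigma, ffr_ref = ffr_ref,
                      ffr_pred = ffr_pred)
  utils::write.csv(preds, file.path(out, "eval", "predictions.csv"),
                   row.names = FALSE)

  summary <- list(
    config = unclass(cfg)[setdiff(names(unclass(cfg)), "out_dir")],
    counts = list(n_geometries = cfg$n,
                  n_train = length(sp$train), n_test = length(sp$test),
                  campaign_rows = nrow(campaign),
                  excluded = sum(campaign$excluded),
                  non_converged = sum(!campaign$converged),
                  usable_test_samples = nrow(ctest)),
    shape_model = list(n_modes_kept = sm$n_modes_kept,
                       cumulative_variance_kept =
                         ev$cumulative[sm$n_modes_kept]),
    metrics = list(kv = as.list(kv_metrics), kt = as.list(kt_metrics),
                   dp = as.list(dp_metrics),
                   ffr = c(list(within_0p02 = agree$within_tol_fraction,
                                accuracy = agree$accuracy),
                           as.list(ba[c("bias", "loa_low", "loa_high")]))))
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res <- out
  attr(res, "summary") <- summary
  attr(res, "objects") <- list(cohort = coh, shape_model = sm,
                               campaign = campaign, table = table,
                               split = sp, bundle = bundle,
                               predictions = preds)
  invisible(res)
}

#' Render a human-readable report for a completed run
#'
#' Reads \code{summary.json} from a run directory and writes
#' \code{report.md} with the performance-metric, agreement and
#' variance-explained tables. Regeneration is idempotent.
#'
#' @param run_dir a directory produced by \code{\link{run_full_pipeline}}.
#' @return path to the report, invisibly.
#' @export
export_report <- function(run_dir) {
  sj <- file.path(run_dir, "summary.json")
  if (!file.exists(sj)) stop("incomplete run: summary.json missing")
  s <- jsonlite::read_json(sj, simplifyVector = TRUE)
  if (is.null(s$metrics)) stop("incomplete run: no evaluation metrics")
  evf <- file.path(run_dir, "ssm", "explained_variance.csv")
  ev <- if (file.exists(evf)) utils::read.csv(evf) else NULL
  fmt <- function(x) formatC(as.numeric(x), digits = 4, format = "g")
  lines <- c(
    "# stenoshape run report", "",
    sprintf("Geometries: %d (train %d / test %d); campaign rows: %d (excluded %d, non-converged %d)",
            s$counts$n_geometries, s$counts$n_train, s$counts$n_test,
            s$counts$campaign_rows, s$counts$excluded, s$counts$non_converged),
    "",
    "## Regressor and pressure-drop metrics", "",
    "| model | R2 (y=x) | RMSE | mean sigma | RMSE/sigma |",
    "|---|---|---|---|---|")
  for (m in c("kv", "kt", "dp")) {
    mm <- s$metrics[[m]]
    lines <- c(lines, sprintf("| %s | %s | %s | %s | %s |", m,
                              fmt(mm$r2), fmt(mm$rmse),
                              fmt(mm$mean_predictive_sigma),
                              fmt(mm$rmse_sigma_ratio)))
  }
  lines <- c(lines, "",
             "## FFR agreement", "",
             sprintf("- within 0.02 of reference: %s", fmt(s$metrics$ffr$within_0p02)),
             sprintf("- classification accuracy at 0.80: %s", fmt(s$metrics$ffr$accuracy)),
             sprintf("- Bland-Altman bias [LoA]: %s [%s, %s]",
                     fmt(s$metrics$ffr$bias), fmt(s$metrics$ffr$loa_low),
                     fmt(s$metrics$ffr$loa_high)))
  if (!is.null(ev)) {
    lines <- c(lines, "", "## Explained variance (first modes)", "",
               "| mode | fraction | cumulative |", "|---|---|---|")
    for (i in seq_len(min(8, nrow(ev)))) {
      lines <- c(lines, sprintf("| %d | %s | %s |", ev$mode[i],
                                fmt(ev$fraction[i]), fmt(ev$cumulative[i])))
    }
  }
  path <- file.path(run_dir, "report.md")
  writeLines(lines, path)
  invisible(path)
}
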