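# Cross-validated hyperparameter search over the composite-kernel GP
# configuration space: polynomial degree {1..3}, log-target transform
# {off,on}, kernel family {Matern, RBF}, Matern nu {0.5, 1.5, 2.5}, scale C
# log-uniform on [1e-1, 1e5], noise sigma^2 log-uniform on [1e-6, 1e1].
# Objective: mean k-fold CV mean-squared-error on the transformed target
# scale. Sampler: a Tree-structured-Parzen-Estimator-style proposal (split
# past trials into good/bad, propose the candidate maximizing the density
# ratio) after a random startup phase, or pure seeded random search.

sample_trial_config <- function(degrees = 1:3) {
  list(degree = sample(degrees, 1),
       log_target = sample(c(FALSE, TRUE), 1),
       family = sample(c("Matern", "RBF"), 1),
       nu = sample(c(0.5, 1.5, 2.5), 1),
       log_c = stats::runif(1, log(.C_BOUNDS[1]), log(.C_BOUNDS[2])),
       log_s2 = stats::runif(1, log(.S2_BOUNDS[1]), log(.S2_BOUNDS[2])))
}

# 1-D Gaussian kernel density estimate evaluated at x.
kde_density <- function(x, obs, lower, upper) {
  if (length(obs) == 0) return(rep(1 / (upper - lower), length(x)))
  bw <- max(1.06 * stats::sd(obs) * length(obs)^(-0.2), (upper - lower) / 50)
  if (!is.finite(bw) || bw <= 0) bw <- (upper - lower) / 50
  vapply(x, function(xx) mean(stats::dnorm(xx, obs, bw)), numeric(1))
}

# Propose one numeric value by the density-ratio rule.
tpe_numeric <- function(good, bad, lower, upper, n_cand = 24) {
  if (length(good) == 0) return(stats::runif(1, lower, upper))
  bw <- max(1.06 * stats::sd(good) * length(good)^(-0.2), (upper - lower) / 50)
  if (!is.finite(bw) || bw <= 0) bw <- (upper - lower) / 50
  cand <- stats::rnorm(n_cand, sample(good, n_cand, replace = TRUE), bw)
  cand <- pmin(pmax(cand, lower), upper)
  l <- kde_density(cand, good, lower, upper)
  g <- kde_density(cand, bad, lower, upper)
  cand[which.max(l / (g + 1e-12))]
}

# Propose one categorical value by smoothed count ratio.
tpe_categorical <- function(levels, good, bad) {
  lg <- (tabulate(match(good, levels), length(levels)) + 1)
  lb <- (tabulate(match(bad, levels), length(levels)) + 1)
  ratio <- (lg / sum(lg)) / (lb / sum(lb))
  # sample proportionally to the good-density, tie-broken by the ratio
  levels[which.max(ratio * stats::runif(length(levels), 0.95, 1.05))]
}

# Assign k CV folds (approximately equal sizes) to n rows.
cv_folds <- function(n, k) {
  sample(rep(seq_len(k), length.out = n))
}

#' Cross-validated hyperparameter search for a loss-coefficient regressor
#'
#' Runs \code{n_trials} configurations through k-fold cross validation,
#' scoring each by mean CV MSE on the transformed target scale, and returns
#' the winner. The first \code{n_startup} trials are random; later trials
#' use a Tree-structured-Parzen-Estimator-style proposal (top-25% trials fit
#' the "good" density). Fully deterministic for a fixed seed.
#'
#' @param X raw shape-coefficient matrix.
#' @param y targets.
#' @param n_trials number of search trials.
#' @param k number of CV folds (must not exceed the number of rows).
#' @param seed integer seed.
#' @param sampler \code{"tpe"} or \code{"random"}.
#' @param degrees candidate polynomial degrees.
#' @param n_startup random startup trials before TPE proposals.
#' @param n_restarts_cv marginal-likelihood restarts inside CV fits.
#' @return list with \code{best} (winning config, as a list), \code{trials}
#'   (data.frame of trial records), \code{best_index}.
#' @export
hyperparameter_search <- function(X, y, n_trials = 20L, k = 5L, seed = 0L,
                                  sampler = c("tpe", "random"),
                                  degrees = 1:3, n_startup = 10L,
                                  n_restarts_cv = 1L) {
  sampler <- match.arg(sampler)
  X <- as.matrix(X)
  n <- nrow(X)
  if (k > n) stop("k exceeds the number of rows")
  with_local_seed(seed, {
    folds <- cv_folds(n, k)
    trials <- vector("list", n_trials)
    scores <- numeric(n_trials)
    for (t in seq_len(n_trials)) {
      cfg <- if (sampler == "random" || t <= n_startup) {
        sample_trial_config(degrees)
      } else {
        done <- do.call(rbind, lapply(trials[seq_len(t - 1)], as.data.frame))
        ord <- order(scores[seq_len(t - 1)])
        n_good <- max(1L, ceiling((t - 1) * 0.25))
        gi <- ord[seq_len(n_good)]; bi <- setdiff(seq_len(t - 1), gi)
        list(degree = as.integer(tpe_categorical(degrees, done$degree[gi],
                                                 done$degree[bi])),
             log_target = as.logical(tpe_categorical(c(FALSE, TRUE),
                                                     done$log_target[gi],
                                                     done$log_target[bi])),
             family = tpe_categorical(c("Matern", "RBF"), done$family[gi],
                                      done$family[bi]),
             nu = as.numeric(tpe_categorical(c(0.5, 1.5, 2.5), done$nu[gi],
                                             done$nu[bi])),
             log_c = tpe_numeric(done$log_c[gi], done$log_c[bi],
                                 log(.C_BOUNDS[1]), log(.C_BOUNDS[2])),
             log_s2 = tpe_numeric(done$log_s2[gi], done$log_s2[bi],
                                  log(.S2_BOUNDS[1]), log(.S2_BOUNDS[2])))
      }
      fold_mse <- vapply(seq_len(k), function(f) {
        tr <- folds != f
        fit <- tryCatch(
          gpr_fit(X[tr, , drop = FALSE], y[tr],
                  cfg = kernel_config(cfg$family, nu = cfg$nu,
                                      c_scale = exp(cfg$log_c),
                                      noise_var = exp(cfg$log_s2)),
                  transform = feature_transform(cfg$degree, cfg$log_target),
                  seed = seed + 1000L * t + f, n_restarts = n_restarts_cv,
                  maxit = 100L, factr = 1e10),
          error = function(e) NULL)
        if (is.null(fit)) return(Inf)
        pred <- gpr_predict(fit, X[!tr, , drop = FALSE],
                            transformed_scale = TRUE)
        yv <- y[!tr]
        yv_t <- if (cfg$log_target) log(yv + fit$transform$log_offset) else yv
        if (any(!is.finite(yv_t))) return(Inf)
        mse(yv_t, pred$mean)
      }, numeric(1))
      scores[t] <- mean(fold_mse)
      trials[[t]] <- c(cfg, list(trial = t, cv_mse = scores[t], seed = seed))
    }
    best_index <- which.min(scores)
    trials_df <- do.call(rbind, lapply(trials, as.data.frame))
    list(best = trials[[best_index]], trials = trials_df,
         best_index = best_index)
  })
}

#' Train a loss-coefficient regressor with hyperparameter search
#'
#' Convenience wrapper: runs \code{\link{hyperparameter_search}}, then refits
#' the winning configuration on all training rows with multi-start
#' marginal-likelihood refinement.
#'
#' @inheritParams hyperparameter_search
#' @param target_name label carried on the model ("kv" or "kt").
#' @param n_restarts_final restarts for the final fit.
#' @return a \code{gpr_model} with the search record in attribute
#'   \code{"search"}.
#' @export
train_coefficient_model <- function(X, y, target_name = "kv", n_trials = 20L,
                                    k = 5L, seed = 0L, sampler = "tpe",
                                    degrees = 1:3, n_restarts_cv = 1L,
                                    n_restarts_final = 3L) {
  sr <- hyperparameter_search(X, y, n_trials = n_trials, k = k, seed = seed,
                              sampler = sampler, degrees = degrees,
                              n_restarts_cv = n_restarts_cv)
  b <- sr$best
  model <- gpr_fit(X, y,
                   cfg = kernel_config(b$family, nu = b$nu,
                                       c_scale = exp(b$log_c),
                                       noise_var = exp(b$log_s2)),
                   transform = feature_transform(b$degree, b$log_target),
                   seed = seed, n_restarts = n_restarts_final,
                   target_name = target_name)
  attr(model, "search") <- sr
  model
}
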