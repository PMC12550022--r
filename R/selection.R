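# Hyperparameter selection: an inclusive lambda grid, a (lambda x seed)
# battery of training runs averaged per lambda, and a seed-stability
# analysis of the recovered dimensionality at a fixed lambda.

#' Inclusive arithmetic grid of sparsity parameters
#'
#' @param low,high grid endpoints (both included).
#' @param step positive step; values are rounded to the step's decimal
#'   precision, so e.g. `lambda_grid(0.006, 0.012, 0.0005)` returns 13
#'   exact 4-decimal values.
#' @return numeric vector of grid values.
#' @export
lambda_grid <- function(low, high, step) {
  if (!is.numeric(step) || length(step) != 1L || step <= 0)
    stop_arg("`step` must be a positive number")
  if (low > high) stop_arg("`low` must not exceed `high`")
  n <- floor((high - low) / step + 1e-9) + 1
  vals <- low + step * (seq_len(n) - 1)
  # smallest number of decimals that represents the step exactly
  digits <- 0
  while (digits < 10 && abs(step * 10^digits - round(step * 10^digits)) > 1e-8)
    digits <- digits + 1
  round(vals, digits)
}

#' Grid search over the sparsity parameter
#'
#' Trains one model per (lambda, seed) pair — seeds are
#' `base_seed + 1, ..., base_seed + n_seeds` — and averages each lambda's
#' optimized validation losses over seeds. The lambda with the smallest
#' mean validation loss wins. Runs that error are skipped and flagged.
#'
#' @param choices choice table of retained trials.
#' @param grid lambda values, e.g. from [lambda_grid()].
#' @param n_seeds random initializations per lambda.
#' @param config base [spose_config()]; its `lambda` and `seed` are
#'   overridden per run.
#' @param base_seed offset for the seed battery (defaults to
#'   `config$seed`).
#' @param item_ids optional stimulus catalog.
#' @return list of class `grid_search_result`: `runs` (data frame with
#'   lambda, seed, validation loss, k_effective, ok), `mean_loss` and
#'   `se_loss` (per lambda, across seeds), `best_lambda` (argmin of the
#'   mean validation loss), `lambda_1se` (the largest — sparsest — lambda
#'   whose mean validation loss is within one standard error of the
#'   minimum, the one-standard-error rule familiar from cross-validated
#'   lasso; the SE is pooled across lambdas because the run-to-run loss
#'   noise does not depend on lambda), `n_runs`, `n_skipped`.
#' @export
grid_search <- function(choices, grid, n_seeds = 10L, config = spose_config(),
                        base_seed = NULL, item_ids = NULL) {
  if (!length(grid)) stop_arg("`grid` must be non-empty")
  n_seeds <- check_count(n_seeds, "n_seeds", 1L)
  base_seed <- base_seed %||% config$seed
  runs <- expand.grid(seed_offset = seq_len(n_seeds), lambda = grid)
  res <- lapply(seq_len(nrow(runs)), function(r) {
    cfg <- config
    cfg$lambda <- runs$lambda[r]
    cfg$seed <- as.integer(base_seed + runs$seed_offset[r])
    fit <- tryCatch(spose_train(choices, cfg, item_ids = item_ids),
                    error = function(e) e)
    if (inherits(fit, "error"))
      data.frame(lambda = cfg$lambda, seed = cfg$seed, val_loss = NA_real_,
                 k_effective = NA_integer_, ok = FALSE)
    else
      data.frame(lambda = cfg$lambda, seed = cfg$seed,
                 val_loss = fit$best_validation_loss,
                 k_effective = fit$k_effective, ok = TRUE)
  })
  tab <- do.call(rbind, res)
  ok <- tab$ok
  mean_loss <- tapply(tab$val_loss[ok], tab$lambda[ok], mean)
  se_loss <- tapply(tab$val_loss[ok], tab$lambda[ok],
                    function(x) sd(x) / sqrt(length(x)))
  best <- which.min(mean_loss)
  best_lambda <- as.numeric(names(mean_loss)[best])
  # One-SE cutoff with a pooled standard error: the run-to-run loss noise
  # (validation split + initialization) does not depend on lambda, so
  # pooling the per-lambda variances gives a far more stable SE than the
  # handful of seeds behind any single lambda.
  n_per <- tapply(tab$val_loss[ok], tab$lambda[ok], length)
  pooled_var <- tapply(tab$val_loss[ok], tab$lambda[ok], stats::var)
  se_pooled <- sqrt(mean(pooled_var, na.rm = TRUE) / mean(n_per))
  cutoff <- mean_loss[best] + if (is.finite(se_pooled)) se_pooled else 0
  lambda_1se <- max(as.numeric(names(mean_loss))[mean_loss <= cutoff])
  structure(list(runs = tab,
                 mean_loss = mean_loss,
                 se_loss = se_loss,
                 best_lambda = best_lambda,
                 lambda_1se = lambda_1se,
                 n_runs = nrow(tab),
                 n_skipped = sum(!ok)),
            class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat(sprintf("Grid search: %d runs over %d lambda values (%d skipped)\n",
              x$n_runs, length(x$mean_loss), x$n_skipped))
  cat(sprintf("  best lambda %g (mean validation loss %.4f)\n",
              x$best_lambda, min(x$mean_loss, na.rm = TRUE)))
  invisible(x)
}

#' Seed stability of the recovered dimensionality
#'
#' Trains `n_runs` models at a fixed lambda that differ only in their
#' random seed and summarizes the distribution of the effective number of
#' dimensions.
#'
#' @param choices choice table of retained trials.
#' @param lambda sparsity weight used for every run.
#' @param n_runs number of runs (>= 2).
#' @param config base [spose_config()].
#' @param base_seed seed offset (defaults to `config$seed`).
#' @param item_ids optional stimulus catalog.
#' @return list of class `stability_result`: `k_per_run`, `mean_k`,
#'   `sd_k`, `n_runs`, `lambda`.
#' @export
seed_stability <- function(choices, lambda, n_runs = 20L,
                           config = spose_config(), base_seed = NULL,
                           item_ids = NULL) {
  n_runs <- check_count(n_runs, "n_runs", 2L)
  base_seed <- base_seed %||% config$seed
  k <- vapply(seq_len(n_runs), function(r) {
    cfg <- config
    cfg$lambda <- lambda
    cfg$seed <- as.integer(base_seed + r)
    fit <- tryCatch(spose_train(choices, cfg, item_ids = item_ids),
                    error = function(e) NULL)
    if (is.null(fit)) NA_integer_ else fit$k_effective
  }, integer(1))
  structure(list(k_per_run = k, mean_k = mean(k, na.rm = TRUE),
                 sd_k = sd(k, na.rm = TRUE),
                 n_runs = n_runs, lambda = lambda),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("Seed stability at lambda %g: mean %.2f dimensions over %d runs (sd %.2f)\n",
              x$lambda, x$mean_k, x$n_runs, x$sd_k))
  invisible(x)
}
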