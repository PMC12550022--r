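# Parameter-recovery study: the package's end-to-end validation surface.
# A ground-truth sparse positive embedding generates a full synthetic
# experiment; the pipeline (QC -> lambda tuning -> training) must then
# recover both the generating dimensionality and the generating similarity
# structure from the choices alone.

#' Simulate the standard recovery experiment
#'
#' Builds the synthetic study used to validate the pipeline end to end:
#' a ground truth of `n_items` stimuli on `k_true` sparse positive
#' dimensions, a pair-coverage design sized to give roughly
#' `pair_coverage * choose(n_items, 2)` trials, and a pool of compliant
#' workers large enough that each answers only a handful of trial sets
#' (as in crowdsourced collections). With the defaults this yields
#' 30,090 choices over 60 items from a 6-dimensional ground truth.
#'
#' @param n_items,k_true,sparsity,scale ground-truth shape; see
#'   [generate_ground_truth()].
#' @param pair_coverage main-block triplets per stimulus pair.
#' @param set_size trials per set.
#' @param n_workers number of compliant workers sharing the sets.
#' @param seed integer seed; ground truth, design and choices use
#'   `seed`, `seed + 1`, `seed + 2`.
#' @return a `simulated_dataset` (see [simulate_dataset()]).
#' @export
simulate_recovery_dataset <- function(n_items = 60, k_true = 6,
                                      sparsity = 0.7, scale = 1,
                                      pair_coverage = 17, set_size = 32,
                                      n_workers = 120, seed = 1L) {
  truth <- generate_ground_truth(n_items, k_true, sparsity, scale,
                                 seed = seed)
  design <- suppressWarnings(
    build_design(rownames(truth), pair_coverage = pair_coverage,
                 set_size = set_size, seed = seed + 1L))
  profiles <- lapply(seq_len(n_workers),
                     function(i) worker_profile(sprintf("w%03d", i)))
  simulate_dataset(truth, design, profiles, seed = seed + 2L)
}

#' Tune the sparsity parameter and train the final embedding
#'
#' Runs [grid_search()] over `grid`, picks a lambda, and trains the final
#' model at that lambda with a longer optimization budget. Two selection
#' rules are available: `"min"` takes the smallest mean validation loss
#' (the protocol used for hyperparameter optimization on real data);
#' `"1se"` takes the sparsest lambda statistically indistinguishable from
#' that minimum (one-standard-error rule), which is the appropriate rule
#' when the goal is recovering dimensionality — near the optimum the
#' validation loss is almost flat in lambda while the number of surviving
#' dimensions is not.
#'
#' @param choices choice table of retained trials.
#' @param grid lambda values to search.
#' @param n_seeds seeds per lambda during the search; the default of 5
#'   keeps the per-lambda mean and standard error stable enough for the
#'   one-standard-error rule.
#' @param tune_config [spose_config()] used for the search runs.
#' @param final_config [spose_config()] for the final fit; its lambda is
#'   replaced by the selected one.
#' @param rule `"1se"` (default) or `"min"`.
#' @param base_seed seed offset for the search battery.
#' @param item_ids optional stimulus catalog.
#' @return list with `grid` (the `grid_search_result`), `lambda`
#'   (selected value) and `fit` (the final `spose_fit`).
#' @export
tune_and_train <- function(choices, grid, n_seeds = 5L,
                           tune_config = spose_config(profile = "reduced",
                                                      max_epochs = 600L,
                                                      window = 75L),
                           final_config = spose_config(profile = "reduced",
                                                       max_epochs = 2000L,
                                                       window = 300L),
                           rule = c("1se", "min"), base_seed = NULL,
                           item_ids = NULL) {
  rule <- match.arg(rule)
  gs <- grid_search(choices, grid, n_seeds = n_seeds, config = tune_config,
                    base_seed = base_seed, item_ids = item_ids)
  lambda <- if (rule == "1se") gs$lambda_1se else gs$best_lambda
  cfg <- final_config
  cfg$lambda <- lambda
  fit <- spose_train(choices, cfg, item_ids = item_ids)
  list(grid = gs, lambda = lambda, fit = fit)
}

#' Compare a recovered embedding against its ground truth
#'
#' The natural invariant of the choice model is the matrix of pairwise
#' dot-product similarities (the embedding itself is only identified up
#' to dimension permutations and splits). This correlates the
#' ground-truth and recovered item-pair similarity vectors and reports
#' the dimensionality error.
#'
#' @param truth ground-truth embedding.
#' @param fit a `spose_fit` (or a recovered weight matrix over the same
#'   items).
#' @return list with `k_true`, `k_recovered`, `k_error` (recovered minus
#'   true) and `similarity_correlation` (Pearson, over the strict lower
#'   triangle of the dot-product matrices).
#' @export
recovery_metrics <- function(truth, fit) {
  w <- if (inherits(fit, "spose_fit")) fit$embedding else fit
  check_embedding(truth, "truth")
  check_embedding(w, "recovered embedding")
  if (!identical(sort(rownames(truth)), sort(rownames(w))))
    stop_arg("ground truth and fit cover different items")
  w <- w[rownames(truth), , drop = FALSE]
  gt <- tcrossprod(truth)
  gm <- tcrossprod(w)
  lt <- lower.tri(gt)
  list(k_true = ncol(truth),
       k_recovered = ncol(w),
       k_error = ncol(w) - ncol(truth),
       similarity_correlation = if (ncol(w) == 0) NA_real_
                                else cor(gt[lt], gm[lt]))
}

#' Default lambda grid for the recovery study
#'
#' Six values spanning weak to strong sparsity pressure at the recovery
#' study's scale (60 items, ~30,000 choices).
#'
#' @return numeric vector of lambda values.
#' @export
recovery_lambda_grid <- function() {
  c(0.005, 0.01, 0.015, 0.02, 0.03, 0.04)
}
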