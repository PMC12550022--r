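# The sparse positive similarity embedding (SPoSE) learner. Choices are
# modeled with the softmax-of-dot-products rule of choice_probabilities();
# the objective is the mean cross-entropy of the observed odd-one-out plus
# an L1 penalty lambda * sum(W) / n_items. Training is projected Adam
# (weights clipped at zero after every step) with early stopping on the
# validation loss, followed by pruning of near-empty dimensions and sorting
# by total weight.

#' Training configuration for the SPoSE learner
#'
#' Defaults follow the standard protocol for full-scale experiments:
#' 100 starting dimensions, lambda 0.008, learning rate 0.001, batches of
#' 128, up to 500 epochs with an early-stopping patience of 50 epochs on
#' the validation loss, a 90/10 train/validation split and a pruning
#' threshold of 0.1 on the column sums. `profile = "reduced"` switches to a
#' smaller setup (30 starting dimensions, 200 epochs, patience 25) sized
#' for simulation studies of a few dozen items.
#'
#' @param k_init starting number of dimensions.
#' @param lambda L1 sparsity weight.
#' @param learning_rate Adam step size.
#' @param batch_size trials per gradient step.
#' @param max_epochs training ceiling.
#' @param window early-stopping patience: training stops once the
#'   validation loss has not improved for this many consecutive epochs.
#' @param split_fraction fraction of trials used for training (the rest is
#'   the validation set).
#' @param prune_threshold minimum column sum a dimension needs to survive
#'   pruning.
#' @param seed integer seed for initialization, the split and batch order.
#' @param profile `"paper"` (full-scale defaults) or `"reduced"`.
#' @return list of class `spose_config`.
#' @export
spose_config <- function(k_init = NULL, lambda = 0.008, learning_rate = 0.001,
                         batch_size = 128L, max_epochs = NULL, window = NULL,
                         split_fraction = 0.9, prune_threshold = 0.1,
                         seed = 42L, profile = c("paper", "reduced")) {
  profile <- match.arg(profile)
  defaults <- if (profile == "paper") c(k = 100L, e = 500L, w = 50L)
              else c(k = 30L, e = 200L, w = 25L)
  cfg <- list(
    k_init = check_count(k_init %||% defaults[["k"]], "k_init", 1L),
    lambda = check_fraction(lambda, "lambda", lo = 0, hi = Inf),
    learning_rate = check_fraction(learning_rate, "learning_rate",
                                   lo = 0, hi = Inf, lo_open = TRUE),
    batch_size = check_count(batch_size, "batch_size", 1L),
    max_epochs = check_count(max_epochs %||% defaults[["e"]], "max_epochs", 1L),
    window = check_count(window %||% defaults[["w"]], "window", 1L),
    split_fraction = check_fraction(split_fraction, "split_fraction",
                                    lo_open = TRUE, hi_open = TRUE),
    prune_threshold = check_fraction(prune_threshold, "prune_threshold",
                                     lo = 0, hi = Inf),
    seed = check_count(seed, "seed"),
    profile = profile
  )
  structure(cfg, class = "spose_config")
}

# Map a choice table onto the learner's index representation: an integer
# matrix of item row indices (screen order) plus the within-triplet index
# of the observed odd one out.
choices_to_trials <- function(choices, item_ids = NULL) {
  check_choices(choices)
  stim <- cbind(as.character(choices$stim_left),
                as.character(choices$stim_center),
                as.character(choices$stim_right))
  item_ids <- item_ids %||% sort(unique(as.vector(stim)))
  idx <- matrix(match(stim, item_ids), ncol = 3L)
  if (anyNA(idx)) stop_arg("choices reference items missing from the catalog")
  if (any(idx[, 1] == idx[, 2] | idx[, 1] == idx[, 3] | idx[, 2] == idx[, 3]))
    stop_arg("trials with duplicated stimuli are not valid triplets")
  list(trips = idx, odd = as.integer(choices$choice_position),
       item_ids = item_ids)
}

#' SPoSE objective and its gradient
#'
#' `spose_loss()` is the mean cross-entropy of the observed odd-one-out
#' choices under [choice_probabilities()] plus the sparsity penalty
#' `lambda * sum(weights) / n_items`. `spose_gradient()` is its exact
#' analytic gradient with respect to every weight; on the non-negative
#' orthant the penalty contributes a constant `lambda / n_items` per
#' coordinate.
#'
#' @param weights non-negative item x dimension matrix with item row names.
#' @param choices choice table (a batch; must be non-empty).
#' @param lambda L1 sparsity weight.
#' @param item_ids optional catalog fixing the row order; defaults to the
#'   row names of `weights`.
#' @return `spose_loss()`: scalar; `spose_gradient()`: matrix shaped like
#'   `weights`.
#' @export
spose_loss <- function(weights, choices, lambda = 0, item_ids = NULL) {
  check_embedding(weights, "weights")
  if (!nrow(choices)) stop_arg("empty batch")
  tr <- choices_to_trials(choices, item_ids %||% rownames(weights))
  p <- trial_probabilities(weights, tr$trips)
  obs <- p[cbind(seq_len(nrow(p)), tr$odd)]
  mean(-log(obs)) + lambda * sum(weights) / nrow(weights)
}

#' @rdname spose_loss
#' @export
spose_gradient <- function(weights, choices, lambda = 0, item_ids = NULL) {
  check_embedding(weights, "weights")
  if (!nrow(choices)) stop_arg("empty batch")
  tr <- choices_to_trials(choices, item_ids %||% rownames(weights))
  trips <- tr$trips
  nt <- nrow(trips)
  q <- trial_probabilities(weights, trips)
  # d(-log p_o)/d s_m = q_m - [m == o], for the three pairwise scores
  cf <- q
  cf[cbind(seq_len(nt), tr$odd)] <- cf[cbind(seq_len(nt), tr$odd)] - 1
  cf <- cf / nt
  # score s_m is the dot product of the two rows other than m, so each
  # trial pushes on its three rows with the opposite rows as directions
  rows <- c(trips[, 1], trips[, 1], trips[, 2], trips[, 2],
            trips[, 3], trips[, 3])
  dirs <- c(trips[, 3], trips[, 2], trips[, 3], trips[, 1],
            trips[, 2], trips[, 1])
  coef <- c(cf[, 2], cf[, 3], cf[, 1], cf[, 3], cf[, 1], cf[, 2])
  g <- rowsum(weights[dirs, , drop = FALSE] * coef, group = rows)
  grad <- matrix(lambda / nrow(weights), nrow(weights), ncol(weights),
                 dimnames = dimnames(weights))
  grad[as.integer(rownames(g)), ] <- grad[as.integer(rownames(g)), ] + g
  grad
}

#' Prune and sort embedding dimensions
#'
#' Drops every dimension whose total weight across items is strictly below
#' `threshold` (a column summing to exactly the threshold survives), sorts
#' the remaining dimensions by descending column sum, and relabels them
#' `dim_001`, `dim_002`, ...
#'
#' @param weights non-negative item x dimension matrix.
#' @param threshold minimum surviving column sum.
#' @return the pruned, sorted, relabelled matrix; warns and returns a
#'   0-column matrix if nothing survives.
#' @export
prune_and_sort <- function(weights, threshold = 0.1) {
  check_embedding(weights, "weights")
  sums <- colSums(weights)
  keep <- which(sums >= threshold)
  if (!length(keep)) {
    warning("all dimensions pruned: no column sum reaches ", threshold)
    out <- weights[, 0, drop = FALSE]
    return(out)
  }
  keep <- keep[order(sums[keep], decreasing = TRUE)]
  out <- weights[, keep, drop = FALSE]
  colnames(out) <- sprintf("dim_%03d", seq_along(keep))
  out
}

#' Predict odd-one-out choices
#'
#' Argmax of the model's choice probabilities per trial; ties go to the
#' lowest screen position.
#'
#' @param weights embedding matrix.
#' @param choices choice table.
#' @param item_ids optional catalog fixing the row order.
#' @return list with `predicted` (positions 1..3), `accuracy` against the
#'   observed choices, and `tie_frequency` (fraction of trials whose
#'   maximal probability was not unique).
#' @export
predict_choices <- function(weights, choices, item_ids = NULL) {
  tr <- choices_to_trials(choices, item_ids %||% rownames(weights))
  if (ncol(weights) == 0L) {
    p <- matrix(1 / 3, nrow(tr$trips), 3)
  } else {
    p <- trial_probabilities(weights, tr$trips)
  }
  pred <- max.col(p, ties.method = "first")
  mx <- p[cbind(seq_len(nrow(p)), pred)]
  ties <- rowSums(abs(p - mx) < 1e-12) > 1L
  list(predicted = pred,
       accuracy = mean(pred == tr$odd),
       tie_frequency = mean(ties))
}

#' Train a sparse positive similarity embedding
#'
#' Initializes an `n_items x k_init` weight matrix uniformly in `[0, 1)`,
#' splits the trials at random into training and validation parts, and
#' runs projected Adam on the SPoSE objective with mini-batches, clipping
#' the weights at zero after every step. Training stops at `max_epochs` or
#' once the validation loss has gone `window` consecutive epochs without
#' improving. The trained matrix is then pruned and sorted
#' ([prune_and_sort()]), and the held-out odd-one-out prediction accuracy
#' of the pruned embedding is reported.
#'
#' @param choices choice table of retained trials.
#' @param config a [spose_config()].
#' @param item_ids optional stimulus catalog; defaults to the ids present
#'   in `choices`.
#' @return list of class `spose_fit`: `embedding` (pruned + sorted),
#'   `k_effective`, `train_loss_history`, `validation_loss_history`,
#'   `best_validation_loss`, `stopped_epoch`, `holdout_accuracy`,
#'   `tie_frequency`, `n_train`, `n_validation` and `config`.
#' @export
spose_train <- function(choices, config = spose_config(), item_ids = NULL) {
  if (!inherits(config, "spose_config")) stop_arg("`config` must be a spose_config")
  tr <- choices_to_trials(choices, item_ids)
  nt <- nrow(tr$trips)
  if (nt < config$batch_size)
    stop_arg("need at least one full batch of trials (", config$batch_size,
             "), got ", nt)
  n_items <- length(tr$item_ids)

  init <- withr::with_seed(config$seed, {
    W0 <- matrix(runif(n_items * config$k_init), n_items, config$k_init)
    n_val <- max(1L, round((1 - config$split_fraction) * nt))
    val_idx <- sample.int(nt, n_val)
    list(W0 = W0, val_idx = val_idx)
  })
  val <- init$val_idx

  fit <- .spose_sgd_cpp(
    init$W0,
    tr$trips[-val, , drop = FALSE] - 1L, tr$odd[-val] - 1L,
    tr$trips[val, , drop = FALSE] - 1L, tr$odd[val] - 1L,
    config$lambda, config$learning_rate, config$batch_size,
    config$max_epochs, config$window, config$seed
  )

  W <- fit$weights
  rownames(W) <- tr$item_ids
  embedding <- prune_and_sort(W, config$prune_threshold)
  hold <- predict_choices(embedding, choices[val, , drop = FALSE],
                          item_ids = tr$item_ids)

  structure(list(embedding = embedding,
                 k_effective = ncol(embedding),
                 train_loss_history = fit$train_loss,
                 validation_loss_history = fit$validation_loss,
                 best_validation_loss = fit$best_validation_loss,
                 stopped_epoch = fit$stopped_epoch,
                 holdout_accuracy = hold$accuracy,
                 tie_frequency = hold$tie_frequency,
                 n_train = nt - length(val),
                 n_validation = length(val),
                 config = config),
            class = "spose_fit")
}

#' @export
print.spose_fit <- function(x, ...) {
  cat(sprintf(paste0("SPoSE fit: %d items, %d effective dimensions ",
                     "(lambda = %g)\n"),
              nrow(x$embedding), x$k_effective, x$config$lambda))
  cat(sprintf("  stopped after %d epochs; validation loss %.4f; holdout accuracy %.3f\n",
              x$stopped_epoch, x$best_validation_loss, x$holdout_accuracy))
  invisible(x)
}
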