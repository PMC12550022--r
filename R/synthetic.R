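# Synthetic experiments: ground-truth embeddings, worker profiles and
# simulated odd-one-out choice tables with reaction times. Everything
# downstream (QC, training, tuning, RSA) can be exercised on these without
# any external data.

#' Generate a ground-truth sparse positive embedding
#'
#' Draws an `n_items` x `k_true` non-negative weight matrix to serve as the
#' generating similarity structure of a simulated odd-one-out experiment.
#' Nonzero entries are exponential with mean `scale`; a Bernoulli mask sets
#' each entry to exactly zero with probability `sparsity`. Rows that end up
#' all-zero are redrawn so every item loads on at least one dimension.
#'
#' @param n_items number of stimuli (>= 3).
#' @param k_true number of generating dimensions (1 <= k_true <= n_items).
#' @param sparsity probability in `[0, 1)` that an entry is exactly zero.
#' @param scale mean of the exponential distribution of nonzero entries.
#' @param seed integer seed; the same call with the same seed is
#'   bit-identical.
#' @return non-negative matrix with row names `item_001`, ... and column
#'   names `dim_001`, ...; the seed is kept in `attr(, "seed")`.
#' @export
generate_ground_truth <- function(n_items, k_true, sparsity = 0.5, scale = 1,
                                  seed = 1L) {
  n_items <- check_count(n_items, "n_items", min = 3L)
  k_true <- check_count(k_true, "k_true", min = 1L)
  if (k_true > n_items) stop_arg("`k_true` must not exceed `n_items`")
  sparsity <- check_fraction(sparsity, "sparsity", hi_open = TRUE)
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    stop_arg("`scale` must be a positive number")

  w <- withr::with_seed(seed, {
    draw_rows <- function(m) {
      vals <- stats::rexp(m * k_true, rate = 1 / scale)
      mask <- stats::rbinom(m * k_true, 1L, prob = 1 - sparsity)
      matrix(vals * mask, nrow = m, ncol = k_true)
    }
    w <- draw_rows(n_items)
    repeat {
      dead <- which(rowSums(w) == 0)
      if (!length(dead)) break
      w[dead, ] <- draw_rows(length(dead))
    }
    w
  })
  dimnames(w) <- list(sprintf("item_%03d", seq_len(n_items)),
                      sprintf("dim_%03d", seq_len(k_true)))
  attr(w, "seed") <- as.integer(seed)
  w
}

#' Describe a simulated crowd worker
#'
#' A worker profile fixes how choices and reaction times are generated:
#' `compliant` workers answer from the embedding's choice model, `speeder`
#' workers respond too fast (and, having no time to deliberate, choose
#' uniformly), `position_biased` workers click one screen position most of
#' the time. Reaction times are log-normal on the millisecond scale with
#' parameters `(meanlog, sdlog)`.
#'
#' @param worker_id identifier.
#' @param kind one of `"compliant"`, `"speeder"`, `"position_biased"`.
#' @param lapse_rate probability in `[0, 1]` of a uniform random response on
#'   any trial.
#' @param rt_meanlog,rt_sdlog log-normal reaction-time parameters; defaults
#'   give a median around 2.5 s for compliant workers and 600 ms for
#'   speeders.
#' @param bias_position screen position (1, 2 or 3) a position-biased worker
#'   favors.
#' @param bias_strength probability that a position-biased worker clicks
#'   `bias_position` instead of consulting the choice model.
#' @return a list of class `worker_profile`.
#' @export
worker_profile <- function(worker_id,
                           kind = c("compliant", "speeder", "position_biased"),
                           lapse_rate = 0,
                           rt_meanlog = NULL, rt_sdlog = 0.35,
                           bias_position = 1L, bias_strength = 0.8) {
  kind <- match.arg(kind)
  lapse_rate <- check_fraction(lapse_rate, "lapse_rate")
  if (kind == "speeder") lapse_rate <- 1
  rt_meanlog <- rt_meanlog %||% if (kind == "speeder") log(600) else log(2500)
  if (rt_sdlog <= 0) stop_arg("`rt_sdlog` must be positive")
  if (!bias_position %in% 1:3) stop_arg("`bias_position` must be 1, 2 or 3")
  structure(list(worker_id = as.character(worker_id), kind = kind,
                 lapse_rate = lapse_rate,
                 rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog,
                 bias_position = as.integer(bias_position),
                 bias_strength = check_fraction(bias_strength, "bias_strength")),
            class = "worker_profile")
}

#' Simulate an odd-one-out experiment
#'
#' Plays a trial design through the softmax choice model of a ground-truth
#' embedding. Sets are assigned to workers round-robin in set order; each
#' worker answers according to its profile (model-based, lapsing, speeding
#' or position-biased) and draws a log-normal reaction time.
#'
#' @param truth ground-truth embedding ([generate_ground_truth()]).
#' @param design a `trial_design` from [build_design()].
#' @param profiles list of [worker_profile()] objects (at least one).
#' @param seed integer seed for all choice and reaction-time randomness.
#' @return a list of class `simulated_dataset` with elements `choices`
#'   (the trial table, see [write_choices_tsv()] for the schema), `truth`
#'   and `profiles`.
#' @export
simulate_dataset <- function(truth, design, profiles, seed = 1L) {
  check_embedding(truth, "truth")
  trials <- if (inherits(design, "trial_design")) design$trials else design
  if (is.null(trials) || !nrow(trials)) stop_arg("`design` has no trials")
  if (!length(profiles)) stop_arg("need at least one worker profile")
  if (inherits(profiles, "worker_profile")) profiles <- list(profiles)

  ids <- rownames(truth)
  stim <- cbind(as.character(trials$stim_left),
                as.character(trials$stim_center),
                as.character(trials$stim_right))
  idx <- matrix(match(stim, ids), ncol = 3L)
  if (anyNA(idx))
    stop_arg("design references items missing from the ground truth")

  # Round-robin assignment of whole sets to workers.
  sets <- sort(unique(trials$set_index))
  worker_of_set <- rep(seq_along(profiles), length.out = length(sets))
  names(worker_of_set) <- as.character(sets)
  wtrial <- worker_of_set[as.character(trials$set_index)]

  probs <- trial_probabilities(truth, idx)
  n <- nrow(trials)

  withr::with_seed(seed, {
    u <- runif(n)
    # Gumbel-max sampling from each trial's choice distribution.
    gumbel <- matrix(-log(-log(runif(n * 3))), n, 3)
    model_choice <- max.col(log(probs) + gumbel, ties.method = "first")
    choice <- integer(n)
    rt <- numeric(n)
    for (wi in seq_along(profiles)) {
      p <- profiles[[wi]]
      rows <- which(wtrial == wi)
      if (!length(rows)) next
      ch <- model_choice[rows]
      lapse <- u[rows] < p$lapse_rate
      if (any(lapse))
        ch[lapse] <- sample.int(3L, sum(lapse), replace = TRUE)
      if (p$kind == "position_biased") {
        biased <- runif(length(rows)) < p$bias_strength
        ch[biased] <- p$bias_position
      }
      choice[rows] <- ch
      rt[rows] <- rlnorm(length(rows), p$rt_meanlog, p$rt_sdlog)
    }
  })

  choices <- data.frame(
    worker_id = vapply(profiles, `[[`, "", "worker_id")[wtrial],
    set_index = trials$set_index,
    trial_index = trials$trial_index,
    stim_left = stim[, 1], stim_center = stim[, 2], stim_right = stim[, 3],
    choice_position = choice,
    rt_ms = round(rt, 1),
    stringsAsFactors = FALSE
  )
  structure(list(choices = choices, truth = truth, profiles = profiles),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("Simulated odd-one-out dataset: %d trials, %d workers, %d items\n",
              nrow(x$choices), length(x$profiles), nrow(x$truth)))
  invisible(x)
}

#' Simulate a contaminated crowdsourcing experiment
#'
#' A quality-control test bed: a pool of compliant workers plus planted
#' speeders (log-normal reaction times around 600 ms, uniform choices)
#' and position-biased workers, each answering several sets, so that the
#' exclusion rules can be validated against known ground truth. The
#' design's pair coverage is sized so every worker receives about
#' `sets_per_worker` sets.
#'
#' @param n_items,k_true,sparsity,scale ground-truth shape; see
#'   [generate_ground_truth()].
#' @param n_compliant,n_speeders,n_biased worker pool composition.
#' @param sets_per_worker target number of sets per worker.
#' @param set_size trials per set.
#' @param seed integer seed; ground truth, design and choices use
#'   `seed`, `seed + 1`, `seed + 2`.
#' @return a `simulated_dataset`; the planted contaminant ids are in
#'   `attr(, "contaminants")`.
#' @export
simulate_contaminated_dataset <- function(n_items = 30, k_true = 4,
                                          sparsity = 0.5, scale = 1,
                                          n_compliant = 10, n_speeders = 3,
                                          n_biased = 3, sets_per_worker = 8,
                                          set_size = 32, seed = 1L) {
  n_workers <- n_compliant + n_speeders + n_biased
  coverage <- max(1, round(n_workers * sets_per_worker * set_size /
                             choose(n_items, 2)))
  truth <- generate_ground_truth(n_items, k_true, sparsity, scale,
                                 seed = seed)
  design <- suppressWarnings(
    build_design(rownames(truth), pair_coverage = coverage,
                 set_size = set_size, seed = seed + 1L))
  profiles <- c(
    lapply(seq_len(n_compliant),
           function(i) worker_profile(sprintf("compliant_%02d", i))),
    lapply(seq_len(n_speeders),
           function(i) worker_profile(sprintf("speeder_%02d", i),
                                      kind = "speeder")),
    lapply(seq_len(n_biased),
           function(i) worker_profile(sprintf("biased_%02d", i),
                                      kind = "position_biased",
                                      bias_position = 1L + (i - 1L) %% 3L))
  )
  sim <- simulate_dataset(truth, design, profiles, seed = seed + 2L)
  attr(sim, "contaminants") <- c(sprintf("speeder_%02d", seq_len(n_speeders)),
                                 sprintf("biased_%02d", seq_len(n_biased)))
  sim
}
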