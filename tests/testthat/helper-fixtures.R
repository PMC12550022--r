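# Shared fixtures: all synthetic, built in code at test time.

# Hand-crafted choice rows with valid distinct-stimulus triplets; stimulus
# content is irrelevant for QC tests, which look at RTs and positions.
choice_rows <- function(worker_id, set_index, rt_ms,
                        choice_position = NULL, n = length(rt_ms)) {
  pool <- sprintf("s%02d", 1:12)
  trip <- t(vapply(seq_len(n) - 1L,
                   function(i) pool[1L + (i + c(0L, 1L, 2L)) %% 12L],
                   character(3)))
  data.frame(
    worker_id = rep_len(worker_id, n),
    set_index = rep_len(set_index, n),
    trial_index = seq_len(n),
    stim_left = trip[, 1], stim_center = trip[, 2], stim_right = trip[, 3],
    choice_position = rep_len(choice_position %||% rep_len(1:3, n), n),
    rt_ms = rep_len(rt_ms, n),
    stringsAsFactors = FALSE
  )
}

# Repeated presentations of one fixed triplet with a given sequence of
# chosen stimulus ids (screen order fixed: a, b, c).
repeat_trials <- function(chosen, worker = "w1") {
  data.frame(
    worker_id = worker,
    set_index = 1L,
    trial_index = seq_along(chosen),
    stim_left = "a", stim_center = "b", stim_right = "c",
    choice_position = match(chosen, c("a", "b", "c")),
    rt_ms = 1500,
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A small simulated experiment reused by several training tests.
small_training_set <- function(n_items = 20, k_true = 2, coverage = 8,
                               seed = 300) {
  truth <- generate_ground_truth(n_items, k_true, sparsity = 0.3,
                                 scale = 1.2, seed = seed)
  design <- suppressWarnings(
    build_design(rownames(truth), pair_coverage = coverage, set_size = 32,
                 seed = seed + 1))
  sim <- simulate_dataset(truth, design,
                          lapply(1:10, function(i) worker_profile(paste0("w", i))),
                          seed = seed + 2)
  list(truth = truth, choices = sim$choices)
}

fast_config <- function(...) {
  spose_config(profile = "reduced", k_init = 8, max_epochs = 60, window = 15,
               ...)
}
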