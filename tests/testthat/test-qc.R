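test_that("fast-set flagging applies both reaction-time thresholds at their boundaries", {
  # 4/32 = 12.5% below 900 and 16/32 = 50% below 1200: both at threshold
  rts <- c(rep(800, 4), rep(1000, 12), rep(1500, 16))
  expect_true(flag_fast_sets(rts))
  expect_false(flag_fast_sets(rep(1500, 32)))
  # many very fast trials but the <1200 ms share stays below 50%
  rts2 <- c(rep(800, 10), rep(1000, 2), rep(1500, 20))
  expect_false(flag_fast_sets(rts2))
  # 3/32 < 12.5% fails the first clause even with everything below 1200
  expect_false(flag_fast_sets(c(rep(800, 3), rep(1000, 29))))
  expect_error(flag_fast_sets(numeric(0)), "empty")
  expect_error(flag_fast_sets(c(1000, NA)), "missing")
})

test_that("worker exclusion needs three fast sets or six position-dominated sets", {
  fast_set <- function(w, s) choice_rows(w, s, c(rep(700, 6), rep(1000, 12),
                                                 rep(1500, 14)))
  slow_set <- function(w, s, pos = NULL) choice_rows(w, s, rep(1500, 32),
                                                     choice_position = pos)

  # exactly three fast sets -> excluded for speeding
  speeder <- do.call(rbind, c(lapply(1:3, function(s) fast_set("sp", s)),
                              list(slow_set("sp", 4))))
  # two fast sets only -> retained
  near <- do.call(rbind, c(lapply(1:2, function(s) fast_set("nr", s)),
                           lapply(3:6, function(s) slow_set("nr", s))))
  # six sets with 16/32 choices on position 1 -> excluded as deterministic
  biased <- do.call(rbind, lapply(1:6, function(s)
    slow_set("bi", s, pos = rep(c(1L, 1L, 2L, 3L), 8))))
  # five dominated sets -> retained
  five <- do.call(rbind, c(lapply(1:5, function(s)
    slow_set("fv", s, pos = rep(c(1L, 1L, 2L, 3L), 8))),
    list(slow_set("fv", 6, pos = rep(1:3, length.out = 32)))))
  # balanced alternation -> retained
  ok <- do.call(rbind, lapply(1:8, function(s) slow_set("ok", s)))

  excl <- exclude_workers(rbind(speeder, near, biased, five, ok))
  expect_setequal(excl$worker_id, c("sp", "bi"))
  expect_identical(excl$reason[excl$worker_id == "sp"], "fast_sets")
  expect_identical(excl$reason[excl$worker_id == "bi"], "deterministic")
})

test_that("trial filtering removes excluded workers then sub-900 ms trials, and is idempotent", {
  tab <- rbind(choice_rows("keep", 1, c(899, 900, 901, rep(1500, 29))),
               choice_rows("gone", 2, rep(1500, 32)))
  excl <- data.frame(worker_id = "gone", reason = "fast_sets")
  flt <- filter_trials(tab, excl)
  expect_identical(unique(flt$retained$worker_id), "keep")
  expect_false(any(flt$retained$rt_ms < 900))      # 899 removed
  expect_true(900 %in% flt$retained$rt_ms)         # boundary kept
  expect_equal(flt$retained_fraction, 31 / 64)

  again <- filter_trials(flt$retained, excl)
  expect_identical(again$retained, flt$retained)
  expect_equal(again$retained_fraction, 1)

  # fully compliant data is untouched
  clean <- choice_rows("c1", 1, rep(1400, 32))
  expect_equal(filter_trials(clean, data.frame(worker_id = character(),
                                               reason = character()))$retained_fraction,
               1)
})

test_that("choice consistency scores pairwise agreement on stimulus identity", {
  expect_equal(choice_consistency(repeat_trials(rep("a", 5))), 1)
  # responses (A, A, B, A): 3 agreeing pairs of C(4,2) = 6
  expect_equal(choice_consistency(repeat_trials(c("a", "a", "b", "a"))), 0.5)
  expect_equal(choice_consistency(repeat_trials(c("a", "a", "b", "a")),
                                  method = "modal"), 0.75)

  # identity, not screen position: same stimulus chosen under permuted screens
  perm <- data.frame(worker_id = "w", set_index = 1, trial_index = 1:2,
                     stim_left = c("a", "b"), stim_center = c("b", "a"),
                     stim_right = c("c", "c"),
                     choice_position = c(1L, 2L), rt_ms = 1500)
  expect_equal(choice_consistency(perm), 1)

  # triplets with a single response are skipped with a warning
  single <- rbind(repeat_trials(c("a", "a")),
                  data.frame(worker_id = "w9", set_index = 2, trial_index = 9,
                             stim_left = "x", stim_center = "y",
                             stim_right = "z", choice_position = 1L,
                             rt_ms = 1500))
  expect_warning(cons <- choice_consistency(single), "fewer than 2")
  expect_equal(cons, 1)

  expect_true(is.na(suppressWarnings(
    choice_consistency(single[3, , drop = FALSE]))))
})

test_that("uniform random responders converge to chance-level consistency", {
  zero <- matrix(0, 20, 1, dimnames = list(sprintf("i%02d", 1:20), NULL))
  des <- suppressWarnings(build_design(rownames(zero),
                                       repeat_n_triplets = 500,
                                       repeat_count = 10, pair_coverage = 0,
                                       set_size = 32, seed = 41))
  sim <- simulate_dataset(zero, des, worker_profile("u"), seed = 42)
  expect_lt(abs(choice_consistency(sim$choices) - 1 / 3), 0.01)
})

test_that("planted contaminants are excluded exactly", {
  sim <- simulate_contaminated_dataset(seed = 11)
  qc <- qc_report(sim$choices)
  expect_setequal(qc$excluded_workers$worker_id, attr(sim, "contaminants"))
  expect_identical(sort(unique(qc$excluded_workers$reason)),
                   c("deterministic", "fast_sets"))
  # consistency of the surviving (model-driven) choices sits above chance
  expect_gt(qc$consistency, 0.4)
})
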