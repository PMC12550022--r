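# Crowdsourcing quality control. Workers are excluded on two grounds:
# repeatedly too-fast trial sets, or a deterministic preference for one
# screen position. Surviving data are then trial-filtered on reaction time,
# and choice consistency is estimated from repeated triplets.

#' Flag a trial set as suspiciously fast
#'
#' A set is flagged when at least 12.5\% of its responses are faster than
#' 900 ms AND at least half are faster than 1200 ms (both thresholds
#' inclusive on the fraction).
#'
#' @param rt_ms reaction times of one set, in milliseconds.
#' @param fast_frac,fast_rt,slow_frac,slow_rt the two fraction/threshold
#'   pairs.
#' @return logical scalar.
#' @export
flag_fast_sets <- function(rt_ms, fast_frac = 0.125, fast_rt = 900,
                           slow_frac = 0.5, slow_rt = 1200) {
  if (!length(rt_ms)) stop_arg("empty set")
  if (anyNA(rt_ms)) stop_arg("missing reaction times in set")
  mean(rt_ms < fast_rt) >= fast_frac && mean(rt_ms < slow_rt) >= slow_frac
}

#' Identify workers to exclude
#'
#' A worker is excluded for speeding when at least `fast_sets_min` of their
#' sets are flagged by [flag_fast_sets()], and for deterministic responding
#' when in at least `deterministic_min` sets a single screen position
#' accounts for half or more of the set's choices.
#'
#' @param choices choice table (see [write_choices_tsv()] for the schema).
#' @param fast_sets_min sets flagged fast needed for exclusion (default 3).
#' @param deterministic_min position-dominated sets needed for exclusion
#'   (default 6).
#' @param position_frac dominance threshold within a set (default 0.5,
#'   inclusive).
#' @param ... thresholds passed on to [flag_fast_sets()].
#' @return data frame with columns `worker_id` and `reason`
#'   (`"fast_sets"` or `"deterministic"`; a worker hit by both rules is
#'   listed once with reason `"fast_sets"`).
#' @export
exclude_workers <- function(choices, fast_sets_min = 3L,
                            deterministic_min = 6L, position_frac = 0.5,
                            ...) {
  check_choices(choices)
  grp <- interaction(choices$worker_id, choices$set_index, drop = TRUE)
  fast <- tapply(choices$rt_ms, grp, flag_fast_sets, ...)
  dominant <- tapply(choices$choice_position, grp, function(p)
    max(tabulate(p, 3L)) / length(p) >= position_frac)
  set_worker <- tapply(as.character(choices$worker_id), grp, `[`, 1L)

  n_fast <- tapply(fast, set_worker, sum)
  n_dom <- tapply(dominant, set_worker, sum)
  workers <- names(n_fast)

  out <- data.frame(worker_id = character(), reason = character(),
                    stringsAsFactors = FALSE)
  for (w in workers) {
    if (n_fast[[w]] >= fast_sets_min)
      out <- rbind(out, data.frame(worker_id = w, reason = "fast_sets"))
    else if (n_dom[[w]] >= deterministic_min)
      out <- rbind(out, data.frame(worker_id = w, reason = "deterministic"))
  }
  out
}

#' Filter trials
#'
#' Removes all trials of the excluded workers, then every remaining trial
#' with a reaction time strictly below `rt_min` (a 900 ms response is
#' kept).
#'
#' @param choices choice table.
#' @param excluded data frame from [exclude_workers()], or `NULL` to
#'   compute it here with default thresholds.
#' @param rt_min trial-level reaction-time cutoff in ms.
#' @return list with `retained` (the surviving trials), `n_retained`,
#'   `n_total` and `retained_fraction`.
#' @export
filter_trials <- function(choices, excluded = NULL, rt_min = 900) {
  check_choices(choices)
  if (is.null(excluded)) excluded <- exclude_workers(choices)
  keep <- !(choices$worker_id %in% excluded$worker_id) &
    choices$rt_ms >= rt_min
  retained <- choices[keep, , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained,
       n_retained = nrow(retained),
       n_total = nrow(choices),
       retained_fraction = nrow(retained) / nrow(choices))
}

#' Choice consistency over repeated triplets
#'
#' For every triplet answered more than once (triplet identity ignores
#' screen order), agreement is the fraction of unordered response pairs
#' that chose the same stimulus — the stimulus identity, not the screen
#' position. Consistency is the unweighted mean of the per-triplet
#' agreements, so triplets with different repeat counts weigh equally.
#' Chance level for three alternatives is 1/3. `method = "modal"` instead
#' scores each triplet by the fraction of responses matching its modal
#' choice.
#'
#' @param choices choice table, typically restricted to the repeat block.
#' @param method `"pairwise"` (default) or `"modal"`.
#' @return consistency as a fraction in `[0, 1]`; `NA` if no triplet has
#'   at least two responses.
#' @export
choice_consistency <- function(choices, method = c("pairwise", "modal")) {
  check_choices(choices)
  method <- match.arg(method)
  key <- triplet_key(choices$stim_left, choices$stim_center,
                     choices$stim_right)
  chosen <- chosen_stimulus(choices)
  counts <- split(chosen, key)
  sizes <- lengths(counts)
  if (any(sizes < 2))
    warning(sum(sizes < 2), " triplet(s) with fewer than 2 responses skipped")
  counts <- counts[sizes >= 2]
  if (!length(counts)) return(NA_real_)
  agree <- vapply(counts, function(ch) {
    tab <- table(ch)
    m <- length(ch)
    if (method == "pairwise")
      sum(choose(tab, 2)) / choose(m, 2)
    else
      max(tab) / m
  }, numeric(1))
  mean(agree)
}

#' Full quality-control report
#'
#' Runs worker exclusion, trial filtering and (where repeated triplets
#' exist) consistency estimation in one pass.
#'
#' @param choices choice table.
#' @param rt_min trial-level reaction-time cutoff in ms.
#' @param ... thresholds passed to [exclude_workers()].
#' @return list of class `qc_report`: `excluded_workers`, `retained`
#'   (trial table), `n_retained`, `n_total`, `retained_fraction`,
#'   `consistency`.
#' @export
qc_report <- function(choices, rt_min = 900, ...) {
  check_choices(choices)
  excluded <- exclude_workers(choices, ...)
  flt <- filter_trials(choices, excluded, rt_min = rt_min)
  key <- triplet_key(flt$retained$stim_left, flt$retained$stim_center,
                     flt$retained$stim_right)
  rep_keys <- names(which(table(key) >= 2))
  consistency <- if (length(rep_keys))
    choice_consistency(flt$retained[key %in% rep_keys, , drop = FALSE])
  else NA_real_
  structure(list(excluded_workers = excluded,
                 retained = flt$retained,
                 n_retained = flt$n_retained,
                 n_total = flt$n_total,
                 retained_fraction = flt$retained_fraction,
                 consistency = consistency),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC: %d/%d trials retained (%.1f%%); %d worker(s) excluded\n",
              x$n_retained, x$n_total, 100 * x$retained_fraction,
              nrow(x$excluded_workers)))
  if (!is.na(x$consistency))
    cat(sprintf("  repeated-triplet choice consistency: %.2f%%\n",
                100 * x$consistency))
  invisible(x)
}
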