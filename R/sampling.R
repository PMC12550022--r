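# Triplet experiment design. A design is built from three sampling blocks:
#   exhaustive - every triplet of a small stimulus subset, repeated
#                `subset_passes` times (anchors the online cohort to a lab
#                pilot on the same subset);
#   repeat     - a random sample of triplets each shown `repeat_count`
#                times (the basis of the choice-consistency estimate);
#   main       - for every unordered pair of stimuli, `pair_coverage`
#                triplets completing the pair with distinct third items.
# Trials from all blocks are interleaved at random and packed into
# consecutive sets of `set_size` trials; the on-screen order of the three
# stimuli is re-randomized per trial.

#' Number of possible triplets
#'
#' Exact count of unordered stimulus triplets, `choose(n, 3)`.
#'
#' @param n number of stimuli (>= 3).
#' @return the exact count as a numeric scalar.
#' @examples
#' count_triplets(768)  # 75,202,816
#' @export
count_triplets <- function(n) {
  n <- check_count(n, "n", min = 3L)
  choose(n, 3)
}

#' Block arithmetic of a sampling plan
#'
#' Computes the trial counts a design will have without materializing it:
#' block sizes, the total, and how many fixed-size sets the trials pack
#' into.
#'
#' @param n_items catalog size.
#' @param subset_size,subset_passes size of the exhaustively sampled subset
#'   and how many passes over its `choose(subset_size, 3)` triplets.
#' @param repeat_n_triplets,repeat_count number of distinct repeat-block
#'   triplets and how often each is shown.
#' @param pair_coverage triplets per unordered stimulus pair in the main
#'   block.
#' @param set_size trials per set.
#' @return list with `n_exhaustive`, `n_repeat`, `n_main`, `n_total`,
#'   `n_sets` and `divisible` (whether `n_total` is a multiple of
#'   `set_size`).
#' @examples
#' # 2 passes over a 48-item subset, 1,000 triplets x 40 repeats, and
#' # 4 triplets per pair of 768 items, packed in sets of 32:
#' design_plan(768, 48, 2, 1000, 40, 4, 32)
#' @export
design_plan <- function(n_items, subset_size = 0, subset_passes = 0,
                        repeat_n_triplets = 0, repeat_count = 0,
                        pair_coverage = 0, set_size = 32) {
  n_items <- check_count(n_items, "n_items", min = 3L)
  set_size <- check_count(set_size, "set_size", min = 1L)
  n_ex <- subset_passes * if (subset_size >= 3) choose(subset_size, 3) else 0
  n_rep <- repeat_n_triplets * repeat_count
  n_main <- pair_coverage * choose(n_items, 2)
  total <- n_ex + n_rep + n_main
  list(n_exhaustive = n_ex, n_repeat = n_rep, n_main = n_main,
       n_total = total, n_sets = ceiling(total / set_size),
       divisible = total %% set_size == 0)
}

# Unrank combinations: map indices in 1..choose(n, 3) to sorted triples,
# lexicographic by (a, b, c). Lets the repeat block sample uniformly from
# all triplets without enumerating them.
unrank_triplets <- function(ranks, n) {
  r <- ranks - 1
  a <- b <- cc <- integer(length(r))
  # count of triples with first element <= x is C(n,3) - C(n-x,3)
  for (i in seq_along(r)) {
    ri <- r[i]
    lo <- 1L
    while (choose(n - lo, 2) <= ri) {
      ri <- ri - choose(n - lo, 2)
      lo <- lo + 1L
    }
    a[i] <- lo
    mid <- lo + 1L
    while (choose(n - mid, 1) <= ri) {
      ri <- ri - (n - mid)
      mid <- mid + 1L
    }
    b[i] <- mid
    cc[i] <- mid + 1L + ri
  }
  cbind(a, b, cc, deparse.level = 0)
}

#' Build a triplet odd-one-out trial design
#'
#' Assembles the exhaustive, repeat and pair-coverage blocks (see the
#' module description above), shuffles all trials together, randomizes the
#' on-screen order of the three stimuli in every trial, and packs the
#' sequence into consecutive sets.
#'
#' @param item_ids character vector of stimulus ids.
#' @param subset_ids ids sampled exhaustively (`NULL` for no exhaustive
#'   block); must be a subset of `item_ids`.
#' @param subset_passes passes over the exhaustive block.
#' @param repeat_n_triplets,repeat_count repeat-block shape: that many
#'   distinct triplets, drawn uniformly without replacement from all
#'   `choose(n, 3)` triplets, each shown `repeat_count` times.
#' @param pair_coverage number of main-block triplets per unordered pair of
#'   `item_ids`; the third items of a pair's triplets are pairwise
#'   distinct, so `pair_coverage <= length(item_ids) - 2`.
#' @param set_size trials per set; if the total is not divisible the final
#'   set is short (with a warning).
#' @param seed integer seed governing every random step.
#' @return object of class `trial_design`: a list with `trials` (data frame
#'   with columns `block`, `set_index`, `trial_index`, `stim_left`,
#'   `stim_center`, `stim_right`) and `params`.
#' @export
build_design <- function(item_ids, subset_ids = NULL, subset_passes = 0,
                         repeat_n_triplets = 0, repeat_count = 0,
                         pair_coverage = 1, set_size = 32, seed = 1L) {
  item_ids <- as.character(item_ids)
  n <- length(item_ids)
  if (n < 3 || anyDuplicated(item_ids))
    stop_arg("`item_ids` must hold at least three distinct ids")
  subset_passes <- check_count(subset_passes, "subset_passes")
  repeat_n_triplets <- check_count(repeat_n_triplets, "repeat_n_triplets")
  repeat_count <- check_count(repeat_count, "repeat_count")
  pair_coverage <- check_count(pair_coverage, "pair_coverage")
  set_size <- check_count(set_size, "set_size", min = 1L)
  if (!is.null(subset_ids) && length(setdiff(subset_ids, item_ids)))
    stop_arg("`subset_ids` must be a subset of `item_ids`")
  if (pair_coverage > n - 2)
    stop_arg("infeasible: `pair_coverage` (", pair_coverage,
             ") exceeds the ", n - 2, " available distinct third items")

  withr::with_seed(seed, {
    blocks <- list()

    if (subset_passes > 0 && length(subset_ids) >= 3) {
      sub_idx <- match(subset_ids, item_ids)
      ex <- t(combn(sub_idx, 3L))
      blocks$exhaustive <- ex[rep(seq_len(nrow(ex)), subset_passes), ,
                              drop = FALSE]
    }

    if (repeat_n_triplets > 0 && repeat_count > 0) {
      total <- count_triplets(n)
      if (repeat_n_triplets > total)
        stop_arg("`repeat_n_triplets` exceeds the number of possible triplets")
      ranks <- sample(total, repeat_n_triplets)
      rp <- unrank_triplets(ranks, n)
      blocks[["repeat"]] <- rp[rep(seq_len(nrow(rp)), repeat_count), ,
                               drop = FALSE]
    }

    if (pair_coverage > 0) {
      pairs <- t(combn(n, 2L))
      thirds <- matrix(0L, nrow(pairs), pair_coverage)
      pool <- seq_len(n)
      for (p in seq_len(nrow(pairs))) {
        avail <- pool[-pairs[p, ]]
        thirds[p, ] <- if (pair_coverage == 1L)
          avail[sample.int(n - 2L, 1L)]
        else sample(avail, pair_coverage)
      }
      blocks$main <- cbind(pairs[rep(seq_len(nrow(pairs)), pair_coverage), ,
                                 drop = FALSE],
                           as.vector(thirds))
    }

    if (!length(blocks)) stop_arg("empty design: all blocks have size zero")

    trips <- do.call(rbind, blocks)
    block <- rep(names(blocks), vapply(blocks, nrow, 0L))
    total_n <- nrow(trips)

    ord <- sample.int(total_n)                    # interleave blocks
    trips <- trips[ord, , drop = FALSE]
    block <- block[ord]

    # per-trial screen-position permutation, uniform over the 6 orderings
    perms <- matrix(c(1, 2, 3, 1, 3, 2, 2, 1, 3, 2, 3, 1, 3, 1, 2, 3, 2, 1),
                    ncol = 3, byrow = TRUE)
    pr <- perms[sample.int(6L, total_n, replace = TRUE), , drop = FALSE]
    scr <- matrix(trips[cbind(rep(seq_len(total_n), 3), as.vector(pr))],
                  ncol = 3)
  })

  if (total_n %% set_size != 0)
    warning("total trial count ", total_n, " is not divisible by set_size ",
            set_size, "; the final set is short")

  trials <- data.frame(
    block = block,
    set_index = ceiling(seq_len(total_n) / set_size),
    trial_index = seq_len(total_n),
    stim_left = item_ids[scr[, 1]],
    stim_center = item_ids[scr[, 2]],
    stim_right = item_ids[scr[, 3]],
    stringsAsFactors = FALSE
  )
  structure(list(
    trials = trials,
    params = list(n_items = n, item_ids = item_ids, subset_ids = subset_ids,
                  subset_passes = subset_passes,
                  repeat_n_triplets = repeat_n_triplets,
                  repeat_count = repeat_count, pair_coverage = pair_coverage,
                  set_size = set_size, seed = as.integer(seed))
  ), class = "trial_design")
}

#' @export
print.trial_design <- function(x, ...) {
  s <- design_summary(x)
  cat(sprintf("Trial design: %d trials in %d sets of %d (%s)\n",
              s$n_total, s$n_sets, x$params$set_size,
              paste(sprintf("%s %d", names(s$block_counts), s$block_counts),
                    collapse = ", ")))
  cat(sprintf("  %d unique triplets = %.2f%% of the %s possible\n",
              s$n_unique, s$unique_percent,
              format(s$n_possible, big.mark = ",")))
  invisible(x)
}

#' Summarize a trial design
#'
#' Counts trials per block, distinct triplets (ignoring screen order), and
#' the fraction of the `choose(n, 3)` possible triplets the design visits.
#'
#' @param design a `trial_design` from [build_design()].
#' @return list with `block_counts`, `n_total`, `n_sets`, `n_unique`,
#'   `n_possible`, `unique_fraction` and `unique_percent` (the fraction as
#'   a percentage, rounded to 2 decimals).
#' @export
design_summary <- function(design) {
  if (!inherits(design, "trial_design")) stop_arg("not a trial_design")
  tr <- design$trials
  key <- triplet_key(tr$stim_left, tr$stim_center, tr$stim_right)
  n_unique <- length(unique(key))
  n_possible <- count_triplets(design$params$n_items)
  frac <- n_unique / n_possible
  list(block_counts = table(tr$block),
       n_total = nrow(tr),
       n_sets = length(unique(tr$set_index)),
       n_unique = n_unique,
       n_possible = n_possible,
       unique_fraction = frac,
       unique_percent = round(100 * frac, 2))
}

#' Fraction of the possible-triplet space covered by a unique-triplet count
#'
#' @param n_unique number of distinct triplets sampled.
#' @param n_items catalog size.
#' @return percentage `100 * n_unique / choose(n_items, 3)`.
#' @examples
#' unique_percent(6720, 48)  # the 48-item pilot subset covers 38.9%
#' @export
unique_percent <- function(n_unique, n_items) {
  100 * n_unique / count_triplets(n_items)
}

#' Write a trial design as tab-separated text
#'
#' @param design a `trial_design`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_design_tsv <- function(design, path) {
  if (!inherits(design, "trial_design")) stop_arg("not a trial_design")
  write.table(design$trials, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
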