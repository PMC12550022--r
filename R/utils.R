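# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_arg <- function(...) stop(..., call. = FALSE)

check_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != floor(x) || x < min)
    stop_arg(sprintf("`%s` must be a single integer >= %d", name, min))
  as.integer(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1,
                           lo_open = FALSE, hi_open = FALSE) {
  ok <- length(x) == 1L && is.numeric(x) && !is.na(x) &&
    (if (lo_open) x > lo else x >= lo) &&
    (if (hi_open) x < hi else x <= hi)
  if (!ok) stop_arg(sprintf("`%s` must be a number in %s%g, %g%s",
                            name, if (lo_open) "(" else "[", lo, hi,
                            if (hi_open) ")" else "]"))
  as.numeric(x)
}

# Canonical key of a triplet: the three ids sorted and concatenated, so that
# repeats of the same triplet are recognized regardless of screen order.
triplet_key <- function(a, b, c) {
  m <- cbind(as.character(a), as.character(b), as.character(c))
  apply(m, 1L, function(r) paste(sort(r), collapse = "\r"))
}

choice_columns <- c("worker_id", "set_index", "trial_index",
                    "stim_left", "stim_center", "stim_right",
                    "choice_position", "rt_ms")

check_choices <- function(choices) {
  missing <- setdiff(choice_columns, names(choices))
  if (length(missing))
    stop_arg("choice table is missing columns: ", paste(missing, collapse = ", "))
  if (!all(choices$choice_position %in% 1:3))
    stop_arg("`choice_position` must be 1, 2 or 3")
  invisible(choices)
}

# Stimulus id actually chosen on each trial (screen position resolved).
chosen_stimulus <- function(choices) {
  stim <- cbind(as.character(choices$stim_left),
                as.character(choices$stim_center),
                as.character(choices$stim_right))
  stim[cbind(seq_len(nrow(stim)), choices$choice_position)]
}

check_embedding <- function(weights, what = "embedding") {
  if (!is.matrix(weights) || !is.numeric(weights))
    stop_arg(what, " must be a numeric matrix")
  if (is.null(rownames(weights)))
    stop_arg(what, " must have item ids as row names")
  if (any(weights < 0))
    stop_arg(what, " must be non-negative")
  invisible(weights)
}

#' Write / read a choice table as tab-separated text
#'
#' The on-disk schema is one row per odd-one-out trial with columns
#' `worker_id`, `set_index`, `trial_index`, `stim_left`, `stim_center`,
#' `stim_right`, `choice_position` (1 = left, 2 = center, 3 = right) and
#' `rt_ms`.
#'
#' @param choices data frame of trials in the schema above.
#' @param path file path.
#' @return `read_choices_tsv()` returns the choice table as a data frame;
#'   `write_choices_tsv()` returns `path` invisibly.
#' @export
write_choices_tsv <- function(choices, path) {
  check_choices(choices)
  write.table(choices[choice_columns], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_choices_tsv
#' @export
read_choices_tsv <- function(path) {
  check_choices(read.delim(path, stringsAsFactors = FALSE))
}

#' Write / read an embedding matrix as tab-separated text
#'
#' Rows are stimuli (first column `item_id`), remaining columns are the
#' dimension weights labelled `dim_001`, `dim_002`, ...
#'
#' @param weights non-negative numeric matrix with item ids as row names.
#' @param path file path.
#' @return `read_embedding_tsv()` returns the weight matrix;
#'   `write_embedding_tsv()` returns `path` invisibly.
#' @export
write_embedding_tsv <- function(weights, path) {
  check_embedding(weights)
  labels <- colnames(weights) %||% sprintf("dim_%03d", seq_len(ncol(weights)))
  df <- data.frame(item_id = rownames(weights), weights,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("item_id", labels)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_embedding_tsv
#' @export
read_embedding_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  w <- as.matrix(df[, -1, drop = FALSE])
  rownames(w) <- df[[1]]
  w
}
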