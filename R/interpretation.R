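# Interpreting a trained embedding: top-ranked stimuli per dimension,
# per-stimulus dimension profiles (the data behind rose plots), and the
# representational similarity analysis (RSA) that compares human dimension
# ratings against model weights, with a label-shuffling randomization test.

#' Top-ranked stimuli on one dimension
#'
#' @param embedding item x dimension matrix with item row names.
#' @param dimension column name or index.
#' @param k how many items to return.
#' @return character vector of item ids sorted by descending weight on the
#'   dimension; ties are broken by item id (lexicographic).
#' @export
top_ranking_items <- function(embedding, dimension, k = 8L) {
  check_embedding(embedding)
  if (is.character(dimension) && !dimension %in% colnames(embedding))
    stop_arg("unknown dimension: ", dimension)
  if (is.numeric(dimension) && (dimension < 1 || dimension > ncol(embedding)))
    stop_arg("dimension index out of range")
  k <- check_count(k, "k", 1L)
  if (k > nrow(embedding)) stop_arg("`k` exceeds the number of items")
  w <- embedding[, dimension]
  ids <- rownames(embedding)
  ids[order(-w, ids)][seq_len(k)]
}

#' Dimension profile of one stimulus
#'
#' The stimulus's row of the embedding in dimension order — the data behind
#' a circular (rose) bar plot of how strongly the stimulus expresses each
#' dimension.
#'
#' @param embedding item x dimension matrix.
#' @param item item id.
#' @return named numeric vector of the item's weights on every dimension.
#' @export
dimension_profile <- function(embedding, item) {
  check_embedding(embedding)
  item <- as.character(item)
  if (!item %in% rownames(embedding)) stop_arg("unknown item: ", item)
  embedding[item, ]
}

#' Preprocess dimension ratings
#'
#' Ratings on a 7-level typicality scale (level 1 = very typical, level
#' 7 = very untypical) plus an off-scale 'not at all' option are mapped to
#' `[0, 1]`: 'not at all' becomes 0, level `l` becomes `(8 - l) / 7` (so
#' even 'very untypical' keeps a small positive value, distinct from 'not
#' at all'), and values are averaged across raters per (stimulus,
#' dimension).
#'
#' @param ratings data frame with columns `rater`, `stimulus`, `dimension`
#'   and `level` (integers 1..7 or the string `"not_at_all"`).
#' @return stimulus x dimension matrix of mean scaled ratings in `[0, 1]`.
#' @export
preprocess_ratings <- function(ratings) {
  need <- c("rater", "stimulus", "dimension", "level")
  missing <- setdiff(need, names(ratings))
  if (length(missing))
    stop_arg("rating table is missing columns: ", paste(missing, collapse = ", "))
  if (!nrow(ratings)) stop_arg("empty rating table")
  lev <- as.character(ratings$level)
  num <- suppressWarnings(as.numeric(lev))
  ok <- lev == "not_at_all" | (!is.na(num) & num %in% 1:7)
  if (!all(ok))
    stop_arg("invalid rating level(s): ",
             paste(unique(lev[!ok]), collapse = ", "))
  if (anyDuplicated(ratings[c("rater", "stimulus", "dimension")]))
    stop_arg("duplicate (rater, stimulus, dimension) rating(s)")
  value <- ifelse(lev == "not_at_all", 0, (8 - num) / 7)
  tapply(value,
         list(as.character(ratings$stimulus), as.character(ratings$dimension)),
         mean)
}

#' Pairwise Pearson similarity matrix of items
#'
#' @param features item x feature matrix (>= 2 features); entry (a, b) of
#'   the result is the Pearson correlation of the two items' feature
#'   vectors. Items with zero feature variance have no defined correlation;
#'   their entries are `NA` and a warning names them.
#' @return symmetric item x item correlation matrix with unit diagonal.
#' @export
similarity_matrix <- function(features) {
  if (!is.matrix(features)) features <- as.matrix(features)
  if (ncol(features) < 2) stop_arg("need at least two features per item")
  if (is.null(rownames(features)))
    rownames(features) <- sprintf("item_%03d", seq_len(nrow(features)))
  degenerate <- apply(features, 1L, function(r) sd(r) == 0)
  if (any(degenerate))
    warning("zero-variance item(s), similarity undefined: ",
            paste(rownames(features)[degenerate], collapse = ", "))
  m <- suppressWarnings(cor(t(features)))
  diag(m) <- 1
  m
}

#' Min-max scale embedding weights over selected items
#'
#' Scales each dimension to `[0, 1]` across the selected items, as done
#' before comparing model weights with human ratings. A dimension that is
#' constant over the selection carries no information there; it is mapped
#' to all zeros with a warning.
#'
#' @param embedding item x dimension matrix.
#' @param items item ids to keep (default: all).
#' @return items x dimension matrix with every column in `[0, 1]`.
#' @export
scale_model_weights <- function(embedding, items = NULL) {
  check_embedding(embedding)
  items <- items %||% rownames(embedding)
  missing <- setdiff(items, rownames(embedding))
  if (length(missing))
    stop_arg("unknown item(s): ", paste(missing, collapse = ", "))
  w <- embedding[items, , drop = FALSE]
  rng <- apply(w, 2L, range)
  span <- rng[2, ] - rng[1, ]
  flat <- span == 0
  if (any(flat))
    warning("constant dimension(s) over the selection mapped to 0: ",
            paste(colnames(w)[flat] %||% which(flat), collapse = ", "))
  span[flat] <- 1
  scaled <- sweep(sweep(w, 2L, rng[1, ]), 2L, span, "/")
  scaled[, flat] <- 0
  scaled
}

#' Correlate two similarity matrices (RSA)
#'
#' Pearson correlation of the strict lower triangles of two item x item
#' similarity matrices over the same items in the same order.
#'
#' @param m1,m2 symmetric similarity matrices with identical item ids.
#' @return correlation coefficient.
#' @export
compare_rsa <- function(m1, m2) {
  if (!identical(dim(m1), dim(m2)))
    stop_arg("similarity matrices have different sizes")
  if (!is.null(rownames(m1)) && !is.null(rownames(m2)) &&
      !identical(rownames(m1), rownames(m2)))
    stop_arg("similarity matrices cover different items (or orders)")
  lt <- lower.tri(m1)
  cor(m1[lt], m2[lt])
}

#' Randomization test for an RSA correlation
#'
#' Builds a null distribution by shuffling the item labels of `m2` —
#' permuting its rows and columns jointly — and recomputing the RSA
#' correlation `n_perm` times. The p-value is the plain proportion of
#' permutations whose correlation is at least the observed one, so the
#' smallest attainable p is `1 / n_perm`.
#'
#' @param m1,m2 similarity matrices as in [compare_rsa()].
#' @param n_perm number of label shuffles.
#' @param seed integer seed.
#' @return list with `observed_r`, `p_value`, `n_perm`, and `perm_r`
#'   (the permutation correlations).
#' @export
randomization_test <- function(m1, m2, n_perm = 100000L, seed = 1L) {
  n_perm <- check_count(n_perm, "n_perm", 1L)
  n <- nrow(m1)
  if (n < 3) stop_arg("need at least 3 items for a meaningful permutation test")
  observed <- compare_rsa(m1, m2)
  lt <- lower.tri(m2)
  v1 <- m1[lt]
  perm_r <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      pp <- sample.int(n)
      mp <- m2[pp, pp]
      cor(v1, mp[lt])
    }, numeric(1))
  })
  list(observed_r = observed,
       p_value = mean(perm_r >= observed),
       n_perm = n_perm,
       perm_r = perm_r)
}
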