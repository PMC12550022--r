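# The softmax-of-dot-products choice model shared by the simulator and the
# embedding learner. In the odd-one-out reading, choosing item k as the odd
# one is the same event as judging the pair {i, j} most similar, so the score
# for "k is odd" is the dot product of the OTHER two items' weight vectors.

#' Odd-one-out choice probabilities under an embedding
#'
#' For a triplet of items `(i, j, k)` the model computes the three pairwise
#' dot-product similarities of their embedding rows and passes them through a
#' softmax: the probability that item `m` is picked as the odd one out is
#' proportional to `exp(s)` where `s` is the similarity of the two remaining
#' items. An all-zero embedding therefore yields the uniform distribution
#' (1/3, 1/3, 1/3).
#'
#' @param embedding non-negative numeric matrix, items in rows (row names are
#'   the item ids), dimensions in columns.
#' @param triplet character vector of three distinct item ids.
#' @return named numeric vector of three probabilities (summing to 1), in the
#'   order of `triplet`; entry `m` is the probability that item `m` is the
#'   odd one out.
#' @examples
#' w <- matrix(c(1, 1, 0), ncol = 1, dimnames = list(c("a", "b", "c"), NULL))
#' choice_probabilities(w, c("a", "b", "c"))  # c is odd with prob e/(e+2)
#' @export
choice_probabilities <- function(embedding, triplet) {
  check_embedding(embedding)
  triplet <- as.character(triplet)
  if (length(triplet) != 3L || anyDuplicated(triplet))
    stop_arg("`triplet` must contain three distinct item ids")
  missing <- setdiff(triplet, rownames(embedding))
  if (length(missing))
    stop_arg("unknown item id(s): ", paste(missing, collapse = ", "))
  w <- embedding[triplet, , drop = FALSE]
  s <- c(sum(w[2, ] * w[3, ]),   # score for "triplet[1] is odd"
         sum(w[1, ] * w[3, ]),
         sum(w[1, ] * w[2, ]))
  e <- exp(s - max(s))
  p <- e / sum(e)
  names(p) <- triplet
  p
}

#' @rdname choice_probabilities
#' @param truth a ground-truth embedding, as returned by
#'   [generate_ground_truth()] (any non-negative matrix with item row names
#'   works).
#' @details `choice_distribution()` is the simulator-facing name for the same
#'   computation; both call one implementation.
#' @export
choice_distribution <- function(truth, triplet) {
  choice_probabilities(truth, triplet)
}

# Vectorized trial probabilities: trips is an integer matrix of row indices
# (one trial per row), returns an n x 3 matrix of odd-one-out probabilities
# by screen position.
trial_probabilities <- function(weights, trips) {
  G <- tcrossprod(weights)
  s <- cbind(G[trips[, c(2, 3), drop = FALSE]],
             G[trips[, c(1, 3), drop = FALSE]],
             G[trips[, c(1, 2), drop = FALSE]])
  s <- s - apply(s, 1L, max)
  e <- exp(s)
  e / rowSums(e)
}
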