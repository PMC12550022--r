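# Stimulus-database curation from per-frame classifier outputs: pick each
# video's most diagnostic frame, average frames into category
# representatives, compute cosine dissimilarities between categories,
# cluster them hierarchically to spot over-represented meta-clusters, and
# apply the naming-accuracy exclusion rule from the validation study.
#
# Frame tables are long data frames with columns `video`, `category`,
# `frame`, plus one numeric probability column per class, named by the
# class label (each row a softmax vector over classes).

frame_prob_columns <- function(frames) {
  setdiff(names(frames), c("video", "category", "frame"))
}

#' Most diagnostic frame of a video
#'
#' Among all frames of one video, returns the full class-probability vector
#' of the frame with the highest probability on the video's correct
#' category; ties go to the lowest frame index.
#'
#' @param frames frame table (see the module description) restricted to one
#'   video.
#' @return named probability vector over classes.
#' @export
best_frame_vector <- function(frames) {
  if (!nrow(frames)) stop_arg("no frames")
  cls <- frame_prob_columns(frames)
  if (!length(cls)) stop_arg("no class-probability columns")
  category <- unique(as.character(frames$category))
  if (length(category) != 1L)
    stop_arg("frames must belong to a single video/category")
  if (!category %in% cls)
    stop_arg("category label '", category, "' is not among the class columns")
  correct <- frames[[category]]
  ord <- order(frames$frame)
  best <- ord[which.max(correct[ord])]   # which.max takes the first maximum
  v <- as.numeric(frames[best, cls])
  names(v) <- cls
  v
}

#' Category-representative class-probability vectors
#'
#' Each video contributes its best frame ([best_frame_vector()]); a
#' category's representative is the arithmetic mean over its videos.
#'
#' @param frames frame table covering one or more categories.
#' @return category x class matrix of representative vectors; the number
#'   of contributing videos is kept in `attr(, "n_videos")`.
#' @export
category_representatives <- function(frames) {
  if (!nrow(frames)) stop_arg("empty frame table")
  cls <- frame_prob_columns(frames)
  by_video <- split(frames, as.character(frames$video))
  best <- t(vapply(by_video, best_frame_vector, numeric(length(cls))))
  video_cat <- vapply(by_video, function(f) as.character(f$category[1]), "")
  reps <- rowsum(best, group = video_cat) / as.vector(table(video_cat))
  attr(reps, "n_videos") <- table(video_cat)
  reps
}

#' Pairwise cosine dissimilarities
#'
#' @param profiles row-wise vectors (e.g. category representatives); no
#'   row may be all-zero.
#' @return symmetric matrix of `1 - cosine similarity` with zero diagonal.
#' @export
cosine_dissimilarity_matrix <- function(profiles) {
  if (!is.matrix(profiles)) profiles <- as.matrix(profiles)
  nrm <- sqrt(rowSums(profiles^2))
  if (any(nrm == 0)) stop_arg("zero vector(s): cosine undefined")
  d <- 1 - tcrossprod(profiles / nrm)
  d[d < 0] <- 0                      # clip numeric negatives like -1e-16
  diag(d) <- 0
  d
}

#' Agglomerative clustering of a dissimilarity matrix
#'
#' Hierarchical clustering of categories (or any items) from a symmetric
#' dissimilarity matrix, used to identify meta-clusters of related
#' categories and flag over-represented ones.
#'
#' @param dissimilarity symmetric matrix with zero diagonal.
#' @param linkage `"average"` (default), `"single"` or `"complete"`.
#' @param k number of flat clusters to cut, or
#' @param h cut height (one of `k`/`h` may be given; with neither, only
#'   the dendrogram is returned).
#' @return list with `hclust` (the full `stats::hclust` tree), `merges`
#'   (data frame of merge pairs and heights), and — when cut —
#'   `assignments`, `cluster_sizes` and `mean_cluster_size`.
#' @export
hierarchical_clusters <- function(dissimilarity,
                                  linkage = c("average", "single", "complete"),
                                  k = NULL, h = NULL) {
  linkage <- match.arg(linkage)
  if (!is.matrix(dissimilarity) || nrow(dissimilarity) < 2)
    stop_arg("need a dissimilarity matrix over at least 2 items")
  if (any(abs(dissimilarity - t(dissimilarity)) > 1e-8))
    stop_arg("dissimilarity matrix must be symmetric")
  hc <- hclust(as.dist(dissimilarity), method = linkage)
  out <- list(hclust = hc,
              merges = data.frame(left = hc$merge[, 1],
                                  right = hc$merge[, 2],
                                  height = hc$height))
  if (!is.null(k) || !is.null(h)) {
    assignments <- cutree(hc, k = k, h = h)
    sizes <- table(assignments)
    out$assignments <- assignments
    out$cluster_sizes <- sizes
    out$mean_cluster_size <- mean(sizes)
  }
  out
}

#' Naming-accuracy exclusion rule
#'
#' A category is excluded when its mean naming accuracy over exemplars is
#' below `threshold` AND at least two exemplars individually fall below
#' the threshold; raising any exemplar's accuracy can therefore never turn
#' a retained category into an excluded one.
#'
#' @param accuracies data frame with columns `category`, `exemplar` and
#'   `accuracy` (fractions in `[0, 1]`).
#' @param threshold accuracy cutoff (default 0.7).
#' @return data frame per category: `mean_accuracy`, `n_below`,
#'   `excluded`, `reason`.
#' @export
naming_accuracy_filter <- function(accuracies, threshold = 0.7) {
  need <- c("category", "exemplar", "accuracy")
  missing <- setdiff(need, names(accuracies))
  if (length(missing))
    stop_arg("accuracy table is missing columns: ",
             paste(missing, collapse = ", "))
  if (!nrow(accuracies)) stop_arg("empty accuracy table")
  check_fraction(threshold, "threshold")
  by_cat <- split(accuracies$accuracy, as.character(accuracies$category))
  res <- lapply(names(by_cat), function(cat) {
    acc <- by_cat[[cat]]
    if (!length(acc) || anyNA(acc)) stop_arg("missing accuracies for ", cat)
    below <- sum(acc < threshold)
    excl <- mean(acc) < threshold && below >= 2
    data.frame(category = cat,
               mean_accuracy = mean(acc),
               n_below = below,
               excluded = excl,
               reason = if (excl) "low_naming_accuracy" else "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
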