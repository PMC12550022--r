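test_that("top-ranked items sort by weight with lexicographic tie-breaks", {
  w <- matrix(c(0.9, 0.1, 0.5,
                0,   1,   0), ncol = 2,
              dimnames = list(c("i1", "i2", "i3"), c("dim_001", "dim_002")))
  expect_identical(top_ranking_items(w, "dim_001", 2), c("i1", "i3"))
  expect_identical(top_ranking_items(w, "dim_002", 1), "i2")  # one-hot column
  expect_identical(top_ranking_items(w, 1, 3), c("i1", "i3", "i2"))
  expect_setequal(top_ranking_items(w, 1, 3), rownames(w))

  tie <- matrix(c(0.5, 0.5, 0.1), ncol = 1,
                dimnames = list(c("b", "a", "c"), "dim_001"))
  expect_identical(top_ranking_items(tie, 1, 2), c("a", "b"))

  expect_error(top_ranking_items(w, "dim_009", 1), "unknown dimension")
  expect_error(top_ranking_items(w, 1, 4), "exceeds")
})

test_that("dimension profiles are exactly the item's embedding row", {
  w <- generate_ground_truth(6, 4, 0.4, seed = 2)
  for (it in rownames(w)[c(1, 4)]) {
    prof <- dimension_profile(w, it)
    expect_equal(prof, w[it, ])
    expect_equal(sum(prof), sum(w[it, ]))
  }
  wz <- rbind(w, zero_item = 0)
  expect_equal(unname(dimension_profile(wz, "zero_item")), rep(0, 4))
  expect_error(dimension_profile(w, "ghost"), "unknown item")
})

test_that("rating preprocessing maps the 7-level scale with 'not at all' pinned to zero", {
  rt <- function(rater, stimulus, dimension, level)
    data.frame(rater = rater, stimulus = stimulus, dimension = dimension,
               level = level, stringsAsFactors = FALSE)

  allna <- rt(paste0("r", 1:3), "s1", "d1", "not_at_all")
  expect_equal(unname(preprocess_ratings(allna)["s1", "d1"]), 0)

  expect_equal(unname(preprocess_ratings(rt("r1", "s1", "d1", 1))["s1", "d1"]),
               1)                                     # very typical
  expect_equal(unname(preprocess_ratings(rt("r1", "s1", "d1", 7))["s1", "d1"]),
               1 / 7)                                 # very untypical, not 0
  two <- rbind(rt("r1", "s1", "d1", 1), rt("r2", "s1", "d1", 7))
  expect_equal(unname(preprocess_ratings(two)["s1", "d1"]), (1 + 1 / 7) / 2)

  expect_error(preprocess_ratings(rt("r1", "s1", "d1", 9)), "invalid")
  expect_error(preprocess_ratings(rbind(rt("r1", "s1", "d1", 1),
                                        rt("r1", "s1", "d1", 2))),
               "duplicate")
})

test_that("similarity matrices are Pearson correlations of item feature rows", {
  f <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(3, 2, 1))
  m <- similarity_matrix(f)
  expect_equal(m["a", "b"], 1)
  expect_equal(m["a", "c"], -1)
  expect_equal(diag(m), c(a = 1, b = 1, c = 1))
  expect_true(isSymmetric(m))

  m2 <- similarity_matrix(rbind(x = c(1, 2, 3), y = c(1, 2, 4)))
  expect_equal(m2["x", "y"], cor(c(1, 2, 3), c(1, 2, 4)))
  expect_equal(round(m2["x", "y"], 3), 0.982)

  expect_warning(mz <- similarity_matrix(rbind(a = c(1, 1, 1),
                                               b = c(1, 2, 3))),
                 "zero-variance")
  expect_true(is.na(mz["a", "b"]))
  expect_error(similarity_matrix(matrix(1, 2, 1)), "two features")
})

test_that("model weights are min-max scaled per dimension over the selection", {
  w <- matrix(c(0, 5,
                1, 2,
                3, 3), nrow = 2,
              dimnames = list(c("a", "b"), paste0("dim_00", 1:3)))
  expect_warning(sc <- scale_model_weights(w), "constant")
  expect_equal(unname(sc[, 1]), c(0, 1))
  expect_equal(unname(sc[, 3]), c(0, 0))      # flat dimension -> zeros

  w2 <- matrix(c(1, 2, 3), ncol = 1, dimnames = list(c("a", "b", "c"), "d"))
  expect_equal(unname(scale_model_weights(w2)[, 1]), c(0, 0.5, 1))
  expect_error(scale_model_weights(w2, items = "nope"), "unknown item")
})

test_that("RSA correlates strict lower triangles", {
  m <- similarity_matrix(generate_ground_truth(6, 4, 0.3, seed = 9))
  expect_equal(compare_rsa(m, m), 1)

  tri <- function(v) {
    m <- diag(3)
    m[lower.tri(m)] <- v
    m[upper.tri(m)] <- t(m)[upper.tri(m)]
    dimnames(m) <- list(letters[1:3], letters[1:3])
    m
  }
  expect_equal(compare_rsa(tri(c(0.1, 0.2, 0.3)), tri(c(0.2, 0.4, 0.6))), 1)
  expect_equal(compare_rsa(tri(c(0.1, 0.2, 0.3)), tri(c(0.3, 0.2, 0.1))), -1)
  expect_error(compare_rsa(m, m[1:4, 1:4]), "different sizes")
})

test_that("the randomization test uses the plain permutation proportion", {
  truth <- generate_ground_truth(8, 3, 0.3, seed = 10)
  m1 <- similarity_matrix(truth)
  m2 <- similarity_matrix(truth + matrix(abs(rnorm(24, 0, 0.05)), 8, 3))
  rt <- randomization_test(m1, m2, n_perm = 200, seed = 3)
  expect_gte(rt$p_value, 0)
  expect_lte(rt$p_value, 1)
  # plain proportion: p is a multiple of 1/n_perm
  expect_equal(rt$p_value * 200, round(rt$p_value * 200))
  expect_length(rt$perm_r, 200)
  # self-similar structure: observed beats essentially all relabelings
  expect_lte(rt$p_value, 0.05)

  # n_perm = 1 with a permutation at least as good gives p = 1
  flat <- tri <- matrix(0.5, 4, 4); diag(flat) <- 1
  dimnames(flat) <- list(letters[1:4], letters[1:4])
  noise <- similarity_matrix(generate_ground_truth(4, 3, 0.2, seed = 4))
  rt1 <- randomization_test(noise, noise, n_perm = 1, seed = 5)
  expect_true(rt1$p_value %in% c(0, 1))
  expect_error(randomization_test(flat[1:2, 1:2], flat[1:2, 1:2], 10),
               "at least 3")

  # determinism
  rt2 <- randomization_test(m1, m2, n_perm = 200, seed = 3)
  expect_identical(rt$perm_r, rt2$perm_r)
})

test_that("model-rating RSA strengthens as rating noise shrinks", {
  truth <- generate_ground_truth(12, 5, 0.4, seed = 21)
  m_model <- similarity_matrix(truth)
  mean_cor <- vapply(c(2, 0.5, 0.1, 0.01), function(noise) {
    mean(vapply(1:5, function(r) {
      ratings <- withr::with_seed(1000 * r + round(noise * 100), {
        abs(truth + matrix(rnorm(60, 0, noise), 12, 5))
      })
      compare_rsa(m_model, similarity_matrix(ratings))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_cor) > 0))
  expect_gt(mean_cor[4], 0.99)
})
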