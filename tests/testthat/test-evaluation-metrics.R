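test_that("kmeans_cluster separates point clouds and is seed-stable", {
  x <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 100), 10, 2))
  truth <- rep(1:2, each = 10)
  cl <- kmeans_cluster(x, 2, seed = 1)
  expect_equal(adjusted_rand_index(cl$assignments, truth), 1)
  expect_identical(kmeans_cluster(x, 2, seed = 5)$assignments,
                   kmeans_cluster(x, 2, seed = 5)$assignments)

  one <- kmeans_cluster(x, 1, seed = 1)
  expect_equal(one$inertia, sum(scale(x, scale = FALSE)^2))
  expect_error(kmeans_cluster(x, 0), "positive")
  expect_error(kmeans_cluster(x, 21), "exceed")
})

test_that("ARI: identity, trivial-partition zero, and pair-counting oracle", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
  expect_equal(adjusted_rand_index(rep(1, 6), c(1, 2, 3, 1, 2, 3)), 0)
  expect_equal(adjusted_rand_index(c(0, 0, 1, 1), c(0, 1, 1, 1)),
               oracle_ari(c(0, 0, 1, 1), c(0, 1, 1, 1)),
               tolerance = 1e-12)
  expect_error(adjusted_rand_index(1:3, 1:4), "length mismatch")
})

test_that("ARI and NMI are symmetric and label-permutation invariant", {
  set.seed(13)
  for (rep in 1:10) {
    a <- sample(1:3, 12, replace = TRUE)
    b <- sample(1:4, 12, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), adjusted_rand_index(b, a), tolerance = 1e-12)
    expect_equal(normalized_mutual_information(a, b),
                 normalized_mutual_information(b, a), tolerance = 1e-12)
    perm <- c(9, 7, 8)[a]  # relabel
    expect_equal(adjusted_rand_index(perm, b), adjusted_rand_index(a, b), tolerance = 1e-12)
    expect_equal(normalized_mutual_information(perm, b),
                 normalized_mutual_information(a, b), tolerance = 1e-12)
  }
})

test_that("NMI: identity, perfect dependence, independence, variants", {
  expect_equal(normalized_mutual_information(c(1, 1, 2, 2), c(5, 5, 6, 6)), 1)
  # 2x2 diagonal contingency (2,0 / 0,2)
  expect_equal(normalized_mutual_information(c("x", "x", "y", "y"), c(1, 1, 2, 2)), 1)

  # permutation oracle: shuffled labels carry ~no information
  set.seed(17)
  a <- rep(1:4, each = 50)
  vals <- replicate(300, normalized_mutual_information(a, sample(a)))
  expect_lt(mean(vals), 0.05)

  for (v in c("min", "geometric", "max")) {
    out <- normalized_mutual_information(c(1, 1, 2, 2), c(1, 2, 1, 2), variant = v)
    expect_gte(out, 0); expect_lte(out, 1)
  }
})

test_that("silhouette matches the definitional oracle and cluster::silhouette", {
  set.seed(19)
  x <- rbind(matrix(rnorm(10, 0, 1), 5, 2), matrix(rnorm(10, 6, 1), 5, 2))
  cl <- rep(1:2, each = 5)
  ours <- silhouette_coefficient(x, cl)
  expect_equal(ours, oracle_silhouette(x, cl), tolerance = 1e-10)
  skip_if_not_installed("cluster")
  ref <- mean(cluster::silhouette(cl, dist(x))[, "sil_width"])
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("silhouette: separated-limit, random-label null, singleton warning", {
  far <- rbind(matrix(0.001 * rnorm(8), 4, 2),
               matrix(1e6 + 0.001 * rnorm(8), 4, 2))
  expect_gt(silhouette_coefficient(far, rep(1:2, each = 4)), 0.999)

  set.seed(23)
  nulls <- sapply(1:10, function(s) {
    set.seed(s)
    blob <- matrix(rnorm(60), 30, 2)
    silhouette_coefficient(blob, sample(1:2, 30, replace = TRUE))
  })
  expect_lt(abs(mean(nulls)), 0.1)

  expect_warning(s <- silhouette_coefficient(matrix(1:6, 3, 2), c(1, 1, 2)),
                 "singleton")
  expect_error(silhouette_coefficient(matrix(1:6, 3, 2), c(1, 1, 1)), "clusters")
})

test_that("Davies-Bouldin matches its oracle and is duplication-invariant", {
  set.seed(29)
  x <- rbind(matrix(rnorm(6, 0), 3, 2), matrix(rnorm(6, 5), 3, 2))
  cl <- rep(1:2, each = 3)
  ours <- davies_bouldin_index(x, cl)
  expect_equal(ours, oracle_dbi(x, cl), tolerance = 1e-10)
  # doubling every point leaves centroids and scatters unchanged
  expect_equal(davies_bouldin_index(rbind(x, x), c(cl, cl)), ours, tolerance = 1e-10)
  # tight well-separated clusters drive DBI toward zero
  far <- rbind(matrix(0.001 * rnorm(8), 4, 2),
               matrix(1e4 + 0.001 * rnorm(8), 4, 2))
  expect_lt(davies_bouldin_index(far, rep(1:2, each = 4)), 1e-4)
})

test_that("SC and DBI are invariant to translation and rotation", {
  set.seed(31)
  x <- matrix(rnorm(40), 20, 2)
  cl <- rep(1:2, 10)
  theta <- 0.7
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  y <- sweep(x %*% rot, 2, c(13, -4), "+")
  expect_equal(silhouette_coefficient(x, cl), silhouette_coefficient(y, cl),
               tolerance = 1e-10)
  expect_equal(davies_bouldin_index(x, cl), davies_bouldin_index(y, cl),
               tolerance = 1e-10)
})

test_that("corr2 flattens and correlates, with affine invariance", {
  a <- matrix(c(1, 2, 3, 4), 2, 2)
  b <- matrix(c(1, 2, 4, 3), 2, 2)
  expect_equal(corr2(a, a), 1)
  expect_equal(corr2(a, 3 * a + 2), 1)
  expect_equal(corr2(a, b), cor(c(1, 2, 3, 4), c(1, 2, 4, 3)), tolerance = 1e-12)
  expect_error(corr2(a, matrix(1, 3, 2)), "shape")
  expect_error(corr2(a, matrix(5, 2, 2)), "constant")
})

test_that("external indices agree with mclust's ARI on random labelings", {
  skip_if_not_installed("mclust")
  set.seed(37)
  for (rep in 1:10) {
    a <- sample(1:3, 15, replace = TRUE)
    b <- sample(1:3, 15, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-10)
  }
})
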