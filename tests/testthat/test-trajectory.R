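test_that("z-scoring standardises rows and flags constant profiles", {
  z <- zscore_profiles(rbind(a = c(1, 2, 3)))
  expect_equal(unname(z[1, ]), c(-1, 0, 1))

  z <- zscore_profiles(rbind(const = c(5, 5, 5), var = c(0, 2, 4)))
  expect_equal(unname(z["const", ]), c(0, 0, 0))
  expect_true(attr(z, "constant")[["const"]])
  expect_false(attr(z, "constant")[["var"]])

  # affine invariance (positive slope)
  x <- matrix(runif(12), 3)
  expect_equal(zscore_profiles(3.2 * x + 7), zscore_profiles(x),
               ignore_attr = TRUE)
  expect_error(zscore_profiles(matrix(1:3, 3, 1)), "at least 2 groups")
})

test_that("fuzzy c-means separates tight groups and normalises memberships", {
  set.seed(2)
  x <- rbind(matrix(rnorm(40, 0, 0.2), ncol = 2),
             matrix(rnorm(40, 5, 0.2), ncol = 2))
  fit <- fuzzy_cmeans(x, 2, m = 2, seed = 3)
  expect_true(all(apply(fit$memberships, 1, max) > 0.99))
  expect_equal(unname(rowSums(fit$memberships)), rep(1, 40), tolerance = 1e-9)
  expect_true(all(diff(fit$trace) <= 1e-8))
  expect_equal(unname(fit$assignment),
               unname(apply(fit$memberships, 1, which.max)))
})

test_that("fuzzy c-means agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(2)
  x <- rbind(matrix(rnorm(40, 0, 0.2), ncol = 2),
             matrix(rnorm(40, 5, 0.2), ncol = 2))
  fit <- fuzzy_cmeans(x, 2, m = 2, seed = 3)
  ref <- e1071::cmeans(x, 2, m = 2, iter.max = 200)
  perm <- if (sum((fit$centers[1, ] - ref$centers[1, ])^2) <
              sum((fit$centers[1, ] - ref$centers[2, ])^2)) 1:2 else 2:1
  expect_lt(max(abs(fit$centers - ref$centers[perm, ])), 1e-4)
  expect_lt(max(abs(fit$memberships - ref$membership[, perm])), 1e-4)
})

test_that("a point equidistant from two symmetric clusters splits 50/50", {
  x <- matrix(c(-1, -1, -1, 1, 1, 1, 0), ncol = 1)
  fit <- fuzzy_cmeans(x, 2, m = 2, seed = 5)
  expect_equal(unname(fit$memberships[7, ]), c(0.5, 0.5), tolerance = 1e-6)
})

test_that("a profile coinciding with a center takes full membership", {
  x <- matrix(c(0, 0, 0, 10, 10, 10), ncol = 1)  # duplicates collapse centers onto points
  fit <- fuzzy_cmeans(x, 2, m = 2, seed = 1)
  expect_equal(max(fit$memberships[1, ]), 1)
})

test_that("as m -> 1 assignments converge to k-means labels", {
  set.seed(7)
  x <- rbind(matrix(rnorm(30, 0, 0.3), ncol = 2),
             matrix(rnorm(30, 6, 0.3), ncol = 2),
             matrix(rnorm(30, c(0, 6), 0.3), ncol = 2))
  fit <- fuzzy_cmeans(x, 3, m = 1.05, seed = 8)
  km <- kmeans(x, 3, nstart = 10)
  # same partition up to label permutation
  tab <- table(fit$assignment, km$cluster)
  expect_equal(sum(apply(tab, 1, max)), nrow(x))
})

test_that("fuzzy c-means validates k and m", {
  x <- matrix(rnorm(20), ncol = 2)
  expect_error(fuzzy_cmeans(x, 1), "at least 2")
  expect_error(fuzzy_cmeans(x, 11), "distinct profiles")
  expect_error(fuzzy_cmeans(x, 2, m = 1), "m must be > 1")
})

test_that("the elbow criterion picks the planted cluster number", {
  set.seed(9)
  centers <- rbind(c(0, 0), c(6, 0), c(0, 6), c(6, 6))
  x <- do.call(rbind, lapply(1:4, function(i) {
    sweep(matrix(rnorm(40, 0, 0.3), ncol = 2), 2, centers[i, ], "+")
  }))
  sel <- choose_k_elbow(x, 2:8, seed = 10)
  expect_equal(sel$k, 4L)
  expect_true(all(diff(sel$curve$objective) < 1e-6))  # J decreasing in k
  expect_warning(two <- choose_k_elbow(x, 2:3, seed = 10), "too short")
  expect_equal(two$k, 2L)
})

test_that("monotone clusters are selected by direction and membership cutoff", {
  fit <- structure(list(
    k = 2, m = 2,
    centers = rbind(cluster1 = c(0, 1, 2), cluster2 = c(2, 1, 0)),
    memberships = rbind(a = c(0.9, 0.1), b = c(0.55, 0.45), c = c(0.45, 0.55),
                        d = c(0.2, 0.8)),
    assignment = c(a = 1L, b = 1L, c = 2L, d = 2L)
  ), class = "fuzzy_cmeans")
  up <- select_monotone_cluster(fit, "increasing")
  expect_setequal(up, c("a", "b"))
  dn <- select_monotone_cluster(fit, "decreasing", min_membership = 0.6)
  expect_equal(as.character(dn), "d")

  flat <- fit
  flat$centers <- rbind(cluster1 = c(0, 0, 0), cluster2 = c(1, 0, 2))
  expect_warning(none <- select_monotone_cluster(flat, "increasing"), "no strictly")
  expect_length(none, 0)
})

test_that("cohort intersection is exact, normalised and order-invariant", {
  got <- intersect_cohorts(list(c("pro", "ser", "ala"), c("Pro", "gly")))
  expect_equal(as.character(got), "PRO")
  a <- list(c("x", "y", "z"), c("y", "z"), c("z", "y", "q"))
  expect_equal(as.character(intersect_cohorts(a)),
               as.character(intersect_cohorts(rev(a))))
  expect_error(intersect_cohorts(list(c("x"))), "at least 2")
})

test_that("PCoA embeds two points at +/- d/2 and reconstructs planar distances", {
  d <- matrix(c(0, 4, 4, 0), 2)
  emb <- pcoa_embed(d, 1)
  expect_equal(sort(emb$points[, 1]), c(-2, 2))

  set.seed(11)
  pts <- matrix(rnorm(24), ncol = 2)
  D <- as.matrix(dist(pts))
  emb <- pcoa_embed(D, 2)
  expect_lt(max(abs(as.matrix(dist(emb$points)) - D)), 1e-8)
  # trace identity: eigenvalue sum equals the trace of the centred Gram matrix
  n <- nrow(D)
  cm <- diag(n) - matrix(1 / n, n, n)
  expect_equal(sum(emb$eigenvalues), sum(diag(-0.5 * cm %*% D^2 %*% cm)),
               tolerance = 1e-8)
  expect_error(pcoa_embed(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("PCoA agrees with the classical-scaling reference implementation", {
  skip_if_not_installed("ape")
  set.seed(12)
  D <- as.matrix(dist(matrix(rnorm(30), ncol = 3)))
  emb <- pcoa_embed(D, 3)
  ref <- ape::pcoa(D)
  expect_equal(emb$eigenvalues[1:3], ref$values$Eigenvalues[1:3], tolerance = 1e-8)
  expect_equal(abs(emb$points), abs(ref$vectors[, 1:3]), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("PERMANOVA reproduces the reference pseudo-F and R2", {
  skip_if_not_installed("vegan")
  set.seed(13)
  y <- matrix(rnorm(36), ncol = 3)
  g <- rep(c("a", "b", "c"), each = 4)
  got <- permanova(dist(y), g, n_permutations = 99, seed = 1)
  ref <- vegan::adonis2(dist(y) ~ g, permutations = 99)
  expect_equal(got$F, ref$F[1], tolerance = 1e-10)
  expect_equal(got$R2, ref$R2[1], tolerance = 1e-10)
})

test_that("PERMANOVA limits: duplicated far-apart groups give minimal p, R2 ~ 1", {
  x <- rbind(matrix(0, 6, 2), matrix(100, 6, 2))
  g <- rep(c("a", "b"), each = 6)
  r <- permanova(dist(x), g, n_permutations = 199, seed = 3)
  expect_equal(r$p_value, 1 / 200)
  expect_gt(r$R2, 0.999)
})

test_that("observed F is invariant to relabeling within groups and R2 is bounded", {
  set.seed(14)
  y <- matrix(rnorm(30), ncol = 3)
  g <- rep(c("a", "b"), each = 5)
  r1 <- permanova(dist(y), g, n_permutations = 49, seed = 1)
  idx <- c(sample(1:5), sample(6:10))
  r2 <- permanova(as.matrix(dist(y))[idx, idx], g, n_permutations = 49, seed = 1)
  expect_equal(r1$F, r2$F)
  expect_true(r1$R2 >= 0 && r1$R2 <= 1)
  expect_error(permanova(dist(y), c(rep("a", 9), "b"), 49), "at least 2 members")
})
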