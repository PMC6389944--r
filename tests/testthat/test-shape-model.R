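test_that("fit_shape_pca recovers exact low-rank structure", {
  set.seed(11)
  # 90-D vectors lying in a 2-D affine subspace
  basis2 <- qr.Q(qr(matrix(rnorm(90 * 2), 90, 2)))
  x <- matrix(rnorm(40 * 2), 40, 2) %*% t(basis2) +
    matrix(rnorm(90), 40, 90, byrow = TRUE)
  model <- fit_shape_pca(x, variance_target = 0.95)
  expect_identical(model$n_components, 2L)
  expect_identical(sum(model$all_eigenvalues > 1e-10), 2L)

  expect_error(fit_shape_pca(matrix(1, 10, 6)), "zero variance")
})

test_that("fit_shape_pca matches a dense covariance eigendecomposition", {
  set.seed(21)
  x <- matrix(rnorm(5 * 6), 5, 6)
  model <- fit_shape_pca(x, variance_target = 1)
  oracle <- brute_pca(x)
  k <- model$n_components
  expect_equal(model$eigenvalues, oracle$values[seq_len(k)], tolerance = 1e-8)
  expect_equal(model$mean_vector, oracle$mean, tolerance = 1e-12,
               ignore_attr = TRUE)
  for (j in seq_len(k)) {     # eigenvectors agree up to sign
    expect_equal(abs(sum(model$basis[j, ] * oracle$vectors[, j])), 1,
                 tolerance = 1e-8)
  }
  # orthonormality invariant
  G <- model$basis %*% t(model$basis)
  expect_equal(G, diag(k), tolerance = 1e-8, ignore_attr = TRUE)
  # sign convention: largest-|element| positive
  for (j in seq_len(k)) {
    expect_gt(model$basis[j, which.max(abs(model$basis[j, ]))], 0)
  }
})

test_that("full-variance basis reconstructs training vectors exactly", {
  set.seed(31)
  x <- matrix(rnorm(12 * 9), 12, 9)
  model <- fit_shape_pca(x, variance_target = 1)
  expect_gte(model$variance_retained, 1 - 1e-12)
  rec <- reconstruct(model, project(model, x))
  expect_lt(max(abs(rec - x)), 1e-8)
})

test_that("project obeys orthonormal basis identities", {
  set.seed(41)
  x <- matrix(rnorm(30 * 12), 30, 12)
  model <- fit_shape_pca(x, variance_target = 0.9)
  expect_equal(project(model, model$mean_vector),
               rep(0, model$n_components), tolerance = 1e-10,
               ignore_attr = TRUE)
  v <- model$mean_vector + 2 * model$basis[1, ]
  w <- project(model, v)
  expect_equal(w, c(2, rep(0, model$n_components - 1)), tolerance = 1e-8,
               ignore_attr = TRUE)
  # average squared reconstruction error ~ discarded eigenvalue mass
  rec <- reconstruct(model, project(model, x))
  mse <- mean(rowSums((x - rec)^2))
  tail_mass <- sum(model$all_eigenvalues) - sum(model$eigenvalues)
  expect_equal(mse, tail_mass * (nrow(x) - 1) / nrow(x), tolerance = 1e-6)
  expect_error(project(model, rnorm(5)), "does not match")
})

test_that("cluster_weights is deterministic, exact on separated blobs, and a Lloyd fixed point", {
  set.seed(51)
  blob1 <- matrix(rnorm(25 * 3, 0, 1), 25, 3)
  blob2 <- matrix(rnorm(25 * 3, 0, 1), 25, 3) + 20   # 10+ sigma separation
  x <- rbind(blob1, blob2)
  cm <- cluster_weights(x, K = 2, seed = 5)
  ids <- assign_clusters(cm, x)
  expect_identical(length(unique(ids[1:25])), 1L)
  expect_identical(length(unique(ids[26:50])), 1L)
  expect_false(ids[1] == ids[26])

  # determinism
  cm2 <- cluster_weights(x, K = 2, seed = 5)
  expect_identical(cm$centroids, cm2$centroids)

  # oracle: the returned solution is a fixed point of brute-force Lloyd
  # iterations started from the returned centroids, with equal inertia
  oracle <- brute_lloyd(x, cm$centroids)
  expect_lt(max(abs(oracle$centers - cm$centroids)), 1e-8)
  expect_equal(oracle$inertia, cm$inertia, tolerance = 1e-8)

  # K = number of distinct points: zero inertia
  pts <- matrix(seq_len(12), 4, 3)
  cm0 <- cluster_weights(pts, K = 4, seed = 1)
  expect_equal(cm0$inertia, 0)

  expect_error(cluster_weights(pts, K = 10, seed = 1), "choose K")
})

test_that("membership_histogram counts and normalises", {
  expect_equal(membership_histogram(rep(4, 10), K = 5), c(0, 0, 0, 10, 0))
  expect_equal(membership_histogram(integer(0), K = 3), c(0, 0, 0))
  set.seed(61)
  h <- membership_histogram(sample.int(6, 40, replace = TRUE), K = 6,
                            normalise = TRUE)
  expect_equal(sum(h), 1, tolerance = 1e-12)
  expect_error(membership_histogram(c(1, 7), K = 6), "\\[1, K\\]")
})

test_that("segmentation assigns >= 95% of synthetic bundle streamlines correctly", {
  fix <- three_bundle_set(seed = 2, n_streamlines = 10)
  feats <- streamlines_to_features(fix$streamlines, 30)
  model <- fit_shape_pca(feats, 0.95, n_components = 7)
  w <- project(model, feats)
  cm <- cluster_weights(w, K = 30, seed = 3)
  cm <- train_bundle_map(cm, w, fix$labels)

  tg <- tractogram(fix$streamlines)
  seg <- segment_bundles(tg, model, cm)
  acc <- mean(seg$bundle_labels == fix$labels)
  expect_gte(acc, 0.95)

  # cluster with no training label stays unassigned
  cm_partial <- train_bundle_map(cm, w[fix$labels != "cc_body", ],
                                 fix$labels[fix$labels != "cc_body"])
  lone <- which(fix$labels == "cc_body")[1]
  seg2 <- segment_bundles(tractogram(fix$streamlines[lone]), model, cm_partial)
  expect_true(seg2$bundle_labels %in% c("unassigned", setdiff(bundle_vocabulary(), "cc_body")))

  # empty map errors
  cm_empty <- cm; cm_empty$cluster_to_bundle <- rep("unassigned", cm$K)
  expect_error(segment_bundles(tg, model, cm_empty), "empty")
})

test_that("shape descriptors are bundle-mean weights with a sign symmetry", {
  set.seed(71)
  x <- matrix(rnorm(60 * 12), 60, 12)
  model <- fit_shape_pca(x, 0.9)
  m <- model$n_components

  # streamlines at the model mean project to zero descriptors
  w0 <- project(model, matrix(model$mean_vector, 6, 12, byrow = TRUE))
  d0 <- shape_descriptors(w0, rep("cc_body", 6), bundles = "cc_body",
                          min_streamlines = 5)
  expect_equal(unname(d0$descriptors["cc_body", ]), rep(0, m),
               tolerance = 1e-10)

  # below the minimum count the descriptor is missing, not zero
  d1 <- shape_descriptors(w0[1:3, ], rep("cc_body", 3), bundles = "cc_body",
                          min_streamlines = 5)
  expect_true(all(is.na(d1$descriptors["cc_body", ])))

  # flipping one eigenvector flips exactly that descriptor
  w <- project(model, x[1:10, ])
  d <- shape_descriptors(w, rep("fornix_l", 10), bundles = "fornix_l",
                         min_streamlines = 5)
  flipped <- model; flipped$basis[2, ] <- -flipped$basis[2, ]
  wf <- project(flipped, x[1:10, ])
  df <- shape_descriptors(wf, rep("fornix_l", 10), bundles = "fornix_l",
                          min_streamlines = 5)
  expect_equal(df$descriptors[1, 2], -d$descriptors[1, 2], tolerance = 1e-10)
  expect_equal(df$descriptors[1, -2], d$descriptors[1, -2], tolerance = 1e-10)
})

test_that("a cingulum-like descriptor tracks arc amplitude monotonically", {
  amplitudes <- seq(2, 10, by = 2)
  streams <- list(); amp_of <- numeric(0)
  for (a in amplitudes) {
    base <- bundle_template("cingulum_dorsal_l", 60, amplitude = a)
    for (i in 1:6) {
      set.seed(1000 + round(a) * 10 + i)
      streams <- c(streams, list(base + matrix(rnorm(180, 0, 0.3), 60, 3)))
      amp_of <- c(amp_of, a)
    }
  }
  feats <- streamlines_to_features(streams, 30)
  model <- fit_shape_pca(feats, 0.95, max_components = 7)
  w <- project(model, feats)
  cors <- abs(stats::cor(w, amp_of))
  j <- which.max(cors)
  # the best-correlated weight is monotone in amplitude up to a global sign
  expect_gt(abs(stats::cor(w[, j], amp_of, method = "spearman")), 0.95)
  means <- tapply(w[, j], amp_of, mean)
  expect_true(all(diff(means) > 0) || all(diff(means) < 0))
})
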