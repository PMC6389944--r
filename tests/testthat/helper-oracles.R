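# Independent brute-force oracles and small fixtures shared across tests.
# Each oracle is written from the defining formula, independently of the
# package code paths it checks.

# dense eigendecomposition of the sample covariance
brute_pca <- function(x) {
  S <- stats::cov(x)
  e <- eigen(S, symmetric = TRUE)
  list(values = e$values, vectors = e$vectors, mean = colMeans(x))
}

# plain Lloyd iterations from a fixed set of initial centers
brute_lloyd <- function(x, centers, iter_max = 200) {
  for (it in seq_len(iter_max)) {
    d2 <- outer(rowSums(x^2), rep(1, nrow(centers))) - 2 * x %*% t(centers) +
      outer(rep(1, nrow(x)), rowSums(centers^2))
    assign <- max.col(-d2, ties.method = "first")
    new_centers <- centers
    for (k in seq_len(nrow(centers))) {
      if (any(assign == k)) new_centers[k, ] <- colMeans(x[assign == k, , drop = FALSE])
    }
    if (max(abs(new_centers - centers)) < 1e-12) break
    centers <- new_centers
  }
  inertia <- sum((x - centers[assign, , drop = FALSE])^2)
  list(centers = centers, assign = assign, inertia = inertia)
}

# OLS coefficient, SE and t for the last column of X via normal equations
brute_ols_t <- function(y, X) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  sigma2 <- sum(res^2) / (length(y) - ncol(X))
  covb <- sigma2 * solve(XtX)
  j <- ncol(X)
  list(beta = beta[j], se = sqrt(covb[j, j]), t = beta[j] / sqrt(covb[j, j]))
}

# Spearman rho as rank-then-Pearson, written out in full
brute_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# planar semicircle of radius r sampled at n points
semicircle <- function(r = 10, n = 500) {
  th <- seq(0, pi, length.out = n)
  cbind(r * cos(th), r * sin(th), 0)
}

# default synthetic cohort (21 carriers, 15 controls)
default_cohort <- function(seed = 1L) {
  build_cohort(simulation_design(seed = seed))
}

# three-bundle labelled streamline set for segmentation tests
three_bundle_set <- function(seed = 1L, n_streamlines = 20L) {
  design <- simulation_design(seed = seed, n_streamlines = n_streamlines)
  cohort <- build_cohort(design, seed)
  sets <- lapply(seq_len(nrow(cohort)), function(i) {
    lapply(design$bundles, function(b) {
      simulate_bundle(b, cohort[i, ], design, seed)
    })
  })
  streamlines <- unlist(lapply(sets, function(s) do.call(c, s)), recursive = FALSE)
  labels <- unlist(lapply(sets, function(s) {
    rep(vapply(s, attr, "", "bundle_label"), vapply(s, length, integer(1)))
  }))
  list(streamlines = streamlines, labels = labels, design = design,
       cohort = cohort)
}
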