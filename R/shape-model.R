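## Shape basis learning and streamline clustering.
##
## Centred streamline feature vectors are decomposed by PCA into a small set
## of orthonormal shape basis functions; each streamline is then represented
## by its projection weights, weight space is partitioned by k-means, and
## clusters carry bundle labels learned from a labelled reference set.

#' The 19-bundle label vocabulary
#'
#' Bilateral arcuate, uncinate, inferior/superior longitudinal and
#' fronto-occipital fasciculi, dorsal and parahippocampal cingulum, fornix
#' branches, and the splenium, body and genu of the corpus callosum.
#'
#' @return Character vector of 19 bundle labels.
#' @export
bundle_vocabulary <- function() {
  c("arcuate_l", "arcuate_r",
    "uncinate_l", "uncinate_r",
    "ilf_l", "ilf_r",
    "slf_l", "slf_r",
    "ifof_l", "ifof_r",
    "cingulum_dorsal_l", "cingulum_dorsal_r",
    "cingulum_parahippocampal_l", "cingulum_parahippocampal_r",
    "fornix_l", "fornix_r",
    "cc_splenium", "cc_body", "cc_genu")
}

#' Fit a PCA shape basis to streamline feature vectors
#'
#' Eigendecomposition of the sample covariance of the feature vectors. The
#' number of retained components is the smallest m whose cumulative explained
#' variance reaches `variance_target`. Each retained eigenvector's sign is
#' fixed so that its largest-magnitude element is positive, making fits
#' comparable across runs (descriptor signs are otherwise arbitrary).
#'
#' @param vectors Matrix with one feature vector per row (or list of vectors).
#' @param variance_target Fraction of variance to retain (default 0.95).
#' @param max_components Optional cap on m.
#' @param n_components Optional fixed number of components; overrides the
#'   variance criterion (the study design fixes the first seven).
#' @return An object of class `shape_model` with elements `mean_vector`,
#'   `basis` (m x d, orthonormal rows), `eigenvalues` (retained, descending),
#'   `all_eigenvalues`, `variance_retained`, `n_components`, `total_variance`.
#' @export
fit_shape_pca <- function(vectors, variance_target = 0.95,
                          max_components = NULL, n_components = NULL) {
  x <- if (is.list(vectors)) do.call(rbind, vectors) else as.matrix(vectors)
  if (nrow(x) < 2L) stop("need at least 2 feature vectors")
  if (!all(is.finite(x))) stop("feature vectors must be finite")
  if (variance_target <= 0 || variance_target > 1) {
    stop("variance_target must be in (0, 1]")
  }
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pmax(pr$sdev^2, 0)
  total <- sum(ev)
  if (total < 1e-24) stop("zero variance: all feature vectors are identical")
  cum <- cumsum(ev) / total
  if (!is.null(n_components)) {
    m <- min(n_components, length(ev))
  } else {
    m <- which(cum >= variance_target - 1e-12)[1]
    if (is.na(m)) m <- length(ev)
    if (!is.null(max_components)) m <- min(m, max_components)
  }
  basis <- t(pr$rotation[, seq_len(m), drop = FALSE])
  for (j in seq_len(m)) {
    k <- which.max(abs(basis[j, ]))
    if (basis[j, k] < 0) basis[j, ] <- -basis[j, ]
  }
  structure(
    list(mean_vector = pr$center,
         basis = basis,
         eigenvalues = ev[seq_len(m)],
         all_eigenvalues = ev,
         variance_retained = cum[m],
         n_components = m,
         total_variance = total),
    class = "shape_model"
  )
}

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf("shape_model: %d components over %d dims, %.1f%% variance retained\n",
              x$n_components, length(x$mean_vector), 100 * x$variance_retained))
  invisible(x)
}

#' Project feature vectors onto a shape basis
#'
#' @param model A [fit_shape_pca()] result.
#' @param v A feature vector, or a matrix with one vector per row.
#' @return Weight vector of length m, or an n x m weight matrix.
#' @export
project <- function(model, v) {
  stopifnot(inherits(model, "shape_model"))
  single <- is.null(dim(v))
  x <- if (single) matrix(v, nrow = 1L) else as.matrix(v)
  if (ncol(x) != length(model$mean_vector)) {
    stop(sprintf("feature length %d does not match model dimension %d",
                 ncol(x), length(model$mean_vector)))
  }
  w <- sweep(x, 2L, model$mean_vector) %*% t(model$basis)
  if (single) drop(w) else w
}

#' Reconstruct feature vectors from shape-basis weights
#'
#' @param model A [fit_shape_pca()] result.
#' @param w Weight vector (length m) or n x m matrix.
#' @return Feature vector(s) `mean + w %*% basis`.
#' @export
reconstruct <- function(model, w) {
  stopifnot(inherits(model, "shape_model"))
  single <- is.null(dim(w))
  wm <- if (single) matrix(w, nrow = 1L) else as.matrix(w)
  x <- sweep(wm %*% model$basis, 2L, model$mean_vector, "+")
  if (single) drop(x) else x
}

## ---- k-means ----------------------------------------------------------------

kmeanspp_init <- function(x, K) {
  n <- nrow(x)
  idx <- integer(K)
  idx[1] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(x, 2L, x[idx[1], ])^2)
  for (j in seq_len(K - 1L)) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx[j + 1L] <- sample.int(n, 1L, prob = p)
    d2 <- pmin(d2, rowSums(sweep(x, 2L, x[idx[j + 1L], ])^2))
  }
  x[idx, , drop = FALSE]
}

#' Cluster projection weights with k-means
#'
#' k-means++ initialisation with `n_restarts` restarts (best within-cluster
#' sum of squares kept), Lloyd iterations, deterministic for a given seed.
#'
#' @param weights n x m weight matrix (n >= K).
#' @param K Number of clusters (study setting 800; scale down for small n).
#' @param seed Integer seed.
#' @param n_restarts Number of k-means++ restarts (default 10).
#' @param iter_max Lloyd iteration cap per restart.
#' @return Object of class `cluster_model` with `centroids` (K x m),
#'   `cluster_to_bundle` (length-K character, initially all "unassigned"),
#'   `inertia`, `K`, `seed`.
#' @export
cluster_weights <- function(weights, K = 800L, seed = 1L, n_restarts = 10L,
                            iter_max = 100L) {
  x <- as.matrix(weights)
  if (nrow(x) < K) {
    stop(sprintf("fewer weight vectors (%d) than clusters (K = %d); choose K <= %d",
                 nrow(x), K, nrow(x)))
  }
  if (K < 1L) stop("K must be at least 1")
  best <- NULL
  for (r in seq_len(n_restarts)) {
    km <- with_seed(derive_seed(seed, "kmeans", r), {
      centers <- kmeanspp_init(x, K)
      tryCatch(
        suppressWarnings(stats::kmeans(x, centers = centers,
                                       iter.max = iter_max,
                                       algorithm = "Lloyd")),
        error = function(e) NULL
      )
    })
    if (!is.null(km) && (is.null(best) || km$tot.withinss < best$tot.withinss)) {
      best <- km
    }
  }
  if (is.null(best)) stop("k-means failed for every restart")
  structure(
    list(centroids = unname(best$centers),
         cluster_to_bundle = rep("unassigned", K),
         inertia = best$tot.withinss,
         K = as.integer(K),
         seed = as.integer(seed)),
    class = "cluster_model"
  )
}

#' Assign weight vectors to their nearest cluster centroid
#'
#' @param clusters A [cluster_weights()] model.
#' @param weights n x m weight matrix.
#' @return Integer vector of 1-based cluster ids in `[1, K]`.
#' @export
assign_clusters <- function(clusters, weights) {
  stopifnot(inherits(clusters, "cluster_model"))
  w <- as.matrix(weights)
  C <- clusters$centroids
  d2 <- outer(rowSums(w^2), rep(1, nrow(C))) - 2 * (w %*% t(C)) +
    outer(rep(1, nrow(w)), rowSums(C^2))
  max.col(-d2, ties.method = "first")
}

#' Histogram of cluster membership for one subject's streamlines
#'
#' @param assignments Integer cluster ids in `[1, K]`.
#' @param K Number of clusters.
#' @param normalise If `TRUE`, entries sum to 1 (zero vector stays zero).
#' @return Numeric vector of length K.
#' @export
membership_histogram <- function(assignments, K, normalise = FALSE) {
  if (length(assignments) &&
      (any(assignments < 1L) || any(assignments > K))) {
    stop("cluster ids must lie in [1, K]")
  }
  h <- tabulate(assignments, nbins = K)
  if (normalise && sum(h) > 0) h <- h / sum(h)
  as.numeric(h)
}

#' Learn the cluster-to-bundle label map from a labelled reference set
#'
#' Each cluster takes the majority bundle label among the labelled
#' streamlines assigned to it (ties broken alphabetically); clusters with no
#' labelled members stay "unassigned".
#'
#' @param clusters A [cluster_weights()] model.
#' @param weights Weight matrix of the labelled reference streamlines.
#' @param labels Character bundle labels, one per row of `weights`; must come
#'   from [bundle_vocabulary()].
#' @return The cluster model with `cluster_to_bundle` populated.
#' @export
train_bundle_map <- function(clusters, weights, labels) {
  stopifnot(inherits(clusters, "cluster_model"))
  labels <- as.character(labels)
  if (nrow(as.matrix(weights)) != length(labels)) {
    stop("one label per weight vector required")
  }
  bad <- setdiff(unique(labels), bundle_vocabulary())
  if (length(bad)) {
    stop("labels outside the bundle vocabulary: ", paste(bad, collapse = ", "))
  }
  ids <- assign_clusters(clusters, weights)
  map <- rep("unassigned", clusters$K)
  for (k in unique(ids)) {
    tab <- sort(table(labels[ids == k]), decreasing = TRUE)
    top <- names(tab)[tab == max(tab)]
    map[k] <- sort(top)[1]
  }
  clusters$cluster_to_bundle <- map
  clusters
}

#' Segment a tractogram into labelled bundles
#'
#' Every streamline is re-parameterised, canonically oriented, projected onto
#' the shape basis, assigned to its nearest cluster centroid, and given that
#' cluster's bundle label.
#'
#' @param tract A [tractogram()].
#' @param model A [fit_shape_pca()] shape model.
#' @param clusters A [cluster_weights()] model whose `cluster_to_bundle` map
#'   has been populated with [train_bundle_map()].
#' @param n_knots Knots per streamline (default 30, matching the model).
#' @return The tractogram with `bundle_labels` filled in; cluster ids are
#'   attached as attribute `"cluster_ids"`.
#' @export
segment_bundles <- function(tract, model, clusters, n_knots = 30L) {
  stopifnot(inherits(tract, "tractogram"), inherits(model, "shape_model"),
            inherits(clusters, "cluster_model"))
  if (all(clusters$cluster_to_bundle == "unassigned")) {
    stop("cluster_to_bundle map is empty; train it with train_bundle_map()")
  }
  if (length(tract$streamlines) == 0L) {
    tract$bundle_labels <- character(0)
    return(tract)
  }
  feats <- streamlines_to_features(tract$streamlines, n_knots)
  ids <- assign_clusters(clusters, project(model, feats))
  tract$bundle_labels <- clusters$cluster_to_bundle[ids]
  attr(tract, "cluster_ids") <- ids
  tract
}

#' Per-bundle shape descriptors: mean projection weight per component
#'
#' For each bundle, descriptor j is the mean over the bundle's streamlines of
#' projection weight j. Bundles with fewer than `min_streamlines` members get
#' missing (`NA`) descriptors rather than zeros. Descriptor signs follow the
#' eigenvector sign convention of the model and are otherwise arbitrary.
#'
#' @param weights n x m weight matrix for one subject's streamlines.
#' @param labels Bundle label per streamline.
#' @param bundles Bundle vocabulary to report (default [bundle_vocabulary()]).
#' @param min_streamlines Minimum members for a defined descriptor (default 5).
#' @return List of class `bundle_shape_descriptors` with `descriptors`
#'   (bundles x m matrix, `NA` rows where undefined) and `n_streamlines`.
#' @export
shape_descriptors <- function(weights, labels, bundles = bundle_vocabulary(),
                              min_streamlines = 5L) {
  w <- as.matrix(weights)
  labels <- as.character(labels)
  if (nrow(w) != length(labels)) stop("one label per weight vector required")
  m <- ncol(w)
  desc <- matrix(NA_real_, nrow = length(bundles), ncol = m,
                 dimnames = list(bundles, paste0("c", seq_len(m))))
  counts <- stats::setNames(integer(length(bundles)), bundles)
  for (b in bundles) {
    rows <- which(labels == b)
    counts[b] <- length(rows)
    if (length(rows) >= min_streamlines) {
      desc[b, ] <- colMeans(w[rows, , drop = FALSE])
    }
  }
  structure(list(descriptors = desc, n_streamlines = counts,
                 min_streamlines = as.integer(min_streamlines)),
            class = "bundle_shape_descriptors")
}
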