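## Streamline and tractogram data model.
##
## A streamline is an ordered polyline through white matter, represented as a
## plain numeric n x 3 matrix of coordinates in mm ("world" space). A
## tractogram collects the streamlines of one subject together with the 4x4
## voxel-to-mm affine of the space they live in. Voxel indices are 0-based
## throughout and the affine maps voxel *centres* to mm, the NIfTI convention.

#' Construct and validate a streamline
#'
#' @param points Numeric matrix with one row per point and columns x, y, z
#'   (mm). At least two rows; consecutive rows must differ; all finite.
#' @param bundle_label Optional bundle name attached as an attribute.
#' @return The validated point matrix (class `streamline`).
#' @export
streamline <- function(points, bundle_label = NULL) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) stop("streamline points must have 3 columns (x, y, z)")
  if (nrow(points) < 2L) stop("a streamline needs at least 2 points")
  if (!all(is.finite(points))) stop("streamline coordinates must all be finite")
  seg <- rowSums((points[-1L, , drop = FALSE] - points[-nrow(points), , drop = FALSE])^2)
  if (any(seg == 0)) stop("consecutive streamline points must not be identical")
  if (!is.null(bundle_label)) attr(points, "bundle_label") <- bundle_label
  class(points) <- c("streamline", class(points))
  points
}

#' Construct a tractogram
#'
#' @param streamlines List of n x 3 point matrices (mm, one shared space).
#' @param affine 4x4 voxel-to-mm transform of that space (invertible).
#' @param subject_id Subject identifier.
#' @param bundle_labels Optional character vector, one label per streamline.
#' @return An object of class `tractogram`.
#' @export
tractogram <- function(streamlines, affine = diag(4), subject_id = NA_character_,
                       bundle_labels = NULL) {
  check_affine(affine)
  if (!is.list(streamlines)) stop("streamlines must be a list of point matrices")
  streamlines <- lapply(streamlines, function(s) {
    s <- as.matrix(s)
    storage.mode(s) <- "double"
    s
  })
  if (!is.null(bundle_labels) && length(bundle_labels) != length(streamlines)) {
    stop("bundle_labels must have one entry per streamline")
  }
  structure(
    list(streamlines = streamlines, affine = affine,
         subject_id = subject_id, bundle_labels = bundle_labels),
    class = "tractogram"
  )
}

#' @export
print.tractogram <- function(x, ...) {
  npts <- vapply(x$streamlines, nrow, integer(1))
  cat("tractogram:", length(x$streamlines), "streamlines",
      if (length(npts)) sprintf("(%d-%d points)", min(npts), max(npts)) else "",
      "\n subject:", x$subject_id, "\n")
  invisible(x)
}

#' @export
length.tractogram <- function(x) length(x$streamlines)

#' Apply a 4x4 affine transform to every point of a tractogram or streamline
#'
#' Used to map subject tractograms into a common template space, preserving
#' streamline shape while removing positional/orientational variance.
#'
#' @param x A `tractogram` or an n x 3 point matrix.
#' @param A Invertible 4x4 homogeneous transform.
#' @return Object of the same type with transformed coordinates; for a
#'   tractogram the stored voxel-to-mm affine is updated to `A %*% affine`.
#' @export
apply_affine <- function(x, A) {
  check_affine(A)
  UseMethod("apply_affine")
}

#' @export
apply_affine.tractogram <- function(x, A) {
  x$streamlines <- lapply(x$streamlines, function(s) transform_points(A, s))
  x$affine <- A %*% x$affine
  x
}

#' @export
apply_affine.default <- function(x, A) {
  transform_points(A, as.matrix(x))
}

#' Re-parameterise a streamline to equally spaced knots along a cubic spline
#'
#' A natural cubic spline is fitted through the input points (chord-length
#' parameterisation, one spline per coordinate), arc length is measured on a
#' 10x-oversampled polyline along the spline, and `n_knots` points are placed
#' at equal arc-length spacing. Endpoints are preserved.
#'
#' @param s n x 3 point matrix (n >= 2).
#' @param n_knots Number of output knots (default 30).
#' @return `n_knots` x 3 matrix of re-parameterised points.
#' @export
reparameterize <- function(s, n_knots = 30L) {
  s <- as.matrix(s)
  if (nrow(s) < 2L) stop("streamline needs at least 2 points")
  if (n_knots < 2L) stop("n_knots must be at least 2")
  seg <- sqrt(rowSums((s[-1L, , drop = FALSE] - s[-nrow(s), , drop = FALSE])^2))
  total <- sum(seg)
  if (!is.finite(total) || total <= 0) {
    stop("degenerate zero-length streamline cannot be re-parameterised")
  }
  keep <- c(TRUE, seg > 0)          # collapse any coincident consecutive points
  s <- s[keep, , drop = FALSE]
  t0 <- c(0, cumsum(seg[seg > 0]))
  if (nrow(s) == 2L) {
    u <- seq(0, 1, length.out = n_knots)
    return(outer(1 - u, s[1L, ]) + outer(u, s[2L, ]))
  }
  fx <- stats::splinefun(t0, s[, 1], method = "natural")
  fy <- stats::splinefun(t0, s[, 2], method = "natural")
  fz <- stats::splinefun(t0, s[, 3], method = "natural")
  tf <- seq(0, t0[length(t0)], length.out = max(10L * nrow(s), 10L * n_knots))
  fine <- cbind(fx(tf), fy(tf), fz(tf))
  darc <- sqrt(rowSums((fine[-1L, ] - fine[-nrow(fine), ])^2))
  arc <- c(0, cumsum(darc))
  targets <- seq(0, arc[length(arc)], length.out = n_knots)
  tq <- stats::approx(arc, tf, xout = targets, ties = "ordered")$y
  out <- cbind(fx(tq), fy(tq), fz(tq))
  out[1L, ] <- s[1L, ]
  out[n_knots, ] <- s[nrow(s), ]
  dimnames(out) <- NULL
  out
}

#' Canonically orient a streamline along a reference axis
#'
#' The streamline is reversed iff its endpoint displacement projects
#' negatively on the reference axis. Displacements orthogonal to the axis are
#' tie-broken by a fixed axis priority list (default: anterior y, then
#' superior z, then left-right x), so the output orientation is deterministic.
#'
#' @param s n x 3 point matrix.
#' @param reference_axis Unit 3-vector (default anterior `c(0, 1, 0)`).
#' @return The streamline, possibly reversed.
#' @export
canonical_orient <- function(s, reference_axis = c(0, 1, 0)) {
  s <- as.matrix(s)
  if (nrow(s) < 2L) stop("streamline needs at least 2 points")
  d <- s[nrow(s), ] - s[1L, ]
  if (all(d == 0)) stop("degenerate streamline: identical endpoints")
  axes <- rbind(reference_axis, c(0, 0, 1), c(1, 0, 0), c(0, 1, 0))
  for (i in seq_len(nrow(axes))) {
    dp <- sum(d * axes[i, ])
    if (dp != 0) {
      return(if (dp < 0) s[rev(seq_len(nrow(s))), , drop = FALSE] else s)
    }
  }
  s
}

#' Reduce a re-parameterised streamline to a centred shape feature vector
#'
#' The point centroid is subtracted (translation invariance) and coordinates
#' are concatenated knot-major: `(x1, y1, z1, x2, y2, z2, ...)`, giving a
#' vector of length `3 * n_knots`.
#'
#' @param s `n_knots` x 3 point matrix, already re-parameterised and
#'   canonically oriented.
#' @param n_knots Expected number of knots (defaults to `nrow(s)`).
#' @return Numeric vector of length `3 * n_knots`.
#' @export
to_feature_vector <- function(s, n_knots = nrow(s)) {
  s <- as.matrix(s)
  if (nrow(s) != n_knots) {
    stop(sprintf("streamline has %d points but n_knots = %d", nrow(s), n_knots))
  }
  centred <- sweep(s, 2L, colMeans(s))
  as.vector(t(centred))
}

#' Rebuild the n x 3 point matrix encoded by a shape feature vector
#' @param v Numeric vector of length `3 * n_knots` (knot-major order).
#' @return Matrix with `length(v) / 3` rows.
#' @export
feature_to_points <- function(v) {
  if (length(v) %% 3L != 0L) stop("feature vector length must be a multiple of 3")
  matrix(v, ncol = 3L, byrow = TRUE)
}

#' Full per-streamline preprocessing: re-parameterise, orient, vectorise
#'
#' @param streamlines List of point matrices.
#' @param n_knots Knots per streamline (default 30).
#' @param reference_axis Orientation axis passed to [canonical_orient()].
#' @return Matrix with one row per streamline and `3 * n_knots` columns.
#' @export
streamlines_to_features <- function(streamlines, n_knots = 30L,
                                    reference_axis = c(0, 1, 0)) {
  feats <- vapply(streamlines, function(s) {
    to_feature_vector(canonical_orient(reparameterize(s, n_knots), reference_axis),
                      n_knots)
  }, numeric(3L * n_knots))
  t(feats)
}
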