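## Tractometry: bundle volume from voxel traversal and per-bundle median
## sampling of scalar microstructure maps, plus assembly of the
## subjects x imaging-variables feature matrix.

## physical ranges used to validate scalar maps, by metric
metric_ranges <- function() {
  list(FA   = c(0, 1),
       MD   = c(0, 0.02),   # mm^2/s, generous upper bound (free water ~3e-3)
       AD   = c(0, 0.02),
       RD   = c(0, 0.02),
       R1   = c(0, 10),     # 1/s scale for qMRI R1 maps
       T1   = c(0, 10),     # s
       ICVF = c(0, 1),
       ISOF = c(0, 1),
       ODI  = c(0, 1))
}

#' Default microstructural metric list
#'
#' Nine metrics: FA, MD, AD, RD from the diffusion tensor; R1 and T1 from
#' relaxometry; ICVF, ISOF, ODI from the NODDI tissue model. Together with
#' bundle volume this gives the 10 variables per bundle of the default
#' configuration.
#' @return Character vector of metric names.
#' @export
default_metrics <- function() {
  c("FA", "MD", "AD", "RD", "R1", "T1", "ICVF", "ISOF", "ODI")
}

## metrics whose maps derive from the diffusion acquisition (motion covariate)
diffusion_metrics <- function() c("FA", "MD", "AD", "RD", "ICVF", "ISOF", "ODI")

#' Construct a scalar volume (3-D map plus voxel-to-mm affine)
#'
#' @param grid 3-D numeric array.
#' @param affine Invertible 4x4 voxel-to-mm transform (0-based voxel centres).
#' @param metric_name Metric identifier (e.g. "FA", "ICVF"); known metrics
#'   are range-checked against their physical range.
#' @return Object of class `scalar_volume`.
#' @export
scalar_volume <- function(grid, affine, metric_name = "scalar") {
  if (length(dim(grid)) != 3L) stop("grid must be a 3-D array")
  check_affine(affine)
  if (!all(is.finite(grid))) stop("scalar map contains non-finite values")
  rng <- metric_ranges()[[metric_name]]
  if (!is.null(rng) && (min(grid) < rng[1] - 1e-9 || max(grid) > rng[2] + 1e-9)) {
    stop(sprintf("%s values outside physical range [%g, %g]",
                 metric_name, rng[1], rng[2]))
  }
  structure(list(grid = grid, affine = affine, metric_name = metric_name),
            class = "scalar_volume")
}

#' Read a scalar map from a NIfTI file
#' @param path NIfTI-1 file (.nii or .nii.gz).
#' @param metric_name Metric identifier for range validation.
#' @return A [scalar_volume()].
#' @export
read_scalar_volume <- function(path, metric_name = "scalar") {
  img <- RNifti::readNifti(path)
  A <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  scalar_volume(array(as.numeric(img), dim = dim(img)), matrix(A, 4, 4),
                metric_name)
}

#' Write a scalar volume to a NIfTI file
#' @param vol A [scalar_volume()].
#' @param path Output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_scalar_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$grid)
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

## resample a polyline so consecutive points are at most `step` apart
densify_streamline <- function(s, step) {
  seg <- sqrt(rowSums((s[-1L, , drop = FALSE] - s[-nrow(s), , drop = FALSE])^2))
  arc <- c(0, cumsum(seg))
  n_out <- max(2L, ceiling(arc[length(arc)] / step) + 1L)
  targets <- seq(0, arc[length(arc)], length.out = n_out)
  cbind(stats::approx(arc, s[, 1], xout = targets, ties = "ordered")$y,
        stats::approx(arc, s[, 2], xout = targets, ties = "ordered")$y,
        stats::approx(arc, s[, 3], xout = targets, ties = "ordered")$y)
}

## 0-based voxel indices (rounded to nearest centre) for a set of mm points
points_to_voxels <- function(pts, affine, dim, what = "streamline") {
  vox <- round(world_to_voxel(affine, pts))
  out_low <- vox < 0
  out_high <- sweep(vox, 2L, dim - 1L, ">")
  if (any(out_low | out_high)) {
    bad <- which(rowSums(out_low | out_high) > 0)[1]
    stop(sprintf("%s extends outside the grid: point (%.2f, %.2f, %.2f) mm maps to voxel (%d, %d, %d), grid %d x %d x %d",
                 what, pts[bad, 1], pts[bad, 2], pts[bad, 3],
                 vox[bad, 1], vox[bad, 2], vox[bad, 3],
                 dim[1], dim[2], dim[3]))
  }
  vox
}

#' Bundle volume by counting voxels traversed by streamlines
#'
#' Streamlines are densely resampled (linear steps no larger than a quarter
#' of the smallest voxel edge) and the number of distinct voxels containing
#' at least one sampled point is multiplied by the voxel volume.
#'
#' @param bundle List of streamline point matrices (mm).
#' @param affine 4x4 voxel-to-mm transform of the counting grid.
#' @param dim Integer grid dimensions (voxels).
#' @param step Sampling step in mm (default `min(voxel_size) / 4`).
#' @return Volume in mm^3 (0 for an empty bundle).
#' @export
bundle_volume <- function(bundle, affine, dim, step = NULL) {
  check_affine(affine)
  dim <- as.integer(dim)
  if (length(bundle) == 0L) return(0)
  if (is.null(step)) step <- min(affine_voxel_size(affine)) / 4
  keys <- lapply(bundle, function(s) {
    vox <- points_to_voxels(densify_streamline(as.matrix(s), step), affine, dim)
    vox[, 1] + dim[1] * (vox[, 2] + dim[2] * vox[, 3])
  })
  n_vox <- length(unique(unlist(keys)))
  n_vox * abs(det(affine[1:3, 1:3]))
}

## trilinear interpolation of a 3-D grid at continuous 0-based voxel coords
trilinear <- function(grid, vox) {
  d <- dim(grid)
  ## clamp so points exactly on the boundary interpolate from the edge cell
  vox <- pmin(pmax(vox, 0), matrix(rep(d - 1L, each = nrow(vox)), ncol = 3L))
  i0 <- pmin(floor(vox), matrix(rep(d - 2L, each = nrow(vox)), ncol = 3L))
  i0 <- pmax(i0, 0)
  f <- vox - i0
  g <- function(dx, dy, dz) {
    grid[cbind(i0[, 1] + dx + 1L, i0[, 2] + dy + 1L, i0[, 3] + dz + 1L)]
  }
  g(0, 0, 0) * (1 - f[, 1]) * (1 - f[, 2]) * (1 - f[, 3]) +
    g(1, 0, 0) * f[, 1] * (1 - f[, 2]) * (1 - f[, 3]) +
    g(0, 1, 0) * (1 - f[, 1]) * f[, 2] * (1 - f[, 3]) +
    g(0, 0, 1) * (1 - f[, 1]) * (1 - f[, 2]) * f[, 3] +
    g(1, 1, 0) * f[, 1] * f[, 2] * (1 - f[, 3]) +
    g(1, 0, 1) * f[, 1] * (1 - f[, 2]) * f[, 3] +
    g(0, 1, 1) * (1 - f[, 1]) * f[, 2] * f[, 3] +
    g(1, 1, 1) * f[, 1] * f[, 2] * f[, 3]
}

#' Median scalar value over a bundle's streamline points
#'
#' The scalar map is sampled by trilinear interpolation at every streamline
#' point and the median over all points of all streamlines is returned. Up to
#' 10% of points may fall outside the map (they are dropped with a message);
#' more than 10% outside is an error.
#'
#' @param bundle List of streamline point matrices (mm).
#' @param vol A [scalar_volume()].
#' @return Median sampled value.
#' @export
sample_bundle_median <- function(bundle, vol) {
  stopifnot(inherits(vol, "scalar_volume"))
  if (length(bundle) == 0L) stop("empty bundle")
  pts <- do.call(rbind, lapply(bundle, as.matrix))
  vox <- world_to_voxel(vol$affine, pts)
  d <- dim(vol$grid)
  inside <- vox[, 1] >= -0.5 & vox[, 1] <= d[1] - 0.5 &
    vox[, 2] >= -0.5 & vox[, 2] <= d[2] - 0.5 &
    vox[, 3] >= -0.5 & vox[, 3] <= d[3] - 0.5
  n_out <- sum(!inside)
  if (n_out > 0.1 * nrow(vox)) {
    stop(sprintf("%d of %d streamline points (%.0f%%) fall outside the %s map",
                 n_out, nrow(vox), 100 * n_out / nrow(vox), vol$metric_name))
  }
  if (n_out > 0) {
    message(n_out, " streamline points outside the ", vol$metric_name,
            " map were dropped")
    vox <- vox[inside, , drop = FALSE]
  }
  stats::median(trilinear(vol$grid, vox))
}

## ---- feature matrix ---------------------------------------------------------

#' Assemble the subjects x imaging-variables feature matrix
#'
#' Combines per-subject bundle shape descriptors, bundle volumes and bundle
#' median microstructure values into one wide data frame. Every column
#' carries a family tag (`shape`, `tract_volume`, `microstructure`) plus
#' `volumetric` and `diffusion_derived` flags that drive the covariate policy
#' of the statistical stage. Missing bundles give missing cells (never
#' silent zeros), with a warning.
#'
#' @param descriptors Named list (by subject) of [shape_descriptors()] results
#'   (or bundles x m matrices), or `NULL` to skip the shape family.
#' @param volumes Named list (by subject) of named numeric vectors
#'   (bundle -> mm^3), or `NULL`.
#' @param medians Named list (by subject) of bundles x metrics matrices, or
#'   `NULL`.
#' @param bundles Bundle vocabulary (default [bundle_vocabulary()]).
#' @param metrics Metric names (default [default_metrics()]).
#' @return Data frame with one row per subject (rownames = subject ids) and
#'   attribute `"families"`: a data frame with columns `column`, `family`,
#'   `volumetric`, `diffusion_derived`.
#' @export
assemble_features <- function(descriptors = NULL, volumes = NULL, medians = NULL,
                              bundles = bundle_vocabulary(),
                              metrics = default_metrics()) {
  subjects <- unique(c(names(descriptors), names(volumes), names(medians)))
  if (length(subjects) == 0L) stop("no per-subject inputs supplied")
  cols <- list()
  fam <- list()
  add_col <- function(name, values, family, volumetric, diffusion) {
    cols[[name]] <<- values
    fam[[name]] <<- data.frame(column = name, family = family,
                               volumetric = volumetric,
                               diffusion_derived = diffusion,
                               stringsAsFactors = FALSE)
  }
  n_missing <- 0L
  if (!is.null(descriptors)) {
    mats <- lapply(descriptors, function(d) {
      if (inherits(d, "bundle_shape_descriptors")) d$descriptors else as.matrix(d)
    })
    m <- max(vapply(mats, ncol, integer(1)))
    for (b in bundles) {
      for (j in seq_len(m)) {
        vals <- vapply(subjects, function(s) {
          d <- mats[[s]]
          if (is.null(d) || !(b %in% rownames(d)) || j > ncol(d)) NA_real_
          else d[b, j]
        }, numeric(1))
        n_missing <- n_missing + sum(is.na(vals))
        add_col(sprintf("shape_%s_c%d", b, j), vals, "shape",
                volumetric = FALSE, diffusion = TRUE)
      }
    }
  }
  if (!is.null(volumes)) {
    for (b in bundles) {
      vals <- vapply(subjects, function(s) {
        v <- volumes[[s]]
        if (is.null(v) || !(b %in% names(v))) NA_real_ else v[[b]]
      }, numeric(1))
      n_missing <- n_missing + sum(is.na(vals))
      add_col(sprintf("volume_%s", b), vals, "tract_volume",
              volumetric = TRUE, diffusion = TRUE)
    }
  }
  if (!is.null(medians)) {
    for (metric in metrics) {
      for (b in bundles) {
        vals <- vapply(subjects, function(s) {
          mm <- medians[[s]]
          if (is.null(mm) || !(b %in% rownames(mm)) || !(metric %in% colnames(mm))) {
            NA_real_
          } else {
            mm[b, metric]
          }
        }, numeric(1))
        n_missing <- n_missing + sum(is.na(vals))
        add_col(sprintf("%s_%s", metric, b), vals, "microstructure",
                volumetric = FALSE,
                diffusion = metric %in% diffusion_metrics())
      }
    }
  }
  if (n_missing > 0L) {
    warning(n_missing, " missing cells in the assembled feature matrix")
  }
  fm <- as.data.frame(cols, row.names = subjects, check.names = FALSE)
  attr(fm, "families") <- do.call(rbind, unname(fam))
  class(fm) <- c("feature_matrix", class(fm))
  fm
}

#' Column family metadata of a feature matrix
#' @param fm A [assemble_features()] result.
#' @return Data frame with `column`, `family`, `volumetric`,
#'   `diffusion_derived`.
#' @export
feature_families <- function(fm) {
  f <- attr(fm, "families")
  if (is.null(f)) stop("not a feature matrix: no family metadata")
  f
}

#' Number of microstructural variables (bundle medians plus bundle volumes)
#'
#' The count the default configuration reports as bundles x (metrics + 1),
#' i.e. 19 x 10 = 190.
#' @param fm A [assemble_features()] result.
#' @return Integer count.
#' @export
n_microstructural_variables <- function(fm) {
  f <- feature_families(fm)
  sum(f$family %in% c("microstructure", "tract_volume"))
}

#' Write a feature matrix as TSV with a JSON column-metadata sidecar
#' @param fm Feature matrix.
#' @param path TSV output path; metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  out <- cbind(subject = rownames(fm), as.data.frame(fm, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(feature_families(fm), paste0(path, ".json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#' @param path TSV path (expects `<path>.json` sidecar).
#' @return Feature matrix with family metadata restored.
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  rownames(df) <- df$subject
  df$subject <- NULL
  attr(df, "families") <- jsonlite::read_json(paste0(path, ".json"),
                                              simplifyVector = TRUE)
  class(df) <- c("feature_matrix", class(df))
  df
}
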