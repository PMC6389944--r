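#' @keywords internal
"_PACKAGE"

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package functions do not
#' disturb the caller's random number stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a reproducible sub-seed from a master seed and a stream label
#'
#' A fixed multiplicative string hash keeps per-subject / per-stage random
#' streams independent and reproducible from one pipeline-level master seed.
#' Results stay inside the 32-bit integer range R requires of seeds.
#'
#' @param seed Integer master seed.
#' @param ... Character or numeric stream labels (e.g. subject id, stage).
#' @return An integer in `[0, 2^31 - 1)`.
#' @keywords internal
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(key)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

## ---- affine helpers ---------------------------------------------------------

check_affine <- function(A, tol = 1e-12) {
  if (!is.matrix(A) || !all(dim(A) == c(4L, 4L)) || !all(is.finite(A))) {
    stop("affine must be a finite 4x4 matrix", call. = FALSE)
  }
  if (abs(det(A)) < tol) {
    stop("affine is singular (|det| < ", tol, ")", call. = FALSE)
  }
  invisible(A)
}

#' Apply a 4x4 homogeneous transform to an n x 3 point matrix
#' @keywords internal
transform_points <- function(A, pts) {
  pts <- as.matrix(pts)
  out <- cbind(pts, 1) %*% t(A)
  out[, 1:3, drop = FALSE]
}

#' World-mm coordinates to continuous 0-based voxel indices
#' @keywords internal
world_to_voxel <- function(affine, pts) {
  transform_points(solve(affine), pts)
}

#' Voxel edge lengths implied by an affine (column norms of the 3x3 block)
#' @keywords internal
affine_voxel_size <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}
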