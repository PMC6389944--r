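## Synthetic cohort generator.
##
## Emulates the study design end-to-end so every downstream stage can be
## exercised without access to individual MRI: a 36-subject cohort (21
## carriers across the 12 study CNV classes, 15 controls) with age, gender,
## total-brain-volume and motion nuisance structure; parametric 3-D
## streamline bundles among which a cingulum-like sagittal arc whose
## anterior-posterior curvature amplitude increases with penetrance; and
## scalar microstructure maps whose bundle-interior values shift linearly
## with penetrance (by default ICVF decreases).
##
## Bundle templates are arcs p(t) = (1-t) p0 + t p1 + bow * amp * sin(pi t),
## t in [0, 1], in template-space mm coordinates.

bundle_template_table <- function() {
  tab <- rbind(
    ## name                         p0                 p1                bow        amp
    c("arcuate_l",                  -45,  25,  10,     -50, -35,  30,    0, 0,  1,  12),
    c("arcuate_r",                   45,  25,  10,      50, -35,  30,    0, 0,  1,  12),
    c("uncinate_l",                 -38,  25, -12,     -35, -15, -25,    0, 0, -1,  10),
    c("uncinate_r",                  38,  25, -12,      35, -15, -25,    0, 0, -1,  10),
    c("ilf_l",                      -40, -70, -10,     -38,  20, -25,    0, 0, -1,   5),
    c("ilf_r",                       40, -70, -10,      38,  20, -25,    0, 0, -1,   5),
    c("slf_l",                      -40, -50,  30,     -40,  40,  25,    0, 0,  1,   5),
    c("slf_r",                       40, -50,  30,      40,  40,  25,    0, 0,  1,   5),
    c("ifof_l",                     -35, -65,  -5,     -30,  40,  -8,    0, 0,  1,   4),
    c("ifof_r",                      35, -65,  -5,      30,  40,  -8,    0, 0,  1,   4),
    c("cingulum_dorsal_l",           -8, -45,  20,      -8,  45,  20,    0, 0,  1,  15),
    c("cingulum_dorsal_r",            8, -45,  20,       8,  45,  20,    0, 0,  1,  15),
    c("cingulum_parahippocampal_l", -25, -40, -18,     -25,  10, -24,    0, 0, -1,   8),
    c("cingulum_parahippocampal_r",  25, -40, -18,      25,  10, -24,    0, 0, -1,   8),
    c("fornix_l",                    -5, -35,  15,     -15,  15,  -5,    0, 0,  1,  10),
    c("fornix_r",                     5, -35,  15,      15,  15,  -5,    0, 0,  1,  10),
    c("cc_splenium",                -30, -40,  25,      30, -40,  25,    0, 0,  1,  12),
    c("cc_body",                    -30,   0,  30,      30,   0,  30,    0, 0,  1,   4),
    c("cc_genu",                    -30,  35,  22,      30,  35,  22,    0, 1,  0,  10)
  )
  data.frame(bundle = tab[, 1],
             matrix(as.numeric(tab[, -1]), ncol = 10,
                    dimnames = list(NULL, c("x0", "y0", "z0", "x1", "y1", "z1",
                                            "bx", "by", "bz", "amp"))),
             stringsAsFactors = FALSE)
}

#' Evaluate a named bundle template curve
#'
#' @param name Bundle name from [bundle_vocabulary()].
#' @param n_points Points along the curve.
#' @param amplitude Bow amplitude in mm; `NULL` uses the template default.
#' @return n x 3 point matrix.
#' @export
bundle_template <- function(name, n_points = 60L, amplitude = NULL) {
  tab <- bundle_template_table()
  row <- tab[tab$bundle == name, ]
  if (nrow(row) == 0L) {
    stop("unknown bundle template: ", name, "; available: ",
         paste(tab$bundle, collapse = ", "))
  }
  if (is.null(amplitude)) amplitude <- row$amp
  t <- seq(0, 1, length.out = n_points)
  p0 <- c(row$x0, row$y0, row$z0)
  p1 <- c(row$x1, row$y1, row$z1)
  bow <- c(row$bx, row$by, row$bz)
  outer(1 - t, p0) + outer(t, p1) + outer(sin(pi * t) * amplitude, bow)
}

#' Define a synthetic study design
#'
#' Defaults reproduce the study conditions: CNV class counts from the
#' built-in penetrance table (21 carriers, 15 controls); a three-bundle
#' template set (left dorsal cingulum plus corpus callosum splenium and
#' body); cingulum arc amplitude increasing with the developmental-delay
#' penetrance score at 0.05 mm per percent; and an ICVF decrease of 0.002
#' per percent inside the bundles.
#'
#' @param cnv_counts Named integer vector, CNV label -> subject count.
#' @param bundles Bundle templates to simulate.
#' @param n_streamlines Streamlines per bundle per subject.
#' @param n_points Raw points per simulated streamline.
#' @param score Penetrance score driving the effects (`"p_dd"` or `"p_sz"`).
#' @param a0 Baseline cingulum arc amplitude (mm).
#' @param beta_amplitude Amplitude slope (mm per penetrance percent).
#' @param amplitude_bundles Bundles whose bow amplitude follows the score.
#' @param amplitude_sd Between-subject amplitude noise (mm).
#' @param bundle_radius Cross-sectional bundle spread (mm).
#' @param jitter_sd Per-point coordinate jitter (mm).
#' @param volume_slopes Named fractional bundle-radius change per percent
#'   (e.g. `c(cc_body = -0.002)`); default no volume effects.
#' @param microstructure Per-metric list with `base`, `slope` (per percent),
#'   `subject_sd`, `map_sd`; defaults cover the nine standard metrics with a
#'   penetrance effect on ICVF only.
#' @param voxel_size Scalar map voxel edge (mm).
#' @param age_mean,age_sd,age_range,tbv_mean,tbv_sd Covariate model.
#' @param seed Master seed.
#' @return List of class `simulation_design`.
#' @export
simulation_design <- function(cnv_counts = NULL,
                              bundles = c("cingulum_dorsal_l", "cc_splenium", "cc_body"),
                              n_streamlines = 20L,
                              n_points = 60L,
                              score = "p_dd",
                              a0 = 15,
                              beta_amplitude = 0.05,
                              amplitude_bundles = c("cingulum_dorsal_l",
                                                    "cingulum_dorsal_r"),
                              amplitude_sd = 1,
                              bundle_radius = 2,
                              jitter_sd = 0.5,
                              volume_slopes = NULL,
                              microstructure = NULL,
                              voxel_size = 2,
                              age_mean = 38, age_sd = 12, age_range = c(18, 65),
                              tbv_mean = 1.1e6, tbv_sd = 1e5,
                              seed = 1L) {
  if (is.null(cnv_counts)) {
    tab <- penetrance_table()
    cnv_counts <- stats::setNames(tab$n_study, tab$cnv_label)
  }
  if (any(cnv_counts < 0)) stop("cnv_counts must be non-negative")
  bad <- setdiff(names(cnv_counts), penetrance_table()$cnv_label)
  if (length(bad)) stop("unknown CNV label(s) in cnv_counts: ",
                        paste(bad, collapse = ", "))
  bad_b <- setdiff(bundles, bundle_template_table()$bundle)
  if (length(bad_b)) stop("unknown bundle template(s): ",
                          paste(bad_b, collapse = ", "))
  if (amplitude_sd < 0 || jitter_sd < 0 || bundle_radius < 0) {
    stop("noise standard deviations must be non-negative")
  }
  defaults <- list(
    FA   = list(base = 0.50,   slope = 0,      subject_sd = 0.02,  map_sd = 0.02),
    MD   = list(base = 8e-4,   slope = 0,      subject_sd = 2e-5,  map_sd = 2e-5),
    AD   = list(base = 1.2e-3, slope = 0,      subject_sd = 3e-5,  map_sd = 3e-5),
    RD   = list(base = 6e-4,   slope = 0,      subject_sd = 2e-5,  map_sd = 2e-5),
    R1   = list(base = 1.0,    slope = 0,      subject_sd = 0.03,  map_sd = 0.03),
    T1   = list(base = 1.0,    slope = 0,      subject_sd = 0.03,  map_sd = 0.03),
    ICVF = list(base = 0.60,   slope = -0.002, subject_sd = 0.02,  map_sd = 0.01),
    ISOF = list(base = 0.10,   slope = 0,      subject_sd = 0.01,  map_sd = 0.01),
    ODI  = list(base = 0.20,   slope = 0,      subject_sd = 0.01,  map_sd = 0.01))
  if (!is.null(microstructure)) {
    for (mname in names(microstructure)) {
      cur <- if (!is.null(defaults[[mname]])) defaults[[mname]] else
        list(base = 0, slope = 0, subject_sd = 0, map_sd = 0)
      defaults[[mname]] <- utils::modifyList(cur, microstructure[[mname]])
    }
  }
  structure(
    list(cnv_counts = cnv_counts, bundles = bundles,
         n_streamlines = as.integer(n_streamlines),
         n_points = as.integer(n_points),
         score = score, a0 = a0, beta_amplitude = beta_amplitude,
         amplitude_bundles = amplitude_bundles, amplitude_sd = amplitude_sd,
         bundle_radius = bundle_radius, jitter_sd = jitter_sd,
         volume_slopes = volume_slopes, microstructure = defaults,
         voxel_size = voxel_size,
         age_mean = age_mean, age_sd = age_sd, age_range = age_range,
         tbv_mean = tbv_mean, tbv_sd = tbv_sd,
         seed = as.integer(seed)),
    class = "simulation_design"
  )
}

#' Build a synthetic cohort table
#'
#' One row per subject: CNV label per the design counts, gender matched to
#' the per-CNV counts of the built-in table where the design count equals the
#' study count (Bernoulli at the table proportion otherwise), truncated
#' normal age, normal total brain volume, half-normal motion index, and the
#' penetrance scores from [assign_scores()]. Deterministic per seed.
#'
#' @param design A [simulation_design()].
#' @param seed Master seed (default the design's).
#' @return Data frame with columns `subject`, `cnv_label`, `age`, `gender`,
#'   `tbv`, `motion`, `p_sz`, `p_dd`, `carrier`.
#' @export
build_cohort <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "simulation_design"))
  tab <- penetrance_table()
  with_seed(derive_seed(seed, "cohort"), {
    labels <- rep(names(design$cnv_counts), design$cnv_counts)
    n <- length(labels)
    gender <- character(n)
    for (lab in unique(labels)) {
      rows <- which(labels == lab)
      ti <- match(lab, tab$cnv_label)
      if (length(rows) == tab$n_male[ti] + tab$n_female[ti]) {
        g <- sample(c(rep("M", tab$n_male[ti]), rep("F", tab$n_female[ti])))
      } else {
        p_m <- tab$n_male[ti] / max(1L, tab$n_male[ti] + tab$n_female[ti])
        g <- ifelse(stats::runif(length(rows)) < p_m, "M", "F")
      }
      gender[rows] <- g
    }
    age <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        a <- stats::rnorm(1, design$age_mean, design$age_sd)
        if (a >= design$age_range[1] && a <= design$age_range[2]) break
      }
      age[i] <- a
    }
    cohort <- data.frame(
      subject = sprintf("sub-%03d", seq_len(n)),
      cnv_label = labels,
      age = age,
      gender = gender,
      tbv = stats::rnorm(n, design$tbv_mean, design$tbv_sd),
      motion = abs(stats::rnorm(n)),
      stringsAsFactors = FALSE
    )
    assign_scores(cohort)
  })
}

#' Simulate one subject's streamline bundle from a template
#'
#' `n_streamlines` noisy copies of the template curve. For bundles listed in
#' `design$amplitude_bundles` the bow amplitude is
#' `a0 + beta_amplitude * P + N(0, amplitude_sd^2)` where P is the subject's
#' penetrance score; each streamline gets a constant cross-sectional offset
#' `N(0, bundle_radius^2 I3)` and per-point jitter `N(0, jitter_sd^2 I3)`.
#'
#' @param template Bundle template name.
#' @param subject One row of a [build_cohort()] table.
#' @param design The [simulation_design()].
#' @param seed Master seed (default the design's).
#' @return List of streamline point matrices, with the true bundle label as
#'   attribute `"bundle_label"`.
#' @export
simulate_bundle <- function(template, subject, design, seed = design$seed) {
  stopifnot(inherits(design, "simulation_design"))
  p_score <- subject[[design$score]]
  with_seed(derive_seed(seed, "bundle", template, subject$subject), {
    amp <- if (template %in% design$amplitude_bundles) {
      design$a0 + design$beta_amplitude * p_score +
        stats::rnorm(1, 0, design$amplitude_sd)
    } else {
      NULL   # template default amplitude
    }
    base <- bundle_template(template, design$n_points, amp)
    radius <- design$bundle_radius
    vs <- design$volume_slopes
    if (!is.null(vs) && template %in% names(vs)) {
      radius <- max(0, radius * (1 + vs[[template]] * p_score))
    }
    streamlines <- lapply(seq_len(design$n_streamlines), function(i) {
      offset <- stats::rnorm(3, 0, radius)
      jitter <- matrix(stats::rnorm(3 * nrow(base), 0, design$jitter_sd),
                       ncol = 3)
      sweep(base + jitter, 2L, offset, "+")
    })
    attr(streamlines, "bundle_label") <- template
    streamlines
  })
}

## grid covering a set of points with a margin, at isotropic voxel size
bounding_grid <- function(pts, voxel_size, margin = 4) {
  lo <- apply(pts, 2L, min) - margin
  hi <- apply(pts, 2L, max) + margin
  dim <- pmax(2L, as.integer(ceiling((hi - lo) / voxel_size)) + 1L)
  affine <- diag(c(rep(voxel_size, 3), 1))
  affine[1:3, 4] <- lo
  list(affine = affine, dim = dim)
}

## 0-based voxel keys traversed by a list of streamlines (dense sampling)
traversed_keys <- function(streamlines, affine, dim, step) {
  keys <- lapply(streamlines, function(s) {
    vox <- round(world_to_voxel(affine, densify_streamline(as.matrix(s), step)))
    vox <- pmin(pmax(vox, 0L), matrix(rep(dim - 1L, each = nrow(vox)), ncol = 3L))
    vox[, 1] + dim[1] * (vox[, 2] + dim[2] * vox[, 3])
  })
  unique(unlist(keys))
}

## dilate a set of voxel keys by one voxel (26-neighbourhood), clamped to grid;
## keeps trilinear interpolation at streamline points interior to the mask
dilate_keys <- function(keys, dim) {
  i <- keys %% dim[1]
  rest <- keys %/% dim[1]
  j <- rest %% dim[2]
  l <- rest %/% dim[2]
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dl = -1:1))
  out <- lapply(seq_len(nrow(off)), function(r) {
    ii <- pmin(pmax(i + off[r, 1], 0L), dim[1] - 1L)
    jj <- pmin(pmax(j + off[r, 2], 0L), dim[2] - 1L)
    ll <- pmin(pmax(l + off[r, 3], 0L), dim[3] - 1L)
    ii + dim[1] * (jj + dim[2] * ll)
  })
  unique(unlist(out))
}

#' Simulate a subject's scalar microstructure map around a bundle
#'
#' Background voxels hold the metric's base value; voxels traversed by the
#' bundle hold `base + slope * P + N(0, subject_sd^2)` (one subject-level
#' draw) plus per-voxel noise `N(0, map_sd^2)`. Values are truncated to the
#' metric's physical range, with a warning if the mean itself fell outside.
#'
#' @param metric Metric name present in the design's microstructure model.
#' @param subject One row of a [build_cohort()] table.
#' @param bundle List of streamline matrices defining the interior mask
#'   (typically the union of all simulated bundles).
#' @param design The [simulation_design()].
#' @param seed Master seed (default the design's).
#' @param grid Optional precomputed `list(affine, dim)`; default bounding box
#'   of the bundle plus margin.
#' @return A [scalar_volume()].
#' @export
simulate_scalar_map <- function(metric, subject, bundle, design,
                                seed = design$seed, grid = NULL) {
  stopifnot(inherits(design, "simulation_design"))
  spec <- design$microstructure[[metric]]
  if (is.null(spec)) stop("metric not in design: ", metric)
  pts <- do.call(rbind, lapply(bundle, as.matrix))
  if (is.null(grid)) grid <- bounding_grid(pts, design$voxel_size)
  p_score <- subject[[design$score]]
  rng <- metric_ranges()[[metric]]
  with_seed(derive_seed(seed, "map", metric, subject$subject), {
    vol <- array(spec$base, dim = grid$dim)
    keys <- dilate_keys(
      traversed_keys(bundle, grid$affine, grid$dim,
                     step = min(affine_voxel_size(grid$affine)) / 4),
      grid$dim)
    inside_mean <- spec$base + spec$slope * p_score +
      stats::rnorm(1, 0, spec$subject_sd)
    if (!is.null(rng) && (inside_mean < rng[1] || inside_mean > rng[2])) {
      warning(sprintf("%s bundle mean %.4f outside [%g, %g]; truncating",
                      metric, inside_mean, rng[1], rng[2]))
    }
    vol[keys + 1L] <- inside_mean + stats::rnorm(length(keys), 0, spec$map_sd)
    if (!is.null(rng)) vol <- pmin(pmax(vol, rng[1]), rng[2])
    dim(vol) <- grid$dim
    scalar_volume(vol, grid$affine, metric)
  })
}

#' Simulate a full synthetic study in memory
#'
#' Cohort plus, per subject, a labelled tractogram over the design's bundle
#' templates and one scalar map per metric (shared grid, bundle-union mask).
#'
#' @param design A [simulation_design()].
#' @param seed Master seed (default the design's).
#' @param metrics Metrics to simulate (default all in the design).
#' @param maps If `FALSE`, skip scalar-map simulation.
#' @return List with `cohort`, and `subjects`: per subject a list with
#'   `tractogram` (bundle_labels set to the true labels) and `maps`.
#' @export
simulate_study <- function(design, seed = design$seed,
                           metrics = names(design$microstructure),
                           maps = TRUE) {
  cohort <- build_cohort(design, seed)
  template_pts <- do.call(rbind, lapply(design$bundles, bundle_template))
  grid <- bounding_grid(template_pts, design$voxel_size,
                        margin = design$a0 + 12)
  subjects <- lapply(seq_len(nrow(cohort)), function(i) {
    subj <- cohort[i, ]
    bundles <- lapply(design$bundles, simulate_bundle,
                      subject = subj, design = design, seed = seed)
    streamlines <- do.call(c, lapply(bundles, identity))
    labels <- rep(design$bundles,
                  vapply(bundles, length, integer(1)))
    tract <- tractogram(streamlines, affine = diag(4),
                        subject_id = subj$subject, bundle_labels = labels)
    out <- list(tractogram = tract)
    if (maps) {
      all_streams <- tract$streamlines
      out$maps <- stats::setNames(lapply(metrics, function(mname) {
        simulate_scalar_map(mname, subj, all_streams, design, seed, grid = grid)
      }), metrics)
    }
    out
  })
  names(subjects) <- cohort$subject
  list(cohort = cohort, subjects = subjects, grid = grid, design = design)
}

#' Simulate a feature matrix directly at the statistical level
#'
#' Bypasses the imaging stages: each feature is a linear function of the
#' nuisance covariates plus (optionally) the penetrance score plus unit
#' Gaussian noise. Used for calibration and power studies of the
#' statistical machinery itself.
#'
#' @param cohort A [build_cohort()] table.
#' @param n_features Number of feature columns.
#' @param slope Penetrance effect per feature (length 1 or `n_features`;
#'   default 0 = global null).
#' @param predictor Score column the effect loads on (default `"p_dd"`).
#' @param beta_age,beta_gender Nuisance effect sizes.
#' @param noise_sd Residual standard deviation.
#' @param seed Integer seed.
#' @return n_subjects x n_features matrix with named columns.
#' @export
simulate_feature_matrix <- function(cohort, n_features, slope = 0,
                                    predictor = "p_dd",
                                    beta_age = 0.02, beta_gender = 0.5,
                                    noise_sd = 1, seed = 1L) {
  slope <- rep_len(slope, n_features)
  n <- nrow(cohort)
  with_seed(derive_seed(seed, "features"), {
    g <- as.numeric(cohort$gender == "M")
    Y <- vapply(seq_len(n_features), function(j) {
      beta_age * cohort$age + beta_gender * g +
        slope[j] * cohort[[predictor]] + stats::rnorm(n, 0, noise_sd)
    }, numeric(n))
    colnames(Y) <- sprintf("feature_%03d", seq_len(n_features))
    rownames(Y) <- cohort$subject
    Y
  })
}
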