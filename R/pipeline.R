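## Pipeline orchestration: simulate -> shape -> tractometry -> stats ->
## report, with a YAML-configurable design, a run manifest for exact
## reproducibility, and files in the same standard formats (TCK + NIfTI +
## CSV/TSV) a real study would use, so the simulator is a drop-in data
## source.

#' Default pipeline configuration
#'
#' Two named profiles: `"desk"` (small, minutes on one CPU: K = 100
#' clusters, 1000 permutations, 10 streamlines per bundle over the full
#' 19-bundle template set) and `"study"` (the faithful study settings:
#' K = 800, B = 5000, 50 streamlines per bundle).
#'
#' @param profile `"desk"` or `"study"`.
#' @param seed Master seed.
#' @return Configuration list.
#' @export
default_config <- function(profile = c("desk", "study"), seed = 1L) {
  profile <- match.arg(profile)
  list(
    profile = profile,
    seed = as.integer(seed),
    n_knots = 30L,
    variance_target = 0.95,
    n_components_shape = 7L,
    K = if (profile == "study") 800L else 100L,
    B = if (profile == "study") 5000L else 1000L,
    n_streamlines = if (profile == "study") 50L else 10L,
    bundles = bundle_vocabulary(),
    metrics = default_metrics(),
    min_streamlines = 5L,
    predictors = c("p_sz", "p_dd"),
    voxel_size = 3
  )
}

#' Validate a pipeline configuration
#' @param config Configuration list (see [default_config()]).
#' @return The config, invisibly; errors on schema violations.
#' @export
validate_config <- function(config) {
  req <- c("seed", "n_knots", "variance_target", "K", "B", "n_streamlines",
           "bundles", "metrics", "min_streamlines", "predictors", "voxel_size")
  missing <- setdiff(req, names(config))
  if (length(missing)) {
    stop("config is missing fields: ", paste(missing, collapse = ", "))
  }
  if (config$B < 100) stop("config: B must be at least 100")
  if (config$n_knots < 2) stop("config: n_knots must be at least 2")
  if (config$K < 1) stop("config: K must be at least 1")
  if (config$n_streamlines < 1) stop("config: n_streamlines must be positive")
  if (config$variance_target <= 0 || config$variance_target > 1) {
    stop("config: variance_target must be in (0, 1]")
  }
  if (!all(config$predictors %in% c("p_sz", "p_dd", "carrier"))) {
    stop("config: predictors must be among p_sz, p_dd, carrier")
  }
  bad <- setdiff(config$bundles, bundle_vocabulary())
  if (length(bad)) stop("config: unknown bundles ", paste(bad, collapse = ", "))
  invisible(config)
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; fields override the profile defaults.
#' @return Validated configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- default_config(profile = user$profile %||% "desk",
                         seed = user$seed %||% 1L)
  cfg <- utils::modifyList(base, user)
  validate_config(cfg)
  cfg
}

#' Run the full penetrance-tractometry pipeline on a synthetic cohort
#'
#' Stages: `simulate` writes the cohort CSV, per-subject TCK tractograms and
#' NIfTI scalar maps; `shape` fits the PCA shape basis on pooled streamlines,
#' clusters projection weights, learns the cluster-to-bundle map from the
#' simulated labels and computes per-subject bundle shape descriptors;
#' `tractometry` computes bundle volumes and median microstructure and
#' assembles the feature matrix (TSV + JSON sidecar); `stats` runs the
#' penetrance GLM with max-|t| permutation correction per family, the binary
#' carrier model, the score correlation and the leave-one-CNV-out table for
#' the top association; `report` writes a human-readable summary. A JSON run
#' manifest records config, seed, versions and output digests.
#'
#' @param config Configuration list (see [default_config()]).
#' @param outdir Output directory (created if needed).
#' @param stages Subset of stages to run (earlier outputs must exist).
#' @return Invisible list with the main in-memory objects (`cohort`,
#'   `feature_matrix`, `results`, `manifest`).
#' @export
run_pipeline <- function(config = default_config(), outdir = tempfile("penetract_"),
                         stages = c("simulate", "shape", "tractometry",
                                    "stats", "report")) {
  validate_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  design <- simulation_design(
    bundles = config$bundles,
    n_streamlines = config$n_streamlines,
    voxel_size = config$voxel_size,
    seed = seed
  )
  state <- list()

  if ("simulate" %in% stages) {
    study <- simulate_study(design, seed, metrics = config$metrics)
    utils::write.csv(study$cohort, file.path(outdir, "cohort.csv"),
                     row.names = FALSE)
    for (sid in names(study$subjects)) {
      sdir <- file.path(outdir, sid)
      dir.create(sdir, showWarnings = FALSE)
      write_tractogram(study$subjects[[sid]]$tractogram,
                       file.path(sdir, "tractogram.tck"))
      writeLines(study$subjects[[sid]]$tractogram$bundle_labels,
                 file.path(sdir, "bundle_labels.txt"))
      for (mname in names(study$subjects[[sid]]$maps)) {
        write_scalar_volume(study$subjects[[sid]]$maps[[mname]],
                            file.path(sdir, paste0(mname, ".nii.gz")))
      }
    }
    state$study <- study
  }
  cohort <- if (!is.null(state$study)) state$study$cohort else
    assign_scores(utils::read.csv(file.path(outdir, "cohort.csv")))
  subjects <- cohort$subject

  load_subject <- function(sid) {
    if (!is.null(state$study)) return(state$study$subjects[[sid]])
    sdir <- file.path(outdir, sid)
    tract <- read_tractogram(file.path(sdir, "tractogram.tck"))
    tract$bundle_labels <- readLines(file.path(sdir, "bundle_labels.txt"))
    maps <- stats::setNames(lapply(config$metrics, function(mname) {
      read_scalar_volume(file.path(sdir, paste0(mname, ".nii.gz")), mname)
    }), config$metrics)
    list(tractogram = tract, maps = maps)
  }

  if (any(c("shape", "tractometry") %in% stages)) {
    state$subject_data <- stats::setNames(lapply(subjects, load_subject),
                                          subjects)
  }

  if ("shape" %in% stages) {
    feats <- lapply(state$subject_data, function(sd) {
      streamlines_to_features(sd$tractogram$streamlines, config$n_knots)
    })
    pooled <- do.call(rbind, feats)
    pooled_labels <- unlist(lapply(state$subject_data,
                                   function(sd) sd$tractogram$bundle_labels),
                            use.names = FALSE)
    model <- fit_shape_pca(pooled, config$variance_target,
                           n_components = config$n_components_shape)
    K <- min(config$K, nrow(pooled))
    clusters <- cluster_weights(project(model, pooled), K = K,
                                seed = derive_seed(seed, "kmeans"))
    clusters <- train_bundle_map(clusters, project(model, pooled),
                                 pooled_labels)
    descriptors <- lapply(state$subject_data, function(sd) {
      seg <- segment_bundles(sd$tractogram, model, clusters, config$n_knots)
      w <- project(model, streamlines_to_features(sd$tractogram$streamlines,
                                                  config$n_knots))
      shape_descriptors(w, seg$bundle_labels, bundles = config$bundles,
                        min_streamlines = config$min_streamlines)
    })
    state$model <- model
    state$clusters <- clusters
    state$descriptors <- descriptors
    jsonlite::write_json(
      list(mean_vector = model$mean_vector,
           basis = model$basis,
           eigenvalues = model$eigenvalues,
           variance_retained = model$variance_retained,
           centroids = clusters$centroids,
           cluster_to_bundle = clusters$cluster_to_bundle,
           kmeans_seed = clusters$seed),
      file.path(outdir, "shape_model.json"), digits = NA, auto_unbox = TRUE)
  }

  if ("tractometry" %in% stages) {
    grid <- if (!is.null(state$study)) state$study$grid else {
      m1 <- state$subject_data[[1]]$maps[[1]]
      list(affine = m1$affine, dim = dim(m1$grid))
    }
    volumes <- lapply(state$subject_data, function(sd) {
      labs <- sd$tractogram$bundle_labels
      out <- stats::setNames(rep(NA_real_, length(config$bundles)),
                             config$bundles)
      for (b in intersect(unique(labs), config$bundles)) {
        out[b] <- bundle_volume(sd$tractogram$streamlines[labs == b],
                                grid$affine, grid$dim)
      }
      out[!is.na(out)]
    })
    medians <- lapply(state$subject_data, function(sd) {
      labs <- sd$tractogram$bundle_labels
      mm <- matrix(NA_real_, length(config$bundles), length(config$metrics),
                   dimnames = list(config$bundles, config$metrics))
      for (b in intersect(unique(labs), config$bundles)) {
        bundle <- sd$tractogram$streamlines[labs == b]
        for (mname in config$metrics) {
          mm[b, mname] <- sample_bundle_median(bundle, sd$maps[[mname]])
        }
      }
      mm
    })
    fm <- assemble_features(descriptors = state$descriptors,
                            volumes = volumes, medians = medians,
                            bundles = config$bundles,
                            metrics = config$metrics)
    write_feature_matrix(fm, file.path(outdir, "features.tsv"))
    state$feature_matrix <- fm
  }

  if ("stats" %in% stages) {
    fm <- state$feature_matrix %||%
      read_feature_matrix(file.path(outdir, "features.tsv"))
    results <- do.call(rbind, lapply(config$predictors, function(pp) {
      association_tests(fm, cohort, pp, B = config$B,
                        seed = derive_seed(seed, "stats", pp))
    }))
    binary <- association_tests(fm, cohort, "carrier", B = config$B,
                                seed = derive_seed(seed, "stats", "carrier"))
    results <- rbind(results, binary)
    utils::write.table(results, file.path(outdir, "associations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    corr <- score_correlation(cohort)
    utils::write.table(corr, file.path(outdir, "score_correlation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    top <- results[results$predictor != "carrier", ]
    top <- top[order(top$p_corr, top$p), ][1, ]
    loo <- loo_cnv_sensitivity(fm[[top$feature]], cohort,
                               predictor = top$predictor,
                               volumetric = feature_families(fm)$volumetric[
                                 match(top$feature, feature_families(fm)$column)],
                               diffusion = TRUE)
    utils::write.table(cbind(feature = top$feature, loo),
                       file.path(outdir, "loo_cnv_sensitivity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    state$results <- results
    state$score_correlation <- corr
    state$loo <- loo
  }

  if ("report" %in% stages) {
    results <- state$results
    lines <- c("penetract pipeline report",
               sprintf("profile: %s   seed: %d   B: %d", config$profile,
                       seed, config$B),
               sprintf("subjects: %d (%d carriers, %d controls)",
                       nrow(cohort), sum(cohort$carrier),
                       sum(!cohort$carrier)),
               "")
    if (!is.null(results)) {
      for (fam in unique(results$family)) {
        sub <- results[results$family == fam & results$predictor != "carrier", ]
        sub <- sub[order(sub$p_corr, sub$p), ]
        best <- sub[1, ]
        lines <- c(lines, sprintf(
          "family %-14s top: %-28s %s beta=%10.4g t=%7.3f p=%8.3g p_corr=%6.4f",
          fam, best$feature, best$predictor, best$beta, best$t, best$p,
          best$p_corr))
      }
    }
    writeLines(lines, file.path(outdir, "report.txt"))
  }

  files <- list.files(outdir, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest[.]json$", files)]
  manifest <- list(
    package_version = as.character(utils::packageVersion("penetract")),
    seed = seed,
    config = config[order(names(config))],
    stages = stages,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    digests = as.list(tools::md5sum(files))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(state, list(cohort = cohort, outdir = outdir,
                          manifest = manifest)))
}
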