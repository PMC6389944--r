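## Penetrance association statistics.
##
## Each imaging variable is regressed on a penetrance score (or the binary
## carrier indicator) by ordinary least squares with the study's covariate
## policy: age and gender always; total brain volume for volumetric
## variables; intra-scan head motion for diffusion-derived variables.
## Family-wise error across the variables of one family is controlled by
## max-|t| permutation testing with the Freedman-Lane scheme: residuals of
## the nuisance-only model are permuted, so exchangeability respects the
## covariates.

`%||%` <- function(a, b) if (is.null(a)) b else a

## nuisance design matrix for the covariate policy
covariate_matrix <- function(cohort, volumetric = FALSE, diffusion = FALSE) {
  Z <- cbind(intercept = 1,
             age = cohort$age,
             gender = as.numeric(cohort$gender == "M"))
  if (volumetric) Z <- cbind(Z, tbv = cohort$tbv)
  if (diffusion) Z <- cbind(Z, motion = cohort$motion)
  Z
}

predictor_vector <- function(cohort, predictor = c("p_sz", "p_dd", "carrier")) {
  predictor <- match.arg(predictor)
  if (predictor == "carrier") as.numeric(cohort$carrier) else cohort[[predictor]]
}

## shared OLS t-statistic algebra for a fixed design and many outcomes
ols_t <- function(Y, Z, g) {
  n <- nrow(Y)
  qrZ <- qr(Z)
  gperp <- qr.resid(qrZ, g)
  gg <- sum(gperp^2)
  if (gg < 1e-10 * sum(g^2)) {
    stop("predictor is collinear with the covariates")
  }
  X <- cbind(Z, g)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("rank-deficient design; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  df <- n - ncol(X)
  stat <- function(Ymat) {
    beta <- drop(crossprod(gperp, Ymat)) / gg
    res <- qr.resid(qrX, Ymat)
    sigma2 <- colSums(res^2) / df
    se <- sqrt(sigma2 / gg)
    t <- ifelse(se > 0, beta / se, sign(beta) * Inf)
    list(beta = beta, se = se, t = t)
  }
  list(stat = stat, qrZ = qrZ, qrX = qrX, df = df, gperp = gperp, gg = gg)
}

#' Fit the penetrance general linear model for one imaging variable
#'
#' OLS of the feature on `[intercept, predictor, age, gender]`, plus total
#' brain volume if the feature is volumetric and motion if it is
#' diffusion-derived. Two-tailed p from the t reference distribution.
#'
#' @param y Numeric feature vector (one value per cohort row; NAs dropped
#'   complete-case).
#' @param cohort A cohort table with `age`, `gender`, `tbv`, `motion` and the
#'   score columns.
#' @param predictor `"p_sz"`, `"p_dd"` or `"carrier"`.
#' @param volumetric,diffusion Covariate policy flags of the feature.
#' @param feature_name Label carried into the result.
#' @return One-row data frame (class `association_result`): `feature`,
#'   `predictor`, `beta`, `se`, `t`, `p`, `p_corr` (NA here), `n`,
#'   `degenerate`. A zero-residual-variance fit gets the minimum
#'   representable p and `degenerate = TRUE`.
#' @export
fit_glm <- function(y, cohort, predictor = c("p_sz", "p_dd", "carrier"),
                    volumetric = FALSE, diffusion = FALSE,
                    feature_name = deparse1(substitute(y))) {
  predictor <- match.arg(predictor)
  g_all <- predictor_vector(cohort, predictor)
  Z_all <- covariate_matrix(cohort, volumetric, diffusion)
  keep <- stats::complete.cases(y, Z_all, g_all)
  y <- y[keep]; Z <- Z_all[keep, , drop = FALSE]; g <- g_all[keep]
  n <- length(y)
  if (n <= ncol(Z) + 1L + 2L) {
    stop(sprintf("too few complete rows (%d) for %d regressors",
                 n, ncol(Z) + 1L))
  }
  alg <- ols_t(matrix(y, ncol = 1L), Z, g)
  st <- alg$stat(matrix(y, ncol = 1L))
  degenerate <- !is.finite(st$t) || st$se == 0 ||
    st$se^2 * alg$gg < 1e-12 * max(stats::var(y), .Machine$double.eps)
  p <- if (degenerate) .Machine$double.xmin else
    2 * stats::pt(-abs(st$t), df = alg$df)
  p <- max(p, .Machine$double.xmin)
  structure(
    data.frame(feature = feature_name, predictor = predictor,
               beta = st$beta, se = st$se, t = st$t, p = p,
               p_corr = NA_real_, n = n, degenerate = degenerate,
               stringsAsFactors = FALSE, row.names = NULL),
    class = c("association_result", "data.frame")
  )
}

#' Max-|t| Freedman-Lane permutation correction across one variable family
#'
#' Residuals of the covariate-only model are permuted (B times), the full
#' model is refitted to each permuted dataset, and the null distribution of
#' the maximum |t| over the family gives the family-wise corrected p:
#' `p_corr = (1 + #\{max|t|_b >= |t|_obs\}) / (B + 1)`. The corrected value is
#' never smaller than the parametric p of the same feature.
#'
#' @param features Matrix or data frame, one column per family member.
#' @param cohort Cohort table.
#' @param predictor `"p_sz"`, `"p_dd"` or `"carrier"`.
#' @param B Number of permutations (study setting 5000; must be >= 100).
#' @param seed Integer seed (results are reproducible given `(seed, B)`).
#' @param volumetric,diffusion Covariate policy flags of the family.
#' @param family_id Label recorded in the results.
#' @return Data frame of association results (one row per feature) with
#'   `p_corr` filled in.
#' @export
permutation_correct <- function(features, cohort,
                                predictor = c("p_sz", "p_dd", "carrier"),
                                B = 5000L, seed = 1L,
                                volumetric = FALSE, diffusion = FALSE,
                                family_id = "family") {
  predictor <- match.arg(predictor)
  Y_all <- as.matrix(features)
  if (ncol(Y_all) < 1L) stop("empty feature family")
  if (B < 100L) stop("B must be at least 100")
  g_all <- predictor_vector(cohort, predictor)
  Z_all <- covariate_matrix(cohort, volumetric, diffusion)
  keep <- stats::complete.cases(Y_all, Z_all, g_all)
  if (sum(!keep) > 0) {
    message(sum(!keep), " rows dropped (incomplete) for family ", family_id)
  }
  Y <- Y_all[keep, , drop = FALSE]
  Z <- Z_all[keep, , drop = FALSE]
  g <- g_all[keep]
  n <- nrow(Y)
  if (n <= ncol(Z) + 3L) stop("too few complete rows for permutation testing")
  alg <- ols_t(Y, Z, g)
  obs <- alg$stat(Y)
  Rz <- qr.resid(alg$qrZ, Y)
  maxt <- with_seed(derive_seed(seed, "maxt", family_id, predictor, B), {
    vapply(seq_len(B), function(b) {
      perm <- sample.int(n)
      max(abs(alg$stat(Rz[perm, , drop = FALSE])$t))
    }, numeric(1))
  })
  abs_t <- abs(obs$t)
  p_corr <- vapply(abs_t, function(tt) (1 + sum(maxt >= tt)) / (B + 1),
                   numeric(1))
  p_par <- pmax(2 * stats::pt(-abs_t, df = alg$df), .Machine$double.xmin)
  degenerate <- !is.finite(obs$t) | obs$se == 0
  p_par[degenerate] <- .Machine$double.xmin
  structure(
    data.frame(feature = colnames(Y_all) %||% paste0("f", seq_len(ncol(Y_all))),
               predictor = predictor,
               beta = obs$beta, se = obs$se, t = obs$t,
               p = p_par, p_corr = pmax(p_corr, p_par),
               family = family_id, n = n, degenerate = degenerate,
               stringsAsFactors = FALSE, row.names = NULL),
    class = c("association_result", "data.frame")
  )
}

#' Run the penetrance model over every family of a feature matrix
#'
#' Families follow the study partition: one family per microstructural
#' metric (across bundles), tract volumes as one family, shape descriptors
#' as one family. Each family is corrected with [permutation_correct()]
#' under its own covariate policy.
#'
#' @param fm A [assemble_features()] feature matrix.
#' @param cohort Cohort table.
#' @param predictor `"p_sz"`, `"p_dd"` or `"carrier"`.
#' @param B Permutations per family.
#' @param seed Integer seed.
#' @return Data frame of association results across all families.
#' @export
association_tests <- function(fm, cohort,
                              predictor = c("p_sz", "p_dd", "carrier"),
                              B = 5000L, seed = 1L) {
  predictor <- match.arg(predictor)
  fams <- feature_families(fm)
  fams$group <- ifelse(fams$family == "microstructure",
                       sub("_.*$", "", fams$column), fams$family)
  out <- lapply(unique(fams$group), function(gname) {
    sel <- fams[fams$group == gname, ]
    cols <- as.matrix(fm[, sel$column, drop = FALSE])
    keep_cols <- colSums(!is.na(cols)) >= nrow(cols) - floor(nrow(cols) / 3)
    cols <- cols[, keep_cols, drop = FALSE]
    if (ncol(cols) == 0L) return(NULL)
    permutation_correct(cols, cohort, predictor, B = B,
                        seed = derive_seed(seed, gname),
                        volumetric = any(sel$volumetric),
                        diffusion = any(sel$diffusion_derived),
                        family_id = gname)
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Binary carrier-vs-control model across a feature family
#'
#' The same analysis as [permutation_correct()] with the predictor replaced
#' by the binary carrier indicator; used to check that effects track the
#' penetrance dose rather than mere CNV presence.
#'
#' @inheritParams permutation_correct
#' @return Data frame of association results.
#' @export
binary_model <- function(features, cohort, B = 5000L, seed = 1L,
                         volumetric = FALSE, diffusion = FALSE,
                         family_id = "family") {
  permutation_correct(features, cohort, predictor = "carrier", B = B,
                      seed = seed, volumetric = volumetric,
                      diffusion = diffusion, family_id = family_id)
}

#' Leave-one-CNV-out sensitivity of a penetrance association
#'
#' Refits the model once per CNV class with that class's carriers removed
#' and reports the change in effect size and t relative to the full fit.
#'
#' @param y Feature vector.
#' @param cohort Cohort table.
#' @param predictor `"p_sz"`, `"p_dd"` or `"carrier"`.
#' @param volumetric,diffusion Covariate policy flags.
#' @param labels CNV classes to omit (default: all carrier classes present).
#' @return Data frame with one row per omitted CNV: `cnv_label`,
#'   `n_removed`, `beta`, `t`, `delta_beta`, `delta_t`, `estimable`.
#' @export
loo_cnv_sensitivity <- function(y, cohort,
                                predictor = c("p_sz", "p_dd", "carrier"),
                                volumetric = FALSE, diffusion = FALSE,
                                labels = NULL) {
  predictor <- match.arg(predictor)
  carrier_labels <- unique(cohort$cnv_label[cohort$carrier])
  if (length(carrier_labels) < 2L) {
    stop("need at least 2 CNV classes among carriers")
  }
  labels <- labels %||% sort(carrier_labels)
  full <- fit_glm(y, cohort, predictor, volumetric, diffusion,
                  feature_name = "full")
  min_n <- ncol(covariate_matrix(cohort, volumetric, diffusion)) + 4L
  rows <- lapply(labels, function(lab) {
    drop_rows <- cohort$cnv_label == lab
    sub <- cohort[!drop_rows, , drop = FALSE]
    ysub <- y[!drop_rows]
    ok <- sum(stats::complete.cases(ysub, sub$age)) >= min_n &&
      stats::var(predictor_vector(sub, predictor), na.rm = TRUE) > 0
    if (!ok) {
      return(data.frame(cnv_label = lab, n_removed = sum(drop_rows),
                        beta = NA_real_, t = NA_real_,
                        delta_beta = NA_real_, delta_t = NA_real_,
                        estimable = FALSE, stringsAsFactors = FALSE))
    }
    fit <- fit_glm(ysub, sub, predictor, volumetric, diffusion,
                   feature_name = lab)
    data.frame(cnv_label = lab, n_removed = sum(drop_rows),
               beta = fit$beta, t = fit$t,
               delta_beta = fit$beta - full$beta, delta_t = fit$t - full$t,
               estimable = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "full_fit") <- full
  out
}

#' Global PCA of all imaging variables with per-component penetrance tests
#'
#' Columns are z-scored (constant columns dropped with a warning; missing
#' cells mean-imputed with a message), decomposed by PCA, and the first
#' `n_components` component score vectors are each tested with the
#' penetrance GLM; family-wise correction is applied across the tested
#' components. All nuisance covariates are included since components mix
#' variable families.
#'
#' @param fm Feature matrix (or plain numeric matrix).
#' @param cohort Cohort table.
#' @param predictor `"p_sz"`, `"p_dd"` or `"carrier"`.
#' @param n_components Number of leading components to test (default
#'   `min(34, n_subjects - 2, n_features)`, the study's printed choice).
#' @param B Permutations.
#' @param seed Integer seed.
#' @return List of class `global_pca_result`: `loadings`, `scores`,
#'   `explained_variance` (fractions, all components), `results`
#'   (association results for the tested components), `imputed_cells`.
#' @export
global_pca_test <- function(fm, cohort, predictor = c("p_sz", "p_dd", "carrier"),
                            n_components = NULL, B = 5000L, seed = 1L) {
  predictor <- match.arg(predictor)
  X <- as.matrix(as.data.frame(fm, check.names = FALSE))
  storage.mode(X) <- "double"
  const <- apply(X, 2L, function(col) stats::var(col, na.rm = TRUE)) < 1e-24
  const[is.na(const)] <- TRUE
  if (any(const)) {
    warning(sum(const), " constant column(s) dropped before standardisation: ",
            paste(utils::head(colnames(X)[const], 5), collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  n_imputed <- sum(is.na(X))
  if (n_imputed > 0L) {
    message(n_imputed, " missing cells mean-imputed for the global PCA")
    for (j in seq_len(ncol(X))) {
      nas <- is.na(X[, j])
      if (any(nas)) X[nas, j] <- mean(X[, j], na.rm = TRUE)
    }
  }
  Xs <- scale(X)
  pr <- stats::prcomp(Xs, center = FALSE, scale. = FALSE)
  ev <- pr$sdev^2
  m <- min(n_components %||% 34L, nrow(X) - 2L, ncol(X))
  scores <- pr$x[, seq_len(m), drop = FALSE]
  res <- permutation_correct(scores, cohort, predictor, B = B, seed = seed,
                             volumetric = TRUE, diffusion = TRUE,
                             family_id = "global_pca")
  structure(
    list(loadings = pr$rotation[, seq_len(m), drop = FALSE],
         scores = scores,
         explained_variance = ev / sum(ev),
         results = res,
         imputed_cells = n_imputed),
    class = "global_pca_result"
  )
}

#' Post-hoc test on the corpus callosum body / splenium volume ratio
#'
#' The per-subject ratio body/splenium is regressed on each penetrance
#' score. The ratio is dimensionless, so total brain volume is not a
#' covariate; motion is retained because tract volumes derive from the
#' diffusion data.
#'
#' @param body_volume,splenium_volume Per-subject volumes (mm^3,
#'   splenium strictly positive).
#' @param cohort Cohort table.
#' @param predictors Predictors to test (default both scores).
#' @return Data frame of association results, one row per predictor, with
#'   the ratio attached as attribute `"ratio"`.
#' @export
cc_ratio_test <- function(body_volume, splenium_volume, cohort,
                          predictors = c("p_sz", "p_dd")) {
  if (any(splenium_volume <= 0, na.rm = TRUE)) {
    stop("zero or negative splenium volume; ratio undefined")
  }
  ratio <- body_volume / splenium_volume
  out <- do.call(rbind, lapply(predictors, function(pp) {
    fit_glm(ratio, cohort, pp, volumetric = FALSE, diffusion = TRUE,
            feature_name = "cc_body_splenium_ratio")
  }))
  attr(out, "ratio") <- ratio
  out
}

## ---- rank correlation -------------------------------------------------------

## Pearson correlation computed explicitly
pearson_r <- function(x, y) {
  xc <- x - mean(x); yc <- y - mean(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

## exact two-sided permutation p for |rho| by full enumeration (n <= 10)
spearman_exact_p <- function(rx, ry, rho_obs) {
  n <- length(rx)
  count <- 0L
  total <- 0L
  recurse <- function(remaining, acc) {
    if (!length(remaining)) {
      total <<- total + 1L
      if (abs(pearson_r(rx, acc)) >= abs(rho_obs) - 1e-12) count <<- count + 1L
      return(invisible())
    }
    for (i in seq_along(remaining)) {
      recurse(remaining[-i], c(acc, remaining[i]))
    }
  }
  recurse(ry, numeric(0))
  count / total
}

#' Spearman rank correlation between the two penetrance scores
#'
#' Midranks for ties, then the Pearson correlation of the ranks. The p-value
#' is an exact permutation p for n <= 10 and the t-approximation otherwise.
#' Reported both over the whole cohort and over carriers only.
#'
#' @param cohort Cohort table with `p_sz` and `p_dd` columns (>= 3 rows).
#' @return Data frame with rows `all` and `carriers`: `subset`, `n`, `rho`,
#'   `p`.
#' @export
score_correlation <- function(cohort) {
  if (nrow(cohort) < 3L) stop("need at least 3 subjects")
  one <- function(x, y, label) {
    n <- length(x)
    if (stats::var(x) == 0 || stats::var(y) == 0) {
      warning("zero-variance score vector; correlation undefined for ", label)
      return(data.frame(subset = label, n = n, rho = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    }
    rx <- rank(x); ry <- rank(y)
    rho <- pearson_r(rx, ry)
    p <- if (n <= 10L) {
      spearman_exact_p(rx, ry, rho)
    } else if (abs(rho) >= 1) {
      .Machine$double.xmin
    } else {
      tt <- rho * sqrt((n - 2) / (1 - rho^2))
      2 * stats::pt(-abs(tt), df = n - 2)
    }
    data.frame(subset = label, n = n, rho = rho, p = p,
               stringsAsFactors = FALSE)
  }
  res <- one(cohort$p_sz, cohort$p_dd, "all")
  carriers <- cohort[cohort$carrier, , drop = FALSE]
  if (nrow(carriers) >= 3L) {
    res <- rbind(res, one(carriers$p_sz, carriers$p_dd, "carriers"))
  }
  res
}
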