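test_that("fit_glm matches explicit normal-equations algebra", {
  set.seed(101)
  cohort <- data.frame(
    subject = paste0("s", 1:10),
    cnv_label = c(rep("22q11.2 deletion", 5), rep("control", 5)),
    age = runif(10, 20, 60), gender = rep(c("M", "F"), 5),
    tbv = rnorm(10, 1.1e6, 1e5), motion = abs(rnorm(10)))
  cohort <- assign_scores(cohort)
  y <- 0.01 * cohort$p_dd + 0.02 * cohort$age + rnorm(10)
  fit <- fit_glm(y, cohort, "p_dd", volumetric = FALSE, diffusion = TRUE)
  X <- cbind(1, cohort$age, as.numeric(cohort$gender == "M"),
             cohort$motion, cohort$p_dd)
  oracle <- brute_ols_t(y, X)
  expect_equal(fit$beta, oracle$beta, tolerance = 1e-10)
  expect_equal(fit$se, oracle$se, tolerance = 1e-10)
  expect_equal(fit$t, oracle$t, tolerance = 1e-10)
  expect_equal(fit$p, 2 * stats::pt(-abs(oracle$t), df = 10 - ncol(X)),
               tolerance = 1e-12)
  expect_identical(fit$n, 10L)
})

test_that("fit_glm handles orthogonal, degenerate and deficient designs", {
  cohort <- default_cohort(seed = 22)
  # construct y orthogonal to the score after covariate projection
  Z <- cbind(1, cohort$age, as.numeric(cohort$gender == "M"))
  g <- cohort$p_dd
  set.seed(5)
  y0 <- rnorm(nrow(cohort))
  gp <- stats::resid(stats::lm(g ~ Z - 1))
  yp <- stats::resid(stats::lm(y0 ~ Z - 1))
  y_orth <- yp - gp * sum(yp * gp) / sum(gp^2)
  fit <- fit_glm(y_orth, cohort, "p_dd")
  expect_lt(abs(fit$t), 1e-8)

  # y equal to the predictor: zero residual variance, flagged
  fit2 <- fit_glm(cohort$p_dd, cohort, "p_dd")
  expect_true(fit2$degenerate)
  expect_equal(fit2$p, .Machine$double.xmin)

  # collinear covariate and predictor
  cohort_bad <- cohort
  cohort_bad$motion <- cohort_bad$p_dd
  expect_error(fit_glm(rnorm(36), cohort_bad, "p_dd", diffusion = TRUE),
               "collinear")

  expect_error(fit_glm(rnorm(5), cohort[1:5, ], "p_dd"), "too few")
})

test_that("permutation p-values are valid, reproducible and subset-monotone", {
  cohort <- default_cohort(seed = 33)
  Y <- simulate_feature_matrix(cohort, 8, slope = c(0.02, rep(0, 7)), seed = 9)
  res <- permutation_correct(Y, cohort, "p_dd", B = 300, seed = 4,
                             family_id = "fam")
  expect_true(all(res$p_corr >= res$p))
  expect_true(all(res$p > 0 & res$p <= 1))
  expect_true(all(res$p_corr > 0 & res$p_corr <= 1))

  # bit-exact reproducibility for the same (seed, B)
  res2 <- permutation_correct(Y, cohort, "p_dd", B = 300, seed = 4,
                              family_id = "fam")
  expect_identical(res, res2)

  # enlarging the family can only increase the corrected p of shared members
  sub <- permutation_correct(Y[, 1:3], cohort, "p_dd", B = 300, seed = 4,
                             family_id = "fam")
  expect_true(all(res$p_corr[1:3] >= sub$p_corr - 1e-12))

  # family of one: corrected p agrees with an uncorrected permutation p
  one <- permutation_correct(Y[, 1, drop = FALSE], cohort, "p_dd", B = 2000,
                             seed = 7, family_id = "solo")
  expect_lt(abs(one$p_corr - one$p), 0.05)

  expect_error(permutation_correct(Y, cohort, "p_dd", B = 50), "at least 100")
})

test_that("the penetrance model outranks the binary model under a dose-response", {
  wins <- vapply(1:100, function(r) {
    cohort <- default_cohort(seed = 4000 + r)
    y <- simulate_feature_matrix(cohort, 1, slope = 0.02, seed = 4000 + r)[, 1]
    t_dose <- abs(fit_glm(y, cohort, "p_dd")$t)
    t_bin <- abs(fit_glm(y, cohort, "carrier")$t)
    t_dose > t_bin
  }, logical(1))
  expect_gte(mean(wins), 0.8)
})

test_that("binary model is calibrated when carriers and controls match", {
  cohort <- default_cohort(seed = 44)
  set.seed(10)
  t_null <- vapply(1:60, function(r) {
    y <- rnorm(nrow(cohort))
    fit_glm(y, cohort, "carrier")$t
  }, numeric(1))
  expect_lt(abs(mean(t_null)), 0.4)
  expect_lt(mean(abs(t_null) > stats::qt(0.975, df = 32)), 0.15)
})

test_that("leave-one-CNV-out isolates the driving variant and keeps books", {
  cohort <- default_cohort(seed = 55)
  # effect carried entirely by 22q11.2 deletion subjects
  set.seed(2)
  y <- rnorm(nrow(cohort), 0, 0.3)
  y[cohort$cnv_label == "22q11.2 deletion"] <- y[cohort$cnv_label == "22q11.2 deletion"] + 3
  loo <- loo_cnv_sensitivity(y, cohort, "p_dd")
  est <- loo[loo$estimable, ]
  expect_identical(est$cnv_label[which.max(abs(est$delta_t))],
                   "22q11.2 deletion")

  # bookkeeping: carriers summed over omission rows = (#CNVs - 1) * total
  expect_equal(sum(loo$n_removed), 21)
  carriers_per_row <- 21 - loo$n_removed
  expect_equal(sum(carriers_per_row), (nrow(loo) - 1) * 21)

  cohort_zero <- cohort[cohort$cnv_label != "NRXN1 deletion", ]
  y_zero <- y[cohort$cnv_label != "NRXN1 deletion"]
  loo_z <- loo_cnv_sensitivity(y_zero, cohort_zero, "p_dd",
                               labels = "NRXN1 deletion")
  expect_equal(loo_z$delta_beta, 0)
  expect_equal(loo_z$delta_t, 0)
})

test_that("global PCA matches a brute-force decomposition and finds rank", {
  set.seed(111)
  cohort <- default_cohort(seed = 66)
  # rank-3 matrix: no variance beyond component 3
  L <- matrix(rnorm(36 * 3), 36, 3)
  X3 <- L %*% matrix(rnorm(3 * 12), 3, 12)
  g3 <- global_pca_test(X3, cohort, "p_dd", n_components = 3, B = 200,
                        seed = 1)
  expect_lt(sum(g3$explained_variance[-(1:3)]), 1e-8)
  # component scores are mutually orthogonal
  cc <- stats::cor(g3$scores)
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-6)

  # small fixture against a dense eigendecomposition oracle (up to sign)
  small_cohort <- default_cohort(seed = 77)[1:12, ]
  X <- matrix(rnorm(12 * 4), 12, 4)
  colnames(X) <- paste0("v", 1:4)
  g <- global_pca_test(X, small_cohort, "p_dd", n_components = 4, B = 200,
                       seed = 2)
  e <- eigen(stats::cov(scale(X)), symmetric = TRUE)
  Xs <- scale(X)
  for (j in 1:4) {
    expect_equal(abs(sum(g$loadings[, j] * e$vectors[, j])), 1,
                 tolerance = 1e-8)
    score_oracle <- Xs %*% e$vectors[, j]
    expect_equal(abs(stats::cor(g$scores[, j], score_oracle))[1], 1,
                 tolerance = 1e-8)
    expect_equal(stats::sd(g$scores[, j])^2, e$values[j], tolerance = 1e-8)
  }

  # constant columns are dropped with a warning
  Xc <- cbind(X, v5 = 1)
  expect_warning(global_pca_test(Xc, small_cohort, "p_dd", n_components = 3,
                                 B = 200, seed = 3), "constant")
})

test_that("global PCA flags the penetrance-linked component", {
  hits <- vapply(1:25, function(r) {
    cohort <- default_cohort(seed = 7000 + r)
    n <- nrow(cohort)
    with_seed_val <- 7000 + r
    set.seed(with_seed_val)
    # latent factor = scaled score, loading on 10 of 30 columns
    latent <- scale(cohort$p_dd)[, 1] * 1.2
    X <- matrix(rnorm(n * 30), n, 30)
    X[, 1:10] <- X[, 1:10] + outer(latent, runif(10, 0.8, 1.2))
    colnames(X) <- paste0("v", 1:30)
    g <- global_pca_test(X, cohort, "p_dd", n_components = 10, B = 500,
                         seed = r)
    sig <- which(g$results$p_corr <= 0.05)
    # the matching component is the one whose score correlates with the factor
    target <- which.max(abs(stats::cor(g$scores, latent)))
    length(sig) >= 1 && target %in% sig && all(sig == target)
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("corpus callosum ratio test recovers opposite-signed volume effects", {
  cohort0 <- default_cohort(seed = 81)
  fit0 <- cc_ratio_test(rep(2000, 36), rep(4000, 36), cohort0)
  expect_equal(attr(fit0, "ratio"), rep(0.5, 36))  # body/splenium per subject
  expect_identical(nrow(fit0), 2L)                 # one row per predictor

  # null: t centred on zero over replicates
  t_null <- vapply(1:40, function(r) {
    cohort <- default_cohort(seed = 8000 + r)
    set.seed(8000 + r)
    body <- rnorm(36, 2000, 100)
    splenium <- rnorm(36, 4000, 150)
    cc_ratio_test(body, splenium, cohort, predictors = "p_dd")$t
  }, numeric(1))
  expect_lt(abs(mean(t_null)), 0.4)

  # body shrinking and splenium growing with P: negative association
  neg <- vapply(1:25, function(r) {
    cohort <- default_cohort(seed = 9000 + r)
    set.seed(9000 + r)
    body <- 2000 * (1 - 0.003 * cohort$p_dd) + rnorm(36, 0, 60)
    splenium <- 4000 * (1 + 0.003 * cohort$p_dd) + rnorm(36, 0, 120)
    fit <- cc_ratio_test(body, splenium, cohort, predictors = "p_dd")
    fit$beta < 0 && fit$p < 0.05
  }, logical(1))
  expect_gte(mean(neg), 0.8)

  expect_error(cc_ratio_test(2000, 0, default_cohort(1)), "splenium")
})

test_that("score_correlation implements midrank Spearman with exact small-n p", {
  base <- data.frame(
    subject = paste0("s", 1:5),
    cnv_label = c("22q11.2 deletion", "3q29 deletion", "17q12 duplication",
                  "1q21.1 deletion", "NRXN1 deletion"),
    age = 30:34, gender = rep("M", 5), tbv = rep(1e6, 5), motion = rep(0.1, 5))
  perfect <- assign_scores(base)
  perfect$p_sz <- 1:5; perfect$p_dd <- c(2, 4, 6, 8, 10)
  r <- score_correlation(perfect)
  expect_equal(r$rho[r$subset == "all"], 1)

  reversed <- perfect; reversed$p_dd <- rev(reversed$p_dd)
  expect_equal(score_correlation(reversed)$rho[1], -1)

  # 5-pair fixture with ties against the brute-force oracle and cor.test
  fix <- perfect
  fix$p_sz <- c(2, 2, 5, 1, 4); fix$p_dd <- c(11, 8, 35, 8, 53)
  r2 <- score_correlation(fix)
  rho_pkg <- r2$rho[r2$subset == "all"]
  expect_equal(rho_pkg, brute_spearman(fix$p_sz, fix$p_dd), tolerance = 1e-12)
  ct <- suppressWarnings(stats::cor.test(fix$p_sz, fix$p_dd,
                                         method = "spearman"))
  expect_equal(rho_pkg, unname(ct$estimate), tolerance = 1e-12)
  expect_true(r2$p[1] > 0 && r2$p[1] <= 1)

  # degenerate zero-variance vector flagged (once per subset reported)
  flat <- perfect; flat$p_dd <- rep(3, 5)
  w <- testthat::capture_warnings(r3 <- score_correlation(flat))
  expect_true(all(grepl("zero-variance", w)))
  expect_true(is.na(r3$rho[1]))
})
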