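grid2mm <- function(extent = 32) {
  list(affine = diag(c(2, 2, 2, 1)), dim = rep(extent, 3))
}

test_that("bundle_volume counts traversed voxels times voxel volume", {
  g <- grid2mm()
  # straight line along x through exactly 3 voxel centres of a 2 mm grid
  s <- rbind(c(0, 0, 0), c(4, 0, 0))
  expect_equal(bundle_volume(list(s), g$affine, g$dim), 3 * 8)

  expect_equal(bundle_volume(list(), g$affine, g$dim), 0)

  # dense bundle filling a 10x10x10 mm box on a 1 mm grid
  set.seed(5)
  g1 <- list(affine = diag(4), dim = c(16L, 16L, 16L))
  box <- replicate(600, {
    y0 <- runif(1, 0, 10); z0 <- runif(1, 0, 10)
    rbind(c(0, y0, z0), c(10, y0 + runif(1, -0.3, 0.3), z0 + runif(1, -0.3, 0.3)))
  }, simplify = FALSE)
  vol <- bundle_volume(box, g1$affine, g1$dim)
  expect_lt(abs(vol - 11^3) / 11^3, 0.05)   # 11 voxel centres span 0..10

  # monotone under adding streamlines
  expect_lte(bundle_volume(box[1:100], g1$affine, g1$dim), vol)

  # oversampling refinement: halving the step changes volume < 2%
  v1 <- bundle_volume(box, g1$affine, g1$dim, step = 0.25)
  v2 <- bundle_volume(box, g1$affine, g1$dim, step = 0.125)
  expect_lt(abs(v1 - v2) / v1, 0.02)

  expect_error(bundle_volume(list(rbind(c(-50, 0, 0), c(0, 0, 0))),
                             g$affine, g$dim),
               "outside the grid")
})

test_that("sample_bundle_median interpolates trilinearly and takes the pooled median", {
  g <- grid2mm(16)
  const <- scalar_volume(array(0.7, rep(16, 3)), g$affine, "FA")
  s <- rbind(c(3, 3, 3), c(20, 18, 12))
  expect_equal(sample_bundle_median(list(s), const), 0.7)

  # map linear in x, straight bundle symmetric about x0: median = value at x0
  gridx <- array(rep(seq_len(16), times = 16 * 16), rep(16, 3))  # value = voxel x+1
  vol <- scalar_volume(gridx / 16, g$affine, "FA")
  x0 <- 14
  pts <- cbind(seq(x0 - 10, x0 + 10, length.out = 21), 8, 8)
  med <- sample_bundle_median(list(pts), vol)
  expect_equal(med, (x0 / 2 + 1) / 16, tolerance = 1e-6)

  # single point at a voxel centre returns the stored value exactly
  one <- scalar_volume(array(runif(16^3), rep(16, 3)), g$affine, "FA")
  p <- c(6, 8, 10)                      # voxel (3,4,5) 0-based
  expect_equal(sample_bundle_median(list(rbind(p, p + c(0, 0, 1e-9))), one),
               one$grid[4, 5, 6], tolerance = 1e-6)

  # invariance to point and streamline order
  set.seed(9)
  b <- replicate(4, cbind(runif(10, 2, 28), runif(10, 2, 28), runif(10, 2, 28)),
                 simplify = FALSE)
  m1 <- sample_bundle_median(b, one)
  m2 <- sample_bundle_median(rev(lapply(b, function(s) s[nrow(s):1, ])), one)
  expect_equal(m1, m2)
})

test_that("points outside the map are dropped up to 10%, then error", {
  g <- grid2mm(8)
  vol <- scalar_volume(array(0.5, rep(8, 3)), g$affine, "FA")
  inside <- cbind(runif(19, 1, 13), runif(19, 1, 13), runif(19, 1, 13))
  outside <- rbind(c(100, 0, 0))
  expect_message(
    med <- sample_bundle_median(list(rbind(inside, outside)), vol),
    "dropped")
  expect_equal(med, 0.5)
  many_out <- matrix(100, 10, 3)
  expect_error(sample_bundle_median(list(rbind(inside[1:10, ], many_out)), vol),
               "outside")
})

test_that("scalar_volume validates physical ranges and round-trips NIfTI", {
  expect_error(scalar_volume(array(1.5, c(4, 4, 4)), diag(4), "FA"),
               "physical range")
  A <- diag(c(2, 2, 2.4, 1)); A[1:3, 4] <- c(-20, -30, -12)
  set.seed(13)
  vol <- scalar_volume(array(runif(6 * 5 * 4), c(6, 5, 4)), A, "ICVF")
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_scalar_volume(vol, f)
  back <- read_scalar_volume(f, "ICVF")
  expect_equal(back$grid, vol$grid, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$affine, vol$affine, tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("assemble_features produces the documented column structure", {
  subjects <- c("s1", "s2")
  m <- 7L
  desc <- lapply(subjects, function(s) {
    matrix(rnorm(19 * m), 19, m, dimnames = list(bundle_vocabulary(), NULL))
  })
  names(desc) <- subjects
  vols <- lapply(subjects, function(s) {
    stats::setNames(runif(19, 1000, 5000), bundle_vocabulary())
  })
  names(vols) <- subjects
  meds <- lapply(subjects, function(s) {
    matrix(runif(19 * 9), 19, 9,
           dimnames = list(bundle_vocabulary(), default_metrics()))
  })
  names(meds) <- subjects
  fm <- assemble_features(desc, vols, meds)
  # 19 bundles x (9 metrics + volume) microstructural variables
  expect_identical(n_microstructural_variables(fm), 190L)
  expect_identical(ncol(fm), 19L * m + 190L)
  expect_false(any(duplicated(names(fm))))
  fams <- feature_families(fm)
  expect_identical(sum(fams$family == "shape"), 19L * m)
  expect_identical(sum(fams$family == "tract_volume"), 19L)
  expect_true(all(fams$volumetric[fams$family == "tract_volume"]))
  expect_false(fams$diffusion_derived[fams$column == "R1_cc_body"])
  expect_true(fams$diffusion_derived[fams$column == "FA_cc_body"])

  # smaller configuration: 2 bundles x (3 metrics + volume) = 8 columns
  fm2 <- assemble_features(
    volumes = list(s1 = c(cc_body = 1, cc_genu = 2),
                   s2 = c(cc_body = 3, cc_genu = 4)),
    medians = list(s1 = matrix(1, 2, 3, dimnames = list(c("cc_body", "cc_genu"),
                                                        c("FA", "MD", "ICVF"))),
                   s2 = matrix(2, 2, 3, dimnames = list(c("cc_body", "cc_genu"),
                                                        c("FA", "MD", "ICVF")))),
    bundles = c("cc_body", "cc_genu"), metrics = c("FA", "MD", "ICVF"))
  expect_identical(n_microstructural_variables(fm2), 8L)

  # a subject missing a bundle yields missing cells plus a warning
  vols_miss <- vols
  vols_miss$s2 <- vols_miss$s2[setdiff(names(vols_miss$s2), "fornix_l")]
  expect_warning(fm3 <- assemble_features(volumes = vols_miss), "missing")
  expect_true(is.na(fm3["s2", "volume_fornix_l"]))
  expect_false(is.na(fm3["s1", "volume_fornix_l"]))
})

test_that("feature matrix TSV round trip preserves values and family tags", {
  fm <- assemble_features(
    volumes = list(a = c(cc_body = 10.5, cc_genu = 2.25),
                   b = c(cc_body = 30.125, cc_genu = 4.5)),
    bundles = c("cc_body", "cc_genu"), metrics = character(0))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(fm, f)
  back <- read_feature_matrix(f)
  expect_equal(as.data.frame(back), as.data.frame(fm), ignore_attr = TRUE)
  expect_equal(feature_families(back)$family, feature_families(fm)$family)
})
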