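test_that("component maps are z-scored, sign-fixed, and thresholdable", {
  dat <- ica_recovery_data(seed = 101, n_subj = 2)
  ic <- group_spatial_ica(dat$subjects, n_components = 2, seed = 5,
                          analysis_window_min = NULL)
  for (k in 1:2) {
    expect_lt(abs(mean(ic$maps[, k])), 1e-10)
    expect_equal(var(ic$maps[, k]), 1, tolerance = 1e-8)
    expect_gte(mean(ic$maps[, k]^3), 0)   # positive skewness convention
  }
  thr <- threshold_components(ic)
  kept <- thr$maps != 0
  expect_true(all(abs(ic$maps[kept]) >= 1.96))
  expect_true(all(abs(ic$maps[!kept]) < 1.96))
  expect_error(group_spatial_ica(dat$subjects, n_components = 500,
                                 analysis_window_min = NULL),
               "smaller than total")
})

test_that("ICA output is reproducible and concatenation-order invariant", {
  dat <- ica_recovery_data(seed = 102)
  ic1 <- group_spatial_ica(dat$subjects, n_components = 2, seed = 9,
                           analysis_window_min = NULL)
  ic2 <- group_spatial_ica(dat$subjects, n_components = 2, seed = 9,
                           analysis_window_min = NULL)
  expect_identical(ic1$maps, ic2$maps)   # bit-for-bit given (inputs, seed)
  ic3 <- group_spatial_ica(rev(dat$subjects), n_components = 2, seed = 9,
                           analysis_window_min = NULL)
  m <- match_components(ic3$maps, ic1$maps)
  expect_true(all(m$abs_r >= 0.99))
})

test_that("planted disjoint patterns are recovered", {
  dat <- ica_recovery_data(seed = 103)
  ic <- group_spatial_ica(dat$subjects, n_components = 2, seed = 103,
                          analysis_window_min = NULL)
  m <- match_components(ic, dat$truth)
  expect_true(all(m$abs_r >= 0.95))
})

test_that("the analysis window restricts the frames used", {
  set.seed(104)
  arr <- array(rnorm(4 * 4 * 2 * 80), dim = c(4, 4, 2, 80))
  img <- tiny_image(arr)
  ic <- group_spatial_ica(list(img, img), n_components = 2, seed = 1,
                          analysis_window_min = c(30, 80))
  expect_equal(nrow(ic$maps), 32L)
  expect_equal(dim(ic$mask), c(4L, 4L, 2L))
  # manual restriction to the same frames gives identical maps
  mats <- lapply(list(img, img), function(im) {
    matrix(im$data, ncol = 80)[, frame_mid_min(im) >= 30 &
                                  frame_mid_min(im) < 80]
  })
  ic2 <- group_spatial_ica(mats, n_components = 2, seed = 1,
                           analysis_window_min = NULL)
  expect_identical(ic$maps, ic2$maps)
})

test_that("regional component scores match a voxel-loop oracle", {
  co <- simulate_cohort(sim_config(n_subjects = 2, make_images = TRUE,
                                   challenge_min = NULL, seed = 105))
  mask <- co$atlas$label_volume > 0
  ic <- group_spatial_ica(co$pet_images, mask = mask, n_components = 2,
                          seed = 1)
  sc <- regional_component_scores(ic, co$atlas)
  expect_equal(nrow(sc), 96L)   # 48 regions x 2 components
  expect_equal(sc$position[1:48], 1:48)  # table order
  labs <- as.integer(co$atlas$label_volume)[as.vector(mask)]
  for (p in c(1L, 25L, 48L)) {
    v <- ic$maps[labs == p, 2]
    row <- sc[sc$component == 2 & sc$position == p, ]
    expect_equal(row$mean_z, mean(v))
    expect_equal(row$sd_z, sd(v))
  }
})

test_that("a spatially uniform component scores equally across regions", {
  atlas <- toy_atlas()
  mask <- atlas$label_volume > 0
  maps <- structure(list(maps = matrix(2, sum(mask), 1), n_components = 1L,
                         threshold_z = 1.96, mask = mask,
                         dims = dim(mask), seed = 1L, n_iter = 0L),
                    class = "component_maps")
  sc <- regional_component_scores(maps, atlas)
  expect_true(all(sc$mean_z == 2))
  expect_true(all(sc$sd_z == 0))
})

test_that("component-effect correlation handles the canonical cases", {
  set.seed(106)
  v <- rnorm(48)
  expect_equal(component_effect_correlation(v, v)$r, 1)
  # orthogonalized vectors: residual of a regression has |r| ~ 0
  w <- rnorm(48)
  resid <- residuals(lm(w ~ v))
  expect_lt(abs(component_effect_correlation(v, resid)$r), 0.05)
  # planted matching pattern with 10% noise
  amp <- abs(rnorm(48, sd = 2))
  noisy <- amp + rnorm(48, sd = 0.1 * sd(amp))
  res <- component_effect_correlation(amp, noisy)
  expect_gt(res$r, 0.9)
  expect_lt(res$p, 0.001)
  expect_error(component_effect_correlation(v, rnorm(10)), "length mismatch")
  expect_error(component_effect_correlation(rnorm(3), rnorm(3)),
               "at least 5 regions")
})
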