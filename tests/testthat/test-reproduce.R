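# End-to-end study composition.

test_that("reproduce_study emits a complete, deterministic report", {
  n <- c(tandem = 12L, homomer = 10L, negative_pair = 12L,
         dimer = 8L, unlinked = 8L)
  s1 <- reproduce_study(seed = 71, n_rois = n)
  s2 <- reproduce_study(seed = 71, n_rois = n)
  expect_identical(s1$report, s2$report)
  expect_equal(nrow(s1$report), 10)
  expect_setequal(unique(s1$report$environment), c("live", "fixed"))
  expect_true(all(c("E_Fmax_mean", "E_Fmax_sem", "interaction_call", "n")
                  %in% names(s1$report)))
  expect_equal(nrow(s1$baseline), 2)
  expect_error(reproduce_study(), "seed")
})

test_that("the tandem calibration is computed per environment", {
  s <- reproduce_study(seed = 72,
                       n_rois = c(tandem = 15L, homomer = 6L,
                                  negative_pair = 6L, dimer = 6L,
                                  unlinked = 6L))
  expect_s3_class(s$calibrations$live, "tandem_calibration")
  expect_s3_class(s$calibrations$fixed, "tandem_calibration")
  expect_gt(s$calibrations$live$cf, 0)
})

test_that("synthetic images are written when requested", {
  skip_if_not_installed("tiff")
  tab <- simulate_experiment(population_config("tandem", n_rois = 4), seed = 73)
  d <- withr::local_tempdir()
  files <- render_roi_images(tab, d)
  expect_length(files, 5)
  expect_true(all(file.exists(file.path(
    d, c("cfp_pre.tif", "cfp_post.tif", "yfp_pre.tif", "yfp_post.tif",
         "roi_mask.tif")))))
  img <- tiff::readTIFF(file.path(d, "cfp_pre.tif"))
  expect_true(all(img >= 0 & img <= 1))
})
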