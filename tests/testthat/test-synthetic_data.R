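# Forward simulator: placement geometries, bleaching kinetics, fixation
# transform, intensity rendering.

test_that("tandem placement gives every donor exactly one acceptor at the linker distance", {
  cfg <- population_config("tandem", n_rois = 3)
  pop <- place_fluorophores(cfg, seed = 1)
  d_link <- tandem_linker_distance(cfg$tandem_efficiency, cfg$r0_nm)
  for (roi in pop$rois) {
    expect_true(all(roi$counts == 1L))
    expect_equal(length(roi$d), roi$n_donors)
    expect_true(all(roi$d == d_link))
    expect_equal(roi$n_acceptors, roi$n_donors)
  }
})

test_that("zero acceptor density leaves every acceptor field empty", {
  cfg <- population_config("unlinked_membrane", n_rois = 4,
                           acceptor_density = 0, ratio_range = NULL)
  pop <- place_fluorophores(cfg, seed = 2)
  for (roi in pop$rois) {
    expect_true(all(roi$counts == 0L))
    expect_length(roi$d, 0)
    expect_equal(roi$n_acceptors, 0)
  }
})

test_that("strand acceptor counts follow the binomial site assignment", {
  # 1e4 lattice sites at fraction 1/2: 3 sigma = 3 * sqrt(1e4 * 0.25) = 150
  cfg <- population_config("strand", n_rois = 1, ratio_range = NULL,
                           acceptor_density = 1, donor_density = 1,
                           strand_length_um = 61, lattice_spacing_nm = 6.1)
  pop <- place_fluorophores(cfg, seed = 3)
  n_sites <- pop$rois[[1]]$n_acceptors + pop$rois[[1]]$n_donors
  expect_equal(n_sites, 10000)
  expect_lt(abs(pop$rois[[1]]$n_acceptors - 5000), 150)
})

test_that("strand neighbours sit at lattice multiples within the cutoff", {
  cfg <- population_config("strand", n_rois = 1)
  pop <- place_fluorophores(cfg, seed = 4)
  roi <- pop$rois[[1]]
  s <- cfg$lattice_spacing_nm
  kmax <- floor(cfg$cutoff_factor * cfg$r0_nm / s)
  expect_true(all(roi$d %in% (seq_len(kmax) * s)))
  expect_true(all(roi$counts <= 2 * kmax))
})

test_that("simulation is deterministic given the seed", {
  cfg <- population_config("strand", n_rois = 6)
  t1 <- simulate_experiment(cfg, seed = 99)
  t2 <- simulate_experiment(cfg, seed = 99)
  expect_identical(t1, t2)
  t3 <- simulate_experiment(cfg, seed = 100)
  expect_false(identical(t1, t3))
})

test_that("seeded simulator calls do not disturb the caller's RNG stream", {
  set.seed(123)
  a <- runif(1)
  set.seed(123)
  invisible(simulate_experiment(population_config("tandem", n_rois = 2), seed = 5))
  expect_identical(runif(1), a)
})

test_that("bleached fraction matches the survival law", {
  cfg <- noiseless("tandem", n_rois = 2)
  pop <- place_fluorophores(cfg, seed = 6)

  b0 <- simulate_bleach(bleach_protocol("live", iterations = 0L,
                                        per_iteration_survival = 0.2), pop, seed = 1)
  expect_equal(b0$bleached_fraction, 0)

  # survival 0.2, one iteration: expected bleached fraction 0.8
  n_acc <- sum(vapply(pop$rois, function(r) r$n_acceptors, numeric(1)))
  b1 <- simulate_bleach(bleach_protocol("live", iterations = 1L,
                                        per_iteration_survival = 0.2), pop, seed = 2)
  expect_lt(abs(b1$bleached_fraction - 0.8), 3 * sqrt(0.8 * 0.2 / n_acc))

  # survival 0.99, 100 iterations: expected 1 - 0.99^100
  p <- 1 - 0.99^100
  b2 <- simulate_bleach(bleach_protocol("live", iterations = 100L,
                                        per_iteration_survival = 0.99), pop, seed = 3)
  expect_lt(abs(b2$bleached_fraction - p), 3 * sqrt(p * (1 - p) / n_acc))
})

test_that("the bleached-fraction estimator is unbiased over replicates", {
  cfg <- population_config("tandem", n_rois = 1, donor_density = 300,
                           roi_area_um2 = 1, roi_depth_um = 0.3)
  pop <- place_fluorophores(cfg, seed = 7)
  n_acc <- pop$rois[[1]]$n_acceptors
  prot <- bleach_protocol("live", iterations = 3L, per_iteration_survival = 0.6)
  truth <- 1 - 0.6^3
  set.seed(8)
  reps <- replicate(1000, simulate_bleach(prot, pop)$bleached_fraction)
  se <- sqrt(truth * (1 - truth) / (n_acc * 1000))
  expect_lt(abs(mean(reps) - truth), 3 * se)
})

test_that("the identity fixation transform leaves fields untouched", {
  pop <- place_fluorophores(population_config("strand", n_rois = 3), seed = 9)
  fixed <- apply_fixation(pop, fixation_transform("none"), seed = 1)
  expect_identical(fixed$rois, pop$rois)
  expect_identical(fixed$environment, "live")
})

test_that("distance compression never decreases any donor's true efficiency", {
  for (geom in c("strand", "unlinked_membrane", "dimer")) {
    pop <- place_fluorophores(population_config(geom, n_rois = 3), seed = 10)
    tr <- fixation_transform("5min", reorient_dipoles = FALSE)
    fixed <- apply_fixation(pop, tr)
    for (i in seq_along(pop$rois)) {
      e_live <- fretfix:::roi_efficiencies(pop$rois[[i]], pop$config$r0_nm)
      e_fix <- fretfix:::roi_efficiencies(fixed$rois[[i]], pop$config$r0_nm)
      expect_true(all(e_fix >= e_live))
    }
  }
})

test_that("fixation raises per-iteration survival via the multiplier", {
  prot <- bleach_protocol("live")
  pop <- place_fluorophores(population_config("tandem", n_rois = 1), seed = 11)
  out <- apply_fixation(pop, fixation_transform("5min"), protocol = prot, seed = 2)
  expect_equal(out$protocol$per_iteration_survival, 0.27^(1 / 43))
  expect_identical(out$population$environment, "fixed")
  # a protocol already in fixed terms is not adjusted twice
  out2 <- apply_fixation(pop, fixation_transform("5min"),
                         protocol = out$protocol, seed = 2)
  expect_equal(out2$protocol$per_iteration_survival,
               out$protocol$per_iteration_survival)
})

test_that("noise-free full-bleach rendering recovers ground truth exactly", {
  cfg <- noiseless("tandem", n_rois = 5)
  tab <- simulate_experiment(cfg, protocol = full_bleach(), seed = 12)
  I_B <- (tab$I_cfp_pre_1 + tab$I_cfp_pre_2) / 2
  I_A <- (tab$I_cfp_post_1 + tab$I_cfp_post_2) / 2
  expect_equal(efficiency_from_intensities(I_B, I_A), tab$ground_truth_E,
               tolerance = 1e-12)
  # duplicate frames are identical only because noise is off
  expect_equal(tab$I_cfp_pre_1, tab$I_cfp_pre_2)
})

test_that("partial bleaching dequenches the tandem donor by the exact closed form", {
  # With a fraction b of acceptors bleached and per-pair efficiency E, the
  # apparent efficiency of a tandem ROI is b*E / (1 - (1-b)*E): linear in b
  # only to first order in E.
  cfg <- noiseless("tandem", n_rois = 4, donor_density = 1e5)
  E_t <- cfg$tandem_efficiency
  tab <- simulate_experiment(
    cfg, protocol = bleach_protocol("live", iterations = 1L,
                                    per_iteration_survival = 0.5),
    seed = 13)
  apparent <- efficiency_from_intensities(
    (tab$I_cfp_pre_1 + tab$I_cfp_pre_2) / 2,
    (tab$I_cfp_post_1 + tab$I_cfp_post_2) / 2)
  b <- 0.5
  expected <- b * E_t / (1 - (1 - b) * E_t)
  # realized bleach fraction fluctuates binomially around 1/2 per ROI
  expect_equal(mean(apparent), expected, tolerance = 0.02)
  expect_gt(mean(apparent), E_t / 2)  # strictly above the first-order value
})

test_that("rendered tables carry the documented schema and non-negative intensities", {
  tab <- simulate_experiment(population_config("dimer", n_rois = 7), seed = 14)
  expect_equal(nrow(tab), 7)
  expect_named(tab, c("roi_id", "condition", "environment",
                      "I_cfp_pre_1", "I_cfp_pre_2", "I_cfp_post_1",
                      "I_cfp_post_2", "I_yfp_pre", "I_yfp_post",
                      "ground_truth_E"))
  expect_true(all(as.matrix(tab[, 4:9]) >= 0))
  expect_true(all(tab$environment == "live"))
})

test_that("default bleach kinetics match the live/fixed iteration counts", {
  live <- bleach_protocol("live")
  expect_gt(1 - live$per_iteration_survival^live$iterations, 0.80)
  expect_lt(1 - live$per_iteration_survival^1, 0.80)
  fixed <- bleach_protocol("fixed")
  expect_lt(1 - fixed$per_iteration_survival^5, 0.80)
  expect_gt(1 - fixed$per_iteration_survival^fixed$iterations, 0.80)
})
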