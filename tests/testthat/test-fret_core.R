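# Analytic FRET physics: orientation factor, radius scaling, transfer
# efficiency, quenching arithmetic.

ex <- c(1, 0, 0)
ey <- c(0, 1, 0)
ez <- c(0, 0, 1)

test_that("kappa_squared reproduces the canonical dipole geometries", {
  expect_equal(kappa_squared(dipole_geometry(ez, ez, ez)), 4)   # collinear
  expect_equal(kappa_squared(dipole_geometry(ex, ex, ez)), 1)   # parallel, perp to R
  expect_equal(kappa_squared(dipole_geometry(ex, ey, ez)), 0)   # orthogonal
  expect_equal(kappa_squared(dipole_geometry(ex, -ex, ez)), 1)  # anti-parallel
})

test_that("kappa_squared rejects non-unit vectors", {
  expect_error(dipole_geometry(c(1, 1, 0), ex, ez), "unit norm")
  expect_error(kappa_squared(list(ex, ex, ez)), "dipole_geometry")
})

test_that("kappa_squared is invariant under joint rotation and dipole sign flips", {
  set.seed(11)
  for (i in 1:25) {
    v <- matrix(rnorm(9), 3)
    v <- sweep(v, 2, sqrt(colSums(v^2)), "/")
    g <- dipole_geometry(v[, 1], v[, 2], v[, 3])
    k <- kappa_squared(g)
    expect_gte(k, 0)
    expect_lte(k, 4)
    # random rotation via QR decomposition
    Q <- qr.Q(qr(matrix(rnorm(9), 3)))
    gr <- dipole_geometry(drop(Q %*% v[, 1]), drop(Q %*% v[, 2]),
                          drop(Q %*% v[, 3]))
    expect_equal(kappa_squared(gr), k, tolerance = 1e-9)
    gs <- dipole_geometry(-v[, 1], v[, 2], v[, 3])
    expect_equal(kappa_squared(gs), k, tolerance = 1e-12)
  }
})

test_that("Forster radius scaling follows the sixth-root law", {
  p <- forster_pair()
  expect_equal(scale_forster_radius(p), p$r0)
  expect_equal(scale_forster_radius(p, new_kappa2 = 2 * p$kappa2),
               p$r0 * 2^(1 / 6))
  expect_equal(scale_forster_radius(p, new_n = 2 * p$refractive_index),
               p$r0 * 2^(-2 / 3))
  expect_equal(scale_forster_radius(p, new_QY = p$quantum_yield / 2,
                                    new_J = 2 * p$overlap_integral),
               p$r0)
  expect_warning(r <- scale_forster_radius(p, new_kappa2 = 0), "kappa")
  expect_identical(r, 0)
})

test_that("pair efficiency is 1/2 at r0, closed-form elsewhere, and monotone", {
  expect_equal(pair_efficiency(4.9, 4.9), 0.5)
  expect_equal(pair_efficiency(0, 3), 1)
  expect_equal(pair_efficiency(2 * 7, 7), 1 / 65)
  r <- seq(0.1, 20, by = 0.1)
  expect_true(all(diff(pair_efficiency(r, 4.9)) < 0))
  expect_error(pair_efficiency(1, -1), "positive")
})

test_that("multi-acceptor efficiency reduces to the pair case and adds monotonically", {
  r0 <- 4.9
  expect_equal(multi_acceptor_efficiency(r0, r0), 0.5)
  expect_equal(multi_acceptor_efficiency(c(r0, r0), r0), 2 / 3)
  expect_identical(multi_acceptor_efficiency(numeric(0), r0), 0)
  set.seed(21)
  for (i in 1:30) {
    d <- runif(sample(1:4, 1), 2, 12)
    expect_equal(multi_acceptor_efficiency(d[1], r0),
                 pair_efficiency(d[1], r0))
    e0 <- multi_acceptor_efficiency(d, r0)
    e1 <- multi_acceptor_efficiency(c(d, runif(1, 2, 12)), r0)
    expect_gte(e1, e0)
  }
})

test_that("quenching and dequenching are exact inverses", {
  expect_equal(quenched_intensity(100, 0.2), 80)
  expect_equal(quenched_intensity(100, 0), 100)
  expect_equal(quenched_intensity(100, 0.5), 50)
  expect_error(quenched_intensity(100, 1), "\\[0, 1\\)")
  E <- seq(0, 0.999, by = 0.001)
  I0 <- 123.4
  back <- efficiency_from_intensities(quenched_intensity(I0, E), I0)
  expect_equal(back, E, tolerance = 1e-12)
})

test_that("static isotropic kappa^2 sampler has mean 2/3 and support [0, 4]", {
  set.seed(5)
  k <- sample_kappa2_static(2e4)
  expect_true(all(k >= 0 & k <= 4))
  # 3 sigma of the Monte Carlo mean (sd of kappa^2 is about 0.7)
  expect_lt(abs(mean(k) - 2 / 3), 3 * sd(k) / sqrt(length(k)))
})
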