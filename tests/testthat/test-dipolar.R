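ge <- g_free_electron()

test_that("dipolar prefactor evaluates to the CODATA value", {
  expect_equal(physical_constants()$D0, 52.04, tolerance = 1e-3)
  expect_equal(nu0(1), physical_constants()$D0)
  expect_equal(nu0(2.50), 52.04 / 2.5^3, tolerance = 1e-3)
  expect_equal(nu0(2 * 1.7), nu0(1.7) / 8)
  expect_error(nu0(0), "r must be")
})

test_that("effective g-factor interpolates the principal values", {
  expect_equal(effective_g(g_heme, c(0, 0, 1)), 2.91)
  expect_equal(effective_g(g_heme, c(1, 0, 0)), 1.56)
  expect_equal(effective_g(g_heme, c(1, 1, 0) / sqrt(2)),
               sqrt((1.56^2 + 2.28^2) / 2), tolerance = 1e-12)
  expect_equal(effective_g(g_heme, c(1, 1, 0) / sqrt(2)), 1.9535,
               tolerance = 1e-4)
  expect_error(effective_g(g_heme, c(1, 1, 0)), "unit vector")
})

test_that("anisotropic frequency reproduces the axis-aligned limits", {
  r <- 2.5
  # field and inter-spin vector along g_zz: parallel edge scaled by g_zz
  expect_equal(abs(dipolar_frequency_aniso(g_heme, c(0, 0, 1), c(0, 0, 1), r)),
               2 * (2.91 / ge) * nu0(r), tolerance = 1e-12)
  # field along g_xx, inter-spin vector along g_zz: perpendicular component
  expect_equal(dipolar_frequency_aniso(g_heme, c(1, 0, 0), c(0, 0, 1), r),
               (1.56 / ge) * nu0(r), tolerance = 1e-12)
  expect_error(dipolar_frequency_aniso(g_heme, c(0, 0, 1), c(0, 0, 1), -1),
               "r must be")
})

test_that("isotropic tensor reduces the anisotropic formula to 1 - 3cos^2", {
  set.seed(21)
  b <- random_unit_vectors(1000)
  n <- random_unit_vectors(1000)
  giso <- principal_g_isotropic()
  va <- dipolar_frequency_aniso(giso, b, n, 2.5)
  theta <- acos(pmin(1, pmax(-1, rowSums(b * n)))) * 180 / pi
  vi <- dipolar_frequency_iso(2.5, theta)
  expect_lt(max(abs(va - vi) / pmax(abs(vi), 1e-12)), 1e-10)
  # magic angle zero
  th_m <- acos(sqrt(1 / 3)) * 180 / pi
  expect_equal(dipolar_frequency_iso(2.5, th_m), 0, tolerance = 1e-12)
  expect_equal(dipolar_frequency_iso(2.5, 90), nu0(2.5))
  expect_equal(dipolar_frequency_iso(2.5, 0), -2 * nu0(2.5))
})

test_that("frequency is even under sign flips of b and n", {
  set.seed(31)
  b <- random_unit_vectors(200)
  n <- random_unit_vectors(200)
  v <- dipolar_frequency_aniso(g_heme, b, n, 2.3)
  expect_equal(dipolar_frequency_aniso(g_heme, b, -n, 2.3), v,
               tolerance = 1e-14)
  expect_equal(dipolar_frequency_aniso(g_heme, -b, n, 2.3), v,
               tolerance = 1e-14)
})

test_that("frequencies scale with inverse cubed distance", {
  set.seed(41)
  b <- random_unit_vectors(50)
  n <- random_unit_vectors(50)
  v1 <- dipolar_frequency_aniso(g_heme, b, n, 2.0)
  v2 <- dipolar_frequency_aniso(g_heme, b, n, 2.0 * 1.7)
  expect_equal(v2, v1 / 1.7^3, tolerance = 1e-14)
})

test_that("powder sampling composes geometry and field draws", {
  m <- geometric_model(2.5, 0, 0, 0, 0, 0)
  f1 <- powder_frequency_samples(m, g_heme, 1, seed = 8)
  set.seed(8)
  geo <- sample_geometry(m, 1)
  b <- random_unit_vectors(1)
  expect_equal(f1, dipolar_frequency_aniso(g_heme, b, geo$nvec, geo$r))
  expect_identical(powder_frequency_samples(m, g_heme, 100, seed = 3),
                   powder_frequency_samples(m, g_heme, 100, seed = 3))
  # parallel edge of the xi = 0 powder pattern
  f <- powder_frequency_samples(m, g_heme, 2e5, seed = 12)
  expect_equal(max(abs(f)), 2 * (2.91 / ge) * nu0(2.5), tolerance = 1e-3)
})

test_that("histogram spectra are symmetric, normalized and Pake-like", {
  sp <- spectrum_from_samples(3.2, bin_width = 0.1)
  hot <- sp$freq[sp$amp > 0]
  expect_equal(sort(hot), c(-3.25, 3.25), tolerance = 1e-9)
  m <- geometric_model(2.5, 0)
  f <- powder_frequency_samples(m, principal_g_isotropic(), 2e5, seed = 13)
  bw <- default_bin_width(m)
  sp2 <- spectrum_from_samples(f, bw)
  expect_equal(sum(sp2$amp) * bw, 1, tolerance = 1e-12)
  expect_equal(sp2$amp, rev(sp2$amp))
  # Pake pattern: singularity at nu0 (theta = 90), edge at 2 nu0
  n0 <- nu0(2.5)
  expect_lt(abs(sp2$freq[which.max(sp2$amp)]) - n0, bw)
  expect_lt(abs(max(abs(sp2$freq[sp2$amp > 0]))) - 2 * n0, 2 * bw)
  expect_error(spectrum_from_samples(numeric(0), 0.1), "no frequencies")
})

test_that("Monte-Carlo spectrum matches the closed-form Pake density", {
  # oracle: with u = cos(theta) uniform, nu = nu0 (1 - 3 u^2) has density
  # 1 / (2 sqrt(3) nu0 sqrt(1 - nu/nu0)) on [-2 nu0, nu0]; symmetrized here
  r <- 2.5
  n0 <- nu0(r)
  m <- geometric_model(r, 0)
  n_mc <- 4e5
  f <- powder_frequency_samples(m, principal_g_isotropic(), n_mc, seed = 17)
  bw <- 2 * n0 / 101
  sp <- spectrum_from_samples(f, bw)
  pake <- function(nu) ifelse(nu < n0 & nu >= -2 * n0,
                              1 / (2 * sqrt(3) * n0 *
                                     sqrt(pmax(1 - nu / n0, 1e-300))), 0)
  # integrate the density over each bin (fine midpoint rule)
  dens <- vapply(sp$freq, function(fc) {
    xs <- seq(fc - bw / 2, fc + bw / 2, length.out = 51)
    mean((pake(xs) + pake(-xs)) / 2)
  }, numeric(1))
  # exclude the integrable singularity bins at +-nu0
  sing <- abs(abs(sp$freq) - n0) < 1.5 * bw
  n_per_bin <- n_mc * dens * bw
  tol <- 3 * sqrt(pmax(n_per_bin, 1)) / (n_mc * bw) + 0.02 * max(dens)
  expect_true(all(abs(sp$amp - dens)[!sing] <= tol[!sing]))
})

test_that("principal-axis singularities match the g-value ratios", {
  expect_equal(unname(principal_axis_singularities(g_heme, "z")),
               c(2 * 2.91, 1.56, 2.28) / ge, tolerance = 1e-12)
  expect_equal(unname(principal_axis_singularities(g_heme, "x")),
               c(2 * 1.56, 2.28, 2.91) / ge, tolerance = 1e-12)
  expect_equal(unname(principal_axis_singularities(g_heme, "y")),
               c(2 * 2.28, 1.56, 2.91) / ge, tolerance = 1e-12)
  expect_error(principal_axis_singularities(g_heme, "w"))
})
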