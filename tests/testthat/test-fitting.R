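test_that("rmsd computes the fit-region root-mean-square deviation", {
  t_ax <- c(-0.05, 0, 0.1, 0.2)
  a <- time_trace(t_ax, c(9, 1, 2, 3))     # the t < 0 point is excluded
  b <- time_trace(t_ax, c(0, 2, 4, 6))
  expect_equal(rmsd(a, a), 0)
  expect_equal(rmsd(a, b), sqrt(mean(c(1, 2, 3)^2)))
  off <- time_trace(t_ax, a$v + 0.25)
  expect_equal(rmsd(off, a), 0.25)
  expect_error(rmsd(a, time_trace(c(0, 0.1), c(1, 1))), "axes")
  # spectra: |nu| < 0.5 MHz excluded
  s1 <- dipolar_spectrum(c(-1, -0.2, 0.2, 1), c(1, 5, 5, 1))
  s2 <- dipolar_spectrum(c(-1, -0.2, 0.2, 1), c(2, 9, 9, 2))
  expect_equal(rmsd(s1, s2), 1)
})

test_that("the fit objective is deterministic and evenhanded on the orbit", {
  m <- geometric_model(2.5, 0.04, 69, 10, 27, 8)
  tr <- simulate_trace(m, g_heme, 0.35, n_mc = 2e5, seed = 22)
  opts <- quick_fit_options(seed = 4)
  opts$n_mc <- 2e4
  obj <- ridmefit:::.trace_objective(tr, g_heme, 0.35, opts)
  p <- c(2.5, 0.04, 69, 10, 27, 8)
  expect_identical(obj(p), obj(p))
  # objective at truth beats random parameter vectors
  set.seed(9)
  rand <- replicate(100, c(runif(1, 1.5, 5), runif(1, 0, 0.5),
                           runif(4, 0, 90)))
  expect_true(all(apply(rand, 2, obj) >= obj(p)))
  # symmetry-equivalent angle solutions give the same objective within
  # Monte-Carlo tolerance
  orb <- symmetry_related_angles(69, 27)
  vals <- apply(orb, 1, function(a) obj(c(2.5, 0.04, a[1], 10, a[2], 8)))
  expect_lt(diff(range(vals)), 5e-4)
})

test_that("a delta-model trace is recovered with near-zero widths", {
  m <- geometric_model(2.5, 0, 30, 0, 0, 0)
  tr <- simulate_trace(m, g_heme, 0.40, n_mc = 5e5, seed = 25)
  opts <- fit_options(n_mc = 1e4, n_mc_final = 1e5, n_mc_refine = 0,
                      n_pop = 32, n_gen = 60, seed = 7)
  res <- fit_time_trace(tr, g_heme, opts)
  v <- model_to_vector(res$model)
  expect_equal(unname(v["r_mean"]), 2.5, tolerance = 0.02 / 2.5)
  expect_lt(v[["r_sd"]], 0.02)
  expect_lt(v[["xi_sd"]], 5)
  expect_equal(res$lam, 0.40, tolerance = 0.02 / 0.40)
})

test_that("spectrum-domain fit agrees with the time-domain fit", {
  m <- geometric_model(2.5, 0, 30, 0, 0, 0)
  t_ax <- default_time_axis()
  tr <- simulate_trace(m, g_heme, 0.40, t_axis = t_ax, n_mc = 5e5, seed = 25)
  sp <- ridme_fft(tr, lam = 0.40)
  opts <- fit_options(n_mc = 1e4, n_mc_final = 5e4, n_mc_refine = 0,
                      n_pop = 28, n_gen = 50, seed = 7)
  opts$t_axis <- t_ax
  res_s <- fit_spectrum(sp, g_heme, opts, lam = 0.40)
  expect_equal(res_s$model$r$mean, 2.5, tolerance = 0.02 / 2.5)
  expect_equal(res_s$mode, "frequency-domain")
  # the spectrum is symmetric by construction: mirroring it is a no-op,
  # so the fit of the mirrored spectrum is identical
  sp_m <- dipolar_spectrum(sp$freq, rev(sp$amp))
  res_m <- fit_spectrum(sp_m, g_heme, opts, lam = 0.40)
  expect_identical(model_to_vector(res_m$model), model_to_vector(res_s$model))
})

test_that("RMSD surfaces locate the minimum and expose flat directions", {
  m <- geometric_model(2.5, 0, 0, 0, 0, 0)
  tr <- simulate_trace(m, g_heme, 0.40, n_mc = 2e5, seed = 33)
  opts <- quick_fit_options(seed = 5)
  opts$n_mc <- 2e4
  best <- structure(list(model = m, lam = 0.40, rmsd = 0,
                         mode = "time-domain", n_mc = opts$n_mc,
                         seed = opts$seed,
                         symmetry_orbit = symmetry_related_angles(0, 0),
                         converged = TRUE),
                    class = "fit_result")
  r_grid <- seq(2.40, 2.60, by = 0.01)
  s <- rmsd_surface(tr, g_heme, best, c("r_mean", "r_sd"), r_grid,
                    seq(0, 0.1, by = 0.02), options = opts)
  loc <- which(s$rmsd == s$rmsd_min, arr.ind = TRUE)
  expect_lt(abs(s$axis1[loc[1]] - 2.5), 0.011)
  expect_lt(s$axis2[loc[2]], 0.021)
  expect_equal(s$threshold, 1.10 * s$rmsd_min)
  # monotone rise away from the distance minimum
  prof <- apply(s$rmsd, 1, min)
  i0 <- which.min(prof)
  expect_true(all(diff(prof[i0:length(prof)]) > -1e-12))
  expect_true(all(diff(rev(prof[1:i0])) > -1e-12))
  # with xi = 0 the spectrum cannot depend on phi: the surface is flat
  s2 <- rmsd_surface(tr, g_heme, best, c("xi_mean", "phi_mean"),
                     c(0, 30), seq(0, 90, by = 30), options = opts)
  expect_lt(diff(range(s2$rmsd[1, ])), 1e-12)
  expect_error(rmsd_surface(tr, g_heme, best, c("bogus", "r_sd"),
                            1:2, 1:2, options = opts), "unknown parameter")
})

test_that("110 percent intervals project the threshold region", {
  m <- geometric_model(2.5, 0, 0, 0, 0, 0)
  tr <- simulate_trace(m, g_heme, 0.40, n_mc = 2e5, seed = 33)
  opts <- quick_fit_options(seed = 5)
  best <- structure(list(model = m, lam = 0.40, rmsd = 0,
                         mode = "time-domain", n_mc = opts$n_mc,
                         seed = opts$seed,
                         symmetry_orbit = symmetry_related_angles(0, 0),
                         converged = TRUE),
                    class = "fit_result")
  s <- rmsd_surface(tr, g_heme, best, c("r_mean", "r_sd"),
                    seq(2.3, 2.7, by = 0.01), seq(0, 0.2, by = 0.02),
                    options = opts)
  ci <- confidence_intervals(list(s))
  r_row <- ci[ci$parameter == "r_mean", ]
  expect_true(r_row$lo <= 2.5 && r_row$hi >= 2.5)
  # noiseless data: the interval shrinks toward the grid resolution
  expect_lt(r_row$half_width, 0.05)
  expect_false(r_row$degenerate)
})

test_that("fit results serialize to JSON with provenance", {
  m <- geometric_model(2.5, 0.03, 40, 10, 20, 5)
  res <- structure(list(model = m, lam = 0.3, rmsd = 0.01,
                        mode = "time-domain", n_mc = 1000, seed = 1,
                        symmetry_orbit = symmetry_related_angles(40, 20),
                        converged = TRUE),
                   class = "fit_result")
  path <- tempfile(fileext = ".json")
  write_fit_result(res, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$model$r_mean, 2.5)
  expect_equal(back$constants$g_e, 2.0023)
  expect_equal(nrow(back$symmetry_orbit), 8)
})
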