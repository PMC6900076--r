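#' Root-mean-square deviation between two traces or spectra
#'
#' RMSD over the fit region: t >= 0 for time traces, |nu| >= nu_min
#' (default 0.5 MHz, where background mis-fit dominates) for spectra.
#' Axes must match.
#'
#' @param sim,exp two \code{\link{time_trace}} or two
#'   \code{\link{dipolar_spectrum}} objects on the same axis.
#' @param nu_min spectral exclusion half-width, MHz.
#' @return Nonnegative scalar.
#' @export
rmsd <- function(sim, exp, nu_min = 0.5) {
  if (inherits(sim, "time_trace") && inherits(exp, "time_trace")) {
    if (length(sim$t) != length(exp$t) || max(abs(sim$t - exp$t)) > 1e-9)
      stop("time axes do not match")
    keep <- exp$t >= -1e-12
    return(sqrt(mean((sim$v[keep] - exp$v[keep])^2)))
  }
  if (inherits(sim, "dipolar_spectrum") && inherits(exp, "dipolar_spectrum")) {
    if (length(sim$freq) != length(exp$freq) ||
        max(abs(sim$freq - exp$freq)) > 1e-9)
      stop("frequency axes do not match")
    keep <- abs(exp$freq) >= nu_min
    return(sqrt(mean((sim$amp[keep] - exp$amp[keep])^2)))
  }
  stop("sim and exp must both be time traces or both dipolar spectra")
}

#' Default fit options
#'
#' Search bounds and optimizer settings for the six-parameter fit. The
#' default Monte-Carlo budget is two-tier: \code{n_mc} samples per objective
#' evaluation during the search and \code{n_mc_final} for the reported RMSD.
#'
#' @param n_mc Monte-Carlo samples per search evaluation (default 1e5).
#' @param n_mc_final samples for the final reported RMSD (default 1e6).
#' @param n_mc_refine samples for the angle-refinement stage (default 3e5;
#'   0 disables the stage). The orientation parameters are only weakly
#'   identified, so near-degenerate angle solutions are re-searched at this
#'   budget before the final selection.
#' @param n_pop,n_gen differential-evolution population and generations.
#' @param seed master seed; the per-evaluation Monte-Carlo seed and the
#'   optimizer seed are derived from it.
#' @param lower,upper named bounds for (r_mean, r_sd, xi_mean, xi_sd,
#'   phi_mean, phi_sd): defaults r_mean in [1.5, 5] nm, r_sd in [0, 0.5] nm,
#'   all angles in [0, 90] degrees.
#' @param refine_lam logical; fit the modulation depth as a 7th parameter.
#' @param polish logical; finish with a bounded quasi-Newton local search.
#' @param jacobian include the sin(xi) weight in P(xi) sampling.
#' @return Options list.
#' @export
fit_options <- function(n_mc = 1e5, n_mc_final = 1e6, n_mc_refine = 3e5,
                        n_pop = 64, n_gen = 200, seed = 1,
                        lower = c(r_mean = 1.5, r_sd = 0, xi_mean = 0,
                                  xi_sd = 0, phi_mean = 0, phi_sd = 0),
                        upper = c(r_mean = 5, r_sd = 0.5, xi_mean = 90,
                                  xi_sd = 90, phi_mean = 90, phi_sd = 90),
                        refine_lam = FALSE, polish = TRUE, jacobian = FALSE) {
  list(n_mc = n_mc, n_mc_final = n_mc_final, n_mc_refine = n_mc_refine,
       n_pop = n_pop, n_gen = n_gen, seed = seed, lower = lower,
       upper = upper, refine_lam = refine_lam, polish = polish,
       jacobian = jacobian)
}

.mc_seed <- function(seed) (seed * 7919L + 13L) %% 2147483647L

# Fast deterministic forward model on a uniform t >= 0 grid.
# The Monte-Carlo draws (standard normals for r, xi, phi and uniform field
# directions) are frozen once per fit, so every evaluation reuses the same
# randomness (common random numbers): the objective is bit-reproducible and
# smooth in the parameters. Frequencies are binned (n_bins) before the
# cosine recurrence; the bin width is far below the trace's frequency
# resolution, so binning error is negligible against Monte-Carlo noise.
.fast_signal_factory <- function(g, n_mc, mc_seed, t0, dt, nt,
                                 jacobian = FALSE, n_bins = 4096) {
  set.seed(mc_seed)
  Z <- matrix(stats::rnorm(3 * n_mc), ncol = 3)
  B <- matrix(stats::rnorm(3 * n_mc), ncol = 3)
  B <- B / sqrt(rowSums(B^2))
  g2 <- as.numeric(g)^2
  geff2 <- rowSums(sweep(B^2, 2, g2, `*`))
  W <- sweep(B, 2, g2, `*`) / geff2
  pc <- .pc()
  pref <- pc$D0 / pc$g_e * sqrt(geff2)
  deg <- pi / 180
  function(par, l) {
    r <- par[1] + par[2] * Z[, 1]
    r <- abs(r)                       # fold the (negligible) r <= 0 tail
    r[r < 1e-3] <- 1e-3
    xi <- (par[3] + par[4] * Z[, 2]) * deg
    phi <- (par[5] + par[6] * Z[, 3]) * deg
    sx <- sin(xi)
    nx <- sx * cos(phi); ny <- sx * sin(phi); nz <- cos(xi)
    wn <- W[, 1] * nx + W[, 2] * ny + W[, 3] * nz
    bn <- B[, 1] * nx + B[, 2] * ny + B[, 3] * nz
    nu <- abs(pref * (1 - 3 * wn * bn) / r^3)
    bw <- max(nu) / (n_bins - 1)
    idx <- pmin.int(as.integer(nu / bw) + 1L, n_bins)
    if (jacobian) {
      wts <- abs(sx)
      h <- numeric(n_bins)
      agg <- rowsum(wts, idx)
      h[as.integer(rownames(agg))] <- agg
      h <- h / sum(h)
    } else {
      h <- tabulate(idx, nbins = n_bins) / n_mc
    }
    s <- wmean_cos_uniform((seq_len(n_bins) - 0.5) * bw, h, t0, dt, nt)
    1 - l * (1 - s)
  }
}

# objective factories: deterministic RMSD as a function of the parameter
# vector (the slow general path handles non-uniform grids)
.trace_objective <- function(exp_trace, g, lam, opts) {
  keep <- exp_trace$t >= -1e-12
  t_fit <- exp_trace$t[keep]
  v_exp <- exp_trace$v[keep]
  mc_seed <- .mc_seed(opts$seed)
  jac <- isTRUE(opts$jacobian)
  n_mc <- opts$n_mc
  if (.is_uniform(t_fit) && length(t_fit) > 1) {
    signal <- .fast_signal_factory(g, n_mc, mc_seed, t_fit[1],
                                   t_fit[2] - t_fit[1], length(t_fit),
                                   jacobian = jac)
    return(function(par) {
      l <- if (length(par) >= 7) par[7] else lam
      sqrt(mean((signal(par, l) - v_exp)^2))
    })
  }
  function(par) {
    model <- vector_to_model(par)
    l <- if (length(par) >= 7) par[7] else lam
    freqs <- powder_frequency_samples(model, g, n_mc, seed = mc_seed,
                                      jacobian = jac)
    sim <- ridme_signal(freqs, l, t_fit)
    sqrt(mean((sim$v - v_exp)^2))
  }
}

.spectrum_objective <- function(exp_spec, g, lam, opts) {
  t_axis <- opts$t_axis
  t_fit <- t_axis[t_axis >= -1e-12]
  zf <- if (is.null(opts$zero_fill_factor)) 4 else opts$zero_fill_factor
  mc_seed <- .mc_seed(opts$seed)
  n_mc <- opts$n_mc
  signal <- .fast_signal_factory(g, n_mc, mc_seed, t_fit[1],
                                 t_fit[2] - t_fit[1], length(t_fit),
                                 jacobian = isTRUE(opts$jacobian))
  function(par) {
    l <- if (length(par) >= 7) par[7] else lam
    sim <- time_trace(t_fit, signal(par, l))
    sspec <- ridme_fft(sim, zero_fill_factor = zf, lam = l)
    rmsd(sspec, exp_spec)
  }
}

# pick up to k population members that are far apart in normalized
# parameter space, in order of objective value (candidate niches)
.distinct_candidates <- function(pop, val, lower, upper, k = 5,
                                 min_dist = 0.15) {
  ord <- order(val)
  span <- pmax(upper - lower, 1e-12)
  picked <- list()
  for (i in ord) {
    x <- (pop[i, ] - lower) / span
    if (all(vapply(picked, function(p)
      sqrt(sum((p - x)^2)) >= min_dist, logical(1)))) {
      picked[[length(picked) + 1]] <- x
      if (length(picked) == k) break
    }
  }
  t(vapply(picked, function(x) lower + x * span, numeric(length(lower))))
}

.polish <- function(objective, par, lower, upper, maxit = 60) {
  scale <- pmax(upper - lower, 1e-6)
  pol <- tryCatch(
    stats::optim(par, objective, method = "L-BFGS-B", lower = lower,
                 upper = upper,
                 control = list(maxit = maxit, parscale = scale)),
    error = function(e) NULL)
  if (!is.null(pol) && is.finite(pol$value)) list(par = pol$par,
                                                  value = pol$value)
  else list(par = par, value = objective(par))
}

# Multi-stage search. The orientation block (xi, phi means and widths) is
# only weakly identified: distinct angle solutions can differ by less than
# the Monte-Carlo noise of a cheap objective, so spurious local minima
# appear and persist until the Monte-Carlo budget is large. The fit
# therefore runs (1) a global differential evolution at the cheap search
# budget, (2) a deterministic lattice scan over the four angle parameters
# (distance pair clamped at the stage-1 optimum) at the intermediate
# n_mc_refine budget, where distinct angle basins separate, (3) a local
# polish of the distinct stage-1 candidates and the best lattice points,
# and (4) selection among all polished candidates at the full n_mc_final
# budget, which is also the reported RMSD.
.run_fit <- function(objective_of, lam, opts, mode, n_par_extra = 0) {
  lower <- unname(opts$lower)
  upper <- unname(opts$upper)
  if (n_par_extra) {
    lower <- c(lower, 0)
    upper <- c(upper, 1)
  }
  objective <- objective_of(opts$n_mc)
  de <- de_optimize(objective, lower, upper, n_pop = opts$n_pop,
                    n_gen = opts$n_gen, seed = opts$seed,
                    return_population = TRUE)
  cand <- .distinct_candidates(de$pop, de$val, lower, upper,
                               k = if (isTRUE(opts$polish)) 3 else 1)
  candidates <- lapply(seq_len(nrow(cand)), function(i) {
    if (isTRUE(opts$polish))
      .polish(objective, cand[i, ], lower, upper)
    else list(par = cand[i, ], value = objective(cand[i, ]))
  })
  n_ref <- if (is.null(opts$n_mc_refine)) 0 else opts$n_mc_refine
  if (isTRUE(opts$polish) && n_ref > opts$n_mc) {
    obj_ref <- objective_of(n_ref)
    base <- candidates[[1]]$par
    means <- seq(9, 81, length.out = 5)
    sds <- c(3, 15, 35, 65)
    lattice <- as.matrix(expand.grid(xi_mean = means, xi_sd = sds,
                                     phi_mean = means, phi_sd = sds))
    vals <- apply(lattice, 1, function(a) {
      p <- base
      p[3:6] <- a
      obj_ref(p)
    })
    for (i in order(vals)[1:3]) {
      p <- base
      p[3:6] <- lattice[i, ]
      candidates[[length(candidates) + 1]] <-
        .polish(obj_ref, p, lower, upper, maxit = 20)
    }
    # re-polish the stage-1 best at the refine budget as well
    candidates[[length(candidates) + 1]] <-
      .polish(obj_ref, base, lower, upper, maxit = 20)
  }
  obj_final <- objective_of(opts$n_mc_final)
  finals <- vapply(candidates, function(cd) obj_final(cd$par), numeric(1))
  b <- which.min(finals)
  par <- candidates[[b]]$par
  value <- finals[b]
  model <- vector_to_model(par)
  lam_fit <- if (n_par_extra) par[7] else lam
  structure(list(model = model, lam = lam_fit, rmsd = value, mode = mode,
                 n_mc = opts$n_mc, seed = opts$seed,
                 symmetry_orbit = symmetry_related_angles(model$xi$mean,
                                                          model$phi$mean),
                 converged = de$converged, evals = de$evals),
            class = "fit_result")
}

#' Fit a background-corrected RIDME time trace
#'
#' Six-parameter global fit of the Gaussian geometric model (means and widths
#' of r, xi, phi) to a background-corrected trace, with the modulation depth
#' fixed from the trace tail (or refined as a 7th parameter). The objective
#' is the RMSD between the Monte-Carlo simulated and the measured trace over
#' t >= 0; a fixed per-evaluation Monte-Carlo seed makes it deterministic.
#' The search is a seeded differential evolution followed by a bounded local
#' polish; the reported RMSD is re-evaluated at \code{n_mc_final} samples.
#'
#' @param exp_trace background-corrected \code{\link{time_trace}}.
#' @param g a \code{principal_g}.
#' @param options a list from \code{\link{fit_options}}.
#' @param lam modulation depth; estimated from the tail if NULL.
#' @return A \code{fit_result}: optimized \code{model}, \code{lam},
#'   \code{rmsd} (at \code{n_mc_final}), \code{mode}, seeds, the symmetry
#'   orbit of the fitted angles, and a convergence flag.
#' @export
fit_time_trace <- function(exp_trace, g, options = fit_options(), lam = NULL) {
  if (is.null(lam)) lam <- estimate_modulation_depth(exp_trace)
  objective_of <- function(n_mc) {
    o <- options
    o$n_mc <- n_mc
    .trace_objective(exp_trace, g, lam, o)
  }
  .run_fit(objective_of, lam, options, "time-domain",
           n_par_extra = as.integer(isTRUE(options$refine_lam)))
}

#' Fit a RIDME spectrum
#'
#' Same six-parameter search as \code{\link{fit_time_trace}} but with a
#' spectral objective: the simulated trace is pushed through the same
#' plateau-subtraction / even-extension FFT as the data and compared on
#' |nu| >= 0.5 MHz. \code{options$t_axis} must carry the time axis the
#' experimental spectrum was computed from (default experimental axis).
#'
#' @param exp_spec a \code{\link{dipolar_spectrum}} from
#'   \code{\link{ridme_fft}}.
#' @param g a \code{principal_g}.
#' @param options from \code{\link{fit_options}}; fields \code{t_axis} and
#'   \code{zero_fill_factor} select the transform grid.
#' @param lam modulation depth of the underlying trace (required).
#' @return A \code{fit_result}.
#' @export
fit_spectrum <- function(exp_spec, g, options = fit_options(), lam) {
  if (is.null(options$t_axis)) options$t_axis <- default_time_axis()
  objective_of <- function(n_mc) {
    o <- options
    o$n_mc <- n_mc
    .spectrum_objective(exp_spec, g, lam, o)
  }
  .run_fit(objective_of, lam, options, "frequency-domain",
           n_par_extra = as.integer(isTRUE(options$refine_lam)))
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("RIDME %s fit (RMSD %.5g, lambda %.3f, %s)\n", x$mode, x$rmsd,
              x$lam, if (x$converged) "converged" else "budget exhausted"))
  print(x$model)
  cat(sprintf("Symmetry-equivalent (xi, phi) solutions: %d\n",
              nrow(x$symmetry_orbit)))
  cat("(2-D RMSD surfaces give a lower bound for parameters' uncertainty)\n")
  invisible(x)
}

.par_names <- c("r_mean", "r_sd", "xi_mean", "xi_sd", "phi_mean", "phi_sd")

#' RMSD error surface over a pair of parameters
#'
#' Grid evaluation of the fit objective over two parameters with the other
#' four clamped at their optimized values — the 2-D slice scheme used to put
#' a lower bound on the parameter uncertainties.
#'
#' @param exp_trace background-corrected \code{\link{time_trace}}.
#' @param g a \code{principal_g}.
#' @param best a \code{fit_result}.
#' @param pair character(2): names among r_mean, r_sd, xi_mean, xi_sd,
#'   phi_mean, phi_sd.
#' @param grid1,grid2 numeric grids for the two parameters.
#' @param options from \code{\link{fit_options}} (controls n_mc and seed).
#' @return An \code{rmsd_surface}: \code{param_pair}, \code{axis1},
#'   \code{axis2}, \code{rmsd} matrix, \code{rmsd_min},
#'   \code{threshold} = 1.10 * rmsd_min.
#' @export
rmsd_surface <- function(exp_trace, g, best, pair, grid1, grid2,
                         options = fit_options()) {
  if (!all(pair %in% .par_names))
    stop("unknown parameter name(s): ", paste(setdiff(pair, .par_names),
                                              collapse = ", "))
  obj <- .trace_objective(exp_trace, g, best$lam, options)
  base <- model_to_vector(best$model)
  m <- matrix(NA_real_, length(grid1), length(grid2))
  i1 <- match(pair[1], .par_names)
  i2 <- match(pair[2], .par_names)
  for (i in seq_along(grid1)) {
    for (j in seq_along(grid2)) {
      p <- base
      p[i1] <- grid1[i]
      p[i2] <- grid2[j]
      m[i, j] <- obj(p)
    }
  }
  rmin <- min(m)
  structure(list(param_pair = pair, axis1 = grid1, axis2 = grid2, rmsd = m,
                 rmsd_min = rmin, threshold = 1.10 * rmin),
            class = "rmsd_surface")
}

#' Confidence intervals from RMSD surfaces (110 percent criterion)
#'
#' For each parameter covered by the surfaces, projects the region
#' \{RMSD <= 1.10 x min RMSD\} onto that parameter's axis. The global
#' minimum is taken across all supplied surfaces. These 2-D slices give a
#' lower bound for the parameters' uncertainty.
#'
#' @param surfaces list of \code{rmsd_surface} objects.
#' @return Data frame: parameter, mean (interval midpoint), half_width, lo,
#'   hi, degenerate (TRUE when the region collapses to grid resolution).
#' @export
confidence_intervals <- function(surfaces) {
  rmin <- min(vapply(surfaces, function(s) s$rmsd_min, numeric(1)))
  thr <- 1.10 * rmin
  acc <- list()
  step <- list()
  for (s in surfaces) {
    ok <- s$rmsd <= thr
    for (k in 1:2) {
      axis <- if (k == 1) s$axis1 else s$axis2
      vals <- if (k == 1) axis[apply(ok, 1, any)]
              else axis[apply(ok, 2, any)]
      nm <- s$param_pair[k]
      acc[[nm]] <- c(acc[[nm]], vals)
      step[[nm]] <- max(step[[nm]], stats::median(diff(axis)))
    }
  }
  out <- do.call(rbind, lapply(names(acc), function(nm) {
    v <- acc[[nm]]
    degen <- length(v) <= 1
    # each grid point represents a cell of one grid step: pad the projected
    # region by half a step so the interval resolution matches the grid
    pad <- step[[nm]] / 2
    lo <- if (length(v) == 0) NA_real_ else min(v) - pad
    hi <- if (length(v) == 0) NA_real_ else max(v) + pad
    data.frame(parameter = nm, mean = (lo + hi) / 2,
               half_width = (hi - lo) / 2, lo = lo, hi = hi,
               degenerate = degen)
  }))
  rownames(out) <- NULL
  out
}

#' Serialize a fit result to JSON
#' @param result a \code{fit_result}.
#' @param path output path.
#' @export
write_fit_result <- function(result, path) {
  out <- list(model = as.list(model_to_vector(result$model)),
              lam = result$lam, rmsd = result$rmsd, mode = result$mode,
              n_mc = result$n_mc, seed = result$seed,
              converged = result$converged,
              symmetry_orbit = result$symmetry_orbit,
              constants = physical_constants()[c("g_e", "D0")])
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
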