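#' Fit a third-order polynomial background
#'
#' Least-squares cubic in t fitted directly to the decaying trace on
#' [fit_start, t_max] (t >= 0 only), the standard practice for RIDME
#' backgrounds. The default fit window starts at 10 percent of t_max.
#'
#' @param trace a \code{\link{time_trace}}.
#' @param fit_start start of the fit window, microseconds (>= 0); default
#'   0.1 * max(t).
#' @return A \code{background_fit} list: \code{coeffs} (intercept, t, t^2,
#'   t^3), \code{fit_start}, \code{window} (index range used), \code{rss}.
#' @export
fit_background_poly3 <- function(trace, fit_start = NULL) {
  tmax <- max(trace$t)
  if (is.null(fit_start)) fit_start <- 0.1 * tmax
  if (fit_start < 0) stop("fit_start must be >= 0")
  idx <- which(trace$t >= fit_start)
  if (length(idx) < 8) stop("need at least 8 points beyond fit_start")
  tt <- trace$t[idx]
  fit <- stats::lm(v ~ t + I(t^2) + I(t^3),
                   data = data.frame(t = tt, v = trace$v[idx]))
  co <- unname(stats::coef(fit))
  bg <- .poly3_eval(co, pmax(trace$t, 0))
  if (any(bg <= 0))
    stop("fitted background is non-positive over the trace support")
  structure(list(coeffs = co, fit_start = fit_start,
                 window = range(idx), rss = sum(stats::resid(fit)^2)),
            class = "background_fit")
}

.poly3_eval <- function(co, t) co[1] + co[2] * t + co[3] * t^2 + co[4] * t^3

#' Evaluate a fitted background on a time axis
#' @param fit a \code{background_fit}.
#' @param t_us time axis, microseconds (clamped at 0 below the echo).
#' @return Background values.
#' @export
background_values <- function(fit, t_us) .poly3_eval(fit$coeffs, pmax(t_us, 0))

#' Divide a trace by its fitted background
#'
#' The background function is fitted to the decaying product of the
#' intermolecular background and the form-factor plateau, so the raw
#' quotient carries an overall factor of about 1/(1 - lambda). The quotient
#' is therefore renormalized to its value at the echo maximum (t = 0),
#' restoring the V(t)/V(0) convention: v'(0) = 1 and the tail plateau sits
#' at 1 - lambda.
#'
#' @param trace a \code{\link{time_trace}}.
#' @param fit a \code{background_fit} from \code{\link{fit_background_poly3}}.
#' @return Background-corrected \code{\link{time_trace}}.
#' @export
background_correct <- function(trace, fit) {
  b <- background_values(fit, trace$t)
  if (any(b <= 0)) stop("background non-positive on trace support")
  v <- trace$v / b
  i0 <- which.min(abs(trace$t))
  time_trace(trace$t, v / v[i0])
}

#' Estimate the modulation depth from the trace tail
#'
#' lambda = 1 - mean(v) over the last \code{tail_fraction} of the points of a
#' background-corrected trace that has decayed to its plateau.
#'
#' @param corrected background-corrected \code{\link{time_trace}}.
#' @param tail_fraction fraction of points averaged (default 0.1).
#' @return Estimated modulation depth.
#' @export
estimate_modulation_depth <- function(corrected, tail_fraction = 0.1) {
  n <- length(corrected$v)
  k <- max(1, round(tail_fraction * n))
  1 - mean(corrected$v[(n - k + 1):n])
}

#' RIDME spectrum by FFT of a corrected trace
#'
#' Takes the t >= 0 part of a background-corrected trace, subtracts the
#' plateau 1 - lambda (estimated from the tail unless supplied), extends the
#' cosine-modulated signal evenly to negative time, zero-fills and
#' transforms. The real part on a symmetric MHz axis is returned.
#'
#' @param corrected background-corrected \code{\link{time_trace}} on a
#'   uniform grid.
#' @param zero_fill_factor zero-filling multiple of the trace length
#'   (default 4).
#' @param apodization \code{"none"} (default) or \code{"hamming"}.
#' @param lam plateau level to subtract; estimated from the tail if NULL.
#' @return A \code{\link{dipolar_spectrum}} (real FFT amplitude; not
#'   density-normalized).
#' @export
ridme_fft <- function(corrected, zero_fill_factor = 4,
                      apodization = c("none", "hamming"), lam = NULL) {
  apodization <- match.arg(apodization)
  keep <- corrected$t >= -1e-12
  t <- corrected$t[keep]
  v <- corrected$v[keep]
  if (!.is_uniform(t)) stop("ridme_fft requires a uniform time grid")
  dt <- t[2] - t[1]
  if (is.null(lam)) lam <- estimate_modulation_depth(time_trace(t, v))
  s <- v - (1 - lam)
  if (apodization == "hamming") {
    n <- length(s)
    s <- s * (0.54 + 0.46 * cos(pi * (seq_len(n) - 1) / (n - 1)))
  }
  # zero-fill the t >= 0 part, then extend evenly so the DFT is exactly real
  m <- stats::nextn(zero_fill_factor * length(s), 2)
  s <- c(s, numeric(m - length(s)))
  ext <- c(s, rev(s[-1])[-1])          # x[k] = x[M - k], M = 2 (m - 1)
  M <- length(ext)
  sp <- Re(stats::fft(ext)) * dt
  fpos <- seq(0, m - 1) / (M * dt)
  apos <- sp[seq_len(m)]
  dipolar_spectrum(c(-rev(fpos[-1]), fpos), c(rev(apos[-1]), apos))
}

#' One-call preprocessing of a raw RIDME trace
#'
#' Background fit, division, modulation-depth estimate and FFT.
#'
#' @param trace raw \code{\link{time_trace}}.
#' @param fit_start background fit start, microseconds (default 10 percent
#'   of t_max).
#' @param tail_fraction tail fraction for the modulation-depth estimate.
#' @param zero_fill_factor,apodization passed to \code{\link{ridme_fft}}.
#' @return List: \code{corrected} trace, \code{background} fit, \code{lam},
#'   \code{spectrum}.
#' @export
preprocess_trace <- function(trace, fit_start = NULL, tail_fraction = 0.1,
                             zero_fill_factor = 4, apodization = "none") {
  bg <- fit_background_poly3(trace, fit_start)
  corr <- background_correct(trace, bg)
  lam <- estimate_modulation_depth(corr, tail_fraction)
  spec <- ridme_fft(corr, zero_fill_factor, apodization, lam = lam)
  list(corrected = corr, background = bg, lam = lam, spectrum = spec)
}
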