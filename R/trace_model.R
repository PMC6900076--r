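#' RIDME time-trace container
#'
#' Holds a time axis (microseconds internally; file interfaces use ns) and a
#' real echo amplitude. Experimental traces typically start at -50 ns; the
#' dipolar signal itself is defined for t >= 0.
#'
#' @param t_us strictly increasing time axis, microseconds.
#' @param v real amplitude, same length.
#' @return A \code{time_trace} list.
#' @export
time_trace <- function(t_us, v) {
  if (length(t_us) != length(v)) stop("t and v lengths differ")
  if (any(diff(t_us) <= 0)) stop("time axis must be strictly increasing")
  structure(list(t = as.numeric(t_us), v = as.numeric(v)), class = "time_trace")
}

#' @export
print.time_trace <- function(x, ...) {
  cat(sprintf("RIDME time trace: %d points, %.0f to %.0f ns\n",
              length(x$t), 1000 * min(x$t), 1000 * max(x$t)))
  invisible(x)
}

#' Default experimental time axis
#'
#' Mirrors the acquisition used for the heme model compounds: 360 points
#' starting at -50 ns in 8 ns increments (the handful of negative-time
#' points locate the echo maximum).
#'
#' @return Time axis in microseconds.
#' @export
default_time_axis <- function() seq(-50, by = 8, length.out = 360) / 1000

.is_uniform <- function(t) {
  d <- diff(t)
  length(d) == 0 || max(abs(d - d[1])) < 1e-9
}

#' RIDME form-factor signal from dipolar frequencies
#'
#' The intramolecular RIDME signal for a set of N Monte-Carlo dipolar
#' frequencies nu_i and a modulation depth lambda:
#' V(t)/V0 = 1 - (lambda/N) sum_i (1 - cos(2 pi nu_i t)).
#' V(0) = 1 exactly and 1 - 2 lambda <= V <= 1.
#'
#' @param freqs signed dipolar frequencies, MHz.
#' @param lam modulation depth in [0, 1].
#' @param t_axis time axis, microseconds.
#' @return A \code{\link{time_trace}}.
#' @export
ridme_signal <- function(freqs, lam, t_axis) {
  if (length(freqs) == 0) stop("no frequencies supplied")
  if (lam < 0 || lam > 1) stop("lam must lie in [0, 1]")
  if (.is_uniform(t_axis) && length(t_axis) > 1) {
    s <- mean_cos_uniform(freqs, t_axis[1], t_axis[2] - t_axis[1],
                          length(t_axis))
  } else {
    s <- mean_cos_general(freqs, t_axis)
  }
  time_trace(t_axis, 1 - lam * (1 - s))
}

#' Simulate a background-free RIDME time trace
#'
#' Monte-Carlo powder average of the anisotropic dipolar signal: draws
#' geometries and field orientations, computes the dipolar frequencies and
#' sums the cosine modulation.
#'
#' @param model a \code{geometric_model}.
#' @param g a \code{principal_g}.
#' @param lam modulation depth in [0, 1].
#' @param t_axis time axis, microseconds (default experimental axis).
#' @param n_mc Monte-Carlo samples (default 1e6).
#' @param seed RNG seed.
#' @param jacobian passed to \code{\link{sample_geometry}}.
#' @return A \code{\link{time_trace}}.
#' @export
simulate_trace <- function(model, g, lam, t_axis = default_time_axis(),
                           n_mc = 1e6, seed = NULL, jacobian = FALSE) {
  freqs <- powder_frequency_samples(model, g, n_mc, seed = seed,
                                    jacobian = jacobian)
  ridme_signal(freqs, lam, t_axis)
}

#' Apply an intermolecular background to a trace
#'
#' Multiplies the form factor by scale * exp(-k1 t - k2 t^2), the
#' linear-plus-quadratic exponent that describes RIDME backgrounds. Time is
#' clamped at zero for t < 0 (the background refocuses at the echo).
#'
#' @param trace a \code{\link{time_trace}}.
#' @param k1 linear decay rate, 1/us.
#' @param k2 quadratic decay rate, 1/us^2.
#' @param scale amplitude at t = 0.
#' @return A \code{\link{time_trace}}.
#' @export
apply_background <- function(trace, k1 = 0, k2 = 0, scale = 1) {
  tt <- pmax(trace$t, 0)
  time_trace(trace$t, trace$v * scale * exp(-k1 * tt - k2 * tt^2))
}

#' Add white Gaussian noise to a trace
#' @param trace a \code{\link{time_trace}}.
#' @param sigma noise standard deviation in amplitude units (>= 0).
#' @param seed RNG seed.
#' @return A \code{\link{time_trace}}.
#' @export
add_noise <- function(trace, sigma, seed = NULL) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(trace)
  if (!is.null(seed)) set.seed(seed)
  time_trace(trace$t, trace$v + sigma * stats::rnorm(length(trace$v)))
}

#' Add a weak ESEEM contaminant peak
#'
#' Optionally mimics an unsuppressed nuclear ESEEM line: a small cosine at a
#' fixed frequency multiplying the trace, off by default in
#' \code{\link{generate_dataset}}.
#'
#' @param trace a \code{\link{time_trace}}.
#' @param freq contaminant frequency, MHz (default 12).
#' @param amplitude fractional modulation amplitude (default 0.02).
#' @return A \code{\link{time_trace}}.
#' @export
add_eseem <- function(trace, freq = 12, amplitude = 0.02) {
  tt <- pmax(trace$t, 0)
  time_trace(trace$t, trace$v * (1 - amplitude * (1 - cos(2 * pi * freq * tt))))
}

#' Generate a synthetic RIDME dataset with ground truth
#'
#' Full fixture pipeline: powder-averaged form factor, multiplicative
#' background, optional ESEEM contaminant, additive white noise. The returned
#' manifest records every parameter and seed, so the dataset regenerates
#' bit-identically.
#'
#' @param model a \code{geometric_model} (ground truth).
#' @param g a \code{principal_g}.
#' @param lam modulation depth.
#' @param k1,k2,scale background parameters (see \code{\link{apply_background}}).
#' @param noise_sd additive Gaussian noise sd.
#' @param eseem logical; include the 12 MHz contaminant.
#' @param eseem_freq,eseem_amp contaminant parameters.
#' @param t_axis time axis, microseconds.
#' @param n_mc Monte-Carlo samples for the form factor.
#' @param seed RNG seed governing the form factor draw.
#' @param noise_seed RNG seed for the noise.
#' @return A \code{synthetic_dataset} list: \code{trace} (with background and
#'   noise), \code{clean} (background-free, noise-free form factor) and
#'   \code{truth} (manifest list).
#' @export
generate_dataset <- function(model, g, lam, k1 = 0.08, k2 = 0.01, scale = 1,
                             noise_sd = 0, eseem = FALSE, eseem_freq = 12,
                             eseem_amp = 0.02, t_axis = default_time_axis(),
                             n_mc = 1e6, seed = 1, noise_seed = seed + 1) {
  clean <- simulate_trace(model, g, lam, t_axis, n_mc = n_mc, seed = seed)
  tr <- apply_background(clean, k1 = k1, k2 = k2, scale = scale)
  if (eseem) tr <- add_eseem(tr, eseem_freq, eseem_amp)
  tr <- add_noise(tr, noise_sd, seed = noise_seed)
  truth <- list(model = model_to_vector(model), g = as.numeric(g), lam = lam,
                k1 = k1, k2 = k2, scale = scale, noise_sd = noise_sd,
                eseem = eseem, eseem_freq = eseem_freq, eseem_amp = eseem_amp,
                n_mc = n_mc, seed = seed, noise_seed = noise_seed)
  structure(list(trace = tr, clean = clean, truth = truth),
            class = "synthetic_dataset")
}

#' Write / read a synthetic-dataset manifest
#'
#' The JSON manifest holds the full ground truth and all seeds;
#' \code{dataset_from_manifest} regenerates the identical dataset.
#'
#' @param dataset a \code{synthetic_dataset}.
#' @param path JSON file path.
#' @export
write_manifest <- function(dataset, path) {
  truth <- dataset$truth
  truth$t_axis_ns <- dataset$trace$t * 1000
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_manifest
#' @return \code{dataset_from_manifest}: the regenerated \code{synthetic_dataset}.
#' @export
dataset_from_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  generate_dataset(vector_to_model(m$model),
                   principal_g(m$g[1], m$g[2], m$g[3]),
                   lam = m$lam, k1 = m$k1, k2 = m$k2, scale = m$scale,
                   noise_sd = m$noise_sd, eseem = m$eseem,
                   eseem_freq = m$eseem_freq, eseem_amp = m$eseem_amp,
                   t_axis = m$t_axis_ns / 1000, n_mc = m$n_mc,
                   seed = m$seed, noise_seed = m$noise_seed)
}
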