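#' Isotropic dipolar coupling constant
#'
#' The dipolar coupling constant of an isotropic spin-1/2 pair at distance r,
#' nu0 = mu0 beta_e^2 g_e^2 / (4 pi h r^3), about 52.04 MHz at 1 nm.
#'
#' @param r inter-spin distance(s), nm (> 0).
#' @return Frequency in MHz.
#' @export
#' @examples
#' nu0(2.50)  # about 3.33 MHz
nu0 <- function(r) {
  if (any(r <= 0)) stop("r must be > 0")
  .pc()$D0 / r^3
}

#' Effective g-factor along a field direction
#'
#' For a rhombic g-tensor with principal values (gx, gy, gz) and a unit field
#' direction b in the eigenframe, g_eff = sqrt(gx^2 bx^2 + gy^2 by^2 + gz^2 bz^2).
#'
#' @param g a \code{principal_g}.
#' @param b unit 3-vector or n x 3 matrix of unit vectors.
#' @return Effective g-factor(s).
#' @export
#' @examples
#' effective_g(principal_g(1.56, 2.28, 2.91), c(0, 0, 1))  # 2.91
effective_g <- function(g, b) {
  b <- rbind(b)
  nb <- sqrt(rowSums(b^2))
  if (any(abs(nb - 1) > 1e-8)) stop("b must be a unit vector")
  unname(sqrt(rowSums(sweep(b^2, 2, as.numeric(g)^2, `*`))))
}

#' Anisotropic dipolar coupling frequency
#'
#' Signed dipolar coupling frequency of a pair made of one anisotropic
#' spin-1/2 (g-tensor with principal values g) and one isotropic spin-1/2 at
#' g_e, for field direction b and inter-spin unit vector n (both in the
#' g-eigenframe) and distance r:
#' \deqn{\nu_{dd} = \frac{\mu_0 \beta_e^2}{4\pi h} \frac{g_{eff} g_e}{r^3}
#'       \left[1 - 3\,(\mathbf{w}\cdot\mathbf{n})(\mathbf{b}\cdot\mathbf{n})\right],}
#' where w = (gx^2 bx, gy^2 by, gz^2 bz) / g_eff^2 is the unit-field vector
#' transported through the g-tensor. For an isotropic tensor at g_e this
#' reduces exactly to the classical 1 - 3 cos^2(theta) form.
#'
#' @param g a \code{principal_g}.
#' @param b unit field direction(s): 3-vector or n x 3 matrix.
#' @param n unit inter-spin direction(s): 3-vector or n x 3 matrix.
#' @param r distance(s), nm.
#' @return Signed frequency in MHz.
#' @export
dipolar_frequency_aniso <- function(g, b, n, r) {
  if (any(r <= 0)) stop("r must be > 0")
  b <- rbind(b); n <- rbind(n)
  g2 <- as.numeric(g)^2
  geff2 <- rowSums(sweep(b^2, 2, g2, `*`))
  geff <- sqrt(geff2)
  wn <- rowSums(sweep(b, 2, g2, `*`) * n) / geff2
  bn <- rowSums(b * n)
  pc <- .pc()
  unname(pc$D0 / pc$g_e * geff / r^3 * (1 - 3 * wn * bn))
}

#' Isotropic dipolar coupling frequency
#'
#' nu = nu0(r) (1 - 3 cos^2 theta) for two isotropic spin-1/2 centers.
#'
#' @param r distance(s), nm.
#' @param theta angle(s) between inter-spin vector and field, degrees.
#' @return Signed frequency in MHz.
#' @export
dipolar_frequency_iso <- function(r, theta) {
  if (any(r <= 0)) stop("r must be > 0")
  nu0(r) * (1 - 3 * cos(theta * pi / 180)^2)
}

#' Monte-Carlo powder sample of dipolar frequencies
#'
#' Combines one geometry draw per sample (from the Gaussian model) with one
#' uniform field orientation, and evaluates the anisotropic dipolar frequency.
#' This is the elementary averaging step behind both simulated spectra and
#' simulated time traces.
#'
#' @param model a \code{geometric_model}.
#' @param g a \code{principal_g}.
#' @param n_mc number of Monte-Carlo samples.
#' @param seed integer RNG seed.
#' @param jacobian passed to \code{\link{sample_geometry}}.
#' @return Numeric vector of n_mc signed frequencies, MHz.
#' @export
powder_frequency_samples <- function(model, g, n_mc, seed = NULL,
                                     jacobian = FALSE) {
  if (n_mc < 1) stop("n_mc must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  geo <- sample_geometry(model, n_mc, seed = NULL, jacobian = jacobian)
  b <- random_unit_vectors(n_mc, seed = NULL)
  dipolar_frequency_aniso(g, b, geo$nvec, geo$r)
}

#' Dipolar spectrum container
#'
#' @param freq frequency axis, MHz.
#' @param amp amplitude density per MHz.
#' @return A \code{dipolar_spectrum} list.
#' @export
dipolar_spectrum <- function(freq, amp) {
  if (length(freq) != length(amp)) stop("freq and amp lengths differ")
  structure(list(freq = freq, amp = amp), class = "dipolar_spectrum")
}

#' @export
print.dipolar_spectrum <- function(x, ...) {
  cat(sprintf("Dipolar spectrum: %d bins, %.3f to %.3f MHz\n",
              length(x$freq), min(x$freq), max(x$freq)))
  invisible(x)
}

#' Symmetrized, density-normalized histogram spectrum
#'
#' Bins signed dipolar frequencies on a symmetric grid about zero,
#' symmetrizes amp(nu) = amp(-nu) and normalizes to unit integral.
#'
#' @param freqs signed frequencies, MHz.
#' @param bin_width histogram bin width, MHz (> 0).
#' @return A \code{\link{dipolar_spectrum}}.
#' @export
spectrum_from_samples <- function(freqs, bin_width) {
  if (length(freqs) == 0) stop("no frequencies supplied")
  if (bin_width <= 0) stop("bin_width must be > 0")
  fmax <- max(abs(freqs)) + bin_width
  k <- ceiling(fmax / bin_width)
  breaks <- seq(-k * bin_width, k * bin_width, by = bin_width)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  idx <- findInterval(freqs, breaks, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = length(centers))
  amp <- (counts + rev(counts)) / 2
  amp <- amp / (sum(amp) * bin_width)
  dipolar_spectrum(centers, amp)
}

#' Default histogram bin width for a model
#' @param model a \code{geometric_model}.
#' @return 2 nu0(r_mean) / 201, MHz.
#' @export
default_bin_width <- function(model) 2 * nu0(model$r$mean) / 201

#' Analytic singularity positions of principal-axis spectra
#'
#' When the inter-spin vector lies along one principal axis of the g-tensor,
#' the powder dipolar spectrum shows three singularities: a parallel edge at
#' 2 g_axis / g_e (in units of nu0) and two perpendicular features at
#' g_i / g_e for the remaining two axes.
#'
#' @param g a \code{principal_g}.
#' @param axis one of "x", "y", "z": the axis the inter-spin vector lies on.
#' @return Named numeric (parallel, perp1, perp2) in units of nu0, the
#'   perpendicular components in x, y, z order of the remaining axes.
#' @export
#' @examples
#' principal_axis_singularities(principal_g(1.56, 2.28, 2.91), "z")
principal_axis_singularities <- function(g, axis = c("z", "x", "y")) {
  axis <- match.arg(axis)
  ge <- .pc()$g_e
  gv <- as.numeric(g)
  names(gv) <- c("x", "y", "z")
  par <- 2 * gv[[axis]] / ge
  perp <- gv[setdiff(c("x", "y", "z"), axis)] / ge
  c(parallel = unname(par), perp1 = unname(perp[1]), perp2 = unname(perp[2]))
}

#' Export a dipolar spectrum to disk
#'
#' Two-column ASCII (MHz, density) with '#' comment header, or CSV.
#'
#' @param spec a \code{dipolar_spectrum}.
#' @param path output file; extension ".csv" selects CSV.
#' @param header extra comment lines to include.
#' @export
write_spectrum <- function(spec, path, header = character()) {
  df <- data.frame(freq_MHz = spec$freq, amplitude = spec$amp)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (h in header) writeLines(paste0("# ", h), con)
    writeLines("# freq_MHz amplitude", con)
    writeLines(sprintf("%.17g %.17g", df$freq_MHz, df$amplitude), con)
  }
  invisible(path)
}
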