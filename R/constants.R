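#' Physical constants for dipolar EPR calculations
#'
#' Evaluates the dipolar prefactor from CODATA values at load time rather than
#' hard-coding it. Internally the package works in MHz, nm and microseconds,
#' so that frequency times time is dimensionless cycles.
#'
#' @return A list with elements \code{mu0} (vacuum permeability, N A^-2),
#'   \code{h} (Planck constant, J s), \code{beta_e} (Bohr magneton, J T^-1),
#'   \code{g_e} (free-electron g-factor, 2.0023), and \code{D0}, the derived
#'   prefactor mu0 beta_e^2 g_e^2 / (4 pi h) expressed in MHz nm^3
#'   (about 52.04).
#' @export
#' @examples
#' physical_constants()$D0
physical_constants <- function() {
  mu0    <- 1.25663706212e-6   # N A^-2
  h      <- 6.62607015e-34     # J s
  beta_e <- 9.2740100783e-24   # J T^-1
  g_e    <- 2.0023
  # mu0 beta_e^2 g_e^2 / (4 pi h): Hz m^3 -> MHz nm^3 is a factor 1e-6/1e-27
  D0 <- mu0 * beta_e^2 * g_e^2 / (4 * pi * h) * 1e21
  list(mu0 = mu0, h = h, beta_e = beta_e, g_e = g_e, D0 = D0)
}

.const <- new.env(parent = emptyenv())

.onLoad <- function(libname, pkgname) {
  cc <- physical_constants()
  assign("pc", cc, envir = .const)
  invisible()
}

# internal accessors (fall back if .onLoad has not run, e.g. during development)
.pc <- function() {
  if (!exists("pc", envir = .const)) assign("pc", physical_constants(), envir = .const)
  get("pc", envir = .const)
}

#' Free-electron g-factor used throughout the package
#' @return The scalar 2.0023.
#' @export
g_free_electron <- function() .pc()$g_e
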