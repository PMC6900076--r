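#' Principal g-values of the anisotropic spin center
#'
#' Constructor for the three principal g-values of the anisotropic spin-1/2
#' center (e.g. a bis-imidazole low-spin ferric heme has roughly
#' gx = 1.56, gy = 2.28, gz = 2.91). All vectors in this package are expressed
#' in the eigenframe of this tensor, so only the principal values are needed.
#'
#' @param gx,gy,gz positive dimensionless principal g-values along the x, y
#'   and z eigenaxes.
#' @return An object of class \code{principal_g} (named numeric of length 3).
#' @export
#' @examples
#' principal_g(1.56, 2.28, 2.91)
#' principal_g_isotropic()  # both spins isotropic at g_e
principal_g <- function(gx, gy, gz) {
  g <- c(gx = gx, gy = gy, gz = gz)
  if (any(!is.finite(g)) || any(g <= 0))
    stop("principal g-values must be finite and > 0")
  structure(g, class = "principal_g")
}

#' @rdname principal_g
#' @export
principal_g_isotropic <- function() {
  ge <- g_free_electron()
  principal_g(ge, ge, ge)
}

#' Gaussian distribution parameter
#'
#' Mean and standard deviation of one geometric variable (distance in nm or
#' angle in degrees). \code{sd = 0} denotes a delta distribution.
#'
#' @param mean mean value, in the variable's unit.
#' @param sd standard deviation, same unit, >= 0.
#' @return A \code{gaussian_param} list.
#' @export
gaussian_param <- function(mean, sd = 0) {
  if (!is.finite(mean) || !is.finite(sd) || sd < 0)
    stop("gaussian_param requires finite mean and sd >= 0")
  structure(list(mean = mean, sd = sd), class = "gaussian_param")
}

#' Gaussian geometric model of a spin pair
#'
#' The six-parameter model used for fitting: uncorrelated Gaussians for the
#' inter-spin distance r (nm) and for the polar (xi) and azimuthal (phi)
#' angles (degrees) of the inter-spin vector in the g-tensor eigenframe.
#'
#' @param r_mean,r_sd distance mean (> 0) and width, nm.
#' @param xi_mean,xi_sd polar angle mean and width, degrees.
#' @param phi_mean,phi_sd azimuthal angle mean and width, degrees.
#' @return A \code{geometric_model} list with \code{gaussian_param} fields
#'   \code{r}, \code{xi}, \code{phi}.
#' @export
#' @examples
#' geometric_model(2.48, 0.05, 69, 24, 27, 20)
geometric_model <- function(r_mean, r_sd = 0, xi_mean = 0, xi_sd = 0,
                            phi_mean = 0, phi_sd = 0) {
  if (r_mean <= 0) stop("r_mean must be > 0")
  structure(list(r = gaussian_param(r_mean, r_sd),
                 xi = gaussian_param(xi_mean, xi_sd),
                 phi = gaussian_param(phi_mean, phi_sd)),
            class = "geometric_model")
}

#' @export
print.geometric_model <- function(x, ...) {
  cat(sprintf("Gaussian spin-pair geometry:\n  r   = %.3f +/- %.3f nm\n  xi  = %.1f +/- %.1f deg\n  phi = %.1f +/- %.1f deg\n",
              x$r$mean, x$r$sd, x$xi$mean, x$xi$sd, x$phi$mean, x$phi$sd))
  invisible(x)
}

#' Model parameters as a named vector
#' @param model a \code{geometric_model}.
#' @return Named numeric of length 6 (r_mean, r_sd, xi_mean, xi_sd, phi_mean, phi_sd).
#' @export
model_to_vector <- function(model) {
  c(r_mean = model$r$mean, r_sd = model$r$sd,
    xi_mean = model$xi$mean, xi_sd = model$xi$sd,
    phi_mean = model$phi$mean, phi_sd = model$phi$sd)
}

#' @rdname model_to_vector
#' @param x named or positional numeric of length 6.
#' @export
vector_to_model <- function(x) {
  geometric_model(x[[1]], x[[2]], x[[3]], x[[4]], x[[5]], x[[6]])
}

#' Unit vector from polar and azimuthal angles in the g-frame
#'
#' Maps the polar angle xi (from the g_zz axis) and azimuth phi (from the
#' g_xx axis in the g_xx/g_yy plane) to a unit 3-vector. Vectorized.
#'
#' @param xi polar angle(s), degrees.
#' @param phi azimuthal angle(s), degrees.
#' @return An n x 3 matrix of unit vectors (columns x, y, z).
#' @export
#' @examples
#' unit_vector_from_angles(0, 45)    # the g_zz pole
#' unit_vector_from_angles(90, 0)    # the g_xx axis
unit_vector_from_angles <- function(xi, phi) {
  xr <- xi * pi / 180
  pr <- phi * pi / 180
  cbind(x = sin(xr) * cos(pr), y = sin(xr) * sin(pr), z = cos(xr))
}

#' Extract (xi, phi) angles from unit vectors
#' @param n an n x 3 matrix of unit vectors.
#' @return A two-column matrix (xi, phi) in degrees, phi in [0, 360).
#' @export
angles_from_unit_vector <- function(n) {
  n <- rbind(n)
  xi <- acos(pmin(1, pmax(-1, n[, 3]))) * 180 / pi
  phi <- atan2(n[, 2], n[, 1]) * 180 / pi
  phi <- ifelse(phi < 0, phi + 360, phi)
  cbind(xi = xi, phi = phi)
}

#' Uniform random unit vectors on the sphere
#'
#' Normalized 3-D standard normals; used for powder averaging of the field
#' direction. Reproducible for a given seed.
#'
#' @param n number of vectors (>= 1).
#' @param seed integer RNG seed.
#' @return An n x 3 matrix of unit vectors.
#' @export
random_unit_vectors <- function(n, seed) {
  if (n < 1) stop("n must be >= 1")
  if (!missing(seed) && !is.null(seed)) set.seed(seed)
  m <- matrix(stats::rnorm(3 * n), ncol = 3)
  m / sqrt(rowSums(m^2))
}

#' Sample spin-pair geometries from a Gaussian model
#'
#' Draws r, xi and phi independently from their Gaussians. Draws with r <= 0
#' are rejected and resampled. By default the angle distributions are taken
#' as Gaussians in the angles themselves, without the sin(xi) solid-angle
#' Jacobian (the convention of Gaussian-model dipolar fitting programs);
#' set \code{jacobian = TRUE} to weight P(xi) by sin(xi) via rejection.
#'
#' @param model a \code{geometric_model}.
#' @param n number of samples.
#' @param seed integer RNG seed (optional; current RNG state used if missing).
#' @param jacobian logical; include the sin(xi) solid-angle factor.
#' @return List with numeric \code{r} (nm), \code{xi}, \code{phi} (degrees)
#'   and the n x 3 unit-vector matrix \code{nvec}.
#' @export
sample_geometry <- function(model, n, seed = NULL, jacobian = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  r <- model$r$mean + model$r$sd * stats::rnorm(n)
  bad <- which(r <= 0)
  while (length(bad) > 0) {
    r[bad] <- model$r$mean + model$r$sd * stats::rnorm(length(bad))
    bad <- bad[r[bad] <= 0]
  }
  xi <- model$xi$mean + model$xi$sd * stats::rnorm(n)
  if (jacobian && model$xi$sd > 0) {
    # accept xi with probability |sin xi| (rejection against the envelope 1)
    u <- stats::runif(n)
    bad <- which(u > abs(sin(xi * pi / 180)))
    while (length(bad) > 0) {
      xi[bad] <- model$xi$mean + model$xi$sd * stats::rnorm(length(bad))
      u <- stats::runif(length(bad))
      bad <- bad[u > abs(sin(xi[bad] * pi / 180))]
    }
  }
  phi <- model$phi$mean + model$phi$sd * stats::rnorm(n)
  list(r = r, xi = xi, phi = phi, nvec = unit_vector_from_angles(xi, phi))
}

#' Symmetry-equivalent orientation angles
#'
#' The powder dipolar spectrum is invariant under sign flips of the components
#' of the inter-spin unit vector in the g-eigenframe, so each (xi, phi) pair
#' belongs to an orbit of up to eight equivalent pairs within [0, 360):
#' \{xi, 180 - xi\} x \{phi, 180 - phi, 180 + phi, 360 - phi\}.
#'
#' @param xi,phi angles in degrees.
#' @return Data frame with columns \code{xi}, \code{phi}, the distinct orbit
#'   members (angles reduced to [0, 360)).
#' @export
#' @examples
#' symmetry_related_angles(69, 27)
symmetry_related_angles <- function(xi, phi) {
  xs <- c(xi, 180 - xi) %% 360
  ps <- c(phi, 180 - phi, 180 + phi, 360 - phi) %% 360
  orb <- expand.grid(xi = xs, phi = ps)
  orb <- unique(round(orb, 9))
  rownames(orb) <- NULL
  orb[order(orb$xi, orb$phi), , drop = FALSE]
}

#' Reduce orientation angles to the canonical search range
#'
#' Maps any (xi, phi) to its symmetry-orbit member with xi and phi in
#' [0, 90], the range in which the angles are fitted.
#'
#' @param xi,phi angles in degrees.
#' @return Named numeric c(xi, phi) in [0, 90]^2.
#' @export
canonical_angles <- function(xi, phi) {
  orb <- symmetry_related_angles(xi, phi)
  ok <- orb[orb$xi <= 90 + 1e-9 & orb$phi <= 90 + 1e-9, , drop = FALSE]
  c(xi = ok$xi[1], phi = ok$phi[1])
}
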