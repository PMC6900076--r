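#' Seeded differential-evolution minimizer
#'
#' Compact DE/rand/1/bin global optimizer with box constraints, used for the
#' six-parameter trace fit. The objective must be deterministic (the fit
#' fixes the Monte-Carlo seed per evaluation), so repeated runs with the same
#' seed are bit-identical.
#'
#' @param fn objective: numeric vector -> scalar.
#' @param lower,upper box bounds (equal length).
#' @param n_pop population size (default 64).
#' @param n_gen number of generations (default 200).
#' @param f differential weight (default 0.7).
#' @param cr crossover probability (default 0.9).
#' @param seed RNG seed.
#' @param init optional matrix of initial members (rows), clamped to bounds.
#' @param tol early stop when the population objective spread falls below
#'   tol * (1 + |best|) (default 1e-8; 0 disables).
#' @param return_population also return the final population and its values.
#' @return List: \code{par}, \code{value}, \code{evals}, \code{converged};
#'   plus \code{pop}, \code{val} if requested.
#' @export
de_optimize <- function(fn, lower, upper, n_pop = 64, n_gen = 200, f = 0.7,
                        cr = 0.9, seed = NULL, init = NULL, tol = 1e-8,
                        return_population = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  d <- length(lower)
  pop <- matrix(stats::runif(n_pop * d, rep(lower, each = n_pop),
                             rep(upper, each = n_pop)), nrow = n_pop)
  if (!is.null(init)) {
    init <- rbind(init)
    k <- min(nrow(init), n_pop)
    pop[seq_len(k), ] <- pmin(pmax(init[seq_len(k), , drop = FALSE],
                                   rep(lower, each = k)),
                              rep(upper, each = k))
  }
  val <- apply(pop, 1, fn)
  evals <- n_pop
  converged <- FALSE
  for (gen in seq_len(n_gen)) {
    for (i in seq_len(n_pop)) {
      idx <- sample(setdiff(seq_len(n_pop), i), 3)
      mut <- pop[idx[1], ] + f * (pop[idx[2], ] - pop[idx[3], ])
      cross <- stats::runif(d) < cr
      cross[sample.int(d, 1)] <- TRUE
      trial <- ifelse(cross, mut, pop[i, ])
      trial <- pmin(pmax(trial, lower), upper)
      tv <- fn(trial)
      evals <- evals + 1
      if (tv <= val[i]) {
        pop[i, ] <- trial
        val[i] <- tv
      }
    }
    if (tol > 0 && diff(range(val)) < tol * (1 + abs(min(val)))) {
      converged <- TRUE
      break
    }
  }
  b <- which.min(val)
  out <- list(par = pop[b, ], value = val[b], evals = evals,
              converged = converged)
  if (return_population) {
    out$pop <- pop
    out$val <- val
  }
  out
}
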