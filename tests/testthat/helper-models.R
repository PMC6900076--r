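# shared fixtures: the heme-compound g-tensor and the published Gaussian
# geometry parameter sets (with their confidence intervals) used as ground
# truth for synthetic-data recovery tests

g_heme <- principal_g(1.56, 2.28, 2.91)

# columns: value, half-width of the confidence interval
compound_models <- list(
  "1-Im2" = list(
    truth = c(r_mean = 2.48, r_sd = 0.05, xi_mean = 69, xi_sd = 24,
              phi_mean = 27, phi_sd = 20),
    ci = c(r_mean = 0.03, r_sd = 0.05, xi_mean = 21, xi_sd = 24,
           phi_mean = 27, phi_sd = 20),
    lam = 0.30),
  "2-Im2" = list(
    truth = c(r_mean = 2.44, r_sd = 0.05, xi_mean = 84, xi_sd = 23,
              phi_mean = 30, phi_sd = 13),
    ci = c(r_mean = 0.02, r_sd = 0.04, xi_mean = 23, xi_sd = 23,
           phi_mean = 30, phi_sd = 17),
    lam = 0.40),
  "1T-Im2" = list(
    truth = c(r_mean = 2.64, r_sd = 0.06, xi_mean = 71, xi_sd = 3,
              phi_mean = 57, phi_sd = 30),
    ci = c(r_mean = 0.01, r_sd = 0.02, xi_mean = 19, xi_sd = 20,
           phi_mean = 7, phi_sd = 9),
    lam = 0.42))

model_of <- function(cm) vector_to_model(cm$truth)

# fast optimizer settings for small test fits
quick_fit_options <- function(seed = 1, ...) {
  fit_options(n_mc = 5e3, n_mc_final = 2e4, n_mc_refine = 0, n_pop = 24,
              n_gen = 40, seed = seed, ...)
}
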