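# Default infusion-study parameter set used across the suite:
# E = 0.15 mL^-1, R = 7 mmHg.mL^-1.min, p_b = 8 mmHg, I = 1.5 mL/min,
# sigma = 0.5 mL/min. Equilibrium R*I + p_b = 18.5 mmHg.
default_params <- function(...) csf_params(...)

# Random valid parameter draw with sigma strictly inside the
# stationary-existence region (as a fixed fraction of the bound).
random_valid_params <- function(frac_of_bound = stats::runif(1, 0.05, 0.95)) {
  E <- stats::runif(1, 0.05, 0.3)
  R <- stats::runif(1, 4, 12)
  p_b <- stats::runif(1, 4, 12)
  I <- stats::runif(1, 0.5, 3)
  bound <- 2 * (R * I + p_b) / (R * E)
  csf_params(E = E, R = R, p_b = p_b, I = I,
             sigma = sqrt(frac_of_bound * bound))
}
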