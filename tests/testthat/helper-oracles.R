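# Closed-form normal-equations OLS, independent of stats::lm.
# Returns c(intercept, slope) of y on x.
ols_normal_equations <- function(x, y) {
  X <- cbind(1, x)
  drop(solve(t(X) %*% X, t(X) %*% y))
}

# Small noiseless campaign config shared by round-trip tests.
noiseless_config <- function(seed = 1L, ...) {
  campaign_config(agb_noise_cv = 0, ndvi_noise_sd = 0,
                  spectral_noise_sd = 0, seed = seed, ...)
}

# Relative difference safe for values away from zero.
rel_err <- function(x, ref) abs(x - ref) / abs(ref)

# Published model constants used as generator defaults.
REF_A <- 12.523
REF_B <- 3.370
REF_C <- 0.462
REF_D <- 0.413
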