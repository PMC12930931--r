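# shared fixture builders: small, fast configurations with known truth

# spline coefficients reproducing straight-line-in-f curves on the default basis
curve_coefs <- function(levels0, levels18, spl = spline_spec()) {
  tg <- seq(0, 18, by = 0.25)
  Xg <- basis_matrix(tg, spl)
  t(mapply(function(a, b) stats::lm.fit(Xg, a + (b - a) * tg / 18)$coefficients,
           levels0, levels18))
}

# K-class config with an optional Hg membership coefficient (standardized
# log2 scale) on the last class; curves spaced by `gap0` at birth and `gap`
# at 18 months (so between-class separation interpolates between the two)
kmix_config <- function(K = 2, n = 400, seed = 1, gap = 25, gamma_hg = 0,
                        sigma_b = 3, sigma_e = 4, jitter = 0.1,
                        missing = 0.1, gap0 = 3) {
  dc <- default_calibration()
  beta <- curve_coefs(seq(64, by = gap0, length.out = K),
                      seq(115, by = gap, length.out = K))
  gam <- matrix(0, K, 14)
  gam[K, 3] <- gamma_hg   # column 3 = Hg
  sim_config(n, 0.5, beta, gam, spline_spec(),
             random_intercept_sd = sigma_b, residual_sd = sigma_e,
             visit_jitter_sd = jitter, missing_visit_prob = missing,
             element_log_means = dc$element_log_means,
             element_log_sds = dc$element_log_sds,
             element_corr = dc$element_corr, lods = dc$lods,
             covariate_specs = dc$covariate_specs, seed = seed)
}

# analysis-ready small cohort
quick_analysis <- function(config) preprocess_cohort(generate_cohort(config))

# dense multivariate-normal log-density by explicit covariance inversion:
# the independent oracle for the Woodbury-form subject likelihood
dense_mvn_loglik <- function(y, X, beta, sigma_b, sigma_e) {
  n <- length(y)
  S <- sigma_b^2 * matrix(1, n, n) + sigma_e^2 * diag(n)
  r <- y - drop(X %*% beta)
  -0.5 * (n * log(2 * pi) + determinant(S)$modulus[1] +
          drop(crossprod(r, solve(S, r))))
}
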