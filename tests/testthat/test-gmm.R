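test_that("Woodbury subject likelihood matches dense covariance inversion", {
  set.seed(4)
  spl <- spline_spec()
  for (i in 1:20) {
    n <- sample(1:8, 1)
    ages <- sort(runif(n, 0, 18))
    X <- basis_matrix(ages, spl)
    beta <- rnorm(5, c(68, 20, 40, 55, 65), 3)
    y <- drop(X %*% beta) + rnorm(n, 0, 5)
    sb <- runif(1, 0.5, 8); se <- runif(1, 0.5, 8)
    expect_equal(subject_loglik(y, X, beta, sb, se),
                 dense_mvn_loglik(y, X, beta, sb, se), tolerance = 1e-10)
  }
})

test_that("subject likelihood limits: independence and single observation", {
  spl <- spline_spec()
  ages <- c(0, 4, 9, 15)
  X <- basis_matrix(ages, spl)
  beta <- c(68, 20, 40, 55, 65)
  y <- drop(X %*% beta) + c(1, -2, 0.5, 3)
  # sigma_b = 0: independent Gaussians
  expect_equal(subject_loglik(y, X, beta, 0, 4),
               sum(dnorm(y, drop(X %*% beta), 4, log = TRUE)),
               tolerance = 1e-12)
  # one observation: variance sigma_b^2 + sigma_e^2
  X1 <- X[2, , drop = FALSE]
  expect_equal(subject_loglik(y[2], X1, beta, 3, 4),
               dnorm(y[2], drop(X1 %*% beta), sqrt(9 + 16), log = TRUE),
               tolerance = 1e-12)
})

test_that("one-class fit matches the linear mixed model ML oracle", {
  skip_if_not_installed("lme4")
  an <- quick_analysis(kmix_config(K = 1, n = 150, seed = 41))
  fit <- fit_gmm(an, K = 1, n_starts = 1, seed = 1, compute_vcov = FALSE)
  X <- basis_matrix(an$growth$age, fit$spline)
  d <- data.frame(y = an$growth$wfl, id = an$growth$subject_id)
  lmer_fit <- lme4::lmer(y ~ X - 1 + (1 | id), data = d, REML = FALSE)
  expect_equal(unname(drop(fit$beta)), unname(lme4::fixef(lmer_fit)),
               tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(stats::logLik(lmer_fit)),
               tolerance = 1e-6)
  vc <- lme4::VarCorr(lmer_fit)
  expect_equal(fit$sigma_b, attr(vc$id, "stddev")[[1]], tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(fit$sigma_e, stats::sigma(lmer_fit), tolerance = 1e-3)
})

test_that("EM log-likelihood is monotone non-decreasing", {
  an <- quick_analysis(kmix_config(K = 3, n = 200, seed = 43, gap = 15))
  fit <- fit_gmm(an, K = 3, n_starts = 2, seed = 2, compute_vcov = FALSE)
  expect_true(all(diff(fit$loglik_trace) > -1e-6))
  expect_true(fit$converged)
})

test_that("classes are reported in ascending 18-month order", {
  an <- quick_analysis(kmix_config(K = 3, n = 250, seed = 45, gap = 18))
  fit <- fit_gmm(an, K = 3, n_starts = 2, seed = 1, compute_vcov = FALSE)
  at18 <- drop(basis_matrix(18, fit$spline) %*% t(fit$beta))
  expect_true(all(diff(at18) > 0))
  expect_equal(unname(fit$gamma[1, ]), rep(0, ncol(fit$gamma)))
})

test_that("posterior probabilities match brute-force evaluation", {
  an <- quick_analysis(kmix_config(K = 2, n = 60, seed = 47))
  fit <- fit_gmm(an, K = 2, n_starts = 2, seed = 1, compute_vcov = FALSE)
  P <- fit$posterior
  expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-8,
               ignore_attr = TRUE)
  d <- fit$data
  for (i in sample(fit$n_subjects, 10)) {
    sel <- d$subj == i
    lf <- vapply(1:2, function(k)
      subject_loglik(d$y[sel], d$X[sel, , drop = FALSE], fit$beta[k, ],
                     fit$sigma_b, fit$sigma_e), numeric(1))
    eta <- drop(fit$gamma %*% d$W[i, ])
    a <- lf + eta - max(eta)
    expect_equal(unname(P[i, ]), unname(exp(a) / sum(exp(a))), tolerance = 1e-8)
  }
})

test_that("posteriors collapse to the prior when classes are identical", {
  an <- quick_analysis(kmix_config(K = 1, n = 50, seed = 49))
  fit1 <- fit_gmm(an, K = 1, n_starts = 1, seed = 1, compute_vcov = FALSE)
  # duplicate the single class: identical curves, posterior = prior
  fit1$beta <- rbind(fit1$beta, fit1$beta)
  fit1$gamma <- rbind(fit1$gamma, fit1$gamma[1, , drop = FALSE])
  fit1$gamma[2, 1] <- log(0.3 / 0.7)
  fit1$K <- 2L
  P <- posterior_probabilities(fit1)
  expect_equal(unname(P[, 2]), rep(0.3, nrow(P)), tolerance = 1e-9)
})

test_that("BIC follows its formula and penalizes by subject count", {
  fake <- structure(list(loglik = 0, n_params = 5, n_subjects = 100),
                    class = "growmix_gmm")
  expect_equal(gmm_bic(fake), 5 * log(100))
  an <- quick_analysis(kmix_config(K = 2, n = 80, seed = 51))
  fit <- fit_gmm(an, K = 2, n_starts = 2, seed = 1, compute_vcov = FALSE)
  expect_equal(gmm_bic(fit), -2 * fit$loglik + fit$n_params * log(fit$n_subjects))
  expect_equal(gmm_bic(fit), BIC(logLik(fit)), tolerance = 1e-10)
})

test_that("modal assignment takes the argmax with ties to the lower index", {
  P <- rbind(c(0.1, 0.7, 0.2), c(0.5, 0.5, 0.0), c(0.2, 0.3, 0.5))
  a <- modal_assignment(P)
  expect_equal(a$class, c(2L, 1L, 3L))
  expect_equal(attr(a, "n_ties"), 1L)
  set.seed(5)
  M <- matrix(runif(300), 100, 3)
  M <- M / rowSums(M)
  expect_equal(modal_assignment(M)$class, apply(M, 1, which.max))
})

test_that("class-constant mixing is recovered without membership terms", {
  an <- quick_analysis(kmix_config(K = 2, n = 300, seed = 53, gap = 30))
  fit <- fit_gmm(an, K = 2, membership = NULL, n_starts = 2, seed = 1,
                 compute_vcov = FALSE)
  # prior collapses to a single mixing proportion; shares near the true 1/2
  pri <- exp(fit$gamma[, 1]) / sum(exp(fit$gamma[, 1]))
  expect_lt(abs(pri[2] - 0.5), 3 * sqrt(0.25 / 300) + 0.02)
  tr <- an$truth$true_class[match(fit$subject_ids, an$truth$subject_id)]
  expect_gt(mean(modal_assignment(fit)$class == tr), 0.95)
})

test_that("the EM optimum is a stationary point of the observed likelihood", {
  an <- quick_analysis(kmix_config(K = 2, n = 150, seed = 55, gap = 30))
  fit <- fit_gmm(an, K = 2, n_starts = 2, seed = 1, compute_vcov = FALSE)
  d <- fit$data
  theta <- c(t(fit$beta), t(fit$gamma[-1, , drop = FALSE]),
             fit$sigma_b, fit$sigma_e)
  f <- function(th) growmix:::.packed_loglik(th, d$y, d$X, d$subj, d$W,
                                             fit$n_subjects, d$n_i, 2L,
                                             ncol(d$X), ncol(d$W))
  gr <- nlme::fdHess(theta, f)$gradient
  # relative gradient criterion at the optimum
  expect_lt(max(abs(gr)) / (abs(fit$loglik) + 1), 5e-4)
})

test_that("selection rules discard small classes and pick BIC among survivors", {
  an <- quick_analysis(kmix_config(K = 3, n = 350, seed = 57, gap = 18))
  sel <- fit_gmm_sweep(an, K_range = 1:4, n_starts = 2, seed = 1,
                       compute_vcov = FALSE)
  expect_s3_class(sel, "growmix_selection")
  expect_equal(nrow(sel$report), 4)
  # K=1 is always admissible
  expect_true(sel$report$admissible[sel$report$K == 1])
  expect_equal(sel$chosen_K, 3)
  # every inadmissible row carries a reason
  expect_true(all(nzchar(sel$report$reason[!sel$report$admissible])))
})

test_that("non-convergence is reported, not raised", {
  an <- quick_analysis(kmix_config(K = 2, n = 60, seed = 59))
  fit <- fit_gmm(an, K = 2, membership = membership_frame(an, "Hg"),
                 n_starts = 1, seed = 1, max_iter = 3, compute_vcov = FALSE)
  expect_false(fit$converged)
  rows <- rrr_onestep(fit, "Hg", "doubling",
                      scale_sd = an$exposures$scale_sd, ref = 1)
  expect_true(all(is.na(rows$estimate)))
  expect_true(all(!rows$converged))
})

test_that("more classes than subjects is an error", {
  an <- quick_analysis(kmix_config(K = 1, n = 30, seed = 61))
  expect_error(fit_gmm(an, K = 40), "more classes than subjects")
})
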