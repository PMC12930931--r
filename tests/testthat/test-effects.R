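# small fitted mixture with an Hg membership effect, shared across tests
fit_cache <- local({
  an <- quick_analysis(kmix_config(K = 2, n = 350, seed = 71, gap = 30,
                                   gamma_hg = 0.6))
  mem <- membership_frame(an, "Hg")
  fit <- fit_gmm(an, K = 2, membership = mem, n_starts = 2, seed = 1)
  list(an = an, mem = mem, fit = fit, asg = modal_assignment(fit))
})

test_that("a zero membership coefficient yields RRR = 1 with CI spanning 1", {
  fit <- fit_cache$fit
  fit0 <- fit
  fit0$gamma[2, "Hg"] <- 0
  rows <- rrr_onestep(fit0, "Hg", "doubling",
                      scale_sd = fit_cache$an$exposures$scale_sd, ref = 1)
  expect_equal(rows$estimate, 1)
  expect_lte(rows$lo95, 1)
  expect_gte(rows$hi95, 1)
})

test_that("gamma = log(2) with delta = 1 gives RRR = 2 and the identity holds", {
  fit2 <- fit_cache$fit
  fit2$gamma[2, "Hg"] <- log(2)
  sd1 <- c(Hg = 1)  # delta = 1/sd = 1
  rows <- rrr_onestep(fit2, "Hg", "doubling", scale_sd = sd1, ref = 1)
  expect_equal(rows$estimate, 2, tolerance = 1e-12)
  expect_lt(verify_rrr_identity(fit2, "Hg", delta = 1, ref = 1), 1e-10)
})

test_that("the probability-ratio identity holds at machine precision", {
  an <- fit_cache$an
  delta <- 1 / an$exposures$scale_sd[["Hg"]]
  expect_lt(verify_rrr_identity(fit_cache$fit, "Hg", delta = delta,
                                ref = 1, n_grid = 50), 1e-10)
})

test_that("doubling RRR is invariant to the standardization constant", {
  an <- fit_cache$an
  # refit with the same exposure on the raw log2 scale (scale_sd = 1)
  mem2 <- fit_cache$mem
  mem2$Hg <- mem2$Hg * an$exposures$scale_sd[["Hg"]]
  fit2 <- fit_gmm(an, K = 2, membership = mem2, n_starts = 2, seed = 1)
  r1 <- rrr_onestep(fit_cache$fit, "Hg", "doubling",
                    scale_sd = an$exposures$scale_sd, ref = 1)
  r2 <- rrr_onestep(fit2, "Hg", "doubling", scale_sd = c(Hg = 1), ref = 1)
  expect_equal(r1$estimate, r2$estimate, tolerance = 1e-3)
  expect_equal(r1$lo95, r2$lo95, tolerance = 1e-2)
})

test_that("two-stage coefficients match an independent Newton multinomial fit", {
  asg <- fit_cache$asg
  mem <- fit_cache$mem
  rows <- rrr_twostage(asg, mem, "Hg", "doubling",
                       scale_sd = fit_cache$an$exposures$scale_sd, ref = 1)
  mfit <- attr(rows, "fit")
  # independent oracle: own Newton ascent on the same likelihood, unit weights
  m <- mem[match(asg$subject_id, mem$subject_id), ]
  W <- cbind(1, as.matrix(m[, setdiff(names(m), "subject_id")]))
  R <- outer(asg$class, 1:2, `==`) * 1
  gam <- matrix(0, 2, ncol(W))
  for (it in 1:50) gam <- growmix:::.mlogit_newton(W, R, gam, iter = 1)
  expect_equal(unname(coef(mfit)), unname(gam[2, ]), tolerance = 1e-6)
})

test_that("Cohen's kappa: identical, hand-computed, and independent cases", {
  a <- rep(1:2, each = 50)
  expect_equal(cohens_kappa(a, a)$kappa, 1)
  # contingency table ((45,5),(5,45)): po = .9, pe = .5, kappa = .8
  b <- c(rep(1, 45), rep(2, 5), rep(1, 5), rep(2, 45))
  k <- cohens_kappa(a, b, align = FALSE)
  expect_equal(k$kappa, 0.8, tolerance = 1e-12)
  expect_true(k$lo95 < 0.8 && k$hi95 > 0.8)
  set.seed(33)
  x <- sample(1:4, 10000, replace = TRUE)
  y <- sample(1:4, 10000, replace = TRUE)
  expect_lt(abs(cohens_kappa(x, y, align = FALSE)$kappa), 0.05)
  expect_message(k1 <- cohens_kappa(rep(1, 10), rep(1, 10)), "undefined")
  expect_true(is.na(k1$kappa))
})

test_that("kappa agrees with the e1071 implementation after no alignment", {
  skip_if_not_installed("e1071")
  set.seed(34)
  a <- sample(1:3, 400, replace = TRUE)
  b <- ifelse(runif(400) < 0.7, a, sample(1:3, 400, replace = TRUE))
  expect_equal(cohens_kappa(a, b, align = FALSE)$kappa,
               e1071::classAgreement(table(a, b))$kappa, tolerance = 1e-10)
})

test_that("label alignment recovers agreement under permuted labels", {
  set.seed(35)
  a <- sample(1:3, 500, replace = TRUE)
  b <- c(3, 1, 2)[a]  # perfect agreement under a label permutation
  k <- cohens_kappa(a, b, align = TRUE)
  expect_equal(k$kappa, 1)
  expect_equal(sort(k$alignment), 1:3)
})

test_that("z-score regression matches the normal-equations oracle", {
  an <- fit_cache$an
  mem <- fit_cache$mem
  set.seed(36)
  z <- data.frame(subject_id = mem$subject_id,
                  z = 0.3 * mem$Hg + rnorm(nrow(mem), 0, 1))
  tab <- linear_z_regression(z, mem)
  X <- cbind(1, as.matrix(mem[, setdiff(names(mem), "subject_id")]))
  beta <- drop(solve(crossprod(X), crossprod(X, z$z)))
  expect_equal(tab$estimate, unname(beta), tolerance = 1e-10)
  # null exposure: estimate near zero with a covering CI
  z0 <- data.frame(subject_id = mem$subject_id, z = rnorm(nrow(mem)))
  t0 <- linear_z_regression(z0, mem)
  hg <- t0[t0$term == "Hg", ]
  expect_lt(abs(hg$estimate), 0.2)
  expect_true(hg$lo95 < 0 && hg$hi95 > 0)
})

test_that("tertile contrasts swap when low/high labels swap", {
  an <- fit_cache$an
  asg <- fit_cache$asg
  mem <- membership_frame(an, "Mn", mode = "tertile")
  rows <- rrr_twostage(asg, mem, "Mn", "tertile", ref = 1)
  mem_sw <- mem
  names(mem_sw)[names(mem_sw) == "Mn_low"] <- ".tmp"
  names(mem_sw)[names(mem_sw) == "Mn_high"] <- "Mn_low"
  names(mem_sw)[names(mem_sw) == ".tmp"] <- "Mn_high"
  rows_sw <- rrr_twostage(asg, mem_sw, "Mn", "tertile", ref = 1)
  lo <- rows$estimate[rows$contrast == "tertile_low_vs_mid"]
  hi_sw <- rows_sw$estimate[rows_sw$contrast == "tertile_high_vs_mid"]
  expect_equal(lo, hi_sw, tolerance = 1e-6)
})

test_that("BMI cross-product near zero implies equal stratified effects", {
  an <- fit_cache$an
  asg <- fit_cache$asg
  rows <- bmi_interaction(an, "Hg", method = "two_stage", assignment = asg,
                          ref = 1)
  expect_equal(nrow(rows), 1)
  expect_true(all(c("estimate", "se", "p") %in% names(rows)))
  # generated without interaction: Wald p should not be extreme
  expect_gt(rows$p, 1e-4)
})
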