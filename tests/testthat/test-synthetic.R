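test_that("LOD substitution replaces sub-LOD values by LOD/sqrt(2) and flags them", {
  lods <- c(As = 0.023, Hg = 0.031)
  r <- censor_at_lod(c(As = 0.010, Hg = 0.05), lods)
  expect_equal(unname(r$values["As"]), 0.023 / sqrt(2), tolerance = 1e-12)
  expect_true(r$below_lod[["As"]])
  expect_equal(unname(r$values["Hg"]), 0.05)
  expect_false(r$below_lod[["Hg"]])
  # fully censored column collapses to a constant
  m <- matrix(c(0.001, 0.002, 0.003), 3, 1, dimnames = list(NULL, "As"))
  r2 <- censor_at_lod(m, lods)
  expect_true(all(r2$below_lod))
  expect_true(all(r2$values == 0.023 / sqrt(2)))
  expect_error(censor_at_lod(c(As = -0.1), lods), "negative")
})

test_that("cohort generation is byte-reproducible given the config seed", {
  cfg <- kmix_config(K = 2, n = 60, seed = 9)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
})

test_that("zero membership coefficients give symmetric class shares", {
  cfg <- kmix_config(K = 4, n = 2000, seed = 11)
  co <- generate_cohort(cfg)
  props <- tabulate(co$truth$true_class, 4) / 2000
  se <- sqrt(0.25 * 0.75 / 2000)
  expect_true(all(abs(props - 0.25) < 3 * se))
})

test_that("noise-free cohorts lie exactly on the class spline curves", {
  cfg <- kmix_config(K = 2, n = 20, seed = 3, sigma_b = 0, sigma_e = 0)
  co <- generate_cohort(cfg)
  X <- basis_matrix(co$growth$age, cfg$spline)
  cls <- co$truth$true_class[match(co$growth$subject_id, co$truth$subject_id)]
  mu <- rowSums(X * cfg$class_mean_coefs[cls, , drop = FALSE])
  expect_equal(co$growth$wfl, mu, tolerance = 1e-10)
})

test_that("calibrated cohort means match the study's birth and 18-month levels", {
  co <- generate_cohort(default_calibration(783, seed = 2))
  g <- assign_nominal_visits(co$growth)
  birth <- g$wfl[!is.na(g$nominal_visit) & g$nominal_visit == 0]
  late <- g$wfl[!is.na(g$nominal_visit) & g$nominal_visit == 18]
  expect_lt(abs(mean(birth) - 68.0), 1.0)
  expect_lt(abs(mean(late) - 135.0), 2.0)
})

test_that("calibrated element medians and correlations match their targets", {
  co <- generate_cohort(default_calibration(5000, seed = 6))
  e <- co$exposures
  expect_lt(abs(median(e$Hg) - 0.08) / 0.08, 0.10)
  expect_gt(median(e$Pb), 0.10)
  expect_lt(median(e$Pb), 0.12)
  r <- cor(log(e$Cu), log(e$Mn))
  expect_lt(abs(r - 0.12), 0.05)
})

test_that("simulated log-concentrations match the target lognormal marginals", {
  cfg <- default_calibration(5000, seed = 8)
  co <- generate_cohort(cfg)
  # elements with negligible LOD censoring: the copula marginal is intact
  for (el in c("Pb", "Cu", "Se")) {
    ks <- suppressWarnings(stats::ks.test(
      log(co$exposures[[el]]), "pnorm",
      mean = cfg$element_log_means[el], sd = cfg$element_log_sds[el]))
    expect_lt(unname(ks$statistic), 0.05)
  }
})

test_that("a multinomial logit of true class recovers the generating coefficients", {
  cfg <- kmix_config(K = 2, n = 5000, seed = 13, gamma_hg = 0.5)
  co <- generate_cohort(cfg)
  Z <- scale(log2(as.matrix(co$exposures[c("As", "Hg", "Pb", "Cu", "Mn", "Se")])))
  d <- data.frame(cl = factor(co$truth$true_class), Hg = Z[, "Hg"])
  m <- nnet::multinom(cl ~ Hg, data = d, trace = FALSE)
  est <- coef(m)["Hg"]
  se <- sqrt(vcov(m)["Hg", "Hg"])
  expect_lt(abs(est - 0.5), 2 * se)
})

test_that("noise variance decomposes into residual and intercept components", {
  cfg <- kmix_config(K = 2, n = 2000, seed = 17, sigma_b = 3, sigma_e = 4,
                     jitter = 0)
  co <- generate_cohort(cfg)
  X <- basis_matrix(co$growth$age, cfg$spline)
  cls <- co$truth$true_class[match(co$growth$subject_id, co$truth$subject_id)]
  r <- co$growth$wfl - rowSums(X * cfg$class_mean_coefs[cls, , drop = FALSE])
  subj <- match(co$growth$subject_id, co$truth$subject_id)
  n_i <- as.numeric(table(subj))
  rbar <- drop(rowsum(r, subj)) / n_i
  within <- sum((r - rbar[subj])^2) / (length(r) - length(n_i))
  between <- var(rbar) - within * mean(1 / n_i)
  expect_lt(abs(within - 16) / 16, 0.15)
  expect_lt(abs(between - 9) / 9, 0.15)
})

test_that("invalid correlation matrices are rejected at configuration time", {
  dc <- default_calibration()
  bad <- dc$element_corr
  bad[1, 2] <- bad[2, 1] <- 0.999
  bad[1, 3] <- bad[3, 1] <- 0.999
  bad[2, 3] <- bad[3, 2] <- -0.999
  expect_error(
    sim_config(50, 0.5, dc$class_mean_coefs, dc$class_membership_coefs,
               dc$spline, random_intercept_sd = 5, residual_sd = 5,
               element_log_means = dc$element_log_means,
               element_log_sds = dc$element_log_sds, element_corr = bad,
               lods = dc$lods, covariate_specs = dc$covariate_specs),
    "positive-definite")
})

test_that("cohort tables round-trip through CSV files", {
  co <- generate_cohort(kmix_config(K = 2, n = 25, seed = 5))
  dir <- tempfile("cohort_")
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$growth$wfl, co$growth$wfl, tolerance = 1e-12)
  expect_equal(back$truth$true_class, co$truth$true_class)
  unlink(dir, recursive = TRUE)
})
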