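#' @importFrom stats rnorm rbinom runif sd quantile median setNames
NULL

ELEMENTS <- c("As", "Hg", "Pb", "Cu", "Mn", "Se")

# canonical order of the generating membership-model design columns
MEMBERSHIP_COLS <- c("(Intercept)", ELEMENTS,
                     "maternal_age", "education", "married", "smoke_exposed",
                     "fish_intake", "prepreg_bmi", "primiparous")

#' Simulation configuration for a synthetic birth-cohort
#'
#' Assembles and validates the full data-generating configuration: latent
#' trajectory classes with quadratic-spline mean curves for weight-for-length
#' (g/cm), a shared subject-level random intercept, Gaussian residual noise at
#' scheduled visits with age jitter and missingness, correlated log-normal
#' toenail element concentrations (Gaussian copula) with limit-of-detection
#' censoring, and the seven maternal adjustment covariates.
#'
#' Class membership is drawn from a multinomial logit whose design row is
#' `[1, As, Hg, Pb, Cu, Mn, Se, maternal_age, education, married,
#' smoke_exposed, fish_intake, prepreg_bmi, primiparous]`, where element
#' columns are the log2 concentrations centered and divided by their sample
#' SD and continuous covariates are standardized. With a coefficient `g` on a
#' standardized log2 element column, the true relative risk ratio per
#' doubling of that element (class k vs class 1) is
#' `exp((g_k - g_1) / sd_log2)`.
#'
#' @param n_subjects Number of mother-infant dyads.
#' @param sex_ratio Proportion male.
#' @param class_mean_coefs K x n_basis matrix of spline coefficients (g/cm)
#'   in the `"intercept"` parameterization of [basis_matrix()].
#' @param class_membership_coefs K x 14 matrix of multinomial-logit
#'   coefficients (columns in the canonical design order above); class
#'   probabilities are `softmax(W %*% t(coefs))` so only row differences
#'   matter.
#' @param spline A [spline_spec()].
#' @param random_intercept_sd,residual_sd Between-subject and within-subject
#'   SDs (g/cm).
#' @param visit_schedule Nominal visit ages (months), strictly increasing
#'   from 0.
#' @param visit_jitter_sd SD of the Gaussian age jitter (months); birth is
#'   never jittered.
#' @param missing_visit_prob Probability each post-birth visit is missing.
#' @param element_log_means,element_log_sds Named per-element log-normal
#'   parameters (natural-log scale, concentrations in ug/g).
#' @param element_corr 6 x 6 log-scale correlation matrix (unit diagonal,
#'   symmetric positive-definite).
#' @param lods Named per-element limits of detection (ug/g).
#' @param covariate_specs Named list of covariate distributions; see
#'   [default_calibration()] for the expected shape.
#' @param seed Integer seed; `generate_cohort()` is byte-reproducible given
#'   the same config.
#' @return An object of class `sim_config`.
#' @seealso [default_calibration()], [generate_cohort()]
#' @export
sim_config <- function(n_subjects, sex_ratio, class_mean_coefs,
                       class_membership_coefs, spline = spline_spec(),
                       random_intercept_sd, residual_sd,
                       visit_schedule = c(0, 0.46, 1, 2, 4, 6, 9, 12, 15, 18),
                       visit_jitter_sd = 0.1, missing_visit_prob = 0.1,
                       element_log_means, element_log_sds, element_corr,
                       lods, covariate_specs, seed = 1L) {
  class_mean_coefs <- as.matrix(class_mean_coefs)
  class_membership_coefs <- as.matrix(class_membership_coefs)
  K <- nrow(class_mean_coefs)
  stopifnot(K >= 1, ncol(class_mean_coefs) == spline$n_basis,
            nrow(class_membership_coefs) == K,
            ncol(class_membership_coefs) == length(MEMBERSHIP_COLS),
            sex_ratio >= 0, sex_ratio <= 1,
            random_intercept_sd >= 0, residual_sd >= 0,
            visit_jitter_sd >= 0,
            missing_visit_prob >= 0, missing_visit_prob <= 1)
  if (K > 1 && anyDuplicated(round(class_mean_coefs, 10)))
    stop("rows of class_mean_coefs must be distinct")
  if (visit_schedule[1] != 0 || is.unsorted(visit_schedule, strictly = TRUE))
    stop("visit_schedule must be strictly increasing and start at 0")
  for (nm in list(element_log_means, element_log_sds, lods))
    stopifnot(setequal(names(nm), ELEMENTS))
  if (any(element_log_sds[ELEMENTS] <= 0)) stop("element_log_sds must be > 0")
  if (any(lods[ELEMENTS] <= 0)) stop("lods must be > 0")
  element_corr <- as.matrix(element_corr)
  if (!isTRUE(all.equal(element_corr, t(element_corr))) ||
      any(abs(diag(element_corr) - 1) > 1e-12))
    stop("element_corr must be symmetric with unit diagonal")
  ev <- eigen(element_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop("element_corr is not positive-definite")
  colnames(class_membership_coefs) <- MEMBERSHIP_COLS
  structure(list(
    n_subjects = as.integer(n_subjects), sex_ratio = sex_ratio,
    class_mean_coefs = class_mean_coefs,
    class_membership_coefs = class_membership_coefs,
    spline = spline, random_intercept_sd = random_intercept_sd,
    residual_sd = residual_sd, visit_schedule = visit_schedule,
    visit_jitter_sd = visit_jitter_sd,
    missing_visit_prob = missing_visit_prob,
    element_log_means = element_log_means[ELEMENTS],
    element_log_sds = element_log_sds[ELEMENTS],
    element_corr = element_corr, lods = lods[ELEMENTS],
    covariate_specs = covariate_specs, seed = as.integer(seed)),
    class = "sim_config")
}

#' Calibrated default simulation configuration
#'
#' Returns a [sim_config()] calibrated to a rural US pregnancy cohort of 783
#' dyads: four latent weight-for-length trajectory classes with proportions
#' (0.32, 0.20, 0.36, 0.12); mean curves rising from about 68 g/cm at birth
#' to about 135 g/cm at 18 months with class-specific slopes and a
#' late-accelerating class; log-normal element concentrations whose medians
#' and IQRs match the cohort's toenail measurements (As 0.05, Hg 0.08,
#' Pb 0.12, Cu 3.96, Mn 0.34, Se 1.00 ug/g medians) with log-scale
#' correlations between 0.12 (Cu-Mn) and 0.41 (Mn-Pb); the reported assay
#' LODs; and covariate distributions matching the cohort's descriptive table.
#' Membership coefficients are intercept-only (exposures and covariates have
#' zero generating effect); callers inject effects by editing
#' `class_membership_coefs`.
#'
#' Log-normal SDs are derived from the reported IQRs via
#' `sigma = log(q75/q25) / (2 * qnorm(0.75))`.
#'
#' @param n_subjects Cohort size (default 783).
#' @param seed Integer seed.
#' @return A `sim_config`.
#' @export
default_calibration <- function(n_subjects = 783, seed = 1L) {
  spl <- spline_spec(c(3.5, 9))
  # class mean curves: birth -> 18-month levels, saturating early-growth shape
  f <- function(t) (t / (t + 2.5)) / (18 / 20.5)
  # class-proportion-weighted means: 68.0 g/cm at birth, 135.0 g/cm at 18 mo;
  # the late class runs below the population mean until ~9 months, then
  # accelerates past it
  curves <- list(
    slow     = function(t) 64.5 + (123.1 - 64.5) * f(t),
    late     = function(t) 64.0 + (120.6 - 64.0) * f(t) + 16.6 * pmax(0, (t - 9) / 9)^2,
    moderate = function(t) 71.8 + (139.0 - 71.8) * f(t),
    rapid    = function(t) 72.5 + (151.1 - 72.5) * f(t))
  # project target curves onto the spline space at the visit ages, with the
  # endpoints pinned hard so simulated birth and 18-month means hit the
  # calibration targets despite the quadratic basis smoothing the early rise
  tg <- c(0, 0.46, 1, 2, 4, 6, 9, 12, 15, 18)
  wg <- c(50, 1, 1, 1, 1, 1, 1, 1, 1, 50)
  Xg <- basis_matrix(tg, spl)
  beta <- t(vapply(curves, function(fn)
    stats::lm.wfit(Xg, fn(tg), wg)$coefficients, numeric(spl$n_basis)))
  props <- c(0.32, 0.20, 0.36, 0.12)
  gamma <- matrix(0, 4, length(MEMBERSHIP_COLS),
                  dimnames = list(names(curves), MEMBERSHIP_COLS))
  gamma[, 1] <- log(props / props[1])
  q75 <- 2 * stats::qnorm(0.75)
  # Pb: class-wise medians span 0.10-0.12, pooled centre 0.11
  med <- c(As = 0.05, Hg = 0.08, Pb = 0.11, Cu = 3.96, Mn = 0.34, Se = 1.00)
  iqr_ratio <- c(As = 0.09 / 0.04, Hg = 0.14 / 0.03, Pb = 0.21 / 0.06,
                 Cu = 4.89 / 3.30, Mn = 0.63 / 0.17, Se = 1.09 / 0.91)
  corr <- matrix(0.2, 6, 6, dimnames = list(ELEMENTS, ELEMENTS))
  diag(corr) <- 1
  corr["Cu", "Mn"] <- corr["Mn", "Cu"] <- 0.12
  corr["Mn", "Pb"] <- corr["Pb", "Mn"] <- 0.41
  sim_config(
    n_subjects = n_subjects, sex_ratio = 387 / 783,
    class_mean_coefs = beta, class_membership_coefs = gamma, spline = spl,
    random_intercept_sd = 5.5, residual_sd = 4.8,
    element_log_means = log(med), element_log_sds = log(iqr_ratio) / q75,
    element_corr = corr,
    lods = c(As = 0.023, Hg = 0.031, Pb = 0.009,
             Cu = 0.105, Mn = 0.038, Se = 0.013),
    covariate_specs = list(
      maternal_age  = list(kind = "normal", mean = 31.6, sd = 4.5),
      education     = list(kind = "categorical", probs = c(0.097, 0.590, 0.313)),
      married       = list(kind = "bernoulli", p = 0.895),
      smoke_exposed = list(kind = "bernoulli", p = 0.180),
      fish_intake   = list(kind = "categorical", probs = c(0.218, 0.635, 0.147)),
      prepreg_bmi   = list(kind = "normal", mean = 25.8, sd = 5.4, min = 15),
      primiparous   = list(kind = "bernoulli", p = 0.411)),
    seed = seed)
}

#' Substitute concentrations below the limit of detection
#'
#' Values below their element's LOD are replaced by LOD / sqrt(2) and
#' flagged; values at or above the LOD pass through unchanged.
#'
#' @param values Numeric matrix or data.frame of concentrations (ug/g),
#'   columns named by element, or a named numeric vector.
#' @param lods Named numeric vector of LODs covering every column of
#'   `values`.
#' @return A list with `values` (substituted, same shape as input) and
#'   `below_lod` (logical, same shape).
#' @export
censor_at_lod <- function(values, lods) {
  if (any(lods <= 0)) stop("lods must be > 0")
  vec <- is.null(dim(values))
  m <- if (vec) matrix(values, nrow = 1, dimnames = list(NULL, names(values)))
       else as.matrix(values)
  if (is.null(colnames(m))) stop("values must have element names")
  if (!all(colnames(m) %in% names(lods))) stop("missing LOD for some element")
  if (any(m < 0, na.rm = TRUE)) stop("negative concentrations are invalid")
  lodrow <- lods[colnames(m)]
  flag <- sweep(m, 2, lodrow, `<`)
  sub <- sweep(m, 2, lodrow / sqrt(2), function(x, s) s)
  m[flag] <- sub[flag]
  if (vec) {
    m <- drop(m); flag <- drop(flag)
  }
  list(values = m, below_lod = flag)
}

# deterministic sex-specific median length curve (cm), ~50 -> ~82 over 0-18 mo
.length_curve <- function(age, sex) {
  base <- 49.9 + (82.3 - 49.9) * (1 - exp(-0.16 * age)) / (1 - exp(-0.16 * 18))
  base + ifelse(sex == "male", 0.8, 0) * (age > 0) + ifelse(sex == "male", 0.3, 0)
}

.draw_covariates <- function(n, specs) {
  draw1 <- function(sp) {
    switch(sp$kind,
      normal = {
        x <- rnorm(n, sp$mean, sp$sd)
        if (!is.null(sp$min)) x <- pmax(x, sp$min)
        x
      },
      categorical = sample.int(length(sp$probs), n, replace = TRUE, prob = sp$probs),
      bernoulli = rbinom(n, 1, sp$p),
      stop("unknown covariate kind: ", sp$kind))
  }
  as.data.frame(lapply(specs, draw1))
}

# standardize the generating membership design: log2 exposures and continuous
# covariates centered/scaled by sample SD; binary/ordinal covariates centered
.membership_design <- function(log2_expo, covars) {
  Z <- scale(log2_expo)
  Cm <- as.matrix(covars[, c("maternal_age", "education", "married",
                             "smoke_exposed", "fish_intake", "prepreg_bmi",
                             "primiparous")])
  s <- apply(Cm, 2, sd)
  Cm <- scale(Cm, center = TRUE, scale = ifelse(s > 0, s, 1))
  W <- cbind(1, Z, Cm)
  colnames(W) <- MEMBERSHIP_COLS
  list(W = W, sd_log2 = attr(Z, "scaled:scale"))
}

#' Generate a synthetic cohort
#'
#' Simulates a full cohort from a [sim_config()]: covariates; correlated
#' log-normal element concentrations via a Gaussian copula, censored at the
#' LOD; latent class drawn from the multinomial logit of the standardized
#' log2 exposures and covariates; a subject random intercept; and, at each
#' retained visit (birth always retained and never jittered), weight-for-
#' length equal to the class spline mean plus intercept plus Gaussian noise.
#' Length follows a deterministic sex-specific median curve and weight is
#' back-derived so that `1000 * weight / length` reproduces the simulated
#' g/cm value exactly.
#'
#' @param config A `sim_config`.
#' @return An object of class `growmix_cohort`: a list of data.frames
#'   `growth` (subject_id, sex, age, weight, length, wfl), `exposures`
#'   (subject_id, six element columns, six `below_lod_*` flags), `covariates`,
#'   and `truth` (subject_id, true_class, true_intercept), plus the
#'   generating `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  K <- nrow(config$class_mean_coefs)
  id <- sprintf("S%04d", seq_len(n))
  sex <- ifelse(runif(n) < config$sex_ratio, "male", "female")
  covars <- .draw_covariates(n, config$covariate_specs)

  # Gaussian copula -> log-normal marginals, then LOD censoring
  L <- chol(config$element_corr)
  Z <- matrix(rnorm(n * 6), n, 6) %*% L
  conc <- exp(sweep(sweep(Z, 2, config$element_log_sds, `*`),
                    2, config$element_log_means, `+`))
  colnames(conc) <- ELEMENTS
  cens <- censor_at_lod(conc, config$lods)

  des <- .membership_design(log2(cens$values), covars)
  eta <- des$W %*% t(config$class_membership_coefs)
  eta <- eta - apply(eta, 1, max)
  p <- exp(eta) / rowSums(exp(eta))
  u <- runif(n)
  cls <- if (K == 1) rep(1L, n)
         else max.col(u < t(apply(p, 1, cumsum)), ties.method = "first")
  b <- rnorm(n, 0, config$random_intercept_sd)

  sched <- config$visit_schedule
  nv <- length(sched)
  keep <- matrix(runif(n * nv) >= config$missing_visit_prob, n, nv)
  keep[, 1] <- TRUE
  jit <- matrix(rnorm(n * nv, 0, config$visit_jitter_sd), n, nv)
  jit[, 1] <- 0
  ages <- sweep(jit, 2, sched, `+`)
  ages <- pmin(pmax(ages, 0), max(sched))

  idx <- which(keep, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  si <- idx[, 1]
  age <- ages[idx]
  X <- basis_matrix(age, config$spline)
  mu <- rowSums(X * config$class_mean_coefs[cls[si], , drop = FALSE])
  wfl <- mu + b[si] + rnorm(length(si), 0, config$residual_sd)
  len <- .length_curve(age, sex[si])
  growth <- data.frame(
    subject_id = id[si], sex = sex[si], age = age,
    weight = wfl * len / 1000, length = len, wfl = wfl,
    stringsAsFactors = FALSE)
  if (anyNA(growth$wfl) || any(growth$wfl <= 0))
    stop("internal error: simulated weight-for-length must be positive")

  expo <- data.frame(subject_id = id, cens$values, stringsAsFactors = FALSE)
  flags <- as.data.frame(cens$below_lod)
  names(flags) <- paste0("below_lod_", ELEMENTS)
  expo <- cbind(expo, flags)
  covariates <- cbind(data.frame(subject_id = id, stringsAsFactors = FALSE), covars)
  truth <- data.frame(subject_id = id, true_class = cls, true_intercept = b,
                      stringsAsFactors = FALSE)
  structure(list(growth = growth, exposures = expo, covariates = covariates,
                 truth = truth, sd_log2 = des$sd_log2, config = config),
            class = "growmix_cohort")
}

#' @export
print.growmix_cohort <- function(x, ...) {
  cat("Synthetic birth cohort:", nrow(x$covariates), "dyads,",
      nrow(x$growth), "anthropometry observations,",
      nrow(x$config$class_mean_coefs), "latent classes\n")
  invisible(x)
}

#' Write / read a cohort as plain CSV tables
#'
#' `write_cohort()` writes `growth.csv`, `exposures.csv`, `covariates.csv`
#' and (if present) `truth.csv` into `dir`; `read_cohort()` reads them back.
#'
#' @param cohort A `growmix_cohort` (or a bare list with the same tables).
#' @param dir Directory path.
#' @return `write_cohort()` the directory invisibly; `read_cohort()` a
#'   `growmix_cohort` without config/truth metadata beyond the files present.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$growth, file.path(dir, "growth.csv"), row.names = FALSE)
  utils::write.csv(cohort$exposures, file.path(dir, "exposures.csv"), row.names = FALSE)
  utils::write.csv(cohort$covariates, file.path(dir, "covariates.csv"), row.names = FALSE)
  if (!is.null(cohort$truth))
    utils::write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  out <- list(growth = rd("growth.csv"), exposures = rd("exposures.csv"),
              covariates = rd("covariates.csv"))
  tf <- file.path(dir, "truth.csv")
  if (file.exists(tf)) out$truth <- rd("truth.csv")
  structure(out, class = "growmix_cohort")
}
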