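#' Marginal log-likelihood of one subject's trajectory under one class
#'
#' Evaluates `log N(y; X beta, sigma_b^2 J + sigma_e^2 I)` — the subject's
#' observations under a class mean curve with a shared random intercept
#' integrated out — using the rank-one Woodbury identity, so no matrix is
#' ever inverted: with `n` observations, residual sum of squares `SS` and
#' residual sum `s`,
#' `-2 logLik = n log(2 pi) + (n-1) log sigma_e^2 + log(sigma_e^2 + n sigma_b^2)
#'  + SS/sigma_e^2 - sigma_b^2 s^2 / (sigma_e^2 (sigma_e^2 + n sigma_b^2))`.
#'
#' @param y Numeric vector of the subject's outcomes (g/cm).
#' @param X Spline design matrix for the subject's ages (rows = length(y)).
#' @param beta Class mean-curve coefficient vector.
#' @param sigma_b,sigma_e Random-intercept and residual SDs (g/cm);
#'   `sigma_b = 0` reduces to independent Gaussians.
#' @return Scalar log-likelihood.
#' @export
subject_loglik <- function(y, X, beta, sigma_b, sigma_e) {
  if (!all(is.finite(X))) stop("non-finite design")
  r <- y - drop(X %*% beta)
  n <- length(y)
  s2e <- sigma_e^2
  den <- s2e + n * sigma_b^2
  -0.5 * (n * log(2 * pi) + (n - 1) * log(s2e) + log(den) +
          sum(r^2) / s2e - sigma_b^2 * sum(r)^2 / (s2e * den))
}

# vectorized subject x class log-density matrix.
# y, X: observation-level; subj: integer subject index per observation.
.loglik_matrix <- function(y, X, subj, n_subj, n_i, beta, sigma_b, sigma_e) {
  s2e <- sigma_e^2
  den <- s2e + n_i * sigma_b^2
  const <- -0.5 * (n_i * log(2 * pi) + (n_i - 1) * log(s2e) + log(den))
  RES <- y - X %*% t(beta)                      # n_obs x K
  SS <- rowsum(RES^2, subj, reorder = TRUE)
  S1 <- rowsum(RES, subj, reorder = TRUE)
  const - 0.5 * (SS / s2e - sigma_b^2 * S1^2 / (s2e * den))
}

# weighted multinomial-logit Newton ascent with step halving.
# W: n x q design; R: n x K responsibilities; gamma: K x q, row 1 pinned at 0.
.mlogit_Q <- function(W, R, gamma) {
  eta <- W %*% t(gamma)
  eta <- eta - apply(eta, 1, max)
  lse <- log(rowSums(exp(eta)))
  sum(R * (eta - lse))
}

.mlogit_newton <- function(W, R, gamma, iter = 3, ridge = 1e-8) {
  K <- nrow(gamma); q <- ncol(W)
  if (K == 1) return(gamma)
  free <- 2:K
  for (it in seq_len(iter)) {
    eta <- W %*% t(gamma)
    eta <- eta - apply(eta, 1, max)
    P <- exp(eta); P <- P / rowSums(P)
    grad <- numeric((K - 1) * q)
    H <- matrix(0, (K - 1) * q, (K - 1) * q)
    for (a in seq_along(free)) {
      ia <- ((a - 1) * q + 1):(a * q)
      grad[ia] <- crossprod(W, R[, free[a]] - P[, free[a]])
      for (b in seq_along(free)) {
        ib <- ((b - 1) * q + 1):(b * q)
        w <- if (a == b) P[, free[a]] * (1 - P[, free[a]])
             else -P[, free[a]] * P[, free[b]]
        H[ia, ib] <- -crossprod(W, W * w)
      }
    }
    step <- tryCatch(solve(H + diag(-ridge, nrow(H)), -grad),
                     error = function(e) grad * 0)
    if (!all(is.finite(step))) break
    q0 <- .mlogit_Q(W, R, gamma)
    lam <- 1
    repeat {
      cand <- gamma
      cand[free, ] <- gamma[free, ] + lam * matrix(step, K - 1, q, byrow = TRUE)
      if (.mlogit_Q(W, R, cand) >= q0 - 1e-12) { gamma <- cand; break }
      lam <- lam / 2
      if (lam < 1e-6) break
    }
  }
  gamma
}

# subject-level features for initialization: OLS coefficients on the reduced
# quadratic polynomial basis (rank-safe at 4-5 observations per subject)
.init_features <- function(y, age, subj, n_subj) {
  feats <- matrix(0, n_subj, 3)
  for (i in seq_len(n_subj)) {
    sel <- subj == i
    ti <- age[sel]; yi <- y[sel]
    d <- min(length(yi) - 1, 2)
    Xi <- stats::poly(ti, degree = max(d, 0), raw = TRUE)
    Xi <- cbind(1, if (d > 0) Xi[, seq_len(d), drop = FALSE])
    cf <- stats::lm.fit(Xi, yi)$coefficients
    feats[i, seq_along(cf)] <- cf
  }
  feats[!is.finite(feats)] <- 0
  s <- apply(feats, 2, sd)
  scale(feats, center = TRUE, scale = ifelse(s > 0, s, 1))
}

.em_from_R <- function(y, X, subj, W, R, n_i, max_iter, tol, param_tol) {
  n_subj <- nrow(R); K <- ncol(R); p <- ncol(X); N <- length(y)
  Rw <- R[subj, , drop = FALSE]
  beta <- matrix(0, K, p)
  for (k in seq_len(K)) {
    w <- Rw[, k] + 1e-10
    beta[k, ] <- stats::lm.wfit(X, y, w)$coefficients
  }
  beta[!is.finite(beta)] <- 0
  sigma_b <- sd(rowsum(y, subj) / n_i) / 2 + 1e-3
  sigma_e <- max(sd(y) / 2, 1e-3)
  gamma <- matrix(0, K, ncol(W))
  gamma[, 1] <- log(pmax(colMeans(R), 1e-6) / pmax(mean(R[, 1]), 1e-6))
  gamma <- sweep(gamma, 2, gamma[1, ])
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  s2e <- sigma_e^2
  for (it in seq_len(max_iter)) {
    # E-step: residual summaries shared by the density and the intercept moments
    s2e <- sigma_e^2
    den <- s2e + n_i * sigma_b^2
    RES <- y - X %*% t(beta)                    # n_obs x K
    SS <- rowsum(RES^2, subj, reorder = TRUE)
    S1 <- rowsum(RES, subj, reorder = TRUE)
    lf <- -0.5 * ((n_i * log(2 * pi) + (n_i - 1) * log(s2e) + log(den)) +
                  SS / s2e - sigma_b^2 * S1^2 / (s2e * den))
    eta <- W %*% t(gamma)
    eta <- eta - apply(eta, 1, max)
    lpi <- eta - log(rowSums(exp(eta)))
    a <- lf + lpi
    amax <- apply(a, 1, max)
    ll <- sum(amax + log(rowSums(exp(a - amax))))
    trace <- c(trace, ll)
    R <- exp(a - amax)
    R <- R / rowSums(R)
    # random-intercept posterior moments per subject x class
    v_i <- sigma_b^2 * s2e / den
    bhat <- sigma_b^2 * S1 / den
    # M-step: mean curves
    old <- c(beta, gamma, sigma_b, sigma_e)
    Rw <- R[subj, , drop = FALSE]
    for (k in seq_len(K)) {
      w <- Rw[, k] + 1e-10
      Xw <- X * w
      beta[k, ] <- drop(solve(crossprod(Xw, X), crossprod(Xw, y - bhat[subj, k])))
    }
    # variances (complete-data closed forms with E-step moments fixed)
    RES2 <- y - X %*% t(beta) - bhat[subj, , drop = FALSE]
    sse <- sum(Rw * RES2^2)
    sigma_e <- sqrt((sse + sum(R * (n_i * v_i))) / N)
    sigma_b <- sqrt(sum(R * (bhat^2 + v_i)) / n_subj)
    sigma_b <- max(sigma_b, 1e-6); sigma_e <- max(sigma_e, 1e-6)
    # membership coefficients
    gamma <- .mlogit_newton(W, R, gamma, iter = 2)
    dp <- max(abs(c(beta, gamma, sigma_b, sigma_e) - old))
    if (it > 1 && abs(ll - ll_old) < tol * (abs(ll_old) + 1) && dp < param_tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(beta = beta, gamma = gamma, sigma_b = sigma_b, sigma_e = sigma_e,
       loglik = trace[length(trace)], trace = trace, R = R,
       converged = converged, iters = length(trace))
}

# central-difference Hessian with steps floored away from zero: parameter
# magnitudes near 0 (membership coefficients) must not shrink the step into
# cancellation against a log-likelihood of magnitude ~1e4
.fd_hessian <- function(f, theta, rel = 1e-4, floor_ = 1) {
  p <- length(theta)
  h <- rel * pmax(abs(theta), floor_)
  H <- matrix(0, p, p)
  f0 <- f(theta)
  for (i in seq_len(p)) {
    ei <- numeric(p); ei[i] <- h[i]
    H[i, i] <- (f(theta + ei) - 2 * f0 + f(theta - ei)) / h[i]^2
    for (j in seq_len(i - 1)) {
      ej <- numeric(p); ej[j] <- h[j]
      H[i, j] <- H[j, i] <-
        (f(theta + ei + ej) - f(theta + ei - ej) -
         f(theta - ei + ej) + f(theta - ei - ej)) / (4 * h[i] * h[j])
    }
  }
  H
}

# observed-data log-likelihood for a packed parameter vector (vcov)
.packed_loglik <- function(theta, y, X, subj, W, n_subj, n_i, K, p, q) {
  beta <- matrix(theta[seq_len(K * p)], K, p, byrow = TRUE)
  gamma <- matrix(0, K, q)
  if (K > 1)
    gamma[-1, ] <- matrix(theta[K * p + seq_len((K - 1) * q)], K - 1, q, byrow = TRUE)
  sigma_b <- theta[K * p + (K - 1) * q + 1]
  sigma_e <- theta[K * p + (K - 1) * q + 2]
  if (sigma_e <= 0 || sigma_b < 0) return(-Inf)
  lf <- .loglik_matrix(y, X, subj, n_subj, n_i, beta, sigma_b, sigma_e)
  eta <- W %*% t(gamma)
  eta <- eta - apply(eta, 1, max)
  lpi <- eta - log(rowSums(exp(eta)))
  a <- lf + lpi
  amax <- apply(a, 1, max)
  sum(amax + log(rowSums(exp(a - amax))))
}

#' Fit a latent-class growth mixture model
#'
#' Maximum-likelihood estimation of a K-class Gaussian growth mixture model:
#' each class has its own quadratic-spline mean curve, all classes share a
#' subject-level random-intercept SD and a residual SD, and class membership
#' follows a multinomial logit of subject-level terms (exposures and
#' covariates). Estimation is EM — responsibility-weighted least squares for
#' the mean curves with the random intercept treated as missing data,
#' closed-form variance updates, and Newton steps with step halving for the
#' membership coefficients — restarted from `n_starts` perturbed k-means
#' initializations of subject-level curve features; the best final
#' log-likelihood wins. The observed-data log-likelihood is non-decreasing
#' across iterations by construction.
#'
#' Classes are reported in canonical order: ascending fitted mean curve at
#' 18 months. The membership coefficients `gamma` are re-referenced so the
#' first (lowest) class is pinned at zero.
#'
#' @param growth Data.frame with `subject_id`, `age` (months) and an outcome
#'   column, or a `growmix_analysis` (its `growth` table is used).
#' @param K Number of latent classes.
#' @param membership Optional data.frame with `subject_id` plus numeric
#'   columns entering the membership submodel (see [membership_frame()]);
#'   `NULL` gives class-constant mixing proportions.
#' @param spline A [spline_spec()].
#' @param outcome Outcome column name (default `"wfl"`).
#' @param n_starts,max_iter,tol,param_tol EM control: number of random
#'   starts, iteration cap, relative log-likelihood tolerance, and max
#'   absolute parameter-change tolerance.
#' @param seed Seed for the random starts.
#' @param compute_vcov Compute the covariance of the estimates from the
#'   finite-difference observed information (needed for Wald inference).
#' @return Object of class `growmix_gmm` with elements `beta` (K x n_basis),
#'   `gamma` (K x q, row 1 zero), `sigma_b`, `sigma_e`, `loglik`,
#'   `loglik_trace`, `n_params`, `vcov`, `posterior`, `converged`,
#'   `n_subjects`, `n_obs`, `subject_ids`, `membership_terms`, `spline`.
#' @export
fit_gmm <- function(growth, K, membership = NULL, spline = spline_spec(),
                    outcome = "wfl", n_starts = 20, max_iter = 1500,
                    tol = 1e-8, param_tol = 1e-5, seed = 1,
                    compute_vcov = TRUE) {
  if (inherits(growth, "growmix_analysis")) growth <- growth$growth
  stopifnot(all(c("subject_id", "age", outcome) %in% names(growth)))
  ids <- unique(growth$subject_id)
  n_subj <- length(ids)
  if (K > n_subj) stop("more classes than subjects")
  subj <- match(growth$subject_id, ids)
  ord <- order(subj, growth$age)
  growth <- growth[ord, ]; subj <- subj[ord]
  y <- growth[[outcome]]
  age <- growth$age
  X <- basis_matrix(age, spline)
  n_i <- as.numeric(table(subj))
  terms <- character(0)
  if (!is.null(membership)) {
    m <- membership[match(ids, membership$subject_id), , drop = FALSE]
    if (anyNA(m)) stop("membership terms incomplete for some subjects")
    terms <- setdiff(names(m), "subject_id")
    W <- cbind(1, as.matrix(m[, terms, drop = FALSE]))
  } else {
    W <- matrix(1, n_subj, 1)
  }
  colnames(W) <- c("(Intercept)", terms)
  q <- ncol(W); p <- ncol(X)

  set.seed(seed)
  feats <- .init_features(y, age, subj, n_subj)
  km <- tryCatch(stats::kmeans(feats, centers = K, nstart = 5)$cluster,
                 error = function(e) sample.int(K, n_subj, replace = TRUE))
  best <- NULL
  for (s in seq_len(n_starts)) {
    assign <- km
    if (s > 1) {
      flip <- runif(n_subj) < 0.25
      assign[flip] <- sample.int(K, sum(flip), replace = TRUE)
    }
    R0 <- matrix(0.2 / max(K - 1, 1), n_subj, K)
    R0[cbind(seq_len(n_subj), assign)] <- if (K > 1) 0.8 else 1
    R0 <- R0 / rowSums(R0)
    fit <- .em_from_R(y, X, subj, W, R0, n_i, max_iter, tol, param_tol)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }

  # canonical class order: ascending mean curve at 18 months
  x18 <- basis_matrix(max(spline$boundary), spline)
  perm <- order(drop(x18 %*% t(best$beta)))
  beta <- best$beta[perm, , drop = FALSE]
  gamma <- best$gamma[perm, , drop = FALSE]
  gamma <- sweep(gamma, 2, gamma[1, ])
  dimnames(beta) <- list(paste0("class", seq_len(K)), colnames(X))
  dimnames(gamma) <- list(paste0("class", seq_len(K)), colnames(W))
  n_params <- K * p + (K - 1) * q + 2

  fit <- structure(list(
    beta = beta, gamma = gamma, sigma_b = best$sigma_b,
    sigma_e = best$sigma_e, loglik = best$loglik,
    loglik_trace = best$trace, n_params = n_params, vcov = NULL,
    converged = best$converged, n_subjects = n_subj, n_obs = length(y),
    subject_ids = ids, membership_terms = terms, spline = spline, K = K,
    data = list(y = y, X = X, subj = subj, W = W, n_i = n_i, age = age),
    call = match.call()), class = "growmix_gmm")
  fit$posterior <- posterior_probabilities(fit)

  if (compute_vcov) {
    theta <- c(t(beta), if (K > 1) t(gamma[-1, , drop = FALSE]),
               best$sigma_b, best$sigma_e)
    nms <- c(paste0(rep(rownames(beta), each = p), ":", rep(colnames(X), K)),
             if (K > 1) paste0(rep(rownames(gamma)[-1], each = q), ":",
                               rep(colnames(W), K - 1)),
             "sigma_b", "sigma_e")
    h <- tryCatch(
      .fd_hessian(function(th)
        .packed_loglik(th, y, X, subj, W, n_subj, n_i, K, p, q), theta),
      error = function(e) NULL)
    V <- if (!is.null(h))
      tryCatch(solve(-h), error = function(e) NULL) else NULL
    if (is.null(V)) {
      V <- matrix(NA_real_, length(theta), length(theta))
      warning("observed information not invertible; vcov is NA")
    }
    dimnames(V) <- list(nms, nms)
    fit$vcov <- V
  }
  fit
}

#' Posterior class-membership probabilities
#'
#' `p_ik = pi_ik f_ik / sum_l pi_il f_il`, with `pi` the fitted multinomial
#' logit prior and `f` the class-conditional trajectory density.
#'
#' @param fit A `growmix_gmm`.
#' @return `n_subjects` x K matrix; rows sum to one.
#' @export
posterior_probabilities <- function(fit) {
  d <- fit$data
  lf <- .loglik_matrix(d$y, d$X, d$subj, fit$n_subjects, d$n_i,
                       fit$beta, fit$sigma_b, fit$sigma_e)
  eta <- d$W %*% t(fit$gamma)
  eta <- eta - apply(eta, 1, max)
  lpi <- eta - log(rowSums(exp(eta)))
  a <- lf + lpi
  a <- a - apply(a, 1, max)
  P <- exp(a) / rowSums(exp(a))
  dimnames(P) <- list(fit$subject_ids, rownames(fit$beta))
  P
}

#' Bayesian Information Criterion of a fitted mixture
#'
#' `-2 logLik + n_params log(n_subjects)`; the sample-size term counts
#' subjects (the independent units), not observations.
#'
#' @param fit A `growmix_gmm`.
#' @return Scalar BIC (lower is better).
#' @export
gmm_bic <- function(fit) {
  -2 * fit$loglik + fit$n_params * log(fit$n_subjects)
}

#' Modal class assignment
#'
#' Assigns each subject to its highest-posterior class; exact ties go to the
#' lower class index and are counted in the `"n_ties"` attribute.
#'
#' @param posterior Posterior matrix (subjects x classes) or a
#'   `growmix_gmm`.
#' @return Data.frame `subject_id`, `class` (integer), `max_posterior`, with
#'   attribute `n_ties`.
#' @export
modal_assignment <- function(posterior) {
  if (inherits(posterior, "growmix_gmm")) posterior <- posterior$posterior
  cls <- max.col(posterior, ties.method = "first")
  mx <- posterior[cbind(seq_len(nrow(posterior)), cls)]
  nt <- sum(rowSums(posterior == mx) > 1)
  ids <- rownames(posterior)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(posterior)))
  structure(data.frame(subject_id = ids, class = cls, max_posterior = mx,
                       stringsAsFactors = FALSE),
            n_ties = nt)
}

#' Rule-based class-number selection
#'
#' Applies the selection rules across a set of fits with increasing K:
#' non-converged fits are discarded; fits with any modal class share below
#' `min_share` are discarded; surviving fits must have, in every class, more
#' than `prop_threshold` of modally assigned members with maximum posterior
#' above `post_threshold`; the lowest BIC among the remainder wins.
#'
#' @param fits List of `growmix_gmm` objects (typically K = 1..6).
#' @param min_share Minimum modal class share (default 0.05).
#' @param post_threshold Posterior-probability quality cutoff (default 0.7).
#' @param prop_threshold Required proportion of members above the cutoff
#'   (default 0.8).
#' @return Object of class `growmix_selection`: data.frame `report` (K, BIC,
#'   min_share, min_posterior_prop, converged, admissible, reason), the
#'   `chosen_K` (NA when every fit is rejected), and `chosen` (the winning
#'   fit).
#' @export
select_model <- function(fits, min_share = 0.05, post_threshold = 0.7,
                         prop_threshold = 0.8) {
  rows <- lapply(fits, function(f) {
    asg <- modal_assignment(f)
    shares <- tabulate(asg$class, nbins = f$K) / f$n_subjects
    props <- vapply(seq_len(f$K), function(k) {
      m <- asg$max_posterior[asg$class == k]
      if (!length(m)) return(0)
      mean(m > post_threshold)
    }, numeric(1))
    reason <- ""
    if (!f$converged) reason <- "did not converge"
    else if (min(shares) < min_share) reason <- sprintf("class share %.1f%% < %.0f%%",
                                                        100 * min(shares), 100 * min_share)
    else if (min(props) <= prop_threshold)
      reason <- sprintf("only %.0f%% of a class above posterior %.1f",
                        100 * min(props), post_threshold)
    data.frame(K = f$K, BIC = gmm_bic(f), min_share = min(shares),
               min_posterior_prop = min(props), converged = f$converged,
               admissible = reason == "", reason = reason,
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  ok <- which(report$admissible)
  chosen_K <- if (length(ok)) report$K[ok[which.min(report$BIC[ok])]] else NA_integer_
  chosen <- if (!is.na(chosen_K)) fits[[which(report$K == chosen_K)]] else NULL
  structure(list(report = report, chosen_K = chosen_K, chosen = chosen),
            class = "growmix_selection")
}

#' @export
print.growmix_selection <- function(x, ...) {
  print(x$report, row.names = FALSE)
  cat("chosen K:", x$chosen_K, "\n")
  invisible(x)
}

#' Fit a sweep of class counts and select one
#'
#' Convenience wrapper: fits K = `K_range` models with shared settings and
#' applies [select_model()].
#'
#' @inheritParams fit_gmm
#' @param K_range Integer vector of class counts (default 1:6).
#' @param ... Passed to [fit_gmm()].
#' @return A `growmix_selection` with the full fit list in `$fits`.
#' @export
fit_gmm_sweep <- function(growth, K_range = 1:6, membership = NULL, ...) {
  fits <- lapply(K_range, function(K)
    fit_gmm(growth, K = K, membership = membership, ...))
  sel <- select_model(fits)
  sel$fits <- fits
  sel
}

#' Build the membership-submodel design from an analysis object
#'
#' Assembles the subject-level data.frame entering the multinomial
#' membership submodel: one exposure term (standardized log2, or the two
#' non-reference tertile indicators) plus the seven adjustment covariates
#' (maternal age, education, marital status, smoke exposure, fish intake,
#' pre-pregnancy BMI, parity). Optionally adds the exposure x BMI>=25
#' cross-product.
#'
#' @param analysis A `growmix_analysis`.
#' @param element Element name (e.g. `"Hg"`), or `NULL` for covariates only.
#' @param mode `"continuous"` (standardized log2) or `"tertile"` (indicator
#'   columns `*_low`, `*_high`; middle tertile is the reference).
#' @param covariates Include the adjustment covariates (default TRUE).
#' @param bmi_interaction Add `element x bmi_ge_25` cross-product columns.
#' @return Data.frame with `subject_id` and numeric term columns.
#' @export
membership_frame <- function(analysis, element = NULL,
                             mode = c("continuous", "tertile"),
                             covariates = TRUE, bmi_interaction = FALSE) {
  mode <- match.arg(mode)
  ed <- analysis$exposures$data
  cov <- analysis$covariates
  out <- data.frame(subject_id = cov$subject_id, stringsAsFactors = FALSE)
  if (!is.null(element)) {
    i <- match(out$subject_id, ed$subject_id)
    if (mode == "continuous") {
      out[[element]] <- ed[[paste0("log2s_", element)]][i]
    } else {
      tert <- ed[[paste0("tert_", element)]][i]
      out[[paste0(element, "_low")]] <- as.integer(tert == "low")
      out[[paste0(element, "_high")]] <- as.integer(tert == "high")
    }
  }
  if (covariates) {
    out$maternal_age <- cov$maternal_age
    out$education <- as.numeric(cov$education)
    out$married <- as.numeric(cov$married)
    out$smoke_exposed <- as.numeric(cov$smoke_exposed)
    out$fish_intake <- as.numeric(cov$fish_intake)
    out$prepreg_bmi <- cov$prepreg_bmi
    out$primiparous <- as.numeric(cov$primiparous)
  }
  if (bmi_interaction) {
    if (is.null(element)) stop("bmi_interaction needs an element")
    out$bmi_ge_25 <- as.numeric(cov$bmi_ge_25)
    base <- setdiff(names(out), c("subject_id", "maternal_age", "education",
                                  "married", "smoke_exposed", "fish_intake",
                                  "prepreg_bmi", "primiparous", "bmi_ge_25"))
    for (b in base) out[[paste0(b, ":bmi_ge_25")]] <- out[[b]] * out$bmi_ge_25
  }
  out
}
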