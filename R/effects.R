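#' @importFrom stats qnorm pnorm coef lm vcov predict
NULL

# vcov lookup: variance of delta*(gamma_{j,term} - gamma_{r,term});
# class 1's gamma is pinned at zero and has no vcov entry.
.gamma_contrast_var <- function(V, j, r, term) {
  nm_j <- paste0("class", j, ":", term)
  nm_r <- paste0("class", r, ":", term)
  vj <- if (j == 1) 0 else V[nm_j, nm_j]
  vr <- if (r == 1) 0 else V[nm_r, nm_r]
  cjr <- if (j == 1 || r == 1) 0 else V[nm_j, nm_r]
  vj + vr - 2 * cjr
}

#' One-step relative risk ratios from the fitted mixture
#'
#' Under the multinomial-logit membership submodel, the probability-ratio
#' definition of the relative risk ratio
#' `RRR = [P(Group j | 2x) / P(Group j | x)] / [P(Group K | 2x) / P(Group K | x)]`
#' reduces exactly to `exp(delta (gamma_j - gamma_ref))` for the contrast's
#' term, independent of the covariate vector: the shared normalizing
#' constants cancel. Estimates and Wald 95% CIs are therefore computed on
#' the log scale from the fitted membership coefficients and their
#' covariance (asymptotic normality of the maximum-likelihood estimator),
#' and [verify_rrr_identity()] confirms the algebraic reduction numerically.
#'
#' For a doubling contrast on an element whose membership column is
#' standardized log2 concentration, `delta = 1 / scale_sd` (one log2 unit in
#' standardized units). For tertile contrasts the indicator columns enter
#' with `delta = 1`.
#'
#' @param fit A converged `growmix_gmm` whose membership submodel contains
#'   the contrast term(s).
#' @param element Element name as used in the membership columns.
#' @param kind `"doubling"` or `"tertile"`.
#' @param scale_sd Standardization SD of the log2 values (from
#'   `growmix_exposures$scale_sd`); required for `"doubling"`.
#' @param ref Reference class index (from [select_reference()]).
#' @return Data.frame rows (element, class, contrast, estimate, lo95, hi95,
#'   method = "one_step", converged); the reference class has no row. For a
#'   non-converged fit the rows are flagged and estimates are `NA`.
#' @export
rrr_onestep <- function(fit, element, kind = c("doubling", "tertile"),
                        scale_sd = NULL, ref = 1) {
  kind <- match.arg(kind)
  terms <- if (kind == "doubling") setNames(element, "doubling")
           else setNames(paste0(element, c("_low", "_high")),
                         c("tertile_low_vs_mid", "tertile_high_vs_mid"))
  if (!all(terms %in% colnames(fit$gamma)))
    stop("membership submodel lacks term(s): ",
         paste(setdiff(terms, colnames(fit$gamma)), collapse = ", "))
  deltas <- if (kind == "doubling") {
    if (is.null(scale_sd)) stop("scale_sd required for a doubling contrast")
    setNames(1 / scale_sd[element], "doubling")
  } else setNames(c(1, 1), names(terms))
  rows <- list()
  for (ct in names(terms)) {
    term <- terms[[ct]]; delta <- deltas[[ct]]
    for (j in setdiff(seq_len(fit$K), ref)) {
      if (!fit$converged) {
        rows[[length(rows) + 1]] <- data.frame(
          element = element, class = j, contrast = ct, estimate = NA_real_,
          lo95 = NA_real_, hi95 = NA_real_, method = "one_step",
          converged = FALSE, stringsAsFactors = FALSE)
        next
      }
      lrr <- delta * (fit$gamma[j, term] - fit$gamma[ref, term])
      se <- if (is.null(fit$vcov)) NA_real_
            else sqrt(.gamma_contrast_var(fit$vcov, j, ref, term)) * abs(delta)
      rows[[length(rows) + 1]] <- data.frame(
        element = element, class = j, contrast = ct, estimate = exp(lrr),
        lo95 = exp(lrr - qnorm(0.975) * se), hi95 = exp(lrr + qnorm(0.975) * se),
        method = "one_step", converged = TRUE, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Numerically verify the RRR probability-ratio identity
#'
#' Evaluates the displayed probability-ratio definition of the RRR at a grid
#' of covariate vectors (rows resampled from the fitted membership design)
#' and compares it with `exp(delta (gamma_j - gamma_ref))`. Under the logit
#' link the two agree to machine precision for every covariate vector.
#'
#' @param fit A `growmix_gmm` containing `term` in its membership submodel.
#' @param term Membership column to perturb.
#' @param delta Change applied to the term.
#' @param ref Reference class.
#' @param n_grid Number of covariate vectors.
#' @param seed RNG seed for the resampling.
#' @return Maximum absolute discrepancy over classes and grid points.
#' @export
verify_rrr_identity <- function(fit, term, delta = 1, ref = 1, n_grid = 50,
                                seed = 1) {
  stopifnot(term %in% colnames(fit$gamma))
  set.seed(seed)
  W <- fit$data$W
  idx <- sample.int(nrow(W), n_grid, replace = TRUE)
  ti <- match(term, colnames(W))
  softmax <- function(w) {
    e <- drop(fit$gamma %*% w); e <- e - max(e); exp(e) / sum(exp(e))
  }
  worst <- 0
  for (i in idx) {
    w0 <- W[i, ]; w1 <- w0; w1[ti] <- w1[ti] + delta
    p0 <- softmax(w0); p1 <- softmax(w1)
    for (j in setdiff(seq_len(fit$K), ref)) {
      ratio <- (p1[j] / p0[j]) / (p1[ref] / p0[ref])
      closed <- exp(delta * (fit$gamma[j, term] - fit$gamma[ref, term]))
      worst <- max(worst, abs(ratio - closed))
    }
  }
  worst
}

#' Two-stage relative risk ratios from modal assignments
#'
#' Multinomial logistic regression of the modal class assignment (reference
#' class releveled first) on the exposure term plus covariates, ignoring
#' classification uncertainty — the comparator for the one-step estimates.
#' Fitting uses `nnet::multinom`.
#'
#' @param assignment Modal assignment data.frame.
#' @param membership Subject-level design (as for [fit_gmm()]).
#' @param element Element term name in `membership`.
#' @param kind,scale_sd,ref As in [rrr_onestep()].
#' @return EffectTable rows with `method = "two_stage"`.
#' @export
rrr_twostage <- function(assignment, membership, element,
                         kind = c("doubling", "tertile"), scale_sd = NULL,
                         ref = 1) {
  kind <- match.arg(kind)
  terms0 <- if (kind == "doubling") setNames(element, "doubling")
            else setNames(paste0(element, c("_low", "_high")),
                          c("tertile_low_vs_mid", "tertile_high_vs_mid"))
  if (length(unique(assignment$class)) < 2) {
    # a degenerate classification cannot support any contrast; report it
    rows <- expand.grid(contrast = names(terms0), class = NA_integer_)
    return(data.frame(element = element, class = rows$class,
                      contrast = as.character(rows$contrast),
                      estimate = NA_real_, lo95 = NA_real_, hi95 = NA_real_,
                      method = "two_stage", converged = FALSE,
                      stringsAsFactors = FALSE))
  }
  m <- membership[match(assignment$subject_id, membership$subject_id), ]
  dat <- m[, setdiff(names(m), "subject_id"), drop = FALSE]
  dat$.class <- stats::relevel(factor(assignment$class), ref = as.character(ref))
  fit <- nnet::multinom(.class ~ ., data = dat, trace = FALSE, maxit = 2000,
                        reltol = 1e-15)
  conv <- fit$convergence == 0
  cf <- coef(fit)
  if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1, dimnames = list(
    setdiff(levels(dat$.class), as.character(ref)), names(cf)))
  V <- vcov(fit)
  terms <- if (kind == "doubling") setNames(element, "doubling")
           else setNames(paste0(element, c("_low", "_high")),
                         c("tertile_low_vs_mid", "tertile_high_vs_mid"))
  deltas <- if (kind == "doubling") {
    if (is.null(scale_sd)) stop("scale_sd required for a doubling contrast")
    setNames(1 / scale_sd[element], "doubling")
  } else setNames(c(1, 1), names(terms))
  rows <- list()
  for (ct in names(terms)) {
    term <- terms[[ct]]; delta <- deltas[[ct]]
    for (cl in rownames(cf)) {
      vnm <- paste0(cl, ":", term)
      if (!vnm %in% rownames(V)) vnm <- term  # binomial case: no class prefix
      est <- delta * cf[cl, term]
      se <- abs(delta) * sqrt(V[vnm, vnm])
      big <- !is.finite(se) || se > 50
      rows[[length(rows) + 1]] <- data.frame(
        element = element, class = as.integer(cl), contrast = ct,
        estimate = if (big) NA_real_ else exp(est),
        lo95 = if (big) NA_real_ else exp(est - qnorm(0.975) * se),
        hi95 = if (big) NA_real_ else exp(est + qnorm(0.975) * se),
        method = "two_stage", converged = conv && !big,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "fit") <- fit
  out
}

.permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in .permutations(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  out
}

#' Cohen's kappa between two class assignments
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with the
#' large-sample standard error `sqrt(p_o (1 - p_o) / (n (1 - p_e)^2))` for
#' the 95% CI. Because latent-class labels are arbitrary, labels of the
#' second assignment are first aligned to the first by the permutation that
#' maximizes diagonal agreement (`align = TRUE`).
#'
#' @param a,b Integer class vectors over the same subjects.
#' @param align Permute `b`'s labels to maximize agreement first.
#' @return List: `kappa`, `lo95`, `hi95`, `se`, `p_observed`, `p_expected`,
#'   `table` (aligned contingency table), and `alignment` (the permutation
#'   matching each category of `b` to a category of `a`). `kappa` is `NA`
#'   when either assignment has a single category.
#' @export
cohens_kappa <- function(a, b, align = TRUE) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (length(unique(a)) < 2 || length(unique(b)) < 2) {
    message("kappa undefined with a single category")
    return(list(kappa = NA_real_, lo95 = NA_real_, hi95 = NA_real_,
                se = NA_real_, table = table(a, b)))
  }
  levs <- sort(unique(c(a, b)))
  a <- factor(a, levels = levs); b <- factor(b, levels = levs)
  alignment <- seq_along(levs)
  if (align && length(levs) <= 7) {
    tab0 <- table(a, b)
    best <- NULL; best_diag <- -1
    for (p in .permutations(seq_along(levs))) {
      d <- sum(diag(tab0[, p, drop = FALSE]))
      if (d > best_diag) { best_diag <- d; best <- p }
    }
    # best pairs a-category i with b-category best[i]; invert so that
    # alignment[l] is the a-category matched to b-category l
    alignment <- order(best)
    b <- factor(levs[alignment[as.integer(b)]], levels = levs)
  }
  tab <- table(a, b)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  kappa <- (po - pe) / (1 - pe)
  se <- sqrt(po * (1 - po) / (n * (1 - pe)^2))
  list(kappa = kappa, lo95 = kappa - qnorm(0.975) * se,
       hi95 = kappa + qnorm(0.975) * se, se = se,
       p_observed = po, p_expected = pe, table = tab,
       alignment = alignment)
}

#' Linear regression of the 18-month weight-for-length z-score
#'
#' Ordinary least squares of a per-subject z-score on the exposure term(s)
#' plus covariates, with Wald 95% CIs — the attained-adiposity sensitivity
#' outcome.
#'
#' @param z Data.frame with `subject_id` and `z` (one row per subject).
#' @param membership Subject-level design data.frame (exposure + covariates).
#' @param exposure_terms Term names whose rows to return (default: all
#'   non-covariate columns are returned anyway; this marks them).
#' @return Data.frame (term, estimate, lo95, hi95, p) for every model term,
#'   with attribute `"fit"` (the `lm` object).
#' @export
linear_z_regression <- function(z, membership, exposure_terms = NULL) {
  m <- membership[match(z$subject_id, membership$subject_id), ]
  dat <- m[, setdiff(names(m), "subject_id"), drop = FALSE]
  dat$.z <- z$z
  if (nrow(dat) <= ncol(dat)) stop("fewer subjects than parameters")
  fit <- lm(.z ~ ., data = dat)
  sm <- summary(fit)$coefficients
  ci <- stats::confint(fit)
  out <- data.frame(term = rownames(sm), estimate = sm[, 1],
                    lo95 = ci[, 1], hi95 = ci[, 2], p = sm[, 4],
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(exposure_terms)) out$exposure <- out$term %in% exposure_terms
  attr(out, "fit") <- fit
  out
}

#' Exposure-by-BMI interaction
#'
#' Adds the element x (pre-pregnancy BMI >= 25) cross-product to the class
#' membership model and reports a Wald test per non-reference class. The
#' `"two_stage"` method refits the multinomial model on modal assignments;
#' the `"one_step"` method refits the growth mixture model with the
#' cross-product in its membership submodel.
#'
#' @param analysis A `growmix_analysis`.
#' @param element Element name.
#' @param method `"two_stage"` or `"one_step"`.
#' @param assignment Modal assignments (required for two-stage).
#' @param K Class count for the one-step refit.
#' @param ref Reference class.
#' @param ... Passed to [fit_gmm()] for the one-step refit.
#' @return Data.frame (element, class, term, estimate, se, p, method).
#' @export
bmi_interaction <- function(analysis, element,
                            method = c("two_stage", "one_step"),
                            assignment = NULL, K = NULL, ref = 1, ...) {
  method <- match.arg(method)
  mem <- membership_frame(analysis, element, bmi_interaction = TRUE)
  iterm <- paste0(element, ":bmi_ge_25")
  if (method == "two_stage") {
    if (is.null(assignment)) stop("two-stage interaction needs assignments")
    m <- mem[match(assignment$subject_id, mem$subject_id), ]
    dat <- m[, setdiff(names(m), "subject_id"), drop = FALSE]
    names(dat) <- make.names(names(dat))
    iterm_s <- make.names(iterm)
    dat$.class <- stats::relevel(factor(assignment$class),
                                 ref = as.character(ref))
    fit <- nnet::multinom(.class ~ ., data = dat, trace = FALSE, maxit = 500)
    cf <- coef(fit); V <- vcov(fit)
    if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1, dimnames = list(
      setdiff(levels(dat$.class), as.character(ref)), names(cf)))
    rows <- lapply(rownames(cf), function(cl) {
      vnm <- paste0(cl, ":", iterm_s)
      if (!vnm %in% rownames(V)) vnm <- iterm_s
      est <- cf[cl, iterm_s]; se <- sqrt(V[vnm, vnm])
      data.frame(element = element, class = as.integer(cl), term = iterm,
                 estimate = est, se = se, p = 2 * pnorm(-abs(est / se)),
                 method = "two_stage", stringsAsFactors = FALSE)
    })
    return(do.call(rbind, rows))
  }
  if (is.null(K)) stop("one-step interaction needs K")
  fit <- fit_gmm(analysis, K = K, membership = mem, ...)
  rows <- lapply(setdiff(seq_len(fit$K), ref), function(j) {
    est <- fit$gamma[j, iterm] - fit$gamma[ref, iterm]
    se <- sqrt(.gamma_contrast_var(fit$vcov, j, ref, iterm))
    data.frame(element = element, class = j, term = iterm, estimate = est,
               se = se, p = 2 * pnorm(-abs(est / se)), method = "one_step",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "fit") <- fit
  out
}
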