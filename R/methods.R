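#' @export
print.growmix_gmm <- function(x, ...) {
  cat("Growth mixture model:", x$K, "classes,", x$n_subjects, "subjects,",
      x$n_obs, "observations\n")
  cat(sprintf("logLik %.2f  BIC %.2f  sigma_b %.3f  sigma_e %.3f  %s\n",
              x$loglik, gmm_bic(x), x$sigma_b, x$sigma_e,
              if (x$converged) "converged" else "DID NOT CONVERGE"))
  shares <- colMeans(x$posterior)
  cat("expected class shares:", paste(sprintf("%.1f%%", 100 * shares),
                                      collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.growmix_gmm <- function(object, ...) {
  asg <- modal_assignment(object)
  shares <- tabulate(asg$class, object$K) / object$n_subjects
  out <- list(
    K = object$K, loglik = object$loglik, bic = gmm_bic(object),
    sigma_b = object$sigma_b, sigma_e = object$sigma_e,
    converged = object$converged, modal_shares = shares,
    mean_max_posterior = vapply(seq_len(object$K), function(k)
      mean(asg$max_posterior[asg$class == k]), numeric(1)),
    beta = object$beta, gamma = object$gamma)
  class(out) <- "summary.growmix_gmm"
  out
}

#' @export
print.summary.growmix_gmm <- function(x, ...) {
  cat(sprintf("%d-class growth mixture model (%s)\n", x$K,
              if (x$converged) "converged" else "not converged"))
  cat(sprintf("logLik %.2f   BIC %.2f   sigma_b %.3f   sigma_e %.3f g/cm\n",
              x$loglik, x$bic, x$sigma_b, x$sigma_e))
  df <- data.frame(class = seq_len(x$K),
                   modal_share = sprintf("%.1f%%", 100 * x$modal_shares),
                   mean_max_posterior = round(x$mean_max_posterior, 3))
  print(df, row.names = FALSE)
  cat("\nMean-curve coefficients (g/cm):\n"); print(round(x$beta, 3))
  cat("\nMembership logit coefficients (reference = class 1):\n")
  print(round(x$gamma, 3))
  invisible(x)
}

#' @export
coef.growmix_gmm <- function(object, ...) {
  list(beta = object$beta, gamma = object$gamma,
       sigma_b = object$sigma_b, sigma_e = object$sigma_e)
}

#' @export
logLik.growmix_gmm <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n_subjects,
            class = "logLik")
}

#' @export
vcov.growmix_gmm <- function(object, ...) object$vcov

#' Class mean curves at new ages
#'
#' @param object A `growmix_gmm`.
#' @param ages Ages in months (default a fine grid over the spline
#'   boundary).
#' @param ... Unused.
#' @return Matrix (ages x classes) of fitted mean weight-for-length.
#' @export
predict.growmix_gmm <- function(object, ages = NULL, ...) {
  if (is.null(ages))
    ages <- seq(object$spline$boundary[1], object$spline$boundary[2],
                length.out = 91)
  X <- basis_matrix(ages, object$spline)
  out <- X %*% t(object$beta)
  rownames(out) <- ages
  out
}

#' @export
plot.growmix_gmm <- function(x, ages = NULL, ...) {
  mu <- predict(x, ages)
  ages <- as.numeric(rownames(mu))
  graphics::matplot(ages, mu, type = "l", lty = 1, lwd = 2,
                    xlab = "Age (months)", ylab = "Weight-for-length (g/cm)",
                    main = sprintf("%d-class mean trajectories", x$K), ...)
  graphics::legend("topleft", legend = colnames(mu), lty = 1, lwd = 2,
                   col = seq_len(x$K), bty = "n")
  invisible(x)
}

#' @export
residuals.growmix_gmm <- function(object, ...) {
  d <- object$data
  asg <- modal_assignment(object)
  k <- asg$class[d$subj]
  mu <- rowSums(d$X * object$beta[k, , drop = FALSE])
  r <- d$y - mu
  # empirical Bayes random-intercept estimate under the modal class
  s1 <- rowsum(r, d$subj)
  bhat <- drop(object$sigma_b^2 * s1 / (object$sigma_e^2 + d$n_i * object$sigma_b^2))
  r - bhat[d$subj]
}
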