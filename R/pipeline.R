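#' Pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs. Inputs are either a
#' [sim_config()] (simulate mode) or paths to the three cohort CSV tables
#' (see [read_cohort()]); exactly one must be provided. The chart is a CSV
#' path for [read_growth_chart()] or `NULL`, in which case the package's
#' [synthetic_chart()] is used (simulated runs only — real analyses should
#' supply a real standard).
#'
#' @param sim A `sim_config`, or `NULL`.
#' @param input_dir Directory containing `growth.csv`, `exposures.csv`,
#'   `covariates.csv`, or `NULL`.
#' @param chart_path CSV path for the growth-standard chart, or `NULL`.
#' @param sexes Strata to analyze (fit separately; parameters are never
#'   shared across strata).
#' @param K_range Class counts to sweep (default 1:6).
#' @param knot_mode `"fixed"` (knots at 3.5 and 9 months), `"select2"` or
#'   `"select3"` (knots chosen by [select_knots()]).
#' @param continuous_elements Elements analyzed per doubling (toxic
#'   elements; default As, Hg, Pb).
#' @param tertile_elements Elements analyzed by tertile with middle
#'   reference (essential elements; default Cu, Mn, Se).
#' @param qgc_q,qgc_B Quantile count and bootstrap resamples for the
#'   mixture analysis.
#' @param n_starts EM restarts per fit.
#' @param max_iter EM iteration budget per start; fits that exhaust it are
#'   recorded as non-converged and rejected by the selection rules.
#' @param weight_channel Also fit raw-weight trajectories at the chosen K,
#'   name classes against the weight chart, and transfer the names to the
#'   weight-for-length classes through their kappa-aligned correspondence
#'   (default TRUE; FALSE names weight-for-length classes directly against
#'   a weight-for-length chart).
#' @param out_dir Output directory for artifacts.
#' @param seed Global seed; every stage derives its stream from it.
#' @return A list of class `growmix_pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, input_dir = NULL, chart_path = NULL,
                            sexes = c("male", "female"), K_range = 1:6,
                            knot_mode = c("fixed", "select2", "select3"),
                            continuous_elements = c("As", "Hg", "Pb"),
                            tertile_elements = c("Cu", "Mn", "Se"),
                            qgc_q = 4, qgc_B = 500, n_starts = 20,
                            max_iter = 1500, weight_channel = TRUE,
                            out_dir = tempfile("growmix_run_"), seed = 1L) {
  knot_mode <- match.arg(knot_mode)
  if (is.null(sim) && is.null(input_dir))
    stop("provide either a sim_config or an input directory")
  if (!is.null(sim) && !is.null(input_dir))
    stop("provide a sim_config or an input directory, not both")
  stopifnot(all(K_range >= 1), all(K_range <= 6))
  structure(list(sim = sim, input_dir = input_dir, chart_path = chart_path,
                 sexes = sexes, K_range = K_range, knot_mode = knot_mode,
                 continuous_elements = continuous_elements,
                 tertile_elements = tertile_elements, qgc_q = qgc_q,
                 qgc_B = qgc_B, n_starts = n_starts, max_iter = max_iter,
                 weight_channel = weight_channel, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "growmix_pipeline_config")
}

.fit_to_doc <- function(fit) {
  list(K = fit$K, loglik = fit$loglik, bic = gmm_bic(fit),
       n_params = fit$n_params, converged = fit$converged,
       n_subjects = fit$n_subjects, n_obs = fit$n_obs,
       sigma_b = fit$sigma_b, sigma_e = fit$sigma_e,
       beta = as.data.frame(fit$beta), gamma = as.data.frame(fit$gamma),
       membership_terms = fit$membership_terms,
       knots = fit$spline$knots)
}

.subset_analysis <- function(analysis, ids) {
  out <- analysis
  out$growth <- analysis$growth[analysis$growth$subject_id %in% ids, ]
  out$covariates <- analysis$covariates[analysis$covariates$subject_id %in% ids, ]
  ed <- analysis$exposures$data
  out$exposures <- analysis$exposures
  out$exposures$data <- ed[ed$subject_id %in% ids, ]
  if (!is.null(analysis$truth))
    out$truth <- analysis$truth[analysis$truth$subject_id %in% ids, ]
  out
}

#' Run the full analysis pipeline
#'
#' Simulate or load the cohort; apply the preprocessing cascade; choose the
#' spline knots; per sex stratum, sweep the class count, apply the selection
#' rules, name classes against the growth-standard chart (via the weight
#' channel and kappa transfer when `weight_channel` is on), estimate
#' one-step and two-stage exposure effects (doubling RRRs for toxic
#' elements, tertile RRRs for essential elements), 18-month z-score
#' regressions, BMI cross-product interactions, and the quantile
#' g-computation mixture model. All artifacts are written under
#' `config$out_dir` as CSV/JSON, and model non-convergence is recorded in
#' the effect tables rather than raised.
#'
#' @param config A [pipeline_config()].
#' @return The output directory path, invisibly; the in-memory results are
#'   returned as the attribute `"results"`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "growmix_pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, f) utils::write.csv(x, file.path(config$out_dir, f),
                                        row.names = FALSE)
  cohort <- if (!is.null(config$sim)) generate_cohort(config$sim)
            else read_cohort(config$input_dir)
  analysis <- preprocess_cohort(cohort)
  wr(analysis$exclusions, "exclusions.csv")
  chart_w <- if (!is.null(config$chart_path))
    read_growth_chart(config$chart_path) else synthetic_chart("weight")
  chart_wfl <- if (!is.null(config$chart_path))
    read_growth_chart(config$chart_path) else synthetic_chart("wfl")

  spline <- switch(config$knot_mode,
    fixed = spline_spec(c(3.5, 9)),
    select2 = select_knots(analysis$growth$age, analysis$growth$wfl, 2),
    select3 = select_knots(analysis$growth$age, analysis$growth$wfl, 3))

  results <- list()
  for (sx in config$sexes) {
    sdir <- file.path(config$out_dir, sx)
    dir.create(sdir, showWarnings = FALSE)
    wrs <- function(x, f) utils::write.csv(x, file.path(sdir, f),
                                           row.names = FALSE)
    ids <- unique(analysis$growth$subject_id[analysis$growth$sex == sx])
    if (length(ids) < 20) { warning("stratum ", sx, " too small; skipped"); next }
    an <- .subset_analysis(analysis, ids)
    an$exposures <- transform_exposures(
      cohort$exposures[cohort$exposures$subject_id %in% ids, , drop = FALSE])
    cov_mem <- membership_frame(an, element = NULL)
    sweep_seed <- config$seed + 101L
    sel <- fit_gmm_sweep(an, K_range = config$K_range, membership = cov_mem,
                         spline = spline, n_starts = config$n_starts,
                         max_iter = config$max_iter, seed = sweep_seed,
                         compute_vcov = FALSE)
    wrs(sel$report, "selection.csv")
    if (is.na(sel$chosen_K)) {
      warning("no admissible model in stratum ", sx)
      results[[sx]] <- list(selection = sel)
      next
    }
    fit <- sel$chosen
    asg <- modal_assignment(fit)
    wrs(asg, "assignments.csv")
    jsonlite::write_json(.fit_to_doc(fit), file.path(sdir, "model.json"),
                         auto_unbox = TRUE, digits = NA)

    # reference selection + semantic labels
    if (config$weight_channel) {
      wfit <- fit_gmm(an, K = fit$K, membership = cov_mem, spline = spline,
                      outcome = "weight", n_starts = config$n_starts,
                      max_iter = config$max_iter, seed = sweep_seed + 1L,
                      compute_vcov = FALSE)
      wasg <- modal_assignment(wfit)
      med_w <- class_median_curves(wasg, an$growth, outcome = "weight")
      ssd <- select_reference(med_w, chart_w, sex = sx)
      kp <- cohens_kappa(wasg$class, asg$class)
      # transfer weight-class names to wfl classes via the kappa alignment
      # (injective: wfl class l corresponds to weight class alignment[l])
      labels <- ssd$labels[kp$alignment]
      ref <- which(labels == "Stable-slow")[1]
      if (is.na(ref)) { ref <- 1; labels[1] <- "Stable-slow" }
      kappa_val <- kp$kappa
    } else {
      med <- class_median_curves(asg, an$growth, outcome = "wfl")
      ssd <- select_reference(med, chart_wfl, sex = sx)
      labels <- ssd$labels
      ref <- ssd$reference
      kappa_val <- NA_real_
    }
    wrs(data.frame(class = seq_along(ssd$ssd), ssd = ssd$ssd,
                   label_chart = ssd$labels), "reference.csv")
    jsonlite::write_json(
      list(reference_class = ref, labels = labels, kappa_weight_vs_wfl = kappa_val),
      file.path(sdir, "reference.json"), auto_unbox = TRUE, digits = NA)

    # effect tables need at least two realized classes to contrast
    multi_class <- fit$K >= 2 && length(unique(asg$class)) >= 2
    effects <- NULL
    if (multi_class) {
      eff <- list()
      for (el in config$continuous_elements) {
        mem <- membership_frame(an, el, mode = "continuous")
        efit <- fit_gmm(an, K = fit$K, membership = mem, spline = spline,
                        n_starts = config$n_starts,
                        max_iter = config$max_iter, seed = sweep_seed + 7L)
        eff[[length(eff) + 1]] <- rrr_onestep(efit, el, "doubling",
                                              scale_sd = an$exposures$scale_sd,
                                              ref = ref)
        eff[[length(eff) + 1]] <- rrr_twostage(asg, mem, el, "doubling",
                                               scale_sd = an$exposures$scale_sd,
                                               ref = ref)
      }
      for (el in config$tertile_elements) {
        mem <- membership_frame(an, el, mode = "tertile")
        efit <- fit_gmm(an, K = fit$K, membership = mem, spline = spline,
                        n_starts = config$n_starts,
                        max_iter = config$max_iter, seed = sweep_seed + 8L)
        eff[[length(eff) + 1]] <- rrr_onestep(efit, el, "tertile", ref = ref)
        eff[[length(eff) + 1]] <- rrr_twostage(asg, mem, el, "tertile", ref = ref)
      }
      effects <- do.call(rbind, eff)
      effects$sex <- sx
      effects$label <- labels[effects$class]
      wrs(effects, "effects.csv")
    } else {
      warning("stratum ", sx, ": only one realized class; ",
              "no exposure contrasts estimated")
    }

    # 18-month weight-for-length z-scores
    g18 <- an$growth[!is.na(an$growth$nominal_visit) &
                     an$growth$nominal_visit == max(an$schedule), ]
    zrows <- NULL
    if (nrow(g18) > 30 && all(c("L", "S") %in% names(chart_wfl))) {
      z <- data.frame(subject_id = g18$subject_id,
                      z = lms_zscore(g18$wfl, g18$nominal_visit, chart_wfl,
                                     sex = sx))
      zr <- lapply(c(config$continuous_elements, config$tertile_elements),
        function(el) {
          mode <- if (el %in% config$continuous_elements) "continuous" else "tertile"
          mem <- membership_frame(an, el, mode = mode)
          tab <- linear_z_regression(z, mem)
          tab$element <- el
          tab[grep(el, tab$term), , drop = FALSE]
        })
      zrows <- do.call(rbind, zr)
      wrs(zrows, "zscore.csv")
    }

    # BMI cross-product interactions (two-stage) and the mixture analysis
    # share the multi-class requirement
    irows <- NULL
    mix <- NULL
    if (multi_class) {
      irows <- do.call(rbind, lapply(config$continuous_elements, function(el)
        bmi_interaction(an, el, method = "two_stage", assignment = asg,
                        ref = ref)))
      wrs(irows, "interactions.csv")

      qz <- quantize(cohort$exposures[cohort$exposures$subject_id %in% ids, ],
                     q = config$qgc_q)
      mix <- qgc_fit(qz, asg, covariates = cov_mem, ref = ref,
                     B = config$qgc_B, seed = config$seed + 211L)
      mixout <- mix$results
      mixout$label <- labels[mixout$class]
      wrs(mixout, "mixture.csv")
      wrs(as.data.frame(cbind(element = rownames(mix$weights), mix$weights)),
          "mixture_weights.csv")
    }

    results[[sx]] <- list(selection = sel, fit = fit, assignment = asg,
                          reference = ref, labels = labels,
                          kappa_weight_vs_wfl = kappa_val, ssd = ssd,
                          effects = effects, zscore = zrows,
                          interactions = irows, mixture = mix)
  }

  saveRDS(config, tf <- tempfile()); on.exit(unlink(tf), add = TRUE)
  manifest <- list(
    config_md5 = unname(tools::md5sum(tf)),
    seed = config$seed, knots = spline$knots,
    package_version = as.character(utils::packageVersion("growmix")),
    r_version = R.version.string,
    n_subjects_analytic = length(unique(analysis$growth$subject_id)),
    exclusions = as.list(table(analysis$exclusions$reason)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  out <- config$out_dir
  attr(out, "results") <- c(results, list(analysis = analysis, spline = spline))
  invisible(out)
}
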