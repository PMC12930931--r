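#' Assign observations to nominal visits
#'
#' Maps each observation age to the nearest scheduled visit if it falls
#' within that visit's window (half the gap to the adjacent visits); ages
#' outside every window are left unassigned (`NA`). When a subject has
#' several observations mapped to the same visit, the closest wins; distance
#' ties go to the earlier observation.
#'
#' @param growth Growth data.frame with `subject_id` and `age` (months).
#' @param schedule Nominal visit ages (months), strictly increasing.
#' @return `growth` with a `nominal_visit` column (scheduled age, or `NA`)
#'   and duplicate per-subject-per-visit rows demoted to `NA`.
#' @export
assign_nominal_visits <- function(growth, schedule = c(0, 0.46, 1, 2, 4, 6, 9, 12, 15, 18)) {
  stopifnot(!is.unsorted(schedule, strictly = TRUE))
  # window half-widths: half gap to neighbours, outermost open to the boundary gap
  gaps <- diff(schedule)
  lo <- schedule - c(gaps[1], gaps) / 2
  hi <- schedule + c(gaps, gaps[length(gaps)]) / 2
  nearest <- vapply(growth$age, function(a) which.min(abs(schedule - a)), 1L)
  inwin <- growth$age >= lo[nearest] & growth$age <= hi[nearest]
  nominal <- ifelse(inwin, schedule[nearest], NA_real_)

  # one observation per subject per visit: closest wins, ties -> earlier row
  dist <- abs(growth$age - nominal)
  ord <- order(growth$subject_id, nominal, dist, seq_len(nrow(growth)))
  dup <- duplicated(data.frame(growth$subject_id, nominal)[ord, ])
  nominal[ord][dup & !is.na(nominal[ord])] <- NA_real_
  growth$nominal_visit <- nominal
  growth
}

#' Exclude subjects with extreme weight-for-length values
#'
#' Computes the mean and SD of weight-for-length per nominal visit (pooled
#' over sexes) and excludes, at the subject level, every subject with at
#' least one observation outside mean +/- 4 SD at its visit. Visits with
#' fewer than two observations cannot define an SD and are skipped with a
#' warning.
#'
#' @param growth Growth data.frame with `wfl` and `nominal_visit`.
#' @param n_sd Multiplier of the per-visit SD (default 4).
#' @return List with `kept` (growth rows of retained subjects) and
#'   `excluded` (character vector of excluded subject ids).
#' @export
filter_outliers <- function(growth, n_sd = 4) {
  stopifnot(all(c("wfl", "nominal_visit") %in% names(growth)))
  g <- growth[!is.na(growth$nominal_visit), ]
  flagged <- character(0)
  for (v in unique(g$nominal_visit)) {
    x <- g[g$nominal_visit == v, ]
    if (nrow(x) < 2) {
      warning("visit ", v, " months has <2 observations; no outlier screen there")
      next
    }
    m <- mean(x$wfl); s <- sd(x$wfl)
    out <- x$wfl < m - n_sd * s | x$wfl > m + n_sd * s
    flagged <- c(flagged, x$subject_id[out])
  }
  flagged <- unique(flagged)
  list(kept = growth[!growth$subject_id %in% flagged, ],
       excluded = flagged)
}

#' Exclude subjects with three or fewer measurements
#'
#' Removes subjects contributing three or fewer observations between 0 and
#' 18 months (a subject needs at least four points to inform a subject-level
#' trajectory).
#'
#' @param growth Growth data.frame.
#' @param min_measures Minimum retained count; subjects with strictly fewer
#'   than `min_measures` rows are excluded (default 4, i.e. "three or
#'   fewer" are dropped).
#' @return List with `kept` and `excluded` as in [filter_outliers()].
#' @export
filter_min_measures <- function(growth, min_measures = 4) {
  counts <- table(growth$subject_id)
  excl <- names(counts)[counts < min_measures]
  list(kept = growth[!growth$subject_id %in% excl, ], excluded = excl)
}

#' Exposure transforms: standardized log2 and tertiles
#'
#' Continuous mode log2-transforms each element, centers, and divides by the
#' sample SD of the log2 values (recorded in `scale_sd` so per-doubling
#' contrasts are exactly invertible). Tertile mode cuts each element into
#' three equal-count groups by stable rank (reported cut points are the
#' sample quantiles at 1/3 and 2/3); the middle tertile is the reference
#' level.
#'
#' @param raw Data.frame with `subject_id` and element concentration columns
#'   (LOD substitution already applied).
#' @param elements Element columns to transform.
#' @return A list of class `growmix_exposures`: `data` (subject_id,
#'   `log2s_<el>` standardized columns, `tert_<el>` factors with levels
#'   low/middle/high), `scale_sd`, `center` (named per element, log2 scale),
#'   `cutpoints` (2 x elements matrix, raw scale).
#' @export
transform_exposures <- function(raw, elements = ELEMENTS) {
  stopifnot(all(elements %in% names(raw)))
  out <- data.frame(subject_id = raw$subject_id, stringsAsFactors = FALSE)
  scale_sd <- center <- setNames(numeric(length(elements)), elements)
  cutpoints <- matrix(NA_real_, 2, length(elements),
                      dimnames = list(c("t1", "t2"), elements))
  n <- nrow(raw)
  for (el in elements) {
    x <- raw[[el]]
    if (any(x <= 0)) stop("non-positive concentration in ", el)
    lx <- log2(x)
    s <- sd(lx)
    if (!is.finite(s) || s == 0) stop("constant column ", el, ": cannot scale")
    center[el] <- mean(lx); scale_sd[el] <- s
    out[[paste0("log2s_", el)]] <- (lx - center[el]) / s
    r <- rank(x, ties.method = "first")
    grp <- ceiling(3 * r / n)
    out[[paste0("tert_", el)]] <-
      factor(c("low", "middle", "high")[grp], levels = c("low", "middle", "high"))
    cutpoints[, el] <- quantile(x, c(1 / 3, 2 / 3), names = FALSE)
  }
  structure(list(data = out, scale_sd = scale_sd, center = center,
                 cutpoints = cutpoints),
            class = "growmix_exposures")
}

#' Apply the full preprocessing cascade to a cohort
#'
#' Assigns nominal visits, then applies the exclusion cascade in study
#' order: (1) any weight-for-length outside the per-visit mean +/- 4 SD
#' (subject-level exclusion), (2) three or fewer measurements, (3) missing
#' covariate data. Exposure transforms are computed on the analytic sample
#' remaining after exclusions.
#'
#' @param cohort A `growmix_cohort` (from [generate_cohort()] or
#'   [read_cohort()]).
#' @param schedule Nominal visit schedule (months).
#' @return A list of class `growmix_analysis`: filtered `growth`,
#'   `exposures` (a `growmix_exposures`), `covariates` (with derived
#'   `bmi_ge_25` flag), `exclusions` (data.frame subject_id, reason), and
#'   `truth` if the cohort carried it.
#' @export
preprocess_cohort <- function(cohort, schedule = c(0, 0.46, 1, 2, 4, 6, 9, 12, 15, 18)) {
  g <- assign_nominal_visits(cohort$growth, schedule)
  excl <- data.frame(subject_id = character(0), reason = character(0),
                     stringsAsFactors = FALSE)
  f1 <- filter_outliers(g)
  if (length(f1$excluded))
    excl <- rbind(excl, data.frame(subject_id = f1$excluded,
                                   reason = "wfl outside mean +/- 4 SD"))
  f2 <- filter_min_measures(f1$kept)
  if (length(f2$excluded))
    excl <- rbind(excl, data.frame(subject_id = f2$excluded,
                                   reason = "three or fewer measures"))
  g <- f2$kept
  cov <- cohort$covariates
  miss <- cov$subject_id[!stats::complete.cases(cov)]
  miss <- intersect(miss, unique(g$subject_id))
  if (length(miss)) {
    excl <- rbind(excl, data.frame(subject_id = miss,
                                   reason = "missing covariate data"))
    g <- g[!g$subject_id %in% miss, ]
  }
  ids <- unique(g$subject_id)
  cov <- cov[cov$subject_id %in% ids, , drop = FALSE]
  cov$bmi_ge_25 <- as.integer(cov$prepreg_bmi >= 25)
  expo_raw <- cohort$exposures[cohort$exposures$subject_id %in% ids, , drop = FALSE]
  expo <- transform_exposures(expo_raw)
  out <- list(growth = g, exposures = expo, covariates = cov,
              exclusions = excl, schedule = schedule)
  if (!is.null(cohort$truth))
    out$truth <- cohort$truth[cohort$truth$subject_id %in% ids, , drop = FALSE]
  structure(out, class = "growmix_analysis")
}

#' @export
print.growmix_analysis <- function(x, ...) {
  cat("Analysis-ready cohort:", length(unique(x$growth$subject_id)),
      "subjects,", nrow(x$growth), "observations;",
      nrow(x$exclusions), "subjects excluded\n")
  if (nrow(x$exclusions)) print(table(x$exclusions$reason))
  invisible(x)
}
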