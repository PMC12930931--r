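#' Read a growth-standard chart from CSV
#'
#' Charts are user-supplied plain CSV with columns `sex`
#' (`male`/`female`), `index` (age in months or length in cm, strictly
#' increasing within sex), `M` (median, mandatory) and optionally `L`
#' (Box-Cox power) and `S` (coefficient of variation) for LMS z-scores.
#'
#' @param path CSV file path.
#' @param index_kind `"age_months"` or `"length_cm"` (metadata only).
#' @return Data.frame of class `growmix_chart`.
#' @export
read_growth_chart <- function(path, index_kind = "age_months") {
  ch <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sex", "index", "M") %in% names(ch)))
  if (any(ch$M <= 0)) stop("chart medians must be positive")
  for (s in unique(ch$sex))
    if (is.unsorted(ch$index[ch$sex == s], strictly = TRUE))
      stop("chart index must be strictly increasing within sex")
  if ("S" %in% names(ch) && any(ch$S <= 0, na.rm = TRUE))
    stop("chart S must be positive")
  attr(ch, "index_kind") <- index_kind
  class(ch) <- c("growmix_chart", "data.frame")
  ch
}

#' Synthetic growth-standard chart
#'
#' Builds a smooth synthetic reference chart (NOT the WHO tables, which are
#' not redistributed here) with the structure growth standards show against
#' a contemporary cohort: a median weight-for-length curve rising from 66 to
#' 127 g/cm over 0-18 months — slightly below the cohort mean, as standards
#' built on optimally breastfed infants sit below average growth in this
#' population — and, for the weight chart, that curve multiplied by the
#' sex-specific median length (kg = g/cm x cm / 1000). Mild skewness
#' (L = -0.2) and a coefficient of variation of 0.11 complete the LMS
#' triplet. Intended for tests, examples and simulated pipelines; real
#' analyses should supply an actual standard via [read_growth_chart()].
#'
#' @param kind `"weight"` (kg, age-indexed) or `"wfl"` (g/cm, age-indexed).
#' @param ages Index ages in months.
#' @return A `growmix_chart` covering both sexes.
#' @export
synthetic_chart <- function(kind = c("weight", "wfl"),
                            ages = c(0, 0.46, 1, 2, 3, 4, 6, 9, 12, 15, 18)) {
  kind <- match.arg(kind)
  f <- function(t) (t / (t + 2.5)) / (18 / 20.5)
  wfl_med <- 65.5 + (125.5 - 65.5) * f(ages)
  rows <- lapply(c("male", "female"), function(s) {
    M <- if (kind == "weight") wfl_med * .length_curve(ages, s) / 1000
         else wfl_med
    data.frame(sex = s, index = ages, L = -0.2, M = M, S = 0.11,
               stringsAsFactors = FALSE)
  })
  ch <- do.call(rbind, rows)
  attr(ch, "index_kind") <- "age_months"
  class(ch) <- c("growmix_chart", "data.frame")
  ch
}

#' Per-class median outcome at each nominal visit
#'
#' @param assignment Modal assignment data.frame ([modal_assignment()]).
#' @param growth Growth table with `nominal_visit` assigned.
#' @param outcome Outcome column (`"wfl"` or `"weight"`).
#' @param schedule Visits to evaluate (default: those present).
#' @return Matrix (classes x visits) of medians; `NA` where a class has no
#'   observation at a visit.
#' @export
class_median_curves <- function(assignment, growth, outcome = "wfl",
                                schedule = NULL) {
  g <- growth[!is.na(growth$nominal_visit), ]
  g$class <- assignment$class[match(g$subject_id, assignment$subject_id)]
  if (anyNA(g$class)) stop("growth contains subjects without an assignment")
  if (is.null(schedule)) schedule <- sort(unique(g$nominal_visit))
  K <- max(assignment$class)
  if (length(unique(assignment$class)) < K ||
      any(tabulate(assignment$class, K) == 0))
    stop("empty class in assignment")
  out <- matrix(NA_real_, K, length(schedule),
                dimnames = list(paste0("class", seq_len(K)), schedule))
  for (k in seq_len(K)) for (j in seq_along(schedule)) {
    x <- g[[outcome]][g$class == k & g$nominal_visit == schedule[j]]
    if (length(x)) out[k, j] <- median(x)
  }
  out
}

# interpolate a chart column at given index values for one sex
.chart_interp <- function(chart, sex, at, col = "M") {
  ch <- chart[chart$sex == sex, ]
  if (!nrow(ch)) stop("chart has no rows for sex ", sex)
  if (any(at < min(ch$index) - 1e-9 | at > max(ch$index) + 1e-9))
    stop("index outside chart range")
  stats::approx(ch$index, ch[[col]], xout = at, rule = 1)$y
}

#' Select the reference class against a growth-standard chart
#'
#' For each class, computes the sum of squared differences (SSD) between the
#' class's median curve at scheduled visits and the chart's median
#' (linearly interpolated at those visits); the class with the smallest SSD
#' becomes the reference. Visits at which some class has no median are
#' dropped for all classes (the SSD is computed over the visit
#' intersection), with a message. Semantic labels are attached: the
#' reference is "Stable-slow"; among the others, a class whose median sits
#' below the chart before 9 months but above it at the end is
#' "Late-moderate"; the remaining classes are ordered by their 18-month
#' (last-visit) median into "Stable-moderate" and "Rapid".
#'
#' @param medians Classes x visits matrix from [class_median_curves()].
#' @param chart A `growmix_chart` with medians comparable to the outcome.
#' @param sex Chart sex to compare against.
#' @return Object of class `growmix_ssd`: `ssd` (per class), `reference`
#'   (class index), `labels` (per class), `diffs` (class x visit differences
#'   from the chart), `visits`.
#' @export
select_reference <- function(medians, chart, sex = "male") {
  visits <- as.numeric(colnames(medians))
  keep <- colSums(is.na(medians)) == 0
  if (!all(keep)) {
    message("dropping visits with missing class medians: ",
            paste(visits[!keep], collapse = ", "))
    medians <- medians[, keep, drop = FALSE]
    visits <- visits[keep]
  }
  chm <- .chart_interp(chart, sex, visits)
  diffs <- sweep(medians, 2, chm)
  ssd <- rowSums(diffs^2)
  ref <- which.min(ssd)
  K <- nrow(medians)
  labels <- rep(NA_character_, K)
  labels[ref] <- "Stable-slow"
  others <- setdiff(seq_len(K), ref)
  if (length(others)) {
    early <- visits < 9
    late_flag <- vapply(others, function(k)
      mean(diffs[k, early]) < 0 && diffs[k, length(visits)] > 0, logical(1))
    lm_k <- integer(0)
    if (any(late_flag) && length(others) >= 3) {
      cand <- others[late_flag]
      lm_k <- cand[which.max(diffs[cand, length(visits)] - rowMeans(diffs[cand, early, drop = FALSE]))]
      labels[lm_k] <- "Late-moderate"
    }
    rest <- setdiff(others, lm_k)
    rest <- rest[order(medians[rest, length(visits)])]
    nm <- if (length(rest) == 2) c("Stable-moderate", "Rapid")
          else if (length(rest) == 1) "Rapid"
          else c(paste0("Moderate-", seq_len(max(length(rest) - 1, 0))), "Rapid")[seq_along(rest)]
    labels[rest] <- nm
  }
  structure(list(ssd = ssd, reference = unname(ref), labels = labels,
                 diffs = diffs, medians = medians, visits = visits,
                 sex = sex),
            class = "growmix_ssd")
}

#' @export
print.growmix_ssd <- function(x, ...) {
  df <- data.frame(class = seq_along(x$ssd), label = x$labels,
                   SSD = round(x$ssd, 2))
  print(df, row.names = FALSE)
  cat("reference class:", x$reference, "(", x$labels[x$reference], ")\n")
  invisible(x)
}

#' LMS z-score
#'
#' Standard Box-Cox (LMS) z-score against a chart:
#' `z = ((value/M)^L - 1) / (L S)` for `L != 0`, `z = log(value/M) / S` for
#' `L = 0`; L, M, S are linearly interpolated at the index value.
#'
#' @param value Measured value(s).
#' @param at Index value(s) (age in months or length in cm per the chart).
#' @param chart A `growmix_chart` carrying L, M and S.
#' @param sex Chart sex.
#' @return Numeric z-score(s), strictly increasing in `value`.
#' @export
lms_zscore <- function(value, at, chart, sex = "male") {
  stopifnot(all(c("L", "S") %in% names(chart)))
  L <- .chart_interp(chart, sex, at, "L")
  M <- .chart_interp(chart, sex, at, "M")
  S <- .chart_interp(chart, sex, at, "S")
  ifelse(abs(L) < 1e-12,
         log(value / M) / S,
         ((value / M)^L - 1) / (L * S))
}
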