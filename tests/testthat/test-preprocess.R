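make_growth <- function(wfl_by_subject, visit = 6) {
  do.call(rbind, lapply(seq_along(wfl_by_subject), function(i)
    data.frame(subject_id = sprintf("S%02d", i), age = visit,
               wfl = wfl_by_subject[[i]], nominal_visit = visit)))
}

test_that("subjects beyond mean +/- 4 SD at any visit are excluded entirely", {
  set.seed(1)
  base <- rnorm(40, 100, 5)
  g <- make_growth(c(base, 100 + 5 * sd(base) * 2))  # far outlier
  r <- filter_outliers(g)
  expect_equal(r$excluded, "S41")
  expect_false("S41" %in% r$kept$subject_id)
  # all within 1 SD: nothing excluded
  g2 <- make_growth(100 + seq(-1, 1, length.out = 30))
  expect_length(filter_outliers(g2)$excluded, 0)
})

test_that("injected extreme subjects are exactly the ones excluded", {
  co <- generate_cohort(kmix_config(K = 2, n = 300, seed = 21))
  g <- assign_nominal_visits(co$growth)
  ids <- unique(g$subject_id)
  bad <- sample(ids, 15)
  for (s in bad) {
    i <- which(g$subject_id == s)[1]
    g$wfl[i] <- g$wfl[i] + 200   # grossly outside any 4-SD band
  }
  r <- filter_outliers(g)
  expect_setequal(r$excluded, bad)
  # brute-force oracle: recompute flags over all records directly
  flagged <- character(0)
  for (v in unique(g$nominal_visit[!is.na(g$nominal_visit)])) {
    x <- g[!is.na(g$nominal_visit) & g$nominal_visit == v, ]
    m <- mean(x$wfl); s <- sd(x$wfl)
    flagged <- c(flagged, x$subject_id[abs(x$wfl - m) > 4 * s])
  }
  expect_setequal(r$excluded, unique(flagged))
})

test_that("three or fewer measures excludes at the stated boundary", {
  g <- rbind(
    data.frame(subject_id = "A", age = c(0, 2, 6), wfl = 100),
    data.frame(subject_id = "B", age = c(0, 2, 6, 12), wfl = 100))
  r <- filter_min_measures(g)
  expect_equal(r$excluded, "A")
  expect_true(all(r$kept$subject_id == "B"))
})

test_that("exclusion count under heavy missingness matches a direct count", {
  co <- generate_cohort(kmix_config(K = 2, n = 400, seed = 23, missing = 0.8))
  r <- filter_min_measures(co$growth)
  oracle <- names(which(table(co$growth$subject_id) <= 3))
  expect_setequal(r$excluded, oracle)
  expect_gt(length(r$excluded), 0)
})

test_that("log2 transform is exact on powers of two and scaling is recorded", {
  raw <- data.frame(subject_id = letters[1:4], As = c(1, 2, 4, 8),
                    Hg = c(3, 1, 4, 2), Pb = 1:4, Cu = 1:4, Mn = 1:4,
                    Se = c(2, 2, 1, 4))
  tr <- transform_exposures(raw)
  rec <- tr$data$log2s_As * tr$scale_sd["As"] + tr$center["As"]
  expect_equal(rec, c(0, 1, 2, 3), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(mean(tr$data$log2s_As), 0, tolerance = 1e-12)
  expect_equal(sd(tr$data$log2s_As), 1, tolerance = 1e-12)
})

test_that("nine subjects split into tertiles of three with middle reference", {
  raw <- data.frame(subject_id = letters[1:9], As = c(5, 2, 9, 1, 7, 3, 8, 4, 6),
                    Hg = 1:9, Pb = 1:9, Cu = 1:9, Mn = 1:9, Se = 1:9)
  tr <- transform_exposures(raw)
  expect_equal(as.vector(table(tr$data$tert_As)), c(3, 3, 3))
  expect_equal(levels(tr$data$tert_As), c("low", "middle", "high"))
  # ordering preserved: low tertile holds the three smallest
  expect_setequal(raw$subject_id[tr$data$tert_As == "low"],
                  raw$subject_id[order(raw$As)][1:3])
})

test_that("tertile cut points match an independent quantile computation", {
  co <- generate_cohort(kmix_config(K = 2, n = 500, seed = 25))
  tr <- transform_exposures(co$exposures)
  expect_equal(unname(tr$cutpoints[, "Mn"]),
               unname(quantile(co$exposures$Mn, c(1 / 3, 2 / 3))),
               tolerance = 1e-12)
})

test_that("transform is monotone and rejects constant columns", {
  co <- generate_cohort(kmix_config(K = 2, n = 80, seed = 27))
  tr <- transform_exposures(co$exposures)
  expect_equal(order(co$exposures$Hg), order(tr$data$log2s_Hg))
  bad <- co$exposures
  bad$Se <- 1
  expect_error(transform_exposures(bad), "constant")
})

test_that("ages map to the nearest scheduled visit within its window", {
  g <- data.frame(subject_id = c("A", "A", "A"), age = c(0, 8.4, 17.2))
  r <- assign_nominal_visits(g)
  expect_equal(r$nominal_visit, c(0, 9, 18))
})

test_that("jittered cohort assignment matches a brute-force nearest search", {
  co <- generate_cohort(kmix_config(K = 2, n = 150, seed = 29, jitter = 0.12))
  sched <- c(0, 0.46, 1, 2, 4, 6, 9, 12, 15, 18)
  r <- assign_nominal_visits(co$growth, sched)
  # brute force: nearest in-window visit, then per subject-visit keep only
  # the closest observation (distance ties -> earliest row)
  nearest <- vapply(co$growth$age, function(a) sched[which.min(abs(sched - a))],
                    numeric(1))
  gaps <- diff(sched)
  lo <- sched - c(gaps[1], gaps) / 2
  hi <- sched + c(gaps, gaps[length(gaps)]) / 2
  j <- match(nearest, sched)
  expected <- ifelse(co$growth$age >= lo[j] & co$growth$age <= hi[j],
                     nearest, NA_real_)
  for (s in unique(co$growth$subject_id)) for (v in sched) {
    rows <- which(co$growth$subject_id == s & !is.na(expected) & expected == v)
    if (length(rows) > 1) {
      d <- abs(co$growth$age[rows] - v)
      expected[setdiff(rows, rows[which.min(d)])] <- NA_real_
    }
  }
  expect_equal(r$nominal_visit, expected)
})

test_that("the preprocessing cascade reports exclusions by reason", {
  co <- generate_cohort(kmix_config(K = 2, n = 200, seed = 31, missing = 0.55))
  # inject one gross outlier subject
  i <- which(co$growth$subject_id == co$growth$subject_id[1])
  co$growth$wfl[i[1]] <- co$growth$wfl[i[1]] + 300
  an <- preprocess_cohort(co)
  expect_true(any(an$exclusions$reason == "wfl outside mean +/- 4 SD"))
  kept <- unique(an$growth$subject_id)
  expect_false(any(an$exclusions$subject_id %in% kept))
  expect_true(all(table(an$growth$subject_id) >= 4))
  expect_true(all(an$covariates$bmi_ge_25 %in% 0:1))
})
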