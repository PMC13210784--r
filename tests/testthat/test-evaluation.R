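# Scoring and nested cross-validation bookkeeping.

# aggregated 3x3 matrices of the published 69-recording validation study
# (rows true normal/short/long, columns predicted)
subjectwise_matrix <- function()
  matrix(c(18, 2, 3,
           1, 20, 2,
           0, 2, 21), 3, 3, byrow = TRUE,
         dimnames = list(true = c("normal", "short", "long"),
                         predicted = c("normal", "short", "long")))

classwise_matrix <- function()
  matrix(c(19, 2, 2,
           1, 20, 2,
           1, 1, 21), 3, 3, byrow = TRUE,
         dimnames = list(true = c("normal", "short", "long"),
                         predicted = c("normal", "short", "long")))

test_that("flat-count metrics reproduce the reference worked example", {
  met <- metrics_from_matrix(subjectwise_matrix())
  expect_equal(met$accuracy, 59 / 69 * 100)
  expect_equal(met$sensitivity_long, 21 / 23 * 100)
  expect_equal(met$sensitivity_short, 20 / 23 * 100)
  expect_equal(met$specificity_normal, 18 / 23 * 100)
  expect_equal(binary_sensitivity(subjectwise_matrix()), 45 / 46 * 100)

  met_c <- metrics_from_matrix(classwise_matrix())
  expect_equal(met_c$accuracy, 60 / 69 * 100)
  expect_equal(met_c$specificity_normal, 19 / 23 * 100)
  expect_equal(binary_sensitivity(classwise_matrix()), 44 / 46 * 100)
})

test_that("a diagonal matrix scores perfectly", {
  m <- diag(c(23, 23, 23))
  met <- metrics_from_matrix(m)
  expect_equal(met$accuracy, 100)
  expect_equal(unname(met$recall), rep(100, 3))
  expect_equal(met$macro_f1, 100)
  expect_equal(collapse_binary(m), diag(c(23, 46)),
               ignore_attr = TRUE)
})

test_that("macro F1 matches a brute-force recomputation from label pairs", {
  set.seed(21)
  classes <- c("normal", "short", "long")
  for (k in 1:20) {
    true <- sample(classes, 60, replace = TRUE)
    pred <- sample(classes, 60, replace = TRUE)
    met <- suppressWarnings(metrics_from_matrix(confusion_matrix3(true, pred)))
    f1_oracle <- vapply(classes, function(cls) {
      tp <- sum(true == cls & pred == cls)
      fp <- sum(true != cls & pred == cls)
      fn <- sum(true == cls & pred != cls)
      if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn) * 100
    }, numeric(1))
    expect_equal(met$macro_f1, mean(f1_oracle, na.rm = TRUE))
    expect_equal(met$accuracy, mean(true == pred) * 100)
  }
})

test_that("binary collapse absorbs duration misclassifications", {
  m <- subjectwise_matrix()
  b <- collapse_binary(m)
  expect_equal(sum(b), sum(m))
  expect_equal(b[2, 2], 20 + 2 + 2 + 21)
  expect_gte(binary_sensitivity(m),
             min(metrics_from_matrix(m)$sensitivity_short,
                 metrics_from_matrix(m)$sensitivity_long))
})

test_that("a class without support is excluded from macro F1 with warning", {
  m <- matrix(c(10, 0, 0,
                0, 0, 0,
                0, 0, 10), 3, 3, byrow = TRUE)
  expect_warning(met <- metrics_from_matrix(m), "support")
  expect_true(is.na(met$sensitivity_short))
  expect_equal(met$macro_f1, 100)
})

test_that("the published subject partition yields test sizes 3,3,3,3,2", {
  assign <- default_subject_assignment()
  expect_equal(lengths(assign, use.names = FALSE), c(3, 3, 3, 3, 2))
  expect_setequal(assign[[5]], c("S03", "S14"))

  # five recordings per subject: folds inherit the partition
  subjects <- rep(sprintf("S%02d", 1:14), each = 5)
  folds <- subject_folds(subjects)
  test_sizes <- vapply(folds, function(f) length(f$test), numeric(1))
  expect_equal(test_sizes, c(3, 3, 3, 3, 2) * 5)
  tested <- sort(unlist(lapply(folds, `[[`, "test")))
  expect_identical(tested, seq_along(subjects))   # partition, no repeats
  for (f in folds) expect_length(intersect(f$train, f$test), 0)

  expect_error(subject_folds("S99"), "not assigned")
  expect_error(subject_folds(subjects,
                             list(c("S01", "S02"), c("S02", "S03"))),
               "more than one fold")
})

test_that("class-stratified folds deal 23 per class into 15,15,15,12,12", {
  labels <- rep(c("normal", "short", "long"), each = 23)
  folds <- class_stratified_folds(labels, n_folds = 5, seed = 3)
  sizes <- vapply(folds, function(f) length(f$test), numeric(1))
  expect_equal(sizes, c(15, 15, 15, 12, 12))
  tested <- sort(unlist(lapply(folds, `[[`, "test")))
  expect_identical(tested, seq_along(labels))
  # per-fold class counts never differ by more than 1 across folds
  for (cls in unique(labels)) {
    counts <- vapply(folds, function(f) sum(labels[f$test] == cls),
                     numeric(1))
    expect_lte(max(counts) - min(counts), 1)
  }
  # determinism and seed sensitivity
  expect_identical(folds, class_stratified_folds(labels, 5, seed = 3))
  expect_false(identical(folds, class_stratified_folds(labels, 5, seed = 4)))

  even <- class_stratified_folds(rep(c("normal", "short", "long"), each = 10),
                                 n_folds = 5, seed = 1)
  expect_equal(vapply(even, function(f) length(f$test), numeric(1)),
               rep(6, 5))
})

test_that("threshold selection maximizes short sensitivity with tie-breaks", {
  grid <- threshold_grid()
  true <- c("short", "short", "long", "long", "normal")
  lab <- function(...) matrix(c(...), nrow = length(grid), byrow = TRUE)
  # THR 0.235 (row 2) detects both shorts; others detect none
  lg <- matrix("normal", length(grid), 5)
  lg[2, ] <- c("short", "short", "long", "long", "normal")
  lg[3, ] <- c("short", "normal", "long", "long", "normal")
  expect_equal(select_threshold(true, lg, grid), 0.235)

  # equal short sensitivity; long sensitivity breaks the tie
  lg2 <- matrix("normal", length(grid), 5)
  lg2[4, ] <- c("short", "short", "long", "normal", "normal")
  lg2[5, ] <- c("short", "short", "long", "long", "normal")
  expect_equal(select_threshold(true, lg2, grid), grid[5])

  # full tie: the smaller threshold wins
  lg3 <- lg2
  lg3[4, ] <- lg3[5, ]
  expect_equal(select_threshold(true, lg3, grid), grid[4])

  # pathological: nothing detects shorts
  lg4 <- matrix("normal", length(grid), 5)
  expect_warning(thr <- select_threshold(true, lg4, grid), "smallest")
  expect_equal(thr, grid[1])

  expect_error(select_threshold(c("normal", "short"), lg4[, 1:2], grid),
               "short and long")
  expect_error(select_threshold(true, lg4, c(0.5, 0.2)), "increasing")
})

test_that("fold summaries use the sample SD and z/sqrt(k) interval", {
  s <- summarize_folds(rep(80, 5))
  expect_equal(s$mean, 80)
  expect_equal(s$sd, 0)
  expect_equal(s$ci, c(80, 80))

  vals <- c(66.7, 83.3, 83.3, 94.4, 94.4)
  s2 <- summarize_folds(vals)
  expect_equal(s2$mean, 84.42)
  expect_equal(s2$sd, 11.3547, tolerance = 1e-4)
  expect_equal(s2$ci[2] - s2$ci[1], 2 * 1.96 * s2$sd / sqrt(5))

  # the multiplier rescales the interval linearly
  s_z <- summarize_folds(vals, z = 0.98)
  expect_equal(s_z$ci[2] - s_z$ci[1], (s2$ci[2] - s2$ci[1]) / 2)
})

# signal-level recording: sinusoid with an optional zeroed gap
gap_recording <- function(id, subject, cls, gap = NA, fs = 25) {
  sig <- sine_signal(freq = 0.25, fs = fs, duration = 60)
  if (!is.na(gap)) {
    t <- seq(0, 60 - 1 / fs, by = 1 / fs)
    sig$values[t >= 20 & t < 20 + gap] <- 0
  }
  labeled_recording(id, subject, cls, sig)
}

synthetic_cohort <- function(n_per_class = 5, fs = 25) {
  recs <- list()
  i <- 0
  for (cls in c("normal", "short", "long")) for (k in seq_len(n_per_class)) {
    i <- i + 1
    gap <- switch(cls, normal = NA, short = 14 + k %% 4, long = 24 + k %% 4)
    recs[[i]] <- gap_recording(sprintf("R%02d", i),
                               sprintf("S%02d", ((i - 1) %% 7) + 1),
                               cls, gap, fs)
  }
  recs
}

test_that("nested CV tests every recording once and aggregates to n", {
  recs <- synthetic_cohort(5)
  cv <- run_nested_cv(recs, scheme = "class_wise", seed = 2)
  expect_identical(sum(cv$confusion), 15L)
  expect_identical(nrow(cv$per_fold), 5L)
  expect_equal(sum(cv$per_fold$n_test), 15)
  expect_true(all(cv$per_fold$threshold %in% threshold_grid()))
  # these clean signals classify perfectly: all metrics 100, SD 0
  expect_equal(cv$summary$mean, rep(100, 5))
  expect_equal(cv$summary$sd, rep(0, 5))
  # accuracy equals trace / total on the pooled matrix
  expect_equal(metrics_from_matrix(cv$confusion)$accuracy,
               sum(diag(cv$confusion)) / sum(cv$confusion) * 100)
})

test_that("subject-wise CV keeps a subject's recordings together", {
  recs <- synthetic_cohort(5)
  assignment <- list(c("S01", "S02"), c("S03"), c("S04"), c("S05"),
                     c("S06", "S07"))
  cv <- run_nested_cv(recs, scheme = "subject_wise", assignment = assignment)
  expect_identical(sum(cv$confusion), 15L)
  subj <- vapply(recs, `[[`, character(1), "subject_id")
  folds <- subject_folds(subj, assignment)
  for (f in folds) {
    test_subjects <- unique(subj[f$test])
    expect_length(intersect(test_subjects, unique(subj[f$train])), 0)
  }
})
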