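# Recording-level scoring: 3-class and binary confusion matrices, per-class
# metrics, and the two nested five-fold cross-validation procedures with
# inner-loop threshold selection.

CLASS_LEVELS <- c("normal", "short", "long")

#' Default normalized threshold grid
#'
#' The six candidate threshold fractions scored by the inner selection loop.
#'
#' @return Strictly increasing numeric vector in `(0, 1]`.
#' @export
threshold_grid <- function() c(0.15, 0.235, 0.3625, 0.575, 0.7875, 1.0)

#' A labeled recording for evaluation
#'
#' @param recording_id,subject_id Identifiers (`subject_id` non-empty).
#' @param true_class One of `"normal"`, `"short"`, `"long"`.
#' @param signal A `respiratory_signal` (filtered breathing trace), or
#'   `NULL` when per-threshold labels are supplied externally.
#' @param posture Optional posture tag.
#' @return An object of class `labeled_recording`.
#' @export
labeled_recording <- function(recording_id, subject_id, true_class,
                              signal = NULL, posture = NA_character_) {
  if (!nzchar(subject_id)) stop("'subject_id' must be non-empty", call. = FALSE)
  true_class <- match.arg(true_class, CLASS_LEVELS)
  structure(list(recording_id = recording_id, subject_id = subject_id,
                 true_class = true_class, signal = signal, posture = posture),
            class = "labeled_recording")
}

#' Three-class confusion matrix
#'
#' Rows are true classes, columns predicted, both ordered
#' normal / short / long; every recording is counted exactly once.
#'
#' @param true,predicted Character vectors of class labels.
#' @return A 3 x 3 integer matrix of class `confusion_matrix3`.
#' @export
confusion_matrix3 <- function(true, predicted) {
  stopifnot(length(true) == length(predicted))
  m <- table(factor(true, CLASS_LEVELS), factor(predicted, CLASS_LEVELS))
  m <- matrix(as.integer(m), 3, 3,
              dimnames = list(true = CLASS_LEVELS, predicted = CLASS_LEVELS))
  structure(m, class = c("confusion_matrix3", "matrix"))
}

as_matrix3 <- function(m) {
  m <- unclass(m)
  if (!is.matrix(m) || !all(dim(m) == c(3, 3)) || any(m < 0))
    stop("expected a 3 x 3 non-negative count matrix", call. = FALSE)
  dimnames(m) <- list(true = CLASS_LEVELS, predicted = CLASS_LEVELS)
  m
}

#' Metrics from a 3-class confusion matrix
#'
#' Flat-count metrics, all in percent. Per-cessation-class sensitivity
#' counts only duration-correct detections as true positives (a short event
#' predicted long is a misclassification, not a TP). Specificity is
#' computed on the normal class: true negatives are normal recordings
#' predicted normal, false positives normal recordings predicted as either
#' cessation class — numerically this equals the normal-class recall of the
#' matrix. Per-class F1 is `2*TP / (2*TP + FP + FN) * 100`, and Macro F1
#' the unweighted mean of the per-class F1 scores. A class with no true
#' recordings has undefined recall/F1 (`NA`) and is excluded from Macro F1
#' with a warning.
#'
#' @param m A 3 x 3 true-by-predicted count matrix
#'   (rows/columns normal, short, long).
#' @return List with `accuracy`, `sensitivity_short`, `sensitivity_long`,
#'   `specificity_normal`, `recall` (per class), `f1` (per class) and
#'   `macro_f1`, all percentages.
#' @export
metrics_from_matrix <- function(m) {
  m <- as_matrix3(m)
  total <- sum(m)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  tp <- diag(m)
  row_tot <- rowSums(m)
  col_tot <- colSums(m)
  recall <- ifelse(row_tot > 0, tp / row_tot * 100, NA_real_)
  denom <- 2 * tp + (col_tot - tp) + (row_tot - tp)
  f1 <- ifelse(denom > 0, 2 * tp / denom * 100, NA_real_)
  names(recall) <- names(f1) <- CLASS_LEVELS
  if (anyNA(f1))
    warning("class with no support excluded from Macro F1")
  list(accuracy = sum(tp) / total * 100,
       sensitivity_short = recall[["short"]],
       sensitivity_long = recall[["long"]],
       specificity_normal = recall[["normal"]],
       recall = recall,
       f1 = f1,
       macro_f1 = mean(f1, na.rm = TRUE))
}

#' Collapse a 3-class matrix to normal vs apnea-like
#'
#' Sums the short and long rows/columns into a single apnea-like category,
#' so duration misclassifications between short and long are absorbed into
#' the true-positive count.
#'
#' @param m A 3 x 3 true-by-predicted count matrix.
#' @return A 2 x 2 matrix (rows true, columns predicted; levels `normal`,
#'   `apnea`).
#' @export
collapse_binary <- function(m) {
  m <- as_matrix3(m)
  out <- matrix(c(m[1, 1], sum(m[1, 2:3]),
                  sum(m[2:3, 1]), sum(m[2:3, 2:3])),
                2, 2, byrow = TRUE,
                dimnames = list(true = c("normal", "apnea"),
                                predicted = c("normal", "apnea")))
  out
}

#' Binary apnea-detection sensitivity
#'
#' Fraction of true apnea-like recordings flagged as apnea-like (either
#' duration class), in percent.
#'
#' @param m A 3 x 3 true-by-predicted count matrix.
#' @return Percentage in `[0, 100]`.
#' @export
binary_sensitivity <- function(m) {
  b <- collapse_binary(m)
  b[2, 2] / sum(b[2, ]) * 100
}

#' The published participant-to-fold partition
#'
#' The fixed five-fold grouping of the fourteen subjects used for
#' participant-level cross-validation (test-set sizes 3, 3, 3, 3, 2).
#'
#' @return A list of five character vectors of subject ids.
#' @export
default_subject_assignment <- function() {
  list(fold1 = c("S01", "S11", "S13"),
       fold2 = c("S04", "S07", "S08"),
       fold3 = c("S02", "S06", "S09"),
       fold4 = c("S05", "S10", "S12"),
       fold5 = c("S03", "S14"))
}

fold_spec <- function(fold_id, train, test)
  list(fold_id = fold_id, train = train, test = test)

#' Subject-wise fold specification
#'
#' All recordings of a subject travel together: the test set of fold k is
#' every recording whose subject belongs to the k-th group of `assignment`,
#' and the training set is everything else. Every subject must be assigned
#' to exactly one fold.
#'
#' @param subject_ids Character vector, one entry per recording.
#' @param assignment List of character vectors of subject ids per fold;
#'   defaults to [default_subject_assignment()].
#' @return List of fold specs, each with `fold_id`, `train` and `test`
#'   recording indices.
#' @export
subject_folds <- function(subject_ids,
                          assignment = default_subject_assignment()) {
  all_assigned <- unlist(assignment)
  if (anyDuplicated(all_assigned))
    stop("a subject appears in more than one fold", call. = FALSE)
  missing <- setdiff(unique(subject_ids), all_assigned)
  if (length(missing))
    stop("subjects not assigned to any fold: ",
         paste(missing, collapse = ", "), call. = FALSE)
  idx <- seq_along(subject_ids)
  lapply(seq_along(assignment), function(k) {
    test <- idx[subject_ids %in% assignment[[k]]]
    fold_spec(k, setdiff(idx, test), test)
  })
}

#' Class-stratified fold specification
#'
#' Within each class the recordings are shuffled (deterministically per
#' seed) and dealt round-robin to the folds, so per-fold class counts never
#' differ by more than one. With 23 recordings per class and five folds
#' this yields fold sizes 15, 15, 15, 12, 12.
#'
#' @param true_class Character vector of class labels, one per recording.
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed for the within-class shuffles.
#' @return List of fold specs (`fold_id`, `train`, `test` indices).
#' @export
class_stratified_folds <- function(true_class, n_folds = 5, seed = 1) {
  idx <- seq_along(true_class)
  fold_of <- integer(length(true_class))
  with_seed(seed, {
    for (cls in unique(true_class)) {
      members <- sample(idx[true_class == cls])
      fold_of[members] <- rep_len(seq_len(n_folds), length(members))
    }
  })
  lapply(seq_len(n_folds), function(k)
    fold_spec(k, idx[fold_of != k], idx[fold_of == k]))
}

# predicted label of every recording at every grid threshold
predict_label_grid <- function(recordings, grid, config = detection_config()) {
  vapply(recordings, function(rec) {
    stopifnot(inherits(rec$signal, "respiratory_signal"))
    peaks <- detect_breath_peaks(rec$signal)
    if (!length(peaks$indices) || max(rec$signal$values[peaks$indices]) <= 0)
      return(rep("normal", length(grid)))
    amax <- max_breathing_amplitude(rec$signal, peaks)
    vapply(grid, function(thr) {
      cfg <- detection_config(thr, config$min_event, config$max_long)
      classify_recording(detect_subthreshold_runs(rec$signal, amax, cfg),
                         cfg, amax)$label
    }, character(1))
  }, character(length(grid)))
}

#' Inner-loop threshold selection
#'
#' Scores every grid threshold on the training recordings and returns the
#' one with the highest short-cessation sensitivity; ties are broken by
#' higher long-cessation sensitivity, remaining ties by the smaller
#' threshold (a tighter threshold preserves specificity). If every
#' threshold scores zero short sensitivity the smallest threshold is
#' returned with a warning.
#'
#' @param true_class Character vector of training labels (must contain at
#'   least one short and one long recording).
#' @param label_grid `length(grid) x n` character matrix of predicted
#'   labels, as built internally by [run_nested_cv()] (columns are
#'   recordings, rows thresholds).
#' @param grid Threshold grid (strictly increasing, in `(0, 1]`).
#' @return The selected threshold fraction.
#' @export
select_threshold <- function(true_class, label_grid, grid = threshold_grid()) {
  if (is.unsorted(grid, strictly = TRUE) || any(grid <= 0) || any(grid > 1))
    stop("'grid' must be strictly increasing within (0, 1]", call. = FALSE)
  if (!any(true_class == "short") || !any(true_class == "long"))
    stop("training set must contain short and long recordings", call. = FALSE)
  sens <- function(k, cls) {
    is_cls <- true_class == cls
    mean(label_grid[k, is_cls] == cls) * 100
  }
  short_s <- vapply(seq_along(grid), sens, numeric(1), cls = "short")
  long_s <- vapply(seq_along(grid), sens, numeric(1), cls = "long")
  if (all(short_s == 0)) {
    warning("no threshold detects any short cessation; returning the smallest")
    return(grid[1])
  }
  best <- which(short_s == max(short_s))
  best <- best[long_s[best] == max(long_s[best])]
  grid[min(best)]
}

#' Summarize a metric across folds
#'
#' Mean, sample SD (k - 1 denominator) and a `mean +- z * SD / sqrt(k)`
#' interval.
#'
#' @param values Numeric per-fold values (k >= 2).
#' @param z Interval multiplier (default 1.96 for a normal 95% interval).
#' @return List with `mean`, `sd` and `ci = c(lower, upper)`.
#' @export
summarize_folds <- function(values, z = 1.96) {
  k <- length(values)
  stopifnot(k >= 2)
  m <- mean(values)
  s <- stats::sd(values)
  half <- z * s / sqrt(k)
  list(mean = m, sd = s, ci = c(m - half, m + half))
}

#' Nested cross-validated evaluation
#'
#' Runs one of the two complementary five-fold procedures: `subject_wise`
#' (all recordings of a held-out subject group form the test set) or
#' `class_wise` (recordings stratified by class and dealt round-robin to
#' folds). In each outer fold the detection threshold is selected on the
#' training recordings only ([select_threshold()]), then applied to the
#' held-out test recordings; per-fold metrics are accumulated together with
#' a pooled confusion matrix in which every recording is tested exactly
#' once.
#'
#' The detector is deterministic given a threshold, so scoring the grid
#' directly on the whole training set is an exact stand-in for an inner
#' resampling loop over the same grid.
#'
#' @param recordings List of [labeled_recording()]s carrying filtered
#'   signals.
#' @param scheme `"subject_wise"` or `"class_wise"`.
#' @param grid Threshold grid.
#' @param config A [detection_config()]; its `threshold` is ignored in
#'   favour of the fold-selected one.
#' @param seed Shuffle seed for the class-wise scheme.
#' @param assignment Subject-to-fold assignment for the subject-wise scheme.
#' @param n_folds Number of folds for the class-wise scheme.
#' @param z Interval multiplier forwarded to [summarize_folds()].
#' @return An object of class `cv_summary`: `per_fold` data frame (selected
#'   threshold and metrics per fold), `summary` data frame (mean/SD/CI per
#'   metric), and the aggregated `confusion` matrix.
#' @export
run_nested_cv <- function(recordings,
                          scheme = c("class_wise", "subject_wise"),
                          grid = threshold_grid(),
                          config = detection_config(),
                          seed = 1,
                          assignment = default_subject_assignment(),
                          n_folds = 5,
                          z = 1.96) {
  scheme <- match.arg(scheme)
  true_class <- vapply(recordings, `[[`, character(1), "true_class")
  folds <- if (scheme == "subject_wise") {
    subject_folds(vapply(recordings, `[[`, character(1), "subject_id"),
                  assignment)
  } else {
    class_stratified_folds(true_class, n_folds, seed)
  }
  label_grid <- predict_label_grid(recordings, grid, config)
  agg_true <- character(0); agg_pred <- character(0)
  per_fold <- lapply(folds, function(fd) {
    thr <- select_threshold(true_class[fd$train],
                            label_grid[, fd$train, drop = FALSE], grid)
    k <- which(grid == thr)
    pred <- label_grid[k, fd$test]
    m <- confusion_matrix3(true_class[fd$test], pred)
    met <- suppressWarnings(metrics_from_matrix(m))
    data.frame(fold = fd$fold_id, threshold = thr, n_test = length(fd$test),
               accuracy = met$accuracy,
               sensitivity_short = met$sensitivity_short,
               sensitivity_long = met$sensitivity_long,
               specificity_normal = met$specificity_normal,
               macro_f1 = met$macro_f1)
  })
  for (fd in folds) {
    thr <- per_fold[[fd$fold_id]]$threshold
    agg_true <- c(agg_true, true_class[fd$test])
    agg_pred <- c(agg_pred, label_grid[which(grid == thr), fd$test])
  }
  per_fold <- do.call(rbind, per_fold)
  metrics <- c("accuracy", "sensitivity_short", "sensitivity_long",
               "specificity_normal", "macro_f1")
  summ <- do.call(rbind, lapply(metrics, function(nm) {
    v <- per_fold[[nm]]
    if (anyNA(v)) v <- v[!is.na(v)]
    s <- summarize_folds(v, z)
    data.frame(metric = nm, mean = s$mean, sd = s$sd,
               ci_lower = s$ci[1], ci_upper = s$ci[2])
  }))
  structure(list(scheme = scheme, per_fold = per_fold, summary = summ,
                 confusion = confusion_matrix3(agg_true, agg_pred)),
            class = "cv_summary")
}

#' @export
print.cv_summary <- function(x, digits = 1, ...) {
  cat(sprintf("<cv_summary> %s nested %d-fold cross-validation (n = %d)\n",
              x$scheme, nrow(x$per_fold), sum(x$confusion)))
  cat("selected thresholds:",
      paste(format(x$per_fold$threshold), collapse = ", "), "\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-20s %5.*f +- %.*f %% (CI %.*f-%.*f)\n", s$metric[i],
                digits, s$mean[i], digits, s$sd[i], digits, s$ci_lower[i],
                digits, s$ci_upper[i]))
  cat("aggregated confusion matrix (rows true, cols predicted):\n")
  print(unclass(x$confusion))
  invisible(x)
}
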