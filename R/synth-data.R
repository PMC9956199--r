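#' Configuration for a synthetic patient cohort
#'
#' Describes a two-class cohort of fixed-length real-valued feature vectors
#' with a controllable standardized mean shift between the classes. Class 0
#' features are drawn from a baseline Gaussian; class 1 features are shifted
#' by `effect_size * noise_sd` on the informative subset. Features are then
#' min-max scaled to \[0, 1\] (the range the CCRBM's visible units assume)
#' and snapped to the 1e-6 fixed-point grid used by the encrypted store, so
#' that encryption, CSV serialization and decryption are all lossless.
#'
#' @param n_records Number of patients to generate (positive integer).
#' @param n_features Number of features per record; default 5.
#' @param class_balance Expected fraction of class-1 (diseased) records,
#'   strictly between 0 and 1. Labels are drawn i.i.d. Bernoulli, so the
#'   realised fraction varies within binomial sampling error.
#' @param effect_size Standardized mean shift between classes on the
#'   informative features, in units of `noise_sd`. Zero gives a null cohort.
#' @param noise_sd Within-class feature standard deviation before scaling.
#' @param informative Integer indices of the features that carry the class
#'   signal; defaults to the first `min(2, n_features)` features.
#' @param seed Integer seed; the cohort is a deterministic function of the
#'   full configuration.
#' @return An object of class `synthetic_config`.
#' @export
#' @examples
#' cfg <- synthetic_config(100, seed = 1)
#' cohort <- generate_cohort(cfg)
#' table(cohort$label)
synthetic_config <- function(n_records, n_features = 5L, class_balance = 0.5,
                             effect_size = 2, noise_sd = 1,
                             informative = NULL, seed = 1L) {
  if (!is_count(n_records)) stopf("n_records must be a positive integer")
  if (!is_count(n_features)) stopf("n_features must be a positive integer")
  if (!is_fraction(class_balance)) stopf("class_balance must lie in (0, 1)")
  if (!is.numeric(effect_size) || effect_size < 0)
    stopf("effect_size must be nonnegative")
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    stopf("noise_sd must be positive")
  if (is.null(informative)) informative <- seq_len(min(2L, n_features))
  informative <- as.integer(informative)
  if (length(informative) == 0L || any(informative < 1L) ||
      any(informative > n_features))
    stopf("informative feature indices must lie in 1..%d", n_features)
  structure(list(n_records = as.integer(n_records),
                 n_features = as.integer(n_features),
                 class_balance = class_balance,
                 effect_size = effect_size,
                 noise_sd = noise_sd,
                 informative = informative,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic patient cohort
#'
#' @param config A [synthetic_config()].
#' @param scale If `TRUE` (default), min-max scale every feature to \[0, 1\]
#'   across the cohort and round to six decimals (the fixed-point precision
#'   of the encrypted store). `scale = FALSE` returns the raw Gaussian
#'   draws, which is what the class-separation contract is stated on.
#' @return A `data.frame` with columns `patient_id`, `f1`..`fF`, `label`.
#' @export
generate_cohort <- function(config, scale = TRUE) {
  if (!inherits(config, "synthetic_config"))
    stopf("config must be a synthetic_config")
  n <- config$n_records
  f <- config$n_features
  with_seed(config$seed, {
    label <- rbinom(n, 1L, config$class_balance)
    x <- matrix(rnorm(n * f, mean = 0, sd = config$noise_sd), nrow = n)
    shift <- config$effect_size * config$noise_sd
    x[label == 1L, config$informative] <-
      x[label == 1L, config$informative] + shift
  })
  if (scale) {
    for (j in seq_len(f)) {
      rng <- range(x[, j])
      x[, j] <- if (rng[2] > rng[1]) (x[, j] - rng[1]) / (rng[2] - rng[1])
                else 0.5
    }
    x <- round(x, 6L)
  }
  cohort <- data.frame(patient_id = sprintf("P%06d", seq_len(n)),
                       x, label = label, stringsAsFactors = FALSE)
  names(cohort) <- c("patient_id", paste0("f", seq_len(f)), "label")
  validate_cohort(cohort)
}

#' @noRd
validate_cohort <- function(cohort, context = "cohort") {
  cols <- names(cohort)
  if (cols[1] != "patient_id" || cols[length(cols)] != "label" ||
      !all(grepl("^f[0-9]+$", cols[-c(1, length(cols))])))
    stopf("%s must have columns patient_id, f1..fF, label", context)
  if (anyDuplicated(cohort$patient_id))
    stopf("%s has duplicate patient_id: %s", context,
          cohort$patient_id[anyDuplicated(cohort$patient_id)])
  feats <- as.matrix(cohort[, setdiff(cols, c("patient_id", "label")),
                            drop = FALSE])
  if (nrow(cohort) > 0 && any(!is.finite(feats)))
    stopf("%s contains missing or non-finite feature values", context)
  if (nrow(cohort) > 0 && !all(cohort$label %in% c(0L, 1L)))
    stopf("%s labels must be 0 or 1", context)
  cohort
}

#' Extract the feature matrix of a cohort
#'
#' @param cohort A cohort `data.frame`.
#' @return A numeric matrix, one row per record, columns `f1`..`fF`.
#' @export
cohort_features <- function(cohort) {
  as.matrix(cohort[, grep("^f[0-9]+$", names(cohort)), drop = FALSE])
}

#' Stratified train/test split of a cohort
#'
#' Partitions a cohort into disjoint, exhaustive train and test sets,
#' shuffled under `seed` and stratified by label so both sides see both
#' classes whenever the counts allow it. Per-class training counts are
#' rounded by largest remainder so the total training size is
#' `round(n * train_fraction)`.
#'
#' @param cohort A cohort `data.frame` (see [generate_cohort()]).
#' @param train_fraction Fraction of records assigned to training, in (0, 1).
#' @param seed Integer seed for the shuffle.
#' @return A list with elements `train` and `test`.
#' @export
split_cohort <- function(cohort, train_fraction = 0.8, seed = 1L) {
  validate_cohort(cohort)
  if (!is_fraction(train_fraction)) stopf("train_fraction must be in (0, 1)")
  n <- nrow(cohort)
  if (n < 2L) stopf("need at least 2 records to split, got %d", n)
  target <- round(n * train_fraction)
  if (target < 1L || target > n - 1L)
    stopf("train_fraction %.3f would leave an empty split at n = %d",
          train_fraction, n)
  classes <- sort(unique(cohort$label))
  n_by <- vapply(classes, function(cl) sum(cohort$label == cl), integer(1))
  raw <- n_by * target / n
  take <- floor(raw)
  rem <- target - sum(take)
  if (rem > 0) {
    ord <- order(raw - take, decreasing = TRUE)
    take[ord[seq_len(rem)]] <- take[ord[seq_len(rem)]] + 1L
  }
  # keep both classes represented on both sides when counts allow
  for (i in seq_along(classes)) {
    if (take[i] == 0L && n_by[i] > 1L) take[i] <- 1L
    if (take[i] == n_by[i] && n_by[i] > 1L) take[i] <- n_by[i] - 1L
  }
  idx_train <- integer(0)
  with_seed(seed, {
    for (i in seq_along(classes)) {
      idx <- which(cohort$label == classes[i])
      idx <- idx[sample.int(length(idx))]
      idx_train <- c(idx_train, idx[seq_len(take[i])])
    }
    idx_train <- sort(idx_train)
  })
  list(train = cohort[idx_train, , drop = FALSE],
       test = cohort[-idx_train, , drop = FALSE])
}

#' Write / read a cohort as CSV
#'
#' The on-disk dialect is comma-separated UTF-8 with header
#' `patient_id,f1..fF,label` and `.` as the decimal mark. Feature values are
#' rendered with enough significant digits that a write/read roundtrip
#' reproduces every double exactly; identical cohorts produce byte-identical
#' files.
#'
#' @param cohort A cohort `data.frame`.
#' @param path File path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns the
#'   cohort. Malformed rows (non-numeric features, bad labels, duplicate ids)
#'   raise an error naming the offending row; a header-only file returns an
#'   empty cohort with a warning.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  feats <- cohort_features(cohort)
  header <- paste(names(cohort), collapse = ",")
  rows <- character(nrow(cohort))
  if (nrow(cohort) > 0) {
    txt <- apply(feats, 2, format_full_precision)
    if (is.null(dim(txt))) txt <- matrix(txt, nrow = nrow(cohort))
    rows <- paste(cohort$patient_id,
                  apply(txt, 1, paste, collapse = ","),
                  cohort$label, sep = ",")
  }
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stopf("no such cohort file: %s", path)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  cols <- names(raw)
  if (length(cols) < 3L || cols[1] != "patient_id" ||
      cols[length(cols)] != "label")
    stopf("malformed cohort header in %s: expected patient_id,f1..fF,label",
          path)
  if (nrow(raw) == 0L) {
    warnf("cohort file %s has a header but no records", path)
    out <- data.frame(patient_id = character(0))
    for (fc in cols[-c(1, length(cols))]) out[[fc]] <- numeric(0)
    out$label <- integer(0)
    return(out)
  }
  feat_cols <- cols[-c(1, length(cols))]
  out <- data.frame(patient_id = raw$patient_id, stringsAsFactors = FALSE)
  for (fc in feat_cols) {
    v <- suppressWarnings(as.numeric(raw[[fc]]))
    if (any(is.na(v)))
      stopf("non-numeric value in column %s at data row %d of %s",
            fc, which(is.na(v))[1], path)
    out[[fc]] <- v
  }
  lab <- suppressWarnings(as.integer(raw$label))
  if (any(is.na(lab) | !(lab %in% c(0L, 1L))))
    stopf("invalid label at data row %d of %s",
          which(is.na(lab) | !(lab %in% c(0L, 1L)))[1], path)
  out$label <- lab
  if (anyDuplicated(out$patient_id))
    stopf("duplicate patient_id at data row %d of %s",
          anyDuplicated(out$patient_id), path)
  validate_cohort(out)
}
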