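#' Confusion counts of a binary classifier
#'
#' Counts with label 1 = diseased: AP true positives, AN true negatives,
#' BP false positives, BN false negatives. The four counts always sum to
#' the number of evaluated records.
#'
#' @param truth,predicted Equal-length binary (0/1) vectors.
#' @return A `confusion_counts` list with fields `AP`, `AN`, `BP`, `BN`.
#' @export
#' @examples
#' confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1))
confusion_counts <- function(truth, predicted) {
  if (length(truth) == 0L) stopf("empty label vectors")
  if (length(truth) != length(predicted))
    stopf("label vectors differ in length: %d vs %d",
          length(truth), length(predicted))
  if (!all(truth %in% c(0, 1)) || !all(predicted %in% c(0, 1)))
    stopf("labels must be binary 0/1")
  structure(list(AP = sum(truth == 1 & predicted == 1),
                 AN = sum(truth == 0 & predicted == 0),
                 BP = sum(truth == 0 & predicted == 1),
                 BN = sum(truth == 1 & predicted == 0)),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Precision `AP / (AP + BP)`, accuracy `(AP + AN) / total`, recall
#' `AP / (AP + BN)` and the F1 score (harmonic mean of precision and
#' recall). A zero denominator yields `NA` with a warning rather than a
#' silent zero. `recall_definition = "tp-over-tn"` switches recall to the
#' nonstandard ratio `AP / (AP + AN)` found in some reports; the default is
#' the conventional sensitivity.
#'
#' @param counts A [confusion_counts()].
#' @param recall_definition `"conventional"` (default) or `"tp-over-tn"`.
#' @return A list with `accuracy`, `precision`, `recall`, `f1` and the
#'   `counts`.
#' @export
compute_metrics <- function(counts,
                            recall_definition = c("conventional",
                                                  "tp-over-tn")) {
  stopifnot(inherits(counts, "confusion_counts"))
  recall_definition <- match.arg(recall_definition)
  total <- counts$AP + counts$AN + counts$BP + counts$BN
  if (total == 0L) stopf("no evaluated records")
  ratio <- function(num, den, what) {
    if (den == 0) {
      warnf("%s undefined: zero denominator", what)
      return(NA_real_)
    }
    num / den
  }
  precision <- ratio(counts$AP, counts$AP + counts$BP, "precision")
  recall <- switch(recall_definition,
                   conventional = ratio(counts$AP, counts$AP + counts$BN,
                                        "recall"),
                   `tp-over-tn` = ratio(counts$AP, counts$AP + counts$AN,
                                        "recall"))
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    if (!is.na(precision) && !is.na(recall))
      warnf("f1 undefined: precision + recall = 0")
    NA_real_
  } else 2 * precision * recall / (precision + recall)
  list(accuracy = (counts$AP + counts$AN) / total,
       precision = precision, recall = recall, f1 = f1, counts = counts)
}

#' Dictionary-attack security analysis of a ciphertext store
#'
#' Simulates a concrete bounded adversary: it holds the public key, the
#' ciphertext store, and a finite dictionary of candidate plaintext values.
#' It encrypts every dictionary value and counts a record as "hacked" when
#' every one of its stored ciphertexts matches some dictionary encryption.
#' The score is `SA = hacked / total` and the security level
#' `100 * (1 - SA)`. Against randomized (Paillier) encryption the match
#' attack fails even with a complete dictionary, because fresh randomness
#' makes equal plaintexts encrypt differently; against deterministic
#' textbook RSA, or a plaintext store, a covering dictionary recovers the
#' records.
#'
#' @param store A `phe_store`.
#' @param public_key The public `phe_keypair` the adversary is assumed to
#'   hold (`NULL` for a plaintext store).
#' @param dictionary Numeric vector of candidate plaintext values.
#' @param seed Seed for the adversary's encryption randomness.
#' @return A list with `sa`, `level_percent`, `hacked`, `total`, and the
#'   adversary configuration.
#' @export
security_analysis <- function(store, public_key = NULL, dictionary,
                              seed = 1L) {
  if (!inherits(store, "phe_store")) stopf("not a phe_store")
  if (length(store$records) == 0L) stopf("ciphertext store is empty")
  digits <- store$meta$exponent
  lookup <- character(0)
  if (length(dictionary) > 0) {
    lookup <- if (identical(store$meta$scheme, "plaintext")) {
      gsub(" ", "", format(round(dictionary * 10^digits),
                           scientific = FALSE))
    } else {
      if (is.null(public_key)) stopf("adversary needs the public key")
      enc <- phe_encode(dictionary, public_key$n, digits)
      with_seed(seed, vapply(enc$mantissa, function(m)
        phe_encrypt(m, public_key, digits)$value, character(1),
        USE.NAMES = FALSE))
    }
  }
  hacked <- sum(vapply(store$records, function(rec)
    length(lookup) > 0 && all(unlist(rec$values) %in% lookup), logical(1)))
  total <- length(store$records)
  sa <- hacked / total
  list(sa = sa, level_percent = 100 * (1 - sa), hacked = hacked,
       total = total,
       adversary = list(dictionary_size = length(dictionary), seed = seed))
}

#' Elapsed-time report from paired timestamps
#'
#' Turns named `(start, end)` millisecond timestamp pairs into nonnegative
#' durations, the form in which encryption time (AT), key-generation time
#' (BT) and decryption time (CT) are reported.
#'
#' @param events Named list; each element a numeric vector `c(start, end)`
#'   in milliseconds.
#' @return Named numeric vector of durations in milliseconds.
#' @export
#' @examples
#' timing_report(list(encrypt = c(1000, 1072)))
timing_report <- function(events) {
  if (length(events) == 0L) stopf("no timing events")
  vapply(events, function(ev) {
    if (length(ev) != 2L || any(!is.finite(ev)))
      stopf("timing event must be a finite (start, end) pair")
    if (ev[2] < ev[1]) stopf("timing event ends before it starts")
    ev[2] - ev[1]
  }, numeric(1))
}

#' Assemble a full evaluation report
#'
#' Bundles confusion counts, derived metrics, the timing triple and the
#' security analysis into one report; [write_report()] serializes it as
#' JSON and `print` renders a table.
#'
#' @param metrics Output of [compute_metrics()].
#' @param timings_ms Named numeric vector (e.g. `at_ms`, `bt_ms`, `ct_ms`).
#' @param security Output of [security_analysis()], or `NULL`.
#' @return An `evaluation_report`.
#' @export
evaluation_report <- function(metrics, timings_ms = NULL, security = NULL) {
  structure(list(counts = unclass(metrics$counts),
                 metrics = metrics[c("accuracy", "precision", "recall",
                                     "f1")],
                 timings_ms = as.list(timings_ms),
                 security = security),
            class = "evaluation_report")
}

#' @rdname evaluation_report
#' @param report An `evaluation_report`.
#' @param path File path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Evaluation report\n")
  cat(sprintf("  counts     AP=%d AN=%d BP=%d BN=%d\n",
              x$counts$AP, x$counts$AN, x$counts$BP, x$counts$BN))
  for (m in names(x$metrics))
    cat(sprintf("  %-10s %s\n", m,
                ifelse(is.na(x$metrics[[m]]), "undefined",
                       sprintf("%.4f", x$metrics[[m]]))))
  for (t in names(x$timings_ms))
    cat(sprintf("  %-10s %.1f ms\n", t, x$timings_ms[[t]]))
  if (!is.null(x$security))
    cat(sprintf("  security   SA=%.3f level=%.1f%%\n",
                x$security$sa, x$security$level_percent))
  invisible(x)
}
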