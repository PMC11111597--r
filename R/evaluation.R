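# Diagnostic-accuracy evaluation: confusion counts with explicit
# numerators/denominators, percent formatting at one decimal (half-up),
# exact association tests, and facility / age-decade stratification.

#' Round a percentage half-up to one decimal
#' @param x Percent value(s).
#' @return `x` rounded half-up to 1 decimal (Table-style formatting;
#'   base `round()` rounds half to even, which would misprint .X5 ties).
#' @export
percent_1dp <- function(x) floor(x * 10 + 0.5 + 1e-9) / 10

#' Confusion counts with dementia as the positive class
#'
#' @param true_labels,predicted_labels Equal-length vectors with values
#'   `"dementia"` / `"cognitively_normal"`.
#' @return List of class `confusion_counts` with fields `tp`, `fn`, `fp`,
#'   `tn`.
#' @export
confusion_counts <- function(true_labels, predicted_labels) {
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  if (length(true_labels) != length(predicted_labels))
    vs_validation("label vectors must have equal length")
  ok <- c(POSITIVE_CLASS, NEGATIVE_CLASS)
  bad <- setdiff(unique(c(true_labels, predicted_labels)), ok)
  if (length(bad))
    vs_validation(sprintf("unknown label(s): %s", paste(bad, collapse = ", ")))
  structure(list(
    tp = sum(true_labels == POSITIVE_CLASS & predicted_labels == POSITIVE_CLASS),
    fn = sum(true_labels == POSITIVE_CLASS & predicted_labels == NEGATIVE_CLASS),
    fp = sum(true_labels == NEGATIVE_CLASS & predicted_labels == POSITIVE_CLASS),
    tn = sum(true_labels == NEGATIVE_CLASS & predicted_labels == NEGATIVE_CLASS)),
    class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> tp %d, fn %d, fp %d, tn %d\n",
              x$tp, x$fn, x$fp, x$tn))
  invisible(x)
}

metric_entry <- function(num, den) {
  list(numerator = num, denominator = den,
       percent = if (den > 0) percent_1dp(100 * num / den) else NA_real_)
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' Each metric carries its numerator and denominator alongside the percent
#' (one decimal, half-up). A zero denominator yields an `NA` percent (the
#' stratum is reported as n/a) rather than an error.
#'
#' @param counts A [confusion_counts()] object.
#' @return List of class `classification_metrics` with entries `accuracy`,
#'   `sensitivity`, `specificity`, each `(numerator, denominator, percent)`.
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  n <- counts$tp + counts$fn + counts$fp + counts$tn
  structure(list(
    accuracy    = metric_entry(counts$tp + counts$tn, n),
    sensitivity = metric_entry(counts$tp, counts$tp + counts$fn),
    specificity = metric_entry(counts$tn, counts$fp + counts$tn),
    counts = counts),
    class = "classification_metrics")
}

fmt_metric <- function(m) {
  if (is.na(m$percent)) return("n/a")
  sprintf("%.1f%% (%d/%d)", m$percent, m$numerator, m$denominator)
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf("accuracy %s, sensitivity %s, specificity %s\n",
              fmt_metric(x$accuracy), fmt_metric(x$sensitivity),
              fmt_metric(x$specificity)))
  invisible(x)
}

#' Classification accuracy by age decade and diagnosis group
#'
#' Bins participants into decades \[20,30) .. \[90,100) and reports, per
#' decade and diagnosis group, the number of participants, the number
#' correctly classified and the percent correct. Decades with no
#' participants in a group are kept with `n = 0` and an `NA` percent.
#'
#' @param records Data frame with columns `age`, `true_label`,
#'   `predicted_label`.
#' @return Data frame with columns `group`, `decade`, `n`, `n_correct`,
#'   `percent`.
#' @export
accuracy_by_age_decade <- function(records) {
  need <- c("age", "true_label", "predicted_label")
  if (!all(need %in% names(records)))
    vs_validation(sprintf("records must have columns %s",
                          paste(need, collapse = ", ")))
  if (any(records$age < 20 | records$age >= 100))
    vs_exclusion("ages outside [20, 100) are excluded from the study")
  decade_lo <- seq(20L, 90L, by = 10L)
  bins <- factor(10L * (records$age %/% 10L), levels = decade_lo)
  correct <- records$true_label == records$predicted_label
  out <- expand.grid(group = c(POSITIVE_CLASS, NEGATIVE_CLASS),
                     decade = decade_lo, stringsAsFactors = FALSE)
  out$n <- mapply(function(g, d)
    sum(records$true_label == g & bins == d), out$group, out$decade)
  out$n_correct <- mapply(function(g, d)
    sum(records$true_label == g & bins == d & correct),
    out$group, out$decade)
  out$percent <- ifelse(out$n > 0,
                        percent_1dp(100 * out$n_correct / out$n), NA_real_)
  out[order(out$group, out$decade), ]
}

stratum_entry <- function(truth, pred) {
  counts <- confusion_counts(truth, pred)
  m <- classification_metrics(counts)
  # association of true diagnosis vs predicted label
  assoc <- matrix(c(counts$tp, counts$fn, counts$fp, counts$tn),
                  2L, 2L, byrow = TRUE)
  p <- if (all(rowSums(assoc) > 0) && all(colSums(assoc) > 0))
    fisher_exact_2x2(assoc) else NA_real_
  list(counts = counts, metrics = m, fisher_p = p)
}

#' Evaluate predictions against clinical diagnoses
#'
#' Produces the full diagnostic-accuracy report: overall and per-facility
#' accuracy/sensitivity/specificity with exact 2x2 association tests
#' (true diagnosis vs predicted label), exact r x c heterogeneity tests of
#' correct/incorrect counts across facilities (for each metric), and the
#' per-age-decade breakdown when ages are present.
#'
#' @param records Data frame with columns `true_label`, `predicted_label`
#'   and optionally `facility` and `age`.
#' @return List of class `evaluation_report`.
#' @export
evaluate_predictions <- function(records) {
  need <- c("true_label", "predicted_label")
  if (!is.data.frame(records) || !all(need %in% names(records)) ||
      nrow(records) == 0L)
    vs_validation("records must be a non-empty data frame with true_label and predicted_label")

  report <- list(n = nrow(records),
                 total = stratum_entry(records$true_label,
                                       records$predicted_label))

  if ("facility" %in% names(records)) {
    facs <- sort(unique(records$facility))
    report$facility <- lapply(stats::setNames(facs, facs), function(f) {
      sub <- records[records$facility == f, ]
      stratum_entry(sub$true_label, sub$predicted_label)
    })
    if (length(facs) >= 2L) {
      het <- function(metric) {
        rows <- t(vapply(report$facility, function(s) {
          m <- s$metrics[[metric]]
          c(m$numerator, m$denominator - m$numerator)
        }, numeric(2)))
        if (any(rowSums(rows) == 0)) return(NA_real_)
        fisher_exact_rxc(rows)
      }
      report$facility_heterogeneity <- list(
        accuracy = het("accuracy"),
        sensitivity = het("sensitivity"),
        specificity = het("specificity"))
    }
  }
  if ("age" %in% names(records))
    report$by_age_decade <- accuracy_by_age_decade(records)
  structure(report, class = "evaluation_report")
}

fmt_p <- function(p) {
  if (is.na(p)) "n/a"
  else if (p < 0.001) "p<0.001"
  else sprintf("p=%.3f", p)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Diagnostic accuracy report (n = %d)\n", x$n))
  row <- function(name, s) {
    cat(sprintf("  %-10s acc %s  sens %s  spec %s  [%s]\n", name,
                fmt_metric(s$metrics$accuracy),
                fmt_metric(s$metrics$sensitivity),
                fmt_metric(s$metrics$specificity),
                fmt_p(s$fisher_p)))
  }
  row("Total", x$total)
  for (f in names(x$facility)) row(paste("Facility", f), x$facility[[f]])
  if (!is.null(x$facility_heterogeneity)) {
    h <- x$facility_heterogeneity
    cat(sprintf("  Between facilities: accuracy %s, sensitivity %s, specificity %s\n",
                fmt_p(h$accuracy), fmt_p(h$sensitivity), fmt_p(h$specificity)))
  }
  if (!is.null(x$by_age_decade)) {
    nonzero <- x$by_age_decade[x$by_age_decade$n > 0, ]
    cat(sprintf("  Age decades with data: %d strata (see $by_age_decade)\n",
                nrow(nonzero)))
  }
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report An `evaluation_report`.
#' @param path Optional output file; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "evaluation_report"))
  json <- jsonlite::toJSON(unclass_deep(report), auto_unbox = TRUE,
                           pretty = TRUE, digits = NA, na = "null")
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

unclass_deep <- function(x) {
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  x
}
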