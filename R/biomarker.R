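# Genotype carrier status as a predictive biomarker for eczema-associated
# asthma: confusion matrix and sensitivity/specificity/PPV/NPV with exact
# binomial intervals.  The default evaluation population contrasts
# outcome-positives (eczema-associated asthma cases) with healthy controls;
# eczema cases who did not develop asthma sit in neither group and are
# excluded from the default matrix (use positives/negatives filters for a
# within-eczema evaluation).

#' Confusion-matrix counts
#'
#' @param tp,fn,fp,tn Non-negative integers: predictor-positive/-negative
#'   among outcome positives (tp, fn) and among outcome negatives (fp, tn).
#' @param predictor,positives,negatives Text labels recorded for reporting.
#' @return A `confusion_matrix` object.
#' @export
confusion_counts <- function(tp, fn, fp, tn, predictor = "",
                             positives = "", negatives = "") {
  cells <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  structure(c(as.list(stats::setNames(as.integer(cells), names(cells))),
              list(predictor = predictor, positives = positives,
                   negatives = negatives)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> predictor: %s\n", x$predictor))
  cat(sprintf("  outcome+ (%s): tp = %d, fn = %d\n", x$positives, x$tp, x$fn))
  cat(sprintf("  outcome- (%s): fp = %d, tn = %d\n", x$negatives, x$fp, x$tn))
  invisible(x)
}

#' Confusion matrix of a binary genetic predictor
#'
#' @param x A [cohort()].
#' @param predictor Binary exposure spec (site carrier, FLG null, or a
#'   [combined_predictor()] conjunction).
#' @param positives Outcome-positive population filter (default "asthma":
#'   eczema-associated asthma cases).
#' @param negatives Outcome-negative population filter (default "controls":
#'   healthy, eczema-free children).
#' @return A [confusion_counts()] object; subjects with a missing predictor
#'   are excluded per group and counted in `n_excluded`.  Overlapping
#'   positive/negative populations are an error listing the offending
#'   subject ids.
#' @export
confusion_matrix <- function(x, predictor, positives = "asthma",
                             negatives = "controls") {
  stopifnot(inherits(x, "cohort"))
  pos <- population_filter(x, positives)
  neg <- population_filter(x, negatives)
  if (any(pos & neg)) {
    stop("positive and negative populations overlap: subject(s) ",
         paste(x$subjects$subject_id[pos & neg], collapse = ", "),
         call. = FALSE)
  }
  if (!any(pos) || !any(neg)) {
    stop("positive and negative populations must both be non-empty",
         call. = FALSE)
  }
  code <- code_exposure(x, predictor)
  if (any(code > 1L, na.rm = TRUE)) {
    stop("predictor must be binary-coded", call. = FALSE)
  }
  ok <- !is.na(code)
  cm <- confusion_counts(
    tp = sum(pos & ok & code == 1L), fn = sum(pos & ok & code == 0L),
    fp = sum(neg & ok & code == 1L), tn = sum(neg & ok & code == 0L),
    predictor = exposure_label(predictor),
    positives = if (is.character(positives)) positives else "<predicate>",
    negatives = if (is.character(negatives)) negatives else "<predicate>")
  attr(cm, "n_excluded") <- sum((pos | neg) & !ok)
  cm
}

clopper_pearson <- function(k, n, level) {
  if (n == 0L) return(c(NA_real_, NA_real_))
  ci <- stats::binom.test(k, n, conf.level = level)$conf.int
  c(ci[1], ci[2])
}

logit_interval <- function(k, n, level) {
  if (n == 0L || k == 0L || k == n) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - level) / 2)
  lo <- stats::qlogis(k / n) - z * sqrt(1 / k + 1 / (n - k))
  hi <- stats::qlogis(k / n) + z * sqrt(1 / k + 1 / (n - k))
  stats::plogis(c(lo, hi))
}

#' Diagnostic metrics with exact binomial intervals
#'
#' Sensitivity = tp/(tp+fn), specificity = tn/(tn+fp), PPV = tp/(tp+fp),
#' NPV = tn/(tn+fn), reported as percentages.  Sensitivity and specificity
#' intervals are Clopper-Pearson exact; PPV/NPV intervals are offered as
#' Clopper-Pearson (default) or the logit Wald variant via `pv_ci`.  A zero
#' denominator leaves that metric undefined (NA with a reason), never a
#' silent 0.
#'
#' @param m A [confusion_counts()] matrix.
#' @param level Confidence level.
#' @param pv_ci Interval method for PPV/NPV.
#' @return Class `"diagnostic_metrics"`: data.frame with metric, numerator,
#'   denominator, estimate (percent), lower, upper, ci_method, note.
#' @export
#' @examples
#' diagnostic_metrics(confusion_counts(16, 12, 19, 66))  # sens 57.14 etc.
diagnostic_metrics <- function(m, level = 0.95,
                               pv_ci = c("clopper-pearson", "logit")) {
  stopifnot(inherits(m, "confusion_matrix"))
  pv_ci <- match.arg(pv_ci)
  spec_rows <- list(
    sensitivity = list(k = m$tp, n = m$tp + m$fn, meth = "clopper-pearson"),
    specificity = list(k = m$tn, n = m$tn + m$fp, meth = "clopper-pearson"),
    ppv = list(k = m$tp, n = m$tp + m$fp, meth = pv_ci),
    npv = list(k = m$tn, n = m$tn + m$fn, meth = pv_ci))
  rows <- lapply(names(spec_rows), function(nm) {
    k <- spec_rows[[nm]]$k
    n <- spec_rows[[nm]]$n
    meth <- spec_rows[[nm]]$meth
    if (n == 0L) {
      return(data.frame(metric = nm, numerator = k, denominator = n,
                        estimate = NA_real_, lower = NA_real_, upper = NA_real_,
                        ci_method = meth, note = "undefined: zero denominator",
                        stringsAsFactors = FALSE))
    }
    ci <- if (meth == "clopper-pearson") clopper_pearson(k, n, level)
          else logit_interval(k, n, level)
    data.frame(metric = nm, numerator = k, denominator = n,
               estimate = 100 * k / n, lower = 100 * ci[1], upper = 100 * ci[2],
               ci_method = meth, note = "", stringsAsFactors = FALSE)
  })
  structure(list(metrics = do.call(rbind, rows), matrix = m, level = level),
            class = "diagnostic_metrics")
}

#' @export
print.diagnostic_metrics <- function(x, ...) {
  cat(sprintf("Predictive metrics: %s (%s vs %s)\n", x$matrix$predictor,
              x$matrix$positives, x$matrix$negatives))
  df <- x$metrics
  for (i in seq_len(nrow(df))) {
    if (is.na(df$estimate[i])) {
      cat(sprintf("  %-12s %s\n", df$metric[i], df$note[i]))
    } else {
      cat(sprintf("  %-12s %6.2f%% (%.2f - %.2f) [%d/%d, %s]\n",
                  df$metric[i], df$estimate[i], df$lower[i], df$upper[i],
                  df$numerator[i], df$denominator[i], df$ci_method[i]))
    }
  }
  invisible(x)
}
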