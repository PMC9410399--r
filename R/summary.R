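# Table-1-style cohort characteristics.

#' Round half away from zero
#'
#' Display rounding used throughout the report tables (so 58.25 renders as
#' 58.3, not banker's 58.2).
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Geometric mean with a t-based confidence interval
#'
#' exp of the mean of logs; the interval is the exp of the t interval for the
#' log-scale mean (df = n - 1).  With n = 1 the interval is undefined; a
#' constant series gives a degenerate interval equal to the mean.
#'
#' @param values Positive numbers (e.g. total IgE in IU/mL).
#' @param level Confidence level, default 0.95.
#' @return List with `mean`, `lower`, `upper`, `level`, `n`.
#' @export
#' @examples
#' geometric_mean_ci(c(5, 20, 80))
geometric_mean_ci <- function(values, level = 0.95) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no values", call. = FALSE)
  if (any(values <= 0)) {
    stop("geometric mean requires positive values; offending index(es): ",
         paste(which(values <= 0), collapse = ","), call. = FALSE)
  }
  lx <- log(values)
  n <- length(lx)
  m <- mean(lx)
  if (n < 2L) {
    return(list(mean = exp(m), lower = NA_real_, upper = NA_real_,
                level = level, n = n))
  }
  se <- stats::sd(lx) / sqrt(n)
  tq <- stats::qt(1 - (1 - level) / 2, df = n - 1)
  list(mean = exp(m), lower = exp(m - tq * se), upper = exp(m + tq * se),
       level = level, n = n)
}

#' Summarize a cohort by case/control group
#'
#' Per-group (eczema cases vs controls) counts and percentages for sex,
#' phenotypes, SCORAD severity, genotype classes at every declared site and
#' the combined FLG genotype, plus mean +/- SD age and the geometric-mean
#' total IgE with its confidence interval.  Percentages use round-half-up to
#' one decimal; genotype percentages are taken over subjects with a
#' non-missing call at that site (the number missing is reported).
#'
#' @param x A [cohort()].
#' @param level Confidence level for the IgE interval.
#' @return An object of class `"cohort_summary"`; `as.data.frame()` gives a
#'   tidy long table (group, variable, class, count, denominator, percent).
#' @export
summarize_cohort <- function(x, level = 0.95) {
  stopifnot(inherits(x, "cohort"))
  s <- x$subjects
  if (nrow(s) == 0L) stop("empty cohort", call. = FALSE)
  groups <- list(cases = s[s$eczema, , drop = FALSE],
                 controls = s[!s$eczema, , drop = FALSE])
  pct <- function(k, n) if (n == 0L) NA_real_ else round_half_up(100 * k / n, 1)
  one_group <- function(g) {
    n <- nrow(g)
    empty <- n == 0L
    cls_count <- function(values, classes) {
      ok <- !is.na(values)
      counts <- vapply(classes, function(cl) sum(values[ok] == cl), integer(1))
      data.frame(class = classes, count = counts,
                 denominator = sum(ok),
                 percent = vapply(counts, pct, numeric(1), n = sum(ok)),
                 stringsAsFactors = FALSE)
    }
    geno <- lapply(seq_len(nrow(x$sites)), function(i) {
      sid <- x$sites$site_id[i]
      ref <- x$sites$ref_allele[i]; risk <- x$sites$risk_allele[i]
      classes <- c(paste0(ref, ref), paste0(ref, risk), paste0(risk, risk))
      out <- cls_count(g[[sid]], classes)
      out$missing <- sum(is.na(g[[sid]]))
      out
    })
    names(geno) <- x$sites$site_id
    ige <- g$total_ige_iu_ml[!is.na(g$total_ige_iu_ml)]
    list(
      n = n,
      empty = empty,
      age_mean = if (empty) NA_real_ else mean(g$age_months),
      age_sd = if (n > 1L) stats::sd(g$age_months) else NA_real_,
      sex = cls_count(g$sex, .SEX_LEVELS),
      phenotypes = do.call(rbind, lapply(
        c("sensitized", "polysensitized", "asthma", "family_atopy"),
        function(col) data.frame(class = col, count = sum(g[[col]]),
                                 denominator = n, percent = pct(sum(g[[col]]), n),
                                 stringsAsFactors = FALSE))),
      scorad = cls_count(g$scorad_class, c("mild", "moderate", "severe")),
      genotypes = geno,
      flg = {
        ok <- !is.na(g$flg_null)
        data.frame(class = c("normal", "null"),
                   count = c(sum(!g$flg_null[ok]), sum(g$flg_null[ok])),
                   denominator = sum(ok),
                   percent = c(pct(sum(!g$flg_null[ok]), sum(ok)),
                               pct(sum(g$flg_null[ok]), sum(ok))),
                   stringsAsFactors = FALSE)
      },
      ige = if (length(ige) >= 2L) geometric_mean_ci(ige, level) else NULL
    )
  }
  structure(list(groups = lapply(groups, one_group), level = level),
            class = "cohort_summary")
}

#' @export
as.data.frame.cohort_summary <- function(x, ...) {
  rows <- list()
  for (gname in names(x$groups)) {
    g <- x$groups[[gname]]
    add <- function(variable, df) {
      df$group <- gname; df$variable <- variable
      rows[[length(rows) + 1L]] <<- df[, c("group", "variable", "class",
                                           "count", "denominator", "percent")]
    }
    add("sex", g$sex)
    add("phenotype", g$phenotypes)
    add("scorad", g$scorad)
    for (sid in names(g$genotypes)) add(sid, g$genotypes[[sid]][, 1:4])
    add("flg_combined", g$flg)
  }
  do.call(rbind, rows)
}

#' @export
print.cohort_summary <- function(x, ...) {
  fmt_n <- function(df) paste(sprintf("%s %d (%s%%)", df$class, df$count,
                                      formatC(df$percent, format = "f", digits = 1)),
                              collapse = "  ")
  for (gname in names(x$groups)) {
    g <- x$groups[[gname]]
    cat(sprintf("== %s (n = %d)%s ==\n", gname, g$n,
                if (g$empty) " [EMPTY GROUP]" else ""))
    if (g$empty) next
    cat(sprintf("age, months: %.1f +/- %.1f\n", g$age_mean, g$age_sd))
    cat("sex:", fmt_n(g$sex), "\n")
    cat("phenotypes:", fmt_n(g$phenotypes), "\n")
    if (gname == "cases") cat("SCORAD:", fmt_n(g$scorad), "\n")
    for (sid in names(g$genotypes)) {
      cat(sprintf("%s: %s%s\n", sid, fmt_n(g$genotypes[[sid]]),
                  if (g$genotypes[[sid]]$missing[1] > 0)
                    sprintf("  [%d missing]", g$genotypes[[sid]]$missing[1]) else ""))
    }
    cat("combined FLG:", fmt_n(g$flg), "\n")
    if (!is.null(g$ige)) {
      cat(sprintf("total IgE, IU/mL: geometric mean %.1f (%.1f - %.1f)\n",
                  g$ige$mean, g$ige$lower, g$ige$upper))
    }
  }
  invisible(x)
}
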