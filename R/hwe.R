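# Hardy-Weinberg goodness-of-fit.

#' Genotype counts at a biallelic site
#'
#' @param n_ref_hom,n_het,n_alt_hom Non-negative integer counts of reference
#'   homozygotes, heterozygotes and risk-allele homozygotes.
#' @param site_id Optional label.
#' @return A `genotype_counts` object.
#' @export
genotype_counts <- function(n_ref_hom, n_het, n_alt_hom, site_id = NULL) {
  counts <- c(n_ref_hom = n_ref_hom, n_het = n_het, n_alt_hom = n_alt_hom)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("genotype counts must be non-negative integers", call. = FALSE)
  }
  structure(list(counts = as.integer(counts), site_id = site_id),
            class = "genotype_counts")
}

#' Tally genotype counts from a cohort
#'
#' Complete-case tally (missing calls excluded) of ref-hom / het / alt-hom at
#' one site, optionally inside a population subgroup.
#'
#' @param x A [cohort()].
#' @param site_id Declared site.
#' @param population Subgroup filter (default "controls", where
#'   Hardy-Weinberg equilibrium is conventionally assessed); see
#'   [population_filter] keywords in [read_cohort()] docs: "all", "eczema",
#'   "controls", "asthma", or a predicate function.
#' @return A [genotype_counts()].
#' @export
count_genotypes <- function(x, site_id, population = "controls") {
  keep <- population_filter(x, population)
  cnt <- risk_allele_count(x, site_id)[keep]
  cnt <- cnt[!is.na(cnt)]
  genotype_counts(sum(cnt == 0L), sum(cnt == 1L), sum(cnt == 2L),
                  site_id = site_id)
}

#' @export
print.genotype_counts <- function(x, ...) {
  cat(sprintf("<genotype_counts>%s ref-hom %d, het %d, alt-hom %d (n = %d)\n",
              if (is.null(x$site_id)) "" else paste0(" ", x$site_id),
              x$counts[1], x$counts[2], x$counts[3], sum(x$counts)))
  invisible(x)
}

#' Hardy-Weinberg equilibrium chi-square goodness-of-fit test
#'
#' Estimates the risk-allele frequency q from the sample, forms expected
#' counts n * ((1-q)^2, 2q(1-q), q^2) and compares observed to expected with
#' the plain Pearson chi-square statistic on 1 degree of freedom (one allele
#' frequency estimated from the data).  No continuity correction by default;
#' `correct = TRUE` applies the Yates-style |obs - exp| - 0.5 adjustment.
#'
#' A monomorphic sample (q = 0 or 1) is flagged degenerate and returns
#' chi-square 0, p = 1.
#'
#' @param counts A [genotype_counts()] (or a cohort together with `site_id`
#'   and `population`, forwarded to [count_genotypes()]).
#' @param site_id,population Used only when `counts` is a cohort.
#' @param correct Continuity correction flag.
#' @return An object of class `"hwe_test"`: `chi2`, `df` (= 1), `p`,
#'   `expected` (three counts summing to the observed total), `q` (estimated
#'   risk-allele frequency), `n`, `degenerate`.
#' @export
#' @examples
#' hwe_test(genotype_counts(66, 15, 4))  # control HRNR counts: out of HWE
hwe_test <- function(counts, site_id = NULL, population = "controls",
                     correct = FALSE) {
  if (inherits(counts, "cohort")) {
    counts <- count_genotypes(counts, site_id, population)
  }
  stopifnot(inherits(counts, "genotype_counts"))
  obs <- as.numeric(counts$counts)
  n <- sum(obs)
  if (n == 0) stop("total genotype count is zero", call. = FALSE)
  q <- (obs[2] + 2 * obs[3]) / (2 * n)
  expected <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  degenerate <- q == 0 || q == 1
  if (degenerate) {
    chi2 <- 0
    p <- 1
  } else {
    dev <- abs(obs - expected)
    if (correct) dev <- pmax(dev - 0.5, 0)
    chi2 <- sum(dev^2 / expected)
    p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  }
  structure(list(chi2 = chi2, df = 1L, p = p, expected = expected, q = q,
                 n = n, degenerate = degenerate, site_id = counts$site_id,
                 correct = correct),
            class = "hwe_test")
}

#' @export
print.hwe_test <- function(x, ...) {
  cat(sprintf("Hardy-Weinberg chi-square goodness-of-fit%s\n",
              if (is.null(x$site_id)) "" else paste0(": ", x$site_id)))
  cat(sprintf("  q(risk allele) = %.4f, n = %d\n", x$q, x$n))
  cat(sprintf("  expected = (%.2f, %.2f, %.2f)\n",
              x$expected[1], x$expected[2], x$expected[3]))
  if (x$degenerate) {
    cat("  monomorphic sample: test degenerate, chi2 = 0, p = 1\n")
  } else {
    cat(sprintf("  chi2 = %.3f, df = 1, p = %.4g%s\n", x$chi2, x$p,
                if (x$correct) " (continuity corrected)" else ""))
  }
  invisible(x)
}
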