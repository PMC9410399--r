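# Contingency-table association statistics: crude odds ratios with Woolf
# intervals, chi-square and Fisher tests, the allele (multiplicative) model,
# logistic regression for crude and adjusted ORs, and the stratified and
# severity analyses.

#' 2x2 contingency table of exposure by outcome
#'
#' @param a Exposed cases.
#' @param b Exposed non-cases.
#' @param c Unexposed cases.
#' @param d Unexposed non-cases.
#' @return A `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("cells must be non-negative integers", call. = FALSE)
  }
  if (sum(cells) == 0) stop("empty table", call. = FALSE)
  structure(as.list(as.integer(cells)) |> stats::setNames(names(cells)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- as.matrix(x)
  cat("<2x2 table> (rows: exposed/unexposed; cols: case/non-case)\n")
  print(m)
  ne <- attr(x, "n_excluded")
  if (!is.null(ne) && ne > 0) cat(ne, "subject(s) excluded (missing data)\n")
  invisible(x)
}

#' @export
as.matrix.contingency_table <- function(x, ...) {
  matrix(c(x$a, x$c, x$b, x$d), nrow = 2,
         dimnames = list(c("exposed", "unexposed"), c("case", "noncase")))
}

#' Build a 2x2 table from a cohort
#'
#' Complete-case cross-classification of a binary-coded exposure against a
#' binary outcome, inside an optional population subgroup (e.g. the
#' within-eczema asthma analyses use `population = "eczema"`).  Subjects with
#' a missing exposure or outcome are excluded and counted in the
#' `n_excluded` attribute.
#'
#' @param x A [cohort()].
#' @param exposure Binary exposure spec ([snp_exposure()], [flg_exposure()],
#'   [combined_predictor()], or a bare site id coded dominant).
#' @param outcome Logical subject column name or predicate function.
#' @param population Subgroup filter (NULL = everyone).
#' @return A [contingency_table()] with attributes `n_excluded`,
#'   `empty_margin`.
#' @export
build_table <- function(x, exposure, outcome, population = NULL) {
  keep <- population_filter(x, population)
  if (!any(keep)) {
    stop("population filter selects no subjects: ",
         if (is.character(population)) population else "<predicate>",
         call. = FALSE)
  }
  code <- code_exposure(x, exposure)
  y <- outcome_values(x, outcome)
  use <- keep & !is.na(code) & !is.na(y)
  code <- code[use]; y <- y[use]
  if (any(!(code %in% c(0L, 1L)))) {
    stop("build_table requires a binary-coded exposure (use dominant/recessive)",
         call. = FALSE)
  }
  tab <- contingency_table(sum(code == 1L & y), sum(code == 1L & !y),
                           sum(code == 0L & y), sum(code == 0L & !y))
  attr(tab, "n_excluded") <- sum(keep) - sum(use)
  attr(tab, "empty_margin") <- with(tab, (a + b) == 0L || (c + d) == 0L ||
                                      (a + c) == 0L || (b + d) == 0L)
  if (attr(tab, "empty_margin")) {
    warning("table has an empty margin (constant exposure or outcome in subgroup)",
            call. = FALSE)
  }
  tab
}

effect_estimate <- function(measure, estimate, lower, upper, level, p = NA_real_,
                            method = "", n_used = NA_integer_, note = NULL) {
  structure(list(measure = measure, estimate = estimate, ci_lower = lower,
                 ci_upper = upper, level = level, p = p, method = method,
                 n_used = n_used, note = note),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, digits = 2, ...) {
  cat(sprintf("%s = %.*f (%.0f%% CI %.*f - %.*f)%s%s\n",
              x$measure, digits, x$estimate, 100 * x$level,
              digits, x$ci_lower, digits, x$ci_upper,
              if (!is.na(x$p)) sprintf(", p = %.4g", x$p) else "",
              sprintf("  [%s, n = %d]", x$method, x$n_used)))
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' Odds ratio with Woolf confidence interval
#'
#' OR = ad/bc with the log-scale Wald (Woolf) interval
#' exp(ln OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d)).  When exactly one cell is
#' zero, the Haldane-Anscombe correction (0.5 added to every cell) is applied
#' to the estimate and interval and noted in `method`; two zero cells on a
#' diagonal leave the OR undefined and raise an error.
#'
#' The attached p-value follows the "chi-square or Fisher exact, as
#' appropriate" rule: Fisher when any expected cell is below 5, Pearson
#' chi-square (no continuity correction) otherwise.  Set `p_method` to force
#' either test, or "none".
#'
#' @param table A [contingency_table()].
#' @param level Confidence level.
#' @param p_method "auto" (default), "chisq", "fisher" or "none".
#' @return An `effect_estimate` (measure "OR").
#' @export
#' @examples
#' odds_ratio(contingency_table(17, 26, 11, 49))  # asthma vs HRNR carriage
odds_ratio <- function(table, level = 0.95,
                       p_method = c("auto", "chisq", "fisher", "none")) {
  stopifnot(inherits(table, "contingency_table"))
  p_method <- match.arg(p_method)
  cells <- with(table, c(a = a, b = b, c = c, d = d))
  if ((cells["a"] == 0 && cells["d"] == 0) || (cells["b"] == 0 && cells["c"] == 0)) {
    stop("odds ratio undefined: two zero cells on a diagonal", call. = FALSE)
  }
  corrected <- sum(cells == 0) == 1L
  w <- if (corrected) cells + 0.5 else cells
  est <- (w["a"] * w["d"]) / (w["b"] * w["c"])
  se <- sqrt(sum(1 / w))
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- NA_real_
  method <- if (corrected) "Woolf, Haldane-Anscombe corrected" else "Woolf"
  if (p_method != "none") {
    use_fisher <- switch(p_method,
      fisher = TRUE, chisq = FALSE,
      auto = min(expected_cells(table)) < 5)
    p <- if (use_fisher) fisher_exact(table) else chi_square_test(table)$p
    method <- paste0(method, "; p: ", if (use_fisher) "Fisher exact" else "chi-square")
  }
  effect_estimate("OR", unname(est), unname(exp(log(est) - z * se)),
                  unname(exp(log(est) + z * se)), level, p = p,
                  method = method, n_used = sum(cells))
}

expected_cells <- function(table) {
  m <- as.matrix(table)
  outer(rowSums(m), colSums(m)) / sum(m)
}

#' Pearson chi-square test of independence
#'
#' No continuity correction by default (`correct = TRUE` for Yates).  Accepts
#' a 2x2 [contingency_table()] or any 2-by-k count matrix (genotype or
#' severity comparisons).  A zero margin leaves the test undefined.
#'
#' @param table A [contingency_table()] or count matrix.
#' @param correct Yates continuity correction flag.
#' @return List with `statistic`, `df`, `p`.
#' @export
chi_square_test <- function(table, correct = FALSE) {
  m <- if (inherits(table, "contingency_table")) as.matrix(table) else as.matrix(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("chi-square test undefined: zero margin", call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(m, correct = correct))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value))
}

#' Fisher exact test (two-sided) for a 2x2 table
#'
#' Two-sided p-value with fixed margins: the sum of hypergeometric
#' probabilities of all tables no more probable than the observed one.
#'
#' @param table A [contingency_table()] or 2x2 matrix.
#' @return The p-value.
#' @export
fisher_exact <- function(table) {
  m <- if (inherits(table, "contingency_table")) as.matrix(table) else as.matrix(table)
  stats::fisher.test(m)$p.value
}

#' Allele (multiplicative) model odds ratio
#'
#' Expands each genotyped subject into two allele-level observations and
#' computes the OR on the resulting allele-by-outcome 2x2 table.  Count-level
#' entry point: [allele_table()].
#'
#' @param x A [cohort()].
#' @param site_id Declared site.
#' @param outcome Logical subject column or predicate.
#' @param population Subgroup filter.
#' @param level Confidence level.
#' @param p_method Passed to [odds_ratio()].
#' @return An `effect_estimate`.
#' @export
allele_model <- function(x, site_id, outcome, population = NULL, level = 0.95,
                         p_method = "auto") {
  keep <- population_filter(x, population)
  cnt <- risk_allele_count(x, site_id)
  y <- outcome_values(x, outcome)
  use <- keep & !is.na(cnt) & !is.na(y)
  cnt <- cnt[use]; y <- y[use]
  risk_case <- sum(cnt[y]); ref_case <- sum(2L - cnt[y])
  risk_ctrl <- sum(cnt[!y]); ref_ctrl <- sum(2L - cnt[!y])
  if ((risk_case + risk_ctrl) == 0L || (ref_case + ref_ctrl) == 0L) {
    stop("allele model undefined: site monomorphic in the analysed population",
         call. = FALSE)
  }
  tab <- contingency_table(risk_case, risk_ctrl, ref_case, ref_ctrl)
  est <- odds_ratio(tab, level = level, p_method = p_method)
  est$method <- paste0("allele model; ", est$method)
  est
}

#' Allele-level 2x2 table from genotype counts
#'
#' @param case_counts,control_counts [genotype_counts()] for cases and
#'   controls.
#' @return A [contingency_table()] of risk vs reference alleles by outcome.
#' @export
allele_table <- function(case_counts, control_counts) {
  stopifnot(inherits(case_counts, "genotype_counts"),
            inherits(control_counts, "genotype_counts"))
  risk <- function(g) g$counts[2] + 2L * g$counts[3]
  ref <- function(g) 2L * g$counts[1] + g$counts[2]
  contingency_table(risk(case_counts), risk(control_counts),
                    ref(case_counts), ref(control_counts))
}

#' Stratified association by combined FLG genotype
#'
#' Runs the requested genetic-model association independently inside each
#' stratum of a binary stratifier (by default the combined FLG genotype), the
#' design behind "eczema risk after stratification for FLG mutations".
#'
#' @param x A [cohort()].
#' @param site_id Site to test.
#' @param model Genetic model passed to [snp_exposure()], or "allele".
#' @param outcome Outcome column/predicate.
#' @param stratifier Binary exposure spec defining the strata (default
#'   [flg_exposure()]).
#' @param population Subgroup filter applied before stratification.
#' @param level Confidence level.
#' @return List of class `"stratified_association"`: one entry per stratum
#'   with the `effect_estimate` (or a not-estimable marker) and the stratum n.
#' @export
stratified_association <- function(x, site_id, model = "dominant",
                                   outcome = "eczema",
                                   stratifier = flg_exposure(),
                                   population = NULL, level = 0.95) {
  keep <- population_filter(x, population)
  strat <- code_exposure(x, stratifier)
  out <- list()
  for (sv in c(0L, 1L)) {
    label <- paste0(exposure_label(stratifier), " = ", sv)
    rows <- keep & !is.na(strat) & strat == sv
    entry <- list(stratum = label, n = sum(rows), estimate = NULL,
                  estimable = FALSE)
    if (sum(rows) > 0L) {
      sub <- cohort_subset(x, rows)
      fit <- tryCatch(suppressWarnings({
        if (identical(model, "allele")) {
          allele_model(sub, site_id, outcome, level = level)
        } else {
          odds_ratio(build_table(sub, snp_exposure(site_id, model), outcome),
                     level = level)
        }
      }), error = function(e) e)
      if (inherits(fit, "effect_estimate")) {
        entry$estimate <- fit
        entry$estimable <- TRUE
      } else {
        entry$reason <- conditionMessage(fit)
      }
    } else {
      entry$reason <- "empty stratum"
    }
    out[[label]] <- entry
  }
  structure(out, class = "stratified_association",
            site_id = site_id, model = model)
}

#' @export
print.stratified_association <- function(x, ...) {
  cat(sprintf("Stratified association: %s (%s model)\n",
              attr(x, "site_id"), attr(x, "model")))
  for (entry in x) {
    cat(sprintf("- %s (n = %d): ", entry$stratum, entry$n))
    if (entry$estimable) print(entry$estimate) else cat("not estimable:", entry$reason, "\n")
  }
  invisible(x)
}

#' Severity association among eczema cases (mild vs moderate)
#'
#' Compares risk-variant carriage between moderate and mild SCORAD classes
#' with mild as the reference (no severe cases occurred in this design; a
#' non-empty severe class is reported but excluded from the 2x2 comparison
#' with a warning).
#'
#' @param x A [cohort()].
#' @param site_id Site to test.
#' @param model Genetic model (binary: dominant or recessive).
#' @param level Confidence level.
#' @return An `effect_estimate` for moderate-vs-mild carriage.
#' @export
severity_association <- function(x, site_id, model = "dominant", level = 0.95) {
  s <- x$subjects
  cases <- s$eczema & s$scorad_class %in% c("mild", "moderate", "severe")
  if (!any(cases)) stop("no graded eczema cases", call. = FALSE)
  if (any(s$scorad_class[cases] == "severe")) {
    warning("severe cases present; comparison restricted to mild vs moderate",
            call. = FALSE)
  }
  sub <- cohort_subset(x, cases & s$scorad_class %in% c("mild", "moderate"))
  tab <- build_table(sub, snp_exposure(site_id, model),
                     outcome = function(d) d$scorad_class == "moderate")
  est <- odds_ratio(tab, level = level)
  est$method <- paste0("moderate vs mild (reference); ", est$method)
  est
}
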