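# Gene-gene interaction on the additive and multiplicative scales from the
# four joint-exposure strata (A-B-, A+B-, A-B+, A+B+).
#
# "RR" here is the ratio of within-stratum case proportions
# cases/(cases+controls) against the double-unexposed reference stratum.  In
# a case-control sample this is a design artifact -- it depends on the case
# and control quota sizes and is NOT a population risk ratio -- but it is the
# scale on which the study's joint-genotype tables and their RERI/AP/S and
# ratio-of-RRs summaries are defined, so the package computes exactly that
# quantity (from unrounded values) and says so.

.STRATUM_LABELS <- c("A-B-", "A+B-", "A-B+", "A+B+")

#' Joint-exposure table from stratum counts
#'
#' @param cases,controls Length-4 integer vectors of case and control counts
#'   in stratum order A-B- (reference), A+B-, A-B+, A+B+.
#' @param factors Length-2 character labels for factors A and B.
#' @return A `joint_table`.
#' @export
joint_table <- function(cases, controls, factors = c("A", "B")) {
  stopifnot(length(cases) == 4L, length(controls) == 4L)
  if (any(is.na(c(cases, controls))) || any(c(cases, controls) < 0)) {
    stop("stratum counts must be non-negative", call. = FALSE)
  }
  if (cases[1] == 0L || controls[1] == 0L) {
    stop("reference stratum (A-B-) must contain cases and controls",
         call. = FALSE)
  }
  structure(list(cases = as.integer(cases), controls = as.integer(controls),
                 factors = factors, strata = .STRATUM_LABELS),
            class = "joint_table")
}

#' @export
print.joint_table <- function(x, ...) {
  cat(sprintf("<joint_table> A = %s, B = %s\n", x$factors[1], x$factors[2]))
  print(data.frame(stratum = x$strata, cases = x$cases, controls = x$controls),
        row.names = FALSE)
  invisible(x)
}

#' Cross-classify a cohort into the four joint-exposure strata
#'
#' @param x A [cohort()].
#' @param factorA,factorB Binary exposure specs.
#' @param outcome Logical subject column or predicate; stratum "cases" are
#'   outcome-positive subjects, "controls" are outcome-negative.
#' @param population Subgroup filter.
#' @return A [joint_table()]; subjects missing either factor or the outcome
#'   are excluded (complete case) and counted in `n_excluded`.
#' @export
joint_strata <- function(x, factorA, factorB, outcome, population = NULL) {
  keep <- population_filter(x, population)
  a <- code_exposure(x, factorA)
  b <- code_exposure(x, factorB)
  y <- outcome_values(x, outcome)
  if (any(a > 1L, na.rm = TRUE) || any(b > 1L, na.rm = TRUE)) {
    stop("joint strata require binary-coded factors", call. = FALSE)
  }
  use <- keep & !is.na(a) & !is.na(b) & !is.na(y)
  a <- a[use]; b <- b[use]; y <- y[use]
  idx <- 1L + a + 2L * b  # 1: A-B-, 2: A+B-, 3: A-B+, 4: A+B+
  cases <- vapply(1:4, function(i) sum(y & idx == i), integer(1))
  ctrls <- vapply(1:4, function(i) sum(!y & idx == i), integer(1))
  empties <- (cases + ctrls) == 0L
  if (any(empties[-1])) {
    warning("empty joint stratum: ",
            paste(.STRATUM_LABELS[-1][empties[-1]], collapse = ", "),
            call. = FALSE)
  }
  jt <- joint_table(cases, ctrls,
                    factors = c(exposure_label(factorA), exposure_label(factorB)))
  attr(jt, "n_excluded") <- sum(keep) - sum(use)
  jt
}

#' Stratum relative risks against the double-unexposed reference
#'
#' Within-stratum case proportion cases/(cases+controls) divided by the
#' reference stratum's proportion (a case-control design artifact, see the
#' note in the package vignette), with Katz log-scale intervals sharing the
#' reference-stratum variance term.  A stratum with zero controls yields its
#' uncorrected point RR and a Haldane-corrected interval flagged degenerate.
#'
#' @param x A [joint_table()].
#' @param level Confidence level.
#' @return Data.frame (class `"stratum_rr"`): stratum, cases, controls, risk,
#'   rr, lower, upper, degenerate.
#' @export
stratum_relative_risks <- function(x, level = 0.95) {
  stopifnot(inherits(x, "joint_table"))
  n <- x$cases + x$controls
  estimable <- n > 0L
  risk <- ifelse(estimable, x$cases / n, NA_real_)
  rr <- risk / risk[1]
  z <- stats::qnorm(1 - (1 - level) / 2)
  # log-RR variance; strata with a zero cell get the 0.5 correction for the
  # interval only, and are flagged
  degen <- estimable & (x$cases == 0L | x$controls == 0L)
  ca <- x$cases + ifelse(degen, 0.5, 0)
  nn <- n + ifelse(degen, 1, 0)
  v_ref <- 1 / ca[1] - 1 / nn[1]
  v <- (1 / ca - 1 / nn) + v_ref
  lower <- exp(log(ifelse(degen, (ca / nn) / (ca[1] / nn[1]), rr)) - z * sqrt(v))
  upper <- exp(log(ifelse(degen, (ca / nn) / (ca[1] / nn[1]), rr)) + z * sqrt(v))
  out <- data.frame(stratum = x$strata, cases = x$cases, controls = x$controls,
                    risk = risk, rr = rr, lower = lower, upper = upper,
                    degenerate = degen, stringsAsFactors = FALSE)
  out$rr[1] <- 1
  out$lower[1] <- out$upper[1] <- NA_real_
  out$degenerate[1] <- FALSE
  class(out) <- c("stratum_rr", "data.frame")
  out
}

rr_triplet <- function(rrs) {
  if (inherits(rrs, "joint_table")) rrs <- stratum_relative_risks(rrs)
  if (is.data.frame(rrs)) rrs <- rrs$rr[2:4]
  stopifnot(is.numeric(rrs), length(rrs) == 3L)
  if (any(!is.finite(rrs)) || any(rrs <= 0)) {
    stop("stratum relative risks must be finite and positive", call. = FALSE)
  }
  rrs  # (rr10, rr01, rr11)
}

#' Additive-scale interaction measures
#'
#' From unrounded stratum relative risks (rr10, rr01, rr11):
#' RERI = rr11 - rr10 - rr01 + 1 (relative excess risk due to interaction),
#' AP = RERI / rr11 (proportion of the joint effect attributable to
#' interaction) and the synergy index
#' S = (rr11 - 1) / ((rr10 - 1) + (rr01 - 1)), undefined when its denominator
#' is 0.  RERI and AP above 0 (and S above 1) indicate superadditivity.
#'
#' @param rrs A [joint_table()], the output of [stratum_relative_risks()], or
#'   a numeric vector (rr10, rr01, rr11).
#' @return List with `reri`, `ap`, `s` (NA when undefined), `s_defined`.
#' @export
#' @examples
#' additive_interaction(c(3.84, 4.80, 8.00))  # RERI 0.36, AP 0.045, S 1.05
additive_interaction <- function(rrs) {
  r <- rr_triplet(rrs)
  reri <- r[3] - r[1] - r[2] + 1
  denom <- (r[1] - 1) + (r[2] - 1)
  list(reri = reri, ap = reri / r[3],
       s = if (denom != 0) (r[3] - 1) / denom else NA_real_,
       s_defined = denom != 0)
}

#' Multiplicative-scale interaction: ratio of relative risks (or ORs)
#'
#' ratio = eff11 / (eff10 * eff01); above 1 indicates positive interaction on
#' the multiplicative scale.
#'
#' @param rrs As in [additive_interaction()]; also accepts a vector of ORs.
#' @return The ratio.
#' @export
multiplicative_interaction <- function(rrs) {
  r <- rr_triplet(rrs)
  r[3] / (r[1] * r[2])
}

#' All interaction measures for a joint-exposure table
#'
#' Convenience wrapper: stratum RRs (with intervals), RERI, AP, S and the
#' ratio of RRs, all computed from unrounded within-stratum case proportions.
#'
#' @param x A [joint_table()].
#' @param level Confidence level for the stratum RRs.
#' @return Class `"interaction_measures"`.
#' @export
interaction_measures <- function(x, level = 0.95) {
  rr <- stratum_relative_risks(x, level = level)
  add <- additive_interaction(rr)
  structure(list(table = x, rr = rr, reri = add$reri, ap = add$ap, s = add$s,
                 s_defined = add$s_defined,
                 ratio_rr = multiplicative_interaction(rr), level = level),
            class = "interaction_measures")
}

#' @export
print.interaction_measures <- function(x, ...) {
  cat(sprintf("Joint-genotype interaction: A = %s, B = %s\n",
              x$table$factors[1], x$table$factors[2]))
  rr <- x$rr
  for (i in seq_len(nrow(rr))) {
    cat(sprintf("  %s  %d/%d  %s\n", rr$stratum[i], rr$cases[i], rr$controls[i],
                if (i == 1L) "1.00 (reference)"
                else sprintf("RR %.2f (%.2f - %.2f)%s", rr$rr[i], rr$lower[i],
                             rr$upper[i],
                             if (rr$degenerate[i]) " [zero-cell stratum]" else "")))
  }
  cat(sprintf("RERI = %.2f; AP = %.3g; S = %s; ratio of RRs = %.2f\n",
              x$reri, x$ap,
              if (x$s_defined) sprintf("%.2f", x$s) else "undefined",
              x$ratio_rr))
  invisible(x)
}

#' Logistic product-term test for multiplicative interaction
#'
#' Fits outcome ~ A + B + A:B (+ covariates) by [logistic_fit()] machinery
#' and reports the Wald test of the product term.  A product term collinear
#' with a main effect (or constant) is dropped with a warning and returns an
#' NA p-value.
#'
#' @param x A [cohort()].
#' @param factorA,factorB Binary exposure specs.
#' @param outcome Logical subject column or predicate.
#' @param covariates Optional covariates (see [logistic_fit()]).
#' @param population Subgroup filter.
#' @param firth Passed through to the fitter; zero-cell strata commonly
#'   separate, which flags the fit and (by default) triggers a Firth refit.
#' @return List: `estimate` (product-term log-odds), `se`, `p`,
#'   `separation_flag`, `dropped`, `fit` (the full `logistic_fit`).
#' @export
interaction_term_test <- function(x, factorA, factorB, outcome,
                                  covariates = NULL, population = NULL,
                                  firth = "auto") {
  keep <- population_filter(x, population)
  a <- as.numeric(code_exposure(x, factorA))
  b <- as.numeric(code_exposure(x, factorB))
  y <- outcome_values(x, outcome)
  cols <- list(A = a, B = b, AxB = a * b)
  for (cv in covariates %||% character(0)) {
    cols[[cv]] <- switch(cv,
      age_months = x$subjects$age_months,
      sex = as.numeric(x$subjects$sex == "male"),
      family_atopy = as.numeric(x$subjects$family_atopy),
      as.numeric(x$subjects[[cv]]))
  }
  M <- do.call(cbind, cols)
  use <- keep & !is.na(y) & stats::complete.cases(M)
  M <- M[use, , drop = FALSE]
  yy <- as.numeric(y[use])
  prod_col <- M[, "AxB"]
  degenerate <- length(unique(prod_col)) < 2L ||
    identical(unname(prod_col), unname(M[, "A"])) ||
    identical(unname(prod_col), unname(M[, "B"]))
  if (degenerate) {
    warning("product term collinear or constant; dropped", call. = FALSE)
    return(list(estimate = NA_real_, se = NA_real_, p = NA_real_,
                separation_flag = NA, dropped = TRUE, fit = NULL))
  }
  const <- apply(M, 2, function(v) length(unique(v)) < 2L)
  M <- M[, !const, drop = FALSE]
  X <- cbind(`(Intercept)` = 1, M)
  fit <- fit_logistic_matrix(X, yy, firth = firth)
  row <- fit$coefficients[fit$coefficients$term == "AxB", ]
  list(estimate = row$estimate, se = row$se, p = row$p,
       separation_flag = fit$separation_flag, dropped = FALSE, fit = fit)
}

#' Confidence intervals for RERI, AP and S
#'
#' Delta method on the joint distribution of the three log-RRs (whose
#' covariance matrix shares the reference-stratum term), in the
#' Hosmer-Lemeshow style: RERI and AP on the natural scale, S through ln S.
#' Any zero case cell (or an all-case stratum) invalidates the log-RR
#' variances, in which case the function falls back to a stratified bootstrap
#' with a warning: cases and controls are resampled as multinomials over the
#' four strata (holding the case and control totals fixed) and percentile
#' intervals are taken over `reps` replicates.
#'
#' @param x A [joint_table()].
#' @param method "delta" or "bootstrap".
#' @param reps Bootstrap replicates (minimum 200).
#' @param seed Seed for the bootstrap (mandatory reproducibility hook).
#' @param level Confidence level.
#' @return List of (estimate, lower, upper) for `reri`, `ap`, `s`, plus
#'   `method` actually used.
#' @export
interaction_cis <- function(x, method = c("delta", "bootstrap"), reps = 2000,
                            seed = NULL, level = 0.95) {
  method <- match.arg(method)
  stopifnot(inherits(x, "joint_table"))
  mi <- interaction_measures(x, level = level)
  n <- x$cases + x$controls
  if (method == "delta" && (any(x$cases == 0L) || any(x$cases == n))) {
    warning("zero-cell stratum: delta-method variances undefined; ",
            "falling back to bootstrap", call. = FALSE)
    method <- "bootstrap"
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (method == "delta") {
    rr <- mi$rr$rr
    v_ref <- 1 / x$cases[1] - 1 / n[1]
    v_own <- 1 / x$cases[2:4] - 1 / n[2:4]
    Sigma <- matrix(v_ref, 3, 3)
    diag(Sigma) <- v_own + v_ref
    grad_reri <- c(-rr[2], -rr[3], rr[4])
    se_reri <- sqrt(drop(t(grad_reri) %*% Sigma %*% grad_reri))
    grad_ap <- c(-rr[2], -rr[3], rr[2] + rr[3] - 1) / rr[4]
    se_ap <- sqrt(drop(t(grad_ap) %*% Sigma %*% grad_ap))
    out <- list(
      reri = c(estimate = mi$reri, lower = mi$reri - z * se_reri,
               upper = mi$reri + z * se_reri),
      ap = c(estimate = mi$ap, lower = mi$ap - z * se_ap,
             upper = mi$ap + z * se_ap))
    if (mi$s_defined && rr[4] > 1 && (rr[2] - 1) + (rr[3] - 1) > 0) {
      denom <- (rr[2] - 1) + (rr[3] - 1)
      grad_lns <- c(-rr[2] / denom, -rr[3] / denom, rr[4] / (rr[4] - 1))
      se_lns <- sqrt(drop(t(grad_lns) %*% Sigma %*% grad_lns))
      out$s <- c(estimate = mi$s, lower = mi$s * exp(-z * se_lns),
                 upper = mi$s * exp(z * se_lns))
    } else {
      out$s <- c(estimate = mi$s, lower = NA_real_, upper = NA_real_)
    }
    out$method <- "delta"
    return(out)
  }
  reps <- max(reps, 200L)
  if (!is.null(seed)) set.seed(seed)
  ncase <- sum(x$cases); nctrl <- sum(x$controls)
  case_draw <- stats::rmultinom(reps, ncase, x$cases / ncase)
  ctrl_draw <- stats::rmultinom(reps, nctrl, x$controls / nctrl)
  stat <- matrix(NA_real_, reps, 3, dimnames = list(NULL, c("reri", "ap", "s")))
  for (r in seq_len(reps)) {
    ca <- case_draw[, r]; co <- ctrl_draw[, r]
    nn <- ca + co
    if (ca[1] == 0L || co[1] == 0L || any(nn == 0L)) next
    risk <- ca / nn
    rr <- risk / risk[1]
    if (any(rr[2:4] <= 0)) next
    add <- additive_interaction(rr[2:4])
    stat[r, ] <- c(add$reri, add$ap, if (add$s_defined) add$s else NA_real_)
  }
  qs <- function(col) {
    v <- stat[, col]
    v <- v[is.finite(v)]
    stats::quantile(v, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  }
  list(reri = c(estimate = mi$reri, lower = qs("reri")[1], upper = qs("reri")[2]),
       ap = c(estimate = mi$ap, lower = qs("ap")[1], upper = qs("ap")[2]),
       s = c(estimate = mi$s, lower = qs("s")[1], upper = qs("s")[2]),
       method = "bootstrap", reps = reps)
}
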