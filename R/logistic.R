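# Logistic regression for crude and covariate-adjusted odds ratios, with
# separation detection and an optional Firth penalized refit.  The study's
# recruitment design (controls all family-history-negative) makes the family
# history covariate quasi-separated in any eczema-vs-control model, so the
# Firth path is not an edge case here.

#' Logistic regression fit on a cohort
#'
#' Maximum-likelihood logistic regression (IRLS, log-likelihood tolerance
#' 1e-10, at most 100 iterations) of a binary outcome on one or more coded
#' genetic exposures plus optional covariates.  With a sole binary exposure
#' and no covariates, `exp(coefficient)` equals the crude OR of the 2x2
#' table.
#'
#' Separation is flagged when any fitted probability lies within 1e-6 of 0 or
#' 1 while a coefficient diverges; with `firth = "auto"` (default) such fits
#' are redone with Firth's penalized likelihood, whose hat-diagonal score
#' correction keeps the estimates finite.  Constant model columns are dropped
#' with a warning.
#'
#' @param x A [cohort()].
#' @param outcome Logical subject column or predicate.
#' @param exposures A single exposure spec or (optionally named) list of
#'   specs; "genotype3" specs enter as 0/1/2 trend terms.
#' @param covariates Character vector among "age_months", "sex",
#'   "family_atopy" (sex coded male = 1).
#' @param population Subgroup filter.
#' @param firth "auto" (refit on separation), "never", or "always".
#' @param level Confidence level for the OR intervals.
#' @return An object of class `"logistic_fit"`: `coefficients` (term,
#'   estimate, se, z, p, or, ci), `converged`, `separation_flag`, `n_used`,
#'   `method` ("mle" or "firth"), `dropped` (constant columns removed).
#' @export
logistic_fit <- function(x, outcome, exposures, covariates = NULL,
                         population = NULL, firth = c("auto", "never", "always"),
                         level = 0.95) {
  firth <- match.arg(firth)
  keep <- population_filter(x, population)
  y <- outcome_values(x, outcome)
  if (inherits(exposures, "exposure_spec") || is.character(exposures)) {
    exposures <- list(exposures)
  }
  cols <- list()
  for (i in seq_along(exposures)) {
    spec <- as_exposure(exposures[[i]])
    nm <- if (!is.null(names(exposures)) && nzchar(names(exposures)[i])) {
      names(exposures)[i]
    } else exposure_label(spec)
    cols[[nm]] <- as.numeric(code_exposure(x, spec))
  }
  for (cv in covariates %||% character(0)) {
    cols[[cv]] <- switch(cv,
      age_months = x$subjects$age_months,
      sex = as.numeric(x$subjects$sex == "male"),
      family_atopy = as.numeric(x$subjects$family_atopy),
      {
        v <- x$subjects[[cv]]
        if (is.null(v)) stop("unknown covariate: ", cv, call. = FALSE)
        as.numeric(v)
      })
  }
  M <- do.call(cbind, cols)
  use <- keep & !is.na(y) & stats::complete.cases(M)
  M <- M[use, , drop = FALSE]
  yy <- as.numeric(y[use])
  if (length(unique(yy)) < 2L) {
    stop("outcome is constant in the analysed population", call. = FALSE)
  }
  const <- apply(M, 2, function(v) length(unique(v)) < 2L)
  if (any(const)) {
    warning("dropping constant model column(s): ",
            paste(colnames(M)[const], collapse = ", "), call. = FALSE)
  }
  M <- M[, !const, drop = FALSE]
  if (ncol(M) == 0L) stop("no non-constant model terms", call. = FALSE)
  X <- cbind(`(Intercept)` = 1, M)
  if (qr(X)$rank < ncol(X)) {
    stop("design matrix not full rank after dropping degenerate columns",
         call. = FALSE)
  }
  fit_logistic_matrix(X, yy, firth = firth, level = level,
                      dropped = colnames(M)[const])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Core fitter shared by logistic_fit() and interaction_term_test().
fit_logistic_matrix <- function(X, y, firth = "auto", level = 0.95,
                                dropped = character(0)) {
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  )
  beta <- fit$coefficients
  mu <- fit$fitted.values
  sep <- any(mu < 1e-6 | mu > 1 - 1e-6) && any(abs(beta[-1]) > 5)
  method <- "mle"
  if ((sep && firth == "auto") || firth == "always") {
    ff <- firth_logistic(X, y)
    beta <- ff$coef
    se <- ff$se
    method <- "firth"
    converged <- ff$converged
  } else {
    if (!fit$converged && !sep) {
      stop("logistic regression did not converge (no separation detected) ",
           "after ", fit$iter, " iterations", call. = FALSE)
    }
    w <- mu * (1 - mu)
    info <- crossprod(X, X * w)
    se <- sqrt(diag(solve(info)))
    converged <- fit$converged
  }
  z <- beta / se
  pvals <- 2 * stats::pnorm(-abs(z))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  coefs <- data.frame(
    term = colnames(X), estimate = unname(beta), se = unname(se),
    z = unname(z), p = unname(pvals), or = exp(unname(beta)),
    or_lower = exp(unname(beta - zq * se)),
    or_upper = exp(unname(beta + zq * se)),
    stringsAsFactors = FALSE
  )
  structure(list(coefficients = coefs, converged = converged,
                 separation_flag = sep, n_used = length(y), method = method,
                 level = level, dropped = dropped),
            class = "logistic_fit")
}

# Firth penalized logistic regression: Newton iteration on the modified score
# U*(beta) = X'(y - p + h (1/2 - p)), h the hat diagonal of the weighted
# design.  Finite estimates under complete or quasi-complete separation.
firth_logistic <- function(X, y, maxit = 100, tol = 1e-8) {
  beta <- numeric(ncol(X))
  converged <- FALSE
  for (it in seq_len(maxit)) {
    p <- stats::plogis(drop(X %*% beta))
    w <- pmax(p * (1 - p), .Machine$double.eps)
    XW <- X * w
    info <- crossprod(X, XW)
    info_inv <- solve(info)
    h <- rowSums((X %*% info_inv) * XW)
    U <- crossprod(X, y - p + h * (0.5 - p))
    step <- drop(info_inv %*% U)
    # dampen oversized steps for stability on small separated samples
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    beta <- beta + step
    if (max(abs(step)) < tol) {
      converged <- TRUE
      break
    }
  }
  p <- stats::plogis(drop(X %*% beta))
  info <- crossprod(X, X * pmax(p * (1 - p), .Machine$double.eps))
  list(coef = stats::setNames(beta, colnames(X)),
       se = sqrt(diag(solve(info))), converged = converged, iter = it)
}

#' @export
print.logistic_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Logistic regression (%s%s), n = %d\n", x$method,
              if (x$separation_flag) ", separation detected" else "",
              x$n_used))
  cf <- x$coefficients
  cf$or_ci <- sprintf("(%.2f - %.2f)", cf$or_lower, cf$or_upper)
  print(cbind(format(cf[, c("term", "estimate", "se", "p")], digits = digits),
              OR = sprintf("%.2f", cf$or), CI = cf$or_ci),
        row.names = FALSE)
  if (length(x$dropped) > 0) cat("dropped constant term(s):",
                                 paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}
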