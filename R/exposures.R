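# Exposure specifications: small S3 objects describing how a subject is coded
# as exposed/unexposed (or 0/1/2) for a given analysis.  Used by contingency
# tables, logistic fits, joint-genotype strata and biomarker predictors.

#' SNP exposure specification
#'
#' @param site_id Declared SNP site, e.g. "rs877776".
#' @param model Genetic model: "dominant" (carrier of >= 1 risk allele vs
#'   wild-type homozygote), "recessive" (risk homozygote vs rest) or
#'   "genotype3" (0/1/2 risk-allele count, the trend coding of the
#'   multiplicative model).
#' @return An `exposure_spec`.
#' @export
snp_exposure <- function(site_id, model = c("dominant", "recessive", "genotype3")) {
  model <- match.arg(model)
  structure(list(type = "snp", site = site_id, model = model),
            class = "exposure_spec")
}

#' Combined FLG genotype exposure (carrier of any null mutation)
#' @return An `exposure_spec`.
#' @export
flg_exposure <- function() {
  structure(list(type = "flg"), class = "exposure_spec")
}

#' Conjunction of two binary predictors
#'
#' A subject is exposed (predictor-positive) if and only if it is positive
#' under both component specifications; used e.g. for "risk-allele carrier AND
#' FLG mutation carrier" biomarkers.
#'
#' @param a,b Binary `exposure_spec`s.
#' @return An `exposure_spec`.
#' @export
combined_predictor <- function(a, b) {
  a <- as_exposure(a); b <- as_exposure(b)
  structure(list(type = "and", a = a, b = b), class = "exposure_spec")
}

as_exposure <- function(x) {
  if (inherits(x, "exposure_spec")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (x %in% c("flg", "flg_null")) return(flg_exposure())
    return(snp_exposure(x))
  }
  stop("cannot interpret exposure specification", call. = FALSE)
}

exposure_label <- function(spec) {
  spec <- as_exposure(spec)
  switch(spec$type,
    snp = paste0(spec$site, ":", spec$model),
    flg = "flg_null",
    and = paste0(exposure_label(spec$a), " & ", exposure_label(spec$b))
  )
}

#' @export
print.exposure_spec <- function(x, ...) {
  cat("<exposure>", exposure_label(x), "\n")
  invisible(x)
}

# Count of risk alleles (0/1/2) at a site, NA when the call is missing.
risk_allele_count <- function(x, site_id) {
  stopifnot(inherits(x, "cohort"))
  i <- match(site_id, x$sites$site_id)
  if (is.na(i)) stop("site not declared in cohort: ", site_id, call. = FALSE)
  g <- x$subjects[[site_id]]
  risk <- x$sites$risk_allele[i]
  (substr(g, 1, 1) == risk) + (substr(g, 2, 2) == risk)
}

#' Code subjects' exposure under a genetic model
#'
#' Vectorized over the cohort.  Missing genotype calls (or unknown FLG
#' status anywhere in a conjunction) yield NA, marking the subject for
#' complete-case exclusion from the analysis at hand -- never a silent 0.
#'
#' @param x A [cohort()].
#' @param spec An `exposure_spec`, or a bare site id (coded dominant), or
#'   "flg_null".
#' @param model Convenience: when `spec` is a bare site id, the genetic model
#'   to use.
#' @return Integer vector: 0/1 for dominant/recessive/conjunction specs,
#'   0/1/2 for "genotype3".  The allele (multiplicative) model is not a
#'   per-subject coding -- each subject contributes two allele-level
#'   observations -- and is handled by [allele_model()].
#' @export
code_exposure <- function(x, spec, model = NULL) {
  if (is.character(spec) && !is.null(model) && !(spec %in% c("flg", "flg_null"))) {
    spec <- snp_exposure(spec, model)
  }
  spec <- as_exposure(spec)
  switch(spec$type,
    snp = {
      cnt <- risk_allele_count(x, spec$site)
      switch(spec$model,
             dominant = as.integer(cnt >= 1L),
             recessive = as.integer(cnt == 2L),
             genotype3 = as.integer(cnt))
    },
    flg = as.integer(x$subjects$flg_null),
    and = {
      a <- code_exposure(x, spec$a)
      b <- code_exposure(x, spec$b)
      if (any(a > 1L, na.rm = TRUE) || any(b > 1L, na.rm = TRUE)) {
        stop("conjunction predictors require binary components", call. = FALSE)
      }
      as.integer(a == 1L & b == 1L)
    }
  )
}

#' Combined FLG genotype classification
#'
#' "null" for carriers of at least one of the four FLG loss-of-function
#' mutations (R501X, 2282del4, R2447X, S3247X), "normal" otherwise, NA when
#' carrier status is unknown.
#'
#' @param x A [cohort()].
#' @return Factor with levels "normal", "null".
#' @export
combined_flg <- function(x) {
  stopifnot(inherits(x, "cohort"))
  factor(ifelse(is.na(x$subjects$flg_null), NA,
                ifelse(x$subjects$flg_null, "null", "normal")),
         levels = c("normal", "null"))
}
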