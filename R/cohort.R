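# Subject/cohort data model and delimited-file IO.
#
# A cohort is a validated data.frame of children (one row each) plus a site
# table declaring, for every genotyped SNP, its reference and risk allele.
# Genotypes are stored as normalized two-letter strings with the reference
# allele first ("GG", "GC", "CC"), so unordered input ("CG", "C/G") compares
# equal after reading.

.SCORAD_LEVELS <- c("none", "mild", "moderate", "severe")
.SEX_LEVELS <- c("male", "female")
.PHENO_COLS <- c("family_atopy", "eczema", "asthma", "sensitized", "polysensitized")
.FLG_MUTATION_COLS <- c("flg_r501x", "flg_2282del4", "flg_r2447x", "flg_s3247x")

#' Default SNP site declarations
#'
#' Site table for the two epidermal differentiation complex SNPs analysed by
#' the package: HRNR rs877776 (reference G, risk C) and FLG2 rs12568784
#' (reference G, risk T).  Risk alleles are declared, never inferred from
#' sample frequencies.
#'
#' @return A data.frame with columns `site_id`, `ref_allele`, `risk_allele`.
#' @export
#' @examples
#' default_sites()
default_sites <- function() {
  data.frame(
    site_id = c("rs877776", "rs12568784"),
    ref_allele = c("G", "G"),
    risk_allele = c("C", "T"),
    stringsAsFactors = FALSE
  )
}

#' Default column schema for cohort files
#'
#' Named character vector mapping canonical subject fields to the column names
#' expected in a delimited input file.  Override entries to adapt foreign
#' files, e.g. `c(default_schema(), age_months = "age_mo")`.
#'
#' @param sites Site table (see [default_sites()]); genotype columns are named
#'   after `site_id`.
#' @return Named character vector, canonical name -> file column name.
#' @export
default_schema <- function(sites = default_sites()) {
  canonical <- c(
    "subject_id", "age_months", "sex", .PHENO_COLS,
    "scorad_class", "total_ige_iu_ml", sites$site_id, "flg_null"
  )
  stats::setNames(canonical, canonical)
}

#' Construct a validated cohort
#'
#' @param subjects A data.frame with one row per child.  Required columns:
#'   `subject_id`, `age_months`, `sex` ("male"/"female"), `family_atopy`,
#'   `eczema`, `scorad_class` ("none"/"mild"/"moderate"/"severe"), `asthma`,
#'   `sensitized`, `polysensitized` (logicals), one character genotype column
#'   per declared site, and `flg_null` (logical; carrier of any of the four
#'   FLG loss-of-function mutations R501X, 2282del4, R2447X, S3247X).
#'   Optional: `total_ige_iu_ml` (positive or NA).
#' @param sites Site declarations, see [default_sites()].
#' @param provenance Free-text description of where the data came from.
#'
#' @details Enforced subject invariants (violations are reported with row
#'   indices): polysensitized implies sensitized; a SCORAD class other than
#'   "none" implies eczema; asthma implies eczema (by recruitment design all
#'   asthma occurs in eczema cases); subjects without eczema (the control
#'   group) have a negative family history of atopy; ages are non-negative;
#'   total IgE, when present, is positive; subject ids are unique.  Missing
#'   genotypes (NA) are allowed: the subject stays in the cohort and is
#'   excluded per-analysis from statistics that need that site.
#'
#' @return An object of class `"cohort"`: a list with elements `subjects`,
#'   `sites`, `provenance`.
#' @seealso [read_cohort()], [summarize_cohort()]
#' @export
cohort <- function(subjects, sites = default_sites(), provenance = "") {
  stopifnot(is.data.frame(subjects), is.data.frame(sites))
  required <- c("subject_id", "age_months", "sex", .PHENO_COLS, "scorad_class",
                sites$site_id, "flg_null")
  missing_cols <- setdiff(required, names(subjects))
  if (length(missing_cols) > 0L) {
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"total_ige_iu_ml" %in% names(subjects)) subjects$total_ige_iu_ml <- NA_real_
  subjects$subject_id <- as.character(subjects$subject_id)
  subjects$age_months <- as.numeric(subjects$age_months)
  subjects$total_ige_iu_ml <- as.numeric(subjects$total_ige_iu_ml)
  for (col in .PHENO_COLS) subjects[[col]] <- as.logical(subjects[[col]])
  subjects$flg_null <- as.logical(subjects$flg_null)
  for (sid in sites$site_id) {
    subjects[[sid]] <- normalize_genotypes(subjects[[sid]],
                                           sites$ref_allele[sites$site_id == sid],
                                           sites$risk_allele[sites$site_id == sid],
                                           site_id = sid)
  }
  problems <- validate_subjects(subjects)
  if (length(problems) > 0L) {
    stop("invalid subject rows:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  canonical <- c("subject_id", "age_months", "sex", "family_atopy", "eczema",
                 "scorad_class", "asthma", "sensitized", "polysensitized",
                 "total_ige_iu_ml", sites$site_id, "flg_null")
  subjects <- subjects[, c(canonical, setdiff(names(subjects), canonical)),
                       drop = FALSE]
  rownames(subjects) <- NULL
  structure(list(subjects = subjects, sites = sites, provenance = provenance),
            class = "cohort")
}

# Row-indexed invariant diagnostics; returns character(0) when clean.
validate_subjects <- function(s) {
  problems <- character(0)
  note <- function(rows, msg) {
    if (any(rows, na.rm = TRUE)) {
      problems <<- c(problems,
                     sprintf("row %s: %s", paste(which(rows), collapse = ","), msg))
    }
    invisible(NULL)
  }
  dup <- duplicated(s$subject_id)
  note(dup, "duplicate subject_id")
  note(is.na(s$age_months) | s$age_months < 0, "age_months must be non-negative")
  note(!(s$sex %in% .SEX_LEVELS), "sex must be 'male' or 'female'")
  note(!(s$scorad_class %in% .SCORAD_LEVELS),
       "scorad_class must be one of none/mild/moderate/severe")
  core <- .PHENO_COLS
  for (col in core) note(is.na(s[[col]]), paste0(col, " must be TRUE/FALSE"))
  ok <- !Reduce(`|`, lapply(core, function(col) is.na(s[[col]])))
  note(ok & s$polysensitized & !s$sensitized,
       "polysensitized implies sensitized")
  note(ok & s$scorad_class != "none" & !s$eczema,
       "scorad_class other than 'none' requires eczema")
  note(ok & s$asthma & !s$eczema, "asthma implies eczema (study design)")
  note(ok & !s$eczema & s$family_atopy,
       "controls must have family_atopy = FALSE (recruitment criterion)")
  note(!is.na(s$total_ige_iu_ml) & s$total_ige_iu_ml <= 0,
       "total_ige_iu_ml must be positive")
  problems
}

# Normalize genotype strings to risk-allele-count canonical form ("GG","GC","CC").
# Accepts "GC", "G/C", "c g", NA; errors name the offending values and rows.
normalize_genotypes <- function(x, ref, risk, site_id = "site") {
  x <- as.character(x)
  cleaned <- toupper(gsub("[/| ]", "", x))
  cleaned[!is.na(cleaned) & cleaned %in% c("", "NA", ".")] <- NA_character_
  out <- rep(NA_character_, length(cleaned))
  idx <- which(!is.na(cleaned))
  if (length(idx) > 0L) {
    g <- cleaned[idx]
    bad <- nchar(g) != 2L |
      !(substr(g, 1, 1) %in% c(ref, risk)) |
      !(substr(g, 2, 2) %in% c(ref, risk))
    if (any(bad)) {
      stop(sprintf("unparseable genotype at %s, row %s: %s (alleles must be %s/%s)",
                   site_id,
                   paste(idx[bad], collapse = ","),
                   paste(unique(x[idx[bad]]), collapse = ", "),
                   ref, risk), call. = FALSE)
    }
    n_risk <- (substr(g, 1, 1) == risk) + (substr(g, 2, 2) == risk)
    out[idx] <- paste0(strrep(ref, 2L - n_risk), strrep(risk, n_risk))
  }
  out
}

#' @export
print.cohort <- function(x, ...) {
  s <- x$subjects
  cat(sprintf("<cohort> %d subjects (%d eczema cases, %d controls)\n",
              nrow(s), sum(s$eczema), sum(!s$eczema)))
  cat("sites:", paste(sprintf("%s [%s>%s]", x$sites$site_id,
                              x$sites$ref_allele, x$sites$risk_allele),
                      collapse = ", "), "\n")
  if (nzchar(x$provenance)) cat("provenance:", x$provenance, "\n")
  invisible(x)
}

#' Number of subjects in a cohort
#' @param x A cohort.
#' @export
nsubjects <- function(x) nrow(x$subjects)

# Subset a cohort by a logical row index, keeping site metadata.
cohort_subset <- function(x, keep) {
  stopifnot(inherits(x, "cohort"), is.logical(keep), length(keep) == nsubjects(x))
  out <- x
  out$subjects <- x$subjects[which(keep), , drop = FALSE]
  rownames(out$subjects) <- NULL
  out
}

#' Read a cohort from a delimited file
#'
#' Reads a CSV/TSV file with a header row, renames columns through `schema`,
#' parses logicals ("TRUE"/"1"/"yes" etc.), normalizes genotype strings
#' ("GC" and "G/C" and "CG" all become the same unordered pair) and validates
#' every subject invariant.  Rows violating an invariant are rejected with
#' row-indexed diagnostics naming the invariant.
#'
#' FLG carrier status may arrive either as a single logical `flg_null` column
#' or as four per-mutation logical columns (`flg_r501x`, `flg_2282del4`,
#' `flg_r2447x`, `flg_s3247x`), which are combined by "carrier of at least
#' one".
#'
#' @param path File path; `sep` is inferred from the extension (".csv" ->
#'   comma, otherwise tab) unless given.
#' @param sites Site declarations ([default_sites()]).
#' @param schema Canonical-to-file column name mapping ([default_schema()]).
#' @param sep Field separator override.
#' @param provenance Free text recorded on the cohort.
#' @return A validated [cohort()].
#' @export
read_cohort <- function(path, sites = default_sites(),
                        schema = default_schema(sites), sep = NULL,
                        provenance = path) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  needed <- schema[setdiff(names(schema), c("total_ige_iu_ml", "flg_null"))]
  have_flg_cols <- all(.FLG_MUTATION_COLS %in% names(raw))
  flg_col <- unname(schema["flg_null"])
  if (is.na(flg_col)) flg_col <- "flg_null"
  if (!(flg_col %in% names(raw)) && !have_flg_cols) {
    stop("schema error: no FLG carrier column ('", flg_col,
         "') and no per-mutation columns (",
         paste(.FLG_MUTATION_COLS, collapse = ", "), ") in ", path, call. = FALSE)
  }
  needed <- needed[setdiff(names(needed), "flg_null")]
  absent <- needed[!(needed %in% names(raw))]
  if (length(absent) > 0L) {
    stop("schema error: required column(s) not found in ", path, ": ",
         paste(sprintf("%s (as %s)", absent, names(absent)), collapse = ", "),
         call. = FALSE)
  }
  s <- data.frame(subject_id = raw[[needed["subject_id"]]],
                  stringsAsFactors = FALSE)
  s$age_months <- as.numeric(raw[[needed["age_months"]]])
  s$sex <- tolower(raw[[needed["sex"]]])
  s$sex[s$sex %in% c("m")] <- "male"
  s$sex[s$sex %in% c("f")] <- "female"
  for (col in .PHENO_COLS) s[[col]] <- parse_logical(raw[[needed[col]]], col)
  s$scorad_class <- tolower(raw[[needed["scorad_class"]]])
  ige_col <- unname(schema["total_ige_iu_ml"])
  s$total_ige_iu_ml <- if (!is.na(ige_col) && ige_col %in% names(raw)) {
    suppressWarnings(as.numeric(raw[[ige_col]]))
  } else NA_real_
  for (sid in sites$site_id) s[[sid]] <- raw[[needed[sid]]]
  s$flg_null <- if (flg_col %in% names(raw)) {
    parse_logical(raw[[flg_col]], "flg_null")
  } else {
    muts <- lapply(.FLG_MUTATION_COLS, function(col) parse_logical(raw[[col]], col))
    Reduce(`|`, muts)
  }
  cohort(s, sites = sites, provenance = provenance)
}

parse_logical <- function(x, col) {
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("true", "t", "1", "yes", "y")] <- TRUE
  out[v %in% c("false", "f", "0", "no", "n")] <- FALSE
  bad <- !is.na(v) & !(v %in% c("true", "t", "1", "yes", "y",
                                "false", "f", "0", "no", "n", "na", ""))
  if (any(bad)) {
    stop(sprintf("column %s: unparseable logical value(s) at row %s: %s",
                 col, paste(which(bad), collapse = ","),
                 paste(unique(v[bad]), collapse = ", ")), call. = FALSE)
  }
  out
}

#' Write a cohort to a delimited file
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(x, f))` reproduces
#' `x`.  Genotypes are written as "G/C" pairs; tab-separated unless the path
#' ends in ".csv".
#'
#' @param x A cohort.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "cohort"))
  s <- x$subjects
  for (sid in x$sites$site_id) {
    g <- s[[sid]]
    s[[sid]] <- ifelse(is.na(g), NA,
                       paste(substr(g, 1, 1), substr(g, 2, 2), sep = "/"))
  }
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(s, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

# Resolve a population filter to a logical vector over subjects.
# Accepted: NULL/"all" (everyone), "eczema" (cases), "controls" (no eczema),
# "asthma" (eczema-associated asthma cases), "asthma_or_control"
# (asthma cases plus healthy controls), or a function(subjects) -> logical.
population_filter <- function(x, population) {
  s <- x$subjects
  if (is.null(population)) return(rep(TRUE, nrow(s)))
  if (is.function(population)) {
    keep <- population(s)
    stopifnot(is.logical(keep), length(keep) == nrow(s))
    return(keep & !is.na(keep))
  }
  stopifnot(is.character(population), length(population) == 1L)
  switch(population,
    all = rep(TRUE, nrow(s)),
    eczema = s$eczema,
    controls = !s$eczema,
    asthma = s$asthma,
    asthma_or_control = s$asthma | !s$eczema,
    stop("unknown population filter: ", population, call. = FALSE)
  )
}

# Resolve an outcome spec to a logical vector: a logical subject column name
# or a function(subjects) -> logical.
outcome_values <- function(x, outcome) {
  s <- x$subjects
  if (is.function(outcome)) {
    y <- outcome(s)
  } else {
    stopifnot(is.character(outcome), length(outcome) == 1L)
    if (!outcome %in% names(s)) stop("unknown outcome column: ", outcome, call. = FALSE)
    y <- s[[outcome]]
  }
  stopifnot(is.logical(y), length(y) == nrow(s))
  y
}
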