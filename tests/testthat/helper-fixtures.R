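# Fixture cohorts built in code.

# Minimal valid subject rows; override any column via ...
make_subjects <- function(n, ...) {
  s <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    age_months = rep(12, n),
    sex = rep("male", n),
    family_atopy = rep(FALSE, n),
    eczema = rep(FALSE, n),
    scorad_class = rep("none", n),
    asthma = rep(FALSE, n),
    sensitized = rep(FALSE, n),
    polysensitized = rep(FALSE, n),
    total_ige_iu_ml = rep(NA_real_, n),
    rs877776 = rep("GG", n),
    rs12568784 = rep("GG", n),
    flg_null = rep(FALSE, n),
    stringsAsFactors = FALSE
  )
  over <- list(...)
  for (nm in names(over)) s[[nm]] <- over[[nm]]
  s
}

# Cohort realizing a 2x2 exposure-outcome table via dominant rs877776 carriage
# and the eczema outcome: a/b carriers ("GC"), c/d wild type.
cohort_from_table <- function(a, b, c, d) {
  n <- a + b + c + d
  geno <- c(rep("GC", a + b), rep("GG", c + d))
  ecz <- c(rep(TRUE, a), rep(FALSE, b), rep(TRUE, c), rep(FALSE, d))
  scorad <- ifelse(ecz, "mild", "none")
  cohort(make_subjects(n, rs877776 = geno, eczema = ecz, scorad_class = scorad))
}

# Cohort reproducing the published marginal genotype, FLG, severity and
# asthma distributions (Tables 1-3).  Genotypes at the two SNPs are assigned
# independently row-wise, which preserves every marginal count the summary
# and single-site association tests assert (joint-genotype analyses use
# count-level constructors instead).
make_study_like_cohort <- function() {
  expand_geno <- function(counts, ref, risk) {
    c(rep(paste0(ref, ref), counts[1]), rep(paste0(ref, risk), counts[2]),
      rep(paste0(risk, risk), counts[3]))
  }
  # cases: n = 103; HRNR 60/37/6, FLG2 74/20/9, FLG null 14,
  # severity 60 mild / 43 moderate, asthma 28.
  hrnr_case <- expand_geno(c(60, 37, 6), "G", "C")
  flg2_case <- expand_geno(c(74, 20, 9), "G", "T")
  # Table 2B: asthma 17 of 43 HRNR carriers, 11 of 60 GG -> order asthma
  # within carrier class; HRNR is laid out GG first, so place asthma cases
  # at the head of each genotype class.
  hrnr_dom <- hrnr_case != "GG"
  asthma <- logical(103)
  asthma[head(which(!hrnr_dom), 11)] <- TRUE
  asthma[head(which(hrnr_dom), 17)] <- TRUE
  # Table 3B needs 15 asthma among 29 FLG2 carriers: align FLG2 assignment to
  # the asthma vector rather than genotype order.
  flg2_dom_target <- logical(103)
  flg2_dom_target[head(which(asthma), 15)] <- TRUE
  flg2_dom_target[head(which(!asthma), 29 - 15)] <- TRUE
  flg2_sorted <- c(sort(flg2_case[flg2_case != "GG"]), flg2_case[flg2_case == "GG"])
  flg2 <- character(103)
  flg2[flg2_dom_target] <- flg2_sorted[seq_len(29)]
  flg2[!flg2_dom_target] <- flg2_sorted[-seq_len(29)]
  # severity: Table 2A mild HRNR split 34 GG / 26 carriers; Table 3A mild
  # FLG2 split 50 GG / 10 carriers -- satisfiable only marginally per site;
  # severity tests pin the FLG2 split, so assign severity against FLG2.
  scorad <- character(103)
  flg2_dom <- flg2 != "GG"
  scorad[head(which(flg2_dom), 19)] <- "moderate"
  scorad[head(which(!flg2_dom), 24)] <- "moderate"
  scorad[scorad == ""] <- "mild"
  flg_null_case <- logical(103)
  flg_null_case[head(which(!asthma), 14)] <- TRUE
  cases <- make_subjects(103,
    subject_id = sprintf("CASE%03d", 1:103),
    eczema = TRUE, scorad_class = scorad, asthma = asthma,
    family_atopy = c(rep(TRUE, 57), rep(FALSE, 46)),
    sensitized = c(rep(TRUE, 55), rep(FALSE, 48)),
    polysensitized = c(rep(TRUE, 19), rep(FALSE, 84)),
    rs877776 = hrnr_case, rs12568784 = flg2,
    flg_null = flg_null_case)
  # controls: n = 85; HRNR 66/15/4, FLG2 72/8/5, FLG null 2, sensitized 11.
  controls <- make_subjects(85,
    subject_id = sprintf("CTRL%03d", 1:85),
    rs877776 = expand_geno(c(66, 15, 4), "G", "C"),
    rs12568784 = expand_geno(c(72, 8, 5), "G", "T"),
    sensitized = c(rep(TRUE, 11), rep(FALSE, 74)),
    flg_null = c(rep(TRUE, 2), rep(FALSE, 83)))
  cohort(rbind(cases, controls), provenance = "synthetic study-like fixture")
}

# Cohort realizing published joint-genotype stratum counts for one SNP
# crossed with the combined FLG genotype: eczema cases split over the four
# strata (S-F-, S+F-, S-F+, S+F+), an asthma subset nested per stratum, and
# healthy controls.
make_joint_cohort <- function(site, case_strata, asthma_strata, control_strata) {
  stopifnot(all(asthma_strata <= case_strata))
  strat_geno <- function(k) c("GG", if (site == "rs12568784") "GT" else "GC")[k]
  one_group <- function(strata, eczema, asthma_counts = NULL) {
    rows <- list()
    for (i in 1:4) {
      n <- strata[i]
      if (n == 0L) next
      carrier <- i %in% c(2L, 4L)
      flg <- i %in% c(3L, 4L)
      asth <- if (is.null(asthma_counts)) rep(FALSE, n) else {
        c(rep(TRUE, asthma_counts[i]), rep(FALSE, n - asthma_counts[i]))
      }
      df <- make_subjects(n, eczema = rep(eczema, n),
                          scorad_class = rep(if (eczema) "mild" else "none", n),
                          asthma = asth,
                          flg_null = rep(flg, n))
      df[[site]] <- rep(strat_geno(1L + carrier), n)
      rows[[length(rows) + 1L]] <- df
    }
    do.call(rbind, rows)
  }
  cases <- one_group(case_strata, TRUE, asthma_strata)
  ctrls <- one_group(control_strata, FALSE)
  all_rows <- rbind(cases, ctrls)
  all_rows$subject_id <- sprintf("J%03d", seq_len(nrow(all_rows)))
  cohort(all_rows, provenance = "synthetic joint-genotype fixture")
}

# FLG2 rs12568784 x combined FLG blocks of the published Tables 5-6.
make_flg2_flg_cohort <- function() {
  make_joint_cohort("rs12568784",
                    case_strata = c(71, 18, 3, 11),
                    asthma_strata = c(10, 12, 3, 3),
                    control_strata = c(70, 13, 2, 0))
}

# HRNR rs877776 x combined FLG blocks of the published Tables 5-6.
make_hrnr_flg_cohort <- function() {
  make_joint_cohort("rs877776",
                    case_strata = c(52, 37, 8, 6),
                    asthma_strata = c(10, 12, 2, 4),
                    control_strata = c(64, 19, 2, 0))
}
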