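# Synthetic case-control cohort generator.
#
# Genotypes are drawn under Hardy-Weinberg equilibrium at configurable risk
# allele frequencies; eczema follows a logistic population model on coded
# exposures (with optional pairwise interaction log-odds, or a direct
# "risk-table" mode for exact additive-scale scenarios); case-control accrual
# is rejection sampling against the recruitment design: asthma is assigned
# only within eczema cases, and controls are family-history-negative.

#' Disease model on the log-odds scale
#'
#' @param intercept Baseline log-odds (log-odds of disease for a subject with
#'   every coded exposure at 0).
#' @param effects Named list, one entry per exposure ("rs877776",
#'   "rs12568784", "flg_null", or -- in the sensitization model -- "eczema"),
#'   each `list(coding =, beta =)` with coding "dominant" (carrier
#'   indicator) or "count" (risk-allele count).
#' @param interactions Optional list of `list(a =, b =, beta =)` pairwise
#'   product terms between the dominant/count codings of two exposures.
#' @return A `disease_model`.
#' @export
disease_model <- function(intercept, effects = list(), interactions = list()) {
  for (e in effects) stopifnot(e$coding %in% c("dominant", "count"),
                               is.numeric(e$beta))
  structure(list(type = "logistic", intercept = intercept, effects = effects,
                 interactions = interactions),
            class = "disease_model")
}

#' Risk-table disease model
#'
#' Specifies the disease probability directly for the four joint strata of
#' two dominant-coded factors, so additive-scale interaction targets (an
#' exact population RERI) can be hit exactly -- a logistic model cannot.
#'
#' @param factors Length-2 character: the two exposures ("rs..." site ids or
#'   "flg_null"), dominant-coded.
#' @param risks 2x2 numeric matrix of disease probabilities,
#'   `risks[a + 1, b + 1]` for factor levels a, b in 0/1.
#' @return A `disease_model` of type "risk_table".
#' @export
risk_table_model <- function(factors, risks) {
  risks <- as.matrix(risks)
  stopifnot(length(factors) == 2L, all(dim(risks) == c(2L, 2L)),
            all(risks >= 0 & risks <= 1))
  structure(list(type = "risk_table", factors = factors, risks = risks),
            class = "disease_model")
}

#' Simulation configuration
#'
#' Defaults emulate the study conditions: 103 eczema cases and 85 healthy
#' controls under 2 years of age; risk-allele frequencies estimated from the
#' control alleles (HRNR rs877776 C 0.135, FLG2 rs12568784 T 0.106);
#' disease-model log-odds matching the crude dominant odds ratios; asthma
#' generated only among eczema cases; controls family-history-negative.
#'
#' @param seed Integer RNG seed (mandatory: identical configs give
#'   byte-identical cohorts).
#' @param n_cases,n_controls Accrual quotas (positive).
#' @param allele_freq Named risk-allele frequencies in `[0, 1]` per site.
#' @param flg_null_freq Population carrier probability of any FLG null
#'   mutation.
#' @param eczema_model,asthma_model,sensitization_model [disease_model()]s;
#'   `asthma_model` is conditional on eczema.
#' @param sites Site declarations ([default_sites()]).
#' @param age_mean,age_sd,age_range Age distribution in months, truncated
#'   normal on `age_range` (recruitment below 2 years).
#' @param p_male Probability of male sex.
#' @param p_family_atopy_case Family-history probability among cases
#'   (controls are negative by design).
#' @param p_moderate Probability a case is moderate rather than mild SCORAD.
#' @param p_poly_given_sens Probability a sensitized child is polysensitized.
#' @param ige_meanlog Named (case, control) log-scale means of the lognormal
#'   total IgE.
#' @param ige_sdlog Lognormal log-scale SD.
#' @param max_draws Rejection-sampling attempt cap.
#' @return A `sim_config`.
#' @export
sim_config <- function(seed,
                       n_cases = 103L, n_controls = 85L,
                       allele_freq = c(rs877776 = 0.135, rs12568784 = 0.106),
                       flg_null_freq = 0.03,
                       eczema_model = disease_model(
                         intercept = -2.0,
                         effects = list(
                           rs877776 = list(coding = "dominant", beta = log(2.49)),
                           rs12568784 = list(coding = "dominant", beta = log(2.17)),
                           flg_null = list(coding = "dominant", beta = log(6.53)))),
                       asthma_model = disease_model(
                         intercept = -2.2,
                         effects = list(
                           rs877776 = list(coding = "dominant", beta = log(2.91)),
                           rs12568784 = list(coding = "dominant", beta = log(5.03)),
                           flg_null = list(coding = "dominant", beta = log(3.0)))),
                       sensitization_model = disease_model(
                         intercept = -2.1,
                         effects = list(
                           eczema = list(coding = "dominant", beta = log(6.0)),
                           rs877776 = list(coding = "dominant", beta = log(1.5)),
                           rs12568784 = list(coding = "dominant", beta = log(2.0)),
                           flg_null = list(coding = "dominant", beta = log(1.5)))),
                       sites = default_sites(),
                       age_mean = 14.5, age_sd = 6.0, age_range = c(0, 24),
                       p_male = 0.569,
                       p_family_atopy_case = 0.553,
                       p_moderate = 0.417,
                       p_poly_given_sens = 0.288,
                       ige_meanlog = c(case = log(24.6), control = log(17.7)),
                       ige_sdlog = 1.1,
                       max_draws = 1e7) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            n_cases > 0, n_controls > 0,
            all(allele_freq >= 0 & allele_freq <= 1),
            flg_null_freq >= 0 && flg_null_freq <= 1,
            all(names(allele_freq) %in% sites$site_id),
            all(sites$site_id %in% names(allele_freq)))
  for (m in list(eczema_model, asthma_model, sensitization_model)) {
    stopifnot(inherits(m, "disease_model"))
    refs <- if (m$type == "logistic") {
      c(names(m$effects),
        unlist(lapply(m$interactions, function(i) c(i$a, i$b))))
    } else m$factors
    bad <- setdiff(refs, c(sites$site_id, "flg_null", "eczema"))
    if (length(bad) > 0L) {
      stop("disease model references undeclared exposure(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(seed = as.integer(seed), n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 allele_freq = allele_freq, flg_null_freq = flg_null_freq,
                 eczema_model = eczema_model, asthma_model = asthma_model,
                 sensitization_model = sensitization_model, sites = sites,
                 age_mean = age_mean, age_sd = age_sd, age_range = age_range,
                 p_male = p_male, p_family_atopy_case = p_family_atopy_case,
                 p_moderate = p_moderate,
                 p_poly_given_sens = p_poly_given_sens,
                 ige_meanlog = ige_meanlog, ige_sdlog = ige_sdlog,
                 max_draws = max_draws),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> seed %d, quotas %d cases / %d controls\n",
              x$seed, x$n_cases, x$n_controls))
  cat("risk allele freq:",
      paste(sprintf("%s %.3f", names(x$allele_freq), x$allele_freq),
            collapse = ", "),
      sprintf("; FLG null carrier %.3f\n", x$flg_null_freq))
  invisible(x)
}

hwe_genotype_probs <- function(q) c((1 - q)^2, 2 * q * (1 - q), q^2)

#' Simulate genotype calls under Hardy-Weinberg equilibrium
#'
#' Draws n genotypes with class probabilities ((1-q)^2, 2q(1-q), q^2) for
#' risk-allele frequency q.
#'
#' @param freq Risk-allele frequency in `[0, 1]`.
#' @param n Number of calls.
#' @param ref,risk Allele symbols used to render the calls.
#' @param seed Optional seed (set when the call is used stand-alone; inside
#'   [simulate_cohort()] the config seed governs the stream).
#' @return Character vector of normalized genotype strings ("GG"/"GC"/"CC").
#' @export
simulate_genotypes <- function(freq, n, ref = "G", risk = "C", seed = NULL) {
  if (is.na(freq) || freq < 0 || freq > 1) {
    stop("allele frequency must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  cnt <- sample.int(3L, n, replace = TRUE, prob = hwe_genotype_probs(freq)) - 1L
  paste0(strrep(ref, 2L - cnt), strrep(risk, cnt))
}

# Disease probability for a chunk of draws.
# geno: integer matrix of risk-allele counts, one column per site; flg: 0/1;
# eczema (0/1) only meaningful for the sensitization model.
model_prob <- function(model, geno, flg, eczema = NULL) {
  coded <- function(name, coding) {
    v <- if (name == "flg_null") flg
         else if (name == "eczema") {
           if (is.null(eczema)) stop("model references eczema before it is drawn",
                                     call. = FALSE)
           eczema
         } else geno[, name]
    if (coding == "dominant") as.numeric(v >= 1L) else as.numeric(v)
  }
  if (model$type == "risk_table") {
    a <- coded(model$factors[1], "dominant")
    b <- coded(model$factors[2], "dominant")
    return(model$risks[cbind(a + 1L, b + 1L)])
  }
  eta <- rep(model$intercept, nrow(geno))
  for (nm in names(model$effects)) {
    e <- model$effects[[nm]]
    eta <- eta + e$beta * coded(nm, e$coding)
  }
  for (ia in model$interactions) {
    eta <- eta + ia$beta * coded(ia$a, "dominant") * coded(ia$b, "dominant")
  }
  stats::plogis(eta)
}

rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Simulate a case-control cohort
#'
#' Subjects are drawn from the population model and retained until the case
#' and control quotas are met: a draw becomes a case when the eczema model
#' fires, and a control otherwise (controls are given a negative family
#' history, matching the recruitment criterion, and can have neither eczema
#' nor asthma).  Asthma, SCORAD class, family history and total IgE are then
#' assigned to cases; sensitization is generated for everyone from its own
#' model.  Identical configs (including seed) produce identical cohorts.
#'
#' @param config A [sim_config()].
#' @return A validated [cohort()]; cases first, then controls.
#' @export
#' @examples
#' coh <- simulate_cohort(sim_config(seed = 1, n_cases = 50, n_controls = 50))
#' summarize_cohort(coh)
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  site_ids <- config$sites$site_id
  need_case <- config$n_cases
  need_ctrl <- config$n_controls
  acc_geno <- list(); acc_flg <- list(); acc_case <- list()
  drawn <- 0
  while (need_case > 0L || need_ctrl > 0L) {
    if (drawn >= config$max_draws) {
      stop(sprintf(paste0("accrual quota unreachable: %d case(s) and %d ",
                          "control(s) still needed after %g draws -- check ",
                          "the disease model intercepts"),
                   need_case, need_ctrl, drawn), call. = FALSE)
    }
    m <- as.integer(min(max(1000L, 4L * (need_case + need_ctrl)),
                        config$max_draws - drawn))
    drawn <- drawn + m
    geno <- vapply(site_ids, function(sid) {
      q <- config$allele_freq[[sid]]
      sample.int(3L, m, replace = TRUE, prob = hwe_genotype_probs(q)) - 1L
    }, integer(m))
    colnames(geno) <- site_ids
    flg <- stats::rbinom(m, 1L, config$flg_null_freq)
    p <- model_prob(config$eczema_model, geno, flg)
    is_case <- stats::runif(m) < p
    take_case <- utils::head(which(is_case), need_case)
    take_ctrl <- utils::head(which(!is_case), need_ctrl)
    need_case <- need_case - length(take_case)
    need_ctrl <- need_ctrl - length(take_ctrl)
    sel <- c(take_case, take_ctrl)
    if (length(sel) > 0L) {
      acc_geno[[length(acc_geno) + 1L]] <- geno[sel, , drop = FALSE]
      acc_flg[[length(acc_flg) + 1L]] <- flg[sel]
      acc_case[[length(acc_case) + 1L]] <- is_case[sel]
    }
  }
  geno <- do.call(rbind, acc_geno)
  flg <- unlist(acc_flg)
  is_case <- unlist(acc_case)
  ord <- order(!is_case)  # cases first, stable
  geno <- geno[ord, , drop = FALSE]; flg <- flg[ord]; is_case <- is_case[ord]
  n <- length(is_case)
  s <- data.frame(subject_id = sprintf("S%05d", seq_len(n)),
                  stringsAsFactors = FALSE)
  s$age_months <- rtruncnorm(n, config$age_mean, config$age_sd,
                             config$age_range[1], config$age_range[2])
  s$sex <- ifelse(stats::runif(n) < config$p_male, "male", "female")
  s$eczema <- is_case
  s$family_atopy <- is_case & (stats::runif(n) < config$p_family_atopy_case)
  s$asthma <- rep(FALSE, n)
  if (any(is_case)) {
    p_asthma <- model_prob(config$asthma_model,
                           geno[is_case, , drop = FALSE], flg[is_case])
    s$asthma[is_case] <- stats::runif(sum(is_case)) < p_asthma
  }
  s$scorad_class <- rep("none", n)
  s$scorad_class[is_case] <- ifelse(
    stats::runif(sum(is_case)) < config$p_moderate, "moderate", "mild")
  p_sens <- model_prob(config$sensitization_model, geno, flg,
                       eczema = as.numeric(is_case))
  s$sensitized <- stats::runif(n) < p_sens
  s$polysensitized <- s$sensitized &
    (stats::runif(n) < config$p_poly_given_sens)
  meanlog <- ifelse(is_case, config$ige_meanlog[["case"]],
                    config$ige_meanlog[["control"]])
  s$total_ige_iu_ml <- stats::rlnorm(n, meanlog, config$ige_sdlog)
  for (i in seq_along(site_ids)) {
    sid <- site_ids[i]
    ref <- config$sites$ref_allele[i]; risk <- config$sites$risk_allele[i]
    cnt <- geno[, sid]
    s[[sid]] <- paste0(strrep(ref, 2L - cnt), strrep(risk, cnt))
  }
  s$flg_null <- flg == 1L
  cohort(s, sites = config$sites,
         provenance = sprintf("simulated (seed %d)", config$seed))
}
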