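# Configuration-driven pipeline: cohort summary -> Hardy-Weinberg ->
# associations (crude, adjusted, stratified, severity) -> gene-gene
# interaction -> biomarker prediction, with TSV/JSON emission and a manifest.

#' Analysis configuration
#'
#' @param input Path to a cohort file, or NULL to simulate.
#' @param simulate A [sim_config()] (required when `input` is NULL).
#' @param sites Site declarations.
#' @param level Confidence level used throughout.
#' @param seed Seed for stochastic steps (bootstrap); mandatory when any is
#'   enabled.
#' @param interaction_pairs List of character pairs naming exposures
#'   ("rs..." site id, coded dominant, or "flg_null") to cross.
#' @param predictors Named list of predictor exposure specs for the biomarker
#'   stage.
#' @param outcomes Character outcomes analysed genome-wide ("eczema" plus
#'   within-population asthma/sensitization analyses are fixed by the roster).
#' @return An `analysis_config`.
#' @export
analysis_config <- function(input = NULL, simulate = NULL,
                            sites = default_sites(), level = 0.95,
                            seed = NULL,
                            interaction_pairs = list(
                              c("rs877776", "flg_null"),
                              c("rs12568784", "flg_null"),
                              c("rs877776", "rs12568784")),
                            predictors = NULL,
                            outcomes = c("eczema", "asthma", "sensitized",
                                         "polysensitized")) {
  if (is.null(input) && is.null(simulate)) {
    stop("either an input path or a simulation config is required",
         call. = FALSE)
  }
  known <- c(sites$site_id, "flg_null")
  for (pair in interaction_pairs) {
    bad <- setdiff(pair, known)
    if (length(bad) > 0L) {
      stop("interaction pair references undeclared exposure(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  if (is.null(predictors)) {
    predictors <- list()
    for (sid in sites$site_id) predictors[[sid]] <- snp_exposure(sid)
    predictors$flg_null <- flg_exposure()
    for (sid in sites$site_id) {
      predictors[[paste0(sid, "+flg_null")]] <-
        combined_predictor(snp_exposure(sid), flg_exposure())
    }
  }
  structure(list(input = input, simulate = simulate, sites = sites,
                 level = level, seed = seed,
                 interaction_pairs = interaction_pairs,
                 predictors = predictors, outcomes = outcomes),
            class = "analysis_config")
}

#' Read an analysis/simulation configuration from YAML or JSON
#'
#' Understands keys `input`, `level`, `seed`, `sites` (list of site_id /
#' ref_allele / risk_allele), `interaction_pairs`, and a `simulate` block
#' (n_cases, n_controls, allele_freq, flg_null_freq, seed); unknown simulate
#' keys are passed through to [sim_config()].
#'
#' @param path YAML (.yml/.yaml) or JSON file.
#' @return An [analysis_config()].
#' @export
read_analysis_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  sites <- if (!is.null(cfg$sites)) {
    do.call(rbind, lapply(cfg$sites, function(s) {
      data.frame(site_id = s$site_id, ref_allele = s$ref_allele,
                 risk_allele = s$risk_allele, stringsAsFactors = FALSE)
    }))
  } else default_sites()
  sim <- NULL
  if (!is.null(cfg$simulate)) {
    args <- cfg$simulate
    if (!is.null(args$allele_freq)) args$allele_freq <- unlist(args$allele_freq)
    args$sites <- sites
    sim <- do.call(sim_config, args)
  }
  pairs <- if (!is.null(cfg$interaction_pairs)) {
    lapply(cfg$interaction_pairs, unlist)
  } else NULL
  args <- list(input = cfg$input, simulate = sim, sites = sites)
  if (!is.null(cfg$level)) args$level <- cfg$level
  if (!is.null(cfg$seed)) args$seed <- cfg$seed
  if (!is.null(pairs)) args$interaction_pairs <- pairs
  do.call(analysis_config, args)
}

pair_spec <- function(name) {
  if (name == "flg_null") flg_exposure() else snp_exposure(name)
}

#' Run the full analysis pipeline
#'
#' Executes every stage on the configured cohort (read or simulated) and
#' writes, under `output_dir`: `table1_summary`, `table_hwe`,
#' `table_association`, `table_stratified`, `table_severity`,
#' `table_interaction` and `table_prediction` (each as `.tsv` and `.json`),
#' plus `manifest.json` recording the package version, seed, and a config
#' hash.  A failing stage is recorded in the bundle's `errors` with its stage
#' name; independent stages still run.
#'
#' @param config An [analysis_config()].
#' @param output_dir Directory (created if needed); NULL to skip writing.
#' @return The report bundle (named list of data.frames), invisibly.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  coh <- if (!is.null(config$input)) {
    read_cohort(config$input, sites = config$sites)
  } else {
    simulate_cohort(config$simulate)
  }
  level <- config$level
  bundle <- list()
  errors <- list()
  stage <- function(name, expr) {
    res <- tryCatch(suppressWarnings(expr), error = function(e) e)
    if (inherits(res, "error")) {
      errors[[name]] <<- conditionMessage(res)
      message(sprintf("stage '%s' failed: %s", name, conditionMessage(res)))
      NULL
    } else res
  }

  bundle$table1_summary <- stage("summary", as.data.frame(summarize_cohort(coh, level)))

  bundle$table_hwe <- stage("hwe", do.call(rbind, lapply(
    config$sites$site_id, function(sid) {
      for (pop in c("controls", "eczema")) {
        h <- hwe_test(coh, sid, population = pop)
        row <- data.frame(site_id = sid, population = pop, n = h$n,
                          risk_allele_freq = h$q, chi2 = h$chi2, p = h$p,
                          degenerate = h$degenerate)
        if (pop == "controls") out <- row else out <- rbind(out, row)
      }
      out
    })))

  est_row <- function(est, ...) {
    data.frame(..., estimate = est$estimate, ci_lower = est$ci_lower,
               ci_upper = est$ci_upper, p = est$p, method = est$method,
               n_used = est$n_used, stringsAsFactors = FALSE)
  }

  bundle$table_association <- stage("association", {
    rows <- list()
    rosters <- list(
      list(outcome = "eczema", population = NULL, label = "whole population"),
      list(outcome = "asthma", population = NULL, label = "whole population"),
      list(outcome = "sensitized", population = NULL, label = "whole population"),
      list(outcome = "polysensitized", population = NULL, label = "whole population"),
      list(outcome = "asthma", population = "eczema", label = "eczema group"),
      list(outcome = "sensitized", population = "eczema", label = "eczema group"))
    rosters <- Filter(function(r) r$outcome %in% c(config$outcomes, "asthma"),
                      rosters)
    for (sid in config$sites$site_id) {
      for (r in rosters) {
        tab <- build_table(coh, snp_exposure(sid), r$outcome, r$population)
        crude <- odds_ratio(tab, level = level)
        rows[[length(rows) + 1L]] <- est_row(
          crude, site_id = sid, model = "dominant", outcome = r$outcome,
          population = r$label, adjustment = "crude",
          a = tab$a, b = tab$b, c = tab$c, d = tab$d)
        adj <- tryCatch(logistic_fit(
          coh, r$outcome, snp_exposure(sid),
          covariates = c("age_months", "sex", "family_atopy"),
          population = r$population, level = level), error = function(e) NULL)
        if (!is.null(adj)) {
          cf <- adj$coefficients[2, ]
          rows[[length(rows) + 1L]] <- data.frame(
            site_id = sid, model = "dominant", outcome = r$outcome,
            population = r$label,
            adjustment = paste0("adjusted (", adj$method, ")"),
            a = NA, b = NA, c = NA, d = NA,
            estimate = cf$or, ci_lower = cf$or_lower, ci_upper = cf$or_upper,
            p = cf$p, method = "logistic Wald", n_used = adj$n_used,
            stringsAsFactors = FALSE)
        }
      }
      al <- allele_model(coh, sid, "eczema", level = level)
      rows[[length(rows) + 1L]] <- est_row(
        al, site_id = sid, model = "allele", outcome = "eczema",
        population = "whole population", adjustment = "crude",
        a = NA, b = NA, c = NA, d = NA)
    }
    do.call(rbind, rows)
  })

  bundle$table_stratified <- stage("stratified", {
    rows <- list()
    for (sid in config$sites$site_id) {
      for (model in c("dominant", "allele")) {
        sa <- stratified_association(coh, sid, model = model,
                                     outcome = "eczema", level = level)
        for (entry in sa) {
          rows[[length(rows) + 1L]] <- data.frame(
            site_id = sid, model = model, stratum = entry$stratum,
            n = entry$n,
            estimate = if (entry$estimable) entry$estimate$estimate else NA,
            ci_lower = if (entry$estimable) entry$estimate$ci_lower else NA,
            ci_upper = if (entry$estimable) entry$estimate$ci_upper else NA,
            p = if (entry$estimable) entry$estimate$p else NA,
            note = if (entry$estimable) "" else entry$reason,
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })

  bundle$table_severity <- stage("severity", do.call(rbind, lapply(
    config$sites$site_id, function(sid) {
      est <- severity_association(coh, sid, level = level)
      est_row(est, site_id = sid, comparison = "moderate vs mild")
    })))

  bundle$table_interaction <- stage("interaction", {
    rows <- list()
    for (pair in config$interaction_pairs) {
      for (out in c("eczema", "asthma")) {
        jt <- joint_strata(coh, pair_spec(pair[1]), pair_spec(pair[2]),
                           outcome = out,
                           population = if (out == "asthma") "asthma_or_control" else NULL)
        mi <- interaction_measures(jt, level = level)
        tt <- tryCatch(
          interaction_term_test(coh, pair_spec(pair[1]), pair_spec(pair[2]),
                                outcome = out),
          error = function(e) list(p = NA_real_))
        rows[[length(rows) + 1L]] <- data.frame(
          factorA = pair[1], factorB = pair[2], outcome = out,
          stratum = mi$rr$stratum, cases = mi$rr$cases,
          controls = mi$rr$controls, rr = mi$rr$rr, rr_lower = mi$rr$lower,
          rr_upper = mi$rr$upper, degenerate = mi$rr$degenerate,
          reri = mi$reri, ap = mi$ap, s = mi$s, ratio_rr = mi$ratio_rr,
          product_term_p = tt$p, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })

  bundle$table_prediction <- stage("prediction", {
    rows <- list()
    for (nm in names(config$predictors)) {
      cm <- confusion_matrix(coh, config$predictors[[nm]])
      dm <- diagnostic_metrics(cm, level = level)
      df <- dm$metrics
      df$predictor <- nm
      rows[[length(rows) + 1L]] <-
        df[, c("predictor", setdiff(names(df), "predictor"))]
    }
    do.call(rbind, rows)
  })

  bundle$errors <- errors
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in setdiff(names(bundle), "errors")) {
      df <- bundle[[nm]]
      if (is.null(df)) next
      utils::write.table(df, file.path(output_dir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(df, file.path(output_dir, paste0(nm, ".json")),
                           dataframe = "rows", na = "null", digits = NA,
                           pretty = TRUE)
    }
    manifest <- list(
      package = "edcassoc",
      version = as.character(utils::packageVersion("edcassoc")),
      seed = config$seed %||% (if (!is.null(config$simulate)) config$simulate$seed),
      config_hash = config_hash(config),
      tables = setdiff(names(bundle), "errors"),
      errors = errors)
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(bundle)
}

# Stable md5 of the serialized config, for the run manifest.
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::serializeJSON(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Render a result in report style
#'
#' "paper" style mirrors the source tables' rounding (2 decimals for
#' ORs/RRs, 3 for p-values) and their "÷" interval separator; "plain" keeps
#' at least six significant digits with a dash separator.  Missing fields
#' render as "not estimable".
#'
#' @param x An `effect_estimate`, `interaction_measures` or
#'   `diagnostic_metrics` object.
#' @param style "paper" or "plain".
#' @return Character vector of table lines.
#' @export
render_table <- function(x, style = c("paper", "plain")) {
  style <- match.arg(style)
  fmt <- function(v) {
    if (is.na(v)) return("not estimable")
    if (style == "paper") sprintf("%.2f", v) else format(v, digits = 6)
  }
  fmt_ci <- function(est, lo, hi) {
    if (is.na(est)) return("not estimable")
    sep <- if (style == "paper") " ÷ " else " - "
    sprintf("%s (%s%s%s)", fmt(est), fmt(lo), sep, fmt(hi))
  }
  fmt_p <- function(p) {
    if (is.na(p)) return("p not estimable")
    if (style == "paper") sprintf("p = %.3f", p) else sprintf("p = %s", format(p, digits = 6))
  }
  UseMethod_render(x, fmt, fmt_ci, fmt_p)
}

UseMethod_render <- function(x, fmt, fmt_ci, fmt_p) {
  if (inherits(x, "effect_estimate")) {
    return(sprintf("%s %s  %s", x$measure,
                   fmt_ci(x$estimate, x$ci_lower, x$ci_upper), fmt_p(x$p)))
  }
  if (inherits(x, "interaction_measures")) {
    rr <- x$rr
    lines <- vapply(seq_len(nrow(rr)), function(i) {
      ci <- if (i == 1L) "1.00 (Reference)"
            else fmt_ci(rr$rr[i], rr$lower[i], rr$upper[i])
      sprintf("%s\t%d\t%d\t%s%s", rr$stratum[i], rr$cases[i], rr$controls[i],
              ci, if (rr$degenerate[i]) "\t[zero-cell stratum CI]" else "")
    }, character(1))
    s_txt <- if (x$s_defined) fmt(x$s) else "not estimable"
    ap_txt <- if (is.na(x$ap)) "not estimable"
              else sprintf("%.3g", x$ap)  # the source tables keep 2-3 figures
    return(c(lines,
             sprintf("RERI = %s; AP = %s; S = %s; ratio of RRs = %s",
                     fmt(x$reri), ap_txt, s_txt, fmt(x$ratio_rr))))
  }
  if (inherits(x, "diagnostic_metrics")) {
    df <- x$metrics
    return(vapply(seq_len(nrow(df)), function(i) {
      sprintf("%s\t%s", df$metric[i],
              fmt_ci(df$estimate[i], df$lower[i], df$upper[i]))
    }, character(1)))
  }
  stop("no renderer for class ", paste(class(x), collapse = "/"), call. = FALSE)
}
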