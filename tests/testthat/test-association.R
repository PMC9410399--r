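test_that("build_table reproduces published 2x2 counts", {
  coh <- make_study_like_cohort()
  # asthma vs HRNR carriage within the eczema group
  t2b <- build_table(coh, snp_exposure("rs877776"), "asthma", "eczema")
  expect_equal(unclass(t2b)[c("a", "b", "c", "d")],
               list(a = 17L, b = 26L, c = 11L, d = 49L))
  # eczema vs FLG2 carriage, whole population
  t3a <- build_table(coh, snp_exposure("rs12568784"), "eczema")
  expect_equal(unclass(t3a)[c("a", "b", "c", "d")],
               list(a = 29L, b = 13L, c = 74L, d = 72L))
})

test_that("build_table excludes missing data and flags empty margins", {
  s <- make_subjects(6, eczema = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                     scorad_class = c(rep("mild", 3), rep("none", 3)),
                     rs877776 = c("GC", NA, "GG", "GC", "GG", "GG"))
  coh <- cohort(s)
  tab <- build_table(coh, snp_exposure("rs877776"), "eczema")
  expect_equal(attr(tab, "n_excluded"), 1L)
  expect_equal(tab$a + tab$b + tab$c + tab$d, 5L)
  # constant outcome in the subgroup -> empty margin, flagged
  expect_warning(
    tab2 <- build_table(coh, snp_exposure("rs877776"), "asthma", "eczema"),
    "empty margin")
  expect_true(attr(tab2, "empty_margin"))
  expect_error(build_table(coh, snp_exposure("rs877776"), "eczema",
                           population = function(d) rep(FALSE, nrow(d))),
               "selects no subjects")
})

test_that("odds_ratio reproduces published crude ORs and Woolf intervals", {
  est <- odds_ratio(contingency_table(17, 26, 11, 49))
  expect_equal(est$estimate, 2.91, tolerance = 0.005)
  expect_equal(est$ci_lower, 1.19, tolerance = 0.005)
  expect_equal(est$ci_upper, 7.13, tolerance = 0.005)
  expect_equal(odds_ratio(contingency_table(5, 5, 5, 5))$estimate, 1)
  expect_equal(odds_ratio(contingency_table(15, 27, 13, 133))$estimate,
               5.68, tolerance = 0.005)
  expect_equal(odds_ratio(contingency_table(15, 14, 13, 61))$estimate,
               5.03, tolerance = 0.005)
})

test_that("odds_ratio is invariant under simultaneous a<->d, b<->c swap", {
  set.seed(23)
  for (i in 1:50) {
    cells <- sample(1:40, 4, replace = TRUE)
    e1 <- odds_ratio(do.call(contingency_table, as.list(cells)),
                     p_method = "none")
    e2 <- odds_ratio(contingency_table(cells[4], cells[3], cells[2], cells[1]),
                     p_method = "none")
    expect_equal(e1$estimate, e2$estimate, tolerance = 1e-12)
    expect_equal(e1$ci_lower, e2$ci_lower, tolerance = 1e-12)
  }
})

test_that("odds_ratio handles zero cells per the Haldane-Anscombe policy", {
  est <- odds_ratio(contingency_table(6, 0, 8, 10))
  expect_match(est$method, "Haldane")
  manual <- (6.5 * 10.5) / (0.5 * 8.5)
  expect_equal(est$estimate, manual, tolerance = 1e-12)
  expect_error(odds_ratio(contingency_table(0, 5, 5, 0)), "undefined")
  expect_error(odds_ratio(contingency_table(5, 0, 0, 5)), "undefined")
})

test_that("chi-square equals the margin-expectation oracle and handles 2xk", {
  expect_equal(chi_square_test(contingency_table(10, 20, 30, 60))$statistic, 0,
               tolerance = 1e-12)
  set.seed(41)
  for (i in 1:50) {
    m <- matrix(sample(1:30, 4, replace = TRUE), 2)
    res <- chi_square_test(contingency_table(m[1, 1], m[1, 2], m[2, 1], m[2, 2]))
    expect_equal(res$statistic,
                 chisq_from_margins(matrix(c(m[1, 1], m[2, 1], m[1, 2], m[2, 2]), 2)),
                 tolerance = 1e-9)
  }
  # mild vs moderate HRNR carriage (dominant split of the severity table)
  m <- matrix(c(34, 26, 26, 17), 2, byrow = TRUE)  # rows: mild, moderate
  res <- chi_square_test(m)
  expect_equal(res$statistic, chisq_from_margins(m), tolerance = 1e-12)
  expect_equal(res$df, 1)
  # 2x3 genotype comparison runs with df = 2
  m3 <- matrix(c(34, 20, 6, 26, 13, 4), 2, byrow = TRUE)
  expect_equal(chi_square_test(m3)$df, 2)
  expect_error(chi_square_test(matrix(c(0, 0, 3, 4), 2)), "zero margin")
})

test_that("fisher_exact equals the enumeration oracle", {
  expect_equal(fisher_exact(contingency_table(1, 0, 0, 1)), 1)
  for (cells in list(c(3, 2, 2, 11), c(6, 0, 8, 10), c(1, 9, 1, 9))) {
    expect_equal(fisher_exact(do.call(contingency_table, as.list(cells))),
                 do.call(fisher_enumeration_p, as.list(cells)),
                 tolerance = 1e-10)
  }
  set.seed(7)
  for (i in 1:100) {
    cells <- sample(0:12, 4, replace = TRUE)
    if (sum(cells) == 0) next
    expect_equal(fisher_exact(do.call(contingency_table, as.list(cells))),
                 do.call(fisher_enumeration_p, as.list(cells)),
                 tolerance = 1e-10)
  }
})

test_that("allele model reproduces the published per-allele ORs", {
  coh <- make_study_like_cohort()
  hrnr <- allele_model(coh, "rs877776", "eczema")
  expect_equal(hrnr$estimate, 1.99, tolerance = 0.005)
  flg2 <- allele_model(coh, "rs12568784", "eczema")
  expect_equal(flg2$estimate, 1.91, tolerance = 0.005)
  # count-level entry point agrees
  expect_equal(
    odds_ratio(allele_table(genotype_counts(60, 37, 6),
                            genotype_counts(66, 15, 4)))$estimate,
    hrnr$estimate, tolerance = 1e-12)
})

test_that("allele model degenerate cases behave", {
  all_het <- cohort(make_subjects(20, eczema = rep(c(TRUE, FALSE), 10),
                                  scorad_class = rep(c("mild", "none"), 10),
                                  rs877776 = "GC"))
  expect_equal(allele_model(all_het, "rs877776", "eczema")$estimate, 1)
  mono <- cohort(make_subjects(10, eczema = rep(c(TRUE, FALSE), 5),
                               scorad_class = rep(c("mild", "none"), 5)))
  expect_error(allele_model(mono, "rs877776", "eczema"), "monomorphic")
})

test_that("logistic fit with a sole binary exposure equals the crude OR", {
  coh <- cohort_from_table(17, 26, 11, 49)
  fit <- logistic_fit(coh, "eczema", snp_exposure("rs877776"))
  expect_equal(exp(fit$coefficients$estimate[2]), 17 * 49 / (26 * 11),
               tolerance = 1e-6)
  expect_false(fit$separation_flag)
  expect_equal(fit$method, "mle")
})

test_that("logistic fit recovers null coefficients in balanced independent data", {
  s <- make_subjects(200,
                     eczema = rep(c(TRUE, FALSE), each = 100),
                     scorad_class = rep(c("mild", "none"), each = 100),
                     rs877776 = rep(c("GC", "GG", "GC", "GG"), each = 50),
                     sex = rep(c("male", "female"), 100))
  fit <- logistic_fit(cohort(s), "eczema", snp_exposure("rs877776"),
                      covariates = "sex")
  expect_lt(max(abs(fit$coefficients$estimate[-1])), 1e-6)
})

test_that("family-history covariate triggers separation and a Firth refit", {
  coh <- simulate_cohort(sim_config(seed = 12, n_cases = 80, n_controls = 80))
  fit <- logistic_fit(coh, "eczema", snp_exposure("rs877776"),
                      covariates = c("age_months", "sex", "family_atopy"))
  expect_true(fit$separation_flag)
  expect_equal(fit$method, "firth")
  expect_true(all(is.finite(fit$coefficients$estimate)))
  mle <- logistic_fit(coh, "eczema", snp_exposure("rs877776"),
                      covariates = c("age_months", "sex", "family_atopy"),
                      firth = "never")
  expect_true(mle$separation_flag)
})

test_that("constant covariates are dropped with a warning", {
  coh <- cohort_from_table(10, 10, 10, 10)
  expect_warning(
    fit <- logistic_fit(coh, "eczema", snp_exposure("rs877776"),
                        covariates = "sex"),
    "constant")
  expect_false("sex" %in% fit$coefficients$term)
})

test_that("stratified association matches the published FLG-normal stratum", {
  coh <- make_hrnr_flg_cohort()
  sa <- stratified_association(coh, "rs877776", outcome = "eczema")
  normal <- sa[["flg_null = 0"]]
  expect_true(normal$estimable)
  expect_equal(normal$estimate$estimate, 37 * 64 / (19 * 52), tolerance = 1e-12)
  expect_equal(normal$estimate$estimate, 2.40, tolerance = 0.005)
  null_str <- sa[["flg_null = 1"]]
  expect_true(null_str$estimable)  # Haldane-corrected (zero-cell)
  expect_equal(null_str$n, 8L + 6L + 2L)
})

test_that("a constant stratifier leaves the other stratum not estimable", {
  coh <- cohort_from_table(10, 10, 10, 10)  # flg_null all FALSE
  sa <- stratified_association(coh, "rs877776", outcome = "eczema")
  expect_true(sa[["flg_null = 0"]]$estimable)
  expect_false(sa[["flg_null = 1"]]$estimable)
  expect_match(sa[["flg_null = 1"]]$reason, "empty")
})

test_that("severity association reproduces published mild-vs-moderate ORs", {
  coh <- make_study_like_cohort()
  flg2 <- severity_association(coh, "rs12568784")
  expect_equal(flg2$estimate, 19 * 50 / (24 * 10), tolerance = 1e-12)
  expect_equal(flg2$estimate, 3.96, tolerance = 0.005)  # crude (paper: 3.95 adj.)
  # HRNR split from the same severity table, dedicated fixture
  hrnr_sev <- cohort(make_subjects(103,
    eczema = TRUE,
    scorad_class = c(rep("mild", 60), rep("moderate", 43)),
    rs877776 = c(rep("GC", 26), rep("GG", 34), rep("GC", 17), rep("GG", 26))))
  hrnr <- severity_association(hrnr_sev, "rs877776")
  expect_equal(hrnr$estimate, 17 * 34 / (26 * 26), tolerance = 1e-12)
  # identical carrier fractions give OR 1
  flat <- cohort(make_subjects(40, eczema = TRUE,
    scorad_class = rep(c("mild", "moderate"), each = 20),
    rs877776 = rep(c("GC", "GG", "GC", "GG"), each = 10)))
  expect_equal(severity_association(flat, "rs877776")$estimate, 1)
})
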