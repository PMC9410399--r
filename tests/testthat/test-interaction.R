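test_that("joint_strata reproduces the published FLG2 x FLG stratum counts", {
  coh <- make_flg2_flg_cohort()
  jt <- joint_strata(coh, snp_exposure("rs12568784"), flg_exposure(), "eczema")
  expect_equal(jt$cases, c(71L, 18L, 3L, 11L))
  expect_equal(jt$controls, c(70L, 13L, 2L, 0L))
  jt6 <- joint_strata(coh, snp_exposure("rs12568784"), flg_exposure(),
                      "asthma", population = "asthma_or_control")
  expect_equal(jt6$cases, c(10L, 12L, 3L, 3L))
  expect_equal(jt6$controls, c(70L, 13L, 2L, 0L))
})

test_that("joint_strata flags degenerate layouts", {
  coh <- cohort_from_table(10, 10, 10, 10)
  w <- capture_warnings(
    jt <- joint_strata(coh, snp_exposure("rs877776"), flg_exposure(), "eczema"))
  expect_match(w, "empty joint stratum", all = TRUE)
  expect_equal(jt$cases[3:4], c(0L, 0L))
  # no reference stratum at all
  s <- make_subjects(8, eczema = rep(c(TRUE, FALSE), 4),
                     scorad_class = rep(c("mild", "none"), 4),
                     rs877776 = "GC")
  expect_error(suppressWarnings(joint_strata(cohort(s), snp_exposure("rs877776"),
                                             flg_exposure(), "eczema")),
               "reference stratum")
})

test_that("stratum relative risks match both published interaction blocks", {
  rr5 <- stratum_relative_risks(joint_table(c(71, 18, 3, 11), c(70, 13, 2, 0)))
  expect_equal(rr5$rr, c(1, 1.15, 1.19, 1.99), tolerance = 0.005)
  expect_true(rr5$degenerate[4])  # zero-control stratum, uncorrected point RR
  rr6 <- stratum_relative_risks(joint_table(c(10, 12, 3, 3), c(70, 13, 2, 0)))
  expect_equal(rr6$rr, c(1, 3.84, 4.80, 8.00), tolerance = 1e-12)
})

test_that("additive measures reproduce the published RERI/AP/S", {
  # eczema-associated asthma block: exact closed form from integer counts
  add6 <- additive_interaction(c(3.84, 4.80, 8.00))
  expect_equal(add6$reri, 0.36, tolerance = 1e-12)
  expect_equal(add6$ap, 0.045, tolerance = 1e-12)
  expect_equal(add6$s, 1.05, tolerance = 0.005)
  # eczema block from unrounded RRs
  mi5 <- interaction_measures(joint_table(c(71, 18, 3, 11), c(70, 13, 2, 0)))
  expect_equal(round(mi5$reri, 2), 0.64)
  expect_equal(round(mi5$ap, 2), 0.32)
  # perfect additivity
  flat <- additive_interaction(c(2, 3, 4))
  expect_equal(flat$reri, 0)
  expect_equal(flat$s, 1)
})

test_that("multiplicative ratio reproduces the published values", {
  expect_equal(round(multiplicative_interaction(c(3.84, 4.80, 8.00)), 2), 0.43)
  mi5 <- interaction_measures(joint_table(c(71, 18, 3, 11), c(70, 13, 2, 0)))
  expect_equal(round(mi5$ratio_rr, 2), 1.45)
  expect_equal(multiplicative_interaction(c(2, 3, 6)), 1)  # eff11 = eff10*eff01
})

test_that("interaction measures are symmetric in the factor labels", {
  jt_ab <- joint_table(c(50, 20, 12, 18), c(60, 15, 20, 5))
  jt_ba <- joint_table(c(50, 12, 20, 18), c(60, 20, 15, 5))  # swap A+B- / A-B+
  a <- interaction_measures(jt_ab)
  b <- interaction_measures(jt_ba)
  expect_equal(a$reri, b$reri, tolerance = 1e-12)
  expect_equal(a$ap, b$ap, tolerance = 1e-12)
  expect_equal(a$s, b$s, tolerance = 1e-12)
  expect_equal(a$ratio_rr, b$ratio_rr, tolerance = 1e-12)
})

test_that("flat relative risks give null interaction on both scales", {
  add <- additive_interaction(c(1, 1, 1))
  expect_equal(add$reri, 0)
  expect_equal(add$ap, 0)
  expect_false(add$s_defined)  # 0/0
  expect_equal(multiplicative_interaction(c(1, 1, 1)), 1)
})

test_that("product-term test detects collinearity and strong interaction", {
  # A x B identical to A when B is constant-true among carriers: use A == B
  s <- make_subjects(40, eczema = rep(c(TRUE, FALSE), 20),
                     scorad_class = rep(c("mild", "none"), 20),
                     rs877776 = rep(c("GC", "GG"), each = 20),
                     flg_null = rep(c(TRUE, FALSE), each = 20))
  expect_warning(
    res <- interaction_term_test(cohort(s), snp_exposure("rs877776"),
                                 flg_exposure(), "eczema"),
    "collinear")
  expect_true(res$dropped)
  expect_true(is.na(res$p))
})

test_that("product-term test has power against a strong multiplicative interaction", {
  reps <- 120
  hits <- 0L
  for (r in seq_len(reps)) {
    cfg <- sim_config(seed = 30000 + r, n_cases = 2000, n_controls = 2000,
                      allele_freq = c(rs877776 = 0.25, rs12568784 = 0.25),
                      eczema_model = disease_model(
                        intercept = qlogis(0.2),
                        effects = list(
                          rs877776 = list(coding = "dominant", beta = log(1.3)),
                          rs12568784 = list(coding = "dominant", beta = log(1.3))),
                        interactions = list(list(a = "rs877776",
                                                 b = "rs12568784",
                                                 beta = log(3)))))
    coh <- simulate_cohort(cfg)
    res <- interaction_term_test(coh, snp_exposure("rs877776"),
                                 snp_exposure("rs12568784"), "eczema")
    if (!is.na(res$p) && res$p < 0.05) hits <- hits + 1L
  }
  expect_gt(hits / reps, 0.8)
})

test_that("delta-method RERI interval covers the additive null at ~ nominal rate", {
  # independent binomial strata with exactly additive risks:
  # p = (0.30, 0.45, 0.51, 0.66) so RERI(p/p00) = 0
  set.seed(404)
  p <- c(0.30, 0.45, 0.51, 0.66)
  n <- c(220, 160, 160, 160)
  reps <- 400
  covered <- 0L
  for (r in seq_len(reps)) {
    ca <- rbinom(4, n, p)
    if (ca[1] == 0 || ca[1] == n[1] || any(ca == 0) || any(ca == n)) next
    ci <- interaction_cis(joint_table(ca, n - ca), method = "delta")
    if (ci$reri["lower"] <= 0 && ci$reri["upper"] >= 0) covered <- covered + 1L
  }
  rate <- covered / reps
  band <- qnorm(0.995) * sqrt(0.95 * 0.05 / reps)
  expect_gt(rate, 0.95 - band)
  expect_lte(rate, 1)
})

test_that("bootstrap interval contains the point estimate and matches delta", {
  jt <- joint_table(c(80, 60, 40, 60), c(120, 60, 50, 30))
  mi <- interaction_measures(jt)
  boot <- interaction_cis(jt, method = "bootstrap", reps = 2000, seed = 11)
  expect_lte(boot$reri["lower"], mi$reri)
  expect_gte(boot$reri["upper"], mi$reri)
  delta <- interaction_cis(jt, method = "delta")
  wd <- delta$reri["upper"] - delta$reri["lower"]
  wb <- boot$reri["upper"] - boot$reri["lower"]
  expect_lt(abs(wd - wb) / wd, 0.15)
  # zero-cell table falls back to bootstrap with a warning
  expect_warning(
    fb <- interaction_cis(joint_table(c(10, 12, 3, 3), c(70, 13, 2, 0)),
                          method = "delta", seed = 2),
    "falling back to bootstrap")
  expect_equal(fb$method, "bootstrap")
})
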