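test_that("impairment classification is strict and monotone in the threshold", {
  s <- tibble::tibble(
    subject_id = rep(c("a", "b", "c"), each = 2),
    measure = rep(c("verbal_fluency", "digit_backward"), 3),
    z = c(-1.31, 0, -1.3, 0, 0, 0))
  imp <- classify_impairment(s, executive = c("verbal_fluency",
                                              "digit_backward"))
  expect_identical(imp$any_executive_impaired[match(c("a", "b", "c"),
                                                    imp$subject_id)],
                   c(TRUE, FALSE, FALSE))
  # idempotent on its own flags; lowering the threshold never adds subjects
  imp_lower <- classify_impairment(s, threshold = -2,
                                   executive = c("verbal_fluency",
                                                 "digit_backward"))
  expect_true(all(imp$any_executive_impaired |
                    !imp_lower$any_executive_impaired))
  expect_error(classify_impairment(s, executive = "bogus_measure"),
               "bogus_measure", class = "ctcnet_input_error")
})

test_that("Wald proportion intervals reproduce closed-form arithmetic", {
  ci <- impairment_proportion_ci(17, 104)
  expect_equal(round(ci$proportion, 2), 16.35)
  expect_equal(round(ci$ci_low, 2), 9.24)
  expect_equal(round(ci$ci_high, 2), 23.45)
  expect_equal(ci$label, "16.35 (9.24-23.45)")

  ci2 <- impairment_proportion_ci(50, 100)
  expect_equal(round(c(ci2$ci_low, ci2$ci_high), 2), c(40.20, 59.80))

  expect_warning(ci0 <- impairment_proportion_ci(0, 50),
                 class = "ctcnet_degenerate_ci_warning")
  expect_equal(c(ci0$proportion, ci0$ci_low, ci0$ci_high), c(0, 0, 0))

  # width shrinks as 1/sqrt(n) at fixed proportion
  w <- vapply(c(100, 400, 1600), function(n) {
    ci <- impairment_proportion_ci(n / 4, n)
    ci$ci_high - ci$ci_low
  }, numeric(1))
  expect_equal(w[1] / w[2], 2, tolerance = 1e-6)
  expect_equal(w[2] / w[3], 2, tolerance = 1e-6)

  # Wilson stays ordered and inside [0, 100]
  cw <- impairment_proportion_ci(3, 10, method = "wilson")
  expect_true(cw$ci_low < cw$proportion && cw$proportion < cw$ci_high)
  expect_error(impairment_proportion_ci(5, 0), class = "ctcnet_config_error")
  expect_error(impairment_proportion_ci(6, 5), class = "ctcnet_input_error")
})

test_that("reference-population t-test matches the textbook statistic", {
  z <- scale(rnorm(100))[, 1]  # mean exactly 0, sd exactly 1
  r0 <- one_sample_vs_reference(z)
  expect_equal(r0$statistic, 0, tolerance = 1e-10)
  expect_equal(r0$p.value, 1, tolerance = 1e-10)

  z2 <- z * 1.03 - 0.49       # mean -0.49, sd 1.03 by construction
  r2 <- one_sample_vs_reference(z2)
  expect_equal(r2$statistic, -0.49 / (1.03 / sqrt(100)), tolerance = 1e-10)
  expect_equal(round(r2$statistic, 3), -4.757)
  expect_equal(r2$df, 99)

  expect_error(one_sample_vs_reference(rep(1, 5)),
               class = "ctcnet_input_error")
  # calibration at the 5% level under the null
  rej <- vapply(1:1000, function(r) {
    set.seed(5000 + r)
    one_sample_vs_reference(rnorm(30))$p.value <= 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("stratified morphometry models recover known coefficients", {
  spec <- cohort_spec(n_male = 60, n_female = 60, seed = 23)
  subjects <- generate_cohort(spec)
  # noiseless construction: volume is an exact linear function of the model
  # terms, so the fit interpolates to machine precision
  male <- subjects[subjects$sex == "male", ]
  z <- rnorm(nrow(subjects))
  scores <- tibble::tibble(subject_id = subjects$subject_id,
                           measure = "digit_backward", z = z)
  subjects$cerebellum_left <-
    40 * z + 0.001 * subjects$dex_auc + 0.002 * subjects$mtx_auc +
    1.5 * subjects$it_count + 2 * subjects$age_dx + 1 * subjects$age_eval +
    0.0001 * subjects$icv + 70000
  fit <- suppressWarnings(
    glm_brain_exposure(subjects, scores, "digit_backward",
                       "cerebellum_left", stratum = "male"))
  tab <- tidy(fit)
  expect_equal(unname(tab$estimate[tab$term == "z"]), 40, tolerance = 1e-6)
  expect_equal(unname(tab$estimate[tab$term == "it_count"]), 1.5,
               tolerance = 1e-6)

  # duplicated predictor is a rank-deficiency error naming the column
  subjects2 <- subjects
  subjects2$mtx_auc <- subjects2$dex_auc
  expect_error(glm_brain_exposure(subjects2, scores, "digit_backward",
                                  "cerebellum_left", stratum = "male"),
               "mtx_auc", class = "ctcnet_input_error")

  # generator round trip: a planted positive cerebellum-cognition slope gives
  # a positive fitted z coefficient within 2 SE
  spec_big <- cohort_spec(n_male = 250, n_female = 250, seed = 31)
  sb <- generate_cohort(spec_big)
  mm <- default_neurocog_model(impaired_shift = 0, cerebellum_slope = 0.8)
  sc <- generate_neurocog(sb, model = mm, seed = 31, enforce_labels = FALSE)
  fitb <- glm_brain_exposure(sb, sc, "rey_osterrieth_copy",
                             "cerebellum_left", stratum = "female")
  tb <- tidy(fitb)
  expect_gt(tb$estimate[tb$term == "z"], 0)
  expect_gt(tb$estimate[tb$term == "z"] / tb$std.error[tb$term == "z"], 2)
})

test_that("correlations and FDR control behave as specified", {
  x <- rnorm(30)
  expect_equal(correlate_metric(x, x)$estimate, 1)
  set.seed(44)
  y <- -x + rnorm(30, sd = 1e-8)
  expect_equal(correlate_metric(x, y)$estimate, -1, tolerance = 1e-6)
  expect_error(correlate_metric(x[1:2], x[1:2]), class = "ctcnet_input_error")
  expect_error(correlate_metric(x, rep(1, 30)), class = "ctcnet_input_error")

  # seeded bivariate normal at rho = -0.24, n = 89: r lies in the Fisher-z
  # 95% sampling band for most seeds
  inside <- vapply(1:40, function(s) {
    set.seed(s)
    x <- rnorm(89)
    y <- -0.24 * x + sqrt(1 - 0.24^2) * rnorm(89)
    r <- correlate_metric(x, y)$estimate
    r >= -0.44 && r <= -0.04
  }, logical(1))
  expect_gte(mean(inside), 0.85)

  # Benjamini-Yekutieli step-up with the harmonic factor c(3) = 11/6
  expect_equal(fdr_correct(c(0.01, 0.02, 0.5), method = "BY"),
               c(0.055, 0.055, 11 / 12), tolerance = 1e-10)
  # equal inputs give equal adjusted values
  expect_true(length(unique(fdr_correct(rep(0.07, 5), "BY"))) == 1)
  expect_equal(fdr_correct(0.03, "BH"), 0.03)
  expect_equal(fdr_correct(0.03, "BY"), 0.03)
  # BY rejections are a subset of BH rejections at the same alpha
  set.seed(2)
  p <- runif(50)^2
  expect_true(all(fdr_correct(p, "BY") >= fdr_correct(p, "BH")))
  expect_error(fdr_correct(c(0.5, 1.2)), class = "ctcnet_input_error")
})
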