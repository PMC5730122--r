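test_that("pearson matches the closed-form oracle on the printed fixture", {
  res <- pearson(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(res$r, 0.8, tolerance = 1e-12)
  t_oracle <- 0.8 * sqrt((4 - 2) / (1 - 0.8^2))
  expect_equal(res$p, 2 * pt(-abs(t_oracle), 2), tolerance = 1e-10)
  expect_equal(res$n, 4)

  exact <- pearson(1:6, 2 * (1:6) + 1)
  expect_equal(exact$r, 1, tolerance = 1e-12)

  set.seed(3)
  for (i in 1:5) {
    x <- rnorm(15); y <- rnorm(15)
    res <- pearson(x, y)
    r0 <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(res$r, r0, tolerance = 1e-10)
    expect_equal(res$p, 2 * pt(-abs(r0 * sqrt(13 / (1 - r0^2))), 13),
                 tolerance = 1e-10)
  }
  expect_error(pearson(rep(1, 5), rnorm(5)), "constant")
  expect_error(pearson(1:2, 1:2), "at least 3")
})

test_that("standardized OLS equals Pearson r for one predictor and a normal-equations oracle in general", {
  tab <- simulate_cohort(cohort_sim_config(seed = 21))
  one <- fit_ols_standardized(tab, "m1_thick_occ", "m1_cbf_occ")
  expect_equal(unname(one$beta), pearson(tab$m1_cbf_occ, tab$m1_thick_occ)$r,
               tolerance = 1e-10)

  preds <- c("m1_cbf_occ", "age", "htn")
  fit <- fit_ols_standardized(tab, "m1_thick_occ", preds)
  z <- scale(as.matrix(as.data.frame(tab)[, c("m1_thick_occ", preds)]))
  X <- cbind(1, z[, preds])
  beta_oracle <- solve(t(X) %*% X, t(X) %*% z[, "m1_thick_occ"])
  expect_equal(unname(fit$beta), unname(beta_oracle[-1]), tolerance = 1e-8)

  # standardized betas are invariant to affine predictor rescaling
  tab2 <- tab
  tab2$age <- tab2$age * 12 + 3
  fit2 <- fit_ols_standardized(tab2, "m1_thick_occ", preds)
  expect_equal(fit2$beta, fit$beta, tolerance = 1e-10)

  tab2$dup <- tab2$age
  expect_error(fit_ols_standardized(tab2, "m1_thick_occ", c("age", "dup")),
               "collinear")
})

test_that("noiseless cohort regression recovers the generating structure with p ~ 0", {
  tab <- simulate_cohort(cohort_sim_config(n_subjects = 50,
                                           thick_noise_sd = 0, seed = 31))
  fit <- fit_ols_standardized(tab, "m1_thick_occ", c("m1_cbf_occ", "age"))
  expect_true(all(fit$p < 1e-20))
  expect_gt(fit$beta[["m1_cbf_occ"]], 0)
  expect_lt(fit$beta[["age"]], 0)
})

test_that("variable screen applies the inclusive p <= alpha rule", {
  tab <- simulate_cohort(cohort_sim_config(seed = 41))
  p_age <- pearson(tab$age, tab$m1_thick_occ)$p
  # boundary: alpha set exactly to a candidate's p keeps that candidate
  sel <- variable_screen(tab, "m1_thick_occ", c("age", "wmh_occ"),
                         alpha = p_age)
  expect_true("age" %in% sel)
  # an outcome-independent candidate is dropped in a large noiseless cohort
  big <- simulate_cohort(cohort_sim_config(n_subjects = 400,
                                           thick_noise_sd = 1e-6, seed = 42))
  sel2 <- variable_screen(big, "m1_thick_occ",
                          c("m1_cbf_occ", "age", "wmh_occ"))
  expect_true(all(c("m1_cbf_occ", "age") %in% sel2))
  expect_false("wmh_occ" %in% sel2)
})

test_that("screen selects a null candidate at ~ the nominal 5% rate", {
  hits <- 0; runs <- 400
  for (s in seq_len(runs)) {
    tab <- simulate_cohort(cohort_sim_config(n_subjects = 28, seed = 5000 + s))
    sel <- variable_screen(tab, "v1_thick_occ", "v1_cbf_occ")
    hits <- hits + ("v1_cbf_occ" %in% sel)
  }
  ci <- qbinom(c(0.0005, 0.9995), runs, 0.05)  # 99.9% binomial band
  expect_gte(hits, ci[1])
  expect_lte(hits, ci[2])
})

test_that("cohort_to_long builds two rows per subject and GEE rejects broken clusters", {
  tab <- simulate_cohort(cohort_sim_config(seed = 51))
  long <- cohort_to_long(tab, "m1")
  expect_equal(nrow(long), 56)
  expect_true(all(table(long$subject_id) == 2))
  expect_error(fit_gee_thickness(long[-1, ]), "exactly 2 rows")
})

test_that("GEE with independence working correlation and singleton clusters equals OLS", {
  tab <- simulate_cohort(cohort_sim_config(seed = 61))
  df <- data.frame(y = tab$m1_thick_occ, cbf = tab$m1_cbf_occ,
                   age = tab$age, id = seq_len(nrow(tab)))
  g <- fit_gee(y ~ cbf + age, df, id = "id", corstr = "independence")
  f <- lm(y ~ cbf + age, data = df)
  expect_equal(g$coefficients, coef(f), tolerance = 1e-10)
  expect_equal(g$n_clusters, 28)
})

test_that("GEE point estimates match a fixed-correlation GLS oracle (nlme)", {
  tab <- simulate_cohort(cohort_sim_config(seed = 71))
  long <- cohort_to_long(tab, "m1")
  g <- fit_gee_thickness(long)
  long$collateral <- factor(long$collateral,
                            levels = c("cross-filling", "none", "unknown"))
  gls_fit <- nlme::gls(
    thickness ~ rcbf + age + side_occluded_row + collateral +
      occlusion_complete,
    data = long,
    correlation = nlme::corCompSymm(value = g$alpha_working,
                                    form = ~ 1 | subject_id, fixed = TRUE))
  expect_equal(unname(g$coefficients), unname(coef(gls_fit)),
               tolerance = 1e-6)
})

test_that("cluster-constant covariates give identical exchangeable and independence estimates", {
  tab <- simulate_cohort(cohort_sim_config(seed = 81))
  long <- cohort_to_long(tab, "m1")
  # age and occlusion status are constant within subject (balanced design)
  ge <- fit_gee(thickness ~ age + occlusion_complete, long, "subject_id",
                corstr = "exchangeable")
  gi <- fit_gee(thickness ~ age + occlusion_complete, long, "subject_id",
                corstr = "independence")
  expect_equal(ge$coefficients, gi$coefficients, tolerance = 1e-8)
  # (for cluster-constant designs the sandwich SEs coincide as well:
  # the working-correlation scalar cancels in the sandwich)
  expect_equal(ge$robust_se, gi$robust_se, tolerance = 1e-8)
})

test_that("noiseless GEE recovers the generating thickness coefficients", {
  tab <- simulate_cohort(cohort_sim_config(n_subjects = 60,
                                           thick_noise_sd = 0, seed = 91))
  g <- fit_gee_thickness(cohort_to_long(tab, "m1"))
  expect_equal(unname(g$coefficients["rcbf"]), 0.0045, tolerance = 1e-6)
  expect_equal(unname(g$coefficients["age"]), -0.0044, tolerance = 1e-6)
})

test_that("the full stats report is deterministic and internally consistent", {
  tab <- simulate_cohort(cohort_sim_config(seed = 101))
  tab$m1_cbf_occ[3] <- NA
  tab <- as_cohort_table(as.data.frame(tab))
  r1 <- stats_report(tab)
  r2 <- stats_report(tab)
  expect_identical(r1, r2)
  expect_equal(r1$n_total, 28)
  expect_equal(r1$n_asl_missing, 1)
  expect_equal(r1$n_analyzed, 27)
  expect_equal(r1$gee$m1$n_rows, 2 * r1$gee$m1$n_subjects)
  # paired block agrees with a direct call on the complete cases
  cc <- as.data.frame(tab)[!tab$asl_missing, ]
  direct <- paired_t(cc$m1_cbf_occ, cc$m1_cbf_unocc)
  expect_equal(r1$paired_tests$m1_cbf$t_statistic, direct$t_statistic)
})
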