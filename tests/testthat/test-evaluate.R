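test_that("predictive R-squared is the squared Pearson correlation", {
  y <- c(1, 3, 2, 5)
  expect_equal(r2(y, y), 1)
  expect_equal(r2(y, 3 + 2 * y), 1)        # affine invariance
  p <- c(2, 2.5, 1.5, 4)
  # textbook formula, frozen by hand for this 4-point example
  num <- sum((y - mean(y)) * (p - mean(p)))
  den <- sqrt(sum((y - mean(y))^2) * sum((p - mean(p))^2))
  expect_equal(r2(y, p), (num / den)^2)
  expect_equal(r2(y, p), 25 / 30.625, tolerance = 1e-12)  # hand-computed
  expect_error(r2(y, rep(1, 4)), "constant")
  expect_error(r2(y, p[1:3]), "equal length")
  expect_error(r2(y[1:2], p[1:2]), "at least 3")
})

test_that("an oracle predictor approaches the theoretical accuracy ceiling", {
  sim <- cached_sim("h2_check", sim_config(n_subjects = 500, n_causal = 18,
                                           n_null = 10, missing_rate = 0,
                                           seed = 77))
  cfg <- sim$truth$config
  tf <- lipidprs:::trait_frame(sim$cohort, "TC")
  at <- age_transform(cfg$age_span[1], cfg$age_span[2])
  # the generative fixed part: everything except subject intercept + noise
  oracle_pred <- cfg$mu + cfg$age_effect * f_age(tf$age, at) +
    cfg$sex_effect * tf$sex + cfg$bmi_effect * tf$bmi +
    sim$truth$genetic_value[tf$subject_id]
  obs_r2 <- r2(tf$y, oracle_pred)
  ceiling <- var(oracle_pred) /
    (var(oracle_pred) + cfg$subject_sd^2 + cfg$residual_sd^2)
  expect_lt(abs(obs_r2 - ceiling), 0.05)
})

test_that("cross-validation predictions ignore the held-out subject's phenotypes", {
  sim <- small_sim()
  subj <- unique(sim$cohort$phenotypes$subject_id)[5]
  cv1 <- loso_cv(sim$cohort, builder_nongenetic(), "TC", subjects = subj)
  mut <- sim$cohort
  idx <- mut$phenotypes$subject_id == subj
  mut$phenotypes$tc[idx] <- mut$phenotypes$tc[idx] + 300
  cv2 <- loso_cv(mut, builder_nongenetic(), "TC", subjects = subj)
  expect_equal(cv1$records$predicted, cv2$records$predicted,
               tolerance = 1e-12)
  expect_equal(cv2$records$observed, cv1$records$observed + 300)
})

test_that("builder failures abort with the fold identity", {
  sim <- small_sim()
  bad <- structure(function(train, trait) stop("boom"), label = "bad")
  expect_error(loso_cv(sim$cohort, bad, "TC",
                       subjects = unique(sim$cohort$phenotypes$subject_id)[1]),
               "fold for subject")
})

test_that("cluster bootstrap brackets the point estimate and is degenerate-safe", {
  sim <- small_sim()
  cv <- loso_cv(sim$cohort, builder_nongenetic(), "TC")
  ci <- bootstrap_ci_r2(cv, n_boot = 300, seed = 8)
  expect_lt(ci[1], cv$r2)
  expect_gt(ci[2], cv$r2)
  expect_error(bootstrap_ci_r2(cv, n_boot = 50), "at least 200")
  # perfect predictions pin the interval at 1
  perfect <- cv
  perfect$records$predicted <- perfect$records$observed
  expect_equal(bootstrap_ci_r2(perfect, 200, 1), c(1, 1))
})

test_that("bootstrap intervals narrow with more subjects", {
  big <- cached_sim("h2_check", sim_config(n_subjects = 500, n_causal = 18,
                                           n_null = 10, missing_rate = 0,
                                           seed = 77))
  small_ <- small_sim()
  cv_b <- loso_cv(big$cohort, builder_nongenetic(), "TC")
  cv_s <- loso_cv(small_$cohort, builder_nongenetic(), "TC")
  w_b <- diff(bootstrap_ci_r2(cv_b, 300, 3))
  w_s <- diff(bootstrap_ci_r2(cv_s, 300, 3))
  expect_lt(w_b, w_s)
})

test_that("score significance behaves under signal and degenerate input", {
  sim <- cached_sim("h2_check", sim_config(n_subjects = 500, n_causal = 18,
                                           n_null = 10, missing_rate = 0,
                                           seed = 77))
  truth <- sim$truth
  sc <- lipidprs:::new_risk_score(names(truth$genetic_value),
                                  truth$genetic_value, "NCBI", "R", "TC",
                                  "truth")
  expect_lt(score_significance(sim$cohort, sc, "TC"), 1e-10)
  flat <- lipidprs:::new_risk_score(names(truth$genetic_value),
                                    rep(1, length(truth$genetic_value)),
                                    "NCBI", "R", "TC", "flat")
  expect_error(score_significance(sim$cohort, flat, "TC"), "constant")
})

test_that("age-window selection follows the nearest-in-window rule", {
  set.seed(55)
  # subject A has visits at 8.1, 9.9, 12.4; target 10 must pick 9.9
  ph <- phenotype_table(data.frame(
    subject_id = c(rep(sprintf("P%02d", 1:40), each = 3)),
    age = c(8.1, 9.9, 12.4, rep(c(8, 10.4, 14), 39)) +
      c(rep(0, 3), rep(seq(0, 1.9, length.out = 39), each = 3)),
    sex = rep(rbinom(40, 1, 0.5), each = 3),
    bmi = 16 + rnorm(120),
    tc = 150 + rnorm(120, 0, 10)))
  g <- mk_geno(matrix(rbinom(40, 2, 0.3) * 1.0, 40, 1),
               subjects = unique(ph$subject_id), markers = "rs1")
  co <- long_cohort(ph, g, mk_catalog("rs1", 1, "TC"))
  sc <- ncbi_score(g, co$catalog, "TC")
  res <- age_window_analysis(co, sc, target_age = 10, trait = "TC")
  expect_s3_class(res, "age_window_result")
  expect_lte(res$n_included, 40)
  # the subject with all visits outside the window is excluded
  ph2 <- ph
  ph2$age[ph2$subject_id == "P01"] <- c(20, 25, 30)
  co2 <- long_cohort(phenotype_table(ph2), g, co$catalog)
  res2 <- age_window_analysis(co2, sc, target_age = 10, trait = "TC")
  expect_equal(res2$n_included, res$n_included - 1)
  # underpowered window
  expect_error(age_window_analysis(co, sc, target_age = 40, trait = "TC"),
               "underpowered")
})

test_that("model roster table is internally consistent on a small cohort", {
  sim <- small_sim()
  tab <- evaluate_models(sim$cohort, "TC",
                         models = c("non-genetic", "NCBI"),
                         n_boot = 200, boot_seed = 2)
  expect_s3_class(tab, "model_roster")
  expect_equal(tab$model, c("non-genetic", "NCBI"))
  expect_true(all(tab$r2 >= 0 & tab$r2 <= 1))
  expect_equal(tab$delta_r2[2], tab$r2[2] - tab$r2[1])
  expect_true(is.na(tab$delta_r2[1]))
  expect_false(is.na(tab$p_value[2]))
  cvs <- attr(tab, "cv")
  expect_equal(cvs[["NCBI"]]$r2, tab$r2[2])
  expect_true(all(tab$ci_low <= tab$r2 & tab$r2 <= tab$ci_high))
})

test_that("baseline accuracy ignores added null markers", {
  sim <- small_sim_complete()
  cv1 <- loso_cv(sim$cohort, builder_nongenetic(), "TC")
  co2 <- sim$cohort
  set.seed(71)
  extra <- matrix(rbinom(40 * 5, 2, 0.3), 40, 5,
                  dimnames = list(rownames(co2$genotypes$dosage),
                                  paste0("null", 1:5)))
  co2$genotypes <- genotype_matrix(cbind(co2$genotypes$dosage, extra))
  cv2 <- loso_cv(co2, builder_nongenetic(), "TC")
  expect_equal(cv1$r2, cv2$r2, tolerance = 1e-12)
})
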