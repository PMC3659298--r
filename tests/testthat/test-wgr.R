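test_that("genotype dispersion MSx follows its definition", {
  expect_equal(ms_x(matrix(c(0, 2), 2, 1)), 2)
  expect_warning(z <- ms_x(matrix(0, 4, 3)), "degenerate")
  expect_equal(z, 0)
  # column-centred standardized genotypes: ms_x ~ number of markers
  set.seed(4)
  X <- scale(matrix(rnorm(5000), 500, 10))
  expect_equal(ms_x(X), 10, tolerance = 0.02)
  expect_error(ms_x(matrix(numeric(0), 0, 0)), "empty")
})

test_that("prior recipe hits the variance-partition targets", {
  pr <- wgr_priors(var_y = 1, h2 = 0.5, ms_x = 100, penalty = "lasso")
  expect_equal(pr$varE_S, 1.5)
  expect_equal(pr$varE_S / (pr$varE_df - 2), 0.5)   # prior mean of varE
  expect_equal(pr$varU_S / (pr$varU_df - 2), 0.5)
  expect_equal(pr$lambda_value, sqrt(2 * 1 * 100), tolerance = 1e-12)
  expect_equal(pr$lambda_value, 14.1421, tolerance = 1e-4)
  expect_equal(pr$lambda_rate, 1 / pr$lambda_value^2)

  prr <- wgr_priors(var_y = 1, h2 = 0.5, ms_x = 50, penalty = "ridge")
  expect_equal(prr$varBR_S, 0.03)
  expect_equal(prr$varBR_S / (prr$varBR_df - 2), 0.01)

  expect_error(wgr_priors(-1, 0.5, 10, "ridge"), "var_y")
  expect_error(wgr_priors(1, 1.2, 10, "ridge"), "h2")
  expect_error(wgr_priors(1, 0.5, 10, "ridge", df = 4), "df")
})

test_that("sampler is reproducible and validates inputs", {
  sim <- small_sim_complete()
  tf <- lipidprs:::trait_frame(sim$cohort, "TC")
  at <- age_transform(min(tf$age), max(tf$age))
  W <- cbind(1, f_age(tf$age, at), tf$sex, tf$bmi)
  X <- sim$cohort$genotypes$dosage[tf$subject_id, ]
  f1 <- fit_brr(tf$y, W, X, tf$subject_id, n_iter = 400, burnin = 100,
                seed = 6)
  f2 <- fit_brr(tf$y, W, X, tf$subject_id, n_iter = 400, burnin = 100,
                seed = 6)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$chains$varE, f2$chains$varE)
  expect_error(fit_brr(tf$y, W, X, tf$subject_id, n_iter = 100, burnin = 100),
               "exceed")
  expect_error(fit_brr(tf$y, W, X[-1, ], tf$subject_id), "rows")
})

test_that("all-zero marker columns leave prediction to the covariates", {
  set.seed(23)
  n <- 120
  subject <- rep(1:40, each = 3)
  W <- cbind(1, rnorm(n))
  y <- drop(W %*% c(2, 1.5)) + rnorm(40, 0, 1)[subject] + rnorm(n)
  X0 <- matrix(0, n, 4, dimnames = list(NULL, paste0("z", 1:4)))
  pr <- wgr_priors(var(y), 0.5, 1, penalty = "ridge")  # ms_x supplied directly
  fit <- fit_wgr(y, W, X0, subject, pr, n_iter = 2000, burnin = 500, seed = 9)
  expect_lt(max(abs(fit$beta)), 0.2)
  pred <- predict(fit, X0[1:5, ], W[1:5, ])
  expect_equal(pred, drop(W[1:5, ] %*% fit$theta), tolerance = 1e-8)
})

test_that("weak shrinkage approaches the least-squares solution", {
  set.seed(33)
  n <- 300
  X <- cbind(m1 = rnorm(n), m2 = rnorm(n))
  y <- drop(X %*% c(1.2, -0.7)) + rnorm(n)
  pr <- wgr_priors(var(y), 0.5, ms_x(X), penalty = "ridge")
  pr$varBR_df <- -1; pr$varBR_S <- 1e6    # pin the marker variance huge
  fit <- fit_wgr(y, matrix(1, n, 1), X, subject = NULL, pr,
                 n_iter = 4000, burnin = 1000, seed = 2)
  ols <- coef(lm(y ~ X))
  expect_equal(unname(fit$beta), unname(ols[-1]), tolerance = 0.02)
  # and pinning it at ~0 shrinks the effects away
  pr0 <- pr; pr0$varBR_S <- 1e-8
  fit0 <- fit_wgr(y, matrix(1, n, 1), X, NULL, pr0, n_iter = 2000,
                  burnin = 500, seed = 2)
  expect_lt(max(abs(fit0$beta)), 1e-2)
})

test_that("posterior prediction is the stated linear rule", {
  obj <- structure(list(beta = c(a = 0.5, b = -1), theta = c(i = 10, s = 2),
                        penalty = "ridge"), class = "wgr_fit")
  Xn <- matrix(c(2, 1,
                 0, 1), 2, 2, byrow = TRUE)
  Wn <- matrix(c(1, 3,
                 1, 0), 2, 2, byrow = TRUE)
  expect_equal(predict(obj, Xn, Wn), c(2 * 0.5 - 1 + 10 + 6, -1 + 10))
  expect_equal(predict(obj, 2 * Xn, Wn) - predict(obj, Xn, Wn),
               as.vector(Xn %*% obj$beta))
  expect_error(predict(obj, Xn[, 1, drop = FALSE], Wn), "mismatch")
})

test_that("chains pass stationarity and effective-size sanity checks", {
  sim <- small_sim_complete()
  tf <- lipidprs:::trait_frame(sim$cohort, "TC")
  at <- age_transform(min(tf$age), max(tf$age))
  W <- cbind(1, f_age(tf$age, at), tf$sex, tf$bmi)
  X <- sim$cohort$genotypes$dosage[tf$subject_id, ]
  fit <- fit_blr(tf$y, W, X, tf$subject_id, n_iter = 4000, burnin = 1000,
                 thin = 2, seed = 14)
  gz <- geweke_z(fit$chains$varE)
  expect_lt(abs(gz[["z"]]), 3)
  expect_gt(fit$ess[["varE"]], 50)
  # iid noise has effective size near its length
  set.seed(1)
  expect_gt(ess(rnorm(2000)), 1200)
})
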