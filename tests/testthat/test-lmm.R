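test_that("fixed effects equal the dense GLS solve at the fitted components", {
  for (s in 1:20) {
    inst <- rand_instance(100 + s)
    fit <- lmm_ri(inst$y, inst$X, inst$subject, method = "REML")
    oracle <- drop(dense_gls(inst$y, inst$X, inst$subject,
                             fit$var_subject, fit$var_residual))
    expect_lt(max(abs(coef(fit) - oracle)), 1e-10)
  }
})

test_that("estimates and likelihoods agree with lme4", {
  skip_if_not_installed("lme4")
  set.seed(17)
  subject <- rep(1:40, each = 5)
  x1 <- rnorm(200); x2 <- rbinom(200, 1, 0.5)
  y <- 2 + 1.5 * x1 - 0.8 * x2 + rnorm(40, 0, 1.3)[subject] + rnorm(200)
  for (m in c("REML", "ML")) {
    fit <- lmm_ri(y, cbind(1, x1, x2), subject, method = m)
    lf <- lme4::lmer(y ~ x1 + x2 + (1 | subject), REML = (m == "REML"))
    expect_equal(unname(coef(fit)), unname(lme4::fixef(lf)), tolerance = 1e-6)
    expect_equal(fit$loglik, as.numeric(logLik(lf)), tolerance = 1e-6)
    expect_equal(fit$var_subject, unname(unlist(lme4::VarCorr(lf))[1]),
                 tolerance = 1e-4)
    expect_equal(unname(fit$se), unname(sqrt(diag(as.matrix(vcov(lf))))),
                 tolerance = 1e-5)
  }
})

test_that("ML optimum beats a fine grid search over the variance ratio", {
  for (s in 1:5) {
    inst <- rand_instance(300 + s)
    fit <- lmm_ri(inst$y, inst$X, inst$subject, method = "ML")
    grid <- c(0, exp(seq(-8, 8, length.out = 250)))
    grid_ll <- vapply(grid, function(g)
      dense_ml_loglik(inst$y, inst$X, inst$subject, g), numeric(1))
    expect_gte(fit$loglik, max(grid_ll) - 1e-6)
    expect_equal(fit$aic, 2 * (ncol(inst$X) + 2) - 2 * fit$loglik)
  }
})

test_that("one observation per subject collapses to ordinary least squares", {
  set.seed(5)
  x <- rnorm(30)
  y <- 1 + 2 * x + rnorm(30)
  fit <- lmm_ri(y, cbind(1, x), subject = seq_len(30))
  expect_true(fit$boundary)
  expect_equal(fit$var_subject, 0)
  expect_equal(unname(coef(fit)), unname(coef(lm(y ~ x))), tolerance = 1e-8)
})

test_that("prediction is the fixed part only and is linear in the design", {
  set.seed(8)
  subject <- rep(1:15, each = 3)
  x <- rnorm(45)
  y <- 3 + 2 * x + rnorm(15, 0, 2)[subject] + rnorm(45)
  fit <- lmm_ri(y, cbind(int = 1, x = x), subject)
  b <- coef(fit)
  # intercept-only row
  expect_equal(predict(fit, matrix(c(1, 0), 1)), unname(b["int"]))
  # hand-computed two-coefficient prediction for an unseen subject
  expect_equal(predict(fit, matrix(c(1, 2.5), 1)),
               unname(b["int"] + 2.5 * b["x"]))
  # doubling a covariate doubles its contribution
  p1 <- predict(fit, matrix(c(0, 1), 1))
  p2 <- predict(fit, matrix(c(0, 2), 1))
  expect_equal(p2, 2 * p1)
  expect_error(predict(fit, matrix(1, 1, 3)), "columns")
})

test_that("input validation catches degenerate designs", {
  set.seed(2)
  subject <- rep(1:10, each = 3)
  x <- rnorm(30)
  expect_error(lmm_ri(rnorm(30), cbind(1, x, x), subject), "rank deficient")
  expect_error(lmm_ri(rnorm(30), cbind(1, x), rep(1, 30)), "2 subjects")
  expect_error(lmm_ri(rnorm(5), cbind(1, rnorm(5), rnorm(5), rnorm(5)),
                      c(1, 1, 2, 2, 3)), "observations")
})

test_that("Wald test follows the normal-quantile identity", {
  set.seed(12)
  subject <- rep(1:20, each = 3)
  x <- rnorm(60)
  y <- 1 + 0.5 * x + rnorm(20, 0, 1)[subject] + rnorm(60)
  fit <- lmm_ri(y, cbind(int = 1, x = x), subject)
  ct <- coef_test(fit, "x")
  z <- ct[["estimate"]] / ct[["se"]]
  expect_equal(ct[["p_value"]], 2 * pnorm(-abs(z)), tolerance = 1e-12)
  tab <- summary(fit)$coefficients
  expect_equal(unname(tab["x", "Pr(>|z|)"]), ct[["p_value"]])
})

test_that("null coefficients give uniform Wald p-values", {
  set.seed(99)
  pvals <- replicate(200, {
    subject <- rep(1:15, each = 3)
    x <- rnorm(15)[subject]          # subject-level null covariate
    y <- 5 + rnorm(15, 0, 1.5)[subject] + rnorm(45)
    fit <- lmm_ri(y, cbind(1, x = x), subject)
    coef_test(fit, "x")[["p_value"]]
  })
  rate <- mean(pvals < 0.05)
  # binomial 99% interval around 0.05 at 200 replicates
  expect_lt(abs(rate - 0.05), 0.05)
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})
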