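#' Predictive R-squared
#'
#' The squared sample Pearson correlation between observed and predicted
#' values — the accuracy measure used for all cross-validated comparisons.
#'
#' @param observed,predicted numeric vectors of equal length (>= 3), neither
#'   constant.
#' @return Scalar in \[0, 1\].
#' @export
r2 <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("r2: vectors must have equal length")
  if (length(observed) < 3L) stop("r2: need at least 3 observations")
  if (sd(observed) == 0 || sd(predicted) == 0)
    stop("r2: constant input, correlation undefined")
  cor(observed, predicted)^2
}

# covariate design at a given age transform
design_w <- function(tf, at) {
  cbind(intercept = 1, fage = f_age(tf$age, at), sex = tf$sex, bmi = tf$bmi)
}

#' Leave-one-subject-out cross-validation
#'
#' For each subject, a model is fitted on all other subjects' observations
#' and used to predict every observation of the held-out subject through its
#' fixed (population-level) part only; a subject's repeated measurements are
#' always excluded together, so no quantity derived from the held-out
#' subject's phenotypes can reach their predictions. Predictive accuracy is
#' the squared Pearson correlation between observed and predicted values
#' pooled over all observations ([r2()]).
#'
#' @param cohort a [long_cohort()].
#' @param model_builder a builder such as [builder_nongenetic()]: a function
#'   `(training cohort, trait)` returning a prediction function
#'   `(held-out trait rows, full genotype matrix, training subject ids)`.
#' @param trait lipid label.
#' @param subjects optional subset of subjects to hold out (all by default);
#'   R-squared is computed over the predicted pool.
#' @param progress print per-fold progress.
#' @return A `cv_result`: per-observation records, `model_label`, `r2`,
#'   `n_subjects`, `n_obs` (fields `r2_ci`, `delta_r2`, `p_value` are filled
#'   by [evaluate_models()] / [bootstrap_ci_r2()]).
#' @export
loso_cv <- function(cohort, model_builder, trait, subjects = NULL,
                    progress = FALSE) {
  trait <- match.arg(trait, TRAITS)
  tf_all <- trait_frame(cohort, trait)
  all_subjects <- unique(tf_all$subject_id)
  folds <- if (is.null(subjects)) all_subjects else {
    stopifnot(all(subjects %in% all_subjects))
    subjects
  }
  records <- vector("list", length(folds))
  for (fi in seq_along(folds)) {
    s <- folds[[fi]]
    train_ids <- setdiff(all_subjects, s)
    train <- subset_cohort(cohort, train_ids)
    predictor <- tryCatch(model_builder(train, trait), error = function(e)
      stop("loso_cv: model builder failed on fold for subject ", s, ": ",
           conditionMessage(e)))
    tf_i <- tf_all[tf_all$subject_id == s, , drop = FALSE]
    pred <- suppressWarnings(predictor(tf_i, cohort$genotypes, train_ids))
    records[[fi]] <- data.frame(subject_id = s, age = tf_i$age,
                                observed = tf_i$y, predicted = pred,
                                stringsAsFactors = FALSE)
    if (progress) message("loso_cv: fold ", fi, "/", length(folds))
  }
  rec <- do.call(rbind, records)
  label <- attr(model_builder, "label")
  structure(list(records = rec,
                 model_label = if (is.null(label)) "custom" else label,
                 r2 = r2(rec$observed, rec$predicted),
                 r2_ci = NULL, delta_r2 = NA_real_, p_value = NA_real_,
                 n_subjects = length(folds), n_obs = nrow(rec)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Leave-one-subject-out CV [%s]: R2 = %.3f (%d subjects, %d observations)\n",
              x$model_label, x$r2, x$n_subjects, x$n_obs))
  if (!is.null(x$r2_ci))
    cat(sprintf("  95%% cluster-bootstrap CI (%.3f, %.3f)\n",
                x$r2_ci[1], x$r2_ci[2]))
  if (!is.na(x$delta_r2))
    cat(sprintf("  delta R2 vs non-genetic baseline = %.3f (p = %.3g)\n",
                x$delta_r2, x$p_value))
  invisible(x)
}

#' Observed-versus-predicted plot for a CV result
#' @param x a [loso_cv()] result.
#' @param ... passed to [plot()].
#' @export
plot.cv_result <- function(x, ...) {
  plot(x$records$predicted, x$records$observed,
       xlab = "Predicted (mg/dL)", ylab = "Observed (mg/dL)",
       main = sprintf("%s: R2 = %.3f", x$model_label, x$r2),
       pch = 19, col = "#00000055", ...)
  abline(lm(observed ~ predicted, data = x$records), col = "red3")
  invisible(x)
}

#' Cluster-bootstrap confidence interval for predictive R-squared
#'
#' Resamples subjects (not observations) with replacement, pools the
#' resampled subjects' observation records, recomputes R-squared, and
#' returns the percentile 95% interval. Subject-level resampling respects
#' the within-subject dependence of repeated measurements. Degenerate
#' resamples (constant pools) are redrawn, up to a bounded number of tries.
#'
#' @param result a [loso_cv()] result.
#' @param n_boot number of resamples (>= 200; default 1000).
#' @param seed integer RNG seed.
#' @return Numeric vector `c(low, high)`.
#' @export
bootstrap_ci_r2 <- function(result, n_boot = 1000L, seed = 1L) {
  stopifnot(inherits(result, "cv_result"))
  if (n_boot < 200L) stop("bootstrap_ci_r2: n_boot must be at least 200")
  rec <- result$records
  by_subj <- split(rec, rec$subject_id)
  subj <- names(by_subj)
  set.seed(as.integer(seed))
  stat <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    for (try in 1:50) {
      pick <- sample(subj, length(subj), replace = TRUE)
      pool <- do.call(rbind, by_subj[pick])
      if (sd(pool$observed) > 0 && sd(pool$predicted) > 0) break
      if (try == 50L) stop("bootstrap_ci_r2: degenerate resamples")
    }
    stat[b] <- r2(pool$observed, pool$predicted)
  }
  unname(quantile(stat, c(0.025, 0.975)))
}

#' Significance of a risk score in the full-cohort mixed model
#'
#' Regresses the lipid trait on the score while controlling for the fixed
#' covariates (intercept, sine age, sex, BMI) and the random subject
#' intercept, and returns the Wald p-value of the score coefficient.
#'
#' @param cohort a [long_cohort()].
#' @param scores a `risk_score` (e.g. from [ncbi_score()] or [bhs_score()]).
#' @param trait lipid label.
#' @return Scalar p-value.
#' @export
score_significance <- function(cohort, scores, trait) {
  stopifnot(inherits(scores, "risk_score"))
  tf <- trait_frame(cohort, trait)
  if (!all(unique(tf$subject_id) %in% names(scores$scores)))
    stop("score_significance: scores missing for some subjects")
  sc <- scores$scores[tf$subject_id]
  if (sd(sc) == 0) stop("score_significance: constant scores")
  at <- age_transform(min(tf$age), max(tf$age))
  W <- cbind(design_w(tf, at), score = sc)
  fit <- lmm_ri(tf$y, W, tf$subject_id, method = "REML")
  unname(coef_test(fit, "score")[["p_value"]])
}

# ---- model builders --------------------------------------------------------

#' Model builders for leave-one-subject-out cross-validation
#'
#' Each builder returns a function `(training cohort, trait)` ->
#' `(held-out trait rows, genotype matrix, training subject ids)` ->
#' predictions, suitable for [loso_cv()]. The age transform and all
#' imputation references come from the training split.
#'
#' * `builder_nongenetic()`: covariates only (intercept, sine age, sex, BMI)
#'   with a random subject intercept.
#' * `builder_ncbi()`: adds the published-weight risk score ([ncbi_score()])
#'   as a fifth fixed covariate.
#' * `builder_bhs(marker_set)`: adds the within-cohort score. Training
#'   subjects' scores use marker effects excluding both the training subject
#'   and the held-out subject (nested leave-one-out, via GLS downdating);
#'   the held-out subject's score uses effects estimated from the full
#'   training split.
#' * `builder_wgr(penalty, marker_set, ...)`: Bayesian lasso/ridge
#'   whole-genome regression fitted on the training split; prediction is
#'   `X beta_bar + W theta_bar`. The sampler is re-seeded identically each
#'   fold, so the builder is deterministic.
#'
#' @param marker_set `"A"` (all catalogued markers) or `"R"` (trait-reported
#'   markers only).
#' @param penalty `"lasso"` or `"ridge"`.
#' @param h2 assumed heritability for the prior recipe.
#' @param n_iter,burnin,thin,seed MCMC controls passed to [fit_wgr()].
#' @return A builder function carrying a `label` attribute.
#' @name builders
NULL

#' @rdname builders
#' @export
builder_nongenetic <- function() {
  f <- function(train, trait) {
    tf <- trait_frame(train, trait)
    at <- age_transform(min(tf$age), max(tf$age))
    fit <- lmm_ri(tf$y, design_w(tf, at), tf$subject_id, method = "REML")
    function(tf_new, genotypes, train_ids)
      predict(fit, design_w(tf_new, at))
  }
  structure(f, label = "non-genetic")
}

#' @rdname builders
#' @export
builder_ncbi <- function() {
  f <- function(train, trait) {
    tf <- trait_frame(train, trait)
    at <- age_transform(min(tf$age), max(tf$age))
    sc_train <- ncbi_score(train$genotypes, train$catalog, trait)
    W <- cbind(design_w(tf, at), score = sc_train$scores[tf$subject_id])
    fit <- lmm_ri(tf$y, W, tf$subject_id, method = "REML")
    function(tf_new, genotypes, train_ids) {
      sc_new <- ncbi_score(genotypes, train$catalog, trait,
                           reference_subjects = train_ids)
      Wn <- cbind(design_w(tf_new, at),
                  score = sc_new$scores[tf_new$subject_id])
      predict(fit, Wn)
    }
  }
  structure(f, label = "NCBI")
}

#' @rdname builders
#' @export
builder_bhs <- function(marker_set = c("R", "A")) {
  marker_set <- match.arg(marker_set)
  f <- function(train, trait) {
    tf <- trait_frame(train, trait)
    at <- age_transform(min(tf$age), max(tf$age))
    eff <- suppressWarnings(
      loo_marker_effects(train, trait, marker_set, mode = "fast",
                         vc = "shared"))
    phi <- bhs_score(eff, train$genotypes)
    W <- cbind(design_w(tf, at), score = phi$scores[tf$subject_id])
    fit <- lmm_ri(tf$y, W, tf$subject_id, method = "REML")
    # effects from the whole training split, for the held-out subject's score
    ids <- colnames(eff)
    agg <- subject_aggregates(tf, at)
    vcfit <- lmm_ri(tf$y, agg$W, tf$subject_id, method = "REML")
    gfull <- impute_missing_dosages(train$genotypes)
    Xtr <- gfull$dosage[agg$subjects, ids, drop = FALSE]
    beta_train <- gls_marker_effects(agg, Xtr, vcfit$gamma,
                                     rep(TRUE, agg$n))$beta
    function(tf_new, genotypes, train_ids) {
      gnew <- impute_missing_dosages(genotypes, reference_subjects = train_ids)
      x_new <- gnew$dosage[tf_new$subject_id[1], ids]
      phi_new <- sum(x_new * beta_train)
      Wn <- cbind(design_w(tf_new, at), score = phi_new)
      predict(fit, Wn)
    }
  }
  structure(f, label = paste0("BHS-", marker_set))
}

#' @rdname builders
#' @export
builder_wgr <- function(penalty = c("lasso", "ridge"),
                        marker_set = c("R", "A"), h2 = 0.5,
                        n_iter = 2000L, burnin = 500L, thin = 2L,
                        seed = 101L) {
  penalty <- match.arg(penalty)
  marker_set <- match.arg(marker_set)
  f <- function(train, trait) {
    tf <- trait_frame(train, trait)
    at <- age_transform(min(tf$age), max(tf$age))
    ids <- marker_set_ids(train$catalog, marker_set, trait)
    ids <- ids[ids %in% marker_ids(train$genotypes)]
    gtr <- impute_missing_dosages(train$genotypes)
    X <- gtr$dosage[tf$subject_id, ids, drop = FALSE]
    W <- design_w(tf, at)
    fit <- fit_wgr(tf$y, W, X, tf$subject_id,
                   wgr_priors(var(tf$y), h2, ms_x(X), penalty = penalty),
                   n_iter = n_iter, burnin = burnin, thin = thin, seed = seed)
    function(tf_new, genotypes, train_ids) {
      gnew <- impute_missing_dosages(genotypes, reference_subjects = train_ids)
      Xn <- gnew$dosage[tf_new$subject_id, ids, drop = FALSE]
      predict(fit, Xn, design_w(tf_new, at))
    }
  }
  structure(f, label = paste0(if (penalty == "lasso") "BLR-" else "BRR-",
                              marker_set))
}

default_roster <- function(mcmc = list()) {
  mc <- modifyList(list(n_iter = 2000L, burnin = 500L, thin = 2L,
                        seed = 101L), mcmc)
  list(
    "non-genetic" = builder_nongenetic(),
    "NCBI" = builder_ncbi(),
    "BHS-A" = builder_bhs("A"),
    "BHS-R" = builder_bhs("R"),
    "BLR-A" = builder_wgr("lasso", "A", n_iter = mc$n_iter,
                          burnin = mc$burnin, thin = mc$thin, seed = mc$seed),
    "BLR-R" = builder_wgr("lasso", "R", n_iter = mc$n_iter,
                          burnin = mc$burnin, thin = mc$thin, seed = mc$seed),
    "BRR-A" = builder_wgr("ridge", "A", n_iter = mc$n_iter,
                          burnin = mc$burnin, thin = mc$thin, seed = mc$seed),
    "BRR-R" = builder_wgr("ridge", "R", n_iter = mc$n_iter,
                          burnin = mc$burnin, thin = mc$thin, seed = mc$seed))
}

#' Cross-validated comparison of the full model roster
#'
#' Runs leave-one-subject-out cross-validation for the non-genetic baseline
#' and the genomic risk models (published-weight NCBI score, within-cohort
#' BHS scores, Bayesian lasso and ridge whole-genome regression, each on the
#' trait-reported R set and the all-markers A set), and tabulates predictive
#' R-squared, its cluster-bootstrap confidence interval, the gain over the
#' baseline (delta R-squared), and — for the score-based models — the Wald
#' p-value of the score coefficient in the full-cohort mixed model.
#'
#' @param cohort a [long_cohort()].
#' @param trait lipid label.
#' @param models character subset of
#'   `c("non-genetic","NCBI","BHS-A","BHS-R","BLR-A","BLR-R","BRR-A","BRR-R")`.
#' @param mcmc list overriding the sampler controls for the BLR/BRR builders
#'   (`n_iter`, `burnin`, `thin`, `seed`).
#' @param n_boot bootstrap resamples for the CI (0 to skip).
#' @param boot_seed seed for the bootstrap.
#' @param progress print per-model progress.
#' @return A `model_roster` data frame (one row per model) with the list of
#'   `cv_result` objects attached as attribute `cv`.
#' @export
evaluate_models <- function(cohort, trait,
                            models = c("non-genetic", "NCBI", "BHS-A",
                                       "BHS-R", "BLR-A", "BLR-R", "BRR-A",
                                       "BRR-R"),
                            mcmc = list(), n_boot = 0L, boot_seed = 1L,
                            progress = FALSE) {
  roster <- default_roster(mcmc)
  models <- match.arg(models, names(roster), several.ok = TRUE)
  if (!"non-genetic" %in% models)
    models <- c("non-genetic", models)
  cvs <- list()
  for (mname in models) {
    if (progress) message("evaluate_models: ", mname)
    cvs[[mname]] <- loso_cv(cohort, roster[[mname]], trait)
  }
  base_r2 <- cvs[["non-genetic"]]$r2
  rows <- lapply(models, function(mname) {
    cv <- cvs[[mname]]
    if (n_boot > 0) cv$r2_ci <- bootstrap_ci_r2(cv, n_boot, boot_seed)
    cv$delta_r2 <- if (mname == "non-genetic") NA_real_ else cv$r2 - base_r2
    cv$p_value <- NA_real_
    if (mname == "NCBI") {
      sc <- ncbi_score(cohort$genotypes, cohort$catalog, trait)
      cv$p_value <- score_significance(cohort, sc, trait)
    } else if (grepl("^BHS", mname)) {
      eff <- suppressWarnings(loo_marker_effects(
        cohort, trait, sub("BHS-", "", mname), mode = "fast"))
      sc <- bhs_score(eff, cohort$genotypes)
      cv$p_value <- score_significance(cohort, sc, trait)
    }
    cvs[[mname]] <<- cv
    data.frame(model = mname, r2 = cv$r2,
               ci_low = if (is.null(cv$r2_ci)) NA_real_ else cv$r2_ci[1],
               ci_high = if (is.null(cv$r2_ci)) NA_real_ else cv$r2_ci[2],
               delta_r2 = cv$delta_r2, p_value = cv$p_value,
               n_subjects = cv$n_subjects, n_obs = cv$n_obs,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "cv") <- cvs
  attr(out, "trait") <- trait
  class(out) <- c("model_roster", "data.frame")
  out
}

#' @export
print.model_roster <- function(x, digits = 3, ...) {
  cat(sprintf("Cross-validated predictive accuracy (%s):\n",
              attr(x, "trait")))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

# ---- age-window analysis ---------------------------------------------------

# leave-one-out OLS predictions via the hat matrix
loo_ols_pred <- function(fit) {
  h <- stats::hatvalues(fit)
  fit$model[[1]] - stats::residuals(fit) / (1 - h)
}

#' Age-window predictive accuracy of a risk score
#'
#' Assesses the score at a target age: each subject contributes at most one
#' observation — the one closest to `target_age` among those within
#' `window` years of it. With one observation per subject the random
#' intercept is unidentifiable, so ordinary linear models are used, with
#' covariates (intercept, sine age, sex, BMI) and optionally the subject's
#' most recent lipid measurement strictly before the selected observation
#' (subjects lacking any earlier measurement are dropped, with the count
#' reported). The gain `delta_r2` is the difference in predictive R-squared
#' between the model with and without the score, both evaluated on exact
#' leave-one-out predictions; `p_value` is the Wald p of the score term.
#'
#' @param cohort a [long_cohort()].
#' @param scores a `risk_score`.
#' @param target_age target age in years (e.g. 10, 20, 30, 40).
#' @param use_previous include the most recent previous lipid measurement as
#'   a covariate.
#' @param trait lipid label.
#' @param window half-width of the age window in years (default 2.5).
#' @return An `age_window_result` list: `target_age`, `window`,
#'   `use_previous`, `n_included`, `r2_with`, `r2_without`, `delta_r2`,
#'   `p_value`.
#' @export
age_window_analysis <- function(cohort, scores, target_age,
                                use_previous = FALSE, trait, window = 2.5) {
  stopifnot(inherits(scores, "risk_score"))
  tf <- trait_frame(cohort, trait)
  at <- age_transform(min(tf$age), max(tf$age))
  picked <- lapply(split(tf, tf$subject_id), function(d) {
    inwin <- abs(d$age - target_age) <= window
    if (!any(inwin)) return(NULL)
    sel <- d[inwin, , drop = FALSE]
    sel <- sel[which.min(abs(sel$age - target_age)), , drop = FALSE]
    if (use_previous) {
      earlier <- d$age < sel$age
      if (!any(earlier)) return(NULL)
      sel$previous <- d$y[earlier][which.max(d$age[earlier])]
    }
    sel
  })
  n_dropped <- sum(vapply(picked, is.null, logical(1)))
  dat <- do.call(rbind, picked[!vapply(picked, is.null, logical(1))])
  if (use_previous && n_dropped > 0)
    message("age_window_analysis: ", n_dropped,
            " subject(s) excluded (no in-window or no previous measurement)")
  if (is.null(dat) || nrow(dat) < 30L)
    stop("age_window_analysis: window underpowered (",
         if (is.null(dat)) 0 else nrow(dat), " subjects)")
  dat$fage <- suppressWarnings(f_age(dat$age, at))
  dat$score <- scores$scores[dat$subject_id]
  base_form <- if (use_previous) y ~ fage + sex + bmi + previous
               else y ~ fage + sex + bmi
  fit0 <- lm(base_form, data = dat)
  fit1 <- lm(update(base_form, . ~ . + score), data = dat)
  r2_without <- r2(dat$y, loo_ols_pred(fit0))
  r2_with <- r2(dat$y, loo_ols_pred(fit1))
  ct <- summary(fit1)$coefficients
  structure(list(target_age = target_age, window = window,
                 use_previous = use_previous, n_included = nrow(dat),
                 r2_with = r2_with, r2_without = r2_without,
                 delta_r2 = r2_with - r2_without,
                 p_value = ct["score", "Pr(>|t|)"]),
            class = "age_window_result")
}

#' @export
print.age_window_result <- function(x, ...) {
  cat(sprintf("Age %g +/- %g y (%s previous measurement): n = %d, delta R2 = %.3f (p = %.3g)\n",
              x$target_age, x$window,
              if (x$use_previous) "with" else "without",
              x$n_included, x$delta_r2, x$p_value))
  invisible(x)
}
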