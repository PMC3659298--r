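#' Sine age transform
#'
#' Lipid levels tend to follow a sigmoidal trend over the life course. Rather
#' than leaving the linear-model framework, age can be replaced by the bounded
#' transform
#' \deqn{f(a) = \sin\!\Big(\frac{\pi}{2}\cdot
#'   \frac{2a - a_{max} - a_{min}}{a_{max} - a_{min}}\Big),}
#' which equals -1 at the study minimum age, +1 at the study maximum age, and
#' is strictly increasing in between, so a single coefficient on \eqn{f(a)}
#' captures a saturating age trend.
#'
#' @param a_min,a_max study minimum and maximum age in years; `a_max` must
#'   exceed `a_min`.
#' @return An object of class `age_transform` with fields `a_min` and `a_max`.
#' @examples
#' at <- age_transform(4, 48)
#' f_age(c(4, 26, 48), at)   # -1, 0, 1
#' @seealso [f_age()], [compare_age_models()]
#' @export
age_transform <- function(a_min, a_max) {
  stopifnot(is.numeric(a_min), is.numeric(a_max),
            length(a_min) == 1L, length(a_max) == 1L,
            is.finite(a_min), is.finite(a_max))
  if (a_max <= a_min)
    stop("age_transform: a_max must be strictly greater than a_min")
  structure(list(a_min = a_min, a_max = a_max), class = "age_transform")
}

#' Evaluate the sine age transform
#'
#' Ages outside `[a_min, a_max]` are clamped to the nearest boundary with a
#' warning (this happens routinely when a transform fitted on a training split
#' is applied to a held-out subject whose ages fall just outside the training
#' span).
#'
#' @param age numeric vector of ages in years.
#' @param transform an [age_transform()] object.
#' @return Numeric vector in \[-1, 1\].
#' @export
f_age <- function(age, transform) {
  stopifnot(inherits(transform, "age_transform"), is.numeric(age))
  a_min <- transform$a_min
  a_max <- transform$a_max
  out_of_range <- !is.na(age) & (age < a_min | age > a_max)
  if (any(out_of_range)) {
    warning(sprintf("f_age: %d age(s) outside [%g, %g] clamped to boundary",
                    sum(out_of_range), a_min, a_max))
    age <- pmin(pmax(age, a_min), a_max)
  }
  sin((pi / 2) * (2 * age - a_max - a_min) / (a_max - a_min))
}

#' @export
print.age_transform <- function(x, ...) {
  cat(sprintf("Sine age transform on [%g, %g] years\n", x$a_min, x$a_max))
  invisible(x)
}

#' Compare linear and sine age terms by AIC
#'
#' Fits the non-genetic random-intercept mixed model (trait ~ intercept + age
#' term + sex + BMI, random subject intercept) twice by maximum likelihood,
#' once with age entered linearly and once through the sine transform
#' [f_age()], and returns both AIC values. Both models have the same number of
#' parameters, so the AIC comparison is a pure log-likelihood comparison.
#'
#' @param cohort a [long_cohort()] object.
#' @param trait one of `"HDL"`, `"LDL"`, `"TC"`, `"TG"` (must be present in
#'   the cohort phenotypes).
#' @return Named numeric vector `c(aic_linear=, aic_sine=)`.
#' @export
compare_age_models <- function(cohort, trait) {
  ph <- trait_frame(cohort, trait)
  at <- age_transform(min(ph$age), max(ph$age))
  W_lin  <- cbind(intercept = 1, age = ph$age, sex = ph$sex, bmi = ph$bmi)
  W_sine <- cbind(intercept = 1, age = f_age(ph$age, at), sex = ph$sex,
                  bmi = ph$bmi)
  fit_lin  <- lmm_ri(ph$y, W_lin,  ph$subject_id, method = "ML")
  fit_sine <- lmm_ri(ph$y, W_sine, ph$subject_id, method = "ML")
  if (!fit_lin$converged || !fit_sine$converged)
    stop("compare_age_models: mixed-model fit did not converge")
  c(aic_linear = fit_lin$aic, aic_sine = fit_sine$aic)
}
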