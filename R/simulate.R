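#' Simulation configuration for a synthetic longitudinal lipid cohort
#'
#' Defaults emulate a longitudinal cardiovascular cohort of 523 unrelated
#' subjects surveyed repeatedly between ages 4 and 48, with a mean of 7.7
#' visits per subject (4--13 per subject, roughly 3 years apart), and a
#' polygenic lipid trait: random subject intercept + sine-shaped age trend +
#' sex and BMI effects + additive marker effects + residual noise.
#'
#' @param n_subjects number of subjects.
#' @param visits_range integer `(min, max)` visits per subject.
#' @param visits_mean target mean visits per subject; the per-subject visit
#'   count is `min + Binomial(max - min, p)` with `p` solving the mean, so
#'   the expectation is exact by construction.
#' @param age_span `(a_min, a_max)` study age span in years.
#' @param n_causal,n_null numbers of causal and null markers
#'   (`n_markers = n_causal + n_null`). The default 18/42 split mirrors the
#'   composition of a lipid GWAS catalog in which roughly 30% of all
#'   catalogued markers are reported for any one trait, so the trait-reported
#'   (R) set is the causal subset and the all-markers (A) set is null-heavy.
#' @param maf_range minor-allele-frequency range, drawn uniformly per marker.
#' @param heritability_target fraction of the non-covariate phenotypic
#'   variance (genetic + subject + residual) attributable to the causal
#'   markers; achieved exactly in expectation by scaling the effect sizes.
#' @param subject_sd random subject-intercept SD (mg/dL).
#' @param residual_sd residual SD (mg/dL).
#' @param mu phenotype intercept (mg/dL).
#' @param age_effect coefficient (mg/dL) on the sine age transform.
#' @param sex_effect,bmi_effect fixed covariate effects (mg/dL per unit).
#' @param weight_noise_sd SD (mg/dL) of the estimation noise added to the
#'   true effects when emitting the "published" catalog weights.
#' @param missing_rate per-entry genotype missingness probability.
#' @param trait lipid label the simulated phenotype is written under; causal
#'   markers are catalogued under this trait (the R set), null markers under
#'   the other traits (so the A set contains all markers).
#' @param seed integer RNG seed (the generator is fully reproducible).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_subjects = 523L,
                       visits_range = c(4L, 13L),
                       visits_mean = 7.7,
                       age_span = c(4, 48),
                       n_causal = 18L, n_null = 42L,
                       maf_range = c(0.1, 0.5),
                       heritability_target = 0.5,
                       subject_sd = 15, residual_sd = 15,
                       mu = 140, age_effect = 20,
                       sex_effect = -5, bmi_effect = 1.5,
                       weight_noise_sd = 1.5,
                       missing_rate = 0.01,
                       trait = "TC",
                       seed = 20130521L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              visits_range = as.integer(visits_range),
              visits_mean = visits_mean,
              age_span = as.numeric(age_span),
              n_causal = as.integer(n_causal), n_null = as.integer(n_null),
              maf_range = as.numeric(maf_range),
              heritability_target = heritability_target,
              subject_sd = subject_sd, residual_sd = residual_sd,
              mu = mu, age_effect = age_effect,
              sex_effect = sex_effect, bmi_effect = bmi_effect,
              weight_noise_sd = weight_noise_sd,
              missing_rate = missing_rate,
              trait = match.arg(trait, TRAITS),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_subjects >= 2, n_causal >= 0, n_null >= 0,
              visits_range[1] >= 1, visits_range[2] >= visits_range[1],
              age_span[2] > age_span[1],
              maf_range[1] > 0, maf_range[2] <= 0.5,
              maf_range[2] >= maf_range[1],
              heritability_target > 0, heritability_target < 1,
              subject_sd >= 0, residual_sd >= 0, weight_noise_sd >= 0,
              missing_rate >= 0, missing_rate < 1)
  })
  if (cfg$visits_mean < cfg$visits_range[1] || cfg$visits_mean > cfg$visits_range[2])
    cfg$visits_mean <- mean(cfg$visits_range)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate an additive-dosage genotype matrix
#'
#' Per-marker allele frequencies are drawn uniformly from `maf_range`;
#' dosages are Binomial(2, MAF) independently across subjects (no linkage
#' disequilibrium); entries are masked missing with probability
#' `missing_rate`.
#'
#' @param cfg a [sim_config()].
#' @return List with `genotypes` (a [genotype_matrix()], possibly with
#'   missing entries), `complete` (the unmasked dosage matrix) and `maf`.
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_subjects
  m <- cfg$n_causal + cfg$n_null
  if (m == 0L) stop("simulate_genotypes: no markers configured")
  maf <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
  d <- vapply(maf, function(p) rbinom(n, 2L, p), numeric(n))
  subj <- sprintf("S%04d", seq_len(n))
  mk <- sprintf("rs%06d", seq_len(m))
  dimnames(d) <- list(subj, mk)
  complete <- d
  if (cfg$missing_rate > 0) {
    mask <- matrix(runif(n * m) < cfg$missing_rate, n, m)
    d[mask] <- NA_real_
  }
  names(maf) <- mk
  list(genotypes = genotype_matrix(d), complete = complete, maf = maf)
}

#' Simulate a longitudinal cohort with known generative truth
#'
#' Generates genotypes, visit schedules, covariates and phenotypes under the
#' random-intercept model
#' \deqn{y_{it} = \mu + a\,f(\mathrm{age}_{it}) + s\,\mathrm{sex}_i
#'   + b\,\mathrm{BMI}_{it} + \sum_j x_{ij}\beta_j + u_i + \varepsilon_{it}}
#' with \eqn{u_i \sim N(0, \sigma^2_u)},
#' \eqn{\varepsilon_{it} \sim N(0, \sigma^2_e)}. Causal effect sizes follow
#' the standard polygenic convention \eqn{|\beta_j| \propto
#' 1/\sqrt{2\,\mathrm{MAF}_j(1-\mathrm{MAF}_j)}} (equal per-marker variance
#' contributions) with random signs, scaled so the genetic variance equals
#' `heritability_target` of the non-covariate variance. The emitted catalog
#' carries `beta_j + Normal(0, weight_noise_sd^2)` for causal markers
#' (emulating published-estimate error, under the run's trait) and pure noise
#' weights for null markers (under the other traits), so the trait-reported
#' (R) set is the causal set and the all-markers (A) set adds the nulls.
#'
#' @param cfg a [sim_config()].
#' @return List with `cohort` (a [long_cohort()]) and `truth` (beta, subject
#'   intercepts, MAFs, the complete dosage matrix, per-subject genetic
#'   values, realized variance components and the config).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  gg <- simulate_genotypes(cfg)        # seeds with cfg$seed
  set.seed(cfg$seed + 1L)
  n <- cfg$n_subjects
  m <- cfg$n_causal + cfg$n_null
  subj <- rownames(gg$complete)
  a_min <- cfg$age_span[1]; a_max <- cfg$age_span[2]

  # visit counts: min + Binomial(max - min, p), mean exact by construction
  vmin <- cfg$visits_range[1]; vmax <- cfg$visits_range[2]
  pvis <- if (vmax > vmin) (cfg$visits_mean - vmin) / (vmax - vmin) else 0
  k <- vmin + rbinom(n, vmax - vmin, pvis)

  # visit ages: first visit uniform over the childhood entry window, later
  # visits ~3-year gaps with jitter, compressed to fit the study span
  first_hi <- min(a_min + 13, a_max)
  ages <- vector("list", n)
  for (i in seq_len(n)) {
    first <- runif(1, a_min, first_hi)
    gaps <- runif(max(k[i] - 1L, 0L), 2.2, 3.8)
    if (length(gaps) && first + sum(gaps) > a_max)
      gaps <- gaps * (a_max - first) / sum(gaps)
    ages[[i]] <- first + cumsum(c(0, gaps))
  }

  sex <- rbinom(n, 1L, 238 / 523)      # male fraction of the emulated cohort
  bmi0 <- rnorm(n, 16, 1.5)
  bmi_slope <- rnorm(n, 0.35, 0.08)

  # causal effects: equal expected variance contributions, exact total
  maf <- gg$maf
  beta <- numeric(m)
  names(beta) <- names(maf)
  causal <- seq_len(cfg$n_causal)
  realized_gvar <- 0
  if (cfg$n_causal > 0L) {
    h2 <- cfg$heritability_target
    target_gvar <- h2 / (1 - h2) * (cfg$subject_sd^2 + cfg$residual_sd^2)
    v2pq <- 2 * maf[causal] * (1 - maf[causal])
    if (all(v2pq == 0))
      stop("simulate_cohort: heritability target unreachable (all causal ",
           "markers monomorphic at the drawn MAFs)")
    raw <- sample(c(-1, 1), cfg$n_causal, replace = TRUE) / sqrt(v2pq)
    scale <- sqrt(target_gvar / sum(v2pq * raw^2))
    beta[causal] <- raw * scale
    realized_gvar <- sum(v2pq * beta[causal]^2)
  }
  gvalue <- drop(gg$complete %*% beta)

  u <- rnorm(n, 0, cfg$subject_sd)
  at <- age_transform(a_min, a_max)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    a <- ages[[i]]
    bmi <- bmi0[i] + bmi_slope[i] * (a - a_min) + rnorm(length(a), 0, 0.5)
    y <- cfg$mu + cfg$age_effect * f_age(a, at) + cfg$sex_effect * sex[i] +
      cfg$bmi_effect * bmi + gvalue[i] + u[i] +
      rnorm(length(a), 0, cfg$residual_sd)
    rows[[i]] <- data.frame(subject_id = subj[i], age = a, sex = sex[i],
                            bmi = bmi, y = y, stringsAsFactors = FALSE)
  }
  ph <- do.call(rbind, rows)
  names(ph)[names(ph) == "y"] <- trait_col(cfg$trait)
  ph <- phenotype_table(ph)

  # emitted catalog: noisy weights for causal markers under the run's trait;
  # pure-noise weights for null markers under the remaining traits
  other <- setdiff(TRAITS, cfg$trait)
  w <- beta + rnorm(m, 0, cfg$weight_noise_sd)
  alle <- t(vapply(seq_len(m),
                   function(j) sample(c("A", "C", "G", "T"), 2L),
                   character(2)))
  catalog <- marker_catalog(data.frame(
    marker_id = names(maf),
    effect_allele = alle[, 1], other_allele = alle[, 2],
    weight = w,
    trait = c(rep(cfg$trait, cfg$n_causal),
              rep(other, length.out = cfg$n_null)),
    study_n = sample(1000:100000, m, replace = TRUE),
    source = "synthetic-study", stringsAsFactors = FALSE))

  truth <- list(beta = beta, u = setNames(u, subj), maf = maf,
                complete_dosage = gg$complete,
                genetic_value = setNames(gvalue, subj),
                realized_genetic_var = realized_gvar,
                subject_var = cfg$subject_sd^2,
                residual_var = cfg$residual_sd^2,
                config = cfg)
  list(cohort = long_cohort(ph, gg$genotypes, catalog), truth = truth)
}

#' Write a simulated cohort to disk
#'
#' Writes the three tabular interfaces (catalog, genotype and phenotype TSV)
#' plus a truth JSON (effect sizes, subject intercepts, variance components,
#' seed) for recovery tests.
#'
#' @param sim output of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of paths written.
#' @export
write_cohort <- function(sim, dir) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("write_cohort: the jsonlite package is required")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("catalog.tsv", "genotypes.tsv", "phenotypes.tsv",
                            "truth.json"))
  write_catalog(sim$cohort$catalog, paths[1])
  write_genotypes(sim$cohort$genotypes, paths[2])
  write_phenotypes(sim$cohort$phenotypes, paths[3])
  tr <- sim$truth
  jsonlite::write_json(
    list(beta = as.list(tr$beta), u = as.list(tr$u), maf = as.list(tr$maf),
         realized_genetic_var = tr$realized_genetic_var,
         subject_var = tr$subject_var, residual_var = tr$residual_var,
         seed = tr$config$seed),
    paths[4], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
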