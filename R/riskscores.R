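#' Resolve a marker set for a trait
#'
#' Two marker sets are used throughout: the R ("Reported") set contains only
#' markers previously reported for the given lipid trait, while the A ("All")
#' set contains every catalogued lipid marker regardless of trait.
#'
#' @param catalog a [marker_catalog()].
#' @param set `"A"` or `"R"`.
#' @param trait lipid label (required for the R set).
#' @return Character vector of unique marker ids.
#' @export
marker_set_ids <- function(catalog, set = c("R", "A"), trait = NULL) {
  set <- match.arg(set)
  stopifnot(inherits(catalog, "marker_catalog"))
  if (set == "A") return(unique(catalog$marker_id))
  if (is.null(trait)) stop("marker_set_ids: trait required for the R set")
  trait <- match.arg(trait, TRAITS)
  unique(catalog$marker_id[catalog$trait == trait])
}

#' Deduplicate catalog entries, keeping the largest study
#'
#' When multiple studies report an association for the same marker (within a
#' trait), the estimate from the largest study is used. Ties in `study_n` are
#' broken by first occurrence with a warning.
#'
#' @param entries a [marker_catalog()] whose rows share a trait.
#' @return A [marker_catalog()] with one row per marker.
#' @export
dedup_largest_study <- function(entries) {
  stopifnot(inherits(entries, "marker_catalog"))
  if (length(unique(entries$trait)) > 1L)
    stop("dedup_largest_study: entries must share a trait")
  keep <- integer(0)
  for (id in unique(entries$marker_id)) {
    rows <- which(entries$marker_id == id)
    nmax <- max(entries$study_n[rows])
    best <- rows[entries$study_n[rows] == nmax]
    if (length(best) > 1L)
      warning("dedup_largest_study: study_n tie for marker ", id,
              "; keeping the first entry")
    keep <- c(keep, best[1])
  }
  out <- entries[sort(keep), , drop = FALSE]
  class(out) <- c("marker_catalog", "data.frame")
  out
}

new_risk_score <- function(subject_ids, scores, method, marker_set, trait,
                           provenance) {
  stopifnot(length(subject_ids) == length(scores), all(is.finite(scores)))
  structure(list(subject_ids = subject_ids,
                 scores = setNames(as.numeric(scores), subject_ids),
                 method = method, marker_set = marker_set, trait = trait,
                 weight_provenance = provenance),
            class = "risk_score")
}

#' @export
print.risk_score <- function(x, ...) {
  cat(sprintf("%s risk score (%s set, %s): %d subjects, mean %.3f, sd %.3f\n",
              x$method, x$marker_set, x$trait, length(x$scores),
              mean(x$scores), sd(x$scores)))
  invisible(x)
}

#' Published-weight (NCBI) polygenic risk score
#'
#' The weighted allele-counting score
#' \eqn{\mathrm{score}_i = \sum_j x_{ij} w_j} using published per-allele
#' weights from the catalog. Only markers previously reported for the target
#' trait are used (the R rule); markers reported by several studies are
#' resolved by [dedup_largest_study()]. Missing dosages are imputed by
#' per-marker mean over `reference_subjects`.
#'
#' @param g a [genotype_matrix()].
#' @param catalog a [marker_catalog()].
#' @param trait lipid label.
#' @param reference_subjects subjects used for missing-dosage imputation
#'   (default all; inside cross-validation pass the training subjects).
#' @return A `risk_score` object.
#' @export
ncbi_score <- function(g, catalog, trait, reference_subjects = subject_ids(g)) {
  trait <- match.arg(trait, TRAITS)
  ent <- catalog[catalog$trait == trait, , drop = FALSE]
  class(ent) <- c("marker_catalog", "data.frame")
  ent <- ent[ent$marker_id %in% marker_ids(g), , drop = FALSE]
  class(ent) <- c("marker_catalog", "data.frame")
  if (nrow(ent) == 0L)
    stop("ncbi_score: no catalog markers for trait ", trait,
         " resolvable in the genotypes")
  ent <- dedup_largest_study(ent)
  gc <- impute_missing_dosages(g, reference_subjects)
  X <- gc$dosage[, ent$marker_id, drop = FALSE]
  new_risk_score(subject_ids(g), drop(X %*% ent$weight), "NCBI", "R", trait,
                 provenance = setNames(ent$source, ent$marker_id))
}

# ---- leave-one-subject-out marker effects ---------------------------------

# subject-level aggregates of the covariate design for fast GLS downdating
subject_aggregates <- function(tf, at) {
  W <- cbind(intercept = 1, fage = f_age(tf$age, at), sex = tf$sex,
             bmi = tf$bmi)
  subj <- factor(tf$subject_id, levels = unique(tf$subject_id))
  idx <- split(seq_len(nrow(W)), subj)
  n <- length(idx)
  k <- lengths(idx)
  SW <- do.call(rbind, lapply(idx, function(ii) colSums(W[ii, , drop = FALSE])))
  sy <- vapply(idx, function(ii) sum(tf$y[ii]), numeric(1))
  WtW <- array(0, c(n, 4L, 4L))
  Wty <- matrix(0, n, 4L)
  yy <- numeric(n)
  for (i in seq_len(n)) {
    ii <- idx[[i]]
    Wi <- W[ii, , drop = FALSE]
    WtW[i, , ] <- crossprod(Wi)
    Wty[i, ] <- crossprod(Wi, tf$y[ii])
    yy[i] <- sum(tf$y[ii]^2)
  }
  # flattened n x 16 / n x 4 forms for vectorized downdating
  WtW_flat <- matrix(WtW, n, 16L)
  SWo_flat <- t(vapply(seq_len(n), function(i) c(tcrossprod(SW[i, ])),
                       numeric(16L)))
  Wty_sy <- SW * sy
  list(subjects = names(idx), W = W, subj = subj, k = k, SW = SW, sy = sy,
       WtW = WtW, Wty = Wty, yy = yy, n = n,
       WtW_flat = WtW_flat, SWo_flat = SWo_flat, Wty_sy = Wty_sy)
}

# profiled REML over the variance ratio gamma from subject-level sufficient
# statistics (A0 = W'W, b0 = W'y, yy = y'y over the included subjects)
profile_gamma_reml <- function(A0, b0, yy, SW, sy, k, K) {
  p <- ncol(SW)
  obj <- function(gamma) {
    cc <- gamma / (1 + gamma * k)
    A <- A0 - crossprod(SW, cc * SW)
    b <- b0 - crossprod(SW, cc * sy)
    cA <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(cA)) return(Inf)
    beta <- backsolve(cA, forwardsolve(t(cA), b))
    q <- max(yy - sum(cc * sy^2) - sum(b * beta), 1e-300)
    (K - p) * log(q / (K - p)) + sum(log1p(gamma * k)) +
      2 * sum(log(diag(cA)))
  }
  opt <- optimize(function(t) obj(exp(t)), interval = c(-12, 12), tol = 1e-4)
  gamma <- exp(opt$minimum)
  if (obj(0) <= opt$objective + 1e-8) gamma <- 0
  gamma
}

# all-subjects leave-one-out single-marker GLS effects at a shared gamma:
# every per-subject quantity is a rank-one downdate of precomputed totals
loo_effects_downdate <- function(agg, X, gamma) {
  n <- agg$n
  m <- ncol(X)
  a <- 1 / (1 + gamma * agg$k)
  cc <- gamma * a
  w <- agg$k * a
  SWW_tot <- matrix(colSums(agg$WtW_flat - cc * agg$SWo_flat), 4L, 4L)
  SWy_tot <- colSums(agg$Wty - cc * agg$Wty_sy)
  Sxx_tot <- colSums(X^2 * w)
  SxW_tot <- crossprod(X, a * agg$SW)
  Sxy_tot <- colSums(X * (a * agg$sy))
  out <- matrix(0, n, m, dimnames = list(agg$subjects, colnames(X)))
  degenerate <- FALSE
  for (i in seq_len(n)) {
    Ci <- matrix(agg$WtW_flat[i, ] - cc[i] * agg$SWo_flat[i, ], 4L, 4L)
    M <- solve(SWW_tot - Ci)
    xi <- X[i, ]
    SxW_i <- SxW_tot - outer(xi * a[i], agg$SW[i, ])
    Sxx_i <- Sxx_tot - xi^2 * w[i]
    Sxy_i <- Sxy_tot - xi * a[i] * agg$sy[i]
    SWy_i <- SWy_tot - (agg$Wty[i, ] - cc[i] * agg$Wty_sy[i, ])
    SxWM <- SxW_i %*% M
    denom <- Sxx_i - rowSums(SxWM * SxW_i)
    numer <- Sxy_i - drop(SxWM %*% SWy_i)
    ok <- denom > 1e-10 * pmax(Sxx_i, 1)
    out[i, ok] <- numer[ok] / denom[ok]
    degenerate <- degenerate || any(!ok)
  }
  list(beta = out, degenerate = degenerate)
}

# per-marker GLS single-marker effects over a subject subset at fixed gamma,
# by partitioned regression on the subject-level aggregates
gls_marker_effects <- function(agg, X, gamma, use) {
  a <- 1 / (1 + gamma * agg$k)          # 1' Vi^-1 = a_i 1'
  cc <- gamma * a                       # c_i = gamma / (1 + gamma k_i)
  w <- agg$k * a
  SWW <- matrix(colSums(agg$WtW_flat[use, , drop = FALSE] -
                          cc[use] * agg$SWo_flat[use, , drop = FALSE]), 4L, 4L)
  SWy <- colSums(agg$Wty[use, , drop = FALSE] -
                   cc[use] * agg$Wty_sy[use, , drop = FALSE])
  M <- solve(SWW)
  Xu <- X[use, , drop = FALSE]
  Sxx <- colSums(Xu^2 * w[use])
  SxW <- crossprod(Xu, (a[use] * agg$SW[use, , drop = FALSE]))   # m x 4
  Sxy <- colSums(Xu * (a[use] * agg$sy[use]))
  MSWy <- drop(M %*% SWy)
  SxWM <- SxW %*% M
  denom <- Sxx - rowSums(SxWM * SxW)
  numer <- Sxy - drop(SxW %*% MSWy)
  beta <- numeric(ncol(X))
  ok <- denom > 1e-10 * pmax(Sxx, 1)
  beta[ok] <- numer[ok] / denom[ok]
  list(beta = beta, degenerate = !ok)
}

#' Leave-one-subject-out single-marker effects
#'
#' For every subject i and marker j, estimates the per-allele marker effect
#' \eqn{\hat\beta_{-i,j}} from the random-intercept model
#' `trait ~ marker + f(age) + sex + bmi + (1 | subject)` fitted on all
#' observations excluding subject i — the within-cohort "n-fold
#' cross-validation" estimate that feeds the BHS score.
#'
#' Two modes are provided. `mode = "exact"` refits the full REML model for
#' every (i, j) pair (reference implementation, quadratic cost). `mode =
#' "fast"` (default) estimates the variance components once per left-out
#' subject from the covariate-only model on the same training split, then
#' computes each marker's GLS effect exactly at those components via
#' cross-product downdating; no quantity derived from the held-out subject's
#' phenotypes enters their row. Missing dosages are imputed with
#' training-split means. Markers monomorphic in a training split get effect 0
#' with a warning.
#'
#' @param cohort a [long_cohort()].
#' @param trait lipid label.
#' @param marker_set `"A"` (all catalogued markers) or `"R"` (markers
#'   reported for `trait`).
#' @param mode `"fast"` or `"exact"`.
#' @param vc in fast mode, where the variance components come from:
#'   `"per_subject"` (default) re-profiles the covariate-only REML on each
#'   training split, so nothing derived from subject i's phenotypes enters
#'   row i; `"shared"` profiles once on all observations and reuses the
#'   ratio (appropriate inside a cross-validation fold, where the subject
#'   whose predictions are at stake is already absent from the data passed
#'   here).
#' @return A `loo_marker_effects` object: subjects x markers matrix of
#'   \eqn{\hat\beta_{-i,j}} with attributes `marker_set` and `trait`.
#' @export
loo_marker_effects <- function(cohort, trait, marker_set = c("R", "A"),
                               mode = c("fast", "exact"),
                               vc = c("per_subject", "shared")) {
  marker_set <- match.arg(marker_set)
  mode <- match.arg(mode)
  vc <- match.arg(vc)
  trait <- match.arg(trait, TRAITS)
  tf <- trait_frame(cohort, trait)
  at <- age_transform(min(tf$age), max(tf$age))
  ids <- marker_set_ids(cohort$catalog, marker_set, trait)
  ids <- ids[ids %in% marker_ids(cohort$genotypes)]
  if (length(ids) == 0L) stop("loo_marker_effects: empty marker set")
  subjects <- unique(tf$subject_id)
  d <- cohort$genotypes$dosage[subjects, ids, drop = FALSE]
  out <- matrix(0, length(subjects), length(ids),
                dimnames = list(subjects, ids))
  any_degenerate <- FALSE
  if (mode == "fast" && vc == "shared") {
    agg <- subject_aggregates(tf, at)
    stopifnot(identical(agg$subjects, subjects))
    A0 <- apply(agg$WtW, c(2, 3), sum)
    b0 <- colSums(agg$Wty)
    yy <- sum(agg$yy)
    gamma <- profile_gamma_reml(A0, b0, yy, agg$SW, agg$sy, agg$k,
                                sum(agg$k))
    Xf <- d
    if (anyNA(Xf)) {
      mu <- colMeans(Xf, na.rm = TRUE)
      nav <- which(is.na(Xf), arr.ind = TRUE)
      Xf[nav] <- mu[nav[, 2]]
    }
    res <- loo_effects_downdate(agg, Xf, gamma)
    out[] <- res$beta
    any_degenerate <- res$degenerate
  } else if (mode == "fast") {
    agg <- subject_aggregates(tf, at)
    stopifnot(identical(agg$subjects, subjects))
    nav <- is.na(d)
    csum <- colSums(d, na.rm = TRUE)
    cnt <- colSums(!nav)
    A0 <- apply(agg$WtW, c(2, 3), sum)
    b0 <- colSums(agg$Wty)
    yy <- sum(agg$yy)
    for (i in seq_along(subjects)) {
      use <- rep(TRUE, length(subjects)); use[i] <- FALSE
      # training-split imputation means (exclude subject i)
      di <- d[i, ]
      si <- ifelse(nav[i, ], 0, di)
      mu <- (csum - si) / pmax(cnt - !nav[i, ], 1)
      Xf <- d
      if (any(nav)) Xf[nav] <- mu[col(d)[nav]]
      # variance components from the covariate-only model on the training
      # split (held-out subject's aggregates subtracted)
      gamma_i <- profile_gamma_reml(A0 - agg$WtW[i, , ], b0 - agg$Wty[i, ],
                                    yy - agg$yy[i],
                                    agg$SW[use, , drop = FALSE],
                                    agg$sy[use], agg$k[use],
                                    sum(agg$k[use]))
      res <- gls_marker_effects(agg, Xf, gamma_i, use)
      out[i, ] <- res$beta
      any_degenerate <- any_degenerate || any(res$degenerate)
    }
  } else {
    for (i in seq_along(subjects)) {
      keep_tf <- tf$subject_id != subjects[i]
      tfi <- tf[keep_tf, , drop = FALSE]
      gi <- impute_missing_dosages(cohort$genotypes,
                                   setdiff(subjects, subjects[i]))
      for (j in seq_along(ids)) {
        x <- gi$dosage[tfi$subject_id, ids[j]]
        if (var(x) < 1e-12) { out[i, j] <- 0; any_degenerate <- TRUE; next }
        W <- cbind(marker = x, intercept = 1, fage = f_age(tfi$age, at),
                   sex = tfi$sex, bmi = tfi$bmi)
        fit <- lmm_ri(tfi$y, W, tfi$subject_id, method = "REML")
        out[i, j] <- fit$coefficients[["marker"]]
      }
    }
  }
  if (any_degenerate)
    warning("loo_marker_effects: marker(s) monomorphic in a training split; ",
            "their effect is set to 0")
  structure(out, marker_set = marker_set, trait = trait, mode = mode,
            class = c("loo_marker_effects", "matrix", "array"))
}

#' Within-cohort (BHS) polygenic risk score
#'
#' The weighted allele-counting score in which each subject's weights are
#' their own leave-one-subject-out marker-effect estimates:
#' \eqn{\phi_i = \sum_j x_{ij}\,\hat\beta_{-i,j}}.
#'
#' @param effects a [loo_marker_effects()] matrix.
#' @param g a [genotype_matrix()] covering the same subjects and markers
#'   (missing dosages are mean-imputed over all subjects).
#' @return A `risk_score` object.
#' @export
bhs_score <- function(effects, g) {
  stopifnot(inherits(effects, "loo_marker_effects"),
            inherits(g, "genotype_matrix"))
  subjects <- rownames(effects)
  ids <- colnames(effects)
  if (!all(subjects %in% subject_ids(g)) || !all(ids %in% marker_ids(g)))
    stop("bhs_score: effects and genotypes are not aligned")
  gc <- impute_missing_dosages(g)
  X <- gc$dosage[subjects, ids, drop = FALSE]
  new_risk_score(subjects, rowSums(X * effects), "BHS",
                 attr(effects, "marker_set"), attr(effects, "trait"),
                 provenance = "leave-one-subject-out within cohort")
}

#' Single-marker association scan
#'
#' Fits, for every catalogued marker, the random-intercept model
#' `trait ~ marker + f(age) + sex + bmi + (1 | subject)` on the full cohort
#' and reports the Wald estimate, standard error and p-value, plus QQ-plot
#' coordinates (expected vs observed -log10 p). Zero-variance markers are
#' skipped with a warning.
#'
#' @param cohort a [long_cohort()].
#' @param trait lipid label.
#' @return A `marker_scan` data frame (`marker_id`, `estimate`, `se`, `p`)
#'   with a `qq` attribute; see [plot.marker_scan()].
#' @export
single_marker_scan <- function(cohort, trait) {
  trait <- match.arg(trait, TRAITS)
  tf <- trait_frame(cohort, trait)
  at <- age_transform(min(tf$age), max(tf$age))
  ids <- unique(cohort$catalog$marker_id)
  ids <- ids[ids %in% marker_ids(cohort$genotypes)]
  gc <- impute_missing_dosages(cohort$genotypes)
  W0 <- cbind(intercept = 1, fage = f_age(tf$age, at), sex = tf$sex,
              bmi = tf$bmi)
  res <- lapply(ids, function(id) {
    x <- gc$dosage[tf$subject_id, id]
    if (var(x) < 1e-12) return(NULL)
    fit <- lmm_ri(tf$y, cbind(marker = x, W0), tf$subject_id, method = "REML")
    ct <- coef_test(fit, "marker")
    data.frame(marker_id = id, estimate = ct[["estimate"]], se = ct[["se"]],
               p = ct[["p_value"]], stringsAsFactors = FALSE)
  })
  dropped <- vapply(res, is.null, logical(1))
  if (any(dropped))
    warning("single_marker_scan: skipped ", sum(dropped),
            " zero-variance marker(s)")
  out <- do.call(rbind, res[!dropped])
  rownames(out) <- NULL
  p_sorted <- sort(out$p)
  attr(out, "qq") <- data.frame(
    expected = -log10(stats::ppoints(length(p_sorted))),
    observed = -log10(p_sorted))
  class(out) <- c("marker_scan", "data.frame")
  out
}

#' QQ plot of a single-marker scan
#'
#' Plots observed against expected -log10 p-values with the identity line;
#' under the global null the points track the diagonal.
#'
#' @param x a [single_marker_scan()] result.
#' @param ... passed to [plot()].
#' @export
plot.marker_scan <- function(x, ...) {
  qq <- attr(x, "qq")
  plot(qq$expected, qq$observed,
       xlab = expression(Expected ~ -log[10](p)),
       ylab = expression(Observed ~ -log[10](p)),
       main = "Single-marker association QQ plot", pch = 19, ...)
  abline(0, 1, col = "grey50")
  invisible(x)
}
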