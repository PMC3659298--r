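test_that("largest-study deduplication keeps the rule-forced entry", {
  ent <- mk_catalog(c("rs1", "rs1", "rs2"), c(0.5, 0.3, 1.0),
                    c("HDL", "HDL", "HDL"), study_n = c(1000L, 5000L, 800L))
  out <- dedup_largest_study(ent)
  expect_equal(nrow(out), 2L)
  expect_equal(out$weight[out$marker_id == "rs1"], 0.3)
  # single entry untouched
  one <- mk_catalog("rs9", 1.1, "TG")
  expect_equal(as.data.frame(dedup_largest_study(one)), as.data.frame(one))
  # tie: first occurrence wins, with a warning
  tie <- mk_catalog(c("rs1", "rs1"), c(0.5, 0.9), c("HDL", "HDL"),
                    study_n = c(4000L, 4000L))
  expect_warning(kept <- dedup_largest_study(tie), "tie")
  expect_equal(kept$weight, 0.5)
  # mixing traits is an error
  expect_error(dedup_largest_study(mk_catalog(c("a", "b"), c(1, 1),
                                              c("HDL", "TG"))),
               "share a trait")
})

test_that("published-weight score is the weighted allele count", {
  d <- matrix(c(0, 1, 2,
                2, 1, 0), 3, 2)
  g <- mk_geno(d)
  cat_ <- mk_catalog(c("rs1", "rs2"), c(0.5, -1), c("TC", "TC"))
  sc <- ncbi_score(g, cat_, "TC")
  expect_equal(unname(sc$scores), c(0 * 0.5 - 2, 0.5 - 1, 1 + 0))
  # zero weights give zero scores
  sc0 <- ncbi_score(g, mk_catalog(c("rs1", "rs2"), c(0, 0), c("TC", "TC")),
                    "TC")
  expect_true(all(sc0$scores == 0))
  # single marker, dosage 2: score = 2w
  sc1 <- ncbi_score(g, mk_catalog("rs1", 0.7, "TC"), "TC")
  expect_equal(unname(sc1$scores[3]), 1.4)
  # marker order does not matter
  cat_r <- cat_[2:1, ]; class(cat_r) <- c("marker_catalog", "data.frame")
  expect_equal(ncbi_score(g, cat_r, "TC")$scores, sc$scores)
  # only trait-reported (R) markers are used
  mixed <- mk_catalog(c("rs1", "rs2"), c(0.5, 99), c("TC", "HDL"))
  expect_equal(unname(ncbi_score(g, mixed, "TC")$scores), d[, 1] * 0.5)
  expect_error(ncbi_score(g, mixed, "LDL"), "resolvable")
})

test_that("score from true weights and complete genotypes recovers the genetic value", {
  sim <- small_sim_complete()
  truth <- sim$truth
  causal <- names(truth$beta)[truth$beta != 0]
  cat_true <- mk_catalog(causal, unname(truth$beta[causal]),
                         rep("TC", length(causal)))
  sc <- ncbi_score(sim$cohort$genotypes, cat_true, "TC")
  expect_equal(sc$scores[names(truth$genetic_value)], truth$genetic_value,
               tolerance = 1e-12)
})

test_that("leave-one-subject-out effects exclude the subject's phenotypes", {
  sim <- small_sim()
  eff <- suppressWarnings(loo_marker_effects(sim$cohort, "TC", "R"))
  subj <- rownames(eff)[3]
  mut <- sim$cohort
  idx <- mut$phenotypes$subject_id == subj
  mut$phenotypes$tc[idx] <- mut$phenotypes$tc[idx] + 500
  eff_mut <- suppressWarnings(loo_marker_effects(mut, "TC", "R"))
  # the mutated subject's own row is untouched (up to float cancellation in
  # the sufficient-statistic downdates); other rows move
  expect_equal(eff[subj, ], eff_mut[subj, ], tolerance = 1e-6)
  other <- setdiff(rownames(eff), subj)[1]
  expect_false(isTRUE(all.equal(eff[other, ], eff_mut[other, ])))
})

test_that("fast and exact leave-one-out modes agree", {
  sim <- cached_sim("loo_modes",
                    sim_config(n_subjects = 50, n_causal = 4, n_null = 4,
                               missing_rate = 0, seed = 21))
  ef <- loo_marker_effects(sim$cohort, "TC", "R", mode = "fast")
  ee <- loo_marker_effects(sim$cohort, "TC", "R", mode = "exact")
  rel <- abs(ef - ee) / pmax(abs(ee), 1e-8)
  expect_lt(max(rel), 0.10)
  # shared-variance-component variant stays close to the per-subject one
  es <- loo_marker_effects(sim$cohort, "TC", "R", vc = "shared")
  expect_lt(max(abs(es - ef) / pmax(abs(ef), 1e-8)), 0.05)
})

test_that("null-marker effects are centred at zero, causal ones recovered", {
  sim <- cached_sim("h2_check", sim_config(n_subjects = 500, n_causal = 18,
                                           n_null = 10, missing_rate = 0,
                                           seed = 77))
  eff <- loo_marker_effects(sim$cohort, "TC", "A", vc = "shared")
  nulls <- names(sim$truth$beta)[sim$truth$beta == 0]
  causal <- setdiff(names(sim$truth$beta), nulls)
  null_means <- colMeans(eff[, nulls, drop = FALSE])
  causal_means <- colMeans(eff[, causal, drop = FALSE])
  # null effects sit well inside the causal effect scale and average to ~0
  expect_lt(mean(abs(null_means)), 0.5 * mean(abs(causal_means)))
  expect_lt(abs(mean(null_means)),
            3 * sd(null_means) / sqrt(length(null_means)) + 0.5)
  expect_gt(cor(causal_means, sim$truth$beta[causal]), 0.8)
})

test_that("within-cohort score is each subject's own weighted allele count", {
  d <- matrix(c(0, 1, 2), 3, 1)
  g <- mk_geno(d)
  eff <- structure(matrix(c(0.5, -1, 2), 3, 1,
                          dimnames = list(c("S1", "S2", "S3"), "rs1")),
                   marker_set = "R", trait = "TC",
                   class = c("loo_marker_effects", "matrix", "array"))
  sc <- bhs_score(eff, g)
  expect_equal(unname(sc$scores), c(0 * 0.5, 1 * -1, 2 * 2))
  # zero effects, zero scores
  eff0 <- eff; eff0[] <- 0
  expect_true(all(bhs_score(eff0, g)$scores == 0))
  # scaling all effects scales scores
  eff3 <- eff; eff3[] <- eff[] * 3
  expect_equal(bhs_score(eff3, g)$scores, 3 * sc$scores)
  # misaligned genotypes are rejected
  expect_error(bhs_score(eff, mk_geno(d, markers = "rsX")), "aligned")
})

test_that("single-marker scan flags a strong causal marker and skips dead ones", {
  # few causal markers concentrate the genetic variance, so the top effect
  # stands far above its standard error
  sim <- cached_sim("scan_strong",
                    sim_config(n_subjects = 300, n_causal = 4, n_null = 4,
                               missing_rate = 0, seed = 83))
  scan <- single_marker_scan(sim$cohort, "TC")
  expect_true(all(c("marker_id", "estimate", "se", "p") %in% names(scan)))
  top_causal <- names(which.max(abs(sim$truth$beta)))
  expect_lt(scan$p[scan$marker_id == top_causal], 1e-7)
  qq <- attr(scan, "qq")
  expect_equal(nrow(qq), nrow(scan))
  expect_true(all(diff(qq$observed) <= 0) || all(diff(qq$observed) >= 0))

  # a zero-variance marker is skipped with a warning
  co <- sim$cohort
  co$genotypes$dosage[, 1] <- 1
  expect_warning(scan2 <- single_marker_scan(co, "TC"), "zero-variance")
  expect_false(colnames(sim$cohort$genotypes$dosage)[1] %in% scan2$marker_id)
})

test_that("scan p-values are near-uniform under a permuted null", {
  sim <- cached_sim("scan_null",
                    sim_config(n_subjects = 120, n_causal = 0, n_null = 30,
                               missing_rate = 0, seed = 41))
  scan <- single_marker_scan(sim$cohort, "TC")
  expect_gt(min(scan$p), 1e-5)      # no spurious genome-wide hits
  expect_lt(abs(mean(scan$p < 0.2) - 0.2), 0.17)
})

test_that("scores are invariant to subject ordering", {
  sim <- small_sim_complete()
  sc <- ncbi_score(sim$cohort$genotypes, sim$cohort$catalog, "TC")
  perm <- rev(subject_ids <- rownames(sim$cohort$genotypes$dosage))
  g2 <- genotype_matrix(sim$cohort$genotypes$dosage[perm, ])
  sc2 <- ncbi_score(g2, sim$cohort$catalog, "TC")
  expect_equal(sc2$scores[names(sc$scores)], sc$scores)
})
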