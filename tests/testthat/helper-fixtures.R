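# shared simulated cohorts, generated once per test run
.fixture_env <- new.env(parent = emptyenv())

cached_sim <- function(key, cfg) {
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- simulate_cohort(cfg)
  .fixture_env[[key]]
}

# 40 subjects, 12 markers, a little missingness: the workhorse small cohort
small_sim <- function() {
  cached_sim("small", sim_config(n_subjects = 40, n_causal = 6, n_null = 6,
                                 missing_rate = 0.02, seed = 11))
}

# complete-genotype variant for algebra checks
small_sim_complete <- function() {
  cached_sim("small_complete",
             sim_config(n_subjects = 40, n_causal = 6, n_null = 6,
                        missing_rate = 0, seed = 13))
}

# quick hand-built catalog
mk_catalog <- function(marker_id, weight, trait,
                       effect_allele = rep("G", length(marker_id)),
                       other_allele = rep("A", length(marker_id)),
                       study_n = rep(10000L, length(marker_id)),
                       source = "test") {
  marker_catalog(data.frame(marker_id = marker_id,
                            effect_allele = effect_allele,
                            other_allele = other_allele,
                            weight = weight, trait = trait,
                            study_n = study_n, source = source,
                            stringsAsFactors = FALSE))
}

# hand-built genotype matrix
mk_geno <- function(m, subjects = paste0("S", seq_len(nrow(m))),
                    markers = paste0("rs", seq_len(ncol(m)))) {
  dimnames(m) <- list(subjects, markers)
  genotype_matrix(m)
}
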