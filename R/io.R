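TRAITS <- c("HDL", "LDL", "TC", "TG")

# map trait label -> phenotype column
trait_col <- function(trait) {
  trait <- match.arg(trait, TRAITS)
  c(HDL = "hdl", LDL = "ldl", TC = "tc", TG = "tg")[[trait]]
}

#' Construct a marker-weights catalog
#'
#' A catalog row records one published association: a marker, its effect
#' allele (the allele the per-allele weight counts), the weight in mg/dL per
#' effect-allele copy, the lipid trait it was reported for, and the source
#' study's sample size. Multiple rows per `(marker_id, trait)` pair are
#' allowed (several studies may report the same marker) and are resolved
#' downstream by [dedup_largest_study()].
#'
#' @param df data frame with columns `marker_id`, `effect_allele`,
#'   `other_allele`, `weight` (mg/dL), `trait` (one of HDL, LDL, TC, TG),
#'   `study_n`, `source`.
#' @return A `marker_catalog` (validated data frame).
#' @export
marker_catalog <- function(df) {
  req <- c("marker_id", "effect_allele", "other_allele", "weight", "trait",
           "study_n", "source")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("marker_catalog: missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[req]
  df$marker_id <- as.character(df$marker_id)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  df$source <- as.character(df$source)
  bad_row <- function(cond, what) {
    if (any(cond))
      stop(sprintf("marker_catalog: %s in row(s) %s", what,
                   paste(head(which(cond), 5L), collapse = ", ")))
  }
  bad_row(!df$effect_allele %in% c("A", "C", "G", "T"), "malformed effect allele")
  bad_row(!df$other_allele %in% c("A", "C", "G", "T"), "malformed other allele")
  bad_row(df$effect_allele == df$other_allele, "effect allele equals other allele")
  w <- suppressWarnings(as.numeric(df$weight))
  bad_row(!is.finite(w), "non-numeric or non-finite weight")
  df$weight <- w
  bad_row(!df$trait %in% TRAITS,
          sprintf("unknown trait label (must be one of %s)",
                  paste(TRAITS, collapse = "/")))
  n <- suppressWarnings(as.numeric(df$study_n))
  bad_row(!is.finite(n) | n <= 0 | n != round(n), "invalid study_n")
  df$study_n <- as.integer(n)
  class(df) <- c("marker_catalog", "data.frame")
  df
}

#' Read a marker-weights catalog from TSV
#'
#' The file must be tab-separated with a header declaring `marker_id`,
#' `effect_allele`, `other_allele`, `weight_mg_dl`, `trait`, `study_n`,
#' `source`. Weights are accepted in mg/dL only: unit conversion (e.g. from
#' mmol/L or variance-scaled estimates) is the curator's job, and a `units`
#' column, if present, must read `mg/dL` in every row. Per-trait unique-marker
#' counts are reported via [count_by_trait()]; duplicate `(marker_id, trait)`
#' rows are preserved for [dedup_largest_study()].
#'
#' @param path path to the TSV file.
#' @return A `marker_catalog`.
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) stop("read_catalog: file not found: ", path)
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   quote = "", comment.char = "")
  if (nrow(df) == 0L) stop("read_catalog: no rows in ", path)
  if ("units" %in% names(df) && !all(df$units %in% c("mg/dL", "mg/dl")))
    stop("read_catalog: catalog weights must be in mg/dL (bad 'units' column)")
  if (!"weight_mg_dl" %in% names(df))
    stop("read_catalog: header must declare weight_mg_dl")
  names(df)[names(df) == "weight_mg_dl"] <- "weight"
  cat_ <- marker_catalog(df)
  cnt <- count_by_trait(cat_)
  message("read_catalog: ", nrow(cat_), " rows; unique markers per trait: ",
          paste(names(cnt), cnt, sep = "=", collapse = ", "))
  cat_
}

#' Per-trait unique marker counts
#'
#' @param catalog a [marker_catalog()].
#' @return Named integer vector over HDL, LDL, TC, TG counting the unique
#'   markers reported for each trait (invariant to row order).
#' @export
count_by_trait <- function(catalog) {
  stopifnot(inherits(catalog, "marker_catalog"))
  vapply(TRAITS, function(tr)
    length(unique(catalog$marker_id[catalog$trait == tr])), integer(1))
}

#' Write a marker catalog to TSV
#' @param catalog a [marker_catalog()].
#' @param path output path.
#' @export
write_catalog <- function(catalog, path) {
  df <- as.data.frame(catalog)
  names(df)[names(df) == "weight"] <- "weight_mg_dl"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct an additive-dosage genotype matrix
#'
#' Dosages count copies of the effect allele (0--2, fractional after
#' imputation); `NA` marks missing calls, which are never silently
#' zero-filled (see [impute_missing_dosages()]).
#'
#' @param dosage numeric matrix, subjects in rows, markers in columns, with
#'   unique row and column names.
#' @return A `genotype_matrix` with per-marker missingness recorded.
#' @export
genotype_matrix <- function(dosage) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (is.null(rownames(dosage)) || anyDuplicated(rownames(dosage)))
    stop("genotype_matrix: rows must carry unique subject ids")
  if (is.null(colnames(dosage)) || anyDuplicated(colnames(dosage)))
    stop("genotype_matrix: columns must carry unique marker ids")
  rng <- range(dosage, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2)
    stop("genotype_matrix: dosages must lie in [0, 2]")
  structure(list(dosage = dosage,
                 missing_frac = colMeans(is.na(dosage))),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype dosage matrix: %d subjects x %d markers, %.2f%% missing\n",
              nrow(x$dosage), ncol(x$dosage), 100 * mean(is.na(x$dosage))))
  invisible(x)
}

subject_ids <- function(g) rownames(g$dosage)
marker_ids <- function(g) colnames(g$dosage)

#' Read a genotype dosage matrix
#'
#' For `format = "tsv"` the file has subjects in rows (first column
#' `subject_id`), markers in columns, `NA` for missing calls; dosages are
#' taken as-given (already oriented to the effect allele). For
#' `format = "vcf"` (requires the vcfR package) dosages are read from the
#' `DS` field when present, otherwise counted from `GT`, and oriented to the
#' catalog's effect allele: when the effect allele is the REF allele the
#' ALT count `d` is flipped to `2 - d`. Markers with more than two alleles,
#' or whose alleles do not match the catalog, are skipped with a warning.
#'
#' @param path input path.
#' @param format `"tsv"` or `"vcf"`.
#' @param catalog optional [marker_catalog()] giving effect alleles for VCF
#'   orientation; without it, VCF dosages count the ALT allele.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf"), catalog = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_genotypes: file not found: ", path)
  if (format == "tsv") {
    df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                     check.names = FALSE)
    if (names(df)[1] != "subject_id")
      stop("read_genotypes: first column must be subject_id")
    m <- as.matrix(df[-1])
    rownames(m) <- as.character(df$subject_id)
    storage.mode(m) <- "double"
    return(genotype_matrix(m))
  }
  read_genotypes_vcf(path, catalog)
}

read_genotypes_vcf <- function(path, catalog = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_genotypes: the vcfR package is required for VCF input")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ids <- fix[, "ID"]
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt) | nchar(ref) != 1L | nchar(alt) != 1L
  ds <- tryCatch(vcfR::extract.gt(v, element = "DS", as.numeric = TRUE),
                 error = function(e) NULL)
  if (is.null(ds) || all(is.na(ds))) {
    gt <- vcfR::extract.gt(v, element = "GT")
    count_alt <- function(x) {
      a <- strsplit(gsub("\\|", "/", x), "/", fixed = TRUE)
      vapply(a, function(z) {
        if (any(z == "." ) || any(is.na(z))) NA_real_ else sum(z == "1")
      }, numeric(1))
    }
    ds <- t(apply(gt, 1, count_alt))
    dimnames(ds) <- dimnames(gt)
  }
  keep <- rep(TRUE, length(ids))
  if (any(multi)) {
    warning("read_genotypes: skipping ", sum(multi),
            " marker(s) with >2 or non-SNP alleles")
    keep <- keep & !multi
  }
  flip <- rep(FALSE, length(ids))
  if (!is.null(catalog)) {
    stopifnot(inherits(catalog, "marker_catalog"))
    first <- !duplicated(catalog$marker_id)
    eff <- setNames(catalog$effect_allele[first], catalog$marker_id[first])
    oth <- setNames(catalog$other_allele[first], catalog$marker_id[first])
    in_cat <- ids %in% names(eff)
    e <- eff[ids]
    o <- oth[ids]
    match_fwd <- in_cat & e == alt & o == ref
    match_rev <- in_cat & e == ref & o == alt
    mismatch <- in_cat & !match_fwd & !match_rev & keep
    if (any(mismatch)) {
      warning("read_genotypes: skipping ", sum(mismatch),
              " marker(s) whose VCF alleles do not match the catalog")
      keep <- keep & !mismatch
    }
    flip <- match_rev
  }
  ds <- ds[keep, , drop = FALSE]
  flip <- flip[keep]
  ds[flip, ] <- 2 - ds[flip, , drop = FALSE]
  m <- t(ds)
  colnames(m) <- ids[keep]
  genotype_matrix(m)
}

#' Write a genotype matrix
#'
#' `format = "tsv"` writes the subjects-by-markers dosage table. `format =
#' "vcf"` writes a minimal VCFv4.2 with a `DS` (dosage) FORMAT field; REF/ALT
#' are taken from the catalog (`other_allele`/`effect_allele`, so the written
#' dosage counts ALT and reads back unflipped) or default to A/G.
#'
#' @param g a [genotype_matrix()].
#' @param path output path.
#' @param format `"tsv"` or `"vcf"`.
#' @param catalog optional [marker_catalog()] supplying alleles for VCF.
#' @export
write_genotypes <- function(g, path, format = c("tsv", "vcf"), catalog = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(g, "genotype_matrix"))
  if (format == "tsv") {
    df <- data.frame(subject_id = subject_ids(g), g$dosage,
                     check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  mk <- marker_ids(g)
  ref <- rep("A", length(mk)); alt <- rep("G", length(mk))
  if (!is.null(catalog)) {
    first <- !duplicated(catalog$marker_id)
    eff <- setNames(catalog$effect_allele[first], catalog$marker_id[first])
    oth <- setNames(catalog$other_allele[first], catalog$marker_id[first])
    hit <- mk %in% names(eff)
    alt[hit] <- eff[mk[hit]]
    ref[hit] <- oth[mk[hit]]
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", subject_ids(g)), collapse = "\t")),
             con)
  for (j in seq_along(mk)) {
    d <- g$dosage[, j]
    d <- ifelse(is.na(d), ".", format(d, digits = 12, trim = TRUE,
                                      scientific = FALSE))
    writeLines(paste(c("1", j, mk[j], ref[j], alt[j], ".", "PASS", ".",
                       "DS", d), collapse = "\t"), con)
  }
  invisible(path)
}

#' Construct a longitudinal phenotype table
#'
#' Long format: one row per clinic visit with `subject_id`, `age` (years),
#' `sex` (0 = female, 1 = male), `bmi` (kg/m^2) and the lipid columns `hdl`,
#' `ldl`, `tc`, `tg` in mg/dL (`NA` allowed per lipid). Rows are sorted by
#' `(subject_id, age)`.
#'
#' @param df data frame as above (missing lipid columns are added as `NA`).
#' @return A `phenotype_table`.
#' @export
phenotype_table <- function(df) {
  req <- c("subject_id", "age", "sex", "bmi")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("phenotype_table: missing columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)
  if (nrow(df) == 0L) stop("phenotype_table: no observations")
  for (cc in c("hdl", "ldl", "tc", "tg")) if (!cc %in% names(df)) df[[cc]] <- NA_real_
  df <- df[c(req, "hdl", "ldl", "tc", "tg")]
  df$subject_id <- as.character(df$subject_id)
  df$age <- as.numeric(df$age)
  if (any(!is.finite(df$age)) || any(df$age < 0))
    stop("phenotype_table: ages must be finite and non-negative")
  if (!all(df$sex %in% c(0, 1)))
    stop("phenotype_table: sex must be coded 0 (female) / 1 (male)")
  df$sex <- as.numeric(df$sex)
  df$bmi <- as.numeric(df$bmi)
  if (any(!is.finite(df$bmi)))
    stop("phenotype_table: bmi must be finite")
  for (cc in c("hdl", "ldl", "tc", "tg")) df[[cc]] <- as.numeric(df[[cc]])
  df <- df[order(df$subject_id, df$age), ]
  rownames(df) <- NULL
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' Read a longitudinal phenotype table from TSV
#'
#' @param path TSV with columns `subject_id`, `age`, `sex`, `bmi`, `hdl`,
#'   `ldl`, `tc`, `tg` (lipids optional, `NA` allowed), one row per visit.
#' @return A `phenotype_table` sorted by `(subject_id, age)`.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("read_phenotypes: file not found: ", path)
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("read_phenotypes: no observations in ", path)
  phenotype_table(df)
}

#' Write a phenotype table to TSV
#' @param ph a [phenotype_table()].
#' @param path output path.
#' @export
write_phenotypes <- function(ph, path) {
  write.table(as.data.frame(ph), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Summary statistics of a phenotype table
#'
#' @param object a `phenotype_table`.
#' @param ... unused.
#' @return List with `n_subjects`, `n_obs`, `mean_visits`, `sd_visits`,
#'   `age_range`, `mean_age_first` and `mean_gap` (mean years between
#'   consecutive visits), for comparison against cohort descriptive tables.
#' @export
summary.phenotype_table <- function(object, ...) {
  k <- table(object$subject_id)
  first_age <- tapply(object$age, object$subject_id, min)
  gaps <- unlist(tapply(object$age, object$subject_id,
                        function(a) diff(sort(a))), use.names = FALSE)
  list(n_subjects = length(k), n_obs = nrow(object),
       mean_visits = mean(k), sd_visits = sd(as.numeric(k)),
       age_range = range(object$age),
       mean_age_first = mean(first_age),
       mean_gap = if (length(gaps)) mean(gaps) else NA_real_)
}

#' Impute missing dosages from a reference subject set
#'
#' Missing entries of each marker are replaced by the marker's mean dosage
#' computed over `reference_subjects` only. Inside cross-validation the
#' reference is the training split, so the held-out subject's genotypes never
#' influence the imputed values (leak-free by construction).
#'
#' @param g a [genotype_matrix()].
#' @param reference_subjects character vector of subject ids used to compute
#'   the per-marker means (default: all subjects).
#' @return A complete [genotype_matrix()] (no missing entries).
#' @export
impute_missing_dosages <- function(g, reference_subjects = subject_ids(g)) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (length(reference_subjects) == 0L)
    stop("impute_missing_dosages: empty reference set")
  if (!all(reference_subjects %in% subject_ids(g)))
    stop("impute_missing_dosages: unknown reference subject(s)")
  d <- g$dosage
  if (!anyNA(d)) return(genotype_matrix(d))
  ref <- d[reference_subjects, , drop = FALSE]
  mu <- colMeans(ref, na.rm = TRUE)
  dead <- !is.finite(mu)
  if (any(dead))
    stop("impute_missing_dosages: marker(s) entirely missing in reference: ",
         paste(head(colnames(d)[dead], 5L), collapse = ", "))
  na_idx <- which(is.na(d), arr.ind = TRUE)
  d[na_idx] <- mu[na_idx[, 2]]
  genotype_matrix(d)
}

#' Assemble a longitudinal cohort
#'
#' Binds phenotypes, genotype dosages and the marker catalog into a single
#' validated container. Every phenotype subject must have a genotype row;
#' catalog markers absent from the genotype matrix are dropped with a message
#' reporting the count.
#'
#' @param phenotypes a [phenotype_table()].
#' @param genotypes a [genotype_matrix()].
#' @param catalog a [marker_catalog()].
#' @return A `long_cohort` with fields `phenotypes`, `genotypes`, `catalog`.
#' @export
long_cohort <- function(phenotypes, genotypes, catalog) {
  stopifnot(inherits(phenotypes, "phenotype_table"),
            inherits(genotypes, "genotype_matrix"),
            inherits(catalog, "marker_catalog"))
  subj <- unique(phenotypes$subject_id)
  missing_geno <- setdiff(subj, subject_ids(genotypes))
  if (length(missing_geno))
    stop("long_cohort: subject(s) without genotypes: ",
         paste(head(missing_geno, 5L), collapse = ", "))
  unresolved <- !catalog$marker_id %in% marker_ids(genotypes)
  if (any(unresolved)) {
    message("long_cohort: dropping ", sum(unresolved),
            " catalog row(s) whose markers are absent from the genotypes")
    catalog <- catalog[!unresolved, , drop = FALSE]
    class(catalog) <- c("marker_catalog", "data.frame")
  }
  structure(list(phenotypes = phenotypes, genotypes = genotypes,
                 catalog = catalog),
            class = "long_cohort")
}

#' @export
print.long_cohort <- function(x, ...) {
  s <- summary(x$phenotypes)
  cat(sprintf("Longitudinal cohort: %d subjects, %d observations (mean %.1f visits)\n",
              s$n_subjects, s$n_obs, s$mean_visits))
  cat(sprintf("  ages %.1f-%.1f years; %d markers; catalog %d rows\n",
              s$age_range[1], s$age_range[2], ncol(x$genotypes$dosage),
              nrow(x$catalog)))
  invisible(x)
}

# observations of one trait with complete covariates, as a plain data frame
trait_frame <- function(cohort, trait) {
  stopifnot(inherits(cohort, "long_cohort"))
  ph <- cohort$phenotypes
  y <- ph[[trait_col(trait)]]
  keep <- !is.na(y) & complete.cases(ph[c("age", "sex", "bmi")])
  if (!any(keep)) stop("trait_frame: no observations with trait ", trait)
  data.frame(subject_id = ph$subject_id[keep], age = ph$age[keep],
             sex = ph$sex[keep], bmi = ph$bmi[keep], y = y[keep],
             stringsAsFactors = FALSE)
}

# subset a cohort to a set of subjects (phenotypes + genotype rows)
subset_cohort <- function(cohort, subjects) {
  ph <- cohort$phenotypes[cohort$phenotypes$subject_id %in% subjects, ]
  class(ph) <- c("phenotype_table", "data.frame")
  g <- genotype_matrix(cohort$genotypes$dosage[
    rownames(cohort$genotypes$dosage) %in% subjects, , drop = FALSE])
  structure(list(phenotypes = ph, genotypes = g, catalog = cohort$catalog),
            class = "long_cohort")
}
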