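# Fixed-effect inverse-variance meta-analysis, genomic control, the 2-df
# sex-dimorphic test, Cochran's Q, and I-squared.

#' Inverse-variance weighted fixed-effect pooling
#'
#' Combines k estimates with weights w_i = 1/se_i^2:
#' pooled beta = sum(w b)/sum(w), pooled se = 1/sqrt(sum(w)).
#'
#' @param beta effect estimates
#' @param se standard errors, all > 0
#' @param n optional per-estimate sample sizes (summed into the result)
#' @return list with `beta`, `se`, and `n` (NA when sizes not supplied)
#' @export
ivw_meta <- function(beta, se, n = NULL) {
  if (length(beta) == 0L) stop("ivw_meta: no estimates supplied")
  if (length(beta) != length(se)) stop("ivw_meta: beta/se length mismatch")
  if (any(!is.finite(se)) || any(se <= 0)) stop("ivw_meta: all se must be > 0")
  w <- 1 / se^2
  list(beta = sum(w * beta) / sum(w),
       se = 1 / sqrt(sum(w)),
       n = if (is.null(n)) NA_real_ else sum(n))
}

#' Genomic-control inflation factor
#'
#' lambda = median(chi-square statistics) / 0.4549364 (the 1-df chi-square
#' median). For Metabochip-design studies the median is taken over a
#' designated null-ish subset of variants (the QT-interval follow-up SNPs in
#' the original design) rather than the full chip, which is enriched for
#' true associations.
#'
#' @param chi2 1-df chi-square association statistics
#' @param subset optional logical or integer index selecting the variants
#'   that enter the median (the Metabochip rule); default all
#' @param subset_rule label recorded in the report
#' @return `gc_report` list: `lambda`, `n_variants_used`, `subset_rule`
#' @export
genomic_control <- function(chi2, subset = NULL, subset_rule = "all") {
  if (!is.null(subset)) {
    chi2 <- chi2[subset]
    if (identical(subset_rule, "all")) subset_rule <- "qt_interval_subset"
  }
  chi2 <- chi2[is.finite(chi2)]
  if (length(chi2) == 0L) stop("genomic_control: no finite statistics")
  structure(list(lambda = median(chi2) / .CHI2_1DF_MEDIAN,
                 n_variants_used = length(chi2),
                 subset_rule = subset_rule),
            class = "gc_report")
}

#' @export
print.gc_report <- function(x, ...) {
  cat(sprintf("<gc_report> lambda = %.4f over %d variants (%s)\n",
              x$lambda, x$n_variants_used, x$subset_rule))
  invisible(x)
}

#' Apply genomic control to standard errors
#'
#' se -> se * sqrt(lambda) when lambda > 1 (equivalently chi2 -> chi2/lambda).
#' Deflation is never applied: lambda <= 1 leaves the data unchanged, the
#' universal GWAS convention.
#'
#' @param se standard errors
#' @param lambda inflation factor (or a `gc_report`)
#' @return corrected standard errors
#' @export
gc_adjust_se <- function(se, lambda) {
  if (inherits(lambda, "gc_report")) lambda <- lambda$lambda
  if (lambda > 1) se * sqrt(lambda) else se
}

#' Cochran's Q heterogeneity test
#'
#' Q = sum w_i (b_i - b_pooled)^2 with IVW weights; chi-square with k-1 df
#' under homogeneity. For k = 2 this reduces to
#' (b1 - b2)^2 / (se1^2 + se2^2), the between-sex heterogeneity test.
#'
#' @inheritParams ivw_meta
#' @return `het_result` list: `q`, `df`, `p`, `i2`
#' @export
cochran_q <- function(beta, se) {
  k <- length(beta)
  if (k < 2L) stop("cochran_q: need at least 2 estimates")
  pooled <- ivw_meta(beta, se)
  w <- 1 / se^2
  q <- sum(w * (beta - pooled$beta)^2)
  df <- k - 1L
  structure(list(q = q, df = df, p = chisq_p(q, df), i2 = i_squared(q, df)),
            class = "het_result")
}

#' @export
print.het_result <- function(x, ...) {
  cat(sprintf("<het_result> Q = %.3f (df %d), p = %.3g, I2 = %.1f%%\n",
              x$q, x$df, x$p, x$i2))
  invisible(x)
}

#' Two-degree-of-freedom sex-dimorphic test
#'
#' t2 = z_f^2 + z_m^2 with z = beta/se per sex; p is the 2-df chi-square
#' survival probability, exp(-t2/2) in closed form. The test allows the
#' allelic effect to differ between women and men, so it retains power both
#' for concordant and for sex-dimorphic effects. Vectorized.
#'
#' @param beta_f,se_f female effect estimate and standard error
#' @param beta_m,se_m male effect estimate and standard error
#' @return data.frame with `t2` and `p`
#' @export
sex_dimorphic_test <- function(beta_f, se_f, beta_m, se_m) {
  t2 <- (beta_f / se_f)^2 + (beta_m / se_m)^2
  data.frame(t2 = t2, p = chisq_p(t2, 2))
}

#' I-squared heterogeneity percentage
#'
#' I2 = max(0, (Q - df)/Q) * 100: the percentage of variation across
#' estimates attributable to heterogeneity rather than chance, independent
#' of the number of estimates. Q = 0 gives 0.
#'
#' @param q Cochran's Q statistic(s)
#' @param df degrees of freedom
#' @return percentage(s) in [0, 100)
#' @export
i_squared <- function(q, df) {
  ifelse(q <= 0, 0, pmax(0, (q - df) / q) * 100)
}

#' Meta-analysis configuration
#'
#' @param study_gc apply first-stage genomic control to each study's
#'   statistics before pooling (default TRUE)
#' @param second_stage_gc apply genomic control to the pooled per-sex
#'   statistics (default TRUE; meta-level inflation is monitored and
#'   corrected like study-level inflation)
#' @param combined_mode `"joint"` pools every contributing study in one IVW
#'   pass (default); `"pooled_sexes"` IVW-combines the female and male pooled
#'   estimates together with combined-only studies
#' @return config list for [meta_pipeline()]
#' @export
meta_config <- function(study_gc = TRUE, second_stage_gc = TRUE,
                        combined_mode = c("joint", "pooled_sexes")) {
  list(study_gc = study_gc, second_stage_gc = second_stage_gc,
       combined_mode = match.arg(combined_mode))
}

#' Sex-stratified fixed-effect meta-analysis pipeline
#'
#' Runs the three meta-analysis strategies over harmonized, QC-passed study
#' panels: (1) sex-specific IVW pooling within each sex, (2) the 2-df
#' sex-dimorphic test on the pooled per-sex estimates, and (3) a sex-combined
#' IVW analysis. Studies supplied with `sex = "combined"` (e.g. family-based
#' cohorts analyzed jointly with a sex adjustment) enter only the combined
#' analysis. First-stage genomic control is estimated per study (Metabochip
#' designs use their designated subset when a `gc_subset` attribute is set on
#' the panel's records) and applied to the standard errors; second-stage GC is
#' applied to the pooled per-sex statistics. Between-sex Cochran's Q and the
#' dimorphic test are computed wherever both sexes contribute; a variant
#' present in one sex only still gets a combined result, with the dimorphic
#' and heterogeneity columns NA.
#'
#' @param panels list of `study_panel` objects
#' @param config from [meta_config()]
#' @return data.frame with one row per variant: MARKER, CHR, POS, EA, NEA,
#'   EAF, BETA_F/SE_F/P_F/N_F, BETA_M/SE_M/P_M/N_M, BETA_ALL/SE_ALL/P_ALL/
#'   N_ALL, CHI2_2DF, P_DIMORPHIC, Q, P_HET, I2. Study- and meta-level GC
#'   lambdas are attached as attributes `study_lambda` and `meta_lambda`.
#' @export
meta_pipeline <- function(panels, config = meta_config()) {
  stopifnot(length(panels) > 0)
  study_lambda <- numeric(0)
  rows <- vector("list", length(panels))
  for (i in seq_along(panels)) {
    p <- panels[[i]]
    r <- p$records
    if (nrow(r) == 0L) next
    chi2 <- (r$beta / r$se)^2
    gc <- genomic_control(chi2, subset = attr(r, "gc_subset"),
                          subset_rule = if (p$design == "metabochip")
                            "qt_interval_subset" else "all")
    study_lambda[paste(p$study_id, p$sex, sep = ":")] <- gc$lambda
    if (config$study_gc) r$se <- gc_adjust_se(r$se, gc)
    rows[[i]] <- data.table::data.table(
      marker_id = r$marker_id, chrom = r$chrom, pos = r$pos,
      ea = r$effect_allele, oa = r$other_allele, eaf = r$eaf,
      beta = r$beta, se = r$se, n = r$n, sex = p$sex)
  }
  long <- data.table::rbindlist(rows)
  if (nrow(long) == 0L) stop("meta_pipeline: no records in any panel")

  pool_one <- function(b, s, nn) {
    w <- 1 / s^2
    list(beta = sum(w * b) / sum(w), se = 1 / sqrt(sum(w)), n = sum(nn))
  }
  beta <- se <- n <- sex <- marker_id <- NULL # data.table NSE

  per_sex <- long[sex %in% c("female", "male"),
                  pool_one(beta, se, n), by = c("marker_id", "sex")]
  meta_lambda <- c(female = NA_real_, male = NA_real_)
  for (sx in c("female", "male")) {
    idx <- per_sex$sex == sx
    if (!any(idx)) next
    chi2 <- (per_sex$beta[idx] / per_sex$se[idx])^2
    gc <- genomic_control(chi2, subset_rule = "all")
    meta_lambda[sx] <- gc$lambda
    if (config$second_stage_gc)
      per_sex$se[idx] <- gc_adjust_se(per_sex$se[idx], gc)
  }

  combined <- if (config$combined_mode == "joint") {
    long[, pool_one(beta, se, n), by = "marker_id"]
  } else {
    second <- long[sex == "combined",
                   data.table::data.table(beta = beta, se = se, n = n,
                                          marker_id = marker_id)]
    stage <- data.table::rbindlist(list(
      per_sex[, c("marker_id", "beta", "se", "n")],
      second[, c("marker_id", "beta", "se", "n")]), use.names = TRUE)
    stage[, pool_one(beta, se, n), by = "marker_id"]
  }

  wide <- data.table::dcast(per_sex, marker_id ~ sex,
                            value.var = c("beta", "se", "n"))
  for (col in c("beta_female", "se_female", "n_female",
                "beta_male", "se_male", "n_male"))
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  out <- merge(combined, wide, by = "marker_id", all.x = TRUE)

  # annotation: first-seen coordinates/alleles, n-weighted EAF
  ann <- long[, list(chrom = chrom[1], pos = pos[1], ea = ea[1], oa = oa[1],
                     eaf = sum(eaf * n) / sum(n)), by = "marker_id"]
  out <- merge(ann, out, by = "marker_id")

  dim_t <- sex_dimorphic_test(out$beta_female, out$se_female,
                              out$beta_male, out$se_male)
  qstat <- (out$beta_female - out$beta_male)^2 / (out$se_female^2 + out$se_male^2)

  res <- data.frame(
    MARKER = out$marker_id, CHR = out$chrom, POS = out$pos,
    EA = out$ea, NEA = out$oa, EAF = out$eaf,
    BETA_F = out$beta_female, SE_F = out$se_female,
    P_F = chisq_p((out$beta_female / out$se_female)^2, 1), N_F = out$n_female,
    BETA_M = out$beta_male, SE_M = out$se_male,
    P_M = chisq_p((out$beta_male / out$se_male)^2, 1), N_M = out$n_male,
    BETA_ALL = out$beta, SE_ALL = out$se,
    P_ALL = chisq_p((out$beta / out$se)^2, 1), N_ALL = out$n,
    CHI2_2DF = dim_t$t2, P_DIMORPHIC = dim_t$p,
    Q = qstat, P_HET = chisq_p(qstat, 1), I2 = i_squared(qstat, 1),
    stringsAsFactors = FALSE)
  res <- res[order(res$CHR, res$POS, res$MARKER), ]
  rownames(res) <- NULL
  attr(res, "study_lambda") <- study_lambda
  attr(res, "meta_lambda") <- meta_lambda
  res
}

#' Write a meta-analysis results table as TSV
#'
#' @param results data.frame from [meta_pipeline()]
#' @param path output path (`.gz` supported)
#' @export
write_meta_results <- function(results, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.table(results, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
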