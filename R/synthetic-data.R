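# Seeded generators for every input the pipeline consumes: phenotype
# preparation, per-study per-sex summary statistics, MR instrument systems,
# and expression matrices. Each generator records its ground truth so
# downstream recovery tests never re-derive it.

#' Prepare raw fasting glucose / fasting insulin phenotypes
#'
#' Applies the glycemic-trait conventions: fasting glucose measured in whole
#' blood is corrected to plasma level by the factor 1.13; individuals with
#' diagnosed/treated diabetes or (corrected) fasting plasma glucose >= 7
#' mmol/L are excluded; fasting insulin (pmol/L) is natural-log transformed
#' and nonpositive values are excluded (log undefined). Fasting glucose
#' itself is left untransformed.
#'
#' @param raw data.frame with columns `id`, `fg` (mmol/L), `fi` (pmol/L),
#'   `fg_whole_blood` (logical), `diabetes` (logical); `fi`/`fg` may be NA
#' @param fg_whole_blood_factor whole-blood-to-plasma factor (default 1.13)
#' @param fg_exclusion_mmol exclusion threshold, applied as >= (default 7)
#' @return list: `data` (id, fg, ln_fi for retained individuals) and
#'   `exclusions` (id, reason)
#' @export
prepare_phenotypes <- function(raw, fg_whole_blood_factor = 1.13,
                               fg_exclusion_mmol = 7.0) {
  stopifnot(fg_whole_blood_factor > 1)
  fg <- ifelse(!is.na(raw$fg_whole_blood) & raw$fg_whole_blood,
               raw$fg * fg_whole_blood_factor, raw$fg)
  reason <- rep(NA_character_, nrow(raw))
  flag <- function(bad, why) ifelse(is.na(reason) & bad & !is.na(bad), why, reason)
  reason <- flag(raw$diabetes, "diabetes")
  reason <- flag(!is.na(fg) & fg >= fg_exclusion_mmol, "fg_at_or_above_threshold")
  reason <- flag(!is.na(raw$fi) & raw$fi <= 0, "nonpositive_fi")
  keep <- is.na(reason)
  list(data = data.frame(id = raw$id[keep], fg = fg[keep],
                         ln_fi = log(raw$fi[keep]),
                         stringsAsFactors = FALSE),
       exclusions = data.frame(id = raw$id[!keep], reason = reason[!keep],
                               stringsAsFactors = FALSE))
}

#' Specify a synthetic meta-analysis cohort
#'
#' Describes the generative model for per-study, per-sex GWAS summary
#' statistics: `n_variants` independent autosomal variants, a fraction
#' `fraction_causal` of which carry true sex-specific effects `beta_f` /
#' `beta_m` (SD units of a unit-variance trait); per-study estimates are
#' drawn around the truth with sampling variance lambda_study / (2 n f(1-f))
#' so `gc_lambda > 1` injects genomic inflation. A fraction
#' `allele_discordance_rate` of emitted rows have their alleles swapped or
#' strand-complemented (palindromic variants opt-in) to exercise
#' harmonization.
#'
#' @param n_f,n_m total per-sex sample sizes, split evenly across studies
#' @param n_studies number of studies per sex
#' @param n_variants number of variants
#' @param fraction_causal fraction of variants with nonzero effects
#' @param beta_f,beta_m true effects at causal variants (SD units)
#' @param caf_range allele-frequency range to draw from
#' @param gc_lambda per-study inflation factor(s), recycled across studies
#' @param allele_discordance_rate fraction of rows with discordant allele
#'   coding (half swapped, half strand-complemented)
#' @param palindromic_rate fraction of variants given A/T or C/G pairs
#' @param seed integer seed (mandatory)
#' @return `cohort_spec` list
#' @export
cohort_spec <- function(n_f = 70000, n_m = 70000, n_studies = 6,
                        n_variants = 1000, fraction_causal = 0,
                        beta_f = 0.03, beta_m = 0,
                        caf_range = c(0.05, 0.5), gc_lambda = 1,
                        allele_discordance_rate = 0, palindromic_rate = 0,
                        seed) {
  if (missing(seed)) stop("cohort_spec: seed is mandatory")
  stopifnot(fraction_causal >= 0, fraction_causal <= 1,
            allele_discordance_rate >= 0, allele_discordance_rate <= 1)
  structure(list(n_f = n_f, n_m = n_m, n_studies = n_studies,
                 n_variants = n_variants, fraction_causal = fraction_causal,
                 beta_f = beta_f, beta_m = beta_m, caf_range = caf_range,
                 gc_lambda = rep_len(gc_lambda, n_studies),
                 allele_discordance_rate = allele_discordance_rate,
                 palindromic_rate = palindromic_rate,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

.NONPAL_PAIRS <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                       c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
.PAL_PAIRS <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

#' Generate per-study, per-sex summary statistics
#'
#' Draws a variant map (chromosome, position, allele pair, CAF, true per-sex
#' effects per `spec`), then per study and sex emits estimates
#' beta_hat ~ Normal(true beta, lambda_study * se^2) with
#' se = 1/sqrt(2 n_study f (1-f)) for the unit-residual trait. The reported
#' SE column is the uninflated sampling SE, so injected inflation shows up
#' as overdispersion of the test statistics, exactly what genomic control
#' corrects. Discordant allele coding is injected after the draw and leaves
#' the underlying effect invariant under harmonization.
#'
#' @param spec a [cohort_spec()]
#' @param dir optional directory; when given, panels are written as
#'   tab-delimited files in the pipeline dialect plus a `truth.tsv`
#' @return list: `panels` (list of `study_panel`), `truth` (data.frame with
#'   the variant map and true effects), `reference` (allele reference table)
#' @export
generate_study_sumstats <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  nv <- spec$n_variants
  chrom <- sort(sample(1:22, nv, replace = TRUE))
  pos <- unlist(lapply(table(chrom), function(k)
    sort(sample.int(2.4e8, k))), use.names = FALSE)
  pal <- runif(nv) < spec$palindromic_rate
  pair_idx_np <- sample(nrow(.NONPAL_PAIRS), nv, replace = TRUE)
  pair_idx_p <- sample(nrow(.PAL_PAIRS), nv, replace = TRUE)
  ea <- ifelse(pal, .PAL_PAIRS[pair_idx_p, 1], .NONPAL_PAIRS[pair_idx_np, 1])
  oa <- ifelse(pal, .PAL_PAIRS[pair_idx_p, 2], .NONPAL_PAIRS[pair_idx_np, 2])
  caf <- runif(nv, spec$caf_range[1], spec$caf_range[2])
  causal <- runif(nv) < spec$fraction_causal
  truth <- data.frame(marker_id = sprintf("rs%07d", seq_len(nv)),
                      chrom = chrom, pos = pos, effect_allele = ea,
                      other_allele = oa, caf = caf, causal = causal,
                      beta_f = ifelse(causal, spec$beta_f, 0),
                      beta_m = ifelse(causal, spec$beta_m, 0),
                      stringsAsFactors = FALSE)

  panels <- list()
  for (s in seq_len(spec$n_studies)) {
    for (sx in c("female", "male")) {
      n_study <- round((if (sx == "female") spec$n_f else spec$n_m) /
                         spec$n_studies)
      se <- 1 / sqrt(2 * n_study * caf * (1 - caf))
      b_true <- if (sx == "female") truth$beta_f else truth$beta_m
      bhat <- rnorm(nv, b_true, se * sqrt(spec$gc_lambda[s]))
      rec <- data.frame(marker_id = truth$marker_id, chrom = chrom, pos = pos,
                        effect_allele = ea, other_allele = oa,
                        eaf = caf, beta = bhat, se = se, n = n_study,
                        info = NA_real_, strand = "+",
                        call_rate = NA_real_, hwe_p = NA_real_,
                        mac = NA_real_, stringsAsFactors = FALSE)
      # discordant allele coding: half swap, half strand complement
      disc <- runif(nv) < spec$allele_discordance_rate
      mode_swap <- disc & runif(nv) < 0.5
      mode_flip <- disc & !mode_swap
      if (any(mode_swap)) {
        rec$effect_allele[mode_swap] <- oa[mode_swap]
        rec$other_allele[mode_swap] <- ea[mode_swap]
        rec$beta[mode_swap] <- -rec$beta[mode_swap]
        rec$eaf[mode_swap] <- 1 - rec$eaf[mode_swap]
      }
      if (any(mode_flip)) {
        rec$effect_allele[mode_flip] <- unname(.complement[ea[mode_flip]])
        rec$other_allele[mode_flip] <- unname(.complement[oa[mode_flip]])
        rec$strand[mode_flip] <- "-"
      }
      panels[[paste0("study", s, "_", sx)]] <-
        study_panel(rec, study_id = paste0("study", s), sex = sx)
    }
  }
  out <- list(panels = panels, truth = truth,
              reference = truth[, c("marker_id", "effect_allele",
                                    "other_allele", "caf")])
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(panels))
      write_sumstats(panels[[nm]], file.path(dir, paste0(nm, ".tsv")))
    write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  out
}

#' Harmonize generated panels to the cohort's allele reference
#'
#' Convenience wrapper aligning every panel to the truth table's effect
#' allele; rows that cannot be reconciled are moved to the panel's
#' malformed set.
#'
#' @param sim output of [generate_study_sumstats()]
#' @return `sim` with harmonized panels
#' @export
harmonize_to_reference <- function(sim) {
  ref <- sim$reference
  sim$panels <- lapply(sim$panels, function(p) {
    i <- match(p$records$marker_id, ref$marker_id)
    h <- harmonize(p$records, ref$effect_allele[i], ref$other_allele[i],
                   reference_eaf = ref$caf[i])
    bad <- !is.na(h$harmonize_reason)
    if (any(bad)) {
      q <- h[bad, setdiff(names(h), "harmonize_reason"), drop = FALSE]
      q$REASON <- h$harmonize_reason[bad]
      p$malformed <- rbind(p$malformed, q)
    }
    p$records <- h[!bad, setdiff(names(h), "harmonize_reason"), drop = FALSE]
    rownames(p$records) <- NULL
    p
  })
  sim
}

#' Generate a two-sample MR instrument system with known truth
#'
#' Exposure effects are drawn from a spread uniform distribution; outcome
#' effects follow beta_out = slope * beta_exp + pleiotropy + noise with the
#' stated outcome SE. The exposure betas in the table are the ones the
#' outcomes are generated from: the design emulates a biobank-scale exposure
#' GWAS whose instrument-exposure associations are precise enough that
#' exposure-side sampling error is negligible relative to the effect spread
#' (the no-measurement-error regime the IVW/Egger weights assume); the
#' `se_exposure` column is the nominal reported SE used by second-order
#' delta-method ratios. Per-sex tables share instruments but may have
#' different causal slopes, emulating a sex-stratified bidirectional design.
#'
#' @param k number of instruments
#' @param true_slope causal slope; scalar or c(female, male)
#' @param pleiotropy_mean mean directional pleiotropy added to each
#'   instrument's outcome effect
#' @param pleiotropy_sd instrument-level pleiotropy spread (default 0)
#' @param se_exposure,se_outcome reported exposure SE / outcome noise SE
#' @param exposure_range range of true exposure effect magnitudes
#' @param seed integer seed
#' @return list: `instruments` (list `female`/`male` of data.frames with
#'   the [mr_ivw()] columns), `truth` (slopes and pleiotropy used)
#' @export
generate_mr_system <- function(k, true_slope, pleiotropy_mean = 0,
                               pleiotropy_sd = 0, se_exposure = 0.003,
                               se_outcome = 0.01,
                               exposure_range = c(0.05, 0.3), seed) {
  if (missing(seed)) stop("generate_mr_system: seed is mandatory")
  set.seed(as.integer(seed))
  slope <- rep_len(true_slope, 2L)
  # instruments oriented to the exposure-increasing allele (beta_exposure > 0),
  # the convention under which pleiotropy_mean is directional
  bx_true <- runif(k, exposure_range[1], exposure_range[2])
  inst <- lapply(c(female = 1L, male = 2L), function(j) {
    alpha <- rnorm(k, pleiotropy_mean, pleiotropy_sd)
    data.frame(marker_id = sprintf("iv%04d", seq_len(k)),
               beta_exposure = bx_true,
               se_exposure = rep(se_exposure, k),
               beta_outcome = rnorm(k, slope[j] * bx_true + alpha, se_outcome),
               se_outcome = rep(se_outcome, k),
               stringsAsFactors = FALSE)
  })
  list(instruments = inst,
       truth = list(slope_female = slope[1], slope_male = slope[2],
                    pleiotropy_mean = pleiotropy_mean,
                    pleiotropy_sd = pleiotropy_sd, bx_true = bx_true))
}

#' Generate an expression dataset with known sex and eQTL structure
#'
#' Each gene's expression is mu + sex_effect * 1[female] + plate effects +
#' beta_sex * genotype + Gaussian noise. A configurable subset of genes
#' carries sex-differential expression and/or sex-specific eQTL slopes.
#'
#' @param n_genes number of genes
#' @param n_per_sex samples per sex
#' @param n_plates number of plates (assigned round-robin, crossed with sex)
#' @param caf allele frequency of the tested variant
#' @param sex_de_genes indices of genes with a sex effect
#' @param sex_effect expression shift in women for those genes
#' @param eqtl_genes indices of genes with an eQTL
#' @param beta_f,beta_m per-sex eQTL slopes for those genes
#' @param plate_sd SD of plate effects
#' @param noise_sd residual SD
#' @param seed integer seed
#' @return list: `data` (an [expression_dataset()]), `truth` (per-gene
#'   data.frame of true sex effects and slopes)
#' @export
generate_expression <- function(n_genes = 100, n_per_sex = 100, n_plates = 4,
                                caf = 0.3, sex_de_genes = integer(0),
                                sex_effect = 1.0, eqtl_genes = integer(0),
                                beta_f = 0.5, beta_m = 0, plate_sd = 0.2,
                                noise_sd = 1.0, seed) {
  if (missing(seed)) stop("generate_expression: seed is mandatory")
  set.seed(as.integer(seed))
  ns <- 2L * n_per_sex
  sex <- factor(rep(c("male", "female"), each = n_per_sex),
                levels = c("male", "female"))
  plate <- factor(rep_len(seq_len(n_plates), ns))
  genotype <- rbinom(ns, 2L, caf)
  plate_eff <- rnorm(n_plates, 0, plate_sd)
  truth <- data.frame(gene = sprintf("gene%04d", seq_len(n_genes)),
                      sex_effect = 0, beta_f = 0, beta_m = 0,
                      stringsAsFactors = FALSE)
  truth$sex_effect[sex_de_genes] <- sex_effect
  truth$beta_f[eqtl_genes] <- beta_f
  truth$beta_m[eqtl_genes] <- beta_m
  female <- as.numeric(sex == "female")
  expr <- matrix(NA_real_, n_genes, ns, dimnames = list(truth$gene, NULL))
  for (i in seq_len(n_genes)) {
    slope <- ifelse(female == 1, truth$beta_f[i], truth$beta_m[i])
    expr[i, ] <- truth$sex_effect[i] * female + plate_eff[as.integer(plate)] +
      slope * genotype + rnorm(ns, 0, noise_sd)
  }
  list(data = expression_dataset(expr, sex = sex, plate = plate,
                                 genotype = genotype),
       truth = truth)
}
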