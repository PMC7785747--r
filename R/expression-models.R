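# Expression analyses: eQTL models with common vs sex-specific genotype
# slopes, sex-differential expression with covariates, BH FDR, optional
# permutation p-values.

#' Assemble an expression dataset
#'
#' @param expression numeric gene x sample matrix of normalized expression
#'   (probe-to-gene averaging, when applicable, happens upstream)
#' @param sex per-sample factor; coded with `"male"` as the reference level
#'   so positive sex coefficients mean higher expression in women
#' @param plate per-sample batch factor
#' @param genotype per-sample dosage in [0, 2] for the tested variant
#'   (optional; needed for eQTL fits)
#' @param covariates optional data.frame of additional per-sample covariates
#' @return `expression_dataset` list
#' @export
expression_dataset <- function(expression, sex, plate = NULL, genotype = NULL,
                               covariates = NULL) {
  expression <- as.matrix(expression)
  ns <- ncol(expression)
  sex <- factor(as.character(sex), levels = c("male", "female"))
  if (anyNA(sex)) stop("expression_dataset: sex must be 'male' or 'female'")
  if (length(sex) != ns) stop("expression_dataset: sex length != samples")
  if (!is.null(plate)) {
    plate <- factor(plate)
    if (length(plate) != ns) stop("expression_dataset: plate length != samples")
  }
  if (!is.null(genotype)) {
    genotype <- as.numeric(genotype)
    if (any(genotype < 0 | genotype > 2, na.rm = TRUE))
      stop("expression_dataset: genotype dosage outside [0, 2]")
  }
  structure(list(expression = expression, sex = sex, plate = plate,
                 genotype = genotype, covariates = covariates),
            class = "expression_dataset")
}

.check_full_rank <- function(fit) {
  aliased <- is.na(coef(fit))
  if (any(aliased))
    stop("design matrix rank deficient; aliased terms: ",
         paste(names(aliased)[aliased], collapse = ", "))
}

#' Per-gene eQTL fits with common or sex-specific genotype slopes
#'
#' Fits, for each gene, the linear model
#' y = mu_sex + pi_plate + beta * g (common slope) and
#' y = mu_sex + pi_plate + beta_sex * g (different slope per sex).
#' The sex-interaction test contrasts beta_female - beta_male with its SE
#' from the joint fit (1-df Wald chi-square); this is asymptotically the
#' nested-model F test comparing the two models, which is also reported.
#' Optional permutation p-values for the interaction are computed by
#' permuting sex labels within the genotype strata.
#'
#' @param data an [expression_dataset()] with genotype present
#' @param n_perm number of sex-label permutations for `p_perm` (0 = none)
#' @param perm_seed seed for the permutation stream
#' @return data.frame, one row per gene: common-slope estimate
#'   (`beta_common`, `se_common`, `p_common`), per-sex slopes (`beta_f`,
#'   `se_f`, `beta_m`, `se_m`), the interaction contrast (`delta`,
#'   `se_delta`, `p_interaction`, `f_stat`, `p_f_test`), `p_bh`
#'   (BH-adjusted interaction p), and `p_perm` when requested
#' @export
fit_eqtl <- function(data, n_perm = 0, perm_seed = 1L) {
  stopifnot(inherits(data, "expression_dataset"))
  if (is.null(data$genotype)) stop("fit_eqtl: dataset has no genotype dosage")
  g <- data$genotype
  sex <- data$sex
  base <- data.frame(sex = sex, g = g)
  if (!is.null(data$plate)) base$plate <- data$plate
  rhs_common <- paste(c("sex", if (!is.null(data$plate)) "plate", "g"),
                      collapse = " + ")
  rhs_sexspec <- paste(c("sex", if (!is.null(data$plate)) "plate", "sex:g"),
                       collapse = " + ")

  genes <- rownames(data$expression) %||% seq_len(nrow(data$expression))
  one_gene <- function(y, dat) {
    dat$y <- y
    fit1 <- lm(stats::as.formula(paste("y ~", rhs_common)), data = dat)
    fit2 <- lm(stats::as.formula(paste("y ~", rhs_sexspec)), data = dat)
    .check_full_rank(fit2)
    cf <- coef(fit2)
    V <- vcov(fit2)
    bm <- cf[["sexmale:g"]]; bf <- cf[["sexfemale:g"]]
    se_m <- sqrt(V["sexmale:g", "sexmale:g"])
    se_f <- sqrt(V["sexfemale:g", "sexfemale:g"])
    delta <- bf - bm
    se_delta <- sqrt(V["sexfemale:g", "sexfemale:g"] +
                       V["sexmale:g", "sexmale:g"] -
                       2 * V["sexfemale:g", "sexmale:g"])
    an <- anova(fit1, fit2)
    s1 <- summary(fit1)$coefficients
    c(beta_common = s1["g", "Estimate"], se_common = s1["g", "Std. Error"],
      p_common = s1["g", "Pr(>|t|)"],
      beta_f = bf, se_f = se_f, beta_m = bm, se_m = se_m,
      delta = delta, se_delta = se_delta,
      p_interaction = chisq_p((delta / se_delta)^2, 1),
      f_stat = an$F[2], p_f_test = an$`Pr(>F)`[2])
  }

  res <- t(apply(data$expression, 1L, one_gene, dat = base))
  res <- as.data.frame(res)
  res <- cbind(gene = genes, res, stringsAsFactors = FALSE)
  res$p_bh <- bh_adjust(res$p_interaction)

  if (n_perm > 0) {
    set.seed(perm_seed)
    obs <- abs(res$delta / res$se_delta)
    exceed <- rep(0L, nrow(res))
    for (b in seq_len(n_perm)) {
      dat_b <- base
      dat_b$sex <- sample(base$sex)
      stat_b <- apply(data$expression, 1L, function(y) {
        dat_b$y <- y
        fit <- lm(stats::as.formula(paste("y ~", rhs_sexspec)), data = dat_b)
        cf <- coef(fit); V <- vcov(fit)
        d <- cf[["sexfemale:g"]] - cf[["sexmale:g"]]
        sd_ <- sqrt(V["sexfemale:g", "sexfemale:g"] +
                      V["sexmale:g", "sexmale:g"] -
                      2 * V["sexfemale:g", "sexmale:g"])
        abs(d / sd_)
      })
      exceed <- exceed + (stat_b >= obs)
    }
    res$p_perm <- (1 + exceed) / (1 + n_perm)
  }
  rownames(res) <- NULL
  res
}

#' Per-gene sex-differential expression
#'
#' Regresses each gene's expression on sex plus the supplied covariates
#' (fixed effects). The sex coefficient is reported with the convention
#' that a positive value means higher expression in women. Genes with zero
#' variance are flagged `excluded` (their SE is undefined) and get NA
#' statistics; BH adjustment runs across the tested genes only.
#'
#' @param data an [expression_dataset()]
#' @param covariates optional data.frame of per-sample covariates (defaults
#'   to the dataset's own, plus plate when present)
#' @return data.frame: gene, beta_sex, se, t, p_raw, p_bh, excluded
#' @export
sex_differential_expression <- function(data, covariates = NULL) {
  stopifnot(inherits(data, "expression_dataset"))
  covars <- covariates %||% data$covariates
  dat <- data.frame(sex = data$sex)
  if (!is.null(data$plate)) dat$plate <- data$plate
  if (!is.null(covars)) dat <- cbind(dat, covars)
  rhs <- paste(setdiff(names(dat), "y"), collapse = " + ")
  genes <- rownames(data$expression) %||% seq_len(nrow(data$expression))

  fit_one <- function(y) {
    if (sd(y) == 0) return(c(NA_real_, NA_real_, NA_real_, NA_real_))
    dat$y <- y
    fit <- lm(stats::as.formula(paste("y ~", rhs)), data = dat)
    .check_full_rank(fit)
    s <- summary(fit)$coefficients
    s["sexfemale", c("Estimate", "Std. Error", "t value", "Pr(>|t|)")]
  }
  res <- t(apply(data$expression, 1L, fit_one))
  out <- data.frame(gene = genes, beta_sex = res[, 1], se = res[, 2],
                    t = res[, 3], p_raw = res[, 4],
                    excluded = !is.finite(res[, 4]),
                    stringsAsFactors = FALSE)
  out$p_bh <- NA_real_
  tested <- !out$excluded
  out$p_bh[tested] <- bh_adjust(out$p_raw[tested])
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values with enforced monotonicity, capped at 1.
#'
#' @param p p-values in [0, 1]
#' @return adjusted p-values, same length and order
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("bh_adjust: p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}
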