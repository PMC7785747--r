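# Bidirectional two-sample Mendelian randomization: instrument selection,
# ratio estimates, random-effect IVW, and MR-Egger regression.

#' Select independent genome-wide-significant instruments
#'
#' Greedy LD pruning of an association results table: keep the remaining SNP
#' with the lowest p-value, drop every SNP with r2 >= `r2_threshold` to it,
#' repeat. When no LD source is supplied, SNPs within 1 Mb of a kept
#' instrument on the same chromosome are dropped instead and the result is
#' flagged (`attr(,"ld_checked") == FALSE`).
#'
#' @param gwas data.frame with columns MARKER, CHR, POS and a p-value column
#' @param p_col name of the p-value column (default "P_ALL")
#' @param p_threshold significance threshold (default 5e-8)
#' @param ld optional pairwise r2 data.frame (MARKER1, MARKER2, R2)
#' @param r2_threshold independence threshold (default 0.001)
#' @param distance_bp fallback pruning distance when `ld` is NULL
#' @return data.frame of retained instrument rows, lowest p first
#' @export
select_instruments <- function(gwas, p_col = "P_ALL", p_threshold = 5e-8,
                               ld = NULL, r2_threshold = 0.001,
                               distance_bp = 1e6) {
  p <- gwas[[p_col]]
  cand <- gwas[is.finite(p) & p <= p_threshold, , drop = FALSE]
  cand$.p <- p[is.finite(p) & p <= p_threshold]
  if (nrow(cand) == 0L)
    stop("select_instruments: no SNP reaches p <= ", p_threshold,
         "; consider relaxing the threshold")
  cand <- cand[order(cand$.p, cand$POS, cand$MARKER), , drop = FALSE]
  kept <- list()
  while (nrow(cand) > 0L) {
    top <- cand[1L, ]
    kept[[length(kept) + 1L]] <- top
    if (is.null(ld)) {
      drop <- cand$CHR == top$CHR & abs(cand$POS - top$POS) <= distance_bp
    } else {
      r2 <- vapply(cand$MARKER, function(m) .ld_lookup(ld, m, top$MARKER),
                   numeric(1))
      drop <- (!is.na(r2) & r2 >= r2_threshold) | cand$MARKER == top$MARKER
    }
    cand <- cand[!drop, , drop = FALSE]
  }
  out <- do.call(rbind, kept)
  out$.p <- NULL
  rownames(out) <- NULL
  attr(out, "ld_checked") <- !is.null(ld)
  out
}

#' Per-variant Wald ratio causal estimate
#'
#' ratio = beta_outcome / beta_exposure with delta-method SE. First order
#' (default): se_outcome / |beta_exposure|. The second-order form adds the
#' exposure-uncertainty term
#' sqrt(se_out^2/bx^2 + by^2 se_exp^2 / bx^4).
#'
#' @param beta_exposure,se_exposure instrument-exposure association
#' @param beta_outcome,se_outcome instrument-outcome association
#' @param second_order use the second-order delta SE (default FALSE)
#' @return data.frame with `beta` and `se` (vectorized)
#' @export
ratio_estimate <- function(beta_exposure, se_exposure,
                           beta_outcome, se_outcome, second_order = FALSE) {
  if (any(beta_exposure == 0))
    stop("ratio_estimate: beta_exposure = 0 has no ratio estimate")
  beta <- beta_outcome / beta_exposure
  se <- if (second_order) {
    sqrt(se_outcome^2 / beta_exposure^2 +
           beta_outcome^2 * se_exposure^2 / beta_exposure^4)
  } else {
    se_outcome / abs(beta_exposure)
  }
  data.frame(beta = beta, se = se)
}

#' Random-effect inverse-variance-weighted MR estimate
#'
#' Weighted zero-intercept regression of outcome on exposure effects with
#' weights 1/se_outcome^2; equivalently the IVW combination of the per-SNP
#' ratio estimates with first-order delta SEs. Cochran's Q over the ratio
#' estimates measures instrument heterogeneity; the SE is inflated
#' multiplicatively by sqrt(max(1, Q/(k-1))), so with homogeneous
#' instruments the random-effect estimate coincides with the fixed-effect
#' one.
#'
#' @param instruments data.frame with columns `beta_exposure`, `se_exposure`,
#'   `beta_outcome`, `se_outcome` (alleles already harmonized so both betas
#'   refer to the same effect allele)
#' @return `mr_result` list: `method`, `beta_iv`, `se_iv`, `p_iv`, `q_ivw`,
#'   `k`
#' @export
mr_ivw <- function(instruments) {
  k <- nrow(instruments)
  if (k < 2L) stop("mr_ivw: need at least 2 instruments")
  bx <- instruments$beta_exposure
  by <- instruments$beta_outcome
  w <- 1 / instruments$se_outcome^2
  slope <- sum(w * bx * by) / sum(w * bx^2)
  se_fixed <- 1 / sqrt(sum(w * bx^2))
  q <- sum(w * (by - slope * bx)^2)
  se <- se_fixed * sqrt(max(1, q / (k - 1)))
  structure(list(method = "ivw_random", beta_iv = slope, se_iv = se,
                 p_iv = chisq_p((slope / se)^2, 1), q_ivw = q, k = k),
            class = "mr_result")
}

#' MR-Egger regression
#'
#' Weighted regression of outcome on exposure effects with a free intercept
#' (weights 1/se_outcome^2), after orienting every instrument so
#' beta_exposure >= 0 (both betas flipped together). The slope is the
#' pleiotropy-robust causal estimate; a non-zero intercept indicates
#' directional pleiotropy. SEs use multiplicative residual dispersion
#' floored at 1 and p-values the t distribution with k-2 df.
#'
#' @inheritParams mr_ivw
#' @return `mr_result` list: slope (`beta_iv`, `se_iv`, `p_iv`), intercept
#'   (`intercept`, `se_intercept`, `p_intercept`), `q_ivw`, `k`
#' @export
mr_egger <- function(instruments) {
  k <- nrow(instruments)
  if (k < 3L) stop("mr_egger: need at least 3 instruments")
  flip <- sign(instruments$beta_exposure)
  flip[flip == 0] <- 1
  bx <- instruments$beta_exposure * flip
  by <- instruments$beta_outcome * flip
  w <- 1 / instruments$se_outcome^2
  fit <- lm(by ~ bx, weights = w)
  sm <- summary(fit)$coefficients
  sigma <- summary(fit)$sigma
  infl <- 1 / min(1, sigma)   # never shrink SEs below the sigma = 1 model
  se_slope <- sm["bx", "Std. Error"] * infl
  se_int <- sm["(Intercept)", "Std. Error"] * infl
  q <- sum(w * fit$residuals^2)
  structure(list(method = "egger",
                 beta_iv = sm["bx", "Estimate"], se_iv = se_slope,
                 p_iv = 2 * pt(abs(sm["bx", "Estimate"] / se_slope),
                               df = k - 2, lower.tail = FALSE),
                 intercept = sm["(Intercept)", "Estimate"],
                 se_intercept = se_int,
                 p_intercept = 2 * pt(abs(sm["(Intercept)", "Estimate"] / se_int),
                                      df = k - 2, lower.tail = FALSE),
                 q_ivw = q, k = k),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("<mr_result> %s: beta_iv = %.4f (SE %.4f), p = %.3g, k = %d\n",
              x$method, x$beta_iv, x$se_iv, x$p_iv, x$k))
  if (!is.null(x$intercept))
    cat(sprintf("  intercept = %.5f (SE %.5f), p = %.3g\n",
                x$intercept, x$se_intercept, x$p_intercept))
  invisible(x)
}

#' Harmonize an MR instrument table
#'
#' Aligns outcome-side alleles to the exposure-side effect allele using the
#' same rules as [harmonize()]; rows that cannot be reconciled (including
#' ambiguous palindromic pairs) are dropped with their reasons attached as
#' the `"dropped"` attribute.
#'
#' @param exposure data.frame: MARKER, EA, NEA, BETA, SE, and optionally EAF
#' @param outcome data.frame with the same columns for the outcome GWAS
#' @return instrument data.frame: marker_id, beta_exposure, se_exposure,
#'   beta_outcome, se_outcome, eaf
#' @export
harmonize_instruments <- function(exposure, outcome) {
  m <- merge(exposure, outcome, by = "MARKER", suffixes = c("_exp", "_out"))
  if (nrow(m) == 0L) stop("harmonize_instruments: no shared markers")
  rec <- data.frame(marker_id = m$MARKER,
                    effect_allele = toupper(m$EA_out),
                    other_allele = toupper(m$NEA_out),
                    beta = m$BETA_out, se = m$SE_out,
                    eaf = if ("EAF_out" %in% names(m)) m$EAF_out else NA_real_,
                    stringsAsFactors = FALSE)
  h <- harmonize(rec, m$EA_exp, m$NEA_exp,
                 reference_eaf = if ("EAF_exp" %in% names(m)) m$EAF_exp else NULL)
  ok <- is.na(h$harmonize_reason)
  out <- data.frame(marker_id = m$MARKER[ok],
                    beta_exposure = m$BETA_exp[ok],
                    se_exposure = m$SE_exp[ok],
                    beta_outcome = h$beta[ok],
                    se_outcome = h$se[ok],
                    eaf = if ("EAF_exp" %in% names(m)) m$EAF_exp[ok] else NA_real_,
                    stringsAsFactors = FALSE)
  attr(out, "dropped") <- data.frame(marker_id = m$MARKER[!ok],
                                     reason = h$harmonize_reason[!ok])
  out
}

#' Bidirectional per-sex Mendelian randomization
#'
#' Runs random-effect IVW and MR-Egger for the four cells of a bidirectional
#' two-sample design: exposure-on-outcome and outcome-on-exposure, in women
#' and in men. Significance is judged at the Bonferroni threshold
#' 0.05/4 = 0.0125 for the four IVW tests.
#'
#' @param instruments named list of four harmonized instrument data.frames:
#'   `forward_women`, `reverse_women`, `forward_men`, `reverse_men` (each
#'   with the [mr_ivw()] columns)
#' @param bonferroni_alpha significance threshold (default 0.0125)
#' @return data.frame: DIRECTION, SEX, METHOD, BETA_IV, SE_IV, P_IV,
#'   INTERCEPT, SE_INTERCEPT, P_INTERCEPT, Q, K, SIGNIFICANT
#' @export
mr_bidirectional <- function(instruments, bonferroni_alpha = 0.05 / 4) {
  needed <- c("forward_women", "reverse_women", "forward_men", "reverse_men")
  if (!all(needed %in% names(instruments)))
    stop("mr_bidirectional: need instrument tables ",
         paste(needed, collapse = ", "))
  rows <- lapply(needed, function(cell) {
    inst <- instruments[[cell]]
    direction <- sub("_(women|men)$", "", cell)
    sex <- sub("^(forward|reverse)_", "", cell)
    res <- lapply(list(mr_ivw(inst), mr_egger(inst)), function(r) {
      data.frame(DIRECTION = direction, SEX = sex, METHOD = r$method,
                 BETA_IV = r$beta_iv, SE_IV = r$se_iv, P_IV = r$p_iv,
                 INTERCEPT = r$intercept %||% NA_real_,
                 SE_INTERCEPT = r$se_intercept %||% NA_real_,
                 P_INTERCEPT = r$p_intercept %||% NA_real_,
                 Q = r$q_ivw, K = r$k,
                 SIGNIFICANT = r$p_iv < bonferroni_alpha,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
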