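# Locus discovery: genome-wide significance, lead-SNP selection, novelty
# classification against established loci, the established-locus
# heterogeneity screen, and two-SNP approximate conditional analysis.

#' Read an established-loci table
#'
#' TSV with columns TRAIT, MARKER, CHR, POS, one row per previously reported
#' lead SNP.
#'
#' @param path file path
#' @return data.frame
#' @export
read_known_loci <- function(path) {
  k <- read.table(path, header = TRUE, sep = "", stringsAsFactors = FALSE)
  stopifnot(all(c("TRAIT", "MARKER", "CHR", "POS") %in% names(k)))
  k
}

#' Read a pairwise LD table
#'
#' TSV with columns MARKER1, MARKER2, R2; lookups are symmetric in the two
#' markers.
#'
#' @param path file path
#' @return data.frame
#' @export
read_ld_table <- function(path) {
  ld <- read.table(path, header = TRUE, sep = "", stringsAsFactors = FALSE)
  stopifnot(all(c("MARKER1", "MARKER2", "R2") %in% names(ld)))
  ld
}

.ld_lookup <- function(ld, a, b) {
  if (is.null(ld) || length(b) == 0L) return(NA_real_)
  hit <- (ld$MARKER1 == a & ld$MARKER2 %in% b) |
         (ld$MARKER2 == a & ld$MARKER1 %in% b)
  if (!any(hit)) return(NA_real_)
  max(ld$R2[hit])
}

#' Classify significant loci as novel or established
#'
#' A variant qualifies when either the 1-df sex-combined or the 2-df
#' sex-dimorphic p-value reaches `p_threshold`. Lead SNPs are selected
#' greedily per chromosome: the remaining variant with the lowest qualifying
#' p-value (ties broken by lowest position, then marker id) claims a
#' +/- `window_bp` window. A lead is novel when it lies more than
#' `novel_distance_bp` from every established lead for the trait AND is not
#' in LD with any of them (r2 < `r2_threshold`); when no LD source is given
#' the distance rule alone decides and `ld_checked` is FALSE. The call set is
#' independent of the input row order.
#'
#' @param results data.frame from [meta_pipeline()]
#' @param known established-loci data.frame (TRAIT, MARKER, CHR, POS);
#'   only rows matching `trait` are used
#' @param trait trait label to match against `known`
#' @param ld optional pairwise r2 data.frame (MARKER1, MARKER2, R2)
#' @param p_threshold genome-wide significance level (default 5e-8)
#' @param novel_distance_bp distance rule for novelty (default 500 kb)
#' @param r2_threshold LD rule for novelty (default 0.01)
#' @param window_bp half-width of the lead-selection window (default 500 kb)
#' @return data.frame of locus calls: LEAD_MARKER, CHR, POS, P_LEAD,
#'   WINNING_TEST, CLASSIFICATION, DIST_TO_KNOWN, NEAREST_KNOWN, R2_TO_KNOWN,
#'   LD_CHECKED
#' @export
classify_loci <- function(results, known, trait = "FG", ld = NULL,
                          p_threshold = 5e-8, novel_distance_bp = 5e5,
                          r2_threshold = 0.01, window_bp = 5e5) {
  known <- known[known$TRAIT == trait, , drop = FALSE]
  p_comb <- results$P_ALL
  p_dim <- results$P_DIMORPHIC
  p_best <- pmin(p_comb, p_dim, na.rm = TRUE)
  sig <- which(is.finite(p_best) & p_best <= p_threshold &
                 is.finite(results$POS))
  cand <- results[sig, c("MARKER", "CHR", "POS"), drop = FALSE]
  cand$P_LEAD <- p_best[sig]
  cand$WINNING_TEST <- ifelse(!is.na(p_dim[sig]) & p_dim[sig] < p_comb[sig],
                              "dimorphic", "combined")
  cand <- cand[order(cand$P_LEAD, cand$POS, cand$MARKER), , drop = FALSE]

  leads <- list()
  while (nrow(cand) > 0L) {
    top <- cand[1L, ]
    leads[[length(leads) + 1L]] <- top
    cand <- cand[!(cand$CHR == top$CHR &
                     abs(cand$POS - top$POS) <= window_bp), , drop = FALSE]
  }
  if (length(leads) == 0L) {
    return(data.frame(LEAD_MARKER = character(0), CHR = numeric(0),
                      POS = numeric(0), P_LEAD = numeric(0),
                      WINNING_TEST = character(0), CLASSIFICATION = character(0),
                      DIST_TO_KNOWN = numeric(0), NEAREST_KNOWN = character(0),
                      R2_TO_KNOWN = numeric(0), LD_CHECKED = logical(0)))
  }
  leads <- do.call(rbind, leads)

  out <- lapply(seq_len(nrow(leads)), function(i) {
    l <- leads[i, ]
    same_chr <- known[known$CHR == l$CHR, , drop = FALSE]
    if (nrow(same_chr)) {
      d <- abs(same_chr$POS - l$POS)
      nearest <- which.min(d)
      dist <- d[nearest]
      nearest_marker <- same_chr$MARKER[nearest]
    } else {
      dist <- Inf
      nearest_marker <- NA_character_
    }
    r2 <- .ld_lookup(ld, l$MARKER, known$MARKER)
    far <- dist > novel_distance_bp
    unlinked <- is.na(r2) || r2 < r2_threshold
    data.frame(LEAD_MARKER = l$MARKER, CHR = l$CHR, POS = l$POS,
               P_LEAD = l$P_LEAD, WINNING_TEST = l$WINNING_TEST,
               CLASSIFICATION = if (far && unlinked) "novel" else "established",
               DIST_TO_KNOWN = dist, NEAREST_KNOWN = nearest_marker,
               R2_TO_KNOWN = r2, LD_CHECKED = !is.null(ld),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$CHR, out$POS), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Screen established loci for between-sex effect heterogeneity
#'
#' Looks up each established lead SNP for the trait in the meta-analysis
#' results and flags between-sex heterogeneity at the Bonferroni level
#' 0.05 / (number of established loci for the trait): 0.05/36 = 0.0014 for
#' FG, 0.05/19 = 0.0026 for FI.
#'
#' @inheritParams classify_loci
#' @param alpha familywise level before Bonferroni division (default 0.05)
#' @return data.frame: MARKER, CHR, POS, Q, P_HET, I2, BONFERRONI_ALPHA,
#'   SIGNIFICANT_HET
#' @export
screen_established_heterogeneity <- function(results, known, trait = "FG",
                                             alpha = 0.05) {
  known <- known[known$TRAIT == trait, , drop = FALSE]
  if (nrow(known) == 0L) stop("no established loci for trait ", trait)
  thr <- alpha / nrow(known)
  idx <- match(known$MARKER, results$MARKER)
  found <- !is.na(idx)
  data.frame(MARKER = known$MARKER[found], CHR = known$CHR[found],
             POS = known$POS[found], Q = results$Q[idx[found]],
             P_HET = results$P_HET[idx[found]], I2 = results$I2[idx[found]],
             BONFERRONI_ALPHA = thr,
             SIGNIFICANT_HET = results$P_HET[idx[found]] <= thr,
             stringsAsFactors = FALSE)
}

#' Two-SNP approximate conditional analysis from summary statistics
#'
#' Reconstructs the two-covariate joint least-squares fit for a target SNP
#' conditioned on an adjacent SNP, using only the marginal summary statistics,
#' the allele frequencies (through the Hardy-Weinberg genotype variances
#' 2f(1-f)), the LD correlation r between the two genotypes, and the sample
#' size. The phenotypic variance is recovered from each SNP's own marginal
#' fit and the joint residual variance from the fitted joint model, mirroring
#' the standard summary-statistic conditional framework.
#'
#' @param target list/row with `beta`, `se`, `eaf` for the SNP being tested
#' @param conditioning same fields for the SNP conditioned on
#' @param r LD correlation between the two genotypes, |r| < 0.99
#' @param n sample size (scalar, or length 2 for target/conditioning; a
#'   relative difference above 10% triggers a warning)
#' @return list: `beta_cond`, `se_cond`, `p_cond`, `r`
#' @export
approx_conditional <- function(target, conditioning, r, n) {
  if (abs(r) >= 0.99)
    stop("approx_conditional: |r| >= 0.99, joint system is singular")
  n <- rep_len(as.numeric(n), 2L)
  if (abs(n[1] - n[2]) / mean(n) > 0.10)
    warning("approx_conditional: sample sizes differ by more than 10%")
  nn <- mean(n)
  v1 <- 2 * target$eaf * (1 - target$eaf)
  v2 <- 2 * conditioning$eaf * (1 - conditioning$eaf)
  if (v1 <= 0 || v2 <= 0) stop("approx_conditional: monomorphic SNP")
  cv <- r * sqrt(v1 * v2)
  D <- matrix(c(v1, cv, cv, v2), 2L)
  b_marg <- c(target$beta, conditioning$beta)
  s_marg <- c(target$se, conditioning$se)
  xty <- c(v1, v2) * b_marg
  b_joint <- solve(D, xty)
  # phenotypic variance implied by each marginal fit; average the two
  vy <- mean(c(v1, v2) * b_marg^2 + c(v1, v2) * s_marg^2 * (nn - 2))
  sse <- nn * (vy - sum(b_joint * xty))
  if (sse <= 0) sse <- .Machine$double.eps * nn * vy
  sigma2 <- sse / (nn - 3)
  se_joint <- sqrt(diag(solve(D) * sigma2 / nn))
  list(beta_cond = b_joint[1], se_cond = se_joint[1],
       p_cond = chisq_p((b_joint[1] / se_joint[1])^2, 1), r = r)
}
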