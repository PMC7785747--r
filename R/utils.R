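#' @importFrom stats pchisq qchisq median rnorm rbinom runif lm anova vcov
#'   coef p.adjust pt sd var cov
#' @importFrom utils read.table write.table
NULL

.datatable.aware <- TRUE

# p-value floor: chi-square tails below this underflow; the statistic is
# always reported alongside so no information is lost.
.P_FLOOR <- 1e-300

#' Two-sided chi-square tail probability with underflow floor
#'
#' @param stat chi-square statistic(s), >= 0
#' @param df degrees of freedom
#' @return p-values in [1e-300, 1]
#' @keywords internal
chisq_p <- function(stat, df) {
  pmax(pchisq(stat, df = df, lower.tail = FALSE), .P_FLOOR)
}

# median of the 1-df chi-square distribution, the genomic-control denominator
.CHI2_1DF_MEDIAN <- qchisq(0.5, df = 1)

.complement <- c(A = "T", C = "G", G = "C", T = "A")

is_palindromic <- function(a1, a2) {
  unname(.complement[a1] == a2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
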