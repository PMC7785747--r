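#!/usr/bin/env Rscript
# Bidirectional two-sample Mendelian randomization on a synthetic system
# emulating the adiposity -> insulin-resistance design: a causal effect of
# the exposure on the outcome planted in women only (slope 1.86, 222
# instruments forward; 19 instruments in the reverse direction), analyzed
# with random-effect IVW and MR-Egger in all four direction-by-sex cells.

suppressPackageStartupMessages(library(sexmeta))
dir.create("results", showWarnings = FALSE)

fwd <- generate_mr_system(k = 222, true_slope = c(1.86, 0),
                          pleiotropy_mean = 0, seed = 401L)
rev <- generate_mr_system(k = 19, true_slope = c(0, 0), seed = 402L)

res <- mr_bidirectional(list(forward_women = fwd$instruments$female,
                             reverse_women = rev$instruments$female,
                             forward_men = fwd$instruments$male,
                             reverse_men = rev$instruments$male))
write.table(res, "results/04_mr_bidirectional.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

ivw <- res[res$METHOD == "ivw_random", ]
for (i in seq_len(nrow(ivw)))
  message(sprintf("%-7s %-6s IVW beta = %6.3f (SE %.3f), p = %.2g%s",
                  ivw$DIRECTION[i], ivw$SEX[i], ivw$BETA_IV[i], ivw$SE_IV[i],
                  ivw$P_IV[i],
                  if (ivw$SIGNIFICANT[i]) "  * significant at 0.05/4" else ""))
egger_fw <- res[res$METHOD == "egger" & res$DIRECTION == "forward" &
                  res$SEX == "women", ]
message(sprintf("MR-Egger forward/women: slope %.3f, intercept %.4f (p_intercept = %.2f; no directional pleiotropy planted)",
                egger_fw$BETA_IV, egger_fw$INTERCEPT, egger_fw$P_INTERCEPT))
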