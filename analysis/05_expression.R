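#!/usr/bin/env Rscript
# Expression analyses: sex-specific eQTL models (common vs per-sex genotype
# slope, interaction = slope contrast / nested F) and sex-differential
# expression with plate as a fixed batch effect, on a generated matrix with
# planted structure; BH FDR across genes and permutation corroboration for
# the strongest interaction.

suppressPackageStartupMessages(library(sexmeta))
dir.create("results", showWarnings = FALSE)

sim <- generate_expression(n_genes = 300, n_per_sex = 300, n_plates = 4,
                           caf = 0.3,
                           sex_de_genes = 1:10, sex_effect = 0.8,
                           eqtl_genes = 11:20, beta_f = 0.6, beta_m = 0,
                           seed = 501L)

eqtl <- fit_eqtl(sim$data)
eqtl <- eqtl[order(eqtl$p_interaction), ]
write.table(eqtl[1:20, ], "results/05_eqtl_interactions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
hits <- eqtl$gene[eqtl$p_bh < 0.05]
planted <- sprintf("gene%04d", 11:20)
message(sprintf("sex-interaction eQTL: %d genes at BH FDR < 0.05, %d of them planted (of 10)",
                length(hits), sum(hits %in% planted)))

de <- sex_differential_expression(sim$data)
de <- de[order(de$p_raw), ]
write.table(de[1:20, ], "results/05_sex_de.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
de_hits <- de$gene[!is.na(de$p_bh) & de$p_bh < 0.01]
de_planted <- sprintf("gene%04d", 1:10)
# female-specific eQTL genes also shift mean expression in women, so they
# legitimately surface in the marginal sex-DE scan as well
message(sprintf("sex-differential expression: %d genes at BH FDR < 0.01 (%d of 10 planted DE genes, %d female-slope eQTL genes; all %d positive = higher in women)",
                length(de_hits), sum(de_hits %in% de_planted),
                sum(de_hits %in% planted),
                sum(de$beta_sex[match(de_hits, de$gene)] > 0)))

# permutation p-value for the top interaction gene, islet-style
top_idx <- match(eqtl$gene[1], sprintf("gene%04d", seq_len(300)))
one <- expression_dataset(sim$data$expression[top_idx, , drop = FALSE],
                          sim$data$sex, sim$data$plate, sim$data$genotype)
perm <- fit_eqtl(one, n_perm = 999, perm_seed = 502L)
message(sprintf("top interaction gene %s: Wald p = %.2g, permutation p = %.3f (999 label permutations)",
                eqtl$gene[1], eqtl$p_interaction[1], perm$p_perm))
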